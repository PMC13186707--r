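.log <- function(cfg, level, fmt, ...) {
  levels <- c(debug = 1, info = 2, warn = 3)
  if (levels[[level]] >= levels[[cfg$log_level %||% "info"]])
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fixed per-stage seed offsets derived from the single top-level seed
.stage_seed <- function(seed, stage) {
  off <- c(simulate = 11L, nup96 = 23L, ratio = 37L, qpcr = 41L)
  (as.integer(seed) + off[[stage]]) %% .Machine$integer.max
}

#' Run the configured pipeline stages into an artifact directory
#'
#' Executes, as configured: `simulate` (time-lapse focus stacks + TMRE
#' trace, NUP96 calibration field, ratio table, qPCR table — all with ground
#' truth), `foci` (per-frame focus quantification and NUP96-calibrated
#' stoichiometry), `kinetics` (per-cell MOMP-referenced summary),
#' `proteomics` (four-criteria candidate report, significance B, term
#' enrichment) and `qpcr` (delta-Ct and AUC). Every output CSV carries a
#' header comment with the package version, the config hash and the seed;
#' outputs contain no timestamps, so runs with identical config and seed
#' are byte-identical.
#'
#' @param config a `run_config` (see [load_config()]).
#' @param seed single top-level integer seed; all per-stage seeds derive
#'   from it.
#' @param out_dir artifact directory (created if missing).
#' @param stages stages to run (default: from the config). Later stages read
#'   the files earlier stages wrote, so a missing upstream output is a
#'   dependency error naming the stage and path.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = default_config(), seed = 1L,
                         out_dir = "apopore-run", stages = config$stages) {
  .validate_config(config)
  .check(.is_count(seed), "seed must be an integer")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  save_config(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  meta <- c(sprintf("config_md5: %s", cfg_hash), sprintf("seed: %d", seed))
  need <- function(stage, path) {
    if (!file.exists(path))
      stop(sprintf("stage '%s': missing upstream input %s (run its producer first)",
                   stage, path), call. = FALSE)
    path
  }
  wt <- function(df, name) .write_table_commented(df, file.path(out_dir, name), meta)

  if ("simulate" %in% stages) {
    .log(config, "info", "simulate: time lapse, NUP96 field, ratio table, qPCR")
    tl_cfg <- config$simulate$timelapse
    tl <- gen_timelapse(do.call(timelapse_sim_spec,
                                c(tl_cfg, seed = .stage_seed(seed, "simulate"))))
    files <- sprintf("gfp_frame%02d.tif", seq_along(tl$stacks) - 1L)
    for (i in seq_along(tl$stacks))
      write_image_stack(tl$stacks[[i]], file.path(out_dir, files[i]))
    write_image_manifest(tl$stacks, files, file.path(out_dir, "manifest.csv"),
                         frame_interval_min = tl_cfg$frame_interval)
    wt(data.frame(frame = seq_along(tl$tmre) - 1L, time_min = tl$time_min,
                  tmre = tl$tmre), "tmre.csv")
    wt(tl$truth$foci, "truth_foci.csv")
    np <- config$simulate$nup96
    nup <- gen_nup96_stack(n_pores = np$n_pores,
                           photons_per_monomer = np$photons_per_monomer,
                           psf_sigma = np$psf_sigma,
                           background_rate = np$background_rate,
                           image_shape = np$image_shape, n_z = np$n_z,
                           seed = .stage_seed(seed, "nup96"))
    write_image_stack(nup$stack, file.path(out_dir, "nup96.tif"))
    rt <- gen_ratio_table(do.call(ratio_sim_spec,
                                  c(config$simulate$ratio,
                                    seed = .stage_seed(seed, "ratio"))))
    wt(rt$table, "ratio_table.csv")
    wt(rt$annotations, "annotations.csv")
    wt(rt$truth, "ratio_truth.csv")
    qp <- gen_qpcr(do.call(qpcr_sim_spec,
                           c(config$simulate$qpcr,
                             seed = .stage_seed(seed, "qpcr"))))
    wt(qp$table, "ct_table.csv")
  }

  if ("foci" %in% stages) {
    .log(config, "info", "foci: quantify stacks and calibrate stoichiometry")
    man <- read_image_manifest(need("foci", file.path(out_dir, "manifest.csv")))
    fc <- config$foci
    nup_stack <- read_image_stack(need("foci", file.path(out_dir, "nup96.tif")),
                                  channel = "NUP96")
    nup_rec <- quantify_foci(nup_stack, psf_sigma = fc$psf_sigma,
                             roi_size = fc$roi_size,
                             annulus_in = fc$annulus_in,
                             annulus_out = fc$annulus_out,
                             min_distance = fc$min_distance,
                             z_edge_margin = fc$z_edge_margin,
                             keep_brighter = fc$keep_brighter)
    cal <- calibrate(nup_rec)
    recs <- do.call(rbind, lapply(seq_along(man$stacks), function(i) {
      r <- quantify_foci(man$stacks[[i]], psf_sigma = fc$psf_sigma,
                         roi_size = fc$roi_size, annulus_in = fc$annulus_in,
                         annulus_out = fc$annulus_out,
                         min_distance = fc$min_distance,
                         z_edge_margin = fc$z_edge_margin,
                         keep_brighter = fc$keep_brighter)
      r$frame <- rep(man$manifest$frame[i], nrow(r))
      r
    }))
    recs$stoichiometry <- ifelse(recs$accepted,
                                 stoichiometry(recs$intensity, cal), NA_real_)
    wt(recs, "foci.csv")
    wt(data.frame(n_nup = length(cal$nup_intensities),
                  mean_intensity = cal$mean_intensity,
                  standard_stoichiometry = cal$standard_stoichiometry),
       "calibration.csv")
  }

  if ("kinetics" %in% stages) {
    .log(config, "info", "kinetics: per-cell MOMP-referenced summary")
    tmre <- read_pipeline_table(need("kinetics", file.path(out_dir, "tmre.csv")))
    foci <- read_pipeline_table(need("kinetics", file.path(out_dir, "foci.csv")))
    acc <- foci[foci$accepted, , drop = FALSE]
    counts <- vapply(tmre$frame, function(f) sum(acc$frame == f), numeric(1))
    mstoich <- vapply(tmre$frame, function(f) {
      s <- acc$stoichiometry[acc$frame == f]
      if (length(s) == 0) NA_real_ else mean(s)
    }, numeric(1))
    tr <- cell_trace("cell1", "wt", tmre$time_min, tmre$tmre,
                     foci_count = counts, foci_mean_stoich = mstoich)
    ks <- summarize_kinetics(tr, config$kinetics$threshold_frac,
                             config$kinetics$baseline_frames)
    wt(ks$per_frame, "kinetics_per_frame.csv")
    wt(data.frame(cell_id = ks$cell_id, condition = ks$condition,
                  depol_frame = ks$depol_frame, depol_time = ks$depol_time,
                  onset_frame = ks$onset_frame, onset_time = ks$onset_time,
                  lag_min = ks$lag_min), "kinetics_summary.csv")
  }

  if ("proteomics" %in% stages) {
    .log(config, "info", "proteomics: candidate selection and statistics")
    tab <- read_pipeline_table(need("proteomics",
                                    file.path(out_dir, "ratio_table.csv")))
    ann_df <- read_pipeline_table(need("proteomics",
                                       file.path(out_dir, "annotations.csv")))
    ann <- annotation_sets(ann_df)
    pc <- config$proteomics
    rep <- select_candidates(tab, ann, percentile = pc$percentile,
                             method = pc$cutoff_method)
    out <- as.data.frame(rep)
    out$cutoff <- attr(rep, "cutoff")
    wt(out, "candidates.csv")
    wt(significance_b(tab, min_bin_size = pc$sig_b_min_bin,
                      alpha = pc$sig_b_alpha), "sig_b.csv")
    wt(hypergeom_enrich(rep$protein_id[rep$is_candidate], ann,
                        tab$protein_id, alpha = pc$enrich_alpha),
       "enrichment.csv")
  }

  if ("qpcr" %in% stages) {
    .log(config, "info", "qpcr: delta-Ct and AUC")
    ct <- read_pipeline_table(need("qpcr", file.path(out_dir, "ct_table.csv")))
    curve <- delta_ct(ct)
    wt(as.data.frame(curve), "release.csv")
    wt(release_auc(curve), "release_auc.csv")
  }

  jsonlite::write_json(
    list(package = "apopore", version = as.character(packageVersion("apopore")),
         seed = seed, config_md5 = cfg_hash, stages = stages,
         outputs = sort(setdiff(list.files(out_dir), "run_manifest.json"))),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
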
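#' Default run configuration
#'
#' The complete set of tunable stage parameters with their defaults. Every
#' key that [load_config()] accepts appears here; unknown keys in a config
#' file are rejected rather than silently ignored.
#'
#' @return nested named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    stages = c("simulate", "foci", "kinetics", "proteomics", "qpcr"),
    log_level = "info",
    simulate = list(
      timelapse = list(n_frames = 6L, frame_interval = 10, depol_frame = 1L,
                       depol_depth = 0.6, focus_onset_frame = 1L,
                       growth_rate = 4, nucleation_rate = 0.5,
                       tmre_baseline = 100, tmre_noise_sd = 0,
                       image_shape = c(48L, 48L), n_z = 8L, psf_sigma = 1.5,
                       photons_per_monomer = 50, background_rate = 2),
      nup96 = list(n_pores = 12L, photons_per_monomer = 50, psf_sigma = 1.5,
                   background_rate = 2, image_shape = c(96L, 96L), n_z = 8L),
      ratio = list(n_proteins = 1000L, base_mu = 0, base_sigma = 1,
                   n_spiked = 20L, spike_shift = 3,
                   intensity_range = c(5, 9)),
      qpcr = list(release_halflife = 1, ct0 = 30, noise_sd = 0.1,
                  n_replicates = 3L, timepoints_h = c(0, 1, 2, 3))),
    proteomics = list(percentile = 90, fold = 1.4, fold_scale = "linear",
                      cutoff_method = "fitted", sig_b_min_bin = 300L,
                      sig_b_alpha = 0.01, enrich_alpha = 0.05),
    foci = list(psf_sigma = 1.5, roi_size = 5L, annulus_in = 3L,
                annulus_out = 6L, min_distance = 4, z_edge_margin = 1L,
                keep_brighter = FALSE),
    kinetics = list(threshold_frac = 0.30, baseline_frames = 1L,
                    reference = "wt")),
    class = "run_config")
}

# recursive merge rejecting keys absent from the defaults
.merge_config <- function(defaults, user, path = "") {
  for (k in names(user)) {
    full <- if (path == "") k else paste(path, k, sep = ".")
    if (!k %in% names(defaults))
      stop(sprintf("unknown config key '%s'", full), call. = FALSE)
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])))
      defaults[[k]] <- .merge_config(defaults[[k]], as.list(user[[k]]), full)
    else
      defaults[[k]] <- user[[k]]
  }
  defaults
}

.validate_config <- function(cfg) {
  chk <- function(ok, key, what)
    if (!isTRUE(ok)) stop(sprintf("config %s: %s", key, what), call. = FALSE)
  p <- cfg$proteomics
  chk(p$percentile > 0 && p$percentile < 100, "proteomics.percentile",
      "must lie in (0, 100)")
  chk(p$fold > 0, "proteomics.fold", "must be > 0")
  chk(p$fold_scale %in% c("linear", "log2"), "proteomics.fold_scale",
      "must be 'linear' or 'log2'")
  chk(p$cutoff_method %in% c("fitted", "empirical"),
      "proteomics.cutoff_method", "must be 'fitted' or 'empirical'")
  chk(p$sig_b_min_bin >= 2, "proteomics.sig_b_min_bin", "must be >= 2")
  chk(p$sig_b_alpha > 0 && p$sig_b_alpha < 1, "proteomics.sig_b_alpha",
      "must lie in (0, 1)")
  f <- cfg$foci
  chk(f$roi_size %% 2 == 1 && f$roi_size >= 3, "foci.roi_size",
      "must be odd and >= 3")
  chk(f$annulus_out > f$annulus_in, "foci.annulus_out",
      "must exceed annulus_in")
  chk(f$psf_sigma > 0, "foci.psf_sigma", "must be > 0")
  k <- cfg$kinetics
  chk(k$threshold_frac > 0 && k$threshold_frac < 1,
      "kinetics.threshold_frac", "must lie in (0, 1)")
  t <- cfg$simulate$timelapse
  chk(t$depol_depth >= 0 && t$depol_depth <= 1,
      "simulate.timelapse.depol_depth", "must lie in [0, 1]")
  chk(all(cfg$stages %in% c("simulate", "foci", "kinetics", "proteomics",
                            "qpcr")), "stages", "unknown stage name")
  invisible(cfg)
}

#' Load and validate a run configuration
#'
#' Reads a YAML config file, fills in every missing key from
#' [default_config()], rejects unknown keys, and range-checks all numeric
#' parameters. An empty (or `NULL`) file yields the full defaults.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return validated `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    .check(file.exists(path), sprintf("config file not found: %s", path))
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- .merge_config(unclass(cfg), user)
  }
  class(cfg) <- "run_config"
  .validate_config(cfg)
  cfg
}

#' Save a run configuration as YAML
#'
#' Round-trips with [load_config()].
#'
#' @param cfg a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
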
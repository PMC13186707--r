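#' Photon-counting image stack
#'
#' Container for one channel of one acquisition frame: an integer voxel array
#' of photon counts indexed `[z, row, col]` plus acquisition metadata.
#'
#' @param counts 3D array `[z, row, col]` of non-negative integer photon
#'   counts (a 2D matrix is promoted to a single-plane stack).
#' @param pixel_size_um pixel size, micrometres.
#' @param z_step_um z interval, micrometres.
#' @param channel channel label (e.g. `"GFP"`, `"TMRE"`).
#' @param frame 0-based time-frame index.
#' @param day acquisition-day identifier (calibration is day-matched).
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(counts, pixel_size_um = 0.045, z_step_um = 0.3,
                        channel = "GFP", frame = 0L, day = "day1") {
  if (is.matrix(counts)) counts <- array(counts, c(1L, dim(counts)))
  .check(is.array(counts) && length(dim(counts)) == 3,
         "counts must be a [z, row, col] array")
  .check(all(counts >= 0) && all(counts == round(counts)),
         "photon counts must be non-negative integers")
  structure(list(counts = counts, pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um, channel = channel,
                 frame = as.integer(frame), day = day),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<image_stack> %s frame %d: %d z-planes of %d x %d px (%g um/px, %g um z-step), %s photons total\n",
              x$channel, x$frame, d[1], d[2], d[3], x$pixel_size_um,
              x$z_step_um, format(sum(x$counts))))
  invisible(x)
}

# Expected-photon rate field for a set of Gaussian foci on a uniform
# background. Separable evaluation: rate[z,r,c] = sum_f N_f * gz(z) * gr(r) *
# gc(c) with gr, gc normalized 2D Gaussian factors and gz a normalized 1D
# Gaussian, all point-sampled at voxel centers (0-based integer coordinates).
.render_rate_field <- function(image_shape, n_z, psf_sigma, psf_sigma_z,
                               photons, positions, background_rate) {
  rate <- array(background_rate, c(n_z, image_shape[1], image_shape[2]))
  if (length(photons) == 0) return(rate)
  z <- seq_len(n_z) - 1
  r <- seq_len(image_shape[1]) - 1
  cc <- seq_len(image_shape[2]) - 1
  for (i in seq_along(photons)) {
    z0 <- if (ncol(positions) == 3) positions[i, 3] else (n_z - 1) / 2
    # a single-plane stack is a plain 2D image: all photons land in the plane
    gz <- if (n_z == 1L) 1 else
      exp(-(z - z0)^2 / (2 * psf_sigma_z^2)) / (sqrt(2 * pi) * psf_sigma_z)
    gr <- exp(-(r - positions[i, 1])^2 / (2 * psf_sigma^2)) /
      (sqrt(2 * pi) * psf_sigma)
    gc <- exp(-(cc - positions[i, 2])^2 / (2 * psf_sigma^2)) /
      (sqrt(2 * pi) * psf_sigma)
    rate <- rate + photons[i] * outer(gz, outer(gr, gc))
  }
  rate
}

#' Generate a synthetic proximity-proteomics ratio table
#'
#' Draws per-protein log2(STS/CTRL) ratios from the background normal
#' distribution, shifts the first `n_spiked` proteins by `spike_shift`
#' (ground-truth enriched set), draws log2(STS/STS) reference ratios from a
#' zero-centered normal of the same spread, log-uniform summed intensities,
#' and Bernoulli annotation membership for a GOCC-like mitochondrial term and
#' a GOBP-like apoptosis term.
#'
#' @param spec a [ratio_sim_spec()].
#' @return a list with elements
#'   \describe{
#'     \item{table}{data.frame `protein_id, log2_sts_ctrl, log2_sts_ref,
#'       intensity`}
#'     \item{annotations}{data.frame `term_id, term_class, protein_id`
#'       (classes `CC` and `BP`)}
#'     \item{truth}{data.frame `protein_id, spiked`}
#'   }
#' @export
gen_ratio_table <- function(spec) {
  .check(inherits(spec, "ratio_sim_spec"), "spec must be a ratio_sim_spec")
  withr::with_seed(spec$seed, {
    n <- spec$n_proteins
    id <- sprintf("P%05d", seq_len(n))
    spiked <- seq_len(n) <= spec$n_spiked
    l2fc <- rnorm(n, spec$base_mu, spec$base_sigma) +
      ifelse(spiked, spec$spike_shift, 0)
    l2ref <- rnorm(n, 0, spec$base_sigma)
    intensity <- 10^runif(n, spec$intensity_range[1], spec$intensity_range[2])
    rates <- spec$annotation_rates
    mito <- runif(n) < ifelse(spiked, rates$mito[2], rates$mito[1])
    apo <- runif(n) < ifelse(spiked, rates$apoptosis[2], rates$apoptosis[1])
    ann <- rbind(
      data.frame(term_id = "CC:mitochondrion", term_class = "CC",
                 protein_id = id[mito], stringsAsFactors = FALSE),
      data.frame(term_id = "BP:apoptotic_process", term_class = "BP",
                 protein_id = id[apo], stringsAsFactors = FALSE))
    list(table = data.frame(protein_id = id, log2_sts_ctrl = l2fc,
                            log2_sts_ref = l2ref, intensity = intensity,
                            stringsAsFactors = FALSE),
         annotations = ann,
         truth = data.frame(protein_id = id, spiked = spiked,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic focus z-stack with ground truth
#'
#' Renders each focus as a 3D Gaussian photon-rate field whose integral over
#' the (infinite) voxel grid is `molecularity * photons_per_monomer`, adds
#' the uniform background rate, and Poisson-samples every voxel.
#'
#' @param spec a [focus_sim_spec()].
#' @param day,frame,channel metadata attached to the returned stack.
#' @return a list with elements
#'   \describe{
#'     \item{stack}{an [image_stack()] of Poisson photon counts}
#'     \item{truth}{data.frame `focus_id, row, col, z, molecularity,
#'       expected_photons` (one row per rendered focus)}
#'   }
#' @export
gen_focus_stack <- function(spec, day = "day1", frame = 0L, channel = "GFP") {
  .check(inherits(spec, "focus_sim_spec"), "spec must be a focus_sim_spec")
  photons <- spec$molecularities * spec$photons_per_monomer
  rate <- .render_rate_field(spec$image_shape, spec$n_z, spec$psf_sigma,
                             spec$psf_sigma_z, photons, spec$positions,
                             spec$background_rate)
  counts <- withr::with_seed(spec$seed,
    array(rpois(length(rate), rate), dim(rate)))
  n_foci <- length(spec$molecularities)
  truth <- data.frame(
    focus_id = seq_len(n_foci),
    row = if (n_foci) spec$positions[, 1] else numeric(0),
    col = if (n_foci) spec$positions[, 2] else numeric(0),
    z = if (n_foci) {
      if (ncol(spec$positions) == 3) spec$positions[, 3]
      else rep((spec$n_z - 1) / 2, n_foci)
    } else numeric(0),
    molecularity = spec$molecularities,
    expected_photons = photons)
  list(stack = image_stack(counts, spec$pixel_size_um, spec$z_step,
                           channel = channel, frame = frame, day = day),
       truth = truth)
}

#' Generate a synthetic NUP96 calibration stack
#'
#' Simulates a field of nuclear pores, each containing exactly 32 GFP-tagged
#' NUP96 copies, for use as the single-particle stoichiometry standard. Pore
#' positions are drawn uniformly inside a margin of the field.
#'
#' @param n_pores number of pores (`>= 1`).
#' @param photons_per_monomer expected photons per GFP copy.
#' @param psf_sigma lateral PSF width, pixels.
#' @param background_rate background photons per voxel.
#' @param seed integer seed.
#' @param image_shape,n_z field geometry (defaults 96 x 96 px, 8 planes).
#' @param margin minimum distance of pore centers from the image border,
#'   pixels.
#' @param day metadata day id for day-matched calibration.
#' @return as [gen_focus_stack()]; every ground-truth molecularity is 32.
#' @export
gen_nup96_stack <- function(n_pores, photons_per_monomer = 50, psf_sigma = 1.5,
                            background_rate = 2, seed = 1L,
                            image_shape = c(96L, 96L), n_z = 8L, margin = 8,
                            day = "day1") {
  .check(.is_count(n_pores, 1L), "n_pores must be >= 1")
  positions <- withr::with_seed(seed + 1L, cbind(
    runif(n_pores, margin, image_shape[1] - 1 - margin),
    runif(n_pores, margin, image_shape[2] - 1 - margin)))
  spec <- focus_sim_spec(image_shape = image_shape, n_z = n_z,
                         psf_sigma = psf_sigma,
                         photons_per_monomer = photons_per_monomer,
                         molecularities = rep(32L, n_pores),
                         positions = positions,
                         background_rate = background_rate, seed = seed)
  gen_focus_stack(spec, day = day, channel = "NUP96")
}

#' Generate a synthetic single-cell MOMP time lapse
#'
#' Produces, per frame, a mean-TMRE value and a GFP focus z-stack. The TMRE
#' trace is the baseline before `depol_frame` and `baseline * (1 -
#' depol_depth)` at and after it, plus optional Gaussian noise. One focus
#' nucleates at `focus_onset_frame`; additional foci nucleate at
#' `nucleation_rate` per subsequent frame (Poisson counts); every focus grows
#' by `growth_rate` monomers per frame from molecularity 1 at its birth
#' frame.
#'
#' @param spec a [timelapse_sim_spec()].
#' @param day metadata day id.
#' @return a list with elements
#'   \describe{
#'     \item{time_min}{frame times, minutes (frame 0 at 0)}
#'     \item{tmre}{TMRE trace, one value per frame}
#'     \item{stacks}{list of [image_stack()] GFP stacks, one per frame}
#'     \item{truth}{list: `depol_frame`, `depol_time`, `onset_frame`,
#'       `onset_time`, `lag_min`, and `foci`, a data.frame `frame, focus_id,
#'       row, col, molecularity`}
#'   }
#' @export
gen_timelapse <- function(spec, day = "day1") {
  .check(inherits(spec, "timelapse_sim_spec"), "spec must be a timelapse_sim_spec")
  frames <- seq_len(spec$n_frames) - 1L
  time_min <- frames * spec$frame_interval
  tmre <- rep(spec$tmre_baseline, spec$n_frames)
  if (!is.na(spec$depol_frame))
    tmre[frames >= spec$depol_frame] <-
      spec$tmre_baseline * (1 - spec$depol_depth)

  withr::with_seed(spec$seed, {
    if (spec$tmre_noise_sd > 0)
      tmre <- tmre + rnorm(spec$n_frames, 0, spec$tmre_noise_sd)
    # nucleation schedule: focus birth frames and positions
    margin <- 6
    birth <- integer(0)
    if (!is.na(spec$focus_onset_frame)) {
      birth <- spec$focus_onset_frame
      later <- frames[frames > spec$focus_onset_frame]
      if (length(later) > 0 && spec$nucleation_rate > 0)
        birth <- c(birth, rep(later, rpois(length(later), spec$nucleation_rate)))
    }
    n_foci <- length(birth)
    pos <- if (n_foci) cbind(
      runif(n_foci, margin, spec$image_shape[1] - 1 - margin),
      runif(n_foci, margin, spec$image_shape[2] - 1 - margin)) else
      matrix(numeric(0), ncol = 2)
    stack_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_frames)
  })

  foci_truth <- list()
  stacks <- vector("list", spec$n_frames)
  for (k in frames) {
    alive <- which(birth <= k)
    mol <- 1 + spec$growth_rate * (k - birth[alive])
    fspec <- focus_sim_spec(image_shape = spec$image_shape, n_z = spec$n_z,
                            psf_sigma = spec$psf_sigma,
                            photons_per_monomer = spec$photons_per_monomer,
                            molecularities = if (length(alive)) mol else integer(0),
                            positions = pos[alive, , drop = FALSE],
                            background_rate = spec$background_rate,
                            seed = stack_seeds[k + 1L])
    stacks[[k + 1L]] <- gen_focus_stack(fspec, day = day, frame = k)$stack
    if (length(alive))
      foci_truth[[length(foci_truth) + 1L]] <- data.frame(
        frame = k, focus_id = alive, row = pos[alive, 1], col = pos[alive, 2],
        molecularity = mol)
  }
  foci <- if (length(foci_truth)) do.call(rbind, foci_truth) else
    data.frame(frame = integer(0), focus_id = integer(0), row = numeric(0),
               col = numeric(0), molecularity = numeric(0))
  lag <- if (!is.na(spec$depol_frame) && !is.na(spec$focus_onset_frame))
    (spec$focus_onset_frame - spec$depol_frame) * spec$frame_interval else NA_real_
  list(time_min = time_min, tmre = tmre, stacks = stacks,
       truth = list(depol_frame = spec$depol_frame,
                    depol_time = if (is.na(spec$depol_frame)) NA_real_ else
                      spec$depol_frame * spec$frame_interval,
                    onset_frame = spec$focus_onset_frame,
                    onset_time = if (is.na(spec$focus_onset_frame)) NA_real_ else
                      spec$focus_onset_frame * spec$frame_interval,
                    lag_min = lag, foci = foci))
}

#' Generate a synthetic mtDNA-release qPCR Ct table
#'
#' The relative cytosolic template amount at time `t` hours is
#' `A(t) = 2^(t / release_halflife)`, so the noise-free mean Ct is
#' `ct0 - log2(A(t)) = ct0 - t / release_halflife`; technical replicates add
#' Gaussian noise of s.d. `noise_sd`.
#'
#' @param spec a [qpcr_sim_spec()].
#' @return a list with elements
#'   \describe{
#'     \item{table}{data.frame `primer, time_h, replicate, ct`}
#'     \item{truth}{data.frame `time_h, log2_amount` — the ground-truth
#'       release curve (equals the expected delta-Ct at each time)}
#'   }
#' @export
gen_qpcr <- function(spec) {
  .check(inherits(spec, "qpcr_sim_spec"), "spec must be a qpcr_sim_spec")
  grid <- expand.grid(replicate = seq_len(spec$n_replicates),
                      time_h = spec$timepoints_h, primer = spec$primers,
                      stringsAsFactors = FALSE)
  log2_amount <- grid$time_h / spec$release_halflife
  ct <- spec$ct0 - log2_amount
  if (spec$noise_sd > 0)
    ct <- ct + withr::with_seed(spec$seed, rnorm(nrow(grid), 0, spec$noise_sd))
  list(table = data.frame(primer = grid$primer, time_h = grid$time_h,
                          replicate = grid$replicate, ct = ct,
                          stringsAsFactors = FALSE),
       truth = data.frame(time_h = spec$timepoints_h,
                          log2_amount = spec$timepoints_h / spec$release_halflife))
}
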
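#' Simulation spec: proximity-proteomics ratio table
#'
#' Describes a synthetic dimethyl-labeling experiment: a background of
#' proteins whose log2(STS/CTRL) ratios follow a normal distribution, with a
#' spiked subpopulation of truly enriched proteins shifted upward by
#' `spike_shift` log2 units. Reference ratios log2(STS/STS) are centered at 0
#' with the same spread for all proteins. Annotation membership (mitochondrial
#' GOCC-like term, apoptosis GOBP-like term) is drawn per protein with
#' different probabilities for background and spiked proteins.
#'
#' @param n_proteins number of proteins in the table.
#' @param base_mu,base_sigma mean and s.d. of the background log2(STS/CTRL)
#'   distribution (log2 units); `base_sigma > 0`.
#' @param n_spiked number of truly enriched proteins (`<= n_proteins`).
#' @param spike_shift log2 units added to the STS/CTRL ratio of spiked
#'   proteins (`>= 0`).
#' @param intensity_range log10 bounds of the summed reporter intensity,
#'   length 2 increasing.
#' @param annotation_rates named list with elements `mito` and `apoptosis`,
#'   each a length-2 numeric `c(background, spiked)` of membership
#'   probabilities in \[0, 1\].
#' @param seed integer seed; every generator is a pure function of its spec.
#' @return an object of class `ratio_sim_spec`.
#' @export
ratio_sim_spec <- function(n_proteins = 1000L, base_mu = 0, base_sigma = 1,
                           n_spiked = 0L, spike_shift = 0,
                           intensity_range = c(5, 9),
                           annotation_rates = list(mito = c(0.2, 0.9),
                                                   apoptosis = c(0.1, 0.8)),
                           seed = 1L) {
  .check(.is_count(n_proteins, 1L), "n_proteins must be a positive integer")
  .check(.is_num(base_mu) && .is_num(base_sigma) && base_sigma > 0,
         "base_sigma must be a positive number")
  .check(.is_count(n_spiked) && n_spiked <= n_proteins,
         "n_spiked must be a count <= n_proteins")
  .check(.is_num(spike_shift) && spike_shift >= 0, "spike_shift must be >= 0")
  .check(.is_num(intensity_range, 2L) && diff(intensity_range) > 0,
         "intensity_range must be increasing length-2")
  .check(is.list(annotation_rates) &&
           all(c("mito", "apoptosis") %in% names(annotation_rates)) &&
           all(vapply(annotation_rates[c("mito", "apoptosis")],
                      function(r) .is_num(r, 2L) && all(r >= 0 & r <= 1),
                      logical(1))),
         "annotation_rates must list mito and apoptosis probabilities in [0,1]")
  .check(.is_count(seed), "seed must be an integer")
  structure(list(n_proteins = as.integer(n_proteins), base_mu = base_mu,
                 base_sigma = base_sigma, n_spiked = as.integer(n_spiked),
                 spike_shift = spike_shift, intensity_range = intensity_range,
                 annotation_rates = annotation_rates, seed = as.integer(seed)),
            class = "ratio_sim_spec")
}

#' Simulation spec: diffraction-limited focus field
#'
#' Describes a photon-counting confocal z-stack containing foci of known
#' molecularity. Each focus is rendered as a 3D Gaussian photon-rate field
#' (isotropic in x,y with width `psf_sigma` pixels; independent, wider
#' Gaussian along z) whose integral is `molecularity * photons_per_monomer`,
#' summed with a uniform `background_rate`, then Poisson-sampled per voxel.
#'
#' @param image_shape pixels, `c(rows, cols)`.
#' @param n_z number of z planes (default 8).
#' @param z_step z interval in micrometres (default 0.3).
#' @param psf_sigma lateral PSF Gaussian width in pixels.
#' @param psf_sigma_z axial Gaussian width in z-plane units (default 1.2
#'   planes = 0.36 um at the 0.3 um z step, the elongated confocal axial PSF
#'   at NA 1.4; much wider than the lateral width in physical units).
#' @param photons_per_monomer expected photons collected per GFP monomer; the
#'   instrument does not fix this value so it is a free parameter.
#' @param molecularities integer vector, true monomer count of each focus
#'   (all `>= 1`); may be empty.
#' @param positions matrix with one row per focus, columns `(row, col)` in
#'   0-based sub-pixel coordinates; optional third column is the 0-based z
#'   center (default: middle plane).
#' @param background_rate expected background photons per voxel.
#' @param pixel_size_um pixel size in micrometres (metadata only).
#' @param seed integer seed.
#' @return an object of class `focus_sim_spec`.
#' @export
focus_sim_spec <- function(image_shape = c(64L, 64L), n_z = 8L, z_step = 0.3,
                           psf_sigma = 1.5, psf_sigma_z = 1.2,
                           photons_per_monomer = 50,
                           molecularities = integer(0), positions = NULL,
                           background_rate = 2, pixel_size_um = 0.045,
                           seed = 1L) {
  .check(.is_num(image_shape, 2L) && all(image_shape >= 4),
         "image_shape must be c(rows, cols), each >= 4")
  .check(.is_count(n_z, 1L), "n_z must be a positive integer")
  .check(.is_num(z_step) && z_step > 0, "z_step must be > 0")
  .check(.is_num(psf_sigma) && psf_sigma > 0, "psf_sigma must be > 0")
  .check(.is_num(psf_sigma_z) && psf_sigma_z > 0, "psf_sigma_z must be > 0")
  .check(.is_num(photons_per_monomer) && photons_per_monomer > 0,
         "photons_per_monomer must be > 0")
  n_foci <- length(molecularities)
  .check(n_foci == 0 || (is.numeric(molecularities) && all(molecularities >= 1)),
         "molecularities must all be >= 1")
  if (n_foci > 0) {
    .check(is.matrix(positions) && nrow(positions) == n_foci &&
             ncol(positions) %in% c(2L, 3L),
           "positions must be an n_foci x 2 (or x 3) matrix")
    .check(all(positions[, 1] >= 0 & positions[, 1] <= image_shape[1] - 1) &&
             all(positions[, 2] >= 0 & positions[, 2] <= image_shape[2] - 1),
           "focus positions must lie inside the image bounds")
    if (ncol(positions) == 3L)
      .check(all(positions[, 3] >= 0 & positions[, 3] <= n_z - 1),
             "focus z centers must lie inside the stack")
  } else {
    positions <- matrix(numeric(0), ncol = 2)
  }
  .check(.is_num(background_rate) && background_rate >= 0,
         "background_rate must be >= 0")
  .check(.is_count(seed), "seed must be an integer")
  structure(list(image_shape = as.integer(image_shape), n_z = as.integer(n_z),
                 z_step = z_step, psf_sigma = psf_sigma,
                 psf_sigma_z = psf_sigma_z,
                 photons_per_monomer = photons_per_monomer,
                 molecularities = molecularities, positions = positions,
                 background_rate = background_rate,
                 pixel_size_um = pixel_size_um, seed = as.integer(seed)),
            class = "focus_sim_spec")
}

#' Simulation spec: single-cell MOMP time lapse
#'
#' Describes one cell followed over `n_frames` frames at `frame_interval`
#' minutes: a TMRE trace with a step depolarization (a fraction `depol_depth`
#' of the baseline is lost at `depol_frame`), and GFP foci that nucleate from
#' `focus_onset_frame` (one seeding focus at onset, further foci at
#' `nucleation_rate` per frame) and grow linearly at `growth_rate`
#' monomers/frame.
#'
#' @param n_frames number of frames.
#' @param frame_interval minutes between frames (default 10).
#' @param depol_frame 0-based frame of the TMRE step drop, or `NA` for none.
#' @param depol_depth fraction of the baseline lost at depolarization, in
#'   \[0, 1\].
#' @param focus_onset_frame 0-based frame at which the first focus appears,
#'   or `NA` for none.
#' @param growth_rate monomers gained per frame by each existing focus.
#' @param nucleation_rate expected new foci per frame after onset (Poisson).
#' @param tmre_baseline baseline TMRE signal at frame 0.
#' @param tmre_noise_sd s.d. of Gaussian noise added to the TMRE trace
#'   (default 0, noise-free).
#' @param image_shape,n_z,psf_sigma,photons_per_monomer,background_rate
#'   geometry of the rendered GFP focus stacks (see [focus_sim_spec()]).
#' @param seed integer seed.
#' @return an object of class `timelapse_sim_spec`.
#' @export
timelapse_sim_spec <- function(n_frames = 6L, frame_interval = 10,
                               depol_frame = 1L, depol_depth = 0.6,
                               focus_onset_frame = 1L, growth_rate = 4,
                               nucleation_rate = 0.5, tmre_baseline = 100,
                               tmre_noise_sd = 0, image_shape = c(48L, 48L),
                               n_z = 8L, psf_sigma = 1.5,
                               photons_per_monomer = 50, background_rate = 2,
                               seed = 1L) {
  .check(.is_count(n_frames, 1L), "n_frames must be a positive integer")
  .check(.is_num(frame_interval) && frame_interval > 0,
         "frame_interval must be > 0")
  if (!is.na(depol_frame))
    .check(.is_count(depol_frame) && depol_frame < n_frames,
           "depol_frame must satisfy 0 <= depol_frame < n_frames")
  .check(.is_num(depol_depth) && depol_depth >= 0 && depol_depth <= 1,
         "depol_depth must lie in [0, 1]")
  if (!is.na(focus_onset_frame))
    .check(.is_count(focus_onset_frame) && focus_onset_frame < n_frames,
           "focus_onset_frame must satisfy 0 <= onset < n_frames")
  .check(.is_num(growth_rate) && growth_rate >= 0, "growth_rate must be >= 0")
  .check(.is_num(nucleation_rate) && nucleation_rate >= 0,
         "nucleation_rate must be >= 0")
  .check(.is_num(tmre_baseline) && tmre_baseline > 0,
         "tmre_baseline must be > 0")
  .check(.is_num(tmre_noise_sd) && tmre_noise_sd >= 0,
         "tmre_noise_sd must be >= 0")
  .check(.is_count(seed), "seed must be an integer")
  structure(list(n_frames = as.integer(n_frames),
                 frame_interval = frame_interval,
                 depol_frame = if (is.na(depol_frame)) NA_integer_ else as.integer(depol_frame),
                 depol_depth = depol_depth,
                 focus_onset_frame = if (is.na(focus_onset_frame)) NA_integer_ else as.integer(focus_onset_frame),
                 growth_rate = growth_rate, nucleation_rate = nucleation_rate,
                 tmre_baseline = tmre_baseline, tmre_noise_sd = tmre_noise_sd,
                 image_shape = as.integer(image_shape), n_z = as.integer(n_z),
                 psf_sigma = psf_sigma,
                 photons_per_monomer = photons_per_monomer,
                 background_rate = background_rate, seed = as.integer(seed)),
            class = "timelapse_sim_spec")
}

#' Simulation spec: mtDNA-release qPCR experiment
#'
#' Describes Ct tables for a panel of mtDNA primers measured over time in
#' technical replicates. The relative cytosolic template amount grows as
#' `2^(t / release_halflife)` (i.e. `release_halflife` is the template
#' doubling time in hours), so the mean Ct at time `t` is
#' `ct0 - t / release_halflife`; replicates add Gaussian noise of s.d.
#' `noise_sd`. `release_halflife = Inf` gives a flat (no-release) curve.
#'
#' @param primers character vector of primer names.
#' @param timepoints_h sampling times in hours (non-negative, including 0).
#' @param release_halflife template doubling time in hours; `Inf` for no
#'   release.
#' @param ct0 baseline Ct at time zero.
#' @param noise_sd replicate noise s.d. in Ct units.
#' @param n_replicates technical replicates per (primer, time) (default 3).
#' @param seed integer seed.
#' @return an object of class `qpcr_sim_spec`.
#' @export
qpcr_sim_spec <- function(primers = c("Dloop", "16S", "non-nuMT", "cytochrome b"),
                          timepoints_h = c(0, 1, 2, 3), release_halflife = 1,
                          ct0 = 30, noise_sd = 0.1, n_replicates = 3L,
                          seed = 1L) {
  .check(is.character(primers) && length(primers) >= 1,
         "primers must be a non-empty character vector")
  .check(is.numeric(timepoints_h) && all(is.finite(timepoints_h)) &&
           all(timepoints_h >= 0), "timepoints_h must be non-negative")
  .check(is.numeric(release_halflife) && length(release_halflife) == 1 &&
           release_halflife > 0, "release_halflife must be > 0 (Inf allowed)")
  .check(.is_num(ct0) && ct0 > 0, "ct0 must be > 0")
  .check(.is_num(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  .check(.is_count(n_replicates, 1L), "n_replicates must be >= 1")
  .check(.is_count(seed), "seed must be an integer")
  structure(list(primers = primers, timepoints_h = timepoints_h,
                 release_halflife = release_halflife, ct0 = ct0,
                 noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "qpcr_sim_spec")
}
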
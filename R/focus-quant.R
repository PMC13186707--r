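#' Maximum-intensity z projection
#'
#' Projects a z-stack to 2D by taking, per pixel, the maximum photon count
#' over z; the z index attaining the maximum (lowest index on ties, 0-based)
#' is recorded so foci peaking in the outer planes can be discarded later.
#'
#' @param stack an [image_stack()] (or bare `[z, row, col]` array).
#' @return list `(image, z_argmax)`: a `row x col` matrix of maxima and an
#'   integer matrix of 0-based argmax z indices.
#' @export
max_project <- function(stack) {
  counts <- if (inherits(stack, "image_stack")) stack$counts else stack
  .check(is.array(counts) && length(dim(counts)) == 3 && all(dim(counts) >= 1),
         "empty or malformed stack")
  n_z <- dim(counts)[1]
  img <- apply(counts, c(2, 3), max)
  amx <- apply(counts, c(2, 3), which.max) - 1L
  list(image = img, z_argmax = amx)
}

# separable Gaussian blur; thin wrapper so the DoG construction below reads
# at the method level
.gblur <- function(img, sigma) {
  EBImage::gblur(img, sigma = sigma,
                 radius = max(3L, 2L * ceiling(3 * sigma) + 1L))
}

#' Detect candidate foci by difference of Gaussians
#'
#' Builds a DoG scale space over geometrically spaced widths in
#' `[sigma_min, sigma_max]`: each layer is `(G(s_i) - G(s_{i+1})) * s_i /
#' (s_{i+1} - s_i)`, an approximation of the scale-normalized Laplacian whose
#' peak response for a Gaussian blob of width s occurs near scale s.
#' Candidates are local maxima over space and scale above
#' `detect_threshold`, deduplicated so that no two candidates are closer
#' than their blob radius.
#'
#' @param image 2D photon-count matrix (typically a max projection).
#' @param sigma_min,sigma_max blob width search range, pixels
#'   (`sigma_min < sigma_max`).
#' @param detect_threshold minimum DoG response (photons/pixel units);
#'   `NULL` (default) uses a 5-sigma rule on the response map itself,
#'   `5 * mad(finest DoG layer)` — the band-pass response to shot noise,
#'   which is what spurious maxima actually ride on.
#' @param n_scales number of scale-space layers (default 6).
#' @return data.frame `row, col, scale, response` (0-based integer pixel
#'   coordinates), ordered by decreasing response.
#' @export
detect_foci <- function(image, sigma_min = 1, sigma_max = 4,
                        detect_threshold = NULL, n_scales = 6L) {
  .check(is.matrix(image), "image must be a 2D matrix")
  .check(sigma_min < sigma_max, "sigma_min must be < sigma_max")
  sig <- exp(seq(log(sigma_min), log(sigma_max), length.out = n_scales + 1L))
  blurred <- lapply(sig, function(s) .gblur(image, s))
  dog <- lapply(seq_len(n_scales), function(i)
    (blurred[[i]] - blurred[[i + 1L]]) * sig[i] / (sig[i + 1L] - sig[i]))
  if (is.null(detect_threshold))
    detect_threshold <- 5 * stats::mad(dog[[1L]])
  cand <- list()
  for (i in seq_len(n_scales)) {
    d <- dog[[i]]
    mx <- .local_max2d(d)
    above <- mx & d > detect_threshold
    if (i > 1L) above <- above & d >= dog[[i - 1L]]
    if (i < n_scales) above <- above & d >= dog[[i + 1L]]
    idx <- which(above, arr.ind = TRUE)
    if (nrow(idx) > 0)
      cand[[length(cand) + 1L]] <- data.frame(
        row = idx[, 1] - 1L, col = idx[, 2] - 1L,
        scale = sqrt(sig[i] * sig[i + 1L]), response = d[idx])
  }
  if (length(cand) == 0)
    return(data.frame(row = integer(0), col = integer(0), scale = numeric(0),
                      response = numeric(0)))
  out <- do.call(rbind, cand)
  out <- out[order(-out$response), , drop = FALSE]
  # greedy non-maximum suppression at the blob radius
  keep <- logical(nrow(out))
  for (j in seq_len(nrow(out))) {
    if (j == 1L) { keep[1L] <- TRUE; next }
    kept <- out[keep, , drop = FALSE]
    dd <- sqrt((kept$row - out$row[j])^2 + (kept$col - out$col[j])^2)
    keep[j] <- all(dd > pmax(kept$scale, out$scale[j]) * sqrt(2))
  }
  rownames(out) <- NULL
  out[keep, , drop = FALSE]
}

# interior local maxima (8-neighborhood, >=); border pixels excluded
.local_max2d <- function(d) {
  nr <- nrow(d); nc <- ncol(d)
  mx <- matrix(FALSE, nr, nc)
  if (nr < 3 || nc < 3) return(mx)
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  ctr <- d[ri, ci]
  ok <- ctr >= d[ri - 1, ci] & ctr >= d[ri + 1, ci] &
    ctr >= d[ri, ci - 1] & ctr >= d[ri, ci + 1] &
    ctr >= d[ri - 1, ci - 1] & ctr >= d[ri - 1, ci + 1] &
    ctr >= d[ri + 1, ci - 1] & ctr >= d[ri + 1, ci + 1]
  mx[ri, ci] <- ok
  mx
}

# empty focus record row
.focus_record <- function(x0 = NA_real_, y0 = NA_real_, sigma = NA_real_,
                          amplitude = NA_real_, offset = NA_real_,
                          intensity = NA_real_, z_argmax = NA_integer_,
                          accepted = FALSE, reason = NA_character_) {
  data.frame(x0 = x0, y0 = y0, sigma = sigma, amplitude = amplitude,
             offset = offset, intensity = intensity, z_argmax = z_argmax,
             accepted = accepted, reason = reason, stringsAsFactors = FALSE)
}

#' Fit an isotropic 2D Gaussian to a focus ROI
#'
#' Least-squares fit of `amplitude * exp(-((x-x0)^2 + (y-y0)^2) / (2 sigma^2))
#' + offset` on a `roi_size x roi_size` window centered on the candidate
#' pixel (Levenberg-Marquardt). The background-subtracted integrated
#' intensity is the analytic Gaussian integral `2 * pi * amplitude *
#' sigma^2`. Candidates whose ROI touches the image border, or whose fit
#' fails or collapses, are returned as rejected records.
#'
#' @param image 2D photon-count matrix.
#' @param center candidate center, `c(row, col)` 0-based.
#' @param roi_size odd ROI side length in pixels (default 5).
#' @param z_argmax optional 0-based z-argmax map from [max_project()]; the
#'   record stores its value at the fitted center.
#' @return a one-row focus-record data.frame (`x0` = col, `y0` = row,
#'   `sigma`, `amplitude`, `offset`, `intensity`, `z_argmax`, `accepted`,
#'   `reason`).
#' @export
fit_focus <- function(image, center, roi_size = 5L, z_argmax = NULL) {
  .check(roi_size %% 2 == 1 && roi_size >= 3, "roi_size must be odd >= 3")
  h <- (roi_size - 1L) %/% 2L
  r0 <- round(center[1]); c0 <- round(center[2])
  if (r0 - h < 0 || c0 - h < 0 ||
      r0 + h > nrow(image) - 1 || c0 + h > ncol(image) - 1)
    return(.focus_record(reason = "border"))
  rows <- (r0 - h):(r0 + h); cols <- (c0 - h):(c0 + h)
  roi <- image[rows + 1L, cols + 1L]
  grid <- expand.grid(y = rows, x = cols)
  xv <- grid$x; yv <- grid$y
  v <- as.vector(roi)
  if (max(v) - min(v) <= 0) return(.focus_record(reason = "degenerate"))
  start <- list(amp = max(v) - min(v), x0 = c0, y0 = r0, sigma = 1.2,
                offset = min(v))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ amp * exp(-((xv - x0)^2 + (yv - y0)^2) / (2 * sigma^2)) + offset,
      start = start,
      lower = c(amp = 0, x0 = c0 - h, y0 = r0 - h, sigma = 0.2,
                offset = -Inf),
      upper = c(amp = Inf, x0 = c0 + h, y0 = r0 + h, sigma = roi_size,
                offset = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(.focus_record(reason = "fit_failed"))
  p <- as.list(coef(fit))
  if (p$amp <= 0 || p$sigma <= 0) return(.focus_record(reason = "degenerate"))
  zi <- if (is.null(z_argmax)) NA_integer_ else
    z_argmax[round(p$y0) + 1L, round(p$x0) + 1L]
  .focus_record(x0 = p$x0, y0 = p$y0, sigma = p$sigma, amplitude = p$amp,
                offset = p$offset, intensity = 2 * pi * p$amp * p$sigma^2,
                z_argmax = zi, accepted = TRUE)
}

#' Re-estimate the local background from an annulus and update the intensity
#'
#' The offset is re-estimated as the median photon count in the square
#' annulus of Chebyshev radius `annulus_in` to `annulus_out` (inclusive)
#' around the focus center; the background-subtracted intensity becomes the
#' ROI photon sum minus `offset * ROI area`, floored at 0. A focus whose
#' annulus extends beyond the image is rejected (reason `border`).
#'
#' @param image 2D photon-count matrix.
#' @param record a one-row focus record from [fit_focus()].
#' @param roi_size ROI side length used for the photon sum (default 5).
#' @param annulus_in,annulus_out inner/outer Chebyshev radii, pixels
#'   (defaults 3 and 6: the ring just outside a 5x5 ROI).
#' @return the updated one-row record (`offset`, `intensity`).
#' @export
subtract_background <- function(image, record, roi_size = 5L,
                                annulus_in = 3L, annulus_out = 6L) {
  .check(annulus_in > (roi_size - 1L) %/% 2L && annulus_out > annulus_in,
         "annulus must lie outside the ROI with annulus_out > annulus_in")
  if (!isTRUE(record$accepted)) return(record)
  r0 <- round(record$y0); c0 <- round(record$x0)
  if (r0 - annulus_out < 0 || c0 - annulus_out < 0 ||
      r0 + annulus_out > nrow(image) - 1 || c0 + annulus_out > ncol(image) - 1) {
    record$accepted <- FALSE
    record$reason <- "border"
    return(record)
  }
  dr <- (-annulus_out):annulus_out
  cheb <- pmax(abs(outer(dr, rep(1, length(dr)))),
               abs(outer(rep(1, length(dr)), dr)))
  patch <- image[r0 + dr + 1L, c0 + dr + 1L]
  ring <- patch[cheb >= annulus_in & cheb <= annulus_out]
  offset <- median(ring)
  h <- (roi_size - 1L) %/% 2L
  roi_sum <- sum(image[(r0 - h):(r0 + h) + 1L, (c0 - h):(c0 + h) + 1L])
  record$offset <- offset
  record$intensity <- max(0, roi_sum - offset * roi_size^2)
  record
}

#' Quality-filter focus records
#'
#' Applies the four rejection rules, in order of priority:
#' \enumerate{
#'   \item `distance` — another focus lies within `min_distance` pixels
#'     (both members of a close pair are rejected unless
#'     `keep_brighter = TRUE`, which keeps the higher-intensity member);
#'   \item `dim` — intensity below `min_intensity`;
#'   \item `sigma` — fitted width outside `sigma_bounds`;
#'   \item `z_edge` — intensity maximum within `z_edge_margin` planes of
#'     either stack end, where depth information is lost.
#' }
#' Records already rejected upstream keep their original reason and do not
#' participate in the distance rule.
#'
#' @param records focus-record data.frame (rows from [fit_focus()] /
#'   [subtract_background()]).
#' @param min_distance minimum center-to-center distance, pixels.
#' @param min_intensity minimum background-subtracted intensity, photons.
#' @param sigma_bounds length-2 inclusive bounds on the fitted sigma, pixels.
#' @param z_edge_margin planes at each stack end considered "outer"
#'   (default 1).
#' @param n_z number of z planes in the source stack (needed for the z rule;
#'   `NULL` skips it).
#' @param keep_brighter keep the brighter member of a close pair instead of
#'   rejecting both (default `FALSE`).
#' @return the records with `accepted`/`reason` updated.
#' @export
filter_foci <- function(records, min_distance = 4, min_intensity = 0,
                        sigma_bounds = c(0.5, 4), z_edge_margin = 1L,
                        n_z = NULL, keep_brighter = FALSE) {
  if (nrow(records) == 0) return(records)
  live <- which(records$accepted)
  if (length(live) >= 2) {
    d <- as.matrix(dist(cbind(records$y0[live], records$x0[live])))
    diag(d) <- Inf
    for (a in seq_along(live)) {
      close <- which(d[a, ] < min_distance)
      if (length(close) == 0) next
      i <- live[a]
      if (keep_brighter &&
          all(records$intensity[i] > records$intensity[live[close]])) next
      records$accepted[i] <- FALSE
      records$reason[i] <- "distance"
    }
  }
  for (i in which(records$accepted)) {
    if (records$intensity[i] < min_intensity) {
      records$accepted[i] <- FALSE; records$reason[i] <- "dim"
    } else if (records$sigma[i] < sigma_bounds[1] ||
               records$sigma[i] > sigma_bounds[2]) {
      records$accepted[i] <- FALSE; records$reason[i] <- "sigma"
    } else if (!is.null(n_z) && !is.na(records$z_argmax[i]) &&
               (records$z_argmax[i] < z_edge_margin ||
                records$z_argmax[i] > n_z - 1L - z_edge_margin)) {
      records$accepted[i] <- FALSE; records$reason[i] <- "z_edge"
    }
  }
  records
}

#' Quantify all foci in one z-stack
#'
#' Convenience wrapper running the full single-stack chain: maximum
#' projection, DoG detection, per-candidate 2D Gaussian fit, annulus
#' background subtraction, and quality filtering.
#'
#' @param stack an [image_stack()].
#' @param psf_sigma expected focus width, pixels; drives the DoG search range
#'   (`0.8 x` to `2.5 x`) and the default sigma acceptance bounds
#'   (`0.5 x` to `2 x`).
#' @param detect_threshold DoG response threshold; `NULL` (default) uses the
#'   5-sigma response-noise rule of [detect_foci()].
#' @param min_intensity dim-focus threshold; `NULL` uses `5 *` the s.d. of a
#'   background ROI sum (`5 * sqrt(roi_size^2 * background)`).
#' @param roi_size,annulus_in,annulus_out,min_distance,z_edge_margin,keep_brighter
#'   see the individual steps.
#' @return focus-record data.frame (accepted and rejected rows).
#' @export
quantify_foci <- function(stack, psf_sigma = 1.5, detect_threshold = NULL,
                          min_intensity = NULL, roi_size = 5L,
                          annulus_in = 3L, annulus_out = 6L,
                          min_distance = 4, z_edge_margin = 1L,
                          keep_brighter = FALSE) {
  proj <- max_project(stack)
  bg <- median(proj$image)
  if (is.null(min_intensity)) min_intensity <- 5 * sqrt(roi_size^2 * max(bg, 1))
  cand <- detect_foci(proj$image, sigma_min = 0.8 * psf_sigma,
                      sigma_max = 2.5 * psf_sigma,
                      detect_threshold = detect_threshold)
  if (nrow(cand) == 0) return(.focus_record()[0, ])
  recs <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i)
    fit_focus(proj$image, c(cand$row[i], cand$col[i]), roi_size = roi_size,
              z_argmax = proj$z_argmax)))
  recs <- do.call(rbind, lapply(seq_len(nrow(recs)), function(i)
    subtract_background(proj$image, recs[i, ], roi_size = roi_size,
                        annulus_in = annulus_in, annulus_out = annulus_out)))
  n_z <- dim(if (inherits(stack, "image_stack")) stack$counts else stack)[1]
  filter_foci(recs, min_distance = min_distance,
              min_intensity = min_intensity,
              sigma_bounds = c(0.5, 2) * psf_sigma,
              z_edge_margin = z_edge_margin, n_z = n_z,
              keep_brighter = keep_brighter)
}

#' Build the NUP96 stoichiometry calibration standard
#'
#' The calibration mean is the arithmetic mean of the background-subtracted
#' intensities of accepted NUP96 focus records. NUP96 sits in the nuclear
#' pore in exactly 32 copies, so this mean corresponds to 32 GFP monomers.
#' Calibration is strictly day-matched: records from mixed acquisition days
#' are refused unless `allow_mixed_days = TRUE`.
#'
#' @param nup_records focus-record data.frame of NUP96 foci; an optional
#'   `day` column enforces day matching.
#' @param day expected acquisition day id (`NULL`: taken from the records).
#' @param allow_mixed_days override the day-matching check.
#' @return list `(nup_intensities, mean_intensity, standard_stoichiometry,
#'   day)` of class `calibration_standard`.
#' @export
calibrate <- function(nup_records, day = NULL, allow_mixed_days = FALSE) {
  acc <- nup_records[nup_records$accepted, , drop = FALSE]
  if (nrow(acc) == 0) stop("no accepted NUP96 records to calibrate from",
                           call. = FALSE)
  days <- if ("day" %in% names(acc)) unique(acc$day) else
    if (!is.null(day)) day else "unspecified"
  if (length(days) > 1 && !allow_mixed_days)
    stop("NUP96 records span several acquisition days; calibration must be day-matched",
         call. = FALSE)
  if (!is.null(day) && !allow_mixed_days && !all(days %in% day))
    stop("NUP96 records are not from the requested day", call. = FALSE)
  m <- mean(acc$intensity)
  if (m <= 0) stop("non-positive mean NUP96 intensity", call. = FALSE)
  structure(list(nup_intensities = acc$intensity, mean_intensity = m,
                 standard_stoichiometry = 32, day = days[1]),
            class = "calibration_standard")
}

#' Ratiometric stoichiometry of a focus
#'
#' Converts a background-subtracted focus intensity to a monomer count via
#' the nuclear-pore standard: `S = 32 * I_focus / <I_NUP96>`. The result is
#' continuous (no rounding); it is linear in the intensity and invariant to
#' any common rescaling of focus and standard intensities.
#'
#' @param record a one-row accepted focus record, or a bare numeric intensity
#'   (photons).
#' @param calibration a `calibration_standard` from [calibrate()].
#' @return estimated monomer count (numeric).
#' @export
stoichiometry <- function(record, calibration) {
  .check(inherits(calibration, "calibration_standard"),
         "calibration must be a calibration_standard")
  .check(calibration$mean_intensity > 0, "mean calibration intensity must be > 0")
  intensity <- if (is.numeric(record)) record else {
    .check(isTRUE(all(record$accepted)), "stoichiometry needs accepted records")
    record$intensity
  }
  calibration$standard_stoichiometry * intensity / calibration$mean_intensity
}

#' Background-normalized PLA intensity over the mitochondrial mask
#'
#' The mitochondrial area is segmented by Otsu's threshold on the
#' mitochondrial channel; the result is the mean PLA intensity inside the
#' mask divided by the mean outside (background).
#'
#' @param pla_image 2D PLA-channel matrix.
#' @param mito_image 2D mitochondrial-channel matrix, same shape.
#' @return the normalized mean intensity (ratio, unitless).
#' @export
pla_mito_intensity <- function(pla_image, mito_image) {
  .check(is.matrix(pla_image) && is.matrix(mito_image) &&
           all(dim(pla_image) == dim(mito_image)),
         "pla and mito images must be matrices of equal shape")
  rng <- range(mito_image)
  if (diff(rng) == 0)
    stop("constant mitochondrial image: Otsu threshold is degenerate",
         call. = FALSE)
  m01 <- (mito_image - rng[1]) / diff(rng)
  thr <- EBImage::otsu(m01, range = c(0, 1), levels = 256)
  mask <- m01 > thr
  if (!any(mask) || all(mask))
    stop("Otsu mask is empty or covers the whole image", call. = FALSE)
  mean(pla_image[mask]) / mean(pla_image[!mask])
}
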
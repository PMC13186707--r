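#' Per-cell time series container
#'
#' Bundles one cell's aligned per-frame series: TMRE mean intensity, GFP
#' dispersion statistics, and accepted-focus summaries.
#'
#' @param cell_id cell identifier.
#' @param condition condition label (e.g. `"wt"`, `"KO"`, `"KO+LPA"`).
#' @param time_min frame times in minutes, strictly increasing.
#' @param tmre mean TMRE intensity per frame.
#' @param gfp_sd,gfp_max s.d. and maximum of GFP pixel intensity per frame
#'   (optional).
#' @param foci_count accepted-focus count per frame (optional).
#' @param foci_mean_stoich mean accepted-focus stoichiometry per frame
#'   (optional; `NA` where the count is 0).
#' @return an object of class `cell_trace`.
#' @export
cell_trace <- function(cell_id, condition, time_min, tmre, gfp_sd = NULL,
                       gfp_max = NULL, foci_count = NULL,
                       foci_mean_stoich = NULL) {
  n <- length(time_min)
  .check(n >= 1 && all(diff(time_min) > 0), "times must be strictly increasing")
  for (s in list(tmre, gfp_sd, gfp_max, foci_count, foci_mean_stoich))
    .check(is.null(s) || length(s) == n, "all series must share one length")
  structure(list(cell_id = cell_id, condition = condition,
                 time_min = time_min, tmre = tmre, gfp_sd = gfp_sd,
                 gfp_max = gfp_max, foci_count = foci_count,
                 foci_mean_stoich = foci_mean_stoich),
            class = "cell_trace")
}

#' Call mitochondrial depolarization from a TMRE trace
#'
#' Depolarization (the MOMP proxy) is called at the first frame where the
#' TMRE signal has dropped by strictly more than `threshold_frac` of its
#' time-zero value: `tmre < baseline * (1 - threshold_frac)`. A drop of
#' exactly `threshold_frac` does not trigger. The call is invariant to
#' rescaling the whole trace.
#'
#' @param trace a [cell_trace()] or bare numeric TMRE vector.
#' @param threshold_frac fractional drop required (default 0.30).
#' @param baseline_frames number of initial frames averaged for the baseline
#'   (default 1: strictly the time-zero value; larger values are a robust
#'   option for noisy traces).
#' @return 0-based frame index of depolarization, or `NA_integer_` if never.
#' @export
call_depolarization <- function(trace, threshold_frac = 0.30,
                                baseline_frames = 1L) {
  tmre <- if (inherits(trace, "cell_trace")) trace$tmre else trace
  .check(is.numeric(tmre) && length(tmre) >= 1, "need a numeric TMRE trace")
  .check(.is_num(threshold_frac) && threshold_frac > 0 && threshold_frac < 1,
         "threshold_frac must lie in (0, 1)")
  baseline <- mean(tmre[seq_len(min(baseline_frames, length(tmre)))])
  if (baseline <= 0) stop("non-positive TMRE baseline", call. = FALSE)
  hit <- which(tmre < baseline * (1 - threshold_frac))
  if (length(hit) == 0) NA_integer_ else hit[1] - 1L
}

#' GFP dispersion traces over a cell mask
#'
#' Computes, per frame, the standard deviation and maximum of GFP pixel
#' intensities within the cell mask. Redistribution of a fixed amount of GFP
#' from a homogeneous mitochondrial pattern into discrete foci raises both
#' statistics, making them model-free focus-formation readouts.
#'
#' @param frames list of 2D GFP matrices (one per frame), all of one shape.
#' @param mask logical matrix of the same shape selecting cell pixels;
#'   `NULL` uses the whole field.
#' @return data.frame `frame, gfp_sd, gfp_max` (frame 0-based).
#' @export
gfp_dispersion_traces <- function(frames, mask = NULL) {
  .check(is.list(frames) && length(frames) >= 1, "need at least one frame")
  if (is.null(mask)) mask <- array(TRUE, dim(frames[[1]]))
  .check(any(mask), "empty cell mask")
  vals <- lapply(frames, function(f) {
    .check(all(dim(f) == dim(mask)), "frame and mask shapes differ")
    f[mask]
  })
  data.frame(frame = seq_along(frames) - 1L,
             gfp_sd = vapply(vals, sd, numeric(1)),
             gfp_max = vapply(vals, max, numeric(1)))
}

#' Normalize per-cell statistic series to a reference condition
#'
#' Divides every cell's series by the mean time-zero value of the cells in
#' the designated reference condition (e.g. wild type), so the reference
#' condition averages 1 at frame 0.
#'
#' @param series named list of numeric vectors, one per cell.
#' @param conditions character vector of condition labels, parallel to
#'   `series`.
#' @param reference reference condition label (default `"wt"`).
#' @return the list with every series divided by the reference frame-0 mean.
#' @export
normalize_to_reference <- function(series, conditions, reference = "wt") {
  .check(length(series) == length(conditions), "series/conditions mismatch")
  ref0 <- vapply(series[conditions == reference], function(s) s[1], numeric(1))
  .check(length(ref0) > 0, "no cells in the reference condition")
  denom <- mean(ref0)
  .check(is.finite(denom) && denom != 0, "reference frame-0 mean is zero")
  lapply(series, function(s) s / denom)
}

#' First frame with at least one accepted focus
#'
#' @param trace a [cell_trace()] or bare numeric vector of accepted-focus
#'   counts per frame.
#' @return 0-based onset frame, or `NA_integer_` if no focus ever appears.
#' @export
focus_onset <- function(trace) {
  counts <- if (inherits(trace, "cell_trace")) trace$foci_count else trace
  .check(is.numeric(counts), "need per-frame focus counts")
  hit <- which(counts >= 1)
  if (length(hit) == 0) NA_integer_ else hit[1] - 1L
}

#' Lag between depolarization and focus onset
#'
#' `lag = onset_time - depol_time` in minutes; negative when foci precede
#' TMRE loss, 0 when concurrent, `NA` (undefined, never imputed) when either
#' event is missing.
#'
#' @param depol_time,onset_time event times in minutes (`NA` if not called).
#' @return signed lag in minutes, or `NA_real_`.
#' @export
momp_foci_lag <- function(depol_time, onset_time) {
  if (is.na(depol_time) || is.na(onset_time)) return(NA_real_)
  onset_time - depol_time
}

#' Summarize one cell's MOMP-referenced kinetics
#'
#' Runs the depolarization caller and onset detector on a [cell_trace()] and
#' assembles the per-cell summary, including the per-frame oligomerized
#' amount where focus summaries are present.
#'
#' @param trace a [cell_trace()].
#' @param threshold_frac,baseline_frames passed to [call_depolarization()].
#' @return list of class `kinetics_summary`: `cell_id`, `condition`,
#'   `depol_frame`, `depol_time`, `onset_frame`, `onset_time`, `lag_min`,
#'   and `per_frame` (data.frame `frame, time_min, tmre, foci_count,
#'   foci_mean_stoich, oligomerized`).
#' @export
summarize_kinetics <- function(trace, threshold_frac = 0.30,
                               baseline_frames = 1L) {
  .check(inherits(trace, "cell_trace"), "trace must be a cell_trace")
  depol <- call_depolarization(trace, threshold_frac, baseline_frames)
  onset <- if (is.null(trace$foci_count)) NA_integer_ else focus_onset(trace)
  t_of <- function(fr) if (is.na(fr)) NA_real_ else trace$time_min[fr + 1L]
  counts <- if (is.null(trace$foci_count))
    rep(NA_real_, length(trace$time_min)) else trace$foci_count
  stoich <- if (is.null(trace$foci_mean_stoich))
    rep(NA_real_, length(trace$time_min)) else trace$foci_mean_stoich
  per_frame <- data.frame(
    frame = seq_along(trace$time_min) - 1L, time_min = trace$time_min,
    tmre = trace$tmre, foci_count = counts, foci_mean_stoich = stoich,
    oligomerized = oligomerized_amount(stoich, counts))
  structure(list(cell_id = trace$cell_id, condition = trace$condition,
                 depol_frame = depol, depol_time = t_of(depol),
                 onset_frame = onset, onset_time = t_of(onset),
                 lag_min = momp_foci_lag(t_of(depol), t_of(onset)),
                 per_frame = per_frame),
            class = "kinetics_summary")
}

#' Cumulative fraction of depolarized cells with foci over time after MOMP
#'
#' At each grid time `tau` (minutes after TMRE loss), the fraction of
#' depolarized cells whose onset lag is `<= tau`. Cells that depolarize but
#' never form foci stay in the denominator (censored), so the curve
#' plateaus at the ever-forming fraction.
#'
#' @param summaries list of `kinetics_summary` objects (or a numeric vector
#'   of lags, `NA` for censored cells).
#' @param time_grid times after depolarization, minutes.
#' @return data.frame `time_min, fraction` (non-decreasing).
#' @export
cumulative_foci_fraction <- function(summaries, time_grid) {
  lags <- if (is.numeric(summaries)) summaries else {
    depol <- vapply(summaries, function(s) s$depol_time, numeric(1))
    l <- vapply(summaries, function(s)
      if (is.na(s$lag_min)) NA_real_ else s$lag_min, numeric(1))
    l[!is.na(depol)]
  }
  if (length(lags) == 0) stop("no depolarized cells", call. = FALSE)
  data.frame(time_min = time_grid,
             fraction = vapply(time_grid, function(tau)
               sum(!is.na(lags) & lags <= tau) / length(lags), numeric(1)))
}

#' Amount of oligomerized protein per frame
#'
#' Monomers per focus multiplied by the number of foci; defined as 0 in
#' frames without foci regardless of the (then meaningless) mean
#' stoichiometry field.
#'
#' @param mean_stoichiometry mean accepted-focus stoichiometry per frame.
#' @param count accepted-focus count per frame (same length).
#' @return numeric vector of oligomerized amounts (monomer units).
#' @export
oligomerized_amount <- function(mean_stoichiometry, count) {
  .check(length(mean_stoichiometry) == length(count),
         "series must be aligned")
  ifelse(!is.na(count) & count == 0, 0, mean_stoichiometry * count)
}
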
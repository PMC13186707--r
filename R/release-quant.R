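#' Replicate-averaged delta-Ct release curve
#'
#' Technical replicates are averaged per (primer, time) on the Ct scale
#' (arithmetic mean of Ct, not of template amounts). The delta-Ct is taken
#' with respect to time zero with the sign convention
#' `delta_ct(t) = mean_ct(0) - mean_ct(t)`, so that template release (lower
#' Ct) gives positive values and one cycle corresponds to a two-fold
#' template change.
#'
#' @param table Ct table: data.frame `primer, time_h, replicate, ct` (Ct
#'   finite and > 0; time zero present for every primer).
#' @return data.frame of class `release_curve`: `primer, time_h, mean_ct,
#'   delta_ct`, ordered by primer then time.
#' @export
delta_ct <- function(table) {
  .check(is.data.frame(table) &&
           all(c("primer", "time_h", "ct") %in% names(table)),
         "table needs columns primer, time_h, ct")
  .check(all(is.finite(table$ct)) && all(table$ct > 0),
         "Ct values must be finite and > 0")
  .check(all(table$time_h >= 0), "negative time points")
  agg <- aggregate(ct ~ primer + time_h, data = table, FUN = mean)
  names(agg)[names(agg) == "ct"] <- "mean_ct"
  agg <- agg[order(agg$primer, agg$time_h), , drop = FALSE]
  out <- do.call(rbind, lapply(split(agg, agg$primer), function(g) {
    t0 <- g$mean_ct[g$time_h == 0]
    if (length(t0) != 1)
      stop(sprintf("primer %s has no (unique) time-zero measurement",
                   g$primer[1]), call. = FALSE)
    g$delta_ct <- t0 - g$mean_ct
    g
  }))
  rownames(out) <- NULL
  class(out) <- c("release_curve", "data.frame")
  out
}

#' Area under the delta-Ct release curve
#'
#' Trapezoidal integral of delta-Ct over time, per primer, on the observed
#' (possibly irregular) time grid with no interpolation or smoothing. Units:
#' cycles x hours.
#'
#' @param curve a `release_curve` from [delta_ct()] (needs `primer, time_h,
#'   delta_ct`; at least 2 time points per primer).
#' @return data.frame `primer, auc`.
#' @export
release_auc <- function(curve) {
  .check(is.data.frame(curve) &&
           all(c("primer", "time_h", "delta_ct") %in% names(curve)),
         "curve needs columns primer, time_h, delta_ct")
  out <- do.call(rbind, lapply(split(curve, curve$primer), function(g) {
    g <- g[order(g$time_h), , drop = FALSE]
    if (nrow(g) < 2)
      stop(sprintf("primer %s has fewer than 2 time points", g$primer[1]),
           call. = FALSE)
    data.frame(primer = g$primer[1],
               auc = pracma::trapz(g$time_h, g$delta_ct),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
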
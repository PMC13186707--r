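# shared fixture builders; everything is generated in code, no stored data

# four-focus field with known molecularities at well-separated positions
make_focus_field <- function(seed, molecularities = c(8, 16, 32, 64),
                             background_rate = 2) {
  gen_focus_stack(focus_sim_spec(
    image_shape = c(64L, 64L),
    molecularities = molecularities,
    positions = cbind(c(15, 15, 45, 45), c(15, 45, 15, 45))[seq_along(molecularities), , drop = FALSE],
    background_rate = background_rate, seed = seed))
}

# analytic isotropic 2D Gaussian image on an n x n grid (0-based coords)
render_gaussian_image <- function(n = 15, amp = 100, x0 = 7, y0 = 7,
                                  sigma = 1.2, offset = 5) {
  r <- seq_len(n) - 1
  outer(r, r, function(y, x)
    amp * exp(-((x - x0)^2 + (y - y0)^2) / (2 * sigma^2)) + offset)
}

# hand-coded type-7 quantile: order-statistic linear interpolation
quantile_type7_oracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# brute-force significance-B oracle for a single-bin table, coded
# independently of the package (own quantile interpolation, own z/p algebra)
sigb_oracle_single_bin <- function(ratios) {
  med <- quantile_type7_oracle(ratios, 0.5)
  scale <- (quantile_type7_oracle(ratios, 0.8413) -
              quantile_type7_oracle(ratios, 0.1587)) / 2
  z <- (ratios - med) / scale
  2 * pnorm(-abs(z))
}

# Benjamini-Hochberg step-up coded by hand: q_(i) = min_{j >= i} m p_(j) / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# match detected/accepted records to a ground-truth table by nearest center
match_to_truth <- function(records, truth, radius = 2) {
  acc <- records[records$accepted, , drop = FALSE]
  vapply(seq_len(nrow(truth)), function(i) {
    if (nrow(acc) == 0) return(NA_integer_)
    d <- sqrt((acc$y0 - truth$row[i])^2 + (acc$x0 - truth$col[i])^2)
    if (min(d) <= radius) which.min(d) else NA_integer_
  }, integer(1))
}
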
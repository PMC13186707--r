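#' Build annotation sets from a membership table
#'
#' Annotation membership is a flat table (no ontology graph): one row per
#' (term, protein). Two designated terms drive candidate selection: a
#' GOCC-like mitochondrial term and a GOBP-like apoptosis term.
#'
#' @param membership data.frame with columns `term_id, term_class, protein_id`
#'   (`term_class` in `CC`/`BP`).
#' @param mito_term term id of the designated mitochondrial set.
#' @param apoptosis_term term id of the designated apoptosis set.
#' @return an object of class `annotation_sets`: a list with `terms` (named
#'   list term id -> character vector of protein ids), `mito`, `apoptosis`.
#' @export
annotation_sets <- function(membership, mito_term = "CC:mitochondrion",
                            apoptosis_term = "BP:apoptotic_process") {
  .check(is.data.frame(membership) &&
           all(c("term_id", "protein_id") %in% names(membership)),
         "membership needs columns term_id, protein_id")
  terms <- lapply(split(as.character(membership$protein_id),
                        as.character(membership$term_id)), unique)
  for (t in c(mito_term, apoptosis_term))
    if (is.null(terms[[t]])) terms[[t]] <- character(0)
  structure(list(terms = terms, mito = mito_term, apoptosis = apoptosis_term),
            class = "annotation_sets")
}

#' Fit a normal distribution to log2 ratios
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' finite log2 ratios; non-finite values are dropped. The fit parameterizes
#' the percentile cutoff of the first selection criterion.
#'
#' @param ratios numeric vector of log2 ratios.
#' @return a list `(mu, sigma, n)` of class `normal_fit`.
#' @export
fit_ratio_distribution <- function(ratios) {
  x <- ratios[is.finite(ratios)]
  if (length(x) < 2) stop("need at least 2 finite ratios to fit", call. = FALSE)
  s <- sd(x)
  if (s == 0) stop("degenerate fit: zero variance in ratios", call. = FALSE)
  structure(list(mu = mean(x), sigma = s, n = length(x)), class = "normal_fit")
}

#' First selection criterion: percentile cutoff on log2(STS/CTRL)
#'
#' The cutoff is the `percentile` quantile of the FITTED normal distribution
#' of the log2(STS/CTRL) ratios, `t = mu + z_p * sigma`; proteins with a
#' ratio strictly above the cutoff are selected. Set `method = "empirical"`
#' to use the empirical sample percentile instead of the fitted quantile.
#'
#' @param table ratio table with columns `protein_id, log2_sts_ctrl`.
#' @param fit a `normal_fit` of the log2(STS/CTRL) ratios; computed from the
#'   table when `NULL`.
#' @param percentile percentile of the cutoff (default 90).
#' @param method `"fitted"` (normal quantile, default) or `"empirical"`.
#' @return list `(selected, cutoff)`: selected protein ids and the cutoff
#'   t value used.
#' @export
criterion1_select <- function(table, fit = NULL, percentile = 90,
                              method = c("fitted", "empirical")) {
  method <- match.arg(method)
  .check(.is_num(percentile) && percentile > 0 && percentile < 100,
         "percentile must lie in (0, 100)")
  if (is.null(fit)) fit <- fit_ratio_distribution(table$log2_sts_ctrl)
  .check(inherits(fit, "normal_fit"), "fit must be a normal_fit")
  cutoff <- if (method == "fitted")
    fit$mu + qnorm(percentile / 100) * fit$sigma
  else
    unname(quantile(table$log2_sts_ctrl[is.finite(table$log2_sts_ctrl)],
                    percentile / 100))
  ok <- is.finite(table$log2_sts_ctrl) & table$log2_sts_ctrl > cutoff
  list(selected = table$protein_id[ok], cutoff = cutoff)
}

#' Second selection criterion: reference-ratio window
#'
#' Proteins whose log2(STS/STS) reference ratio lies within the arithmetic
#' mean +/- one sample s.d. of all reference ratios (inclusive bounds) are
#' kept: similar enrichment for both baits indicates shared neighborhood.
#' Missing reference ratios fail the criterion.
#'
#' @param table ratio table with columns `protein_id, log2_sts_ref`.
#' @return list `(selected, mean, sd)`.
#' @export
criterion2_select <- function(table) {
  x <- table$log2_sts_ref
  fit <- fit_ratio_distribution(x)
  ok <- is.finite(x) & abs(x - fit$mu) <= fit$sigma
  list(selected = table$protein_id[ok], mean = fit$mu, sd = fit$sigma)
}

#' Select apoptotic-pore neighborhood candidates (four criteria)
#'
#' Composes the full selection: (1) log2(STS/CTRL) strictly above the
#' fitted-normal percentile cutoff; (2) log2(STS/STS) within mean +/- s.d.;
#' (3) membership in the designated mitochondrial annotation set;
#' (4) membership in the designated apoptosis set. Bait (fusion-construct)
#' proteins are excluded regardless, since their overexpression inflates
#' their ratios.
#'
#' @param table ratio table (`protein_id, log2_sts_ctrl, log2_sts_ref`).
#' @param annotations an [annotation_sets()].
#' @param baits character vector of bait protein ids to exclude.
#' @param percentile,method passed to [criterion1_select()].
#' @return data.frame of class `candidate_report` with per-protein logical
#'   flags `passes_c1, passes_c2, is_mito, is_apoptotic, excluded_as_bait,
#'   is_candidate`; attributes `cutoff` (criterion-1 t value) and
#'   `c2_window` (mean, sd).
#' @export
select_candidates <- function(table, annotations, baits = character(0),
                              percentile = 90,
                              method = c("fitted", "empirical")) {
  .check(inherits(annotations, "annotation_sets"),
         "annotations must be an annotation_sets")
  c1 <- criterion1_select(table, percentile = percentile, method = method)
  c2 <- criterion2_select(table)
  id <- table$protein_id
  rep <- data.frame(
    protein_id = id,
    passes_c1 = id %in% c1$selected,
    passes_c2 = id %in% c2$selected,
    is_mito = id %in% annotations$terms[[annotations$mito]],
    is_apoptotic = id %in% annotations$terms[[annotations$apoptosis]],
    excluded_as_bait = id %in% baits,
    stringsAsFactors = FALSE)
  rep$is_candidate <- rep$passes_c1 & rep$passes_c2 & rep$is_mito &
    rep$is_apoptotic & !rep$excluded_as_bait
  attr(rep, "cutoff") <- c1$cutoff
  attr(rep, "c2_window") <- c(mean = c2$mean, sd = c2$sd)
  class(rep) <- c("candidate_report", "data.frame")
  rep
}

#' Per-construct enriched sets and their intersections (Venn rule)
#'
#' A protein counts as apoptosis-enriched for a construct iff its STS/CTRL
#' ratio on the linear scale is strictly greater than `fold` (equivalently,
#' log2 ratio > log2(fold)); a ratio of exactly `fold` is NOT enriched. With
#' `fold_scale = "log2"` the threshold is applied to the log2 ratio directly
#' (the alternative reading of a "fold increase" stated in log2 units).
#'
#' @param tables named list of ratio tables, one per construct (>= 2).
#' @param fold fold-change threshold (default 1.4).
#' @param fold_scale `"linear"` (ratio > fold, default) or `"log2"`
#'   (log2 ratio > fold).
#' @return list with `sets` (named list of per-construct enriched protein
#'   ids) and `intersections` (named list over all combinations of >= 2
#'   constructs, names joined by `&`).
#' @export
venn_enriched <- function(tables, fold = 1.4,
                          fold_scale = c("linear", "log2")) {
  fold_scale <- match.arg(fold_scale)
  .check(is.list(tables) && length(tables) >= 1 && !is.null(names(tables)),
         "tables must be a named list of ratio tables")
  .check(!any(vapply(tables, function(t) nrow(t) == 0, logical(1))),
         "empty ratio table")
  thr <- if (fold_scale == "linear") log2(fold) else fold
  sets <- lapply(tables, function(t)
    t$protein_id[is.finite(t$log2_sts_ctrl) & t$log2_sts_ctrl > thr])
  inters <- list()
  if (length(sets) >= 2) {
    for (k in 2:length(sets)) {
      for (idx in as.data.frame(combn(length(sets), k))) {
        nm <- paste(names(sets)[idx], collapse = "&")
        inters[[nm]] <- Reduce(intersect, sets[idx])
      }
    }
  }
  list(sets = sets, intersections = inters)
}

# type-7 quantile of a numeric vector (R default); kept as an explicit call
# site so the significance-B scale definition is visible in one place
.sigb_scale <- function(x) {
  q <- quantile(x, c(0.1587, 0.8413), names = FALSE, type = 7)
  (q[2] - q[1]) / 2
}

#' Significance B: intensity-binned robust outlier test for protein ratios
#'
#' Proteins are ordered by summed intensity and grouped into equal-count bins
#' of at least `min_bin_size` (the last bin absorbs the remainder; fewer
#' proteins than `min_bin_size` gives a single bin). Within each bin the
#' ratio distribution is summarized robustly: location = median, scale =
#' (q0.8413 - q0.1587)/2 (half the central ~68% spread, a robust sigma).
#' Each protein's z-score against its own bin yields a two-sided standard
#' normal tail p-value; proteins with p below `alpha` are flagged as
#' differentially regulated.
#'
#' @param table ratio table with columns `protein_id, log2_sts_ctrl,
#'   intensity`.
#' @param min_bin_size minimum proteins per intensity bin (default 300).
#' @param alpha significance threshold for the flag (default 0.01).
#' @return data.frame `protein_id, log2_sts_ctrl, intensity, bin, z, p_sig_b,
#'   significant`, in the input row order.
#' @export
significance_b <- function(table, min_bin_size = 300, alpha = 0.01) {
  .check(all(c("log2_sts_ctrl", "intensity") %in% names(table)),
         "table needs log2_sts_ctrl and intensity columns")
  ratio <- table$log2_sts_ctrl
  .check(all(is.finite(ratio)) && all(is.finite(table$intensity)),
         "ratios and intensities must be finite")
  n <- nrow(table)
  n_bins <- max(1L, n %/% as.integer(min_bin_size))
  ord <- order(table$intensity)
  bin <- integer(n)
  base_size <- n %/% n_bins
  bin[ord] <- pmin(((seq_len(n) - 1L) %/% base_size) + 1L, n_bins)
  z <- numeric(n)
  for (b in seq_len(n_bins)) {
    in_b <- bin == b
    med <- median(ratio[in_b])
    sc <- .sigb_scale(ratio[in_b])
    if (sc <= 0)
      stop(sprintf("degenerate bin %d: zero ratio spread", b), call. = FALSE)
    z[in_b] <- (ratio[in_b] - med) / sc
  }
  p <- 2 * pnorm(-abs(z))
  data.frame(protein_id = table$protein_id, log2_sts_ctrl = ratio,
             intensity = table$intensity, bin = bin, z = z, p_sig_b = p,
             significant = p < alpha, stringsAsFactors = FALSE)
}

#' Hypergeometric term enrichment with Benjamini-Hochberg correction
#'
#' For each annotation term, the upper-tail hypergeometric probability of
#' observing at least `k` term members among the `n` candidates, given `K`
#' term members in a background of `N` proteins (one-sided overrepresentation
#' test, equivalent to one-sided Fisher). BH step-up q-values are computed
#' over all tested terms.
#'
#' @param candidates character vector of candidate protein ids (must be a
#'   subset of `background`).
#' @param annotations an [annotation_sets()].
#' @param background character vector of background protein ids.
#' @param alpha FDR threshold for the `enriched` flag (default 0.05).
#' @return data.frame `term_id, k, n, K, N, p, q, enriched`, ordered by p.
#' @export
hypergeom_enrich <- function(candidates, annotations, background,
                             alpha = 0.05) {
  .check(inherits(annotations, "annotation_sets"),
         "annotations must be an annotation_sets")
  candidates <- unique(candidates)
  background <- unique(background)
  .check(all(candidates %in% background),
         "candidates must be a subset of the background")
  N <- length(background)
  n <- length(candidates)
  res <- lapply(names(annotations$terms), function(t) {
    members <- intersect(annotations$terms[[t]], background)
    K <- length(members)
    k <- length(intersect(members, candidates))
    # P(X >= k), X ~ Hypergeom(N, K, n)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = t, k = k, n = n, K = K, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- p.adjust(out$p, method = "BH")
  out$enriched <- out$q < alpha
  out[order(out$p), , drop = FALSE]
}
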
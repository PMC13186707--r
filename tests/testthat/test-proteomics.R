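test_that("ratio distribution fit uses mean and n-1 sample s.d.", {
  fit <- fit_ratio_distribution(c(0, 2))
  expect_equal(fit$mu, 1)
  expect_equal(fit$sigma, sqrt(2))
  expect_error(fit_ratio_distribution(c(5, 5, 5)), "degenerate")
  expect_error(fit_ratio_distribution(c(1, NA, Inf)), "at least 2")

  # large-sample parameter recovery
  x <- withr::with_seed(99L, rnorm(1e5, 0.3, 0.7))
  fit <- fit_ratio_distribution(x)
  expect_lt(abs(fit$mu - 0.3), 0.01)
  expect_lt(abs(fit$sigma - 0.7), 0.01)
})

test_that("criterion-1 cutoff is the fitted-normal percentile", {
  fit01 <- structure(list(mu = 0, sigma = 1, n = 100L), class = "normal_fit")
  tab <- data.frame(protein_id = "p1", log2_sts_ctrl = 0)
  expect_equal(criterion1_select(tab, fit01)$cutoff, qnorm(0.9),
               tolerance = 1e-12)
  fit2 <- structure(list(mu = 2, sigma = 0.5, n = 100L), class = "normal_fit")
  expect_equal(criterion1_select(tab, fit2)$cutoff, 2 + 0.5 * qnorm(0.9),
               tolerance = 1e-12)

  # every ratio below the cutoff: empty selection, no error
  sel <- criterion1_select(data.frame(protein_id = c("a", "b"),
                                      log2_sts_ctrl = c(-1, 0)), fit01)
  expect_length(sel$selected, 0)

  # strictness: a ratio exactly at the cutoff is not selected
  at <- data.frame(protein_id = "x", log2_sts_ctrl = qnorm(0.9))
  expect_length(criterion1_select(at, fit01)$selected, 0)
})

test_that("criterion-2 window is mean +/- sd with inclusive bounds", {
  tab <- data.frame(protein_id = c("a", "b", "c"),
                    log2_sts_ref = c(-1, 0, 1))
  sel <- criterion2_select(tab)
  expect_setequal(sel$selected, c("a", "b", "c"))

  # a single extreme value excludes itself only
  tab2 <- data.frame(protein_id = letters[1:6],
                     log2_sts_ref = c(-0.1, 0, 0.1, 0.05, -0.05, 8))
  sel2 <- criterion2_select(tab2)
  inside <- abs(tab2$log2_sts_ref - mean(tab2$log2_sts_ref)) <=
    sd(tab2$log2_sts_ref)
  expect_setequal(sel2$selected, tab2$protein_id[inside])
  expect_false("f" %in% sel2$selected)
})

test_that("central-mass pass fraction of criterion 2 approaches 68.27%", {
  tab <- data.frame(protein_id = as.character(1:1e5),
                    log2_sts_ref = withr::with_seed(5L, rnorm(1e5, 2, 3)))
  frac <- length(criterion2_select(tab)$selected) / nrow(tab)
  expect_lt(abs(frac - 0.6827), 0.01)
})

test_that("candidate selection composes the four criteria and bait exclusion", {
  tab <- data.frame(
    protein_id = c("hit", "notmito", "notapo", "bait", "low"),
    log2_sts_ctrl = c(5, 5, 5, 5, 0),
    log2_sts_ref = c(0, 0, 0, 0, 0),
    intensity = 1e6)
  # spread of ratios so the fit is not degenerate
  tab <- rbind(tab, data.frame(
    protein_id = sprintf("bg%02d", 1:20),
    log2_sts_ctrl = withr::with_seed(1L, rnorm(20, 0, 0.5)),
    log2_sts_ref = withr::with_seed(2L, rnorm(20, 0, 0.5)),
    intensity = 1e6))
  ann <- annotation_sets(data.frame(
    term_id = c(rep("CC:mitochondrion", 3), rep("BP:apoptotic_process", 3)),
    term_class = rep(c("CC", "BP"), each = 3),
    protein_id = c("hit", "notapo", "bait", "hit", "notmito", "bait")))
  rep <- select_candidates(tab, ann, baits = "bait")
  get <- function(id, col) rep[rep$protein_id == id, col]
  expect_true(get("hit", "is_candidate"))
  expect_false(get("notmito", "is_candidate"))
  expect_false(get("notapo", "is_candidate"))
  expect_true(get("bait", "excluded_as_bait"))
  expect_false(get("bait", "is_candidate"))
  expect_false(get("low", "passes_c1"))

  # the report flags must agree with an independent recomputation
  cutoff <- attr(rep, "cutoff")
  expect_equal(rep$passes_c1, tab$log2_sts_ctrl > cutoff)
  w <- attr(rep, "c2_window")
  expect_equal(rep$passes_c2, abs(tab$log2_sts_ref - w["mean"]) <= w["sd"],
               ignore_attr = TRUE)
})

test_that("spike recovery is strong at 3-sigma shifts and monotone in shift", {
  recovered <- vapply(c(0.5, 1.5, 3), function(shift) {
    sim <- gen_ratio_table(ratio_sim_spec(
      n_proteins = 1000L, n_spiked = 20L, spike_shift = shift,
      base_sigma = 1, annotation_rates = list(mito = c(0.2, 1),
                                              apoptosis = c(0.1, 1)),
      seed = 31L))
    rep <- select_candidates(sim$table, annotation_sets(sim$annotations))
    sum(rep$is_candidate & sim$truth$spiked)
  }, numeric(1))
  expect_true(all(diff(recovered) >= 0))
  expect_gte(recovered[3], 18)
})

test_that("venn enrichment uses a strict >1.4-fold rule and set algebra", {
  tab_at <- data.frame(protein_id = "p", log2_sts_ctrl = log2(1.4))
  expect_length(venn_enriched(list(a = tab_at))$sets$a, 0)
  tab_above <- data.frame(protein_id = "p", log2_sts_ctrl = log2(1.401))
  expect_equal(venn_enriched(list(a = tab_above))$sets$a, "p")

  # identical tables: the intersection equals either set
  tt <- data.frame(protein_id = c("A", "B", "C"),
                   log2_sts_ctrl = c(2, 1, 0))
  v <- venn_enriched(list(x = tt, y = tt))
  expect_setequal(v$intersections[["x&y"]], v$sets$x)

  # constructed sets {A,B}, {B,C}, {B}: triple intersection {B}
  mk <- function(ids) data.frame(protein_id = ids, log2_sts_ctrl = 2)
  v3 <- venn_enriched(list(p = mk(c("A", "B")), q = mk(c("B", "C")),
                           r = mk("B")))
  expect_equal(v3$intersections[["p&q&r"]], "B")

  # log2-scale reading of the threshold
  vl <- venn_enriched(list(a = data.frame(protein_id = "p",
                                          log2_sts_ctrl = 1.5)),
                      fold = 1.4, fold_scale = "log2")
  expect_equal(vl$sets$a, "p")
})

test_that("significance B matches the brute-force quantile oracle", {
  ratios <- withr::with_seed(13L, rnorm(10, 0, 1.3))
  tab <- data.frame(protein_id = letters[1:10], log2_sts_ctrl = ratios,
                    intensity = withr::with_seed(14L, 10^runif(10, 5, 9)))
  res <- significance_b(tab, min_bin_size = 300)
  expect_true(all(res$bin == 1L))
  expect_equal(res$p_sig_b, sigb_oracle_single_bin(ratios), tolerance = 1e-12)

  # a ratio at its bin median has p = 1 (odd-sized bin)
  tab_odd <- data.frame(protein_id = letters[1:9],
                        log2_sts_ctrl = c(-4, -3, -2, -1, 0, 1, 2, 3, 4),
                        intensity = 1:9)
  res_odd <- significance_b(tab_odd)
  expect_equal(res_odd$p_sig_b[res_odd$log2_sts_ctrl == 0], 1)

  # z = 2.576 sits at p ~ 0.01
  expect_equal(2 * pnorm(-2.576), 0.01, tolerance = 1e-3)
  expect_error(significance_b(data.frame(protein_id = 1:5,
                                         log2_sts_ctrl = rep(1, 5),
                                         intensity = 1:5)), "degenerate")
})

test_that("significance B bins by intensity with the remainder in the last bin", {
  n <- 25L
  tab <- data.frame(protein_id = as.character(1:n),
                    log2_sts_ctrl = withr::with_seed(3L, rnorm(n)),
                    intensity = withr::with_seed(4L, runif(n)))
  res <- significance_b(tab, min_bin_size = 10)
  expect_equal(sort(unique(res$bin)), 1:2)
  # two equal-count bins of >= 10; the last absorbs the odd protein
  expect_equal(sum(res$bin == 1), 12L)
  expect_equal(sum(res$bin == 2), 13L)
  expect_true(max(res$intensity[res$bin == 1]) <=
                min(res$intensity[res$bin == 2]))
  # within each bin, p-values match the oracle
  for (b in 1:2) {
    sel <- res$bin == b
    expect_equal(res$p_sig_b[sel],
                 sigb_oracle_single_bin(res$log2_sts_ctrl[sel]),
                 tolerance = 1e-12)
  }
})

test_that("hypergeometric enrichment matches exact combinatorics and BH", {
  bg <- sprintf("g%02d", 1:10)
  ann <- annotation_sets(
    data.frame(term_id = c(rep("CC:mitochondrion", 5), rep("all", 10)),
               term_class = "CC", protein_id = c(bg[1:5], bg)))
  res <- hypergeom_enrich(bg[1:5], ann, bg)
  # all 5 candidates inside a 5-member term in a background of 10: 1/C(10,5)
  expect_equal(res$p[res$term_id == "CC:mitochondrion"], 1 / choose(10, 5),
               tolerance = 1e-12)
  # a term equal to the background is never enriched: p = 1
  expect_equal(res$p[res$term_id == "all"], 1)
  expect_error(hypergeom_enrich(c(bg[1], "absent"), ann, bg), "subset")
})

test_that("BH q-values follow the step-up oracle and are monotone in rank", {
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p <- withr::with_seed(21L, runif(40)^2)
  expect_equal(p.adjust(p, "BH"), bh_oracle(p), tolerance = 1e-12)
  q <- p.adjust(p, "BH")
  expect_true(all(diff(q[order(p)]) >= 0))
  expect_true(all(q > 0 & q <= 1))
})
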
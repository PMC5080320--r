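test_that("score_from_pvalue follows the sign conventions", {
  expect_equal(score_from_pvalue(1, 5), 0)
  expect_equal(score_from_pvalue(0.01, 5), 2)
  expect_equal(score_from_pvalue(0.01, 0.2), -2)
  expect_equal(score_from_pvalue(0.01, 1), 0)
  expect_equal(score_from_pvalue(0.01, 5, convention = "phast"), -2)
  expect_warning(s <- score_from_pvalue(0, 5), "capped")
  expect_equal(s, 308)
  expect_error(score_from_pvalue(1.5, 1), "0, 1")
})

test_that("bonferroni_alpha reproduces the reported thresholds", {
  expect_equal(signif(bonferroni_alpha(0.05, 942411), 2), 5.3e-8)
  expect_equal(signif(bonferroni_alpha(0.05, 647478), 2), 7.7e-8)
  expect_equal(signif(bonferroni_alpha(0.05, 1236027), 2), 4.0e-8)
})

test_that("overlap_table partitions the site universe", {
  mk <- function(p) data.frame(family_id = "f", column = seq_along(p),
                               pvalue = p)
  s <- mk(c(0.01, 0.5, 0.9, 0.7))
  i <- mk(c(0.9, 0.01, 0.8, 0.6))
  ov <- overlap_table(s, i, 0.05)
  expect_equal(ov["significant", "significant"], 0L, ignore_attr = TRUE)
  expect_equal(ov["significant", "not"], 1L, ignore_attr = TRUE)
  expect_equal(ov["not", "significant"], 1L, ignore_attr = TRUE)
  expect_equal(sum(ov), 4L)
  expect_error(overlap_table(s, mk(c(0.1, 0.1)), 0.05), "universe")
})

test_that("normalize_family_scores is a linear, idempotent per-family map", {
  sc <- data.frame(family_id = c("a", "a", "a", "b", "z"),
                   score = c(0, -10, 25, 4, 0))
  out <- normalize_family_scores(sc, 50)
  expect_equal(out$score, c(0, -20, 50, 50, 0))
  expect_equal(normalize_family_scores(out, 50)$score, out$score)
})

test_that("indel LRT: degenerate columns, acceleration fixture, gap topology", {
  m <- default_indel_model()
  tr <- benchmark_tree()
  di <- m$mu / m$lambda

  # gapless column: rho below 1 (a residue column mildly prefers slower
  # indel rates -- as conserved as a site can be) and non-significant
  col <- stats::setNames(rep("A", 10), tr$tip.label)
  s <- site_lrt_indel(col, m, tr, di)
  expect_lte(s$scale, 1)
  expect_gt(s$pvalue, 0.3)
  expect_lte(s$score, 0)
  expect_gt(s$score, -1)
  expect_true(s$lnl_alt >= s$lnl_null)

  # scattered gaps across unrelated clades: strong acceleration signal
  scattered <- stats::setNames(c("-", "A", "A", "-", "A", "-", "A", "A", "-",
                                 "A"), tr$tip.label)
  s_sc <- site_lrt_indel(scattered, m, tr, di)
  expect_gt(s_sc$scale, 1)
  expect_lt(s_sc$pvalue, 0.01)
  expect_gt(s_sc$score, 0)

  # same number of gaps concentrated in one clade: phylogenetic clustering
  # is explainable by a single event, hence the larger p-value
  clustered <- stats::setNames(c("-", "-", "-", "-", "A", "A", "A", "A", "A",
                                 "A"), tr$tip.label)
  s_cl <- site_lrt_indel(clustered, m, tr, di)
  expect_gt(s_cl$pvalue, s_sc$pvalue)

  # a zero LRT statistic maps to p = 1 and score 0: score a column under a
  # null whose indel-free alternative cannot improve on it
  m0 <- indel_model(0, 0, m$f84, m$p)
  s0 <- site_lrt_indel(col, m0, tr, di)
  expect_equal(s0$pvalue, 1)
  expect_equal(s0$score, 0)
})

test_that("subst LRT: acceleration fixture and zero-statistic case", {
  pi <- c(0.25, 0.25, 0.25, 0.25)
  f84 <- f84_params(0.5, 0.5, pi)
  tr <- benchmark_tree()
  tr$edge.length <- tr$edge.length / 5   # short branches
  every_diff <- stats::setNames(c("A", "C", "G", "T", "A", "C", "G", "T",
                                  "A", "C"), tr$tip.label)
  s <- site_lrt_subst(every_diff, f84, tr)
  expect_gt(s$scale, 1)
  expect_lt(s$pvalue, 0.01)
  expect_gt(s$score, 0)

  # constant column on the same tree: conserved direction
  cons <- stats::setNames(rep("G", 10), benchmark_tree()$tip.label)
  s2 <- site_lrt_subst(cons, f84, benchmark_tree())
  expect_lt(s2$scale, 1)
  expect_lte(s2$score, 0)
})

test_that("null simulations are calibrated for both tests", {
  m <- default_indel_model()
  tr <- benchmark_tree()
  di <- m$mu / m$lambda
  sim <- simulate_family(tr, m, 1200, seed = 91)
  sc_i <- indel_rate_test(sim$alignment, tr, m, di)
  expect_lte(mean(sc_i$pvalue < 0.05), 0.07)
  expect_false(any(!is.finite(sc_i$score)))

  # substitution test on gapless data simulated under its own null, on the
  # primate-scale tree (the deep benchmark tree is a known anticonservative
  # regime for single-column chi-squared tests; see the methods vignette)
  f84 <- f84_params(0.513467, 0.486533, c(0.254698, 0.260464, 0.263575,
                                          0.221263))
  m0 <- indel_model(0, 0, f84, 0.998)
  sim0 <- simulate_family(primate_tree(), m0, 2000, seed = 92)
  sc_s <- subst_rate_test(sim0$alignment, primate_tree(), f84)
  expect_lte(mean(sc_s$pvalue < 0.05), 0.07)

  # independence: indel-only acceleration leaves the subst test null
  macc <- apply_indel_scaling(m, scale_context(8, di))
  sim_acc <- simulate_family(tr, macc, 800, seed = 93)
  sc_cross <- subst_rate_test(sim_acc$alignment, tr, f84)
  expect_lte(mean(sc_cross$pvalue < 0.01), 0.03)
})
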
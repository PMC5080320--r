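# Per-column likelihood-ratio tests.
#
# Substitution test (phyloP analogue): F84 vs F84 + rho, where rho scales
# every branch length; properly nested, 1 d.f.
#
# Indel test (indelP): F84e-relaxed vs F84e-relaxed + rho_indel, where
# rho_indel scales mu directly and lambda weighted by the deletion/insertion
# length ratio.  Because of the D/I weighting the alternative family does
# not pass exactly through the null point, so the LRT statistic is clamped
# at zero and the test is conservative.  Column likelihoods use the plain
# per-column form (length-prior weight only; no termination or observability
# terms).
#
# rho is optimized on a log10 grid shared across all columns (vectorized
# pruning), then refined per bracket group by two rounds of local grids;
# final resolution ~0.005 in log10(rho), far below the curvature scale of
# any column's likelihood.

DEFAULT_RHO_GRID <- 10^seq(-6, 4, length.out = 41)

# Generic vectorized 1-D scale scan.
# ll_fun(rho, idx) must return the column log-likelihoods for columns idx.
# Columns sharing a bracket are refined together so every likelihood
# evaluation stays vectorized over columns.
scan_scales <- function(ncols, ll_fun, grid = DEFAULT_RHO_GRID,
                        refine_rounds = 2L, refine_points = 7L) {
  lg <- log10(grid)
  best_ll <- rep(-Inf, ncols)
  best_i <- rep(1L, ncols)
  for (i in seq_along(grid)) {
    v <- ll_fun(grid[i], seq_len(ncols))
    upd <- v > best_ll
    best_ll[upd] <- v[upd]
    best_i[upd] <- i
  }
  best_lrho <- lg[best_i]
  interior <- best_i > 1L & best_i < length(grid)
  lo <- ifelse(interior, lg[pmax(best_i - 1L, 1L)], NA_real_)
  hi <- ifelse(interior, lg[pmin(best_i + 1L, length(grid))], NA_real_)
  for (round in seq_len(refine_rounds)) {
    todo <- which(!is.na(lo))
    if (length(todo) == 0) break
    groups <- split(todo, paste(lo[todo], hi[todo]))
    for (g in groups) {
      glo <- lo[g[1]]
      ghi <- hi[g[1]]
      cand <- seq(glo, ghi,
                  length.out = refine_points + 2L)[-c(1L, refine_points + 2L)]
      sub <- matrix(NA_real_, length(cand), length(g))
      for (ci in seq_along(cand)) sub[ci, ] <- ll_fun(10^cand[ci], g)
      mx <- max.col(t(sub), ties.method = "first")
      val <- sub[cbind(mx, seq_along(g))]
      better <- val > best_ll[g]
      best_ll[g[better]] <- val[better]
      best_lrho[g[better]] <- cand[mx[better]]
      step <- (ghi - glo) / (refine_points + 1L)
      lo[g] <- pmax(glo, best_lrho[g] - step)
      hi[g] <- pmin(ghi, best_lrho[g] + step)
    }
  }
  list(lnl_alt = best_ll, rho = 10^best_lrho)
}

assemble_site_scores <- function(family_id, columns, test, lnl_null, lnl_alt,
                                 rho, convention = "figure") {
  lnl_alt <- pmax(lnl_alt, lnl_null)  # clamp: conservative LRT
  stat <- 2 * (lnl_alt - lnl_null)
  pval <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  score <- score_from_pvalue(pval, rho, convention = convention)
  data.frame(family_id = family_id, column = columns, test = test,
             lnl_null = lnl_null, lnl_alt = lnl_alt, scale = rho,
             pvalue = pval, score = score, stringsAsFactors = FALSE)
}

#' Per-column indel-rate LRT over an alignment (indelP)
#'
#' For every column, the null F84e-relaxed model is compared against the
#' alternative in which the indel rates are scaled by a free per-column
#' `rho_indel` (insertions additionally weighted by `di_ratio`), optimized
#' over `[1e-6, 1e4]` on a log grid with local refinement.  The LRT
#' statistic is clamped at zero and referred to chi-squared with 1 d.f.
#'
#' @param aln an `indel_alignment`.
#' @param tree the family's `phylo` tree.
#' @param null_model the globally fitted [indel_model()].
#' @param di_ratio deletion/insertion total-length ratio from
#'   [count_indel_events()] (falls back to 1 with a warning upstream when
#'   no insertions were inferred).
#' @param columns integer vector of 1-based column indices (default all).
#' @param convention score sign convention, `"figure"` (acceleration
#'   positive) or `"phast"` (flipped); see [score_from_pvalue()].
#' @return a `data.frame` of site scores with columns `family_id, column,
#'   test, lnl_null, lnl_alt, scale, pvalue, score`.
#' @export
indel_rate_test <- function(aln, tree, null_model, di_ratio = 1,
                            columns = NULL, convention = "figure") {
  stopifnot(inherits(null_model, "indel_model"))
  ti <- tree_index(tree)
  codes <- aln$codes[match(ti$tip_label, rownames(aln$codes)), , drop = FALSE]
  if (anyNA(codes)) stop("alignment and tree leaves do not match")
  if (is.null(columns)) columns <- seq_len(ncol(codes))
  codes <- codes[, columns, drop = FALSE]
  tips <- make_tip_partials(ti, codes, 5L)
  lnl_null <- col_logliks(ti, codes, null_model, tips = tips)
  ll_fun <- function(rho, idx) {
    m <- apply_indel_scaling(null_model, scale_context(rho, di_ratio))
    tt <- if (length(idx) == ncol(codes)) tips
          else lapply(tips, function(x) x[, idx, drop = FALSE])
    col_logliks(ti, codes[, idx, drop = FALSE], m, tips = tt)
  }
  sc <- scan_scales(ncol(codes), ll_fun)
  assemble_site_scores(aln$family_id, columns, "indel", lnl_null,
                       sc$lnl_alt, sc$rho, convention)
}

#' Per-column substitution-rate LRT over an alignment (phyloP analogue)
#'
#' F84 (gaps as missing data) against F84 with every branch length scaled by
#' a free per-column `rho`; properly nested, chi-squared with 1 d.f.
#'
#' @param aln an `indel_alignment`.
#' @param tree the family's `phylo` tree.
#' @param null_model the globally fitted [f84_params()].
#' @inheritParams indel_rate_test
#' @return a `data.frame` of site scores (`test = "subst"`).
#' @export
subst_rate_test <- function(aln, tree, null_model, columns = NULL,
                            convention = "figure") {
  stopifnot(inherits(null_model, "f84_params"))
  ti <- tree_index(tree)
  codes <- aln$codes[match(ti$tip_label, rownames(aln$codes)), , drop = FALSE]
  if (anyNA(codes)) stop("alignment and tree leaves do not match")
  if (is.null(columns)) columns <- seq_len(ncol(codes))
  codes <- codes[, columns, drop = FALSE]
  tips <- make_tip_partials(ti, codes, 4L)
  ll_fun <- function(rho, idx) {
    P <- branch_matrices(ti, null_model, rho_branch = rho)
    tt <- if (length(idx) == ncol(codes)) tips
          else lapply(tips, function(x) x[, idx, drop = FALSE])
    col_logliks(ti, codes[, idx, drop = FALSE], null_model, P, tips = tt)
  }
  lnl_null <- ll_fun(1, seq_len(ncol(codes)))
  sc <- scan_scales(ncol(codes), ll_fun)
  assemble_site_scores(aln$family_id, columns, "subst", lnl_null,
                       sc$lnl_alt, sc$rho, convention)
}

#' Indel-rate LRT for a single column
#'
#' @param column named character vector of leaf symbols.
#' @param null_indel_model the globally fitted [indel_model()].
#' @param tree the family's `phylo` tree.
#' @param di_ratio deletion/insertion length ratio.
#' @param ... passed to [indel_rate_test()].
#' @return one-row site-score `data.frame`.
#' @export
site_lrt_indel <- function(column, null_indel_model, tree, di_ratio = 1, ...) {
  aln <- new_alignment(matrix(column, ncol = 1,
                              dimnames = list(names(column), NULL)),
                       family_id = "column")
  indel_rate_test(aln, tree, null_indel_model, di_ratio, ...)
}

#' Substitution-rate LRT for a single column
#'
#' @param column named character vector of leaf symbols.
#' @param null_f84_model the globally fitted [f84_params()].
#' @param tree the family's `phylo` tree.
#' @param ... passed to [subst_rate_test()].
#' @return one-row site-score `data.frame`.
#' @export
site_lrt_subst <- function(column, null_f84_model, tree, ...) {
  aln <- new_alignment(matrix(column, ncol = 1,
                              dimnames = list(names(column), NULL)),
                       family_id = "column")
  subst_rate_test(aln, tree, null_f84_model, ...)
}

#' Signed score from an LRT p-value
#'
#' Default (`"figure"`) convention: acceleration (scale > 1) maps to
#' `-log10(p)` (positive), conservation (scale < 1) to `log10(p)`
#' (negative), scale = 1 to 0.  The `"phast"` convention flips the sign
#' (conserved positive).
#'
#' @param p p-value(s) in (0, 1].
#' @param scale_estimate fitted scale(s), same length as `p` (or scalar).
#' @param convention `"figure"` or `"phast"`.
#' @return signed score(s); `p = 0` is capped at +-308 with a warning.
#' @export
score_from_pvalue <- function(p, scale_estimate,
                              convention = c("figure", "phast")) {
  convention <- match.arg(convention)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  lp <- log10(p)
  if (any(p == 0)) {
    warning("p-value of 0 capped at score magnitude 308")
    lp[p == 0] <- -308
  }
  sgn <- sign(scale_estimate - 1)     # +1 acceleration, -1 conservation
  score <- -sgn * lp                   # acceleration positive
  score[sgn == 0] <- 0
  if (convention == "phast") score <- -score
  score
}

#' Bonferroni per-site threshold
#' @param family_wise_alpha family-wise error level (e.g. 0.05).
#' @param total_sites number of tested columns (>= 1).
#' @return per-site significance threshold.
#' @export
bonferroni_alpha <- function(family_wise_alpha, total_sites) {
  stopifnot(total_sites >= 1)
  family_wise_alpha / total_sites
}

#' Overlap between indel-significant and substitution-significant sites
#'
#' @param subst_scores,indel_scores site-score data frames over the same
#'   site universe (matched on `family_id` and `column`).
#' @param alpha significance threshold applied to both tests.
#' @return 2x2 integer matrix of counts (rows: indel significant yes/no,
#'   columns: substitution significant yes/no).
#' @export
overlap_table <- function(subst_scores, indel_scores, alpha) {
  ks <- paste(subst_scores$family_id, subst_scores$column)
  ki <- paste(indel_scores$family_id, indel_scores$column)
  if (length(ks) != length(ki) || !setequal(ks, ki)) {
    stop("score tables cover different site universes")
  }
  sig_s <- subst_scores$pvalue[match(ki, ks)] < alpha
  sig_i <- indel_scores$pvalue < alpha
  out <- matrix(c(sum(sig_i & sig_s), sum(sig_i & !sig_s),
                  sum(!sig_i & sig_s), sum(!sig_i & !sig_s)),
                2, 2, byrow = FALSE,
                dimnames = list(indel = c("significant", "not"),
                                subst = c("significant", "not")))
  out
}

#' Rescale scores within each family to a symmetric display range
#'
#' Per family, scores are linearly scaled so the largest absolute score maps
#' to `bound`; zero stays zero; all-zero families are unchanged.  Applying
#' the map twice is a no-op.
#'
#' @param scores a site-score `data.frame` (needs `family_id` and `score`).
#' @param bound positive half-range (default 50).
#' @return the data frame with `score` rescaled.
#' @export
normalize_family_scores <- function(scores, bound = 50) {
  stopifnot(bound > 0)
  for (fam in unique(scores$family_id)) {
    idx <- scores$family_id == fam
    m <- max(abs(scores$score[idx]))
    if (m > 0) scores$score[idx] <- scores$score[idx] * bound / m
  }
  scores
}
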
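# Maximum-likelihood estimation over a multi-family alignment set.
#
# Free parameters per model kind (background frequencies are fixed at their
# empirical values, branch lengths are taken from the input trees and never
# re-estimated):
#   F84           alpha, beta
#   F84E_RELAXED  alpha, beta, lambda, mu   (p handled separately, see below)
#   HKYG          kappa, sigma
#
# The geometric length parameter p is fixed at its closed-form estimate
# given the mean alignment length, p = L/(L+1), then profiled once on cached
# root-partial components (p enters the likelihood only through the root
# prior and the per-alignment terms, so the profile is exact and cheap); if
# the profile moves p materially the rates are refitted once.
#
# Optimizer: Nelder-Mead on log-parameters with box bounds enforced inside
# the objective, restarted from deterministically perturbed initial points.

PARAM_BOUNDS <- list(
  alpha = c(1e-6, 100), beta = c(1e-6, 100),
  lambda = c(1e-8, 10), mu = c(1e-8, 10),
  kappa = c(1e-6, 100), sigma = c(1e-8, 100)
)

FREE_PARAMS <- list(
  F84 = c("alpha", "beta"),
  F84E_RELAXED = c("alpha", "beta", "lambda", "mu"),
  HKYG = c("kappa", "sigma")
)

DEFAULT_INIT <- c(alpha = 0.5, beta = 0.5, lambda = 0.01, mu = 0.05,
                  kappa = 2, sigma = 0.05)

#' Empirical symbol frequencies of an alignment set
#'
#' @param aset an [alignment_set()].
#' @param include_gap if `TRUE`, return frequencies over A,C,G,T,- ; else
#'   over the four residues.  Unknown symbols (`N`) are excluded either way.
#' @return named frequency vector summing to 1.
#' @export
empirical_frequencies <- function(aset, include_gap = FALSE) {
  if (length(aset) == 0) stop("empty alignment set")
  counts <- numeric(5)
  for (p in aset) {
    tab <- tabulate(p$alignment$codes, nbins = 6L)
    counts <- counts + tab[1:5]
  }
  if (!include_gap) counts <- counts[1:4]
  freq <- counts / sum(counts)
  names(freq) <- ALPHA5[seq_along(freq)]
  freq
}

build_model_from_params <- function(kind, par, pi, pi5, p) {
  switch(kind,
    F84 = f84_params(par[["alpha"]], par[["beta"]], pi),
    F84E_RELAXED = indel_model(par[["lambda"]], par[["mu"]],
                               f84_params(par[["alpha"]], par[["beta"]], pi),
                               p),
    HKYG = hkyg_params(par[["kappa"]], par[["sigma"]], pi5),
    stop("unknown model kind: ", kind))
}

#' Fit a model to a multi-family alignment set by maximum likelihood
#'
#' @param aset an [alignment_set()].
#' @param model_kind one of `"F84"`, `"F84E_RELAXED"`, `"HKYG"`.
#' @param fixed named list pinning parameters (e.g. `list(lambda = 0,
#'   mu = 0)`); pinned values bypass the optimizer bounds.
#' @param init named numeric vector of starting values for the free
#'   parameters (defaults chosen per kind).
#' @param options list: `restarts` (default 3), `reltol` (1e-8), `maxit`
#'   (500 per restart), `profile_p` (TRUE; F84E only).
#' @return object of class `ip_fit`: list with `model` (fitted model
#'   object), `kind`, `loglik`, `converged`, `evals`, `restart_logliks`,
#'   `frequencies`, `p`, `n_alignments`, `total_sites`.
#' @export
fit_model <- function(aset, model_kind = c("F84", "F84E_RELAXED", "HKYG"),
                      fixed = list(), init = NULL, options = list()) {
  model_kind <- match.arg(model_kind)
  opts <- utils::modifyList(list(restarts = 3L, reltol = 1e-8, maxit = 500L,
                                 profile_p = FALSE), options)
  prep <- prepare_dataset(aset)
  pi <- empirical_frequencies(aset, include_gap = FALSE)
  pi5 <- empirical_frequencies(aset, include_gap = TRUE)
  Lbar <- mean(vapply(aset, function(p) n_sites(p$alignment), 0L))
  p_len <- if (!is.null(fixed$p)) fixed$p else Lbar / (Lbar + 1)

  free <- setdiff(FREE_PARAMS[[model_kind]], names(fixed))
  fixed_vals <- unlist(fixed[setdiff(names(fixed), "p")])
  mode <- if (model_kind == "F84E_RELAXED") "fit" else "site_test"
  n_evals <- 0L

  assemble <- function(theta, p_cur) {
    par <- exp(theta)
    lo <- vapply(free, function(nm) PARAM_BOUNDS[[nm]][1], 0)
    hi <- vapply(free, function(nm) PARAM_BOUNDS[[nm]][2], 0)
    par <- pmin(pmax(par, lo), hi)
    names(par) <- free
    build_model_from_params(model_kind, c(par, fixed_vals), pi, pi5, p_cur)
  }
  objective <- function(theta, p_cur) {
    n_evals <<- n_evals + 1L
    ll <- tryCatch(dataset_loglik_prepared(prep, assemble(theta, p_cur), mode),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  run_fit <- function(p_cur, theta0) {
    if (length(free) == 0) {
      return(list(theta = theta0, value = objective(theta0, p_cur),
                  converged = TRUE))
    }
    if (length(free) == 1) {
      b <- PARAM_BOUNDS[[free]]
      o <- stats::optimize(function(th) objective(th, p_cur),
                           interval = log(b), tol = 1e-10)
      return(list(theta = o$minimum, value = o$objective, converged = TRUE))
    }
    # deterministic perturbations for the restarts
    offsets <- rbind(0, 0.7 * diag(length(free)),
                     -0.7 * diag(length(free)))[seq_len(opts$restarts + 1L), ,
                                               drop = FALSE]
    best <- NULL
    vals <- numeric(0)
    for (r in seq_len(nrow(offsets))) {
      o <- stats::optim(theta0 + offsets[r, ], objective, p_cur = p_cur,
                        method = "Nelder-Mead",
                        control = list(reltol = opts$reltol,
                                       maxit = opts$maxit))
      vals <- c(vals, -o$value)
      if (is.null(best) || o$value < best$value) {
        best <- o
      }
    }
    # polish from the incumbent: Nelder-Mead restarts can stall on a
    # shrunken simplex
    o <- stats::optim(best$par, objective, p_cur = p_cur,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = opts$maxit))
    if (o$value < best$value) best <- o
    list(theta = best$par, value = best$value,
         converged = best$convergence == 0, restart_logliks = vals)
  }

  init_vec <- DEFAULT_INIT[free]
  if (!is.null(init)) init_vec[names(init)] <- unlist(init)[names(init)]
  theta0 <- log(pmax(init_vec, 1e-8))

  fit <- run_fit(p_len, theta0)
  p_final <- p_len
  if (model_kind == "F84E_RELAXED" && opts$profile_p && is.null(fixed$p)) {
    model_hat <- assemble(fit$theta, p_len)
    p_prof <- profile_p(prep, model_hat)
    if (abs(p_prof - p_len) / (1 - p_len) > 0.01) {
      fit2 <- run_fit(p_prof, fit$theta)
      if (fit2$value < fit$value) fit <- fit2
      p_final <- p_prof
    } else {
      p_final <- p_prof
    }
  }
  model_hat <- assemble(fit$theta, p_final)
  ll_final <- dataset_loglik_prepared(prep, model_hat, mode)
  structure(list(model = model_hat, kind = model_kind,
                 loglik = ll_final, converged = isTRUE(fit$converged),
                 evals = n_evals,
                 restart_logliks = fit$restart_logliks,
                 frequencies = list(pi = pi, pi5 = pi5),
                 p = if (model_kind == "F84E_RELAXED") p_final else NA_real_,
                 n_alignments = length(aset),
                 total_sites = prep$total_sites),
            class = "ip_fit")
}

#' @export
print.ip_fit <- function(x, ...) {
  cat("<ip_fit>", x$kind, "logLik", format(x$loglik),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  m <- x$model
  pars <- switch(x$kind,
    F84 = c(alpha = m$alpha, beta = m$beta),
    F84E_RELAXED = c(alpha = m$f84$alpha, beta = m$f84$beta,
                     lambda = m$lambda, mu = m$mu, p = m$p),
    HKYG = c(kappa = m$kappa, sigma = m$sigma))
  print(signif(pars, 6))
  invisible(x)
}

# Exact 1-D profile of the geometric length parameter p.  The root partials
# do not depend on p, so per column we cache A = sum_a pi_a partial(root,a)
# and B = partial(root,-) and maximize
#   sum_cols w [log(p A + (1-p) B) + ls] + n_aln log(1-p)
#   - sum_aln n_cols log(1 - (p A* + (1-p) B*))
profile_p <- function(prep, model) {
  parts <- lapply(prep$groups, function(g) {
    P <- branch_matrices(g$ti, model)
    res <- prune_columns_prepared(g$ti, g$codes, model, P)
    pi <- model$f84$pi
    A <- as.vector(pi %*% res$partials[1:4, , drop = FALSE])
    B <- res$partials[5, ]
    sc <- exp(res$log_scale)
    gap_codes <- matrix(GAP_CODE, nrow = g$ti$ntip, ncol = 1)
    res_inv <- prune_columns_prepared(g$ti, gap_codes, model, P)
    A_inv <- sum(pi * res_inv$partials[1:4, 1]) * exp(res_inv$log_scale[1])
    B_inv <- res_inv$partials[5, 1] * exp(res_inv$log_scale[1])
    list(A = A * sc, B = B * sc, w = g$weights,
         n_sites = sum(g$n_cols), n_aln = g$n_alignments,
         A_inv = A_inv, B_inv = B_inv)
  })
  negll <- function(p) {
    ll <- 0
    for (z in parts) {
      v <- p * z$A + (1 - p) * z$B
      if (any(v <= 0)) return(1e10)
      p_inv <- p * z$A_inv + (1 - p) * z$B_inv
      ll <- ll + sum(z$w * log(v)) + z$n_aln * log(1 - p) -
        z$n_sites * log(1 - p_inv)
    }
    -ll
  }
  stats::optimize(negll, interval = c(0.5, 1 - 1e-9), tol = 1e-10)$minimum
}

#' Branch-length normalization and midpoint rerooting compatibility options
#'
#' Mirrors the preprocessing another F84-with-gaps implementation applies
#' before likelihood computation: optionally divide every branch length by
#' the expected F84 substitution rate at stationarity computed from the
#' background frequencies, and optionally reroot the tree at the midpoint of
#' the longest leaf-to-leaf path.  Both transforms are off by default.
#'
#' @param tree a `phylo` tree.
#' @param f84 an [f84_params()] supplying the frequencies and rates for the
#'   normalizing constant (required when `normalize_branches = TRUE`).
#' @param normalize_branches divide branch lengths by
#'   `sum_i pi_i * (-q_ii)` of the F84 rate matrix.
#' @param midpoint_reroot reroot at the midpoint of the longest path.
#' @return the transformed tree.
#' @export
dnaml_compat_transform <- function(tree, f84 = NULL,
                                   normalize_branches = FALSE,
                                   midpoint_reroot = FALSE) {
  if (normalize_branches) {
    stopifnot(inherits(f84, "f84_params"))
    Q <- build_f84_rate_matrix(f84)
    rate <- sum(f84$pi * (-diag(Q)))
    tree$edge.length <- tree$edge.length / rate
  }
  if (midpoint_reroot) {
    tree <- phangorn::midpoint(tree)
    tree <- validate_tree(tree)
  }
  tree
}
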
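# Relaxed pruning over the gap-extended alphabet.
#
# The recursion is standard Felsenstein pruning except that the gap state is
# a first-class member of the state space: the inner-node partial for state i
# is the product over children of
#   sum_q partial(child, q) P(q | i, t_child)  +  partial(child, -) P(- | i, t_child)
# with i ranging over residues AND the gap state.  Column likelihoods weight
# the root partial by the ancestral-length prior: p*pi_a for an ancestral
# residue, (1 - p) for "no ancestral residue" (the gap state).
#
# The engine is vectorized over columns: partials are k x ncol matrices,
# rescaled per node with accumulated per-column log factors so results match
# unscaled arithmetic exactly in exact arithmetic.

# conditional matrices for every edge of an indexed tree
branch_matrices <- function(ti, model, rho_branch = 1) {
  Q <- model_rate_matrix(model)
  lapply(seq_len(nrow(ti$edge)),
         function(e) conditional_matrix(Q, ti$len[e] * rho_branch))
}

# precomputed per-tip partial matrices (k x ncol), reusable across models
# that share the alphabet size (they do not depend on rates)
make_tip_partials <- function(ti, codes, k) {
  leafmat <- t(if (k == 5L) LEAF_PARTIALS5 else LEAF_PARTIALS4)
  lapply(seq_len(ti$ntip), function(i) leafmat[, codes[i, ], drop = FALSE])
}

# codes: integer matrix (rows = tree tips, in ti$tip_label order) x columns.
# Returns list(partials = k x ncol root partials, log_scale = ncol vector).
prune_columns_prepared <- function(ti, codes, model, P, tips = NULL) {
  k <- model_nstates(model)
  if (is.null(tips)) tips <- make_tip_partials(ti, codes, k)
  nn <- ti$nnodes_total
  partials <- vector("list", nn)
  for (e in seq_len(nrow(ti$edge))) {
    par <- ti$edge[e, 1]
    ch <- ti$edge[e, 2]
    chp <- if (ch <= ti$ntip) tips[[ch]] else partials[[ch]]
    contrib <- P[[e]] %*% chp
    partials[[par]] <- if (is.null(partials[[par]])) contrib
                       else partials[[par]] * contrib
  }
  root <- partials[[ti$root]]
  # single rescue rescaling at the root is enough for desk-scale trees;
  # rescale before returning so downstream exp() stays in range
  m <- colSums(root)
  bad <- m == 0 | !is.finite(m)
  m[bad] <- 1
  root <- root * rep(1 / m, each = k)
  list(partials = root, log_scale = log(m))
}

# deep-tree safe variant: rescales at every internal node
prune_columns <- function(ti, codes, model, P = NULL) {
  if (is.null(P)) P <- branch_matrices(ti, model)
  k <- model_nstates(model)
  leafmat <- t(model_leaf_partials(model))
  partials <- vector("list", ti$nnodes_total)
  log_scale <- numeric(ncol(codes))
  done <- logical(ti$nnodes_total)
  for (e in seq_len(nrow(ti$edge))) {
    par <- ti$edge[e, 1]
    ch <- ti$edge[e, 2]
    chp <- partials[[ch]]
    if (is.null(chp)) chp <- leafmat[, codes[ch, ], drop = FALSE]
    contrib <- P[[e]] %*% chp
    if (is.null(partials[[par]])) {
      partials[[par]] <- contrib
    } else {
      x <- partials[[par]] * contrib
      m <- colSums(x)
      zero <- m == 0
      m[zero] <- 1
      log_scale <- log_scale + log(m)
      partials[[par]] <- sweep(x, 2, m, "/")
    }
  }
  list(partials = partials[[ti$root]], log_scale = log_scale,
       all_partials = partials, P = P)
}

#' Prune a single alignment column
#'
#' Runs the gap-extended pruning recursion for one column and returns the
#' root partial likelihoods.
#'
#' @param tree a rooted binary `phylo` tree.
#' @param column named character vector of leaf symbols (names = leaf
#'   labels), over `A,C,G,T,-` and ambiguity codes.
#' @param model a model object ([indel_model()], [f84_params()] or
#'   [hkyg_params()]).
#' @param branch_P_cache optional list of per-edge conditional matrices (in
#'   postorder edge order) to reuse across columns.
#' @return object of class `partial_likelihoods`: list with `partials`
#'   (named k-vector at the root) and `log_scale` (scalar log rescaling
#'   factor; unscaled partials are `partials * exp(log_scale)`).
#' @export
prune_column <- function(tree, column, model, branch_P_cache = NULL) {
  ti <- tree_index(tree)
  if (is.null(names(column))) {
    if (length(column) != ti$ntip) stop("column length does not match tree")
    names(column) <- ti$tip_label
  }
  missing <- setdiff(ti$tip_label, names(column))
  if (length(missing) > 0) {
    stop("column is missing leaves: ", paste(missing, collapse = ", "))
  }
  codes <- matrix(encode_symbols(normalize_symbols(column[ti$tip_label])),
                  ncol = 1)
  res <- prune_columns(ti, codes, model, P = branch_P_cache)
  structure(list(partials = stats::setNames(res$partials[, 1],
                                            rownames(model_rate_matrix(model))),
                 log_scale = res$log_scale[1]),
            class = "partial_likelihoods")
}

#' Column log-likelihood from root partials
#'
#' Weights the root partials by the model's root prior.  For the indel model
#' this is the ancestral-length prior `p * pi_a` on residues and `1 - p` on
#' the gap ("no ancestral residue") state; for F84 and HKY+G it is the
#' stationary distribution.
#'
#' @param root_partials a `partial_likelihoods` object from
#'   [prune_column()].
#' @param model the model used for pruning.
#' @return log-likelihood of the column (`-Inf` with a warning if the
#'   partials are all zero).
#' @export
column_loglik <- function(root_partials, model) {
  stopifnot(inherits(root_partials, "partial_likelihoods"))
  prior <- model_root_prior(model)
  v <- sum(prior * root_partials$partials)
  if (v <= 0) {
    warning("column has zero likelihood under the model")
    return(-Inf)
  }
  unname(log(v) + root_partials$log_scale)
}

# vectorized column log-likelihoods for a code matrix
col_logliks <- function(ti, codes, model, P = NULL, tips = NULL) {
  if (is.null(P)) P <- branch_matrices(ti, model)
  res <- prune_columns_prepared(ti, codes, model, P, tips)
  prior <- model_root_prior(model)
  v <- as.vector(prior %*% res$partials)
  out <- rep(-Inf, length(v))
  pos <- v > 0
  out[pos] <- log(v[pos]) + res$log_scale[pos]
  out
}

# probability that a column leaves no trace at the leaves (all-gap pattern)
invisible_column_prob <- function(ti, model, P = NULL) {
  codes <- matrix(GAP_CODE, nrow = ti$ntip, ncol = 1)
  exp(col_logliks(ti, codes, model, P))
}

#' Dataset log-likelihood
#'
#' `mode = "site_test"` returns the plain sum of column log-likelihoods.
#' For models with the ancestral-length prior, `mode = "fit"` additionally
#' adds one geometric termination term `log(1 - p)` per alignment and
#' conditions every column on being observable, subtracting
#' `n_cols * log(1 - P_invisible)` per alignment where `P_invisible` is the
#' probability of the all-gap leaf pattern under that alignment's tree
#' (this marginalizes ancestral residues that left no trace).  For F84 and
#' HKY+G the two modes coincide.
#'
#' @param aset an [alignment_set()].
#' @param model a model object.
#' @param mode `"site_test"` or `"fit"`.
#' @return total log-likelihood (scalar).
#' @export
dataset_loglik <- function(aset, model, mode = c("site_test", "fit")) {
  mode <- match.arg(mode)
  if (length(aset) == 0) stop("empty alignment set")
  prep <- prepare_dataset(aset)
  dataset_loglik_prepared(prep, model, mode)
}

# Group families by identical tree, concatenate their columns and collapse
# duplicate column patterns with weights.  Reused across optimizer steps.
prepare_dataset <- function(aset) {
  keys <- vapply(aset, function(p) tree_key(p$tree), "")
  groups <- split(seq_along(aset), keys)
  out <- lapply(groups, function(idx) {
    ti <- tree_index(aset[[idx[1]]]$tree)
    mats <- lapply(idx, function(i) {
      codes <- aset[[i]]$alignment$codes
      codes[match(ti$tip_label, rownames(codes)), , drop = FALSE]
    })
    big <- do.call(cbind, mats)
    # collapse duplicate column patterns (exact for <= 20 tips via base-6 key)
    if (ti$ntip <= 20) {
      key <- as.vector(6^(seq_len(ti$ntip) - 1) %*% big)
    } else {
      key <- apply(big, 2, paste, collapse = "")
    }
    first <- !duplicated(key)
    uniq <- big[, first, drop = FALSE]
    w <- as.vector(table(factor(key, levels = key[first])))
    list(ti = ti, codes = uniq, weights = w,
         n_cols = vapply(idx, function(i) n_sites(aset[[i]]$alignment), 0L),
         n_alignments = length(idx))
  })
  structure(list(groups = out,
                 total_sites = total_sites(aset),
                 n_alignments = length(aset)),
            class = "ip_prepared")
}

dataset_loglik_prepared <- function(prep, model, mode) {
  ll <- 0
  for (g in prep$groups) {
    P <- branch_matrices(g$ti, model)
    lls <- col_logliks(g$ti, g$codes, model, P)
    ll <- ll + sum(lls * g$weights)
    if (mode == "fit" && has_length_prior(model)) {
      p_inv <- invisible_column_prob(g$ti, model, P)
      ll <- ll + g$n_alignments * log(1 - model$p) -
        sum(g$n_cols) * log(1 - p_inv)
    }
  }
  ll
}
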
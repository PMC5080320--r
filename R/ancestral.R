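# Marginal ancestral reconstruction (up-down algorithm) and
# implicit-parsimony counting of insertion/deletion lengths.
#
# Up pass: the pruning recursion, keeping per-node partials and per-edge
# child contributions.  Down pass: outside vectors propagated from the root
# prior; the marginal posterior at a node is (up partial) * (outside),
# normalized per column.  Scale factors cancel in the normalization.
#
# Event counting reads the most-likely state per node: a branch whose parent
# is most likely a gap while the child is most likely a residue contributes
# one insertion site; the opposite pattern one deletion site.  A deletion
# spanning n contiguous columns therefore contributes n deletion sites (the
# per-residue independence limitation of the model).

# Per-node most-likely states for all columns at once.
# Returns an (ntips + nnodes) x ncol integer matrix of state codes 1..k.
#
# method "marginal": argmax of the marginal posterior (up-down algorithm).
# method "subtree": argmax of the pruning partial at each internal node
#   (the subtree-conditional likelihood, with no contribution from the rest
#   of the tree or the root prior) -- the literal reading of picking the
#   state with the "highest likelihood value" during estimation, and the
#   reading that reproduces the insertion/deletion inversion a gap-as-fifth-
#   character HKY model shows on deletion-biased data.
# method "joint": max-product (Viterbi-like) joint reconstruction.
reconstruct_states <- function(ti, codes, model, P = NULL,
                               method = c("marginal", "subtree", "joint")) {
  method <- match.arg(method)
  if (method == "joint") return(reconstruct_states_joint(ti, codes, model, P))
  if (is.null(P)) P <- branch_matrices(ti, model)
  k <- model_nstates(model)
  leafmat <- t(model_leaf_partials(model))
  ncols <- ncol(codes)
  nn <- ti$nnodes_total
  up <- vector("list", nn)
  contrib <- vector("list", nrow(ti$edge))
  for (e in seq_len(nrow(ti$edge))) {
    par <- ti$edge[e, 1]
    ch <- ti$edge[e, 2]
    chp <- up[[ch]]
    if (is.null(chp)) {
      chp <- leafmat[, codes[ch, ], drop = FALSE]
      up[[ch]] <- chp
    }
    contrib[[e]] <- P[[e]] %*% chp
    if (is.null(up[[par]])) {
      up[[par]] <- contrib[[e]]
    } else {
      x <- up[[par]] * contrib[[e]]
      m <- colSums(x)
      m[m == 0] <- 1
      up[[par]] <- sweep(x, 2, m, "/")
    }
  }
  if (method == "subtree") {
    states <- matrix(NA_integer_, nn, ncols)
    for (v in seq_len(nn)) {
      states[v, ] <- max.col(t(up[[v]]), ties.method = "first")
    }
    return(states)
  }
  out <- vector("list", nn)
  out[[ti$root]] <- matrix(model_root_prior(model), k, ncols)
  # preorder = reverse postorder
  for (e in rev(seq_len(nrow(ti$edge)))) {
    par <- ti$edge[e, 1]
    ch <- ti$edge[e, 2]
    sibs <- setdiff(ti$child_edges[[as.character(par)]], e)
    above <- out[[par]]
    for (s in sibs) above <- above * contrib[[s]]
    o <- crossprod(P[[e]], above)   # t(P) %*% above
    m <- colSums(o)
    m[m == 0] <- 1
    out[[ch]] <- sweep(o, 2, m, "/")
  }
  states <- matrix(NA_integer_, nn, ncols)
  for (v in seq_len(nn)) {
    post <- up[[v]] * out[[v]]
    # ties broken toward residue, then alphabetically: state order A,C,G,T,-
    states[v, ] <- max.col(t(post), ties.method = "first")
  }
  states
}

# max-product joint reconstruction with backtracking
reconstruct_states_joint <- function(ti, codes, model, P = NULL) {
  if (is.null(P)) P <- branch_matrices(ti, model)
  k <- model_nstates(model)
  leafmat <- t(model_leaf_partials(model))
  ncols <- ncol(codes)
  nn <- ti$nnodes_total
  M <- vector("list", nn)       # max-subtree values (rescaled)
  bp <- vector("list", nrow(ti$edge))  # backpointer arrays k x ncols
  for (e in seq_len(nrow(ti$edge))) {
    par <- ti$edge[e, 1]
    ch <- ti$edge[e, 2]
    chm <- M[[ch]]
    if (is.null(chm)) {
      chm <- leafmat[, codes[ch, ], drop = FALSE]
      M[[ch]] <- chm
    }
    best <- matrix(-Inf, k, ncols)
    arg <- matrix(1L, k, ncols)
    for (q in seq_len(k)) {
      cand <- outer(P[[e]][, q], chm[q, ])   # k x ncols
      upd <- cand > best
      best[upd] <- cand[upd]
      arg[upd] <- q
    }
    bp[[e]] <- arg
    M[[par]] <- if (is.null(M[[par]])) best else {
      x <- M[[par]] * best
      m <- apply(x, 2, max)
      m[m == 0] <- 1
      x * rep(1 / m, each = k)
    }
  }
  states <- matrix(NA_integer_, nn, ncols)
  rootv <- M[[ti$root]] * model_root_prior(model)
  states[ti$root, ] <- max.col(t(rootv), ties.method = "first")
  for (e in rev(seq_len(nrow(ti$edge)))) {
    par_states <- states[ti$edge[e, 1], ]
    states[ti$edge[e, 2], ] <- bp[[e]][cbind(par_states, seq_len(ncols))]
  }
  states
}

#' Marginal ancestral reconstruction of one column
#'
#' For each node, the state with maximal marginal posterior probability
#' given the whole column (up-down algorithm with the model's root prior).
#' Ties are broken toward residues, then alphabetically.  Leaves are
#' included: an observed residue or gap reconstructs as itself, an `N`
#' resolves to its most probable residue.
#'
#' @param tree a rooted binary `phylo` tree.
#' @param column named character vector of leaf symbols.
#' @param model the fitted model.
#' @return character vector of states (`A,C,G,T,-`), named by tip label for
#'   leaves and `node<k>` for internal nodes (root first).
#' @export
marginal_reconstruction <- function(tree, column, model) {
  ti <- tree_index(tree)
  if (is.null(names(column))) {
    stopifnot(length(column) == ti$ntip)
    names(column) <- ti$tip_label
  }
  codes <- matrix(encode_symbols(normalize_symbols(column[ti$tip_label])),
                  ncol = 1)
  st <- reconstruct_states(ti, codes, model)
  labs <- c(ti$tip_label, paste0("node", seq_len(ti$nnode) + ti$ntip))
  alphabet <- rownames(model_rate_matrix(model))
  stats::setNames(alphabet[st[, 1]], labs)
}

#' Count insertion and deletion lengths by implicit parsimony
#'
#' Reconstructs the most likely state at every node of every column and
#' counts, per branch: parent gap & child residue as one insertion site,
#' parent residue & child gap as one deletion site.  Totals are aggregated
#' over columns, branches and families.
#'
#' @param aset an [alignment_set()].
#' @param model the globally fitted model (any 5-state model; the F84
#'   missing-data model has no gap state and cannot be used).
#' @param method state reconstruction: `"marginal"` (posterior argmax,
#'   default), `"subtree"` (argmax of the pruning partial, i.e. the state
#'   with the highest likelihood value given its subtree only) or `"joint"`
#'   (max-product).  See the methods vignette for when they differ.
#' @return object of class `event_counts`: list with `insertions`,
#'   `deletions`, `di_ratio` (NA with `no_insertions = TRUE` when no
#'   insertion was inferred), and `per_branch`, a data frame with columns
#'   `family_id, branch, insertion_sites, deletion_sites` (branches labeled
#'   by their child node).
#' @export
count_indel_events <- function(aset, model,
                               method = c("marginal", "subtree", "joint")) {
  method <- match.arg(method)
  if (model_nstates(model) == 4L) {
    stop("event counting requires a gap-extended (5-state) model")
  }
  rows <- list()
  ins_total <- 0
  del_total <- 0
  for (fam in aset) {
    ti <- tree_index(fam$tree)
    codes <- fam$alignment$codes[match(ti$tip_label,
                                       rownames(fam$alignment$codes)), ,
                                 drop = FALSE]
    st <- reconstruct_states(ti, codes, model, method = method)
    labs <- c(ti$tip_label, paste0("node", seq_len(ti$nnode) + ti$ntip))
    ins_b <- integer(nrow(ti$edge))
    del_b <- integer(nrow(ti$edge))
    for (e in seq_len(nrow(ti$edge))) {
      par_gap <- st[ti$edge[e, 1], ] == GAP_CODE
      ch_gap <- st[ti$edge[e, 2], ] == GAP_CODE
      ins_b[e] <- sum(par_gap & !ch_gap)
      del_b[e] <- sum(!par_gap & ch_gap)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(family_id = fam$alignment$family_id,
                 branch = labs[ti$edge[, 2]],
                 insertion_sites = ins_b, deletion_sites = del_b,
                 stringsAsFactors = FALSE)
    ins_total <- ins_total + sum(ins_b)
    del_total <- del_total + sum(del_b)
  }
  per_branch <- do.call(rbind, rows)
  no_ins <- ins_total == 0
  if (no_ins) {
    warning("no insertions inferred; DI ratio undefined ",
            "(site tests fall back to di_ratio = 1)")
  }
  structure(list(insertions = ins_total, deletions = del_total,
                 di_ratio = if (no_ins) NA_real_ else del_total / ins_total,
                 no_insertions = no_ins, per_branch = per_branch),
            class = "event_counts")
}

#' @export
print.event_counts <- function(x, ...) {
  cat("<event_counts> insertions:", x$insertions,
      " deletions:", x$deletions,
      " D/I:", format(x$di_ratio, digits = 5), "\n")
  invisible(x)
}
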
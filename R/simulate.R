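# Forward simulator over the gap-extended alphabet with recorded truth.
#
# Columns are independent (matching the model): the root state of each
# column is drawn from the ancestral-length prior (weight p*pi_a for residue
# a, 1-p for "no ancestral residue" = gap), then every branch applies the
# finite-time conditional matrix.  Leaves emit '-' for the gap state.
# All-gap columns are unobservable and are dropped before emission, with
# the count recorded in the truth bundle.
#
# An optional tract mode overlays multi-column deletion/insertion tracts
# (geometric lengths) on the substitution process.  This deliberately
# violates the per-column independence of the model and exists to study the
# rate overestimation that long tracts induce in per-residue indel models.

#' Fixed 10-taxon benchmark tree
#'
#' A balanced 10-leaf tree with root-to-tip depth 1.0 (total branch length
#' 4.6).  The depth is chosen so that, at realistic deletion-biased rates,
#' gap occupancy along the tree is a few percent and the insertion rate is
#' identifiable from desk-scale simulated data.
#'
#' @return a `phylo` tree with tips `t1..t10`.
#' @export
benchmark_tree <- function() {
  read_newick(paste0(
    "((((t1:0.15,t2:0.15):0.25,(t3:0.15,t4:0.15):0.25):0.3,",
    "((t5:0.15,t6:0.15):0.25,(t7:0.15,t8:0.15):0.25):0.3):0.3,",
    "(t9:0.5,t10:0.5):0.5);"))
}

#' Fixed 10-taxon primate-like tree
#'
#' A caterpillar-shaped tree whose topology and branch lengths (expected
#' substitutions per site) mimic the primate phylogeny at literature scale:
#' very short terminal branches within the apes, deeper splits toward
#' tarsier and the strepsirrhines.  Simulations on this tree under the
#' default deletion-biased model yield a leaf gap fraction near 1%, the
#' regime of conserved protein-coding primate alignments.
#'
#' @return a `phylo` tree with 10 tips.
#' @export
primate_tree <- function() {
  read_newick(paste0(
    "(((((((hsap:0.007,ptro:0.007):0.002,ggor:0.009):0.010,pabe:0.018):0.014,",
    "nleu:0.033):0.030,mmul:0.062):0.042,cjac:0.107):0.065,",
    "(tsyr:0.180,(mmur:0.093,ogar:0.128):0.060):0.030);"))
}

#' Default deletion-biased indel model
#'
#' The package's reference parameter set for simulation: insertion rate
#' 0.008509, deletion rate 0.061660, F84 rates alpha = 0.513467,
#' beta = 0.486533, residue frequencies (0.254698, 0.260464, 0.263575,
#' 0.221263) and geometric length parameter p = 0.998058 — a realistic
#' deletion-biased regime for conserved protein-coding alignments.
#'
#' @return an [indel_model()].
#' @export
default_indel_model <- function() {
  indel_model(lambda = 0.008509, mu = 0.061660,
              f84 = f84_params(0.513467, 0.486533,
                               c(0.254698, 0.260464, 0.263575, 0.221263)),
              p = 0.998058)
}

#' Simulate one gene-family alignment
#'
#' @param tree a rooted binary `phylo` tree.
#' @param model an [indel_model()] (use `lambda = mu = 0` for gapless data).
#' @param n_columns number of ancestral columns to draw (all-gap columns are
#'   dropped from the emitted alignment).
#' @param seed mandatory RNG seed.
#' @param family_id identifier for the emitted alignment.
#' @param tract_length if not `NULL`, mean geometric tract length for the
#'   model-violating multi-column indel mode.
#' @return list with `alignment` (an `indel_alignment`) and `truth`: true
#'   parameters, per-node state matrix (`node_states`, rows ordered tips
#'   then internal nodes), per-branch true event counts (`events`), the
#'   number of dropped all-gap columns and the seed.
#' @export
simulate_family <- function(tree, model, n_columns, seed,
                            family_id = "sim", tract_length = NULL) {
  stopifnot(inherits(model, "indel_model"), n_columns >= 1)
  set.seed(seed)
  ti <- tree_index(tree)
  k <- 5L
  nn <- ti$nnodes_total
  prior <- model_root_prior(model)
  states <- matrix(NA_integer_, nn, n_columns)
  states[ti$root, ] <- sample.int(k, n_columns, replace = TRUE, prob = prior)
  Q <- build_f84e_rate_matrix(model)
  edges_pre <- rev(seq_len(nrow(ti$edge)))
  P <- lapply(seq_len(nrow(ti$edge)),
              function(e) conditional_matrix(Q, ti$len[e]))
  for (e in edges_pre) {
    par <- ti$edge[e, 1]
    ch <- ti$edge[e, 2]
    child <- integer(n_columns)
    for (s in seq_len(k)) {
      idx <- which(states[par, ] == s)
      if (length(idx) > 0) {
        child[idx] <- sample.int(k, length(idx), replace = TRUE,
                                 prob = P[[e]][s, ])
      }
    }
    states[ch, ] <- child
  }
  if (!is.null(tract_length)) {
    states <- overlay_indel_tracts(ti, states, model, tract_length)
  }
  leaf_states <- states[seq_len(ti$ntip), , drop = FALSE]
  all_gap <- colSums(leaf_states == GAP_CODE) == ti$ntip
  n_drop <- sum(all_gap)
  keep <- !all_gap
  states <- states[, keep, drop = FALSE]
  # per-branch true events on the kept columns
  ev <- data.frame(
    branch = c(ti$tip_label,
               paste0("node", seq_len(ti$nnode) + ti$ntip))[ti$edge[, 2]],
    insertions = 0L, deletions = 0L, substitutions = 0L)
  for (e in seq_len(nrow(ti$edge))) {
    ps <- states[ti$edge[e, 1], ]
    cs <- states[ti$edge[e, 2], ]
    ev$insertions[e] <- sum(ps == GAP_CODE & cs != GAP_CODE)
    ev$deletions[e] <- sum(ps != GAP_CODE & cs == GAP_CODE)
    ev$substitutions[e] <- sum(ps != cs & ps != GAP_CODE & cs != GAP_CODE)
  }
  mat <- matrix(ALPHA5[states[seq_len(ti$ntip), , drop = FALSE]],
                nrow = ti$ntip,
                dimnames = list(ti$tip_label, NULL))
  aln <- suppressMessages(new_alignment(mat, family_id))
  list(alignment = aln,
       truth = list(model = model, node_states = states,
                    node_labels = c(ti$tip_label,
                                    paste0("node",
                                           seq_len(ti$nnode) + ti$ntip)),
                    events = ev, dropped_allgap = n_drop, seed = seed,
                    tree = ti$tree))
}

# model-violating overlay: geometric-length deletion and insertion tracts
# applied branch by branch (children re-evolve from the modified states)
overlay_indel_tracts <- function(ti, states, model, tract_length) {
  n_columns <- ncol(states)
  for (e in rev(seq_len(nrow(ti$edge)))) {
    ch <- ti$edge[e, 2]
    t_e <- ti$len[e]
    n_del <- stats::rpois(1, model$mu * t_e * n_columns / tract_length)
    if (n_del > 0) {
      starts <- sample.int(n_columns, n_del, replace = TRUE)
      lens <- stats::rgeom(n_del, 1 / tract_length) + 1L
      for (d in seq_len(n_del)) {
        cols <- starts[d]:min(n_columns, starts[d] + lens[d] - 1L)
        desc <- subtree_nodes(ti, ch)
        states[desc, cols] <- GAP_CODE
      }
    }
  }
  states
}

subtree_nodes <- function(ti, node) {
  out <- node
  frontier <- node
  repeat {
    kids <- ti$edge[ti$edge[, 1] %in% frontier, 2]
    if (length(kids) == 0) break
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Simulation configuration
#'
#' @param tree tree used for every family (default [benchmark_tree()]).
#' @param model generating [indel_model()] (default
#'   [default_indel_model()]).
#' @param n_families number of independent families.
#' @param n_columns ancestral columns per family.
#' @param seed mandatory master seed; per-family seeds are derived from it.
#' @param accel_fraction fraction of columns simulated under an accelerated
#'   indel model (planted signal; 0 disables).
#' @param accel_rho indel-rate scale factor for planted columns.
#' @param tract_length optional mean tract length (model-violating mode).
#' @return a `sim_config` list.
#' @export
sim_config <- function(tree = benchmark_tree(), model = default_indel_model(),
                       n_families = 10L, n_columns = 300L, seed,
                       accel_fraction = 0, accel_rho = 1,
                       tract_length = NULL) {
  stopifnot(!missing(seed), n_families >= 1, n_columns >= 1,
            accel_fraction >= 0, accel_fraction < 1, accel_rho >= 0)
  structure(list(tree = tree, model = model, n_families = n_families,
                 n_columns = n_columns, seed = as.integer(seed),
                 accel_fraction = accel_fraction, accel_rho = accel_rho,
                 tract_length = tract_length),
            class = "sim_config")
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + i * 9973) %% 2147483647)
}

#' Simulate a multi-family benchmark set with recorded truth
#'
#' Families are independent and deterministic under the master seed.  When
#' `accel_fraction > 0`, that fraction of each family's columns is simulated
#' under the model with indel rates scaled by `accel_rho` (both rates
#' equally); the truth records which emitted columns carry planted
#' acceleration.  When `out_dir` is given, writes per-family FASTA and
#' Newick files plus a `truth.json` summary so the bundle can be reloaded
#' without rerunning the simulator.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return list with `aset` (an [alignment_set()]), `truth` (per-family
#'   truth records; each gains `accel_columns`, indices into the emitted
#'   alignment) and `config`.
#' @export
make_benchmark_set <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  alns <- vector("list", config$n_families)
  truths <- vector("list", config$n_families)
  n_acc <- round(config$accel_fraction * config$n_columns)
  accel_model <- if (n_acc > 0) {
    indel_model(config$model$lambda * config$accel_rho,
                config$model$mu * config$accel_rho,
                config$model$f84, config$model$p)
  } else NULL
  for (i in seq_len(config$n_families)) {
    fid <- sprintf("fam%04d", i)
    base <- simulate_family(config$tree, config$model,
                            config$n_columns - n_acc,
                            seed = derive_seed(config$seed, i),
                            family_id = fid,
                            tract_length = config$tract_length)
    if (n_acc > 0) {
      acc <- simulate_family(config$tree, accel_model, n_acc,
                             seed = derive_seed(config$seed,
                                                i + config$n_families),
                             family_id = fid)
      n_base <- ncol(base$alignment$codes)
      mat <- cbind(base$alignment$seqs, acc$alignment$seqs)
      aln <- suppressMessages(new_alignment(mat, fid))
      truth <- base$truth
      truth$node_states <- cbind(base$truth$node_states,
                                 acc$truth$node_states)
      truth$dropped_allgap <- base$truth$dropped_allgap +
        acc$truth$dropped_allgap
      truth$accel_columns <- n_base + seq_len(ncol(acc$alignment$codes))
      alns[[i]] <- aln
      truths[[i]] <- truth
    } else {
      base$truth$accel_columns <- integer(0)
      alns[[i]] <- base$alignment
      truths[[i]] <- base$truth
    }
  }
  aset <- alignment_set(alns, rep(list(config$tree), config$n_families))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(config$n_families)) {
      fid <- alns[[i]]$family_id
      write_fasta_alignment(alns[[i]], file.path(out_dir,
                                                 paste0(fid, ".fa")))
      write_newick(config$tree, file.path(out_dir, paste0(fid, ".nwk")))
    }
    truth_summary <- lapply(truths, function(tr) {
      list(events = tr$events, dropped_allgap = tr$dropped_allgap,
           accel_columns = tr$accel_columns, seed = tr$seed)
    })
    names(truth_summary) <- vapply(alns, function(a) a$family_id, "")
    jsonlite::write_json(
      list(model = list(lambda = config$model$lambda, mu = config$model$mu,
                        alpha = config$model$f84$alpha,
                        beta = config$model$f84$beta,
                        pi = config$model$f84$pi, p = config$model$p),
           seed = config$seed, families = truth_summary),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  list(aset = aset, truth = truths, config = config)
}
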
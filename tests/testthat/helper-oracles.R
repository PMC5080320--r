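# Shared fixtures and independent oracles.
#
# enum_column_loglik() is the brute-force oracle for the pruning recursion:
# it sums the joint probability over ALL internal-node state assignments
# (k^n_internal terms), marginalizing each leaf against its partial vector
# edge by edge.  It never calls the pruning code.

# leaf partial lookup rows: A, C, G, T, gap, N
LEAF5_ORACLE <- rbind(cbind(diag(4), 0),
                      c(0, 0, 0, 0, 1),
                      c(1, 1, 1, 1, 0))
LEAF4_ORACLE <- rbind(diag(4), c(1, 1, 1, 1), c(1, 1, 1, 1))

model_bits <- function(model) {
  if (inherits(model, "indel_model")) {
    list(k = 5L, Q = build_f84e_rate_matrix(model),
         prior = c(model$p * model$f84$pi, 1 - model$p), leaf = LEAF5_ORACLE)
  } else if (inherits(model, "hkyg_params")) {
    list(k = 5L, Q = build_hkyg_rate_matrix(model), prior = model$pi5,
         leaf = LEAF5_ORACLE)
  } else {
    list(k = 4L, Q = build_f84_rate_matrix(model), prior = model$pi,
         leaf = LEAF4_ORACLE)
  }
}

# postorder edge list straight from ape, independent of the package's index
oracle_edges <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  list(edge = tree$edge, len = tree$edge.length,
       ntip = length(tree$tip.label), labels = tree$tip.label,
       nnode = tree$Nnode, root = length(tree$tip.label) + 1L)
}

SYMBOL_ORDER <- c("A", "C", "G", "T", "-", "N")

enum_column_loglik <- function(tree, column, model) {
  bits <- model_bits(model)
  ed <- oracle_edges(tree)
  P <- lapply(seq_len(nrow(ed$edge)),
              function(e) conditional_matrix(bits$Q, ed$len[e]))
  codes <- match(toupper(column[ed$labels]), SYMBOL_ORDER)
  stopifnot(!anyNA(codes))
  internal <- ed$ntip + seq_len(ed$nnode)
  grid <- as.matrix(expand.grid(rep(list(seq_len(bits$k)), ed$nnode)))
  total <- 0
  for (r in seq_len(nrow(grid))) {
    st <- integer(ed$ntip + ed$nnode)
    st[internal] <- grid[r, ]
    pr <- bits$prior[st[ed$root]]
    for (e in seq_len(nrow(ed$edge))) {
      par <- ed$edge[e, 1]
      ch <- ed$edge[e, 2]
      pr <- pr * if (ch <= ed$ntip) {
        sum(P[[e]][st[par], ] * bits$leaf[codes[ch], seq_len(bits$k)])
      } else {
        P[[e]][st[par], st[ch]]
      }
    }
    total <- total + pr
  }
  log(total)
}

# column log-likelihood via the package (one column, tidy wrapper)
pkg_column_loglik <- function(tree, column, model) {
  column_loglik(prune_column(tree, column, model), model)
}

# brute-force marginal posterior at every node of a small tree
enum_node_posteriors <- function(tree, column, model) {
  bits <- model_bits(model)
  ed <- oracle_edges(tree)
  P <- lapply(seq_len(nrow(ed$edge)),
              function(e) conditional_matrix(bits$Q, ed$len[e]))
  codes <- match(toupper(column[ed$labels]), SYMBOL_ORDER)
  nn <- ed$ntip + ed$nnode
  # enumerate over every node, leaves included (weighted by leaf partial)
  grid <- as.matrix(expand.grid(rep(list(seq_len(bits$k)), nn)))
  post <- matrix(0, nn, bits$k)
  for (r in seq_len(nrow(grid))) {
    st <- grid[r, ]
    pr <- bits$prior[st[ed$root]]
    for (i in seq_len(ed$ntip)) pr <- pr * bits$leaf[codes[i], st[i]]
    if (pr == 0) next
    for (e in seq_len(nrow(ed$edge))) {
      pr <- pr * P[[e]][st[ed$edge[e, 1]], st[ed$edge[e, 2]]]
    }
    for (v in seq_len(nn)) post[v, st[v]] <- post[v, st[v]] + pr
  }
  sweep(post, 1, rowSums(post), "/")
}

random_f84 <- function() {
  pi <- as.vector(stats::runif(4, 0.1, 1))
  pi <- pi / sum(pi)
  f84_params(stats::runif(1, 0.05, 2), stats::runif(1, 0.05, 2), pi)
}

random_indel_model <- function() {
  indel_model(stats::runif(1, 0.001, 0.3), stats::runif(1, 0.001, 0.5),
              random_f84(), stats::runif(1, 0.9, 0.999))
}

random_small_tree <- function(ntip) {
  tr <- ape::rtree(ntip, rooted = TRUE,
                   br = function(n) stats::runif(n, 0.02, 0.6))
  tr$tip.label <- paste0("L", seq_len(ntip))
  tr
}

# tiny deterministic alignment-set builder
toy_aset <- function(seqs, tree, family_id = "toy") {
  mat <- do.call(rbind, strsplit(seqs, ""))
  rownames(mat) <- names(seqs)
  aln <- suppressMessages(new_alignment(mat, family_id))
  alignment_set(list(aln), list(tree))
}
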
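# Tree input and indexing.  Trees are ape "phylo" objects throughout; the
# package requires rooted binary trees with finite non-negative branch
# lengths.  Polytomies are resolved into binary nodes with zero-length
# branches at parse time.

# Cheap syntax pre-scan so malformed Newick reports a character offset before
# delegating real parsing to ape.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("malformed Newick: unmatched ')' at character offset ", i)
      }
    }
  }
  if (depth != 0L) {
    stop("malformed Newick: ", depth, " unclosed '(' at character offset ",
         length(chars))
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop("malformed Newick: missing terminating ';' at character offset ",
         length(chars))
  }
  invisible(TRUE)
}

#' Read a rooted phylogenetic tree from a Newick string
#'
#' Branch lengths (expected substitutions per site) are required on every
#' branch.  Polytomies, including an unrooted trifurcating root, are resolved
#' arbitrarily into binary nodes with zero-length branches and a message is
#' emitted.
#'
#' @param text a Newick string, or the path of a file whose first line holds
#'   one.
#' @return an object of class `phylo` (rooted, binary, with `edge.length`).
#' @examples
#' tr <- read_newick("((A:0.1,B:0.1):0.05,C:0.2);")
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("(", text, fixed = TRUE) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  }
  check_newick_syntax(text)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("malformed Newick: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("malformed Newick: ape could not parse the string")
  validate_tree(tr)
}

validate_tree <- function(tr) {
  if (is.null(tr$edge.length) || length(tr$edge.length) != nrow(tr$edge)) {
    stop("tree is missing branch lengths")
  }
  if (anyNA(tr$edge.length) || any(!is.finite(tr$edge.length))) {
    stop("tree has missing or non-finite branch lengths")
  }
  if (any(tr$edge.length < 0)) stop("tree has negative branch lengths")
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in tree")
  if (!ape::is.rooted(tr) || !ape::is.binary(tr)) {
    n_before <- nrow(tr$edge)
    tr <- ape::multi2di(tr, random = FALSE)
    if (is.null(tr$edge.length)) stop("tree is missing branch lengths")
    tr$edge.length[is.na(tr$edge.length)] <- 0
    message("resolved polytomies into ", nrow(tr$edge) - n_before,
            " zero-length branch(es)")
  }
  tr
}

#' Write a tree as a Newick string
#' @param tree a `phylo` object.
#' @param path optional file path; when `NULL` the string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

# Postorder index used by the pruning engine.  Guarantees child edges are
# visited before the edge above them; nodes are 1..Ntip (tips, in tip.label
# order) then Ntip+1 (root) .. per the ape convention.
tree_index <- function(tree) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edge <- tree$edge
  # children edges per internal node (binary after validate_tree)
  child_edges <- split(seq_len(nrow(edge)), edge[, 1])
  list(tree = tree, edge = edge, len = tree$edge.length, ntip = ntip,
       nnode = nnode, root = ntip + 1L, nnodes_total = ntip + nnode,
       child_edges = child_edges, tip_label = tree$tip.label)
}

tree_key <- function(tree) ape::write.tree(tree)
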
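# Gapped DNA alignments for one gene family, stored as a character matrix
# (rows = sequences) plus an integer-coded copy used by the likelihood
# engine.  All-gap columns are unobservable under the model and are dropped
# at construction with a logged count.

#' Construct an alignment object
#'
#' @param mat character matrix of single symbols, rows named by sequence.
#' @param family_id identifier of the gene family.
#' @return an object of class `indel_alignment` with fields `family_id`,
#'   `seqs` (normalized character matrix) and `codes` (integer matrix);
#'   attribute `dropped_allgap` counts all-gap columns removed.
#' @export
new_alignment <- function(mat, family_id) {
  stopifnot(is.matrix(mat), is.character(mat))
  if (is.null(rownames(mat))) stop("alignment matrix must have row names")
  if (anyDuplicated(rownames(mat))) stop("duplicate sequence names")
  syms <- normalize_symbols(mat)
  dim(syms) <- dim(mat)
  dimnames(syms) <- dimnames(mat)
  codes <- encode_symbols(syms)
  dim(codes) <- dim(mat)
  dimnames(codes) <- dimnames(mat)
  all_gap <- colSums(codes == GAP_CODE) == nrow(codes)
  n_drop <- sum(all_gap)
  if (n_drop > 0) {
    syms <- syms[, !all_gap, drop = FALSE]
    codes <- codes[, !all_gap, drop = FALSE]
    message("alignment ", family_id, ": dropped ", n_drop, " all-gap column(s)")
  }
  structure(list(family_id = family_id, seqs = syms, codes = codes),
            dropped_allgap = n_drop, class = "indel_alignment")
}

#' @export
dim.indel_alignment <- function(x) dim(x$codes)

n_sites <- function(aln) ncol(aln$codes)

#' @export
print.indel_alignment <- function(x, ...) {
  cat("<indel_alignment> family", x$family_id, "-", nrow(x$codes),
      "sequences x", ncol(x$codes), "columns\n")
  invisible(x)
}

#' Read a gapped FASTA alignment
#'
#' Symbols are uppercased; `.` and `*` are normalized to `-`; IUPAC
#' ambiguity codes map to `N` (unknown residue).  All-gap columns are
#' dropped with a logged count.
#'
#' @param path FASTA file.
#' @param family_id family identifier; defaults to the file name without
#'   extension.
#' @return an `indel_alignment`.
#' @export
read_fasta_alignment <- function(path, family_id = NULL) {
  if (is.null(family_id)) {
    family_id <- sub("\\.[^.]*$", "", basename(path))
  }
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("empty FASTA file: ", path)
  lens <- Biostrings::width(ss)
  if (length(unique(lens)) != 1L) {
    modal <- as.integer(names(which.max(table(lens))))
    off <- names(ss)[lens != modal]
    stop("ragged alignment in ", path, ": sequence length differs for ",
         paste(off, collapse = ", "))
  }
  chars <- strsplit(as.character(ss), "")
  mat <- do.call(rbind, chars)
  rownames(mat) <- sub("\\s.*$", "", names(ss))
  new_alignment(mat, family_id)
}

#' Write an alignment as FASTA
#' @param aln an `indel_alignment`.
#' @param path output file.
#' @export
write_fasta_alignment <- function(aln, path) {
  seqs <- apply(aln$seqs, 1, paste, collapse = "")
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Pair alignments with trees into an analysis set
#'
#' Every sequence name must match a tree leaf; trees carrying extra leaves
#' are pruned to the alignment's taxa (with a message).
#'
#' @param alignments list of `indel_alignment`.
#' @param trees list of `phylo`, parallel to `alignments`.
#' @return an `alignment_set`: a list of `list(alignment, tree)` pairs with
#'   attribute `total_sites`.
#' @export
alignment_set <- function(alignments, trees) {
  stopifnot(length(alignments) == length(trees))
  pairs <- vector("list", length(alignments))
  for (i in seq_along(alignments)) {
    aln <- alignments[[i]]
    tr <- trees[[i]]
    stopifnot(inherits(aln, "indel_alignment"), inherits(tr, "phylo"))
    missing <- setdiff(rownames(aln$codes), tr$tip.label)
    if (length(missing) > 0) {
      stop("alignment ", aln$family_id, ": sequence(s) not in tree: ",
           paste(missing, collapse = ", "))
    }
    extra <- setdiff(tr$tip.label, rownames(aln$codes))
    if (length(extra) > 0) {
      message("alignment ", aln$family_id, ": pruning ", length(extra),
              " tree leaf(ves) without sequence data")
      tr <- ape::keep.tip(tr, rownames(aln$codes))
    }
    pairs[[i]] <- list(alignment = aln, tree = tr)
  }
  structure(pairs,
            total_sites = sum(vapply(pairs, function(p) n_sites(p$alignment),
                                     0L)),
            class = "alignment_set")
}

#' @export
print.alignment_set <- function(x, ...) {
  cat("<alignment_set>", length(x), "families,",
      attr(x, "total_sites"), "total sites\n")
  invisible(x)
}

total_sites <- function(aset) attr(aset, "total_sites")

# TRUE when some sequence holds a gap run of >= max_gap_run columns
has_long_gap_run <- function(aln, max_gap_run) {
  for (i in seq_len(nrow(aln$codes))) {
    r <- rle(aln$codes[i, ] == GAP_CODE)
    if (any(r$lengths[r$values] >= max_gap_run)) return(TRUE)
  }
  FALSE
}

#' Filter a multi-family dataset
#'
#' Keeps an alignment iff it contains the required species, has at least
#' `min_sequences` rows, and no sequence contains a run of `max_gap_run` or
#' more consecutive gap columns ("allowing gaps that are shorter than" the
#' threshold, i.e. strictly shorter runs pass).
#'
#' @param alignments list of `indel_alignment`.
#' @param trees list of `phylo`, parallel to `alignments`.
#' @param max_gap_run reject when any per-sequence gap run reaches this
#'   length (>= semantics; must be >= 1).
#' @param min_sequences minimum number of rows (default 5).
#' @param required_species sequence name that must be present, or `NULL`.
#' @return an `alignment_set` of retained families with attribute
#'   `rejections`, a named integer vector of per-criterion rejection counts.
#' @export
filter_dataset <- function(alignments, trees, max_gap_run,
                           min_sequences = 5L, required_species = NULL) {
  stopifnot(max_gap_run >= 1)
  keep <- logical(length(alignments))
  rej <- c(no_required_species = 0L, too_few_sequences = 0L,
           gap_run_too_long = 0L)
  for (i in seq_along(alignments)) {
    aln <- alignments[[i]]
    if (!is.null(required_species) &&
        !(required_species %in% rownames(aln$codes))) {
      rej["no_required_species"] <- rej["no_required_species"] + 1L
      next
    }
    if (nrow(aln$codes) < min_sequences) {
      rej["too_few_sequences"] <- rej["too_few_sequences"] + 1L
      next
    }
    if (has_long_gap_run(aln, max_gap_run)) {
      rej["gap_run_too_long"] <- rej["gap_run_too_long"] + 1L
      next
    }
    keep[i] <- TRUE
  }
  if (!any(keep)) warning("no alignments retained by filter")
  out <- alignment_set(alignments[keep], trees[keep])
  attr(out, "rejections") <- rej
  attr(out, "kept") <- which(keep)
  out
}
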
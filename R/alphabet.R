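# Gap-extended DNA alphabet {A,C,G,T,-} plus the unknown-residue symbol N.
# Internal integer codes: A=1, C=2, G=3, T=4, "-"=5, N=6.  Code 6 covers every
# IUPAC ambiguity: an unknown residue carries no information about which base
# is present but is definitely not a deletion, so its leaf partial spreads
# over the four residues and puts zero mass on the gap state.

ALPHA5 <- c("A", "C", "G", "T", "-")
GAP_CODE <- 5L
UNKNOWN_CODE <- 6L

# leaf partial rows indexed by symbol code; columns are states
LEAF_PARTIALS5 <- rbind(
  A   = c(1, 0, 0, 0, 0),
  C   = c(0, 1, 0, 0, 0),
  G   = c(0, 0, 1, 0, 0),
  T   = c(0, 0, 0, 1, 0),
  gap = c(0, 0, 0, 0, 1),
  N   = c(1, 1, 1, 1, 0)
)
colnames(LEAF_PARTIALS5) <- ALPHA5

# 4-state version used when gaps are treated as missing data (F84)
LEAF_PARTIALS4 <- rbind(
  A   = c(1, 0, 0, 0),
  C   = c(0, 1, 0, 0),
  G   = c(0, 0, 1, 0),
  T   = c(0, 0, 0, 1),
  gap = c(1, 1, 1, 1),
  N   = c(1, 1, 1, 1)
)
colnames(LEAF_PARTIALS4) <- ALPHA5[1:4]

IUPAC_AMBIGUITY <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Normalize raw alignment symbols
#'
#' Uppercases, maps `.` and `*` to `-`, `U` to `T`, and every IUPAC ambiguity
#' code to `N`.  Any other character is an error.
#'
#' @param x character vector of single symbols.
#' @return character vector over `A,C,G,T,-,N`.
#' @keywords internal
normalize_symbols <- function(x) {
  x <- toupper(x)
  x[x %in% c(".", "*")] <- "-"
  x[x == "U"] <- "T"
  x[x %in% IUPAC_AMBIGUITY] <- "N"
  bad <- setdiff(unique(x), c(ALPHA5, "N"))
  if (length(bad) > 0) {
    stop("unmapped alignment symbol(s): ", paste(bad, collapse = " "))
  }
  x
}

encode_symbols <- function(x) {
  code <- match(x, c(ALPHA5, "N"))
  if (anyNA(code)) {
    stop("unmapped alignment symbol(s): ",
         paste(unique(x[is.na(code)]), collapse = " "))
  }
  code
}

decode_symbols <- function(code) c(ALPHA5, "N")[code]

#' Leaf partial-likelihood vector over the gap-extended alphabet
#'
#' A residue symbol maps to the indicator of that residue; `-` maps to the
#' indicator of the gap state (a gap at a leaf is an observation, not missing
#' data); `N` (or any ambiguity code) maps to 1 on all four residues and 0 on
#' the gap state.
#'
#' @param symbol a single character in `A,C,G,T,-` or an IUPAC ambiguity code.
#' @return numeric vector of length 5 over states `A,C,G,T,-`.
#' @examples
#' leaf_partials("A")
#' leaf_partials("-")
#' leaf_partials("N")
#' @export
leaf_partials <- function(symbol) {
  if (length(symbol) != 1L) stop("`symbol` must be a single character")
  code <- encode_symbols(normalize_symbols(symbol))
  stats::setNames(LEAF_PARTIALS5[code, ], ALPHA5)
}
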
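#' IUPAC nucleotide ambiguity-code algebra
#'
#' The 15 IUPAC nucleotide symbols are in bijection with the non-empty
#' subsets of \{A, C, G, T\}.  Internally each symbol is a 4-bit mask
#' (A = 1, C = 2, G = 4, T = 8), so set union is bitwise OR.  The gap
#' character \code{"-"} is deliberately \emph{not} part of this algebra:
#' gaps are handled as missing data or as indel characters, never as
#' nucleotide states.
#'
#' @name iupac
#' @keywords internal
NULL

# symbol order is mask order: index into this vector IS the bitmask
.IUPAC_BY_MASK <- c(
  "A", "C", "M", "G", "R", "S", "V",
  "T", "W", "Y", "H", "K", "D", "B", "N"
)

.IUPAC_MASK <- stats::setNames(seq_len(15L), .IUPAC_BY_MASK)

.BASES <- c("A", "C", "G", "T")
.BASE_BITS <- stats::setNames(c(1L, 2L, 4L, 8L), .BASES)

#' Convert IUPAC symbols to internal bitmasks
#'
#' Vectorised; case-insensitive; \code{'U'} is accepted as \code{'T'}.
#' Unknown symbols (including \code{'-'}) raise an invalid-symbol error
#' naming the first offending character.
#'
#' @param symbol character vector of single characters.
#' @return integer vector of bitmasks in 1..15.
#' @keywords internal
iupac_mask <- function(symbol) {
  s <- toupper(as.character(symbol))
  s[s == "U"] <- "T"
  m <- .IUPAC_MASK[s]
  if (anyNA(m)) {
    bad <- s[is.na(m)][1L]
    stop("invalid IUPAC symbol: '", bad, "'", call. = FALSE)
  }
  unname(m)
}

#' Convert internal bitmasks back to IUPAC symbols
#' @param mask integer vector in 1..15.
#' @return character vector of symbols.
#' @keywords internal
iupac_symbol <- function(mask) {
  mask <- as.integer(mask)
  if (any(mask < 1L | mask > 15L)) {
    stop("state mask out of range (empty or invalid state set)", call. = FALSE)
  }
  .IUPAC_BY_MASK[mask]
}

#' Expand an IUPAC symbol into its nucleotide state set
#'
#' @param symbol a single IUPAC nucleotide symbol (case-insensitive;
#'   \code{'U'} is read as \code{'T'}).
#' @return character vector: the subset of \code{c("A","C","G","T")}
#'   the symbol denotes, e.g. \code{parse_iupac("R")} is
#'   \code{c("A","G")}.
#' @examples
#' parse_iupac("R") # A G
#' parse_iupac("N") # A C G T
#' @export
parse_iupac <- function(symbol) {
  if (length(symbol) != 1L) stop("'symbol' must be a single character")
  m <- iupac_mask(symbol)
  .BASES[bitwAnd(m, .BASE_BITS) > 0L]
}

#' Encode a nucleotide state set as its IUPAC symbol
#'
#' Inverse of [parse_iupac()].
#'
#' @param states character vector, a non-empty subset of
#'   \code{c("A","C","G","T")}.
#' @return single IUPAC symbol.
#' @examples
#' encode_iupac(c("C", "T")) # "Y"
#' @export
encode_iupac <- function(states) {
  states <- toupper(unique(as.character(states)))
  if (length(states) == 0L) stop("state set must be non-empty")
  if (!all(states %in% .BASES)) {
    stop("states must be drawn from A, C, G, T; got: ",
         paste(setdiff(states, .BASES), collapse = ", "))
  }
  iupac_symbol(sum(.BASE_BITS[states]))
}

#' Union of IUPAC symbols
#'
#' Returns the unique symbol whose state set is the union of the inputs'
#' state sets; this is the additivity operation used to predict the
#' expected hybrid character at a diagnostic position (e.g. parental
#' states C and T combine to Y).  Vectorised over both arguments.
#'
#' @param a,b IUPAC symbols.
#' @return IUPAC symbol(s) of the per-element unions.
#' @examples
#' iupac_union("C", "T") # "Y"
#' iupac_union("M", "T") # "H"
#' @export
iupac_union <- function(a, b) {
  iupac_symbol(bitwOr(iupac_mask(a), iupac_mask(b)))
}

#' Test whether a symbol is ambiguous (more than one state)
#' @param symbol IUPAC symbol vector.
#' @return logical vector.
#' @export
is_ambiguous <- function(symbol) {
  m <- iupac_mask(symbol)
  # popcount > 1
  n_states(m) > 1L
}

# number of set bits for masks 1..15
n_states <- function(mask) {
  bitwAnd(mask, 1L) + bitwAnd(mask, 2L) %/% 2L +
    bitwAnd(mask, 4L) %/% 4L + bitwAnd(mask, 8L) %/% 8L
}
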
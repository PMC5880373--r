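# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately naive (per-column / per-range enumeration) and
# share no code with the package internals they check.

BASES <- c("A", "C", "G", "T")
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# random toy alignment: IUPAC symbols plus gaps, as named sequences
random_alignment <- function(n_seq, n_col, p_ambig = 0.1, p_gap = 0.05,
                             ids = sprintf("s%02d", seq_len(n_seq))) {
  symbols <- names(IUPAC_SETS)
  ambig <- setdiff(symbols, BASES)
  draw <- function() {
    r <- runif(1)
    if (r < p_gap) "-" else if (r < p_gap + p_ambig) sample(ambig, 1)
    else sample(BASES, 1)
  }
  mat <- matrix(replicate(n_seq * n_col, draw()), n_seq, n_col)
  rownames(mat) <- ids
  hyb_alignment(mat)
}

# brute-force diagnostic-site oracle: naive per-column set arithmetic
# using the IUPAC_SETS table, mirroring the documented rules
oracle_sites <- function(aln, idsA, idsB,
                         mode = "strict_union",
                         rule = "omit_if_one_sided") {
  mat <- unclass(aln)
  col_set <- function(ids, j) {
    syms <- mat[ids, j]
    syms <- syms[syms != "-"]
    if (length(syms) == 0L) return(NULL)
    if (mode == "strict_union") {
      sort(unique(unlist(IUPAC_SETS[syms])))
    } else if (mode == "single_reference") {
      sort(IUPAC_SETS[[mat[ids[1L], j]]])
    } else { # majority
      tab <- table(syms)
      top <- names(tab)[tab == max(tab)]
      sort(unique(unlist(IUPAC_SETS[top])))
    }
  }
  keep <- logical(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    if (any(mat[c(idsA, idsB), j] == "-")) next
    sA <- col_set(idsA, j); sB <- col_set(idsB, j)
    if (is.null(sA) || is.null(sB)) next
    if (length(intersect(sA, sB)) > 0L) next
    if (rule == "omit_if_one_sided" &&
        xor(length(sA) > 1L, length(sB) > 1L)) next
    keep[j] <- TRUE
  }
  which(keep)
}

# exhaustive gap-range enumerator: distinct internal maximal '-' runs
oracle_gap_ranges <- function(aln) {
  mat <- unclass(aln)
  seen <- character()
  for (i in seq_len(nrow(mat))) {
    in_gap <- FALSE; s <- 0L
    for (j in seq_len(ncol(mat))) {
      if (mat[i, j] == "-") {
        if (!in_gap) { in_gap <- TRUE; s <- j }
      } else if (in_gap) {
        in_gap <- FALSE
        if (s > 1L) seen <- c(seen, paste(s, j - 1L))
      }
    }
    # a run still open at the last column is terminal: dropped
  }
  unique(seen)
}

# naive degenerate-pattern site finder (forward strand only)
oracle_find_forward <- function(sequence, recognition) {
  seq_chars <- strsplit(sequence, "")[[1]]
  pat <- strsplit(recognition, "")[[1]]
  n <- length(seq_chars); k <- length(pat)
  hits <- integer()
  for (s in seq_len(max(n - k + 1L, 0L))) {
    ok <- TRUE
    for (t in seq_len(k)) {
      if (!(seq_chars[s + t - 1L] %in% IUPAC_SETS[[pat[t]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")
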
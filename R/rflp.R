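#' Restriction enzyme definition
#'
#' @param name enzyme name.
#' @param recognition recognition sequence (IUPAC string, length >= 4;
#'   degenerate positions allowed).
#' @param cut_offset top-strand cut position within the recognition
#'   site: the duplex is cut after this many bases (0..site length).
#' @return an `enzyme` object.
#' @examples
#' enzyme("PaeI", "GCATGC", 5)
#' @export
enzyme <- function(name, recognition, cut_offset) {
  recognition <- toupper(recognition)
  if (nchar(recognition) < 4L) stop("recognition sequence must be >= 4 bp")
  iupac_mask(strsplit(recognition, "")[[1]]) # validates symbols
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0L || cut_offset > nchar(recognition)) {
    stop("cut_offset must be within 0..", nchar(recognition))
  }
  structure(list(name = name, recognition = recognition,
                 cut_offset = cut_offset),
            class = "enzyme")
}

#' Load an enzyme library from TSV
#'
#' Three tab-separated columns with header: `name`, `recognition`,
#' `cut_offset`.  The default is the small library bundled with the
#' package (including PaeI, recognition GCATGC).
#'
#' @param path TSV path; defaults to the bundled library.
#' @return named list of [enzyme()] objects.
#' @export
read_enzyme_library <- function(path = system.file("extdata", "enzymes.tsv",
                                                   package = "hybdiag")) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "integer"))
  lib <- lapply(seq_len(nrow(df)), function(i) {
    enzyme(df$name[i], df$recognition[i], df$cut_offset[i])
  })
  stats::setNames(lib, df$name)
}

degap_check <- function(sequence) {
  sequence <- toupper(sequence)
  if (grepl("-", sequence, fixed = TRUE)) {
    stop("sequence contains gaps; degap it before restriction analysis",
         call. = FALSE)
  }
  sequence
}

#' Find restriction sites in a linear sequence
#'
#' Scans both strands with IUPAC-aware matching of the (possibly
#' degenerate) recognition sequence; positions are reported as 1-based
#' start coordinates on the forward strand, sorted and deduplicated
#' (palindromic sites appear once).  Overlapping matches are all
#' counted.
#'
#' @param sequence ungapped nucleotide sequence (character string).
#' @param enz an [enzyme()].
#' @return sorted integer vector of site start positions.
#' @examples
#' find_sites("AAGCATGCAA", enzyme("PaeI", "GCATGC", 5)) # 3
#' @export
find_sites <- function(sequence, enz) {
  sequence <- degap_check(sequence)
  subj <- Biostrings::DNAString(sequence)
  pat <- Biostrings::DNAString(enz$recognition)
  fwd <- Biostrings::start(Biostrings::matchPattern(pat, subj,
                                                    fixed = "subject"))
  rev_pat <- Biostrings::reverseComplement(pat)
  rev <- Biostrings::start(Biostrings::matchPattern(rev_pat, subj,
                                                    fixed = "subject"))
  sort(unique(c(fwd, rev)))
}

#' Digest a linear sequence in silico
#'
#' Cut coordinates are `site_start + cut_offset - 1` (the last base of
#' the fragment left of the cut); fragment lengths are the distances
#' between successive cuts and the molecule ends, and always sum to the
#' sequence length.
#'
#' @inheritParams find_sites
#' @return list with `cut_positions` and `fragment_lengths`.
#' @export
digest_linear <- function(sequence, enz) {
  sequence <- degap_check(sequence)
  n <- nchar(sequence)
  sites <- find_sites(sequence, enz)
  cuts <- sites + enz$cut_offset - 1L
  cuts <- sort(unique(cuts[cuts >= 1L & cuts < n]))
  list(cut_positions = cuts,
       fragment_lengths = diff(c(0L, cuts, n)))
}

#' Find enzymes that discriminate two ribotypes
#'
#' Screens an enzyme library for recognition-site count differences
#' between two sequences — the basis of an RFLP pre-screen in which a
#' site present in the major ribotype but lost in the underrepresented
#' one lets uncut clones be picked cheaply before sequencing.
#'
#' @param seqA,seqB ungapped nucleotide sequences.
#' @param library named list of [enzyme()]s (default: bundled library).
#' @return data frame `name`, `recognition`, `sites_a`, `sites_b`,
#'   `delta`, sorted by `abs(delta)` descending then name; only enzymes
#'   with differing site counts are listed.
#' @export
find_discriminating_enzymes <- function(seqA, seqB,
                                        library = read_enzyme_library()) {
  if (length(library) == 0L) stop("enzyme library is empty")
  rows <- lapply(library, function(enz) {
    a <- length(find_sites(seqA, enz))
    b <- length(find_sites(seqB, enz))
    data.frame(name = enz$name, recognition = enz$recognition,
               sites_a = a, sites_b = b, delta = a - b,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[df$delta != 0L, , drop = FALSE]
  df <- df[order(-abs(df$delta), df$name), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Size a clone screen for a rare ribotype
#'
#' With a minor ribotype at frequency `minor_fraction` among clones, the
#' probability that at least one of `n` screened clones carries it is
#' `1 - (1 - f)^n`; the number of clones needed to reach
#' `target_probability` is `ceiling(log(1 - p) / log(1 - f))`.
#'
#' @param minor_fraction expected clone frequency of the rare ribotype,
#'   in (0, 1).
#' @param target_probability desired detection probability, in (0, 1).
#' @return a `clone_screen_plan`: list with `minor_fraction`,
#'   `target_probability`, `clones_needed` and
#'   `detection_probability_at(n)` (a function of the clone count).
#' @examples
#' plan <- plan_clone_screen(0.025, 0.95)
#' plan$detection_probability_at(39) # ~0.627
#' @export
plan_clone_screen <- function(minor_fraction, target_probability) {
  if (!(minor_fraction > 0 && minor_fraction < 1)) {
    stop("minor_fraction must be in (0, 1)")
  }
  if (!(target_probability > 0 && target_probability < 1)) {
    stop("target_probability must be in (0, 1)")
  }
  f <- minor_fraction
  n <- as.integer(ceiling(log(1 - target_probability) / log(1 - f)))
  structure(list(
    minor_fraction = f,
    target_probability = target_probability,
    clones_needed = max(n, 1L),
    detection_probability_at = function(n_clones) 1 - (1 - f)^n_clones
  ), class = "clone_screen_plan")
}

#' @export
print.clone_screen_plan <- function(x, ...) {
  cat(sprintf(
    "clone screen: minor fraction %.3g, target detection %.3g -> %d clones\n",
    x$minor_fraction, x$target_probability, x$clones_needed))
  invisible(x)
}
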
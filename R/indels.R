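#' Extract maximal gap runs from an alignment
#'
#' Per sequence, every maximal run of `-` is reported with its 1-based
#' inclusive column range.  Runs touching either alignment end are
#' flagged `terminal`; terminal runs represent missing flanks rather
#' than indel events and are excluded from character building.
#'
#' @param aln a [hyb_alignment()].
#' @return data frame with columns `sequence_id`, `start`, `end`,
#'   `terminal` (logical).
#' @export
extract_gaps <- function(aln) {
  mat <- unclass(aln)
  out <- lapply(rownames(mat), function(id) {
    r <- rle(mat[id, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gi <- which(r$values)
    if (length(gi) == 0L) return(NULL)
    data.frame(sequence_id = id, start = starts[gi], end = ends[gi],
               terminal = starts[gi] == 1L | ends[gi] == ncol(mat),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(sequence_id = character(), start = integer(),
                      end = integer(), terminal = logical(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Simple indel coding of alignment gaps
#'
#' Codes every distinct internal gap range observed in at least one
#' sequence as one binary presence/absence character: a taxon scores
#' `1` when its gap matches the range exactly, `?` (inapplicable) when
#' one of its gaps properly contains the range, and `0` otherwise.
#' Terminal gaps score `?` for every character whose range they span.
#' Characters are ordered by `(start, end)`.
#'
#' @param aln a [hyb_alignment()] with at least 2 sequences.
#' @return list with `characters` (data frame `start`, `end`) and
#'   `matrix` (character matrix, taxa x characters, entries
#'   `"0"`/`"1"`/`"?"`).
#' @examples
#' aln <- hyb_alignment(c(t1 = "ACTTGT", t2 = "AC--GT", t3 = "A----T"))
#' simple_indel_code(aln)$matrix
#' @export
simple_indel_code <- function(aln) {
  if (nrow(aln) < 2L) stop("indel coding needs at least 2 sequences")
  gaps <- extract_gaps(aln)
  internal <- gaps[!gaps$terminal, , drop = FALSE]
  ranges <- unique(internal[, c("start", "end")])
  ranges <- ranges[order(ranges$start, ranges$end), , drop = FALSE]
  rownames(ranges) <- NULL
  taxa <- rownames(aln)
  mat <- matrix("0", length(taxa), nrow(ranges),
                dimnames = list(taxa, NULL))
  if (nrow(ranges)) {
    colnames(mat) <- sprintf("indel_%d_%d", ranges$start, ranges$end)
    for (k in seq_len(nrow(ranges))) {
      s <- ranges$start[k]; e <- ranges$end[k]
      for (tx in taxa) {
        g <- gaps[gaps$sequence_id == tx, , drop = FALSE]
        gi <- g[!g$terminal, , drop = FALSE]
        gt <- g[g$terminal, , drop = FALSE]
        if (any(gi$start == s & gi$end == e)) {
          mat[tx, k] <- "1"
        } else if (any(gi$start <= s & gi$end >= e &
                       (gi$start < s | gi$end > e))) {
          mat[tx, k] <- "?" # properly contained in a longer gap
        } else if (any(gt$start <= s & gt$end >= e)) {
          mat[tx, k] <- "?" # spanned by a terminal gap
        }
      }
    }
  }
  list(characters = ranges, matrix = mat)
}

#' Write an indel character matrix as TSV
#' @param sic result of [simple_indel_code()].
#' @param path output path; columns are `taxon` plus one
#'   `indel_<start>_<end>` column per character.
#' @return `path`, invisibly.
#' @export
write_indel_tsv <- function(sic, path) {
  df <- data.frame(taxon = rownames(sic$matrix), sic$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a combined NEXUS file: nucleotides plus binary indel block
#'
#' The binary characters are appended after the nucleotide matrix, with
#' a `mixed(DNA:...,restriction:...)` datatype declaration, the
#' convention of indel-coding tools.
#'
#' @param aln the source [hyb_alignment()].
#' @param sic result of [simple_indel_code()] on `aln`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_indel_nexus <- function(aln, sic, path) {
  L <- ncol(aln)
  k <- ncol(sic$matrix)
  taxa <- rownames(aln)
  safe <- gsub("[^A-Za-z0-9_.]", "_", taxa)
  fmt <- if (k > 0L) {
    sprintf("  FORMAT DATATYPE=mixed(DNA:1-%d,RESTRICTION:%d-%d) GAP=- MISSING=?;",
            L, L + 1L, L + k)
  } else {
    "  FORMAT DATATYPE=DNA GAP=- MISSING=?;"
  }
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(taxa), L + k),
    fmt,
    "  MATRIX"
  )
  width <- max(nchar(safe)) + 2L
  for (i in seq_along(taxa)) {
    lines <- c(lines, sprintf(
      "    %-*s %s%s", width, safe[i],
      paste(unclass(aln)[i, ], collapse = ""),
      paste(sic$matrix[i, ], collapse = "")))
  }
  lines <- c(lines, "  ;", "END;")
  writeLines(lines, path)
  invisible(path)
}
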
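#' Aligned nucleotide sequences with IUPAC ambiguity codes
#'
#' A `hyb_alignment` is a character matrix (rows = sequences, columns =
#' alignment positions) whose entries are uppercase IUPAC symbols or the
#' gap character `-`.  Row names are the (unique) sequence ids.  All
#' reporting interfaces use 1-based inclusive column coordinates.
#'
#' @param seqs named character vector of equal-length aligned sequences,
#'   or a character matrix of single symbols with row names.
#' @return a `hyb_alignment` object.
#' @examples
#' aln <- hyb_alignment(c(s1 = "AC-G", s2 = "ACTG"))
#' alignment_length(aln)
#' @export
hyb_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    mat <- seqs
  } else {
    ids <- names(seqs)
    seqs <- stats::setNames(as.character(seqs), ids)
    if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == "")) {
      stop("sequences must be named (names become sequence ids)")
    }
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      stop("alignment-shape error: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")", call. = FALSE)
    }
    mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
    rownames(mat) <- names(seqs)
  }
  if (nrow(mat) < 1L || ncol(mat) < 1L) stop("alignment must be non-empty")
  if (anyDuplicated(rownames(mat))) {
    stop("sequence ids must be unique; duplicated: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  }
  mat[mat == "U"] <- "T"
  ok <- mat %in% c(.IUPAC_BY_MASK, "-")
  if (!all(ok)) {
    idx <- which(!ok)[1L]
    rc <- arrayInd(idx, dim(mat))
    stop("invalid-symbol error: '", mat[idx], "' in record '",
         rownames(mat)[rc[1L]], "' at column ", rc[2L], call. = FALSE)
  }
  structure(mat, class = c("hyb_alignment", "matrix", "array"))
}

#' @export
print.hyb_alignment <- function(x, ...) {
  cat("hyb_alignment: ", nrow(x), " sequences x ", ncol(x), " columns\n",
      sep = "")
  show <- min(ncol(x), 60L)
  for (i in seq_len(min(nrow(x), 10L))) {
    cat(sprintf("  %-15s %s%s\n", rownames(x)[i],
                paste(x[i, seq_len(show)], collapse = ""),
                if (ncol(x) > show) "..." else ""))
  }
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Number of columns of an alignment
#' @param aln a `hyb_alignment`.
#' @return integer.
#' @export
alignment_length <- function(aln) ncol(aln)

#' Sequence ids of an alignment
#' @param aln a `hyb_alignment`.
#' @return character vector.
#' @export
sequence_ids <- function(aln) rownames(aln)

#' Read an aligned FASTA file
#'
#' Multi-record FASTA (wrapped or unwrapped), parsed with
#' \pkg{Biostrings}.  Lowercase is normalised to uppercase and `U` to
#' `T`; `?` and any other non-IUPAC character are rejected with the
#' record id and column.  All records must have equal length.
#'
#' @param path path to a FASTA file with at least 2 records.
#' @return a [hyb_alignment()].
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) < 2L) {
    stop("alignment FASTA must contain at least 2 records; got ", length(set))
  }
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set)) # id = first token of header
  hyb_alignment(seqs)
}

#' Write an alignment to FASTA
#'
#' @param aln a `hyb_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Sample-role groups for a hybrid diagnosis
#'
#' Assigns sequence ids to the roles `parentA`, `parentB` and `query`.
#' Roles must be disjoint; whether every id exists in a given alignment
#' is checked by [validate_groups()] (and by every analysis entry
#' point).
#'
#' @param parentA,parentB character vectors of sequence ids, non-empty.
#' @param query character vector of query ids; may be empty for
#'   manifests that only fix the parental panels.
#' @return a `sample_groups` object (a named list).
#' @export
sample_groups <- function(parentA, parentB, query = character()) {
  g <- list(parentA = as.character(parentA),
            parentB = as.character(parentB),
            query = as.character(query))
  if (length(g$parentA) == 0L || length(g$parentB) == 0L) {
    stop("every role needs at least one sequence id")
  }
  all_ids <- unlist(g, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    stop("roles must be disjoint; duplicated id(s): ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  }
  structure(g, class = "sample_groups")
}

#' Read a sample-group manifest
#'
#' Tab-separated file with two columns, `sequence_id` and `role`
#' (header optional); roles are `parentA`, `parentB`, `query`.
#'
#' @param path path to the TSV manifest.
#' @return a [sample_groups()] object.
#' @export
read_manifest <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("sequence_id", "role"),
                          colClasses = "character", strip.white = TRUE)
  if (identical(tolower(df$sequence_id[1L]), "sequence_id")) df <- df[-1L, ]
  roles <- c("parentA", "parentB", "query")
  if (!all(df$role %in% roles)) {
    stop("unknown role(s) in manifest: ",
         paste(unique(setdiff(df$role, roles)), collapse = ", "))
  }
  sample_groups(parentA = df$sequence_id[df$role == "parentA"],
                parentB = df$sequence_id[df$role == "parentB"],
                query = df$sequence_id[df$role == "query"])
}

#' Write a sample-group manifest
#' @param groups a [sample_groups()] object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(groups, path) {
  df <- data.frame(
    sequence_id = unlist(groups, use.names = FALSE),
    role = rep(names(groups), lengths(groups))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Check that every id in the groups exists in the alignment
#' @param aln a `hyb_alignment`.
#' @param groups a `sample_groups`.
#' @return `groups`, invisibly; errors on unknown ids.
#' @export
validate_groups <- function(aln, groups) {
  missing <- setdiff(unlist(groups, use.names = FALSE), sequence_ids(aln))
  if (length(missing)) {
    stop("sequence id(s) not in alignment: ", paste(missing, collapse = ", "))
  }
  invisible(groups)
}
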
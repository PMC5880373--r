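#' Four-channel trace matrix
#'
#' A `trace_matrix` holds per-position relative intensities of the four
#' dye channels (A, C, G, T) of a direct Sanger read — the quantitative
#' abstraction of an electropherogram.  Rows are positions; intensities
#' are non-negative and renormalised to sum to 1 per row.
#'
#' @param intensity numeric matrix with 4 columns (A, C, G, T) or a
#'   4-column data frame; raw (unnormalised) intensities are accepted.
#' @param provenance free-text origin note.
#' @return a `trace_matrix` object.
#' @export
trace_matrix <- function(intensity, provenance = "") {
  m <- as.matrix(intensity)
  if (ncol(m) != 4L) stop("a trace needs exactly 4 channels (A, C, G, T)")
  colnames(m) <- .BASES
  if (any(m < 0)) stop("channel intensities must be non-negative")
  tot <- rowSums(m)
  zero <- which(tot == 0)
  if (length(zero)) {
    stop("invalid-trace error: all-zero intensities at column ", zero[1L],
         call. = FALSE)
  }
  m <- m / tot
  structure(m, provenance = provenance,
            class = c("trace_matrix", "matrix", "array"))
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat("trace_matrix:", nrow(x), "positions\n")
  prov <- attr(x, "provenance")
  if (nzchar(prov)) cat("  provenance:", prov, "\n")
  print(utils::head(round(unclass(x), 3)))
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' Read a trace TSV (`pos A C G T` header, 1-based positions)
#' @param path input path.
#' @return a [trace_matrix()]; intensities are normalised on load.
#' @export
read_trace_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("pos", "A", "C", "G", "T")
  if (!all(need %in% names(df))) {
    stop("trace TSV must have columns: ", paste(need, collapse = " "))
  }
  df <- df[order(df$pos), ]
  if (!identical(as.integer(df$pos), seq_len(nrow(df)))) {
    stop("trace positions must be 1..n with no gaps")
  }
  trace_matrix(df[, .BASES], provenance = path)
}

#' Write a trace as TSV (`pos A C G T`)
#' @param trace a [trace_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(trace, path) {
  df <- data.frame(pos = seq_len(nrow(trace)), round(unclass(trace), 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Base-calling policy for polymorphic traces
#'
#' `major_threshold` (default 0.30): channels contributing strictly more
#' than this fraction of the column's total signal enter the 'major'
#' call; small secondary peaks at or below it are ignored, mirroring the
#' manual editing convention for noisy multi-copy markers.
#' `sensitive_floor` (default 0.02): channels at or above this fraction
#' enter the 'sensitive' call; rare ribotypes contributing only a few
#' percent of the signal remain visible there.
#'
#' @param major_threshold fraction in (sensitive_floor, 1).
#' @param sensitive_floor fraction in (0, major_threshold).
#' @return a `call_policy` object.
#' @export
call_policy <- function(major_threshold = 0.30, sensitive_floor = 0.02) {
  if (!(sensitive_floor > 0 && sensitive_floor < major_threshold &&
        major_threshold < 1)) {
    stop("need 0 < sensitive_floor < major_threshold < 1")
  }
  structure(list(major_threshold = major_threshold,
                 sensitive_floor = sensitive_floor),
            class = "call_policy")
}

#' Call 'major' and sensitive sequences from a trace
#'
#' Per column, the major symbol is the IUPAC union of the channels whose
#' fraction exceeds `major_threshold`; if no channel exceeds it, the
#' maximal channel(s) are used.  The sensitive symbol is the union of
#' all channels at or above `sensitive_floor`.  The major state set is
#' always a subset of the sensitive state set.
#'
#' @param trace a [trace_matrix()].
#' @param policy a [call_policy()].
#' @return list with `major` and `sensitive` (character strings of IUPAC
#'   symbols).
#' @examples
#' tr <- trace_matrix(rbind(c(0.8, 0, 0.2, 0)))
#' call_sequences(tr) # major "A", sensitive "R"
#' @export
call_sequences <- function(trace, policy = call_policy()) {
  frac <- unclass(trace) # rows already normalised
  over <- frac > policy$major_threshold
  none <- rowSums(over) == 0L
  if (any(none)) {
    mx <- apply(frac[none, , drop = FALSE], 1L, max)
    over[none, ] <- frac[none, , drop = FALSE] == mx
  }
  major_mask <- over %*% .BASE_BITS
  sens_mask <- (frac >= policy$sensitive_floor) %*% .BASE_BITS
  # floor below the smallest representable fraction can in principle
  # select nothing; fall back to the maximal channel
  empty <- sens_mask == 0L
  if (any(empty)) sens_mask[empty] <- major_mask[empty]
  list(major = paste(iupac_symbol(major_mask), collapse = ""),
       sensitive = paste(iupac_symbol(sens_mask), collapse = ""))
}

# map each position of `major` (ungapped) to the aligned position of
# `minor` (ungapped), via a global pairwise alignment; NA where the
# minor template has no base aligned to that major position.
aligned_cursor <- function(major_hap, minor_hap) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(minor_hap), Biostrings::DNAString(major_hap),
    type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -2, baseOnly = TRUE),
    gapOpening = 6, gapExtension = 2
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  i <- cumsum(s != "-") # major index per alignment column
  j <- cumsum(p != "-") # minor index per alignment column
  keep <- s != "-"
  out <- ifelse(p[keep] == "-", NA_integer_, j[keep])
  out
}

#' Simulate a skewed two-ribotype mixture trace
#'
#' Superimposes two ungapped haplotypes into one four-channel trace,
#' indexed on the major haplotype: each column receives intensity
#' `1 - minor_fraction` on the major base and `minor_fraction` on the
#' minor base at the \emph{aligned} position (the cursor shifts by one at
#' each 1-bp indel between the haplotypes, so the minor signal carries
#' the shift/backshift signature downstream of indels that
#' [detect_minor_component()] exploits).  Columns where the minor
#' template has no aligned base carry major signal only.  Multiplicative
#' log-normal noise of standard deviation `noise_sd` is applied per
#' channel, then each column is renormalised.
#'
#' @param major_hap,minor_hap ungapped sequences over A, C, G, T
#'   (character strings); lengths may differ by small indels.
#' @param minor_fraction fraction of total signal from the minor
#'   ribotype, in (0, 0.5].
#' @param noise_sd log-scale standard deviation of the multiplicative
#'   channel noise (>= 0).
#' @param seed integer seed; the simulation is deterministic given it.
#' @return a [trace_matrix()] of `nchar(major_hap)` positions.
#' @export
simulate_mixture_trace <- function(major_hap, minor_hap, minor_fraction,
                                   noise_sd = 0, seed = 1L) {
  if (!(minor_fraction > 0 && minor_fraction <= 0.5)) {
    stop("minor_fraction must be in (0, 0.5]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  maj <- strsplit(toupper(major_hap), "")[[1]]
  mnr <- strsplit(toupper(minor_hap), "")[[1]]
  if (!all(maj %in% .BASES) || !all(mnr %in% .BASES)) {
    stop("haplotypes must be ungapped sequences over A, C, G, T")
  }
  L <- length(maj)
  cursor <- if (identical(maj, mnr)) seq_len(L) else
    aligned_cursor(major_hap, minor_hap)
  inten <- matrix(0, L, 4L, dimnames = list(NULL, .BASES))
  inten[cbind(seq_len(L), match(maj, .BASES))] <- 1 - minor_fraction
  has_minor <- !is.na(cursor)
  idx <- cbind(which(has_minor), match(mnr[cursor[has_minor]], .BASES))
  inten[idx] <- inten[idx] + minor_fraction
  if (noise_sd > 0) {
    inten <- with_local_seed(seed, {
      inten * matrix(exp(stats::rnorm(4L * L, 0, noise_sd)), L, 4L)
    })
  }
  trace_matrix(inten, provenance = sprintf(
    "simulated mixture (f=%g, sd=%g, seed=%s)", minor_fraction, noise_sd,
    format(seed)))
}

#' Winner-take-all base call (chimeric-read artifact)
#'
#' Emulates an automatic base caller that resolves every polymorphic
#' position towards the locally taller peak: each channel is multiplied
#' by an independent log-normal jitter of standard deviation `jitter_sd`
#' and the argmax channel's base is emitted.  On a balanced two-ribotype
#' trace this produces a chimera — a mosaic of the two parental states.
#'
#' @param trace a [trace_matrix()].
#' @param jitter_sd log-scale sd of the per-channel jitter (>= 0); 0
#'   gives the plain argmax (exact ties resolved to the first channel in
#'   A, C, G, T order).
#' @param seed integer seed.
#' @return character string of called bases, one per trace position.
#' @export
winner_take_all_call <- function(trace, jitter_sd = 0, seed = 1L) {
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  frac <- unclass(trace)
  if (jitter_sd > 0) {
    frac <- with_local_seed(seed, {
      frac * matrix(exp(stats::rnorm(length(frac), 0, jitter_sd)),
                    nrow(frac), 4L)
    })
  }
  paste(.BASES[max.col(frac, ties.method = "first")], collapse = "")
}

#' Detect a minor ribotype in a polymorphic trace
#'
#' Extracts the secondary signal — channels whose fraction lies in
#' `[sensitive_floor, major_threshold]` — and asks which candidate
#' haplotype, at which integer frame offset, explains it.  For every
#' candidate and offset in `-max_offset..max_offset` the score is the
#' fraction of secondary-signal columns whose secondary channels contain
#' the candidate base at position `column - offset` (so a 1-bp deletion
#' in the minor template yields offset +1 downstream of it).  The trace
#' is then segmented into constant-offset runs by a sliding-window
#' change-point scan over the secondary-signal columns: a new segment
#' opens where a different offset outscores the current one over a
#' window of `window` secondary columns.
#'
#' @param trace a [trace_matrix()].
#' @param policy a [call_policy()].
#' @param candidates named character vector of ungapped candidate
#'   haplotypes.
#' @param max_offset maximum absolute frame offset considered.
#' @param window sliding-window length (in secondary-signal columns) of
#'   the change-point scan.
#' @return list with `best_candidate` (name, or `NA` when the trace has
#'   no secondary signal), `scores` (named vector: best-offset score per
#'   candidate) and `segments` (data frame `start`, `end`, `offset`,
#'   `candidate_id`, `score`; trace coordinates, 1-based inclusive).
#' @export
detect_minor_component <- function(trace, policy = call_policy(), candidates,
                                   max_offset = 2L, window = 20L) {
  if (length(candidates) < 1L) stop("need at least one candidate")
  if (is.null(names(candidates))) {
    names(candidates) <- paste0("candidate", seq_along(candidates))
  }
  if (any(grepl("-", candidates, fixed = TRUE))) {
    stop("candidates must be ungapped")
  }
  frac <- unclass(trace)
  sec <- frac >= policy$sensitive_floor & frac <= policy$major_threshold
  cols <- which(rowSums(sec) > 0L)
  empty_seg <- data.frame(start = integer(), end = integer(),
                          offset = integer(), candidate_id = character(),
                          score = numeric(), stringsAsFactors = FALSE)
  if (length(cols) == 0L) {
    return(list(best_candidate = NA_character_,
                scores = stats::setNames(numeric(length(candidates)),
                                         names(candidates)),
                segments = empty_seg))
  }
  offsets <- seq.int(-max_offset, max_offset)
  # match[[cand]][k, o]: candidate base at cols[k] - offset[o] is among
  # the secondary channels of column cols[k]
  sec_mask <- sec[cols, , drop = FALSE] %*% .BASE_BITS
  match_mats <- lapply(candidates, function(cand) {
    cs <- strsplit(toupper(cand), "")[[1]]
    cm <- iupac_mask(cs)
    sapply(offsets, function(o) {
      pos <- cols - o
      ok <- pos >= 1L & pos <= length(cs)
      hit <- logical(length(cols))
      hit[ok] <- bitwAnd(sec_mask[ok], cm[pos[ok]]) > 0L
      hit
    })
  })
  best_off_score <- vapply(match_mats, function(m) max(colMeans(m)),
                           numeric(1L))
  best <- names(candidates)[which.max(best_off_score)]
  # change-point scan over the best candidate's offset match profile
  m <- match_mats[[best]]
  k <- nrow(m)
  w <- min(window, k)
  nwin <- k - w + 1L
  csum <- apply(m, 2L, function(v) cumsum(c(0, v)))
  roll <- (csum[(w + 1L):(w + nwin), , drop = FALSE] -
             csum[1L:nwin, , drop = FALSE]) / w
  cur <- which.max(roll[1L, ])
  seg_start <- 1L # index into cols
  segs <- list()
  if (nwin > 1L) {
    for (t in 2L:nwin) {
      cand_off <- which.max(roll[t, ])
      if (cand_off != cur && roll[t, cand_off] > roll[t, cur]) {
        # refine the boundary: exact best split between the segment start
        # and the far end of the triggering window
        hi <- t + w - 1L
        splits <- (seg_start + 1L):hi
        gain <- vapply(splits, function(s) {
          sum(m[seg_start:(s - 1L), cur]) + sum(m[s:hi, cand_off])
        }, numeric(1L))
        # ties span columns compatible with both offsets; take the last
        # maximal split so the boundary sits at the first column that
        # positively supports the new offset
        s_best <- splits[max(which(gain == max(gain)))]
        segs[[length(segs) + 1L]] <- c(seg_start, s_best - 1L, cur)
        seg_start <- s_best
        cur <- cand_off
      }
    }
  }
  segs[[length(segs) + 1L]] <- c(seg_start, k, cur)
  seg_df <- do.call(rbind, lapply(seq_along(segs), function(si) {
    s <- segs[[si]]
    ki <- s[1L]:s[2L]
    data.frame(
      # segments tile the whole trace: extend to neighbours' midpoints
      start = if (si == 1L) 1L else as.integer(cols[s[1L]]),
      end = if (si == length(segs)) nrow(trace) else
        as.integer(cols[segs[[si + 1L]][1L]] - 1L),
      offset = offsets[s[3L]],
      candidate_id = best,
      score = mean(m[ki, s[3L]]),
      stringsAsFactors = FALSE
    )
  }))
  list(best_candidate = best,
       scores = best_off_score,
       segments = seg_df)
}
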
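#' Consensus policy for summarising a parental sample group
#'
#' Controls how the sequences assigned to one parent are collapsed into a
#' single per-column state set before diagnostic sites are searched.
#'
#' * `strict_union` (default): the state set is the union over all group
#'   members; intra-individual/intra-specific polymorphism widens the set.
#' * `majority`: the single most frequent resolved symbol; ties collapse
#'   to the union of the tied symbols.
#' * `single_reference`: the first listed id speaks for the group.
#'
#' `polymorphic_site_rule` governs columns where only one parent is
#' polymorphic: `omit_if_one_sided` (default) drops a column when exactly
#' one of the two parental state sets is ambiguous — the convention used
#' when tabulating diagnostic positions from electropherograms, since a
#' one-sided polymorphism cannot be told apart from unrelated
#' intra-individual variation.  `keep` retains such columns as long as
#' the sets are disjoint.
#'
#' @param mode one of `"strict_union"`, `"majority"`, `"single_reference"`.
#' @param polymorphic_site_rule one of `"omit_if_one_sided"`, `"keep"`.
#' @return a `consensus_policy` object.
#' @export
consensus_policy <- function(mode = c("strict_union", "majority",
                                      "single_reference"),
                             polymorphic_site_rule = c("omit_if_one_sided",
                                                       "keep")) {
  structure(list(mode = match.arg(mode),
                 polymorphic_site_rule = match.arg(polymorphic_site_rule)),
            class = "consensus_policy")
}

# per-column consensus bitmasks for a group of rows; 0 encodes MISSING
# (all members gapped at that column)
consensus_masks <- function(aln, ids, policy) {
  sub <- unclass(aln)[ids, , drop = FALSE]
  gap <- sub == "-"
  mask <- matrix(0L, nrow(sub), ncol(sub))
  mask[!gap] <- iupac_mask(sub[!gap])
  if (policy$mode == "single_reference") {
    return(mask[1L, ])
  }
  if (policy$mode == "strict_union") {
    out <- mask[1L, ]
    for (i in seq_len(nrow(mask))[-1L]) out <- bitwOr(out, mask[i, ])
    return(out)
  }
  # majority: most frequent non-gap symbol; ties -> union of tied symbols
  vapply(seq_len(ncol(sub)), function(j) {
    syms <- sub[!gap[, j], j]
    if (length(syms) == 0L) return(0L)
    tab <- table(syms)
    top <- names(tab)[tab == max(tab)]
    Reduce(bitwOr, iupac_mask(top))
  }, integer(1L))
}

#' Consensus state set of a parental group at one column
#'
#' @param aln a [hyb_alignment()].
#' @param ids sequence ids of the group members.
#' @param column 1-based column index.
#' @param policy a [consensus_policy()].
#' @return character vector of nucleotide states, or `NA` if every group
#'   member is gapped at the column (missing).
#' @export
parent_consensus <- function(aln, ids, column, policy = consensus_policy()) {
  if (column < 1L || column > ncol(aln)) {
    stop("column ", column, " outside alignment (1..", ncol(aln), ")")
  }
  if (length(setdiff(ids, rownames(aln)))) {
    stop("unknown sequence id(s): ",
         paste(setdiff(ids, rownames(aln)), collapse = ", "))
  }
  m <- consensus_masks(aln, ids, policy)[column]
  if (m == 0L) return(NA_character_)
  .BASES[bitwAnd(m, .BASE_BITS) > 0L]
}

#' Find positions diagnostic between two parental taxa
#'
#' A column is diagnostic when both parental consensus state sets are
#' present (not all-gap), \emph{disjoint}, and — under the default
#' `omit_if_one_sided` rule — not polymorphic on exactly one side.
#' Columns where any parental group member carries a gap are excluded:
#' indels are handled as separate binary characters
#' ([simple_indel_code()]), not as additivity characters.
#'
#' @param aln a [hyb_alignment()].
#' @param parentA,parentB character vectors of sequence ids (or a
#'   [sample_groups()] object passed via `groups`).
#' @param policy a [consensus_policy()].
#' @return data frame of class `diagnostic_sites` with columns `column`
#'   (1-based, ascending), `state_a`, `state_b` (IUPAC symbols of the
#'   parental consensus sets).  An empty result is returned with a
#'   warning, not an error.
#' @export
find_diagnostic_sites <- function(aln, parentA, parentB,
                                  policy = consensus_policy()) {
  ids <- c(parentA, parentB)
  if (length(setdiff(ids, rownames(aln)))) {
    stop("unknown sequence id(s): ",
         paste(setdiff(ids, rownames(aln)), collapse = ", "))
  }
  mA <- consensus_masks(aln, parentA, policy)
  mB <- consensus_masks(aln, parentB, policy)
  any_gap <- colSums(unclass(aln)[ids, , drop = FALSE] == "-") > 0L
  keep <- mA > 0L & mB > 0L & !any_gap & bitwAnd(mA, mB) == 0L
  if (policy$polymorphic_site_rule == "omit_if_one_sided") {
    one_sided <- xor(n_states(pmax(mA, 1L)) > 1L, n_states(pmax(mB, 1L)) > 1L)
    keep <- keep & !one_sided
  }
  cols <- which(keep)
  if (length(cols) == 0L) {
    warning("no diagnostic sites found between the parental groups")
  }
  structure(
    data.frame(column = cols,
               state_a = if (length(cols)) iupac_symbol(mA[cols]) else character(),
               state_b = if (length(cols)) iupac_symbol(mB[cols]) else character(),
               stringsAsFactors = FALSE),
    class = c("diagnostic_sites", "data.frame")
  )
}

#' Classify a query symbol at a diagnostic site
#'
#' Vectorised over sites.  The call is
#' * `ADDITIVE` when the query state set equals the union of the two
#'   parental sets (the hybrid expectation),
#' * `PARENT_A` / `PARENT_B` when it equals one parental set exactly,
#' * `MISSING` for a gap,
#' * `OTHER` for anything else (including partial or superset
#'   ambiguities).
#'
#' @param state_a,state_b IUPAC symbols of the parental state sets
#'   (disjoint).
#' @param query IUPAC symbols or `"-"` observed in the query.
#' @return character vector of calls.
#' @examples
#' classify_site("C", "T", "Y") # ADDITIVE
#' classify_site("C", "T", "C") # PARENT_A
#' @export
classify_site <- function(state_a, state_b, query) {
  n <- max(length(state_a), length(state_b), length(query))
  state_a <- rep_len(state_a, n); state_b <- rep_len(state_b, n)
  query <- rep_len(query, n)
  mA <- iupac_mask(state_a); mB <- iupac_mask(state_b)
  if (any(bitwAnd(mA, mB) != 0L)) {
    stop("parental state sets must be disjoint at a diagnostic site")
  }
  out <- rep("OTHER", n)
  gap <- query == "-"
  mQ <- rep(0L, n)
  mQ[!gap] <- iupac_mask(query[!gap])
  out[gap] <- "MISSING"
  out[!gap & mQ == bitwOr(mA, mB)] <- "ADDITIVE"
  out[!gap & mQ == mA] <- "PARENT_A"
  out[!gap & mQ == mB] <- "PARENT_B"
  out
}

#' Verdict thresholds for the additivity decision table
#'
#' With `a` the additivity index and `fA`, `fB` the parent-specific call
#' fractions (all over the non-missing diagnostic sites), the default
#' table is:
#' `PURE_A` if `fA >= 0.95` and `a <= 0.05` (`PURE_B` symmetric);
#' `HYBRID_FULL` if `a == 1`; `HYBRID` if `a >= 0.8`;
#' `CHIMERIC` if `a < 0.8` and `min(fA, fB) >= 0.2`;
#' `PARTIALLY_RESOLVED` if `0.1 <= a < 0.8` and `max(fA, fB) >= 0.5`;
#' otherwise `AMBIGUOUS`.  Chimeric reads — base-caller artifacts that
#' resolve each polymorphic position towards the locally taller peak —
#' show a mosaic of both parental states with little additivity;
#' partially resolved reads lean towards one parent but retain residual
#' polymorphism.
#'
#' @param pure_min_parent minimum parent-specific fraction for `PURE_*`.
#' @param pure_max_additivity maximum additivity index for `PURE_*`.
#' @param hybrid_min_additivity minimum index for `HYBRID`.
#' @param chimeric_min_parent minimum of both parental fractions for
#'   `CHIMERIC`.
#' @param partial_min_additivity,partial_max_additivity index window for
#'   `PARTIALLY_RESOLVED`.
#' @param partial_min_parent minimum of the larger parental fraction for
#'   `PARTIALLY_RESOLVED`.
#' @return a `verdict_thresholds` object.
#' @export
verdict_thresholds <- function(pure_min_parent = 0.95,
                               pure_max_additivity = 0.05,
                               hybrid_min_additivity = 0.8,
                               chimeric_min_parent = 0.2,
                               partial_min_additivity = 0.1,
                               partial_max_additivity = 0.8,
                               partial_min_parent = 0.5) {
  structure(list(pure_min_parent = pure_min_parent,
                 pure_max_additivity = pure_max_additivity,
                 hybrid_min_additivity = hybrid_min_additivity,
                 chimeric_min_parent = chimeric_min_parent,
                 partial_min_additivity = partial_min_additivity,
                 partial_max_additivity = partial_max_additivity,
                 partial_min_parent = partial_min_parent),
            class = "verdict_thresholds")
}

assign_verdict <- function(counts, thresholds) {
  usable <- counts[["n_diagnostic"]] - counts[["n_missing"]]
  if (usable <= 0L) return("AMBIGUOUS")
  a <- counts[["n_additive"]] / usable
  fA <- counts[["n_parentA"]] / usable
  fB <- counts[["n_parentB"]] / usable
  th <- thresholds
  if (fA >= th$pure_min_parent && a <= th$pure_max_additivity) return("PURE_A")
  if (fB >= th$pure_min_parent && a <= th$pure_max_additivity) return("PURE_B")
  if (a == 1) return("HYBRID_FULL")
  if (a >= th$hybrid_min_additivity) return("HYBRID")
  if (a < th$hybrid_min_additivity && min(fA, fB) >= th$chimeric_min_parent) {
    return("CHIMERIC")
  }
  if (a >= th$partial_min_additivity && a < th$partial_max_additivity &&
      max(fA, fB) >= th$partial_min_parent) {
    return("PARTIALLY_RESOLVED")
  }
  "AMBIGUOUS"
}

#' Diagnose a putative hybrid from character additivity
#'
#' Finds positions diagnostic between the two parental groups, classifies
#' the (single) query sequence at each of them, and aggregates the calls
#' into an additivity index and a verdict.  A fully additive query — one
#' that carries the combined IUPAC states of both parents at every
#' diagnostic position — is the molecular signature of a hybrid.
#'
#' @param aln a [hyb_alignment()].
#' @param groups a [sample_groups()] with exactly one `query` id.
#' @param policy a [consensus_policy()].
#' @param thresholds a [verdict_thresholds()].
#' @return an `additivity_report`: list with `n_diagnostic`, the call
#'   counts (`n_additive`, `n_parentA`, `n_parentB`, `n_other`,
#'   `n_missing`), `additivity_index` (additive fraction of non-missing
#'   diagnostic sites), `verdict`, `site_calls` (per-site data frame),
#'   plus the policy and thresholds used and an explanatory `note` when
#'   no usable site exists.
#' @export
diagnose <- function(aln, groups, policy = consensus_policy(),
                     thresholds = verdict_thresholds()) {
  validate_groups(aln, groups)
  if (length(groups$query) != 1L) {
    stop("diagnose() needs exactly one query sequence; got ",
         length(groups$query))
  }
  sites <- withCallingHandlers(
    find_diagnostic_sites(aln, groups$parentA, groups$parentB, policy),
    warning = function(w) invokeRestart("muffleWarning")
  )
  qrow <- unclass(aln)[groups$query, ]
  if (nrow(sites) > 0L) {
    qsym <- qrow[sites$column]
    calls <- classify_site(sites$state_a, sites$state_b, qsym)
    site_calls <- data.frame(column = sites$column,
                             state_a = sites$state_a,
                             state_b = sites$state_b,
                             query = qsym,
                             call = calls,
                             stringsAsFactors = FALSE,
                             row.names = NULL)
  } else {
    site_calls <- data.frame(column = integer(), state_a = character(),
                             state_b = character(), query = character(),
                             call = character(), stringsAsFactors = FALSE)
    calls <- character()
  }
  counts <- c(
    n_diagnostic = nrow(site_calls),
    n_additive = sum(calls == "ADDITIVE"),
    n_parentA = sum(calls == "PARENT_A"),
    n_parentB = sum(calls == "PARENT_B"),
    n_other = sum(calls == "OTHER"),
    n_missing = sum(calls == "MISSING")
  )
  usable <- counts[["n_diagnostic"]] - counts[["n_missing"]]
  idx <- if (usable > 0L) counts[["n_additive"]] / usable else NA_real_
  verdict <- assign_verdict(counts, thresholds)
  note <- if (usable <= 0L) {
    "no usable diagnostic sites (none found, or all missing in the query)"
  } else NA_character_
  structure(list(query_id = groups$query,
                 n_diagnostic = counts[["n_diagnostic"]],
                 n_additive = counts[["n_additive"]],
                 n_parentA = counts[["n_parentA"]],
                 n_parentB = counts[["n_parentB"]],
                 n_other = counts[["n_other"]],
                 n_missing = counts[["n_missing"]],
                 additivity_index = idx,
                 verdict = verdict,
                 site_calls = site_calls,
                 policy = policy,
                 thresholds = thresholds,
                 note = note),
            class = "additivity_report")
}

#' @export
print.additivity_report <- function(x, ...) {
  cat("Additivity report for query '", x$query_id, "'\n", sep = "")
  cat("  diagnostic sites:", x$n_diagnostic, "\n")
  cat(sprintf("  additive %d | parentA %d | parentB %d | other %d | missing %d\n",
              x$n_additive, x$n_parentA, x$n_parentB, x$n_other, x$n_missing))
  cat("  additivity index:",
      if (is.na(x$additivity_index)) "NA" else
        sprintf("%.3f", x$additivity_index), "\n")
  cat("  verdict:", x$verdict, "\n")
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Write an additivity report as JSON
#'
#' Counts, index (3 decimals), verdict and the policy/thresholds used;
#' per-site calls go to TSV via [write_site_calls()].
#'
#' @param report an `additivity_report`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  obj <- list(
    query_id = report$query_id,
    n_diagnostic = report$n_diagnostic,
    n_additive = report$n_additive,
    n_parentA = report$n_parentA,
    n_parentB = report$n_parentB,
    n_other = report$n_other,
    n_missing = report$n_missing,
    additivity_index = if (is.na(report$additivity_index)) NULL else
      round(report$additivity_index, 3),
    verdict = report$verdict,
    policy = unclass(report$policy),
    thresholds = unclass(report$thresholds),
    note = if (is.na(report$note)) NULL else report$note
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write per-site calls as TSV
#' @param report an `additivity_report`.
#' @param path output TSV path (columns: column, state_a, state_b,
#'   query, call).
#' @return `path`, invisibly.
#' @export
write_site_calls <- function(report, path) {
  utils::write.table(report$site_calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
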
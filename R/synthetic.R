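#' Scenario specification for synthetic hybrid-diagnosis data
#'
#' Describes a pair of parental haplotypes and the reads derived from
#' them.  Defaults emulate a highly polymorphic multi-copy nuclear
#' spacer in closely related congeners: 600 aligned columns at 5%
#' parental divergence yield on the order of 25-30 diagnostic positions;
#' two 1-bp indels — an early deletion and a late insertion in parent B —
#' reproduce the shift/backshift frame signature that indels leave in a
#' mixed direct read; 5% of positions per parent carry a taxon-level
#' intra-individual ambiguity code.
#'
#' @param length number of alignment columns.
#' @param divergence per-site probability that parent B carries a
#'   different base than parent A.
#' @param indels data frame with columns `column` (1-based) and `kind`
#'   (`"del_b"`: 1-bp gap in B; `"ins_b"`: 1-bp gap in A, extra base in
#'   B); default one `del_b` at 25% and one `ins_b` at 75% of the
#'   length.  Use a 0-row data frame for no indels.
#' @param intra_polymorphism_rate per-site probability that a parent
#'   carries an ambiguity code (its own base united with one random
#'   other base).  Polymorphisms are attached to the taxon, so every
#'   read of that parent shows them.
#' @param minor_fraction minor-ribotype signal fraction for mixture
#'   traces, in (0, 0.5].
#' @param noise_sd log-normal channel noise sd for traces (also the
#'   base-caller jitter for chimeric reads).
#' @param artifact_mode `"none"` or `"winner_take_all"`.
#' @param seed integer seed; everything downstream is deterministic
#'   given it.
#' @return a `scenario_spec` object.
#' @export
scenario_spec <- function(length = 600L,
                          divergence = 0.05,
                          indels = NULL,
                          intra_polymorphism_rate = 0.05,
                          minor_fraction = 0.5,
                          noise_sd = 0.1,
                          artifact_mode = c("none", "winner_take_all"),
                          seed = 1L) {
  length <- as.integer(length)
  if (length <= 0L) stop("length must be positive")
  if (divergence < 0 || divergence > 1) stop("divergence must be in [0, 1]")
  if (intra_polymorphism_rate < 0 || intra_polymorphism_rate > 1) {
    stop("intra_polymorphism_rate must be in [0, 1]")
  }
  if (!(minor_fraction > 0 && minor_fraction <= 0.5)) {
    stop("minor_fraction must be in (0, 0.5]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(indels)) {
    indels <- data.frame(column = c(round(length * 0.25), round(length * 0.75)),
                         kind = c("del_b", "ins_b"),
                         stringsAsFactors = FALSE)
  }
  if (nrow(indels)) {
    stopifnot(all(indels$kind %in% c("del_b", "ins_b")),
              all(indels$column >= 1L & indels$column <= length),
              !anyDuplicated(indels$column))
  }
  structure(list(length = length, divergence = divergence, indels = indels,
                 intra_polymorphism_rate = intra_polymorphism_rate,
                 minor_fraction = minor_fraction, noise_sd = noise_sd,
                 artifact_mode = match.arg(artifact_mode),
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Generate a parental haplotype pair with known truth
#'
#' Parent A is i.i.d. uniform over A, C, G, T; parent B substitutes each
#' site to a different base with probability `divergence`, then the
#' scenario's 1-bp indels are applied.  Taxon-level ambiguity codes are
#' injected at rate `intra_polymorphism_rate` into each parent's
#' \emph{read} (the coded aligned sequence); the clean haplotypes
#' underlie all trace simulation.  The truth record lists the diagnostic
#' columns a consensus under the default policy (strict union,
#' one-sided-polymorphism omission) will find — computed here by direct
#' set logic on the known substitution and injection positions.
#'
#' @param spec a [scenario_spec()].
#' @return a `parent_pair`: list with `read_a`/`read_b` (aligned coded
#'   character vectors), `aligned_a`/`aligned_b` (clean aligned
#'   vectors), `hap_a`/`hap_b` (ungapped clean strings), `truth` (list:
#'   `diagnostic_columns`, `substitution_columns`, `poly_a_columns`,
#'   `poly_b_columns`, `indels`) and `spec`.
#' @export
generate_parent_pair <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  L <- spec$length
  with_local_seed(spec$seed, {
    a <- sample(.BASES, L, replace = TRUE)
    b <- a
    sub <- stats::runif(L) < spec$divergence
    if (any(sub)) {
      b[sub] <- vapply(a[sub], function(x) sample(setdiff(.BASES, x), 1L),
                       character(1L))
    }
    del_cols <- spec$indels$column[spec$indels$kind == "del_b"]
    ins_cols <- spec$indels$column[spec$indels$kind == "ins_b"]
    b[del_cols] <- "-"
    a[ins_cols] <- "-"
    b[ins_cols] <- sample(.BASES, length(ins_cols), replace = TRUE)
    sub[c(del_cols, ins_cols)] <- FALSE
    # taxon-level intra-individual polymorphism codes
    inject <- function(x) {
      hit <- stats::runif(L) < spec$intra_polymorphism_rate & x != "-"
      coded <- x
      if (any(hit)) {
        extra <- vapply(x[hit], function(base) {
          sample(setdiff(.BASES, base), 1L)
        }, character(1L))
        coded[hit] <- iupac_union(x[hit], extra)
      }
      list(coded = coded, columns = which(hit))
    }
    ia <- inject(a)
    ib <- inject(b)
    # diagnostic columns under strict_union + omit_if_one_sided, by set
    # logic on the known truth
    amb_a <- seq_len(L) %in% ia$columns
    amb_b <- seq_len(L) %in% ib$columns
    disjoint <- vapply(seq_len(L), function(j) {
      if (a[j] == "-" || b[j] == "-") return(FALSE)
      bitwAnd(iupac_mask(ia$coded[j]), iupac_mask(ib$coded[j])) == 0L
    }, logical(1L))
    diag_cols <- which(sub & disjoint & !xor(amb_a, amb_b))
    structure(list(
      read_a = ia$coded, read_b = ib$coded,
      aligned_a = a, aligned_b = b,
      hap_a = paste(a[a != "-"], collapse = ""),
      hap_b = paste(b[b != "-"], collapse = ""),
      truth = list(diagnostic_columns = diag_cols,
                   substitution_columns = which(sub),
                   poly_a_columns = ia$columns,
                   poly_b_columns = ib$columns,
                   indels = spec$indels),
      spec = spec
    ), class = "parent_pair")
  })
}

# place a string called on parent A's ungapped coordinates back into
# alignment coordinates ('-' where A is gapped)
aframe_read <- function(pair, called) {
  L <- pair$spec$length
  read <- rep("-", L)
  read[pair$aligned_a != "-"] <- strsplit(called, "")[[1]]
  read
}

#' Generate one sample read (and trace) of a known category
#'
#' * `PURE_A` / `PURE_B`: the parent's coded read (taxon-level
#'   polymorphisms included; clonal, so identical to the reference).
#' * `HYBRID`: a mixture trace of the two clean haplotypes at the
#'   scenario's `minor_fraction` and `noise_sd`; the read is the
#'   sensitive IUPAC call mapped back to alignment coordinates.
#' * `CHIMERIC`: a balanced (50/50) mixture trace passed through the
#'   winner-take-all base caller with jitter `noise_sd`.
#'
#' @param pair a [generate_parent_pair()] result.
#' @param category one of `"PURE_A"`, `"PURE_B"`, `"HYBRID"`,
#'   `"CHIMERIC"`.
#' @param seed integer seed for the stochastic categories.
#' @param policy a [call_policy()] used for the sensitive call.
#' @return list with `read` (aligned character vector), `trace` (a
#'   [trace_matrix()] or `NULL`), `category`, `seed`.
#' @export
generate_sample <- function(pair, category, seed = 1L,
                            policy = call_policy()) {
  stopifnot(inherits(pair, "parent_pair"))
  category <- match.arg(category, c("PURE_A", "PURE_B", "HYBRID", "CHIMERIC"))
  spec <- pair$spec
  out <- switch(
    category,
    PURE_A = list(read = pair$read_a, trace = NULL),
    PURE_B = {
      # B's read in alignment coordinates (gap where B is gapped)
      list(read = pair$read_b, trace = NULL)
    },
    HYBRID = {
      tr <- simulate_mixture_trace(pair$hap_a, pair$hap_b,
                                   minor_fraction = spec$minor_fraction,
                                   noise_sd = spec$noise_sd, seed = seed)
      sens <- call_sequences(tr, policy)$sensitive
      list(read = aframe_read(pair, sens), trace = tr)
    },
    CHIMERIC = {
      tr <- simulate_mixture_trace(pair$hap_a, pair$hap_b,
                                   minor_fraction = 0.5,
                                   noise_sd = spec$noise_sd, seed = seed)
      wta <- winner_take_all_call(tr, jitter_sd = spec$noise_sd,
                                  seed = child_seed(seed, 1L))
      list(read = aframe_read(pair, wta), trace = tr)
    }
  )
  out$category <- category
  out$seed <- seed
  out
}

#' Assemble parents plus one query into an alignment with groups
#'
#' Convenience for diagnosing generated samples: builds a
#' [hyb_alignment()] holding the two parental reads and the query read,
#' plus the matching [sample_groups()].
#'
#' @param pair a [generate_parent_pair()] result.
#' @param read aligned query read (character vector, as returned by
#'   [generate_sample()]).
#' @param query_id id for the query row.
#' @return list with `alignment` and `groups`.
#' @export
pair_alignment <- function(pair, read, query_id = "query") {
  seqs <- c(parentA = paste(pair$read_a, collapse = ""),
            parentB = paste(pair$read_b, collapse = ""))
  seqs[query_id] <- paste(read, collapse = "")
  list(alignment = hyb_alignment(seqs),
       groups = sample_groups("parentA", "parentB", query_id))
}

#' Generate a benchmark data set on disk
#'
#' Writes, under `out_dir`: `alignment.fasta` (parental reads plus every
#' sample read, all in alignment coordinates), `groups.tsv` (parental
#' role manifest), `truth.json` (scenario parameters, true diagnostic
#' columns, and the true category of every sample) and
#' `traces/<id>.tsv` for the trace-bearing samples.  Regenerating with
#' the same spec produces byte-identical files.
#'
#' @param spec a [scenario_spec()].
#' @param n_per_category samples per category (all four categories are
#'   generated).
#' @param out_dir output directory (created if needed).
#' @return data frame manifest of written files (`file`, `type`),
#'   invisibly plus the `parent_pair` as attribute `"pair"`.
#' @export
generate_benchmark <- function(spec, n_per_category, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  trace_dir <- file.path(out_dir, "traces")
  dir.create(trace_dir, showWarnings = FALSE)
  pair <- generate_parent_pair(spec)
  cats <- c("PURE_A", "PURE_B", "HYBRID", "CHIMERIC")
  ids <- character(); reads <- list(); truth_samples <- list()
  files <- data.frame(file = character(), type = character(),
                      stringsAsFactors = FALSE)
  k <- 0L
  for (cat in cats) {
    for (i in seq_len(n_per_category)) {
      k <- k + 1L
      id <- sprintf("%s_%02d", tolower(cat), i)
      smp <- generate_sample(pair, cat, seed = child_seed(spec$seed, k))
      ids <- c(ids, id)
      reads[[id]] <- smp$read
      truth_samples[[id]] <- list(category = cat, seed = smp$seed)
      if (!is.null(smp$trace)) {
        tp <- file.path(trace_dir, paste0(id, ".tsv"))
        write_trace_tsv(smp$trace, tp)
        files <- rbind(files, data.frame(file = tp, type = "trace"))
      }
    }
  }
  seqs <- c(parentA = paste(pair$read_a, collapse = ""),
            parentB = paste(pair$read_b, collapse = ""),
            vapply(reads, paste, character(1L), collapse = ""))
  aln_path <- file.path(out_dir, "alignment.fasta")
  write_alignment(hyb_alignment(seqs), aln_path)
  grp_path <- file.path(out_dir, "groups.tsv")
  utils::write.table(
    data.frame(id = c("parentA", "parentB"), role = c("parentA", "parentB")),
    grp_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(list(
    scenario = list(length = spec$length, divergence = spec$divergence,
                    intra_polymorphism_rate = spec$intra_polymorphism_rate,
                    minor_fraction = spec$minor_fraction,
                    noise_sd = spec$noise_sd, seed = spec$seed,
                    indels = spec$indels),
    diagnostic_columns = pair$truth$diagnostic_columns,
    samples = truth_samples
  ), truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- rbind(
    data.frame(file = c(aln_path, grp_path, truth_path),
               type = c("alignment", "manifest", "truth")),
    files)
  rownames(files) <- NULL
  attr(files, "pair") <- pair
  invisible(files)
}
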
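test_that("trace construction normalises and validates intensities", {
  tr <- trace_matrix(rbind(c(2, 0, 0, 0), c(1, 1, 0, 0)))
  expect_equal(rowSums(unclass(tr)), c(1, 1))
  expect_error(trace_matrix(rbind(c(1, 0, 0, 0), c(0, 0, 0, 0))),
               "invalid-trace.*column 2")
  expect_error(trace_matrix(rbind(c(-1, 1, 0, 0))), "non-negative")
  expect_error(call_policy(0.3, 0.4), "sensitive_floor < major_threshold")
})

test_that("trace TSV round-trips through pos/A/C/G/T format", {
  set.seed(5)
  tr <- trace_matrix(matrix(runif(40, 0.01, 1), 10, 4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace_tsv(tr, path)
  back <- read_trace_tsv(path)
  expect_equal(unclass(back), unclass(tr), tolerance = 1e-4,
               ignore_attr = TRUE)
  writeLines("pos\tA\tC\tG", path)
  expect_error(read_trace_tsv(path), "columns")
})

test_that("major/sensitive calling follows the threshold rules", {
  tr <- trace_matrix(rbind(
    c(0.80, 0, 0.20, 0),   # major A, sensitive R
    c(0.50, 0, 0.50, 0),   # both channels above 0.30 -> R / R
    c(0.97, 0, 0.03, 0),   # secondary at 3%: ignored by major, kept by sensitive
    c(0.99, 0, 0.01, 0)))  # below the 2% floor: invisible even to sensitive
  calls <- call_sequences(tr)
  expect_identical(calls$major, "ARAA")
  expect_identical(calls$sensitive, "RRRA")
  # exactly 30% is ignored: the major rule is strictly greater-than
  tr2 <- trace_matrix(rbind(c(0.70, 0.30, 0, 0)))
  expect_identical(call_sequences(tr2)$major, "A")
  # no channel above the threshold: argmax channel(s) used
  tr3 <- trace_matrix(rbind(c(0.28, 0.26, 0.26, 0.20)))
  expect_identical(call_sequences(tr3)$major, "A")
})

test_that("major states are always a subset of sensitive states", {
  set.seed(31)
  for (i in 1:20) {
    tr <- trace_matrix(matrix(rexp(200), 50, 4))
    calls <- call_sequences(tr)
    maj <- strsplit(calls$major, "")[[1]]
    sen <- strsplit(calls$sensitive, "")[[1]]
    for (j in seq_along(maj)) {
      expect_true(all(parse_iupac(maj[j]) %in% parse_iupac(sen[j])))
    }
  }
})

test_that("mixture simulation reproduces degenerate and additive cases", {
  set.seed(9)
  hapA <- random_seq(120)
  # near-zero minor fraction: major call is the major haplotype
  hapB <- random_seq(120)
  tr <- simulate_mixture_trace(hapA, hapB, 1e-9, 0, seed = 1)
  expect_identical(call_sequences(tr)$major, hapA)
  # identical haplotypes: every column single-channel
  tr2 <- simulate_mixture_trace(hapA, hapA, 0.5, 0, seed = 1)
  expect_true(all(rowSums(unclass(tr2) > 0) == 1))
  # 30 known differences, balanced, noiseless: sensitive call additive
  # at exactly those sites (construction oracle)
  a <- strsplit(hapA, "")[[1]]
  b <- a
  sites <- sort(sample(120, 30))
  for (j in sites) b[j] <- sample(setdiff(BASES, a[j]), 1)
  tr3 <- simulate_mixture_trace(hapA, paste(b, collapse = ""), 0.5, 0, seed = 1)
  sens <- strsplit(call_sequences(tr3)$sensitive, "")[[1]]
  for (j in seq_len(120)) {
    expected <- if (j %in% sites) iupac_union(a[j], b[j]) else a[j]
    expect_identical(sens[j], expected)
  }
  expect_error(simulate_mixture_trace(hapA, hapB, 0.7, 0), "minor_fraction")
  expect_error(simulate_mixture_trace("AC-G", "ACG", 0.1, 0), "ungapped")
})

test_that("stochastic trace operations are deterministic under a fixed seed", {
  hapA <- random_seq(80); hapB <- random_seq(80)
  t1 <- simulate_mixture_trace(hapA, hapB, 0.1, 0.2, seed = 42)
  t2 <- simulate_mixture_trace(hapA, hapB, 0.1, 0.2, seed = 42)
  t3 <- simulate_mixture_trace(hapA, hapB, 0.1, 0.2, seed = 43)
  expect_identical(unclass(t1), unclass(t2))
  expect_false(identical(unclass(t1), unclass(t3)))
  expect_identical(winner_take_all_call(t1, 0.2, seed = 7),
                   winner_take_all_call(t1, 0.2, seed = 7))
  # no global RNG disturbance
  set.seed(1); before <- .Random.seed
  invisible(simulate_mixture_trace(hapA, hapB, 0.1, 0.2, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("winner-take-all calling resolves towards the taller peak", {
  hapA <- random_seq(60)
  # 70/30 skew without jitter: always the 70% base
  hapB <- chartr("ACGT", "GTAC", hapA) # differs everywhere
  tr <- simulate_mixture_trace(hapA, hapB, 0.3, 0, seed = 1)
  expect_identical(winner_take_all_call(tr, 0, seed = 1), hapA)
  # pure trace: input returned regardless of jitter
  trp <- simulate_mixture_trace(hapA, hapA, 0.5, 0, seed = 1)
  expect_identical(winner_take_all_call(trp, 0.3, seed = 2), hapA)
})

test_that("balanced chimeric resolution splits ~50/50 across many columns", {
  set.seed(77)
  a <- rep("A", 1000)
  b <- rep("G", 1000)
  tr <- simulate_mixture_trace(paste(a, collapse = ""),
                               paste(b, collapse = ""), 0.5, 0, seed = 1)
  called <- strsplit(winner_take_all_call(tr, 0.2, seed = 11), "")[[1]]
  frac_a <- mean(called == "A")
  expect_gt(frac_a, 0.45)
  expect_lt(frac_a, 0.55)
  expect_true(all(called %in% c("A", "G")))
})

test_that("minor-component detection recovers the candidate and its frame shifts", {
  set.seed(13)
  a <- strsplit(random_seq(300), "")[[1]]
  diffs <- sort(sample(300, 16))
  b <- a
  for (j in diffs) b[j] <- sample(setdiff(BASES, a[j]), 1)
  hapA <- paste(a, collapse = "")
  minor <- paste(b[-150], collapse = "") # 1-bp deletion at column 150
  tr <- simulate_mixture_trace(hapA, minor, 0.05, 0, seed = 1)
  det <- detect_minor_component(tr, call_policy(),
                                c(parentA = hapA, parentB = minor),
                                window = 5)
  expect_identical(det$best_candidate, "parentB")
  expect_gt(det$scores[["parentB"]], det$scores[["parentA"]])
  expect_equal(det$segments$offset[1], 0)
  expect_equal(det$segments$offset[nrow(det$segments)], 1)
  # segments tile the trace and the boundary falls inside the
  # uninformative interval around the true indel position
  expect_equal(det$segments$start[1], 1)
  expect_equal(det$segments$end[nrow(det$segments)], 300)
  boundary <- det$segments$start[nrow(det$segments)]
  lo <- max(diffs[diffs < 150])
  # the first downstream difference whose secondary base distinguishes
  # offset +1 from offset 0 (a site can coincidentally match both)
  post <- diffs[diffs > 150 & diffs < 300]
  hi <- post[vapply(post, function(j) b[j + 1] != b[j], logical(1))][1]
  expect_gt(boundary, lo)
  expect_lte(boundary, hi)

  # pure trace: nothing to detect
  trp <- simulate_mixture_trace(hapA, hapA, 0.5, 0, seed = 1)
  detp <- detect_minor_component(trp, call_policy(), c(parentA = hapA))
  expect_true(is.na(detp$best_candidate))
  expect_equal(nrow(detp$segments), 0)
})
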
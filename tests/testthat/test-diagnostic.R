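test_that("parental consensus follows the policy modes", {
  aln <- hyb_alignment(c(a1 = "AACA", a2 = "ARTC", a3 = "AAC-",
                         b1 = "GGGG", q = "AAAA"))
  ids <- c("a1", "a2", "a3")
  expect_identical(parent_consensus(aln, ids, 1), "A")
  expect_setequal(parent_consensus(aln, ids, 2,
                                   consensus_policy("strict_union")),
                  c("A", "G"))
  # majority: most frequent resolved symbol
  expect_identical(parent_consensus(aln, ids, 3,
                                    consensus_policy("majority")), "C")
  # majority tie at column 4 (A, C after dropping the gap) -> union
  expect_setequal(parent_consensus(aln, ids, 4,
                                   consensus_policy("majority")),
                  c("A", "C"))
  expect_identical(parent_consensus(aln, ids, 2,
                                    consensus_policy("single_reference")), "A")
  # all-gap column is missing
  aln2 <- hyb_alignment(c(a1 = "A-", a2 = "A-", b = "GG"))
  expect_true(is.na(parent_consensus(aln2, c("a1", "a2"), 2)))
  expect_error(parent_consensus(aln, ids, 99), "outside")
})

test_that("diagnostic sites require disjoint parental state sets", {
  aln <- hyb_alignment(c(pa = "AAYAG", pb = "GRAC-", q = "RRWAG"))
  sites <- find_diagnostic_sites(aln, "pa", "pb")
  # col1 A|G diagnostic; col2 A|R overlap; col3 Y|A one-sided (omitted);
  # col4 A|C diagnostic; col5 gap in a parent (excluded)
  expect_identical(sites$column, c(1L, 4L))
  expect_identical(sites$state_a, c("A", "A"))
  expect_identical(sites$state_b, c("G", "C"))

  # keep rule retains the one-sided polymorphic column (Y vs A disjoint)
  keep <- find_diagnostic_sites(aln, "pa", "pb",
                                consensus_policy(polymorphic_site_rule = "keep"))
  expect_identical(keep$column, c(1L, 3L, 4L))

  # two-sided polymorphic columns are kept only when unions are disjoint
  aln2 <- hyb_alignment(c(pa = "YY", pb = "RK", q = "NN"))
  s2 <- find_diagnostic_sites(aln2, "pa", "pb")
  expect_identical(s2$column, 1L) # Y={C,T} vs R={A,G} disjoint; Y vs K share T

  expect_warning(
    find_diagnostic_sites(hyb_alignment(c(a = "AC", b = "AC")), "a", "b"),
    "no diagnostic sites")
})

test_that("diagnostic sites match the brute-force column oracle across policies", {
  set.seed(101)
  for (i in 1:25) {
    aln <- random_alignment(5, 200, p_ambig = 0.15, p_gap = 0.08)
    idsA <- c("s01", "s02"); idsB <- c("s03", "s04")
    for (mode in c("strict_union", "majority", "single_reference")) {
      for (rule in c("omit_if_one_sided", "keep")) {
        got <- suppressWarnings(
          find_diagnostic_sites(aln, idsA, idsB,
                                consensus_policy(mode, rule)))
        expect_identical(got$column, oracle_sites(aln, idsA, idsB, mode, rule),
                         info = sprintf("rep %d %s/%s", i, mode, rule))
      }
    }
  }
})

test_that("site classification distinguishes additive, parental and other states", {
  expect_identical(classify_site("C", "T", "Y"), "ADDITIVE")
  expect_identical(classify_site("C", "T", "C"), "PARENT_A")
  expect_identical(classify_site("C", "T", "T"), "PARENT_B")
  expect_identical(classify_site("C", "T", "G"), "OTHER")
  expect_identical(classify_site("C", "T", "H"), "OTHER") # superset
  expect_identical(classify_site("C", "T", "-"), "MISSING")
  # ambiguous parental sets: additivity is the union of the sets
  expect_identical(classify_site("M", "T", "H"), "ADDITIVE")
  expect_identical(classify_site("M", "T", "M"), "PARENT_A")
  expect_error(classify_site("A", "R", "A"), "disjoint")
  expect_error(classify_site("C", "T", "Z"), "invalid IUPAC")
})

test_that("diagnose reproduces the canonical verdict patterns", {
  # fully additive query over 28 diagnostic sites
  sA <- strrep("C", 28); sB <- strrep("T", 28); q <- strrep("Y", 28)
  rep1 <- diagnose(hyb_alignment(c(pa = sA, pb = sB, q = q)),
                   sample_groups("pa", "pb", "q"))
  expect_equal(rep1$n_diagnostic, 28)
  expect_equal(rep1$n_additive, 28)
  expect_equal(rep1$additivity_index, 1)
  expect_identical(rep1$verdict, "HYBRID_FULL")

  # mosaic towards both parents (8 additive / 13 A / 18 B of 39)
  q2 <- paste0(strrep("Y", 8), strrep("C", 13), strrep("T", 18))
  rep2 <- diagnose(hyb_alignment(c(pa = strrep("C", 39), pb = strrep("T", 39),
                                   q = q2)),
                   sample_groups("pa", "pb", "q"))
  expect_equal(rep2$n_additive, 8)
  expect_equal(rep2$n_parentA, 13)
  expect_equal(rep2$n_parentB, 18)
  expect_identical(rep2$verdict, "CHIMERIC")

  # mosaic towards one parent with residual polymorphism (10/1/17 of 28)
  q3 <- paste0(strrep("Y", 10), strrep("C", 1), strrep("T", 17))
  rep3 <- diagnose(hyb_alignment(c(pa = strrep("C", 28), pb = strrep("T", 28),
                                   q = q3)),
                   sample_groups("pa", "pb", "q"))
  expect_identical(rep3$verdict, "PARTIALLY_RESOLVED")

  # query identical to parent A
  rep4 <- diagnose(hyb_alignment(c(pa = strrep("C", 20), pb = strrep("T", 20),
                                   q = strrep("C", 20))),
                   sample_groups("pa", "pb", "q"))
  expect_identical(rep4$verdict, "PURE_A")
  expect_equal(rep4$additivity_index, 0)

  # no usable diagnostic sites
  rep5 <- diagnose(hyb_alignment(c(pa = "ACGT", pb = "ACGT", q = "ACGT")),
                   sample_groups("pa", "pb", "q"))
  expect_identical(rep5$verdict, "AMBIGUOUS")
  expect_false(is.na(rep5$note))
  expect_true(is.na(rep5$additivity_index))

  expect_error(
    diagnose(hyb_alignment(c(a = "AC", b = "GT", q1 = "AC", q2 = "AC")),
             sample_groups("a", "b", c("q1", "q2"))),
    "exactly one query")
})

test_that("site calls partition the diagnostic sites and swapping parents is symmetric", {
  set.seed(202)
  for (i in 1:20) {
    aln <- random_alignment(5, 150, p_ambig = 0.12, p_gap = 0.06)
    g <- sample_groups(c("s01", "s02"), c("s03", "s04"), "s05")
    rep_ab <- suppressWarnings(diagnose(aln, g))
    expect_equal(rep_ab$n_additive + rep_ab$n_parentA + rep_ab$n_parentB +
                   rep_ab$n_other + rep_ab$n_missing,
                 rep_ab$n_diagnostic)
    g_swap <- sample_groups(c("s03", "s04"), c("s01", "s02"), "s05")
    rep_ba <- suppressWarnings(diagnose(aln, g_swap))
    expect_equal(rep_ba$n_parentA, rep_ab$n_parentB)
    expect_equal(rep_ba$n_parentB, rep_ab$n_parentA)
    expect_equal(rep_ba$additivity_index, rep_ab$additivity_index)
    v1 <- rep_ab$verdict; v2 <- rep_ba$verdict
    swap_map <- c(PURE_A = "PURE_B", PURE_B = "PURE_A")
    expect_identical(v2, if (v1 %in% names(swap_map)) swap_map[[v1]] else v1)
  }
})

test_that("report serialises to JSON and per-site TSV", {
  aln <- hyb_alignment(c(pa = "CCCC", pb = "TTTT", q = "YYCT"))
  rep <- diagnose(aln, sample_groups("pa", "pb", "q"))
  jp <- withr::local_tempfile(fileext = ".json")
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_report_json(rep, jp)
  obj <- jsonlite::read_json(jp)
  expect_equal(obj$n_diagnostic, 4)
  expect_equal(obj$additivity_index, 0.5)
  expect_identical(obj$policy$mode, "strict_union")
  write_site_calls(rep, tp)
  df <- read.delim(tp)
  expect_equal(nrow(df), 4)
  expect_identical(df$call, c("ADDITIVE", "ADDITIVE", "PARENT_A", "PARENT_B"))
})
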
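---
title: "Diagnosing hybrids from character additivity in multi-copy nuclear markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing hybrids from character additivity in multi-copy nuclear markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybdiag)
```

## The problem

Multi-copy nuclear ribosomal markers (the ITS region, the 5S
non-transcribed spacer) are the workhorses of plant hybrid
identification.  In a hybrid individual both parental repeat families
are present, so a direct Sanger read of the PCR pool shows double peaks
at every position where the parents differ.  Manually edited, such a
read is recorded with IUPAC ambiguity codes: if one parent carries `C`
and the other `T`, the hybrid shows `Y`.  When a putative hybrid carries
the *combined* parental states at every position at which the two
candidate parents differ — complete character additivity — its hybrid
origin and both parents are established in a single assay.

Two artifacts complicate this picture, and both are modelled here.

1. **Skewed repeat ratios.**  Concerted evolution can drive one parental
   repeat family down to a few percent of the pool.  The minor
   ribotype's peaks are then small secondary peaks, visible only if one
   looks for them, and 1-bp indels between the ribotypes shift the
   secondary peak series out of frame with the primary one (and back, if
   a compensating indel follows).
2. **Winner-take-all base calling.**  Automatic base callers resolve a
   double peak to the locally taller peak.  On a balanced mixture with
   reaction-typical fluctuation of relative peak heights this
   manufactures a *chimera*: a mosaic sequence carrying one parent's
   state at some diagnostic positions and the other parent's at the
   rest.  Chimeric reads placed in phylogenies sit in spurious
   intermediate positions and have polluted public databases.

## The diagnostic procedure

### Diagnostic sites

Given an alignment and two parental sample groups, each group is
collapsed per column into a state set (default policy: `strict_union` —
the union over all group members, so intra-specific and intra-individual
polymorphism widens the set).  A column is **diagnostic** when

* both parental sets are present (not all-gap),
* no member of either group carries a gap there (indels are coded
  separately, see below),
* the two sets are **disjoint**, and
* under the default `omit_if_one_sided` rule, not exactly one of the two
  sets is ambiguous.  One-sided polymorphic columns are dropped because
  a polymorphism confined to one taxon cannot be distinguished from
  unrelated intra-individual variation; two-sided polymorphic columns
  are kept when the unions are still disjoint.

### Site calls and verdict

At each diagnostic site the query symbol is classified by exact state
set comparison: `ADDITIVE` (equal to the union of the parental sets),
`PARENT_A`/`PARENT_B` (equal to one side), `MISSING` (gap), `OTHER`
(anything else; note that a superset such as `H` over parents `C`/`T` is
*not* counted additive — the additivity criterion is exact).  With
`a` the additive fraction and `fA`, `fB` the parent-specific fractions
of the non-missing diagnostic sites, the default decision table is:

| verdict | condition |
|---|---|
| `PURE_A` / `PURE_B` | `fA >= 0.95` (resp. `fB`) and `a <= 0.05` |
| `HYBRID_FULL` | `a == 1` |
| `HYBRID` | `a >= 0.8` |
| `CHIMERIC` | `a < 0.8` and `min(fA, fB) >= 0.2` |
| `PARTIALLY_RESOLVED` | `0.1 <= a < 0.8` and `max(fA, fB) >= 0.5` |
| `AMBIGUOUS` | otherwise |

The table is checked top to bottom and every threshold is a
`verdict_thresholds()` argument.  The two mosaic categories are
deliberately distinct: a chimera is pulled towards *both* parents (the
signature of winner-take-all resolution of a balanced mixture), while a
partially resolved read leans towards one parent with residual
polymorphism (the signature of a mixture resolved towards a slightly
dominant ribotype).  Thresholds compare with `>=`/`<=` exactly as
written; the additivity index is reported to three decimals in
serialised output but kept at full precision internally.

```{r}
aln <- hyb_alignment(c(parentA = "CCGATT", parentB = "TCGGTT",
                       query   = "YCGRTT"))
diagnose(aln, sample_groups("parentA", "parentB", "query"))
```

## The trace model

A `trace_matrix` holds per-position relative intensities of the four
dye channels — the quantitative abstraction of an electropherogram.
Two sequences are called from it (`call_sequences()`):

* the **major** call unions the channels whose fraction *strictly
  exceeds* `major_threshold` (default 0.30).  The 30% convention comes
  from manual editing practice for noisy multi-copy markers: secondary
  peaks at up to roughly a third of the signal are treated as noise when
  building a sequence for phylogenetic use.  The boundary case (exactly
  0.30) is excluded on purpose and the threshold is configurable.
  If no channel exceeds the threshold the maximal channel(s) are used,
  ties resolving to their union (reachable only on exactly equal
  intensities).
* the **sensitive** call unions all channels at or above
  `sensitive_floor` (default 0.02).  The floor sits just below the
  2–5% relative signal at which a rare ribotype is still visible by eye
  in a clean trace; there is no sharper community definition of
  "readable", so the default is a judgement call and configurable.

`simulate_mixture_trace()` superimposes two ungapped haplotypes at a
mixture fraction `f`: each column of the major haplotype receives
`1 - f` on its own base and `f` on the minor haplotype's base at the
*aligned* position.  The aligned cursor (obtained from a global pairwise
alignment) shifts by one at each 1-bp indel between the haplotypes, so
in the coordinate system of the minor candidate's own sequence the
secondary signal runs at frame offset 0 up to an indel, +1 after a minor
deletion, and back after a compensating insertion — the shift/backshift
signature that `detect_minor_component()` exploits.  Channel noise is
multiplicative log-normal (sd `noise_sd`), chosen because what varies
between reactions is the *relative* height of peaks, not an additive
baseline; zero channels stay zero.

`winner_take_all_call()` models the artifact: each channel is jittered
by an independent log-normal factor and the argmax base is emitted.  On
a balanced mixture this resolves each diagnostic position to either
parent with probability about one half each.

`detect_minor_component()` extracts the secondary band (channel
fractions within `[sensitive_floor, major_threshold]`) and scores every
candidate haplotype at every frame offset in `-2..+2` by the fraction of
secondary-signal columns whose band contains the candidate base at
`column - offset`.  The best candidate's offset profile is segmented by
a sliding-window change-point scan (window default: 20 secondary-signal
columns) with exact split refinement; where several split points explain
the data equally (columns coincidentally matching both offsets) the
boundary is placed at the first column positively supporting the new
offset.  Detection requires a *skewed* mixture: at `f = 0.5` both
channels sit above the major threshold and there is no secondary band,
which is the correct behaviour (such samples are diagnosed directly from
the additive calls instead).

All stochastic operations take an explicit seed, restore the caller's
RNG state, and are reproducible bit-for-bit.

## Indel coding

Gaps are excluded from additivity scoring and handled by simple indel
coding: every distinct internal maximal gap range becomes one binary
character; a taxon scores `1` on exact range match, `?` when a longer
gap of that taxon properly contains the range (the event is
unobservable), `0` otherwise.  Terminal gap runs are treated as missing
flanks: they found no characters and score `?` for every character they
span entirely (a terminal gap covering a range only partially leaves the
taxon scored `0`, since the taxon demonstrably lacks that exact gap).
Output is a TSV matrix or a combined NEXUS file with a
`mixed(DNA,RESTRICTION)` datatype, the convention of indel-coding tools.

## RFLP screen design

For cloning a rare ribotype it is cheaper to pre-screen clones with a
restriction enzyme whose site is present in one ribotype and lost in the
other than to sequence blindly.  `find_discriminating_enzymes()` scans a
bundled library (PaeI/SphI, GCATGC, among others) for site-count
differences; `find_sites()` matches degenerate recognition sequences on
both strands (positions on the forward strand, palindromic duplicates
reported once, overlapping matches all counted).  Cut coordinates use
`site_start + cut_offset - 1`; where an enzyme's cut position within its
site is not documented the bundled `cut_offset` is a convention and
flagged as such — site presence/absence, the quantity a screen actually
uses, does not depend on it.

Clone-screen sizing is closed-form: with minor frequency `f`, screening
`n` clones detects the minor ribotype with probability `1 - (1 - f)^n`,
and `plan_clone_screen(f, p)` returns
`n = ceiling(log(1 - p) / log(1 - f))`.

```{r}
plan <- plan_clone_screen(minor_fraction = 0.025, target_probability = 0.95)
plan
plan$detection_probability_at(39)
```

A 39-clone screen of a 2.5% ribotype succeeds only with probability
0.63 — a reminder that a single positive clone in such a screen is a
lucky draw, and that target-driven sizing (119 clones for 95%) is the
safer design.

## The synthetic benchmark

`scenario_spec()` fixes the simulated study conditions; the defaults are
the regime in which this kind of analysis operates and are not meant to
be tuned per run:

* `length = 600`, `divergence = 0.05` — a spacer-sized alignment of two
  congeners, yielding a mean of ~28 diagnostic sites, matching the
  25–40 diagnostic positions typical of such marker comparisons;
* two 1-bp indels (an early deletion, a late insertion in parent B),
  reproducing the shift-then-backshift frame signature;
* `intra_polymorphism_rate = 0.05` — each parent carries an ambiguity
  code (its base united with one random alternative) at 5% of its
  positions.  Polymorphisms are attached to the *taxon*, not drawn per
  read: multi-copy spacer polymorphisms are features of a species'
  repeat pool, and intraspecific sequence variation in the clonal
  aquatic plants this method is aimed at is known to be minimal.  A
  pure individual therefore reproduces its parent's coded sequence, and
  one-sided polymorphic columns are dropped from the diagnostic set by
  the consensus rule rather than misclassified;
* `minor_fraction = 0.5`, `noise_sd = 0.1` — a balanced hybrid read at
  moderate reaction noise (0.2 is used for the chimera experiments,
  where peak-height fluctuation is the driver of the artifact).

`generate_parent_pair()` records the ground truth (diagnostic columns by
direct set logic on the known substitution and injection positions — an
independent path from `find_diagnostic_sites()`, which the test suite
exploits as a closure check).  `generate_sample()` produces reads of the
four truth categories and `generate_benchmark()` writes a reproducible
on-disk set (FASTA, trace TSVs, truth JSON).

What the generator does **not** emulate: positional error profiles of
real electropherograms (noise is i.i.d. across positions), baseline or
dye-blob artifacts, PCR recombination between ribotypes, more than two
parental haplotypes, and length variation beyond 1-bp indels.  Passing
the benchmark therefore shows that the inference machinery is correct
under its stated model, not that every real trace will be as clean; the
2–5% minor-signal regime in particular is near the sensitive floor, and
real detections at that level warrant confirmation by cloning.

## Problem sizes and numerical choices

The test suite and the acceptance script run the benchmark at the
default scale (600 columns), with 100–200 replicates per category for
verdict recovery and 100 seeded replicates per minor fraction for
detection power — sizes chosen so the whole suite completes in a few
minutes on one core while keeping the binomial noise on any estimated
rate below about three percentage points.  Degenerate inputs are handled
explicitly: an all-gap parental column is missing, zero usable
diagnostic sites yield an `AMBIGUOUS` verdict with a note rather than an
error, an all-zero trace column is an error naming the column, and empty
diagnostic-site lists warn instead of failing.

## Limitations

* Inputs must be pre-aligned; no multiple alignment is computed.
* The trace model abstracts chromatograms as relative channel
  intensities; binary AB1/SCF parsing and Phred-quality modelling are
  out of scope.
* Only the simple presence/absence indel coding is implemented.
* Digestion is for linear molecules (PCR products); circular molecules,
  methylation sensitivity and gel migration are not modelled.
* The verdict table is a calibrated heuristic, not a likelihood model;
  its thresholds are exposed precisely so users can stress them.
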
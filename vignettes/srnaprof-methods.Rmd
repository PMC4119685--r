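---
title: "srnaprof: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{srnaprof: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnaprof)
```

This vignette is the package's own account of what it computes and why
the defaults are what they are. It states no empirical result that the
test suite and `scripts/acceptance.R` do not themselves compute.

## The measurement problem

A small-RNA sequencing library is a census of ~22 nt RNA fragments.
Three artifacts stand between the raw FASTQ file and a usable miRNA
profile. First, the 5' adaptor can ligate directly to the 3' adaptor,
producing *self-ligation* reads that contain no biology and waste
sequencing depth. Second, every genuine read ends in the 3' adaptor,
which must be located and trimmed before any mapping; reads where it
cannot be found are unusable. Third, rRNA, tRNA, mRNA and other ncRNA
fragments that escaped the in-gel size selection masquerade as small
RNAs. The package quantifies each artifact (they are the quality
indices a lab inspects before trusting a library) and then profiles
the miRNA content of the clean remainder.

## Read processing

Raw reads are collapsed to unique tags (descending count, then
lexicographic — every ordering in the package is total, so identical
inputs give byte-identical outputs). The adaptor search returns the
leftmost 0-based position *p* such that either the full adaptor
matches at *p*, or the adaptor runs off the read end and a prefix of
at least `min_overlap` nt matches the read suffix. Defaults are exact
matching (`max_mismatch = 0`) and `min_overlap = 8`:

* Exact matching is fully reproducible and is what makes the
  simulator-closure tests meaningful; a mismatch tolerance is
  supported (`max_mismatch`) for degraded libraries, at the cost of a
  slower scan.
* 8 nt is long enough that a random read suffix qualifies with
  probability ~4⁻⁸ ≈ 1.5e-5, and short enough to rescue reads whose
  insert pushes most of the adaptor off the 3' end.
* When several positions qualify, the leftmost (shortest insert) wins:
  it is the conservative choice and makes the result independent of
  scan order.

`p = 0` defines self-ligation (zero-length insert); `p ≥ 1` yields a
clean insert; no match is nonclean. The three classes partition the
library exactly — the test suite asserts the identity on thousands of
randomized libraries rather than trusting the arithmetic.

Clean inserts are re-collapsed (two reads with different adaptor
positions but the same insert merge) before the qualification filter:
insert length within 15–30 nt, collapsed count at least 2, and no N.
The length window matches the size-selected fragment range of typical
protocols; the count filter removes singleton sequences, which at
small-RNA depths are dominated by PCR and sequencing noise; N-containing
inserts are excluded because every downstream placement is exact. The
qualified percentage is therefore sensitive to all three parameters,
and the summary reports raw counts alongside percentages so nothing is
lost to rounding (percentages are printed to two decimals).

## Mapping and the soft-clip contract

Placement on hairpin precursors uses an exact-substring index with
3'-only soft-clipping: for clip c = 0, 1, ..., `max_mod` (default 3),
all exact hits of the tag minus its last c bases are collected, and
the search stops at the smallest c with a hit. This encodes two domain
facts: read variation concentrates at the 3' end of small-RNA reads
(the clipped bases are exactly the read's 3' end modification, shown
lowercase with T as u), and an unmodified placement must always beat a
clipped one. The index is deliberately an internal, fully specified
component rather than a wrapper around an external aligner: its
results are defined to equal a naive window scan, and the tests hold
it to that definition on randomized references, including
reverse-complement hits for genome references. Mismatches inside the
matched region are not allowed; `min_match = 15` (the lower bound of
the qualification window) stops clipping from eroding a tag below a
placeable core.

Tags that miss the hairpins are classified by first hit in the fixed
order rRNA → tRNA → mRNA → ncRNA → genome, then unknown. Non-miRNA
categories use full-length exact matching only — 3' modification is a
miRNA-specific concept here, and clipping in later categories would
blur the hierarchy. Transcript categories are sense-strand; the genome
is searched on both strands.

## From hits to tables

A hit is assigned to the annotated mature with maximal overlap with
the matched span, accepted when the overlap covers at least half the
matched length (`overlap_frac = 0.5`); ties go to the 5p arm. The
shifts are `shift5 = start − mature start` and `shift3 = matched end −
mature end`. Spans failing the overlap test fall to the arm containing
their midpoint: an arm with no annotated mature makes the read an
opposite-arm (opp-miRNA) candidate, anything else is loop/flank. The
0.5 threshold and the midpoint rule are the package's own choices —
no published rule exists — and both are deterministic and exposed as
parameters. Coordinates are 1-based inclusive in every report.

Expression is reported in TPM with the denominator equal to total
mature-assigned reads, so TPM always sums to one million and profiles
are comparable between libraries with unequal miRNA yield. A tag
hitting k distinct targets contributes count/k to each; duplicated
loci that produce the same mature name are merged *before* the split,
so the same molecule is never counted twice. When a tag's targets mix
mature and opposite-arm/loop placements, the split still runs over all
distinct targets, keeping total read mass conserved — the suite checks
conservation on every profile it produces. IsomiRs merge by
(mature, shift5, shift3, suffix), so each mature's isomiR counts sum
exactly to its raw count. Opposite-arm candidates are reported per
hairpin when their summed count reaches `opp_min_count` (default 2,
mirroring the count ≥ 2 qualification filter); the defining span is
the most abundant distinct span, ties to the smaller start. Detection
counts a mature as present at any positive raw count (`detect_min =
0`) — detection thresholds are unstated in the field's reports, so the
permissive default is exposed as a flag rather than baked in.

## The simulator and what closure proves

`make_toy_references()` builds random hairpins (default 30 × 80 nt)
each carrying a 5p mature of 20–23 nt starting at position 8; 40%
also carry a 3p mature ending 4 nt from the hairpin end, and the rest
carry a *latent* opposite-arm span at the same coordinates that is
deliberately left unannotated, so opposite-arm detection has a known
answer. Small decoy sets (5 × 200 nt per category) stand in for
rRNA/tRNA/mRNA/ncRNA references.

Two construction rules make end-to-end recovery exact rather than
statistical:

1. **15-mer uniqueness.** Every 15-mer across the whole reference set
   is unique (generation retries until this holds). Any templated core
   of ≥ 15 nt therefore places at exactly one position, so a simulated
   read can never multi-map or cross categories by accident.
2. **C/G flanks.** The last two bases of every planted product and the
   three bases following it are drawn from {C, G}, and simulated 3'
   tails are restricted to the a/u alphabet. A planted tail is then
   non-templated at every shifted 3' end in −2..2, so the aligner's
   minimal-clip rule recovers exactly the planted
   (shift5, shift3, tail) triple.

`simulate_library()` allocates category counts by largest remainder
(planted fractions are reproduced exactly at integer resolution),
draws annotated-mature reads from the expression weights with shifts
and tails from their models, draws contaminant inserts from per-category
pools of decoy substrings (pools are what let collapsed counts reach
the ≥ 2 filter at realistic depths), rejection-samples unknown reads
against every reference 15-mer, and emits insert + adaptor with a
constant-quality FASTQ line. No reference contains the adaptor's 8 nt
prefix and the adaptor must be aperiodic below 8 nt, so the planted
adaptor position is always the leftmost match. `truth_summaries()`
rolls the per-read records up with plain tabulation — independent of
the pipeline code — and the acceptance suite requires the pipeline to
reproduce those tables *exactly* at tag level on a 100,000-read
library.

Default study conditions (chosen once, as a portrait of a well-made
library): fractions self-ligation 0.5%, nonclean 4%, miRNA 75%, rRNA
5%, tRNA 3%, mRNA 3%, ncRNA 3%, unknown 6.5%; Zipf (1/rank)
expression weights, which put roughly half of all miRNA reads in the
top five matures; shift model concentrated at (0,0) with ±1 single-end
shifts; tail model dominated by `u`, then `a`, with AU-dinucleotide
tails in the few-percent range; 3% of miRNA reads from latent
opposite-arm products.

What passing closure does *not* show about real data: the simulator
has no sequencing-error model (errors would shift reads toward
nonclean/unknown, not corrupt placements, because matching is exact),
no quality-string information, no PCR-duplicate structure, and its
references are far smaller and more separable than a real
miRBase-plus-transcriptome index, where multi-mapping and
cross-category homology are common. Closure certifies the bookkeeping
and the algorithmic contracts, not biological realism.

## Numerical and degenerate-input behavior

TPM is checked to sum to 1e6 within 1e-6 relative; all merges use
exact string keys, so no tolerance is involved anywhere else. Empty
inputs are defined everywhere: an empty FASTQ gives an empty tag list,
an empty profile reports zero detections and no TPM, an empty index
answers no hits. Ties are fixed throughout (count desc then
lexicographic for tags; 5p over 3p for arm and overlap ties; smaller
start then end for defining spans) so that re-runs are byte-identical —
the pipeline test compares report files byte-for-byte across runs.

## Problem sizes

The shipped tests run the property checks on ~10⁴ randomized
libraries and ~10⁴ randomized adaptor/index cases, and the closure
check on one 100,000-read library over 30 hairpins — sizes chosen so
the whole suite completes in about a minute on a single core while
still exercising every code path at depths where the count filters
and tie rules matter. `scripts/acceptance.R` uses the same 100,000-read
conditions.

## Known limitations

* Exact matching throughout: a single sequencing error inside the
  matched region sends a read to a later category or to unknown; there
  is no mismatch-tolerant hairpin placement (only the adaptor search
  has a mismatch option).
* No 5' adaptor handling, quality filtering, UMI support, or
  paired-end input.
* No novel-miRNA prediction from hairpin folding, and no
  differential-expression statistics between libraries.
* Whether a 3' tail is RNA editing or non-templated addition is not
  (and cannot be) decided from the read alone; the package reports the
  neutral "3' end modification" and leaves attribution to the user.
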
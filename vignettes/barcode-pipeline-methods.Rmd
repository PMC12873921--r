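---
title: "Methods: barcode extraction, error collapse and diversity statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: barcode extraction, error collapse and diversity statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicbc)
```

## The measurement problem

Delayed PhiC31 integration at a single genomic AttP landing site makes each
cell of an injected embryo carry at most one library member. Sequencing the
random 15-nt barcodes amplified from a whole larva therefore measures two
things at once: *how many independent integration events* the animal carries
(the number of distinct barcodes, after error correction) and *how the
founding cells expanded clonally* (the shape of the barcode abundance
distribution). Both are corrupted by PCR and sequencing errors, which this
package removes with an anchored extraction step and a Levenshtein-1
collapse, and both are validated here against simulations with known truth.

## Barcode extraction

A raw read carries a 5-nt sample multiplexing barcode at its start and the
amplicon in reverse-complement orientation. After demultiplexing (exactly one
sample-sheet entry within Hamming distance 1 of the 5-nt slot; ambiguous and
unmatched reads are set aside, never silently dropped) and
reverse-complementing, the 15-nt barcode is located between two anchors:

* the 12-nt upstream anchor `AGCCCCCAGGGA`, searched with **progressive
  stringency** — exact substring, then Hamming distance ≤ 2, then Levenshtein
  distance ≤ 2;
* the 5-nt downstream anchor `CACGC`, which must follow the 15-base candidate
  exactly.

Position validation applies at every stage: the anchor start must fall within
`expected_anchor_offset ± position_tolerance` (default tolerance 5 nt; the
Levenshtein stage widens the window by the 2 allowed edits, since an indel
upstream shifts the anchor). Applying the window uniformly — rather than only
at the fuzzy stages — was a genuinely open choice; we chose uniformity
because it is the stricter, order-independent reading and it rejects
off-template exact matches as well as fuzzy ones.

Determinism demanded explicit tie-breaking: among candidate matches the
*leftmost minimal-distance* position wins, and at the Levenshtein stage ties
at one position prefer the narrowest window. The candidate barcode is always
exactly the 15 bases after the matched anchor end — no slot-length adjustment
for anchor indels — because indel errors inside the barcode itself are
corrected downstream by the collapse, and a fixed slot keeps the extraction
auditable. Candidates containing `N` are dropped and counted (an `N` cannot
be reliably collapse-corrected). The test suite checks the whole ladder
against a brute-force scan over all offsets, window widths and edit scripts
of cost ≤ 2, implemented independently with a hand-rolled dynamic program.

## Error collapse and filtering

Barcodes within Levenshtein distance 1 (one substitution, insertion or
deletion) are collapsed into a single parent, defined as the most abundant
sequence. The rule is a single greedy sweep in decreasing cross-sample total
count (ties broken lexicographically, for determinism): a barcode becomes a
parent if no already-finalised parent lies within distance 1, otherwise it
merges — with its full per-sample counts — into the most abundant such
parent. Children never absorb other children, so a chain A–B–C with
d(A,B) = d(B,C) = 1 and d(A,C) = 2 resolves to parents {A+B, C}, matching
standard directional-adjacency practice for UMI error networks. The collapse
is global across samples with per-sample bookkeeping: a true barcode observed
in several fish keeps one identity. Counts are conserved exactly, per sample,
and collapsing twice is the identity — both are asserted under fuzzing.

Candidate neighbour pairs are found by hashing each barcode together with all
of its single-character deletions: two sequences within edit distance 1
necessarily share such a key, and sharing a key is cheap to verify with a
true distance computation. This keeps the collapse near-linear in the number
of distinct barcodes instead of quadratic. Because extraction emits
fixed-length 15-nt barcodes, distance-1 pairs are in practice single
substitutions, but the implementation computes full Levenshtein distance so
externally supplied tables with mixed lengths behave correctly.

After collapsing, confidence filters apply in the published order: fish
samples keep a barcode only with ≥ 3 reads in that fish (the cell is zeroed
per fish, independently); the injected source library uses the more
permissive ≥ 2 (its complexity far exceeds sequencing depth, so genuine
barcodes are mostly rare); and any barcode within Levenshtein distance 2 of a
window of conserved template sequence (window lengths within ± 2 of the
barcode length) is removed as an extraction artifact. Whether the library's
singleton filter preceded or followed the collapse is stated in the source
workflow only as narrative order; we implement collapse first, uniformly for
both sample classes.

## Abundance and diversity statistics

Counts are normalised to reads per million (RPM) per sample; all-zero
columns are flagged, never divided. Per sample, over the *nonzero*
abundances: unique-barcode count; coefficient of variation using the
population SD (SD/mean is scale-free, so the choice of denominator convention
only needs to be fixed, not argued); Shannon diversity −Σ pᵢ log₂ pᵢ in bits
with 0·log 0 := 0; and the quartile ratio Q3/Q1 with linear-interpolation
quartiles (R's default type 7). A uniform sample of N barcodes attains
Shannon = log₂ N, CV = 0 and Q3/Q1 = 1 exactly, which the tests assert; the
clonal-expansion signature is the joint departure from all three.

Sequence diversity uses the mean pairwise Hamming distance over 20,000
barcode pairs sampled uniformly without replacement from the unordered-pair
space (with replacement only when fewer distinct pairs exist), seeded for
reproducibility. For uniform-random length-L sequences the expectation is
L·3/4 — 11.25 for L = 15, reported as 11.3 at one decimal. The reporting
convention is round-half-up, since that is the only rounding under which the
analytic value prints as the published one-decimal figure; base R's
round-half-to-even would print 11.2.

Two estimator helpers round only at formatting time and keep full precision
internally: `mutual_exclusivity_stats()` reports the double-positive
percentage of fluorescent cells, its complement, and the multi-transgene
upper bound 2 × double-positive (for a 50:50 color mix a two-transgene cell
shows both colors with probability 1/2, so doubling is an unbiased upper
bound — a property the simulator reproduces within Monte-Carlo error);
`brain_coverage()` reports the mean per-fish fluorescent-neuron count
truncated toward zero (1,255 from counts 980 and 1,531) and its percentage of
the hindbrain total rounded to an integer. The unique-barcode summary uses
the sample SD (n − 1): a dozen fish are a sample, not a population.

## What the simulator emulates — and what it does not

`generate_library()` draws barcodes i.i.d. uniform over {A,C,G,T}^L;
duplicates occur with birthday-problem probability, which the tests track
(expected collisions n²/(2·4¹⁵)). `simulate_mosaic_fish()` gives each fish
`n_integrations` independent events, each drawing one library member and
founding a clone; the default 1,600 events per fish matches the order of the
observed per-animal barcode counts, and a 10⁶-member library reflects a
complexity far above sequencing depth. Clone sizes default to
lognormal(meanlog 0, sdlog 1) — the source observations attribute abundance
variance to variable integration timing and proliferative capacity without a
quantitative model, and a lognormal captures the long tail while keeping most
clones small; `fixed(k)` and `geometric(p)` are provided for testing.
`simulate_reads()` samples reads multinomially in proportion to clone size,
lays them on the conserved template, reverse-complements them into sequencing
orientation, prefixes the 5-nt sample barcode at a fixed offset at the read
start (the real offset is a template parameter, not hard-coded), and applies
independent per-base errors — substitutions at 0.002 by default, insertions
and deletions at 10⁻⁵ (no published indel rate exists; these are typical
Illumina orders). Reads are emitted single-ended spanning the whole barcode
region: the real experiment sequenced 2×150 paired-end amplicons, and mate
merging is deliberately out of scope, so one read stands in for the merged
pair.

The simulator does **not** model embryo geometry, lineage-tree structure,
PCR-cycle chimeras, quality-score-dependent errors, or episome partitioning
dynamics — injected molar dose and partitioning are abstracted into
`n_integrations` and the clone-size model. Passing tests therefore
demonstrate that the pipeline's inference is correct *under this error and
expansion model*, not that real libraries are free of, say, chimeric
artifacts. The template's conserved flank sequences shipped as defaults are
synthetic stand-ins (the real amplicon flanks are not distributed with the
package); the anchors, lengths and tolerances are the real design values.

`simulate_two_color()` models each cell as acquiring at most one landing-site
integrant (the recombined AttP cannot accept a second) and at most one
spontaneous enzyme-free integrant, with i.i.d. construct colors. Double
positives then arise only from spontaneous co-integration of the opposite
color, the mechanism hypothesised for the rare observed double-positive
neurons.

## Numerical and degenerate-input choices

* Zero-depth, zero-fish and empty-table inputs return empty but valid
  objects (a valid manifest, 0-row tables), never errors mid-pipeline.
* Samples with no nonzero barcode report `NA` metrics rather than numbers.
* All stochastic functions take an explicit seed; pipeline stages derive
  their randomness from the single config seed, and two runs of one config
  are byte-identical, which the tests assert on the written files.
* Read accounting is an invariant, not a log line: assigned + unassigned =
  input, per-stage extraction counts partition the assigned reads, and
  collapse conserves totals; `run_pipeline()` stops if any identity fails.

## Problem sizes used in validation

The full-scale validation simulates the study conditions exactly — 12 fish ×
1,600 integrations from a 10⁶-member uniform library at 50 reads per clone
(≈ 0.96M reads) with substitution rate 0.002 — and recovers per-fish founder
counts within ±2%; it completes in about a minute. Unit and property tests
use smaller instances (hundreds of barcodes, 10³–10⁵ reads) chosen so each
stochastic assertion sits several standard errors away from its threshold.
Oracle-equivalence checks run the extraction ladder against exhaustive search
on ~1,000 reads of ≤ 60 nt and the greedy collapse against an independent
rule trace on 500 random sets of ≤ 12 barcodes.

## Known limitations

* The ≥ 3-read fish filter assumes every genuine clone is sequenced several
  times; at coverage below ~10 reads per clone, small clones are lost and
  founder counts are underestimated. The recovery guarantee is stated (and
  tested) at 50× mean clone coverage.
* The Levenshtein-1 collapse cannot separate a genuine barcode that happens
  to lie within distance 1 of a much more abundant one; with a 15-nt uniform
  library this is a birthday-scale event and is accepted rather than
  modelled.
* The multi-transgene upper bound is exact only for a 50:50 color mix and
  small spontaneous-integration rates; for other mixes the factor
  2·mix·(1−mix) in the double-positive expectation changes and the ×2 rule
  becomes conservative in one direction.
* Paired-end mate handling for the deposited real data (merge versus R1-only)
  is not implemented; the optional real-data reproduction documented in the
  README should state which choice it uses when comparing to the published
  per-fish counts.
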
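# mosaicbc

Barcode sequencing analysis for mosaic integrase (PhiC31 landing-site)
transgenesis in zebrafish.

When a plasmid library carrying random 15-nt DNA barcodes is injected into a
1-cell embryo together with PhiC31 integrase mRNA, delayed integration places
a single, randomly chosen library member into the genomic AttP landing site
of each cell. Deep sequencing of the integrated barcodes from a whole larva
then reveals how many independent integration events the animal carries and
how the resulting clones expanded. `mosaicbc` implements the full analysis
from raw amplicon reads to per-animal unique-integrant counts and diversity
statistics, together with a synthetic-data generator so every stage can be
validated against known ground truth.

## The analysis

Raw pooled reads are processed in the following stage order, with read
accounting at every boundary:

1. **Demultiplex** by the 5-nt sample barcode at the read start, tolerating 1
   mismatch; reads matching zero or several samples are set aside.
2. **Reverse-complement** into template orientation.
3. **Extract** the 15-nt barcode between conserved anchors: the 12-nt
   upstream anchor `AGCCCCCAGGGA` is located with progressive search
   stringency — exact match, then Hamming distance ≤ 2, then Levenshtein
   distance ≤ 2 — with position validation at each stage; the 5-nt downstream
   anchor `CACGC` must match exactly.
4. **Collapse** barcode variants within Levenshtein distance 1 (one
   substitution, insertion or deletion) into their most abundant parent,
   preserving per-sample counts; total counts are conserved exactly.
5. **Filter**: a barcode is kept in a fish only with ≥ 3 reads in that fish
   (≥ 2 reads for the injected source library), and barcodes within
   Levenshtein distance 2 of any conserved template region are removed as
   extraction artifacts.
6. **Report** reads-per-million (RPM) abundances and, per sample, the number
   of unique barcodes, coefficient of variation, Shannon diversity
   (−Σ pᵢ log₂ pᵢ, in bits), quartile ratio Q3/Q1, positional nucleotide
   composition, and the mean pairwise Hamming distance over 20,000 sampled
   barcode pairs (uniform-random expectation L·3/4 = 11.25 ≈ 11.3 for
   L = 15).

Two small estimators accompany the pipeline: `mutual_exclusivity_stats()`
computes the double-positive fraction of a two-color cell tally and the
multi-transgene upper bound (twice the double-positive fraction for a 50:50
color mix), and `brain_coverage()` turns per-fish fluorescent-neuron counts
into a fraction of the estimated hindbrain total.

The simulator (`generate_library()`, `simulate_mosaic_fish()`,
`simulate_reads()`, `simulate_two_color()`) emulates a high-complexity
uniform random library, per-fish independent integrations, lognormal clonal
expansion, and amplicon reads with substitution/indel errors and sample
barcodes, all reproducible under a seed.

## Worked example

Simulate 4 fish with 800 integrations each from a 50,000-member library at
30× clone coverage, then run the pipeline on the pooled FASTQ:

```r
library(mosaicbc)

cfg <- default_config(seed = 1)
cfg$library$n_members <- 50000
cfg$fish$n_fish <- 4
cfg$fish$n_integrations <- 800
cfg$reads$coverage_per_clone <- 30

sim <- run_simulation(cfg, out_dir = "demo_sim")
res <- run_pipeline(sim$paths$fastq, sim$paths$sheet, cfg, out_dir = "demo_out")

res$unique_summary$per_fish
#> fish01 fish02 fish03 fish04
#>    789    793    791    795
tapply(sim$truth$barcode, sim$truth$fish_id, function(b) length(unique(b)))
#> fish01 fish02 fish03 fish04
#>    789    793    791    795
```

The recovered unique-barcode counts equal the simulated founder distinct
counts exactly: errors were corrected by the collapse and the rare-barcode
filter. (800 draws from a 50,000-member library collide occasionally, which
is why truth itself is slightly below 800.) The per-fish diversity report
shows the clonal-expansion signature — high CV and quartile ratio, Shannon
below the log₂(richness) ceiling of ~9.6 bits:

```r
round(res$diversity[, -1], 3)
#>   unique_barcodes    cv shannon_bits quartile_ratio
#> 1             789 0.965        9.183          2.200
#> 2             793 1.083        9.119          2.286
#> 3             791 1.089        9.138          2.200
#> 4             795 1.063        9.168          2.429
```

The two-color mutual-exclusivity estimator, applied to a tally of 33
double-positive neurons among 4,984:

```r
print(mutual_exclusivity_stats(two_color_tally(2475, 2476, 33)))
#> Double-positive cells      : 0.66% (33 / 4984)
#> Exclusive single-color     : 99.34%
#> Multi-transgene upper bound: 1.3%

bc <- brain_coverage(c(980, 1531), 25000)
#> mean fluorescent neurons: 1255 (~5% of hindbrain)

mh <- mean_pairwise_hamming(rownames(res$counts_final), 20000, seed = 2)
#> mean pairwise Hamming: 11.26 (uniform expectation 11.25)
```

A thin CLI wrapping the same functions is installed at
`system.file("scripts", "mosaicbc", package = "mosaicbc")` with `simulate`,
`run` and `run-all` subcommands.

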
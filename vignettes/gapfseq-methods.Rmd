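---
title: "Methods: palindrome-enrichment coverage profiles and the HCB threshold classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: palindrome-enrichment coverage profiles and the HCB threshold classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gapfseq)
```

## The assay and its computational model

DNA palindromes (fold-back inversions) are structural variants in which a
genomic segment is followed by its own reverse complement. They arise
*de novo* in tumors — notably during breakage-fusion-bridge cycles that
drive gene amplification — which makes them attractive tumor-specific
markers, including in plasma cell-free DNA where the tumor fraction is
small. A snap-back enrichment protocol (denature, rapidly renature so that
palindromic junctions self-anneal, digest everything single-stranded)
leaves palindromic junction DNA double-stranded; sequencing the survivors
yields a library in which palindromic loci pile up reads and everything
else is close to empty.

`gapfseq` models the downstream analysis of such libraries:

1. **Binned coverage.** Aligned reads are counted in fixed 1-kb, half-open,
   0-based bins tiled from position 0 of every chromosome
   (`build_bins()`, `count_reads_in_bins()`). A read overlapping a bin by
   at least 1 bp increments that bin, so boundary-straddling reads count
   in two bins; mates of a pair count independently. A mapping-quality
   floor (MAPQ ≥ 40) restricts counting to uniquely mapped reads. Counts
   are normalized by a per-million scaling factor:
   `cpm = raw / (total_mapped_reads / 1e6)`.
2. **Quality control.** Known germline inverted repeats (mostly on chrX)
   are amplified by any successful enrichment but collapse under the
   uniqueness filter because they are repeated in the reference. The mean
   of per-region mean coverage before filtering (amplification score,
   pass > 1.0) and after filtering (depletion score, pass < 0.075)
   summarizes both effects; both bounds are strict.
3. **Blocklist.** Some bins are enriched in every library regardless of
   disease — GC-rich sequence resistant to denaturation, repeats,
   germline palindromes. Bins whose coverage exceeds 5 cpm in at least
   75% of tumors *and* 75% of normals are blocklisted and removed before
   ranking.
4. **HCB profiles.** Retained bins are ranked by coverage; the top K
   (default 1,000) are the sample's high-coverage bins (HCBs), and the
   per-chromosome counts of those HCBs are its profile. Normal DNA
   spreads HCBs over almost every chromosome; tumor DNA concentrates
   them on one or a few.
5. **Threshold classifier.** A sample's decision score is the maximum
   per-chromosome HCB count. Sweeping a threshold over the observed
   scores yields a ROC curve; the AUC is the trapezoidal integral
   (identical to the Mann–Whitney pair statistic, ties = 1/2), and the
   operating threshold maximizes Youden's J = sensitivity +
   specificity − 1.
6. **ML comparison.** The same per-chromosome counts (chr1–22 + chrX, 23
   features) feed fixed-hyperparameter baselines — Gaussian naive Bayes,
   random forest (500 trees), gradient boosting (50 rounds, depth 3,
   η = 0.3) — under the identical CV protocol, with permutation feature
   importance and a composite importance that normalizes within each
   algorithm and weights by its median AUC.
7. **Read-pair evidence.** Mates mapping in the same orientation (FF/RR)
   flank fold-back junctions. `find_same_orientation_clusters()` merges
   same-orientation pairs whose mate positions are mutually within a
   merge distance and reports clusters with enough support.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `bin_width` | 1000 | bp | resolution of the assay; palindromic junction pile-ups are sub-kb |
| `mapq_min` | 40 | MAPQ | uniqueness filter; pass is `MAPQ >= 40` |
| `amp_min`, `dep_max` | 1.0, 0.075 | cpm | QC pass bounds, strict on both sides |
| `enrich_cutoff` | 5 | cpm | the low/high coverage divide: the vast majority of bins sit below 5 cpm |
| `min_fraction` | 0.75 | proportion | "consistently enriched" operationalized as ≥ 75% of each arm |
| `k` | 1000 | bins | profile size; 300 and 10,000 are the alternatives worth comparing |
| `folds`, `seeds` | 3, {22, 32, 42} | — | the evaluation protocol: stratified 3-fold CV repeated under three fold-assignment seeds |
| `min_support`, `merge_distance` | 3, 1000 | pairs, bp | read-pair cluster reporting floor and merge radius |
| insert-size `cutoff` | 200 | bp | short/long fragment boundary; 200 bp itself goes to "long" (`strict_long` flips the convention) |

## Boundary conventions and numerical choices

Several conventions are underdetermined by the assay description; the
package fixes each one explicitly and exposes a flag where both readings
are defensible.

- **Positive calls** use `score >= threshold`; `strict_gt = TRUE` gives
  the strict reading.
- **Top-K ties** are broken deterministically: coverage descending, then
  chromosome order, then start ascending — so runs are bit-exact.
- **Youden ties** resolve toward the smallest (most sensitive) threshold.
- **ROC sweep** thresholds are the distinct observed scores plus an
  all-negative sentinel; endpoints are therefore exactly (1, 1) and
  (0, 0), and at a threshold equal to the smallest score every sample is
  positive.
- **Cross-validation** refits the Youden threshold on each training
  split (proper CV). The whole-cohort Youden threshold — the number one
  would quote as "the" operating point — is reported alongside, not
  instead. Summary statistics are emitted under both aggregations
  (pooled over the 9 fold×seed results, and over per-seed means), since
  either could be meant by a quoted standard deviation.
- **QC scores** are two-level means: bins are averaged within each
  control region, then regions are averaged, so a long region does not
  outweigh a short one.
- **Cytoband assignment** places a bin in the band containing its start;
  bins are 1 kb and bands are Mb-scale, so edge effects are negligible.
  Band coverage divides summed bin cpm by band length in bp.
- **Composite importance** normalizes raw permutation importances within
  each algorithm by the maximum positive score (negatives floored at 0)
  before weighting by median AUC; "normalize" is not otherwise defined,
  and max-normalization maps every algorithm onto the same 0–1 scale.
- **Insert size** is the outer span of the two mates; the 200 bp
  boundary value is "long" by default.
- **Duplicates** are not marked or removed anywhere; the counting
  semantics deliberately mirror `bedtools coverage -counts` on
  MAPQ-filtered reads.
- **Degenerate inputs**: a two-point exponential fit is flagged
  `degenerate` (R² = 1 by construction); empty HCB sets yield all-zero
  profiles; a held-out CV fold lacking one class reports missing
  sensitivity/specificity and is excluded from aggregation with a
  warning rather than silently averaged.

## The simulator: what it emulates, and what it does not

`simulate_cohort()` generates per-bin coverage directly in count space;
it does not simulate sequence. Its default parameters are the package's
fixed description of the data regime the analysis expects:

- **Genome**: 24 pseudo-chromosomes of 5,000 × 1-kb bins (120,000 bins),
  so a full 40-pair cohort simulates in seconds while preserving the
  many-chromosomes structure the profile statistic needs.
- **Background**: negative-binomial counts with mean 0.31 cpm — the
  genome-wide average of a real enrichment library — and size 0.5. The
  dispersion is chosen so the background's upper order statistics are
  consistent with the two observable anchors: nearly all bins fall below
  5 cpm, yet a planted peak of ~3.7 cpm still clears the 1,000th-ranked
  background bin (which sits near 2.3 cpm under these parameters).
- **Artifacts**: 2.5% of bins are enriched (mean 20 cpm) in every sample
  of both classes — the blocklist's target, matching the observed
  fraction of recurrently enriched bins.
- **Normals**: 1,200 sample-specific dispersed bins at mean 10 cpm,
  drawn uniformly over bins and hence proportional to chromosome length.
  With 24 chromosomes this puts the normal profile maximum around 50–65
  of the top 1,000 — dispersed, never clustered.
- **Tumors**: the same dispersed component plus one contiguous cluster
  of 100–300 bins (uniform) at mean 30 cpm on one of chr1/8/11/16/17 —
  the chromosome-clustered signal of a palindromic amplification. The
  cluster floor of 100 bins sits just above the normal maximum, so the
  classes are separable but not trivially so.
- **Dilution**: `simulate_dilution_series()` scales the planted peak's
  expected coverage linearly with tumor fraction (base 65.5 cpm) over an
  unchanged background — the simplest mechanism whose geometric dilution
  series produces the observed exponential decay of peak coverage.
- **Junctions**: `simulate_junction_alignments()` emits same-orientation
  mate pairs mirrored about a planted junction (FF on the left arm or RR
  on the right, per the fold-back geometry chosen), with concordant FR
  pairs elsewhere; spanning mates lie within ~300 bp of the junction, as
  fragments physically must.

What the simulator does **not** emulate: GC-dependent enrichment bias,
mappability structure, fragment-length biology of cfDNA, per-base error,
germline copy-number variation, and any correlation between neighboring
background bins. Passing recovery tests therefore demonstrates that the
pipeline's statistics behave as designed under the assumed generative
structure — not that the assay achieves any particular accuracy on real
libraries.

## Worked example

```{r example, eval = FALSE}
co  <- simulate_cohort(cohort_spec(seed = 1))
run <- gapf_pipeline(co$coverages, co$labels)
run
run$cv
head(run$calls)
```

On this synthetic cohort the 3,000 planted artifact bins are recovered by
the blocklist, every profile sums to 1,000, and the threshold model
separates the arms (cross-validated mean AUC 1.0 at the default signal
strength); permuting the labels collapses the AUC to chance. The same
stages run from the shell via the `gapf` script
(`gapf sim-cohort`, `gapf run`) and from a YAML config via
`run_pipeline()`.

## Problem sizes

The test suite exercises module logic on 6-chromosome toy genomes
(1,800 bins) and the recovery checks on the full default simulator
(120,000 bins, 40 pairs); the acceptance script additionally tiles a
reference-scale 25-contig manifest (3.2 million bins) to check bin
accounting. These sizes keep a complete run in the low tens of seconds
on one CPU while leaving every statistic's sample size large enough to
be meaningful.

## Known limitations

- The blocklist criterion (5 cpm in ≥ 75% of each arm) is an empirical
  operationalization; the published recurrent-artifact list was curated
  once on a specific cohort, so a supplied blocklist BED is accepted
  verbatim and takes precedence.
- The control-region BED shipped under `inst/extdata/` is **synthetic**:
  real inverted-repeat coordinates belong to a specific reference build
  and should be supplied by the user; the file exists so examples run on
  the toy genome.
- Fold-assignment RNGs differ between implementations, so seed-matched
  cross-validation partitions are reproducible within this package but
  not across tools.
- chrY is included in profiles by default but excluded from the
  23-feature ML matrix (chr1–22 + chrX); whether to count chrY HCBs in
  profiles is configurable via the `chromosomes` argument of
  `chromosome_profile()`.
- The ML layer deliberately fixes hyperparameters; it is a comparison
  baseline, not an AutoML replacement.
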
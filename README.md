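# gapfseq

Genome-wide profiling of DNA palindrome (fold-back inversion) enrichment
sequencing, and tumor/normal DNA calling from the chromosomal clustering
of high-coverage bins.

## The problem

DNA palindromes — loci whose sequence equals its own reverse complement
across a junction — arise *de novo* in tumors, typically during
breakage-fusion-bridge cycles that drive gene amplification. A snap-back
enrichment protocol (denature, rapidly renature so palindromic junctions
self-anneal, digest single-stranded DNA) leaves palindromic junction DNA
double-stranded, so shallow sequencing of the survivors concentrates
reads at palindromic loci. This package is the computational half of that
assay, for genomicists analyzing enriched libraries from tumor tissue or
plasma cell-free DNA: from aligned reads to per-bin coverage, artifact
curation, high-coverage-bin (HCB) profiles, and a binary tumor/normal
classifier.

## The model

Reads with MAPQ ≥ 40 are counted in 1-kb half-open bins and normalized
per million mapped reads (`cpm = raw / (N / 10^6)`). Bins recurrently
enriched in *both* tumors and normals (cpm > 5 in ≥ 75% of each arm) are
blocklisted. For each sample the top *K* = 1,000 retained bins by
coverage are its HCBs, and the per-chromosome HCB counts are its *GAPF
profile*. Normal DNA disperses HCBs across nearly all chromosomes; tumor
DNA clusters them. The decision statistic is

&nbsp;&nbsp;&nbsp;&nbsp;*s* = max over chromosomes *c* of HCB count(*c*),

and a sample is called positive when *s* ≥ *t*. Sweeping *t* over the
observed scores gives a ROC curve; the AUC is the trapezoidal integral
(provably equal to the Mann–Whitney statistic with ties counted ½), and
the operating threshold maximizes Youden's *J* = sensitivity +
specificity − 1. The protocol is evaluated with stratified 3-fold
cross-validation under fold-assignment seeds {22, 32, 42}, refitting the
threshold on each training split. A comparative ML layer (naive Bayes,
random forest, gradient boosting on the 23-feature chr1–22 + chrX count
matrix) runs under the same protocol, with permutation feature
importance and an AUC-weighted composite. Same-orientation (FF/RR)
read-pair clusters — the direct junction signature — and an insert-size
partitioner round out the toolkit, and a seeded simulator generates
cohorts, dilution series, and junction libraries with known truth.

## Worked example

```r
library(gapfseq)
co  <- simulate_cohort(cohort_spec(seed = 1))   # 40 tumor/normal pairs
run <- gapf_pipeline(co$coverages, co$labels)
run
#> gapf_run: 80 samples (40 tumor / 40 normal)
#>   bins: 120000 total - 3000 blocklisted = 117000 retained
#>   threshold 143: 40 positive calls; full-cohort AUC 1.0000, CV mean AUC 1.0000
run$cv
#> gapf_cv: 3-fold CV over seeds {22, 32, 42}
#>   mean AUC 1.0000 (sd 0.0000)
#>   sensitivity 97.44% (sd 3.85), specificity 100.00% (sd 0.00) at per-fold Youden thresholds
#>   whole-cohort Youden threshold: 143 (AUC 1.0000)
head(run$calls, 4)
#>   sample_id score threshold          call label qc_fail
#> 1   tumor01   200       143 GAPF-positive tumor   FALSE
#> 2   tumor02   248       143 GAPF-positive tumor   FALSE
#> 3   tumor03   248       143 GAPF-positive tumor   FALSE
#> 4   tumor04   166       143 GAPF-positive tumor   FALSE
```

Reading the output: the blocklist recovered the 3,000 planted artifact
bins; each sample's profile sums to 1,000 HCBs; the whole-cohort Youden
threshold (143 HCBs on some chromosome) separates every tumor from every
normal on this synthetic cohort, and cross-validated performance matches.
The same stages are scriptable from the shell via `exec/gapf`
(`gapf coverage`, `gapf blocklist-build`, `gapf classify-cv`,
`gapf sim-cohort`, `gapf run --config run.yaml`).

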
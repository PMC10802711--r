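# Independent brute-force oracles and small fixtures used across the suite.

# O(reads x bins) overlap count: a record with mapq >= mapq_min adds 1 to
# every bin it overlaps by >= 1 bp.
oracle_count <- function(aln, bins, mapq_min) {
  b <- bins$bins
  counts <- integer(nrow(b))
  for (i in seq_len(nrow(aln))) {
    if (aln$mapq[i] < mapq_min) next
    if (!(aln$chrom[i] %in% names(bins$chrom_sizes))) next
    hit <- b$chrom == aln$chrom[i] & b$start < aln$end[i] &
      b$end > aln$start[i]
    counts[hit] <- counts[hit] + 1L
  }
  counts
}

# Mann-Whitney pair statistic: over tumor x normal pairs, 1 if t > n,
# 1/2 if t == n, normalized by n1 * n2.
oracle_auc_mw <- function(scores, is_tumor) {
  t <- scores[is_tumor]; n <- scores[!is_tumor]
  s <- 0
  for (ti in t) for (ni in n) s <- s + (ti > ni) + 0.5 * (ti == ni)
  s / (length(t) * length(n))
}

# random BED-like alignment table on a given bin set
random_alignments <- function(bins, n, read_len = 150, seed = 1) {
  set.seed(seed)
  chrom <- sample(names(bins$chrom_sizes), n, replace = TRUE)
  start <- floor(runif(n, 0, bins$chrom_sizes[chrom] - read_len))
  data.frame(chrom = chrom, start = start, end = start + read_len,
             name = sprintf("r%d", seq_len(n)),
             mapq = sample(c(0, 10, 40, 60), n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE))
}

# small, fast cohort spec for module-level tests (6 chromosomes x 300
# bins; clusters of 40-80 bins; 6 vs 6 samples)
small_spec <- function(seed = 1, n_tumor = 6, n_normal = 6, ...) {
  genome <- stats::setNames(rep(3e5, 6),
                            c(paste0("chr", 1:4), "chrX", "chrY"))
  cohort_spec(n_tumor = n_tumor, n_normal = n_normal, genome = genome,
              n_artifact_bins = 50, n_dispersed = 120,
              cluster_chromosomes = c("chr1", "chr2"),
              cluster_size_range = c(40, 80), seed = seed, ...)
}

# toy cytoband table for a genome: each chromosome split into `per_chrom`
# equal bands named p1, q1, q2, ...
toy_cytobands <- function(genome, per_chrom = 4) {
  do.call(rbind, lapply(names(genome), function(chr) {
    edges <- round(seq(0, genome[[chr]], length.out = per_chrom + 1))
    data.frame(chrom = chr, start = edges[-length(edges)], end = edges[-1],
               name = c("p1", paste0("q", seq_len(per_chrom - 1))),
               stain = "gneg")
  }))
}
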
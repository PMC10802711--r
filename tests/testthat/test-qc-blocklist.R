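make_cov <- function(bins, cpm10, sample_id = "s", mapq_min = 40) {
  # counts in raw space with total 1e7 mapped reads: 1 cpm = 10 raw
  gapf_coverage(bins, as.integer(round(cpm10 * 10)),
                total_mapped_reads = 1e7, sample_id = sample_id,
                mapq_min = mapq_min)
}

test_that("control-region scores are two-level means with strict QC bounds", {
  bins <- build_bins(c(chr1 = 6000), bin_width = 1000)
  regions <- data.frame(chrom = "chr1", start = c(0, 2000, 4000),
                        end = c(1000, 3000, 5000),
                        label = c("IR1", "IR2", "IR3"))
  cov <- make_cov(bins, c(2, 0, 0.5, 0, 0.5, 0), mapq_min = 0)
  expect_equal(amplification_score(cov, regions), 1.0)
  # score exactly 1.0 fails the strict > 1.0 bound
  expect_false(qc_evaluate(1.0, 0.05)$pass)
  expect_true(qc_evaluate(1.2, 0.05)$pass)
  expect_false(qc_evaluate(0.9, 0.05)$pass)
  expect_false(qc_evaluate(1.2, 0.075)$pass)  # strict < 0.075
  expect_error(qc_evaluate(Inf, 0), "finite")

  zero <- make_cov(bins, rep(0, 6), mapq_min = 0)
  expect_equal(amplification_score(zero, regions), 0)
  bad <- data.frame(chrom = "chr9", start = 0, end = 100, label = "OFF")
  expect_error(amplification_score(cov, bad), "OFF")
})

test_that("region averaging matches an independent two-level oracle", {
  bins <- build_bins(c(chr1 = 25000, chr2 = 12000), bin_width = 1000)
  set.seed(9)
  cpm <- rexp(n_bins(bins))
  cov <- gapf_coverage(bins, as.integer(round(cpm * 100)), 1e8,
                       mapq_min = 0)
  regions <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                        start = c(500, 9000, 0),
                        end = c(4500, 9100, 12000),
                        label = c("a", "b", "c"))
  per_region <- sapply(seq_len(nrow(regions)), function(i) {
    b <- cov$table
    sel <- b$chrom == regions$chrom[i] & b$start < regions$end[i] &
      b$end > regions$start[i]
    mean(b$cpm[sel])
  })
  expect_equal(amplification_score(cov, regions), mean(per_region),
               tolerance = 1e-12)
})

test_that("MAPQ filtering depletes multi-mapping control regions", {
  bins <- build_bins(c(chr1 = 10000), bin_width = 1000)
  regions <- data.frame(chrom = "chr1", start = 2000, end = 4000,
                        label = "IR")
  # multi-mapping reads (MAPQ 0) pile on the control repeat
  n <- 200
  aln <- data.frame(chrom = "chr1",
                    start = sample(2000:3800, n, replace = TRUE),
                    name = sprintf("r%d", 1:n),
                    mapq = 0, strand = "+")
  aln$end <- aln$start + 150
  aln <- aln[, c("chrom", "start", "end", "name", "mapq", "strand")]
  unfilt <- bin_coverage(aln, bins, mapq_min = 0, total_mapped_reads = 1e6)
  filt <- bin_coverage(aln, bins, mapq_min = 40, total_mapped_reads = 1e6)
  expect_lt(depletion_score(filt, regions),
            amplification_score(unfilt, regions))
  expect_equal(depletion_score(filt, regions), 0)
  # identity case: same coverage in, same score out
  expect_equal(suppressWarnings(depletion_score(unfilt, regions)),
               amplification_score(unfilt, regions))
})

test_that("background bins require recurrent enrichment in both arms", {
  bins <- build_bins(c(chr1 = 5000), bin_width = 1000)
  # bin 1: enriched everywhere; bin 2: tumors only; bin 3: one normal
  tum <- lapply(1:4, function(i)
    make_cov(bins, c(50, 50, 0, 0, 0), sprintf("t%d", i)))
  nor <- lapply(1:4, function(i)
    make_cov(bins, c(50, 0, if (i == 1) 50 else 0, 0, 0),
             sprintf("n%d", i)))
  bl <- identify_background_bins(c(tum, nor), rep(c("tumor", "normal"),
                                                  each = 4),
                                 enrich_cutoff = 5, min_fraction = 0.75)
  expect_equal(bl$bins, data.frame(chrom = "chr1", start = 0))
  expect_error(identify_background_bins(list(), character(0)), "empty")
  expect_error(identify_background_bins(tum, rep("tumor", 4)), "normal")
})

test_that("blocklist construction matches a per-bin tally oracle and is monotone", {
  spec <- small_spec(seed = 4)
  co <- simulate_cohort(spec)
  bl <- identify_background_bins(co$coverages, co$labels)
  # oracle: explicit loop over bins
  cpms <- sapply(co$coverages, function(cv) cv$table$cpm)
  is_t <- co$labels == "tumor"
  expected <- which(vapply(seq_len(nrow(cpms)), function(i) {
    e <- cpms[i, ] > 5
    mean(e[is_t]) >= 0.75 && mean(e[!is_t]) >= 0.75
  }, logical(1)))
  got <- match(paste(bl$bins$chrom, bl$bins$start),
               paste(co$bins$bins$chrom, co$bins$bins$start))
  expect_setequal(got, expected)
  # planted artifact bins are recovered
  expect_true(all(co$truth$artifact_bin_index %in% got))

  # monotonicity: larger cutoff or fraction never grows the list
  bl_hi <- identify_background_bins(co$coverages, co$labels,
                                    enrich_cutoff = 10)
  bl_frac <- identify_background_bins(co$coverages, co$labels,
                                      min_fraction = 0.9)
  key <- function(b) paste(b$bins$chrom, b$bins$start)
  expect_true(all(key(bl_hi) %in% key(bl)))
  expect_true(all(key(bl_frac) %in% key(bl)))

  # symmetry: sample order within arms is irrelevant
  perm <- c(sample(which(is_t)), sample(which(!is_t)))
  bl_perm <- identify_background_bins(co$coverages[perm], co$labels[perm])
  expect_equal(bl_perm$bins, bl$bins)
})

test_that("blocklist application is exact, idempotent, and validated", {
  bins <- build_bins(c(chr1 = 8000, chr2 = 4000), bin_width = 1000)
  cov <- make_cov(bins, seq_len(n_bins(bins)))
  bl <- structure(list(bins = data.frame(chrom = c("chr1", "chr2"),
                                         start = c(2000, 0)),
                       provenance = list()),
                  class = "gapf_blocklist")
  f1 <- apply_blocklist(cov, bl)
  expect_equal(nrow(f1$table), n_bins(bins) - 2)
  # retained values unchanged
  expect_equal(f1$table$cpm,
               cov$table$cpm[-match(c("chr1 2000", "chr2 0"),
                                    paste(cov$table$chrom,
                                          cov$table$start))])
  f2 <- apply_blocklist(f1, bl)
  expect_equal(f2$table, f1$table)
  # empty blocklist is the identity
  empty <- structure(list(bins = data.frame(chrom = character(),
                                            start = numeric()),
                          provenance = list()),
                     class = "gapf_blocklist")
  expect_equal(apply_blocklist(cov, empty)$table, cov$table)
  # bins outside the universe are rejected
  alien <- structure(list(bins = data.frame(chrom = "chr9", start = 0),
                          provenance = list()),
                     class = "gapf_blocklist")
  expect_error(apply_blocklist(cov, alien), "absent")
})

test_that("blocklist BED round-trips with provenance", {
  spec <- small_spec(seed = 6, n_tumor = 3, n_normal = 3)
  co <- simulate_cohort(spec)
  bl <- identify_background_bins(co$coverages, co$labels)
  path <- withr::local_tempfile(fileext = ".bed")
  write_blocklist(bl, path)
  back <- read_blocklist(path)
  expect_equal(back$bins, bl$bins)
  expect_equal(back$provenance$enrich_cutoff, 5)
})
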
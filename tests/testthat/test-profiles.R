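cov_from_cpm <- function(bins, cpm10) {
  gapf_coverage(bins, as.integer(round(cpm10 * 10)),
                total_mapped_reads = 1e7, sample_id = "s", mapq_min = 40)
}

test_that("top-K selection is deterministic under the tie rule", {
  bins <- build_bins(c(chr1 = 4000, chr2 = 4000), bin_width = 1000)
  # chr2:0 and chr1:3000 tie at the K-th value; chr1 (earlier chromosome)
  # must win
  cov <- cov_from_cpm(bins, c(9, 8, 0, 5, 5, 0, 0, 0))
  h <- top_k_hcbs(cov, k = 3)
  expect_equal(h$chrom, c("chr1", "chr1", "chr1"))
  expect_equal(h$start, c(0, 1000, 3000))

  # within-chromosome tie: smaller start wins
  cov2 <- cov_from_cpm(bins, c(5, 0, 5, 5, 0, 0, 0, 0))
  h2 <- top_k_hcbs(cov2, k = 2)
  expect_equal(h2$start, c(0, 2000))

  expect_error(top_k_hcbs(cov, k = 0), "positive")
})

test_that("top-K matches a full-sort oracle and is scale-invariant", {
  bins <- build_bins(c(chr1 = 50000, chr2 = 30000), bin_width = 1000)
  set.seed(21)
  raw <- rnbinom(n_bins(bins), size = 0.5, mu = 5)
  cov <- gapf_coverage(bins, raw, 1e7)
  h <- top_k_hcbs(cov, k = 25)
  ord <- order(-cov$table$cpm,
               match(cov$table$chrom, names(bins$chrom_sizes)),
               cov$table$start)
  expect_equal(h$cpm, cov$table$cpm[ord][1:25])
  expect_setequal(paste(h$chrom, h$start),
                  paste(cov$table$chrom, cov$table$start)[ord][1:25])
  # scaling every cpm by a positive constant leaves the set unchanged
  cov3 <- cov; cov3$table$cpm <- cov3$table$cpm * 7.5
  h3 <- top_k_hcbs(cov3, k = 25)
  expect_equal(paste(h3$chrom, h3$start), paste(h$chrom, h$start))
})

test_that("chromosome profiles count HCBs and always sum to K", {
  bins <- build_bins(stats::setNames(rep(10000, 3),
                                     c("chr1", "chr8", "chrX")), 1000)
  cpm10 <- numeric(30); cpm10[11:20] <- 50  # all signal on chr8
  cov <- cov_from_cpm(bins, cpm10)
  prof <- chromosome_profile(top_k_hcbs(cov, k = 10))
  expect_equal(as.integer(prof), c(0, 10, 0))
  expect_equal(sum(prof), 10)

  # restriction to a chromosome subset: error by default, drop on request
  h <- top_k_hcbs(cov, k = 12)  # picks 2 zero-cpm bins on chr1 too
  expect_error(chromosome_profile(h, chromosomes = c("chr8")), "outside")
  expect_warning(p2 <- chromosome_profile(h, chromosomes = c("chr8"),
                                          drop = TRUE), "dropped")
  expect_equal(sum(p2), 10)
})

test_that("cytoband counts agree with interval lookup and chromosome totals", {
  spec <- small_spec(seed = 13, n_tumor = 2, n_normal = 2)
  co <- simulate_cohort(spec)
  bands <- toy_cytobands(spec$genome)
  cov <- co$coverages[[1]]
  h <- top_k_hcbs(cov, k = 200)
  bc <- cytoband_counts(h, bands)
  expect_equal(sum(bc$count), nrow(h))
  # interval-lookup oracle
  expected <- vapply(seq_len(nrow(bands)), function(i)
    sum(h$chrom == bands$chrom[i] & h$start >= bands$start[i] &
          h$start < bands$end[i]), numeric(1))
  expect_equal(bc$count, as.integer(expected))
  # per-chromosome band sums equal the chromosome profile
  prof <- chromosome_profile(h)
  band_sums <- tapply(bc$count, bc$chrom, sum)
  expect_equal(as.integer(band_sums[names(prof)]), as.integer(prof))
})

test_that("cytoband coverage is length-normalized cpm mass", {
  bins <- build_bins(c(chr1 = 8000), bin_width = 1000)
  bands <- data.frame(chrom = "chr1", start = c(0, 4000),
                      end = c(4000, 8000), name = c("p1", "q1"),
                      stain = "gneg")
  # uniform cpm c over a band of L 1-kb bins -> c * L / (1000 * L) = c/1000
  cov <- cov_from_cpm(bins, rep(c(2, 0), each = 4))
  bc <- cytoband_coverage(cov, bands)
  expect_equal(bc$coverage, c(2 / 1000, 0))
  # oracle on irregular values
  cov2 <- cov_from_cpm(bins, c(1, 2, 3, 4, 5, 6, 7, 8))
  bc2 <- cytoband_coverage(cov2, bands)
  expect_equal(bc2$coverage, c(sum(1:4) / 4000, sum(5:8) / 4000))
  bad <- bands; bad$end[1] <- bad$start[1]
  expect_error(cytoband_coverage(cov, bad), "zero-length")
})

test_that("cytoband ingestion drops unplaced sequences and rejects overlap", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("chr1\t0\t500\tp1\tgneg",
               "chr1\t500\t1000\tq1\tgpos50",
               "chr1_random\t0\t100\tq9\tgneg"), path)
  bands <- read_cytobands(path)
  expect_equal(nrow(bands), 2)
  expect_equal(attr(bands, "n_downloaded"), 3)
  writeLines(c("chr1\t0\t600\tp1\tgneg",
               "chr1\t500\t1000\tq1\tgneg"), path)
  expect_error(read_cytobands(path), "overlap")
})

test_that("log-linear decay fit recovers exact exponentials and OLS coefficients", {
  x <- c(0, 0.5, 1, 2, 4)
  y <- 3 * exp(-0.5 * x)
  fit <- fit_exponential_decay(x, y)
  expect_equal(fit$a, 3)
  expect_equal(fit$b, -0.5)
  expect_equal(fit$r_squared, 1)

  two <- fit_exponential_decay(c(0, 1), c(4, 2))
  expect_true(two$degenerate)
  expect_equal(two$r_squared, 1)

  # closed-form OLS oracle on noisy data
  set.seed(2)
  yn <- y * exp(rnorm(5, 0, 0.1))
  fitn <- fit_exponential_decay(x, yn)
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% log(yn))
  expect_equal(fitn$a, exp(beta[1]), tolerance = 1e-12)
  expect_equal(fitn$b, beta[2], tolerance = 1e-12)

  expect_error(fit_exponential_decay(c(0, 1, 2), c(1, 0, 2)), "positive")
  expect_error(fit_exponential_decay(1, 1), ">= 2")
})
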
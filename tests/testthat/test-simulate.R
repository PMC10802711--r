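test_that("simulation is deterministic given (spec, seed)", {
  spec <- small_spec(seed = 3, n_tumor = 3, n_normal = 3)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(lapply(a$coverages, `[[`, "table"),
                   lapply(b$coverages, `[[`, "table"))
  expect_identical(a$truth, b$truth)

  d1 <- simulate_dilution_series(dilution_spec(genome = spec$genome),
                                 seed = 8)
  d2 <- simulate_dilution_series(dilution_spec(genome = spec$genome),
                                 seed = 8)
  expect_identical(lapply(d1$coverages, `[[`, "table"),
                   lapply(d2$coverages, `[[`, "table"))

  j1 <- simulate_junction_alignments(junction_spec(), seed = 4)
  j2 <- simulate_junction_alignments(junction_spec(), seed = 4)
  expect_identical(j1$pairs, j2$pairs)
})

test_that("planted tumor clusters dominate the tumors' profiles", {
  spec <- small_spec(seed = 12,
                     cluster_cpm = 40, dispersed_cpm = 8)
  co <- simulate_cohort(spec)
  bl <- identify_background_bins(co$coverages, co$labels)
  for (i in which(co$labels == "tumor")) {
    cv <- apply_blocklist(co$coverages[[i]], bl)
    prof <- chromosome_profile(top_k_hcbs(cv, k = 1000))
    truth <- co$truth$clusters[[cv$sample_id]]
    expect_gte(prof[truth$chrom], truth$size)
  }
})

test_that("a normals-only cohort is rejected downstream, not by the simulator", {
  spec <- small_spec(seed = 5, n_tumor = 0, n_normal = 4)
  co <- simulate_cohort(spec)
  expect_equal(unique(co$labels), "normal")
  profs <- profile_set(lapply(co$coverages, function(cv)
    chromosome_profile(top_k_hcbs(cv, k = 200))), labels = co$labels)
  expect_error(roc_curve(profs), "both classes")
})

test_that("cluster sizes beyond the chromosome are rejected", {
  genome <- c(chr1 = 3e5, chr2 = 3e5)
  expect_error(cohort_spec(genome = genome,
                           cluster_chromosomes = "chr1",
                           cluster_size_range = c(100, 500)),
               "exceeds")
  expect_error(dilution_spec(fractions = c(0.5, 0)), "fraction")
  expect_error(junction_spec(read_length = 5000, arm_length = 5000),
               "arm length")
})

test_that("noise-free dilution peaks scale linearly and fit exactly", {
  spec <- dilution_spec(fractions = c(1, 0.5, 0.1), base_peak_cpm = 60,
                        genome = c(chr1 = 3e5))
  ser <- simulate_dilution_series(spec, seed = 1, noise = FALSE)
  expect_equal(ser$peak_mean_cpm, c(60, 30, 6))
  # geometric fractions decay exponentially along the series index
  geo <- dilution_spec(fractions = c(1, 0.5, 0.25, 0.125),
                       base_peak_cpm = 60, genome = c(chr1 = 3e5))
  serg <- simulate_dilution_series(geo, seed = 1, noise = FALSE)
  fit <- fit_exponential_decay(seq_along(serg$fractions),
                               serg$peak_mean_cpm)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$b, log(0.5))
})

test_that("background coverage matches its generative rate across seeds", {
  genome <- c(chr1 = 3e5, chr2 = 3e5)
  rates <- vapply(1:20, function(s) {
    spec <- cohort_spec(n_tumor = 1, n_normal = 1, genome = genome,
                        n_artifact_bins = 10, n_dispersed = 20,
                        cluster_chromosomes = "chr1",
                        cluster_size_range = c(20, 30), seed = s)
    co <- simulate_cohort(spec)
    cv <- co$coverages[[2]]  # a normal sample
    bg <- setdiff(seq_len(n_bins(co$bins)),
                  c(co$truth$artifact_bin_index,
                    co$truth$dispersed_bin_index[[cv$sample_id]]))
    mean(cv$table$cpm[bg])
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.31) / 0.31, 0.1)
})

test_that("junction libraries plant recoverable same-orientation evidence", {
  # no spanning pairs -> no FF/RR clusters
  none <- simulate_junction_alignments(
    junction_spec(fraction_spanning = 0), seed = 3)
  expect_equal(nrow(find_same_orientation_clusters(none$pairs)), 0)

  # 20 spanning pairs at position p -> one cluster near p, support 20
  spec <- junction_spec(n_pairs = 100, fraction_spanning = 0.2)
  sim <- simulate_junction_alignments(spec, seed = 9)
  expect_equal(sim$truth$n_spanning, 20)
  cl <- find_same_orientation_clusters(sim$pairs, min_support = 3,
                                       merge_distance = 1000)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$support, 20)
  expect_equal(cl$orientation, "FF")
  expect_lt(abs(cl$end - spec$junction_pos), 1000 + spec$read_length)

  # RR geometry sits on the other side of the junction
  rr <- simulate_junction_alignments(
    junction_spec(n_pairs = 50, fraction_spanning = 0.4,
                  orientation = "RR"), seed = 9)
  clr <- find_same_orientation_clusters(rr$pairs)
  expect_equal(clr$orientation, "RR")
  expect_gte(clr$start, rr$truth$junction_pos)

  # conservation: emitted records match the spec totals
  expect_equal(nrow(sim$pairs), 100)
})

test_that("simulated pairs round-trip through the coverage module", {
  spec <- junction_spec(chrom = "chr1", junction_pos = 50000,
                        arm_length = 3000, n_pairs = 60,
                        fraction_spanning = 0.2)
  sim <- simulate_junction_alignments(spec, seed = 6)
  aln <- pairs_to_alignments(sim$pairs)
  bins <- build_bins(c(chr1 = 100000), bin_width = 1000)
  counts <- count_reads_in_bins(aln, bins, mapq_min = 40)
  expect_equal(as.integer(counts), oracle_count(aln, bins, 40))
  expect_equal(sum(counts >= 1), sum(oracle_count(aln, bins, 40) >= 1))
})
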
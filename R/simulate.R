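# Synthetic-data generators. They emulate the statistical structure of
# palindrome-enrichment sequencing: a heavy mass of near-zero bins
# (genome-wide mean coverage ~0.31 cpm), shared artifact-enriched bins
# present in both classes, sample-specific dispersed high bins in normals,
# chromosome-clustered high bins in tumors, dilution series whose planted
# peak coverage scales linearly with tumor fraction, and paired alignments
# with FF/RR mates flanking a planted fold-back junction. Counts are
# negative-binomial (mean/dispersion); every generator is deterministic
# given (spec, seed).

with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# default toy genome: 24 pseudo-chromosomes of 5,000 bins each, so full
# cohort runs finish in seconds
toy_genome <- function(n_bins_per_chrom = 5000, bin_width = 1000) {
  stats::setNames(rep(n_bins_per_chrom * bin_width, 24),
                  paste0("chr", c(1:22, "X", "Y")))
}

#' Generative parameters for a synthetic tumor/normal cohort
#'
#' Defaults encode the cohort structure the analysis assumes: 40 matched
#' pairs; background bins at a genome-wide mean of 0.31 cpm with strong
#' overdispersion (most bins near zero); ~2.5% of bins artifact-enriched in
#' every sample of both classes (the blocklist's target); per-sample
#' dispersed high bins drawn uniformly over bins (hence proportional to
#' chromosome length) in all samples; and, in tumors only, one contiguous
#' cluster of 100-300 enriched bins on a single chromosome.
#'
#' @param n_tumor,n_normal samples per arm (default 40 each)
#' @param genome named chromosome-length vector (default: 24
#'   pseudo-chromosomes of 5 Mb)
#' @param bin_width bin width in bp (default 1000)
#' @param total_reads per-million normalization denominator; 1e7 makes
#'   1 cpm = 10 raw counts
#' @param background_rate mean background coverage in cpm (default 0.31)
#' @param background_dispersion negative-binomial size of background counts
#'   (default 0.5; small = heavy near-zero mass with a long tail)
#' @param n_artifact_bins shared artifact-enriched bins (default 2.5% of
#'   the genome's bins)
#' @param artifact_cpm,artifact_dispersion artifact enrichment level
#'   (mean 20 cpm) and NB size
#' @param n_dispersed,dispersed_cpm,dispersed_dispersion sample-specific
#'   dispersed high bins per sample (1,200 at mean 10 cpm)
#' @param cluster_chromosomes chromosomes a tumor's cluster may land on
#' @param cluster_size_range inclusive range of cluster bin counts
#'   (default 100-300)
#' @param cluster_cpm,cluster_dispersion cluster enrichment level
#'   (mean 30 cpm) and NB size
#' @param seed RNG seed; identical (spec, seed) gives identical cohorts
#' @return a `gapf_cohort_spec` list
#' @export
cohort_spec <- function(n_tumor = 40, n_normal = 40,
                        genome = toy_genome(), bin_width = 1000,
                        total_reads = 1e7,
                        background_rate = 0.31,
                        background_dispersion = 0.5,
                        n_artifact_bins = NULL,
                        artifact_cpm = 20, artifact_dispersion = 5,
                        n_dispersed = 1200, dispersed_cpm = 10,
                        dispersed_dispersion = 10,
                        cluster_chromosomes = c("chr1", "chr8", "chr11",
                                                "chr16", "chr17"),
                        cluster_size_range = c(100, 300),
                        cluster_cpm = 30, cluster_dispersion = 10,
                        seed = 1) {
  nb_total <- sum(ceiling(genome / bin_width))
  if (is.null(n_artifact_bins))
    n_artifact_bins <- round(0.025 * nb_total)
  if (!all(cluster_chromosomes %in% names(genome)))
    stop("cluster chromosome(s) absent from the genome")
  if (any(cluster_size_range > min(ceiling(genome[cluster_chromosomes] /
                                           bin_width))))
    stop("cluster size exceeds the chromosome's bin count")
  structure(as.list(environment()), class = "gapf_cohort_spec")
}

# NB draw in raw-count space for a component stated in cpm
rnb_cpm <- function(n, cpm_mean, size, total_reads) {
  stats::rnbinom(n, size = size, mu = cpm_mean * total_reads / 1e6)
}

# one sample's raw counts: background everywhere, plus enrichment
# components added at the given bin indices
sim_sample_counts <- function(spec, nb, artifact_idx, extra_idx, extra_cpm,
                              extra_size) {
  raw <- rnb_cpm(nb, spec$background_rate, spec$background_dispersion,
                 spec$total_reads)
  raw[artifact_idx] <- raw[artifact_idx] +
    rnb_cpm(length(artifact_idx), spec$artifact_cpm,
            spec$artifact_dispersion, spec$total_reads)
  disp_idx <- sample.int(nb, spec$n_dispersed)
  raw[disp_idx] <- raw[disp_idx] +
    rnb_cpm(spec$n_dispersed, spec$dispersed_cpm,
            spec$dispersed_dispersion, spec$total_reads)
  if (length(extra_idx))
    raw[extra_idx] <- raw[extra_idx] +
      rnb_cpm(length(extra_idx), extra_cpm, extra_size, spec$total_reads)
  list(raw = raw, dispersed_idx = disp_idx)
}

#' Simulate a tumor/normal cohort of per-bin coverage tables
#'
#' Every sample shares the artifact bins; every sample carries dispersed
#' high bins; each tumor additionally carries one planted contiguous
#' cluster. The truth list records the artifact bins and each tumor's
#' cluster so downstream recovery can be checked exactly.
#'
#' @param spec a [cohort_spec()]
#' @return a `gapf_cohort` list: `bins` (`gapf_bins`), `coverages` (list of
#'   `gapf_coverage`), `labels`, `truth` (artifact bin indices, per-tumor
#'   cluster chromosome/bins, per-sample dispersed bin indices), `spec`
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "gapf_cohort_spec"))
  bins <- build_bins(spec$genome, spec$bin_width)
  nb <- n_bins(bins)
  with_preserved_seed(spec$seed, {
    artifact_idx <- sort(sample.int(nb, spec$n_artifact_bins))
    labels <- c(rep("tumor", spec$n_tumor), rep("normal", spec$n_normal))
    ids <- c(sprintf("tumor%02d", seq_len(spec$n_tumor)),
             sprintf("normal%02d", seq_len(spec$n_normal)))
    clusters <- list()
    dispersed <- list()
    coverages <- vector("list", length(labels))
    for (i in seq_along(labels)) {
      if (labels[i] == "tumor") {
        chr <- sample(spec$cluster_chromosomes, 1)
        csize <- sample(seq(spec$cluster_size_range[1],
                            spec$cluster_size_range[2]), 1)
        chr_bins <- which(bins$bins$chrom == chr)
        start_at <- sample.int(length(chr_bins) - csize + 1, 1)
        cl_idx <- chr_bins[start_at:(start_at + csize - 1)]
        clusters[[ids[i]]] <- list(chrom = chr, size = csize,
                                   bin_index = cl_idx)
      } else {
        cl_idx <- integer()
      }
      sim <- sim_sample_counts(spec, nb, artifact_idx, cl_idx,
                               spec$cluster_cpm, spec$cluster_dispersion)
      dispersed[[ids[i]]] <- sim$dispersed_idx
      coverages[[i]] <- gapf_coverage(bins, sim$raw,
                                      total_mapped_reads = spec$total_reads,
                                      sample_id = ids[i], mapq_min = 40)
    }
    structure(list(bins = bins, coverages = coverages, labels = labels,
                   truth = list(artifact_bin_index = artifact_idx,
                                clusters = clusters,
                                dispersed_bin_index = dispersed),
                   spec = spec),
              class = "gapf_cohort")
  })
}

#' @export
print.gapf_cohort <- function(x, ...) {
  cat(sprintf("gapf_cohort: %d tumors + %d normals, %d bins, seed %d\n",
              sum(x$labels == "tumor"), sum(x$labels == "normal"),
              n_bins(x$bins), x$spec$seed))
  invisible(x)
}

#' Generative parameters for a tumor-DNA dilution series
#'
#' A planted palindromic peak (a short run of contiguous bins) whose
#' expected coverage scales linearly with tumor fraction before noise, on
#' an unchanged background — the in vitro dilution experiment.
#'
#' @param fractions tumor fractions in (0, 1] (default 1, 0.5, 0.25, 0.1)
#' @param base_peak_cpm peak mean coverage at fraction 1 (default 65.5)
#' @param peak_chrom,peak_n_bins peak locus (default 5 bins on chr1)
#' @param genome,bin_width,total_reads as in [cohort_spec()]
#' @param background_rate,background_dispersion background noise (mean
#'   0.31 cpm)
#' @param peak_dispersion NB size of the peak counts
#' @return a `gapf_dilution_spec` list
#' @export
dilution_spec <- function(fractions = c(1, 0.5, 0.25, 0.1),
                          base_peak_cpm = 65.5,
                          peak_chrom = "chr1", peak_n_bins = 5,
                          genome = toy_genome(), bin_width = 1000,
                          total_reads = 1e7, background_rate = 0.31,
                          background_dispersion = 0.5,
                          peak_dispersion = 10) {
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]; simulate a pure normal sample ",
         "instead of fraction 0")
  if (!(peak_chrom %in% names(genome)))
    stop("peak chromosome absent from the genome")
  structure(as.list(environment()), class = "gapf_dilution_spec")
}

#' Simulate a dilution series of coverage tables
#'
#' @param spec a [dilution_spec()]
#' @param seed RNG seed
#' @param noise draw negative-binomial counts (default); `FALSE` plants
#'   exact expected counts, for closed-form checks
#' @return a `gapf_dilution` list: `coverages` (one per fraction),
#'   `fractions`, `peak_mean_cpm` (observed mean peak coverage per
#'   fraction), `truth` (peak chromosome and bin indices), `spec`
#' @export
simulate_dilution_series <- function(spec, seed = 1, noise = TRUE) {
  stopifnot(inherits(spec, "gapf_dilution_spec"))
  bins <- build_bins(spec$genome, spec$bin_width)
  nb <- n_bins(bins)
  with_preserved_seed(seed, {
    chr_bins <- which(bins$bins$chrom == spec$peak_chrom)
    start_at <- sample.int(length(chr_bins) - spec$peak_n_bins + 1, 1)
    peak_idx <- chr_bins[start_at:(start_at + spec$peak_n_bins - 1)]
    scale <- spec$total_reads / 1e6
    coverages <- lapply(seq_along(spec$fractions), function(i) {
      f <- spec$fractions[i]
      if (noise) {
        raw <- stats::rnbinom(nb, size = spec$background_dispersion,
                              mu = spec$background_rate * scale)
        raw[peak_idx] <- raw[peak_idx] +
          stats::rnbinom(length(peak_idx), size = spec$peak_dispersion,
                         mu = f * spec$base_peak_cpm * scale)
      } else {
        raw <- numeric(nb)
        raw[peak_idx] <- f * spec$base_peak_cpm * scale
      }
      gapf_coverage(bins, raw, total_mapped_reads = spec$total_reads,
                    sample_id = sprintf("dilution_%g", f), mapq_min = 40)
    })
    peak_mean <- vapply(coverages, function(cv)
      mean(cv$table$cpm[peak_idx]), numeric(1))
    structure(list(coverages = coverages, fractions = spec$fractions,
                   peak_mean_cpm = peak_mean,
                   truth = list(peak_chrom = spec$peak_chrom,
                                peak_bin_index = peak_idx),
                   spec = spec),
              class = "gapf_dilution")
  })
}

#' Generative parameters for a fold-back junction read-pair library
#'
#' @param chrom,junction_pos junction locus (bp, 0-based)
#' @param arm_length palindrome arm length in bp (must exceed the read
#'   length)
#' @param read_length read length in bp (default 150)
#' @param n_pairs pairs to emit
#' @param fraction_spanning fraction of pairs spanning the junction, hence
#'   emitted with same-orientation mates
#' @param orientation orientation class of the spanning pairs (`"FF"`,
#'   mates mirrored left of the junction, or `"RR"`, right of it)
#' @param span_window maximum mate offset from the junction for spanning
#'   pairs in bp (default 300 — a spanning fragment's mates lie within
#'   roughly one fragment length of the junction)
#' @param insert_mean,insert_sd concordant-pair insert-size model (bp)
#' @param mapq MAPQ assigned to every mate
#' @return a `gapf_junction_spec` list
#' @export
junction_spec <- function(chrom = "chr1", junction_pos = 2.5e6,
                          arm_length = 5000, read_length = 150,
                          n_pairs = 200, fraction_spanning = 0.1,
                          orientation = c("FF", "RR"), span_window = 300,
                          insert_mean = 300, insert_sd = 30, mapq = 60) {
  orientation <- match.arg(orientation)
  if (read_length >= arm_length)
    stop("read length must be smaller than the arm length")
  if (fraction_spanning < 0 || fraction_spanning > 1)
    stop("fraction_spanning must lie in [0, 1]")
  structure(as.list(environment()), class = "gapf_junction_spec")
}

#' Simulate paired alignments around a planted fold-back junction
#'
#' Junction-spanning pairs are emitted with same-orientation mates
#' mirrored about the junction (both forward on the left arm for `"FF"`,
#' both reverse on the right arm for `"RR"`); the rest are concordant FR
#' pairs drawn along both arms.
#'
#' @param spec a [junction_spec()]
#' @param seed RNG seed
#' @return a `gapf_junction_sim` list: `pairs` (paired records),
#'   `truth` (junction position, spanning-pair count, orientation), `spec`
#' @export
simulate_junction_alignments <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "gapf_junction_spec"))
  with_preserved_seed(seed, {
    n_span <- round(spec$n_pairs * spec$fraction_spanning)
    n_conc <- spec$n_pairs - n_span
    rl <- spec$read_length
    j <- spec$junction_pos
    rows <- list()
    if (n_span > 0) {
      # mate offsets from the junction, within one arm
      w <- min(spec$arm_length - rl, spec$span_window)
      d1 <- sample.int(w, n_span, replace = TRUE)
      d2 <- sample.int(w, n_span, replace = TRUE)
      if (spec$orientation == "FF") {
        rows$span <- data.frame(
          chrom = spec$chrom,
          start1 = j - d1 - rl, end1 = j - d1, strand1 = "+",
          start2 = j - d2 - rl, end2 = j - d2, strand2 = "+",
          mapq1 = spec$mapq, mapq2 = spec$mapq)
      } else {
        rows$span <- data.frame(
          chrom = spec$chrom,
          start1 = j + d1, end1 = j + d1 + rl, strand1 = "-",
          start2 = j + d2, end2 = j + d2 + rl, strand2 = "-",
          mapq1 = spec$mapq, mapq2 = spec$mapq)
      }
    }
    if (n_conc > 0) {
      ins <- pmax(rl + 1,
                  round(stats::rnorm(n_conc, spec$insert_mean,
                                     spec$insert_sd)))
      lo <- j - spec$arm_length
      s1 <- lo + sample.int(2 * spec$arm_length - max(ins) - rl, n_conc,
                            replace = TRUE)
      rows$conc <- data.frame(
        chrom = spec$chrom,
        start1 = s1, end1 = s1 + rl, strand1 = "+",
        start2 = s1 + ins - rl, end2 = s1 + ins, strand2 = "-",
        mapq1 = spec$mapq, mapq2 = spec$mapq)
    }
    pairs <- do.call(rbind, rows)
    rownames(pairs) <- NULL
    structure(list(pairs = pairs,
                   truth = list(junction_pos = j, n_spanning = n_span,
                                orientation = spec$orientation),
                   spec = spec),
              class = "gapf_junction_sim")
  })
}
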
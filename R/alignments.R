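#' Read mapped alignment records from a BED-like TSV or a BAM file
#'
#' The BED dialect is six or more tab-separated columns
#' (`chrom`, `start`, `end`, `name`, `mapq`, `strand`) with 0-based
#' half-open coordinates and no header; it exists so the whole pipeline can
#' be exercised without binary inputs. BAM access goes through Rsamtools
#' and excludes unmapped, secondary, and supplementary records.
#'
#' @param path input file
#' @param format `"bed"` or `"bam"`; default guessed from the extension
#' @return data frame of mapped records: `chrom`, `start`, `end` (0-based
#'   half-open), `name`, `mapq`, `strand`
#' @export
read_alignments <- function(path, format = c("auto", "bed", "bam")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "bed"
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (format == "bed") {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             comment.char = "#", stringsAsFactors = FALSE)
    if (ncol(tab) < 6)
      stop("BED-like alignment input needs >= 6 columns ",
           "(chrom, start, end, name, mapq, strand)")
    data.frame(chrom = as.character(tab[[1]]), start = as.numeric(tab[[2]]),
               end = as.numeric(tab[[3]]), name = as.character(tab[[4]]),
               mapq = as.numeric(tab[[5]]), strand = as.character(tab[[6]]))
  } else {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("BAM input requires the Rsamtools package")
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
    par <- Rsamtools::ScanBamParam(
      flag = flag, what = c("rname", "pos", "qwidth", "qname", "mapq",
                            "strand", "cigar"))
    res <- Rsamtools::scanBam(path, param = par)[[1]]
    width <- GenomicAlignments_width(res$cigar, res$qwidth)
    data.frame(chrom = as.character(res$rname), start = res$pos - 1,
               end = res$pos - 1 + width, name = res$qname,
               mapq = res$mapq, strand = as.character(res$strand))
  }
}

# Reference-space width from CIGAR, falling back to query width.
GenomicAlignments_width <- function(cigar, qwidth) {
  ok <- !is.na(cigar) & cigar != "*"
  w <- qwidth
  if (any(ok)) {
    ops <- regmatches(cigar[ok], gregexpr("\\d+[MIDNSHP=X]", cigar[ok]))
    w[ok] <- vapply(ops, function(o) {
      n <- as.numeric(sub("[MIDNSHP=X]", "", o))
      type <- sub("\\d+", "", o)
      sum(n[type %in% c("M", "D", "N", "=", "X")])
    }, numeric(1))
  }
  w
}

#' Count aligned reads into genome bins
#'
#' bedtools-coverage counting semantics: a record passing the MAPQ filter
#' adds 1 to every bin it overlaps by at least one bp, so a read straddling
#' a bin boundary is counted in both bins. Mates of a pair are counted
#' independently. Records on chromosomes absent from the bin set are skipped
#' (reported via the `skipped` attribute and a message), not fatal.
#'
#' @param alignments data frame as returned by [read_alignments()]
#' @param bins a `gapf_bins` object built for the same chromosome names
#' @param mapq_min records with MAPQ >= `mapq_min` are counted (default 40,
#'   the uniqueness filter)
#' @return integer vector of raw counts, one per bin, with attribute
#'   `skipped` (records on unknown chromosomes)
#' @export
count_reads_in_bins <- function(alignments, bins, mapq_min = 40) {
  stopifnot(inherits(bins, "gapf_bins"))
  aln <- alignments[alignments$mapq >= mapq_min, , drop = FALSE]
  known <- aln$chrom %in% names(bins$chrom_sizes)
  n_skip <- sum(!known)
  if (n_skip > 0) {
    message(n_skip, " record(s) on chromosomes absent from the bin set; skipped")
    aln <- aln[known, , drop = FALSE]
  }
  if (nrow(aln) == 0) {
    counts <- integer(n_bins(bins))
  } else {
    reads <- GenomicRanges::GRanges(
      seqnames = aln$chrom,
      ranges = IRanges::IRanges(start = aln$start + 1, end = aln$end))
    counts <- GenomicRanges::countOverlaps(bins_granges(bins), reads,
                                           minoverlap = 1L)
  }
  structure(as.integer(counts), skipped = n_skip)
}

#' Per-million normalization of raw bin counts
#'
#' `cpm[i] = raw[i] / (total_mapped_reads / 1e6)` — a single scalar rescale
#' adjusting for sequencing depth.
#'
#' @param raw non-negative integer counts
#' @param total_mapped_reads total mapped reads in the library (> 0)
#' @return numeric vector of per-million-normalized coverage
#' @export
normalize_per_million <- function(raw, total_mapped_reads) {
  if (length(total_mapped_reads) != 1 || !is.finite(total_mapped_reads) ||
      total_mapped_reads <= 0)
    stop("total_mapped_reads must be a single positive number")
  if (any(raw < 0)) stop("raw counts must be non-negative")
  as.numeric(raw) / (total_mapped_reads / 1e6)
}

#' Bin coverage for one sample
#'
#' Convenience wrapper: count reads into bins at the given MAPQ floor and
#' normalize per million. The normalization denominator defaults to the
#' number of mapped input records (before MAPQ filtering), so coverage
#' computed at different MAPQ floors from the same library shares one
#' scaling factor.
#'
#' @param alignments data frame of mapped records
#' @param bins a `gapf_bins` object
#' @param mapq_min MAPQ floor for counting (default 40)
#' @param sample_id sample label carried through all downstream tables
#' @param total_mapped_reads normalization denominator; default
#'   `nrow(alignments)`
#' @return a `gapf_coverage` object; see [gapf_coverage()]
#' @export
bin_coverage <- function(alignments, bins, mapq_min = 40,
                         sample_id = "sample",
                         total_mapped_reads = nrow(alignments)) {
  raw <- count_reads_in_bins(alignments, bins, mapq_min = mapq_min)
  gapf_coverage(bins, raw = raw, total_mapped_reads = total_mapped_reads,
                sample_id = sample_id, mapq_min = mapq_min)
}

#' Construct a per-bin coverage object
#'
#' The container used throughout: a data frame of retained bins
#' (`chrom`, `start`, `end`, `raw`, `cpm`) plus the scalars needed to
#' reproduce it. Blocklist application subsets the rows; the full bin
#' universe (`chrom_sizes`, `bin_width`, `n_total_bins`) is kept for
#' validation.
#'
#' @param bins a `gapf_bins` object
#' @param raw integer raw counts, one per bin
#' @param total_mapped_reads normalization denominator (> 0)
#' @param sample_id sample label
#' @param mapq_min the MAPQ floor the counts were produced with
#' @return a `gapf_coverage` object
#' @export
gapf_coverage <- function(bins, raw, total_mapped_reads,
                          sample_id = "sample", mapq_min = 40) {
  stopifnot(inherits(bins, "gapf_bins"))
  if (length(raw) != n_bins(bins))
    stop("length(raw) must equal the number of bins")
  cpm <- normalize_per_million(raw, total_mapped_reads)
  tab <- bins$bins[, c("chrom", "start", "end")]
  tab$raw <- as.integer(raw)
  tab$cpm <- cpm
  structure(list(sample_id = sample_id, mapq_min = mapq_min,
                 total_mapped_reads = total_mapped_reads,
                 chrom_sizes = bins$chrom_sizes, bin_width = bins$bin_width,
                 n_total_bins = n_bins(bins), table = tab,
                 blocklist_applied = FALSE),
            class = "gapf_coverage")
}

#' @export
print.gapf_coverage <- function(x, ...) {
  cat(sprintf(
    "gapf_coverage '%s': %d/%d bins retained, MAPQ >= %d, %g mapped reads\n",
    x$sample_id, nrow(x$table), x$n_total_bins, x$mapq_min,
    x$total_mapped_reads))
  cat(sprintf("  mean cpm %.4g, max cpm %.4g\n",
              mean(x$table$cpm), max(x$table$cpm)))
  invisible(x)
}

#' Histogram of per-bin coverage over half-open ranges
#'
#' Counts bins whose coverage falls in each half-open range
#' `[edges[i], edges[i+1])`. Values below the lowest edge are excluded;
#' use `Inf` as the last edge to make the top range open-ended.
#'
#' @param cpm numeric per-bin coverage vector
#' @param edges strictly ascending range edges (length >= 2)
#' @return a `gapf_histogram` data frame: `lower`, `upper`, `count`
#' @export
coverage_histogram <- function(cpm, edges) {
  if (length(edges) < 2 || any(diff(edges) <= 0))
    stop("edges must be strictly ascending with length >= 2")
  idx <- findInterval(cpm, edges)
  counts <- tabulate(idx[idx >= 1 & idx <= length(edges) - 1],
                     nbins = length(edges) - 1)
  structure(data.frame(lower = edges[-length(edges)], upper = edges[-1],
                       count = as.integer(counts)),
            class = c("gapf_histogram", "data.frame"))
}

#' Write / read the per-bin coverage TSV
#'
#' Tab-separated with a header line (`chrom`, `start`, `end`, `raw_count`,
#' `cpm`) preceded by `#`-prefixed metadata lines recording the sample id,
#' MAPQ floor, total mapped reads, bin width, and chromosome sizes, so the
#' file round-trips to an identical object.
#'
#' @param x a `gapf_coverage` object
#' @param path output path
#' @return `write_coverage_tsv` returns `path` invisibly;
#'   `read_coverage_tsv` returns a `gapf_coverage` object
#' @export
write_coverage_tsv <- function(x, path) {
  stopifnot(inherits(x, "gapf_coverage"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# sample_id=", x$sample_id),
    paste0("# mapq_min=", x$mapq_min),
    paste0("# total_mapped_reads=", format(x$total_mapped_reads,
                                           scientific = FALSE)),
    paste0("# bin_width=", x$bin_width),
    paste0("# chrom_sizes=", paste(names(x$chrom_sizes),
                                   format(x$chrom_sizes, scientific = FALSE),
                                   sep = ":", collapse = ",")),
    paste0("# blocklist_applied=", x$blocklist_applied),
    "chrom\tstart\tend\traw_count\tcpm"), con)
  utils::write.table(
    data.frame(x$table$chrom, format(x$table$start, scientific = FALSE),
               format(x$table$end, scientific = FALSE), x$table$raw,
               format(x$table$cpm, digits = 15, scientific = FALSE)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_coverage_tsv
#' @export
read_coverage_tsv <- function(path) {
  if (!file.exists(path)) stop("coverage TSV not found: ", path)
  lines <- readLines(path, n = 20)
  meta_lines <- grep("^# ", lines, value = TRUE)
  meta <- list()
  for (m in meta_lines) {
    kv <- sub("^# ", "", m)
    key <- sub("=.*$", "", kv)
    meta[[key]] <- sub("^[^=]*=", "", kv)
  }
  need <- c("sample_id", "mapq_min", "total_mapped_reads", "bin_width",
            "chrom_sizes")
  if (!all(need %in% names(meta)))
    stop("coverage TSV is missing metadata header lines")
  cs_parts <- strsplit(strsplit(meta$chrom_sizes, ",")[[1]], ":")
  chrom_sizes <- stats::setNames(
    as.numeric(trimws(vapply(cs_parts, `[`, "", 2))),
    vapply(cs_parts, `[`, "", 1))
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           comment.char = "#", stringsAsFactors = FALSE)
  bins <- build_bins(chrom_sizes, as.numeric(meta$bin_width))
  key <- paste(tab$chrom, tab$start)
  full_key <- paste(bins$bins$chrom, bins$bins$start)
  idx <- match(key, full_key)
  if (anyNA(idx)) stop("coverage TSV contains bins outside its own bin set")
  raw <- integer(n_bins(bins))
  raw[idx] <- tab$raw_count
  cov <- gapf_coverage(bins, raw,
                       total_mapped_reads = as.numeric(meta$total_mapped_reads),
                       sample_id = meta$sample_id,
                       mapq_min = as.numeric(meta$mapq_min))
  if (length(idx) < n_bins(bins)) {
    cov$table <- cov$table[sort(idx), , drop = FALSE]
    rownames(cov$table) <- NULL
    cov$blocklist_applied <- TRUE
  }
  cov
}
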
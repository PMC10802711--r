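#' Top-K high-coverage bins
#'
#' Ranks the retained bins of a (blocklist-filtered, MAPQ-filtered) coverage
#' table in descending per-million coverage and keeps the top K. Ties are
#' broken deterministically: coverage descending, then chromosome order as
#' given by the bin set, then start ascending.
#'
#' @param coverage a `gapf_coverage`
#' @param k number of bins to keep (default 1000; 300 and 10000 are the
#'   other usual choices). If fewer bins are retained, all are returned.
#' @return a `gapf_hcbs` data frame (`chrom`, `start`, `cpm`) with
#'   attributes `k` and `sample_id`
#' @export
top_k_hcbs <- function(coverage, k = 1000) {
  stopifnot(inherits(coverage, "gapf_coverage"))
  if (length(k) != 1 || k <= 0) stop("k must be a positive integer")
  tab <- coverage$table
  chrom_order <- names(coverage$chrom_sizes)
  ord <- order(-tab$cpm, match(tab$chrom, chrom_order), tab$start)
  keep <- ord[seq_len(min(k, nrow(tab)))]
  out <- tab[keep, c("chrom", "start", "cpm"), drop = FALSE]
  rownames(out) <- NULL
  structure(out, k = k, sample_id = coverage$sample_id,
            chromosomes = chrom_order,
            class = c("gapf_hcbs", "data.frame"))
}

#' Per-chromosome distribution of high-coverage bins
#'
#' The sample's "profile": how many of its top-K HCBs fall on each
#' chromosome of `chromosomes`. Counts sum to the number of HCBs (K, or
#' fewer for small bin sets). An HCB on a chromosome outside the set is an
#' error unless `drop = TRUE`, in which case it is dropped with a warning
#' and the sum shrinks accordingly.
#'
#' @param hcbs a `gapf_hcbs` from [top_k_hcbs()]
#' @param chromosomes ordered chromosome set (default: the bin set's
#'   chromosomes)
#' @param drop drop out-of-set HCBs with a warning instead of failing
#' @return a named integer vector (class `gapf_profile`) with attributes
#'   `sample_id` and `k`
#' @export
chromosome_profile <- function(hcbs, chromosomes = attr(hcbs, "chromosomes"),
                               drop = FALSE) {
  stopifnot(inherits(hcbs, "gapf_hcbs"))
  outside <- !(hcbs$chrom %in% chromosomes)
  if (any(outside)) {
    if (!drop)
      stop(sum(outside), " HCB(s) on chromosomes outside the profile set; ",
           "use drop = TRUE to discard them")
    warning(sum(outside), " HCB(s) dropped from the profile ",
            "(outside the chromosome set)")
    hcbs <- hcbs[!outside, , drop = FALSE]
  }
  counts <- table(factor(hcbs$chrom, levels = chromosomes))
  structure(stats::setNames(as.integer(counts), chromosomes),
            sample_id = attr(hcbs, "sample_id"), k = attr(hcbs, "k"),
            class = "gapf_profile")
}

#' @export
print.gapf_profile <- function(x, ...) {
  cat(sprintf("gapf_profile '%s' (top %d HCBs, sum %d):\n",
              attr(x, "sample_id"), attr(x, "k"), sum(x)))
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Assemble profiles into a labeled cohort matrix
#'
#' @param profiles list of `gapf_profile` vectors on the same chromosome set
#' @param labels `"tumor"` / `"normal"` per profile (optional for unlabeled
#'   sets, but required by the classifier)
#' @param sample_ids sample names (default taken from each profile)
#' @return a `gapf_profile_set`: list with `counts` (samples x chromosomes
#'   integer matrix), `labels`, and `k`
#' @export
profile_set <- function(profiles, labels = NULL, sample_ids = NULL) {
  if (length(profiles) == 0) stop("empty profile list")
  chroms <- names(profiles[[1]])
  for (p in profiles)
    if (!identical(names(p), chroms))
      stop("all profiles must share one chromosome set")
  counts <- do.call(rbind, lapply(profiles, as.integer))
  colnames(counts) <- chroms
  if (is.null(sample_ids))
    sample_ids <- vapply(profiles, function(p) {
      s <- attr(p, "sample_id"); if (is.null(s)) NA_character_ else s
    }, character(1))
  if (anyNA(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(counts)))
  rownames(counts) <- make.unique(sample_ids)
  if (!is.null(labels)) {
    if (length(labels) != nrow(counts)) stop("one label per profile required")
    labels <- match.arg(labels, c("tumor", "normal"), several.ok = TRUE)
  }
  structure(list(counts = counts, labels = labels,
                 k = attr(profiles[[1]], "k")),
            class = "gapf_profile_set")
}

#' @export
print.gapf_profile_set <- function(x, ...) {
  cat(sprintf("gapf_profile_set: %d samples x %d chromosomes (top %s HCBs)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$k)) "?" else x$k))
  if (!is.null(x$labels))
    cat("  labels:", paste(sprintf("%s=%d", names(table(x$labels)),
                                   table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a profile-set TSV (samples x chromosomes)
#'
#' One row per sample: `sample_id`, optional `label`, then one column per
#' chromosome — the layout of a per-sample per-chromosome HCB count table.
#'
#' @param x a `gapf_profile_set`
#' @param path output path
#' @return `write_profile_tsv` returns `path` invisibly; `read_profile_tsv`
#'   returns a `gapf_profile_set`
#' @export
write_profile_tsv <- function(x, path) {
  stopifnot(inherits(x, "gapf_profile_set"))
  out <- data.frame(sample_id = rownames(x$counts))
  if (!is.null(x$labels)) out$label <- x$labels
  out <- cbind(out, as.data.frame(x$counts))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  labels <- if ("label" %in% names(tab)) tab$label else NULL
  chrom_cols <- setdiff(names(tab), c("sample_id", "label"))
  counts <- as.matrix(tab[, chrom_cols, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- tab$sample_id
  structure(list(counts = counts, labels = labels, k = sum(counts[1, ])),
            class = "gapf_profile_set")
}

#' Read a UCSC cytoBand.txt table
#'
#' Five tab-separated columns, 0-based half-open: chrom, start, end, band
#' name, Giemsa stain. Bands on unlocalized/unplaced sequences (chromosome
#' name containing `_`) are dropped. Overlapping bands within a chromosome
#' are rejected.
#'
#' @param path cytoBand.txt path (uncompressed)
#' @return data frame `chrom`, `start`, `end`, `name`, `stain` with
#'   attribute `n_downloaded` (band count before filtering)
#' @export
read_cytobands <- function(path) {
  if (!file.exists(path)) stop("cytoband file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "stain"))
  n0 <- nrow(tab)
  tab <- tab[!grepl("_", tab$chrom, fixed = TRUE), , drop = FALSE]
  tab <- tab[order(tab$chrom, tab$start), , drop = FALSE]
  by_chr <- split(tab, tab$chrom)
  for (b in by_chr) {
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)]))
      stop("overlapping cytobands on ", b$chrom[1])
  }
  rownames(tab) <- NULL
  structure(tab, n_downloaded = n0)
}

#' Count high-coverage bins per cytoband
#'
#' Each HCB is assigned to the band containing its bin start (bins are 1 kb
#' and bands are Mb-scale, so start-based assignment is effectively exact).
#' Band counts within a chromosome sum to that chromosome's profile count.
#'
#' @param hcbs a `gapf_hcbs`
#' @param cytobands data frame from [read_cytobands()]
#' @return the cytoband table with an added integer `count` column
#' @export
cytoband_counts <- function(hcbs, cytobands) {
  stopifnot(inherits(hcbs, "gapf_hcbs"))
  counts <- integer(nrow(cytobands))
  on_bands <- hcbs$chrom %in% unique(cytobands$chrom)
  if (!any(on_bands) && nrow(hcbs) > 0)
    warning("no HCB lies on a cytoband chromosome; all counts zero")
  h <- hcbs[on_bands, , drop = FALSE]
  for (chr in unique(h$chrom)) {
    b <- which(cytobands$chrom == chr)
    idx <- findInterval(h$start[h$chrom == chr], cytobands$start[b])
    idx <- idx[idx >= 1]
    # drop positions beyond the last band end (should not occur on a
    # matching assembly)
    ok <- h$start[h$chrom == chr][idx > 0] < cytobands$end[b][idx]
    tt <- tabulate(idx[ok], nbins = length(b))
    counts[b] <- counts[b] + tt
  }
  out <- cytobands
  out$count <- counts
  out
}

#' Length-normalized coverage per cytoband
#'
#' Band value = (sum of the cpm of the bins whose start lies in the band)
#' divided by the band length in bp.
#'
#' @param coverage a `gapf_coverage`
#' @param cytobands data frame from [read_cytobands()]
#' @return the cytoband table with an added numeric `coverage` column
#' @export
cytoband_coverage <- function(coverage, cytobands) {
  stopifnot(inherits(coverage, "gapf_coverage"))
  if (any(cytobands$end <= cytobands$start)) stop("zero-length cytoband")
  vals <- numeric(nrow(cytobands))
  tab <- coverage$table
  for (chr in unique(cytobands$chrom)) {
    b <- which(cytobands$chrom == chr)
    rows <- tab$chrom == chr
    if (!any(rows)) next
    idx <- findInterval(tab$start[rows], cytobands$start[b])
    ok <- idx >= 1 & tab$start[rows] < cytobands$end[b][pmax(idx, 1)]
    sums <- vapply(seq_along(b), function(j)
      sum(tab$cpm[rows][ok & idx == j]), numeric(1))
    vals[b] <- sums
  }
  out <- cytobands
  out$coverage <- vals / (cytobands$end - cytobands$start)
  out
}

#' Log-linear exponential-decay fit
#'
#' Fits `y = a * exp(b * x)` by ordinary least squares of `log(y)` on `x`
#' — the model for palindromic peak coverage along a tumor-DNA dilution
#' series. `r_squared` is the R-squared of the log-space fit.
#'
#' @param x numeric predictor (e.g. dilution fraction or series index)
#' @param y positive response (e.g. mean peak cpm); length >= 2
#' @return a `gapf_decay_fit` list: `a`, `b`, `r_squared`, `degenerate`
#'   (TRUE when only two points, where R-squared = 1 by construction)
#' @export
fit_exponential_decay <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("need >= 2 (x, y) points")
  if (any(y <= 0)) stop("y must be strictly positive for a log-linear fit")
  fit <- stats::lm(log(y) ~ x)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((log(y) - mean(log(y)))^2)
  r2 <- if (length(x) == 2 || tss <= 0) 1 else 1 - rss / tss
  structure(list(a = unname(exp(stats::coef(fit)[1])),
                 b = unname(stats::coef(fit)[2]),
                 r_squared = r2, degenerate = length(x) == 2),
            class = "gapf_decay_fit")
}

#' @export
print.gapf_decay_fit <- function(x, ...) {
  cat(sprintf("gapf_decay_fit: y = %.4g * exp(%.4g x), R^2 = %.4f%s\n",
              x$a, x$b, x$r_squared,
              if (x$degenerate) " (two points; degenerate)" else ""))
  invisible(x)
}

#' Pie-chart rendering of a GAPF profile
#'
#' @param x a `gapf_profile`
#' @param min_label chromosomes holding fewer than this many HCBs are left
#'   unlabeled to keep the chart readable
#' @param ... passed to [graphics::pie()]
#' @return invisibly, `x`
#' @export
plot_profile <- function(x, min_label = 25, ...) {
  stopifnot(inherits(x, "gapf_profile"))
  lab <- ifelse(x >= min_label, names(x), "")
  graphics::pie(as.integer(x), labels = lab,
                main = attr(x, "sample_id"), ...)
  invisible(x)
}
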
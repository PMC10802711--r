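#' Identify recurrent background bins across a tumor/normal cohort
#'
#' Bins enriched in both arms of the cohort are artifacts of the enrichment
#' chemistry (GC-rich or repetitive sequence resistant to denaturation, or
#' germline palindromes) rather than tumor-specific signal, and are removed
#' before high-coverage-bin ranking. A bin enters the blocklist iff its
#' coverage exceeds `enrich_cutoff` cpm in at least `min_fraction` of the
#' tumor samples AND at least `min_fraction` of the normal samples.
#'
#' @param coverages list of `gapf_coverage` objects on one shared bin set
#' @param labels character vector, `"tumor"` or `"normal"`, one per coverage
#' @param enrich_cutoff cpm above which a bin counts as enriched (default 5,
#'   the low/high coverage divide; strict `>`)
#' @param min_fraction minimum fraction of samples per arm (default 0.75)
#' @return a `gapf_blocklist`: data frame `bins` (`chrom`, `start`, sorted)
#'   plus a `provenance` list recording the criterion
#' @export
identify_background_bins <- function(coverages, labels, enrich_cutoff = 5,
                                     min_fraction = 0.75) {
  if (length(coverages) == 0) stop("empty cohort")
  labels <- match.arg(labels, c("tumor", "normal"), several.ok = TRUE)
  if (length(labels) != length(coverages))
    stop("one label per coverage required")
  if (!any(labels == "tumor") || !any(labels == "normal"))
    stop("cohort needs at least one tumor and one normal sample")
  nb <- nrow(coverages[[1]]$table)
  key1 <- paste(coverages[[1]]$table$chrom, coverages[[1]]$table$start)
  for (cv in coverages) {
    if (nrow(cv$table) != nb ||
        !identical(paste(cv$table$chrom, cv$table$start), key1))
      stop("all coverages must share the same bin universe")
  }
  enriched <- vapply(coverages, function(cv) cv$table$cpm > enrich_cutoff,
                     logical(nb))
  if (nb == 1) enriched <- matrix(enriched, nrow = 1)
  frac_t <- rowMeans(enriched[, labels == "tumor", drop = FALSE])
  frac_n <- rowMeans(enriched[, labels == "normal", drop = FALSE])
  sel <- frac_t >= min_fraction & frac_n >= min_fraction
  tab <- coverages[[1]]$table[sel, c("chrom", "start"), drop = FALSE]
  chrom_order <- names(coverages[[1]]$chrom_sizes)
  ord <- order(match(tab$chrom, chrom_order), tab$start)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(bins = tab,
                 provenance = list(
                   n_tumor = sum(labels == "tumor"),
                   n_normal = sum(labels == "normal"),
                   enrich_cutoff = enrich_cutoff,
                   min_fraction = min_fraction)),
            class = "gapf_blocklist")
}

#' @export
print.gapf_blocklist <- function(x, ...) {
  cat(sprintf(
    "gapf_blocklist: %d bins (cpm > %g in >= %g of %d tumors and %d normals)\n",
    nrow(x$bins), x$provenance$enrich_cutoff, x$provenance$min_fraction,
    x$provenance$n_tumor, x$provenance$n_normal))
  invisible(x)
}

#' Remove blocklisted bins from a coverage table
#'
#' Drops the blocklisted bins; retained coverage values are unchanged, and
#' retained bin count equals total bins minus the blocklist size (when the
#' coverage still holds its full bin universe). Applying the same blocklist
#' twice is the same as applying it once. Every blocklist bin must belong to
#' the coverage's bin universe.
#'
#' @param coverage a `gapf_coverage`
#' @param blocklist a `gapf_blocklist`, or a data frame with `chrom`, `start`
#' @return the coverage restricted to retained bins
#' @export
apply_blocklist <- function(coverage, blocklist) {
  stopifnot(inherits(coverage, "gapf_coverage"))
  bl <- if (inherits(blocklist, "gapf_blocklist")) blocklist$bins else blocklist
  if (!all(c("chrom", "start") %in% names(bl)))
    stop("blocklist must have chrom and start columns")
  # validate against the full bin universe, not the (possibly already
  # filtered) current rows, so re-application stays legal and idempotent
  full <- build_bins(coverage$chrom_sizes, coverage$bin_width)$bins
  bl_key <- paste(bl$chrom, as.integer(bl$start))
  bad <- !(bl_key %in% paste(full$chrom, full$start))
  if (any(bad))
    stop(sum(bad), " blocklist bin(s) absent from the coverage's bin set")
  drop <- paste(coverage$table$chrom, coverage$table$start) %in% bl_key
  coverage$table <- coverage$table[!drop, , drop = FALSE]
  rownames(coverage$table) <- NULL
  coverage$blocklist_applied <- TRUE
  coverage
}

#' Write / read a blocklist as 3-column BED with a JSON provenance sidecar
#'
#' @param x a `gapf_blocklist`
#' @param path BED output path; provenance goes to `<path>.json`
#' @param bin_width bin width used to derive the BED end column (default 1000)
#' @return `write_blocklist` returns `path` invisibly; `read_blocklist`
#'   returns a `gapf_blocklist`
#' @export
write_blocklist <- function(x, path, bin_width = 1000) {
  stopifnot(inherits(x, "gapf_blocklist"))
  utils::write.table(
    data.frame(x$bins$chrom, format(x$bins$start, scientific = FALSE),
               format(x$bins$start + bin_width, scientific = FALSE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(x$provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_blocklist
#' @export
read_blocklist <- function(path) {
  if (!file.exists(path)) stop("blocklist BED not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  prov_path <- paste0(path, ".json")
  prov <- if (file.exists(prov_path))
    jsonlite::read_json(prov_path, simplifyVector = TRUE) else list()
  structure(list(bins = data.frame(chrom = as.character(tab[[1]]),
                                   start = as.numeric(tab[[2]])),
                 provenance = prov),
            class = "gapf_blocklist")
}
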
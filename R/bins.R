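#' Read a UCSC-style chrom.sizes file
#'
#' Two tab-separated columns: sequence name and length in bp. Lines whose
#' name contains an underscore (unplaced/unlocalized contigs) can be dropped
#' with `canonical = TRUE`, which also restricts to chr1-22, chrX, chrY.
#'
#' @param path path to a two-column chrom.sizes text file
#' @param canonical restrict to the canonical chromosomes chr1-22, chrX, chrY
#' @return named numeric vector of chromosome lengths, in file order
#' @export
read_chrom_sizes <- function(path, canonical = FALSE) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  sizes <- stats::setNames(tab$length, tab$chrom)
  if (canonical) {
    keep <- paste0("chr", c(1:22, "X", "Y"))
    sizes <- sizes[names(sizes) %in% keep]
  }
  sizes
}

#' Partition a genome into fixed-width bins
#'
#' Tiles every chromosome from position 0 with half-open, 0-based bins of
#' `bin_width` bp; the final bin of a chromosome may be shorter. The number
#' of bins per chromosome is `ceiling(length / bin_width)`.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths in bp
#'   (order is preserved and defines chromosome order throughout)
#' @param bin_width bin width in bp (default 1000)
#' @return a `gapf_bins` object: list with `chrom_sizes`, `bin_width`, and a
#'   `bins` data frame (`chrom`, `start`, `end`, `bin_index`), ordered by
#'   chromosome then start
#' @examples
#' b <- build_bins(c(chrA = 2500), bin_width = 1000)
#' b$bins  # [0,1000), [1000,2000), [2000,2500)
#' @export
build_bins <- function(chrom_sizes, bin_width = 1000) {
  if (length(chrom_sizes) == 0) stop("empty chromosome list")
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  bad <- names(chrom_sizes)[chrom_sizes <= 0 | !is.finite(chrom_sizes)]
  if (length(bad))
    stop("non-positive length for chromosome: ", paste(bad, collapse = ", "))
  if (length(bin_width) != 1 || bin_width <= 0) stop("bin_width must be > 0")

  n_per <- ceiling(chrom_sizes / bin_width)
  chrom <- rep(names(chrom_sizes), n_per)
  start <- unlist(lapply(n_per, function(n) (seq_len(n) - 1) * bin_width),
                  use.names = FALSE)
  end <- pmin(start + bin_width, rep(unname(chrom_sizes), n_per))
  # integer coordinates: positions fit in 32 bits for any real assembly,
  # and integer keys print without scientific notation
  bins <- data.frame(chrom = chrom, start = as.integer(start),
                     end = as.integer(end), bin_index = seq_along(start))
  structure(list(chrom_sizes = chrom_sizes, bin_width = bin_width,
                 bins = bins),
            class = "gapf_bins")
}

#' @export
print.gapf_bins <- function(x, ...) {
  cat(sprintf("gapf_bins: %d chromosomes, %d bins of %d bp\n",
              length(x$chrom_sizes), nrow(x$bins), x$bin_width))
  invisible(x)
}

#' Number of bins in a bin set
#' @param bins a `gapf_bins` object
#' @return integer bin count
#' @export
n_bins <- function(bins) {
  stopifnot(inherits(bins, "gapf_bins"))
  nrow(bins$bins)
}

# GRanges view of the bin tiling (1-based closed, as IRanges expects).
bins_granges <- function(bins) {
  GenomicRanges::GRanges(
    seqnames = bins$bins$chrom,
    ranges = IRanges::IRanges(start = bins$bins$start + 1,
                              end = bins$bins$end))
}
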
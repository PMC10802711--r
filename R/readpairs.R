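# Paired-alignment scanning for fold-back junction evidence. A pair whose
# mates map to the reference in the same orientation (FF or RR) is the
# signature of a palindromic (fold-back) junction; concordant pairs are FR.
#
# The paired record layout used throughout (one row per pair, 0-based
# half-open mate intervals on one chromosome):
#   chrom, start1, end1, strand1, start2, end2, strand2, mapq1, mapq2

#' Read a paired-BED TSV of read pairs
#'
#' Nine tab-separated columns, no header: chrom, start1, end1, strand1,
#' start2, end2, strand2, mapq1, mapq2. Lines with `chrom` equal to `"*"`
#' (or `strand` missing) are treated as unpaired/unmapped records.
#'
#' @param path input TSV
#' @return data frame of pairs
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop("pair file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 9) stop("paired BED needs 9 columns")
  stats::setNames(tab[, 1:9],
                  c("chrom", "start1", "end1", "strand1", "start2", "end2",
                    "strand2", "mapq1", "mapq2"))
}

#' Write pairs as a paired-BED TSV
#' @param pairs data frame of pairs
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs[, c("chrom", "start1", "end1", "strand1",
                               "start2", "end2", "strand2", "mapq1",
                               "mapq2")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Orientation class of read pairs
#'
#' FF if both mates map forward, RR if both map reverse; otherwise FR or RF
#' by the strand of the leftmost mate (FR = leftmost forward, the
#' concordant configuration). Pairs with an unmapped mate or mates on
#' different chromosomes are classed `"other"`. Classification is symmetric
#' in mate order. Vectorized over the rows of a pair table.
#'
#' @param pairs data frame of pairs (see [read_pairs()]), or a list/row
#'   with the same fields
#' @return character vector in `{"FF", "RR", "FR", "RF", "other"}`
#' @export
classify_pair_orientation <- function(pairs) {
  pairs <- as.data.frame(pairs)
  s1 <- pairs$strand1; s2 <- pairs$strand2
  mapped <- s1 %in% c("+", "-") & s2 %in% c("+", "-") & pairs$chrom != "*"
  left_fwd <- ifelse(pairs$start1 <= pairs$start2, s1, s2) == "+"
  out <- ifelse(!mapped, "other",
         ifelse(s1 == "+" & s2 == "+", "FF",
         ifelse(s1 == "-" & s2 == "-", "RR",
         ifelse(left_fwd, "FR", "RF"))))
  out
}

#' Insert size of read pairs (outer span)
#'
#' @param pairs data frame of pairs
#' @return numeric vector: `max(end) - min(start)` per pair
#' @export
pair_insert_size <- function(pairs) {
  pmax(pairs$end1, pairs$end2) - pmin(pairs$start1, pairs$start2)
}

#' Cluster same-orientation read pairs
#'
#' Keeps FF/RR pairs with both mates at or above `min_mapq`, restricted to
#' `region` when given, and merges pairs greedily (within each orientation
#' class, scanning by leftmost mate position): a pair joins the current
#' cluster when both of its mate positions are within `merge_distance` of
#' the cluster's previous pair. Clusters supported by fewer than
#' `min_support` pairs are discarded.
#'
#' @param pairs data frame of pairs
#' @param region optional `list(chrom, start, end)` restricting the scan
#' @param min_mapq MAPQ floor applied to both mates (default 40)
#' @param min_support minimum supporting pairs per cluster (default 3)
#' @param merge_distance maximum mate-position gap within a cluster in bp
#'   (default 1000)
#' @return data frame of clusters: `chrom`, `start`, `end`, `orientation`,
#'   `support`
#' @export
find_same_orientation_clusters <- function(pairs, region = NULL,
                                           min_mapq = 40, min_support = 3,
                                           merge_distance = 1000) {
  orient <- classify_pair_orientation(pairs)
  keep <- orient %in% c("FF", "RR") & pairs$mapq1 >= min_mapq &
    pairs$mapq2 >= min_mapq
  p <- pairs[keep, , drop = FALSE]
  orient <- orient[keep]
  if (!is.null(region)) {
    if (!(region$chrom %in% pairs$chrom) && nrow(pairs) > 0)
      stop("region chromosome not present in the pair set: ", region$chrom)
    inr <- p$chrom == region$chrom &
      pmin(p$start1, p$start2) < region$end &
      pmax(p$end1, p$end2) > region$start
    p <- p[inr, , drop = FALSE]
    orient <- orient[inr]
  }
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), orientation = character(),
                      support = integer())
  if (nrow(p) == 0) return(empty)
  out <- list()
  for (key in unique(paste(p$chrom, orient))) {
    sel <- paste(p$chrom, orient) == key
    q <- p[sel, , drop = FALSE]
    left <- pmin(q$start1, q$start2)
    ord <- order(left)
    q <- q[ord, , drop = FALSE]
    cluster_id <- cumsum(c(1, abs(diff(q$start1)) > merge_distance |
                             abs(diff(q$start2)) > merge_distance))
    for (cid in unique(cluster_id)) {
      m <- q[cluster_id == cid, , drop = FALSE]
      if (nrow(m) < min_support) next
      out[[length(out) + 1]] <- data.frame(
        chrom = m$chrom[1],
        start = min(m$start1, m$start2), end = max(m$end1, m$end2),
        orientation = strsplit(key, " ")[[1]][2],
        support = nrow(m))
    }
  }
  if (length(out) == 0) return(empty)
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Partition read pairs by insert size
#'
#' Exhaustive, disjoint split of the mapped pairs: `short` iff insert size
#' (outer span) is strictly below `cutoff`, `long` iff at or above it — so
#' a 200 bp insert is long at the default cutoff. Records that are not a
#' mapped pair (orientation `"other"`) go to neither stream and are
#' counted.
#'
#' @param pairs data frame of pairs
#' @param cutoff insert-size boundary in bp (default 200)
#' @param strict_long use `insert > cutoff` for the long stream instead
#'   (the boundary value then goes to `short` via `insert <= cutoff`)
#' @return list: `short` and `long` pair data frames, `n_unpaired`
#' @export
partition_by_insert_size <- function(pairs, cutoff = 200,
                                     strict_long = FALSE) {
  orient <- classify_pair_orientation(pairs)
  paired <- orient != "other"
  ins <- pair_insert_size(pairs)
  if (strict_long) {
    short <- paired & ins <= cutoff
    long <- paired & ins > cutoff
  } else {
    short <- paired & ins < cutoff
    long <- paired & ins >= cutoff
  }
  list(short = pairs[short, , drop = FALSE],
       long = pairs[long, , drop = FALSE],
       n_unpaired = sum(!paired))
}

#' Expand pairs into per-mate alignment records
#'
#' One row per mate in the BED-like layout [count_reads_in_bins()]
#' consumes, so simulated pairs can round-trip through the coverage module.
#'
#' @param pairs data frame of pairs
#' @return data frame: `chrom`, `start`, `end`, `name`, `mapq`, `strand`
#' @export
pairs_to_alignments <- function(pairs) {
  n <- nrow(pairs)
  data.frame(
    chrom = rep(pairs$chrom, 2),
    start = c(pairs$start1, pairs$start2),
    end = c(pairs$end1, pairs$end2),
    name = rep(sprintf("pair%d", seq_len(n)), 2),
    mapq = c(pairs$mapq1, pairs$mapq2),
    strand = c(pairs$strand1, pairs$strand2))
}
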
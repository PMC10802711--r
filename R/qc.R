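#' Read a control inverted-repeat region BED
#'
#' Four tab-separated columns, 0-based half-open: chrom, start, end, label.
#' These are known germline inverted repeats (on the X chromosome and a few
#' autosomal loci) that any palindrome-enrichment library should amplify,
#' and that a uniqueness (MAPQ) filter should then deplete because they are
#' repeated in the reference.
#'
#' @param path BED path
#' @return data frame `chrom`, `start`, `end`, `label`
#' @export
read_control_regions <- function(path) {
  if (!file.exists(path)) stop("control region BED not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("control region BED needs 4 columns")
  data.frame(chrom = as.character(tab[[1]]), start = as.numeric(tab[[2]]),
             end = as.numeric(tab[[3]]), label = as.character(tab[[4]]))
}

# Two-level mean: mean cpm of the bins overlapping each region, then the
# mean over regions. Errors if a region touches no bin.
region_mean_cpm <- function(coverage, control_regions) {
  stopifnot(inherits(coverage, "gapf_coverage"))
  if (nrow(control_regions) == 0) stop("control region set is empty")
  tab <- coverage$table
  per_region <- vapply(seq_len(nrow(control_regions)), function(i) {
    r <- control_regions[i, ]
    hit <- tab$chrom == r$chrom & tab$start < r$end & tab$end > r$start
    if (!any(hit))
      stop("control region overlaps no bin: ", r$label)
    mean(tab$cpm[hit])
  }, numeric(1))
  mean(per_region)
}

#' Amplification score over control inverted repeats
#'
#' Mean, over the control regions, of the mean unfiltered (MAPQ floor 0)
#' per-million coverage of the bins each region overlaps. A well-enriched
#' library amplifies these germline inverted repeats, so the score should
#' exceed 1.0.
#'
#' @param coverage a `gapf_coverage` computed with `mapq_min = 0`
#' @param control_regions data frame from [read_control_regions()]
#' @return numeric score
#' @export
amplification_score <- function(coverage, control_regions) {
  if (coverage$mapq_min != 0)
    warning("amplification score expects unfiltered coverage (mapq_min = 0); ",
            "got mapq_min = ", coverage$mapq_min)
  region_mean_cpm(coverage, control_regions)
}

#' Depletion score over control inverted repeats
#'
#' Same two-level averaging as [amplification_score()], computed on
#' uniqueness-filtered coverage (MAPQ floor 40). Because the control repeats
#' are multi-mapping, the filter should remove their reads; a clean library
#' scores below 0.075.
#'
#' @param coverage a `gapf_coverage` computed with `mapq_min = 40`
#' @param control_regions data frame from [read_control_regions()]
#' @return numeric score
#' @export
depletion_score <- function(coverage, control_regions) {
  if (coverage$mapq_min < 40)
    warning("depletion score expects uniqueness-filtered coverage ",
            "(mapq_min >= 40); got mapq_min = ", coverage$mapq_min)
  region_mean_cpm(coverage, control_regions)
}

#' Evaluate library quality control
#'
#' Pass requires an amplification score strictly above `amp_min` and a
#' depletion score strictly below `dep_max` — adequate palindrome enrichment
#' and adequate elimination of repeated sequence, respectively. Both
#' inequalities are strict.
#'
#' @param amplification_score numeric, from [amplification_score()]
#' @param depletion_score numeric, from [depletion_score()]
#' @param amp_min pass floor for amplification (default 1.0)
#' @param dep_max pass ceiling for depletion (default 0.075)
#' @return a `gapf_qc` list: the scores, thresholds, and `pass` flag
#' @export
qc_evaluate <- function(amplification_score, depletion_score,
                        amp_min = 1.0, dep_max = 0.075) {
  if (!is.finite(amplification_score) || !is.finite(depletion_score))
    stop("QC scores must be finite")
  structure(list(amplification_score = amplification_score,
                 depletion_score = depletion_score,
                 amp_min = amp_min, dep_max = dep_max,
                 pass = amplification_score > amp_min &&
                   depletion_score < dep_max),
            class = "gapf_qc")
}

#' @export
print.gapf_qc <- function(x, ...) {
  cat(sprintf("gapf_qc: amplification %.4g (> %g), depletion %.4g (< %g) -> %s\n",
              x$amplification_score, x$amp_min, x$depletion_score, x$dep_max,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
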
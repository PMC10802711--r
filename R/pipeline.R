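#' Run the full analysis on an in-memory cohort
#'
#' Stage order: per-sample QC (when control regions and unfiltered
#' coverage are supplied) -> cohort blocklist build (unless one is given)
#' -> blocklist application -> top-K HCB ranking -> per-chromosome
#' profiles -> threshold-model ROC, seeded cross-validation, and calls at
#' the whole-cohort Youden threshold. A sample failing QC is not removed:
#' it is flagged `qc_fail` in every downstream table. Re-running with the
#' same inputs reproduces identical outputs.
#'
#' @param coverages list of MAPQ-filtered `gapf_coverage` objects on one
#'   bin set
#' @param labels `"tumor"` / `"normal"` per sample
#' @param control_regions optional control-region data frame for QC
#' @param unfiltered_coverages optional list of matching `mapq_min = 0`
#'   coverages (required for QC amplification scores)
#' @param blocklist optional pre-built `gapf_blocklist`; default: built
#'   from this cohort
#' @param k top-K HCB count (default 1000)
#' @param enrich_cutoff,min_fraction blocklist criterion (see
#'   [identify_background_bins()])
#' @param folds,seeds cross-validation protocol (default 3-fold, seeds
#'   22/32/42)
#' @param threshold fixed call threshold; default: the whole-cohort Youden
#'   optimum
#' @return a `gapf_run` list: `qc`, `blocklist`, `profiles`
#'   (`gapf_profile_set`), `roc`, `cv`, `calls`, and a `report` of
#'   per-stage counts
#' @export
gapf_pipeline <- function(coverages, labels, control_regions = NULL,
                          unfiltered_coverages = NULL, blocklist = NULL,
                          k = 1000, enrich_cutoff = 5, min_fraction = 0.75,
                          folds = 3, seeds = c(22, 32, 42),
                          threshold = NULL) {
  if (length(coverages) == 0) stop("empty cohort")
  if (length(labels) != length(coverages))
    stop("one label per sample required")
  ids <- vapply(coverages, function(cv) cv$sample_id, character(1))

  qc <- NULL
  qc_fail <- rep(FALSE, length(coverages))
  if (!is.null(control_regions) && !is.null(unfiltered_coverages)) {
    qc <- lapply(seq_along(coverages), function(i)
      qc_evaluate(amplification_score(unfiltered_coverages[[i]],
                                      control_regions),
                  depletion_score(coverages[[i]], control_regions)))
    names(qc) <- ids
    qc_fail <- !vapply(qc, `[[`, logical(1), "pass")
  }

  if (is.null(blocklist))
    blocklist <- identify_background_bins(coverages, labels,
                                          enrich_cutoff = enrich_cutoff,
                                          min_fraction = min_fraction)
  filtered <- lapply(coverages, apply_blocklist, blocklist = blocklist)
  profiles <- profile_set(lapply(filtered, function(cv)
    chromosome_profile(top_k_hcbs(cv, k = k))),
    labels = labels, sample_ids = ids)

  roc <- roc_curve(profiles)
  cv <- cross_validate_threshold(profiles, folds = folds, seeds = seeds)
  if (is.null(threshold)) threshold <- roc$optimal_threshold
  calls <- call_samples(profiles, threshold)
  calls$qc_fail <- qc_fail

  n_total <- coverages[[1]]$n_total_bins
  report <- list(
    n_samples = length(coverages),
    n_tumor = sum(labels == "tumor"), n_normal = sum(labels == "normal"),
    n_total_bins = n_total,
    n_blocklist_bins = nrow(blocklist$bins),
    n_retained_bins = nrow(filtered[[1]]$table),
    k = k, profile_sums = unname(rowSums(profiles$counts)),
    threshold = threshold,
    full_cohort_auc = roc$auc,
    cv_mean_auc = cv$summary$mean_auc[cv$summary$aggregation == "pooled"],
    n_positive = sum(calls$call == "GAPF-positive"),
    n_qc_fail = sum(qc_fail))
  structure(list(qc = qc, blocklist = blocklist, profiles = profiles,
                 roc = roc, cv = cv, calls = calls, report = report),
            class = "gapf_run")
}

#' @export
print.gapf_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("gapf_run: %d samples (%d tumor / %d normal)\n",
              r$n_samples, r$n_tumor, r$n_normal))
  cat(sprintf("  bins: %d total - %d blocklisted = %d retained\n",
              r$n_total_bins, r$n_blocklist_bins, r$n_retained_bins))
  cat(sprintf("  threshold %s: %d positive calls; full-cohort AUC %.4f, CV mean AUC %.4f\n",
              format(r$threshold), r$n_positive, r$full_cohort_auc,
              r$cv_mean_auc))
  invisible(x)
}

#' Run the pipeline from a YAML configuration
#'
#' The configuration names per-sample coverage TSVs (written by
#' [write_coverage_tsv()]) with labels, plus optional control regions,
#' an optional pre-built blocklist BED, parameters, and an output
#' directory. Every referenced path is validated before any computation.
#' Outputs: `profiles.tsv`, `roc_points.tsv`, `calls.tsv`,
#' `blocklist.bed` (+ provenance JSON), `cv_report.json`, `report.json`.
#'
#' Config keys: `samples` (list of `id`, `coverage`, `label`, optional
#' `unfiltered`), optional `control_regions`, optional `blocklist`,
#' optional `params` (`k`, `enrich_cutoff`, `min_fraction`, `folds`,
#' `seeds`, `threshold`), `out_dir`.
#'
#' @param config path to a YAML file, or an equivalent named list
#' @return the `gapf_run` result, invisibly
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$samples) || length(config$samples) == 0)
    stop("config must list at least one sample")
  for (s in config$samples) {
    if (is.null(s$coverage) || !file.exists(s$coverage))
      stop("missing coverage TSV for sample ",
           if (is.null(s$id)) "?" else s$id, ": ", s$coverage)
    if (!is.null(s$unfiltered) && !file.exists(s$unfiltered))
      stop("missing unfiltered coverage TSV: ", s$unfiltered)
  }
  if (!is.null(config$control_regions) &&
      !file.exists(config$control_regions))
    stop("missing control region BED: ", config$control_regions)
  if (!is.null(config$blocklist) && !file.exists(config$blocklist))
    stop("missing blocklist BED: ", config$blocklist)

  coverages <- lapply(config$samples, function(s) {
    cv <- read_coverage_tsv(s$coverage)
    if (!is.null(s$id)) cv$sample_id <- s$id
    cv
  })
  labels <- vapply(config$samples, `[[`, "", "label")
  unf <- NULL
  if (all(vapply(config$samples,
                 function(s) !is.null(s$unfiltered), logical(1))))
    unf <- lapply(config$samples,
                  function(s) read_coverage_tsv(s$unfiltered))
  ctrl <- if (!is.null(config$control_regions))
    read_control_regions(config$control_regions) else NULL
  bl <- if (!is.null(config$blocklist))
    read_blocklist(config$blocklist) else NULL
  p <- config$params
  if (is.null(p)) p <- list()
  res <- gapf_pipeline(
    coverages, labels, control_regions = ctrl,
    unfiltered_coverages = unf, blocklist = bl,
    k = p$k %||% 1000,
    enrich_cutoff = p$enrich_cutoff %||% 5,
    min_fraction = p$min_fraction %||% 0.75,
    folds = p$folds %||% 3,
    seeds = unlist(p$seeds) %||% c(22, 32, 42),
    threshold = p$threshold)

  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_profile_tsv(res$profiles, file.path(out_dir, "profiles.tsv"))
  utils::write.table(res$roc$points, file.path(out_dir, "roc_points.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$calls, file.path(out_dir, "calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_blocklist(res$blocklist, file.path(out_dir, "blocklist.bed"),
                  bin_width = coverages[[1]]$bin_width)
  jsonlite::write_json(list(results = res$cv$results,
                            summary = res$cv$summary,
                            folds = res$cv$folds, seeds = res$cv$seeds),
                       file.path(out_dir, "cv_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(res$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
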
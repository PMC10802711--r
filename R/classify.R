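#' Decision statistic of the threshold model
#'
#' A sample's score is the maximum per-chromosome HCB count of its profile:
#' tumors concentrate their top-K HCBs on one or a few chromosomes, normals
#' disperse them, so the maximum separates the classes.
#'
#' @param profile a `gapf_profile` (named integer vector) or plain named
#'   integer vector of per-chromosome counts
#' @return integer score
#' @export
sample_score <- function(profile) {
  if (length(profile) == 0) stop("empty profile")
  max(as.integer(profile))
}

#' Threshold call on one profile
#'
#' GAPF-positive iff the sample's score (max per-chromosome HCB count)
#' reaches the threshold. The default boundary convention is `score >=
#' threshold`; `strict_gt = TRUE` switches to `score > threshold`.
#'
#' @param profile a profile vector (see [sample_score()])
#' @param threshold non-negative integer HCB-count threshold
#' @param strict_gt use strict `>` at the boundary
#' @return `"GAPF-positive"` or `"GAPF-negative"`
#' @export
classify_threshold <- function(profile, threshold, strict_gt = FALSE) {
  if (threshold < 0) stop("threshold must be >= 0")
  s <- sample_score(profile)
  pos <- if (strict_gt) s > threshold else s >= threshold
  if (pos) "GAPF-positive" else "GAPF-negative"
}

# scores + binary labels from a profile set
scores_and_labels <- function(profiles) {
  stopifnot(inherits(profiles, "gapf_profile_set"))
  if (is.null(profiles$labels))
    stop("profile set has no labels; the classifier needs tumor/normal labels")
  list(scores = apply(profiles$counts, 1, max),
       is_tumor = profiles$labels == "tumor")
}

#' ROC curve of the threshold model
#'
#' Sweeps the decision threshold over every distinct sample score plus an
#' all-negative sentinel, calling a sample positive when its score is at or
#' above the threshold. Sensitivity is computed on the tumor labels,
#' specificity on the normals; the AUC is the trapezoidal integral of
#' sensitivity against 1 - specificity (identical to the Mann-Whitney
#' pair statistic with ties counted 1/2). The optimal threshold maximizes
#' Youden's J = sensitivity + specificity - 1, ties broken toward the
#' smallest (most sensitive) threshold.
#'
#' @param profiles a labeled `gapf_profile_set`, or a numeric score vector
#' @param labels when `profiles` is a score vector: `"tumor"`/`"normal"`
#'   labels of the same length
#' @return a `gapf_roc` list: `points` data frame (`threshold`,
#'   `sensitivity`, `specificity`), `auc`, `optimal_threshold`, `youden_j`
#' @export
roc_curve <- function(profiles, labels = NULL) {
  if (inherits(profiles, "gapf_profile_set")) {
    sl <- scores_and_labels(profiles)
    scores <- sl$scores; is_tumor <- sl$is_tumor
  } else {
    if (is.null(labels)) stop("labels required with a raw score vector")
    scores <- as.numeric(profiles)
    is_tumor <- match.arg(labels, c("tumor", "normal"),
                          several.ok = TRUE) == "tumor"
  }
  n_t <- sum(is_tumor); n_n <- sum(!is_tumor)
  if (n_t == 0 || n_n == 0)
    stop("ROC requires both classes; got ", n_t, " tumors and ", n_n,
         " normals")
  thr <- c(sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) sum(scores[is_tumor] >= t) / n_t, numeric(1))
  spec <- vapply(thr, function(t) sum(scores[!is_tumor] < t) / n_n, numeric(1))
  points <- data.frame(threshold = thr, sensitivity = sens,
                       specificity = spec)
  # trapezoid over (1 - specificity, sensitivity); thresholds ascending
  # traverse the curve from (1,1) down to (0,0)
  fpr <- 1 - spec
  auc <- sum((fpr[-length(fpr)] - fpr[-1]) *
               (sens[-length(sens)] + sens[-1]) / 2)
  j <- sens + spec - 1
  best <- which(j == max(j))
  opt <- thr[best[1]]  # thresholds ascending: first maximum = smallest
  structure(list(points = points, auc = auc, optimal_threshold = opt,
                 youden_j = max(j)),
            class = "gapf_roc")
}

#' @export
print.gapf_roc <- function(x, ...) {
  cat(sprintf("gapf_roc: AUC %.4f; Youden-optimal threshold %s (J = %.4f)\n",
              x$auc, format(x$optimal_threshold), x$youden_j))
  invisible(x)
}

#' @export
plot.gapf_roc <- function(x, ...) {
  with(x$points, {
    graphics::plot(1 - specificity, sensitivity, type = "s",
                   xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "1 - specificity", ylab = "sensitivity", ...)
    graphics::abline(0, 1, lty = 3)
  })
  opt <- x$points[x$points$threshold == x$optimal_threshold, ]
  graphics::points(1 - opt$specificity, opt$sensitivity, col = "red",
                   pch = 19)
  invisible(x)
}

#' Sensitivity and specificity at a fixed threshold
#'
#' @param scores numeric sample scores
#' @param is_tumor logical truth labels
#' @param threshold decision threshold (positive iff score >= threshold)
#' @return list with `sensitivity`, `specificity`
#' @keywords internal
threshold_performance <- function(scores, is_tumor, threshold) {
  list(sensitivity = if (any(is_tumor))
    mean(scores[is_tumor] >= threshold) else NA_real_,
    specificity = if (any(!is_tumor))
      mean(scores[!is_tumor] < threshold) else NA_real_)
}

# Stratified fold assignment: within each class, samples are shuffled with
# the seeded RNG and dealt cyclically into `folds` groups.
make_folds <- function(is_tumor, folds, seed) {
  assign <- integer(length(is_tumor))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  for (cls in c(TRUE, FALSE)) {
    idx <- which(is_tumor == cls)
    assign[idx[sample.int(length(idx))]] <- rep_len(seq_len(folds),
                                                    length(idx))
  }
  assign
}

#' Seeded cross-validation of the threshold model
#'
#' For each seed, samples are shuffled and dealt into `folds` stratified
#' groups. For each fold, the Youden-optimal threshold is fit on the
#' training folds and the held-out fold is scored: test AUC plus
#' sensitivity/specificity at the trained threshold. A held-out fold
#' lacking a class yields missing sensitivity or specificity, reported and
#' excluded from aggregation with a warning. Means and standard deviations
#' are given both pooled over all fold x seed results and over per-seed
#' means. The whole-cohort Youden threshold (no CV) is reported alongside.
#'
#' @param profiles a labeled `gapf_profile_set`
#' @param folds number of folds (default 3)
#' @param seeds integer seeds for the fold assignment (default 22, 32, 42)
#' @return a `gapf_cv` list: `results` data frame (seed, fold, train
#'   threshold, test auc/sensitivity/specificity), `summary` (pooled and
#'   per-seed means/sds), `full_cohort` (whole-data ROC)
#' @export
cross_validate_threshold <- function(profiles, folds = 3,
                                     seeds = c(22, 32, 42)) {
  sl <- scores_and_labels(profiles)
  scores <- sl$scores; is_tumor <- sl$is_tumor
  if (min(sum(is_tumor), sum(!is_tumor)) < folds)
    stop("need at least `folds` samples per class")
  rows <- list()
  for (seed in seeds) {
    fold_of <- make_folds(is_tumor, folds, seed)
    for (f in seq_len(folds)) {
      test <- fold_of == f
      train_roc <- roc_curve(scores[!test],
                             ifelse(is_tumor[!test], "tumor", "normal"))
      thr <- train_roc$optimal_threshold
      test_roc <- roc_curve(scores[test],
                            ifelse(is_tumor[test], "tumor", "normal"))
      perf <- threshold_performance(scores[test], is_tumor[test], thr)
      rows[[length(rows) + 1]] <- data.frame(
        seed = seed, fold = f, train_threshold = thr, auc = test_roc$auc,
        sensitivity = perf$sensitivity, specificity = perf$specificity)
    }
  }
  results <- do.call(rbind, rows)
  if (anyNA(results[, c("sensitivity", "specificity")]))
    warning("fold(s) without both classes: missing values excluded from ",
            "aggregation")
  pooled <- data.frame(
    aggregation = "pooled",
    mean_auc = mean(results$auc), sd_auc = stats::sd(results$auc),
    mean_sensitivity = mean(results$sensitivity, na.rm = TRUE),
    sd_sensitivity = stats::sd(results$sensitivity, na.rm = TRUE),
    mean_specificity = mean(results$specificity, na.rm = TRUE),
    sd_specificity = stats::sd(results$specificity, na.rm = TRUE))
  seed_means <- stats::aggregate(
    results[, c("auc", "sensitivity", "specificity")],
    by = list(seed = results$seed), FUN = mean, na.rm = TRUE)
  per_seed <- data.frame(
    aggregation = "per_seed",
    mean_auc = mean(seed_means$auc), sd_auc = stats::sd(seed_means$auc),
    mean_sensitivity = mean(seed_means$sensitivity),
    sd_sensitivity = stats::sd(seed_means$sensitivity),
    mean_specificity = mean(seed_means$specificity),
    sd_specificity = stats::sd(seed_means$specificity))
  structure(list(results = results, summary = rbind(pooled, per_seed),
                 folds = folds, seeds = seeds,
                 full_cohort = roc_curve(profiles)),
            class = "gapf_cv")
}

#' @export
print.gapf_cv <- function(x, ...) {
  s <- x$summary[x$summary$aggregation == "pooled", ]
  cat(sprintf("gapf_cv: %d-fold CV over seeds {%s}\n", x$folds,
              paste(x$seeds, collapse = ", ")))
  cat(sprintf("  mean AUC %.4f (sd %.4f)\n", s$mean_auc, s$sd_auc))
  cat(sprintf("  sensitivity %.2f%% (sd %.2f), specificity %.2f%% (sd %.2f) at per-fold Youden thresholds\n",
              100 * s$mean_sensitivity, 100 * s$sd_sensitivity,
              100 * s$mean_specificity, 100 * s$sd_specificity))
  cat(sprintf("  whole-cohort Youden threshold: %s (AUC %.4f)\n",
              format(x$full_cohort$optimal_threshold), x$full_cohort$auc))
  invisible(x)
}

#' Threshold calls for every sample of a profile set
#'
#' @param profiles a `gapf_profile_set`
#' @param threshold HCB-count threshold (e.g. the whole-cohort Youden
#'   optimum)
#' @param strict_gt use strict `>` at the boundary
#' @return data frame: `sample_id`, `score`, `threshold`, `call`, and
#'   `label` when the set is labeled
#' @export
call_samples <- function(profiles, threshold, strict_gt = FALSE) {
  stopifnot(inherits(profiles, "gapf_profile_set"))
  scores <- apply(profiles$counts, 1, max)
  pos <- if (strict_gt) scores > threshold else scores >= threshold
  out <- data.frame(sample_id = rownames(profiles$counts),
                    score = as.integer(scores), threshold = threshold,
                    call = ifelse(pos, "GAPF-positive", "GAPF-negative"))
  if (!is.null(profiles$labels)) out$label <- profiles$labels
  rownames(out) <- NULL
  out
}

#' Per-group chrX HCB counts
#'
#' Extracts the chrX column of each group's profile matrix for downstream
#' rank testing or plotting (tumor cfDNA carries more chrX HCBs than
#' matched normal DNA; the rank tests themselves are standard routines).
#'
#' @param groups named list of `gapf_profile_set` objects or count matrices
#'   with a `chrX` column
#' @param chrom column to extract (default `"chrX"`)
#' @return named list of integer vectors, one per group
#' @export
chrx_hcb_compare <- function(groups, chrom = "chrX") {
  if (length(groups) < 2) stop("need >= 2 groups")
  lapply(groups, function(g) {
    m <- if (inherits(g, "gapf_profile_set")) g$counts else as.matrix(g)
    if (nrow(m) == 0) stop("empty group")
    if (!(chrom %in% colnames(m)))
      stop("group lacks a ", chrom, " column")
    stats::setNames(as.integer(m[, chrom]), rownames(m))
  })
}
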
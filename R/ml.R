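# Comparative ML layer: fixed-hyperparameter baselines evaluated with the
# same seeded stratified CV protocol as the threshold model. Each algorithm
# is a (fit, score) pair behind one interface; scores are P(tumor).

ml_algorithms <- function() {
  list(
    "naive_bayes" = list(
      fit = function(x, y, seed) e1071::naiveBayes(as.data.frame(x), y),
      score = function(model, x)
        stats::predict(model, as.data.frame(x), type = "raw")[, "tumor"]),
    "random_forest" = list(
      fit = function(x, y, seed) {
        set.seed(seed)
        randomForest::randomForest(x, y, ntree = 500)
      },
      score = function(model, x)
        stats::predict(model, x, type = "prob")[, "tumor"]),
    "gradient_boosting" = list(
      fit = function(x, y, seed) {
        set.seed(seed)
        xgboost::xgb.train(
          params = list(objective = "binary:logistic", max_depth = 3,
                        eta = 0.3, nthread = 1),
          data = xgboost::xgb.DMatrix(x, label = as.numeric(y == "tumor"),
                                      nthread = 1),
          nrounds = 50, verbose = 0)
      },
      score = function(model, x)
        stats::predict(model, xgboost::xgb.DMatrix(x, nthread = 1))))
}

#' Seeded cross-validated evaluation of ML classifiers on HCB profiles
#'
#' Trains fixed-hyperparameter baseline classifiers on the per-chromosome
#' HCB-count feature matrix (chr1-22 + chrX, 23 features, by default) with
#' the same stratified fold protocol as [cross_validate_threshold()]: for
#' each seed, deal into `folds` groups; train on the rest, report held-out
#' AUC. No hyperparameter search is performed. Optionally computes seeded
#' permutation feature importance on each held-out fold.
#'
#' @param x samples x features numeric matrix (e.g.
#'   `profiles$counts[, c(paste0("chr", 1:22), "chrX")]`)
#' @param y labels, `"tumor"` / `"normal"`
#' @param algorithms subset of `"naive_bayes"`, `"random_forest"`,
#'   `"gradient_boosting"`
#' @param folds number of CV folds (default 3)
#' @param seeds fold-assignment seeds (default 22, 32, 42)
#' @param importance also compute permutation feature importance per fold
#' @param importance_repeats permutation repeats per feature (default 10)
#' @return a `gapf_ml` list: `results` (algorithm x seed x fold AUC rows),
#'   `summary` (per-algorithm mean/sd/median AUC), and when requested
#'   `importance` (per-algorithm feature matrix of mean importances)
#' @export
evaluate_ml_models <- function(x, y,
                               algorithms = c("naive_bayes", "random_forest",
                                              "gradient_boosting"),
                               folds = 3, seeds = c(22, 32, 42),
                               importance = FALSE, importance_repeats = 10) {
  algs <- ml_algorithms()
  unknown <- setdiff(algorithms, names(algs))
  if (length(unknown))
    stop("unknown algorithm: ", paste(unknown, collapse = ", "))
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(match.arg(y, c("tumor", "normal"), several.ok = TRUE),
              levels = c("normal", "tumor"))
  is_tumor <- y == "tumor"
  if (min(table(y)) < folds) stop("need at least `folds` samples per class")
  rows <- list()
  imp_acc <- stats::setNames(vector("list", length(algorithms)), algorithms)
  for (alg in algorithms) {
    for (seed in seeds) {
      fold_of <- make_folds(is_tumor, folds, seed)
      for (f in seq_len(folds)) {
        test <- fold_of == f
        model <- algs[[alg]]$fit(x[!test, , drop = FALSE], y[!test],
                                 seed = seed)
        p <- algs[[alg]]$score(model, x[test, , drop = FALSE])
        auc <- roc_curve(p, ifelse(is_tumor[test], "tumor", "normal"))$auc
        rows[[length(rows) + 1]] <- data.frame(algorithm = alg, seed = seed,
                                               fold = f, auc = auc)
        if (importance) {
          imp <- permutation_importance(
            function(newx) algs[[alg]]$score(model, newx),
            x[test, , drop = FALSE],
            ifelse(is_tumor[test], "tumor", "normal"),
            repeats = importance_repeats, seed = seed)
          imp_acc[[alg]] <- rbind(imp_acc[[alg]], imp)
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(results, results$algorithm),
                                   function(d) data.frame(
                                     algorithm = d$algorithm[1],
                                     mean_auc = mean(d$auc),
                                     sd_auc = stats::sd(d$auc),
                                     median_auc = stats::median(d$auc))))
  rownames(summary) <- NULL
  out <- list(results = results, summary = summary, folds = folds,
              seeds = seeds)
  if (importance)
    out$importance <- lapply(imp_acc, function(m) colMeans(m))
  structure(out, class = "gapf_ml")
}

#' @export
print.gapf_ml <- function(x, ...) {
  cat(sprintf("gapf_ml: %d-fold CV over seeds {%s}\n", x$folds,
              paste(x$seeds, collapse = ", ")))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Permutation feature importance
#'
#' Importance of feature f = baseline AUC minus the mean AUC after
#' shuffling column f (`repeats` times, seeded). A feature the model
#' ignores scores near zero; a feature carrying the decision scores high.
#'
#' @param score_fun function mapping a feature matrix to numeric scores
#'   (higher = more tumor-like)
#' @param x test feature matrix
#' @param labels `"tumor"` / `"normal"` test labels (both classes required)
#' @param repeats shuffles per feature (default 10)
#' @param seed RNG seed for the shuffles
#' @return named numeric vector of importances, one per column of `x`
#' @export
permutation_importance <- function(score_fun, x, labels, repeats = 10,
                                   seed = 1) {
  x <- as.matrix(x)
  is_tumor <- match.arg(labels, c("tumor", "normal"),
                        several.ok = TRUE) == "tumor"
  if (!any(is_tumor) || !any(!is_tumor))
    stop("single-class test data: importance undefined")
  lab <- ifelse(is_tumor, "tumor", "normal")
  baseline <- roc_curve(score_fun(x), lab)$auc
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  imp <- vapply(seq_len(ncol(x)), function(j) {
    drop <- vapply(seq_len(repeats), function(r) {
      xs <- x
      xs[, j] <- xs[sample.int(nrow(xs)), j]
      baseline - roc_curve(score_fun(xs), lab)$auc
    }, numeric(1))
    mean(drop)
  }, numeric(1))
  stats::setNames(imp, colnames(x))
}

#' Composite normalized, AUC-weighted feature importance
#'
#' Within each algorithm, raw permutation importances are floored at zero
#' and divided by the algorithm's maximum positive score (0-1 range), then
#' weighted by that algorithm's median AUC so accurate models count more;
#' the weighted scores are summed across algorithms per feature.
#'
#' @param raw_scores named list (or matrix with algorithm rows) of raw
#'   per-feature importance vectors
#' @param median_auc named numeric vector of per-algorithm median AUCs
#' @return list: `normalized` (algorithms x features matrix), `weighted`
#'   (same, scaled by median AUC), `composite` (per-feature sums)
#' @export
composite_importance <- function(raw_scores, median_auc) {
  if (is.matrix(raw_scores))
    raw_scores <- stats::setNames(
      lapply(seq_len(nrow(raw_scores)), function(i) raw_scores[i, ]),
      rownames(raw_scores))
  if (length(raw_scores) == 0) stop("need >= 1 algorithm")
  if (!all(names(raw_scores) %in% names(median_auc)))
    stop("median_auc must name every algorithm")
  norm <- t(vapply(raw_scores, function(s) {
    s <- pmax(s, 0)
    m <- max(s)
    if (m > 0) s / m else s
  }, numeric(length(raw_scores[[1]]))))
  rownames(norm) <- names(raw_scores)
  colnames(norm) <- names(raw_scores[[1]])
  weighted <- norm * median_auc[rownames(norm)]
  list(normalized = norm, weighted = weighted,
       composite = colSums(weighted))
}
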
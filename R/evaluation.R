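#' Assign individuals to cross-validation folds
#'
#' Folds partition INDIVIDUALS, not measurements, so no individual's
#' records are split between training and testing.
#'
#' @param individual_ids character vector of unique individual ids.
#' @param n_folds number of folds (>= 2).
#' @param seed RNG seed.
#' @return Named integer vector: fold number per individual.
#' @export
make_folds <- function(individual_ids, n_folds = 10L, seed = NULL) {
  individual_ids <- unique(as.character(individual_ids))
  n <- length(individual_ids)
  if (n_folds < 2L) stop("n_folds must be at least 2")
  if (n < n_folds) stop("fewer individuals (", n, ") than folds")
  if (!is.null(seed)) set.seed(seed)
  folds <- sample(rep_len(seq_len(n_folds), n))
  stats::setNames(folds, individual_ids)
}

#' Prediction accuracy
#'
#' Pearson correlation between predicted breeding values and the mean
#' phenotype per individual, unscaled (not divided by the square root of
#' heritability), so it is directly comparable to the analytic
#' `sqrt(E[R^2])` of [expected_r2()].
#'
#' @param g_hat predicted breeding values.
#' @param y_bar mean observed phenotype per individual.
#' @return Pearson correlation.
#' @export
accuracy <- function(g_hat, y_bar) {
  if (length(g_hat) != length(y_bar)) stop("length mismatch")
  if (length(g_hat) < 3L) stop("need at least 3 individuals")
  if (stats::sd(g_hat) == 0 || stats::sd(y_bar) == 0)
    stop("zero variance input: correlation undefined")
  stats::cor(g_hat, y_bar)
}

#' Calibration (bias) slope of genomic predictions
#'
#' Ordinary-least-squares slope of the mean observed phenotype regressed
#' ON the predicted breeding values. Unbiased predictions give an expected
#' slope of 1; slopes below 1 indicate over-dispersed (over-shrunk toward
#' extremes) predictions.
#'
#' @param g_hat predicted breeding values (predictor).
#' @param y_bar mean observed phenotype per individual (response).
#' @return OLS slope.
#' @export
bias_slope <- function(g_hat, y_bar) {
  if (length(g_hat) != length(y_bar)) stop("length mismatch")
  if (stats::var(g_hat) == 0) stop("zero variance in predictions; slope undefined")
  sum((g_hat - mean(g_hat)) * (y_bar - mean(y_bar))) /
    sum((g_hat - mean(g_hat))^2)
}

#' Individual-level k-fold cross-validation of genomic prediction
#'
#' For each requested number of PCs and each fold: refit the model on the
#' training individuals' measurements only, predict held-out individuals'
#' breeding values from their (shared, genotype-only) PC scores, and score
#' the predictions against the held-out raw mean phenotype per individual
#' with [accuracy()] and [bias_slope()]. Metrics are reported per fold and
#' pooled over the concatenated held-out predictions; the mean of fold-wise
#' metrics is also given.
#'
#' The PC basis is computed from genotypes alone, so sharing it across
#' folds leaks no phenotype information. Held-out phenotypes never enter
#' the training frame.
#'
#' @param data phenotype/covariate data.frame (one row per measurement).
#' @param basis a scaled [compute_basis()] result.
#' @param trait,fixed,random,id_col as in [model_frame()].
#' @param k_list integer vector of PC counts to evaluate.
#' @param n_folds number of folds (default 10).
#' @param prior a [prior_spec()].
#' @param sampler a [sampler_config()].
#' @param seed seed for the fold assignment (fit seeds derive from it).
#' @param adjust_ybar if `TRUE`, score against fixed-effect-adjusted mean
#'   phenotypes (residuals of `y ~ fixed` averaged per individual) instead
#'   of the raw mean.
#' @return An object of class `cv_report`: data.frame `folds` (k, fold,
#'   n_test, accuracy, slope), data.frame `pooled` (k, accuracy, slope,
#'   accuracy_foldmean, slope_foldmean), the fold `assignment`, and the
#'   pooled predictions.
#' @export
run_cv <- function(data, basis, trait, fixed = character(),
                   random = character(), id_col = "id",
                   k_list = c(50L, 100L, 200L), n_folds = 10L,
                   prior = prior_spec("default"),
                   sampler = sampler_config(), seed = NULL,
                   adjust_ybar = FALSE) {
  ids <- unique(as.character(data[[id_col]]))
  assignment <- make_folds(ids, n_folds, seed)

  yv <- as.numeric(data[[trait]])
  if (adjust_ybar && length(fixed) > 0L) {
    res <- stats::residuals(stats::lm(
      stats::reformulate(fixed, response = trait), data = data))
    ybar_all <- tapply(res, as.character(data[[id_col]]), mean)
  } else {
    ybar_all <- tapply(yv, as.character(data[[id_col]]), mean)
  }

  fold_rows <- list()
  pooled_rows <- list()
  predictions <- list()
  for (k in k_list) {
    all_ghat <- numeric(0)
    all_ybar <- numeric(0)
    fold_acc <- numeric(0)
    fold_slope <- numeric(0)
    for (f in seq_len(n_folds)) {
      test_ids <- names(assignment)[assignment == f]
      if (length(test_ids) < 3L) {
        warning("fold ", f, " has fewer than 3 test individuals; skipped")
        next
      }
      train <- data[!(as.character(data[[id_col]]) %in% test_ids), ,
                    drop = FALSE]
      frame <- model_frame(train, trait, basis, fixed, random, id_col)
      fit_seed <- if (is.null(seed)) NULL else seed + 1000L * k + f
      fit <- fit_bpcrr(frame, basis, prior, k = k,
                       sampler = sampler_config(
                         n_iter = sampler$n_iter, burnin = sampler$burnin,
                         thin = sampler$thin, seed = fit_seed,
                         store_g = FALSE))
      pos <- match(test_ids, basis$individual_ids)
      ghat <- as.numeric(
        basis$scaled_scores[pos, seq_len(k), drop = FALSE] %*%
          colMeans(fit$u))
      ybar <- as.numeric(ybar_all[test_ids])
      acc <- accuracy(ghat, ybar)
      slp <- bias_slope(ghat, ybar)
      fold_rows[[length(fold_rows) + 1L]] <-
        data.frame(k = k, fold = f, n_test = length(test_ids),
                   accuracy = acc, slope = slp)
      fold_acc <- c(fold_acc, acc)
      fold_slope <- c(fold_slope, slp)
      all_ghat <- c(all_ghat, ghat)
      all_ybar <- c(all_ybar, ybar)
    }
    pooled_rows[[length(pooled_rows) + 1L]] <- data.frame(
      k = k,
      accuracy = accuracy(all_ghat, all_ybar),
      slope = bias_slope(all_ghat, all_ybar),
      accuracy_foldmean = mean(fold_acc),
      slope_foldmean = mean(fold_slope))
    predictions[[as.character(k)]] <- data.frame(
      g_hat = all_ghat, y_bar = all_ybar)
  }
  structure(list(folds = do.call(rbind, fold_rows),
                 pooled = do.call(rbind, pooled_rows),
                 assignment = assignment, predictions = predictions,
                 prior_mode = prior$mode, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cv_report (", x$prior_mode, " prior):\n", sep = "")
  print(x$pooled, row.names = FALSE)
  invisible(x)
}

#' Write a CV report to disk
#'
#' @param report a [run_cv()] result.
#' @param dir output directory; writes `cv_folds.csv` and
#'   `cv_summary.json`.
#' @export
write_cv_report <- function(report, dir) {
  stopifnot(inherits(report, "cv_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$folds, file.path(dir, "cv_folds.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$pooled, file.path(dir, "cv_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
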
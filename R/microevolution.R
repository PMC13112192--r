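#' Temporal trend in breeding values
#'
#' Ordinary-least-squares regression of (posterior-mean) breeding values
#' on birth year: the slope is the per-year change in mean genetic merit.
#'
#' @param bv breeding values (response).
#' @param birth_year numeric birth years (predictor).
#' @return List with `slope`, `se`, `intercept`.
#' @export
trend_slope <- function(bv, birth_year) {
  if (length(bv) != length(birth_year)) stop("length mismatch")
  if (length(unique(birth_year)) < 2L)
    stop("need at least 2 distinct birth years (3+ recommended)")
  fit <- stats::lm(bv ~ birth_year)
  cf <- summary(fit)$coefficients
  list(slope = cf["birth_year", "Estimate"],
       se = cf["birth_year", "Std. Error"],
       intercept = cf["(Intercept)", "Estimate"])
}

#' Posterior distribution of the breeding-value trend
#'
#' Propagates posterior uncertainty in the breeding values into the trend:
#' breeding-value vectors are drawn from the posterior (rows of
#' `bv_draws`), each is regressed on birth year, and the slopes form an
#' empirical posterior. When fewer draws than `n_rep` are stored, draws
#' are resampled with replacement (with a message).
#'
#' Trend analysis is a within-sample exercise: use a fit with a large
#' number of PCs, not cross-validated predictions.
#'
#' @param bv_draws draws x individuals matrix of posterior breeding
#'   values (`g_draws` of a fit).
#' @param birth_year numeric vector, one per individual.
#' @param n_rep number of regression replicates (default 1000).
#' @param seed RNG seed.
#' @return An object of class `trend_report`: `slope`/`se` of the OLS fit
#'   on posterior means, and `posterior` (mean, sd, 2.5/50/97.5% quantiles
#'   of the replicate slopes) plus the replicate `slopes`.
#' @export
posterior_trend <- function(bv_draws, birth_year, n_rep = 1000L,
                            seed = NULL) {
  if (is.null(bv_draws) || nrow(bv_draws) == 0L)
    stop("no posterior draws available")
  if (ncol(bv_draws) != length(birth_year))
    stop("bv_draws columns must match birth_year length")
  if (!is.null(seed)) set.seed(seed)
  n_draws <- nrow(bv_draws)
  take <- if (n_draws >= n_rep) sample.int(n_draws, n_rep)
  else {
    message("only ", n_draws, " draws stored; resampling with replacement")
    sample.int(n_draws, n_rep, replace = TRUE)
  }
  yr_c <- birth_year - mean(birth_year)
  sxx <- sum(yr_c^2)
  slopes <- as.numeric((bv_draws[take, , drop = FALSE] %*% yr_c) / sxx)
  point <- trend_slope(colMeans(bv_draws), birth_year)
  structure(list(
    slope = point$slope, se = point$se,
    posterior = data.frame(mean = mean(slopes), sd = stats::sd(slopes),
                           q025 = stats::quantile(slopes, 0.025, names = FALSE),
                           q50 = stats::quantile(slopes, 0.5, names = FALSE),
                           q975 = stats::quantile(slopes, 0.975, names = FALSE)),
    slopes = slopes, n_rep = n_rep),
    class = "trend_report")
}

#' @export
print.trend_report <- function(x, ...) {
  cat(sprintf("trend_report: slope %.4g (SE %.3g) per year\n",
              x$slope, x$se))
  cat(sprintf("  posterior of slope: %.4g [%.4g, %.4g] (%d replicates)\n",
              x$posterior$mean, x$posterior$q025, x$posterior$q975,
              x$n_rep))
  invisible(x)
}

#' Breeding-value summaries by cohort or location
#'
#' Groups posterior-mean breeding values by a label (birth cohort, natal
#' island, ...) and summarizes each group.
#'
#' @param bv posterior-mean breeding values.
#' @param grouping vector of group labels, one per individual.
#' @param labels optional subset/order of groups to report; unknown labels
#'   are an error.
#' @return data.frame: group, n, mean, sd, q025, q50, q975.
#' @export
group_summaries <- function(bv, grouping, labels = NULL) {
  if (length(bv) != length(grouping)) stop("length mismatch")
  grouping <- as.character(grouping)
  if (!is.null(labels)) {
    unknown <- setdiff(labels, unique(grouping))
    if (length(unknown) > 0L)
      stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  } else {
    labels <- sort(unique(grouping))
  }
  out <- do.call(rbind, lapply(labels, function(gr) {
    x <- bv[grouping == gr]
    data.frame(group = gr, n = length(x), mean = mean(x),
               sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
               q025 = stats::quantile(x, 0.025, names = FALSE),
               q50 = stats::quantile(x, 0.5, names = FALSE),
               q975 = stats::quantile(x, 0.975, names = FALSE))
  }))
  rownames(out) <- NULL
  out
}

#' Write a trend report to disk
#'
#' @param report a [posterior_trend()] result.
#' @param groups optional [group_summaries()] table.
#' @param dir output directory; writes `trend.json` and, if given,
#'   `group_summaries.csv`.
#' @export
write_trend_report <- function(report, dir, groups = NULL) {
  stopifnot(inherits(report, "trend_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(slope = report$slope, se = report$se,
         posterior = as.list(report$posterior), n_rep = report$n_rep),
    file.path(dir, "trend.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(groups))
    utils::write.csv(groups, file.path(dir, "group_summaries.csv"),
                     row.names = FALSE)
  invisible(dir)
}
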
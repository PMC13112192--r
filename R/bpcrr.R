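#' Build a model frame for a BPCRR or animal-model fit
#'
#' Joins a phenotype/covariate table against the individuals of a PC basis
#' and assembles the response, the fixed-effect design (intercept first),
#' the group-indicator designs of the random terms, and the map from
#' observation to basis row. Repeated measurements per individual are
#' supported; add the individual id itself as a random term to model a
#' permanent-environment effect.
#'
#' @param data data.frame with one row per measurement.
#' @param trait name of the response column.
#' @param basis a [compute_basis()] result (or any object with
#'   `individual_ids`) used to resolve individuals.
#' @param fixed character vector of fixed-effect column names (may be empty;
#'   an intercept is always included). Factors/characters are expanded to
#'   treatment contrasts.
#' @param random character vector of random-effect grouping columns (each
#'   becomes an i.i.d. Gaussian group effect).
#' @param id_col individual-id column name.
#' @return An object of class `model_frame` with fields `y`, `X`,
#'   `random_terms` (named list of indicator matrices), `individual_index`
#'   (observation -> basis row), `individual_ids`, `data`.
#' @export
model_frame <- function(data, trait, basis, fixed = character(),
                        random = character(), id_col = "id") {
  stopifnot(is.data.frame(data))
  for (col in c(trait, fixed, random, id_col))
    if (!col %in% colnames(data)) stop("column '", col, "' not in data")
  ids <- as.character(data[[id_col]])
  pos <- match(ids, basis$individual_ids)
  if (anyNA(pos))
    stop("individuals absent from the genotype basis: ",
         paste(utils::head(unique(ids[is.na(pos)]), 5L), collapse = ", "))
  y <- as.numeric(data[[trait]])
  if (anyNA(y)) {
    keep <- !is.na(y)
    data <- data[keep, , drop = FALSE]
    y <- y[keep]; ids <- ids[keep]; pos <- pos[keep]
  }
  X <- if (length(fixed) > 0L) {
    stats::model.matrix(stats::reformulate(fixed), data = data)
  } else {
    matrix(1, length(y), 1L, dimnames = list(NULL, "(Intercept)"))
  }
  random_terms <- lapply(random, function(r) {
    f <- factor(data[[r]])
    stats::model.matrix(~ 0 + f)
  })
  names(random_terms) <- random
  structure(list(y = y, X = X, random_terms = random_terms,
                 individual_index = pos, individual_ids = ids,
                 trait = trait, data = data),
            class = "model_frame")
}

#' Prior specification for the ridge model
#'
#' Two modes for the PC-effect variance `sigma_u2`:
#' * `"fixed"`: the ridge shrinkage prior. The variance is set to
#'   `sigma_g2 / sum(pc_variances)` (see [prior_variance()]), which carries
#'   a prior guess of the additive genetic variance into a SNP-BLUP-matched
#'   amount of shrinkage.
#' * `"default"`: a vague hyperprior, Gamma(1, 5e-5) on the precision
#'   1/sigma_u2, sampled alongside the other parameters.
#'
#' Fixed effects get independent N(0, 1e4) priors. Residual and
#' random-term variances get weak conjugate inverse-gamma(0.01, 0.01)
#' priors unless fixed explicitly (fixing both `sigma_u2` and the residual
#' variance turns the posterior into an exact closed-form Gaussian).
#'
#' @param mode `"fixed"` or `"default"`.
#' @param sigma_g2 prior guess of the additive genetic variance
#'   (required in fixed mode unless `sigma_u2` is given directly).
#' @param sigma_u2 optional: set the PC-effect variance directly.
#' @param hyper_shape,hyper_rate Gamma prior on the PC-effect precision in
#'   default mode.
#' @param fixed_effect_var prior variance of each fixed effect.
#' @param ranef_shape,ranef_rate inverse-gamma prior for random-term
#'   variances.
#' @param resid_shape,resid_rate inverse-gamma prior for the residual
#'   variance.
#' @param resid_fixed optional: hold the residual variance at this value.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(mode = c("fixed", "default"), sigma_g2 = NULL,
                       sigma_u2 = NULL, hyper_shape = 1, hyper_rate = 5e-5,
                       fixed_effect_var = 1e4,
                       ranef_shape = 0.01, ranef_rate = 0.01,
                       resid_shape = 0.01, resid_rate = 0.01,
                       resid_fixed = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed" && is.null(sigma_g2) && is.null(sigma_u2))
    stop("mode = 'fixed' needs sigma_g2 (or sigma_u2) to derive the shrinkage prior")
  structure(list(mode = mode, sigma_g2 = sigma_g2, sigma_u2 = sigma_u2,
                 hyper_shape = hyper_shape, hyper_rate = hyper_rate,
                 fixed_effect_var = fixed_effect_var,
                 ranef_shape = ranef_shape, ranef_rate = ranef_rate,
                 resid_shape = resid_shape, resid_rate = resid_rate,
                 resid_fixed = resid_fixed),
            class = "prior_spec")
}

#' Sampler settings
#'
#' @param n_iter kept iterations after burn-in.
#' @param burnin discarded iterations.
#' @param thin keep every `thin`-th draw.
#' @param seed RNG seed for reproducible chains.
#' @param store_g keep the per-draw breeding-value matrix (needed for
#'   posterior trend analysis; adds draws x N doubles of memory).
#' @return A list of class `sampler_config`.
#' @export
sampler_config <- function(n_iter = 4000L, burnin = 1000L, thin = 1L,
                           seed = NULL, store_g = TRUE) {
  structure(list(n_iter = as.integer(n_iter), burnin = as.integer(burnin),
                 thin = as.integer(thin), seed = seed, store_g = store_g),
            class = "sampler_config")
}

#' Shrinkage-prior variance for the PC effects
#'
#' The ridge prior variance that transfers a given additive genetic
#' variance onto k variance-scaled principal components:
#' `sigma_g2 / sum(pc_variances)`. With a single PC of variance 1 the
#' PC-effect variance equals the genetic variance itself.
#'
#' @param sigma_g2 additive genetic variance (> 0).
#' @param pc_variances variances of the scaled PC columns
#'   (see [pc_variances()]).
#' @return Scalar prior variance for the PC effects.
#' @export
prior_variance <- function(sigma_g2, pc_variances) {
  if (length(pc_variances) == 0L) stop("pc_variances is empty")
  if (!is.finite(sigma_g2) || sigma_g2 <= 0) stop("sigma_g2 must be > 0")
  if (any(pc_variances <= 0)) stop("pc_variances must be positive")
  sigma_g2 / sum(pc_variances)
}

#' Fit the Bayesian PC ridge regression model
#'
#' Fits `y = X b + Z* u* + W d + eps` where `Z*` holds the first k scaled
#' PC scores (rows expanded to observations for repeated measurements),
#' with a common Gaussian prior on the PC effects. In `"fixed"` prior mode
#' the PC-effect variance is held at [prior_variance()]; in `"default"`
#' mode it gets a vague hyperprior and is sampled. Inference is a blocked
#' Gibbs sampler with conjugate variance updates; when every variance
#' component is held fixed the exact Gaussian posterior is used instead.
#'
#' @param frame a [model_frame()].
#' @param basis a scaled [compute_basis()] result.
#' @param prior a [prior_spec()].
#' @param k number of leading PCs (default: all).
#' @param sampler a [sampler_config()].
#' @return An object of class `bpcrr_fit` containing posterior draws of the
#'   fixed effects (`b`), PC effects (`u`), random-term effects and all
#'   variance components; per-individual breeding values `g = Z* u*` for
#'   every individual in the basis (posterior mean, sd, 95% interval and,
#'   if `store_g`, full draws); the additive-genetic-variance draws
#'   (`va_draws`, empirical variance of g across individuals per draw);
#'   and split-chain convergence diagnostics.
#' @export
fit_bpcrr <- function(frame, basis, prior, k = basis$k_max,
                      sampler = sampler_config()) {
  stopifnot(inherits(frame, "model_frame"), inherits(basis, "pc_basis"),
            inherits(prior, "prior_spec"))
  if (is.null(basis$scaled_scores)) basis <- scale_scores(basis)
  if (k < 1L || k > basis$k_max) stop("k must be in 1..k_max = ", basis$k_max)
  Zs <- basis$scaled_scores[, seq_len(k), drop = FALSE]
  Zobs <- Zs[frame$individual_index, , drop = FALSE]

  pcv <- pc_variances(basis, k)
  sigma_u2 <- prior$sigma_u2
  if (prior$mode == "fixed" && is.null(sigma_u2))
    sigma_u2 <- prior_variance(prior$sigma_g2, pcv)

  blocks <- list(new_block("fixed", frame$X, "fixed",
                           value = prior$fixed_effect_var))
  blocks$u <- if (prior$mode == "fixed")
    new_block("u", Zobs, "fixed", value = sigma_u2, collapse = TRUE)
  else
    new_block("u", Zobs, "ig", shape = prior$hyper_shape,
              rate = prior$hyper_rate, collapse = TRUE)
  for (nm in names(frame$random_terms))
    blocks[[nm]] <- new_block(nm, frame$random_terms[[nm]], "ig",
                              shape = prior$ranef_shape,
                              rate = prior$ranef_rate)
  resid <- if (is.null(prior$resid_fixed))
    list(type = "ig", shape = prior$resid_shape, rate = prior$resid_rate,
         value = NA_real_)
  else list(type = "fixed", value = prior$resid_fixed)

  res <- gibbs_lmm(frame$y, unname(blocks), resid,
                   n_iter = sampler$n_iter, burnin = sampler$burnin,
                   thin = sampler$thin, seed = sampler$seed)

  nb <- length(blocks)
  b_draws <- res$theta[, res$idx[[1L]], drop = FALSE]
  colnames(b_draws) <- colnames(frame$X)
  u_draws <- res$theta[, res$idx[[2L]], drop = FALSE]
  d_draws <- if (nb > 2L) {
    out <- lapply(3:nb, function(i) res$theta[, res$idx[[i]], drop = FALSE])
    names(out) <- names(frame$random_terms)
    out
  } else list()

  # breeding values for every basis individual; exact-mode posterior mean
  # of g uses the analytic coefficient mean
  g_draws <- u_draws %*% t(Zs)
  g_mean <- if (res$exact)
    as.numeric(Zs %*% res$theta_mean_exact[res$idx[[2L]]])
  else colMeans(g_draws)
  N <- nrow(Zs)
  gc_draws <- g_draws - rowMeans(g_draws)
  va_draws <- rowSums(gc_draws^2) / (N - 1)

  vcomp <- cbind(res$sigma2, res$block_variances[, -1L, drop = FALSE])
  rhat <- apply(vcomp, 2L, split_rhat)
  if (any(rhat > 1.05, na.rm = TRUE))
    warning("split-chain R-hat > 1.05 for: ",
            paste(colnames(vcomp)[which(rhat > 1.05)], collapse = ", "),
            "; consider more iterations")

  fit <- structure(list(
    k = k, prior = prior, sigma_u2_fixed = sigma_u2,
    b = b_draws, u = u_draws, d = d_draws,
    sigma_e2 = as.numeric(res$sigma2[, 1L]),
    sigma_u2 = if (prior$mode == "default")
      as.numeric(res$block_variances[, "u"]) else NULL,
    ranef_var = if (nb > 2L)
      res$block_variances[, -(1:2), drop = FALSE] else NULL,
    g_mean = stats::setNames(g_mean, basis$individual_ids),
    g_sd = stats::setNames(apply(g_draws, 2L, stats::sd),
                           basis$individual_ids),
    g_ci = apply(g_draws, 2L, stats::quantile, probs = c(0.025, 0.975)),
    g_draws = if (sampler$store_g) g_draws else NULL,
    va_draws = va_draws,
    pc_variance_sum = sum(pcv),
    individual_ids = basis$individual_ids,
    exact = res$exact, diag_path = res$diag_path,
    rhat = rhat, sampler = sampler),
    class = "bpcrr_fit")
  fit
}

#' @export
print.bpcrr_fit <- function(x, ...) {
  va <- estimate_va(x)
  cat(sprintf("bpcrr_fit: k = %d PCs, prior mode '%s'%s\n", x$k,
              x$prior$mode, if (x$exact) " (exact posterior)" else ""))
  cat(sprintf("  V_A: %.4f [%.4f, %.4f]\n", va$mean, va$lower, va$upper))
  cat(sprintf("  sigma2_e: %.4f   h2: %.4f\n", mean(x$sigma_e2),
              va$mean / (va$mean + mean(x$sigma_e2))))
  invisible(x)
}

#' Posterior summary of the additive genetic variance
#'
#' For every posterior draw of the PC effects the breeding values
#' `g = Z* u*` are formed and their empirical variance across individuals
#' (denominator N-1) is taken; this draw-wise variance is the additive
#' genetic variance V_A. The alternative plug-in
#' `sigma_u2 * sum(var(PC_i))` is attached as attribute `"plugin"`.
#'
#' @param fit a [fit_bpcrr()] result.
#' @return A one-row data.frame: posterior `mean`, `sd`, `lower`/`upper`
#'   (95% credible interval) of V_A.
#' @export
estimate_va <- function(fit) {
  stopifnot(inherits(fit, "bpcrr_fit") || inherits(fit, "animal_fit"))
  v <- fit$va_draws
  if (length(v) == 0L) stop("fit has no posterior draws")
  out <- data.frame(mean = mean(v), sd = stats::sd(v),
                    lower = stats::quantile(v, 0.025, names = FALSE),
                    upper = stats::quantile(v, 0.975, names = FALSE))
  su2 <- if (!is.null(fit$sigma_u2)) mean(fit$sigma_u2) else fit$sigma_u2_fixed
  if (!is.null(su2) && !is.null(fit$pc_variance_sum))
    attr(out, "plugin") <- su2 * fit$pc_variance_sum
  out
}

#' Predict breeding values for (new) individuals
#'
#' Projects genotypes onto the training PC basis and multiplies by the
#' posterior-mean PC effects: `g_hat = project(basis, g_new, k) %*% mean(u*)`.
#'
#' @param fit a [fit_bpcrr()] result.
#' @param basis the `pc_basis` the fit used.
#' @param g_new a [genotype_matrix()] with the training markers; raw codes
#'   are centered with the training column means.
#' @return Named numeric vector of predicted breeding values.
#' @export
predict_bv <- function(fit, basis, g_new) {
  stopifnot(inherits(fit, "bpcrr_fit"))
  scores <- project(basis, g_new, fit$k)
  u_mean <- colMeans(fit$u)
  stats::setNames(as.numeric(scores %*% u_mean), g_new$individual_ids)
}

#' Write breeding-value and variance-component summaries
#'
#' @param fit a [fit_bpcrr()] or [fit_animal_model()] result.
#' @param dir output directory (created if absent). Writes
#'   `breeding_values.csv` and `variance_components.json`.
#' @export
write_fit_summary <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bv <- data.frame(individual_id = fit$individual_ids,
                   mean = fit$g_mean, sd = fit$g_sd,
                   q025 = fit$g_ci[1L, ], q975 = fit$g_ci[2L, ])
  utils::write.csv(bv, file.path(dir, "breeding_values.csv"),
                   row.names = FALSE)
  va <- estimate_va(fit)
  vc <- list(va = as.list(va),
             sigma_e2 = list(mean = mean(fit$sigma_e2),
                             sd = stats::sd(fit$sigma_e2)),
             h2 = va$mean / (va$mean + mean(fit$sigma_e2)),
             k = fit$k)
  jsonlite::write_json(vc, file.path(dir, "variance_components.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
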
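#' VanRaden genomic relatedness matrix
#'
#' Two variants from the centered dosage matrix Z:
#' * `"empirical"` (default): `G = (N - 1) Z Z' / trace(Z'Z)`, which gives
#'   trace(G) = N - 1 (mean diagonal near 1) and matches the sample-variance
#'   convention
#'   used by the PC eigenvalues, so full-rank ridge fits and the animal
#'   model are exactly equivalent.
#' * `"expected"`: `G = Z Z' / (2 * sum p_j (1 - p_j))`, the conventional
#'   allele-frequency denominator.
#'
#' @param g a centered [genotype_matrix()].
#' @param denominator `"empirical"` or `"expected"`.
#' @return An object of class `grm`: fields `G` (N x N), `denominator`,
#'   `individual_ids`.
#' @export
vanraden_grm <- function(g, denominator = c("empirical", "expected")) {
  stopifnot(inherits(g, "genotype_matrix"))
  denominator <- match.arg(denominator)
  if (!g$centered) stop("vanraden_grm() needs a centered genotype matrix")
  Z <- g$codes
  ZZt <- tcrossprod(Z)
  den <- if (denominator == "empirical") {
    tr <- sum(Z^2)  # trace(Z'Z)
    if (tr <= 0) stop("all markers are monomorphic; GRM undefined")
    tr / (nrow(Z) - 1)
  } else {
    p <- g$column_means / 2
    s <- 2 * sum(p * (1 - p))
    if (s <= 0) stop("all markers are monomorphic; GRM undefined")
    s
  }
  structure(list(G = ZZt / den, denominator = denominator,
                 individual_ids = g$individual_ids),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm: %d individuals, %s denominator, mean diagonal %.4f\n",
              nrow(x$G), x$denominator, mean(diag(x$G))))
  invisible(x)
}

#' Genomic animal model (GBLUP baseline)
#'
#' Fits `y = X b + g + W d + eps` with `g ~ N(0, sigma_g2 * G)`. The
#' genetic effect is reparameterized as `g = L a` with `G = L L'`
#' (Cholesky, with an escalating diagonal jitter if G is not numerically
#' positive definite) and `a ~ N(0, sigma_g2 I)`, so the same conjugate
#' Gibbs machinery as [fit_bpcrr()] applies. `sigma_g2` gets a weak
#' inverse-gamma prior unless fixed.
#'
#' @param frame a [model_frame()] built against an object carrying the GRM
#'   individual ids (pass the `grm` as `basis`; it has `individual_ids`).
#' @param grm a [vanraden_grm()] result.
#' @param prior a [prior_spec()]; `sigma_u2`/`sigma_g2` fix the genetic
#'   variance in fixed mode, otherwise it is sampled.
#' @param sampler a [sampler_config()].
#' @return An object of class `animal_fit` with posterior draws of the
#'   variance components, per-individual GBLUPs (`g_mean`, `g_sd`, draws),
#'   draw-wise empirical V_A (`va_draws`) and the sampled `sigma_g2` chain.
#' @export
fit_animal_model <- function(frame, grm, prior = prior_spec("default"),
                             sampler = sampler_config()) {
  stopifnot(inherits(frame, "model_frame"), inherits(grm, "grm"))
  N <- nrow(grm$G)
  L <- chol_psd(grm$G)
  J <- matrix(0, length(frame$y), N)
  J[cbind(seq_along(frame$y), frame$individual_index)] <- 1
  M <- J %*% t(L)

  gen_var_fixed <- !is.null(prior$sigma_u2) || !is.null(prior$sigma_g2)
  blocks <- list(new_block("fixed", frame$X, "fixed",
                           value = prior$fixed_effect_var))
  blocks$a <- if (prior$mode == "fixed" && gen_var_fixed)
    new_block("a", M, "fixed",
              value = if (!is.null(prior$sigma_u2)) prior$sigma_u2
                      else prior$sigma_g2, collapse = TRUE)
  else
    new_block("a", M, "ig", shape = prior$ranef_shape,
              rate = prior$ranef_rate, collapse = TRUE)
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

  a_draws <- res$theta[, res$idx[[2L]], drop = FALSE]
  g_draws <- a_draws %*% L
  g_mean <- if (res$exact)
    as.numeric(t(L) %*% res$theta_mean_exact[res$idx[[2L]]])
  else colMeans(g_draws)
  gc_draws <- g_draws - rowMeans(g_draws)
  va_draws <- rowSums(gc_draws^2) / (N - 1)

  structure(list(
    prior = prior,
    b = res$theta[, res$idx[[1L]], drop = FALSE],
    sigma_e2 = as.numeric(res$sigma2[, 1L]),
    sigma_g2 = as.numeric(res$block_variances[, "a"]),
    g_mean = stats::setNames(g_mean, grm$individual_ids),
    g_sd = stats::setNames(apply(g_draws, 2L, stats::sd),
                           grm$individual_ids),
    g_ci = apply(g_draws, 2L, stats::quantile, probs = c(0.025, 0.975)),
    g_draws = if (sampler$store_g) g_draws else NULL,
    va_draws = va_draws,
    individual_ids = grm$individual_ids,
    exact = res$exact, sampler = sampler),
    class = "animal_fit")
}

#' @export
print.animal_fit <- function(x, ...) {
  va <- estimate_va(x)
  cat(sprintf("animal_fit (GBLUP): V_A %.4f [%.4f, %.4f], sigma2_e %.4f\n",
              va$mean, va$lower, va$upper, mean(x$sigma_e2)))
  invisible(x)
}

# upper-triangular Cholesky with escalating jitter; errors if 1e-4 of the
# mean diagonal is not enough
chol_psd <- function(G) {
  scale <- mean(diag(G))
  for (jit in c(0, 1e-10, 1e-8, 1e-6, 1e-4)) {
    R <- tryCatch(chol(G + diag(jit * scale, nrow(G))),
                  error = function(e) NULL)
    if (!is.null(R)) {
      if (jit > 0)
        message("GRM jittered by ", format(jit * scale), " for Cholesky")
      return(R)
    }
  }
  stop("GRM is not positive semi-definite even after jitter")
}

#' Export / import a GRM as whitespace-delimited text
#'
#' Full-matrix format: a header line of individual ids, then one row per
#' individual.
#'
#' @param grm a [vanraden_grm()] result.
#' @param path output path.
#' @export
write_grm <- function(grm, path) {
  stopifnot(inherits(grm, "grm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(grm$individual_ids, collapse = " "), con)
  utils::write.table(grm$G, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  ids <- strsplit(readLines(path, n = 1L), "\\s+")[[1L]]
  G <- as.matrix(utils::read.table(path, skip = 1L))
  dimnames(G) <- list(ids, ids)
  structure(list(G = G, denominator = "unknown", individual_ids = ids),
            class = "grm")
}
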
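#' Simulate SNP genotypes under Hardy-Weinberg equilibrium
#'
#' Each marker draws an allele frequency uniformly on
#' `[maf_range[1], maf_range[2]]` and genotypes are Binomial(2, p)
#' independently across individuals. With `ld_block_size > 1` the markers
#' are generated in blocks that share a latent column: within a block each
#' derived marker copies the block's seed column and resamples a fraction
#' of individuals, creating local dependence reminiscent of linkage
#' disequilibrium (a crude stand-in, not a genetic map).
#'
#' @param n individuals (>= 2).
#' @param m markers (>= 1).
#' @param maf_range allele-frequency bounds, within (0, 0.5].
#' @param ld_block_size markers per LD block (1 = independent markers).
#' @param ld_resample fraction of individuals resampled per derived marker.
#' @param seed RNG seed.
#' @return An uncentered [genotype_matrix()].
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5),
                               ld_block_size = 1L, ld_resample = 0.1,
                               seed = NULL) {
  stopifnot(n >= 2, m >= 1)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must satisfy 0 < min <= max <= 0.5")
  if (!is.null(seed)) set.seed(seed)
  codes <- matrix(NA_real_, n, m)
  if (ld_block_size <= 1L) {
    p <- stats::runif(m, maf_range[1], maf_range[2])
    for (j in seq_len(m)) codes[, j] <- stats::rbinom(n, 2L, p[j])
  } else {
    j <- 1L
    while (j <= m) {
      p <- stats::runif(1L, maf_range[1], maf_range[2])
      seed_col <- stats::rbinom(n, 2L, p)
      block_end <- min(j + ld_block_size - 1L, m)
      codes[, j] <- seed_col
      for (jj in seq(j + 1L, length.out = block_end - j)) {
        col <- seed_col
        flip <- stats::runif(n) < ld_resample
        col[flip] <- stats::rbinom(sum(flip), 2L, p)
        codes[, jj] <- col
      }
      j <- block_end + 1L
    }
  }
  genotype_matrix(codes, paste0("ind_", seq_len(n)),
                  paste0("snp_", seq_len(m)))
}

#' Simulate SNP effects from the four-component Gaussian mixture
#'
#' Each effect is exactly zero with probability `pi[1]` and otherwise drawn
#' from a zero-mean Gaussian whose variance is `sigma_g2` times the
#' component multiplier (defaults 1e-4, 1e-3, 1e-2): most markers do
#' nothing, a few have small-to-moderate effects, very few are large. This
#' is the classic spike-plus-three-slabs architecture of BayesR-type
#' models.
#'
#' @param m number of markers.
#' @param pi mixture weights (length 4, sums to 1).
#' @param sigma_g2 additive genetic variance scale.
#' @param multipliers per-component variance multipliers (first must be 0).
#' @param seed RNG seed.
#' @return Numeric vector of m SNP effects.
#' @export
simulate_effects <- function(m, pi = c(0.95, 0.04, 0.008, 0.002),
                             sigma_g2 = 0.33,
                             multipliers = c(0, 1e-4, 1e-3, 1e-2),
                             seed = NULL) {
  stopifnot(length(pi) == length(multipliers), all(pi >= 0))
  if (abs(sum(pi) - 1) > 1e-8) stop("mixture weights must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  comp <- sample.int(length(pi), m, replace = TRUE, prob = pi)
  sd_comp <- sqrt(sigma_g2 * multipliers)
  u <- numeric(m)
  nz <- comp > 1L
  u[nz] <- stats::rnorm(sum(nz), 0, sd_comp[comp[nz]])
  u
}

#' Simulate SNP effects from a two-component (spike-and-slab) mixture
#'
#' @param m number of markers.
#' @param pi0 probability of a zero effect (0 <= pi0 < 1).
#' @param tau2 variance of non-zero effects.
#' @param seed RNG seed.
#' @return Numeric vector of m SNP effects.
#' @export
simulate_two_component <- function(m, pi0, tau2, seed = NULL) {
  stopifnot(pi0 >= 0, pi0 < 1, tau2 > 0)
  if (!is.null(seed)) set.seed(seed)
  u <- numeric(m)
  nz <- stats::runif(m) >= pi0
  u[nz] <- stats::rnorm(sum(nz), 0, sqrt(tau2))
  u
}

#' Generate phenotypes from genotypes and SNP effects
#'
#' Breeding values are the raw-dosage linear combination `g = X u`,
#' mean-centered and rescaled so their sample variance (denominator N-1)
#' equals `sigma_g2` EXACTLY; phenotypes add Gaussian residuals of
#' variance `sigma_e2`, giving heritability
#' `sigma_g2 / (sigma_g2 + sigma_e2)` in expectation. Optional machinery:
#'
#' * `fixed_effects`: named list of coefficients; for each entry a binary
#'   covariate is simulated and its effect added (named column in the
#'   phenotype table).
#' * `random_effects`: named list of `list(n_levels, var)`; each adds an
#'   i.i.d. Gaussian group effect with a simulated grouping column.
#' * `repeats = TRUE`: measurement counts per individual follow the
#'   default wild-study profile (about half singletons, a quarter doubles,
#'   the rest 3-5), plus an i.i.d. permanent-environment effect of
#'   variance `pe_var`; the table then has one row per measurement.
#'
#' @param genotypes a raw (uncentered) [genotype_matrix()].
#' @param u SNP-effect vector (length m).
#' @param sigma_g2 target additive genetic variance (exact after
#'   rescaling).
#' @param sigma_e2 residual variance.
#' @param fixed_effects,random_effects see above.
#' @param repeats logical; repeated measurements per individual.
#' @param pe_var permanent-environment variance when `repeats = TRUE`.
#' @param seed RNG seed.
#' @return A list: `pheno` (data.frame of id, y and covariates) and
#'   `truth` (class `sim_truth`: `u`, `g`, `scale` applied to u,
#'   `sigma_g2`, `sigma_e2`, `h2`, `seed`).
#' @export
simulate_phenotypes <- function(genotypes, u, sigma_g2 = 0.33,
                                sigma_e2 = 0.67, fixed_effects = NULL,
                                random_effects = NULL, repeats = FALSE,
                                pe_var = 0.1, seed = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (genotypes$centered)
    stop("simulate_phenotypes() expects raw dosages (uncentered)")
  if (length(u) != ncol(genotypes$codes))
    stop("length(u) must equal the number of markers")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genotypes$codes)
  g_raw <- as.numeric(genotypes$codes %*% u)
  g_c <- g_raw - mean(g_raw)
  v <- sum(g_c^2) / (n - 1)
  if (v <= 0)
    stop("breeding values have zero variance (all SNP effects zero?); ",
         "cannot rescale to sigma_g2 > 0")
  scl <- sqrt(sigma_g2 / v)
  g <- g_c * scl

  ids <- genotypes$individual_ids
  if (repeats) {
    n_meas <- sample(c(1L, 2L, 3L, 4L, 5L), n, replace = TRUE,
                     prob = c(0.5, 0.25, 0.15, 0.07, 0.03))
    obs_id <- rep(seq_len(n), n_meas)
  } else {
    obs_id <- seq_len(n)
  }
  n_obs <- length(obs_id)
  y <- g[obs_id]
  df <- data.frame(id = ids[obs_id], stringsAsFactors = FALSE)

  if (repeats && pe_var > 0) {
    pe <- stats::rnorm(n, 0, sqrt(pe_var))
    y <- y + pe[obs_id]
  }
  for (nm in names(fixed_effects)) {
    x <- stats::rbinom(n_obs, 1L, 0.5)
    y <- y + fixed_effects[[nm]] * x
    df[[nm]] <- x
  }
  for (nm in names(random_effects)) {
    re <- random_effects[[nm]]
    lev <- sample.int(re$n_levels, n_obs, replace = TRUE)
    eff <- stats::rnorm(re$n_levels, 0, sqrt(re$var))
    y <- y + eff[lev]
    df[[nm]] <- paste0(nm, "_", lev)
  }
  y <- y + stats::rnorm(n_obs, 0, sqrt(sigma_e2))
  df$y <- y
  truth <- structure(list(u = u * scl, g = stats::setNames(g, ids),
                          scale = scl, sigma_g2 = sigma_g2,
                          sigma_e2 = sigma_e2,
                          h2 = sigma_g2 / (sigma_g2 + sigma_e2),
                          seed = seed),
                     class = "sim_truth")
  list(pheno = df, truth = truth)
}

#' One-call simulation of a complete data set
#'
#' Genotypes, four-component-mixture SNP effects and phenotypes in one
#' step, with the genotype matrix returned both raw and centered and the
#' PC basis optionally precomputed. The defaults are the reference study
#' conditions: mixture weights (0.95, 0.04, 0.008, 0.002), component
#' variance multipliers (0, 1e-4, 1e-3, 1e-2), `sigma_g2 = 0.33`,
#' `sigma_e2 = 0.67`, heritability 0.33.
#'
#' @param n,m individuals and markers.
#' @param pi mixture weights.
#' @param sigma_g2,sigma_e2 variance components.
#' @param maf_range allele-frequency bounds.
#' @param compute_pcs also run [compute_basis()] on the centered matrix.
#' @param seed RNG seed (drives genotypes, effects and residuals).
#' @param ... passed to [simulate_phenotypes()].
#' @return List: `genotypes` (raw), `centered`, `basis` (or `NULL`),
#'   `pheno`, `truth`.
#' @export
simulate_dataset <- function(n, m, pi = c(0.95, 0.04, 0.008, 0.002),
                             sigma_g2 = 0.33, sigma_e2 = 0.67,
                             maf_range = c(0.05, 0.5),
                             compute_pcs = TRUE, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  geno <- simulate_genotypes(n, m, maf_range)
  u <- simulate_effects(m, pi, sigma_g2)
  # a draw with no causal markers cannot be rescaled; redraw (vanishingly
  # rare except at tiny m)
  tries <- 0L
  while (all(u == 0) && tries < 100L) {
    u <- simulate_effects(m, pi, sigma_g2)
    tries <- tries + 1L
  }
  sim <- simulate_phenotypes(geno, u, sigma_g2, sigma_e2, ...)
  centered <- center_columns(geno)
  list(genotypes = geno, centered = centered,
       basis = if (compute_pcs) compute_basis(centered) else NULL,
       pheno = sim$pheno, truth = sim$truth)
}

#' Write simulation truth to CSV
#'
#' @param truth a `sim_truth`.
#' @param dir output directory; writes `truth_effects.csv` (marker
#'   effects), `truth_bv.csv` (breeding values) and
#'   `truth_variances.json`.
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(effect = truth$u),
                   file.path(dir, "truth_effects.csv"), row.names = FALSE)
  utils::write.csv(data.frame(id = names(truth$g), g = truth$g),
                   file.path(dir, "truth_bv.csv"), row.names = FALSE)
  jsonlite::write_json(list(sigma_g2 = truth$sigma_g2,
                            sigma_e2 = truth$sigma_e2, h2 = truth$h2),
                       file.path(dir, "truth_variances.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
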
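test_that("GRM matches the brute-force double loop on a hand fixture", {
  set.seed(31)
  codes <- matrix(rbinom(5 * 8, 2, 0.4), 5, 8)
  codes[1, 1] <- 2  # ensure polymorphism
  g <- center_columns(genotype_matrix(codes))
  Z <- g$codes
  for (den in c("empirical", "expected")) {
    grm <- vanraden_grm(g, den)
    d <- if (den == "empirical") sum(Z^2) / (nrow(Z) - 1)
         else 2 * sum((g$column_means / 2) * (1 - g$column_means / 2))
    oracle <- matrix(NA_real_, 5, 5)
    for (i in 1:5) for (j in 1:5)
      oracle[i, j] <- sum(Z[i, ] * Z[j, ]) / d
    expect_equal(unname(grm$G), oracle, tolerance = 1e-12)
    expect_equal(grm$G, t(grm$G))
  }
})

test_that("empirical GRM trace identity holds by construction", {
  sim <- small_sim(n = 40, m = 200, seed = 32)
  grm <- vanraden_grm(sim$centered, "empirical")
  # trace(G) = N - 1 exactly, hence mean diagonal = (N-1)/N ~ 1
  expect_equal(sum(diag(grm$G)), 39, tolerance = 1e-12)
  expect_equal(mean(diag(grm$G)), 1, tolerance = 1 / 40 + 1e-12)
})

test_that("duplicated genomes give off-diagonals equal to diagonals", {
  set.seed(33)
  codes <- matrix(rbinom(4 * 50, 2, 0.3), 4, 50)
  codes <- rbind(codes, codes[1, ])
  g <- center_columns(genotype_matrix(codes))
  grm <- vanraden_grm(g)
  expect_equal(grm$G[1, 5], grm$G[1, 1], tolerance = 1e-12)
  expect_equal(grm$G[5, 5], grm$G[1, 1], tolerance = 1e-12)
})

test_that("GRM is invariant to marker order and to monomorphic markers", {
  sim <- small_sim(n = 25, m = 60, seed = 34)
  g <- sim$centered
  grm <- vanraden_grm(g, "expected")
  perm <- sample(60)
  g2 <- g; g2$codes <- g$codes[, perm]
  g2$marker_ids <- g$marker_ids[perm]
  g2$column_means <- g$column_means[perm]
  expect_equal(vanraden_grm(g2, "expected")$G, grm$G, tolerance = 1e-12)
  # appending a monomorphic marker changes nothing (centered column is 0,
  # and p(1-p) = 0 adds nothing to the expected denominator)
  g3 <- g
  g3$codes <- cbind(g$codes, 0)
  g3$marker_ids <- c(g$marker_ids, "mono")
  g3$column_means <- c(g$column_means, 2)
  expect_equal(vanraden_grm(g3, "expected")$G, grm$G, tolerance = 1e-12)
})

test_that("identity GRM reduces the animal model to iid effects (REML oracle)", {
  set.seed(35)
  n <- 50
  sig_g <- 0.5; sig_e <- 0.5
  gi <- rnorm(n, 0, sqrt(sig_g))
  ids <- paste0("i", 1:n)
  # three measurements per individual so both components are identifiable
  pheno <- data.frame(id = rep(ids, each = 3),
                      y = 2 + rep(gi, each = 3) +
                        rnorm(3 * n, 0, sqrt(sig_e)))
  grm <- structure(list(G = diag(n), denominator = "identity",
                        individual_ids = ids), class = "grm")
  frame <- model_frame(pheno, "y", grm)
  fit <- fit_animal_model(frame, grm, prior_spec("default"),
                          sampler_config(n_iter = 3000, burnin = 1000,
                                         seed = 36))
  # independent oracle: REML via lme4 on the equivalent iid-effect model
  oracle <- lme4::lmer(y ~ 1 + (1 | id), data = pheno, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(oracle))
  expect_lt(abs(mean(fit$sigma_g2) - vc$vcov[1]), 0.25)
  expect_lt(abs(mean(fit$sigma_e2) - vc$vcov[2]), 0.25)
})

test_that("full-rank fixed-prior ridge predictions equal GBLUP", {
  sim <- small_sim(n = 80, m = 250, seed = 37)
  frame <- model_frame(sim$pheno, "y", sim$basis)
  pr <- prior_spec("fixed", sigma_g2 = 0.33, resid_fixed = 0.67)
  fit <- fit_bpcrr(frame, sim$basis, pr,
                   sampler = sampler_config(n_iter = 20, seed = 38))
  grm <- vanraden_grm(sim$centered, "empirical")
  fra <- model_frame(sim$pheno, "y", grm)
  fita <- fit_animal_model(fra, grm, pr, sampler_config(n_iter = 20,
                                                        seed = 39))
  expect_true(fit$exact && fita$exact)
  expect_lt(max(abs(fit$g_mean - fita$g_mean)), 1e-6)
})

test_that("animal model recovers simulated variance components", {
  sim <- small_sim(n = 200, m = 500, seed = 40)
  grm <- vanraden_grm(sim$centered, "empirical")
  frame <- model_frame(sim$pheno, "y", grm)
  fit <- fit_animal_model(frame, grm, prior_spec("default"),
                          sampler_config(n_iter = 2000, burnin = 500,
                                         seed = 41))
  expect_lt(abs(mean(fit$sigma_g2) - 0.33), 0.2)
  expect_lt(abs(mean(fit$sigma_e2) - 0.67), 0.2)
})

test_that("GRM round-trips through the whitespace text format", {
  sim <- small_sim(n = 15, m = 40, seed = 42)
  grm <- vanraden_grm(sim$centered)
  path <- withr::local_tempfile(fileext = ".txt")
  write_grm(grm, path)
  grm2 <- read_grm(path)
  expect_equal(unname(grm2$G), unname(grm$G), tolerance = 1e-10)
  expect_identical(grm2$individual_ids, grm$individual_ids)
})
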
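test_that("prior_variance divides the genetic variance by total PC variance", {
  expect_equal(prior_variance(0.33, rep(1, 10) * c(1)), 0.033)
  expect_equal(prior_variance(0.5, 1), 0.5)  # single PC of variance 1
  set.seed(2)
  for (i in 1:5) {
    v <- runif(sample(3:20, 1))
    s <- runif(1, 0.1, 2)
    expect_equal(prior_variance(s, v), s / sum(v))
  }
  expect_error(prior_variance(0.3, numeric(0)), "empty")
  expect_error(prior_variance(-1, 1), "sigma_g2")
})

test_that("exact fixed-variance posterior equals the generalized ridge oracle", {
  sim <- small_sim(n = 60, m = 150, seed = 21)
  frame <- model_frame(sim$pheno, "y", sim$basis)
  k <- 25L
  su2 <- prior_variance(0.33, pc_variances(sim$basis, k))
  se2 <- 0.67
  fit <- fit_bpcrr(frame, sim$basis,
                   prior_spec("fixed", sigma_u2 = su2, resid_fixed = se2),
                   k = k, sampler = sampler_config(n_iter = 500, seed = 1))
  expect_true(fit$exact)
  # independent dense penalized least-squares solve
  C <- cbind(1, sim$basis$scaled_scores[frame$individual_index, 1:k])
  pen <- diag(c(se2 / 1e4, rep(se2 / su2, k)))
  theta <- solve(crossprod(C) + pen, crossprod(C, frame$y))
  g_oracle <- sim$basis$scaled_scores[, 1:k] %*% theta[-1]
  expect_equal(unname(fit$g_mean), as.numeric(g_oracle), tolerance = 1e-8)
})

test_that("dense and diagonal coefficient updates agree", {
  # same model solved with and without the orthogonal-design fast path:
  # permuting observations breaks nothing, but appending a duplicate
  # observation row makes the cross-product non-diagonal
  sim <- small_sim(n = 50, m = 100, seed = 22)
  frame <- model_frame(sim$pheno, "y", sim$basis)
  pr <- prior_spec("fixed", sigma_g2 = 0.33, resid_fixed = 0.67)
  fit1 <- fit_bpcrr(frame, sim$basis, pr, k = 15L,
                    sampler = sampler_config(n_iter = 10, seed = 3))
  pheno2 <- sim$pheno[c(seq_len(50), 1L), ]  # repeat one measurement
  frame2 <- model_frame(pheno2, "y", sim$basis)
  fit2 <- fit_bpcrr(frame2, sim$basis, pr, k = 15L,
                    sampler = sampler_config(n_iter = 10, seed = 3))
  expect_true(fit1$diag_path)
  expect_false(fit2$diag_path)
  # oracle check of the non-diagonal solve
  C <- cbind(1, sim$basis$scaled_scores[frame2$individual_index, 1:15])
  su2 <- prior_variance(0.33, pc_variances(sim$basis, 15L))
  theta <- solve(crossprod(C) + diag(c(0.67 / 1e4, rep(0.67 / su2, 15))),
                 crossprod(C, frame2$y))
  g_oracle <- sim$basis$scaled_scores[, 1:15] %*% theta[-1]
  expect_equal(unname(fit2$g_mean), as.numeric(g_oracle), tolerance = 1e-8)
})

test_that("a constant response yields null PC effects and V_A near zero", {
  sim <- small_sim(n = 40, m = 80, seed = 23)
  pheno <- sim$pheno
  pheno$y <- 5
  frame <- model_frame(pheno, "y", sim$basis)
  fit <- fit_bpcrr(frame, sim$basis, prior_spec("default"),
                   sampler = sampler_config(n_iter = 1000, burnin = 200,
                                            seed = 4))
  expect_lt(max(abs(colMeans(fit$u))), 0.05)
  expect_lt(estimate_va(fit)$mean, 0.01)
})

test_that("V_A draw identities hold for degenerate posteriors", {
  sim <- small_sim(n = 30, m = 60, seed = 24)
  frame <- model_frame(sim$pheno, "y", sim$basis)
  fit <- fit_bpcrr(frame, sim$basis,
                   prior_spec("fixed", sigma_g2 = 0.33, resid_fixed = 0.67),
                   k = 1L, sampler = sampler_config(n_iter = 200, seed = 5))
  # single PC: V_A draw = u1^2 * var(PC1) for every draw
  v1 <- var(sim$basis$scaled_scores[, 1])
  expect_equal(fit$va_draws, as.numeric(fit$u[, 1]^2 * v1),
               tolerance = 1e-10)
  # all-zero draws give V_A = 0
  fit$u[] <- 0
  g0 <- fit$u %*% t(sim$basis$scaled_scores[, 1, drop = FALSE])
  expect_equal(sum(apply(g0, 1, var)), 0)
})

test_that("summary means track draw means and g has one entry per individual", {
  sim <- small_sim(n = 45, m = 90, seed = 25, repeats = TRUE)
  pheno <- sim$pheno
  frame <- model_frame(pheno, "y", sim$basis, random = "id")
  fit <- fit_bpcrr(frame, sim$basis, prior_spec("fixed", sigma_g2 = 0.33),
                   k = 20L,
                   sampler = sampler_config(n_iter = 2000, burnin = 500,
                                            seed = 6))
  expect_length(fit$g_mean, 45L)          # individuals, not measurements
  expect_gt(nrow(pheno), 45L)             # repeats present
  expect_equal(unname(fit$g_mean), unname(colMeans(fit$g_draws)),
               tolerance = 1e-8)
  expect_equal(mean(fit$va_draws), estimate_va(fit)$mean)
})

test_that("identical seed and config give bit-identical draws", {
  sim <- small_sim(n = 30, m = 60, seed = 26)
  frame <- model_frame(sim$pheno, "y", sim$basis)
  f1 <- fit_bpcrr(frame, sim$basis, prior_spec("default"),
                  sampler = sampler_config(n_iter = 300, burnin = 100,
                                           seed = 7))
  f2 <- fit_bpcrr(frame, sim$basis, prior_spec("default"),
                  sampler = sampler_config(n_iter = 300, burnin = 100,
                                           seed = 7))
  expect_identical(f1$u, f2$u)
  expect_identical(f1$sigma_e2, f2$sigma_e2)
  expect_identical(f1$sigma_u2, f2$sigma_u2)
})

test_that("predictions for training individuals equal the stored breeding values", {
  sim <- small_sim(n = 30, m = 60, seed = 27)
  frame <- model_frame(sim$pheno, "y", sim$basis)
  fit <- fit_bpcrr(frame, sim$basis, prior_spec("fixed", sigma_g2 = 0.33),
                   k = 10L, sampler = sampler_config(n_iter = 300,
                                                     burnin = 100, seed = 8))
  pred <- predict_bv(fit, sim$basis, sim$centered)
  g_from_umean <- as.numeric(sim$basis$scaled_scores[, 1:10] %*%
                               colMeans(fit$u))
  expect_equal(unname(pred), g_from_umean, tolerance = 1e-10)
  # zero posterior mean -> zero predictions
  fit$u[] <- 0
  expect_equal(unname(predict_bv(fit, sim$basis, sim$centered)),
               rep(0, 30))
})

test_that("fixed effects and random terms are recovered in the joint model", {
  sim <- small_sim(n = 150, m = 200, seed = 28,
                   fixed_effects = list(sex = 1.5),
                   random_effects = list(grp = list(n_levels = 8,
                                                    var = 0.3)))
  frame <- model_frame(sim$pheno, "y", sim$basis, fixed = "sex",
                       random = "grp")
  fit <- fit_bpcrr(frame, sim$basis, prior_spec("fixed", sigma_g2 = 0.33),
                   k = 50L,
                   sampler = sampler_config(n_iter = 1500, burnin = 500,
                                            seed = 9))
  b_sex <- mean(fit$b[, "sex"])
  expect_lt(abs(b_sex - 1.5), 0.35)
  expect_true("grp" %in% colnames(fit$ranef_var))
})

test_that("posterior V_A is nondecreasing in k on a fixed dataset", {
  sim <- small_sim(n = 150, m = 400, seed = 29)
  frame <- model_frame(sim$pheno, "y", sim$basis)
  vas <- vapply(c(10L, 40L, 100L, 149L), function(k) {
    fit <- fit_bpcrr(frame, sim$basis,
                     prior_spec("fixed", sigma_g2 = 0.33), k = k,
                     sampler = sampler_config(n_iter = 1000, burnin = 300,
                                              seed = 10))
    estimate_va(fit)$mean
  }, numeric(1))
  expect_true(all(diff(vas) >= -0.02))
})
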
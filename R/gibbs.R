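# Blocked Gibbs sampler for the Gaussian linear mixed model
#
#   y = C theta + eps,  eps ~ N(0, se2 I)
#
# with theta partitioned into blocks, each block b having an exchangeable
# N(0, s2_b I) prior. Block variances are either held fixed or given
# conjugate inverse-gamma priors (equivalently Gamma priors on the
# precision), so the full conditionals are:
#   theta | . ~ N(A^-1 C'y / se2, A^-1),  A = C'C/se2 + Dinv
#   se2   | . ~ IG(a + n/2, b + rss/2)
#   s2_b  | . ~ IG(a_b + q_b/2, b_b + ||theta_b||^2/2)
#
# When all variances are fixed the model is a plain Gaussian posterior and
# is handled exactly (single solve + independent draws).
#
# When C'C is numerically diagonal -- which it is for an intercept plus
# orthogonal scaled PC scores with one observation per individual -- the
# joint update factorizes coefficient-wise and is done in O(d) per sweep
# instead of a dense Cholesky.
#
# Funnel geometry: when one block is high-dimensional relative to n (PC
# effects with k close to N, or a genetic effect with one level per
# individual), the pair (theta_b, s2_b) -- and with it se2 -- mixes
# arbitrarily slowly under one-at-a-time conjugate updates: small s2_b
# shrinks theta_b, which keeps s2_b small. For a block flagged `collapse`
# the sampler therefore updates (s2_b, se2) from their PARTIALLY COLLAPSED
# conditional p(s2_b, se2 | y, other blocks) with theta_b integrated out
# analytically (one SVD of the block design, precomputed; O(n) per density
# evaluation), via univariate slice sampling on the log scale. The
# coefficients are then redrawn from their full conditional at the start
# of the next sweep, which keeps the chain's stationary distribution
# intact (partially collapsed Gibbs with marginalized components redrawn
# before reuse).

new_block <- function(name, M, var_type = c("fixed", "ig"),
                      value = NA_real_, shape = 0.01, rate = 0.01,
                      collapse = FALSE) {
  var_type <- match.arg(var_type)
  if (var_type == "fixed" && (!is.finite(value) || value <= 0))
    stop("block '", name, "': fixed variance must be a positive number")
  list(name = name, M = as.matrix(M), q = ncol(M), var_type = var_type,
       value = value, shape = shape, rate = rate, collapse = collapse)
}

# univariate slice sampler (Neal 2003, stepping out + shrinkage)
slice_sample1 <- function(x0, logf, w = 1, max_steps = 50L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) return(x0)
  z <- f0 - stats::rexp(1L)
  lo <- x0 - stats::runif(1L) * w
  hi <- lo + w
  for (i in seq_len(max_steps)) {
    if (logf(lo) <= z) break
    lo <- lo - w
  }
  for (i in seq_len(max_steps)) {
    if (logf(hi) <= z) break
    hi <- hi + w
  }
  repeat {
    x1 <- stats::runif(1L, lo, hi)
    if (logf(x1) >= z) return(x1)
    if (x1 < x0) lo <- x1 else hi <- x1
  }
}

gibbs_lmm <- function(y, blocks,
                      resid = list(type = "ig", shape = 0.01, rate = 0.01,
                                   value = NA_real_),
                      n_iter = 4000L, burnin = 1000L, thin = 1L,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("non-finite values in the response")
  n <- length(y)
  C <- do.call(cbind, lapply(blocks, `[[`, "M"))
  d <- ncol(C)
  q <- vapply(blocks, `[[`, integer(1), "q")
  block_of <- rep(seq_along(blocks), q)
  idx <- split(seq_len(d), block_of)

  CtC <- crossprod(C)
  Cty <- crossprod(C, y)[, 1L]
  diagC <- diag(CtC)
  offmax <- max(abs(CtC - diag(diagC, d)))
  diag_path <- offmax < 1e-8 * max(diagC, 1)

  all_fixed <- all(vapply(blocks, `[[`, character(1), "var_type") == "fixed") &&
    resid$type == "fixed"

  col_b <- which(vapply(blocks, function(b) isTRUE(b$collapse), logical(1)))
  if (length(col_b) > 1L)
    stop("at most one block can be collapsed")
  do_collapse <- length(col_b) == 1L && !all_fixed &&
    (blocks[[col_b]]$var_type == "ig" || resid$type == "ig")
  if (do_collapse) {
    sv <- svd(blocks[[col_b]]$M, nv = 0L)
    keepc <- sv$d > max(dim(blocks[[col_b]]$M)) * .Machine$double.eps * sv$d[1L]
    Acol <- sv$u[, keepc, drop = FALSE]
    delta2 <- sv$d[keepc]^2
    r_rank <- sum(keepc)
  }

  s2 <- vapply(blocks, function(b)
    if (b$var_type == "fixed") b$value else max(stats::var(y) / 2, 1e-4),
    numeric(1))
  se2 <- if (resid$type == "fixed") resid$value else max(stats::var(y) / 2, 1e-4)
  if (!is.finite(se2) || se2 <= 0) se2 <- 1

  draw_theta <- function(se2, dinv) {
    if (diag_path) {
      a <- diagC / se2 + dinv
      mu <- (Cty / se2) / a
      list(theta = mu + stats::rnorm(d) / sqrt(a), mu = mu,
           sd = 1 / sqrt(a))
    } else {
      A <- CtC / se2
      diag(A) <- diag(A) + dinv
      R <- chol(A)
      mu <- backsolve(R, backsolve(R, Cty / se2, transpose = TRUE))
      list(theta = mu + backsolve(R, stats::rnorm(d)), mu = mu, R = R)
    }
  }

  if (all_fixed) {
    # exact Gaussian posterior: analytic mean, independent draws
    dinv <- rep(1 / s2, q)
    upd <- draw_theta(se2, dinv)
    n_keep <- max(n_iter, 1L)
    theta_draws <- matrix(NA_real_, n_keep, d)
    for (i in seq_len(n_keep)) {
      theta_draws[i, ] <- if (diag_path)
        upd$mu + stats::rnorm(d) * upd$sd
      else upd$mu + backsolve(upd$R, stats::rnorm(d))
    }
    colnames(theta_draws) <- colnames(C)
    return(list(theta = theta_draws, theta_mean_exact = upd$mu,
                sigma2 = matrix(se2, n_keep, 1L,
                                dimnames = list(NULL, "residual")),
                block_variances = matrix(
                  rep(s2, each = n_keep), n_keep, length(blocks),
                  dimnames = list(NULL, vapply(blocks, `[[`, character(1),
                                               "name"))),
                idx = idx, exact = TRUE, diag_path = diag_path))
  }

  n_keep <- floor(n_iter / thin)
  theta_draws <- matrix(NA_real_, n_keep, d)
  colnames(theta_draws) <- colnames(C)
  se2_draws <- numeric(n_keep)
  s2_draws <- matrix(NA_real_, n_keep, length(blocks))
  colnames(s2_draws) <- vapply(blocks, `[[`, character(1), "name")

  theta <- numeric(d)
  kept <- 0L
  total <- burnin + n_iter
  for (it in seq_len(total)) {
    dinv <- rep(1 / s2, q)
    theta <- draw_theta(se2, dinv)$theta
    resid_vec <- y - as.numeric(C %*% theta)
    rss <- sum(resid_vec^2)

    # conjugate variance updates for non-collapsed components
    if (resid$type == "ig" && !do_collapse)
      se2 <- 1 / stats::rgamma(1L, shape = resid$shape + n / 2,
                               rate = resid$rate + rss / 2)
    for (b in seq_along(blocks)) {
      if (blocks[[b]]$var_type == "ig" &&
          !(do_collapse && b == col_b)) {
        ss <- sum(theta[idx[[b]]]^2)
        s2[b] <- 1 / stats::rgamma(1L, shape = blocks[[b]]$shape + q[b] / 2,
                                   rate = blocks[[b]]$rate + ss / 2)
      }
    }

    if (do_collapse) {
      # residual of everything except the collapsed block
      r <- y - as.numeric(C[, -idx[[col_b]], drop = FALSE] %*%
                            theta[-idx[[col_b]]])
      t_coord <- crossprod(Acol, r)[, 1L]
      rem <- sum(r^2) - sum(t_coord^2)
      bsh <- blocks[[col_b]]$shape; brt <- blocks[[col_b]]$rate
      logpost <- function(su2, sev2) {
        v <- su2 * delta2 + sev2
        ll <- -0.5 * (sum(t_coord^2 / v) + sum(log(v)) +
                        rem / sev2 + (n - r_rank) * log(sev2))
        # log-scale parameterization: IG(a,b) density + Jacobian
        if (blocks[[col_b]]$var_type == "ig")
          ll <- ll - bsh * log(su2) - brt / su2
        if (resid$type == "ig")
          ll <- ll - resid$shape * log(sev2) - resid$rate / sev2
        ll
      }
      su2 <- s2[col_b]
      for (rep2 in 1:2) {
        if (blocks[[col_b]]$var_type == "ig")
          su2 <- exp(slice_sample1(log(su2), function(l)
            logpost(exp(l), se2)))
        if (resid$type == "ig")
          se2 <- exp(slice_sample1(log(se2), function(l)
            logpost(su2, exp(l))))
      }
      s2[col_b] <- su2
    }

    if (it > burnin && (it - burnin) %% thin == 0L) {
      kept <- kept + 1L
      theta_draws[kept, ] <- theta
      se2_draws[kept] <- se2
      s2_draws[kept, ] <- s2
    }
  }
  list(theta = theta_draws,
       sigma2 = matrix(se2_draws, ncol = 1L,
                       dimnames = list(NULL, "residual")),
       block_variances = s2_draws, idx = idx,
       exact = FALSE, diag_path = diag_path)
}

# split-half potential scale reduction on a single chain of draws
split_rhat <- function(x) {
  n <- length(x)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  chains <- list(x[seq_len(half)], x[(n - half + 1L):n])
  m <- vapply(chains, mean, numeric(1))
  v <- vapply(chains, stats::var, numeric(1))
  W <- mean(v)
  B <- half * stats::var(m)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}
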
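test_that("sampler recovers an analytic 5-D Gaussian target", {
  mu <- c(1.5, 1.5, 0.4, 0.2, 2.0)   # inside every prior support
  sdv <- c(0.5, 0.2, 0.08, 0.04, 0.3)
  # target expressed on the sampler's parameter space; support bounds of the
  # default priors comfortably contain mu +/- 6 sd
  lt <- function(theta) sum(dnorm(theta, mu, sdv, log = TRUE))
  cfg <- sampler_config(n_iter = 3000, burn_in = 1500, seed = 99)
  ch <- run_demc(NULL, NULL, cfg, log_target = lt)
  x <- ch$samples[, 1501:3000, ]
  for (j in 1:5) {
    draws <- as.vector(x[, , j])
    n_eff <- 200  # conservative effective sample size for correlated draws
    mc_se <- sdv[j] / sqrt(n_eff)
    expect_lt(abs(mean(draws) - mu[j]), 3 * mc_se)
    # detailed-balance smoke test: marginal spread matches the target
    expect_lt(abs(sd(draws) - sdv[j]) / sdv[j], 0.25)
  }
})

test_that("sampling is deterministic under the config seed", {
  p <- ddm_params(v = 4.098, a = 1.0, t0 = 0.347, st0 = 0.15, sv = 0.8)
  tr <- generate_trials(p, 80, seed = 2)
  ok <- tr$response != "none"
  cfg <- sampler_config(n_iter = 120, burn_in = 60, seed = 4)
  ch1 <- run_demc(tr$rt[ok], tr$response[ok] == "correct", cfg)
  ch2 <- run_demc(tr$rt[ok], tr$response[ok] == "correct", cfg)
  expect_identical(ch1$samples, ch2$samples)
  expect_identical(ch1$accepted, ch2$accepted)
})

test_that("retained samples respect the prior supports", {
  p <- ddm_params(v = 4.098, a = 1.0, t0 = 0.347, st0 = 0.15, sv = 0.8)
  tr <- generate_trials(p, 80, seed = 3)
  ok <- tr$response != "none"
  cfg <- sampler_config(n_iter = 300, burn_in = 150, seed = 8)
  ch <- run_demc(tr$rt[ok], tr$response[ok] == "correct", cfg)
  x <- ch$samples
  expect_true(all(x[, , "a"] > 0.2 & x[, , "a"] < 5))
  expect_true(all(x[, , "t0"] - x[, , "st0"] / 2 > 0.05))
  expect_true(all(x[, , "sv"] >= 0))
  expect_error(run_demc(tr$rt[1:10], rep(TRUE, 10), cfg), "too few")
})

test_that("single-boundary data are flagged as degenerate", {
  p <- ddm_params(v = 8, a = 2, t0 = 0.3)
  tr <- generate_trials(p, 60, seed = 12)
  ch <- run_demc(tr$rt, rep(TRUE, nrow(tr)),
                 sampler_config(n_iter = 60, burn_in = 30, seed = 1))
  expect_true(ch$degenerate)
})

test_that("MPSF: identical chains give 1, an offset chain exceeds the criterion", {
  set.seed(77)
  one <- matrix(rnorm(500 * 3), 500, 3)
  x <- array(NA_real_, c(4, 500, 3))
  for (k in 1:4) x[k, , ] <- one
  rep1 <- compute_mpsf(x)
  expect_equal(rep1$mpsf, 1.0, tolerance = 1e-6)
  expect_true(rep1$converged)
  x[4, , 1] <- x[4, , 1] + 5
  rep2 <- compute_mpsf(x)
  expect_gt(rep2$mpsf, 1.15)
  expect_false(rep2$converged)
})

test_that("MPSF reduces to the univariate PSRF for one parameter and is affine-invariant", {
  set.seed(101)
  x <- array(rnorm(6 * 400), c(6, 400, 1))
  x[2, , 1] <- x[2, , 1] + 0.4
  rep1 <- compute_mpsf(x)
  expect_equal(rep1$mpsf, unname(rep1$psrf[1]), tolerance = 1e-10)
  # affine reparameterization applied to all chains leaves MPSF unchanged
  set.seed(102)
  y <- array(rnorm(5 * 300 * 3), c(5, 300, 3))
  y[1, , ] <- y[1, , ] + 0.3
  A <- matrix(c(2, 0.5, 0, 0.1, -1, 0.2, 0, 0.3, 4), 3, 3)
  b <- c(10, -5, 3)
  yt <- y
  for (k in 1:5) yt[k, , ] <- sweep(matrix(y[k, , ], 300, 3) %*% t(A), 2,
                                    -b)
  expect_equal(compute_mpsf(yt)$mpsf, compute_mpsf(y)$mpsf,
               tolerance = 1e-8)
})

test_that("point estimates are pooled posterior means", {
  x <- array(2.5, c(3, 40, 5))
  dimnames(x) <- list(NULL, NULL, c("v", "a", "t0", "st0", "sv"))
  x[, , "a"] <- 1.2
  x[, , "t0"] <- 0.3
  x[, , "st0"] <- 0.1
  x[, , "sv"] <- 0.5
  ch <- structure(list(samples = x, burn_in = 20), class = "chain_set")
  # constant chains: estimate equals the constant; convergence check skipped
  est <- point_estimates(ch, check_convergence = FALSE)
  expect_equal(est$v, 2.5)
  expect_equal(est$a, 1.2)
  # pooled mean equals mean of per-chain means for equal-length chains
  set.seed(55)
  x2 <- array(rnorm(3 * 40 * 5, mean = 2, sd = 0.2), c(3, 40, 5))
  dimnames(x2) <- dimnames(x)
  x2[, , "t0"] <- abs(x2[, , "t0"]) / 4 + 0.2
  x2[, , "st0"] <- abs(x2[, , "st0"]) / 10
  ch2 <- structure(list(samples = x2, burn_in = 0), class = "chain_set")
  est2 <- suppressWarnings(point_estimates(ch2, check_convergence = FALSE))
  per_chain <- apply(x2[, , "v"], 1, mean)
  expect_equal(est2$v, mean(per_chain), tolerance = 1e-12)
})
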
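test_that("log-likelihood and error function satisfy their identities", {
  m <- model_predict("logistic", c(lam = 1, Rmax = 300), grid21)
  d <- dataset(grid21, m, 20)
  ## zero residual: ell = -n log(sigma sqrt(2 pi))
  expect_equal(log_likelihood(d, "logistic", c(lam = 1, Rmax = 300)),
               -22 * log(20 * sqrt(2 * pi)))
  expect_equal(sse(d, "logistic", c(lam = 1, Rmax = 300)), 0)
  ## one observation, residual of one sigma
  d1 <- dataset(5, logistic_oracle(1, 300, 10, 5) + 20, 20)
  expect_equal(log_likelihood(d1, "logistic", c(lam = 1, Rmax = 300)),
               -log(20 * sqrt(2 * pi)) - 0.5)
  ## Pythagorean residuals
  y <- m; y[3] <- y[3] + 3; y[7] <- y[7] - 4
  expect_equal(sse(dataset(grid21, y, 20), "logistic",
                   c(lam = 1, Rmax = 300)), 25)
  ## identity -2 sigma^2 (ell + n log(sigma sqrt(2 pi))) = sse, random data
  set.seed(42)
  yr <- m + rnorm(22, 0, 15)
  dr <- dataset(grid21, yr, 15)
  p <- c(lam = 1.3, Rmax = 280)
  expect_equal(-2 * 15^2 * (log_likelihood(dr, "logistic", p) +
                              22 * log(15 * sqrt(2 * pi))),
               sse(dr, "logistic", p), tolerance = 1e-10)
  ## monotone in a single growing residual
  lls <- sapply(c(1, 5, 25), function(r)
    log_likelihood(dataset(5, logistic_oracle(1, 300, 10, 5) + r, 20),
                   "logistic", c(lam = 1, Rmax = 300)))
  expect_true(all(diff(lls) < 0))
  ## unsolvable parameters give -Inf with a warning
  expect_warning(
    ll <- log_likelihood(d, "richards", c(lam = 1, Rmax = 300, beta = -1)),
    "solver")
  expect_identical(ll, -Inf)
})

test_that("MLE recovers generating parameters from noise-free data", {
  d <- noise_free_data("logistic", c(lam = 1, Rmax = 300))
  f <- fit_mle(d, "logistic")
  expect_lt(max(abs(f$p_hat / c(lam = 1, Rmax = 300) - 1)), 1e-3)
  expect_gte(f$loglik, log_likelihood(d, "logistic", c(lam = 1, Rmax = 300)) - 1e-6)
  expect_equal(f$aic, 2 * f$k - 2 * f$loglik)
  f5 <- fit_mle(noise_free_data("radial_death", radial_death_params()),
                "radial_death")
  expect_lt(max(abs(f5$p_hat / radial_death_params() - 1)), 0.01)
})

test_that("parameter recovery holds across random generating points", {
  set.seed(1)
  for (i in 1:10) {
    pt <- c(lam = exp(runif(1, -0.7, 0.7)),
            Rmax = 300 * exp(runif(1, -0.5, 0.5)))
    f <- fit_mle(noise_free_data("logistic", pt), "logistic", n_starts = 3)
    expect_lt(max(abs(f$p_hat / pt - 1)), 0.01)
  }
  for (i in 1:5) {
    pt <- c(lam = exp(runif(1, -0.4, 0.4)), zeta = exp(runif(1, -0.4, 0.4)),
            Rd = 150 * exp(runif(1, -0.3, 0.3)))
    f <- fit_mle(noise_free_data("radial_death", pt), "radial_death",
                 n_starts = 2)
    expect_lt(max(abs(f$p_hat / pt - 1)), 0.01)
  }
})

test_that("profile likelihood is normalised, thresholded and classified", {
  ## the 95% chi-squared threshold
  d <- generate_dataset(scenario("main"), seed = 1)
  f <- fit_mle(d, "logistic")
  pr <- profile_parameter(d, "logistic", "lam", f, n_grid = 21)
  expect_equal(pr$threshold, -qchisq(0.95, 1) / 2, tolerance = 1e-12)
  expect_lt(abs(pr$threshold + 1.92), 0.005)
  expect_true(all(pr$pll <= 1e-8, na.rm = TRUE))
  expect_gt(max(pr$pll, na.rm = TRUE), -1e-3)    # zero at the MLE
  expect_identical(pr$classification, "identifiable")
  expect_true(pr$ci_lower < f$p_hat[["lam"]] &&
                f$p_hat[["lam"]] < pr$ci_upper)
  ## confidence intervals shrink with the noise level (same noise draw)
  sc <- scenario("main"); sc$sigma <- 5
  d5 <- generate_dataset(sc, seed = 1)
  f5 <- fit_mle(d5, "logistic")
  pr5 <- profile_parameter(d5, "logistic", "lam", f5, n_grid = 21)
  expect_lt(pr5$ci_upper - pr5$ci_lower, pr$ci_upper - pr$ci_lower)
})

test_that("classification logic counts threshold crossings", {
  mk <- function(pll) structure(list(grid = exp(seq(-1, 1, length.out = length(pll))),
                                     pll = pll, threshold = -1.92),
                                class = "sg_profile")
  expect_identical(classify_identifiability(mk(rep(0, 11)))$classification,
                   "non_identifiable")
  para <- -(seq(-3, 3, length.out = 13))^2
  expect_identical(classify_identifiability(mk(para))$classification,
                   "identifiable")
  oneside <- c(rep(-0.1, 7), -1, -3, -6, -9)
  expect_identical(classify_identifiability(mk(oneside))$classification,
                   "one_sided")
  expect_error(classify_identifiability(mk(c(NA, NA, 0))), "degenerate")
})

test_that("error-function profiles on noise-free data locate the truth", {
  ## logistic: profiled error vanishes at the generating parameters
  dfree <- noise_free_data("logistic", c(lam = 1, Rmax = 300), sigma = 0)
  pe <- profile_error_function(dfree, "logistic", "lam",
                               grid = c(0.5, 0.8, 1, 1.25, 2),
                               centre = c(lam = 1, Rmax = 300))
  expect_true(all(pe$profile >= 0))
  expect_equal(pe$profile[3], 0)
  expect_true(which.min(pe$profile) == 3)
  ## Greenspan: error profile in Q has its minimum at the true Q = 0.8
  gfree <- noise_free_data("greenspan", p1, sigma = 0)
  peg <- profile_error_function(gfree, "greenspan", "Q",
                                grid = c(0.5, 0.65, 0.8, 0.92),
                                centre = p1)
  expect_true(all(peg$profile >= 0))
  expect_identical(which.min(peg$profile), 3L)
  expect_lt(peg$profile[3], 1e-4)
})

test_that("AIC sweep arithmetic and small-noise model ranking", {
  expect_error(aic_sweep("greenspan", p1, 20, reps = 0, "logistic"),
               "reps")
  ## nested models on logistic self-data: equal fit, AIC differs by 2 dk
  d <- noise_free_data("logistic", c(lam = 1, Rmax = 300), sigma = 10)
  fl <- fit_mle(d, "logistic")
  fr <- fit_mle(d, "richards")
  expect_equal(fr$aic - fl$aic, 2 * (fr$k - fl$k), tolerance = 0.01)
  ## near noise-free data: the generating model beats the logistic model
  tab <- aic_sweep("greenspan", p1, sigmas = 0.1, reps = 2,
                   candidate_models = c("logistic", "greenspan"),
                   seed = 5, n_starts = 2)
  expect_lt(tab$mean_aic[tab$model == "greenspan"],
            tab$mean_aic[tab$model == "logistic"])
})
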
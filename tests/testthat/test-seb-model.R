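test_that("encoding noise follows min(R sqrt(t)/sigma, B) with a 1/B floor", {
  lp <- prior_spec("lognormal", mu = 1, sigma = 2)
  p <- seb_params(R = 10, B = 5, g = 0, prior = lp)
  expect_equal(encoding_noise(p, 0.04), 1)  # G = min(10*0.2/2, 5) = 1
  tmax <- (5 * 2 / 10)^2
  expect_equal(encoding_noise(p, tmax), 1 / 5)
  expect_equal(encoding_noise(p, 10 * tmax), 1 / 5)
  # sqrt scaling below the plateau: quadrupling t halves the noise
  p2 <- seb_params(R = 50, B = 20, g = 0)
  t <- c(0.04, 0.16, 0.64) / 100  # well below the plateau
  nu <- encoding_noise(p2, t)
  expect_equal(nu[1] / nu[2], 2, tolerance = 1e-12)
  expect_equal(nu[2] / nu[3], 2, tolerance = 1e-12)
  expect_error(encoding_noise(p, 0), "t must be")
})

test_that("channel capacity is 0.5*ln(1 + R^2 tau), nondecreasing, concave", {
  p <- seb_params(R = 1, B = 1e6, g = 0)
  expect_equal(channel_capacity(p, 1), 0.5 * log(2))
  tt <- seq(0.01, 2, length.out = 50)
  C <- channel_capacity(p, tt)
  expect_true(all(diff(C) > 0))
  expect_true(all(diff(diff(C)) < 1e-12))
  expect_equal(channel_capacity(p, 1e-12), 0, tolerance = 1e-10)
})

test_that("estimate law matches the conjugate update and a numeric decoder", {
  lp <- prior_spec("lognormal", mu = 0, sigma = 1)
  p <- seb_params(R = 100, B = 1, g = 0, prior = lp)  # nu = 1/B = 1
  law <- estimate_law(1, p, 1)
  expect_equal(law$lambda, 0.5)
  expect_equal(law$mu_hat, 0.25)
  expect_equal(law$sigma_hat_sq, 0.25)

  # independent oracle: numeric posterior-mean integration over r draws
  mu <- 1.5; sigma <- 0.6; n <- 9
  params <- seb_params(R = 3.75, B = 20, g = 0,
                       prior = prior_spec("lognormal", mu = mu, sigma = sigma))
  t <- 0.16
  nu <- encoding_noise(params, t)
  expect_equal(nu, 0.4)
  law <- estimate_law(n, params, t)
  r_grid <- seq(log(n) - 6 * nu, log(n) + 6 * nu, length.out = 121)
  w <- stats::dnorm(r_grid, log(n), nu); w <- w / sum(w)
  log_nhat <- log(vapply(r_grid, numeric_nhat, numeric(1),
                         mu = mu, sigma = sigma, nu = nu))
  expect_equal(sum(w * log_nhat), law$mu_hat, tolerance = 1e-4)
  expect_equal(sum(w * (log_nhat - sum(w * log_nhat))^2), law$sigma_hat_sq,
               tolerance = 1e-4)
})

test_that("the 1/n^2 prior gives a conditionally unbiased continuous decoder", {
  p <- seb_params(R = 5, B = 20, g = 0)
  for (n in c(2, 7, 13)) {
    law <- estimate_law(n, p, 0.08)
    expect_equal(exp(law$mu_hat + law$sigma_hat_sq / 2), n, tolerance = 1e-12)
  }
  # Monte-Carlo over the full encode-decode chain
  set.seed(42)
  nu <- encoding_noise(p, 0.08)
  r <- stats::rnorm(2e5, log(9), nu)
  nhat <- exp(r - nu^2 / 2)  # alpha = 2 decoder
  expect_lt(abs(mean(nhat) - 9), 3 * stats::sd(nhat) / sqrt(2e5))
})

test_that("noiseless and pure-guessing limits of the continuous pmf", {
  prior <- prior_spec("powerlaw", alpha = 2)
  pg <- seb_params(R = 10, B = 5, g = 0.5, prior = prior)
  pg$g <- 1  # past the constructor cap on purpose: pure guessing limit
  expect_equal(seb_continuous_response_pmf(9, pg, 0.16), prior_pmf(prior))
  p0 <- seb_params(R = 1e9, B = 1e6, g = 0, prior = prior)
  pmf <- seb_continuous_response_pmf(7, p0, 0.64)
  expect_equal(which.max(pmf), 7)
  expect_gt(pmf[7], 1 - 1e-9)
})

test_that("CV formula matches its closed form and simulated estimates", {
  expect_equal(coefficient_of_variation(
    structure(list(sigma_hat_sq = 0), class = "estimate_law")), 0)
  expect_equal(coefficient_of_variation(
    structure(list(sigma_hat_sq = log(2)), class = "estimate_law")), 1)
  params <- seb_params(R = 3.75, B = 20, g = 0,
                       prior = prior_spec("lognormal", mu = 1.5, sigma = 0.6))
  law <- estimate_law(5, params, 0.16)
  set.seed(1)
  r <- stats::rnorm(1e5, log(5), law$nu)
  nhat <- exp(law$lambda * r + (1 - law$lambda) * 1.5 +
                law$lambda * law$nu^2 / 2)
  cv_hat <- stats::sd(nhat) / mean(nhat)
  boot <- vapply(1:200, function(i) {
    idx <- sample.int(1e5, replace = TRUE)
    stats::sd(nhat[idx]) / mean(nhat[idx])
  }, numeric(1))
  expect_lt(abs(cv_hat - coefficient_of_variation(law)),
            3 * stats::sd(boot))
  # scalar variability: the analytic CV is numerosity-independent
  cvs <- vapply(1:15, function(n) {
    coefficient_of_variation(estimate_law(n, params, 0.16))
  }, numeric(1))
  expect_equal(max(cvs) - min(cvs), 0)
})

test_that("discrete pmf hits its trivial limits", {
  prior <- prior_spec("lognormal", mu = 1.5, sigma = 0.6)
  p <- seb_params(R = 1e9, B = 1e7, g = 0, prior = prior,
                  variant = "discrete")
  pmf <- seb_discrete_response_pmf(5, p, 0.64)
  expect_equal(pmf[5], 1)
  pg <- seb_params(R = 10, B = 5, g = 0.5, prior = prior,
                   variant = "discrete")
  pg$g <- 1
  expect_equal(seb_discrete_response_pmf(5, pg, 0.16), prior_pmf(prior),
               tolerance = 1e-12)
})

test_that("continuous and discrete variants agree at high precision", {
  # at small encoding noise the density-at-integers and rounding
  # conventions coincide; agreement degrades once nu approaches the log
  # spacing of neighbouring large integers (~1/n), so the high-n case
  # needs nu well below 1/15
  prior <- prior_spec("lognormal", mu = 1.5, sigma = 0.6)
  pc <- seb_params(1e5, 66, 0, prior = prior)  # nu ~ 0.015 at the plateau
  pd <- seb_params(1e5, 66, 0, prior = prior, variant = "discrete")
  expect_lt(encoding_noise(pc, 0.64), 0.05)
  for (n in c(3, 8, 14)) {
    expect_lt(tv(seb_continuous_response_pmf(n, pc, 0.64),
                 seb_discrete_response_pmf(n, pd, 0.64)), 5e-2)
  }
})

test_that("response pmfs are valid and moments behave with viewing time", {
  prior <- prior_spec("lognormal", mu = 1.5, sigma = 0.6)
  params <- seb_params(R = 10, B = 10, g = 0.05, prior = prior)
  tt <- c(0.04, 0.08, 0.16, 0.32, 0.64)
  for (t in tt) {
    pmf <- response_pmf(params, 9, t)
    expect_true(all(pmf >= 0))
    expect_equal(sum(pmf), 1, tolerance = 1e-9)
  }
  g0 <- seb_params(R = 10, B = 10, g = 0, prior = prior)
  for (n in c(2, 9, 14)) {
    mom <- predicted_moments(g0, n, tt)
    expect_true(all(diff(abs(mom$bias)) < 1e-9))
    expect_true(all(diff(mom$sd) < 1e-9))
  }
})

test_that("bias is concave in n: overestimation small n, underestimation large n", {
  prior <- prior_spec("lognormal", mu = 1.5, sigma = 0.6)
  params <- seb_params(R = 10, B = 10, g = 0, prior = prior)
  mom <- predicted_moments(params, 1:15, 0.08)
  expect_gt(mom$bias[mom$n == 2], 0)
  expect_lt(mom$bias[mom$n == 15], 0)
  # direct pmf-summation cross-check of one row
  pmf <- response_pmf(params, 9, 0.08)
  expect_equal(mom$mean[mom$n == 9], sum(seq_along(pmf) * pmf),
               tolerance = 1e-12)
})

test_that("pure guessing collapses moments onto the prior", {
  prior <- prior_spec("powerlaw", alpha = 2)
  pg <- seb_params(R = 10, B = 5, g = 0.5, prior = prior)
  pg$g <- 1
  mom <- predicted_moments(pg, c(3, 12), 0.16)
  prior_mean <- sum(seq_len(100) * prior_pmf(prior))
  expect_equal(mom$mean, rep(prior_mean, 2), tolerance = 1e-12)
})

test_that("crossover point exists for lognormal priors and grows with sigma", {
  p_narrow <- seb_params(R = 10, B = 10, g = 0,
                         prior = prior_spec("lognormal", mu = 1.5, sigma = 0.4))
  p_wide <- seb_params(R = 10, B = 10, g = 0,
                       prior = prior_spec("lognormal", mu = 1.5, sigma = 0.8))
  x_narrow <- crossover_point(p_narrow, 0.08)
  x_wide <- crossover_point(p_wide, 0.08)
  expect_true(is.finite(x_narrow) && is.finite(x_wide))
  expect_gte(x_wide, x_narrow)
  # the continuous power-law law is exactly unbiased, so at the law level
  # there is no over/under-estimation crossover (integer renormalization
  # adds only sub-1% rounding wiggles, exercised elsewhere)
  p_pl <- seb_params(R = 5, B = 20, g = 0)
  law_bias <- vapply(1:15, function(n) {
    law <- estimate_law(n, p_pl, 0.16)
    exp(law$mu_hat + law$sigma_hat_sq / 2) - n
  }, numeric(1))
  expect_equal(law_bias, rep(0, 15), tolerance = 1e-10)
  # noiseless limit: no crossover
  p_sharp <- seb_params(R = 1e9, B = 1e7, g = 0,
                        prior = prior_spec("lognormal", mu = 1.5, sigma = 0.6))
  expect_true(is.na(crossover_point(p_sharp, 0.64, tol = 1e-6)))
})
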
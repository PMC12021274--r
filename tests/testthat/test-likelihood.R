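make_trials <- function(n, evidence, response, rt = NULL, experiment = 1L) {
  tb <- tibble::tibble(participant = "p1", experiment = experiment,
                       n = n, evidence = evidence, response = response)
  if (!is.null(rt)) tb$rt <- rt
  tb
}

test_that("cleaning applies strict exclusion rules with exact boundaries", {
  trials <- make_trials(
    n = c(4, 1, 1, 5, 5, 9),
    evidence = rep(40, 6),
    response = c(50, 10, 11, 5, 5, 101),
    rt = c(1, 1, 1, 10.0, 10.01, 1)
  )
  cl <- clean_trials(trials)
  kept <- cl$trials
  expect_equal(kept$response, c(10, 5))      # rows 2 and 4 survive
  expect_equal(kept$rt, c(1, 10.0))          # rt == 10 s retained
  rep_tbl <- cl$report
  expect_equal(rep_tbl$n_trials[rep_tbl$rule == "response > 10 * n"], 3)
  expect_equal(rep_tbl$n_trials[rep_tbl$rule == "rt > 10 s"], 1)
  expect_equal(rep_tbl$n_trials[rep_tbl$rule == "response > 100"], 1)
  expect_equal(rep_tbl$n_trials[rep_tbl$rule == "total removed"], 4)
  expect_error(clean_trials(trials[, -3]), "missing column")
})

test_that("trial likelihood equals the mixture of model pmf and prior", {
  params <- seb_params(R = 20, B = 10, g = 0.05)
  trial <- make_trials(9, 160, 7)
  ll <- trial_loglik(trial, params)
  p0 <- seb_continuous_response_pmf(9, seb_params(R = 20, B = 10, g = 0),
                                    0.16)
  q <- prior_pmf(params$prior)
  expect_equal(ll, log(0.95 * p0[7] + 0.05 * q[7]), tolerance = 1e-12)
  # pure guessing: likelihood is the prior mass, independent of n
  pg <- seb_params(R = 20, B = 10, g = 0.5)
  pg$g <- 1
  ll1 <- trial_loglik(make_trials(2, 160, 7), pg)
  ll2 <- trial_loglik(make_trials(14, 160, 7), pg)
  expect_equal(ll1, log(q[7]))
  expect_equal(ll1, ll2)
  # deterministic observer scoring its own certain response: log 1 = 0
  free <- tim_params(R = 100, B = 6, g = 0)
  expect_equal(trial_loglik(make_trials(9, 640, 9), free), 0)
})

test_that("dataset likelihood sums trials and is order/caching invariant", {
  params <- seb_params(R = 20, B = 10, g = 0.05)
  expect_equal(dataset_loglik(make_trials(integer(0), numeric(0),
                                          integer(0)), params), 0)
  design <- make_design(1, seed = 41)
  trials <- simulate_participant(seb_params(R = 30, B = 8, g = 0.02),
                                 design, seed = 42)
  ll_vec <- trial_loglik(trials, params)
  naive <- vapply(seq_len(nrow(trials)), function(i) {
    trial_loglik(trials[i, ], params)
  }, numeric(1))
  expect_equal(ll_vec, naive, tolerance = 1e-10)
  perm <- sample(nrow(trials))
  expect_equal(dataset_loglik(trials[perm, ], params),
               sum(ll_vec), tolerance = 1e-10)
})

test_that("free-prior parameter vectors build the matching observers", {
  p <- make_model_params("seb_continuous", "free", c(20, 10, 0.05, 1.5, 0.6))
  expect_s3_class(p, "seb_params")
  expect_equal(p$prior$mu, 1.5)
  expect_equal(p$sigma_eff, 0.6)
  tp <- make_model_params("tim", "fixed", c(5, 3, 0.1))
  expect_s3_class(tp, "tim_params")
  expect_equal(tp$prior$alpha, 2)
  expect_error(make_model_params("tim", "free", c(5, 3, 0.1)), "length")
})

test_that("the DE optimizer solves a separable box problem reproducibly", {
  sphere <- function(x) sum((x - c(1, -2, 3))^2)
  fit1 <- de_optimize(sphere, lower = c(-5, -5, -5), upper = c(5, 5, 5),
                      seed = 3, n_gen = 60)
  expect_equal(fit1$par, c(1, -2, 3), tolerance = 1e-3)
  fit2 <- de_optimize(sphere, lower = c(-5, -5, -5), upper = c(5, 5, 5),
                      seed = 3, n_gen = 60)
  expect_identical(fit1$par, fit2$par)
  expect_true(all(diff(fit1$trace) <= 0))
})

test_that("participant fits beat the generating parameters and are reproducible", {
  sim <- simulate_cohort(1, "seb_continuous", "fixed", experiment = 1,
                         seed = 51, fixed_params = c(30, 8, 0.02))
  fit <- fit_participant(sim$trials, "seb_continuous", "fixed", seed = 52)
  truth <- make_model_params("seb_continuous", "fixed", c(30, 8, 0.02))
  expect_gte(fit$loglik, dataset_loglik(sim$trials, truth) - 1e-6)
  expect_equal(fit$aic, 2 * 3 - 2 * fit$loglik)
  expect_equal(sum(fit$trial_ll), fit$loglik, tolerance = 1e-9)
  refit <- fit_participant(sim$trials, "seb_continuous", "fixed", seed = 52)
  expect_identical(fit$par, refit$par)
  # AIC strictly decreasing in loglik at fixed k
  expect_lt(2 * 3 - 2 * (fit$loglik + 1), fit$aic)
})
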
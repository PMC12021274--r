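test_that("cohort comparison reproduces hand-computed paired statistics", {
  fits_a <- fake_cohort(c(101, 102, 103))
  fits_b <- fake_cohort(c(100, 100, 100))
  rep <- compare_models(fits_a, fits_b, n_boot = 2000, seed = 1)
  expect_equal(rep$delta$delta_aic, c(1, 2, 3))
  expect_equal(rep$delta_sum, 6)
  expect_equal(rep$cohens_d, 2)
  expect_equal(rep$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(rep$df, 2)
  expect_true(rep$ci[1] <= rep$delta_sum && rep$delta_sum <= rep$ci[2])
  # degenerate case: all differences zero
  same <- compare_models(fake_cohort(c(10, 20)), fake_cohort(c(10, 20)),
                         n_boot = 100, seed = 1)
  expect_equal(same$delta_sum, 0)
  expect_equal(unname(same$ci), c(0, 0))
  expect_true(is.na(same$cohens_d))
  expect_error(compare_models(fits_a, fake_cohort(c(1, 2))), "participants")
})

test_that("bootstrap interval covers zero at the nominal rate on null data", {
  set.seed(99)
  cover <- vapply(1:120, function(i) {
    diffs <- stats::rnorm(25)
    a <- fake_cohort(100 + diffs)
    b <- fake_cohort(rep(100, 25))
    ci <- compare_models(a, b, n_boot = 400, seed = i)$ci
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  # binomial fluctuation around 0.95 at 120 replicates
  expect_gt(mean(cover), 0.86)
})

test_that("descriptive statistics match an independent two-pass computation", {
  sim <- simulate_cohort(3, "seb_continuous", "fixed", experiment = 1,
                         seed = 61, fixed_params = c(30, 8, 0.05))
  st <- descriptive_stats(sim$trials)
  for (row in c(1, 20, 60)) {
    cell <- sim$trials[sim$trials$n == st$n[row] &
                         sim$trials$evidence == st$evidence[row], ]
    m <- sum(cell$response) / nrow(cell)
    v <- sum((cell$response - m)^2) / (nrow(cell) - 1)
    expect_equal(st$mean[row], m, tolerance = 1e-10)
    expect_equal(st$sd[row], sqrt(v), tolerance = 1e-10)
    expect_equal(st$cv[row], sqrt(v) / m, tolerance = 1e-10)
    expect_equal(st$bias[row], m - st$n[row], tolerance = 1e-10)
    expect_equal(st$abs_error[row], mean(abs(cell$response - cell$n)),
                 tolerance = 1e-10)
  }
  # error-free responses give all-zero dispersion statistics
  perfect <- sim$trials
  perfect$response <- perfect$n
  stp <- descriptive_stats(perfect)
  expect_true(all(stp$bias == 0 & stp$sd == 0 & stp$abs_error == 0))
})

test_that("pure-guessing data show numerosity-independent statistics", {
  prior <- prior_spec("powerlaw", alpha = 2)
  params <- seb_params(R = 10, B = 5, g = 0.5, prior = prior)
  params$g <- 1
  design <- make_design(1, seed = 71)
  big <- design[rep(seq_len(150), 20), ]
  trials <- simulate_participant(params, big, seed = 72)
  kw <- stats::kruskal.test(trials$response, factor(trials$n))
  expect_gt(kw$p.value, 0.001)
})

test_that("AIC splits partition the total likelihood difference", {
  sim <- simulate_cohort(2, "seb_continuous", "fixed", experiment = 1,
                         seed = 81, fixed_params = c(30, 8, 0.02))
  fa <- fit_cohort(sim$trials, "seb_continuous", "fixed", seed = 82,
                   n_gen = 15)
  fb <- fit_cohort(sim$trials, "tim", "fixed", seed = 83, n_gen = 15)
  total <- sum(vapply(names(fa), function(id) {
    2 * (fb[[id]]$loglik - fa[[id]]$loglik)
  }, numeric(1)))
  by_n <- aic_split(fa, fb, sim$trials, by = "numerosity")
  expect_equal(sum(by_n$delta_aic), total, tolerance = 1e-9)
  by_ne <- aic_split(fa, fb, sim$trials, by = "numerosity_evidence")
  expect_equal(sum(by_ne$delta_aic), total, tolerance = 1e-9)
  expect_equal(nrow(by_n), 15)
  # direct per-cell recomputation for one numerosity
  cell_n <- 9
  manual <- 0
  for (id in names(fa)) {
    tr <- sim$trials[sim$trials$participant == id, ]
    pick <- tr$n == cell_n
    manual <- manual +
      2 * sum(trial_loglik(tr[pick, ], fb[[id]]$params) -
                trial_loglik(tr[pick, ], fa[[id]]$params))
  }
  expect_equal(by_n$delta_aic[by_n$n == cell_n], manual, tolerance = 1e-9)
})

test_that("recovery study reports complete pairs and boundary flags", {
  rec <- parameter_recovery("seb_continuous", n_participants = 3,
                            seed = 91, n_gen = 10)
  expect_equal(nrow(rec$pairs), 9)
  expect_setequal(unique(rec$pairs$param), c("R", "B", "g"))
  expect_true(all(c("r", "p_value", "bias", "rmse") %in% names(rec$stats)))
  expect_true(is.logical(rec$pairs$at_boundary))
})
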
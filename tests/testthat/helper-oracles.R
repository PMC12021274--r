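# Shared numerical oracles and fixtures, independent of the package's own
# computation paths wherever they are used as a cross-check.

tv <- function(p, q) 0.5 * sum(abs(p - q))

# Posterior-mean decoder computed by direct numerical integration over the
# continuous log-numerosity scale (independent of the conjugate closed
# form): E[n | r] = int e^x L(r|x) prior(x) dx / int L(r|x) prior(x) dx.
numeric_nhat <- function(r, mu, sigma, nu) {
  num <- stats::integrate(function(x) {
    exp(x) * stats::dnorm(r, x, nu) * stats::dnorm(x, mu, sigma)
  }, lower = mu - 12 * sigma, upper = mu + 12 * sigma,
  rel.tol = 1e-12)$value
  den <- stats::integrate(function(x) {
    stats::dnorm(r, x, nu) * stats::dnorm(x, mu, sigma)
  }, lower = mu - 12 * sigma, upper = mu + 12 * sigma,
  rel.tol = 1e-12)$value
  num / den
}

# Dual-ascent convex solve of the KL-constrained MSE problem via the
# pre-installed python/scipy; returns the optimal pmf.
run_tim_oracle <- function(q, n, C) {
  script <- system.file("oracles", "tim_constrained_mse.py",
                        package = "sebtim")
  stopifnot(nzchar(script))
  spec_file <- tempfile(fileext = ".json")
  out_file <- tempfile(fileext = ".json")
  writeLines(sprintf(
    '{"q": [%s], "n": %d, "C": %.17g}',
    paste(sprintf("%.17g", q), collapse = ", "), n, C
  ), spec_file)
  status <- system2("python", c(script, spec_file), stdout = out_file)
  stopifnot(status == 0)
  txt <- paste(readLines(out_file, warn = FALSE), collapse = "")
  # minimal JSON pull of the pmf array (avoids a JSON dependency here)
  arr <- sub('.*"pmf": \\[', "", txt)
  arr <- sub("\\].*", "", arr)
  as.numeric(strsplit(arr, ",")[[1]])
}

# Default desk-scale parameter sets used by the qualitative-signature
# checks: fixed power-law prior for both observers. Scalar variability is
# a property of the g = 0 encoder/decoder, so the SEB set carries no
# lapses; the TIM signature set carries the small lapse rate that fitted
# TIM parameters typically require.
default_seb_discrete <- function() {
  seb_params(R = 15, B = 10, g = 0,
             prior = prior_spec("powerlaw", alpha = 2),
             variant = "discrete")
}
default_tim <- function() {
  tim_params(R = 5, B = 3, g = 0.05,
             prior = prior_spec("powerlaw", alpha = 2))
}

# Minimal stand-in fit object carrying just what cohort summaries use.
fake_fit <- function(participant, aic, loglik = -aic / 2 + 3, k = 3L,
                     model = "seb_continuous", trial_ll = NULL) {
  structure(
    list(participant = participant, model = model, prior_mode = "fixed",
         par = c(R = 1, B = 1, g = 0.01), params = NULL, loglik = loglik,
         aic = aic, k = k, n_trials = 150L, seed = 1L, trace = NULL,
         trial_ll = trial_ll),
    class = "seb_fit"
  )
}

fake_cohort <- function(aics, ids = sprintf("p%02d", seq_along(aics))) {
  fits <- Map(fake_fit, ids, aics)
  names(fits) <- ids
  structure(fits, class = "cohort_fits")
}
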
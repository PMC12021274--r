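#' Sequential-encoding/Bayesian-decoding (SEB) observer parameters
#'
#' The SEB observer encodes \eqn{\log n} through a Brownian-diffusion
#' channel whose precision grows with viewing time, then decodes the noisy
#' representation with the Bayesian minimum mean-squared-error estimator
#' under the contextual prior. Its resource parameters are:
#'
#' * `R`: information accumulation rate, the ratio of the drift power bound
#'   to the instantaneous diffusion noise (evidence units per sqrt(second)).
#'   Only the ratio is behaviourally identifiable, so the two underlying
#'   quantities are never represented separately.
#' * `B`: maximum encoding precision (inverse log-units). Encoding precision
#'   is \eqn{G = \min(R\sqrt{t}/\sigma_{eff}, B)}, so `B` corresponds to a
#'   largest useful accumulation time
#'   \eqn{t_{max} = (B\sigma_{eff}/R)^2}.
#' * `g`: guessing (lapse) rate in \[0, 0.5\]: the probability that a
#'   response is an uninformed draw from the prior.
#'
#' `sigma_eff` is the prior's sigma for a log-normal prior; for the fixed
#' power-law prior it is 1 and `R` absorbs the scale, keeping the
#' fixed-prior model at three free parameters.
#'
#' @param R Accumulation rate, > 0 (fitting box (0.1, 200)).
#' @param B Precision bound, > 0 (fitting box (0.1, 20)).
#' @param g Guessing rate in \[0, 0.5\].
#' @param prior A [prior_spec()]; defaults to the fixed power-law
#'   \eqn{1/n^2} prior on 1..100.
#' @param variant `"continuous"` (analytic estimate law, densities
#'   normalized at the integers) or `"discrete"` (integer-restricted
#'   encoding/decoding by quadrature).
#' @return An object of class `seb_params`.
#' @examples
#' seb_params(R = 30, B = 8, g = 0.02)
#' @export
seb_params <- function(R, B, g = 0,
                       prior = prior_spec("powerlaw", alpha = 2),
                       variant = c("continuous", "discrete")) {
  variant <- match.arg(variant)
  stopifnot(is_prior_spec(prior))
  if (!is.finite(R) || R <= 0) stop("R must be > 0", call. = FALSE)
  if (!is.finite(B) || B <= 0) stop("B must be > 0", call. = FALSE)
  if (!is.finite(g) || g < 0 || g > 0.5) {
    stop("g must lie in [0, 0.5]", call. = FALSE)
  }
  structure(
    list(R = R, B = B, g = g, prior = prior, variant = variant,
         sigma_eff = if (prior$family == "lognormal") prior$sigma else 1),
    class = "seb_params"
  )
}

#' @export
print.seb_params <- function(x, ...) {
  cat(sprintf("<seb_params> %s: R = %g, B = %g, g = %g; prior %s\n",
              x$variant, x$R, x$B, x$g, x$prior$family))
  invisible(x)
}

#' Encoding noise as a function of viewing time
#'
#' Standard deviation \eqn{\nu(t)} of the internal log-scale representation,
#' \eqn{\nu = 1/G} with precision \eqn{G = \min(R\sqrt{t}/\sigma_{eff}, B)}.
#' Noise shrinks as \eqn{1/\sqrt{t}} until the precision bound `B` is hit
#' at \eqn{t_{max} = (B\sigma_{eff}/R)^2}, after which it stays at
#' \eqn{1/B}.
#'
#' @param params A [seb_params()].
#' @param t Viewing time(s) in seconds, > 0.
#' @return \eqn{\nu} in log-units, same length as `t`.
#' @export
encoding_noise <- function(params, t) {
  stopifnot(inherits(params, "seb_params"))
  if (any(!is.finite(t) | t <= 0)) stop("t must be > 0 (seconds)", call. = FALSE)
  G <- pmin(params$R * sqrt(t) / params$sigma_eff, params$B)
  1 / G
}

#' Channel capacity of the diffusion encoder
#'
#' Capacity in nats of the Gaussian channel implied by accumulating
#' evidence for \eqn{\tau = \min(t, t_{max})} seconds:
#' \eqn{C = \frac{1}{2}\ln(1 + R^2\tau)}. Diagnostic only; it is not used
#' in the likelihood.
#'
#' @inheritParams encoding_noise
#' @return Capacity in nats, same length as `t`.
#' @export
channel_capacity <- function(params, t) {
  stopifnot(inherits(params, "seb_params"))
  if (any(!is.finite(t) | t <= 0)) stop("t must be > 0 (seconds)", call. = FALSE)
  tmax <- (params$B * params$sigma_eff / params$R)^2
  tau <- pmin(t, tmax)
  0.5 * log(1 + params$R^2 * tau)
}

#' Conditional law of the decoded estimate
#'
#' Given stimulus `n` and viewing time `t`, the MMSE-decoded estimate
#' \eqn{\hat n} is log-normally distributed:
#' \eqn{\log\hat n \mid n \sim N(\hat\mu, \hat\sigma^2)}.
#'
#' For a log-normal prior, with shrinkage weight
#' \eqn{\lambda = \sigma^2/(\sigma^2 + \nu^2)} and posterior variance
#' \eqn{v = \lambda\nu^2}:
#' \eqn{\hat\mu = \lambda\log n + (1-\lambda)\mu + v/2},
#' \eqn{\hat\sigma^2 = \lambda^2\nu^2}.
#' For the improper power-law prior (\eqn{\lambda = 1}):
#' \eqn{\hat\mu = \log n - (\alpha-1)\nu^2 + \nu^2/2},
#' \eqn{\hat\sigma^2 = \nu^2}; at \eqn{\alpha = 2} the two corrections
#' cancel and \eqn{E[\hat n \mid n] = n} exactly.
#'
#' @param n Stimulus numerosity (positive integer).
#' @param params A [seb_params()].
#' @param t Viewing time in seconds.
#' @return An object of class `estimate_law`: list with `mu_hat`,
#'   `sigma_hat_sq`, `nu`, `lambda`.
#' @export
estimate_law <- function(n, params, t) {
  stopifnot(inherits(params, "seb_params"), n >= 1)
  nu <- encoding_noise(params, t)
  pr <- params$prior
  if (pr$family == "lognormal") {
    lambda <- pr$sigma^2 / (pr$sigma^2 + nu^2)
    v <- lambda * nu^2
    mu_hat <- lambda * log(n) + (1 - lambda) * pr$mu + v / 2
    s2 <- lambda^2 * nu^2
  } else {
    lambda <- 1
    mu_hat <- log(n) - (pr$alpha - 1) * nu^2 + nu^2 / 2
    s2 <- nu^2
  }
  structure(list(mu_hat = mu_hat, sigma_hat_sq = s2, nu = nu,
                 lambda = lambda),
            class = "estimate_law")
}

#' Coefficient of variation of the estimate law
#'
#' \eqn{CV = \sqrt{e^{\hat\sigma^2} - 1}}: a property of the log-normal
#' estimate distribution that does not depend on the stimulus numerosity —
#' the scalar-variability signature. It decreases with viewing time through
#' \eqn{\hat\sigma^2(t)}.
#'
#' @param law An [estimate_law()].
#' @return CV (dimensionless).
#' @export
coefficient_of_variation <- function(law) {
  stopifnot(inherits(law, "estimate_law"), law$sigma_hat_sq >= 0)
  sqrt(exp(law$sigma_hat_sq) - 1)
}

#' Response probabilities over integer estimates
#'
#' Probability mass function of the observer's integer response for a
#' stimulus `n` viewed for `t` seconds, including the guessing mixture
#' \eqn{(1-g)p_0 + g\,q} with \eqn{q} the prior pmf.
#'
#' @param params A model parameter object ([seb_params()] or
#'   [tim_params()]).
#' @param n Stimulus numerosity.
#' @param t Viewing time in seconds (contrast levels must first be mapped
#'   to effective durations, see [map_evidence()]).
#' @param ... Passed to methods.
#' @return Numeric pmf over `1..support_max`.
#' @export
response_pmf <- function(params, n, t, ...) UseMethod("response_pmf")

#' @rdname response_pmf
#' @export
response_pmf.seb_params <- function(params, n, t, ...) {
  if (params$variant == "continuous") {
    seb_continuous_response_pmf(n, params, t)
  } else {
    seb_discrete_response_pmf(n, params, t, ...)
  }
}

#' Continuous-variant SEB response pmf
#'
#' The analytic log-normal density of the estimate is evaluated at the
#' integers `1..support_max` and normalized (density-at-integers
#' convention), then mixed with the guessing distribution. A degenerate
#' law (`sigma_hat_sq == 0`) yields a point mass at
#' `round(exp(mu_hat))` before the guessing mixture.
#'
#' @inheritParams estimate_law
#' @return Numeric pmf over `1..support_max`.
#' @export
seb_continuous_response_pmf <- function(n, params, t) {
  law <- estimate_law(n, params, t)
  p0 <- lognormal_integer_pmf(law$mu_hat, law$sigma_hat_sq,
                              params$prior$support_max)
  mix_guessing(p0, params$g, prior_pmf(params$prior))
}

# density of lognormal(mu, s2) at integers 1..Nmax, normalized; point mass
# when s2 == 0 (or numerically indistinguishable from it).
lognormal_integer_pmf <- function(mu, s2, support_max) {
  k <- seq_len(support_max)
  if (s2 <= 0) {
    p0 <- numeric(support_max)
    p0[min(max(round_half_up(exp(mu)), 1), support_max)] <- 1
    return(p0)
  }
  logk <- log(k)
  logw <- -(logk - mu)^2 / (2 * s2) - logk
  m <- max(logw)
  if (!is.finite(m)) {
    p0 <- numeric(support_max)
    p0[min(max(round_half_up(exp(mu)), 1), support_max)] <- 1
    return(p0)
  }
  w <- exp(logw - m)
  w / sum(w)
}

#' Discrete-variant SEB response pmf
#'
#' Integer-restricted encode/decode pipeline: the prior is discretized over
#' `1..support_max`; for each representation value `r` on a quadrature grid
#' the integer posterior \eqn{p(j \mid r) \propto p(j)
#' \exp(-(r - \log j)^2 / (2\nu^2))} is formed and its mean rounded to the
#' nearest integer; the resulting point estimates are aggregated under the
#' \eqn{N(\log n, \nu^2)} weights of the grid. The grid spans
#' \eqn{\log n \pm 6\nu} with `n_grid` points and trapezoid weights.
#'
#' @inheritParams estimate_law
#' @param n_grid Number of quadrature points (default 8001; the default
#'   resolves the response pmf to well under 1e-3 total variation).
#' @return Numeric pmf over `1..support_max`.
#' @export
seb_discrete_response_pmf <- function(n, params, t, n_grid = 8001L) {
  stopifnot(inherits(params, "seb_params"), n >= 1)
  nu <- encoding_noise(params, t)
  prior_p <- prior_pmf(params$prior)
  Nmax <- params$prior$support_max
  if (nu <= 0) {
    p0 <- numeric(Nmax)
    p0[min(n, Nmax)] <- 1
  } else {
    p0 <- seb_discrete_pmf_cpp(prior_p, log(n), nu, as.integer(n_grid), 6.0)
    s <- sum(p0)
    if (abs(s - 1) > 1e-9) {
      stop("quadrature grid too coarse: pmf sums to ", s, call. = FALSE)
    }
    p0 <- p0 / s
  }
  mix_guessing(p0, params$g, prior_p)
}

#' Predicted response moments
#'
#' Mean, SD, CV and bias of the integer response distribution for each
#' combination of stimulus numerosity and viewing time. Bias is
#' \eqn{E[\hat n \mid n] - n}.
#'
#' @param params A [seb_params()] or [tim_params()].
#' @param n Vector of stimulus numerosities.
#' @param t Vector of viewing times (seconds).
#' @param ... Passed to the pmf computation.
#' @return A tibble with columns `n`, `t`, `mean`, `sd`, `cv`, `bias`,
#'   one row per (n, t) combination.
#' @export
predicted_moments <- function(params, n, t, ...) {
  grid <- expand.grid(n = n, t = t, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- response_pmf(params, grid$n[i], grid$t[i], ...)
    m <- pmf_moments(p)
    tibble::tibble(n = grid$n[i], t = grid$t[i], mean = m$mean, sd = m$sd,
                   cv = m$cv, bias = m$mean - grid$n[i])
  })
  dplyr::bind_rows(rows)
}

#' Crossover numerosity between over- and underestimation
#'
#' The bias of the predicted estimate typically changes sign along the
#' numerosity axis: small numbers are overestimated, large ones
#' underestimated. This returns the linearly interpolated zero of the bias
#' curve over integer stimuli, or `NA` (no crossover) when the bias never
#' changes sign, e.g. for the unbiased continuous power-law observer.
#' The crossover grows with the prior's spread.
#'
#' @param params A [seb_params()] or [tim_params()].
#' @param t Viewing time in seconds.
#' @param n_range Integer stimuli to scan (default `1:15`).
#' @param tol Biases with absolute value below `tol` count as zero.
#' @return Interpolated crossover numerosity, or `NA_real_`.
#' @export
crossover_point <- function(params, t, n_range = 1:15, tol = 1e-10) {
  mom <- predicted_moments(params, n_range, t)
  b <- mom$bias
  if (all(abs(b) <= tol)) return(NA_real_)
  hit <- which(abs(b) <= tol)
  if (length(hit) > 0) return(as.numeric(n_range[hit[1]]))
  sgn <- sign(b)
  flip <- which(sgn[-1] != sgn[-length(sgn)])
  if (length(flip) == 0) return(NA_real_)
  i <- flip[1]
  n0 <- n_range[i]; n1 <- n_range[i + 1]
  n0 + b[i] * (n1 - n0) / (b[i] - b[i + 1])
}
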
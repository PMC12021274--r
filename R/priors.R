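#' Contextual numerosity prior
#'
#' Constructs the prior (or, for the TIM observer, the default-state)
#' distribution over numerosities. Two families are supported:
#'
#' * `"lognormal"`: \eqn{\log n \sim N(\mu, \sigma^2)}, the two-parameter
#'   family used when the prior is fitted freely. On the integer response
#'   range the pmf is proportional to
#'   \eqn{\exp(-\alpha \log k - \gamma (\log k)^2)} with
#'   \eqn{\gamma = 1/(2\sigma^2)} and \eqn{\mu = (1-\alpha)/(2\gamma)}.
#' * `"powerlaw"`: \eqn{p(n) \propto n^{-\alpha}}, the \eqn{\gamma \to 0}
#'   limit of the log-normal family. The ecologically motivated fixed choice
#'   is \eqn{\alpha = 2}.
#'
#' @param family `"lognormal"` or `"powerlaw"`.
#' @param mu Location of \eqn{\log n} (log-units; log-normal family only).
#' @param sigma Standard deviation of \eqn{\log n} (log-units, > 0;
#'   log-normal family only).
#' @param alpha Power-law exponent (dimensionless; power-law family only).
#' @param support_max Largest representable integer response \eqn{N_{max}}.
#' @return An object of class `prior_spec`.
#' @examples
#' prior_spec("powerlaw", alpha = 2)
#' prior_spec("lognormal", mu = 1.5, sigma = 0.6)
#' @export
prior_spec <- function(family = c("lognormal", "powerlaw"),
                       mu = NULL, sigma = NULL, alpha = NULL,
                       support_max = 100L) {
  family <- match.arg(family)
  support_max <- as.integer(support_max)
  if (is.na(support_max) || support_max < 1L) {
    stop("`support_max` must be a positive integer", call. = FALSE)
  }
  if (family == "lognormal") {
    if (is.null(mu) || is.null(sigma)) {
      stop("lognormal prior requires `mu` and `sigma`", call. = FALSE)
    }
    if (!is.finite(mu)) stop("`mu` must be finite", call. = FALSE)
    if (!is.finite(sigma) || sigma <= 0) {
      stop("lognormal prior requires sigma > 0", call. = FALSE)
    }
    if (!is.null(alpha)) {
      stop("`alpha` applies only to the powerlaw family", call. = FALSE)
    }
  } else {
    if (is.null(alpha)) {
      stop("powerlaw prior requires `alpha`", call. = FALSE)
    }
    if (!is.finite(alpha)) stop("`alpha` must be finite", call. = FALSE)
    if (!is.null(mu) || !is.null(sigma)) {
      stop("`mu`/`sigma` apply only to the lognormal family", call. = FALSE)
    }
  }
  structure(
    list(family = family, mu = mu, sigma = sigma, alpha = alpha,
         support_max = support_max),
    class = "prior_spec"
  )
}

#' @export
print.prior_spec <- function(x, ...) {
  if (x$family == "lognormal") {
    cat(sprintf("<prior_spec> lognormal(mu = %g, sigma = %g), support 1..%d\n",
                x$mu, x$sigma, x$support_max))
  } else {
    cat(sprintf("<prior_spec> powerlaw(alpha = %g), support 1..%d\n",
                x$alpha, x$support_max))
  }
  invisible(x)
}

is_prior_spec <- function(x) inherits(x, "prior_spec")

#' Discretized prior pmf over the integer response range
#'
#' Evaluates the prior on the integers \eqn{1..N_{max}} and normalizes.
#' All arithmetic is done in log space so that extreme parameter values
#' (e.g. sigma up to 100, |mu| up to 50, as in the fitting search box)
#' neither underflow nor overflow.
#'
#' @param spec A [prior_spec()].
#' @return Numeric vector of length `support_max`; strictly positive,
#'   sums to 1.
#' @examples
#' p <- prior_pmf(prior_spec("powerlaw", alpha = 2, support_max = 5))
#' sum(p)
#' @export
prior_pmf <- function(spec) {
  stopifnot(is_prior_spec(spec))
  k <- seq_len(spec$support_max)
  logk <- log(k)
  if (spec$family == "lognormal") {
    # density of n (with 1/n Jacobian): -(log k - mu)^2/(2 sigma^2) - log k
    logw <- -(logk - spec$mu)^2 / (2 * spec$sigma^2) - logk
  } else {
    logw <- -spec$alpha * logk
  }
  logw <- logw - max(logw)
  w <- exp(logw)
  w / sum(w)
}

#' Log-density of the prior on the log-numerosity scale
#'
#' Continuous form used by the analytic Bayesian decoder. For the
#' log-normal family this is the (normalized) normal log-density of
#' \eqn{x = \log n}. For the power-law family the improper log-scale
#' density \eqn{p(x) \propto \exp(-(\alpha - 1) x)} is returned
#' unnormalized; the \eqn{\alpha - 1} (rather than \eqn{\alpha}) exponent
#' carries the Jacobian of the change of variables from
#' \eqn{p(n) \propto n^{-\alpha}}.
#'
#' @param spec A [prior_spec()].
#' @param x Log-numerosity value(s).
#' @return Log-density (possibly unnormalized for the power-law family).
#' @export
prior_log_density <- function(spec, x) {
  stopifnot(is_prior_spec(spec), is.numeric(x))
  if (spec$family == "lognormal") {
    stats::dnorm(x, mean = spec$mu, sd = spec$sigma, log = TRUE)
  } else {
    -(spec$alpha - 1) * x
  }
}

#' Sample integer numerosities from the prior
#'
#' Used for the guessing (lapse) process: on a lapse trial the response is
#' an uninformed draw from the prior.
#'
#' @param spec A [prior_spec()].
#' @param k Number of draws (>= 0).
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is left untouched.
#' @return Integer vector of length `k` with values in `1..support_max`.
#' @export
sample_prior <- function(spec, k, seed = NULL) {
  stopifnot(is_prior_spec(spec), k >= 0)
  if (k == 0) return(integer(0))
  with_local_seed(seed, {
    sample.int(spec$support_max, size = k, replace = TRUE,
               prob = prior_pmf(spec))
  })
}

# Evaluate `expr` under `seed` (if non-NULL) restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}
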
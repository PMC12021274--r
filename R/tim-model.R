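#' Thermodynamically inspired (TIM) observer parameters
#'
#' The TIM observer perceives the stimulus noiselessly but pays a "cost of
#' control" for responding: the response distribution \eqn{p(\hat n \mid n)}
#' minimizes the mean squared error subject to a Kullback-Leibler budget
#' around a default state \eqn{q},
#' \eqn{D_{KL}(p \| q) \le C(t) = \min(R t, B)}.
#' The constrained optimum is the exponential tilt
#' \eqn{p(k) \propto q(k)\exp(-b (n-k)^2)} with the multiplier `b` solved
#' per stimulus so the budget binds.
#'
#' `R` and `B` are in nats per second and nats; although they share names
#' and fitting boxes with the SEB parameters, their units differ and the
#' two models' values must never be compared numerically.
#'
#' @param R Information rate in nats/second, > 0 (fitting box (0.1, 200)).
#' @param B Information bound in nats, > 0 (fitting box (0.1, 20)).
#' @param g Guessing rate in \[0, 0.5\].
#' @param prior A [prior_spec()] discretized as the default state `q`;
#'   defaults to the fixed power-law \eqn{1/n^2} prior on 1..100.
#' @return An object of class `tim_params`.
#' @examples
#' tim_params(R = 5, B = 4, g = 0.02)
#' @export
tim_params <- function(R, B, g = 0,
                       prior = prior_spec("powerlaw", alpha = 2)) {
  stopifnot(is_prior_spec(prior))
  if (!is.finite(R) || R <= 0) stop("R must be > 0", call. = FALSE)
  if (!is.finite(B) || B <= 0) stop("B must be > 0", call. = FALSE)
  if (!is.finite(g) || g < 0 || g > 0.5) {
    stop("g must lie in [0, 0.5]", call. = FALSE)
  }
  structure(list(R = R, B = B, g = g, prior = prior), class = "tim_params")
}

#' @export
print.tim_params <- function(x, ...) {
  cat(sprintf("<tim_params> R = %g nats/s, B = %g nats, g = %g; default %s\n",
              x$R, x$B, x$g, x$prior$family))
  invisible(x)
}

#' Kullback-Leibler divergence between two response pmfs
#'
#' \eqn{\sum_k p_k \log(p_k / q_k)} in nats, with the convention
#' \eqn{0 \log 0 = 0}. `q` must be strictly positive on the support.
#'
#' @param p,q Probability vectors on the same support.
#' @return Divergence in nats (>= 0; 0 iff `p == q`).
#' @export
kl_divergence <- function(p, q) {
  if (length(p) != length(q)) {
    stop("p and q must share a support", call. = FALSE)
  }
  stopifnot(all(q > 0), all(p >= 0))
  nz <- p > 0
  sum(p[nz] * (log(p[nz]) - log(q[nz])))
}

#' Solve the KL multiplier for one stimulus
#'
#' Finds \eqn{b \ge 0} such that the tilted distribution
#' \eqn{p_b(k) \propto q(k) e^{-b (n-k)^2}} satisfies
#' \eqn{D_{KL}(p_b \| q) = C_{target}} (the divergence is strictly
#' increasing in `b`, so bisection applies). When the budget exceeds the
#' largest achievable divergence \eqn{-\ln q(n)}, the point mass at `n` is
#' returned with `b = Inf`. The per-stimulus multiplier solved here is the
#' single effective coefficient of the squared-error term (any constant
#' factor, such as a `q(n)` weight in the loss, is absorbed into it).
#'
#' @param n Stimulus (index into the support of `q`).
#' @param q Default-state pmf, strictly positive.
#' @param C_target KL budget in nats, >= 0.
#' @param tol Bisection tolerance on the divergence (nats).
#' @return List with `b`, `pmf`, `kl`, `saturated`.
#' @export
solve_beta <- function(n, q, C_target, tol = 1e-8) {
  stopifnot(C_target >= 0, n >= 1, n <= length(q), all(q > 0))
  res <- tim_solve_beta_cpp(q, as.integer(n), C_target, tol)
  list(b = res$b, pmf = as.numeric(res$pmf), kl = res$kl,
       saturated = res$saturated)
}

#' @rdname response_pmf
#' @export
response_pmf.tim_params <- function(params, n, t, ...) {
  tim_response_pmf(n, params, t)
}

#' TIM response pmf
#'
#' Information budget \eqn{C(t) = \min(R t, B)}; the KL-constrained optimal
#' tilt of the default state is solved by [solve_beta()] and then mixed
#' with the guessing distribution. As \eqn{t \to 0} the pmf collapses onto
#' the default state `q` (maximum response variability); once the budget
#' exceeds \eqn{-\ln q(n)} the response is the point mass at `n`.
#'
#' @param n Stimulus numerosity.
#' @param params A [tim_params()].
#' @param t Viewing time in seconds.
#' @return Numeric pmf over `1..support_max`.
#' @export
tim_response_pmf <- function(n, params, t) {
  stopifnot(inherits(params, "tim_params"))
  if (!is.finite(t) || t <= 0) stop("t must be > 0 (seconds)", call. = FALSE)
  q <- prior_pmf(params$prior)
  C <- min(params$R * t, params$B)
  p0 <- solve_beta(n, q, C)$pmf
  mix_guessing(p0, params$g, q)
}

# pmf matrix for several (n, C) pairs at once (rows follow the input order);
# used by the likelihood code, where speed matters.
tim_pmf_matrix <- function(q, n_vec, C_vec, tol = 1e-8) {
  tim_solve_batch_cpp(q, as.integer(n_vec), as.numeric(C_vec), tol)
}
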
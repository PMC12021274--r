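# Shared helpers for probability vectors over the integer response range.

# Moments of a pmf on support 1..Nmax.
pmf_moments <- function(p) {
  k <- seq_along(p)
  m <- sum(k * p)
  v <- sum((k - m)^2 * p)
  s <- sqrt(max(v, 0))
  list(mean = m, sd = s, cv = if (m > 0) s / m else NA_real_)
}

# Total variation distance between two pmfs on the same support.
tv_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  0.5 * sum(abs(p - q))
}

assert_pmf <- function(p, tol = 1e-9) {
  stopifnot(all(p >= 0), abs(sum(p) - 1) <= tol)
  invisible(p)
}

# Mix a model pmf with the guessing (lapse) distribution.
mix_guessing <- function(p0, g, prior_p) {
  if (g <= 0) return(p0)
  (1 - g) * p0 + g * prior_p
}

# round-half-away-from-zero, for positive x
round_half_up <- function(x) floor(x + 0.5)
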
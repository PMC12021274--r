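#' Differential-evolution box-constrained minimizer
#'
#' Classic rand/1/bin differential evolution, used as the global optimizer
#' for the per-participant likelihood fits. Defaults follow common
#' practice: population `10 * length(lower)`, crossover rate 0.9,
#' differential weight dithered uniformly in \[0.5, 1\] per mutant, and
#' 100 generations.
#'
#' @param fn Objective to minimize; takes a numeric vector.
#' @param lower,upper Box bounds (numeric vectors of equal length).
#' @param n_pop Population size; default `10 * length(lower)`.
#' @param n_gen Number of generations.
#' @param cr Crossover probability.
#' @param f_range Range for the dithered differential weight.
#' @param seed Optional integer seed (restores the caller's RNG state).
#' @param trace Keep the best objective value per generation.
#' @return List with `par`, `value`, `trace` (or `NULL`), `n_eval`.
#' @export
de_optimize <- function(fn, lower, upper,
                        n_pop = 10L * length(lower), n_gen = 100L,
                        cr = 0.9, f_range = c(0.5, 1),
                        seed = NULL, trace = TRUE) {
  stopifnot(length(lower) == length(upper), all(upper > lower),
            n_pop >= 4, n_gen >= 1)
  d <- length(lower)
  with_local_seed(seed, {
    pop <- matrix(stats::runif(n_pop * d, rep(lower, each = n_pop),
                               rep(upper, each = n_pop)),
                  nrow = n_pop, ncol = d)
    val <- apply(pop, 1, fn)
    n_eval <- n_pop
    best_trace <- if (trace) numeric(n_gen) else NULL
    for (gen in seq_len(n_gen)) {
      for (i in seq_len(n_pop)) {
        idx <- sample.int(n_pop, 3L)
        while (any(idx == i)) idx <- sample.int(n_pop, 3L)
        f <- stats::runif(1, f_range[1], f_range[2])
        mutant <- pop[idx[1], ] + f * (pop[idx[2], ] - pop[idx[3], ])
        mutant <- pmin(pmax(mutant, lower), upper)
        jrand <- sample.int(d, 1L)
        cross <- stats::runif(d) < cr
        cross[jrand] <- TRUE
        cand <- ifelse(cross, mutant, pop[i, ])
        v <- fn(cand)
        n_eval <- n_eval + 1L
        if (v <= val[i]) {
          pop[i, ] <- cand
          val[i] <- v
        }
      }
      if (trace) best_trace[gen] <- min(val)
    }
    b <- which.min(val)
    list(par = pop[b, ], value = val[b], trace = best_trace, n_eval = n_eval)
  })
}
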
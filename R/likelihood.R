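# Trial-level likelihoods, data cleaning, and per-participant ML fitting.

#' Clean a trial table
#'
#' Applies the exclusion rules used before fitting: a trial is removed when
#' the response is strictly more than 10 times the presented numerosity, or
#' the response time is strictly above 10 s (where a response time is
#' recorded). Responses above the likelihood support `1..support_max` are
#' also removed (they would otherwise carry zero model probability).
#' Boundary cases are retained: `response == 10 * n` and `rt == 10` stay.
#'
#' @param trials A trial tibble (see [read_trials()] for the schema).
#' @param support_max Largest representable response.
#' @return List with `trials` (the retained rows) and `report`, a tibble of
#'   per-rule violation counts (a row violating several rules is counted
#'   under each) plus the total number of rows removed.
#' @export
clean_trials <- function(trials, support_max = 100L) {
  problems <- validate_trials(trials)
  if (length(problems) > 0) {
    stop("invalid trial table:\n  ",
         paste(utils::head(problems, 20), collapse = "\n  "), call. = FALSE)
  }
  ratio_bad <- trials$response > 10 * trials$n
  rt_bad <- if ("rt" %in% names(trials)) {
    !is.na(trials$rt) & trials$rt > 10
  } else {
    rep(FALSE, nrow(trials))
  }
  support_bad <- trials$response > support_max
  drop <- ratio_bad | rt_bad | support_bad
  report <- tibble::tibble(
    rule = c("response > 10 * n", "rt > 10 s",
             paste0("response > ", support_max), "total removed"),
    n_trials = c(sum(ratio_bad), sum(rt_bad), sum(support_bad), sum(drop))
  )
  list(trials = trials[!drop, , drop = FALSE], report = report)
}

# Matrix of g = 0 response pmfs, one row per (n, t) pair, columns
# 1..support_max. This is the shared fast path for likelihoods and
# simulation; the guessing mixture is applied by the caller.
response_pmf_matrix <- function(params, n_vec, t_vec) {
  UseMethod("response_pmf_matrix")
}

#' @export
response_pmf_matrix.seb_params <- function(params, n_vec, t_vec) {
  Nmax <- params$prior$support_max
  if (params$variant == "discrete") {
    prior_p <- prior_pmf(params$prior)
    nu <- encoding_noise(params, t_vec)
    out <- matrix(0, length(n_vec), Nmax)
    for (i in seq_along(n_vec)) {
      out[i, ] <- seb_discrete_pmf_cpp(prior_p, log(n_vec[i]), nu[i],
                                       8001L, 6.0)
    }
    return(out / rowSums(out))
  }
  nu <- encoding_noise(params, t_vec)
  pr <- params$prior
  if (pr$family == "lognormal") {
    lambda <- pr$sigma^2 / (pr$sigma^2 + nu^2)
    mu_hat <- lambda * log(n_vec) + (1 - lambda) * pr$mu + lambda * nu^2 / 2
    s2 <- lambda^2 * nu^2
  } else {
    mu_hat <- log(n_vec) - (pr$alpha - 1) * nu^2 + nu^2 / 2
    s2 <- nu^2
  }
  logk <- log(seq_len(Nmax))
  # rows: cells; columns: integer responses
  logw <- -(outer(mu_hat, logk, `-`))^2 / (2 * s2) -
    matrix(logk, length(n_vec), Nmax, byrow = TRUE)
  mx <- apply(logw, 1, max)
  w <- exp(logw - mx)
  degenerate <- s2 <= 0 | !is.finite(mx)
  if (any(degenerate)) {
    for (i in which(degenerate)) {
      w[i, ] <- 0
      w[i, min(max(round_half_up(exp(mu_hat[i])), 1), Nmax)] <- 1
    }
  }
  w / rowSums(w)
}

#' @export
response_pmf_matrix.tim_params <- function(params, n_vec, t_vec) {
  q <- prior_pmf(params$prior)
  C <- pmin(params$R * t_vec, params$B)
  tim_pmf_matrix(q, n_vec, C)
}

#' Per-trial log-likelihood
#'
#' Log of the guessing mixture
#' \eqn{(1-g)\,p_{model}(response \mid n, t) + g\,q(response)}, where the
#' model pmf is computed with `g = 0` (the mixture is applied exactly once,
#' here). Trials sharing an (n, evidence) cell reuse one pmf computation.
#' Zero total probability is floored at `log(1e-300)`.
#'
#' @param trials A trial tibble.
#' @param params A [seb_params()] or [tim_params()] carrying the guessing
#'   rate `g`.
#' @return Numeric vector of per-trial log-likelihoods (nats).
#' @export
trial_loglik <- function(trials, params) {
  if (nrow(trials) == 0) return(numeric(0))
  Nmax <- params$prior$support_max
  if (any(trials$response > Nmax)) {
    stop("responses above the likelihood support; run clean_trials() first",
         call. = FALSE)
  }
  t <- map_evidence(trials$evidence, trials$experiment)
  key <- paste(trials$n, t)
  cells <- !duplicated(key)
  cell_idx <- match(key, key[cells])
  P0 <- response_pmf_matrix(params, trials$n[cells], t[cells])
  q <- prior_pmf(params$prior)
  p0 <- P0[cbind(cell_idx, trials$response)]
  lik <- (1 - params$g) * p0 + params$g * q[trials$response]
  log(pmax(lik, 1e-300))
}

#' Dataset log-likelihood
#'
#' Sum of [trial_loglik()] over a trial table (0 for an empty table).
#'
#' @inheritParams trial_loglik
#' @return Total log-likelihood in nats.
#' @export
dataset_loglik <- function(trials, params) {
  sum(trial_loglik(trials, params))
}

model_names <- c("seb_continuous", "seb_discrete", "tim")

# Parameter box and constructor for a (model, prior_mode) pair.
model_box <- function(model, prior_mode) {
  lower <- c(R = 0.1, B = 0.1, g = 1e-4)
  upper <- c(R = 200, B = 20, g = 0.5)
  if (prior_mode == "free") {
    lower <- c(lower, mu = -50, sigma = 0.1)
    upper <- c(upper, mu = 50, sigma = 100)
  }
  list(lower = lower, upper = upper)
}

#' Build model parameters from a fitted parameter vector
#'
#' @param model One of `"seb_continuous"`, `"seb_discrete"`, `"tim"`.
#' @param prior_mode `"fixed"` (power-law prior, exponent 2; 3 free
#'   parameters R, B, g) or `"free"` (log-normal prior with fitted mu and
#'   sigma; 5 free parameters).
#' @param theta Named or positional numeric vector: `(R, B, g)` or
#'   `(R, B, g, mu, sigma)`.
#' @param support_max Largest representable response.
#' @return A [seb_params()] or [tim_params()].
#' @export
make_model_params <- function(model = model_names,
                              prior_mode = c("fixed", "free"),
                              theta, support_max = 100L) {
  model <- match.arg(model)
  prior_mode <- match.arg(prior_mode)
  k <- if (prior_mode == "fixed") 3L else 5L
  stopifnot(length(theta) == k)
  prior <- if (prior_mode == "fixed") {
    prior_spec("powerlaw", alpha = 2, support_max = support_max)
  } else {
    prior_spec("lognormal", mu = theta[4], sigma = theta[5],
               support_max = support_max)
  }
  if (model == "tim") {
    tim_params(R = theta[1], B = theta[2], g = theta[3], prior = prior)
  } else {
    seb_params(R = theta[1], B = theta[2], g = theta[3], prior = prior,
               variant = sub("seb_", "", model))
  }
}

#' Maximum-likelihood fit for one participant
#'
#' Differential-evolution maximization of the dataset log-likelihood over
#' the standard search box: R in (0.1, 200), B in (0.1, 20), g in
#' (0.0001, 0.5), and for the free-prior models mu in (-50, 50) and sigma
#' in (0.1, 100). The optimizer runs `n_gen` generations (default 100).
#' AIC is \eqn{2k - 2\,\mathrm{loglik}} with k the number of free
#' parameters (3 fixed-prior, 5 free-prior).
#'
#' @param trials Trial tibble for a single participant (cleaned).
#' @param model One of `"seb_continuous"`, `"seb_discrete"`, `"tim"`.
#' @param prior_mode `"fixed"` or `"free"`.
#' @param seed Integer seed for the optimizer (fits are reproducible
#'   bit-for-bit given data, seed and settings).
#' @param n_gen Differential-evolution generations.
#' @param support_max Largest representable response.
#' @param keep_trial_loglik Keep the per-trial log-likelihood vector at the
#'   optimum (needed by [aic_split()]).
#' @param ... Further arguments to [de_optimize()].
#' @return An object of class `seb_fit`: list with `participant`, `model`,
#'   `prior_mode`, `par` (named vector), `params` (parameter object),
#'   `loglik`, `aic`, `k`, `n_trials`, `seed`, `trace`, and optionally
#'   `trial_ll`.
#' @export
fit_participant <- function(trials, model = model_names,
                            prior_mode = c("fixed", "free"),
                            seed = NULL, n_gen = 100L, support_max = 100L,
                            keep_trial_loglik = TRUE, ...) {
  model <- match.arg(model)
  prior_mode <- match.arg(prior_mode)
  stopifnot(nrow(trials) >= 1)
  box <- model_box(model, prior_mode)
  # cell structure is independent of the parameters: precompute once
  t <- map_evidence(trials$evidence, trials$experiment)
  if (any(trials$response > support_max)) {
    stop("responses above the likelihood support; run clean_trials() first",
         call. = FALSE)
  }
  key <- paste(trials$n, t)
  cells <- !duplicated(key)
  cell_n <- trials$n[cells]
  cell_t <- t[cells]
  pick <- cbind(match(key, key[cells]), trials$response)
  resp <- trials$response
  objective <- function(theta) {
    p <- make_model_params(model, prior_mode, theta, support_max)
    P0 <- response_pmf_matrix(p, cell_n, cell_t)
    q <- prior_pmf(p$prior)
    lik <- (1 - p$g) * P0[pick] + p$g * q[resp]
    -sum(log(pmax(lik, 1e-300)))
  }
  opt <- de_optimize(objective, box$lower, box$upper, n_gen = n_gen,
                     seed = seed, ...)
  par <- stats::setNames(opt$par, names(box$lower))
  k <- length(par)
  params <- make_model_params(model, prior_mode, par, support_max)
  loglik <- -opt$value
  fit <- list(
    participant = if (length(unique(trials$participant)) == 1) {
      as.character(trials$participant[1])
    } else NA_character_,
    model = model, prior_mode = prior_mode,
    par = par, params = params,
    loglik = loglik, aic = 2 * k - 2 * loglik, k = k,
    n_trials = nrow(trials), seed = seed, trace = opt$trace
  )
  if (keep_trial_loglik) fit$trial_ll <- trial_loglik(trials, params)
  structure(fit, class = "seb_fit")
}

#' @export
print.seb_fit <- function(x, ...) {
  cat(sprintf("<seb_fit> %s (%s prior), participant %s\n", x$model,
              x$prior_mode, x$participant))
  cat("  par:", paste(sprintf("%s = %.4g", names(x$par), x$par),
                      collapse = ", "), "\n")
  cat(sprintf("  loglik = %.3f, AIC = %.3f (k = %d, %d trials)\n",
              x$loglik, x$aic, x$k, x$n_trials))
  invisible(x)
}

#' Fit every participant of a cohort
#'
#' Splits a trial table by participant and runs [fit_participant()] on
#' each, with per-participant optimizer seeds derived deterministically
#' from `seed`.
#'
#' @inheritParams fit_participant
#' @param trials Trial tibble for the whole cohort.
#' @param seed Master seed.
#' @return Object of class `cohort_fits`: a named list of `seb_fit`.
#' @export
fit_cohort <- function(trials, model = model_names,
                       prior_mode = c("fixed", "free"),
                       seed = 1L, n_gen = 100L, ...) {
  model <- match.arg(model)
  prior_mode <- match.arg(prior_mode)
  ids <- unique(trials$participant)
  seeds <- with_local_seed(seed,
                           sample.int(.Machine$integer.max - 1L, length(ids)))
  fits <- lapply(seq_along(ids), function(i) {
    fit_participant(trials[trials$participant == ids[i], , drop = FALSE],
                    model = model, prior_mode = prior_mode,
                    seed = seeds[i], n_gen = n_gen, ...)
  })
  names(fits) <- ids
  structure(fits, class = "cohort_fits")
}

#' Tidy table of cohort fit results
#'
#' @param fits A `cohort_fits` object (or list of `seb_fit`).
#' @return Tibble with one row per participant: model, prior mode, fitted
#'   parameters, log-likelihood, AIC.
#' @export
fits_table <- function(fits) {
  dplyr::bind_rows(lapply(fits, function(f) {
    tibble::as_tibble(c(
      list(participant = f$participant, model = f$model,
           prior_mode = f$prior_mode),
      as.list(f$par),
      list(loglik = f$loglik, aic = f$aic, k = f$k, n_trials = f$n_trials)
    ))
  }))
}
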
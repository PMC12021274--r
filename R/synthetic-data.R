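# Synthetic cohorts with the rapid-estimation experiments' trial structure.

# Documented generating ranges for recovery studies; all inside the
# fitting search box.
default_param_ranges <- list(
  R = c(5, 100), B = c(2, 15), g = c(0.001, 0.1),
  mu = c(0.5, 2.5), sigma = c(0.3, 1.2)
)

#' Trial design of one experiment
#'
#' Full factorial crossing of the 15 numerosities with the experiment's 5
#' evidence levels, each combination presented twice: 150 trials, shuffled
#' (reproducibly when `seed` is given).
#'
#' @param experiment Experiment id 1-4.
#' @param seed Optional integer seed for the trial order.
#' @return Tibble with columns `experiment`, `n`, `evidence` (ms for
#'   experiments 1-3, % contrast for experiment 4), 150 rows.
#' @export
make_design <- function(experiment, seed = NULL) {
  levels <- evidence_levels(experiment)
  grid <- expand.grid(n = 1:15, evidence = levels, rep = 1:2,
                      KEEP.OUT.ATTRS = FALSE)
  ord <- with_local_seed(seed, sample.int(nrow(grid)))
  tibble::tibble(experiment = as.integer(experiment),
                 n = as.integer(grid$n[ord]),
                 evidence = grid$evidence[ord])
}

#' Simulate one participant's responses
#'
#' Forward-samples the generating model: on each trial, with probability
#' `g` the response is an uninformed draw from the prior; otherwise it is
#' drawn from the model's `g = 0` response pmf for that (numerosity,
#' evidence) cell. A placeholder response-time column (log-normal around
#' ~0.9 s) is attached solely so that the response-time exclusion rule can
#' be exercised; response times are not modeled.
#'
#' @param params A [seb_params()] or [tim_params()].
#' @param design A design tibble from [make_design()].
#' @param seed Optional integer seed.
#' @param participant Participant id recorded in the output.
#' @return Trial tibble with columns `participant`, `experiment`, `n`,
#'   `evidence`, `response`, `rt`.
#' @export
simulate_participant <- function(params, design, seed = NULL,
                                 participant = "p1") {
  t <- map_evidence(design$evidence, design$experiment)
  key <- paste(design$n, t)
  cells <- !duplicated(key)
  cell_idx <- match(key, key[cells])
  P0 <- response_pmf_matrix(params, design$n[cells], t[cells])
  Nmax <- params$prior$support_max
  prior_p <- prior_pmf(params$prior)
  with_local_seed(seed, {
    guess <- stats::runif(nrow(design)) < params$g
    response <- integer(nrow(design))
    for (i in seq_len(nrow(design))) {
      p <- if (guess[i]) prior_p else P0[cell_idx[i], ]
      response[i] <- sample.int(Nmax, 1L, prob = p)
    }
    rt <- stats::rlnorm(nrow(design), meanlog = log(0.9), sdlog = 0.4)
    tibble::tibble(participant = participant,
                   experiment = design$experiment,
                   n = design$n, evidence = design$evidence,
                   response = response, rt = rt)
  })
}

draw_cohort_params <- function(n, prior_mode, ranges) {
  pars <- c("R", "B", "g", if (prior_mode == "free") c("mu", "sigma"))
  out <- lapply(pars, function(p) {
    stats::runif(n, ranges[[p]][1], ranges[[p]][2])
  })
  names(out) <- pars
  tibble::as_tibble(out)
}

#' Simulate a synthetic cohort
#'
#' Generates `n_participants` independent participants under one model,
#' each with 150 trials of the requested experiment's design. Generating
#' parameters are either fixed (via `fixed_params`) or drawn independently
#' per participant from documented uniform ranges (R in \[5, 100\], B in
#' \[2, 15\], g in \[0.001, 0.1\]; free-prior mode additionally mu in
#' \[0.5, 2.5\], sigma in \[0.3, 1.2\]). Per-participant seeds are derived
#' deterministically from the master seed, so the whole cohort is
#' reproducible.
#'
#' @param n_participants Number of participants.
#' @param model One of `"seb_continuous"`, `"seb_discrete"`, `"tim"`.
#' @param prior_mode `"fixed"` or `"free"`.
#' @param experiment Experiment id 1-4.
#' @param seed Master seed.
#' @param fixed_params Optional named vector `(R, B, g[, mu, sigma])` used
#'   for every participant instead of random draws.
#' @param param_ranges Ranges for random parameter draws.
#' @param support_max Largest representable response.
#' @return List with `trials` (all participants stacked) and `params`
#'   (ledger tibble of true generating parameters, one row per
#'   participant).
#' @export
simulate_cohort <- function(n_participants, model = model_names,
                            prior_mode = c("fixed", "free"),
                            experiment = 1, seed = 1L,
                            fixed_params = NULL,
                            param_ranges = default_param_ranges,
                            support_max = 100L) {
  model <- match.arg(model)
  prior_mode <- match.arg(prior_mode)
  k <- if (prior_mode == "fixed") 3L else 5L
  ids <- sprintf("p%03d", seq_len(n_participants))
  with_local_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_participants)
    ledger <- if (is.null(fixed_params)) {
      draw_cohort_params(n_participants, prior_mode, param_ranges)
    } else {
      stopifnot(length(fixed_params) == k)
      tibble::as_tibble(as.list(stats::setNames(
        rep(fixed_params, 1), c("R", "B", "g",
                                if (k == 5L) c("mu", "sigma"))
      )))[rep(1, n_participants), ]
    }
  })
  trials <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    theta <- as.numeric(ledger[i, ])
    params <- make_model_params(model, prior_mode, theta, support_max)
    design <- make_design(experiment, seed = sub_seeds[2 * i - 1])
    trials[[i]] <- simulate_participant(params, design,
                                        seed = sub_seeds[2 * i],
                                        participant = ids[i])
  }
  ledger <- dplyr::bind_cols(
    tibble::tibble(participant = ids, model = model,
                   prior_mode = prior_mode, experiment = experiment),
    ledger
  )
  list(trials = dplyr::bind_rows(trials), params = ledger)
}
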
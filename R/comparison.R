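# Cohort-level model comparison, descriptive statistics, and recovery
# studies.

align_fits <- function(fits_a, fits_b) {
  ta <- fits_table(fits_a)
  tb <- fits_table(fits_b)
  if (nrow(ta) != nrow(tb) ||
      !setequal(ta$participant, tb$participant)) {
    stop("the two fit sets must cover the same participants", call. = FALSE)
  }
  tb <- tb[match(ta$participant, tb$participant), , drop = FALSE]
  list(a = ta, b = tb)
}

#' Compare two fitted models across a cohort
#'
#' Per-participant AIC differences (model A minus model B; negative values
#' favour A), their sum, a seeded percentile bootstrap confidence interval
#' of the sum over participants, a two-sided paired t-test, and the paired
#' Cohen's d (mean difference over the SD of the differences; reported as
#' `NA` when the differences are constant).
#'
#' @param fits_a,fits_b `cohort_fits` for the same participants.
#' @param n_boot Bootstrap resamples (participants are the resampling
#'   unit).
#' @param seed Optional seed for the bootstrap.
#' @param conf Confidence level of the percentile interval.
#' @return Object of class `comparison_report`: list with `delta` (tibble
#'   of per-participant differences), `delta_sum`, `ci`, `t`, `df`, `p`,
#'   `cohens_d`, `n_boot`.
#' @export
compare_models <- function(fits_a, fits_b, n_boot = 10000L, seed = NULL,
                           conf = 0.95) {
  al <- align_fits(fits_a, fits_b)
  diff <- al$a$aic - al$b$aic
  delta <- tibble::tibble(participant = al$a$participant,
                          aic_a = al$a$aic, aic_b = al$b$aic,
                          delta_aic = diff)
  sums <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      sum(diff[sample.int(length(diff), replace = TRUE)])
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(sums, c(alpha, 1 - alpha), type = 7))
  sd_diff <- stats::sd(diff)
  if (length(diff) >= 2 && sd_diff > 0) {
    tt <- stats::t.test(al$a$aic, al$b$aic, paired = TRUE)
    t_stat <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
    d <- mean(diff) / sd_diff
  } else {
    t_stat <- df <- p <- d <- NA_real_
  }
  structure(
    list(delta = delta, delta_sum = sum(diff), ci = ci,
         t = t_stat, df = df, p = p, cohens_d = d, n_boot = n_boot),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d participants\n", nrow(x$delta)))
  cat(sprintf("  summed delta-AIC (A - B) = %.2f [%.2f, %.2f]\n",
              x$delta_sum, x$ci[1], x$ci[2]))
  cat(sprintf("  paired t(%s) = %.3f, p = %.3g, Cohen's d = %.3f\n",
              format(x$df), x$t, x$p, x$cohens_d))
  invisible(x)
}

#' Descriptive behavioral statistics per design cell
#'
#' Empirical mean, standard deviation, coefficient of variation, bias and
#' mean absolute error of the responses for each (numerosity, evidence)
#' cell. Cells absent from the data are returned with `NA` statistics and
#' flagged.
#'
#' @param trials A (cleaned) trial tibble.
#' @return Tibble with one row per (n, evidence) cell.
#' @export
descriptive_stats <- function(trials) {
  stats_tbl <- trials |>
    dplyr::group_by(n = .data$n, evidence = .data$evidence) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      mean = mean(.data$response),
      sd = stats::sd(.data$response),
      cv = ifelse(mean(.data$response) > 0,
                  stats::sd(.data$response) / mean(.data$response),
                  NA_real_),
      bias = mean(.data$response) - .data$n[1],
      abs_error = mean(abs(.data$response - .data$n)),
      .groups = "drop"
    )
  full <- expand.grid(n = sort(unique(trials$n)),
                      evidence = sort(unique(trials$evidence)),
                      KEEP.OUT.ATTRS = FALSE)
  out <- dplyr::left_join(tibble::as_tibble(full), stats_tbl,
                          by = c("n", "evidence"))
  out$n_trials[is.na(out$n_trials)] <- 0L
  out$empty <- out$n_trials == 0L
  out
}

#' AIC differences split by design cell
#'
#' Aggregates the per-trial log-likelihood contributions retained in the
#' fits into \eqn{2\Delta\mathrm{loglik}} per split cell (numerosity, or
#' numerosity by evidence). The parameter-count term of the AIC cancels in
#' within-participant comparisons of models with equal k and is not split.
#' The split cells sum to the total \eqn{2\Delta\mathrm{loglik}}.
#'
#' @param fits_a,fits_b `cohort_fits` fitted with
#'   `keep_trial_loglik = TRUE`.
#' @param trials The trial tibble the fits were computed on.
#' @param by `"numerosity"` or `"numerosity_evidence"`.
#' @return Tibble of per-cell delta-AIC contributions (model A minus
#'   model B; negative favours A).
#' @export
aic_split <- function(fits_a, fits_b, trials,
                      by = c("numerosity", "numerosity_evidence")) {
  by <- match.arg(by)
  ids <- names(fits_a)
  if (!setequal(ids, names(fits_b))) {
    stop("the two fit sets must cover the same participants", call. = FALSE)
  }
  rows <- lapply(ids, function(id) {
    fa <- fits_a[[id]]; fb <- fits_b[[id]]
    tr <- trials[trials$participant == id, , drop = FALSE]
    if (is.null(fa$trial_ll) || is.null(fb$trial_ll)) {
      stop("fits must retain per-trial log-likelihoods", call. = FALSE)
    }
    stopifnot(nrow(tr) == length(fa$trial_ll),
              nrow(tr) == length(fb$trial_ll))
    tibble::tibble(participant = id, n = tr$n, evidence = tr$evidence,
                   delta = 2 * (fb$trial_ll - fa$trial_ll))
  })
  contrib <- dplyr::bind_rows(rows)
  keys <- if (by == "numerosity") "n" else c("n", "evidence")
  contrib |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(delta_aic = sum(.data$delta),
                     n_trials = dplyr::n(), .groups = "drop")
}

#' Parameter recovery study
#'
#' Simulates a cohort from one model with known parameters, refits the
#' same model, and summarizes recovery per parameter (Pearson correlation
#' with a one-sided test for positive association, bias, RMSE) plus flags
#' for estimates at the search-box boundary.
#'
#' @param model One of `"seb_continuous"`, `"seb_discrete"`, `"tim"`.
#' @param n_participants Simulated participants.
#' @param prior_mode `"fixed"` or `"free"`.
#' @param experiment Experiment id 1-4.
#' @param seed Master seed (simulation and fitting seeds derive from it).
#' @param n_gen Differential-evolution generations per fit.
#' @param ... Further arguments to [fit_cohort()].
#' @return Object of class `recovery_report`: list with `pairs` (tibble of
#'   participant, parameter, true, estimated, at_boundary) and `stats`
#'   (tibble of parameter, correlation, p-value, bias, rmse).
#' @export
parameter_recovery <- function(model = model_names, n_participants = 100L,
                               prior_mode = c("fixed", "free"),
                               experiment = 1, seed = 1L, n_gen = 100L,
                               ...) {
  model <- match.arg(model)
  prior_mode <- match.arg(prior_mode)
  sim <- simulate_cohort(n_participants, model, prior_mode,
                         experiment = experiment, seed = seed)
  fits <- fit_cohort(sim$trials, model, prior_mode, seed = seed + 1L,
                     n_gen = n_gen, keep_trial_loglik = FALSE, ...)
  ft <- fits_table(fits)
  box <- model_box(model, prior_mode)
  pars <- names(box$lower)
  pairs <- dplyr::bind_rows(lapply(pars, function(p) {
    est <- ft[[p]][match(sim$params$participant, ft$participant)]
    edge <- 1e-6 * (box$upper[[p]] - box$lower[[p]])
    tibble::tibble(participant = sim$params$participant, param = p,
                   true = sim$params[[p]], estimated = est,
                   at_boundary = est <= box$lower[[p]] + edge |
                     est >= box$upper[[p]] - edge)
  }))
  stats_tbl <- pairs |>
    dplyr::group_by(param = .data$param) |>
    dplyr::summarise(
      r = stats::cor(.data$true, .data$estimated),
      p_value = stats::cor.test(.data$true, .data$estimated,
                                alternative = "greater")$p.value,
      bias = mean(.data$estimated - .data$true),
      rmse = sqrt(mean((.data$estimated - .data$true)^2)),
      n_boundary = sum(.data$at_boundary),
      .groups = "drop"
    )
  structure(list(model = model, prior_mode = prior_mode, pairs = pairs,
                 stats = stats_tbl, n_participants = n_participants,
                 seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %s (%s prior), %d participants\n",
              x$model, x$prior_mode, x$n_participants))
  print(x$stats)
  invisible(x)
}

#' Model recovery study
#'
#' For each replicate, simulates one cohort from each generating model,
#' fits both models to each cohort, and records the summed AIC difference
#' (generating model minus competitor; negative means the generator is
#' recovered) together with the per-participant best-model confusion
#' counts.
#'
#' @param generators Generating models (default SEB continuous and TIM).
#' @param n_replicates Seeded replicates.
#' @param n_participants Participants per cohort.
#' @param prior_mode `"fixed"` or `"free"`.
#' @param experiment Experiment id 1-4.
#' @param seed Master seed.
#' @param n_gen Differential-evolution generations per fit.
#' @return List with `replicates` (tibble: replicate, generator,
#'   delta_aic_sum, n_best_generator, n_participants) and `confusion`
#'   (tibble: generator x best-fitting counts).
#' @export
model_recovery <- function(generators = c("seb_continuous", "tim"),
                           n_replicates = 20L, n_participants = 20L,
                           prior_mode = c("fixed", "free"),
                           experiment = 1, seed = 1L, n_gen = 100L) {
  prior_mode <- match.arg(prior_mode)
  stopifnot(all(generators %in% model_names), length(generators) == 2)
  rows <- list()
  for (rep_i in seq_len(n_replicates)) {
    for (gen in generators) {
      other <- setdiff(generators, gen)
      rep_seed <- seed + 1000L * rep_i + 7L * match(gen, generators)
      sim <- simulate_cohort(n_participants, gen, prior_mode,
                             experiment = experiment, seed = rep_seed)
      fit_gen <- fit_cohort(sim$trials, gen, prior_mode,
                            seed = rep_seed + 1L, n_gen = n_gen,
                            keep_trial_loglik = FALSE)
      fit_oth <- fit_cohort(sim$trials, other, prior_mode,
                            seed = rep_seed + 2L, n_gen = n_gen,
                            keep_trial_loglik = FALSE)
      aic_gen <- fits_table(fit_gen)$aic
      aic_oth <- fits_table(fit_oth)$aic
      rows[[length(rows) + 1L]] <- tibble::tibble(
        replicate = rep_i, generator = gen,
        delta_aic_sum = sum(aic_gen) - sum(aic_oth),
        n_best_generator = sum(aic_gen < aic_oth),
        n_participants = n_participants
      )
    }
  }
  replicates <- dplyr::bind_rows(rows)
  confusion <- replicates |>
    dplyr::group_by(generator = .data$generator) |>
    dplyr::summarise(
      best_generator = sum(.data$n_best_generator),
      best_other = sum(.data$n_participants - .data$n_best_generator),
      .groups = "drop"
    )
  list(replicates = replicates, confusion = confusion)
}
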
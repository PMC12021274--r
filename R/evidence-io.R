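# Evidence-unit mapping and trial-table I/O.

duration_levels_ms <- c(40, 80, 160, 320, 640)
contrast_levels_pct <- c(10, 20, 40, 80, 160)

#' Evidence levels of an experiment
#'
#' Experiments 1-3 manipulate presentation duration (ms); experiment 4
#' manipulates Weber contrast (%) at a fixed 200 ms presentation.
#'
#' @param experiment Experiment id, 1-4.
#' @return Numeric vector of the five evidence levels.
#' @export
evidence_levels <- function(experiment) {
  if (!experiment %in% 1:4) stop("unknown experiment id", call. = FALSE)
  if (experiment == 4) contrast_levels_pct else duration_levels_ms
}

#' Map an evidence level to an effective duration in seconds
#'
#' Durations pass through (ms to s). Contrast levels of experiment 4 are
#' assigned the durations used for pooling across experiments:
#' 10% -> 40 ms, 20% -> 80 ms, 40% -> 160 ms, 80% -> 320 ms,
#' 160% -> 640 ms.
#'
#' @param evidence Evidence level(s): duration in ms (experiments 1-3) or
#'   Weber contrast in % (experiment 4).
#' @param experiment Experiment id(s), 1-4; recycled against `evidence`.
#' @return Effective duration(s) in seconds.
#' @export
map_evidence <- function(evidence, experiment) {
  stopifnot(length(experiment) %in% c(1L, length(evidence)))
  experiment <- rep_len(experiment, length(evidence))
  if (any(!experiment %in% 1:4)) stop("unknown experiment id", call. = FALSE)
  out <- numeric(length(evidence))
  dur <- experiment %in% 1:3
  if (any(dur)) {
    bad <- !evidence[dur] %in% duration_levels_ms
    if (any(bad)) {
      stop("unknown duration level(s): ",
           paste(unique(evidence[dur][bad]), collapse = ", "), call. = FALSE)
    }
    out[dur] <- evidence[dur] / 1000
  }
  if (any(!dur)) {
    idx <- match(evidence[!dur], contrast_levels_pct)
    if (anyNA(idx)) {
      stop("unknown contrast level(s): ",
           paste(unique(evidence[!dur][is.na(idx)]), collapse = ", "),
           call. = FALSE)
    }
    out[!dur] <- duration_levels_ms[idx] / 1000
  }
  out
}

trial_required_cols <- c("participant", "experiment", "n", "evidence",
                         "response")

# Validate a trial table; returns a character vector of problems (empty if
# the table is schema-valid). Row numbers refer to the data rows.
validate_trials <- function(trials) {
  problems <- character(0)
  missing <- setdiff(trial_required_cols, names(trials))
  if (length(missing) > 0) {
    return(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(trials) == 0) return(problems)  # headed but empty is valid
  check_int <- function(x, col, lo = 1, hi = Inf) {
    bad <- which(!is.finite(x) | x < lo | x > hi | x != floor(x))
    if (length(bad) > 0) {
      paste0("row ", bad, ": column `", col, "` must be an integer in [",
             lo, ", ", ifelse(is.finite(hi), hi, "Inf"), "], got ", x[bad])
    } else character(0)
  }
  if (!is.numeric(trials$n)) {
    problems <- c(problems, "column `n` must be numeric")
  } else {
    problems <- c(problems, check_int(trials$n, "n", 1, 15))
  }
  if (!is.numeric(trials$response)) {
    problems <- c(problems, "column `response` must be numeric")
  } else {
    problems <- c(problems, check_int(trials$response, "response", 1))
  }
  if (!is.numeric(trials$experiment)) {
    problems <- c(problems, "column `experiment` must be numeric")
  } else {
    bad <- which(!trials$experiment %in% 1:4)
    if (length(bad) > 0) {
      problems <- c(problems,
                    paste0("row ", bad, ": column `experiment` must be 1-4"))
    }
  }
  if (length(problems) == 0) {
    for (ex in unique(trials$experiment)) {
      lv <- evidence_levels(ex)
      rows <- which(trials$experiment == ex & !trials$evidence %in% lv)
      if (length(rows) > 0) {
        problems <- c(problems,
                      paste0("row ", rows, ": column `evidence` not in the ",
                             "level set of experiment ", ex))
      }
    }
  }
  if ("rt" %in% names(trials) && !is.numeric(trials$rt)) {
    problems <- c(problems, "column `rt` must be numeric (seconds)")
  }
  problems
}

#' Read a trial table from CSV
#'
#' Expects columns `participant`, `experiment`, `n`, `evidence`,
#' `response` and optionally `rt` (seconds) plus any extra columns (e.g.
#' the true-parameter columns written for synthetic cohorts). The schema
#' is validated and all offending rows are reported together.
#'
#' @param path CSV file path.
#' @return A tibble of trials.
#' @export
read_trials <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  trials <- tibble::as_tibble(raw)
  problems <- validate_trials(trials)
  if (length(problems) > 0) {
    stop("invalid trial table `", path, "`:\n  ",
         paste(utils::head(problems, 20), collapse = "\n  "),
         if (length(problems) > 20) "\n  ..." else "",
         call. = FALSE)
  }
  trials$participant <- as.character(trials$participant)
  trials
}

#' Write a trial table to CSV
#'
#' @param trials A trial tibble (validated before writing).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  problems <- validate_trials(trials)
  if (length(problems) > 0) {
    stop("refusing to write invalid trial table:\n  ",
         paste(utils::head(problems, 20), collapse = "\n  "), call. = FALSE)
  }
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}
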
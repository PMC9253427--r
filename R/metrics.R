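# Behavioral variables, subject classification, and the experiment loop.

#' Discounted- and immediate-choice frequencies
#'
#' A discounted choice is the immediate choice in the reward condition and
#' the delayed choice in the loss condition (in reward trials the target
#' probability p1 is also the discounting probability; in loss trials the
#' discounting probability is 1 - p1). Frequencies are computed over
#' responded trials, stratified by condition, run (when present) and —
#' optionally — the target probability level; empty strata are omitted
#' with a warning. Reaction times are summarized by the lower median.
#'
#' @param data Choice data frame.
#' @param stratify_by_target Also stratify by `target_p1` (default `TRUE`
#'   when the column carries non-missing values).
#' @return Tibble with `condition`, optional `run` and `target_p1`,
#'   `n_trials`, `discounted_frequency`, `immediate_frequency`,
#'   `median_rt_ms`.
#' @export
discounted_choice_frequency <- function(data, stratify_by_target = TRUE) {
  resp <- data[.is_responded(data$action), , drop = FALSE]
  if (nrow(resp) == 0L) {
    warning("no responded trials; empty summary", call. = FALSE)
    return(tibble::tibble())
  }
  keys <- intersect(c("condition", "run"), names(resp))
  use_target <- stratify_by_target && !is.null(resp$target_p1) &&
    any(!is.na(resp$target_p1))
  if (use_target) keys <- c(keys, "target_p1")
  if (!length(keys)) {
    stop("data must carry at least a 'condition' column", call. = FALSE)
  }
  key_df <- resp[keys]
  key_df[] <- lapply(key_df, function(k) {
    k[is.na(k)] <- if (is.numeric(k)) NaN else "<none>"
    k
  })
  groups <- split(seq_len(nrow(resp)), key_df, drop = TRUE)
  rows <- lapply(groups, function(idx) {
    g <- resp[idx, , drop = FALSE]
    imm <- mean(g$action == "immediate")
    disc <- ifelse(g$condition[1] == "reward", imm, 1 - imm)
    out <- g[1, keys, drop = FALSE]
    out$n_trials <- length(idx)
    out$discounted_frequency <- disc
    out$immediate_frequency <- imm
    out$median_rt_ms <- if (is.null(g$rt_ms)) NA_real_ else
      lower_median(g$rt_ms)
    out
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  ord <- do.call(order, out[keys])
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default subject-exclusion thresholds
#'
#' Non-discounter: fewer than 5% discounted choices in a condition.
#' Repeater: the same option in more than 95% of run-A trials. Extreme
#' discount rate: fitted kappa > 2. Excess missingness: more than 10%
#' unanswered trials in a run (a stricter 30%-per-condition variant can be
#' set via `excess_missing`).
#'
#' @param non_discounter,repeater,extreme_kappa,excess_missing Numeric
#'   thresholds.
#' @return Named list of thresholds.
#' @export
classification_thresholds <- function(non_discounter = 0.05,
                                      repeater = 0.95,
                                      extreme_kappa = 2,
                                      excess_missing = 0.10) {
  list(non_discounter = non_discounter, repeater = repeater,
       extreme_kappa = extreme_kappa, excess_missing = excess_missing)
}

#' Classify a subject against exclusion criteria
#'
#' Flags derive deterministically from the thresholds and are invariant to
#' trial order: `non_discounter` per condition (share of discounted
#' choices below threshold), `repeater` per run (one option repeated in
#' more than the threshold share of responded trials), `excess_missing`
#' per run, and `extreme_kappa` per supplied fit.
#'
#' @param data Choice data frame for one subject (any mix of runs and
#'   conditions).
#' @param fits Optional named list of `dd_fit`/`model_params` whose kappa
#'   values are screened.
#' @param thresholds See [classification_thresholds()].
#' @return List of class `subject_flags` with named logical vectors
#'   `non_discounter`, `repeater`, `excess_missing`, `extreme_kappa`.
#' @export
classify_subjects <- function(data, fits = NULL,
                              thresholds = classification_thresholds()) {
  resp <- data[.is_responded(data$action), , drop = FALSE]
  non_disc <- vapply(unique(data$condition), function(cond) {
    g <- resp[resp$condition == cond, , drop = FALSE]
    if (nrow(g) == 0L) return(NA)
    imm <- mean(g$action == "immediate")
    disc <- if (cond == "reward") imm else 1 - imm
    disc < thresholds$non_discounter
  }, logical(1))
  runs <- if (is.null(data$run)) "A" else unique(data$run)
  repeater <- vapply(runs, function(r) {
    g <- if (is.null(data$run)) resp else
      resp[resp$run == r, , drop = FALSE]
    if (nrow(g) == 0L) return(NA)
    imm <- mean(g$action == "immediate")
    max(imm, 1 - imm) > thresholds$repeater
  }, logical(1))
  missingness <- vapply(runs, function(r) {
    g <- if (is.null(data$run)) data else data[data$run == r, , drop = FALSE]
    if (nrow(g) == 0L) return(NA)
    mean(!.is_responded(g$action)) > thresholds$excess_missing
  }, logical(1))
  extreme <- logical(0)
  if (!is.null(fits)) {
    extreme <- vapply(fits, function(f) {
      as_model_params(f)$kappa > thresholds$extreme_kappa
    }, logical(1))
  }
  structure(list(non_discounter = non_disc, repeater = repeater,
                 excess_missing = missingness, extreme_kappa = extreme),
            class = "subject_flags")
}

#' Run the full adaptive-paradigm loop on a synthetic population
#'
#' Orchestrates, per subject: generate the common run-A trials, simulate
#' (or ingest) choices, fit the generating model per condition, generate
#' the adaptive run-B trials from the fits, simulate (or ingest) run-B
#' choices, and compute behavioral summaries, exclusion flags and —
#' optionally — the cross-run model-comparison table. All derived seeds
#' are recorded in the report; a rerun with identical inputs reproduces it
#' exactly.
#'
#' @param population A [population_spec()] (synthetic path), or a choice
#'   data frame with a `subject_id` column containing observed run-A (and
#'   optionally run-B) choices (ingest path).
#' @param run_a_config,run_b_config Grid configurations.
#' @param generating_model Model used to fit run A and generate run B
#'   (default: the population's model, or `"hyperbolic"` for ingested
#'   data).
#' @param compare_models Optional character vector of models for the
#'   out-of-sample comparison (`NULL` skips it; comparison needs run-B
#'   choices).
#' @param config A [fit_config()].
#' @param seed Master seed for all randomized stages.
#' @return List of class `dd_experiment_report`: per-subject entries
#'   (trials, choices, fits, flags, optional comparison), a pooled
#'   `behavioral_summary`, and `seeds`.
#' @export
run_experiment_loop <- function(population,
                                run_a_config = run_a_config("exp1"),
                                run_b_config = run_b_config("exp1"),
                                generating_model = NULL,
                                compare_models = NULL,
                                config = fit_config(), seed = 1L) {
  synthetic <- inherits(population, "population_spec")
  if (synthetic) {
    generating_model <- generating_model %||% population$model
    agents <- sample_population(population)
    conditions <- population$conditions
    ids <- vapply(agents, `[[`, character(1), "subject_id")
  } else {
    generating_model <- generating_model %||% "hyperbolic"
    ids <- unique(population$subject_id)
    conditions <- run_a_config$conditions
    agents <- NULL
  }
  run_a_config$conditions <- conditions
  run_b_config$conditions <- conditions

  subjects <- list()
  for (i in seq_along(ids)) {
    id <- ids[[i]]
    entry <- tryCatch({
      if (synthetic) {
        run_a <- generate_run_a(run_a_config,
                                seed = derive_seed(seed, i, 10L),
                                subject_id = id)
        choices_a <- simulate_choices(agents[[i]], run_a,
                                      seed = derive_seed(seed, i, 11L),
                                      missing_rate = population$missing_rate)
      } else {
        subj <- population[population$subject_id == id, , drop = FALSE]
        choices_a <- subj[subj$run == "A", , drop = FALSE]
        if (nrow(choices_a) == 0L) stop("no run-A choices")
      }
      fits_a <- lapply(setNames(conditions, conditions), function(cond) {
        fit_mle(generating_model,
                choices_a[choices_a$condition == cond, , drop = FALSE],
                config)
      })
      run_b <- generate_run_b(fits_a, run_b_config,
                              seed = derive_seed(seed, i, 12L),
                              subject_id = id)
      choices_b <- NULL
      if (synthetic) {
        choices_b <- simulate_choices(agents[[i]], run_b,
                                      seed = derive_seed(seed, i, 13L),
                                      missing_rate = population$missing_rate)
      } else {
        subj <- population[population$subject_id == id, , drop = FALSE]
        cb <- subj[subj$run == "B", , drop = FALSE]
        if (nrow(cb) > 0L) choices_b <- cb
      }
      all_choices <- if (is.null(choices_b)) choices_a else {
        shared <- intersect(names(choices_a), names(choices_b))
        rbind(choices_a[shared], choices_b[shared])
      }
      flags <- classify_subjects(all_choices, fits_a)
      comparison <- NULL
      if (!is.null(compare_models) && !is.null(choices_b)) {
        comparison <- do.call(rbind, lapply(conditions, function(cond) {
          tab <- cross_run_model_comparison(
            choices_a[choices_a$condition == cond, , drop = FALSE],
            choices_b[choices_b$condition == cond, , drop = FALSE],
            compare_models, config)
          tab$condition <- cond
          tab
        }))
      }
      list(subject_id = id, run_a = choices_a, run_b = choices_b,
           fits_run_a = fits_a, flags = flags, comparison = comparison,
           true_params = if (synthetic) agents[[i]]$params else NULL,
           error = NULL, stage = NA_character_)
    }, error = function(e) {
      list(subject_id = id, error = conditionMessage(e))
    })
    subjects[[id]] <- entry
  }

  pooled <- do.call(rbind, lapply(subjects, function(s) {
    if (!is.null(s$error)) return(NULL)
    x <- if (is.null(s$run_b)) s$run_a else {
      shared <- intersect(names(s$run_a), names(s$run_b))
      rbind(s$run_a[shared], s$run_b[shared])
    }
    x$subject_id <- s$subject_id
    x
  }))
  behavioral_summary <- if (is.null(pooled)) NULL else
    discounted_choice_frequency(pooled)
  structure(list(subjects = subjects,
                 behavioral_summary = behavioral_summary,
                 generating_model = generating_model,
                 seeds = list(master = seed),
                 n_subjects = length(ids)),
            class = "dd_experiment_report")
}

#' @export
print.dd_experiment_report <- function(x, ...) {
  failed <- sum(vapply(x$subjects, function(s) !is.null(s$error), logical(1)))
  cat(sprintf("<dd_experiment_report: %d subjects (%d failed), model %s>\n",
              x$n_subjects, failed, x$generating_model))
  if (!is.null(x$behavioral_summary)) {
    print(x$behavioral_summary, n = 12)
  }
  invisible(x)
}
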
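# Synthetic-agent generator and choice simulator.
#
# Agents are parameter draws from configurable distributions; their choices
# on a trial table are Bernoulli draws from the softmax immediate-choice
# probability under their own (condition-specific) parameters. This module
# provides all simulation fixtures, plus the full-loop parameter-recovery
# harness (generate run A -> simulate -> fit -> generate run B -> simulate
# -> refit).

#' Distribution specifications for population parameters
#'
#' Small declarative specs used by [population_spec()]: a point mass, a
#' uniform, a log-uniform, or a finite mixture of such components.
#'
#' @param value,min,max Distribution parameters; `dist_loguniform()`
#'   requires `min > 0`.
#' @param specs List of component specs (for `dist_mixture()`).
#' @param weights Positive component weights (normalized internally).
#' @return A list of class `dd_dist`.
#' @export
dist_fixed <- function(value) {
  structure(list(dist = "fixed", value = value), class = "dd_dist")
}

#' @rdname dist_fixed
#' @export
dist_uniform <- function(min, max) {
  stopifnot(min <= max)
  structure(list(dist = "uniform", min = min, max = max), class = "dd_dist")
}

#' @rdname dist_fixed
#' @export
dist_loguniform <- function(min, max) {
  stopifnot(min > 0, min <= max)
  structure(list(dist = "loguniform", min = min, max = max),
            class = "dd_dist")
}

#' @rdname dist_fixed
#' @export
dist_mixture <- function(specs, weights) {
  stopifnot(length(specs) == length(weights), all(weights > 0))
  structure(list(dist = "mixture", specs = specs,
                 weights = weights / sum(weights)),
            class = "dd_dist")
}

# inverse CDF; for mixtures the unit interval is partitioned by the
# cumulative weights (comonotone transform, exact for sampling and
# well-suited to copula-based cross-condition coupling)
.dist_quantile <- function(spec, u) {
  switch(spec$dist,
    fixed = rep(spec$value, length(u)),
    uniform = spec$min + u * (spec$max - spec$min),
    loguniform = exp(log(spec$min) + u * (log(spec$max) - log(spec$min))),
    mixture = {
      cw <- cumsum(spec$weights)
      comp <- findInterval(u, c(0, head(cw, -1) + .Machine$double.eps))
      comp <- clamp(comp, 1L, length(spec$weights))
      lo <- c(0, head(cw, -1))[comp]
      u_local <- clamp((u - lo) / spec$weights[comp], 0, 1)
      out <- numeric(length(u))
      for (k in unique(comp)) {
        idx <- comp == k
        out[idx] <- .dist_quantile(spec$specs[[k]], u_local[idx])
      }
      out
    },
    stop(sprintf("unknown distribution '%s'", spec$dist), call. = FALSE)
  )
}

.default_kappa_dist <- function(model) {
  if (model %in% c("hyperbolic", "hyperboloid", "modified_hyperboloid")) {
    # bimodal: a dominant low-rate mode spanning several orders of
    # magnitude plus a small extreme-discounter mode
    dist_mixture(list(dist_loguniform(1e-5, 3), dist_uniform(7, 10)),
                 weights = c(0.9, 0.1))
  } else if (model == "constant_sensitivity") {
    dist_loguniform(1e-4, 0.5)
  } else {
    # per-day retention rates close to 1 (mild daily decay)
    dist_uniform(0.9, 0.999)
  }
}

.default_extras_dists <- function(model) {
  switch(model,
    quasi_hyperbolic = list(gamma = dist_uniform(0.7, 1)),
    hyperboloid = list(s = dist_uniform(0.3, 0.9)),
    modified_hyperboloid = list(s = dist_uniform(0.3, 0.9)),
    double_exponential = list(kappa2 = dist_uniform(0.5, 0.95),
                              w = dist_uniform(0.3, 0.7)),
    constant_sensitivity = list(delta = dist_loguniform(0.5, 2)),
    list()
  )
}

#' Specify a synthetic agent population
#'
#' @param n_subjects Number of agents.
#' @param model Generating model identifier.
#' @param kappa,beta `dd_dist` specs for the discount rate and choice
#'   sensitivity (defaults: a bimodal kappa mixture for the hyperbolic
#'   family, log-uniform beta over \[0.1, 5\]).
#' @param extras Named list of `dd_dist` specs for model-specific
#'   parameters (defaults filled per model).
#' @param reward_loss_cor Rank-correlation knob in \[-1, 1\] linking reward
#'   and loss parameters of the same agent via a Gaussian copula
#'   (default 0.5).
#' @param conditions Conditions for which parameters are drawn.
#' @param missing_rate Probability of a missing response per trial when
#'   simulating (default 0).
#' @param seed RNG seed; sampling is deterministic given the seed.
#' @return A list of class `population_spec`.
#' @export
population_spec <- function(n_subjects, model, kappa = NULL, beta = NULL,
                            extras = NULL, reward_loss_cor = 0.5,
                            conditions = c("reward", "loss"),
                            missing_rate = 0, seed = 1L) {
  model <- match.arg(model, .DD_MODELS)
  extras_def <- .default_extras_dists(model)
  extras <- modifyList(extras_def, extras %||% list())
  dists <- c(list(kappa = kappa %||% .default_kappa_dist(model),
                  beta = beta %||% dist_loguniform(0.1, 5)),
             extras)
  for (nm in names(dists)) {
    if (!inherits(dists[[nm]], "dd_dist")) {
      stop(sprintf("'%s' must be a dd_dist specification", nm),
           call. = FALSE)
    }
  }
  needed <- model_free_params(model)
  if (!all(needed %in% names(dists))) {
    stop(sprintf("missing distribution(s) for: %s",
                 paste(setdiff(needed, names(dists)), collapse = ", ")),
         call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects), model = model,
                 dists = dists[needed],
                 reward_loss_cor = reward_loss_cor,
                 conditions = match.arg(conditions, c("reward", "loss"),
                                        several.ok = TRUE),
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "population_spec")
}

#' Sample a synthetic agent population
#'
#' Draws per-condition parameter sets for each agent. For two conditions,
#' each parameter's reward and loss draws are coupled through a Gaussian
#' copula with correlation `reward_loss_cor`, so the same agent tends to
#' discount similarly (but not identically) for gains and losses. All
#' sampled parameters are clamped into the model's bounds and validated.
#'
#' @param spec A [population_spec()].
#' @return List of agents, each a list with `subject_id` and `params`
#'   (named list of `model_params` per condition).
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_subjects
  if (n == 0L) return(list())
  rho <- spec$reward_loss_cor
  two_cond <- length(spec$conditions) == 2L
  draws <- withr::with_seed(spec$seed, {
    lapply(spec$dists, function(d) {
      z1 <- stats::rnorm(n)
      if (two_cond) {
        z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
        list(pnorm(z1), pnorm(z2))
      } else {
        list(pnorm(z1))
      }
    })
  })
  bounds <- param_bounds(spec$model)
  cond_values <- lapply(seq_along(spec$conditions), function(ci) {
    vals <- lapply(names(spec$dists), function(nm) {
      v <- .dist_quantile(spec$dists[[nm]], draws[[nm]][[ci]])
      clamp(v, bounds[[nm]][1], bounds[[nm]][2])
    })
    names(vals) <- names(spec$dists)
    vals
  })
  names(cond_values) <- spec$conditions
  lapply(seq_len(n), function(i) {
    params <- lapply(spec$conditions, function(cond) {
      v <- lapply(cond_values[[cond]], `[[`, i)
      do.call(model_params, c(list(model = spec$model), v))
    })
    names(params) <- spec$conditions
    list(subject_id = sprintf("agent%03d", i), params = params)
  })
}

.agent_params <- function(agent, condition) {
  if (inherits(agent, "model_params") || inherits(agent, "dd_fit")) {
    return(as_model_params(agent))
  }
  p <- agent$params %||% agent
  if (!is.null(p[[condition]])) return(as_model_params(p[[condition]]))
  stop(sprintf("agent has no parameters for condition '%s'", condition),
       call. = FALSE)
}

#' Simulate choices of a synthetic agent on a trial table
#'
#' Each trial's action is a Bernoulli draw from the agent's softmax
#' immediate-choice probability under its condition-specific parameters;
#' optionally a fraction of responses is replaced by `"missing"` uniformly
#' at random. Reaction times are not modeled and are emitted as `NA`.
#'
#' @param agent An agent from [sample_population()], or a single
#'   `model_params`/`dd_fit` (applied to all conditions), or a named list
#'   of parameter sets per condition.
#' @param trials Trial table as produced by [generate_run_a()] /
#'   [generate_run_b()].
#' @param seed Integer seed; the simulation is deterministic given it.
#' @param missing_rate Probability of a missing response per trial.
#' @return The trial table with `action` and `rt_ms` columns appended.
#' @export
simulate_choices <- function(agent, trials, seed = 1L, missing_rate = 0) {
  n <- nrow(trials)
  p1 <- numeric(n)
  for (cond in unique(trials$condition)) {
    idx <- trials$condition == cond
    params <- .agent_params(agent, cond)
    assert_params(params)
    f <- discount_factor(params, trials$delay_days[idx])
    p1[idx] <- immediate_choice_prob(params$beta, trials$r1[idx],
                                     f * trials$r2[idx])
  }
  withr::with_seed(seed, {
    u <- runif(n)
    action <- ifelse(u < p1, "immediate", "delayed")
    if (missing_rate > 0) {
      action[runif(n) < missing_rate] <- "missing"
    }
  })
  trials$action <- action
  trials$rt_ms <- NA_real_
  trials
}

#' Full-loop parameter-recovery study
#'
#' For each agent of a synthetic population: generate the common run-A
#' trials, simulate choices, fit the generating model per condition,
#' generate the adaptive run-B trials from the fit, simulate choices on
#' them with the agent's true parameters, and refit. Reports
#' true-vs-estimated parameter agreement and how closely the evoked
#' run-B choice frequencies track the target probabilities.
#'
#' @param spec A [population_spec()].
#' @param run_a_config,run_b_config Grid configurations.
#' @param config A [fit_config()].
#' @return List of class `dd_recovery`: `per_agent` (tibble of true and
#'   estimated parameters per agent x condition), `observed_freq` (tibble
#'   of observed vs target immediate-choice frequencies per target level),
#'   `summary` (per-parameter Spearman correlations, bias, RMSE, cross-run
#'   estimate correlation), `errors` (per-agent failures, never fatal).
#' @export
parameter_recovery <- function(spec,
                               run_a_config = run_a_config("exp2"),
                               run_b_config = run_b_config("exp2"),
                               config = fit_config()) {
  agents <- sample_population(spec)
  run_b_config$conditions <- intersect(run_b_config$conditions,
                                       spec$conditions)
  run_a_config$conditions <- intersect(run_a_config$conditions,
                                       spec$conditions)
  par_names <- model_free_params(spec$model)
  rows <- list()
  freq_rows <- list()
  errors <- character(0)

  run_a <- generate_run_a(run_a_config, seed = derive_seed(spec$seed, 0L))
  for (i in seq_along(agents)) {
    agent <- agents[[i]]
    res <- tryCatch({
      choices_a <- simulate_choices(agent, run_a,
                                    seed = derive_seed(spec$seed, i, 1L),
                                    missing_rate = spec$missing_rate)
      fits_a <- lapply(setNames(spec$conditions, spec$conditions),
                       function(cond) {
        fit_mle(spec$model,
                choices_a[choices_a$condition == cond, , drop = FALSE],
                config)
      })
      run_b <- generate_run_b(fits_a, run_b_config,
                              seed = derive_seed(spec$seed, i, 2L),
                              subject_id = agent$subject_id)
      choices_b <- simulate_choices(agent, run_b,
                                    seed = derive_seed(spec$seed, i, 3L),
                                    missing_rate = spec$missing_rate)
      fits_b <- lapply(setNames(spec$conditions, spec$conditions),
                       function(cond) {
        fit_mle(spec$model,
                choices_b[choices_b$condition == cond, , drop = FALSE],
                config)
      })
      for (cond in spec$conditions) {
        true_p <- agent$params[[cond]]
        row <- tibble::tibble(subject_id = agent$subject_id,
                              condition = cond)
        for (nm in par_names) {
          row[[paste0("true_", nm)]] <- true_p[[nm]]
          row[[paste0("est_a_", nm)]] <- fits_a[[cond]]$params[[nm]]
          row[[paste0("est_b_", nm)]] <- fits_b[[cond]]$params[[nm]]
        }
        rows[[length(rows) + 1L]] <- row
        cb <- choices_b[choices_b$condition == cond &
                          .is_responded(choices_b$action), , drop = FALSE]
        agg <- stats::aggregate(cb$action == "immediate",
                                by = list(target_p1 = cb$target_p1), mean)
        freq_rows[[length(freq_rows) + 1L]] <- tibble::tibble(
          subject_id = agent$subject_id, condition = cond,
          target_p1 = agg$target_p1, observed_freq = agg$x
        )
      }
      TRUE
    }, error = function(e) {
      errors <<- c(errors,
                   sprintf("%s: %s", agent$subject_id, conditionMessage(e)))
      FALSE
    })
  }
  per_agent <- if (length(rows)) do.call(rbind, rows) else tibble::tibble()
  observed <- if (length(freq_rows)) {
    do.call(rbind, freq_rows)
  } else {
    tibble::tibble()
  }

  summ <- NULL
  if (nrow(per_agent)) {
    summ <- do.call(rbind, lapply(par_names, function(nm) {
      true <- per_agent[[paste0("true_", nm)]]
      ea <- per_agent[[paste0("est_a_", nm)]]
      eb <- per_agent[[paste0("est_b_", nm)]]
      tibble::tibble(
        param = nm,
        spearman_run_a = suppressWarnings(cor(true, ea, method = "spearman")),
        spearman_run_b = suppressWarnings(cor(true, eb, method = "spearman")),
        cross_run_spearman = suppressWarnings(cor(ea, eb,
                                                  method = "spearman")),
        bias_run_a = mean(ea - true),
        rmse_run_a = sqrt(mean((ea - true)^2))
      )
    }))
  }
  freq_summary <- NULL
  if (nrow(observed)) {
    agg <- stats::aggregate(observed$observed_freq,
                            by = list(condition = observed$condition,
                                      target_p1 = observed$target_p1),
                            mean)
    freq_summary <- tibble::tibble(condition = agg$condition,
                                   target_p1 = agg$target_p1,
                                   mean_observed = agg$x)
  }
  structure(list(per_agent = per_agent, observed_freq = observed,
                 freq_summary = freq_summary, summary = summ,
                 errors = errors),
            class = "dd_recovery")
}
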
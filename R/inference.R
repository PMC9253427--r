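# Softmax choice link, likelihood, maximum-likelihood fitting and
# out-of-sample prediction summaries.
#
# Choice data live in plain data frames with (at least) the columns
# r1, r2, delay_days, action ("immediate"/"delayed"/"missing") and,
# optionally, condition, run, target_p1, rt_ms — the same schema written
# and read by read_choices()/write_choices().

#' Probability of choosing the immediate option
#'
#' The softmax (logistic) link `p(a1) = 1 / (1 + exp(beta * (v2 - v1)))`
#' mapping the subjective value difference to an immediate-choice
#' probability. `beta = 0` yields indifference (0.5) regardless of values;
#' large `beta` approaches a deterministic choice of the higher-valued
#' option.
#'
#' @param beta Choice sensitivity, >= 0.
#' @param v1 Subjective value(s) of the immediate option.
#' @param v2 Subjective value(s) of the delayed option.
#' @return Probability vector in (0, 1).
#' @export
immediate_choice_prob <- function(beta, v1, v2) {
  if (!is.numeric(beta) || any(beta < 0)) {
    stop("beta must be nonnegative", call. = FALSE)
  }
  z <- clamp(beta * (v2 - v1), -700, 700)  # exp() overflow guard
  1 / (1 + exp(z))
}

.is_responded <- function(action) {
  !is.na(action) & action %in% c("immediate", "delayed")
}

# tolerate tables without an action column (treated as all-missing)
.action_col <- function(data) {
  if ("action" %in% names(data)) data$action else
    rep(NA_character_, nrow(data))
}

# predicted probability of each *observed* choice (responded rows only)
.observed_choice_prob <- function(params, data) {
  f <- .factor_unchecked(params, data$delay_days)
  p1 <- immediate_choice_prob(params$beta, data$r1, f * data$r2)
  ifelse(data$action == "immediate", p1, 1 - p1)
}

#' Log-likelihood of observed choices under a discounting model
#'
#' Sums, over responded trials, the log predicted probability of the
#' observed action; missing responses contribute nothing and an empty (or
#' all-missing) dataset has log-likelihood 0. Probabilities are clipped to
#' \[1e-12, 1 - 1e-12\] for numerical safety.
#'
#' @param params A `model_params` object.
#' @param data Choice data frame (see module description).
#' @return Scalar log-likelihood (<= 0).
#' @export
log_likelihood <- function(params, data) {
  params <- as_model_params(params)
  assert_params(params)
  data <- data[.is_responded(.action_col(data)), , drop = FALSE]
  if (nrow(data) == 0L) return(0)
  p <- clamp(.observed_choice_prob(params, data), 1e-12, 1 - 1e-12)
  sum(log(p))
}

#' Configuration for maximum-likelihood fitting
#'
#' @param n_starts Number of multi-start initializations (default 10; the
#'   likelihood surface of the flexible models is multimodal, so a single
#'   start is fragile).
#' @param seed RNG seed used to draw the starts; fits are fully
#'   deterministic given the seed.
#' @param boundary_tol Absolute tolerance for flagging a fitted parameter
#'   as sitting at a box constraint.
#' @param maxit Iteration cap per local optimization.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_starts = 10L, seed = 1L, boundary_tol = 1e-6,
                       maxit = 500L) {
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 boundary_tol = boundary_tol, maxit = as.integer(maxit)),
            class = "fit_config")
}

# coarse deterministic scan of the objective over a small parameter grid;
# the best points seed additional local optimizations, guarding the
# multi-start search against the likelihood's ridges and plateaus
.grid_prescan_starts <- function(model, nll, n_top = 3L) {
  bounds <- param_bounds(model)
  axes <- lapply(names(bounds), function(nm) {
    b <- bounds[[nm]]
    if (nm %in% c("kappa", "kappa2", "delta", "beta")) {
      lo <- max(b[1], if (nm == "beta") 0.05 else 1e-5)
      clamp(exp(seq(log(lo), log(b[2]), length.out = 6)), b[1], b[2])
    } else {
      seq(b[1], b[2], length.out = 4)
    }
  })
  names(axes) <- names(bounds)
  grid <- as.matrix(do.call(expand.grid, axes))
  vals <- apply(grid, 1L, nll)
  grid[order(vals)[seq_len(min(n_top, nrow(grid)))], , drop = FALSE]
}

# multi-start initial values: kappa (and delta) log-uniform over the usable
# range, beta log-uniform over [0.01, 100], remaining extras uniform
.draw_starts <- function(model, n, seed) {
  bounds <- param_bounds(model)
  nms <- names(bounds)
  withr::with_seed(seed, {
    starts <- vapply(nms, function(nm) {
      b <- bounds[[nm]]
      if (nm %in% c("kappa", "kappa2", "delta", "beta")) {
        lo <- max(b[1], if (nm == "beta") 0.01 else 1e-6)
        clamp(exp(runif(n, log(lo), log(b[2]))), b[1], b[2])
      } else {
        runif(n, b[1], b[2])
      }
    }, numeric(n))
  })
  matrix(starts, nrow = n, dimnames = list(NULL, nms))
}

#' Fit a discounting model by constrained maximum likelihood
#'
#' Maximizes [log_likelihood()] over the model's box-constrained parameter
#' space with multi-start L-BFGS-B and returns the best local optimum.
#'
#' @param model Model identifier (see [dd_models()]).
#' @param data Choice data frame with at least one responded trial; if a
#'   `condition` column is present it must be homogeneous (reward and loss
#'   are fitted independently).
#' @param config A [fit_config()].
#' @return An object of class `dd_fit`: `params` (fitted `model_params`),
#'   `log_lik`, `converged`, `n_starts`, `at_boundary` (named logical),
#'   `n_used`.
#' @export
fit_mle <- function(model, data, config = fit_config()) {
  model <- match.arg(model, .DD_MODELS)
  if (!is.null(data$condition) &&
      length(unique(data$condition[.is_responded(.action_col(data))])) > 1L) {
    stop("fit one condition at a time (reward and loss are fitted separately)",
         call. = FALSE)
  }
  used <- data[.is_responded(.action_col(data)), , drop = FALSE]
  if (nrow(used) == 0L) {
    stop("no responded trials to fit", call. = FALSE)
  }

  bounds <- param_bounds(model)
  nms <- names(bounds)
  lower <- vapply(bounds, `[`, numeric(1), 1L)
  upper <- vapply(bounds, `[`, numeric(1), 2L)
  imm <- used$action == "immediate"
  r1 <- used$r1; r2 <- used$r2; D <- used$delay_days

  nll <- function(theta) {
    p <- as.list(theta)
    names(p) <- nms
    p$model <- model
    f <- .factor_unchecked(p, D)
    z <- clamp(p$beta * (f * r2 - r1), -700, 700)
    p1 <- 1 / (1 + exp(z))
    pobs <- clamp(ifelse(imm, p1, 1 - p1), 1e-12, 1 - 1e-12)
    -sum(log(pobs))
  }

  starts <- .draw_starts(model, config$n_starts, config$seed)
  starts <- rbind(starts, .grid_prescan_starts(model, nll, n_top = 3L))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[i, ], nll, method = "L-BFGS-B", lower = lower,
            upper = upper, control = list(maxit = config$maxit)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    return(structure(list(model = model, params = NULL, log_lik = NA_real_,
                          converged = FALSE, n_starts = nrow(starts),
                          at_boundary = setNames(rep(NA, length(nms)), nms),
                          n_used = nrow(used)),
                     class = "dd_fit"))
  }
  theta <- clamp(best$par, lower, upper)
  params <- do.call(model_params, c(list(model = model), as.list(theta)))
  at_boundary <- (theta - lower) < config$boundary_tol |
    (upper - theta) < config$boundary_tol
  structure(list(model = model, params = params, log_lik = -best$value,
                 converged = best$convergence == 0,
                 n_starts = nrow(starts),
                 at_boundary = setNames(at_boundary, nms),
                 n_used = nrow(used)),
            class = "dd_fit")
}

#' @export
print.dd_fit <- function(x, ...) {
  cat(sprintf("<dd_fit: %s>  logLik = %.4f  (n = %d, converged = %s)\n",
              x$model, x$log_lik, x$n_used, x$converged))
  if (!is.null(x$params)) {
    print(signif(unlist(x$params[model_free_params(x$model)]), 6))
    if (any(x$at_boundary)) {
      cat("at boundary:", paste(names(which(x$at_boundary)), collapse = ", "),
          "\n")
    }
  }
  invisible(x)
}

#' Average predicted probability of observed choices
#'
#' `p_hat` is the mean over responded trials of the model's predicted
#' probability of the observed action; the prediction error is
#' `pe = 1 - p_hat`. The class-balanced variant `p_hat_weighted` averages
#' the mean prediction over immediate-observed trials and the mean over
#' delayed-observed trials with equal weight, guarding against a model that
#' merely predicts the dominant response; when one observed class is absent
#' it falls back to `p_hat` and is flagged.
#'
#' @param params A `model_params` object.
#' @param data Choice data frame with at least one responded trial.
#' @return One-row tibble: `p_hat`, `pe`, `p_hat_weighted`,
#'   `weighted_fallback`, `n_immediate`, `n_delayed`, `n_used`.
#' @export
predicted_probability_summary <- function(params, data) {
  params <- as_model_params(params)
  assert_params(params)
  data <- data[.is_responded(.action_col(data)), , drop = FALSE]
  if (nrow(data) == 0L) {
    stop("no responded trials to summarize", call. = FALSE)
  }
  p <- .observed_choice_prob(params, data)
  imm <- data$action == "immediate"
  p_hat <- mean(p)
  n_imm <- sum(imm); n_del <- sum(!imm)
  if (n_imm > 0L && n_del > 0L) {
    p_w <- (mean(p[imm]) + mean(p[!imm])) / 2
    fallback <- FALSE
  } else {
    p_w <- p_hat
    fallback <- TRUE
  }
  tibble::tibble(p_hat = p_hat, pe = 1 - p_hat, p_hat_weighted = p_w,
                 weighted_fallback = fallback, n_immediate = n_imm,
                 n_delayed = n_del, n_used = nrow(data))
}

#' Out-of-sample model comparison across two experimental runs
#'
#' For each candidate model: infer parameters on run A and evaluate the
#' average predicted probability of observed choices on run B, and vice
#' versa. Models are ranked by the average of the two directions (higher
#' `p_hat_avg` = lower out-of-sample prediction error); ties are broken in
#' favor of fewer free parameters.
#'
#' @param run_a,run_b Choice data frames for the two runs (same subject and
#'   condition).
#' @param models Character vector of model identifiers (default: all seven).
#' @param config A [fit_config()].
#' @return Tibble with one row per model, sorted by `p_hat_avg` descending;
#'   per-model fit errors are captured in the `error` column rather than
#'   aborting the table.
#' @export
cross_run_model_comparison <- function(run_a, run_b, models = dd_models(),
                                       config = fit_config()) {
  models <- match.arg(models, .DD_MODELS, several.ok = TRUE)
  rows <- lapply(models, function(m) {
    out <- tibble::tibble(
      model = m, n_free_params = length(model_free_params(m)),
      p_hat_a_to_b = NA_real_, p_hat_b_to_a = NA_real_,
      p_hat_avg = NA_real_, pe_avg = NA_real_,
      p_hat_weighted_avg = NA_real_,
      converged_a = NA, converged_b = NA, error = NA_character_
    )
    tryCatch({
      fit_a <- fit_mle(m, run_a, config)
      fit_b <- fit_mle(m, run_b, config)
      pred_b <- predicted_probability_summary(fit_a$params, run_b)
      pred_a <- predicted_probability_summary(fit_b$params, run_a)
      out$p_hat_a_to_b <- pred_b$p_hat
      out$p_hat_b_to_a <- pred_a$p_hat
      out$p_hat_avg <- (pred_b$p_hat + pred_a$p_hat) / 2
      out$pe_avg <- 1 - out$p_hat_avg
      out$p_hat_weighted_avg <-
        (pred_b$p_hat_weighted + pred_a$p_hat_weighted) / 2
      out$converged_a <- fit_a$converged
      out$converged_b <- fit_b$converged
      out
    }, error = function(e) {
      out$error <- conditionMessage(e)
      out
    })
  })
  tab <- do.call(rbind, rows)
  tab[order(-tab$p_hat_avg, tab$n_free_params), , drop = FALSE]
}
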
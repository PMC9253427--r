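# Trial construction for the two experimental runs.
#
# Run A presents a common grid of indifference-point trials: for a set of
# hypothetical hyperbolic discount rates, the immediate outcome is placed
# exactly at the discounted value of the delayed outcome (target
# probability 0.5, beta fixed to 1 — at 0.5 the logit offset vanishes so
# beta is immaterial).
#
# Run B inverts the fitted subject-level choice model to place immediate
# outcomes that evoke predetermined immediate-choice probabilities
# (0.3/0.5/0.7 by default), with resolution rules for atypical trials.

#' Configuration of the common (run A) trial grid
#'
#' Presets reproduce the three experiment stages: `exp1` uses delays
#' \{2, 7, 30, 90, 180\} days, delayed outcomes ±\{2, 5, 10, 20\} GBP and
#' hypothetical discount rates \{0.01, 0.1, 0.2, 0.6\}; `exp2` shifts to
#' delays \{7, 30, 90, 180, 365\}, outcomes ±\{5, 10, 20, 50\} and rates
#' \{1e-5, 1e-3, 0.01, 0.6\} to cover the low-rate mode actually observed;
#' `exp3` additionally lengthens the loss-condition delays to
#' \{30, 90, 180, 365, 1095\}.
#'
#' @param preset One of "exp1", "exp2", "exp3"; explicit arguments override
#'   preset values.
#' @param delays Positive integer delays, days.
#' @param delayed_outcomes Positive magnitudes of the delayed outcome, GBP
#'   (the sign is applied per condition).
#' @param hypothetical_kappas Hypothetical hyperbolic discount rates.
#' @param conditions Subset of `c("reward", "loss")`.
#' @param loss_delays Optional delay override for the loss condition.
#' @param block_size Trials per presentation block (alternating reward and
#'   loss blocks).
#' @return A list of class `run_a_config`.
#' @export
run_a_config <- function(preset = c("exp1", "exp2", "exp3"),
                         delays = NULL, delayed_outcomes = NULL,
                         hypothetical_kappas = NULL,
                         conditions = c("reward", "loss"),
                         loss_delays = NULL, block_size = 40L) {
  preset <- match.arg(preset)
  def <- switch(preset,
    exp1 = list(delays = c(2, 7, 30, 90, 180),
                delayed_outcomes = c(2, 5, 10, 20),
                hypothetical_kappas = c(0.01, 0.1, 0.2, 0.6),
                loss_delays = NULL),
    exp2 = list(delays = c(7, 30, 90, 180, 365),
                delayed_outcomes = c(5, 10, 20, 50),
                hypothetical_kappas = c(0.00001, 0.001, 0.01, 0.6),
                loss_delays = NULL),
    exp3 = list(delays = c(7, 30, 90, 180, 365),
                delayed_outcomes = c(5, 10, 20, 50),
                hypothetical_kappas = c(0.00001, 0.001, 0.01, 0.6),
                loss_delays = c(30, 90, 180, 365, 1095))
  )
  loss_delays <- loss_delays %||% def$loss_delays
  cfg <- list(
    delays = as.numeric(delays %||% def$delays),
    delayed_outcomes = as.numeric(delayed_outcomes %||%
                                    def$delayed_outcomes),
    hypothetical_kappas = as.numeric(hypothetical_kappas %||%
                                       def$hypothetical_kappas),
    conditions = match.arg(conditions, c("reward", "loss"),
                           several.ok = TRUE),
    loss_delays = if (is.null(loss_delays)) NULL else
      as.numeric(loss_delays),
    block_size = as.integer(block_size)
  )
  .check_grid(cfg)
  structure(cfg, class = "run_a_config")
}

#' Configuration of the adaptive (run B) trial grid
#'
#' @inheritParams run_a_config
#' @param target_probs Target immediate-choice probabilities, each strictly
#'   inside (0, 1).
#' @param min_delay,max_delay Bounds for the atypical-trial delay sweep;
#'   default to the smallest/largest delay of the grid (per condition).
#' @param penny Smallest currency unit, GBP.
#' @return A list of class `run_b_config`.
#' @export
run_b_config <- function(preset = c("exp1", "exp2", "exp3"),
                         target_probs = c(0.3, 0.5, 0.7),
                         delays = NULL, delayed_outcomes = NULL,
                         conditions = c("reward", "loss"),
                         loss_delays = NULL, min_delay = NULL,
                         max_delay = NULL, penny = 0.01,
                         block_size = 20L) {
  preset <- match.arg(preset)
  base <- run_a_config(preset, delays = delays,
                       delayed_outcomes = delayed_outcomes,
                       conditions = conditions, loss_delays = loss_delays)
  if (any(target_probs <= 0 | target_probs >= 1)) {
    stop("target probabilities must lie strictly inside (0, 1)",
         call. = FALSE)
  }
  structure(list(
    target_probs = as.numeric(target_probs),
    delays = base$delays,
    delayed_outcomes = base$delayed_outcomes,
    conditions = base$conditions,
    loss_delays = base$loss_delays,
    min_delay = min_delay, max_delay = max_delay,
    penny = penny, block_size = as.integer(block_size)
  ), class = "run_b_config")
}

.check_grid <- function(cfg) {
  if (!length(cfg$delays) || !length(cfg$delayed_outcomes) ||
      !length(cfg$conditions)) {
    stop("empty trial grid", call. = FALSE)
  }
  if (!is.null(cfg$hypothetical_kappas) && !length(cfg$hypothetical_kappas)) {
    stop("empty trial grid", call. = FALSE)
  }
  if (any(cfg$delays <= 0) || any((cfg$loss_delays %||% 1) <= 0)) {
    stop("delays must be positive", call. = FALSE)
  }
  if (any(cfg$delayed_outcomes <= 0)) {
    stop("delayed outcome magnitudes must be positive", call. = FALSE)
  }
  invisible(cfg)
}

.condition_delays <- function(cfg, condition) {
  if (condition == "loss" && !is.null(cfg$loss_delays)) {
    cfg$loss_delays
  } else {
    cfg$delays
  }
}

#' Solve for the immediate outcome that evokes a target choice probability
#'
#' Inverts the softmax choice link: the immediate outcome
#' `r1 = v2 + log(p1 / (1 - p1)) / beta`, where `v2` is the model's
#' discounted value of `(r2, delay_days)`, makes the immediate option be
#' chosen with probability exactly `p1` under the given parameters. At
#' `p1 = 0.5` the logit offset vanishes and `r1` equals the discounted
#' value (the indifference point). The returned value is unrounded and may
#' be atypical (wrong sign, or at/beyond `r2`); see
#' [resolve_atypical_trial()].
#'
#' @param params A `model_params` object with `beta > 0`.
#' @param r2 Delayed outcome(s), GBP (signed).
#' @param delay_days Delay(s), days.
#' @param p1 Target immediate-choice probabilit(ies), strictly in (0, 1).
#' @return Numeric vector of raw immediate outcomes.
#' @export
solve_immediate_outcome <- function(params, r2, delay_days, p1) {
  params <- as_model_params(params)
  assert_params(params)
  if (any(p1 <= 0 | p1 >= 1)) {
    stop("p1 must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (params$beta <= 0) {
    stop("inversion undefined for beta = 0 (no value sensitivity)",
         call. = FALSE)
  }
  v2 <- discount_factor(params, delay_days) * r2
  v2 + log(p1 / (1 - p1)) / params$beta
}

#' Generate the common run-A trial table
#'
#' One trial per condition x delay x delayed outcome x hypothetical
#' discount rate, with the immediate outcome set to the hyperbolic
#' discounted value `r2 / (1 + kappa * D)` rounded to the penny
#' (indifference-point placement; the loss condition mirrors the reward
#' grid with negated outcomes). Trial order is randomized within condition
#' blocks; blocks alternate between conditions.
#'
#' @param config A [run_a_config()].
#' @param seed Integer seed controlling the within-block shuffle.
#' @param subject_id Identifier written to the table.
#' @return Tibble with columns `subject_id`, `run`, `condition`, `block`,
#'   `trial_index`, `r1`, `r2`, `delay_days`, `target_p1`, `hyp_kappa`,
#'   `generating_model`, `adjusted`, `seed`.
#' @export
generate_run_a <- function(config = run_a_config(), seed = 1L,
                           subject_id = "sim") {
  stopifnot(inherits(config, "run_a_config"))
  per_cond <- lapply(config$conditions, function(cond) {
    sgn <- if (cond == "loss") -1 else 1
    g <- expand.grid(delay_days = .condition_delays(config, cond),
                     r2 = sgn * config$delayed_outcomes,
                     hyp_kappa = config$hypothetical_kappas,
                     KEEP.OUT.ATTRS = FALSE)
    g$r1 <- penny_round(g$r2 / (1 + g$hyp_kappa * g$delay_days))
    g$condition <- cond
    shuffle <- withr::with_seed(
      derive_seed(seed, match(cond, c("reward", "loss"))),
      sample.int(nrow(g))
    )
    g <- g[shuffle, , drop = FALSE]
    g$block_within <- ceiling(seq_len(nrow(g)) / config$block_size)
    g
  })
  out <- .interleave_blocks(per_cond, config$conditions)
  tibble::tibble(
    subject_id = subject_id, run = "A", condition = out$condition,
    block = out$block, trial_index = seq_len(nrow(out)),
    r1 = out$r1, r2 = out$r2, delay_days = out$delay_days,
    target_p1 = NA_real_, hyp_kappa = out$hyp_kappa,
    generating_model = "hyperbolic", adjusted = FALSE,
    seed = as.integer(seed)
  )
}

# alternate condition blocks: reward block 1, loss block 1, reward block 2, ...
.interleave_blocks <- function(per_cond, conditions) {
  names(per_cond) <- conditions
  n_blocks <- max(vapply(per_cond, function(g) max(g$block_within),
                         numeric(1)))
  pieces <- list()
  blk <- 0L
  for (b in seq_len(n_blocks)) {
    for (cond in conditions) {
      g <- per_cond[[cond]]
      piece <- g[g$block_within == b, , drop = FALSE]
      if (nrow(piece) == 0L) next
      blk <- blk + 1L
      piece$block <- blk
      pieces[[length(pieces) + 1L]] <- piece
    }
  }
  do.call(rbind, pieces)
}

# 0 = valid; 1 = sign violation; 2 = equal outcomes; 3 = |r1| >= |r2|
# (comparisons on penny-rounded values, in integer pennies)
.atypical_case <- function(r1, r2, condition, penny = 0.01) {
  p1 <- .pennies(r1, penny); p2 <- .pennies(r2, penny)
  if (condition == "reward") {
    if (p1 <= 0L) return(1L)
    if (p1 == p2) return(2L)
    if (p1 > p2) return(3L)
  } else {
    if (p1 >= 0L) return(1L)
    if (p1 == p2) return(2L)
    if (p1 < p2) return(3L)
  }
  0L
}

#' Resolve an atypical adaptive trial
#'
#' Three atypical cases can arise from the inversion: (1) a sign-violating
#' immediate outcome (negative immediate reward or positive immediate
#' loss), (2) immediate equal to delayed outcome, and (3) an immediate
#' outcome exceeding the delayed one in magnitude. The delay is stepped by
#' 1 day — shortened for case (1), which raises the discounted value and
#' with it the immediate outcome toward the valid range, lengthened for
#' cases (2) and (3) — with the immediate outcome recomputed at each step,
#' until the trial is valid or the sweep bound is reached. Unresolved
#' trials fall back to penny adjustments: case (1) sets the immediate
#' outcome to plus/minus one penny, case (2) moves it one penny toward
#' zero, and case (3) clamps it one penny inside the delayed outcome
#' (flagged via `clamped`).
#'
#' Resolving an already-valid trial changes nothing.
#'
#' @param r1 Penny-rounded candidate immediate outcome, GBP.
#' @param r2 Delayed outcome, GBP (signed per condition).
#' @param delay_days Candidate delay, days.
#' @param condition `"reward"` or `"loss"`.
#' @param params Generating `model_params` (with `beta > 0`).
#' @param target_p1 The trial's target immediate-choice probability.
#' @param min_delay,max_delay Sweep bounds, days.
#' @param penny Smallest currency unit, GBP.
#' @return List with `r1`, `delay_days`, `adjusted` (did anything change),
#'   `clamped` (case-3 fallback used).
#' @export
resolve_atypical_trial <- function(r1, r2, delay_days, condition, params,
                                   target_p1, min_delay, max_delay,
                                   penny = 0.01) {
  r1_in <- r1; d_in <- delay_days
  d <- delay_days
  case <- .atypical_case(r1, r2, condition, penny)
  max_iter <- (max_delay - min_delay) + 2L
  iter <- 0L
  while (case != 0L && iter < max_iter) {
    step <- if (case == 1L) -1L else 1L
    nd <- d + step
    if (nd < min_delay || nd > max_delay) break
    d <- nd
    r1 <- penny_round(solve_immediate_outcome(params, r2, d, target_p1),
                      penny)
    case <- .atypical_case(r1, r2, condition, penny)
    iter <- iter + 1L
  }
  clamped <- FALSE
  if (case == 1L) {
    r1 <- if (condition == "reward") penny else -penny
  } else if (case == 2L) {
    r1 <- r2 - sign(r2) * penny
  } else if (case == 3L) {
    r1 <- r2 - sign(r2) * penny
    clamped <- TRUE
  }
  list(r1 = r1, delay_days = d,
       adjusted = .pennies(r1, penny) != .pennies(r1_in, penny) || d != d_in,
       clamped = clamped)
}

#' Generate the subject-tailored run-B trial table
#'
#' For each condition x target probability x delay x delayed outcome, the
#' immediate outcome is obtained by inverting the subject's fitted choice
#' model ([solve_immediate_outcome()]), rounded to the penny and passed
#' through [resolve_atypical_trial()]. Trial order is randomized within
#' condition blocks.
#'
#' @param fits Named list with one fitted `dd_fit` (or `model_params`) per
#'   condition in `config$conditions`; each must have `beta > 0`.
#' @param config A [run_b_config()].
#' @param seed Integer seed controlling the within-block shuffle.
#' @param subject_id Identifier written to the table.
#' @return Tibble in the run-A schema plus `r1_raw` (the unrounded solved
#'   outcome at the emitted delay) and `clamped`.
#' @export
generate_run_b <- function(fits, config = run_b_config(), seed = 1L,
                           subject_id = "sim") {
  stopifnot(inherits(config, "run_b_config"))
  per_cond <- lapply(config$conditions, function(cond) {
    fit <- fits[[cond]]
    if (is.null(fit)) {
      stop(sprintf("no fitted parameters supplied for condition '%s'", cond),
           call. = FALSE)
    }
    params <- as_model_params(fit)
    assert_params(params)
    if (params$beta <= 0) {
      stop(sprintf(paste0(
        "fitted beta is 0 for condition '%s': the inversion is undefined; ",
        "refit or supply fallback parameters"), cond), call. = FALSE)
    }
    delays <- .condition_delays(config, cond)
    min_d <- config$min_delay %||% min(delays)
    max_d <- config$max_delay %||% max(delays)
    sgn <- if (cond == "loss") -1 else 1
    g <- expand.grid(delay_days = delays,
                     r2 = sgn * config$delayed_outcomes,
                     target_p1 = config$target_probs,
                     KEEP.OUT.ATTRS = FALSE)
    raw <- solve_immediate_outcome(params, g$r2, g$delay_days, g$target_p1)
    g$r1 <- penny_round(raw, config$penny)
    g$adjusted <- FALSE
    g$clamped <- FALSE
    for (i in seq_len(nrow(g))) {
      if (.atypical_case(g$r1[i], g$r2[i], cond, config$penny) != 0L) {
        res <- resolve_atypical_trial(g$r1[i], g$r2[i], g$delay_days[i],
                                      cond, params, g$target_p1[i],
                                      min_d, max_d, config$penny)
        g$r1[i] <- res$r1
        g$delay_days[i] <- res$delay_days
        g$adjusted[i] <- res$adjusted
        g$clamped[i] <- res$clamped
      }
    }
    g$r1_raw <- solve_immediate_outcome(params, g$r2, g$delay_days,
                                        g$target_p1)
    g$condition <- cond
    shuffle <- withr::with_seed(
      derive_seed(seed, match(cond, c("reward", "loss")), salt = 2L),
      sample.int(nrow(g))
    )
    g <- g[shuffle, , drop = FALSE]
    g$block_within <- ceiling(seq_len(nrow(g)) / config$block_size)
    g$generating_model <- params$model
    g
  })
  out <- .interleave_blocks(per_cond, config$conditions)
  tibble::tibble(
    subject_id = subject_id, run = "B", condition = out$condition,
    block = out$block, trial_index = seq_len(nrow(out)),
    r1 = out$r1, r2 = out$r2, delay_days = out$delay_days,
    target_p1 = out$target_p1, r1_raw = out$r1_raw,
    generating_model = out$generating_model, adjusted = out$adjusted,
    clamped = out$clamped, seed = as.integer(seed)
  )
}

#' Read or write an experiment grid configuration as JSON
#'
#' @param config A `run_a_config` or `run_b_config`.
#' @param path File path.
#' @return `read_config()` returns the reconstructed config object.
#' @export
write_config <- function(config, path) {
  kind <- if (inherits(config, "run_b_config")) "run_b" else "run_a"
  x <- c(list(kind = kind), unclass(config))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::fromJSON(path)
  kind <- x$kind
  x$kind <- NULL
  x <- x[!vapply(x, is.null, logical(1))]
  if (identical(kind, "run_b")) {
    do.call(run_b_config, c(list(preset = "exp1"), x))
  } else {
    do.call(run_a_config, c(list(preset = "exp1"), x))
  }
}
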
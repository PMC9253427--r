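# Discounting value functions and their parameter spaces.
#
# Every model maps a delay D (days) to a discount factor in [0, 1] that
# multiplies the delayed outcome r2; the immediate option is always taken at
# face value (V(a1) = r1). The seven families differ only in the shape of
# that factor.

.DD_MODELS <- c(
  "hyperbolic", "exponential", "quasi_hyperbolic", "hyperboloid",
  "modified_hyperboloid", "double_exponential", "constant_sensitivity"
)

# operational cap for the kappa of models whose natural domain is [0, Inf);
# matches the constrained-optimization bound used during inference
.KAPPA_CAP <- 10
.BETA_MAX <- 100

#' Admissible discounting model names
#'
#' @return Character vector of the seven supported model identifiers.
#' @export
dd_models <- function() .DD_MODELS

#' Free parameters of a discounting model
#'
#' @param model Model identifier (see [dd_models()]).
#' @return Character vector of parameter names, choice sensitivity `beta`
#'   last.
#' @export
model_free_params <- function(model) {
  model <- match.arg(model, .DD_MODELS)
  switch(model,
    hyperbolic = c("kappa", "beta"),
    exponential = c("kappa", "beta"),
    quasi_hyperbolic = c("kappa", "gamma", "beta"),
    hyperboloid = c("kappa", "s", "beta"),
    modified_hyperboloid = c("kappa", "s", "beta"),
    double_exponential = c("kappa", "kappa2", "w", "beta"),
    constant_sensitivity = c("kappa", "delta", "beta")
  )
}

#' Box constraints of a model's parameter space
#'
#' `kappa` lives in \[0, 1\] for the exponential-family models and in
#' \[0, 10\] (an operational cap on the unbounded natural domain) for the
#' hyperbolic family; `beta` in \[0, 100\]; the extras `gamma`, `s`, `w`,
#' `kappa2` in \[0, 1\]. The constant-sensitivity model requires strictly
#' positive `kappa` and `delta`; a small positive floor and a cap of 10
#' stand in for the open, unbounded domain during optimization.
#'
#' @param model Model identifier.
#' @return Named list of `c(lower, upper)` bounds per free parameter.
#' @export
param_bounds <- function(model) {
  model <- match.arg(model, .DD_MODELS)
  unit <- c(0, 1)
  capped <- c(0, .KAPPA_CAP)
  pos <- c(1e-6, .KAPPA_CAP)
  bounds <- switch(model,
    hyperbolic = list(kappa = capped),
    exponential = list(kappa = unit),
    quasi_hyperbolic = list(kappa = unit, gamma = unit),
    hyperboloid = list(kappa = capped, s = unit),
    modified_hyperboloid = list(kappa = capped, s = unit),
    double_exponential = list(kappa = unit, kappa2 = unit, w = unit),
    constant_sensitivity = list(kappa = pos, delta = pos)
  )
  bounds$beta <- c(0, .BETA_MAX)
  bounds
}

#' Construct a discounting model parameter set
#'
#' @param model Model identifier (see [dd_models()]).
#' @param kappa Discount rate (per day).
#' @param beta Choice sensitivity (inverse temperature) in \[0, 100\].
#' @param gamma Linear discount weight in \[0, 1\] (quasi-hyperbolic only).
#' @param s Scaling exponent in \[0, 1\] (hyperboloid models only).
#' @param w Mixture weight in \[0, 1\] (double-exponential only).
#' @param kappa2 Second decay rate in \[0, 1\] (double-exponential only).
#' @param delta Time-sensitivity exponent > 0 (constant-sensitivity only).
#' @param validate If `TRUE` (default), stop on any constraint violation;
#'   set to `FALSE` to construct an out-of-range set for inspection with
#'   [validate_params()].
#' @return An object of class `model_params`.
#' @export
model_params <- function(model, kappa, beta, gamma = NULL, s = NULL, w = NULL,
                         kappa2 = NULL, delta = NULL, validate = TRUE) {
  model <- match.arg(model, .DD_MODELS)
  supplied <- list(kappa = kappa, beta = beta, gamma = gamma, s = s, w = w,
                   kappa2 = kappa2, delta = delta)
  needed <- model_free_params(model)
  missing <- needed[vapply(supplied[needed], is.null, logical(1))]
  if (length(missing)) {
    stop(sprintf("model '%s' requires parameter(s): %s", model,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  # fields not used by the model are dropped
  obj <- structure(c(list(model = model), supplied[needed]),
                   class = "model_params")
  for (nm in needed) {
    if (!is.numeric(obj[[nm]]) || length(obj[[nm]]) != 1L || is.na(obj[[nm]])) {
      stop(sprintf("parameter '%s' must be a single finite number", nm),
           call. = FALSE)
    }
  }
  if (validate) {
    bad <- validate_params(obj)
    if (length(bad)) {
      stop(paste(c("invalid parameters:", bad), collapse = "\n  "),
           call. = FALSE)
    }
  }
  obj
}

as_model_params <- function(x) {
  if (inherits(x, "model_params")) return(x)
  if (inherits(x, "dd_fit")) return(x$params)
  if (is.list(x) && !is.null(x$model)) {
    return(do.call(model_params, c(x, list(validate = FALSE))))
  }
  stop("cannot interpret object as model parameters", call. = FALSE)
}

#' @export
print.model_params <- function(x, ...) {
  vals <- unlist(x[model_free_params(x$model)])
  cat(sprintf("<model_params: %s>\n", x$model))
  print(signif(vals, 6))
  invisible(x)
}

#' Check a parameter set against its model's constraints
#'
#' Reports, rather than throws: an empty character vector means all
#' constraints hold.
#'
#' @param params A `model_params` object (possibly built with
#'   `validate = FALSE`) or a plain list with a `model` element.
#' @return Character vector of human-readable violations (empty if valid).
#' @export
validate_params <- function(params) {
  params <- as_model_params(params)
  bounds <- param_bounds(params$model)
  out <- character(0)
  for (nm in names(bounds)) {
    v <- params[[nm]]
    b <- bounds[[nm]]
    if (is.null(v) || !is.finite(v)) {
      out <- c(out, sprintf("%s missing or non-finite", nm))
    } else if (v < b[1] || v > b[2]) {
      out <- c(out, sprintf("%s out of [%g,%g]", nm, b[1], b[2]))
    }
  }
  if (params$model == "constant_sensitivity") {
    if (is.finite(params$kappa %||% NA) && params$kappa <= 0) {
      out <- c(out, "kappa must be > 0")
    }
    if (is.finite(params$delta %||% NA) && params$delta <= 0) {
      out <- c(out, "delta must be > 0")
    }
  }
  out
}

assert_params <- function(params) {
  bad <- validate_params(params)
  if (length(bad)) {
    stop(paste(c("invalid parameters:", bad), collapse = "\n  "),
         call. = FALSE)
  }
  invisible(params)
}

#' Discount factor of a model at given delays
#'
#' The multiplier in \[0, 1\] applied to the delayed outcome: hyperbolic
#' `1/(1 + kappa*D)`; exponential `kappa^D`; quasi-hyperbolic
#' `gamma * kappa^D`; hyperboloid `1/(1 + kappa*D)^s`; modified hyperboloid
#' `1/(1 + kappa*D^s)`; double-exponential `w*kappa^D + (1-w)*kappa2^D`;
#' constant-sensitivity `exp(-(kappa*D)^delta)`.
#'
#' @param params A `model_params` object.
#' @param delay_days Positive delay(s) in days.
#' @return Numeric vector of discount factors in \[0, 1\].
#' @export
discount_factor <- function(params, delay_days) {
  params <- as_model_params(params)
  assert_params(params)
  if (!is.numeric(delay_days) || any(!is.finite(delay_days)) ||
      any(delay_days <= 0)) {
    stop("delay_days must be positive and finite", call. = FALSE)
  }
  .factor_unchecked(params, delay_days)
}

# hot path shared with the likelihood: no validation
.factor_unchecked <- function(params, D) {
  k <- params$kappa
  switch(params$model,
    hyperbolic = 1 / (1 + k * D),
    exponential = k^D,
    quasi_hyperbolic = params$gamma * k^D,
    hyperboloid = (1 + k * D)^(-params$s),
    modified_hyperboloid = 1 / (1 + k * D^params$s),
    double_exponential = params$w * k^D + (1 - params$w) * params$kappa2^D,
    constant_sensitivity = exp(-(k * D)^params$delta)
  )
}

#' Subjective values of an option pair
#'
#' The immediate option keeps its face value (`v1 = r1`, delay 0); the
#' delayed option is multiplied by the model's discount factor
#' (`v2 = factor * r2`), identically for gains and (signed) losses.
#'
#' @param params A `model_params` object.
#' @param r1 Immediate outcome(s), GBP (signed).
#' @param r2 Delayed outcome(s), GBP (signed).
#' @param delay_days Delay(s) of the delayed option, days (> 0).
#' @return A list with components `v1`, `v2` and `factor`.
#' @export
discounted_value <- function(params, r1, r2, delay_days) {
  f <- discount_factor(params, delay_days)
  list(v1 = r1, v2 = f * r2, factor = f)
}

#' Serialize model parameters to JSON
#'
#' @param params A `model_params` object.
#' @return A JSON string of the form
#'   `{"model": ..., "params": {"kappa": ..., ...}}`.
#' @export
params_to_json <- function(params) {
  params <- as_model_params(params)
  jsonlite::toJSON(
    list(model = params$model,
         params = params[model_free_params(params$model)]),
    auto_unbox = TRUE, digits = NA
  )
}

#' Deserialize model parameters from JSON
#'
#' @param json A JSON string or path as produced by [params_to_json()].
#' @return A validated `model_params` object.
#' @export
params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  do.call(model_params, c(list(model = x$model), x$params))
}
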
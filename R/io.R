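# CSV schemas.
#
# Trial tables: subject_id, run, condition, block, trial_index, r1, r2,
#   delay_days, target_p1, generating_model, adjusted, seed (plus any extra
#   columns such as hyp_kappa or r1_raw, which round-trip untouched).
# Choice tables: the trial columns plus action ("immediate"/"delayed"/
#   "missing") and rt_ms.

#' Read and write trial / choice tables
#'
#' Plain CSV with currency amounts written as fixed-point with two
#' decimals.
#'
#' @param x A trial or choice tibble.
#' @param path File path.
#' @return `read_trials()`/`read_choices()` return a tibble.
#' @export
write_trials <- function(x, path) {
  x <- as.data.frame(x)
  for (nm in intersect(c("r1", "r2"), names(x))) {
    x[[nm]] <- sprintf("%.2f", x[[nm]])
  }
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  for (nm in intersect(c("r1", "r2", "target_p1", "rt_ms"), names(x))) {
    x[[nm]] <- as.numeric(x[[nm]])
  }
  tibble::as_tibble(x)
}

#' @rdname write_trials
#' @export
write_choices <- write_trials

#' @rdname write_trials
#' @export
read_choices <- function(path) {
  x <- read_trials(path)
  if (is.null(x$action)) {
    stop("choice table must have an 'action' column", call. = FALSE)
  }
  x$action[is.na(x$action) | x$action == ""] <- "missing"
  x
}

#' Serialize a fit result to JSON
#'
#' @param fit A `dd_fit`.
#' @param path Optional path; if omitted the JSON string is returned.
#' @return JSON string (invisibly, when written to a file).
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "dd_fit"))
  x <- list(
    model = fit$model,
    params = if (is.null(fit$params)) NULL else
      fit$params[model_free_params(fit$model)],
    log_lik = fit$log_lik, converged = fit$converged,
    n_starts = fit$n_starts, at_boundary = as.list(fit$at_boundary),
    n_used = fit$n_used
  )
  if (is.null(path)) {
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(path)
  }
}
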
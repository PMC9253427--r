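# Fixtures are built in code: random interior parameter draws per model, a
# tiny handcrafted trial grid, and an independent dense grid-search oracle
# for two-parameter likelihood maxima.

random_interior_params <- function(model) {
  bounds <- param_bounds(model)
  vals <- lapply(names(bounds), function(nm) {
    b <- bounds[[nm]]
    if (nm %in% c("kappa", "kappa2") && b[2] <= 1) {
      # per-day retention rates: keep kappa^D representable at D ~ 1000
      runif(1, 0.8, 0.999)
    } else if (nm %in% c("kappa", "delta")) {
      lo <- max(b[1], 1e-4)
      exp(runif(1, log(lo), log(min(b[2], 2))))
    } else if (nm == "beta") {
      exp(runif(1, log(0.05), log(20)))
    } else {
      runif(1, b[1] + 0.05, b[2] - 0.05)
    }
  })
  names(vals) <- names(bounds)
  do.call(model_params, c(list(model = model), vals))
}

# small fixed reward trial grid used by likelihood / fitting tests
toy_trials <- function(condition = "reward") {
  sgn <- if (condition == "loss") -1 else 1
  g <- expand.grid(delay_days = c(2, 7, 30, 90, 180),
                   r2 = sgn * c(2, 5, 10, 20),
                   hyp_kappa = c(0.05, 0.3))
  g$r1 <- penny_round(g$r2 / (1 + g$hyp_kappa * g$delay_days))
  g$condition <- condition
  tibble::as_tibble(g)
}

# independent oracle: dense grid evaluation of the likelihood for the
# two-parameter models (kappa x beta), including both boundary values
grid_loglik_max <- function(model, data, n_kappa = 61, n_beta = 61) {
  b <- param_bounds(model)
  kappas <- c(b$kappa[1],
              pmin(exp(seq(log(max(b$kappa[1], 1e-6)), log(b$kappa[2]),
                           length.out = n_kappa)), b$kappa[2]))
  betas <- c(0, pmin(exp(seq(log(0.01), log(b$beta[2]),
                             length.out = n_beta)), b$beta[2]))
  best <- -Inf
  for (k in kappas) {
    for (be in betas) {
      ll <- log_likelihood(model_params(model, kappa = k, beta = be), data)
      if (ll > best) best <- ll
    }
  }
  best
}
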
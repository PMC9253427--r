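test_that("inversion places immediate outcomes at the target probability", {
  hyp <- model_params("hyperbolic", kappa = 0.1, beta = 1)
  # p1 = 0.5: the logit offset vanishes, r1 equals the discounted value
  expect_identical(solve_immediate_outcome(hyp, 20, 30, 0.5), 5)

  hyp04 <- model_params("hyperbolic", kappa = 0.1, beta = 0.4)
  r1 <- solve_immediate_outcome(hyp04, 20, 30, 0.7)
  expect_equal(r1, 5 + log(7 / 3) / 0.4, tolerance = 1e-12)
  v2 <- discount_factor(hyp04, 30) * 20
  expect_equal(immediate_choice_prob(0.4, r1, v2), 0.7, tolerance = 1e-12)

  expect_error(solve_immediate_outcome(hyp, 20, 30, 1), "strictly inside")
  expect_error(solve_immediate_outcome(hyp, 20, 30, 0), "strictly inside")
  b0 <- model_params("hyperbolic", kappa = 0.1, beta = 0)
  expect_error(solve_immediate_outcome(b0, 20, 30, 0.5), "beta")

  # strictly increasing in p1, reward and loss alike
  ps <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(solve_immediate_outcome(hyp04, 20, 30, ps)) > 0))
  expect_true(all(diff(solve_immediate_outcome(hyp04, -20, 30, ps)) > 0))

  # the immediate-minus-discounted-value offset is constant across delays
  Ds <- c(2, 7, 30, 90, 180)
  off <- solve_immediate_outcome(hyp04, 20, Ds, 0.7) -
    discount_factor(hyp04, Ds) * 20
  expect_equal(off, rep(log(7 / 3) / 0.4, 5), tolerance = 1e-12)
})

test_that("run-A generation produces the full indifference-point grid", {
  ra <- generate_run_a(run_a_config("exp1"), seed = 7)
  expect_identical(nrow(ra), 160L)
  expect_identical(ra$trial_index, 1:160)
  expect_setequal(unique(ra$condition), c("reward", "loss"))

  row <- ra[ra$condition == "reward" & ra$hyp_kappa == 0.2 &
              ra$delay_days == 90 & ra$r2 == 10, ]
  expect_identical(nrow(row), 1L)
  expect_equal(row$r1, 0.53)  # 10/19 penny-rounded

  mirror <- ra[ra$condition == "loss" & ra$hyp_kappa == 0.1 &
                 ra$delay_days == 30 & ra$r2 == -20, ]
  expect_equal(mirror$r1, -5.00)

  # all run-A trials satisfy the smaller-sooner structure
  rew <- ra[ra$condition == "reward", ]
  los <- ra[ra$condition == "loss", ]
  expect_true(all(rew$r1 > 0 & rew$r1 < rew$r2))
  expect_true(all(los$r1 < 0 & los$r1 > los$r2))

  # blocks alternate conditions; same seed reproduces the table
  expect_identical(ra$condition[!duplicated(ra$block)],
                   rep(c("reward", "loss"), 2))
  expect_identical(generate_run_a(run_a_config("exp1"), seed = 7), ra)
  expect_false(identical(generate_run_a(run_a_config("exp1"), seed = 8)$r1,
                         ra$r1))
  expect_error(run_a_config(delays = numeric(0)), "empty")
})

test_that("atypical trials are resolved by delay sweep or penny fallback", {
  # sign-violating immediate reward resolvable by shortening the delay:
  # kappa = 0.6, beta = 5, p1 = 0.3, r2 = 2 -> offset = ln(3/7)/5 = -0.169;
  # independent step-by-step oracle over the sweep
  p <- model_params("hyperbolic", kappa = 0.6, beta = 5)
  oracle_d <- NA
  for (d in 179:2) {
    r1d <- penny_round(solve_immediate_outcome(p, 2, d, 0.3))
    if (r1d > 0 && r1d < 2) { oracle_d <- d; break }
  }
  r1_cand <- penny_round(solve_immediate_outcome(p, 2, 180, 0.3))
  expect_lt(r1_cand, 0)
  res <- resolve_atypical_trial(r1_cand, 2, 180, "reward", p, 0.3,
                                min_delay = 2, max_delay = 180)
  expect_equal(res$delay_days, oracle_d)
  expect_true(res$adjusted)
  expect_gt(res$r1, 0)

  # unresolvable sign violation -> one penny
  p2 <- model_params("hyperbolic", kappa = 0.6, beta = 0.05)
  r1_cand <- penny_round(solve_immediate_outcome(p2, 2, 180, 0.3))
  res <- resolve_atypical_trial(r1_cand, 2, 180, "reward", p2, 0.3,
                                min_delay = 2, max_delay = 180)
  expect_identical(res$r1, 0.01)
  res_l <- resolve_atypical_trial(-r1_cand, -2, 180, "loss", p2, 0.7,
                                  min_delay = 2, max_delay = 180)
  expect_identical(res_l$r1, -0.01)

  # equal outcomes move one penny toward zero (here unresolvable: the
  # offset is ~0 so every delay at the indifference point ties)
  p3 <- model_params("hyperbolic", kappa = 1e-9, beta = 100)
  res <- resolve_atypical_trial(5.00, 5, 30, "reward", p3, 0.5,
                                min_delay = 2, max_delay = 180)
  expect_equal(res$r1, 4.99)
  res <- resolve_atypical_trial(-5.00, -5, 30, "loss", p3, 0.5,
                                min_delay = 2, max_delay = 180)
  expect_equal(res$r1, -4.99)

  # already-valid trials pass through untouched
  res <- resolve_atypical_trial(3.20, 5, 30, "reward", p, 0.5,
                                min_delay = 2, max_delay = 180)
  expect_identical(res, list(r1 = 3.20, delay_days = 30, adjusted = FALSE,
                             clamped = FALSE))
})

test_that("run-B generation tailors, rounds and validates every trial", {
  fit_r <- model_params("hyperbolic", kappa = 0.05, beta = 2)
  fit_l <- model_params("hyperbolic", kappa = 0.02, beta = 1.5)
  cfg <- run_b_config("exp1")
  rb <- generate_run_b(list(reward = fit_r, loss = fit_l), cfg, seed = 3)
  expect_identical(nrow(rb), 120L)

  # every emitted trial satisfies the smaller-sooner structure
  rew <- rb[rb$condition == "reward", ]
  los <- rb[rb$condition == "loss", ]
  expect_true(all(rew$r1 > 0 & rew$r1 < rew$r2))
  expect_true(all(los$r1 < 0 & los$r1 > los$r2))

  # inversion identity on non-adjusted trials: unrounded r1 recovers the
  # target probability exactly
  ok <- !rb$adjusted & rb$condition == "reward"
  f <- discount_factor(fit_r, rb$delay_days[ok])
  p <- immediate_choice_prob(fit_r$beta, rb$r1_raw[ok], f * rb$r2[ok])
  expect_equal(p, rb$target_p1[ok], tolerance = 1e-12)

  # smaller beta -> larger |r1 - v2| offsets at p1 = 0.7
  lo_beta <- model_params("hyperbolic", kappa = 0.05, beta = 0.5)
  rb_lo <- generate_run_b(list(reward = lo_beta),
                          run_b_config("exp1", conditions = "reward"),
                          seed = 3)
  off <- function(tab, prm) {
    idx <- tab$target_p1 == 0.7 & !tab$adjusted
    abs(tab$r1_raw[idx] -
          discount_factor(prm, tab$delay_days[idx]) * tab$r2[idx])
  }
  expect_gt(min(off(rb_lo, lo_beta)), max(off(rew, fit_r)))

  # structure: per-condition blocks, reproducibility, beta = 0 refusal
  expect_identical(generate_run_b(list(reward = fit_r, loss = fit_l), cfg,
                                  seed = 3), rb)
  b0 <- model_params("hyperbolic", kappa = 0.05, beta = 0)
  expect_error(generate_run_b(list(reward = b0), cfg, seed = 1), "beta")
  expect_error(generate_run_b(list(reward = fit_r), cfg, seed = 1),
               "condition 'loss'")
})

test_that("grid configs round-trip through JSON", {
  withr::with_tempdir({
    cfg <- run_a_config("exp3")
    write_config(cfg, "a.json")
    expect_identical(read_config("a.json"), cfg)
    cfgb <- run_b_config("exp2", target_probs = c(0.2, 0.5, 0.8))
    write_config(cfgb, "b.json")
    expect_identical(read_config("b.json"), cfgb)
  })
})
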
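make_choice_df <- function(condition, actions, run = "A",
                           target_p1 = NA_real_, rt_ms = NA_real_) {
  n <- length(actions)
  r2 <- if (condition == "reward") 5 else -5
  tibble::tibble(subject_id = "s1", run = run, condition = condition,
                 trial_index = seq_len(n), r1 = 1, r2 = r2,
                 delay_days = 30, target_p1 = target_p1,
                 action = actions, rt_ms = rt_ms)
}

test_that("discounted-choice frequencies apply the condition mapping", {
  rew <- make_choice_df("reward", rep("immediate", 10))
  expect_equal(discounted_choice_frequency(rew)$discounted_frequency, 1.0)

  los <- make_choice_df("loss", rep("immediate", 10))
  expect_equal(discounted_choice_frequency(los)$discounted_frequency, 0.0)

  part <- make_choice_df("reward",
                         c(rep("immediate", 10), rep("delayed", 30)))
  expect_equal(discounted_choice_frequency(part)$discounted_frequency, 0.25)

  # immediate_frequency identities hold exactly, and missing responses are
  # excluded from the denominator
  both <- rbind(make_choice_df("reward", c(rep("immediate", 3),
                                           rep("delayed", 5),
                                           rep("missing", 2))),
                make_choice_df("loss", c(rep("immediate", 6),
                                         rep("delayed", 2))))
  s <- discounted_choice_frequency(both)
  rew_row <- s[s$condition == "reward", ]
  los_row <- s[s$condition == "loss", ]
  expect_identical(rew_row$immediate_frequency,
                   rew_row$discounted_frequency)
  expect_identical(los_row$immediate_frequency,
                   1 - los_row$discounted_frequency)
  expect_identical(rew_row$n_trials, 8L)

  # lower median for even reaction-time counts
  rt <- make_choice_df("reward", rep("immediate", 4),
                       rt_ms = c(400, 100, 300, 200))
  expect_equal(discounted_choice_frequency(rt)$median_rt_ms, 200)

  # target stratification
  strat <- make_choice_df("reward", rep(c("immediate", "delayed"), 10),
                          run = "B",
                          target_p1 = rep(c(0.3, 0.7), each = 10))
  ss <- discounted_choice_frequency(strat)
  expect_identical(nrow(ss), 2L)
  expect_true(all(ss$target_p1 %in% c(0.3, 0.7)))
})

test_that("subject classification applies the stated thresholds", {
  # 2 discounted of 80 loss trials (2.5%) -> non-discounter
  los <- make_choice_df("loss", c(rep("delayed", 2), rep("immediate", 78)))
  flags <- classify_subjects(los)
  expect_true(flags$non_discounter[["loss"]])

  # 77 of 80 immediate (96.25%) in run A -> repeater
  rep_a <- make_choice_df("reward", c(rep("immediate", 77),
                                      rep("delayed", 3)))
  expect_true(classify_subjects(rep_a)$repeater[["A"]])
  ok_a <- make_choice_df("reward", c(rep("immediate", 76),
                                     rep("delayed", 4)))
  expect_false(classify_subjects(ok_a)$repeater[["A"]])  # exactly 95%

  # kappa > 2 flags the fit; missingness over 10% flags the run
  fit3 <- model_params("hyperbolic", kappa = 3, beta = 1)
  fit1 <- model_params("hyperbolic", kappa = 1.9, beta = 1)
  fl <- classify_subjects(rep_a, fits = list(a = fit3, b = fit1))
  expect_identical(unname(fl$extreme_kappa), c(TRUE, FALSE))
  miss <- make_choice_df("reward", c(rep("missing", 9),
                                     rep("immediate", 71)))
  expect_true(classify_subjects(miss)$excess_missing[["A"]])

  # invariance to trial order
  shuffled <- rep_a[sample(nrow(rep_a)), ]
  expect_identical(classify_subjects(shuffled)$repeater,
                   classify_subjects(rep_a)$repeater)
})

test_that("the experiment loop produces a reproducible bundled report", {
  spec <- population_spec(3, "hyperbolic",
                          kappa = dist_loguniform(0.01, 0.5),
                          beta = dist_loguniform(1, 5), seed = 21)
  rep1 <- run_experiment_loop(spec, run_a_config("exp1"),
                              run_b_config("exp1"),
                              config = fit_config(seed = 2, n_starts = 5),
                              seed = 77)
  expect_identical(rep1$n_subjects, 3L)
  for (s in rep1$subjects) {
    expect_null(s$error)
    expect_identical(nrow(s$run_a), 160L)
    expect_identical(nrow(s$run_b), 120L)
  }
  rep2 <- run_experiment_loop(spec, run_a_config("exp1"),
                              run_b_config("exp1"),
                              config = fit_config(seed = 2, n_starts = 5),
                              seed = 77)
  expect_identical(serialize(rep1, NULL), serialize(rep2, NULL))

  # graded immediate-choice frequencies across target levels (reward)
  bs <- rep1$behavioral_summary
  rew_b <- bs[bs$condition == "reward" & bs$run == "B", ]
  rew_b <- rew_b[order(rew_b$target_p1), ]
  expect_true(all(diff(rew_b$immediate_frequency) > 0))
})

test_that("trial and choice tables round-trip through CSV", {
  withr::with_tempdir({
    ra <- generate_run_a(run_a_config("exp1"), seed = 2)
    write_trials(ra, "ra.csv")
    back <- read_trials("ra.csv")
    expect_equal(back$r1, ra$r1)
    expect_identical(back$condition, ra$condition)

    ch <- simulate_choices(model_params("hyperbolic", kappa = 0.1,
                                        beta = 2),
                           ra, seed = 3, missing_rate = 0.05)
    write_choices(ch, "ch.csv")
    back <- read_choices("ch.csv")
    expect_identical(back$action, ch$action)
  })
})
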
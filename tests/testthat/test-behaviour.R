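test_that("accuracy: greedy agent scores 100%, random agent ~50%", {
  sched <- generate_schedule(n_per_condition = 70, seed = 23)
  greedy <- simulate_agent(sched, prospect_params(1, 1, 1e-9), seed = 24)
  acc <- accuracy_higher_ev(greedy)
  expect_equal(acc$accuracy_pct, rep(100, 3))

  rand <- simulate_agent(sched, prospect_params(1, 1, 1e6), seed = 25)
  acc_r <- accuracy_higher_ev(rand)
  # binomial 99.9% band at n = 70 per condition
  expect_true(all(abs(acc_r$accuracy_pct - 50) < 100 * 3.3 * sqrt(0.25 / 70)))
})

test_that("equal-EV trials are excluded from the accuracy denominator", {
  d <- toy_dataset(30, conditions = "middle")
  d$magnitude_right[1:5] <- d$magnitude_left[1:5]
  d$probability_right[1:5] <- d$probability_left[1:5]
  acc <- accuracy_higher_ev(d)
  expect_equal(acc$n_trials[acc$condition == "middle"], 25)
  expect_error(accuracy_higher_ev(d[1:5, ]), "eligible")
})

test_that("accuracy is invariant to relabelling left and right", {
  sched <- generate_schedule(n_per_condition = 20, seed = 26)
  ds <- simulate_agent(sched, prospect_params(0.9, 0.8, 0.02), seed = 27)
  flip <- ds
  flip$magnitude_left <- ds$magnitude_right
  flip$magnitude_right <- ds$magnitude_left
  flip$probability_left <- ds$probability_right
  flip$probability_right <- ds$probability_left
  flip$outcome_left <- ds$outcome_right
  flip$outcome_right <- ds$outcome_left
  flip$choice <- ifelse(ds$choice == "left", "right", "left")
  expect_equal(accuracy_higher_ev(flip), accuracy_higher_ev(ds))
})

test_that("swapping the option columns flips the difference-coded coefficients", {
  sched <- generate_schedule(n_per_condition = 30, seed = 28)
  ds <- simulate_agent(sched, prospect_params(0.9, 0.8, 0.05), seed = 29)
  swap <- ds
  swap$magnitude_left <- ds$magnitude_right
  swap$magnitude_right <- ds$magnitude_left
  swap$probability_left <- ds$probability_right
  swap$probability_right <- ds$probability_left
  regs <- c("RP", "RM", "RP_RT", "RM_RT")
  c1 <- choice_regression(ds, regressors = regs)
  c2 <- choice_regression(swap, regressors = regs)
  diffed <- c1$regressor %in% regs
  expect_equal(c2$estimate[diffed], -c1$estimate[diffed], tolerance = 1e-6)
  expect_equal(c2$estimate[!diffed], c1$estimate[!diffed], tolerance = 1e-6)
})

test_that("planted decision weights are recovered in sign", {
  sched <- generate_schedule(n_per_condition = 30, seed = 30)
  ds <- simulate_linear_agent(sched, weights = c(rp = 6), seed = 31)
  co <- choice_regression(ds)
  rp <- co$estimate[co$regressor == "RP"]
  rm_ <- co$estimate[co$regressor == "RM"]
  expect_true(all(rp > 0))
  expect_true(all(abs(rm_) < min(rp)))
})

test_that("separation falls back to a flagged ridge fit", {
  sched <- generate_schedule(n_per_condition = 30, seed = 32)
  ds <- simulate_linear_agent(sched, weights = c(rp = 80, rm = 80),
                              seed = 33)
  co <- choice_regression(ds, regressors = c("RP", "RM"))
  expect_true(all(co$diagnostic == "ridge"))
  expect_true(all(is.finite(co$estimate)))
})

test_that("condition comparisons match a hand-computed paired t", {
  vals <- data.frame(
    subject = rep(1:5, 2),
    condition = rep(c("short", "long"), each = 5),
    value = c(1.2, 0.8, 1.0, 1.4, 0.9, 0.7, 0.9, 0.8, 1.1, 0.6))
  cc <- compare_conditions(vals)
  t_hand <- oracle_paired_t(vals$value[1:5], vals$value[6:10])
  expect_equal(cc$paired$t, t_hand, tolerance = 1e-10)
  expect_equal(cc$paired$df, 4)

  # identical values in both conditions: t = 0, p = 1
  same <- vals; same$value <- rep(c(1, 2, 3, 4, 5), 2)
  cc0 <- compare_conditions(same)
  expect_equal(cc0$paired$t, 0)
  expect_equal(cc0$paired$p, 1)

  # constant column equal to the reference: t = 0
  ones <- data.frame(subject = 1:5, condition = "short", value = rep(1, 5))
  cc1 <- compare_conditions(rbind(ones, transform(ones, condition = "long")),
                            reference = 1)
  expect_true(all(cc1$one_sample$t == 0))
  expect_error(compare_conditions(vals[vals$subject == 1, ]), "2 subjects")
})
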
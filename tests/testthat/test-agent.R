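test_that("a near-noiseless identity agent picks the higher objective EV", {
  sched <- generate_schedule(n_per_condition = 30, seed = 13)
  ds <- simulate_agent(sched, prospect_params(1, 1, 1e-9), seed = 14)
  ev_l <- ds$magnitude_left * ds$probability_left
  ev_r <- ds$magnitude_right * ds$probability_right
  unequal <- ev_l != ev_r
  expect_true(all(
    ifelse(ev_l > ev_r, "left", "right")[unequal] == ds$choice[unequal]))
})

test_that("reaction-time medians hit the calibrated condition targets", {
  sched <- generate_schedule(n_per_condition = 70, seed = 15)
  ds <- simulate_agent(sched, prospect_params(0.9, 0.8, 0.02), seed = 16)
  med <- tapply(ds$reaction_time_s, ds$condition, median)
  target <- c(short = 0.793, middle = 1.180, long = 3.366)
  for (cond in names(target))
    expect_lt(abs(med[[cond]] / target[[cond]] - 1), 0.10)
  # deadline conditions respect the response window
  expect_true(all(ds$reaction_time_s[ds$condition == "short"] < 1))
  expect_true(all(ds$reaction_time_s[ds$condition == "long"] >= 3 &
                    ds$reaction_time_s[ds$condition == "long"] < 4))
})

test_that("empirical choice rates converge to the softmax probabilities", {
  # equal-sEV trial: left rate -> 0.5; unequal trials -> softmax p
  d <- toy_dataset(3)
  d$magnitude_right[1] <- d$magnitude_left[1]
  d$probability_right[1] <- d$probability_left[1]
  pp <- prospect_params(0.9, 0.8, 0.05)
  sl <- subjective_ev(d$magnitude_left, d$probability_left, pp)
  sr <- subjective_ev(d$magnitude_right, d$probability_right, pp)
  p_theory <- choice_probability(sl, sr, pp$tau, pp$softmax_form)$left
  n_draw <- 10000
  big <- d[rep(1:3, each = n_draw), ]
  big$condition <- factor(rep("middle", nrow(big)),
                          levels = c("short", "middle", "long"))
  big$block_index <- 1L
  ds <- simulate_agent(big, pp, seed = 31)
  for (t in 1:3) {
    rate <- mean(ds$choice[seq((t - 1) * n_draw + 1, t * n_draw)] == "left")
    # exact binomial test against the theoretical softmax probability
    bt <- binom.test(round(rate * n_draw), n_draw, p_theory[t])
    expect_gt(bt$p.value, 1e-4)
  }
  expect_equal(p_theory[1], 0.5, tolerance = 1e-12)
})

test_that("outcomes resolve independently per option", {
  sched <- generate_schedule(n_per_condition = 50, seed = 41)
  ds <- simulate_agent(sched, seed = 42)
  # both, one or neither option may be rewarded
  expect_true(any(ds$outcome_left & ds$outcome_right))
  expect_true(any(!ds$outcome_left & !ds$outcome_right))
  expect_true(any(xor(ds$outcome_left, ds$outcome_right)))
  # reward rates track the printed probabilities
  expect_lt(abs(mean(ds$outcome_left) - mean(ds$probability_left)), 0.1)
})

test_that("agent rejects rt models missing a condition and codes misses", {
  sched <- generate_schedule(n_per_condition = 20, seed = 43)
  bad_rt <- rt_config()
  bad_rt$medians_s <- bad_rt$medians_s[c("short", "middle")]
  expect_error(simulate_agent(sched, rt_model = bad_rt), "long")
  ds <- simulate_agent(sched, rt_model = rt_config(miss_prob = 0.2),
                       seed = 44)
  expect_gt(sum(ds$choice == "missed"), 0)
  expect_true(all(is.na(ds$reaction_time_s[ds$choice == "missed"])))
  expect_true(all(is.na(ds$chosen_value[ds$choice == "missed"])))
})

test_that("linear agent plants recoverable decision weights", {
  sched <- generate_schedule(n_per_condition = 30, seed = 45)
  ds <- simulate_linear_agent(sched, weights = c(rp = 50), seed = 46)
  # probability-only chooser: picks higher-probability side almost always
  hp <- ifelse(ds$probability_left > ds$probability_right, "left", "right")
  neq <- ds$probability_left != ds$probability_right
  expect_gt(mean((hp == ds$choice)[neq]), 0.95)
})
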
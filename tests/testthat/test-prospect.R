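test_that("value transforms match direct formula evaluation", {
  expect_identical(subjective_magnitude(0.5, 1), 0.5)
  expect_identical(subjective_magnitude(1, 3.7), 1)
  expect_equal(subjective_magnitude(0.25, 0.5), 0.5, tolerance = 1e-12)

  expect_equal(subjective_probability(0.5, 1), 0.5, tolerance = 1e-12)
  expect_identical(subjective_probability(0, 0.7), 0)
  expect_identical(subjective_probability(1, 0.7), 1)
  expect_equal(subjective_probability(0.1, 0.6), oracle_pweight(0.1, 0.6),
               tolerance = 1e-12)

  set.seed(1)
  for (i in 1:100) {
    m <- runif(1, 0.01, 1); p <- runif(1, 0.01, 0.99)
    a <- runif(1, 0.2, 3); g <- runif(1, 0.2, 3)
    expect_equal(subjective_ev(m, p, prospect_params(a, g, 1)),
                 oracle_sev(m, p, a, g), tolerance = 1e-12)
  }
})

test_that("transform domain errors and bounds", {
  expect_error(subjective_magnitude(0, 1), "> 0")
  expect_error(subjective_magnitude(-0.5, 1), "> 0")
  expect_error(subjective_probability(-0.1, 1), "\\[0, 1\\]")
  expect_error(subjective_probability(1.1, 1), "\\[0, 1\\]")
  # sEV is bounded by the subjective magnitude (p_S <= 1)
  set.seed(2)
  for (i in 1:50) {
    m <- runif(1, 0.01, 1); p <- runif(1, 0.01, 0.99)
    pp <- prospect_params(runif(1, 0.3, 2), runif(1, 0.3, 2), 1)
    expect_lte(subjective_ev(m, p, pp), subjective_magnitude(m, pp$alpha))
  }
})

test_that("identity parameters reduce sEV to the objective EV", {
  set.seed(3)
  m <- runif(200, 0.01, 1); p <- runif(200, 0.01, 0.99)
  pp <- prospect_params(1, 1, 0.1)
  expect_equal(subjective_ev(m, p, pp), m * p, tolerance = 1e-12)
})

test_that("softmax choice probabilities are symmetric, stable and exact", {
  for (form in c("temperature_divide", "inverse_temperature_multiply")) {
    pr <- choice_probability(0.37, 0.37, 2.5, form)
    expect_equal(pr$left, 0.5, tolerance = 1e-15)
    expect_equal(pr$left + pr$right, 1, tolerance = 1e-15)
  }
  # noiseless limit of the divide form
  pr <- choice_probability(1, 0, 1e-12, "temperature_divide")
  expect_equal(pr$left, 1)
  # exact match to the printed multiplicative form
  pr <- choice_probability(0.6, 0.4, 2, "inverse_temperature_multiply")
  expect_equal(pr$left, exp(1.2) / (exp(1.2) + exp(0.8)), tolerance = 1e-12)
  # stability at extreme value/noise ratios
  pr <- choice_probability(1000, -1000, 1e-6, "temperature_divide")
  expect_true(is.finite(pr$left) && pr$left == 1)
  expect_error(choice_probability(1, 0, -1), "tau")
})

test_that("log-likelihood equals the product oracle and is additive", {
  d <- toy_dataset(10)
  pp <- prospect_params(0.8, 0.9, 0.05)
  # brute-force per-trial product
  logp <- 0
  for (t in seq_len(nrow(d))) {
    sl <- oracle_sev(d$magnitude_left[t], d$probability_left[t], 0.8, 0.9)
    sr <- oracle_sev(d$magnitude_right[t], d$probability_right[t], 0.8, 0.9)
    pl <- exp(sl / 0.05) / (exp(sl / 0.05) + exp(sr / 0.05))
    logp <- logp + log(if (d$choice[t] == "left") pl else 1 - pl)
  }
  expect_equal(choice_log_likelihood(d, pp), logp, tolerance = 1e-10)

  # single equal-sEV trial
  d1 <- d[1, ]
  d1$magnitude_right <- d1$magnitude_left
  d1$probability_right <- d1$probability_left
  expect_equal(choice_log_likelihood(d1, pp), log(0.5), tolerance = 1e-12)

  # duplicating a trial adds exactly its log-probability
  ll <- choice_log_likelihood(d, pp)
  ll1 <- choice_log_likelihood(d[1, ], pp)
  expect_equal(choice_log_likelihood(rbind(d[1, ], d), pp), ll + ll1,
               tolerance = 1e-10)

  # missed trials are skipped; all-missed errors
  dm <- d; dm$choice[1] <- "missed"
  expect_equal(choice_log_likelihood(dm, pp),
               choice_log_likelihood(d[-1, ], pp), tolerance = 1e-12)
  dall <- d; dall$choice <- "missed"
  expect_error(choice_log_likelihood(dall, pp), "non-missed")
})
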
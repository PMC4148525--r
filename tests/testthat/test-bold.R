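make_noiseless <- function(regime, seed = 51, weight = 1) {
  sched <- generate_schedule(n_per_condition = 20, seed = seed)
  ds <- simulate_agent(sched, prospect_params(0.9, 0.8, 0.02), seed = seed + 1)
  truth <- bold_ground_truth("roi", regime = regime, weight = weight,
                             noise_sd = 0)
  list(ds = ds, bold = simulate_bold(ds, truth, seed = seed + 2))
}

test_that("null regime without noise carries no value information", {
  x <- make_noiseless("null")
  ep <- epoch_timeseries(x$bold, x$ds$stimulus_onset_s)
  des <- build_trial_design(x$ds, "chosen_unchosen")
  etc <- fit_timepoint_glm(ep, des)
  expect_lt(max(abs(etc$beta["chosen_value", ])), 1e-9)
  expect_lt(max(abs(etc$beta["unchosen_value", ])), 1e-9)
})

test_that("difference coder responds identically to value-matched trials", {
  sched <- generate_schedule(n_per_condition = 20, seed = 61)
  # TR-aligned, widely spaced onsets so every trial sees the same sampling
  # phase and no overlap from its neighbours
  sched$stimulus_onset_s <- seq(0, by = 210, length.out = nrow(sched))
  ds <- simulate_agent(sched, prospect_params(1, 1, 0.02), seed = 62)
  # plant two trials with exactly equal chosen and unchosen value
  ds$chosen_value[c(3, 7)] <- 0.4
  ds$unchosen_value[c(3, 7)] <- 0.4
  truth <- bold_ground_truth("roi", "diff_coder", noise_sd = 0)
  bold <- simulate_bold(ds, truth, hrf_duration_s = 16, seed = 63)
  # spacing > HRF support: epochs reflect only their own trial
  ep <- epoch_timeseries(bold, ds$stimulus_onset_s)
  expect_lt(max(abs(ep$epochs[3, ] - ep$epochs[7, ])), 1e-10)
})

test_that("noiseless sum coder: planted weights recovered from the generating design", {
  x <- make_noiseless("sum_coder", seed = 71)
  ds <- x$ds
  # regress the TR samples on the generating design (drive convolved with
  # the same kernel), the direct inversion of the forward model
  amp <- x$bold$neural_amplitude
  ok <- !is.na(amp)
  h <- canonical_hrf(dt_s = 0.1, duration_s = 32)
  n_fine <- ceiling((max(ds$stimulus_onset_s) + 16 + 3) / 0.1) + 1
  basis <- sapply(c("chosen_value", "unchosen_value"), function(col) {
    zc <- rep(NA_real_, nrow(ds))
    for (cond in unique(as.character(ds$condition))) {
      i <- ok & ds$condition == cond
      zc[i] <- as.numeric(scale(ds[[col]][i]))
    }
    drive <- numeric(n_fine)
    idx <- floor(ds$stimulus_onset_s[ok] / 0.1) + 1
    drive[idx] <- zc[ok]
    conv <- stats::convolve(drive, rev(h), type = "open")[seq_len(n_fine)]
    conv[seq(1, n_fine, by = 30)]
  })
  y <- x$bold$values
  fit <- lm.fit(cbind(1, basis[seq_len(length(y)), ]), y)
  expect_equal(unname(fit$coefficients[2]), 1, tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[3]), 1, tolerance = 1e-8)
})

test_that("AR(1) noise has the configured marginal variance and autocorrelation", {
  sched <- generate_schedule(n_per_condition = 20, seed = 81)
  ds <- simulate_agent(sched, seed = 82)
  truth <- bold_ground_truth("roi", "null", noise_sd = 2,
                             ar1_coefficient = 0.5)
  set.seed(1)
  vals <- unlist(lapply(1:20, function(k)
    simulate_bold(ds, truth, seed = 1000 + k)$values))
  expect_lt(abs(sd(vals) - 2), 0.15)
  r1 <- cor(vals[-1], vals[-length(vals)])
  expect_lt(abs(r1 - 0.5), 0.1)
})
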
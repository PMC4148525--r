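# independent one-line re-implementations used as oracles; these must stay
# naive (loops, direct formula evaluation), never calls into the package path
# they check

oracle_pweight <- function(p, g) p^g / (p^g + (1 - p)^g)^(1 / g)

oracle_sev <- function(m, p, a, g) m^a * oracle_pweight(p, g)

# brute-force grid posterior: triple loop, per-trial probability products
oracle_grid_posterior <- function(d, alphas, gammas, taus,
                                  form = "temperature_divide") {
  d <- d[d$choice %in% c("left", "right"), ]
  lik <- array(NA_real_, c(length(alphas), length(gammas), length(taus)))
  for (i in seq_along(alphas)) for (j in seq_along(gammas))
    for (k in seq_along(taus)) {
      prod_p <- 1
      for (t in seq_len(nrow(d))) {
        sl <- oracle_sev(d$magnitude_left[t], d$probability_left[t],
                         alphas[i], gammas[j])
        sr <- oracle_sev(d$magnitude_right[t], d$probability_right[t],
                         alphas[i], gammas[j])
        if (form == "temperature_divide") {
          el <- exp(sl / taus[k]); er <- exp(sr / taus[k])
        } else {
          el <- exp(sl * taus[k]); er <- exp(sr * taus[k])
        }
        p_left <- el / (el + er)
        prod_p <- prod_p *
          (if (d$choice[t] == "left") p_left else 1 - p_left)
      }
      lik[i, j, k] <- prod_p
    }
  lik / sum(lik)
}

# textbook paired t statistic
oracle_paired_t <- function(x, y) {
  d <- x - y
  mean(d) / (sd(d) / sqrt(length(d)))
}

# minimal dataset builder for likelihood and design tests
toy_dataset <- function(n = 12, seed = 99, conditions = c("short", "middle",
                                                          "long")) {
  set.seed(seed)
  d <- data.frame(
    trial_index = seq_len(n),
    condition = factor(rep(conditions, length.out = n),
                       levels = c("short", "middle", "long")),
    block_index = rep(seq_len(ceiling(n / 4)), each = 4)[seq_len(n)],
    magnitude_left = runif(n, 0.1, 1),
    magnitude_right = runif(n, 0.1, 1),
    probability_left = round(runif(n, 0.1, 0.9), 2),
    probability_right = round(runif(n, 0.1, 0.9), 2),
    is_nobrainer = FALSE, is_tradeoff = FALSE,
    stimulus_onset_s = seq(0, by = 12, length.out = n),
    planned_iti_s = 4, planned_outcome_delay_s = 4,
    choice = sample(c("left", "right"), n, TRUE),
    reaction_time_s = runif(n, 0.5, 1.5),
    outcome_left = runif(n) < 0.5,
    outcome_right = runif(n) < 0.5,
    stringsAsFactors = FALSE)
  ev_l <- d$magnitude_left * d$probability_left
  ev_r <- d$magnitude_right * d$probability_right
  d$chosen_value <- ifelse(d$choice == "left", ev_l, ev_r)
  d$unchosen_value <- ifelse(d$choice == "left", ev_r, ev_l)
  class(d) <- c("choice_dataset", "data.frame")
  d
}
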
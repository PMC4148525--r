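#' Reaction-time model configuration
#'
#' Per-condition log-normal response-time model. In the `short` and `middle`
#' conditions the reaction time is the response latency itself; in the `long`
#' condition the options are viewed for a fixed 3 s before the response
#' prompt, so the reaction time is the viewing period plus a (truncated)
#' log-normal latency. Default medians are calibrated to the canonical
#' condition medians of 793, 1180 and 3366 ms.
#'
#' @param medians_s Named medians (seconds) for `short`, `middle`, `long`
#'   (the `long` median includes the viewing period).
#' @param sdlog Log-scale standard deviation of the latency distributions.
#' @param viewing_period_s Fixed viewing period in `long` (seconds).
#' @param response_window_s Response deadline applied in `short` and to the
#'   post-prompt latency in `long`; latencies are resampled to fall within it.
#' @param miss_prob Probability that a trial is emitted as a missed response.
#' @return An object of class `rt_config`.
#' @export
rt_config <- function(medians_s = c(short = 0.793, middle = 1.180, long = 3.366),
                      sdlog = 0.2, viewing_period_s = 3.0,
                      response_window_s = 1.0, miss_prob = 0) {
  stopifnot(all(c("short", "middle", "long") %in% names(medians_s)),
            sdlog > 0, miss_prob >= 0, miss_prob < 1)
  if (medians_s[["long"]] <= viewing_period_s)
    stop("`long` median must exceed the viewing period")
  structure(list(medians_s = medians_s, sdlog = sdlog,
                 viewing_period_s = viewing_period_s,
                 response_window_s = response_window_s,
                 miss_prob = miss_prob), class = "rt_config")
}

# truncated log-normal draws (resample above the cap; cap of Inf disables)
rlnorm_trunc <- function(n, meanlog, sdlog, cap = Inf) {
  x <- stats::rlnorm(n, meanlog, sdlog)
  for (tries in 1:50) {
    bad <- x >= cap
    if (!any(bad)) break
    x[bad] <- stats::rlnorm(sum(bad), meanlog, sdlog)
  }
  pmin(x, cap * 0.999)
}

draw_rts <- function(condition, rt_model) {
  n <- length(condition)
  out <- numeric(n)
  for (cond in levels(factor(condition))) {
    idx <- which(condition == cond)
    if (!length(idx)) next
    med <- unname(rt_model$medians_s[cond])
    if (is.na(med))
      stop(sprintf("rt_config has no median for condition '%s'", cond))
    if (cond == "long") {
      lat <- rlnorm_trunc(length(idx), log(med - rt_model$viewing_period_s),
                          rt_model$sdlog, rt_model$response_window_s)
      out[idx] <- rt_model$viewing_period_s + lat
    } else {
      cap <- if (cond == "short") rt_model$response_window_s else Inf
      out[idx] <- rlnorm_trunc(length(idx), log(med), rt_model$sdlog, cap)
    }
  }
  out
}

draw_outcomes <- function(dataset) {
  # both options resolve independently: one, both or neither may pay out
  dataset$outcome_left <- stats::runif(nrow(dataset)) < dataset$probability_left
  dataset$outcome_right <- stats::runif(nrow(dataset)) < dataset$probability_right
  dataset
}

finalize_choice_dataset <- function(d, value_params, seed) {
  ok <- d$choice %in% c("left", "right")
  d$reaction_time_s[!ok] <- NA_real_
  pick <- function(l, r) ifelse(d$choice == "left", l, r)
  if (is.list(value_params) && !inherits(value_params, "prospect_params")) {
    sl <- sr <- numeric(nrow(d))
    for (cond in names(value_params)) {
      idx <- d$condition == cond
      sl[idx] <- subjective_ev(d$magnitude_left[idx], d$probability_left[idx],
                               value_params[[cond]])
      sr[idx] <- subjective_ev(d$magnitude_right[idx], d$probability_right[idx],
                               value_params[[cond]])
    }
  } else {
    sl <- subjective_ev(d$magnitude_left, d$probability_left, value_params)
    sr <- subjective_ev(d$magnitude_right, d$probability_right, value_params)
  }
  d$chosen_value <- ifelse(ok, pick(sl, sr), NA_real_)
  d$unchosen_value <- ifelse(ok, pick(sr, sl), NA_real_)
  class(d) <- c("choice_dataset", "data.frame")
  attr(d, "value_params") <- value_params
  attr(d, "seed") <- as.integer(seed)
  d
}

#' Simulate a prospect-theory softmax agent on a schedule
#'
#' Samples one choice per trial from the softmax over subjective expected
#' values, draws reaction times from the condition-specific log-normal model,
#' and resolves both options' outcomes independently.
#'
#' @param schedule A [generate_schedule()] trial schedule.
#' @param params A [prospect_params()] object, or a named list of them (one
#'   per condition) to give the agent condition-specific parameters.
#' @param rt_model An [rt_config()] object.
#' @param seed Integer seed.
#' @return A data frame of class `choice_dataset`: the schedule plus columns
#'   `choice` (`"left"`/`"right"`/`"missed"`), `reaction_time_s`,
#'   `outcome_left/right` (logical), `chosen_value`, `unchosen_value`
#'   (subjective EVs under the generating parameters; `NA` on missed trials).
#' @export
simulate_agent <- function(schedule, params = prospect_params(),
                           rt_model = rt_config(), seed = 1) {
  if (is.list(params) && !inherits(params, "prospect_params")) {
    missing_conds <- setdiff(levels(schedule$condition), names(params))
    if (length(missing_conds))
      stop("`params` list lacks conditions: ", paste(missing_conds, collapse = ", "))
  }
  set.seed(as.integer(seed))
  d <- as.data.frame(schedule)
  n <- nrow(d)

  get_par <- function(cond) {
    if (inherits(params, "prospect_params")) params else params[[cond]]
  }
  pl <- numeric(n)
  for (cond in levels(d$condition)) {
    idx <- d$condition == cond
    if (!any(idx)) next
    pp <- get_par(cond)
    sl <- subjective_ev(d$magnitude_left[idx], d$probability_left[idx], pp)
    sr <- subjective_ev(d$magnitude_right[idx], d$probability_right[idx], pp)
    pl[idx] <- choice_probability(sl, sr, pp$tau, pp$softmax_form)$left
  }
  choice <- ifelse(stats::runif(n) < pl, "left", "right")
  if (rt_model$miss_prob > 0)
    choice[stats::runif(n) < rt_model$miss_prob] <- "missed"
  d$choice <- choice
  d$reaction_time_s <- draw_rts(d$condition, rt_model)
  d <- draw_outcomes(d)
  finalize_choice_dataset(d, params, seed)
}

#' Simulate an agent with planted linear decision weights
#'
#' Samples choices from a logistic model on the left-minus-right attribute
#' differences, optionally with reaction-time interactions and
#' previous-trial terms. This is the ground-truth generator for validating
#' the trial-level choice regression: an agent built with only `w_rp > 0`
#' chooses on reward probability alone; a positive `w_rp_rt` makes the
#' probability weight grow with (standardized) reaction time, the signature
#' of slower choices relying more on probability.
#'
#' The linear predictor for choosing left is
#' `w_rp * dRP + w_rm * dRM + w_po * pO + w_pc * pC +
#'  (w_rp_rt * dRP + w_rm_rt * dRM) * zRT`,
#' with `dRP`/`dRM` the probability/magnitude differences, `zRT` the reaction
#' time standardized within condition, and `pO`/`pC` the previous-trial
#' outcome/choice side codes (first trial of a block coded 0). Because `pO`
#' and `pC` depend on history, trials are simulated sequentially.
#'
#' @param schedule A [generate_schedule()] schedule.
#' @param weights Named numeric vector; recognised names `rp`, `rm`, `po`,
#'   `pc`, `rp_rt`, `rm_rt` (missing entries default to 0).
#' @param rt_model An [rt_config()] object; reaction times are drawn first,
#'   then choices conditioned on them.
#' @param seed Integer seed.
#' @return A `choice_dataset`; `chosen_value`/`unchosen_value` are objective
#'   EVs (identity transforms).
#' @export
simulate_linear_agent <- function(schedule,
                                  weights = c(rp = 3, rm = 3),
                                  rt_model = rt_config(), seed = 1) {
  set.seed(as.integer(seed))
  w <- c(rp = 0, rm = 0, po = 0, pc = 0, rp_rt = 0, rm_rt = 0)
  w[names(weights)] <- weights
  d <- as.data.frame(schedule)
  n <- nrow(d)
  d$reaction_time_s <- draw_rts(d$condition, rt_model)
  zrt <- stats::ave(d$reaction_time_s, d$condition,
                    FUN = function(x) as.numeric(scale(x)))
  drp <- d$probability_left - d$probability_right
  drm <- d$magnitude_left - d$magnitude_right
  d <- draw_outcomes(d)

  choice <- character(n)
  po <- pc <- numeric(n)
  u <- stats::runif(n)
  for (i in seq_len(n)) {
    first_in_block <- i == 1L || d$block_index[i] != d$block_index[i - 1L]
    if (first_in_block) {
      po[i] <- 0; pc[i] <- 0
    } else {
      pc[i] <- if (choice[i - 1L] == "left") 1 else -1
      rewarded <- if (choice[i - 1L] == "left") d$outcome_left[i - 1L]
                  else d$outcome_right[i - 1L]
      po[i] <- if (rewarded) 1 else -1
    }
    eta <- w[["rp"]] * drp[i] + w[["rm"]] * drm[i] +
      w[["po"]] * po[i] + w[["pc"]] * pc[i] +
      (w[["rp_rt"]] * drp[i] + w[["rm_rt"]] * drm[i]) * zrt[i]
    choice[i] <- if (u[i] < stats::plogis(eta)) "left" else "right"
  }
  d$choice <- choice
  finalize_choice_dataset(d, prospect_params(), seed)
}
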
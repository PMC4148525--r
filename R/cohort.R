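#' Simulate a full cohort of subjects
#'
#' Convenience wrapper generating, per subject, a fresh schedule, a softmax
#' agent and one BOLD series per ROI ground truth. Per-subject seeds are
#' drawn from the master seed, so the whole cohort is reproducible from one
#' integer.
#'
#' @param n_subjects Number of subjects.
#' @param truths List of [bold_ground_truth()] objects (one per ROI); may be
#'   empty to simulate behaviour only.
#' @param params A [prospect_params()], a per-condition named list, or a
#'   function `function(subject_seed)` returning either (for heterogeneous
#'   cohorts).
#' @param rt_model An [rt_config()].
#' @param schedule_args Named list of extra arguments for
#'   [generate_schedule()].
#' @param seed Master integer seed.
#' @return A list with `datasets` (list of `choice_dataset`), `timeseries`
#'   (list per subject of lists per ROI), `params` (the realised per-subject
#'   parameter objects), and `seeds`.
#' @export
simulate_cohort <- function(n_subjects = 28, truths = list(),
                            params = prospect_params(alpha = 0.9, gamma = 0.8,
                                                     tau = 0.01),
                            rt_model = rt_config(),
                            schedule_args = list(), seed = 1) {
  set.seed(as.integer(seed))
  seeds <- sample.int(2^30, n_subjects * (2 + max(1, length(truths))))
  seeds <- matrix(seeds, nrow = n_subjects)
  datasets <- vector("list", n_subjects)
  series <- vector("list", n_subjects)
  realised <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    sched <- do.call(generate_schedule,
                     c(list(seed = seeds[s, 1]), schedule_args))
    par_s <- if (is.function(params)) params(seeds[s, 2]) else params
    realised[[s]] <- par_s
    datasets[[s]] <- simulate_agent(sched, par_s, rt_model,
                                    seed = seeds[s, 2])
    if (length(truths)) {
      series[[s]] <- lapply(seq_along(truths), function(k)
        simulate_bold(datasets[[s]], truths[[k]], seed = seeds[s, 2 + k]))
      names(series[[s]]) <- vapply(truths, `[[`, "", "roi_label")
    }
  }
  list(datasets = datasets, timeseries = series, params = realised,
       seeds = seeds)
}

#' Ground-truth regimes of the time-pressure double dissociation
#'
#' The qualitative coding pattern under study: a prefrontal-like region
#' (`vmPFC`) codes value sum under time pressure and value difference when
#' more time is available, while a parietal-like region (`pSPL`) codes value
#' difference under time pressure and carries no value signal when the
#' decision is slow.
#'
#' @param weight,noise_sd,ar1_coefficient,tr_s Passed to
#'   [bold_ground_truth()].
#' @return List of two [bold_ground_truth()] objects.
#' @export
dissociation_truths <- function(weight = 1, noise_sd = 1,
                                ar1_coefficient = 0.3, tr_s = 3) {
  list(
    bold_ground_truth("vmPFC",
                      regime = c(short = "sum_coder", middle = "diff_coder",
                                 long = "diff_coder"),
                      weight = weight, noise_sd = noise_sd,
                      ar1_coefficient = ar1_coefficient, tr_s = tr_s),
    bold_ground_truth("pSPL",
                      regime = c(short = "diff_coder", middle = "diff_coder",
                                 long = "null"),
                      weight = weight, noise_sd = noise_sd,
                      ar1_coefficient = ar1_coefficient, tr_s = tr_s))
}

#' Expected group-level unchosen-value signs under the dissociation pattern
#'
#' Ground-truth sign of the unchosen-value amplitude per ROI x condition for
#' [dissociation_truths()]: positive where a region sums values, negative
#' where it codes their difference, zero where value coding is absent.
#'
#' @return Data frame with columns `roi`, `condition`, `sign` (+1, -1, 0).
#' @export
dissociation_expected_signs <- function() {
  data.frame(
    roi = rep(c("vmPFC", "pSPL"), each = 3),
    condition = rep(c("short", "middle", "long"), 2),
    sign = c(1, -1, -1, -1, -1, 0))
}
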
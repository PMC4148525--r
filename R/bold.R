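#' Ground-truth value-coding regime for a synthetic ROI
#'
#' Describes how a simulated region's trial-wise neural amplitude depends on
#' the chosen and unchosen option values. Three regimes are supported:
#' `sum_coder` (equal positive weights on chosen and unchosen value -- the
#' signature of a region representing decision *inputs*), `diff_coder`
#' (positive weight on chosen, equally negative on unchosen -- a resolved
#' value *comparison*), and `null` (no value coding). A regime may be given
#' per timing condition to emulate regions whose coding changes with time
#' pressure.
#'
#' @param roi_label Region name, e.g. `"vmPFC"`.
#' @param regime Either a single string (`"sum_coder"`, `"diff_coder"`,
#'   `"null"`) or a named character vector with one regime per condition,
#'   e.g. `c(short = "sum_coder", middle = "diff_coder", long = "diff_coder")`.
#' @param weight Magnitude of the value weights (effect amplitude in noise-SD
#'   units per SD of value).
#' @param noise_sd Marginal standard deviation of the AR(1) scan noise.
#' @param ar1_coefficient AR(1) coefficient of the noise, in `[0, 1)`.
#' @param tr_s Repetition time of the simulated scan, seconds.
#' @return An object of class `bold_ground_truth`.
#' @export
bold_ground_truth <- function(roi_label, regime = "diff_coder", weight = 1,
                              noise_sd = 1, ar1_coefficient = 0.3, tr_s = 3) {
  stopifnot(weight >= 0, noise_sd >= 0,
            ar1_coefficient >= 0, ar1_coefficient < 1, tr_s > 0)
  if (!all(regime %in% c("sum_coder", "diff_coder", "null")))
    stop("unknown regime; use sum_coder, diff_coder or null")
  structure(list(roi_label = roi_label, regime = regime, weight = weight,
                 noise_sd = noise_sd, ar1_coefficient = ar1_coefficient,
                 tr_s = tr_s), class = "bold_ground_truth")
}

regime_weights <- function(truth, condition) {
  reg <- if (length(truth$regime) == 1L && is.null(names(truth$regime)))
    rep(truth$regime, length(condition))
  else truth$regime[as.character(condition)]
  if (any(is.na(reg))) stop("regime not defined for every condition present")
  w <- truth$weight
  data.frame(
    chosen = ifelse(reg == "null", 0, w),
    unchosen = ifelse(reg == "sum_coder", w,
                      ifelse(reg == "diff_coder", -w, 0)))
}

#' Simulate an ROI BOLD timeseries from a choice dataset
#'
#' Forward model for a region's scan: each non-missed trial contributes a
#' brief (0.1 s) neural event at stimulus onset with amplitude
#' `intercept + w_chosen * z(chosen_value) + w_unchosen * z(unchosen_value)`
#' (values standardized within condition, matching the per-condition epoch
#' analyses). The event train is convolved with the canonical double-gamma
#' HRF on a fine grid, sampled at the repetition time, and AR(1) Gaussian
#' noise with marginal SD `noise_sd` is added. The series extends one full
#' epoch window past the last onset.
#'
#' @param dataset A `choice_dataset` with at least one non-missed trial.
#' @param truth A [bold_ground_truth()] object.
#' @param intercept Baseline neural amplitude common to all trials.
#' @param hrf_duration_s Support of the simulated HRF kernel, seconds. The
#'   default 32 s lets the undershoot relax fully, so consecutive trials
#'   overlap as they do in a real event-related scan.
#' @param epoch_window_s Epoch length the series must cover after the last
#'   onset (seconds).
#' @param fine_dt_s Fine simulation grid, seconds.
#' @param seed Integer seed (noise only; the drive is deterministic given the
#'   dataset).
#' @param ... HRF shape arguments forwarded to [canonical_hrf()].
#' @return An object of class `roi_timeseries`: list with `values`,
#'   `tr_s`, `roi_label`, `n_volumes`, and the per-trial `neural_amplitude`
#'   used (ground truth, `NA` for missed trials).
#' @export
simulate_bold <- function(dataset, truth, intercept = 0,
                          hrf_duration_s = 32, epoch_window_s = 16,
                          fine_dt_s = 0.1, seed = 1, ...) {
  ok <- dataset$choice %in% c("left", "right")
  if (!any(ok)) stop("dataset has no non-missed trials")
  set.seed(as.integer(seed))
  tr <- truth$tr_s

  zc <- zu <- rep(NA_real_, nrow(dataset))
  for (cond in unique(as.character(dataset$condition))) {
    idx <- ok & dataset$condition == cond
    zc[idx] <- as.numeric(scale(dataset$chosen_value[idx]))
    zu[idx] <- as.numeric(scale(dataset$unchosen_value[idx]))
  }
  w <- regime_weights(truth, dataset$condition)
  amp <- ifelse(ok, intercept + w$chosen * zc + w$unchosen * zu, NA_real_)

  onsets <- dataset$stimulus_onset_s[ok]
  total_s <- max(onsets) + epoch_window_s + tr
  n_fine <- ceiling(total_s / fine_dt_s) + 1L
  drive <- numeric(n_fine)
  ev_idx <- pmin(n_fine, floor(onsets / fine_dt_s) + 1L)
  drive[ev_idx] <- drive[ev_idx] + amp[ok]

  h <- canonical_hrf(dt_s = fine_dt_s, duration_s = hrf_duration_s, ...)
  neural <- stats::convolve(drive, rev(h), type = "open")[seq_len(n_fine)]

  step <- max(1L, round(tr / fine_dt_s))
  vol_idx <- seq(1L, n_fine, by = step)
  values <- neural[vol_idx]
  if (truth$noise_sd > 0) {
    phi <- truth$ar1_coefficient
    innov_sd <- truth$noise_sd * sqrt(1 - phi^2)
    eps <- stats::rnorm(length(values), sd = innov_sd)
    noise <- as.numeric(stats::filter(eps, phi, method = "recursive"))
    values <- values + noise
  }
  n_vol <- length(values)
  if ((n_vol - 1) * tr < max(onsets) + epoch_window_s - tr)
    stop("generated series too short for the last trial's epoch window")
  structure(list(values = values, tr_s = tr, roi_label = truth$roi_label,
                 n_volumes = n_vol, neural_amplitude = amp,
                 truth = truth, seed = as.integer(seed)),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("roi_timeseries '%s': %d volumes @ TR = %g s\n",
              x$roi_label, x$n_volumes, x$tr_s))
  invisible(x)
}
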
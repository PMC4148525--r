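#' Epoch, fit and summarize one ROI for one subject
#'
#' Runs the per-condition epoch analysis for a single subject and ROI:
#' the ROI series is epoched around the condition's stimulus onsets, the
#' trial-level GLM is fitted at every epoch timepoint, and each regressor's
#' effect timecourse is reduced to one amplitude by a least-squares fit of
#' the reference HRF shape.
#'
#' @param dataset The subject's `choice_dataset`.
#' @param ts The subject's `roi_timeseries` for this ROI.
#' @param variant GLM variant, see [build_trial_design()].
#' @param params Optional prospect parameters for the value columns,
#'   see [build_trial_design()].
#' @param hrf Reference kernel for amplitude fitting; defaults to
#'   [effective_hrf_kernel()] at the series' TR.
#' @param window_s,dt_s Epoch window and resolution.
#' @param lag_search_s Optional HRF lag search half-width (seconds).
#' @return A list with `amplitudes` (data frame: roi, condition, regressor,
#'   amplitude, lag_s, residual_norm) and `timecourses` (data frame: roi,
#'   condition, regressor, time_s, beta).
#' @export
analyze_roi_subject <- function(dataset, ts,
                                variant = c("sum_diff", "chosen_unchosen"),
                                params = NULL, hrf = NULL,
                                window_s = 16, dt_s = 0.3,
                                lag_search_s = 0) {
  variant <- match.arg(variant)
  if (is.null(hrf))
    hrf <- effective_hrf_kernel(tr_s = ts$tr_s, dt_s = dt_s,
                                duration_s = window_s)
  design <- build_trial_design(dataset, variant, params = params)
  amps <- list(); tcs <- list()
  for (cond in unique(design$condition)) {
    rows <- which(design$condition == cond)
    trial_idx <- design$trials[rows]
    ep <- epoch_timeseries(ts, dataset$stimulus_onset_s[trial_idx],
                           window_s = window_s, dt_s = dt_s)
    if (!length(ep$kept)) next
    # drop design columns that are constant within this condition
    Xc <- design$X[rows[ep$kept], , drop = FALSE]
    keep_cols <- c(TRUE, apply(Xc[, -1, drop = FALSE], 2, stats::sd) > 0)
    etc <- fit_timepoint_glm(ep, Xc[, keep_cols, drop = FALSE])
    for (rg in etc$regressors) {
      fit <- hrf_amplitude(etc$beta[rg, ], hrf, lag_search_s, dt_s)
      amps[[length(amps) + 1L]] <- data.frame(
        roi = ts$roi_label, condition = cond, regressor = rg,
        amplitude = fit$amplitude, lag_s = fit$lag_s,
        residual_norm = fit$residual_norm, stringsAsFactors = FALSE)
      tcs[[length(tcs) + 1L]] <- data.frame(
        roi = ts$roi_label, condition = cond, regressor = rg,
        time_s = etc$time_s, beta = etc$beta[rg, ],
        stringsAsFactors = FALSE)
    }
  }
  list(amplitudes = do.call(rbind, amps), timecourses = do.call(rbind, tcs))
}

#' ROI epoch analysis across a cohort
#'
#' Applies [analyze_roi_subject()] to every subject and ROI and stacks the
#' results into tidy tables.
#'
#' @param datasets List of `choice_dataset`s, one per subject.
#' @param timeseries List (per subject) of lists (per ROI) of
#'   `roi_timeseries`.
#' @param variant,params,hrf,window_s,dt_s,lag_search_s See
#'   [analyze_roi_subject()]; `params` may be a list indexed by subject.
#' @return A list with `amplitudes` and `timecourses` data frames, each with
#'   a leading `subject` column.
#' @export
analyze_roi_cohort <- function(datasets, timeseries,
                               variant = c("sum_diff", "chosen_unchosen"),
                               params = NULL, hrf = NULL,
                               window_s = 16, dt_s = 0.3, lag_search_s = 0) {
  variant <- match.arg(variant)
  amps <- list(); tcs <- list()
  for (s in seq_along(datasets)) {
    par_s <- if (is.null(params)) NULL
             else if (!is.null(names(params)) || inherits(params, "prospect_params")) params
             else params[[s]]
    for (ts in timeseries[[s]]) {
      res <- analyze_roi_subject(datasets[[s]], ts, variant, par_s, hrf,
                                 window_s, dt_s, lag_search_s)
      if (!is.null(res$amplitudes)) {
        res$amplitudes <- cbind(subject = s, res$amplitudes)
        res$timecourses <- cbind(subject = s, res$timecourses)
        amps[[length(amps) + 1L]] <- res$amplitudes
        tcs[[length(tcs) + 1L]] <- res$timecourses
      }
    }
  }
  list(amplitudes = do.call(rbind, amps), timecourses = do.call(rbind, tcs))
}
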
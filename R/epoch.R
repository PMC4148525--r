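#' Epoch an ROI timeseries around stimulus onsets
#'
#' Cuts a continuous ROI series into fixed-length trial epochs. One cubic
#' spline is fitted through the whole series (so the interpolant passes
#' exactly through every scan sample) and evaluated on each trial's epoch
#' grid `onset + {0, dt_s, ..., window_s - dt_s}`. Trials whose window would
#' run past the last scan sample are dropped and counted.
#'
#' @param ts A `roi_timeseries` (see [simulate_bold()] / [read_timeseries()]),
#'   or a plain numeric vector (then supply `tr_s`).
#' @param onsets Stimulus onset times in seconds (run time origin 0 at the
#'   first volume).
#' @param window_s Epoch duration, default 16 s.
#' @param dt_s Epoch resolution, default 0.3 s (54 samples over 16 s).
#' @param tr_s Repetition time; taken from `ts` when it is a
#'   `roi_timeseries`.
#' @return An object of class `epoched_trials`: list with `epochs` (matrix,
#'   trials x timepoints), `time_s` (the epoch grid), `kept` (indices into
#'   `onsets` of retained trials) and `n_dropped`.
#' @export
epoch_timeseries <- function(ts, onsets, window_s = 16, dt_s = 0.3,
                             tr_s = NULL) {
  if (inherits(ts, "roi_timeseries")) {
    values <- ts$values
    tr_s <- ts$tr_s
  } else {
    values <- as.numeric(ts)
    if (is.null(tr_s)) stop("supply `tr_s` for a plain numeric series")
  }
  if (any(!is.finite(values))) stop("series contains non-finite values")
  t_scan <- (seq_along(values) - 1) * tr_s
  # half-open window [0, window_s): ceiling(window/dt) samples
  t_rel <- (seq_len(ceiling(window_s / dt_s - 1e-9)) - 1) * dt_s
  last_ok <- max(t_scan)
  keep <- which(is.finite(onsets) & onsets >= 0 &
                  (onsets + max(t_rel)) <= last_ok)
  n_dropped <- length(onsets) - length(keep)
  if (!length(keep)) {
    warning("all trials dropped: epoch windows overrun the series")
    return(structure(list(epochs = matrix(0, 0, length(t_rel)),
                          time_s = t_rel, kept = integer(0),
                          n_dropped = n_dropped), class = "epoched_trials"))
  }
  f <- stats::splinefun(t_scan, values, method = "fmm")
  epochs <- t(vapply(onsets[keep], function(o) f(o + t_rel),
                     numeric(length(t_rel))))
  structure(list(epochs = epochs, time_s = t_rel, kept = keep,
                 n_dropped = n_dropped), class = "epoched_trials")
}

#' Canonical within-epoch event times by condition
#'
#' Mean response and outcome onset times (seconds from stimulus onset) for
#' the three timing conditions, useful for annotating effect timecourses.
#'
#' @return A data frame with columns `condition`, `response_s`, `outcome_s`.
#' @export
epoch_event_times <- function() {
  data.frame(condition = c("short", "middle", "long"),
             response_s = c(0.77, 1.41, 3.4),
             outcome_s = c(5.56, 6.21, 8.24))
}
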
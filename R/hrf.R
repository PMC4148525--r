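#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities: a response peaking at `peak_s` and an
#' undershoot peaking at `undershoot_s`, scaled by `undershoot_ratio` and
#' peak-normalized so `max(h) = 1`. Gamma shapes are `peak * rate + 1` with
#' unit rate, so the density mode falls exactly at the requested peak time.
#'
#' @param dt_s Sampling step in seconds.
#' @param duration_s Length of the returned kernel; the grid is the
#'   half-open interval `[0, duration_s)`.
#' @param peak_s Response peak time (default 6 s).
#' @param undershoot_s Undershoot peak time (default 16 s).
#' @param undershoot_ratio Undershoot amplitude relative to the response
#'   (default 1/6).
#' @return Numeric vector of length `duration_s / dt_s`; `h[1] = h(0) = 0`.
#' @examples
#' h <- canonical_hrf(0.3)
#' which.max(h)  # peak at ~6 s
#' @export
canonical_hrf <- function(dt_s = 0.3, duration_s = 16, peak_s = 6,
                          undershoot_s = 16, undershoot_ratio = 1 / 6) {
  if (dt_s <= 0 || duration_s <= 0) stop("`dt_s` and `duration_s` must be > 0")
  if (peak_s <= 0 || undershoot_s <= peak_s || undershoot_ratio < 0)
    stop("invalid HRF shape parameters")
  t <- (seq_len(ceiling(duration_s / dt_s - 1e-9)) - 1) * dt_s
  h <- stats::dgamma(t, shape = peak_s + 1, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_s + 1, rate = 1)
  h / max(h)
}

#' Effective HRF kernel under TR sampling and spline epoching
#'
#' The shape that a unit-amplitude stimulus-locked impulse response takes
#' after passing through the acquisition/analysis chain: convolution on a
#' fine grid, sampling at the scan repetition time, and cubic-spline
#' resampling onto the epoch grid. This is the appropriate reference shape
#' for amplitude fitting of effect timecourses estimated from TR-sampled
#' data, since the scan's coarse sampling slightly smooths the peak relative
#' to the underlying canonical response.
#'
#' @param tr_s Repetition time of the scan, seconds (default 3).
#' @param dt_s Epoch grid resolution, seconds (default 0.3).
#' @param duration_s Epoch duration, seconds (default 16).
#' @param fine_dt_s Fine simulation grid, seconds (default 0.1).
#' @param ... HRF shape arguments passed to [canonical_hrf()].
#' @return Numeric vector on the epoch grid `[0, duration_s)`.
#' @export
effective_hrf_kernel <- function(tr_s = 3, dt_s = 0.3, duration_s = 16,
                                 fine_dt_s = 0.1, ...) {
  # simulate past the epoch so the spline is anchored beyond its right edge,
  # as it is when epochs are cut from a spline of the whole scan series
  pad <- 4 * tr_s
  h_fine <- canonical_hrf(dt_s = fine_dt_s, duration_s = duration_s + pad, ...)
  t_fine <- (seq_along(h_fine) - 1) * fine_dt_s
  step <- max(1L, round(tr_s / fine_dt_s))
  idx <- seq(1L, length(h_fine), by = step)
  f <- stats::splinefun(t_fine[idx], h_fine[idx], method = "fmm")
  t_epoch <- (seq_len(ceiling(duration_s / dt_s - 1e-9)) - 1) * dt_s
  f(t_epoch)
}

#' Least-squares HRF amplitude of an effect timecourse
#'
#' Fits a single amplitude `a` minimizing `||e - a * h||^2`, i.e.
#' `a = <e, h> / <h, h>`. With `lag_search_s > 0` the kernel is additionally
#' shifted over a grid of lags in `[-lag_search_s, +lag_search_s]` (in steps
#' of `dt_s`, zero-padded) and the lag with minimal residual sum of squares
#' is selected.
#'
#' @param effect_tc Numeric effect-size timecourse on the epoch grid.
#' @param hrf Reference kernel on the same grid (see
#'   [effective_hrf_kernel()]).
#' @param lag_search_s Half-width of the optional lag grid, seconds; 0
#'   disables the search.
#' @param dt_s Grid step, needed only when `lag_search_s > 0`.
#' @return A list with `amplitude`, `lag_s`, and `residual_norm`.
#' @export
hrf_amplitude <- function(effect_tc, hrf, lag_search_s = 0, dt_s = 0.3) {
  if (length(effect_tc) != length(hrf))
    stop("`effect_tc` and `hrf` must share a grid")
  if (sum(hrf^2) == 0) stop("`hrf` has zero norm")
  fit_at <- function(h) {
    a <- sum(effect_tc * h) / sum(h^2)
    list(amplitude = a, residual_norm = sqrt(sum((effect_tc - a * h)^2)))
  }
  if (lag_search_s <= 0) {
    f <- fit_at(hrf)
    return(list(amplitude = f$amplitude, lag_s = 0,
                residual_norm = f$residual_norm))
  }
  max_shift <- round(lag_search_s / dt_s)
  best <- NULL
  for (k in -max_shift:max_shift) {
    h <- if (k >= 0) c(rep(0, k), hrf[seq_len(length(hrf) - k)])
         else c(hrf[(1 - k):length(hrf)], rep(0, -k))
    if (sum(h^2) == 0) next
    f <- fit_at(h)
    if (is.null(best) || f$residual_norm < best$residual_norm)
      best <- list(amplitude = f$amplitude, lag_s = k * dt_s,
                   residual_norm = f$residual_norm)
  }
  best
}
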
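#' Prospect-theory parameter set
#'
#' Bundles the three free parameters of the choice model: the magnitude
#' curvature `alpha`, the probability-weighting exponent `gamma`, and the
#' softmax decision-noise parameter `tau`. All three must be strictly
#' positive and finite.
#'
#' Two softmax parameterizations are supported. With
#' `softmax_form = "temperature_divide"` (the default) choice probabilities
#' are proportional to `exp(sEV / tau)`, so larger `tau` means noisier
#' choices, matching the usual reading of a softmax temperature. With
#' `"inverse_temperature_multiply"` they are proportional to
#' `exp(sEV * tau)`, i.e. `tau` acts as an inverse temperature. The two forms
#' are related by `tau -> 1/tau`; both are carried through the likelihood and
#' estimation machinery unchanged.
#'
#' @param alpha Magnitude curvature, > 0. `alpha = 1` leaves magnitudes
#'   untransformed; `alpha < 1` compresses (under-weights) large magnitudes.
#' @param gamma Probability-weighting exponent, > 0. `gamma = 1` is the
#'   identity weighting.
#' @param tau Decision-noise parameter, > 0. Interpretation depends on
#'   `softmax_form`.
#' @param softmax_form One of `"temperature_divide"` or
#'   `"inverse_temperature_multiply"`.
#' @return An object of class `prospect_params`.
#' @examples
#' prospect_params(alpha = 0.8, gamma = 0.9, tau = 0.05)
#' @export
prospect_params <- function(alpha = 1, gamma = 1, tau = 0.05,
                            softmax_form = c("temperature_divide",
                                             "inverse_temperature_multiply")) {
  softmax_form <- match.arg(softmax_form)
  for (nm in c("alpha", "gamma", "tau")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("`%s` must be a single finite positive number", nm))
  }
  structure(list(alpha = alpha, gamma = gamma, tau = tau,
                 softmax_form = softmax_form),
            class = "prospect_params")
}

#' @export
print.prospect_params <- function(x, ...) {
  cat(sprintf("prospect_params: alpha = %.4g, gamma = %.4g, tau = %.4g (%s)\n",
              x$alpha, x$gamma, x$tau, x$softmax_form))
  invisible(x)
}

#' Subjective reward magnitude
#'
#' Power transform of the objective reward magnitude, `r_S = r_O ^ alpha`.
#'
#' @param r_obj Objective magnitude(s), > 0 (task magnitudes live in (0, 1]).
#' @param alpha Curvature parameter, > 0.
#' @return Subjective magnitude(s), same length as `r_obj`.
#' @examples
#' subjective_magnitude(0.25, 0.5)  # 0.5
#' @export
subjective_magnitude <- function(r_obj, alpha) {
  if (any(!is.finite(r_obj)) || any(r_obj <= 0))
    stop("`r_obj` must be finite and > 0")
  r_obj ^ alpha
}

#' Subjective probability weighting
#'
#' The single-parameter probability weighting function
#' `p_S = p^gamma / (p^gamma + (1 - p)^gamma)^(1/gamma)`. `gamma = 1` is the
#' identity; `gamma < 1` gives the classic inverse-S overweighting of small
#' probabilities. The endpoints 0 and 1 pass through exactly.
#'
#' @param p_obj Objective probability(ies) in \[0, 1\].
#' @param gamma Weighting exponent, > 0.
#' @return Weighted probability(ies).
#' @examples
#' subjective_probability(0.5, 1)    # 0.5
#' subjective_probability(0.1, 0.6)
#' @export
subjective_probability <- function(p_obj, gamma) {
  if (any(!is.finite(p_obj)) || any(p_obj < 0) || any(p_obj > 1))
    stop("`p_obj` must lie in [0, 1]")
  out <- p_obj ^ gamma / (p_obj ^ gamma + (1 - p_obj) ^ gamma) ^ (1 / gamma)
  # endpoints are exact pass-throughs by convention
  out[p_obj == 0] <- 0
  out[p_obj == 1] <- 1
  out
}

#' Subjective expected value
#'
#' Product of the transformed magnitude and weighted probability,
#' `sEV = r_S * p_S`. With `alpha = gamma = 1` this is the objective
#' (Pascalian) expected value.
#'
#' @param r_obj Objective magnitude(s), > 0.
#' @param p_obj Objective probability(ies) in \[0, 1\].
#' @param params A [prospect_params()] object (only `alpha` and `gamma` are
#'   used).
#' @return Subjective expected value(s).
#' @export
subjective_ev <- function(r_obj, p_obj, params) {
  subjective_magnitude(r_obj, params$alpha) *
    subjective_probability(p_obj, params$gamma)
}

#' Softmax choice probabilities for a two-option trial
#'
#' Returns the probability of choosing each of two options given their
#' subjective expected values. The computation is shift-by-max stabilized so
#' extreme value/noise ratios do not overflow.
#'
#' @param sev_left,sev_right Subjective expected values of the two options
#'   (vectorized; recycled to common length).
#' @param tau Decision-noise parameter, > 0.
#' @param form Softmax parameterization, see [prospect_params()].
#' @return A list with components `left` and `right`, each a probability
#'   vector; `left + right == 1`.
#' @examples
#' choice_probability(0.6, 0.4, tau = 2, form = "inverse_temperature_multiply")
#' @export
choice_probability <- function(sev_left, sev_right, tau,
                               form = c("temperature_divide",
                                        "inverse_temperature_multiply")) {
  form <- match.arg(form)
  if (!is.numeric(tau) || any(tau <= 0)) stop("`tau` must be > 0")
  if (form == "temperature_divide") {
    xl <- sev_left / tau; xr <- sev_right / tau
  } else {
    xl <- sev_left * tau; xr <- sev_right * tau
  }
  m <- pmax(xl, xr)
  el <- exp(xl - m); er <- exp(xr - m)
  pl <- el / (el + er)
  list(left = pl, right = 1 - pl)
}

#' Choice log-likelihood of a dataset under prospect-theory parameters
#'
#' Sum over non-missed trials of the log softmax probability of the observed
#' choice. Missed-response trials are skipped.
#'
#' @param dataset A `choice_dataset` (see [simulate_agent()]) or any data
#'   frame with columns `magnitude_left/right`, `probability_left/right`,
#'   `choice`.
#' @param params A [prospect_params()] object.
#' @return A single log-likelihood value.
#' @export
choice_log_likelihood <- function(dataset, params) {
  keep <- dataset$choice %in% c("left", "right")
  if (!any(keep)) stop("dataset contains no non-missed trials")
  d <- dataset[keep, , drop = FALSE]
  sl <- subjective_ev(d$magnitude_left, d$probability_left, params)
  sr <- subjective_ev(d$magnitude_right, d$probability_right, params)
  pr <- choice_probability(sl, sr, params$tau, params$softmax_form)
  p_obs <- ifelse(d$choice == "left", pr$left, pr$right)
  sum(log(p_obs))
}
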
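#' Log-spaced parameter grid for Bayesian estimation
#'
#' Builds a three-dimensional grid over (alpha, gamma, tau) with each axis
#' equally spaced in log space, inclusive of both bounds.
#'
#' Default bounds are chosen for the `temperature_divide` softmax, where task
#' values live in (0, 1] so plausible temperatures are well below 1:
#' alpha and gamma in \[0.2, 3\] span the regimes reported for human choosers,
#' and tau in \[0.001, 1\] runs from near-deterministic to near-random
#' behaviour. For the `inverse_temperature_multiply` form use mirrored tau
#' bounds, e.g. `tau = c(1, 1000)`.
#'
#' @param alpha,gamma,tau Length-2 numeric `(low, high)` bounds per axis;
#'   `0 < low < high`.
#' @param n_points Number of grid points per axis (>= 2). The default 150
#'   gives the full-resolution grid; coarser grids (40--60) are accurate to
#'   within the corresponding grid resolution and much faster.
#' @return An object of class `parameter_grid`: list with numeric axes
#'   `alpha`, `gamma`, `tau` and `n_points`.
#' @examples
#' g <- build_grid(alpha = c(1, 100), n_points = 3)
#' g$alpha  # 1 10 100
#' @export
build_grid <- function(alpha = c(0.2, 3), gamma = c(0.2, 3),
                       tau = c(0.001, 1), n_points = 150) {
  axes <- list(alpha = alpha, gamma = gamma, tau = tau)
  if (n_points < 2) stop("`n_points` must be >= 2")
  out <- lapply(axes, function(b) {
    if (length(b) != 2L || any(!is.finite(b)) || b[1] <= 0 || b[2] <= b[1])
      stop("each bound must be (low, high) with 0 < low < high")
    exp(seq(log(b[1]), log(b[2]), length.out = n_points))
  })
  structure(c(out, list(n_points = as.integer(n_points))),
            class = "parameter_grid")
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf(
    "parameter_grid: %d points/axis; alpha [%.3g, %.3g], gamma [%.3g, %.3g], tau [%.3g, %.3g]\n",
    x$n_points, min(x$alpha), max(x$alpha), min(x$gamma), max(x$gamma),
    min(x$tau), max(x$tau)))
  invisible(x)
}

#' Joint posterior of (alpha, gamma, tau) on a grid
#'
#' Evaluates the choice log-likelihood of `dataset` at every grid cell
#' (uniform prior over cells), normalizes in the log domain, and returns the
#' joint posterior mass together with the three marginal distributions.
#'
#' The evaluation is vectorized: subjective values are precomputed for every
#' (alpha, gamma) pair, then the softmax likelihood is accumulated across
#' trials for each tau. This reproduces a literal cell-by-cell product of
#' choice probabilities to floating-point accuracy.
#'
#' @param dataset A `choice_dataset` or compatible data frame; missed trials
#'   are excluded from the likelihood.
#' @param grid A [build_grid()] object.
#' @param form Softmax parameterization, see [prospect_params()].
#' @return An object of class `posterior_grid`: list with the `grid`,
#'   `log_joint` and `posterior_mass` 3-D arrays (dimensions alpha x gamma x
#'   tau), marginal mass vectors `marginal_alpha/gamma/tau`, the
#'   log-evidence `log_evidence` (log mean likelihood over cells), and `form`.
#' @export
grid_posterior <- function(dataset, grid,
                           form = c("temperature_divide",
                                    "inverse_temperature_multiply")) {
  form <- match.arg(form)
  if (!inherits(grid, "parameter_grid")) stop("`grid` must be a parameter_grid")
  keep <- dataset$choice %in% c("left", "right")
  if (!any(keep)) stop("dataset contains no non-missed trials")
  d <- dataset[keep, , drop = FALSE]
  na <- length(grid$alpha); ng <- length(grid$gamma); nt <- length(grid$tau)

  # subjective values for every (alpha, gamma) pair: trials x (na*ng)
  rAL <- outer(d$magnitude_left, grid$alpha, `^`)
  rAR <- outer(d$magnitude_right, grid$alpha, `^`)
  pGL <- outer(d$probability_left, grid$gamma, subjective_probability)
  pGR <- outer(d$probability_right, grid$gamma, subjective_probability)
  ia <- rep(seq_len(na), times = ng)
  ig <- rep(seq_len(ng), each = na)
  # signed sEV difference: chosen minus unchosen
  sgn <- ifelse(d$choice == "left", 1, -1)
  X <- (rAL[, ia, drop = FALSE] * pGL[, ig, drop = FALSE] -
        rAR[, ia, drop = FALSE] * pGR[, ig, drop = FALSE]) * sgn

  log_joint <- array(NA_real_, dim = c(na, ng, nt))
  for (k in seq_len(nt)) {
    z <- if (form == "temperature_divide") X / grid$tau[k] else X * grid$tau[k]
    # log sigmoid, stable on both tails
    ll <- ifelse(z > 0, -log1p(exp(-z)), z - log1p(exp(z)))
    log_joint[, , k] <- colSums(ll)
  }

  m <- max(log_joint)
  w <- exp(log_joint - m)
  total <- sum(w)
  if (!is.finite(total) || total <= 0)
    stop("posterior mass underflowed; check the dataset and grid")
  post <- w / total
  structure(list(
    grid = grid,
    log_joint = log_joint,
    posterior_mass = post,
    marginal_alpha = apply(post, 1, sum),
    marginal_gamma = apply(post, 2, sum),
    marginal_tau = apply(post, 3, sum),
    log_evidence = m + log(total) - log(length(post)),
    form = form), class = "posterior_grid")
}

#' Posterior-mean parameter estimates from a grid posterior
#'
#' Each parameter is estimated as the mean of its marginal posterior on the
#' linear parameter scale, `sum(axis * marginal_mass)`.
#'
#' @param posterior A [grid_posterior()] object.
#' @return A [prospect_params()] object carrying the three estimates and the
#'   softmax form the posterior was computed under.
#' @export
marginal_means <- function(posterior) {
  if (!inherits(posterior, "posterior_grid"))
    stop("`posterior` must be a posterior_grid")
  g <- posterior$grid
  prospect_params(
    alpha = sum(g$alpha * posterior$marginal_alpha),
    gamma = sum(g$gamma * posterior$marginal_gamma),
    tau = sum(g$tau * posterior$marginal_tau),
    softmax_form = posterior$form)
}

#' Fit the prospect-theory choice model by grid-based Bayesian estimation
#'
#' Composes [build_grid()], [grid_posterior()] and [marginal_means()]. With
#' `per_condition = TRUE` (the default, matching the study design in which
#' the parameters are compared across timing conditions) the model is fitted
#' separately to each condition's trials; otherwise one joint fit is
#' returned.
#'
#' @param dataset A `choice_dataset`.
#' @param grid A [build_grid()] object, or `NULL` to build one from
#'   `n_points` and default bounds.
#' @param per_condition Fit each timing condition separately?
#' @param form Softmax parameterization.
#' @param n_points Grid points per axis when `grid` is `NULL`.
#' @param keep_posterior Keep the full `posterior_grid` object(s) in the
#'   result (can be large at high `n_points`).
#' @return An object of class `prospect_fit`: list with `estimates` (a data
#'   frame with one row per fit: condition, alpha, gamma, tau, log_evidence,
#'   n_trials) and, if requested, `posteriors` (named list).
#' @export
fit_prospect <- function(dataset, grid = NULL, per_condition = TRUE,
                         form = c("temperature_divide",
                                  "inverse_temperature_multiply"),
                         n_points = 60, keep_posterior = FALSE) {
  form <- match.arg(form)
  if (is.null(grid)) grid <- build_grid(n_points = n_points)
  splits <- if (per_condition) {
    split(seq_len(nrow(dataset)), dataset$condition)
  } else {
    list(all = seq_len(nrow(dataset)))
  }
  posteriors <- list()
  rows <- lapply(names(splits), function(cond) {
    d <- dataset[splits[[cond]], , drop = FALSE]
    post <- grid_posterior(d, grid, form)
    est <- marginal_means(post)
    if (keep_posterior) posteriors[[cond]] <<- post
    data.frame(condition = cond, alpha = est$alpha, gamma = est$gamma,
               tau = est$tau, log_evidence = post$log_evidence,
               n_trials = sum(d$choice %in% c("left", "right")),
               stringsAsFactors = FALSE)
  })
  structure(list(estimates = do.call(rbind, rows),
                 posteriors = if (keep_posterior) posteriors,
                 grid = grid, form = form),
            class = "prospect_fit")
}

#' @export
print.prospect_fit <- function(x, ...) {
  cat("prospect_fit (", x$form, ")\n", sep = "")
  print(x$estimates, row.names = FALSE)
  invisible(x)
}
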
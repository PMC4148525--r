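#' Trial-level design matrix for the epoch GLMs
#'
#' Builds the per-trial design used by [fit_timepoint_glm()]. Two equivalent
#' parameterizations of value coding are available: `sum_diff` carries
#' `value_difference` (chosen - unchosen) and `value_sum`
#' (chosen + unchosen); `chosen_unchosen` carries the two constituent values
#' directly. Both share `outcome_value` (chosen option rewarded, +/-1),
#' `response_side` (+1 left, -1 right), a reaction-time covariate, and an
#' intercept. The two variants span the same column space, so fitted values
#' are identical and betas map onto each other linearly.
#'
#' Values are the subjective expected values stored in the dataset
#' (`chosen_value`/`unchosen_value`); pass `params` to recompute them under
#' other (e.g. freshly fitted) prospect-theory parameters.
#'
#' @param dataset A `choice_dataset`; missed trials are excluded.
#' @param variant `"sum_diff"` or `"chosen_unchosen"`.
#' @param params Optional [prospect_params()] (or per-condition list) used to
#'   recompute subjective values.
#' @param standardize Z-score the parametric columns within condition
#'   (default). Disable to obtain raw columns, e.g. when verifying the
#'   linear map between the two variants.
#' @return A list of class `trial_design`: `X` (matrix, trials x columns),
#'   `trials` (row indices into `dataset`), `variant`, `condition` (per
#'   retained trial). Constant parametric columns are dropped with a
#'   warning; a rank-deficient design is an error naming the columns.
#' @export
build_trial_design <- function(dataset,
                               variant = c("sum_diff", "chosen_unchosen"),
                               params = NULL, standardize = TRUE) {
  variant <- match.arg(variant)
  ok <- which(dataset$choice %in% c("left", "right"))
  if (!length(ok)) stop("no non-missed trials")
  d <- dataset[ok, , drop = FALSE]

  if (!is.null(params)) {
    pick <- function(l, r) ifelse(d$choice == "left", l, r)
    if (is.list(params) && !inherits(params, "prospect_params")) {
      sl <- sr <- numeric(nrow(d))
      for (cond in names(params)) {
        i <- d$condition == cond
        sl[i] <- subjective_ev(d$magnitude_left[i], d$probability_left[i],
                               params[[cond]])
        sr[i] <- subjective_ev(d$magnitude_right[i], d$probability_right[i],
                               params[[cond]])
      }
    } else {
      sl <- subjective_ev(d$magnitude_left, d$probability_left, params)
      sr <- subjective_ev(d$magnitude_right, d$probability_right, params)
    }
    chosen <- pick(sl, sr); unchosen <- pick(sr, sl)
  } else {
    chosen <- d$chosen_value; unchosen <- d$unchosen_value
  }

  rewarded <- ifelse(d$choice == "left", d$outcome_left, d$outcome_right)
  cols <- if (variant == "sum_diff") {
    list(value_difference = chosen - unchosen,
         value_sum = chosen + unchosen)
  } else {
    list(chosen_value = chosen, unchosen_value = unchosen)
  }
  cols$outcome_value <- ifelse(rewarded, 1, -1)
  cols$response_side <- ifelse(d$choice == "left", 1, -1)
  cols$rt_covariate <- d$reaction_time_s

  zcols <- names(cols)
  X <- do.call(cbind, cols)
  if (standardize) {
    for (j in zcols) {
      v <- X[, j]
      for (cond in unique(as.character(d$condition))) {
        i <- d$condition == cond
        s <- stats::sd(v[i])
        v[i] <- if (is.na(s) || s == 0) v[i] - mean(v[i])
                else (v[i] - mean(v[i])) / s
      }
      X[, j] <- v
    }
  }
  const <- apply(X, 2, function(v) stats::sd(v) == 0 || all(!is.finite(v)))
  if (any(const)) {
    warning("dropping constant column(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
  }
  X <- cbind(intercept = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(X = X, trials = ok, variant = variant,
                 condition = as.character(d$condition)),
            class = "trial_design")
}

#' Per-timepoint ordinary least squares across trials
#'
#' At each epoch timepoint, regresses the across-trial vector of epoched
#' signal values on the trial design, giving a timecourse of effect sizes
#' (betas) for every regressor.
#'
#' @param epochs An [epoch_timeseries()] result; its rows must correspond to
#'   the design's trials (subset the design with `design_rows` when epoching
#'   dropped trials).
#' @param design A [build_trial_design()] object or a bare numeric matrix.
#' @param design_rows Optional row indices aligning the design with
#'   `epochs$epochs`.
#' @return Object of class `effect_timecourse`: list with `beta` (matrix,
#'   regressors x timepoints), `time_s`, and regressor names.
#' @export
fit_timepoint_glm <- function(epochs, design, design_rows = NULL) {
  X <- if (inherits(design, "trial_design")) design$X else as.matrix(design)
  if (!is.null(design_rows)) X <- X[design_rows, , drop = FALSE]
  Y <- epochs$epochs
  if (nrow(X) != nrow(Y))
    stop("design rows (", nrow(X), ") do not match epoch rows (", nrow(Y), ")")
  if (nrow(X) < ncol(X) + 5)
    stop("too few trials (", nrow(X), ") for ", ncol(X), " regressors")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("singular design matrix")
  beta <- qr.coef(qrX, Y)
  rownames(beta) <- colnames(X)
  structure(list(beta = beta, time_s = epochs$time_s,
                 regressors = colnames(X)), class = "effect_timecourse")
}
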
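#' Across-subject design linking value coding to choice performance
#'
#' Assembles, for one condition, the per-subject regression of choice
#' performance (percent higher-EV choices) on the chosen- and unchosen-value
#' HRF amplitudes of two ROIs. Predictors are z-scored across subjects.
#'
#' @param amplitudes Amplitude table from [analyze_roi_cohort()] run with the
#'   `chosen_unchosen` GLM variant.
#' @param accuracy Data frame with columns `subject`, `condition`,
#'   `accuracy_pct` (see [accuracy_higher_ev()]).
#' @param condition Which timing condition to model.
#' @param rois Length-2 character vector naming the two ROIs (order defines
#'   the region-difference contrast, second minus first).
#' @return A data frame of class `brain_behaviour_design` with one row per
#'   subject: `accuracy_pct`, then `chosen_<roi>` / `unchosen_<roi>` for both
#'   ROIs.
#' @export
build_brain_behaviour_design <- function(amplitudes, accuracy, condition,
                                         rois = c("vmPFC", "pSPL")) {
  stopifnot(length(rois) == 2)
  a <- amplitudes[amplitudes$condition == condition &
                    amplitudes$regressor %in% c("chosen_value",
                                                "unchosen_value") &
                    amplitudes$roi %in% rois, ]
  acc <- accuracy[accuracy$condition == condition, ]
  subjects <- sort(intersect(unique(a$subject), acc$subject))
  if (length(subjects) < 8)
    stop("need at least 8 subjects with amplitudes and accuracy")
  grab <- function(roi, reg) {
    v <- a$amplitude[a$roi == roi & a$regressor == reg][
      match(subjects, a$subject[a$roi == roi & a$regressor == reg])]
    as.numeric(scale(v))
  }
  out <- data.frame(
    subject = subjects,
    accuracy_pct = acc$accuracy_pct[match(subjects, acc$subject)])
  for (roi in rois) {
    out[[paste0("chosen_", roi)]] <- grab(roi, "chosen_value")
    out[[paste0("unchosen_", roi)]] <- grab(roi, "unchosen_value")
  }
  attr(out, "rois") <- rois
  attr(out, "condition") <- condition
  class(out) <- c("brain_behaviour_design", "data.frame")
  out
}

#' Across-subject GLM of choice performance on ROI value amplitudes
#'
#' Ordinary least squares of accuracy on the four (z-scored) value-amplitude
#' predictors, with contrast t-tests for the chosen-value effect in each
#' region and for the region difference of the chosen-value effect.
#'
#' A zero-variance response is reported as degenerate (all t = 0, p = 1)
#' rather than an error.
#'
#' @param design A [build_brain_behaviour_design()] data frame.
#' @param contrasts Optional named list of numeric contrast vectors over the
#'   model coefficients `(intercept, chosen_roi1, unchosen_roi1, chosen_roi2,
#'   unchosen_roi2)`; defaults to the chosen-value effect per region and the
#'   region difference `chosen_roi2 - chosen_roi1`.
#' @param tails Named character vector of alternatives per contrast
#'   (default two-sided); one-tailed p-values are reported alongside
#'   two-tailed ones either way.
#' @return Data frame: contrast, estimate, t, df, p (stated tail),
#'   p_two_sided, tail.
#' @export
fit_brain_behaviour <- function(design, contrasts = NULL, tails = NULL) {
  rois <- attr(design, "rois")
  if (is.null(rois))
    stop("`design` must come from build_brain_behaviour_design()")
  preds <- c(paste0(c("chosen_", "unchosen_"), rois[1]),
             paste0(c("chosen_", "unchosen_"), rois[2]))
  X <- cbind(intercept = 1, as.matrix(design[, preds]))
  y <- design$accuracy_pct
  n <- nrow(X); p <- ncol(X)
  if (n < p + 3) stop("need at least ", p + 3, " subjects")
  qrX <- qr(X)
  if (qrX$rank < p) stop("rank-deficient brain-behaviour design")
  beta <- qr.coef(qrX, y)
  res <- y - drop(X %*% beta)
  df <- n - p
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))

  if (is.null(contrasts)) {
    contrasts <- list()
    contrasts[[paste0("chosen_", rois[1])]] <- c(0, 1, 0, 0, 0)
    contrasts[[paste0("chosen_", rois[2])]] <- c(0, 0, 0, 1, 0)
    contrasts[[paste0("chosen_", rois[2], "_minus_", rois[1])]] <-
      c(0, -1, 0, 1, 0)
  }
  degenerate <- stats::sd(y) == 0
  rows <- lapply(names(contrasts), function(nm) {
    cv <- contrasts[[nm]]
    est <- sum(cv * beta)
    se <- sqrt(sigma2 * drop(t(cv) %*% XtXinv %*% cv))
    tval <- if (degenerate || se == 0) 0 else est / se
    alt <- if (!is.null(tails) && nm %in% names(tails)) tails[[nm]]
           else "two.sided"
    p1 <- switch(alt,
                 greater = stats::pt(tval, df, lower.tail = FALSE),
                 less = stats::pt(tval, df),
                 2 * stats::pt(-abs(tval), df))
    data.frame(contrast = nm, estimate = est, t = tval, df = df, p = p1,
               p_two_sided = 2 * stats::pt(-abs(tval), df), tail = alt,
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
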
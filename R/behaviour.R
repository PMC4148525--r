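#' Percent choices of the higher objective-EV option
#'
#' Choice accuracy per condition: among non-missed trials whose options
#' differ in objective expected value (magnitude x probability), the
#' percentage on which the higher-EV option was chosen. Equal-EV trials are
#' excluded from both numerator and denominator.
#'
#' @param dataset A `choice_dataset`.
#' @return Data frame with columns `condition`, `accuracy_pct`, `n_trials`.
#' @export
accuracy_higher_ev <- function(dataset) {
  ok <- dataset$choice %in% c("left", "right")
  ev_l <- dataset$magnitude_left * dataset$probability_left
  ev_r <- dataset$magnitude_right * dataset$probability_right
  eligible <- ok & ev_l != ev_r
  rows <- lapply(levels(factor(dataset$condition)), function(cond) {
    i <- eligible & dataset$condition == cond
    if (!any(i)) stop("condition '", cond, "' has no eligible trials")
    correct <- ifelse(ev_l[i] > ev_r[i], "left", "right") == dataset$choice[i]
    data.frame(condition = cond, accuracy_pct = 100 * mean(correct),
               n_trials = sum(i), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# logistic regression by iteratively reweighted least squares with an
# optional ridge penalty (excluding the intercept); used when plain glm
# hits separation
ridge_logistic <- function(X, y, ridge = 1e-2, max_iter = 100, tol = 1e-10) {
  p <- ncol(X)
  pen <- diag(c(0, rep(ridge, p - 1)), p)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    new <- solve(crossprod(X, w * X) + pen, crossprod(X, w * z))
    if (max(abs(new - beta)) < tol) { beta <- drop(new); break }
    beta <- drop(new)
  }
  beta
}

#' Trial-level choice regression
#'
#' Per-condition logistic regression of choosing the left option on the
#' experimental parameters that could drive the choice: the left-minus-right
#' reward-probability (`RP`) and reward-magnitude (`RM`) differences,
#' previous-trial outcome (`pO`) and choice (`pC`) side codes, and the
#' interactions of RP and RM with the standardized reaction time
#' (`RP_RT`, `RM_RT`). Positive coefficients mean the parameter increases
#' the probability of selecting the option carrying it.
#'
#' Coding conventions: `pC` is +1/-1 for a previous left/right choice; `pO`
#' is +1 when the previously chosen side was rewarded, -1 otherwise; both are
#' 0 on the first trial of a block or after a missed trial. With
#' `prev_coding = "winstay"`, `pO` is instead the win-stay code `pC * pO`
#' (previous outcome signed by previous side). Reaction time is z-scored
#' within condition before forming the interactions.
#'
#' If the plain ML fit does not converge or shows complete separation, the
#' model is refitted with a small ridge penalty and the row is flagged in
#' the `diagnostic` column.
#'
#' @param dataset A `choice_dataset`.
#' @param regressors Character vector choosing columns among
#'   `"RP"`, `"RM"`, `"pO"`, `"pC"`, `"RP_RT"`, `"RM_RT"`.
#' @param prev_coding `"side"` (default) or `"winstay"`.
#' @param ridge Ridge penalty used only on separation/non-convergence.
#' @param min_trials Minimum non-missed trials per condition.
#' @return Data frame with columns `condition`, `regressor`, `estimate`,
#'   `diagnostic` (`"ok"` or `"ridge"`).
#' @export
choice_regression <- function(dataset,
                              regressors = c("RP", "RM", "pO", "pC",
                                             "RP_RT", "RM_RT"),
                              prev_coding = c("side", "winstay"),
                              ridge = 1e-2, min_trials = 20) {
  prev_coding <- match.arg(prev_coding)
  d <- as.data.frame(dataset)
  n <- nrow(d)
  ok <- d$choice %in% c("left", "right")

  # previous-trial codes (block-local history)
  pc <- po <- numeric(n)
  for (i in seq_len(n)) {
    if (i == 1L || d$block_index[i] != d$block_index[i - 1L] ||
        !ok[i - 1L]) next
    pc[i] <- if (d$choice[i - 1L] == "left") 1 else -1
    rewarded <- if (d$choice[i - 1L] == "left") d$outcome_left[i - 1L]
                else d$outcome_right[i - 1L]
    po[i] <- if (rewarded) 1 else -1
  }
  if (prev_coding == "winstay") po <- po * pc

  drp <- d$probability_left - d$probability_right
  drm <- d$magnitude_left - d$magnitude_right
  zrt <- rep(NA_real_, n)
  for (cond in levels(factor(d$condition))) {
    i <- ok & d$condition == cond
    zrt[i] <- as.numeric(scale(d$reaction_time_s[i]))
  }

  all_cols <- list(RP = drp, RM = drm, pO = po, pC = pc,
                   RP_RT = drp * zrt, RM_RT = drm * zrt)
  unknown <- setdiff(regressors, names(all_cols))
  if (length(unknown)) stop("unknown regressor(s): ",
                            paste(unknown, collapse = ", "))

  rows <- list()
  for (cond in levels(factor(d$condition))) {
    i <- which(ok & d$condition == cond)
    if (length(i) < min_trials)
      stop("condition '", cond, "' has fewer than ", min_trials, " valid trials")
    X <- cbind(intercept = 1,
               do.call(cbind, lapply(all_cols[regressors], `[`, i)))
    if (qr(X)$rank < ncol(X))
      stop("degenerate design in condition '", cond, "'")
    y <- as.integer(d$choice[i] == "left")
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = stats::binomial()))
    mu <- fit$fitted.values
    separated <- any(mu > 1 - 1e-8) || any(mu < 1e-8)
    if (!fit$converged || separated) {
      beta <- ridge_logistic(X, y, ridge)
      diag_flag <- "ridge"
    } else {
      beta <- stats::coef(fit)
      diag_flag <- "ok"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      condition = cond, regressor = colnames(X),
      estimate = unname(beta), diagnostic = diag_flag,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Paired and one-sample comparisons of per-subject behavioural values
#'
#' Group-level comparisons of any per-subject, per-condition quantity
#' (prospect-theory parameter estimates, regression coefficients,
#' accuracies): paired t-tests between all condition pairs and, optionally,
#' one-sample t-tests of each condition against a reference value (e.g.
#' alpha against 1).
#'
#' @param values Data frame with columns `subject`, `condition`, `value`.
#' @param reference Optional scalar for one-sample tests against a
#'   reference.
#' @param alternative Tail for all tests (`"two.sided"`, `"greater"`,
#'   `"less"`).
#' @return A list with `paired` (condition pairs; only subjects present in
#'   both conditions enter) and, when `reference` is given, `one_sample`
#'   data frames. Columns: t, df, p, mean difference, tail, n.
#' @export
compare_conditions <- function(values, reference = NULL,
                               alternative = "two.sided") {
  stopifnot(all(c("subject", "condition", "value") %in% names(values)))
  conds <- unique(as.character(values$condition))
  if (length(unique(values$subject)) < 2) stop("need at least 2 subjects")
  paired <- list()
  if (length(conds) >= 2) {
    for (i in seq_len(length(conds) - 1)) for (j in (i + 1):length(conds)) {
      x <- values[values$condition == conds[i], ]
      y <- values[values$condition == conds[j], ]
      common <- intersect(x$subject, y$subject)
      xv <- x$value[match(common, x$subject)]
      yv <- y$value[match(common, y$subject)]
      tt <- t_paired(xv, yv, alternative)
      paired[[length(paired) + 1L]] <- data.frame(
        condition_a = conds[i], condition_b = conds[j],
        mean_diff = mean(xv - yv), t = tt$t, df = tt$df, p = tt$p,
        tail = alternative, n = length(common), stringsAsFactors = FALSE)
    }
  }
  out <- list(paired = do.call(rbind, paired))
  if (!is.null(reference)) {
    os <- lapply(conds, function(cond) {
      v <- values$value[values$condition == cond]
      tt <- t_one_sample(v, reference, alternative)
      data.frame(condition = cond, mean = mean(v), reference = reference,
                 t = tt$t, df = tt$df, p = tt$p, tail = alternative,
                 n = length(v), stringsAsFactors = FALSE)
    })
    out$one_sample <- do.call(rbind, os)
  }
  out
}
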
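#' One-sample and between-condition tests on HRF amplitudes
#'
#' For every regressor x ROI x condition cell, tests the across-subject
#' amplitudes against zero with a one-sample t-test. Directional (one-tailed)
#' alternatives may be declared per cell; every row of the output states the
#' tail used. Optionally, paired between-condition contrasts are computed for
#' a chosen regressor (classically the unchosen value, whose sign is the
#' diagnostic of input vs comparison coding).
#'
#' @param amplitudes Data frame from [analyze_roi_cohort()] (columns
#'   `subject`, `roi`, `condition`, `regressor`, `amplitude`).
#' @param tails Optional data frame with columns `roi`, `condition`,
#'   `regressor`, `alternative` (`"greater"`, `"less"`, `"two.sided"`); cells
#'   not listed default to two-sided.
#' @param paired_regressor Regressor for paired condition contrasts, or
#'   `NULL` to skip.
#' @return A list with `one_sample` and (optionally) `paired` data frames
#'   carrying estimates, t, df, p and tail.
#' @export
group_effect_tests <- function(amplitudes, tails = NULL,
                               paired_regressor = "unchosen_value") {
  cells <- unique(amplitudes[, c("roi", "condition", "regressor")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    x <- amplitudes$amplitude[
      amplitudes$roi == cell$roi & amplitudes$condition == cell$condition &
        amplitudes$regressor == cell$regressor]
    if (length(x) < 3) stop("fewer than 3 subjects in cell ",
                            paste(unlist(cell), collapse = "/"))
    alt <- "two.sided"
    if (!is.null(tails)) {
      hit <- tails$roi == cell$roi & tails$condition == cell$condition &
        tails$regressor == cell$regressor
      if (any(hit)) alt <- tails$alternative[which(hit)[1]]
    }
    tt <- t_one_sample(x, 0, alt)
    data.frame(cell, mean = mean(x), t = tt$t, df = tt$df, p = tt$p,
               tail = alt, n = length(x), stringsAsFactors = FALSE)
  })
  out <- list(one_sample = do.call(rbind, rows))
  if (!is.null(paired_regressor)) {
    a <- amplitudes[amplitudes$regressor == paired_regressor, ]
    prs <- list()
    for (roi in unique(a$roi)) {
      conds <- unique(a$condition[a$roi == roi])
      if (length(conds) < 2) next
      for (i in seq_len(length(conds) - 1)) for (j in (i + 1):length(conds)) {
        x <- a[a$roi == roi & a$condition == conds[i], ]
        y <- a[a$roi == roi & a$condition == conds[j], ]
        common <- intersect(x$subject, y$subject)
        xv <- x$amplitude[match(common, x$subject)]
        yv <- y$amplitude[match(common, y$subject)]
        tt <- t_paired(xv, yv)
        prs[[length(prs) + 1L]] <- data.frame(
          roi = roi, regressor = paired_regressor,
          condition_a = conds[i], condition_b = conds[j],
          mean_diff = mean(xv - yv), t = tt$t, df = tt$df, p = tt$p,
          tail = "two.sided", n = length(common), stringsAsFactors = FALSE)
      }
    }
    out$paired <- do.call(rbind, prs)
  }
  out
}

#' Two-way within-subject ANOVA: brain area x timing condition
#'
#' Repeated-measures ANOVA on one regressor's HRF amplitudes with the
#' within-subject factors brain area (2 levels) and condition (3 levels).
#' Each effect is tested against its own effect-by-subject interaction, the
#' standard fully-within decomposition, giving df (1, n-1) for area and
#' (2, 2(n-1)) for condition and the interaction at 2 areas x 3 conditions.
#'
#' @param amplitudes Data frame as in [group_effect_tests()], restricted to
#'   (or filtered by) `regressor`.
#' @param regressor Which regressor's amplitudes to analyse.
#' @return Data frame with one row per effect (`area`, `condition`,
#'   `area:condition`): F, df1, df2, p.
#' @export
rm_anova_area_by_condition <- function(amplitudes,
                                       regressor = "unchosen_value") {
  a <- amplitudes[amplitudes$regressor == regressor, ]
  if (!nrow(a)) stop("no rows for regressor ", regressor)
  a$subject <- factor(a$subject)
  a$roi <- factor(a$roi)
  a$condition <- factor(a$condition)
  tab <- table(a$subject, a$roi, a$condition)
  if (any(tab != 1))
    stop("each subject needs exactly one amplitude per area x condition cell")
  fit <- stats::aov(amplitude ~ roi * condition +
                      Error(subject / (roi * condition)), data = a)
  sm <- summary(fit)
  ss_tol <- 1e-12 * (sum((a$amplitude - mean(a$amplitude))^2) + 1e-300)
  grab <- function(stratum, label) {
    s <- sm[[stratum]][[1]]
    i <- match(label, trimws(rownames(s)))
    Fv <- s$`F value`[i]; pv <- s$`Pr(>F)`[i]
    # no between-cell variation: effect and error SS numerically zero
    if (s$`Sum Sq`[i] < ss_tol && s$`Sum Sq`[nrow(s)] < ss_tol) {
      Fv <- 0; pv <- 1
    }
    data.frame(effect = label,
               F = Fv, df1 = s$Df[i],
               df2 = s$Df[nrow(s)], p = pv,
               stringsAsFactors = FALSE)
  }
  out <- rbind(grab("Error: subject:roi", "roi"),
               grab("Error: subject:condition", "condition"),
               grab("Error: subject:roi:condition", "roi:condition"))
  out$effect <- c("area", "condition", "area:condition")
  rownames(out) <- NULL
  out
}
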
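#' Plot effect timecourses with across-subject mean and SEM
#'
#' One panel per ROI x condition, one ribbon per regressor: solid line is
#' the across-subject mean effect size at each epoch timepoint, shading is
#' +/- 1 SEM.
#'
#' @param timecourses Tidy timecourse table from [analyze_roi_cohort()]
#'   (columns `subject`, `roi`, `condition`, `regressor`, `time_s`, `beta`).
#' @param regressors Which regressors to show (default: the value
#'   regressors present).
#' @return A ggplot object.
#' @export
plot_effect_timecourses <- function(timecourses, regressors = NULL) {
  tc <- timecourses
  if (is.null(regressors))
    regressors <- intersect(unique(tc$regressor),
                            c("value_sum", "value_difference",
                              "chosen_value", "unchosen_value"))
  tc <- tc[tc$regressor %in% regressors, ]
  agg <- stats::aggregate(beta ~ roi + condition + regressor + time_s,
                          data = tc, FUN = function(x)
                            c(mean = mean(x),
                              sem = stats::sd(x) / sqrt(length(x))))
  agg <- do.call(data.frame, agg)
  names(agg)[names(agg) == "beta.mean"] <- "mean"
  names(agg)[names(agg) == "beta.sem"] <- "sem"
  agg$condition <- factor(agg$condition,
                          levels = c("short", "middle", "long"))
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$time_s, y = .data$mean,
                                    colour = .data$regressor,
                                    fill = .data$regressor)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(roi ~ condition) +
    ggplot2::labs(x = "time from stimulus onset (s)",
                  y = "effect size (a.u.)") +
    ggplot2::theme_minimal()
}

#' Plot per-condition behavioural summaries
#'
#' Bar chart (mean +/- SEM across subjects) of any per-subject,
#' per-condition behavioural quantity, e.g. accuracy or regression
#' coefficients by regressor.
#'
#' @param values Data frame with columns `condition`, `value` and optionally
#'   a `group` column for side-by-side bars (e.g. regressor).
#' @return A ggplot object.
#' @export
plot_condition_summary <- function(values) {
  values$condition <- factor(values$condition,
                             levels = c("short", "middle", "long"))
  has_group <- "group" %in% names(values)
  form <- if (has_group) value ~ condition + group else value ~ condition
  agg <- stats::aggregate(form, data = values, FUN = function(x)
    c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x))))
  agg <- do.call(data.frame, agg)
  names(agg)[names(agg) == "value.mean"] <- "mean"
  names(agg)[names(agg) == "value.sem"] <- "sem"
  pos <- if (has_group) ggplot2::position_dodge(0.8) else "identity"
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$condition,
                                         y = .data$mean))
  if (has_group)
    p <- p + ggplot2::aes(fill = .data$group)
  p + ggplot2::geom_col(position = pos, width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           position = pos, width = 0.2) +
    ggplot2::labs(x = NULL, y = "mean ± SEM") +
    ggplot2::theme_minimal()
}
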
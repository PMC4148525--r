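# full-precision number formatting so TSV round-trips are exact
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "n/a" else sprintf("%.17g", v)
  }, "")
  out
}

events_columns <- c("onset", "duration", "condition", "block_index",
                    "magnitude_left", "magnitude_right",
                    "probability_left", "probability_right",
                    "is_nobrainer", "is_tradeoff", "choice", "rt",
                    "outcome_left", "outcome_right",
                    "chosen_value", "unchosen_value",
                    "planned_iti_s", "planned_outcome_delay_s")

#' Write a choice dataset as a BIDS-style events table
#'
#' Tab-separated, one row per trial, with `onset` (stimulus onset, seconds
#' from run start) and `duration` (the reaction time) as the first two
#' columns, followed by the task-specific columns. Missing values are
#' written as `n/a`. Numbers are written at full precision, so
#' [read_events()] restores the dataset exactly.
#'
#' @param dataset A `choice_dataset`.
#' @param path Output file path (conventionally `*_events.tsv`).
#' @return `path`, invisibly.
#' @export
write_events <- function(dataset, path) {
  d <- as.data.frame(dataset)
  out <- data.frame(
    onset = fmt_num(d$stimulus_onset_s),
    duration = fmt_num(d$reaction_time_s),
    condition = as.character(d$condition),
    block_index = d$block_index,
    magnitude_left = fmt_num(d$magnitude_left),
    magnitude_right = fmt_num(d$magnitude_right),
    probability_left = fmt_num(d$probability_left),
    probability_right = fmt_num(d$probability_right),
    is_nobrainer = as.integer(d$is_nobrainer),
    is_tradeoff = as.integer(d$is_tradeoff),
    choice = d$choice,
    rt = fmt_num(d$reaction_time_s),
    outcome_left = as.integer(d$outcome_left),
    outcome_right = as.integer(d$outcome_right),
    chosen_value = fmt_num(d$chosen_value),
    unchosen_value = fmt_num(d$unchosen_value),
    planned_iti_s = fmt_num(d$planned_iti_s),
    planned_outcome_delay_s = fmt_num(d$planned_outcome_delay_s),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "n/a")
  invisible(path)
}

#' Read a choice dataset from an events table
#'
#' Inverse of [write_events()]. Schema violations are reported with the
#' name of the missing column.
#'
#' @param path Path to a tab-separated events file.
#' @return A `choice_dataset`.
#' @export
read_events <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = "n/a", check.names = FALSE)
  missing_cols <- setdiff(events_columns, names(raw))
  if (length(missing_cols))
    stop("events file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  num <- function(v) as.numeric(v)
  d <- data.frame(
    trial_index = seq_len(nrow(raw)),
    condition = factor(raw$condition,
                       levels = c("short", "middle", "long")),
    block_index = as.integer(raw$block_index),
    magnitude_left = num(raw$magnitude_left),
    magnitude_right = num(raw$magnitude_right),
    probability_left = num(raw$probability_left),
    probability_right = num(raw$probability_right),
    is_nobrainer = raw$is_nobrainer == 1,
    is_tradeoff = raw$is_tradeoff == 1,
    stimulus_onset_s = num(raw$onset),
    planned_iti_s = num(raw$planned_iti_s),
    planned_outcome_delay_s = num(raw$planned_outcome_delay_s),
    choice = raw$choice,
    reaction_time_s = num(raw$rt),
    outcome_left = raw$outcome_left == 1,
    outcome_right = raw$outcome_right == 1,
    chosen_value = num(raw$chosen_value),
    unchosen_value = num(raw$unchosen_value),
    stringsAsFactors = FALSE)
  bad_choice <- !d$choice %in% c("left", "right", "missed")
  if (any(bad_choice))
    stop("ill-typed `choice` values: ",
         paste(unique(d$choice[bad_choice]), collapse = ", "))
  class(d) <- c("choice_dataset", "data.frame")
  d
}

#' Write ROI timeseries as a tab-separated table
#'
#' One column per ROI, one row per volume; the repetition time is recorded
#' in a `# tr_s = <value>` header comment.
#'
#' @param ts_list A list of `roi_timeseries` sharing TR and length (or a
#'   single `roi_timeseries`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts_list, path) {
  if (inherits(ts_list, "roi_timeseries")) ts_list <- list(ts_list)
  trs <- unique(vapply(ts_list, `[[`, 0, "tr_s"))
  ns <- unique(vapply(ts_list, `[[`, 0L, "n_volumes"))
  if (length(trs) != 1 || length(ns) != 1)
    stop("all ROI series must share tr_s and length")
  labels <- vapply(ts_list, `[[`, "", "roi_label")
  mat <- vapply(ts_list, function(t) fmt_num(t$values), character(ns))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# tr_s = %.17g", trs), con)
  writeLines(paste(labels, collapse = "\t"), con)
  utils::write.table(mat, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read ROI timeseries written by [write_timeseries()]
#'
#' @param path Path to the tab-separated timeseries table.
#' @return A named list of `roi_timeseries`.
#' @export
read_timeseries <- function(path) {
  lines <- readLines(path, n = 2)
  if (!grepl("^# tr_s = ", lines[1]))
    stop("timeseries file lacks the '# tr_s = ' header")
  tr <- as.numeric(sub("^# tr_s = ", "", lines[1]))
  labels <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  mat <- utils::read.table(path, sep = "\t", skip = 2,
                           stringsAsFactors = FALSE)
  if (ncol(mat) != length(labels))
    stop("column count (", ncol(mat), ") does not match ROI labels (",
         length(labels), ")")
  out <- lapply(seq_along(labels), function(j)
    structure(list(values = as.numeric(mat[[j]]), tr_s = tr,
                   roi_label = labels[j], n_volumes = nrow(mat)),
              class = "roi_timeseries"))
  names(out) <- labels
  out
}

#' Default pipeline run configuration
#'
#' All knobs of the end-to-end synthetic pipeline in one list: cohort size,
#' schedule, agent parameters per condition, reaction-time model, ROI
#' ground-truth regimes, estimation grid, GLM variant and seeds. Defaults
#' reproduce the study's design scale (28 subjects, 70 trials per condition,
#' 150-point grid).
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    n_subjects = 28,
    n_per_condition = 70,
    nobrainer_fraction = 0.1,
    tradeoff_fraction = 0.4,
    corr_target = 0.2,
    display_mode = "magnitude_as_bar",
    agent = list(
      short = list(alpha = 1.0, gamma = 0.75, tau = 0.02),
      middle = list(alpha = 0.85, gamma = 0.75, tau = 0.012),
      long = list(alpha = 0.8, gamma = 0.75, tau = 0.008)),
    rt_medians_s = c(short = 0.793, middle = 1.180, long = 3.366),
    rt_sdlog = 0.2,
    bold = list(weight = 1, noise_sd = 1, ar1 = 0.3, tr_s = 3),
    grid_points = 150,
    softmax_form = "temperature_divide",
    glm_variant = "chosen_unchosen",
    seed = 1)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration (YAML)
#'
#' @param config A `run_config` list.
#' @param path YAML file path.
#' @return `write_run_config`: `path` invisibly; `read_run_config`: a
#'   `run_config` that round-trips identically.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$rt_medians_s <- as.list(cfg$rt_medians_s)  # keep names in YAML
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$rt_medians_s <- unlist(cfg$rt_medians_s)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$n_subjects) || cfg$n_subjects < 1)
    stop("config error: `n_subjects` must be >= 1")
  if (cfg$n_per_condition %% 10 != 0)
    stop("config error: `n_per_condition` must be a multiple of 10")
  if (is.null(cfg$seed)) stop("config error: `seed` is required")
  if (!cfg$glm_variant %in% c("chosen_unchosen", "sum_diff"))
    stop("config error: unknown `glm_variant`")
  invisible(cfg)
}
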
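#' Generate a trial schedule for the timed value-guided choice task
#'
#' Builds a schedule of two-attribute trials (reward magnitude shown as a bar,
#' reward probability as a percentage) organised in alternating 10-trial
#' blocks of three timing conditions (`short`, `middle`, `long`), with
#' `n_per_condition` trials per condition.
#'
#' Three trial kinds are mixed:
#' \describe{
#'   \item{trade-off}{objective EVs of the two options matched within ~10%
#'     at a value level drawn from a narrow band, with opposite
#'     magnitude/probability compositions. These are the difficult trials
#'     that make the curvature and weighting parameters identifiable.}
#'   \item{no-brainer}{one option strictly dominates on both magnitude and
#'     probability.}
#'   \item{free}{both options drawn independently and uniformly.}
#' }
#'
#' The schedule is then decorrelated: single trials are iteratively resampled
#' (a proposal is kept only if it lowers the absolute correlation between the
#' higher and lower objective EV across trials, i.e. the chosen/unchosen value
#' correlation of a greedy chooser) until `|r| <= corr_target` or `max_iter`
#' proposals have been tried. Keeping the matched trials' value levels in a
#' narrow band prevents them from inflating this correlation.
#'
#' Stimulus onsets are planned deterministically from the condition's
#' canonical response time (0.77 / 1.41 / 3.4 s), the drawn outcome delay and
#' inter-trial interval, a 1 s outcome display, and a 1 s block precue before
#' each 10-trial block.
#'
#' @param n_per_condition Trials per timing condition; must be a multiple of
#'   the block length (10). Default 70 (the study design).
#' @param nobrainer_fraction Fraction of dominated trials in `[0, 0.5)`.
#' @param tradeoff_fraction Fraction of EV-matched trade-off trials.
#' @param corr_target Absolute bound on the greedy-chooser chosen/unchosen
#'   EV correlation. Default 0.2 (the study schedule achieved r = 0.18).
#' @param display_mode `"magnitude_as_bar"` (default) or
#'   `"probability_as_bar"` (the control experiment's reversed display).
#'   Relabels which attribute is carried by the bar; see [simulate_agent()].
#' @param iti_range,outcome_delay_range Length-2 ranges (seconds) for the
#'   inter-trial interval and the response-to-outcome delay. Defaults 3.5--6 s.
#' @param magnitude_range Range of objective magnitudes (arbitrary reward
#'   units in (0, 1]).
#' @param probability_range Range of reward probabilities; values are rounded
#'   to whole percent as displayed.
#' @param max_iter Cap on decorrelation proposals; exceeding it is an error.
#' @param seed Integer seed; the schedule is a deterministic function of its
#'   arguments and the seed.
#' @return A data frame of class `trial_schedule` with one row per trial and
#'   columns `trial_index`, `condition`, `block_index`, `magnitude_left/right`,
#'   `probability_left/right`, `is_nobrainer`, `is_tradeoff`,
#'   `stimulus_onset_s`, `planned_iti_s`, `planned_outcome_delay_s`.
#'   Attributes: `display_mode`, `achieved_corr`, `seed`.
#' @examples
#' sched <- generate_schedule(n_per_condition = 20, seed = 1)
#' attr(sched, "achieved_corr")
#' @export
generate_schedule <- function(n_per_condition = 70,
                              nobrainer_fraction = 0.1,
                              tradeoff_fraction = 0.4,
                              corr_target = 0.2,
                              display_mode = c("magnitude_as_bar",
                                               "probability_as_bar"),
                              iti_range = c(3.5, 6),
                              outcome_delay_range = c(3.5, 6),
                              magnitude_range = c(0.1, 1),
                              probability_range = c(0.10, 0.90),
                              max_iter = 10000,
                              seed = 1) {
  display_mode <- match.arg(display_mode)
  block_len <- 10L
  if (n_per_condition %% block_len != 0)
    stop("`n_per_condition` must be a multiple of the block length (10)")
  if (nobrainer_fraction < 0 || nobrainer_fraction >= 0.5)
    stop("`nobrainer_fraction` must be in [0, 0.5)")
  if (tradeoff_fraction < 0 || nobrainer_fraction + tradeoff_fraction > 0.9)
    stop("`tradeoff_fraction` invalid or leaves too few free trials")
  set.seed(as.integer(seed))

  conditions <- c("short", "middle", "long")
  n_blocks_per_cond <- n_per_condition / block_len
  cond_seq <- rep(rep(conditions, n_blocks_per_cond), each = block_len)
  n <- length(cond_seq)

  n_nb <- round(nobrainer_fraction * n)
  n_to <- round(tradeoff_fraction * n)
  kind <- sample(rep(c("nobrainer", "tradeoff", "free"),
                     c(n_nb, n_to, n - n_nb - n_to)))

  mlo <- magnitude_range[1]; mhi <- magnitude_range[2]
  plo <- probability_range[1]; phi <- probability_range[2]
  rp <- function(x) round(x, 2)

  mL <- numeric(n); mR <- numeric(n); pL <- numeric(n); pR <- numeric(n)
  dominated <- function(v) {
    (v[1] > v[2] && v[3] > v[4]) || (v[2] > v[1] && v[4] > v[3])
  }
  draw_trial <- function(k) {
    if (k == "nobrainer") {
      ms <- sort(stats::runif(2, mlo, mhi))
      ps <- sort(rp(stats::runif(2, plo, phi)))
      if (ps[1] == ps[2]) ps[1] <- max(0.01, ps[1] - 0.01)
      return(if (stats::runif(1) < 0.5) c(ms[2], ms[1], ps[2], ps[1])
             else c(ms[1], ms[2], ps[1], ps[2]))
    }
    # dominance is reserved for designated no-brainer trials: redraw on
    # accidental domination so is_nobrainer <=> one option dominates
    repeat {
      v <- if (k == "tradeoff") {
        ev <- stats::runif(1, 0.15, 0.45)
        p1 <- rp(stats::runif(1, max(plo, ev / mhi), phi))
        m1 <- min(mhi, max(mlo, ev / p1))
        p2 <- rp(stats::runif(1, max(plo, ev / mhi), phi))
        m2 <- min(mhi, max(mlo, ev / p2 * stats::runif(1, 0.9, 1.11)))
        c(m1, m2, p1, p2)
      } else {
        c(stats::runif(2, mlo, mhi), rp(stats::runif(2, plo, phi)))
      }
      if (!dominated(v)) return(v)
    }
  }
  for (i in seq_len(n)) {
    v <- draw_trial(kind[i])
    mL[i] <- v[1]; mR[i] <- v[2]; pL[i] <- v[3]; pR[i] <- v[4]
  }

  greedy_corr <- function() {
    evL <- mL * pL; evR <- mR * pR
    stats::cor(pmax(evL, evR), pmin(evL, evR))
  }
  cur <- greedy_corr()
  it <- 0L
  while (abs(cur) > corr_target && it < max_iter) {
    it <- it + 1L
    i <- sample.int(n, 1L)
    old <- c(mL[i], mR[i], pL[i], pR[i])
    v <- draw_trial(kind[i])
    mL[i] <- v[1]; mR[i] <- v[2]; pL[i] <- v[3]; pR[i] <- v[4]
    new <- greedy_corr()
    if (abs(new) < abs(cur)) cur <- new
    else { mL[i] <- old[1]; mR[i] <- old[2]; pL[i] <- old[3]; pR[i] <- old[4] }
  }
  if (abs(cur) > corr_target)
    stop(sprintf(paste0(
      "could not reach |greedy chosen/unchosen correlation| <= %.3g within ",
      "%d resampling steps (achieved %.3g); relax `corr_target` or raise ",
      "`max_iter`"), corr_target, max_iter, cur))

  # planned event timing: canonical response times per condition
  canonical_rt <- c(short = 0.77, middle = 1.41, long = 3.4)
  iti <- stats::runif(n, iti_range[1], iti_range[2])
  odel <- stats::runif(n, outcome_delay_range[1], outcome_delay_range[2])
  onset <- numeric(n)
  t_cur <- 0
  for (i in seq_len(n)) {
    if ((i - 1L) %% block_len == 0L) t_cur <- t_cur + 1  # block precue, 1 s
    onset[i] <- t_cur
    t_cur <- t_cur + canonical_rt[[cond_seq[i]]] + odel[i] + 1 + iti[i]
  }

  out <- data.frame(
    trial_index = seq_len(n),
    condition = factor(cond_seq, levels = conditions),
    block_index = rep(seq_len(n / block_len), each = block_len),
    magnitude_left = mL, magnitude_right = mR,
    probability_left = pL, probability_right = pR,
    is_nobrainer = kind == "nobrainer",
    is_tradeoff = kind == "tradeoff",
    stimulus_onset_s = onset,
    planned_iti_s = iti,
    planned_outcome_delay_s = odel,
    stringsAsFactors = FALSE)
  class(out) <- c("trial_schedule", "data.frame")
  attr(out, "display_mode") <- display_mode
  attr(out, "achieved_corr") <- cur
  attr(out, "seed") <- as.integer(seed)
  out
}
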
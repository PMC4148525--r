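make_amplitude_table <- function(values_fun, n = 6,
                                 rois = c("vmPFC", "pSPL"),
                                 conditions = c("short", "middle", "long"),
                                 regressor = "unchosen_value") {
  g <- expand.grid(subject = seq_len(n), roi = rois, condition = conditions,
                   stringsAsFactors = FALSE)
  g$regressor <- regressor
  g$amplitude <- values_fun(g)
  g
}

test_that("one-sample amplitude tests match the closed form and tails", {
  x <- c(0.3, 0.5, 0.1, 0.6, 0.4)
  tab <- data.frame(subject = 1:5, roi = "vmPFC", condition = "short",
                    regressor = "value_sum", amplitude = x)
  gt <- group_effect_tests(tab, paired_regressor = NULL)
  t_hand <- mean(x) / (sd(x) / sqrt(5))
  expect_equal(gt$one_sample$t, t_hand, tolerance = 1e-10)
  expect_equal(gt$one_sample$df, 4)
  # one-tailed p is half of two-tailed when t > 0
  tails <- data.frame(roi = "vmPFC", condition = "short",
                      regressor = "value_sum", alternative = "greater")
  gt1 <- group_effect_tests(tab, tails = tails, paired_regressor = NULL)
  expect_equal(gt1$one_sample$p, gt$one_sample$p / 2, tolerance = 1e-12)
  # all-zero amplitudes give t = 0
  tab0 <- tab; tab0$amplitude <- 0
  expect_equal(group_effect_tests(tab0, paired_regressor = NULL)$one_sample$t, 0)
})

test_that("paired condition contrasts use shared subjects", {
  tab <- make_amplitude_table(function(g)
    ifelse(g$condition == "short", 1, -1) + 0.1 * g$subject)
  gt <- group_effect_tests(tab, paired_regressor = "unchosen_value")
  sm <- gt$paired[gt$paired$roi == "vmPFC" &
                    gt$paired$condition_a == "short" &
                    gt$paired$condition_b == "middle", ]
  # constant difference of 2 across subjects -> infinite t
  expect_equal(sm$mean_diff, 2, tolerance = 1e-12)
  expect_true(is.infinite(sm$t) && sm$t > 0)
})

test_that("two-way within-subject ANOVA reproduces explicit SS formulas", {
  # 4-subject toy table worked through the standard decomposition below
  set.seed(77)
  tab <- make_amplitude_table(function(g)
    0.5 * (g$roi == "pSPL") +
      0.3 * (g$condition == "long") +
      0.4 * (g$roi == "pSPL" & g$condition == "short") +
      0.2 * g$subject + rnorm(nrow(g), sd = 0.3), n = 4)
  an <- rm_anova_area_by_condition(tab)

  # explicit sums of squares (fully within-subject design)
  y <- array(NA_real_, c(4, 2, 3))
  for (r in seq_len(nrow(tab)))
    y[tab$subject[r], match(tab$roi[r], c("vmPFC", "pSPL")),
      match(tab$condition[r], c("short", "middle", "long"))] <- tab$amplitude[r]
  gm <- mean(y)
  m_s <- apply(y, 1, mean); m_a <- apply(y, 2, mean); m_c <- apply(y, 3, mean)
  m_sa <- apply(y, c(1, 2), mean); m_sc <- apply(y, c(1, 3), mean)
  m_ac <- apply(y, c(2, 3), mean)
  ss_a <- 4 * 3 * sum((m_a - gm)^2)
  ss_c <- 4 * 2 * sum((m_c - gm)^2)
  ss_sa <- 3 * sum((m_sa - outer(m_s, rep(1, 2)) -
                      outer(rep(1, 4), m_a) + gm)^2)
  ss_sc <- 2 * sum((m_sc - outer(m_s, rep(1, 3)) -
                      outer(rep(1, 4), m_c) + gm)^2)
  ss_ac <- 4 * sum((m_ac - outer(m_a, rep(1, 3)) -
                      outer(rep(1, 2), m_c) + gm)^2)
  ss_res <- 0
  for (s in 1:4) for (a in 1:2) for (c in 1:3)
    ss_res <- ss_res + (y[s, a, c] - m_sa[s, a] - m_sc[s, c] - m_ac[a, c] +
                          m_s[s] + m_a[a] + m_c[c] - gm)^2
  F_a <- (ss_a / 1) / (ss_sa / 3)
  F_c <- (ss_c / 2) / (ss_sc / 6)
  F_ac <- (ss_ac / 2) / (ss_res / 6)
  expect_equal(an$F, c(F_a, F_c, F_ac), tolerance = 1e-10)
  expect_equal(an$df1, c(1, 2, 2))
  expect_equal(an$df2, c(3, 6, 6))
})

test_that("ANOVA df convention scales as (1, n-1) and (2, 2(n-1))", {
  tab <- make_amplitude_table(function(g) rnorm(nrow(g)), n = 28)
  an <- rm_anova_area_by_condition(tab)
  expect_equal(an$df2, c(27, 54, 54))
  # zero between-cell variation: all F reported as 0
  tab0 <- make_amplitude_table(function(g) 0.2 * g$subject, n = 5)
  an0 <- rm_anova_area_by_condition(tab0)
  expect_equal(an0$F, c(0, 0, 0))
  expect_error(rm_anova_area_by_condition(tab[-1, ]), "exactly one")
})
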
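# one-sample t on x - mu with graceful handling of zero-variance input:
# a constant vector equal to mu gives t = 0, p = 1 (two-sided); a constant
# vector away from mu gives t = +/-Inf, p = 0 or 1 depending on the tail
t_one_sample <- function(x, mu = 0, alternative = "two.sided") {
  n <- length(x)
  df <- n - 1
  s <- stats::sd(x)
  m <- mean(x) - mu
  if (is.na(s) || s == 0) {
    tval <- if (m == 0) 0 else sign(m) * Inf
  } else {
    tval <- m / (s / sqrt(n))
  }
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(tval), df),
              greater = stats::pt(tval, df, lower.tail = FALSE),
              less = stats::pt(tval, df),
              stop("bad alternative"))
  list(t = tval, df = df, p = p, mean = mean(x))
}

t_paired <- function(x, y, alternative = "two.sided") {
  t_one_sample(x - y, 0, alternative)
}
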
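test_that("grid axes are log-spaced and inclusive of bounds", {
  g <- build_grid(alpha = c(1, 100), gamma = c(1, 100), tau = c(1, 100),
                  n_points = 3)
  expect_equal(g$alpha, c(1, 10, 100), tolerance = 1e-12)
  g2 <- build_grid(n_points = 2)
  expect_equal(g2$tau, c(0.001, 1), tolerance = 1e-12)
  # ratio of consecutive axis values is constant
  g3 <- build_grid(n_points = 37)
  r <- g3$gamma[-1] / g3$gamma[-37]
  expect_lt(max(abs(r / r[1] - 1)), 1e-10)
  # full-resolution default
  expect_equal(build_grid()$n_points, 150L)
  expect_error(build_grid(alpha = c(-1, 2)), "0 < low < high")
  expect_error(build_grid(alpha = c(2, 1)), "0 < low < high")
})

test_that("grid posterior equals the brute-force enumeration oracle", {
  set.seed(7)
  sched <- generate_schedule(n_per_condition = 10, seed = 11)
  d <- simulate_agent(sched[1:20, ], prospect_params(0.9, 0.8, 0.02),
                      seed = 12)
  # tau bounds kept moderate so the oracle's literal probability products
  # stay within double-precision range
  g <- build_grid(alpha = c(0.5, 2), gamma = c(0.5, 2), tau = c(0.05, 0.5),
                  n_points = 5)
  for (form in c("temperature_divide", "inverse_temperature_multiply")) {
    post <- grid_posterior(d, g, form)
    oracle <- oracle_grid_posterior(d, g$alpha, g$gamma, g$tau, form)
    expect_equal(max(abs(post$posterior_mass - oracle) /
                       pmax(oracle, 1e-300)), 0, tolerance = 1e-12)
    expect_equal(post$marginal_alpha, apply(oracle, 1, sum),
                 tolerance = 1e-12)
    expect_equal(sum(post$posterior_mass), 1, tolerance = 1e-10)
    expect_equal(sum(post$marginal_gamma), 1, tolerance = 1e-10)
  }
})

test_that("posterior is uniform when the likelihood is flat", {
  d <- toy_dataset(1)
  d$magnitude_right <- d$magnitude_left
  d$probability_right <- d$probability_left
  g <- build_grid(n_points = 4)
  post <- grid_posterior(d, g)
  expect_equal(as.numeric(post$posterior_mass), rep(1 / 64, 64),
               tolerance = 1e-12)
})

test_that("posterior is invariant to trial order", {
  d <- toy_dataset(20)
  g <- build_grid(n_points = 5)
  p1 <- grid_posterior(d, g)
  set.seed(4)
  p2 <- grid_posterior(d[sample(nrow(d)), ], g)
  expect_equal(p1$posterior_mass, p2$posterior_mass, tolerance = 1e-12)
})

test_that("marginal means reduce the posterior correctly", {
  g <- build_grid(n_points = 3)
  # point mass at one cell
  post <- structure(list(grid = g,
                         posterior_mass = array(0, c(3, 3, 3)),
                         form = "temperature_divide"),
                    class = "posterior_grid")
  post$posterior_mass[2, 3, 1] <- 1
  post$marginal_alpha <- apply(post$posterior_mass, 1, sum)
  post$marginal_gamma <- apply(post$posterior_mass, 2, sum)
  post$marginal_tau <- apply(post$posterior_mass, 3, sum)
  est <- marginal_means(post)
  expect_equal(est$alpha, g$alpha[2], tolerance = 1e-12)
  expect_equal(est$gamma, g$gamma[3], tolerance = 1e-12)
  expect_equal(est$tau, g$tau[1], tolerance = 1e-12)

  # symmetric two-point marginal and a random-mass oracle
  set.seed(5)
  w <- array(runif(27), c(3, 3, 3)); w <- w / sum(w)
  post$posterior_mass <- w
  post$marginal_alpha <- apply(w, 1, sum)
  post$marginal_gamma <- apply(w, 2, sum)
  post$marginal_tau <- apply(w, 3, sum)
  est <- marginal_means(post)
  expect_equal(est$alpha, sum(g$alpha * apply(w, 1, sum)), tolerance = 1e-12)
  expect_equal(est$tau, sum(g$tau * apply(w, 3, sum)), tolerance = 1e-12)
})

test_that("fit_prospect is deterministic and pins tau for a greedy agent", {
  sched <- generate_schedule(n_per_condition = 20, seed = 21)
  ds <- simulate_agent(sched, prospect_params(1, 1, 1e-8), seed = 22)
  f1 <- fit_prospect(ds, per_condition = FALSE, n_points = 20)
  f2 <- fit_prospect(ds, per_condition = FALSE, n_points = 20)
  expect_identical(f1$estimates, f2$estimates)
  # near-deterministic data: tau estimate in the lowest decade of the grid
  expect_lt(f1$estimates$tau, 0.01)
  # per-condition fitting returns one row per condition
  f3 <- fit_prospect(ds, n_points = 10, per_condition = TRUE)
  expect_setequal(f3$estimates$condition, c("short", "middle", "long"))
})
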
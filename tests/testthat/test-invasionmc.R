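test_that("Monte Carlo invasion matches binomial expectations", {
  z <- withr::with_seed(1, rnorm(1e5))
  ones <- landscape_from_function(function(x) rep(1, length(x)), c(-4, 4))
  res1 <- simulate_invasion(z, ones, seed = 2)
  expect_equal(res1$v_sim, 1)
  expect_identical(res1$invaded_values, res1$seeded_values)
  flat <- landscape_from_function(function(x) rep(0.3, length(x)), c(-4, 4))
  res <- simulate_invasion(z, flat, seed = 3)
  expect_lt(abs(res$v_sim - 0.3), 3 * sqrt(0.3 * 0.7 / 1e5))
  # determinism
  expect_identical(simulate_invasion(z, flat, seed = 3)$v_sim, res$v_sim)
})

test_that("step landscape selects the truncated-normal upper tail", {
  z <- withr::with_seed(4, rnorm(1e5))
  stepl <- landscape_from_function(function(x) ifelse(x >= 0, 0.5, 0),
                                   c(-4, 4))
  res <- simulate_invasion(z, stepl, seed = 5)
  expect_equal(res$v_sim, 0.25, tolerance = 0.02)
  # invaded mean ~ phi(0) / (1 - Phi(0)) = 0.7979
  expect_equal(mean(res$invaded_values), dnorm(0) / pnorm(0, lower.tail = FALSE),
               tolerance = 0.02)
  # shared-bin histograms cover both compartments
  h <- res$histograms
  expect_length(h$seeded, 64L)
  expect_length(h$invaded, 64L)
  expect_true(all(h$invaded <= h$seeded + 1e-9 + 0))
})

test_that("MC invasiveness agrees with the analytic expectation", {
  truth <- landscape_from_function(valley_truth_fn(), c(1, 4.5))
  z <- withr::with_seed(6, rnorm(5000, 2.75, 0.35))
  ev <- expected_invasiveness(truth, z)
  vs <- vapply(1:20, function(k) simulate_invasion(z, truth, seed = k)$v_sim, 0)
  se <- sqrt(ev * (1 - ev) / 5000) / sqrt(20)
  expect_lt(abs(mean(vs) - ev), 3 * se)
})

test_that("thinning identity closes the loop back through inference", {
  truth <- landscape_from_function(valley_truth_fn(), c(1, 4.5))
  s <- sample_cells(high_noise_clone(), 0.2, 3e4, seed = 8)
  mc <- simulate_invasion(log10(s$values), truth, seed = 9)
  fit <- fit_landscape(s, expression_sample(10^mc$invaded_values,
                                            compartment = "invaded"),
                       v = mc$v_sim)
  err <- abs(fit$w - landscape_value(truth, fit$z_grid))[fit$support_mask]
  expect_lt(max(err), 0.1)
})

test_that("frozen OU fluctuations reduce to the static Monte Carlo", {
  truth <- landscape_from_function(valley_truth_fn(), c(1, 4.5))
  p_frozen <- ou_params(mu = 2.75, sigma = 0.3, tau = 1e9)
  ev <- NULL
  vs <- vapply(1:20, function(k) {
    simulate_invasion_ou(p_frozen, truth, n_cells = 5000, assay_hours = 16,
                         seed = k)$v_sim
  }, 0)
  # stationary draw expectation: integrate w against N(mu, sigma^2)
  zg <- seq(1, 4.5, length.out = 2001)
  ev <- sum(landscape_value(truth, zg) * dnorm(zg, 2.75, 0.3)) *
    (zg[2] - zg[1])
  se <- sqrt(ev * (1 - ev) / 5000) / sqrt(20)
  expect_lt(abs(mean(vs) - ev), 4 * se)
})

test_that("invasiveness on a flat landscape is tau-independent", {
  flat <- flat_truth(0.3, c(0, 5))
  vs <- vapply(c(1, 24, 1000), function(tau) {
    mean(vapply(1:10, function(k) {
      simulate_invasion_ou(ou_params(2.5, 0.3, tau), flat, n_cells = 5000,
                           assay_hours = 16, seed = 100 * tau + k)$v_sim
    }, 0))
  }, 0)
  se <- sqrt(0.3 * 0.7 / 5000) / sqrt(10)
  expect_lt(max(vs) - min(vs), 6 * se)
})

test_that("fast fluctuations decouple seeding-time level from fate", {
  # valley: with frozen levels the invaded seeding-time spread widens;
  # with tau << assay the decision decorrelates from the seeding level and
  # the invaded-vs-seeded SD gap shrinks
  truth <- landscape_from_function(valley_truth_fn(), c(1, 4.5))
  gap <- function(tau) {
    r <- simulate_invasion_ou(ou_params(2.75, 0.3, tau), truth,
                              n_cells = 4e4, assay_hours = 16,
                              bin_on = "seeding", seed = 11)
    sd(r$invaded_values) - sd(r$seeded_values)
  }
  gap_frozen <- gap(1e9)
  gap_fast <- gap(0.5)
  expect_gt(gap_frozen, 0.01)
  expect_lt(gap_fast, gap_frozen / 2)
})

test_that("hazard mode integrates the landscape along trajectories", {
  flat <- flat_truth(0.3, c(0, 5))
  r <- simulate_invasion_ou(ou_params(2.5, 0.3, 24), flat, n_cells = 2e4,
                            assay_hours = 16, eval_mode = "hazard", dt = 2,
                            seed = 13)
  # flat landscape: hazard compounds to exactly w overall
  expect_equal(r$v_sim, 0.3, tolerance = 3 * sqrt(0.3 * 0.7 / 2e4) / 0.3)
  expect_error(simulate_invasion_ou(ou_params(2.5, 0.3, 24), flat,
                                    n_cells = 10, assay_hours = 16,
                                    eval_mode = "drift", seed = 1))
})

test_that("selection signatures follow landscape geometry", {
  # light sign check (full significance sweep lives in the acceptance suite)
  mu <- 2.75; sg <- 0.3
  z <- withr::with_seed(14, rnorm(2e4, mu, sg))
  up <- landscape_from_function(function(x) pmin(.95, pmax(.05, .5 + .6 * (x - mu))),
                                c(1, 4.5))
  res_up <- simulate_invasion(z, up, seed = 15)
  expect_gt(mean(res_up$invaded_values), mean(z))
  valley <- landscape_from_function(function(x) pmin(.9, .1 + 2 * (x - mu)^2),
                                    c(1, 4.5))
  res_v <- simulate_invasion(z, valley, seed = 16)
  expect_gt(sd(res_v$invaded_values), sd(z))
  peak <- landscape_from_function(function(x) pmax(.1, .9 - 2 * (x - mu)^2),
                                  c(1, 4.5))
  res_p <- simulate_invasion(z, peak, seed = 17)
  expect_lt(sd(res_p$invaded_values), sd(z))
})

test_that("simulate() method on a landscape wraps the Monte Carlo assay", {
  truth <- landscape_from_function(valley_truth_fn(), c(1, 4.5))
  sims <- simulate(truth, nsim = 3, seed = 18, n_cells = 2000, mu = 2.75,
                   sigma = 0.3)
  expect_length(sims, 3L)
  expect_s3_class(sims[[1]], "invasion_result")
  sims2 <- simulate(truth, nsim = 3, seed = 18, n_cells = 2000, mu = 2.75,
                    sigma = 0.3)
  expect_identical(vapply(sims, `[[`, 0, "v_sim"),
                   vapply(sims2, `[[`, 0, "v_sim"))
})
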
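test_that("constant fitness produces no shifts", {
  z <- withr::with_seed(1, rnorm(500))
  rep <- price_shifts(z, rep(0.4, 500), n_boot = 50, seed = 2)
  expect_equal(rep$delta_mean, 0)
  expect_equal(rep$delta_var, 0)
  expect_error(price_shifts(z, rep(0, 500)), "zero")
})

test_that("exponential tilting shifts the mean by beta*sigma^2", {
  # w ~ exp(0.5 z) reweights N(0,1) to N(0.5, 1): mean +0.5, variance kept
  z <- withr::with_seed(3, rnorm(1e6))
  w <- exp(0.5 * z); w <- w / max(w)
  rep <- price_shifts(z, w, n_boot = 0)
  expect_equal(rep$delta_mean, 0.5, tolerance = 0.02)
  expect_equal(rep$delta_var, 0, tolerance = 0.02)
})

test_that("a quadratic valley inflates variance, matching quadrature", {
  z <- withr::with_seed(4, rnorm(2e5))
  wfun <- function(x) pmin(1, 0.5 + 0.4 * x^2)
  rep <- price_shifts(z, wfun(z), n_boot = 0)
  expect_gt(rep$delta_var, 0)
  oracle <- quad_shifts(wfun, 0, 1)
  expect_equal(rep$delta_mean, oracle$delta_mean, tolerance = 0.02)
  expect_equal(rep$delta_var, oracle$delta_var, tolerance = 0.03)
})

test_that("gaussian_taylor reproduces the closed-form worked values", {
  expect_equal(gaussian_taylor(0, 1, 0.5, 0, 0),
               list(delta_mean = 0, delta_var = 0, mean_fitness = 0.5))
  gt <- gaussian_taylor(0, 1, w0 = 0.5, w1 = 0, w2 = 0.4)
  expect_equal(gt$delta_var, (0.5 + 0.6) / 0.7 - 1, tolerance = 1e-12)
  gt2 <- gaussian_taylor(0, 1, w0 = 0.5, w1 = 0.1, w2 = 0)
  expect_equal(gt2$delta_mean, 0.2, tolerance = 1e-12)
  expect_equal(gt2$delta_var, -0.04, tolerance = 1e-12)
  expect_error(gaussian_taylor(0, 1, w0 = 0.1, w1 = 0, w2 = -0.5),
               "mean fitness")
})

test_that("gaussian_taylor agrees with quadrature on quadratic landscapes", {
  cases <- list(c(0.5, 0, 0.4), c(0.5, 0.1, 0), c(0.6, 0.05, 0.1),
                c(0.3, -0.08, 0.25), c(0.7, 0.1, -0.2))
  for (cs in cases) {
    for (sg in c(0.5, 1)) {
      gt <- gaussian_taylor(0.3, sg, cs[1], cs[2], cs[3])
      wfun <- function(x) cs[1] + cs[2] * (x - 0.3) + cs[3] / 2 * (x - 0.3)^2
      q <- quad_shifts(wfun, 0.3, sg)
      expect_equal(gt$delta_mean, q$delta_mean, tolerance = 1e-6)
      expect_equal(gt$delta_var, q$delta_var, tolerance = 1e-6)
    }
  }
})

test_that("Price shifts agree with gaussian_taylor on large Gaussian samples", {
  z <- withr::with_seed(5, rnorm(5e5, 2, 0.4))
  w0 <- 0.4; w1 <- 0.1; w2 <- 0.2
  w <- w0 + w1 * (z - 2) + w2 / 2 * (z - 2)^2
  stopifnot(all(w >= 0 & w <= 1))
  rep <- price_shifts(z, w, n_boot = 0)
  gt <- gaussian_taylor(2, 0.4, w0, w1, w2)
  expect_equal(rep$delta_mean, gt$delta_mean, tolerance = 0.01)
  expect_equal(rep$delta_var, gt$delta_var, tolerance = 0.01)
})

test_that("Price prediction matches invaded-sample moments from the MC", {
  mu <- 2.75; sg <- 0.3
  truth <- landscape_from_function(valley_truth_fn(), c(1, 4.5))
  z <- withr::with_seed(6, rnorm(2e4, mu, sg))
  w <- landscape_value(truth, z)
  rep <- price_shifts(z, w, n_boot = 300, seed = 7)
  dm <- vapply(1:20, function(k) {
    r <- simulate_invasion(z, truth, seed = 20 + k)
    c(mean(r$invaded_values) - mean(z))
  }, 0)
  expect_lt(abs(mean(dm) - rep$delta_mean), 3 * rep$se_mean)
})

test_that("selection modes are classified from shift significance", {
  mk <- function(dm, dv, sem = 0.01, sev = 0.05) {
    structure(list(delta_mean = dm, delta_var = dv, delta_cv_linear = 0,
                   se_mean = sem, se_var = sev, mean_fitness = 0.4, n = 1000,
                   mode = NA_character_),
              class = "selection_report")
  }
  expect_equal(as.character(classify_mode(mk(0.3, 0))), "directional_up")
  expect_equal(as.character(classify_mode(mk(-0.3, 0))), "directional_down")
  expect_equal(as.character(classify_mode(mk(0.001, 0.5))), "disruptive")
  expect_equal(as.character(classify_mode(mk(0.001, -0.5))), "stabilizing")
  expect_equal(classify_mode(mk(0.005, 0.02)), "none")
  mixed <- classify_mode(mk(0.3, 0.5))
  expect_equal(as.character(mixed), "directional_up")
  expect_true(isTRUE(attr(mixed, "mixed")))
  expect_error(classify_mode(mk(0.1, 0, sem = NA)), "bootstrap")
})

test_that("bootstrap SEs are seeded and reproducible", {
  z <- withr::with_seed(8, rnorm(2000))
  w <- pmin(1, pmax(0, 0.4 + 0.2 * z))
  a <- price_shifts(z, w, n_boot = 200, seed = 9)
  b <- price_shifts(z, w, n_boot = 200, seed = 9)
  expect_identical(a$se_mean, b$se_mean)
  expect_identical(a$se_var, b$se_var)
  expect_gt(a$se_mean, 0)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_selection_json(a, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$delta_mean, a$delta_mean)
})
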
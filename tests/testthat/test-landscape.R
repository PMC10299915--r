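test_that("landscape constructor enforces its invariants", {
  expect_error(landscape(c(1, 2), c(0.5, 1.2)), "0, 1")
  expect_error(landscape(c(2, 1), c(0.5, 0.5)), "increasing")
  l <- landscape(c(0, 1, 2), c(0, 0.5, 1))
  expect_equal(landscape_value(l, c(0.5, 1.5)), c(0.25, 0.75))
  # boundary values held outside the grid
  expect_equal(landscape_value(l, c(-5, 5)), c(0, 1))
})

test_that("flat-landscape identity: invaded == seeded recovers w = v", {
  z <- withr::with_seed(1, rnorm(2e4, 2, 0.3))
  s <- expression_sample(10^z)
  fit <- fit_landscape(s, invaded = expression_sample(10^z,
                                                      compartment = "invaded"),
                       v = 0.4)
  expect_true(all(abs(fit$w[fit$support_mask] - 0.4) < 0.01))
})

test_that("ratio inference recovers a step landscape analytically", {
  # seeded N(0,1); truth w = 0.5 above 0, else 0; V = 0.25;
  # the invaded law is the upper truncated normal
  n <- 5e4
  z <- withr::with_seed(2, rnorm(n))
  stepl <- landscape_from_function(function(x) ifelse(x >= 0, 0.5, 0),
                                   c(-4, 4))
  mc <- simulate_invasion(z, stepl, seed = 3)
  expect_equal(mc$v_sim, 0.25, tolerance = 3 * sqrt(0.25 * 0.75 / n) / 0.25)
  fit <- fit_landscape(expression_sample(10^z),
                       invaded = expression_sample(10^mc$invaded_values,
                                                   compartment = "invaded"),
                       v = mc$v_sim)
  sup <- fit$support_mask
  lo <- sup & fit$z_grid < -0.3
  hi <- sup & fit$z_grid > 0.3
  expect_lt(max(fit$w[lo]), 0.05)
  expect_lt(max(abs(fit$w[hi] - 0.5)), 0.06)
})

test_that("zero invasiveness is consistent only with an empty invaded set", {
  z <- withr::with_seed(4, rnorm(1000, 2, 0.2))
  s <- expression_sample(10^z)
  expect_error(fit_landscape(s, invaded = s, v = 0), "inconsistent")
  fit0 <- fit_landscape(s, invaded = NULL, v = 0)
  expect_true(all(fit0$w == 0))
})

test_that("global fit recovers a flat truth and rejects degenerate designs", {
  cl <- low_noise_clone()
  doses <- c(0, 0.2, 1, 10)
  seeded <- lapply(seq_along(doses),
                   function(i) sample_cells(cl, doses[i], 5000, seed = 40 + i))
  truth <- flat_truth(0.35)
  v <- vapply(seeded, function(s)
    simulate_invasion(log10(s$values), truth, seed = 77)$v_sim, 0)
  fit <- fit_landscape(seeded, v = v, method = "global")
  expect_true(all(abs(fit$w[fit$support_mask] - 0.35) < 0.04))
  expect_lt(sqrt(mean(residuals(fit)^2)), 0.01)
  expect_error(fit_landscape(seeded[1], v = v[1], method = "global"),
               "underdetermined")
  same <- lapply(1:3, function(i) sample_cells(cl, 1, 1000, seed = 50 + i))
  expect_error(fit_landscape(same, v = c(0.3, 0.3, 0.3), method = "global"),
               "degenerate|distinct")
})

test_that("ratio and global estimators agree where both are identifiable", {
  # flat truth: the dose-sweep fit and the pooled density ratio must land
  # on the same constant
  cl <- low_noise_clone()
  doses <- c(0, 0.5, 10)
  truth <- flat_truth(0.3)
  seeded <- lapply(seq_along(doses),
                   function(i) sample_cells(cl, doses[i], 8000, seed = 80 + i))
  mcs <- lapply(seeded, function(s)
    simulate_invasion(log10(s$values), truth, seed = 99))
  v <- vapply(mcs, function(m) m$v_sim, 0)
  gfit <- fit_landscape(seeded, v = v, method = "global")
  pool_s <- unlist(lapply(seeded, function(s) s$values))
  pool_i <- 10^unlist(lapply(mcs, function(m) m$invaded_values))
  rfit <- fit_landscape(expression_sample(pool_s),
                        invaded = expression_sample(pool_i,
                                                    compartment = "invaded"),
                        v = length(pool_i) / length(pool_s))
  zs <- gfit$z_grid[gfit$support_mask]
  zs <- zs[zs >= min(rfit$z_grid) & zs <= max(rfit$z_grid)]
  expect_lt(max(abs(landscape_value(gfit, zs) - landscape_value(rfit, zs))),
            0.08)
})

test_that("expected invasiveness is the analytic mean of w and is monotone", {
  ones <- landscape_from_function(function(z) rep(1, length(z)), c(-3, 3))
  z <- withr::with_seed(6, rnorm(5e4))
  expect_equal(expected_invasiveness(ones, z), 1)
  stepl <- landscape_from_function(function(x) ifelse(x >= 0, 0.5, 0),
                                   c(-4, 4))
  expect_equal(expected_invasiveness(stepl, z), 0.25, tolerance = 0.01)
  # pointwise ordering of landscapes implies ordered invasiveness
  withr::with_seed(7, {
    for (k in 1:10) {
      base <- runif(6, 0, 0.8)
      la <- landscape(seq(-3, 3, length.out = 6), base)
      lb <- landscape(seq(-3, 3, length.out = 6),
                      pmin(1, base + runif(6, 0, 0.2)))
      zz <- rnorm(2000)
      expect_lte(expected_invasiveness(la, zz),
                 expected_invasiveness(lb, zz))
    }
  })
})

test_that("local geometry classifies slopes, peaks, valleys and flats", {
  up <- landscape_from_function(function(z) pmin(.95, pmax(.05, .5 + .8 * (z - 3))),
                                c(1, 5))
  g <- local_geometry(up, 3, 0.25)
  expect_equal(g$shape, "upslope")
  expect_lt(abs(g$curvature), 0.05)
  down <- landscape_from_function(function(z) pmin(.95, pmax(.05, .5 - .8 * (z - 3))),
                                  c(1, 5))
  expect_equal(local_geometry(down, 3, 0.25)$shape, "downslope")
  val <- landscape_from_function(function(z) pmin(.9, .15 + 2 * (z - 3)^2),
                                 c(1, 5))
  gv <- local_geometry(val, 3, 0.25)
  expect_equal(gv$shape, "valley")
  expect_lt(abs(gv$slope), 0.05)
  expect_gt(gv$curvature, 0)
  pk <- landscape_from_function(function(z) pmax(.1, .85 - 2 * (z - 3)^2),
                                c(1, 5))
  expect_equal(local_geometry(pk, 3, 0.25)$shape, "peak")
  fl <- flat_truth(0.4, c(1, 5))
  expect_equal(local_geometry(fl, 3, 0.25)$shape, "flat")
  expect_error(local_geometry(up, 0.9, 0.25), "outside")
})

test_that("noisy flat landscapes read as flat in at least 95% of replicates", {
  truth <- flat_truth(0.4, c(1, 5))
  cl <- high_noise_clone()
  shapes <- vapply(1:60, function(k) {
    s <- sample_cells(cl, 1, 1e4, seed = k)
    z <- log10(s$values)
    mc <- simulate_invasion(z, truth, seed = k + 1000)
    fit <- fit_landscape(s, expression_sample(10^mc$invaded_values,
                                              compartment = "invaded"),
                         v = mc$v_sim)
    local_geometry(fit, z0 = mean(z), window = 0.25)$shape
  }, "")
  expect_gte(mean(shapes == "flat"), 0.95)
})

test_that("thin-plate surface interpolates exactly and reproduces planes", {
  pts <- data.frame(mean = c(0, 1, 0, 1, 0.4), cv = c(0, 0, 1, 1, 0.6),
                    invasiveness = c(0.12, 0.53, 0.21, 0.44, 0.3))
  surf <- fit_invasion_surface(pts)
  at_pts <- predict(surf, pts)
  expect_equal(as.numeric(at_pts), pts$invasiveness, tolerance = 1e-9)
  expect_false(any(attr(at_pts, "extrapolated")))
  # affine reproduction: v = a + b*mean + c*cv recovered exactly inside
  plane <- function(m, cv) 0.1 + 0.3 * m + 0.2 * cv
  pp <- expand.grid(mean = c(0, 1), cv = c(0, 1))
  pp$invasiveness <- plane(pp$mean, pp$cv)
  sp <- fit_invasion_surface(pp)
  q <- data.frame(mean = c(0.3, 0.7), cv = c(0.4, 0.2))
  expect_equal(as.numeric(predict(sp, q)), plane(q$mean, q$cv),
               tolerance = 1e-6)
  out <- predict(sp, data.frame(mean = 2, cv = 2))
  expect_true(attr(out, "extrapolated"))
  coll <- data.frame(mean = 1:4, cv = 2 * (1:4), invasiveness = runif(4))
  expect_error(fit_invasion_surface(coll), "collinear")
  dup <- pts; dup$invasiveness[2] <- 0.9; dup$mean[2] <- 0; dup$cv[2] <- 0
  expect_error(fit_invasion_surface(dup), "duplicate")
})

test_that("landscapes serialize losslessly to TSV + JSON", {
  truth <- landscape_from_function(valley_truth_fn(), c(1, 4.5))
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(path, sub("\\.tsv$", ".json", path))))
  write_landscape_tsv(truth, path)
  back <- read_landscape_tsv(path)
  expect_equal(back$z_grid, truth$z_grid)
  expect_equal(back$w, truth$w)
  expect_equal(back$support_mask, truth$support_mask)
})
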
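test_that("hill_mean follows the dose-response algebra", {
  spec <- clone_spec(basal_mfi = 100, fold = 30, ec50 = 0.5, hill_n = 1.2)
  expect_equal(hill_mean(0, spec), 100)
  expect_equal(hill_mean(1e9, spec), 100 * 30, tolerance = 1e-6)
  expect_equal(hill_mean(Inf, spec), 3000)
  # at the EC50 the Hill term is exactly 1/2 regardless of hill_n
  expect_equal(hill_mean(0.5, spec), 100 * (1 + 29 * 0.5))
  d <- c(0, 0.01, 0.1, 0.5, 1, 10, 100)
  expect_true(all(diff(hill_mean(d, spec)) >= 0))
  expect_error(hill_mean(-1, spec), "non-negative")
})

test_that("clone_spec and dose_grid validate their invariants", {
  expect_error(clone_spec(basal_mfi = -1))
  expect_error(clone_spec(fold = 0.5))
  expect_error(clone_spec(sigma_log10 = 0))
  expect_error(dose_grid(c(1, 0.5)), "increasing")
  expect_error(dose_grid(c(-1, 0)), "non-negative")
  expect_length(dose_grid(), 12L)
  # dose-dependent noise profiles are allowed
  spec <- clone_spec(sigma_log10 = function(d) 0.1 + 0.01 * log10(1 + d))
  expect_gt(spec$sigma_log10(100), spec$sigma_log10(0))
})

test_that("sample_cells matches its target moments and is reproducible", {
  spec <- low_noise_clone()
  s1 <- sample_cells(spec, d = 0.5, n = 1e5, seed = 11)
  s2 <- sample_cells(spec, d = 0.5, n = 1e5, seed = 11)
  expect_identical(s1$values, s2$values)
  expect_equal(mean(s1$values), hill_mean(0.5, spec), tolerance = 0.01)
  expect_equal(sd(log10(s1$values)), 0.15, tolerance = 0.01)
  # near-degenerate noise collapses onto the Hill mean
  tiny <- clone_spec(sigma_log10 = 1e-9)
  st <- sample_cells(tiny, d = 2, n = 100, seed = 1)
  expect_equal(st$values, rep(hill_mean(2, tiny), 100), tolerance = 1e-6)
  expect_error(sample_cells(spec, d = 1, n = 0, seed = 1))
})

test_that("noise-decoupled clones share means but separate CVs", {
  lo <- low_noise_clone(); hi <- high_noise_clone()
  for (d in c(0, 0.5, 10)) {
    slo <- sample_cells(lo, d, 5e4, seed = 21)
    shi <- sample_cells(hi, d, 5e4, seed = 22)
    expect_equal(mean(slo$values), mean(shi$values), tolerance = 0.02)
    expect_gt(summarize_sample(shi)$cv, summarize_sample(slo)$cv + 0.2)
  }
})

test_that("benchmark generator obeys limiting landscapes", {
  spec <- low_noise_clone()
  grid <- dose_grid(c(0, 0.5, 10))
  all_in <- landscape_from_function(function(z) rep(1, length(z)), c(-1, 6))
  ds <- generate_benchmark_dataset(spec, grid, all_in, n_per_dose = 500,
                                   reps = 2, seed = 3)
  expect_true(all(ds$invasiveness$v == 1))
  expect_identical(sort(ds$invaded[[1]]$values), sort(ds$seeded[[1]]$values))
  none <- landscape_from_function(function(z) rep(0, length(z)), c(-1, 6))
  ds0 <- generate_benchmark_dataset(spec, grid, none, n_per_dose = 500,
                                    reps = 1, seed = 4)
  expect_true(all(ds0$invasiveness$v == 0))
  expect_true(all(vapply(ds0$invaded, is.null, TRUE)))
})

test_that("step landscape centered on the seeded mean halves twice", {
  # w = 0.5 above the seeded log-mean: realized invasiveness ~ 0.25
  spec <- low_noise_clone()
  z0 <- log10(hill_mean(0.5, spec)) - 0.15^2 * log(10) / 2
  stepl <- landscape_from_function(function(z) ifelse(z >= z0, 0.5, 0),
                                   c(z0 - 2, z0 + 2))
  ds <- generate_benchmark_dataset(spec, dose_grid(0.5), stepl,
                                   n_per_dose = 2e4, reps = 3, seed = 5)
  se <- sqrt(0.25 * 0.75 / 2e4)
  expect_true(all(abs(ds$invasiveness$v - 0.25) < 4 * se))
})

test_that("generator refuses landscapes that do not cover the seeded mass", {
  spec <- low_noise_clone()
  narrow <- landscape_from_function(function(z) rep(0.5, length(z)),
                                    c(2.0, 2.05))
  expect_error(
    generate_benchmark_dataset(spec, dose_grid(c(0, 10)), narrow,
                               n_per_dose = 100, reps = 1, seed = 1),
    "undefined over")
})

test_that("single-cell CSV schema round-trips at full float precision", {
  spec <- high_noise_clone()
  s <- sample_cells(spec, d = 2, n = 500, seed = 9)
  inv <- expression_sample(s$values[1:100], clone = s$clone, dose = 2,
                           compartment = "invaded", replicate = 1L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cells_csv(list(s, inv), path)
  header <- readLines(path, n = 1)
  expect_identical(header,
                   "cell_id,clone,dose_ng_ml,replicate,compartment,fluor_au")
  back <- read_cells_csv(path)
  expect_length(back, 2L)
  comp <- vapply(back, function(x) x$compartment, "")
  expect_identical(back[[which(comp == "seeded")]]$values, s$values)
  expect_identical(back[[which(comp == "invaded")]]$values, inv$values)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), bad)
  expect_error(read_cells_csv(bad))
})
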
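# Shared fixtures: ground-truth landscapes and clones used across tests.
# Everything is generated in code; tests pass explicit seeds.

# valley: quadratic dip to 0.1 at the center, 0.6 at the shoulders
valley_truth_fn <- function(center = 2.75, halfwidth = 0.45) {
  function(z) pmin(0.6, 0.1 + 0.5 * ((z - center) / halfwidth)^2)
}

# up-down-up: rise to 0.55, dip to 0.1, rise back to 0.6
updownup_truth_fn <- function() {
  function(z) {
    w <- ifelse(z < 2.2, 0.15 + 0.4 * (z - 1.2),
         ifelse(z < 2.8, 0.55 - 0.45 * (z - 2.2) / 0.6,
                0.1 + 0.5 * (z - 2.8) / 0.7))
    pmin(0.6, pmax(0.05, w))
  }
}

flat_truth <- function(c0 = 0.4, z_range = c(0, 6)) {
  landscape_from_function(function(z) rep(c0, length(z)), z_range)
}

low_noise_clone <- function() clone_spec(sigma_log10 = 0.15, label = "BL")
high_noise_clone <- function() clone_spec(sigma_log10 = 0.30, label = "BH")

# quadrature oracle for selection shifts: trait z ~ N(mu, sigma^2),
# arbitrary fitness function wfun; independent of the package's formulas
quad_shifts <- function(wfun, mu, sigma) {
  wbar <- stats::integrate(function(z) wfun(z) * stats::dnorm(z, mu, sigma),
                           -Inf, Inf, rel.tol = 1e-12)$value
  m1 <- stats::integrate(function(z) z * wfun(z) * stats::dnorm(z, mu, sigma),
                         -Inf, Inf, rel.tol = 1e-12)$value / wbar
  m2 <- stats::integrate(function(z) z^2 * wfun(z) * stats::dnorm(z, mu, sigma),
                         -Inf, Inf, rel.tol = 1e-12)$value / wbar
  list(delta_mean = m1 - mu, delta_var = (m2 - m1^2) - sigma^2)
}
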
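#' Ornstein-Uhlenbeck parameters for log10 expression dynamics
#'
#' The OU process is the standard mean-reverting Gaussian model for
#' fluctuating log-scale gene expression: stationary mean `mu`, stationary
#' SD `sigma` (both in log10 a.u.), and relaxation (autocorrelation) time
#' `tau` in hours. The default `tau` of 24 h is commensurate with a 16-24 h
#' invasion assay, so endpoint expression is partially decorrelated from the
#' level at seeding.
#'
#' @param mu stationary mean (log10 a.u.).
#' @param sigma stationary SD (log10 a.u.), > 0.
#' @param tau relaxation time in hours, > 0.
#' @return object of class `ou_params`.
#' @export
ou_params <- function(mu, sigma, tau = 24) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma), length(sigma) == 1L, sigma > 0,
            is.numeric(tau), length(tau) == 1L, tau > 0)
  structure(list(mu = mu, sigma = sigma, tau = tau), class = "ou_params")
}

#' @export
print.ou_params <- function(x, ...) {
  cat(sprintf("OU parameters: mu = %.4g, sigma = %.4g (log10 a.u.), tau = %.4g h\n",
              x$mu, x$sigma, x$tau))
  invisible(x)
}

#' Fit OU stationary moments to a log10 expression sample
#'
#' Moment matching: the stationary mean and SD are set to the sample mean
#' and population SD of the log-transformed data. The relaxation time cannot
#' be identified from a single snapshot and is taken from `tau`.
#'
#' @param log_values log10 expression values (>= 2, non-constant).
#' @param tau relaxation time (hours) to attach; default 24.
#' @return an [ou_params()] object.
#' @export
fit_stationary <- function(log_values, tau = 24) {
  stopifnot(is.numeric(log_values))
  if (length(log_values) < 2L) stop("need at least 2 values")
  s <- pop_sd(log_values)
  if (s == 0) stop("zero variance: OU stationary SD undefined")
  ou_params(mu = mean(log_values), sigma = s, tau = tau)
}

#' Exact simulation of OU trajectories
#'
#' Uses the exact transition density of the OU process rather than
#' Euler-Maruyama: with `a = exp(-dt/tau)`,
#' `x' = mu + (x - mu) * a + sigma * sqrt(1 - a^2) * xi`, `xi ~ N(0,1)`.
#' The update is exact for any step size, so the stationary law N(mu,
#' sigma^2) is preserved over arbitrary horizons and one step of size 2*dt
#' is distributionally identical to two steps of size dt.
#'
#' @param params an [ou_params()].
#' @param x0 initial log10 values, one per cell; or an integer `n_cells`
#'   via `n_cells` below.
#' @param dt time step (hours), > 0.
#' @param n_steps number of steps (>= 1).
#' @param seed integer seed.
#' @param n_cells if `x0` is NULL, draw this many initial values from the
#'   stationary law (seeded populations are at steady state after
#'   pre-induction).
#' @return numeric matrix (cells x (n_steps + 1)); column 1 is the initial
#'   condition.
#' @examples
#' p <- ou_params(mu = 2, sigma = 0.2, tau = 24)
#' tr <- ou_simulate(p, dt = 6, n_steps = 4, seed = 1, n_cells = 100)
#' dim(tr)
#' @export
ou_simulate <- function(params, x0 = NULL, dt, n_steps, seed,
                        n_cells = NULL) {
  stopifnot(inherits(params, "ou_params"))
  if (dt <= 0) stop("dt must be positive")
  if (n_steps < 1) stop("n_steps must be >= 1")
  withr_seed(seed, {
    if (is.null(x0)) {
      stopifnot(!is.null(n_cells), n_cells >= 1)
      x0 <- stats::rnorm(n_cells, params$mu, params$sigma)
    }
    n <- length(x0)
    a <- exp(-dt / params$tau)
    sd_step <- params$sigma * sqrt(1 - a^2)
    out <- matrix(NA_real_, nrow = n, ncol = n_steps + 1L)
    out[, 1L] <- x0
    for (k in seq_len(n_steps)) {
      out[, k + 1L] <- params$mu + (out[, k] - params$mu) * a +
        sd_step * stats::rnorm(n)
    }
    out
  })
}
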
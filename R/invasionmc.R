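#' Monte Carlo invasion assay on a landscape
#'
#' Each cell invades independently when a standard-uniform draw falls below
#' the landscape value at its log10 expression level; the fraction of
#' invaders is the simulated population invasiveness. This is the
#' generative model the thinning identity (and hence landscape inference)
#' inverts.
#'
#' @param cells numeric vector of log10 expression levels (non-empty).
#' @param landscape an `invasion_landscape`.
#' @param seed integer seed.
#' @return object of class `invasion_result`: `v_sim` (invaders / total),
#'   `invaded_values` and `seeded_values` (log10 a.u.), `histograms`
#'   (64 shared bins over the seeded 0.5-99.5 percentile range), `seed`.
#' @examples
#' flat <- landscape_from_function(function(z) rep(0.3, length(z)), c(-3, 3))
#' res <- simulate_invasion(rnorm(1000), flat, seed = 1)
#' res$v_sim
#' @export
simulate_invasion <- function(cells, landscape, seed) {
  stopifnot(is.numeric(cells), length(cells) >= 1L,
            inherits(landscape, "invasion_landscape"))
  w <- landscape_value(landscape, cells)
  invaded <- withr_seed(seed, stats::runif(length(cells)) < w)
  new_invasion_result(seeded = cells, invaded = cells[invaded], seed = seed)
}

new_invasion_result <- function(seeded, invaded, seed, extra = list()) {
  structure(c(list(v_sim = length(invaded) / length(seeded),
                   invaded_values = invaded, seeded_values = seeded,
                   histograms = compartment_histograms(seeded, invaded),
                   seed = seed), extra),
            class = "invasion_result")
}

# shared-bin histograms: 64 equal-width bins over the seeded 0.5-99.5
# percentile range so seeded and invaded counts are directly comparable
compartment_histograms <- function(seeded, invaded, nbins = 64L) {
  q <- stats::quantile(seeded, c(0.005, 0.995), names = FALSE, type = 7)
  if (q[2] <= q[1]) q <- q + c(-0.5, 0.5)
  breaks <- seq(q[1], q[2], length.out = nbins + 1L)
  count <- function(x) {
    x <- x[x >= breaks[1] & x <= breaks[nbins + 1L]]
    tabulate(findInterval(x, breaks, all.inside = TRUE), nbins)
  }
  list(breaks = breaks, mids = (breaks[-1] + breaks[-(nbins + 1L)]) / 2,
       seeded = count(seeded), invaded = count(invaded))
}

#' @export
print.invasion_result <- function(x, ...) {
  cat(sprintf("invasion_result: %d / %d cells invaded (v_sim = %.4g)\n",
              length(x$invaded_values), length(x$seeded_values), x$v_sim))
  if (length(x$invaded_values)) {
    cat(sprintf("  seeded log10 mean %.4g (sd %.3g); invaded %.4g (sd %.3g)\n",
                mean(x$seeded_values), pop_sd(x$seeded_values),
                mean(x$invaded_values), pop_sd(x$invaded_values)))
  }
  invisible(x)
}

#' Monte Carlo invasion with Ornstein-Uhlenbeck expression fluctuations
#'
#' Couples the invasion assay to fluctuating expression. In `"endpoint"`
#' mode (default), cells start from the OU stationary law, evolve for the
#' assay duration, and the single uniform-number comparison is made against
#' the landscape at the endpoint level — one stochastic decision per cell,
#' matching the single-comparison Monte Carlo rule. In `"hazard"` mode the
#' assay is discretized into steps of `dt` and each step carries invasion
#' probability `1 - (1 - w(z_t))^(dt/assay_hours)`; the first success
#' removes the cell, so the landscape is integrated along the fluctuating
#' trajectory.
#'
#' The invaded histogram is binned on the expression level used for the
#' invasion decision (`bin_on = "decision"`, reflecting what a flow
#' measurement of harvested invaded cells would see); `bin_on = "seeding"`
#' bins on the level at seeding time instead.
#'
#' @param params an [ou_params()] (stationary mean/SD in log10 a.u.,
#'   relaxation time in hours).
#' @param landscape an `invasion_landscape`.
#' @param n_cells number of seeded cells.
#' @param assay_hours assay duration (default 16 h).
#' @param eval_mode `"endpoint"` or `"hazard"`.
#' @param dt hazard-mode time step in hours (default 1).
#' @param bin_on `"decision"` or `"seeding"`.
#' @param seed integer seed.
#' @return an `invasion_result`; `seeded_values`/`invaded_values` are the
#'   levels selected by `bin_on`, and `x0` holds the seeding-time levels.
#' @export
simulate_invasion_ou <- function(params, landscape, n_cells,
                                 assay_hours = 16, eval_mode = c("endpoint",
                                                                 "hazard"),
                                 dt = 1, bin_on = c("decision", "seeding"),
                                 seed = 1) {
  eval_mode <- match.arg(eval_mode)
  bin_on <- match.arg(bin_on)
  stopifnot(inherits(params, "ou_params"),
            inherits(landscape, "invasion_landscape"), n_cells >= 1)
  if (assay_hours <= 0) stop("assay_hours must be positive")
  if (eval_mode == "endpoint") {
    # one exact OU step over the whole assay is distributionally exact
    traj <- ou_simulate(params, dt = assay_hours, n_steps = 1L,
                        seed = child_seed(seed, "ou"), n_cells = n_cells)
    x0 <- traj[, 1]; xe <- traj[, 2]
    w <- landscape_value(landscape, xe)
    hit <- withr_seed(child_seed(seed, "mc"), stats::runif(n_cells) < w)
    level <- if (bin_on == "decision") xe else x0
    new_invasion_result(seeded = level, invaded = level[hit], seed = seed,
                        extra = list(x0 = x0, endpoint = xe,
                                     eval_mode = eval_mode, bin_on = bin_on))
  } else {
    n_steps <- max(1L, ceiling(assay_hours / dt))
    traj <- ou_simulate(params, dt = assay_hours / n_steps, n_steps = n_steps,
                        seed = child_seed(seed, "ou"), n_cells = n_cells)
    alive <- rep(TRUE, n_cells)
    hit_level <- rep(NA_real_, n_cells)
    frac <- 1 / n_steps
    withr_seed(child_seed(seed, "mc"), {
      for (k in seq_len(n_steps)) {
        z <- traj[, k + 1L]
        p <- 1 - (1 - landscape_value(landscape, z))^frac
        u <- stats::runif(n_cells)
        new_hit <- alive & (u < p)
        hit_level[new_hit] <- z[new_hit]
        alive <- alive & !new_hit
      }
    })
    hit <- !is.na(hit_level)
    level <- if (bin_on == "decision") {
      ifelse(hit, hit_level, traj[, n_steps + 1L])
    } else traj[, 1]
    new_invasion_result(seeded = level, invaded = level[hit], seed = seed,
                        extra = list(x0 = traj[, 1],
                                     endpoint = traj[, n_steps + 1L],
                                     eval_mode = eval_mode, bin_on = bin_on))
  }
}
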
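#' @export
print.invasion_landscape <- function(x, ...) {
  m <- x$meta
  cat("Invasion landscape")
  if (!is.null(m$method)) cat(" (", m$method, " fit)", sep = "")
  cat("\n")
  cat(sprintf("  grid: %d points on [%.3g, %.3g] log10 a.u.; support %.0f%%\n",
              length(x$z_grid), min(x$z_grid), max(x$z_grid),
              100 * mean(x$support_mask)))
  cat(sprintf("  w range: [%.3g, %.3g]\n", min(x$w), max(x$w)))
  if (!is.null(m$residuals)) {
    cat(sprintf("  global fit: %d doses, ridge %.3g, RMS residual %.3g\n",
                length(m$residuals), m$ridge, sqrt(mean(m$residuals^2))))
  }
  invisible(x)
}

#' @export
summary.invasion_landscape <- function(object, ...) {
  m <- object$meta
  ws <- object$w[object$support_mask]
  zs <- object$z_grid[object$support_mask]
  out <- list(
    method = if (is.null(m$method)) "constructed" else m$method,
    n_grid = length(object$z_grid),
    z_range = range(object$z_grid),
    support_range = range(zs),
    w_range = range(ws),
    argmin = zs[which.min(ws)], argmax = zs[which.max(ws)],
    meta = m)
  class(out) <- "summary.invasion_landscape"
  out
}

#' @export
print.summary.invasion_landscape <- function(x, ...) {
  cat("Invasion landscape summary (", x$method, ")\n", sep = "")
  cat(sprintf("  support: [%.3g, %.3g] log10 a.u. (%d grid points total)\n",
              x$support_range[1], x$support_range[2], x$n_grid))
  cat(sprintf("  w on support: min %.3g at z = %.3g, max %.3g at z = %.3g\n",
              x$w_range[1], x$argmin, x$w_range[2], x$argmax))
  if (!is.null(x$meta$residuals)) {
    cat("  dose-level residuals (fitted - observed invasiveness):\n")
    print(round(x$meta$residuals, 4))
  }
  invisible(x)
}

#' Predict invasion probabilities from a fitted landscape
#'
#' @param object an `invasion_landscape`.
#' @param newdata log10 expression values (numeric) or an
#'   [expression_sample()]; omitted returns w on the fit grid.
#' @param ... unused.
#' @return numeric vector of invasion probabilities.
#' @export
predict.invasion_landscape <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$w)
  landscape_value(object, sample_log10(newdata))
}

#' @export
coef.invasion_landscape <- function(object, ...) {
  m <- object$meta
  if (!is.null(m$w_knots)) {
    stats::setNames(m$w_knots, sprintf("z=%.3g", m$knots))
  } else {
    stats::setNames(object$w, sprintf("z=%.3g", object$z_grid))
  }
}

#' Residuals of a global landscape fit
#'
#' For `method = "global"` fits: fitted minus observed population
#' invasiveness per dose. Ratio fits have no dose-level residuals and
#' return an empty vector.
#'
#' @param object an `invasion_landscape`.
#' @param ... unused.
#' @export
residuals.invasion_landscape <- function(object, ...) {
  r <- object$meta$residuals
  if (is.null(r)) numeric(0) else r
}

#' Plot an invasion landscape
#'
#' Draws w(z) over the grid, with the unsupported region (too little seeded
#' density to trust the estimate) shown dashed.
#'
#' @param x an `invasion_landscape`.
#' @param truth optional second landscape overlaid for comparison.
#' @param ... passed to [graphics::plot()].
#' @export
plot.invasion_landscape <- function(x, truth = NULL, ...) {
  graphics::plot(x$z_grid, x$w, type = "n", ylim = c(0, 1),
                 xlab = expression(log[10] ~ "expression (a.u.)"),
                 ylab = "invasion probability w(z)", ...)
  on_sup <- x$w; on_sup[!x$support_mask] <- NA
  off_sup <- x$w; off_sup[x$support_mask] <- NA
  graphics::lines(x$z_grid, on_sup, lwd = 2, col = "steelblue4")
  graphics::lines(x$z_grid, off_sup, lwd = 1, lty = 2, col = "steelblue4")
  if (!is.null(truth)) {
    graphics::lines(truth$z_grid, truth$w, col = "grey40", lty = 3, lwd = 2)
    graphics::legend("topleft", legend = c("fit", "truth"),
                     col = c("steelblue4", "grey40"), lty = c(1, 3), lwd = 2,
                     bty = "n")
  }
  invisible(x)
}

#' Simulate Monte Carlo invasion assays from a landscape
#'
#' `simulate()` on a fitted landscape runs the Monte Carlo invasion assay
#' (see [simulate_invasion()]) on supplied cells, or on cells drawn from a
#' Gaussian log10 law when `mu`/`sigma` are given.
#'
#' @param object an `invasion_landscape`.
#' @param nsim number of assay replicates.
#' @param seed integer seed.
#' @param cells log10 expression values of the seeded population; or NULL
#'   to draw `n_cells` from N(mu, sigma^2) per replicate.
#' @param n_cells,mu,sigma population size and Gaussian log10 law used when
#'   `cells` is NULL.
#' @param ... unused.
#' @return list of `invasion_result` objects, length `nsim`.
#' @export
simulate.invasion_landscape <- function(object, nsim = 1, seed = 1,
                                        cells = NULL, n_cells = 10000L,
                                        mu = NULL, sigma = NULL, ...) {
  lapply(seq_len(nsim), function(k) {
    kseed <- child_seed(seed, paste0("sim", k))
    z <- if (!is.null(cells)) cells else {
      stopifnot(!is.null(mu), !is.null(sigma))
      withr_seed(child_seed(seed, paste0("draw", k)),
                 stats::rnorm(n_cells, mu, sigma))
    }
    simulate_invasion(z, object, seed = kseed)
  })
}
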
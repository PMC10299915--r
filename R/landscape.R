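#' Construct an invasion landscape on a grid
#'
#' An invasion landscape w(z) gives the probability that a cell at log10
#' expression level z crosses the membrane during one invasion assay. It is
#' represented on a strictly increasing grid of log10 values with w in
#' [0, 1] everywhere, plus a support mask marking where the representation
#' is trusted (for inferred landscapes, where the seeded density was high
#' enough for the ratio estimate to be meaningful).
#'
#' @param z_grid strictly increasing log10 expression values.
#' @param w invasion probabilities, same length as `z_grid`, in [0, 1].
#' @param support_mask logical vector, same length; defaults to all TRUE.
#' @param meta named list of provenance information.
#' @return object of class `invasion_landscape`.
#' @seealso [fit_landscape()] for inferring a landscape from data,
#'   [landscape_from_function()] for building one from w(z).
#' @export
landscape <- function(z_grid, w, support_mask = NULL, meta = list()) {
  stopifnot(is.numeric(z_grid), is.numeric(w),
            length(z_grid) == length(w), length(z_grid) >= 2L,
            all(is.finite(z_grid)), all(is.finite(w)))
  if (is.unsorted(z_grid, strictly = TRUE)) {
    stop("z_grid must be strictly increasing")
  }
  if (any(w < 0 | w > 1)) stop("w must lie in [0, 1]")
  if (is.null(support_mask)) support_mask <- rep(TRUE, length(z_grid))
  stopifnot(is.logical(support_mask), length(support_mask) == length(z_grid))
  structure(list(z_grid = as.numeric(z_grid), w = as.numeric(w),
                 support_mask = support_mask, meta = meta),
            class = "invasion_landscape")
}

#' Build a landscape by evaluating a function on a grid
#'
#' @param f function of z returning invasion probability (values are clipped
#'   to [0, 1]).
#' @param z_range length-2 range of log10 expression.
#' @param n grid size.
#' @param meta provenance list.
#' @return an `invasion_landscape`.
#' @examples
#' valley <- landscape_from_function(function(z) 0.6 - 0.5 * exp(-z^2),
#'                                   z_range = c(-3, 3))
#' @export
landscape_from_function <- function(f, z_range, n = 256L, meta = list()) {
  z <- seq(z_range[1], z_range[2], length.out = n)
  landscape(z, pmin(1, pmax(0, f(z))), meta = meta)
}

#' Evaluate a landscape at arbitrary log10 expression levels
#'
#' Linear interpolation between grid points; outside the grid the boundary
#' value is held constant (the ratio is undefined where no seeded cells
#' exist, so the nearest trusted value is the only defensible extrapolation
#' for simulation purposes).
#'
#' @param object an `invasion_landscape`.
#' @param z log10 expression values.
#' @return invasion probabilities at `z`.
#' @export
landscape_value <- function(object, z) {
  stopifnot(inherits(object, "invasion_landscape"))
  stats::approx(object$z_grid, object$w, xout = z, rule = 2)$y
}

#' Infer an invasion landscape from seeded and invaded expression data
#'
#' The fitting function of the package. Two estimators are available,
#' both rooted in the Bernoulli thinning identity
#' `f_inv(z) = w(z) * f_seed(z) / V`, where V is the population
#' invasiveness:
#'
#' * `method = "ratio"` (single condition): the per-cell invasion
#'   probability is estimated as `w(z) = V * f_inv(z) / f_seed(z)` from
#'   kernel density estimates of the seeded and invaded log10 expression
#'   distributions, computed with a shared bandwidth and clipped to [0, 1].
#'   A support mask marks grid points where the seeded density exceeds
#'   `support_frac` of its peak; outside support the boundary value is held.
#' * `method = "global"` (dose sweep): a single piecewise-linear landscape
#'   with `knots` knots is fitted so that the expected invasiveness of every
#'   seeded population matches its measured invasiveness, by
#'   bound-constrained penalized least squares
#'   (`sum_d (E_seed,d[w] - v_d)^2 + ridge * sum (second differences)^2`,
#'   `0 <= w <= 1`). As the mean expression sweeps across doses, the dose
#'   sweep triangulates w(z) even though each v_d is a single number.
#'
#' @param seeded an [expression_sample()] (ratio) or a list of them, one per
#'   dose (global).
#' @param invaded the invaded [expression_sample()] (ratio only).
#' @param v population invasiveness: scalar in (0, 1] for ratio; numeric
#'   vector matched to `seeded` for global.
#' @param method `"ratio"` or `"global"`.
#' @param bandwidth kernel bandwidth on the log10 scale; `NULL` uses
#'   Silverman's rule on the seeded sample (shared by both compartments so
#'   smoothing bias cancels in the ratio).
#' @param estimator `"kde"` (default) or `"hist"` (ratio of shared-bin
#'   histograms, the rawer estimate the density ratio replaces).
#' @param support_frac support threshold as a fraction of the peak seeded
#'   density (default 0.01).
#' @param min_eff reliability floor for the ratio support mask: a grid point
#'   is trusted only where the effective kernel count
#'   `n_seeded * f_seed * bandwidth / R(K)` is at least `min_eff`
#'   (default 800, which caps the pointwise binomial noise floor of the
#'   ratio near 0.5/sqrt(800) ~ 0.018 at w = 0.5). When the floor would
#'   empty the mask (small samples) it relaxes to half the peak effective
#'   count.
#' @param grid_n landscape grid size (default 256, spanning the pooled
#'   0.1-99.9 percentiles of seeded log10 values).
#' @param knots number of knots for the global piecewise-linear fit
#'   (default 12).
#' @param ridge smoothness penalty weight for the global fit; `NULL` selects
#'   it by 5-fold dose-blocked cross-validation.
#' @return an `invasion_landscape` whose `meta` records the method,
#'   bandwidth, and (for global fits) knot positions, fitted values and
#'   residuals.
#' @examples
#' cl <- clone_spec()
#' truth <- landscape_from_function(function(z) ifelse(z > 2.5, 0.5, 0.1),
#'                                  z_range = c(0, 5))
#' s <- sample_cells(cl, d = 1, n = 5000, seed = 1)
#' mc <- simulate_invasion(log10(s$values), truth, seed = 2)
#' fit <- fit_landscape(s, invaded = expression_sample(10^mc$invaded_values),
#'                      v = mc$v_sim)
#' print(fit)
#' @export
fit_landscape <- function(seeded, invaded = NULL, v = NULL,
                          method = c("ratio", "global"), bandwidth = NULL,
                          estimator = c("kde", "hist"),
                          support_frac = 0.01, min_eff = 800, grid_n = 256L,
                          knots = 12L, ridge = NULL) {
  method <- match.arg(method)
  estimator <- match.arg(estimator)
  if (method == "ratio") {
    infer_ratio_landscape(seeded, invaded, v, bandwidth = bandwidth,
                          estimator = estimator, support_frac = support_frac,
                          min_eff = min_eff, grid_n = grid_n)
  } else {
    infer_global_landscape(seeded, v, knots = knots, ridge = ridge,
                           support_frac = support_frac, grid_n = grid_n)
  }
}

sample_log10 <- function(x) {
  if (inherits(x, "expression_sample")) log10_transform(x) else as.numeric(x)
}

landscape_grid <- function(z_pool, grid_n) {
  q <- stats::quantile(z_pool, c(0.001, 0.999), names = FALSE, type = 7)
  if (q[2] <= q[1]) stop("degenerate expression range")
  seq(q[1], q[2], length.out = grid_n)
}

infer_ratio_landscape <- function(seeded, invaded, v, bandwidth, estimator,
                                  support_frac, min_eff, grid_n) {
  z_seed <- sample_log10(seeded)
  if (is.null(v) || length(v) != 1L || v < 0 || v > 1) {
    stop("v must be a single invasiveness value in [0, 1]")
  }
  n_inv <- if (is.null(invaded)) 0L else length(sample_log10(invaded))
  if (v == 0) {
    if (n_inv > 0) stop("v = 0 is inconsistent with a non-empty invaded sample")
    grid <- landscape_grid(z_seed, grid_n)
    return(landscape(grid, rep(0, grid_n),
                     meta = list(method = "ratio", v = 0)))
  }
  if (n_inv == 0L) stop("invaded sample required when v > 0")
  z_inv <- sample_log10(invaded)
  grid <- landscape_grid(z_seed, grid_n)
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(z_seed)
  if (estimator == "kde") {
    f_seed <- stats::density(z_seed, bw = bandwidth, from = grid[1],
                             to = grid[grid_n], n = grid_n)$y
    f_inv <- stats::density(z_inv, bw = bandwidth, from = grid[1],
                            to = grid[grid_n], n = grid_n)$y
    # effective kernel count behind the seeded density at each grid point
    n_eff <- length(z_seed) * f_seed * bandwidth * 2 * sqrt(pi)
  } else {
    # shared-bin histogram densities on the landscape grid
    step <- grid[2] - grid[1]
    breaks <- c(grid - step / 2, grid[grid_n] + step / 2)
    cs <- tabulate(findInterval(z_seed, breaks, all.inside = TRUE), grid_n)
    ci <- tabulate(findInterval(z_inv, breaks, all.inside = TRUE), grid_n)
    f_seed <- cs / (length(z_seed) * step)
    f_inv <- ci / (length(z_inv) * step)
    n_eff <- cs
  }
  eff_floor <- min(min_eff, max(n_eff) / 2)
  support <- f_seed >= support_frac * max(f_seed) & n_eff >= eff_floor
  w <- rep(NA_real_, grid_n)
  pos <- f_seed > 0
  w[pos] <- pmin(1, pmax(0, v * f_inv[pos] / f_seed[pos]))
  # hold the boundary support value outside support
  idx <- which(support)
  w[seq_len(min(idx) - 1L)] <- w[min(idx)]
  if (max(idx) < grid_n) w[(max(idx) + 1L):grid_n] <- w[max(idx)]
  w[is.na(w)] <- stats::approx(grid[!is.na(w)], w[!is.na(w)], grid[is.na(w)],
                               rule = 2)$y
  landscape(grid, w, support_mask = support,
            meta = list(method = "ratio", estimator = estimator,
                        bandwidth = bandwidth, v = v,
                        n_seeded = length(z_seed), n_invaded = length(z_inv),
                        support_frac = support_frac, min_eff = eff_floor))
}

# hat-function basis on knot positions, evaluated at z (rows) x knots (cols)
hat_basis <- function(z, kn) {
  K <- length(kn)
  B <- matrix(0, length(z), K)
  zi <- pmin(pmax(z, kn[1]), kn[K])
  seg <- pmax(1L, pmin(K - 1L, findInterval(zi, kn, all.inside = TRUE)))
  t <- (zi - kn[seg]) / (kn[seg + 1L] - kn[seg])
  for (k in seq_len(K)) {
    B[seg == k, k] <- B[seg == k, k] + (1 - t[seg == k])
    B[seg + 1L == k, k] <- B[seg + 1L == k, k] + t[seg + 1L == k]
  }
  B
}

solve_box_ls <- function(A, v, ridge, D2, start) {
  obj <- function(w) {
    r <- A %*% w - v
    sum(r^2) + ridge * sum((D2 %*% w)^2)
  }
  grad <- function(w) {
    2 * drop(crossprod(A, A %*% w - v)) + 2 * ridge * drop(crossprod(D2, D2 %*% w))
  }
  fit <- stats::optim(start, obj, grad, method = "L-BFGS-B",
                      lower = 0, upper = 1,
                      control = list(maxit = 500, factr = 1e4))
  fit$par
}

infer_global_landscape <- function(seeded, v, knots, ridge, support_frac,
                                   grid_n) {
  if (inherits(seeded, "expression_sample")) seeded <- list(seeded)
  nd <- length(seeded)
  if (nd < 3L) stop("global fit needs >= 3 doses (got ", nd, "): underdetermined")
  stopifnot(is.numeric(v), length(v) == nd, all(v >= 0), all(v <= 1))
  zs <- lapply(seeded, sample_log10)
  means <- vapply(zs, mean, 0)
  # the dose sweep must actually move the seeded mean for w to be
  # triangulated; 0.05 log10 units is well below any real induction step
  if (diff(range(means)) < 0.05) {
    stop("seeded means are not distinct across doses: design is degenerate")
  }
  pool <- unlist(zs)
  grid <- landscape_grid(pool, grid_n)
  kn <- seq(grid[1], grid[grid_n], length.out = knots)
  A <- t(vapply(zs, function(z) colMeans(hat_basis(z, kn)), numeric(knots)))
  K <- knots
  D2 <- diag(K)[-c(1, 2), , drop = FALSE] * 0
  if (K >= 3) {
    D2 <- matrix(0, K - 2L, K)
    for (i in seq_len(K - 2L)) D2[i, i:(i + 2L)] <- c(1, -2, 1)
  }
  if (is.null(ridge)) {
    ridge <- choose_ridge_cv(A, v, D2)
  }
  w_kn <- solve_box_ls(A, v, ridge, D2, start = rep(mean(v), K))
  fitted_v <- drop(A %*% w_kn)
  w <- stats::approx(kn, w_kn, xout = grid, rule = 2)$y
  dens <- stats::density(pool, from = grid[1], to = grid[grid_n], n = grid_n)$y
  support <- dens >= support_frac * max(dens)
  cond <- tryCatch(kappa(A, exact = FALSE), error = function(e) NA_real_)
  landscape(grid, pmin(1, pmax(0, w)), support_mask = support,
            meta = list(method = "global", knots = kn, w_knots = w_kn,
                        ridge = ridge, fitted = fitted_v, observed = v,
                        residuals = fitted_v - v, condition_number = cond,
                        seeded_means = means))
}

# 5-fold dose-blocked cross-validation over a log-spaced ridge grid
choose_ridge_cv <- function(A, v, D2, grid = 10^seq(-6, 0, length.out = 7)) {
  nd <- nrow(A)
  nfold <- min(5L, nd)
  folds <- split(seq_len(nd), rep_len(seq_len(nfold), nd))
  cv_err <- vapply(grid, function(lam) {
    err <- 0
    for (f in folds) {
      train <- setdiff(seq_len(nd), f)
      if (length(train) < 2L) next
      w <- solve_box_ls(A[train, , drop = FALSE], v[train], lam, D2,
                        start = rep(mean(v[train]), ncol(A)))
      err <- err + sum((A[f, , drop = FALSE] %*% w - v[f])^2)
    }
    err
  }, 0)
  grid[which.min(cv_err)]
}

#' Expected invasiveness of a seeded population on a landscape
#'
#' The analytic expectation of the Monte Carlo invasion assay: the mean of
#' w evaluated at each cell's log10 expression level (linear interpolation;
#' boundary values held outside the grid).
#'
#' @param object an `invasion_landscape`.
#' @param seeded an [expression_sample()] or numeric vector of log10 values.
#' @return expected invasiveness, a fraction in [0, 1].
#' @export
expected_invasiveness <- function(object, seeded) {
  z <- sample_log10(seeded)
  mean(landscape_value(object, z))
}

#' Classify the local geometry of a landscape around a point
#'
#' Fits a quadratic to w over `[z0 - window, z0 + window]` and classifies
#' the local shape from the fitted slope `w1` and curvature `w2` (second
#' derivative): upslope/downslope where the slope dominates, peak/valley
#' where the curvature dominates, and flat where neither effect clears the
#' tolerance band. An effect counts only if (a) its predicted change in w
#' across the window exceeds `band` and (b) when the quadratic leaves
#' residual noise, its coefficient is significant at `alpha`.
#'
#' Landscape slopes impose directional selection on invading populations;
#' peaks and valleys impose stabilizing and disruptive selection, so this
#' classification is the geometric side of [classify_mode()].
#'
#' @param object an `invasion_landscape`.
#' @param z0 center of the window (log10 a.u.).
#' @param window half-width of the window (log10 a.u.).
#' @param band minimum change in w across the window to call an effect real
#'   (default 0.05, matching the landscape-recovery noise floor: effects
#'   smaller than the estimator's own uncertainty are not classified).
#' @param alpha significance level for the coefficient t-tests (default
#'   0.01).
#' @return list of class `landscape_geometry`: `shape` (one of `"upslope"`,
#'   `"downslope"`, `"peak"`, `"valley"`, `"flat"`), `slope` (w1),
#'   `curvature` (w2), `p_slope`, `p_curvature`.
#' @export
local_geometry <- function(object, z0, window, band = 0.05, alpha = 0.01) {
  stopifnot(inherits(object, "invasion_landscape"), window > 0)
  zlo <- z0 - window; zhi <- z0 + window
  sup <- range(object$z_grid[object$support_mask])
  if (zlo < sup[1] || zhi > sup[2]) {
    stop(sprintf("window [%.3g, %.3g] outside landscape support [%.3g, %.3g]",
                 zlo, zhi, sup[1], sup[2]))
  }
  sel <- object$z_grid >= zlo & object$z_grid <= zhi
  if (sum(sel) < 5L) stop("fewer than 5 grid points in window")
  x <- object$z_grid[sel] - z0
  y <- object$w[sel]
  fit <- stats::lm(y ~ x + I(x^2))
  # a noiseless quadratic grid fits exactly; the warning is expected there
  cf <- suppressWarnings(summary(fit))$coefficients
  w1 <- cf["x", "Estimate"]
  c2 <- cf["I(x^2)", "Estimate"]
  w2 <- 2 * c2
  p1 <- cf["x", "Pr(>|t|)"]
  p2 <- cf["I(x^2)", "Pr(>|t|)"]
  # effect sizes: predicted |change in w| across the window
  eff1 <- abs(w1) * 2 * window
  eff2 <- abs(c2) * window^2
  sig1 <- eff1 > band && (is.nan(p1) || p1 < alpha)
  sig2 <- eff2 > band && (is.nan(p2) || p2 < alpha)
  shape <- if (sig1 && (!sig2 || eff1 >= eff2)) {
    if (w1 > 0) "upslope" else "downslope"
  } else if (sig2) {
    if (w2 > 0) "valley" else "peak"
  } else "flat"
  structure(list(shape = shape, slope = w1, curvature = w2,
                 p_slope = p1, p_curvature = p2, z0 = z0, window = window),
            class = "landscape_geometry")
}

#' @export
print.landscape_geometry <- function(x, ...) {
  cat(sprintf("local geometry at z0 = %.3g (window %.3g): %s\n",
              x$z0, x$window, x$shape))
  cat(sprintf("  slope w1 = %.4g, curvature w2 = %.4g\n", x$slope, x$curvature))
  invisible(x)
}

#' Write a landscape to a two-column TSV plus JSON metadata
#'
#' @param object an `invasion_landscape`.
#' @param path TSV path (columns `z`, `w`); a `.json` sidecar with the
#'   support mask and fit metadata is written next to it.
#' @return `path`, invisibly.
#' @export
write_landscape_tsv <- function(object, path) {
  stopifnot(inherits(object, "invasion_landscape"))
  df <- data.frame(z = sprintf("%.17g", object$z_grid),
                   w = sprintf("%.17g", object$w))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(c(object$meta, list(support_mask = object$support_mask)),
                       sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a landscape written by [write_landscape_tsv()]
#'
#' @param path TSV path.
#' @return an `invasion_landscape` (support mask restored from the JSON
#'   sidecar when present).
#' @export
read_landscape_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  jp <- sub("\\.tsv$", ".json", path)
  mask <- NULL; meta <- list()
  if (file.exists(jp)) {
    meta <- jsonlite::read_json(jp, simplifyVector = TRUE)
    mask <- as.logical(meta$support_mask)
    meta$support_mask <- NULL
  }
  landscape(df$z, df$w, support_mask = mask, meta = as.list(meta))
}
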
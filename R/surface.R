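#' Interpolate invasiveness over the (mean, CV) plane
#'
#' Fits an exact thin-plate (biharmonic) spline surface through scattered
#' invasiveness observations indexed by the mean and CV of log10 expression.
#' The interpolant is `s(x) = a0 + a1*mean + a2*cv + sum_i c_i U(|x - x_i|)`
#' with `U(r) = r^2 log r`, subject to the usual orthogonality constraints;
#' it passes exactly through every input point and reproduces affine
#' surfaces exactly. Coordinates are rescaled to unit range internally for
#' conditioning.
#'
#' @param points data.frame with numeric columns `mean`, `cv`,
#'   `invasiveness`; at least 4 non-collinear points, no duplicated
#'   (mean, cv) locations with conflicting invasiveness.
#' @return object of class `invasion_surface` with a [predict][
#'   predict.invasion_surface] method.
#' @examples
#' pts <- data.frame(mean = c(0, 1, 0, 1), cv = c(0, 0, 1, 1),
#'                   invasiveness = c(0.1, 0.5, 0.2, 0.4))
#' surf <- fit_invasion_surface(pts)
#' predict(surf, data.frame(mean = 0.5, cv = 0.5))
#' @export
fit_invasion_surface <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("mean", "cv", "invasiveness") %in% names(points)))
  pts <- points[c("mean", "cv", "invasiveness")]
  dup <- duplicated(pts)
  pts <- pts[!dup, , drop = FALSE]
  key <- paste(pts$mean, pts$cv)
  if (anyDuplicated(key)) {
    stop("duplicate (mean, cv) locations with conflicting invasiveness")
  }
  n <- nrow(pts)
  if (n < 4L) stop("need at least 4 points")
  sx <- diff(range(pts$mean)); sy <- diff(range(pts$cv))
  if (sx == 0 || sy == 0) stop("points are collinear (degenerate coordinate)")
  x <- (pts$mean - min(pts$mean)) / sx
  y <- (pts$cv - min(pts$cv)) / sy
  P <- cbind(1, x, y)
  if (qr(P)$rank < 3L) stop("points are collinear: surface underdetermined")
  K <- tps_kernel_matrix(x, y, x, y)
  M <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(pts$invasiveness, rep(0, 3))
  sol <- solve(M, rhs)
  hull <- grDevices::chull(x, y)
  structure(list(x = x, y = y, c = sol[seq_len(n)], a = sol[n + 1:3],
                 shift = c(min(pts$mean), min(pts$cv)), scale = c(sx, sy),
                 hull = cbind(x[hull], y[hull]), points = pts),
            class = "invasion_surface")
}

tps_kernel <- function(r2) {
  u <- numeric(length(r2))
  pos <- r2 > 0
  u[pos] <- r2[pos] * log(sqrt(r2[pos]))
  u
}

tps_kernel_matrix <- function(x1, y1, x2, y2) {
  r2 <- outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2
  matrix(tps_kernel(as.vector(r2)), nrow = length(x1))
}

# ray-casting point-in-polygon (boundary counts as inside)
in_hull <- function(px, py, hull) {
  n <- nrow(hull)
  inside <- logical(length(px))
  for (j in seq_along(px)) {
    x <- px[j]; y <- py[j]
    cross <- FALSE
    i2 <- n
    for (i1 in seq_len(n)) {
      x1 <- hull[i1, 1]; y1 <- hull[i1, 2]
      x2 <- hull[i2, 1]; y2 <- hull[i2, 2]
      if (((y1 > y) != (y2 > y)) &&
          (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)) cross <- !cross
      i2 <- i1
    }
    inside[j] <- cross
  }
  inside
}

#' Evaluate an interpolated invasiveness surface
#'
#' @param object an `invasion_surface`.
#' @param newdata data.frame with columns `mean` and `cv`.
#' @param ... unused.
#' @return numeric vector of interpolated invasiveness values with a logical
#'   attribute `extrapolated` flagging queries outside the convex hull of
#'   the input points.
#' @export
predict.invasion_surface <- function(object, newdata, ...) {
  stopifnot(all(c("mean", "cv") %in% names(newdata)))
  qx <- (newdata$mean - object$shift[1]) / object$scale[1]
  qy <- (newdata$cv - object$shift[2]) / object$scale[2]
  K <- tps_kernel_matrix(qx, qy, object$x, object$y)
  val <- drop(K %*% object$c) + object$a[1] + object$a[2] * qx +
    object$a[3] * qy
  # points numerically on the hull boundary are not extrapolation
  extrap <- !in_hull(qx, qy, object$hull)
  near <- vapply(seq_along(qx), function(j) {
    min((object$x - qx[j])^2 + (object$y - qy[j])^2) < 1e-16
  }, TRUE)
  extrap[near] <- FALSE
  structure(val, extrapolated = extrap)
}

#' @export
print.invasion_surface <- function(x, ...) {
  cat(sprintf("Thin-plate invasiveness surface over (mean, CV): %d points\n",
              nrow(x$points)))
  cat(sprintf("  mean in [%.3g, %.3g], cv in [%.3g, %.3g], v in [%.3g, %.3g]\n",
              min(x$points$mean), max(x$points$mean), min(x$points$cv),
              max(x$points$cv), min(x$points$invasiveness),
              max(x$points$invasiveness)))
  invisible(x)
}
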
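#' Hemin-accelerated protein degradation model
#'
#' Hemin accelerates degradation of the target protein without touching its
#' production. At first-order steady state the protein level is
#' proportional to production / (delta0 + k_h * h), so the fraction of
#' protein remaining at hemin concentration h is `delta0 / (delta0 + k_h *
#' h)` — independent of the production rate, and hence of the inducer dose.
#'
#' @param delta0 basal degradation rate constant (1/h), > 0.
#' @param k_h hemin-dependent degradation coefficient (1/h per uM), > 0.
#' @return object of class `hemin_model`.
#' @export
hemin_model <- function(delta0, k_h) {
  stopifnot(is.numeric(delta0), length(delta0) == 1L, delta0 > 0,
            is.numeric(k_h), length(k_h) == 1L, k_h > 0)
  structure(list(delta0 = delta0, k_h = k_h), class = "hemin_model")
}

#' @export
print.hemin_model <- function(x, ...) {
  cat(sprintf("hemin degradation model: delta0 = %.4g /h, k_h = %.4g /h/uM\n",
              x$delta0, x$k_h))
  cat(sprintf("  half-reduction at h = %.4g uM\n", x$delta0 / x$k_h))
  invisible(x)
}

#' Fraction of protein remaining under hemin treatment
#'
#' @param model a [hemin_model()].
#' @param h hemin concentration(s), uM, non-negative.
#' @return fraction remaining in (0, 1], strictly decreasing in `h` and
#'   independent of production (dose independence).
#' @export
fraction_remaining <- function(model, h) {
  stopifnot(inherits(model, "hemin_model"), is.numeric(h))
  if (any(h < 0)) stop("hemin concentration must be non-negative")
  model$delta0 / (model$delta0 + model$k_h * h)
}

#' Hemin dose needed to move mean expression between two inducer doses
#'
#' Solves for the hemin concentration that scales the mean level at dose
#' `d_from` down to the mean at dose `d_to`: with target ratio
#' `rho = M(d_to) / M(d_from)`, `h = delta0 (1 - rho) / (k_h rho)`, so that
#' `fraction_remaining(h) = rho` exactly. Degradation can only lower
#' levels, so `M(d_to) <= M(d_from)` is required. This is the calculation
#' behind treating cells at a landscape downslope or upslope so that their
#' expression resembles a lower inducer dose.
#'
#' @param model a [hemin_model()].
#' @param spec a [clone_spec()] providing the dose response M(d).
#' @param d_from current inducer dose (ng/ml).
#' @param d_to target-equivalent inducer dose (ng/ml).
#' @return list: `h` (uM), `rho` (target fraction), `d_from`, `d_to`.
#' @export
hemin_dose_for_target <- function(model, spec, d_from, d_to) {
  stopifnot(inherits(model, "hemin_model"), inherits(spec, "clone_spec"))
  m_from <- hill_mean(d_from, spec)
  m_to <- hill_mean(d_to, spec)
  rho <- m_to / m_from
  if (rho > 1) {
    stop(sprintf("infeasible target: M(%.4g) = %.4g exceeds M(%.4g) = %.4g; ",
                 d_to, m_to, d_from, m_from),
         "degradation cannot raise expression")
  }
  if (rho <= 0) stop("zero target level requires unbounded hemin")
  list(h = model$delta0 * (1 - rho) / (model$k_h * rho), rho = rho,
       d_from = d_from, d_to = d_to)
}

#' Incoherent feedforward loop parameters
#'
#' One regulator both activates and represses a target through Hill
#' response functions of different sharpness; the multiplicative (AND-gate)
#' composition of a sharp activation with a gradual repression produces a
#' band-pass, nonmonotone response. Either arm can be disabled (held at 1)
#' to recover the monotone single-link modes.
#'
#' @param beta maximal output (a.u.), >= 0.
#' @param K_act,n_act activation threshold (a.u., > 0) and Hill coefficient
#'   (> 0); default sharp (n = 4).
#' @param K_rep,n_rep repression threshold and Hill coefficient; default
#'   gradual (n = 1).
#' @param basal floor output (a.u.), >= 0.
#' @param act_on,rep_on logical; disable an arm by setting it FALSE.
#' @return object of class `iffl_params`.
#' @export
iffl_params <- function(beta = 1, K_act = 1, n_act = 4, K_rep = 1, n_rep = 1,
                        basal = 0, act_on = TRUE, rep_on = TRUE) {
  stopifnot(beta >= 0, K_act > 0, n_act > 0, K_rep > 0, n_rep > 0,
            basal >= 0, is.logical(act_on), is.logical(rep_on))
  structure(list(beta = beta, K_act = K_act, n_act = n_act, K_rep = K_rep,
                 n_rep = n_rep, basal = basal, act_on = act_on,
                 rep_on = rep_on),
            class = "iffl_params")
}

#' @export
print.iffl_params <- function(x, ...) {
  arm <- function(on, K, n, kind) {
    if (on) sprintf("%s (K = %.3g, n = %.3g)", kind, K, n)
    else sprintf("%s disabled", kind)
  }
  cat("iFFL response: ", arm(x$act_on, x$K_act, x$n_act, "activation"),
      " x ", arm(x$rep_on, x$K_rep, x$n_rep, "repression"),
      sprintf("; beta = %.3g, basal = %.3g\n", x$beta, x$basal), sep = "")
  invisible(x)
}

#' Evaluate the iFFL response function
#'
#' `basal + beta * act(b) * rep(b)` with
#' `act(b) = b^n_act / (K_act^n_act + b^n_act)` and
#' `rep(b) = K_rep^n_rep / (K_rep^n_rep + b^n_rep)`; a disabled arm
#' contributes 1.
#'
#' @param params an [iffl_params()].
#' @param b regulator input level(s), a.u., non-negative.
#' @return output level(s), a.u.
#' @export
iffl_response <- function(params, b) {
  stopifnot(inherits(params, "iffl_params"), is.numeric(b))
  if (any(b < 0)) stop("input level must be non-negative")
  act <- if (params$act_on) {
    b^params$n_act / (params$K_act^params$n_act + b^params$n_act)
  } else 1
  rep_ <- if (params$rep_on) {
    params$K_rep^params$n_rep / (params$K_rep^params$n_rep + b^params$n_rep)
  } else 1
  params$basal + params$beta * act * rep_
}

#' Locate interior extrema of an iFFL response
#'
#' Dense-grid evaluation with sign changes of finite differences, refined
#' by golden-section search ([stats::optimize()]) in each bracketing
#' interval. Extrema whose prominence (height above/below both flanks)
#' falls below `prominence` times the output range are discarded as
#' numerical wiggles. The verdict is nonmonotone iff at least one interior
#' extremum survives.
#'
#' @param params an [iffl_params()].
#' @param b_range input range to scan (length 2, increasing).
#' @param grid_n grid size, >= 100.
#' @param prominence relative prominence tolerance (default 0.01 of the
#'   output range).
#' @return list of class `iffl_extrema`: `extrema` (data.frame with
#'   location, value, type), `monotone` (logical verdict),
#'   `direction` (`"increasing"`, `"decreasing"`, `"constant"`, or
#'   `"nonmonotone"`).
#' @export
iffl_extrema <- function(params, b_range = c(0, 20), grid_n = 2000L,
                         prominence = 0.01) {
  stopifnot(inherits(params, "iffl_params"), length(b_range) == 2L)
  if (b_range[2] <= b_range[1]) stop("empty input range")
  if (grid_n < 100L) stop("grid_n must be >= 100")
  b <- seq(b_range[1], b_range[2], length.out = grid_n)
  y <- iffl_response(params, b)
  rng <- max(y) - min(y)
  tol <- prominence * max(rng, .Machine$double.eps)
  d <- diff(y)
  s <- sign(d)
  s[s == 0] <- NA
  s <- filled_sign(s)
  flips <- which(s[-1] * s[-length(s)] < 0)
  ext <- list()
  f <- function(x) iffl_response(params, x)
  for (i in flips) {
    lo <- b[max(1L, i - 1L)]; hi <- b[min(grid_n, i + 2L)]
    is_max <- s[i] > 0
    opt <- stats::optimize(f, c(lo, hi), maximum = is_max)
    loc <- if (is_max) opt$maximum else opt$minimum
    val <- if (is_max) opt$objective else opt$objective
    # prominence against the nearest flanking extreme values
    left <- y[seq_len(i)]; right <- y[(i + 1L):grid_n]
    prom <- if (is_max) {
      min(val - min(left), val - min(right))
    } else {
      min(max(left) - val, max(right) - val)
    }
    if (prom >= tol) {
      ext[[length(ext) + 1L]] <- data.frame(
        location = loc, value = val,
        type = if (is_max) "maximum" else "minimum")
    }
  }
  ext_df <- if (length(ext)) {
    do.call(rbind, c(ext, make.row.names = FALSE))
  } else {
    data.frame(location = numeric(), value = numeric(), type = character())
  }
  monotone <- nrow(ext_df) == 0L
  direction <- if (!monotone) "nonmonotone"
  else if (rng <= .Machine$double.eps * 10) "constant"
  else if (y[grid_n] >= y[1]) "increasing" else "decreasing"
  structure(list(extrema = ext_df, monotone = monotone,
                 direction = direction, b_range = b_range),
            class = "iffl_extrema")
}

# carry the last non-NA sign forward (flat stretches inherit the
# approaching slope), then backward for a leading flat
filled_sign <- function(s) {
  if (all(is.na(s))) return(rep(0, length(s)))
  for (i in seq_along(s)) if (is.na(s[i]) && i > 1L) s[i] <- s[i - 1L]
  for (i in rev(seq_along(s))) if (is.na(s[i]) && i < length(s)) s[i] <- s[i + 1L]
  s
}

#' @export
print.iffl_extrema <- function(x, ...) {
  cat(sprintf("iFFL response on [%.3g, %.3g]: %s\n", x$b_range[1],
              x$b_range[2], x$direction))
  if (nrow(x$extrema)) {
    for (i in seq_len(nrow(x$extrema))) {
      cat(sprintf("  interior %s at b = %.4g (value %.4g)\n",
                  x$extrema$type[i], x$extrema$location[i], x$extrema$value[i]))
    }
  }
  invisible(x)
}
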
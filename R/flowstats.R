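#' Summary statistics of a single-cell fluorescence sample
#'
#' Computes the mean fluorescence intensity (MFI) and coefficient of
#' variation (CV = SD/mean) on the linear scale, plus the mean and SD of
#' log10 fluorescence. Non-positive values (which have no log) are excluded
#' from all statistics and counted in `n_dropped`. SDs use the population
#' convention (divide by n): at flow-cytometry sample sizes the distinction
#' from n-1 is negligible and fixing one convention keeps results
#' reproducible.
#'
#' CV is returned as a fraction; multiply by 100 for the conventional
#' percent display.
#'
#' @param sample an [expression_sample()] or a bare numeric vector of linear
#'   fluorescence values.
#' @return a list of class `sample_summary` with fields `mfi`, `cv`, `n`,
#'   `log10_mean`, `log10_sd`, `n_dropped`, plus the sample's `clone`,
#'   `dose`, `compartment`, `replicate` when available.
#' @examples
#' summarize_sample(expression_sample(c(1, 2, 3)))
#' @export
summarize_sample <- function(sample) {
  v <- if (inherits(sample, "expression_sample")) sample$values else sample
  stopifnot(is.numeric(v), length(v) >= 1L)
  keep <- is.finite(v) & v > 0
  n_dropped <- sum(!keep)
  v <- v[keep]
  if (!length(v)) stop("no positive values remain after exclusions")
  mfi <- mean(v)
  cv <- pop_sd(v) / mfi
  lg <- log10(v)
  out <- list(mfi = mfi, cv = cv, n = length(v),
              log10_mean = mean(lg), log10_sd = pop_sd(lg),
              n_dropped = n_dropped)
  if (inherits(sample, "expression_sample")) {
    out <- c(out, sample[c("clone", "dose", "compartment", "replicate")])
  }
  structure(out, class = "sample_summary")
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("sample_summary: n = %d (%d dropped), MFI = %.4g a.u., CV = %.1f%%\n",
              x$n, x$n_dropped, x$mfi, 100 * x$cv))
  cat(sprintf("  log10 mean = %.4g, log10 SD = %.4g\n", x$log10_mean, x$log10_sd))
  invisible(x)
}

#' Log10-transform a fluorescence sample
#'
#' Returns log10 of the positive values; the count of excluded non-positive
#' values is attached as attribute `n_dropped`. On log scale, flow-cytometry
#' expression histograms are approximately Gaussian, which is what the OU
#' model and the landscape inference operate on.
#'
#' @param sample an [expression_sample()] or numeric vector.
#' @return numeric vector of log10 values with attribute `n_dropped`.
#' @export
log10_transform <- function(sample) {
  v <- if (inherits(sample, "expression_sample")) sample$values else sample
  stopifnot(is.numeric(v), length(v) >= 1L)
  keep <- is.finite(v) & v > 0
  if (!any(keep)) stop("no positive values to transform")
  structure(log10(v[keep]), n_dropped = sum(!keep))
}

#' Correlate paired expression differences with invasiveness differences
#'
#' Given per-dose differences between a high-noise and a low-noise clone
#' (Delta = high minus low), computes the Pearson correlation (and two-sided
#' t-test p-value) of Delta CV vs Delta invasiveness and of Delta mean vs
#' Delta invasiveness. A positive noise correlation with a weak mean
#' correlation is the signature that expression noise, not mean level,
#' tracks the invasiveness difference.
#'
#' @param deltas data.frame with numeric columns `delta_cv`, `delta_mean`,
#'   `delta_invasiveness`; at least 3 rows.
#' @return data.frame with one row per comparison: `metric`, `r`, `p`, `n`.
#' @export
delta_correlation <- function(deltas) {
  stopifnot(is.data.frame(deltas),
            all(c("delta_cv", "delta_mean", "delta_invasiveness") %in%
                  names(deltas)))
  if (nrow(deltas) < 3L) stop("need at least 3 paired differences")
  one <- function(x, label) {
    if (pop_sd(x) == 0 || pop_sd(deltas$delta_invasiveness) == 0) {
      stop("zero variance in ", label,
           " or delta_invasiveness: correlation undefined")
    }
    ct <- stats::cor.test(x, deltas$delta_invasiveness, method = "pearson")
    data.frame(metric = label, r = unname(ct$estimate), p = ct$p.value,
               n = nrow(deltas))
  }
  rbind(one(deltas$delta_cv, "delta_cv"),
        one(deltas$delta_mean, "delta_mean"))
}

#' Find decoupled noise points among condition summaries
#'
#' Decoupled noise points are pairs of conditions with matched mean
#' expression but clearly different CV; they allow noise effects on a
#' phenotype to be tested independently of the mean. A pair qualifies when
#' the MFI ratio is within `mean_tol` of 1 and the absolute CV difference is
#' at least `cv_gap`.
#'
#' @param summaries list of [summarize_sample()] results (>= 2).
#' @param mean_tol relative tolerance on the MFI ratio (default 0.1).
#' @param cv_gap minimum absolute CV difference, as a fraction (default 0.1).
#' @return data.frame with one row per qualifying pair: indices `i`, `j`,
#'   labels, `mfi_ratio`, `cv_gap`. Zero rows when none qualify.
#' @export
find_decoupled_pairs <- function(summaries, mean_tol = 0.1, cv_gap = 0.1) {
  stopifnot(is.list(summaries), length(summaries) >= 2L)
  lab <- function(s, k) {
    if (!is.null(s$clone)) sprintf("%s@%.4g", s$clone, s$dose) else paste0("s", k)
  }
  out <- list()
  for (i in seq_along(summaries)) {
    for (j in seq_along(summaries)) {
      if (j <= i) next
      a <- summaries[[i]]; b <- summaries[[j]]
      ratio <- a$mfi / b$mfi
      gap <- abs(a$cv - b$cv)
      if (abs(ratio - 1) <= mean_tol && gap >= cv_gap) {
        out[[length(out) + 1L]] <- data.frame(
          i = i, j = j, label_i = lab(a, i), label_j = lab(b, j),
          mfi_ratio = ratio, cv_gap = gap)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(i = integer(), j = integer(), label_i = character(),
                      label_j = character(), mfi_ratio = numeric(),
                      cv_gap = numeric()))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Tabulate summaries for a set of samples and write a summary TSV
#'
#' @param samples list of [expression_sample()] objects.
#' @param path optional TSV output path; when given the table is also written
#'   (tab-separated, LF).
#' @return data.frame with columns clone, dose, compartment, replicate, n,
#'   mfi, cv, log10_mean, log10_sd, n_dropped.
#' @export
summarize_conditions <- function(samples, path = NULL) {
  samples <- Filter(Negate(is.null), samples)
  rows <- lapply(samples, function(s) {
    sm <- summarize_sample(s)
    data.frame(clone = s$clone, dose = s$dose, compartment = s$compartment,
               replicate = s$replicate, n = sm$n, mfi = sm$mfi, cv = sm$cv,
               log10_mean = sm$log10_mean, log10_sd = sm$log10_sd,
               n_dropped = sm$n_dropped)
  })
  df <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  df
}
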
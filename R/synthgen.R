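#' Define a synthetic clone: Hill dose response plus a noise profile
#'
#' A clone is parameterized by its basal mean fluorescence, the maximal fold
#' induction, the inducer concentration at half-maximal induction, a Hill
#' coefficient, and the per-dose standard deviation of log10 fluorescence.
#' Together these stand in for an engineered doxycycline-tunable expression
#' clone: mean expression follows a monotone Hill dose response (full
#' induction up to `fold` times basal, 30-fold by default) while cell-to-cell
#' variability is controlled independently through `sigma_log10`, so that
#' low-noise and high-noise clones with matched means can be generated.
#'
#' @param basal_mfi basal (uninduced) mean fluorescence intensity, linear
#'   arbitrary units; must be positive.
#' @param fold ratio of fully induced to basal mean; must be >= 1.
#' @param ec50 inducer concentration at half-maximal induction (ng/ml).
#' @param hill_n Hill coefficient of the dose response (> 0).
#' @param sigma_log10 SD of log10 fluorescence. Either a single positive
#'   number (constant across doses) or a function of dose returning the SD.
#' @param label clone identifier.
#' @return An object of class `clone_spec`.
#' @examples
#' cl <- clone_spec(basal_mfi = 100, sigma_log10 = 0.15, label = "BL")
#' hill_mean(c(0, 0.5, 100), cl)
#' @export
clone_spec <- function(basal_mfi = 100, fold = 30, ec50 = 0.5, hill_n = 1.2,
                       sigma_log10 = 0.15, label = "clone") {
  stopifnot(is.numeric(basal_mfi), length(basal_mfi) == 1L, basal_mfi > 0,
            is.numeric(fold), length(fold) == 1L, fold >= 1,
            is.numeric(ec50), length(ec50) == 1L, ec50 > 0,
            is.numeric(hill_n), length(hill_n) == 1L, hill_n > 0)
  if (is.function(sigma_log10)) {
    sigma_fun <- sigma_log10
  } else {
    stopifnot(is.numeric(sigma_log10), length(sigma_log10) == 1L,
              sigma_log10 > 0)
    sconst <- sigma_log10
    sigma_fun <- function(d) rep_len(sconst, length(d))
  }
  structure(list(basal_mfi = basal_mfi, fold = fold, ec50 = ec50,
                 hill_n = hill_n, sigma_log10 = sigma_fun,
                 label = as.character(label)),
            class = "clone_spec")
}

#' @export
print.clone_spec <- function(x, ...) {
  cat("Synthetic clone '", x$label, "'\n", sep = "")
  cat(sprintf("  basal MFI %.4g a.u., fold %.4g, EC50 %.4g ng/ml, Hill n %.3g\n",
              x$basal_mfi, x$fold, x$ec50, x$hill_n))
  cat(sprintf("  sigma_log10 at 0 / EC50 / 100 ng/ml: %.3g / %.3g / %.3g\n",
              x$sigma_log10(0), x$sigma_log10(x$ec50), x$sigma_log10(100)))
  invisible(x)
}

#' Doxycycline dose grid
#'
#' Validates a vector of inducer concentrations (non-negative, strictly
#' increasing). The default is the 12-point grid used for full dose-response
#' characterization: 0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10 and
#' 100 ng/ml.
#'
#' @param doses numeric vector of doxycycline concentrations (ng/ml).
#' @return the validated numeric vector, classed `dose_grid`.
#' @export
dose_grid <- function(doses = c(0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5,
                                1, 2, 5, 10, 100)) {
  stopifnot(is.numeric(doses), length(doses) >= 1L, all(is.finite(doses)))
  if (any(doses < 0)) stop("doses must be non-negative")
  if (is.unsorted(doses, strictly = TRUE)) {
    stop("doses must be strictly increasing")
  }
  structure(as.numeric(doses), class = "dose_grid")
}

#' Mean fluorescence at a given inducer dose
#'
#' Hill dose-response for the clone mean on the linear fluorescence scale:
#' `M(d) = basal * (1 + (fold - 1) * d^n / (ec50^n + d^n))`.
#' Monotone nondecreasing in `d`; `M(0) = basal`, `M(Inf) = basal * fold`.
#'
#' @param d dose(s), ng/ml, non-negative.
#' @param spec a [clone_spec()].
#' @return mean linear fluorescence (a.u.), same length as `d`.
#' @export
hill_mean <- function(d, spec) {
  stopifnot(inherits(spec, "clone_spec"), is.numeric(d))
  if (any(d < 0)) stop("dose must be non-negative")
  hn <- d^spec$hill_n / (spec$ec50^spec$hill_n + d^spec$hill_n)
  hn[is.infinite(d)] <- 1
  spec$basal_mfi * (1 + (spec$fold - 1) * hn)
}

#' Single-cell expression sample container
#'
#' Holds linear-scale fluorescence values for one (clone, dose, compartment,
#' replicate) condition, mirroring one flow-cytometry acquisition.
#'
#' @param values linear fluorescence values (a.u.), finite, non-empty.
#' @param clone clone label.
#' @param dose dose (ng/ml).
#' @param compartment `"seeded"` or `"invaded"`.
#' @param replicate replicate index (integer).
#' @return object of class `expression_sample`.
#' @export
expression_sample <- function(values, clone = "clone", dose = 0,
                              compartment = c("seeded", "invaded"),
                              replicate = 1L) {
  compartment <- match.arg(compartment)
  stopifnot(is.numeric(values), length(values) >= 1L, all(is.finite(values)))
  structure(list(values = as.numeric(values), clone = as.character(clone),
                 dose = as.numeric(dose), compartment = compartment,
                 replicate = as.integer(replicate)),
            class = "expression_sample")
}

#' @export
print.expression_sample <- function(x, ...) {
  cat(sprintf("expression_sample: %d cells, clone %s, dose %.4g ng/ml, %s, rep %d\n",
              length(x$values), x$clone, x$dose, x$compartment, x$replicate))
  invisible(x)
}

# Deterministic child seed from a master seed and a key string; keeps
# per-(dose, replicate, compartment) streams independent but reproducible.
child_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  (as.integer(seed) * 7919L + as.integer(h %% 104729L)) %% 2147483587L
}

#' Draw a synthetic single-cell sample at one dose
#'
#' log10 fluorescence is Gaussian with SD `sigma_log10(d)` and location chosen
#' so that the *linear*-scale mean equals the Hill mean `hill_mean(d, spec)`:
#' `m = log10(M(d)) - sigma^2 * ln(10) / 2` (the lognormal mean correction).
#' This reproduces the empirical structure of flow-cytometry data, where
#' log-transformed histograms are approximately Gaussian while MFI is
#' reported on the linear scale.
#'
#' @param spec a [clone_spec()].
#' @param d dose (ng/ml, scalar, >= 0).
#' @param n number of cells (>= 1).
#' @param seed integer seed; same seed gives an identical sample.
#' @param replicate replicate index stored in the sample.
#' @param compartment compartment label stored in the sample.
#' @return an [expression_sample()].
#' @examples
#' s <- sample_cells(clone_spec(), d = 0.5, n = 1000, seed = 1)
#' mean(s$values) / hill_mean(0.5, clone_spec())  # close to 1
#' @export
sample_cells <- function(spec, d, n, seed, replicate = 1L,
                         compartment = "seeded") {
  stopifnot(inherits(spec, "clone_spec"), length(d) == 1L, d >= 0)
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  sig <- spec$sigma_log10(d)
  m <- log10(hill_mean(d, spec)) - sig^2 * log(10) / 2
  z <- withr_seed(seed, stats::rnorm(n, mean = m, sd = sig))
  expression_sample(10^z, clone = spec$label, dose = d,
                    compartment = compartment, replicate = replicate)
}

# Evaluate an expression under a local RNG seed without disturbing the
# caller's RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a seeded/invaded benchmark dataset under a known landscape
#'
#' For each dose in `grid` and each replicate, draws a seeded sample from the
#' clone's dose response, thins it by independent Bernoulli draws with
#' per-cell probability `w(log10 value)` from the ground-truth landscape, and
#' records the realized invasiveness (invaded / seeded count). The truth is
#' carried alongside so that landscape-recovery error can be measured.
#'
#' @param spec a [clone_spec()].
#' @param grid a [dose_grid()].
#' @param truth an `invasion_landscape` (the ground truth `w(z)`).
#' @param n_per_dose seeded cells per dose and replicate.
#' @param reps replicates per dose.
#' @param seed master seed; per-(dose, replicate) child streams are derived
#'   deterministically.
#' @return a list of class `benchmark_dataset` with elements `seeded` and
#'   `invaded` (lists of [expression_sample()]), `invasiveness` (data.frame
#'   with dose, replicate, v, n_seeded, n_invaded), `truth`, `spec`, `grid`,
#'   `seed`.
#' @export
generate_benchmark_dataset <- function(spec, grid, truth, n_per_dose = 10000L,
                                       reps = 3L, seed = 1L) {
  stopifnot(inherits(spec, "clone_spec"), inherits(truth, "invasion_landscape"),
            n_per_dose >= 1, reps >= 1)
  grid <- dose_grid(unclass(grid))
  seeded <- list(); invaded <- list()
  rows <- list()
  zmin <- min(truth$z_grid); zmax <- max(truth$z_grid)
  for (d in grid) {
    # coverage check: fraction of seeded probability mass outside the
    # landscape grid must stay under 5%
    sig <- spec$sigma_log10(d)
    m <- log10(hill_mean(d, spec)) - sig^2 * log(10) / 2
    outside <- stats::pnorm(zmin, m, sig) + stats::pnorm(zmax, m, sig,
                                                         lower.tail = FALSE)
    if (outside > 0.05) {
      stop(sprintf(paste0("landscape undefined over %.1f%% of seeded mass at ",
                          "dose %.4g ng/ml (grid [%.3g, %.3g], seeded mean %.3g, ",
                          "sd %.3g)"), 100 * outside, d, zmin, zmax, m, sig))
    }
    for (r in seq_len(reps)) {
      sseed <- child_seed(seed, sprintf("d%.6g_r%d_seeded", d, r))
      s <- sample_cells(spec, d, n_per_dose, seed = sseed, replicate = r)
      res <- simulate_invasion(log10(s$values), truth,
                               seed = child_seed(seed,
                                 sprintf("d%.6g_r%d_invaded", d, r)))
      inv_values <- 10^res$invaded_values
      key <- sprintf("d=%.6g_rep=%d", d, r)
      seeded[[key]] <- s
      invaded[[key]] <- if (length(inv_values)) {
        expression_sample(inv_values, clone = spec$label, dose = d,
                          compartment = "invaded", replicate = r)
      } else NULL
      rows[[key]] <- data.frame(dose = d, replicate = r, v = res$v_sim,
                                n_seeded = n_per_dose,
                                n_invaded = length(inv_values))
    }
  }
  structure(list(seeded = seeded, invaded = invaded,
                 invasiveness = do.call(rbind, c(rows, make.row.names = FALSE)),
                 truth = truth, spec = spec, grid = grid, seed = seed),
            class = "benchmark_dataset")
}

#' @export
print.benchmark_dataset <- function(x, ...) {
  cat(sprintf("benchmark_dataset: clone %s, %d doses x %d reps, %d cells/dose\n",
              x$spec$label, length(x$grid), max(x$invasiveness$replicate),
              x$invasiveness$n_seeded[1]))
  cat(sprintf("  realized invasiveness %.3g-%.3g\n",
              min(x$invasiveness$v), max(x$invasiveness$v)))
  invisible(x)
}

#' Write expression samples to the single-cell CSV schema
#'
#' Schema (bit-exact contract): header
#' `cell_id,clone,dose_ng_ml,replicate,compartment,fluor_au`; UTF-8, LF line
#' endings, '.' decimal separator. Fluorescence is written with 17 significant
#' digits so values round-trip losslessly through the file.
#'
#' @param samples a single [expression_sample()] or a list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cells_csv <- function(samples, path) {
  if (inherits(samples, "expression_sample")) samples <- list(samples)
  samples <- Filter(Negate(is.null), samples)
  stopifnot(length(samples) >= 1L)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("cell_id,clone,dose_ng_ml,replicate,compartment,fluor_au",
             con, sep = "\n", useBytes = TRUE)
  id <- 0L
  for (s in samples) {
    n <- length(s$values)
    lines <- sprintf("%d,%s,%s,%d,%s,%s", id + seq_len(n), s$clone,
                     sprintf("%.17g", s$dose), s$replicate, s$compartment,
                     sprintf("%.17g", s$values))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    id <- id + n
  }
  invisible(path)
}

#' Read the single-cell CSV schema back into expression samples
#'
#' @param path CSV file written by [write_cells_csv()] (or conforming to the
#'   same schema).
#' @return a list of [expression_sample()] objects, one per
#'   (clone, dose, replicate, compartment) combination present.
#' @export
read_cells_csv <- function(path) {
  need <- c("cell_id", "clone", "dose_ng_ml", "replicate", "compartment",
            "fluor_au")
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(header, need)) {
    stop("CSV header does not match the single-cell schema: expected ",
         paste(need, collapse = ","))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cell_id = "integer",
                                       clone = "character",
                                       dose_ng_ml = "numeric",
                                       replicate = "integer",
                                       compartment = "character",
                                       fluor_au = "numeric"))
  keys <- interaction(df$clone, df$dose_ng_ml, df$replicate, df$compartment,
                      drop = TRUE)
  lapply(split(df, keys), function(g) {
    expression_sample(g$fluor_au, clone = g$clone[1], dose = g$dose_ng_ml[1],
                      compartment = g$compartment[1], replicate = g$replicate[1])
  })
}

#' Write the JSON sidecar describing a benchmark dataset
#'
#' Records the clone parameters, dose grid, ground-truth landscape knots and
#' the master seed next to the CSV so a dataset is self-describing.
#'
#' @param dataset a `benchmark_dataset`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_dataset_json <- function(dataset, path) {
  stopifnot(inherits(dataset, "benchmark_dataset"))
  spec <- dataset$spec
  meta <- list(
    clone = list(label = spec$label, basal_mfi = spec$basal_mfi,
                 fold = spec$fold, ec50 = spec$ec50, hill_n = spec$hill_n,
                 sigma_log10_at_doses = spec$sigma_log10(as.numeric(dataset$grid))),
    dose_grid = as.numeric(dataset$grid),
    landscape = list(z_grid = dataset$truth$z_grid, w = dataset$truth$w),
    seed = dataset$seed)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
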
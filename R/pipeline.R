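#' Default pipeline configuration
#'
#' A complete, versioned configuration for [run_pipeline()]: a 30-fold
#' Hill dose response (EC50 0.5 ng/ml, Hill coefficient 1.2, basal
#' 100 a.u.), the 12-point dose grid, a low-noise profile
#' (sigma_log10 = 0.15), a valley-shaped ground-truth landscape, OU
#' relaxation time 24 h over a 16 h assay, and Monte Carlo sizes sized for
#' an interactive run.
#'
#' @param seed master seed.
#' @return named list (the `run_config` schema, version 1).
#' @export
default_run_config <- function(seed = 1L) {
  list(
    schema_version = 1L,
    clone = list(basal_mfi = 100, fold = 30, ec50 = 0.5, hill_n = 1.2,
                 sigma_log10 = 0.15, label = "BL"),
    doses = c(0, 0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10, 100),
    truth = list(z = c(0.5, 2.0, 2.75, 3.5, 5.0),
                 w = c(0.45, 0.45, 0.10, 0.55, 0.55)),
    landscape = list(method = "global", knots = 12L, ridge = NULL,
                     support_frac = 0.01, bandwidth = NULL),
    ou = list(tau = 24, assay_hours = 16),
    mc = list(n_per_dose = 5000L, reps = 3L),
    hemin = list(delta0 = 0.1, k_h = 0.05,
                 mappings = list(list(d_from = 0.5, d_to = 0.3),
                                 list(d_from = 10, d_to = 0.5))),
    iffl = list(beta = 1, K_act = 1, n_act = 4, K_rep = 1, n_rep = 1,
                basal = 0),
    seed = as.integer(seed))
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; missing keys are filled from
#'   [default_run_config()].
#' @return a validated config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_run_config(), user)
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (is.null(cfg$schema_version) || cfg$schema_version != 1L) {
    stop("config schema_version must be 1")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L) {
    stop("config field 'seed' must be a single integer")
  }
  if (cfg$mc$n_per_dose < 1 || cfg$mc$reps < 1) {
    stop("mc sizes must be positive")
  }
  with(cfg$truth, stopifnot(length(z) == length(w), length(z) >= 2))
  invisible(cfg)
}

config_clone <- function(cfg) {
  c <- cfg$clone
  clone_spec(basal_mfi = c$basal_mfi, fold = c$fold, ec50 = c$ec50,
             hill_n = c$hill_n, sigma_log10 = c$sigma_log10, label = c$label)
}

config_truth <- function(cfg) {
  z <- seq(min(cfg$truth$z), max(cfg$truth$z), length.out = 256L)
  w <- stats::approx(cfg$truth$z, cfg$truth$w, xout = z, rule = 2)$y
  landscape(z, pmin(1, pmax(0, w)), meta = list(method = "truth"))
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(cfg, tf)
  unname(tools::md5sum(tf))
}

pipeline_log <- function(out_dir, msg, verbose = FALSE) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  cat(line, "\n", file = file.path(out_dir, "run.log"), append = TRUE,
      sep = "")
  if (verbose) message(line)
}

#' Run one step of the analysis pipeline
#'
#' Chains the package's modules into the full analysis arc:
#'
#' * `"simulate"` — generate a seeded/invaded benchmark dataset under the
#'   configured clone and ground-truth landscape (single-cell CSV, JSON
#'   sidecar, invasiveness and summary tables).
#' * `"infer-landscape"` — fit the invasion landscape from the simulated
#'   data ([fit_landscape()]), write it as TSV + JSON, and, when the
#'   ground truth is available, recovery diagnostics.
#' * `"select"` — per-dose Price-equation selection reports on the seeded
#'   populations under the fitted landscape (TSV of shifts and modes).
#' * `"respond"` — hemin degradation dose mappings and iFFL extrema
#'   analysis (JSON).
#' * `"metrics"` — invasiveness from a field-counts TSV
#'   (`config$metrics$counts_tsv`).
#' * `"report"` — single JSON summary of the artifacts above.
#'
#' Every run logs the master seed, config hash and package version to
#' `run.log` in the output directory. All randomness derives from the
#' config seed, so rerunning a subcommand with the same config and seed
#' reproduces numeric outputs byte for byte.
#'
#' @param subcommand one of `"simulate"`, `"infer-landscape"`, `"select"`,
#'   `"respond"`, `"metrics"`, `"report"`.
#' @param config a config list, a YAML path, or NULL for
#'   [default_run_config()].
#' @param seed optional master-seed override.
#' @param out_dir output directory (created if needed).
#' @param verbose echo log lines to the console.
#' @return named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(subcommand = c("simulate", "infer-landscape",
                                        "select", "respond", "metrics",
                                        "report"),
                         config = NULL, seed = NULL, out_dir = tempdir(),
                         verbose = FALSE) {
  subcommand <- match.arg(subcommand)
  cfg <- if (is.null(config)) default_run_config()
  else if (is.character(config)) read_run_config(config)
  else utils::modifyList(default_run_config(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  validate_run_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pipeline_log(out_dir, sprintf("%s | seed=%d | config=%s | invscape %s on R %s",
                                subcommand, cfg$seed, config_hash(cfg),
                                as.character(utils::packageVersion("invscape")),
                                paste(R.version$major, R.version$minor,
                                      sep = ".")),
               verbose)
  switch(subcommand,
         "simulate" = pl_simulate(cfg, out_dir),
         "infer-landscape" = pl_infer(cfg, out_dir),
         "select" = pl_select(cfg, out_dir),
         "respond" = pl_respond(cfg, out_dir),
         "metrics" = pl_metrics(cfg, out_dir),
         "report" = pl_report(cfg, out_dir))
}

pl_simulate <- function(cfg, out_dir) {
  spec <- config_clone(cfg)
  truth <- config_truth(cfg)
  ds <- generate_benchmark_dataset(spec, dose_grid(cfg$doses), truth,
                                   n_per_dose = cfg$mc$n_per_dose,
                                   reps = cfg$mc$reps, seed = cfg$seed)
  paths <- list(cells = file.path(out_dir, "cells.csv"),
                sidecar = file.path(out_dir, "dataset.json"),
                invasiveness = file.path(out_dir, "invasiveness.tsv"),
                summaries = file.path(out_dir, "summaries.tsv"))
  write_cells_csv(c(ds$seeded, ds$invaded), paths$cells)
  write_dataset_json(ds, paths$sidecar)
  inv <- ds$invasiveness
  inv$v <- sprintf("%.17g", inv$v)
  utils::write.table(inv, paths$invasiveness, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  summarize_conditions(c(ds$seeded, ds$invaded), paths$summaries)
  invisible(paths)
}

pl_load_dataset <- function(out_dir) {
  cells <- file.path(out_dir, "cells.csv")
  inv <- file.path(out_dir, "invasiveness.tsv")
  if (!file.exists(cells) || !file.exists(inv)) {
    stop("missing input: run the 'simulate' step first (need cells.csv and ",
         "invasiveness.tsv in ", out_dir, ")")
  }
  list(samples = read_cells_csv(cells),
       invasiveness = utils::read.table(inv, header = TRUE, sep = "\t"))
}

pl_infer <- function(cfg, out_dir) {
  ds <- pl_load_dataset(out_dir)
  seeded <- Filter(function(s) s$compartment == "seeded", ds$samples)
  inv <- ds$invasiveness
  ls_cfg <- cfg$landscape
  if (identical(ls_cfg$method, "ratio")) {
    pool_s <- unlist(lapply(seeded, function(s) s$values))
    invd <- Filter(function(s) s$compartment == "invaded", ds$samples)
    pool_i <- unlist(lapply(invd, function(s) s$values))
    v <- length(pool_i) / length(pool_s)
    fit <- fit_landscape(expression_sample(pool_s),
                         invaded = expression_sample(pool_i,
                                                     compartment = "invaded"),
                         v = v, method = "ratio",
                         bandwidth = ls_cfg$bandwidth,
                         support_frac = ls_cfg$support_frac)
  } else {
    key <- vapply(seeded, function(s) sprintf("%.10g|%d", s$dose, s$replicate),
                  "")
    ikey <- sprintf("%.10g|%d", inv$dose, inv$replicate)
    v <- inv$v[match(key, ikey)]
    if (anyNA(v)) stop("invasiveness.tsv does not cover every seeded sample")
    fit <- fit_landscape(seeded, v = v, method = "global",
                         knots = ls_cfg$knots, ridge = ls_cfg$ridge,
                         support_frac = ls_cfg$support_frac)
  }
  paths <- list(landscape = file.path(out_dir, "landscape.tsv"),
                diagnostics = file.path(out_dir, "landscape_diagnostics.json"))
  write_landscape_tsv(fit, paths$landscape)
  diag <- list(method = fit$meta$method)
  sidecar <- file.path(out_dir, "dataset.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    truth_w <- stats::approx(meta$landscape$z_grid, meta$landscape$w,
                             xout = fit$z_grid, rule = 2)$y
    err <- abs(fit$w - truth_w)[fit$support_mask]
    diag$recovery_max_abs_error <- max(err)
    diag$recovery_mean_abs_error <- mean(err)
  }
  if (!is.null(fit$meta$residuals)) {
    diag$rms_residual <- sqrt(mean(fit$meta$residuals^2))
  }
  jsonlite::write_json(diag, paths$diagnostics, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

pl_select <- function(cfg, out_dir) {
  ls_path <- file.path(out_dir, "landscape.tsv")
  if (!file.exists(ls_path)) {
    stop("missing input: run 'infer-landscape' first (need landscape.tsv)")
  }
  fit <- read_landscape_tsv(ls_path)
  ds <- pl_load_dataset(out_dir)
  seeded <- Filter(function(s) s$compartment == "seeded", ds$samples)
  rows <- lapply(seeded, function(s) {
    z <- log10_transform(s)
    rep <- price_shifts(z, landscape_value(fit, z), n_boot = 200L,
                        seed = child_seed(cfg$seed,
                                          sprintf("sel%.6g_%d", s$dose,
                                                  s$replicate)))
    data.frame(dose = s$dose, replicate = s$replicate,
               delta_mean = rep$delta_mean, delta_var = rep$delta_var,
               se_mean = rep$se_mean, se_var = rep$se_var,
               mode = as.character(rep$mode))
  })
  df <- do.call(rbind, c(rows, make.row.names = FALSE))
  df <- df[order(df$dose, df$replicate), ]
  path <- file.path(out_dir, "selection.tsv")
  num <- vapply(df, is.numeric, TRUE) & !(names(df) %in% c("dose", "replicate"))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(list(selection = path))
}

pl_respond <- function(cfg, out_dir) {
  hm <- hemin_model(cfg$hemin$delta0, cfg$hemin$k_h)
  spec <- config_clone(cfg)
  mappings <- lapply(cfg$hemin$mappings, function(m) {
    hemin_dose_for_target(hm, spec, m$d_from, m$d_to)
  })
  ip <- iffl_params(beta = cfg$iffl$beta, K_act = cfg$iffl$K_act,
                    n_act = cfg$iffl$n_act, K_rep = cfg$iffl$K_rep,
                    n_rep = cfg$iffl$n_rep, basal = cfg$iffl$basal)
  ext <- iffl_extrema(ip)
  h_grid <- c(0, 0.5, 1, 2, 5, 10, 20, 50)
  out <- list(hemin = list(delta0 = hm$delta0, k_h = hm$k_h,
                           fraction_remaining = stats::setNames(
                             fraction_remaining(hm, h_grid),
                             paste0("h_", h_grid)),
                           mappings = mappings),
              iffl = list(params = unclass(ip), monotone = ext$monotone,
                          direction = ext$direction, extrema = ext$extrema))
  path <- file.path(out_dir, "respond.json")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(list(respond = path))
}

pl_metrics <- function(cfg, out_dir) {
  counts <- cfg$metrics$counts_tsv
  if (is.null(counts)) stop("config$metrics$counts_tsv is required for 'metrics'")
  path <- file.path(out_dir, "invasiveness_metrics.tsv")
  invasiveness_table(counts, out = path)
  invisible(list(metrics = path))
}

pl_report <- function(cfg, out_dir) {
  need <- c(landscape = "landscape.tsv",
            diagnostics = "landscape_diagnostics.json",
            selection = "selection.tsv")
  paths <- file.path(out_dir, need)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing input artifact(s): ", paste(need[missing], collapse = ", "),
         " — run the earlier pipeline steps first")
  }
  fit <- read_landscape_tsv(paths[1])
  diag <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
  sel <- utils::read.table(paths[3], header = TRUE, sep = "\t")
  report <- list(
    seed = cfg$seed,
    landscape = list(z = fit$z_grid, w = fit$w,
                     support = fit$support_mask, diagnostics = diag),
    selection_modes = stats::aggregate(mode ~ dose, sel,
                                       function(m) names(sort(table(m),
                                                              decreasing = TRUE))[1]),
    mean_abs_delta_mean = mean(abs(sel$delta_mean)))
  path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(list(report = path))
}
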
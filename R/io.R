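# Cohort/config readers and writers, run manifests, and the command
# functions behind the shell front end (inst/cli/mrhet).

#' Read and write simulation configurations
#'
#' Configurations are stored as flat key: value maps in YAML or JSON
#' (chosen by file extension), with keys exactly the [sim_config()] field
#' names. Unknown keys are rejected so typos fail loudly.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @param cfg A `sim_config`.
#' @return `read_sim_config()` returns a validated `sim_config`;
#'   `write_sim_config()` returns `path` invisibly.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  # YAML 1.1 reads a bare key `n` as boolean FALSE; map it back
  if ("FALSE" %in% names(raw) && !"n" %in% names(raw)) {
    names(raw)[names(raw) == "FALSE"] <- "n"
  }
  defaults <- sim_config()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(unclass(defaults), raw)
  validate_sim_config(cfg)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  cfg <- validate_sim_config(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(unclass(cfg), path)
  }
  invisible(path)
}

# Serialize numerics at 17 significant digits so write-then-read
# round-trips doubles exactly.
format_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}

#' Read and write cohort CSV files
#'
#' Cohorts are stored as UTF-8 comma-separated files with a mandatory header
#' `y,s,g,g2[,...]`; latent-truth columns (`u`, `s_if_g1`, `s_if_g0`,
#' `y_s1`, `y_s0`) are included when present. Doubles are written with 17
#' significant digits, so a write/read round trip reproduces every value
#' exactly. Missing values in required columns are an error (complete-case
#' contract).
#'
#' @param cohort A `cohort` or compatible data.frame.
#' @param path CSV file path.
#' @param dichotomize_g If `TRUE`, an allele-count `g` column in \{0,1,2\}
#'   is collapsed to carrier status (\{1,2\} become 1) on read.
#' @return `read_cohort()` returns a `cohort`; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  out <- as.data.frame(lapply(df, format_full), stringsAsFactors = FALSE)
  names(out) <- names(df)
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, dichotomize_g = FALSE) {
  if (!file.exists(path)) {
    stop("cohort file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, header = TRUE, fileEncoding = "UTF-8")
  if (dichotomize_g) {
    if (!"g" %in% names(df)) {
      stop("cohort is missing required column 'g'", call. = FALSE)
    }
    if (!all(df$g %in% c(0, 1, 2))) {
      stop("--dichotomize-g expects allele counts in {0,1,2}", call. = FALSE)
    }
    df$g <- as.integer(df$g >= 1)
  }
  as_cohort(df)
}

#' Serialize estimator output to a tidy table
#'
#' One row per (tag, parameter) with `estimate`, `se`, `ci_low`, `ci_high`,
#' `p_value` — the common exchange format written by [cmd_estimate()].
#'
#' @param est A `group_effects` or `scalar_estimate`.
#' @return A data.frame.
#' @export
tidy_estimate <- function(est) {
  as.data.frame(est)
}

write_manifest <- function(path, command, config, params, seeds, outputs) {
  manifest <- list(
    command = command,
    config = config,
    parameters = params,
    seeds = seeds,
    package_version = as.character(utils::packageVersion("mrhet")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

log_info <- function(...) {
  message(sprintf("[mrhet] %s", sprintf(...)))
}

#' Command: simulate a cohort to CSV
#'
#' Reads a simulation config, simulates the cohort, writes it as CSV and a
#' JSON run manifest next to it (`<out>.manifest.json`). Deterministic:
#' identical config (including seed) yields byte-identical CSVs.
#'
#' @param config_path Path to a YAML/JSON [sim_config()] file.
#' @param out_path Output CSV path.
#' @param seed Optional seed override.
#' @return Invisibly, the output path.
#' @export
cmd_simulate <- function(config_path, out_path, seed = NULL) {
  cfg <- read_sim_config(config_path)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cohort <- simulate_cohort(cfg)
  write_cohort(cohort, out_path)
  write_manifest(paste0(out_path, ".manifest.json"),
                 command = "simulate", config = config_path,
                 params = unclass(cfg), seeds = cfg$seed,
                 outputs = out_path)
  log_info("simulated cohort of n=%d to %s", cfg$n, out_path)
  invisible(out_path)
}

#' Command: run one estimator on a cohort CSV
#'
#' @param cohort_path Path to a cohort CSV.
#' @param method One of `"method1"`, `"method2"`, `"rgmee"`, `"gmee1"`,
#'   `"gmee0"`, `"standard_mr"`, `"observational"`.
#' @param out_path Output CSV path for the tidy estimate table.
#' @param covariates_s,covariates_y Covariate column names for the exposure
#'   and outcome models.
#' @param dichotomize_g Collapse an allele-count `g` column to carrier status.
#' @param link First-stage link for the two-stage methods.
#' @return Invisibly, the tidy results data.frame.
#' @export
cmd_estimate <- function(cohort_path, method, out_path,
                         covariates_s = NULL, covariates_y = NULL,
                         dichotomize_g = FALSE, link = "logistic") {
  cohort <- read_cohort(cohort_path, dichotomize_g = dichotomize_g)
  est <- withCallingHandlers(
    switch(method,
      method1 = method1(cohort, covariates_s, covariates_y, link = link),
      method2 = method2(cohort, covariates_s, covariates_y, link = link),
      rgmee = rgmee(cohort),
      gmee1 = gmee_exposed(cohort),
      gmee0 = gmee_unexposed(cohort),
      standard_mr = standard_mr(cohort, "g2", covariates = covariates_y,
                                link = link),
      observational = observational(cohort, covariates_y),
      stop("unknown method: ", method, call. = FALSE)
    ),
    warning = function(w) {
      log_info("warning: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  tidy <- tidy_estimate(est)
  utils::write.csv(tidy, out_path, row.names = FALSE)
  write_manifest(paste0(out_path, ".manifest.json"),
                 command = "estimate", config = cohort_path,
                 params = list(method = method,
                               covariates_s = covariates_s,
                               covariates_y = covariates_y,
                               dichotomize_g = dichotomize_g),
                 seeds = NULL, outputs = out_path)
  log_info("wrote %s estimate to %s", method, out_path)
  invisible(tidy)
}

read_study_scenario <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$study)) {
    stop("scenario file must contain a 'study' block", call. = FALSE)
  }
  base_keys <- setdiff(names(raw), "study")
  defaults <- sim_config()
  unknown <- setdiff(base_keys, names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base <- validate_sim_config(utils::modifyList(unclass(defaults),
                                                raw[base_keys]))
  st <- raw$study
  scn <- study_scenario(
    base,
    sample_sizes = st$sample_sizes,
    n_reps = st$n_reps,
    methods = if (is.null(st$methods)) c("method1", "method2") else
      unlist(st$methods),
    master_seed = if (is.null(st$master_seed)) 1L else
      as.integer(st$master_seed)
  )
  scn$truth <- list(beta1 = base$beta1, beta0 = base$beta0,
                    diff = base$beta1 - base$beta0)
  scn$diffs <- if (!is.null(st$diffs)) unlist(st$diffs)
  scn
}

#' Command: run a replicate study from a scenario file
#'
#' The scenario file is the [sim_config()] dialect plus a nested `study`
#' block with `sample_sizes`, `n_reps`, optional `methods` and
#' `master_seed`. Writes `replicates.csv`, `summary.csv` and a manifest to
#' `out_dir`.
#'
#' @param scenario_path Path to the scenario YAML/JSON.
#' @param out_dir Output directory (created if needed).
#' @param seed Optional master-seed override.
#' @return Invisibly, the `study_summary` data.frame.
#' @export
cmd_study <- function(scenario_path, out_dir, seed = NULL) {
  scn <- read_study_scenario(scenario_path)
  if (!is.null(seed)) scn$master_seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reps <- run_replicates(scn)
  truth <- scn$truth
  if ("standard_mr" %in% scn$methods) {
    # the ACE implied by the generating parameters and E[G | S = 1]
    mom <- exposure_moments(scn$base)
    p_s <- scn$base$p_g * mom[["e_s_g1"]] + (1 - scn$base$p_g) * mom[["e_s_g0"]]
    p_g_s1 <- scn$base$p_g * mom[["e_s_g1"]] / p_s
    truth$ace <- ace_identity(scn$base$beta0,
                              scn$base$beta1 - scn$base$beta0, p_g_s1)
  }
  smry <- summarize_study(reps, truth)
  rep_path <- file.path(out_dir, "replicates.csv")
  sum_path <- file.path(out_dir, "summary.csv")
  utils::write.csv(reps, rep_path, row.names = FALSE)
  utils::write.csv(smry, sum_path, row.names = FALSE)
  write_manifest(file.path(out_dir, "manifest.json"),
                 command = "study", config = scenario_path,
                 params = list(sample_sizes = scn$sample_sizes,
                               n_reps = scn$n_reps, methods = scn$methods),
                 seeds = scn$master_seed,
                 outputs = c(rep_path, sum_path))
  log_info("study written to %s", out_dir)
  invisible(smry)
}

#' Command: power curve from a scenario file
#'
#' Uses the scenario's `study` block; the `diffs` entry gives the grid of
#' true differences. Writes `power_curve.csv` and a manifest.
#'
#' @inheritParams cmd_study
#' @return Invisibly, the power-curve data.frame.
#' @export
cmd_power_curve <- function(scenario_path, out_dir, seed = NULL) {
  scn <- read_study_scenario(scenario_path)
  if (is.null(scn$diffs)) {
    stop("scenario 'study' block must contain 'diffs' for a power curve",
         call. = FALSE)
  }
  if (!is.null(seed)) scn$master_seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pc <- power_curve(scn$base, diffs = scn$diffs,
                    sample_sizes = scn$sample_sizes, n_reps = scn$n_reps,
                    methods = intersect(scn$methods,
                                        c("method1", "method2", "rgmee")),
                    master_seed = scn$master_seed)
  out_path <- file.path(out_dir, "power_curve.csv")
  utils::write.csv(pc, out_path, row.names = FALSE)
  write_manifest(file.path(out_dir, "manifest.json"),
                 command = "power-curve", config = scenario_path,
                 params = list(diffs = scn$diffs,
                               sample_sizes = scn$sample_sizes,
                               n_reps = scn$n_reps, methods = scn$methods),
                 seeds = scn$master_seed,
                 outputs = out_path)
  log_info("power curve written to %s", out_path)
  invisible(pc)
}
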
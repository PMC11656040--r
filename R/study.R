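# Monte-Carlo study engine: replicate runner, Morris-style summaries
# (bias, power, coverage with Monte-Carlo standard errors), power curves.

#' Define a simulation-study scenario
#'
#' @param base A [sim_config()] giving the data-generating process; its `n`
#'   and `seed` are overridden per replicate.
#' @param sample_sizes Strictly increasing vector of cohort sizes.
#' @param n_reps Number of replicates per sample size (>= 2).
#' @param methods Subset of `c("method1", "method2", "rgmee", "standard_mr")`.
#' @param master_seed Integer master seed; per-replicate seeds are derived
#'   deterministically from `(master_seed, n, replicate)` so any subset of
#'   the grid is reproducible on its own.
#' @return Object of class `study_scenario`.
#' @export
study_scenario <- function(base, sample_sizes, n_reps,
                           methods = c("method1", "method2"),
                           master_seed = 1L) {
  base <- validate_sim_config(base)
  methods <- match.arg(methods,
                       c("method1", "method2", "rgmee", "standard_mr"),
                       several.ok = TRUE)
  if (length(sample_sizes) < 1L || any(sample_sizes < 1) ||
      any(sample_sizes != floor(sample_sizes))) {
    stop("sample_sizes must be positive integers", call. = FALSE)
  }
  if (is.unsorted(sample_sizes, strictly = TRUE)) {
    stop("sample_sizes must be strictly increasing", call. = FALSE)
  }
  if (length(n_reps) != 1L || n_reps < 2 || n_reps != floor(n_reps)) {
    stop("n_reps must be an integer >= 2", call. = FALSE)
  }
  structure(
    list(base = base, sample_sizes = as.integer(sample_sizes),
         n_reps = as.integer(n_reps), methods = methods,
         master_seed = as.integer(master_seed)),
    class = "study_scenario"
  )
}

# Deterministic child seed in [1, 2^31 - 2] from (master_seed, n, replicate).
# Splittable: depends only on its own coordinates, so grid subsets are
# independently reproducible. Arithmetic stays below 2^53 (exact in doubles).
child_seed <- function(master_seed, n, replicate) {
  m <- 2147483647                       # 2^31 - 1, prime
  h <- (abs(master_seed) %% m)
  h <- (h * 48271 + (n %% m)) %% m
  h <- (h * 48271 + (replicate %% m)) %% m
  as.integer(h %% (m - 1) + 1)
}

apply_method <- function(method, cohort, covariates_s, covariates_y) {
  est <- switch(method,
    method1 = method1(cohort, covariates_s, covariates_y),
    method2 = suppressWarnings(method2(cohort, covariates_s, covariates_y)),
    rgmee = rgmee(cohort),
    standard_mr = suppressWarnings(
      standard_mr(cohort, "g2", covariates = covariates_y)),
    stop("unknown method: ", method, call. = FALSE)
  )
  df <- as.data.frame(est)
  if (inherits(est, "scalar_estimate")) {
    df$parameter <- if (method == "rgmee") "diff" else "ace"
    df$tag <- method
  }
  df
}

#' Run replicated simulations and apply estimators
#'
#' For each sample size and replicate, derives a child seed from
#' `(master_seed, n, replicate)`, simulates a cohort from the scenario's base
#' configuration, applies every requested method, and records point
#' estimates, standard errors, nominal 95% confidence limits and two-sided
#' Wald p-values in a long table keyed by
#' `(method, parameter, n, replicate)`. Fit failures are caught, excluded,
#' and reported in the `"failures"` attribute; any `(method, n)` cell with
#' more than 1% failures is listed in the `"flagged"` attribute.
#'
#' @param scn A [study_scenario()].
#' @param covariates_s,covariates_y Optional covariate names forwarded to the
#'   estimators.
#' @return A data.frame of class `replicate_table` with columns `method`,
#'   `parameter`, `n`, `replicate`, `estimate`, `se`, `ci_low`, `ci_high`,
#'   `p_value`.
#' @export
run_replicates <- function(scn, covariates_s = NULL, covariates_y = NULL) {
  stopifnot(inherits(scn, "study_scenario"))
  rows <- vector("list", length(scn$sample_sizes) * scn$n_reps)
  failures <- list()
  k <- 0L
  for (n in scn$sample_sizes) {
    cfg <- scn$base
    cfg$n <- n
    for (r in seq_len(scn$n_reps)) {
      cfg$seed <- child_seed(scn$master_seed, n, r)
      cohort <- simulate_cohort(cfg)
      per_method <- lapply(scn$methods, function(m) {
        tryCatch({
          df <- apply_method(m, cohort, covariates_s, covariates_y)
          df$method <- m
          df
        }, error = function(e) {
          failures[[length(failures) + 1L]] <<- data.frame(
            method = m, n = n, replicate = r,
            message = conditionMessage(e))
          NULL
        })
      })
      per_method <- per_method[!vapply(per_method, is.null, logical(1))]
      if (length(per_method) > 0L) {
        df <- do.call(rbind, per_method)
        df$n <- n
        df$replicate <- r
        k <- k + 1L
        rows[[k]] <- df
      }
    }
  }
  out <- if (k > 0L) {
    do.call(rbind, rows[seq_len(k)])
  } else {
    data.frame(method = character(), parameter = character(), n = integer(),
               replicate = integer(), estimate = numeric(), se = numeric(),
               ci_low = numeric(), ci_high = numeric(), p_value = numeric())
  }
  out <- out[, c("method", "parameter", "n", "replicate",
                 "estimate", "se", "ci_low", "ci_high", "p_value")]
  rownames(out) <- NULL
  fail_df <- if (length(failures) > 0L) {
    do.call(rbind, failures)
  } else {
    data.frame(method = character(), n = integer(), replicate = integer(),
               message = character())
  }
  flagged <- character()
  if (nrow(fail_df) > 0L) {
    counts <- stats::aggregate(replicate ~ method + n, data = fail_df,
                               FUN = length)
    bad <- counts[counts$replicate > 0.01 * scn$n_reps, , drop = FALSE]
    if (nrow(bad) > 0L) {
      flagged <- sprintf("%s@n=%d", bad$method, bad$n)
      warning("scenario flagged invalid: >1% fit failures in cell(s) ",
              paste(flagged, collapse = ", "), call. = FALSE)
    }
  }
  attr(out, "failures") <- fail_df
  attr(out, "flagged") <- flagged
  attr(out, "n_reps") <- scn$n_reps
  class(out) <- c("replicate_table", "data.frame")
  out
}

#' Summarize replicate estimates into bias, power and coverage
#'
#' Per `(method, parameter, n)` cell, computes the mean estimate, bias
#' against the supplied truth, empirical SD across replicates, power of the
#' two-sided 5% Wald test, and empirical coverage of the nominal 95%
#' confidence intervals, each with its Monte-Carlo standard error:
#' `mcse_bias = sd/sqrt(R)` and `mcse = sqrt(p(1-p)/R)` for the proportions.
#'
#' @param replicates A `replicate_table` from [run_replicates()].
#' @param truth Named list/vector of true values, one entry per parameter
#'   present in `replicates` (e.g. `list(beta1 = -200, beta0 = -100,
#'   diff = -100)`).
#' @param alpha Significance level of the power test (default 0.05).
#' @return A data.frame of class `study_summary` with one row per cell and
#'   columns `mean_estimate`, `bias`, `empirical_sd`, `mcse_bias`, `power`,
#'   `mcse_power`, `coverage`, `mcse_coverage`, `n_reps_used`, `n_failed`,
#'   `flagged`.
#' @export
summarize_study <- function(replicates, truth, alpha = 0.05) {
  stopifnot(is.data.frame(replicates))
  params <- unique(replicates$parameter)
  missing <- setdiff(params, names(truth))
  if (length(missing) > 0L) {
    stop("truth is missing component(s) for parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fail_df <- attr(replicates, "failures")
  flagged <- attr(replicates, "flagged")
  if (is.null(flagged)) flagged <- character()
  cells <- unique(replicates[, c("method", "parameter", "n")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    sub <- replicates[replicates$method == cell$method &
                      replicates$parameter == cell$parameter &
                      replicates$n == cell$n, ]
    R <- nrow(sub)
    if (R < 2L) {
      stop(sprintf("fewer than 2 successful replicates for %s/%s at n=%d",
                   cell$method, cell$parameter, cell$n), call. = FALSE)
    }
    tv <- truth[[cell$parameter]]
    mean_est <- mean(sub$estimate)
    emp_sd <- stats::sd(sub$estimate)
    power <- mean(sub$p_value < alpha)
    coverage <- mean(sub$ci_low <= tv & tv <= sub$ci_high)
    n_failed <- if (!is.null(fail_df)) {
      sum(fail_df$method == cell$method & fail_df$n == cell$n)
    } else 0L
    data.frame(
      method = cell$method, parameter = cell$parameter, n = cell$n,
      mean_estimate = mean_est, bias = mean_est - tv,
      empirical_sd = emp_sd, mcse_bias = emp_sd / sqrt(R),
      power = power, mcse_power = sqrt(power * (1 - power) / R),
      coverage = coverage,
      mcse_coverage = sqrt(coverage * (1 - coverage) / R),
      n_reps_used = R, n_failed = n_failed,
      flagged = sprintf("%s@n=%d", cell$method, cell$n) %in% flagged
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("study_summary", "data.frame")
  out
}

#' Power curve over effect differences and sample sizes
#'
#' For each requested true group-effect difference, sets
#' `beta1 = beta0 + diff` (holding `beta0` and everything else at the base
#' configuration) and estimates the power of the two-sided 5% Wald test of
#' the difference parameter for each method and sample size.
#'
#' @param base A [sim_config()]; `beta1` is overridden per grid point.
#' @param diffs Vector of true differences \eqn{\beta_1 - \beta_0} (grams).
#' @param sample_sizes Strictly increasing vector of cohort sizes.
#' @param n_reps Replicates per grid point (>= 2).
#' @param methods Methods reporting a `diff` parameter
#'   (`"method1"`, `"method2"`, `"rgmee"`).
#' @param master_seed Master seed (each diff offsets it deterministically).
#' @return Data.frame with columns `method`, `diff`, `n`, `power`,
#'   `mcse_power`, `n_reps_used`.
#' @export
power_curve <- function(base, diffs, sample_sizes, n_reps,
                        methods = c("method1", "method2"),
                        master_seed = 1L) {
  methods <- match.arg(methods, c("method1", "method2", "rgmee"),
                       several.ok = TRUE)
  out <- vector("list", length(diffs))
  for (i in seq_along(diffs)) {
    cfg <- base
    cfg$beta1 <- cfg$beta0 + diffs[i]
    scn <- study_scenario(cfg, sample_sizes, n_reps, methods,
                          master_seed = child_seed(master_seed, 1000003L, i))
    reps <- run_replicates(scn)
    reps <- reps[reps$parameter == "diff", ]
    truth <- list(diff = diffs[i])
    smry <- summarize_study(reps, truth)
    out[[i]] <- data.frame(
      method = smry$method, diff = diffs[i], n = smry$n,
      power = smry$power, mcse_power = smry$mcse_power,
      n_reps_used = smry$n_reps_used
    )
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
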
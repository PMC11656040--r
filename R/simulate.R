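#' @keywords internal
expit <- function(x) 1 / (1 + exp(-x))

#' Simulate a cohort from the linear interaction model
#'
#' Draws a cohort of `cfg$n` individuals from the data-generating process
#' described in [sim_config()]. Alongside the observed variables
#' (`y`, `s`, `g`, `g2` and the interaction `s_star = g * s`), the returned
#' table carries the latent ground truth needed by simulation oracles:
#' the confounder `u`, the potential exposures `s_if_g1` / `s_if_g0`
#' obtained by re-evaluating the exposure model with `G` forced to 1 / 0
#' while all noise draws are held fixed (the "same person, different allele"
#' counterfactual; `G`'s contribution to `U` switches with the forced value),
#' and the potential outcomes `y_s1` / `y_s0` under `S` set to 1 / 0.
#'
#' The whole draw is a deterministic function of `cfg` including its `seed`;
#' identical configurations give bit-identical cohorts.
#'
#' @param cfg A [sim_config()].
#' @param n_covariates Number of optional independent standard-normal measured
#'   covariates `z1..zk` to append. These are pure noise (not part of the
#'   structural model) and exist to exercise covariate-adjustment code paths.
#' @return A `cohort`: a data.frame with columns
#'   `y, s, g, g2, s_star, u, s_if_g1, s_if_g0, y_s1, y_s0` (and `z*` if
#'   requested), with the generating `sim_config` attached as attribute
#'   `"config"`.
#' @seealso [true_cace()], [wald_estimand()], [write_cohort()]
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n = 500, seed = 42))
#' mean(cohort$s)          # exposure prevalence
#' attr(cohort, "config")$beta1
simulate_cohort <- function(cfg, n_covariates = 0L) {
  cfg <- validate_sim_config(cfg)
  n <- cfg$n
  set.seed(cfg$seed)

  g  <- rbinom(n, 1L, cfg$p_g)
  g2 <- rbinom(n, 1L, cfg$p_g2)
  eps_u   <- rnorm(n)
  eps_eta <- rnorm(n, 0, cfg$sd_eta)
  u_s     <- runif(n)                    # shared uniform for the exposure draw
  eps_y   <- rnorm(n, 0, cfg$sd_y)

  u <- cfg$gamma_ug * g + eps_u

  eta_at <- function(g_val) {
    u_at <- cfg$gamma_ug * g_val + eps_u
    cfg$eta0 + cfg$gamma_sg * g_val + cfg$gamma_sg2 * g2 +
      cfg$gamma_su * u_at + eps_eta
  }
  s_if_g1 <- as.integer(u_s < expit(eta_at(1)))
  s_if_g0 <- as.integer(u_s < expit(eta_at(0)))
  s <- ifelse(g == 1L, s_if_g1, s_if_g0)

  y_at <- function(s_val) {
    cfg$y0 + cfg$beta1 * s_val * g + cfg$beta0 * s_val * (1 - g) +
      cfg$gamma_yg * g + cfg$gamma_yu * u + eps_y
  }
  y_s1 <- y_at(1)
  y_s0 <- y_at(0)
  y <- ifelse(s == 1L, y_s1, y_s0)

  cohort <- data.frame(
    y = y, s = s, g = g, g2 = g2, s_star = g * s,
    u = u, s_if_g1 = s_if_g1, s_if_g0 = s_if_g0, y_s1 = y_s1, y_s0 = y_s0
  )
  if (n_covariates > 0L) {
    z <- matrix(rnorm(n * n_covariates), nrow = n)
    colnames(z) <- paste0("z", seq_len(n_covariates))
    cohort <- cbind(cohort, as.data.frame(z))
  }
  attr(cohort, "config") <- cfg
  class(cohort) <- c("cohort", "data.frame")
  cohort
}

#' Coerce a data.frame to a cohort
#'
#' Validates the column contract shared by all estimators: `y` numeric,
#' `s` and `g` binary in \{0, 1\}, `g2` numeric (binary when simulated, but a
#' real-valued genetic risk score is allowed on CSV input). Latent-truth
#' columns (`u`, `s_if_g1`, `s_if_g0`, `y_s1`, `y_s0`) must be all present or
#' all absent. `s_star` is recomputed as `g * s` when missing.
#'
#' @param df A data.frame with at least columns `y`, `s`, `g`, `g2`.
#' @return A `cohort` data.frame.
#' @export
as_cohort <- function(df) {
  df <- as.data.frame(df)
  for (col in c("y", "s", "g", "g2")) {
    if (!col %in% names(df)) {
      stop("cohort is missing required column '", col, "'", call. = FALSE)
    }
    if (!is.numeric(df[[col]])) {
      stop("cohort column '", col, "' must be numeric", call. = FALSE)
    }
    if (anyNA(df[[col]])) {
      stop("cohort column '", col, "' contains missing values", call. = FALSE)
    }
  }
  for (col in c("s", "g")) {
    if (!all(df[[col]] %in% c(0, 1))) {
      stop("cohort column '", col, "' must be binary {0,1}", call. = FALSE)
    }
  }
  latent <- c("u", "s_if_g1", "s_if_g0", "y_s1", "y_s0")
  present <- latent %in% names(df)
  if (any(present) && !all(present)) {
    stop("latent-truth columns must be all present or all absent; missing: ",
         paste(latent[!present], collapse = ", "), call. = FALSE)
  }
  if (!"s_star" %in% names(df)) {
    df$s_star <- df$g * df$s
  }
  if (!inherits(df, "cohort")) class(df) <- c("cohort", "data.frame")
  df
}

#' @keywords internal
has_latent <- function(cohort) {
  all(c("u", "s_if_g1", "s_if_g0", "y_s1", "y_s0") %in% names(cohort))
}

#' Complier average causal effect from latent ground truth
#'
#' Computes the true complier average causal effect (CACE) in a simulated
#' cohort: the mean of the individual effects `y_s1 - y_s0` over compliers,
#' the individuals whose exposure tracks the moderator allele
#' (`s_if_g1 = 1` and `s_if_g0 = 0`). Monotonicity — the absence of defiers
#' with `s_if_g1 < s_if_g0` — is verified in the generated data, not assumed.
#'
#' @param cohort A simulated `cohort` carrying latent truth.
#' @return The CACE in grams.
#' @export
true_cace <- function(cohort) {
  cohort <- as_cohort(cohort)
  if (!has_latent(cohort)) {
    stop("true_cace requires a cohort with latent potential-outcome columns",
         call. = FALSE)
  }
  defiers <- cohort$s_if_g1 < cohort$s_if_g0
  if (any(defiers)) {
    stop("monotonicity violation: ", sum(defiers),
         " defier(s) present (s_if_g1 < s_if_g0)", call. = FALSE)
  }
  complier <- cohort$s_if_g1 == 1L & cohort$s_if_g0 == 0L
  if (!any(complier)) {
    stop("CACE is undefined: no compliers in cohort", call. = FALSE)
  }
  mean(cohort$y_s1[complier] - cohort$y_s0[complier])
}

#' Population exposure moments under a known data-generating process
#'
#' Computes \eqn{E[S | G = g]} for `g = 1, 0` under the configuration's
#' data-generating process, marginalising over `G2` and the Gaussian part of
#' the linear predictor. Given `G = g` and `G2 = g2` the linear predictor is
#' \eqn{m(g, g2) + N(0, \gamma_{SU}^2 + \sigma_\eta^2)} with
#' \eqn{m = \eta_0 + \gamma_{SG} g + \gamma_{SG2} g2 +
#' \gamma_{SU}\gamma_{UG} g}, so the moment is a two-point mixture of 1-D
#' logistic-normal integrals.
#'
#' @inheritParams wald_estimand
#' @return Named vector `c(e_s_g1, e_s_g0)`.
#' @export
exposure_moments <- function(cfg, backend = c("integrate", "mc"),
                             mc_n = 1e6, mc_seed = 20240901L) {
  cfg <- validate_sim_config(cfg)
  backend <- match.arg(backend)
  sigma <- sqrt(cfg$gamma_su^2 + cfg$sd_eta^2)
  mean_lp <- function(g, g2) {
    cfg$eta0 + cfg$gamma_sg * g + cfg$gamma_sg2 * g2 +
      cfg$gamma_su * cfg$gamma_ug * g
  }
  mc_z <- NULL
  if (backend == "mc") {
    rng_state <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(rng_state)) {
        assign(".Random.seed", rng_state, envir = globalenv())
      }
    })
    set.seed(mc_seed)
    mc_z <- rnorm(mc_n)
  }
  e_s_given_g <- function(g) {
    cell <- function(g2) {
      m <- mean_lp(g, g2)
      if (sigma == 0) return(expit(m))
      if (backend == "integrate") {
        stats::integrate(function(z) expit(m + sigma * z) * stats::dnorm(z),
                         lower = -Inf, upper = Inf,
                         rel.tol = 1e-10)$value
      } else {
        mean(expit(m + sigma * mc_z))
      }
    }
    (1 - cfg$p_g2) * cell(0) + cfg$p_g2 * cell(1)
  }
  c(e_s_g1 = e_s_given_g(1), e_s_g0 = e_s_given_g(0))
}

#' Population Wald-ratio decomposition under a known data-generating process
#'
#' Evaluates, at the population level implied by `cfg`, the decomposition of
#' the Wald ratio \eqn{Cov(G,Y)/Cov(G,S)} for the moderator variant `G` into
#' a causal ratio term and a bias term:
#' \deqn{\frac{\beta_1 E[S|G{=}1] - \beta_0 E[S|G{=}0]}
#'            {E[S|G{=}1] - E[S|G{=}0]} + B,\qquad
#'       B = \frac{\gamma_{YG} + \gamma_{YU}\,(E[U|G{=}1]-E[U|G{=}0])}
#'                {E[S|G{=}1] - E[S|G{=}0]}.}
#' Under monotonicity the ratio term equals the complier average causal
#' effect, so the Wald estimand is the CACE plus the bias `B` induced by
#' violations of independence (IV2) and exclusion (IV3).
#'
#' The conditional exposure moments \eqn{E[S|G{=}g]} have no closed form
#' (logistic-normal mixture); they are computed either by deterministic 1-D
#' numeric integration over the combined Gaussian
#' \eqn{\gamma_{SU} U + \epsilon_\eta} (default) or by large-n Monte Carlo
#' with an internal fixed seed. \eqn{E[U|G{=}1]-E[U|G{=}0]} is
#' \eqn{\gamma_{UG}} analytically.
#'
#' @param cfg A [sim_config()].
#' @param backend `"integrate"` (deterministic quadrature, default) or
#'   `"mc"` (Monte Carlo).
#' @param mc_n Number of Monte-Carlo draws for the `"mc"` backend.
#' @param mc_seed Internal seed for the `"mc"` backend; does not disturb the
#'   caller's RNG state.
#' @param tol Weak-instrument tolerance: error if
#'   `|E[S|G=1] - E[S|G=0]| < tol`.
#' @return An object of class `wald_decomposition`: list with elements
#'   `cace` (the ratio term), `bias` (B), `wald` (their sum), `e_s_g1`,
#'   `e_s_g0`, and `backend`.
#' @export
wald_estimand <- function(cfg, backend = c("integrate", "mc"),
                          mc_n = 1e6, mc_seed = 20240901L, tol = 1e-6) {
  cfg <- validate_sim_config(cfg)
  backend <- match.arg(backend)
  mom <- exposure_moments(cfg, backend = backend, mc_n = mc_n,
                          mc_seed = mc_seed)
  e_s_g1 <- mom[["e_s_g1"]]
  e_s_g0 <- mom[["e_s_g0"]]
  denom <- e_s_g1 - e_s_g0
  if (abs(denom) < tol) {
    stop("weak instrument: E[S|G=1] - E[S|G=0] = ",
         format(denom), " is below tolerance ", tol, call. = FALSE)
  }

  cace <- (cfg$beta1 * e_s_g1 - cfg$beta0 * e_s_g0) / denom
  bias <- (cfg$gamma_yg + cfg$gamma_yu * cfg$gamma_ug) / denom

  structure(
    list(cace = cace, bias = bias, wald = cace + bias,
         e_s_g1 = e_s_g1, e_s_g0 = e_s_g0, backend = backend),
    class = "wald_decomposition"
  )
}

#' @export
print.wald_decomposition <- function(x, ...) {
  cat("Wald-ratio decomposition for the moderator variant G\n")
  cat(sprintf("  E[S|G=1] = %.6f, E[S|G=0] = %.6f  (backend: %s)\n",
              x$e_s_g1, x$e_s_g0, x$backend))
  cat(sprintf("  ratio term (CACE under monotonicity): %10.3f g\n", x$cace))
  cat(sprintf("  bias term B (IV2/IV3 violations):     %10.3f g\n", x$bias))
  cat(sprintf("  Wald estimand:                        %10.3f g\n", x$wald))
  invisible(x)
}
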
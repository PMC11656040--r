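# Estimators for group-specific causal effects and genetically moderated
# exposure effects. All stage-2 standard errors are model-based (taken
# straight from the linear-model output, no first-stage correction); the
# simulation study validates their coverage.

# Least-squares fit from a model matrix; returns coefficients and their
# model-based covariance. Errors on rank deficiency, naming the column.
fast_lm <- function(X, y) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("collinear or constant regressor(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  xtx_inv <- chol2inv(chol(crossprod(X)))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  coefs <- drop(xtx_inv %*% crossprod(X, y))
  names(coefs) <- colnames(X)
  resid <- y - X %*% coefs
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(resid^2) / df
  list(coef = coefs, vcov = sigma2 * xtx_inv, sigma2 = sigma2, df = df)
}

covariate_matrix <- function(cohort, covariates) {
  if (is.null(covariates) || length(covariates) == 0L) {
    return(NULL)
  }
  missing <- setdiff(covariates, names(cohort))
  if (length(missing) > 0L) {
    stop("cohort is missing covariate column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  as.matrix(cohort[, covariates, drop = FALSE])
}

#' First-stage exposure model
#'
#' Fits the probability of exposure given genetic instruments and measured
#' covariates, \eqn{E[S \mid \mathrm{instruments}, Z]}, by logistic regression
#' (default) or a linear probability model. Reports a per-instrument Wald
#' table including an F statistic (the squared z statistic for a single
#' coefficient), the conventional instrument-strength diagnostic.
#'
#' @param cohort A `cohort` (or data.frame coercible via [as_cohort()]).
#' @param instruments Character vector of instrument column names (e.g.
#'   `c("g", "g2")`).
#' @param covariates Optional character vector of covariate column names.
#' @param link `"logistic"` (default) or `"linear"`.
#' @return Object of class `first_stage_fit`: list with `fitted_probs`,
#'   `coefficient_table` (one row per instrument: estimate, se, statistic,
#'   p_value, f_statistic), `instruments_used`, `link`, `n`.
#' @export
first_stage <- function(cohort, instruments, covariates = NULL,
                        link = c("logistic", "linear")) {
  cohort <- as_cohort(cohort)
  link <- match.arg(link)
  if (length(instruments) == 0L) {
    stop("at least one instrument must be supplied", call. = FALSE)
  }
  missing <- setdiff(instruments, names(cohort))
  if (length(missing) > 0L) {
    stop("cohort is missing instrument column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  Z <- covariate_matrix(cohort, covariates)
  X <- cbind(`(Intercept)` = 1, as.matrix(cohort[, instruments, drop = FALSE]))
  if (!is.null(Z)) X <- cbind(X, Z)

  if (link == "linear") {
    fit <- fast_lm(X, cohort$s)
    est <- fit$coef
    se <- sqrt(diag(fit$vcov))
    fitted_probs <- drop(X %*% fit$coef)
  } else {
    fit <- withCallingHandlers(
      stats::glm.fit(X, cohort$s, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          stop("first-stage fit failure: perfect or quasi-perfect separation",
               call. = FALSE)
        }
        invokeRestart("muffleWarning")
      }
    )
    if (!fit$converged) {
      stop("first-stage fit failure: logistic regression did not converge",
           call. = FALSE)
    }
    if (any(fit$fitted.values < 1e-7) || any(fit$fitted.values > 1 - 1e-7)) {
      stop("first-stage fit failure: perfect or quasi-perfect separation",
           call. = FALSE)
    }
    est <- fit$coefficients
    # model-based covariance from the IRLS weighted cross-product
    w <- fit$weights
    xtwx <- crossprod(X * sqrt(w))
    se <- sqrt(diag(chol2inv(chol(xtwx))))
    names(se) <- names(est)
    fitted_probs <- fit$fitted.values
  }

  z <- est[instruments] / se[instruments]
  coefficient_table <- data.frame(
    term = instruments,
    estimate = unname(est[instruments]),
    se = unname(se[instruments]),
    statistic = unname(z),
    p_value = unname(2 * stats::pnorm(-abs(z))),
    f_statistic = unname(z^2),
    row.names = NULL
  )
  structure(
    list(fitted_probs = fitted_probs, coefficient_table = coefficient_table,
         instruments_used = instruments, link = link, n = nrow(cohort)),
    class = "first_stage_fit"
  )
}

#' @export
print.first_stage_fit <- function(x, ...) {
  cat(sprintf("First-stage exposure model (%s link, n = %d)\n", x$link, x$n))
  print(x$coefficient_table, row.names = FALSE)
  invisible(x)
}

scalar_estimate <- function(value, se, estimand_tag, n_used) {
  p <- if (se > 0) {
    2 * stats::pnorm(-abs(value / se))
  } else if (value == 0) 1 else 0
  structure(
    list(value = value, se = se,
         ci_low = value - 1.96 * se, ci_high = value + 1.96 * se,
         p_value = p,
         estimand_tag = estimand_tag, n_used = n_used),
    class = "scalar_estimate"
  )
}

#' @export
print.scalar_estimate <- function(x, ...) {
  cat(sprintf("%s: %.2f g (SE %.2f, 95%% CI [%.2f, %.2f], p = %.3g, n = %d)\n",
              x$estimand_tag, x$value, x$se, x$ci_low, x$ci_high,
              x$p_value, x$n_used))
  invisible(x)
}

#' @export
as.data.frame.scalar_estimate <- function(x, ...) {
  data.frame(tag = x$estimand_tag, parameter = x$estimand_tag,
             estimate = x$value, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, p_value = x$p_value)
}

cell_stats <- function(cohort, s_val, g_val) {
  idx <- cohort$s == s_val & cohort$g == g_val
  n <- sum(idx)
  if (n == 0L) {
    stop(sprintf("empty cell: no records with S=%d, G=%d", s_val, g_val),
         call. = FALSE)
  }
  y <- cohort$y[idx]
  list(mean = mean(y), var = if (n > 1L) stats::var(y) else 0, n = n)
}

#' Genetically moderated exposure effect estimators (GMEE family)
#'
#' Between-genotype outcome-mean contrasts:
#' `gmee_exposed()` estimates
#' \eqn{\mathrm{GMEE}(1) = \hat E[Y|S{=}1,G{=}1] - \hat E[Y|S{=}1,G{=}0]}
#' among the exposed; `gmee_unexposed()` the analogous
#' \eqn{\mathrm{GMEE}(0)} contrast among the unexposed, which captures any
#' direct (pleiotropic) effect of `G` on `Y`; and
#' `rgmee() = gmee_exposed() - gmee_unexposed()` is the robust estimator of
#' the effect difference \eqn{\beta_1 - \beta_0}: unbiased under a
#' pleiotropic `G`, but it requires `G` independent of the exposure and of
#' the confounders — a G–S association test is an important prerequisite
#' for its use (see the eligibility gate in [method2()]).
#'
#' Standard errors come from within-cell variances:
#' \eqn{\sqrt{s_1^2/n_1 + s_0^2/n_0}} for each contrast, combined in
#' quadrature for the RGMEE.
#'
#' @param cohort A `cohort` or compatible data.frame.
#' @return A `scalar_estimate` with tag `gmee1`, `gmee0` or `rgmee`.
#' @export
gmee_exposed <- function(cohort) {
  cohort <- as_cohort(cohort)
  c1 <- cell_stats(cohort, 1L, 1L)
  c0 <- cell_stats(cohort, 1L, 0L)
  scalar_estimate(c1$mean - c0$mean, sqrt(c1$var / c1$n + c0$var / c0$n),
                  "gmee1", c1$n + c0$n)
}

#' @rdname gmee_exposed
#' @export
gmee_unexposed <- function(cohort) {
  cohort <- as_cohort(cohort)
  c1 <- cell_stats(cohort, 0L, 1L)
  c0 <- cell_stats(cohort, 0L, 0L)
  scalar_estimate(c1$mean - c0$mean, sqrt(c1$var / c1$n + c0$var / c0$n),
                  "gmee0", c1$n + c0$n)
}

#' @rdname gmee_exposed
#' @export
rgmee <- function(cohort) {
  cohort <- as_cohort(cohort)
  e1 <- gmee_exposed(cohort)
  e0 <- gmee_unexposed(cohort)
  out <- scalar_estimate(e1$value - e0$value, sqrt(e1$se^2 + e0$se^2),
                         "rgmee", nrow(cohort))
  out
}

group_effects <- function(beta1_hat, beta0_hat, diff_hat,
                          se_beta1, se_beta0, se_diff,
                          cov_b1_b0, method_tag, n_used, first_stage = NULL) {
  structure(
    list(beta1_hat = beta1_hat, beta0_hat = beta0_hat, diff_hat = diff_hat,
         se_beta1 = se_beta1, se_beta0 = se_beta0, se_diff = se_diff,
         cov_b1_b0 = cov_b1_b0, method_tag = method_tag, n_used = n_used,
         first_stage = first_stage),
    class = "group_effects"
  )
}

#' @export
print.group_effects <- function(x, ...) {
  cat(sprintf("Group-specific causal effects (%s, n = %d)\n",
              x$method_tag, x$n_used))
  df <- as.data.frame(x)
  print(df[, c("parameter", "estimate", "se", "ci_low", "ci_high", "p_value")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.group_effects <- function(x, ...) {
  est <- c(x$beta1_hat, x$beta0_hat, x$diff_hat)
  se <- c(x$se_beta1, x$se_beta0, x$se_diff)
  z <- est / se
  data.frame(
    tag = x$method_tag,
    parameter = c("beta1", "beta0", "diff"),
    estimate = est, se = se,
    ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
    p_value = 2 * stats::pnorm(-abs(z))
  )
}

#' Method 1: joint two-stage estimation with both variants
#'
#' Uses the moderator variant `G` and the standard instrument `G2` jointly.
#' Stage 1 predicts the exposure from both variants (plus covariates);
#' stage 2 regresses the outcome on \eqn{\hat S G} and \eqn{\hat S (1-G)}:
#' \deqn{Y = \gamma_0 + \beta_1 \hat S G + \beta_0 \hat S (1-G)}
#' so the two coefficients are the group-specific causal effects. Consistent
#' when `G` satisfies independence (IV2) and exclusion (IV3); `G` may predict
#' the exposure. Biased when `G` has a direct pleiotropic outcome effect.
#' The difference \eqn{\beta_1-\beta_0} and its standard error come from the
#' stage-2 coefficient covariance:
#' \eqn{SE^2 = SE_1^2 + SE_0^2 - 2\,\mathrm{cov}(\hat\beta_1,\hat\beta_0)}.
#'
#' @param cohort A `cohort` with columns `g` and `g2`.
#' @param covariates_s Covariate names for the exposure (stage 1) model.
#' @param covariates_y Covariate names for the outcome (stage 2) model.
#' @param link First-stage link, `"logistic"` (default) or `"linear"`.
#' @return A `group_effects` with `method_tag = "method1"`.
#' @seealso [method2()], [standard_mr()]
#' @export
method1 <- function(cohort, covariates_s = NULL, covariates_y = NULL,
                    link = "logistic") {
  cohort <- as_cohort(cohort)
  fs <- first_stage(cohort, c("g", "g2"), covariates_s, link)
  shat <- fs$fitted_probs
  X <- cbind(`(Intercept)` = 1,
             shat_g = shat * cohort$g,
             shat_1mg = shat * (1 - cohort$g))
  for (col in c("shat_g", "shat_1mg")) {
    if (stats::var(X[, col]) == 0) {
      stop("collinear or constant regressor(s): ", col, call. = FALSE)
    }
  }
  Z <- covariate_matrix(cohort, covariates_y)
  if (!is.null(Z)) X <- cbind(X, Z)
  fit <- fast_lm(X, cohort$y)
  b1 <- fit$coef[["shat_g"]]
  b0 <- fit$coef[["shat_1mg"]]
  v <- fit$vcov[c("shat_g", "shat_1mg"), c("shat_g", "shat_1mg")]
  se_diff <- sqrt(v[1, 1] + v[2, 2] - 2 * v[1, 2])
  group_effects(
    beta1_hat = b1, beta0_hat = b0, diff_hat = b1 - b0,
    se_beta1 = sqrt(v[1, 1]), se_beta0 = sqrt(v[2, 2]), se_diff = se_diff,
    cov_b1_b0 = v[1, 2], method_tag = "method1", n_used = nrow(cohort),
    first_stage = fs
  )
}

#' Method 2: RGMEE plus MR on the deactivated-interaction outcome
#'
#' A three-step procedure that tolerates a pleiotropic `G` but requires `G`
#' to be independent of the exposure:
#' 1. estimate the effect difference \eqn{\widehat{\beta_1-\beta_0}} by
#'    [rgmee()] using `G`;
#' 2. predict the exposure from the standard instrument `G2` alone;
#' 3. regress the adjusted outcome
#'    \eqn{Y(S^*{=}0) = Y - \widehat{(\beta_1-\beta_0)}\,S^*} on \eqn{\hat S}
#'    (plus covariates), giving \eqn{\hat\beta_0}; then
#'    \eqn{\hat\beta_1 = \hat\beta_0 + \widehat{(\beta_1-\beta_0)}}.
#'
#' The standard error for \eqn{\hat\beta_1} treats the two components as
#' independent: \eqn{SE(\hat\beta_1) \approx
#' \sqrt{Var(\widehat{\beta_1-\beta_0}) + Var(\hat\beta_0)}}, which yields
#' slightly conservative confidence intervals.
#'
#' A G–S association test (instrument `G` alone in the first-stage model) is
#' run as an eligibility gate: rejection at `gate_alpha` raises a warning —
#' never an error — because RGMEE consistency requires `G` independent of
#' the exposure.
#'
#' @inheritParams method1
#' @param gate_alpha Significance level of the G–S association gate.
#' @return A `group_effects` with `method_tag = "method2"`
#'   (`cov_b1_b0 = NA`; the components are treated as independent).
#' @export
method2 <- function(cohort, covariates_s = NULL, covariates_y = NULL,
                    link = "logistic", gate_alpha = 0.05) {
  cohort <- as_cohort(cohort)
  step1 <- rgmee(cohort)

  gate <- first_stage(cohort, "g", covariates_s, link)$coefficient_table
  if (gate$p_value[1] < gate_alpha) {
    warning(sprintf(
      paste0("G is associated with the exposure (F = %.2f, p = %.3g): ",
             "the RGMEE step of Method 2 requires G independent of S; ",
             "interpret results cautiously"),
      gate$f_statistic[1], gate$p_value[1]), call. = FALSE)
  }

  fs <- first_stage(cohort, "g2", covariates_s, link)
  y_adj <- cohort$y - step1$value * cohort$s_star
  X <- cbind(`(Intercept)` = 1, shat = fs$fitted_probs)
  Z <- covariate_matrix(cohort, covariates_y)
  if (!is.null(Z)) X <- cbind(X, Z)
  fit <- fast_lm(X, y_adj)
  b0 <- fit$coef[["shat"]]
  se_b0 <- sqrt(fit$vcov["shat", "shat"])
  se_b1 <- sqrt(step1$se^2 + se_b0^2)
  group_effects(
    beta1_hat = b0 + step1$value, beta0_hat = b0, diff_hat = step1$value,
    se_beta1 = se_b1, se_beta0 = se_b0, se_diff = step1$se,
    cov_b1_b0 = NA_real_, method_tag = "method2", n_used = nrow(cohort),
    first_stage = fs
  )
}

#' Standard two-stage Mendelian randomization estimate
#'
#' Classical individual-level two-stage MR: the exposure is predicted from a
#' single instrument (stage 1), and the outcome is regressed on the
#' prediction plus covariates (stage 2),
#' \eqn{Y = \alpha_0 + \alpha_1 \hat S + \alpha_2^T Z + \epsilon}.
#' With a homogeneity-respecting instrument \eqn{\alpha_1} is the average
#' causal effect; with a homogeneity-violating instrument it targets the
#' complier average causal effect under monotonicity. Under effect
#' heterogeneity the ACE satisfies
#' \eqn{\alpha_1 = \beta_0 + (\beta_1-\beta_0) E[G|S{=}1]} (see
#' [ace_identity()]).
#'
#' @param cohort A `cohort` or compatible data.frame.
#' @param instrument Instrument column name (default `"g2"`).
#' @param covariates Covariate names, used in both stages.
#' @param link First-stage link.
#' @param f_threshold Weak-instrument warning threshold for the first-stage
#'   F statistic (default 10).
#' @return A `scalar_estimate` with tag `mr_ace`.
#' @export
standard_mr <- function(cohort, instrument = "g2", covariates = NULL,
                        link = "logistic", f_threshold = 10) {
  cohort <- as_cohort(cohort)
  fs <- first_stage(cohort, instrument, covariates, link)
  f_stat <- fs$coefficient_table$f_statistic[1]
  if (f_stat < f_threshold) {
    warning(sprintf("weak instrument: first-stage F = %.2f < %.1f for '%s'",
                    f_stat, f_threshold, instrument), call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, shat = fs$fitted_probs)
  Z <- covariate_matrix(cohort, covariates)
  if (!is.null(Z)) X <- cbind(X, Z)
  fit <- fast_lm(X, cohort$y)
  scalar_estimate(fit$coef[["shat"]], sqrt(fit$vcov["shat", "shat"]),
                  "mr_ace", nrow(cohort))
}

#' Average causal effect identity under effect heterogeneity
#'
#' Computes the value a standard MR analysis with a homogeneity-respecting
#' instrument targets when the exposure effect differs between genetic
#' groups: \deqn{\alpha_1 = \beta_0 + (\beta_1 - \beta_0)\, E[G \mid S = 1].}
#'
#' @param beta0 Effect in the `G = 0` group, grams.
#' @param diff Effect difference \eqn{\beta_1 - \beta_0}, grams.
#' @param p_g_given_s1 \eqn{E[G | S = 1]}, a probability in \[0, 1\].
#' @return The implied average causal effect, grams.
#' @export
#' @examples
#' ace_identity(-100, -100, 0.5)  # -150
ace_identity <- function(beta0, diff, p_g_given_s1) {
  if (!is.numeric(p_g_given_s1) || length(p_g_given_s1) != 1L ||
      is.na(p_g_given_s1) || p_g_given_s1 < 0 || p_g_given_s1 > 1) {
    stop("p_g_given_s1 must be a probability in [0, 1]", call. = FALSE)
  }
  beta0 + diff * p_g_given_s1
}

#' Observational (confounded) comparator
#'
#' Covariate-adjusted linear regression coefficient of the exposure on the
#' outcome. Provided only as the confounded comparator to the instrumental
#' estimators; it does not have a causal interpretation in the presence of
#' unmeasured confounding.
#'
#' @inheritParams standard_mr
#' @return A `scalar_estimate` with tag `observational`.
#' @export
observational <- function(cohort, covariates = NULL) {
  cohort <- as_cohort(cohort)
  if (stats::var(cohort$s) == 0) {
    stop("exposure column 's' is constant; observational contrast undefined",
         call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, s = cohort$s)
  Z <- covariate_matrix(cohort, covariates)
  if (!is.null(Z)) X <- cbind(X, Z)
  fit <- fast_lm(X, cohort$y)
  scalar_estimate(fit$coef[["s"]], sqrt(fit$vcov["s", "s"]),
                  "observational", nrow(cohort))
}
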
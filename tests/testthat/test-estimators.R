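# Large single-cohort consistency checks use the estimator's own model SE
# as the Monte-Carlo yardstick (3 SEs unless noted).

test_that("first stage recovers a deterministic exposure with the linear link", {
  cohort <- make_deterministic_cohort()
  fs <- first_stage(cohort, instruments = c("g", "g2"), link = "linear")
  expect_equal(fs$fitted_probs, cohort$g2, tolerance = 1e-12)
  expect_true(all(fs$coefficient_table$f_statistic >= 0))
})

test_that("first stage flags configuration and degenerate-fit errors", {
  cohort <- make_symmetric_cohort()
  expect_error(first_stage(cohort, character(0)), "instrument")
  expect_error(first_stage(cohort, "not_a_column"), "not_a_column")
  det <- make_deterministic_cohort()
  expect_error(first_stage(det, "g2", link = "logistic"), "separation")
})

test_that("a null instrument shows no spurious first-stage association", {
  cohort <- simulate_cohort(scenario_both(n = 1000000L, seed = 43L))
  fs <- first_stage(cohort, instruments = c("g", "g2"))
  tab <- fs$coefficient_table
  expect_lt(abs(tab$statistic[tab$term == "g"]), 4)
  expect_gt(tab$f_statistic[tab$term == "g2"], 100)
})

test_that("logistic fitted probabilities track the saturated cell means", {
  cohort <- simulate_cohort(scenario_method1(n = 100000L, seed = 47L))
  fs <- first_stage(cohort, instruments = c("g", "g2"))
  cell <- interaction(cohort$g, cohort$g2)
  saturated <- ave(cohort$s, cell)
  expect_lt(max(abs(fs$fitted_probs - saturated)), 0.01)
})

test_that("GMEE contrasts reproduce prescribed cell means", {
  cohort <- make_cell_mean_cohort(3300, 3450, 3600, 3600)
  expect_equal(gmee_exposed(cohort)$value, -150)
  expect_equal(gmee_unexposed(cohort)$value, 0)
  expect_equal(rgmee(cohort)$value, -150)
  expect_equal(gmee_unexposed(cohort)$p_value, 1)  # zero estimate, zero SE
})

test_that("empty exposure-genotype cells raise estimability errors naming the cell", {
  cohort <- make_cell_mean_cohort(3300, 3450, 3600, 3600)
  no_s1g1 <- as_cohort(cohort[!(cohort$s == 1 & cohort$g == 1), ])
  expect_error(gmee_exposed(no_s1g1), "S=1, G=1")
  expect_error(rgmee(no_s1g1), "S=1, G=1")
  no_s0g0 <- as_cohort(cohort[!(cohort$s == 0 & cohort$g == 0), ])
  expect_error(gmee_unexposed(no_s0g0), "S=0, G=0")
})

test_that("RGMEE is definitionally GMEE(1) - GMEE(0) on any cohort", {
  for (seed in 1:5) {
    cohort <- simulate_cohort(sim_config(
      n = 3000L, gamma_sg = 0.3, gamma_yg = 80, gamma_ug = 0.2, seed = seed))
    r <- rgmee(cohort)
    e1 <- gmee_exposed(cohort)
    e0 <- gmee_unexposed(cohort)
    expect_identical(r$value, e1$value - e0$value)
    expect_identical(r$se, sqrt(e1$se^2 + e0$se^2))
    expect_identical(r$ci_low, r$value - 1.96 * r$se)
    expect_identical(r$ci_high, r$value + 1.96 * r$se)
  }
})

test_that("GMEE estimators have the published bias structure at large n", {
  # all violations off: GMEE(1) consistent for beta1 - beta0, GMEE(0) for 0
  clean <- simulate_cohort(scenario_both(n = 1000000L, seed = 53L))
  e1 <- gmee_exposed(clean)
  expect_lt(abs(e1$value - (-100)), 3 * e1$se)
  e0 <- gmee_unexposed(clean)
  expect_lt(abs(e0$value), 3 * e0$se)

  # direct pleiotropy shifts GMEE(1) by exactly the pleiotropy scale and is
  # estimated by GMEE(0), so RGMEE subtracts it back out
  pleio <- simulate_cohort(scenario_method2(n = 1000000L, seed = 53L))
  p1 <- gmee_exposed(pleio)
  expect_lt(abs(p1$value - (-100 + 150)), 3 * p1$se)
  p0 <- gmee_unexposed(pleio)
  expect_lt(abs(p0$value - 150), 3 * p0$se)
  pr <- rgmee(pleio)
  expect_lt(abs(pr$value - (-100)), 3 * pr$se)

  # confounder-mediated G effect (IV2 violation) biases the RGMEE; the bias
  # scales with confounding strength, so demonstrate it where it is
  # measurable and resolve it with a replicate mean
  rm <- replicate_mean(strong_iv2_violation(),
                       function(co) rgmee(co)$value)
  expect_gt(abs(rm[["mean"]] - (-100)), 3 * rm[["mcse"]])
})

test_that("Method 1 solves the deterministic homogeneous system exactly", {
  cohort <- make_deterministic_cohort(beta = -100)
  fit <- method1(cohort, link = "linear")
  expect_equal(fit$beta1_hat, -100, tolerance = 1e-9)
  expect_equal(fit$beta0_hat, -100, tolerance = 1e-9)
  expect_equal(fit$diff_hat, fit$beta1_hat - fit$beta0_hat)
})

test_that("Method 1 exposes the stage-2 covariance and exact difference SE", {
  cohort <- simulate_cohort(scenario_method1(n = 20000L, seed = 61L))
  fit <- method1(cohort)
  expect_identical(fit$diff_hat, fit$beta1_hat - fit$beta0_hat)
  expect_identical(fit$se_diff,
                   sqrt(fit$se_beta1^2 + fit$se_beta0^2 - 2 * fit$cov_b1_b0))
  expect_identical(fit$method_tag, "method1")
})

test_that("Method 1 is biased by direct pleiotropy of G", {
  cohort <- simulate_cohort(scenario_method2(n = 1000000L, seed = 67L))
  fit <- method1(cohort)
  expect_gt(abs(fit$beta1_hat - (-200)), 3 * fit$se_beta1)
})

test_that("Method 2 reduces to standard MR when the RGMEE adjustment is zero", {
  cohort <- make_symmetric_cohort()
  expect_identical(rgmee(cohort)$value, 0)
  m2 <- method2(cohort)
  mr <- standard_mr(cohort)
  expect_equal(m2$beta0_hat, mr$value, tolerance = 1e-12)
  expect_identical(m2$beta1_hat, m2$beta0_hat + m2$diff_hat)
  expect_identical(m2$se_beta1, sqrt(m2$se_diff^2 + m2$se_beta0^2))
})

test_that("Method 2 warns through its G-S eligibility gate", {
  strong <- simulate_cohort(sim_config(n = 50000L, gamma_sg = 1, seed = 71L))
  expect_warning(method2(strong), "requires G independent of S")
  clean <- simulate_cohort(scenario_method2(n = 50000L, seed = 71L))
  expect_no_warning(method2(clean, gate_alpha = 0.001))
})

test_that("Method 2 is biased when G predicts the exposure", {
  rm <- replicate_mean(strong_gs_dependence(), function(co) {
    suppressWarnings(method2(co))$diff_hat
  })
  expect_gt(abs(rm[["mean"]] - (-100)), 3 * rm[["mcse"]])
  # whereas Method 1 tolerates the G-S path (its own assumption regime)
  rm1 <- replicate_mean(strong_gs_dependence(),
                        function(co) method1(co)$diff_hat)
  expect_lt(abs(rm1[["mean"]] - (-100)), 3 * rm1[["mcse"]])
})

test_that("standard MR recovers the shared effect under homogeneity", {
  cohort <- simulate_cohort(sim_config(n = 1000000L, beta1 = -150,
                                       beta0 = -150, seed = 79L))
  mr <- standard_mr(cohort)
  expect_lt(abs(mr$value - (-150)), 3 * mr$se)
})

test_that("standard MR with G2 closes on the heterogeneity ACE identity", {
  cohort <- simulate_cohort(scenario_both(n = 1000000L, seed = 83L))
  mr <- standard_mr(cohort)
  p_g_s1 <- mean(cohort$g[cohort$s == 1])
  expect_lt(abs(p_g_s1 - 0.55), 0.005)  # G disconnected from S here
  target <- ace_identity(-100, -100, p_g_s1)
  expect_lt(abs(mr$value - target), 3 * mr$se)
})

test_that("standard MR with the moderator variant targets the latent IV contrast", {
  cohort <- simulate_cohort(scenario_method1(n = 1000000L, seed = 89L))
  mr <- suppressWarnings(standard_mr(cohort, instrument = "g"))
  e_s1 <- mean(cohort$s_if_g1)
  e_s0 <- mean(cohort$s_if_g0)
  oracle <- (-200 * e_s1 + 100 * e_s0) / (e_s1 - e_s0)
  expect_lt(abs(mr$value - oracle), 3 * mr$se)
})

test_that("weak instruments raise a warning, not an error", {
  cohort <- simulate_cohort(sim_config(n = 5000L, gamma_sg = 0.05, seed = 97L))
  expect_warning(standard_mr(cohort, instrument = "g"), "weak instrument")
})

test_that("ACE identity arithmetic and domain checks", {
  expect_identical(ace_identity(-100, -100, 0.5), -150)
  expect_identical(ace_identity(-42, 0, 0.77), -42)
  expect_error(ace_identity(-100, -100, 1.5), "probability")
  expect_error(ace_identity(-100, -100, -0.1), "probability")
})

test_that("observational contrast is unbiased only without confounding", {
  unconf <- simulate_cohort(sim_config(n = 1000000L, beta1 = -150,
                                       beta0 = -150, gamma_su = 0,
                                       gamma_yu = 0, seed = 101L))
  est <- observational(unconf)
  expect_lt(abs(est$value - (-150)), 3 * est$se)

  # gamma_su > 0 and gamma_yu > 0: omitted-variable bias pushes the estimate
  # upward (exposed have higher U, which raises Y)
  conf <- simulate_cohort(scenario_both(n = 1000000L, seed = 103L))
  w_truth <- -200 * mean(conf$g[conf$s == 1]) +
    -100 * (1 - mean(conf$g[conf$s == 1]))
  biased <- observational(conf)
  expect_gt(biased$value - w_truth, 3 * biased$se)

  # adjusting for the (here, measured) confounder removes the bias
  adj <- observational(conf, covariates = "u")
  expect_lt(abs(adj$value - w_truth), 3 * adj$se)
})

test_that("collinear or constant regressors are reported by name", {
  cohort <- make_symmetric_cohort()
  cohort$dup <- cohort$g2
  expect_error(
    observational(cohort, covariates = c("dup", "dup")), "collinear")
  allg1 <- simulate_cohort(sim_config(n = 200L, p_g = 0.999, seed = 5L))
  allg1$g <- 1L  # moderator fixed: the g column carries no information
  expect_error(method1(as_cohort(allg1), link = "linear"), "collinear")
})

test_that("tidy serialization carries one row per parameter with Wald intervals", {
  cohort <- simulate_cohort(scenario_method1(n = 5000L, seed = 7L))
  td <- tidy_estimate(method1(cohort))
  expect_identical(td$parameter, c("beta1", "beta0", "diff"))
  expect_equal(td$ci_low, td$estimate - 1.96 * td$se)
  sc <- tidy_estimate(rgmee(cohort))
  expect_identical(names(sc), names(td))
})
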
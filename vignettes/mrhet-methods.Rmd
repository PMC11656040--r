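---
title: "Estimating genetically driven effect heterogeneity with mrhet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating genetically driven effect heterogeneity with mrhet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mendelian randomization (MR) uses genetic variants as instrumental variables
to estimate the causal effect of a modifiable exposure on an outcome. The
usual point-identifying assumption, *homogeneity*, says the causal effect
does not vary with the instrument. Pharmacogenetics works from the opposite
premise: some variants exist precisely because they *moderate* an exposure's
effect. A motivating example is maternal smoking and offspring birth weight,
where a variant in the nicotine-receptor gene cluster makes it harder to quit
smoking and plausibly moderates the damage smoking does, while a genetic risk
score for smoking initiation acts as a conventional instrument.

`mrhet` estimates, from individual-level data on an outcome $Y$ (grams), a
binary exposure $S$, a binary moderator variant $G$ and a standard
instrument $G_2$, the group-specific causal effects $\beta_1$ (effect of $S$
when $G=1$), $\beta_0$ (when $G=0$) and the genetically moderated exposure
effect $\beta_1-\beta_0$, under the linear interaction model

$$E[Y \mid S, G, Z, U] = \gamma_0 + \beta_1 S G + \beta_0 S (1-G)
  + \gamma_{YG} G + \gamma_{YZ} Z + \gamma_{YU} U.$$

Here $U$ is an unmeasured confounder and $Z$ are measured covariates. The
coefficients $\gamma_{YG}$ (direct, pleiotropic effect of $G$ on $Y$) and
the paths from $G$ to $U$ or to $S$ encode violations of the classical IV
assumptions IV1 (relevance), IV2 (independence), IV3 (exclusion) and IV4
(homogeneity) for $G$.

## Estimators

**GMEE family.** Among the exposed, the between-genotype contrast
$\mathrm{GMEE}(1)=\hat E[Y|S{=}1,G{=}1]-\hat E[Y|S{=}1,G{=}0]$ estimates
$\beta_1-\beta_0$ when $G$ is independent of $S$ and of $U$ and has no
direct outcome effect. The analogous contrast among the unexposed,
$\mathrm{GMEE}(0)$, estimates the direct effect of $G$ on $Y$, so
$\mathrm{RGMEE}=\mathrm{GMEE}(1)-\mathrm{GMEE}(0)$ remains consistent under
pleiotropy. It is *not* robust to $G$–confounder dependence, and since an
IV2 violation also induces a $G$–$S$ association, testing for a $G$–$S$
association is the practical eligibility check (`method2()` runs it and
warns, never errors — a weak association may still pass the test by chance,
so the user decides). Standard errors come from within-cell variances,
combined in quadrature.

**Method 1** (`method1()`) instruments both the exposure and its moderated
version jointly: stage 1 fits $\hat S = \hat E[S \mid G, G_2, Z_S]$; stage 2
fits $Y = \gamma_0 + \beta_1 \hat S G + \beta_0 \hat S(1-G) + Z_Y$. The
coefficient covariance gives
$SE(\widehat{\beta_1-\beta_0})^2 = SE_1^2+SE_0^2-2\,\mathrm{cov}$. Method 1
tolerates a $G \to S$ path but is biased by pleiotropy of $G$.

**Method 2** (`method2()`) estimates $\beta_1-\beta_0$ by RGMEE, removes the
moderated effect from the outcome, $Y(S^*{=}0) = Y - \widehat{(\beta_1-\beta_0)}
\, S^*$ with $S^* = G \times S$, and then runs a standard two-stage MR of the
adjusted outcome on $\hat S = \hat E[S\mid G_2, Z_S]$ to get $\beta_0$;
$\hat\beta_1 = \hat\beta_0 + \widehat{(\beta_1-\beta_0)}$ with
$SE(\hat\beta_1) \approx \sqrt{SE_{\text{diff}}^2 + SE_{\beta_0}^2}$
(components treated as independent — slightly conservative in simulation).
Method 2 tolerates pleiotropy of $G$ but requires $G$ independent of $S$.

**Standard MR and identities.** `standard_mr()` is the classical two-stage
estimator with a single instrument. With a homogeneity-respecting $G_2$ it
targets the average causal effect, which under heterogeneity satisfies
$\alpha_1 = \beta_0 + (\beta_1-\beta_0)E[G \mid S{=}1]$ (`ace_identity()`).
`observational()` is the confounded comparator. `wald_estimand()` evaluates,
at the population level of a known data-generating process, the
decomposition of the Wald ratio for $G$ into the ratio term
$(\beta_1 E[S|G{=}1]-\beta_0 E[S|G{=}0])/(E[S|G{=}1]-E[S|G{=}0])$ and the
bias $B = (\gamma_{YG}+\gamma_{YU}\gamma_{UG})/(E[S|G{=}1]-E[S|G{=}0])$.

### What the Wald ratio targets under heterogeneity

A point worth spelling out, because our simulations forced us to be precise
about it. With monotonicity (no defiers) the ratio term above equals, from
the latent potential-exposure table,
$\beta_1 + (\beta_1-\beta_0)\,P(\text{always-taker})/P(\text{complier}).$
It therefore coincides with the complier average causal effect (the mean of
$Y(S{=}1)-Y(S{=}0)$ over compliers) only when the heterogeneity leakage term
vanishes — under homogeneity ($\beta_1=\beta_0$), where the package's tests
verify the equality exactly. In heterogeneous settings with a non-trivial
always-taker stratum the two quantities can differ by hundreds of grams at
the package's default calibration. The test suite asserts the identities
that hold: the ratio term against the latent-table IV contrast, the exact
$B$-term arithmetic, and the homogeneous collapse.

## The synthetic cohort generator

`simulate_cohort()` draws, for a configuration `sim_config()`:

$$G \sim B(p_g), \quad G_2 \sim B(p_{g2}), \quad U = \gamma_{UG} G + N(0,1),$$
$$\eta = \eta_0 + \gamma_{SG} G + \gamma_{SG2} G_2 + \gamma_{SU} U +
  N(0, \sigma_\eta), \quad S \sim B(\mathrm{expit}(\eta)),$$
$$Y = y_0 + \beta_1 S G + \beta_0 S(1-G) + \gamma_{YG} G + \gamma_{YU} U +
  N(0, \sigma_Y).$$

Fixed defaults follow the published birth-weight calibration: $p_g = 0.55$,
$p_{g2} = 0.4$, $\eta_0 = -2$, $\sigma_\eta = 0.5$ (interpreted as an SD, in
parallel with $\sigma_Y = 470$ g), $y_0 = 3500$ g, $\beta_1 = -200$ g,
$\beta_0 = -100$ g. Three nuisance values are not printed in the main text
of the source calibration and are the package's own choices, made once:
$\gamma_{SG2} = 1.5$, $\gamma_{SU} = 0.5$, $\gamma_{YU} = 50$. They were
selected so that the implied cohort looks like a pregnancy cohort with a
smoking-related exposure: prevalence $E[S] \approx 0.24$, a strong
instrument first stage, ~50 g of confounding on the outcome per SD of $U$ —
and so that the implied design sensitivity matches the published
sample-size guidance (a $-15$ g moderated effect detectable with 80% power
by the RGMEE route around $n = 200{,}000$ and by the joint two-stage route
around $n = 500{,}000$). They are labelled *paper-consistent, not
paper-exact*.

Alongside the observed columns the generator stores latent ground truth:
the confounder `u`, potential exposures `s_if_g1`/`s_if_g0` obtained by
re-evaluating $\eta$ (including $G$'s contribution to $U$) with $G$ forced
to 1/0 while every noise draw is held fixed, and potential outcomes
`y_s1`/`y_s0`. These power the oracles: `true_cace()` averages
$y_{s1}-y_{s0}$ over compliers after verifying monotonicity empirically
(configurations with $\gamma_{SG} < 0$ can create defiers, which raise an
error rather than being silently dropped).

Scenario presets encode the assumption regimes: `scenario_method1()`
($\gamma_{SG}=0.5$, no pleiotropy), `scenario_method2()` ($\gamma_{SG}=0$,
$\gamma_{YG}=150$ g) and `scenario_both()` (all violations for $G$ off, for
head-to-head power comparisons on common ground). The pleiotropy scale of
150 g is a package choice: large enough to visibly break non-robust
estimators, small relative to the outcome SD.

What the generator does **not** emulate: linkage between variants, allele
dosages (G is carrier status), genuinely continuous risk scores with
measurement error, covariate-driven confounding (optional `z` columns are
pure noise, present only to exercise adjustment code paths), missing data,
and non-Gaussian or non-linear outcome mechanics. Passing tests therefore
show correctness of the estimators under the stated structural model, not
robustness to those real-data features.

## The Monte-Carlo study engine

`study_scenario()` + `run_replicates()` simulate a grid of sample sizes,
apply the requested estimators, and record estimate, SE, nominal 95% Wald
interval ($\pm 1.96 \times SE$ by convention) and two-sided p-value per
replicate. `summarize_study()` reports, per (method, parameter, sample
size): mean estimate, bias, empirical SD, power of the 5% Wald test and
coverage, each with its Monte-Carlo standard error
($\mathrm{SD}/\sqrt{R}$ for means, $\sqrt{p(1-p)/R}$ for proportions).
`power_curve()` sweeps true differences by setting
$\beta_1 = \beta_0 + \text{diff}$.

Child seeds derive deterministically from (master seed, $n$, replicate) via
a 32-bit multiplicative mix, so any subset of the grid reproduces
independently. Fit failures (e.g. an empty $S \times G$ cell in a tiny
cohort) are caught, excluded, counted, and any cell with more than 1%
failures is flagged invalid rather than silently summarized.

Replicate counts are configurable; the reference study used 20,000 per
cell, while this package's tests and acceptance script use desk-scale
counts (500 at $n=80{,}000$ for parameter recovery, 1,000 at $n=20{,}000$
for coverage, 100–300 for power points) with all assertions stated in units
of the resulting Monte-Carlo SEs.

## Numerical choices and edge cases

* **Standard errors** are model-based, read directly off the stage-2 linear
  model — no two-stage variance correction. The coverage study largely
  validates the choice: Method 1 is near-nominal at $n \ge 20{,}000$ and
  Method 2's $\beta_1$ is slightly conservative by construction. The one
  systematic exception is Method 2's $\beta_0$, whose stage-3 model SE
  ignores the RGMEE-step error carried into the adjusted outcome
  $Y - \widehat{(\beta_1-\beta_0)}S^*$: at this package's calibration the
  empirical SD exceeds the mean model SE by ~9%, giving ~92–93% coverage at
  every $n$. The shortfall grows with instrument strength (a precise
  $\hat\beta_0$ makes the ignored term relatively larger), so it is a
  property of the stated SE procedure, not of sample size; a bootstrap is
  the remedy if calibrated $\beta_0$ intervals matter.
* **First stage** is logistic by default; a linear-probability backend
  exists because the identities are link-free, and the two are
  cross-checked in tests. Perfect or quasi-perfect separation (fitted
  probabilities within $10^{-7}$ of 0 or 1) is a hard error, as is
  non-convergence. The per-instrument F statistic is the squared Wald z.
* **Wald-estimand moments** $E[S \mid G{=}g]$ are computed by deterministic
  1-D quadrature over the collapsed Gaussian
  $\gamma_{SU}U + \epsilon_\eta \sim N(\cdot, \gamma_{SU}^2+\sigma_\eta^2)$
  (default), with a Monte-Carlo backend (fixed internal seed, caller's RNG
  state restored) as the cross-check; the two agree to ~$10^{-4}$ on the
  probability scale.
* **Degenerate inputs**: empty exposure-genotype cells raise errors naming
  the cell; collinear or constant regressors raise errors naming the
  column; zero-SE estimates (noise-free fixtures) get p-value 0 for nonzero
  and 1 for zero estimates.
* **Violation magnitudes matter.** Under the default mild confounding
  ($\gamma_{SU}=0.5$, $\gamma_{YU}=50$) the theoretical biases of RGMEE
  under IV2 violation and of Method 2 under $G$–$S$ dependence are real but
  numerically negligible (under 1 g). The bias-direction tests therefore
  use strong-confounding configurations ($\gamma_{SU}=1.5$,
  $\gamma_{YU}=300$) and resolve the bias with replicate means (30 cohorts
  of $n=250{,}000$), asserted at 3 Monte-Carlo SEs. Method 2's bias under a
  $G \to S$ path shows up almost entirely in the difference parameter (its
  RGMEE step), not in $\beta_0$.
* **YAML configs**: a bare `n:` key is a YAML 1.1 boolean; the reader maps
  it back to the sample-size field.

## Limitations

The package implements the one-sample, individual-level setting only: no
summary-statistic (two-sample) MR, no multi-SNP pleiotropy-robust
estimators, no correlated pleiotropy, and a single binary moderator (allele
counts can be collapsed to carrier status with `--dichotomize-g`). The ACE
identity and the estimators assume the linear interaction outcome model;
nothing here addresses non-linear effects or binary outcomes.
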
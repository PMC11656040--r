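# Programmatic fixtures shared across test files.

# Replicate-mean of an estimator under a fixed DGP, with the Monte-Carlo SE
# of the mean. Used for bias-direction demonstrations, where single-cohort
# model SEs are too coarse to resolve small systematic biases.
replicate_mean <- function(cfg, extract, n_reps = 30L, seed_base = 7000L) {
  vals <- vapply(seq_len(n_reps), function(r) {
    cfg$seed <- seed_base + r
    extract(simulate_cohort(cfg))
  }, numeric(1))
  c(mean = mean(vals), mcse = stats::sd(vals) / sqrt(n_reps))
}

# Violation configurations with confounding strong enough that the
# qualitative biases are measurable at desk scale; under the default mild
# confounding they are numerically negligible (< 1 g).
strong_iv2_violation <- function(n = 250000L) {
  sim_config(n = n, gamma_ug = 0.5, gamma_su = 1.5, gamma_yu = 300)
}
strong_gs_dependence <- function(n = 250000L) {
  sim_config(n = n, gamma_sg = 1, gamma_su = 1.5, gamma_yu = 300)
}

# Cohort with exactly equal means in all four S x G cells (so RGMEE = 0
# exactly) but within-cell variation and a g2-dependent exposure.
# Cell counts over (g2, s): (0,0) heavy, (1,1) heavy, so g2 predicts s
# without separation.
make_symmetric_cohort <- function(center = 3500, spread = 100) {
  w <- c("00" = 6L, "01" = 2L, "10" = 2L, "11" = 6L)  # key: paste0(g2, s)
  rows <- list()
  for (g in 0:1) for (g2 in 0:1) for (s in 0:1) {
    k <- w[paste0(g2, s)]
    rows[[length(rows) + 1L]] <- data.frame(
      y = rep(c(center - spread, center + spread), k),
      s = s, g = g, g2 = g2
    )
  }
  as_cohort(do.call(rbind, rows))
}

# Deterministic homogeneous cohort: s = g2 exactly, y = y0 + beta * s,
# no noise. g varies independently of g2.
make_deterministic_cohort <- function(beta = -100, y0 = 3500, n_block = 8L) {
  df <- expand.grid(g = 0:1, g2 = 0:1, rep = seq_len(n_block))
  df$s <- df$g2
  df$y <- y0 + beta * df$s
  as_cohort(df[, c("y", "s", "g", "g2")])
}

# Four-cell toy with prescribed (S,G) cell means and a tiny deterministic
# within-cell spread: means stay exact because the spread is +/-d balanced.
make_cell_mean_cohort <- function(m_s1g1, m_s1g0, m_s0g1, m_s0g0,
                                  n_per_cell = 10L, d = 0) {
  cells <- data.frame(
    s = c(1, 1, 0, 0), g = c(1, 0, 1, 0),
    m = c(m_s1g1, m_s1g0, m_s0g1, m_s0g0)
  )
  rows <- lapply(seq_len(4), function(i) {
    data.frame(
      y = cells$m[i] + rep(c(-d, d), length.out = n_per_cell),
      s = cells$s[i], g = cells$g[i],
      g2 = rep(0:1, length.out = n_per_cell)
    )
  })
  as_cohort(do.call(rbind, rows))
}
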
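# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive results by brute force / enumeration /
# off-the-shelf fits rather than calling the code paths they check.

# Exhaustive transmission enumeration for one trio genotype combination:
# list every (tm, tf) haplotype transmission consistent with the dosages.
oracle_trio <- function(gm, gf, go) {
  allowed <- function(g) switch(as.character(g), "0" = 0L, "1" = 0:1, "2" = 1L)
  configs <- list()
  for (tm in allowed(gm)) for (tf in allowed(gf))
    if (tm + tf == go) configs[[length(configs) + 1L]] <- c(tm = tm, tf = tf)
  if (length(configs) == 0L)
    return(list(status = "mendelian_error"))
  tms <- vapply(configs, `[`, integer(1), "tm")
  tfs <- vapply(configs, `[`, integer(1), "tf")
  if (length(unique(tms)) == 1L && length(unique(tfs)) == 1L)
    return(list(status = "resolved",
                m_inherited = tms[1], m_non_inherited = gm - tms[1],
                f_inherited = tfs[1], f_non_inherited = gf - tfs[1]))
  list(status = "ambiguous")
}

oracle_duo <- function(gp, go) {
  allowed <- function(g) switch(as.character(g), "0" = 0L, "1" = 0:1, "2" = 1L)
  tps <- Filter(function(tp) (go - tp) %in% 0:1, as.list(allowed(gp)))
  if (length(tps) == 0L) return(list(status = "mendelian_error"))
  tps <- unlist(tps)
  if (length(unique(tps)) == 1L)
    return(list(status = "resolved",
                p_inherited = tps[1], p_non_inherited = gp - tps[1],
                other_contributed = go - tps[1]))
  list(status = "ambiguous")
}

# Classical IVW via a weighted least-squares fit (independent of the package's
# moment-system code).
oracle_ivw <- function(beta_x, beta_y, se_y) {
  fit <- stats::lm(beta_y ~ 0 + beta_x, weights = 1 / se_y^2)
  unname(stats::coef(fit))
}

# Straightforward one-exposure adjusted-profile-score estimator (squared loss,
# no overdispersion): direct golden-section minimisation of the profiled
# objective on a wide bracket.
oracle_raps_simple <- function(beta_x, se_x, beta_y, se_y) {
  obj <- function(b) sum((beta_y - b * beta_x)^2 / (se_y^2 + b^2 * se_x^2))
  stats::optimize(obj, lower = -50, upper = 50, tol = 1e-10)
}

# Score-only benchmark configuration used across tests.
bench_config <- function(...) scenario_config(n_families = 10000, ...)

# Draw a summary-statistic dataset from the linear summary model (shared by
# the summary-estimator and acceptance tests).
simulate_summaries <- function(J = 10, K = 1, theta = 0.5, sx = 0.05,
                               sy = 0.1, bx_scale = 0.3, seed = 1) {
  set.seed(seed)
  bx_true <- matrix(abs(rnorm(J * K, bx_scale, 0.05)), J, K)
  bx_obs <- bx_true + matrix(rnorm(J * K, 0, sx), J, K)
  by_obs <- drop(bx_true %*% rep(theta, K)) + rnorm(J, 0, sy)
  summary_associations(bx_obs, matrix(sx, J, K), by_obs, rep(sy, J))
}

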
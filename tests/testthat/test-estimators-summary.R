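test_that("per-variant summaries match per-variant least-squares fits", {
  set.seed(71)
  n <- 500
  Z <- matrix(rbinom(n * 5, 2, 0.3), n, 5)
  Z[sample(length(Z), 100)] <- NA
  x <- rnorm(n); y <- rnorm(n); cv <- rnorm(n)
  s <- compute_variant_summaries(Z, x, y, covariates = cv)
  for (j in c(1, 4)) {
    obs <- !is.na(Z[, j])
    zj <- Z[, j]
    zj[obs] <- zj[obs] - mean(zj[obs]); zj[!obs] <- 0
    fx <- lm(x ~ zj + cv); fy <- lm(y ~ zj + cv)
    expect_equal(unname(s$beta_x[j, 1]), unname(coef(fx)["zj"]),
                 tolerance = 1e-10)
    expect_equal(unname(s$se_x[j, 1]), unname(summary(fx)$coefficients["zj", 2]),
                 tolerance = 1e-8)
    expect_equal(unname(s$beta_y[j]), unname(coef(fy)["zj"]), tolerance = 1e-10)
  }
  # a constant covariate is absorbed by the intercept: identical to unadjusted
  s_const <- compute_variant_summaries(Z, x, y, covariates = rep(2, n))
  s_unadj <- compute_variant_summaries(Z, x, y)
  expect_equal(s_const$beta_x, s_unadj$beta_x)
  expect_equal(s_const$beta_y, s_unadj$beta_y)
  # monomorphic instrument dropped with a warning
  Z2 <- cbind(Z, 1)
  expect_warning(s2 <- compute_variant_summaries(Z2, x, y), "zero variance")
  expect_equal(s2$J, 5)
  # null model: standardised outcome associations are ~ standard normal
  set.seed(72)
  Zbig <- matrix(rbinom(2000 * 80, 2, 0.3), 2000, 80)
  ynull <- rnorm(2000)
  sn <- compute_variant_summaries(Zbig, rnorm(2000), ynull)
  zstat <- sn$beta_y / sn$se_y
  expect_lt(abs(mean(zstat)), 0.35)
  expect_lt(abs(sd(zstat) - 1), 0.25)
  expect_gt(ks.test(zstat, pnorm)$p.value, 0.01)
})

test_that("strong instruments give the plug-in identity beta_y ~ theta * beta_x", {
  set.seed(73)
  n <- 4000; J <- 6
  Z <- matrix(rbinom(n * J, 2, 0.4), n, J)
  x <- rowSums(Z) * 0.3 + rnorm(n)
  y <- 0.5 * x + rnorm(n)
  s <- compute_variant_summaries(Z, x, y)
  expect_lt(max(abs(s$beta_y - 0.5 * s$beta_x[, 1])), 0.1)
})

test_that("debiased IVW reduces to IVW when instrument-exposure noise vanishes", {
  s <- simulate_summaries(J = 12, sx = 0, seed = 74)
  d <- divw(s)
  expect_equal(unname(d$beta), oracle_ivw(s$beta_x[, 1], s$beta_y, s$se_y),
               tolerance = 1e-10)
  # exact linear summaries recover theta exactly
  s2 <- summary_associations(seq(0.1, 0.5, length.out = 8),
                             rep(0, 8),
                             0.7 * seq(0.1, 0.5, length.out = 8),
                             rep(0.1, 8))
  expect_equal(unname(divw(s2)$beta), 0.7, tolerance = 1e-12)
})

test_that("debiasing shrinks the weak-instrument attenuation of IVW", {
  # paired summary-level simulation: same draws feed both estimators
  reps <- 300
  est <- vapply(1:reps, function(r) {
    s <- simulate_summaries(J = 25, theta = 0.5, sx = 0.15, sy = 0.05,
                            bx_scale = 0.15, seed = 9000 + r)
    c(divw = unname(divw(s)$beta),
      ivw = oracle_ivw(s$beta_x[, 1], s$beta_y, s$se_y))
  }, numeric(2))
  bias_divw <- abs(mean(est["divw", ]) - 0.5)
  bias_ivw <- abs(mean(est["ivw", ]) - 0.5)
  expect_lt(bias_divw, bias_ivw)
  expect_gt(bias_ivw, 0.05)  # the naive estimator really is attenuated here
})

test_that("CUE-GMM coincides with IVW in the zero-noise limit and with the Wald ratio when just-identified", {
  s <- simulate_summaries(J = 12, sx = 0, seed = 75)
  g <- cue_gmm(s)
  expect_true(g$converged)
  expect_equal(unname(g$beta), oracle_ivw(s$beta_x[, 1], s$beta_y, s$se_y),
               tolerance = 1e-6)
  # J = K = 1: the moment has an exact root at the Wald ratio
  s1 <- summary_associations(0.4, 0.1, 0.26, 0.05)
  g1 <- cue_gmm(s1)
  expect_equal(unname(g1$beta), 0.26 / 0.4, tolerance = 1e-6)
  expect_lt(g1$objective_value, 1e-10)
  q1 <- qhet(s1)
  expect_equal(unname(q1$beta), 0.26 / 0.4, tolerance = 1e-6)
})

test_that("the Q-minimisation objective at the fit behaves like chi-square(J - K)", {
  # well-specified summary model with strong instruments: the minimised
  # heterogeneity statistic has mean J - K across simulations
  reps <- 300; J <- 8
  qs <- vapply(1:reps, function(r) {
    s <- simulate_summaries(J = J, theta = 0.5, sx = 0.02, sy = 0.08,
                            bx_scale = 0.4, seed = 20000 + r)
    qhet(s)$objective_value
  }, numeric(1))
  mcse <- sd(qs) / sqrt(reps)
  expect_lt(abs(mean(qs) - (J - 1)), 3 * mcse)
  # exact summaries: objective 0 and theta recovered
  sx0 <- summary_associations(c(0.2, 0.3, 0.4), rep(0, 3),
                              0.6 * c(0.2, 0.3, 0.4), rep(0.1, 3))
  q0 <- qhet(sx0)
  expect_equal(unname(q0$beta), 0.6, tolerance = 1e-8)
  expect_lt(q0$objective_value, 1e-12)
  # bootstrap CI machinery runs and brackets the point estimate
  sboot <- simulate_summaries(J = 10, seed = 76)
  qb <- qhet(sboot, ci = "bootstrap", boot_reps = 50, seed = 1)
  expect_true(is.finite(qb$se))
})

test_that("profile-likelihood estimator matches an independent implementation and handles outliers", {
  s <- simulate_summaries(J = 20, theta = 0.5, sx = 0.05, sy = 0.08, seed = 77)
  oracle <- oracle_raps_simple(s$beta_x[, 1], s$se_x[, 1], s$beta_y, s$se_y)
  g <- grapple_profile(s, loss = "squared")
  expect_true(g$converged)
  # well-specified data: overdispersion shrinks to ~0 and the estimate agrees
  # with the straightforward profile-score oracle
  expect_lt(g$tau2, 0.005)
  # the joint fit co-estimates a (small) overdispersion, so agreement with the
  # fixed-dispersion oracle is approximate
  expect_lt(abs(unname(g$beta) - oracle$minimum), 0.05)
  # a gross outlier moves the robust fit less than the squared-loss fit
  s_out <- s
  s_out$beta_y[1] <- s_out$beta_y[1] + 2
  b_sq <- unname(grapple_profile(s_out, loss = "squared")$beta)
  b_rob <- unname(grapple_profile(s_out, loss = "robust")$beta)
  clean <- unname(grapple_profile(s, loss = "squared")$beta)
  expect_lt(abs(b_rob - clean), abs(b_sq - clean))
})

test_that("proxy MVMR-NIV wires duo resolution into the summary estimators", {
  duo <- simulate_trios(scenario_config(n_families = 3000, n_variants = 20,
                                        duo_mode = TRUE), seed = 78)
  ps <- proxy_summaries(duo)
  expect_s3_class(ps, "mrniv_summaries")
  expect_equal(ps$K, 2)
  expect_equal(colnames(ps$beta_x), c("mother", "father"))
  expect_lte(ps$J, 40)
  est <- proxy_mvmr_niv(duo, "divw", summaries = ps)
  expect_equal(est$method, "proxy_divw")
  expect_equal(unname(est$interpretable), c(TRUE, FALSE))
  expect_equal(est$genotyped_parent, "mother")
  # father-genotyped duos put the father first
  duof <- simulate_trios(scenario_config(n_families = 2000, n_variants = 20,
                                         duo_mode = TRUE,
                                         genotyped_parent = "father"),
                         seed = 79)
  estf <- proxy_mvmr_niv(duof, "qhet")
  expect_equal(estf$genotyped_parent, "father")
  # trio input: warns, then proxies the father
  trio <- simulate_trios(scenario_config(n_families = 1000, n_variants = 20),
                         seed = 80)
  expect_warning(proxy_summaries(trio), "both parents genotyped")
  # too few variants to identify two exposures
  tiny <- simulate_trios(scenario_config(n_families = 500, n_variants = 1,
                                         duo_mode = TRUE), seed = 81)
  expect_error(proxy_summaries(tiny), "too few resolved instruments")
  expect_error(proxy_mvmr_niv(simulate_trios(bench_config(), seed = 1)),
               "per-variant")
})
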
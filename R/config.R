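#' Scenario configuration for the family simulator
#'
#' Defines the data-generating mechanism for a simulated population of
#' mother-father-offspring trios (or parent-offspring duos). The defaults
#' reproduce the benchmark conditions used throughout the package: a parental
#' genetic risk score (GRS) explaining 0.5% of the variance of each
#' standardised parental exposure, a per-parent causal effect of 0.75 on the
#' offspring outcome, roughly 10,000 families, and an outcome whose variance is
#' dominated (>90%) by non-genetic, non-parental environmental noise.
#'
#' @param n_families Number of families to simulate.
#' @param n_variants Number of biallelic variants. `0` (the default) selects
#'   score-only mode, where the parental GRS is simulated directly as a
#'   standardised Gaussian score split into equal-variance transmitted and
#'   non-transmitted halves. A positive count (126 mirrors the applied
#'   lifetime-smoking instrument) selects per-variant mode with explicit
#'   genotypes, which the inheritance resolver and summary-statistic
#'   estimators require.
#' @param maf_range Length-2 numeric in (0,1): minor-allele-frequency range for
#'   per-variant mode (drawn uniformly).
#' @param grs_r2 Fraction of each parental exposure's variance explained by
#'   that parent's full GRS.
#' @param theta Per-parent causal effect of the parental exposure on the
#'   offspring outcome (standardised-exposure units); 0 for null scenarios.
#' @param am_rho Target correlation between maternal and paternal genotypic
#'   scores under assortative mating; 0 means random mating.
#' @param confounder_effect Effect of a shared standard-normal confounder on
#'   each parental exposure and on the offspring outcome.
#' @param offspring_direct_effect Direct effect of the offspring GRS on the
#'   offspring outcome. `NULL` (default) solves for the value at which the
#'   offspring GRS explains `grs_r2` of the outcome variance, mirroring the
#'   parental first stage.
#' @param resid_var_y Residual (environmental) variance of the offspring
#'   outcome. The default of 14 keeps the parental-plus-genetic share of
#'   Var(Y) just under 10% at `theta = 0.75`.
#' @param duo_mode If `TRUE`, genotypes of one parent are dropped after
#'   simulation (phenotypes of both parents are kept, as in studies that
#'   genotype one parent but phenotype both).
#' @param genotyped_parent Which parent keeps genotypes in duo mode.
#' @param outcome_prevalence Optional prevalence in (0,1); if supplied the
#'   outcome is additionally dichotomised at the matching liability threshold.
#' @param seed Optional integer seed used by [simulate_trios()].
#'
#' @return An object of class `mrniv_config` (a validated list).
#' @seealso [simulate_trios()], [run_scenario()]
#' @examples
#' cfg <- scenario_config(n_families = 1000, theta = 0.75, am_rho = 0)
#' cfg$offspring_direct_effect
#' @export
scenario_config <- function(n_families = 10000L,
                            n_variants = 0L,
                            maf_range = c(0.1, 0.5),
                            grs_r2 = 0.005,
                            theta = 0.75,
                            am_rho = 0,
                            confounder_effect = 0.3,
                            offspring_direct_effect = NULL,
                            resid_var_y = 14,
                            duo_mode = FALSE,
                            genotyped_parent = c("mother", "father"),
                            outcome_prevalence = NULL,
                            seed = NULL) {
  genotyped_parent <- match.arg(genotyped_parent)
  cfg <- list(
    n_families = as.integer(n_families),
    n_variants = as.integer(n_variants),
    maf_range = as.numeric(maf_range),
    grs_r2 = grs_r2,
    theta = theta,
    am_rho = am_rho,
    confounder_effect = confounder_effect,
    offspring_direct_effect = offspring_direct_effect,
    resid_var_y = resid_var_y,
    duo_mode = isTRUE(duo_mode),
    genotyped_parent = genotyped_parent,
    outcome_prevalence = outcome_prevalence,
    seed = if (!is.null(seed)) as.integer(seed) else NULL
  )
  class(cfg) <- "mrniv_config"
  validate_config(cfg)
}

config_error <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

validate_config <- function(cfg) {
  if (is.na(cfg$n_families) || cfg$n_families < 1L)
    config_error("n_families", "must be >= 1")
  if (is.na(cfg$n_variants) || cfg$n_variants < 0L)
    config_error("n_variants", "must be 0 (score-only mode) or a positive count")
  if (length(cfg$maf_range) != 2L || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range >= 1) || cfg$maf_range[1] > cfg$maf_range[2])
    config_error("maf_range", "must be an increasing pair inside (0,1)")
  if (!is.numeric(cfg$grs_r2) || cfg$grs_r2 <= 0 || cfg$grs_r2 >= 1)
    config_error("grs_r2", "must lie in (0,1)")
  if (!is.numeric(cfg$theta) || cfg$theta < 0)
    config_error("theta", "must be >= 0")
  if (!is.numeric(cfg$am_rho) || cfg$am_rho < 0 || cfg$am_rho >= 1)
    config_error("am_rho", "must lie in [0,1)")
  if (!is.numeric(cfg$confounder_effect))
    config_error("confounder_effect", "must be numeric")
  if (!is.numeric(cfg$resid_var_y) || cfg$resid_var_y <= 0)
    config_error("resid_var_y", "must be > 0")
  if (!is.null(cfg$outcome_prevalence) &&
      (cfg$outcome_prevalence <= 0 || cfg$outcome_prevalence >= 1))
    config_error("outcome_prevalence", "must lie in (0,1)")
  # exposure residual variance: X = sqrt(r2) G + c U + e, Var(X) = 1
  resid_x <- 1 - cfg$grs_r2 - cfg$confounder_effect^2
  if (resid_x <= 0)
    config_error("confounder_effect",
                 "implies negative residual exposure variance (grs_r2 + confounder_effect^2 >= 1)")
  if (is.null(cfg$offspring_direct_effect)) {
    cfg$offspring_direct_effect <- solve_offspring_effect(cfg)
  } else if (!is.numeric(cfg$offspring_direct_effect)) {
    config_error("offspring_direct_effect", "must be numeric or NULL")
  }
  m <- theoretical_moments(cfg)
  if (m$var_y <= 0)
    config_error("resid_var_y", "implies non-positive outcome variance")
  cfg
}

# Population moments of the score-only generating model.
# G_p = T_p + N_p with T,N ~ N(0, 1/2); pairing on total scores gives
# corr(T_m, T_f) = am_rho / 2 and Var(G_o) = 1 + am_rho / 2.
theoretical_moments <- function(cfg) {
  r2 <- cfg$grs_r2; th <- cfg$theta; rho <- cfg$am_rho
  cc <- cfg$confounder_effect; dd <- cfg$offspring_direct_effect %||% 0
  var_go <- 1 + rho / 2
  cov_xx <- r2 * rho + cc^2                      # Cov(X_m, X_f)
  var_s <- 2 + 2 * cov_xx                        # Var(X_m + X_f)
  cov_s_go <- sqrt(r2) * (1 + rho)               # Cov(X_m + X_f, G_o)
  var_y <- th^2 * var_s + dd^2 * var_go + cc^2 + cfg$resid_var_y +
    2 * th * dd * cov_s_go + 4 * th * cc^2
  list(var_go = var_go, cov_xx = cov_xx, var_s = var_s,
       cov_s_go = cov_s_go, var_y = var_y,
       parental_genetic_share =
         (th^2 * var_s + dd^2 * var_go + 2 * th * dd * cov_s_go) / var_y)
}

# delta such that delta^2 Var(G_o) = grs_r2 * Var(Y); Var(Y) itself depends on
# delta, so solve the implied quadratic in closed form (positive root).
solve_offspring_effect <- function(cfg) {
  r2 <- cfg$grs_r2
  m0 <- theoretical_moments(within_cfg(cfg, offspring_direct_effect = 0))
  k0 <- m0$var_y
  k1 <- 2 * cfg$theta * m0$cov_s_go
  vg <- m0$var_go
  a <- (1 - r2) * vg
  b <- -r2 * k1
  cc <- -r2 * k0
  (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
}

within_cfg <- function(cfg, ...) {
  mods <- list(...)
  cfg[names(mods)] <- mods
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mrniv_config <- function(x, ...) {
  m <- theoretical_moments(x)
  cat("MR-NIV scenario configuration\n")
  cat(sprintf("  families: %d  variants: %s  duo mode: %s\n",
              x$n_families,
              if (x$n_variants == 0L) "score-only" else x$n_variants,
              if (x$duo_mode) x$genotyped_parent else "FALSE"))
  cat(sprintf("  theta: %.3g  grs_r2: %.3g  am_rho: %.3g  confounder: %.3g\n",
              x$theta, x$grs_r2, x$am_rho, x$confounder_effect))
  cat(sprintf("  offspring direct effect: %.4g  Var(Y): %.3g  parental+genetic share: %.1f%%\n",
              x$offspring_direct_effect, m$var_y, 100 * m$parental_genetic_share))
  invisible(x)
}

#' Read or write a scenario configuration as YAML
#'
#' Flat key-value YAML mirroring the [scenario_config()] fields.
#'
#' @param path File path.
#' @return `read_config()` returns an `mrniv_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(scenario_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(scenario_config, vals)
}

#' @rdname read_config
#' @param cfg An `mrniv_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "mrniv_config"))
  out <- unclass(cfg)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}
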
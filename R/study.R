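# Monte-Carlo study harness: runs a scenario configuration for many
# replicates, fits the requested estimators, and summarises bias, empirical
# variance, 95% CI coverage and mean CI width, each with its Monte-Carlo
# standard error.

harness_methods <- c("uvmr_niv", "uvmr_adj", "mvmr_niv", "mvmr_adj",
                     "composite", "proxy_divw", "proxy_gmm",
                     "proxy_grapple", "proxy_qhet")

#' Run a simulation scenario over many replicates
#'
#' Simulates `n_reps` independent datasets from `config` (replicate `r` uses
#' seed `master_seed + r`, so any replicate is reproducible in isolation),
#' fits each requested method, and returns performance rows per method and
#' parent plus a both-parent average row. Methods incompatible with the
#' scenario's data (e.g. multivariable models on duo genotypes) are skipped
#' with a logged reason; non-converged replicates are excluded and counted.
#'
#' @param config An [scenario_config()].
#' @param methods Character vector from
#'   `c("uvmr_niv", "uvmr_adj", "mvmr_niv", "mvmr_adj", "composite",
#'   "proxy_divw", "proxy_gmm", "proxy_grapple", "proxy_qhet")`.
#' @param n_reps Number of replicates (>= 2, since the empirical variance of
#'   the estimates is reported).
#' @param master_seed Integer master seed.
#' @param adjust_offspring_grs Adjust UVMR-NIV / MVMR-NIV / composite models
#'   for the offspring GRS (default TRUE; the full-GRS models always adjust).
#' @param robust HC1 robust standard errors for the 2SLS fits.
#' @return An `mrniv_performance` data.frame with columns `scenario`,
#'   `method`, `parent`, `bias`, `variance`, `coverage`, `ci_width`, their
#'   `*_mcse` companions, `n_reps` and `n_converged`.
#' @examples
#' cfg <- scenario_config(n_families = 500)
#' run_scenario(cfg, "uvmr_niv", n_reps = 5, master_seed = 1)
#' @export
run_scenario <- function(config, methods = c("uvmr_niv", "mvmr_niv"),
                         n_reps = 1000, master_seed = 1,
                         adjust_offspring_grs = TRUE, robust = TRUE) {
  stopifnot(inherits(config, "mrniv_config"))
  methods <- match.arg(methods, harness_methods, several.ok = TRUE)
  if (n_reps < 2)
    stop("n_reps must be >= 2 (the empirical variance needs replication)",
         call. = FALSE)
  methods <- check_method_compat(methods, config)
  rows <- vector("list", n_reps)
  any_proxy <- any(grepl("^proxy_", methods))
  any_individual <- any(!grepl("^proxy_", methods))
  for (r in seq_len(n_reps)) {
    ds <- simulate_trios(config, seed = master_seed + r)
    grs <- if (!is.null(ds$geno) && any_individual) grs_set(ds) else NULL
    psum <- if (any_proxy)
      tryCatch(proxy_summaries(ds), error = function(e) NULL) else NULL
    fits <- lapply(methods, function(m) {
      fit_one_method(ds, m, grs, adjust_offspring_grs, robust, psum)
    })
    df <- do.call(rbind, fits)
    df$rep <- r
    rows[[r]] <- df
  }
  est <- do.call(rbind, rows)
  scen <- sprintf("%s/%s/%s",
                  if (config$theta > 0) "causal" else "null",
                  if (config$am_rho > 0) "am" else "noam",
                  if (config$duo_mode) "duo" else "trio")
  out <- summarise_performance(est, theta_true = config$theta, scenario = scen)
  class(out) <- c("mrniv_performance", "data.frame")
  out
}

check_method_compat <- function(methods, config) {
  drop <- character(0)
  if (config$duo_mode) {
    bad <- intersect(methods, c("mvmr_niv", "mvmr_adj", "composite"))
    if (length(bad)) {
      message("skipping method(s) requiring trio genotypes on duo data: ",
              paste(bad, collapse = ", "))
      drop <- c(drop, bad)
    }
  }
  if (config$n_variants == 0L) {
    bad <- intersect(methods, grep("^proxy_", methods, value = TRUE))
    if (length(bad)) {
      message("skipping summary-statistic method(s) requiring per-variant mode: ",
              paste(bad, collapse = ", "))
      drop <- c(drop, bad)
    }
  } else if (!config$duo_mode && any(grepl("^proxy_", methods))) {
    message("note: proxy methods on trio data will proxy the father from offspring alleles")
  }
  out <- setdiff(methods, drop)
  if (!length(out)) stop("no compatible methods left to run", call. = FALSE)
  out
}

estimate_row <- function(method, parent, est, coef = 1) {
  data.frame(
    method = method, parent = parent,
    beta = unname(est$beta[coef]), se = unname(est$se[coef]),
    ci_low = unname(est$ci_low[coef]), ci_high = unname(est$ci_high[coef]),
    converged = !is.na(est$beta[coef]) &&
      (is.null(est$converged) || isTRUE(est$converged)),
    stringsAsFactors = FALSE
  )
}

fit_one_method <- function(ds, method, grs, adjust, robust, psum = NULL) {
  cfg <- ds$config
  parents <- if (cfg$duo_mode) cfg$genotyped_parent else c("mother", "father")
  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  rows <- list()
  if (method %in% c("uvmr_niv", "uvmr_adj")) {
    for (p in parents) {
      est <- safe(if (method == "uvmr_niv")
        uvmr_niv(ds, p, adjust_offspring_grs = adjust, grs = grs, robust = robust)
      else uvmr_adjusted(ds, p, grs = grs, robust = robust))
      rows[[p]] <- if (is.null(est)) failed_row(method, p) else
        estimate_row(method, p, est)
    }
  } else if (method == "mvmr_niv") {
    est <- safe(mvmr_niv(ds, adjust_offspring_grs = adjust, grs = grs,
                         robust = robust))
    rows <- mvmr_rows(method, est)
  } else if (method == "mvmr_adj") {
    est <- safe(mvmr_adjusted(ds, grs = grs, robust = robust))
    rows <- mvmr_rows(method, est)
  } else if (method == "composite") {
    est <- safe(composite_parent(ds, adjust_offspring_grs = adjust, grs = grs,
                                 robust = robust))
    rows$both <- if (is.null(est)) failed_row(method, "both") else
      estimate_row(method, "both", est)
  } else if (grepl("^proxy_", method)) {
    inner <- sub("^proxy_", "", method)
    inner <- if (inner == "gmm") "cue_gmm" else inner
    est <- if (is.null(psum)) NULL else
      safe(proxy_mvmr_niv(ds, estimator = inner, summaries = psum))
    p <- if (is.null(est)) parents[1] else est$genotyped_parent
    rows[[p]] <- if (is.null(est)) failed_row(method, p) else
      estimate_row(method, p, est, coef = 1)
  }
  do.call(rbind, rows)
}

mvmr_rows <- function(method, est) {
  if (is.null(est))
    return(list(mother = failed_row(method, "mother"),
                father = failed_row(method, "father")))
  list(mother = estimate_row(method, "mother", est, "mother"),
       father = estimate_row(method, "father", est, "father"))
}

failed_row <- function(method, parent) {
  data.frame(method = method, parent = parent, beta = NA_real_, se = NA_real_,
             ci_low = NA_real_, ci_high = NA_real_, converged = FALSE,
             stringsAsFactors = FALSE)
}

summarise_performance <- function(est, theta_true, scenario) {
  pieces <- list()
  for (m in unique(est$method)) {
    sub <- est[est$method == m, ]
    parents <- unique(sub$parent)
    per_parent <- lapply(parents, function(p) {
      s <- sub[sub$parent == p, ]
      cbind(data.frame(scenario = scenario, method = m, parent = p,
                       stringsAsFactors = FALSE),
            metric_block(s, theta_true))
    })
    per_parent <- do.call(rbind, per_parent)
    pieces[[m]] <- per_parent
    if (all(c("mother", "father") %in% parents)) {
      avg <- per_parent[per_parent$parent %in% c("mother", "father"), ]
      num <- vapply(avg, is.numeric, logical(1))
      row <- avg[1, ]
      row$parent <- "average"
      row[num] <- as.list(colMeans(avg[num]))
      pieces[[paste0(m, "_avg")]] <- row
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

metric_block <- function(s, theta_true) {
  ok <- s$converged & !is.na(s$beta)
  b <- s$beta[ok]
  R <- length(b)
  covered <- s$ci_low[ok] <= theta_true & theta_true <= s$ci_high[ok]
  width <- s$ci_high[ok] - s$ci_low[ok]
  has_ci <- any(!is.na(covered))
  cover <- if (has_ci) mean(covered, na.rm = TRUE) else NA_real_
  vb <- stats::var(b)
  data.frame(
    bias = mean(b) - theta_true,
    variance = vb,
    coverage = cover,
    ci_width = if (has_ci) mean(width, na.rm = TRUE) else NA_real_,
    bias_mcse = stats::sd(b) / sqrt(R),
    variance_mcse = vb * sqrt(2 / (R - 1)),
    coverage_mcse = if (has_ci) sqrt(cover * (1 - cover) / sum(!is.na(covered)))
      else NA_real_,
    ci_width_mcse = if (has_ci) stats::sd(width, na.rm = TRUE) /
      sqrt(sum(!is.na(width))) else NA_real_,
    n_reps = nrow(s),
    n_converged = sum(ok)
  )
}

#' Performance measures for a set of replicate estimates
#'
#' Computes mean bias, empirical variance, 95% CI coverage and mean CI width
#' against a known true effect, each with its Monte-Carlo standard error
#' (bias: `sd/sqrt(R)`; variance: `var * sqrt(2/(R-1))`; coverage:
#' `sqrt(c(1-c)/R)`; width: empirical SE of the mean width).
#'
#' @param estimates A list of `mrniv_estimate` objects with scalar
#'   coefficients, or a data.frame with columns `beta`, `ci_low`, `ci_high`
#'   (optionally `converged`).
#' @param theta_true True effect.
#' @return A one-row data.frame of performance measures.
#' @examples
#' df <- data.frame(beta = c(0.7, 0.8), ci_low = c(0.5, 0.6),
#'                  ci_high = c(0.9, 1.0))
#' performance_metrics(df, 0.75)
#' @export
performance_metrics <- function(estimates, theta_true) {
  if (is.data.frame(estimates)) {
    df <- estimates
  } else {
    df <- do.call(rbind, lapply(estimates, function(e) {
      data.frame(beta = unname(e$beta[1]), ci_low = unname(e$ci_low[1]),
                 ci_high = unname(e$ci_high[1]))
    }))
  }
  if (is.null(df$converged)) df$converged <- !is.na(df$beta)
  if (nrow(df) < 2)
    stop("at least two replicate estimates are required", call. = FALSE)
  metric_block(df, theta_true)
}

#' Fixed-effect (inverse-variance) meta-analysis
#'
#' Pools estimates with weights `1/se^2`; the pooled standard error is
#' `(sum(se^-2))^(-1/2)`.
#'
#' @param estimates List of `mrniv_estimate` objects with scalar
#'   coefficients, or a data.frame with columns `beta` and `se`.
#' @return An `mrniv_estimate` with method `"meta_fixed"`.
#' @examples
#' meta_fixed(data.frame(beta = c(0.2, 0.4), se = c(0.1, 0.2)))
#' @export
meta_fixed <- function(estimates) {
  if (is.data.frame(estimates)) {
    b <- estimates$beta; se <- estimates$se
  } else {
    b <- vapply(estimates, function(e) unname(e$beta[1]), numeric(1))
    se <- vapply(estimates, function(e) unname(e$se[1]), numeric(1))
  }
  if (any(se <= 0)) stop("standard errors must be positive", call. = FALSE)
  w <- 1 / se^2
  new_estimate(beta = c(pooled = sum(w * b) / sum(w)),
               se = c(pooled = sqrt(1 / sum(w))),
               method = "meta_fixed", n_used = length(b))
}

#' Cochran's Q and I-squared across per-variant estimates
#'
#' Heterogeneity of variant-specific Wald ratios:
#' `Q = sum w_j (b_j - b_pooled)^2` with `w_j = 1/se_j^2`, and
#' `I2 = max(0, (Q - (J-1)) / Q) * 100`.
#'
#' @param beta Per-variant estimates (or a data.frame with `beta`, `se`).
#' @param se Their standard errors.
#' @return List with `Q`, `df`, `I2` (percent) and the pooled estimate.
#' @examples
#' heterogeneity_i2(c(0.2, 0.5, 0.3), c(0.1, 0.1, 0.1))
#' @export
heterogeneity_i2 <- function(beta, se = NULL) {
  if (is.data.frame(beta)) { se <- beta$se; beta <- beta$beta }
  if (any(se <= 0)) stop("standard errors must be positive", call. = FALSE)
  J <- length(beta)
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - pooled)^2)
  I2 <- if (Q > 0) max(0, (Q - (J - 1)) / Q) * 100 else 0
  list(Q = Q, df = J - 1, I2 = I2, pooled = pooled)
}

#' @export
print.mrniv_performance <- function(x, digits = 3, ...) {
  cat("MR-NIV simulation performance\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
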
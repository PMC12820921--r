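# Summary-statistic, weak-instrument-robust estimators. All operate on
# per-instrument association summaries (instrument-exposure and
# instrument-outcome regression coefficients with standard errors), the
# representation needed when per-variant instruments are individually very
# weak, as in proxy MVMR-NIV from duo data.

#' Per-variant association summaries
#'
#' Computes, for every instrument column, covariate-adjusted linear-regression
#' coefficients (and SEs) of each exposure and of the outcome on that
#' instrument. Missing instrument entries (e.g. families where a variant's
#' transmission could not be resolved) are handled by centring the instrument
#' within its observed set and setting it to zero elsewhere; the masked,
#' centred count is itself a deterministic function of the genotypes and so
#' remains a valid instrument, while keeping every regression a full-sample
#' regression that can be computed in a single matrix product.
#'
#' @param instruments n x J numeric matrix (NA allowed).
#' @param exposures n x K numeric matrix (or vector).
#' @param outcome Length-n numeric outcome.
#' @param covariates Optional n x C matrix (e.g. the offspring GRS).
#' @param min_var Instrument columns whose masked variance falls below this
#'   threshold are dropped with a warning (monomorphic or never resolved).
#' @return An object of class `mrniv_summaries`: list with `beta_x`, `se_x`
#'   (J x K), `beta_y`, `se_y` (length J), `J`, `K`, `kept` (indices of
#'   retained instrument columns).
#' @examples
#' z <- matrix(rbinom(600, 2, 0.3), 200, 3)
#' x <- rowSums(z) * 0.1 + rnorm(200)
#' y <- 0.5 * x + rnorm(200)
#' compute_variant_summaries(z, x, y)
#' @export
compute_variant_summaries <- function(instruments, exposures, outcome,
                                      covariates = NULL, min_var = 1e-12) {
  Z <- as.matrix(instruments)
  X <- as.matrix(exposures)
  y <- as.numeric(outcome)
  n <- length(y)
  stopifnot(nrow(Z) == n, nrow(X) == n)
  # mask-and-centre: observed entries centred within column, missing -> 0
  obs <- !is.na(Z)
  Zm <- Z
  mu <- colSums(Z * obs, na.rm = TRUE) / pmax(colSums(obs), 1)
  Zm <- sweep(Z, 2, mu, "-")
  Zm[!obs] <- 0
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    # constant covariate columns are absorbed by the intercept
    covariates <- covariates[, apply(covariates, 2, stats::sd) > 0, drop = FALSE]
    if (ncol(covariates) == 0L) covariates <- NULL
  }
  C <- cbind(rep(1, n), covariates)
  pc <- ncol(C)
  # Residualise on the covariates via normal equations. The residualised
  # instrument matrix is never formed: with Zt = Zm - C B (B = (C'C)^-1 C'Zm)
  # and Xt, yt orthogonal to C, Zt'Xt = Zm'Xt and diag(Zt'Zt) follows from
  # the projection correction. Keeps memory at one n x J matrix.
  CtCi <- solve(crossprod(C))
  resid_on_C <- function(M) M - C %*% (CtCi %*% crossprod(C, M))
  Xt <- resid_on_C(X)
  yt <- drop(resid_on_C(matrix(y, ncol = 1)))
  CtZ <- crossprod(C, Zm)                     # pc x J
  d <- colSums(Zm^2) - colSums(CtZ * (CtCi %*% CtZ))
  keep <- which(d / n > min_var)
  if (length(keep) < ncol(Zm))
    warning(sprintf("dropped %d instrument column(s) with (near-)zero variance",
                    ncol(Zm) - length(keep)), call. = FALSE)
  J <- length(keep); K <- ncol(X)
  num_x <- crossprod(Zm, Xt)[keep, , drop = FALSE]   # = Zt'Xt
  num_y <- drop(crossprod(Zm, yt))[keep]             # = Zt'yt
  d <- d[keep]
  beta_x <- matrix(NA_real_, J, K)
  se_x <- matrix(NA_real_, J, K)
  df <- n - pc - 1
  for (k in seq_len(K)) {
    bx <- num_x[, k] / d
    s2 <- (sum(Xt[, k]^2) - bx^2 * d) / df
    beta_x[, k] <- bx
    se_x[, k] <- sqrt(pmax(s2, 0) / d)
  }
  by <- num_y / d
  s2y <- (sum(yt^2) - by^2 * d) / df
  colnames(beta_x) <- colnames(se_x) <-
    colnames(X) %||% paste0("exposure", seq_len(K))
  out <- list(beta_x = beta_x, se_x = se_x,
              beta_y = by, se_y = sqrt(pmax(s2y, 0) / d),
              J = J, K = K, kept = keep)
  class(out) <- "mrniv_summaries"
  out
}

#' Construct an association-summary object from precomputed statistics
#'
#' @param beta_x,se_x J x K matrices (or length-J vectors for one exposure).
#' @param beta_y,se_y Length-J vectors.
#' @return An `mrniv_summaries` object (see [compute_variant_summaries()]).
#' @export
summary_associations <- function(beta_x, se_x, beta_y, se_y) {
  beta_x <- as.matrix(beta_x); se_x <- as.matrix(se_x)
  J <- nrow(beta_x); K <- ncol(beta_x)
  stopifnot(nrow(se_x) == J, ncol(se_x) == K,
            length(beta_y) == J, length(se_y) == J)
  if (any(se_y <= 0) || any(se_x < 0))
    stop("standard errors must be positive (se_x may be 0 in limit checks)",
         call. = FALSE)
  if (J < K) stop("need at least as many instruments as exposures", call. = FALSE)
  out <- list(beta_x = beta_x, se_x = se_x,
              beta_y = as.numeric(beta_y), se_y = as.numeric(se_y),
              J = J, K = K, kept = seq_len(J))
  class(out) <- "mrniv_summaries"
  out
}

#' @export
print.mrniv_summaries <- function(x, ...) {
  cat(sprintf("Variant association summaries: J = %d instruments, K = %d exposure(s)\n",
              x$J, x$K))
  invisible(x)
}

new_summary_estimate <- function(beta, se, method, objective_value = NA_real_,
                                 converged = TRUE, interpretable = NULL,
                                 extra = list()) {
  K <- length(beta)
  est <- c(list(
    beta = beta, se = se,
    ci_low = beta - stats::qnorm(0.975) * se,
    ci_high = beta + stats::qnorm(0.975) * se,
    method = method, objective_value = objective_value,
    converged = converged,
    interpretable = interpretable %||% rep(TRUE, K)
  ), extra)
  class(est) <- c("mrniv_summary_estimate", "mrniv_estimate")
  est
}

ivw_solve <- function(s) {
  A <- matrix(0, s$K, s$K); b <- numeric(s$K)
  for (j in seq_len(s$J)) {
    bx <- s$beta_x[j, ]
    A <- A + tcrossprod(bx) / s$se_y[j]^2
    b <- b + bx * s$beta_y[j] / s$se_y[j]^2
  }
  drop(solve(A, b))
}

#' Debiased inverse-variance-weighted estimator
#'
#' IVW with the instrument-exposure sampling variance subtracted from the
#' denominator, removing first-order weak-instrument (regression-dilution)
#' bias. Univariable form: `sum(bx * by / sy^2) / sum((bx^2 - sx^2) / sy^2)`;
#' the multivariable form solves the analogous moment system with the
#' `diag(sx^2)` correction. A non-positive-definite corrected matrix
#' (ultra-weak instruments) is flagged as non-convergence.
#'
#' @param s An `mrniv_summaries` object.
#' @return An `mrniv_summary_estimate`.
#' @export
divw <- function(s) {
  stopifnot(inherits(s, "mrniv_summaries"))
  A <- matrix(0, s$K, s$K); b <- numeric(s$K)
  for (j in seq_len(s$J)) {
    bx <- s$beta_x[j, ]
    A <- A + (tcrossprod(bx) - diag(s$se_x[j, ]^2, s$K)) / s$se_y[j]^2
    b <- b + bx * s$beta_y[j] / s$se_y[j]^2
  }
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  converged <- all(ev > 0)
  if (!converged && any(abs(ev) < .Machine$double.eps * max(abs(ev), 1)))
    return(new_summary_estimate(rep(NA_real_, s$K), rep(NA_real_, s$K),
                                "divw", converged = FALSE))
  beta <- drop(solve(A, b))
  # sandwich-style variance around the corrected moment system
  B <- matrix(0, s$K, s$K)
  for (j in seq_len(s$J)) {
    bx <- s$beta_x[j, ]
    g2 <- (s$beta_y[j] - sum(bx * beta))^2 + sum(beta^2 * s$se_x[j, ]^2)
    B <- B + g2 * tcrossprod(bx) / s$se_y[j]^4
  }
  Ai <- solve(A)
  se <- sqrt(pmax(diag(Ai %*% B %*% Ai), 0))
  names(beta) <- names(se) <- colnames(s$beta_x)
  new_summary_estimate(beta, se, "divw", converged = converged)
}

q_objective <- function(beta, s) {
  g <- s$beta_y - drop(s$beta_x %*% beta)
  v <- s$se_y^2 + drop(s$se_x^2 %*% beta^2)
  sum(g^2 / v)
}

q_gradient <- function(beta, s) {
  g <- s$beta_y - drop(s$beta_x %*% beta)
  v <- s$se_y^2 + drop(s$se_x^2 %*% beta^2)
  -2 * drop(crossprod(s$beta_x, g / v)) -
    2 * beta * drop(crossprod(s$se_x^2, g^2 / v^2))
}

gmm_starts <- function(s, n_starts) {
  b0 <- tryCatch(ivw_solve(s), error = function(e) rep(0, s$K))
  starts <- list(b0, 0.5 * b0, 1.5 * b0, rep(0, s$K))
  while (length(starts) < n_starts)
    starts[[length(starts) + 1L]] <- b0 + stats::rnorm(s$K, 0, 0.25 + 0.5 * abs(b0))
  starts
}

#' Continuously-updating GMM estimator
#'
#' Minimises the continuously-updating GMM objective with per-instrument
#' moments `g_j(beta) = beta_y_j - sum_k beta_k beta_x_jk` and weight
#' `1 / Var(g_j)(beta)` re-evaluated at `beta`, where
#' `Var(g_j)(beta) = se_y_j^2 + sum_k beta_k^2 se_x_jk^2`. Gradient-based
#' optimisation with multiple starts around the IVW solution; standard errors
#' from the GMM asymptotic variance `(sum bx bx' / v)^{-1}` at the optimum.
#'
#' @param s An `mrniv_summaries` object.
#' @param n_starts Number of optimisation starts (default 5).
#' @param tol Convergence tolerance passed to the optimiser.
#' @return An `mrniv_summary_estimate` with the objective value attained.
#' @export
cue_gmm <- function(s, n_starts = 5, tol = 1e-8) {
  stopifnot(inherits(s, "mrniv_summaries"))
  best <- NULL
  any_conv <- FALSE
  for (b0 in gmm_starts(s, n_starts)) {
    fit <- tryCatch(
      stats::optim(b0, q_objective, q_gradient, s = s, method = "BFGS",
                   control = list(reltol = tol, maxit = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    any_conv <- any_conv || fit$convergence == 0
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    return(new_summary_estimate(rep(NA_real_, s$K), rep(NA_real_, s$K),
                                "cue_gmm", converged = FALSE))
  beta <- best$par
  v <- s$se_y^2 + drop(s$se_x^2 %*% beta^2)
  info <- crossprod(s$beta_x / sqrt(v))
  se <- sqrt(diag(solve(info)))
  names(beta) <- names(se) <- colnames(s$beta_x)
  new_summary_estimate(beta, se, "cue_gmm", objective_value = best$value,
                       converged = any_conv)
}

#' Q-statistic heterogeneity-minimisation estimator
#'
#' Point estimate minimising the heterogeneity Q statistic
#' `sum_j (beta_y_j - sum_k beta_k beta_x_jk)^2 / (se_y_j^2 + sum_k beta_k^2
#' se_x_jk^2)`, whose weights acknowledge the uncertainty in the
#' instrument-exposure associations. By default only the point estimate is
#' returned (interval estimation for this estimator is expensive); a
#' parametric bootstrap CI is available. Minimisation uses a coarse grid
#' around the per-instrument ratios followed by derivative-free polishing.
#'
#' @param s An `mrniv_summaries` object.
#' @param ci `"none"` (default) or `"bootstrap"`.
#' @param boot_reps Bootstrap replicates (default 200).
#' @param seed Optional seed for the bootstrap.
#' @return An `mrniv_summary_estimate`; `se`/CI are NA unless bootstrapped.
#' @export
qhet <- function(s, ci = c("none", "bootstrap"), boot_reps = 200, seed = NULL) {
  stopifnot(inherits(s, "mrniv_summaries"))
  ci <- match.arg(ci)
  fit <- qhet_minimise(s)
  beta <- fit$par
  se <- rep(NA_real_, s$K)
  extra <- list()
  if (ci == "bootstrap") {
    if (!is.null(seed)) set.seed(as.integer(seed))
    bs <- replicate(boot_reps, {
      sb <- s
      sb$beta_y <- stats::rnorm(s$J, s$beta_y, s$se_y)
      sb$beta_x <- s$beta_x + matrix(stats::rnorm(s$J * s$K), s$J, s$K) * s$se_x
      qhet_minimise(sb)$par
    })
    bs <- matrix(bs, nrow = s$K)
    se <- apply(bs, 1, stats::sd)
    extra$ci_boot <- apply(bs, 1, stats::quantile, probs = c(0.025, 0.975))
  }
  names(beta) <- colnames(s$beta_x)
  est <- new_summary_estimate(beta, se, "qhet", objective_value = fit$value,
                              converged = fit$converged, extra = extra)
  if (ci == "none") est$ci_low <- est$ci_high <- rep(NA_real_, s$K)
  est
}

qhet_minimise <- function(s) {
  # coarse grid on each coordinate around the spread of per-instrument ratios,
  # then Nelder-Mead / BFGS polish from the best grid point and the IVW start
  ratios <- s$beta_y / s$beta_x[, 1]
  ctr <- stats::median(ratios[is.finite(ratios)], na.rm = TRUE)
  if (!is.finite(ctr)) ctr <- 0
  span <- max(1, 2 * stats::mad(ratios[is.finite(ratios)], na.rm = TRUE),
              abs(ctr))
  grid1 <- seq(ctr - span, ctr + span, length.out = 41)
  starts <- gmm_starts(s, 3)
  if (s$K == 1) {
    vals <- vapply(grid1, function(b) q_objective(b, s), numeric(1))
    starts <- c(starts, list(grid1[which.min(vals)]))
  }
  best <- NULL
  for (b0 in starts) {
    fit <- tryCatch(
      stats::optim(b0, q_objective, q_gradient, s = s, method = "BFGS",
                   control = list(reltol = 1e-10, maxit = 1000)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    return(list(par = rep(NA_real_, s$K), value = NA_real_, converged = FALSE))
  list(par = best$par, value = best$value, converged = best$convergence == 0)
}

tukey_rho <- function(t, c = 4.685) {
  inside <- abs(t) <= c
  out <- rep(c^2 / 6, length(t))
  out[inside] <- c^2 / 6 * (1 - (1 - (t[inside] / c)^2)^3)
  out
}

tukey_kappa <- function(c = 4.685) {
  # E[psi_c(Z) * Z] for Z ~ N(0,1); psi = rho'
  stats::integrate(function(z) z^2 * (1 - (z / c)^2)^2 * stats::dnorm(z),
                   -c, c)$value
}

#' Robust profile-likelihood estimator with overdispersion
#'
#' Maximises the profile (pseudo-)likelihood of the standardised residuals
#' `t_j = (beta_y_j - sum_k beta_k beta_x_jk) / sqrt(se_y_j^2 + sum_k beta_k^2
#' se_x_jk^2 + tau2)`, with an overdispersion parameter `tau2 >= 0` absorbing
#' balanced horizontal pleiotropy and an optional bounded (Tukey biweight)
#' loss limiting the influence of outlying instruments. With squared loss and
#' `tau2 = 0` this is the adjusted-profile-score estimator for a single
#' exposure. Standard errors come from the observed information of the
#' profiled objective.
#'
#' @param s An `mrniv_summaries` object.
#' @param loss `"robust"` (Tukey biweight, default) or `"squared"`.
#' @param tuning Tukey tuning constant (default 4.685).
#' @param n_starts Number of optimisation starts.
#' @return An `mrniv_summary_estimate` carrying `tau2`.
#' @export
grapple_profile <- function(s, loss = c("robust", "squared"), tuning = 4.685,
                            n_starts = 5) {
  stopifnot(inherits(s, "mrniv_summaries"))
  loss <- match.arg(loss)
  kappa <- if (loss == "squared") 1 else tukey_kappa(tuning)
  rho_fun <- if (loss == "squared") function(t) t^2 / 2 else
    function(t) tukey_rho(t, tuning)
  obj <- function(par) {
    beta <- par[seq_len(s$K)]
    tau2 <- par[s$K + 1L]^2
    v <- s$se_y^2 + drop(s$se_x^2 %*% beta^2) + tau2
    g <- s$beta_y - drop(s$beta_x %*% beta)
    sum(rho_fun(g / sqrt(v))) + kappa / 2 * sum(log(v))
  }
  best <- NULL
  any_conv <- FALSE
  for (b0 in gmm_starts(s, n_starts)) {
    fit <- tryCatch(
      stats::optim(c(b0, 0.1), obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-10, maxit = 2000)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    any_conv <- any_conv || fit$convergence == 0
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    return(new_summary_estimate(rep(NA_real_, s$K), rep(NA_real_, s$K),
                                "grapple", converged = FALSE))
  H <- tryCatch(stats::optimHess(best$par, obj), error = function(e) NULL)
  se <- rep(NA_real_, s$K)
  if (!is.null(H)) {
    Hi <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(Hi)) {
      dg <- diag(Hi)[seq_len(s$K)]
      se <- sqrt(pmax(dg, 0))
    }
  }
  beta <- best$par[seq_len(s$K)]
  names(beta) <- names(se) <- colnames(s$beta_x)
  new_summary_estimate(beta, se, "grapple", objective_value = best$value,
                       converged = any_conv,
                       extra = list(tau2 = best$par[s$K + 1L]^2, loss = loss))
}

#' Proxy MVMR-NIV for duo data
#'
#' Multivariable MR-NIV when only one parent is genotyped: the genotyped
#' parent's phenotype is instrumented by that parent's per-variant
#' non-inherited allele counts, and the non-genotyped parent's phenotype by
#' the offspring alleles that must have come from that parent (resolved by
#' [resolve_duo()]). Associations are adjusted for the offspring's full GRS.
#' Because the proxy instruments are inherited alleles, the proxied parent's
#' coefficient is an exclusion-restriction violation and is flagged
#' `interpretable = FALSE`; only the genotyped parent's estimate should be
#' read. Per-variant instruments from duo resolution are individually very
#' weak, hence the weak-instrument-robust summary estimators.
#'
#' @param dataset A per-variant, duo-mode `mrniv_dataset` (or an equivalent
#'   list with `geno` and `pheno` components).
#' @param estimator One of `"divw"`, `"cue_gmm"`, `"grapple"`, `"qhet"`.
#' @param summaries Optional precomputed [proxy_summaries()] result; supply it
#'   when running several estimators on the same dataset so the resolution and
#'   per-variant regressions are done once.
#' @param ... Passed to the chosen estimator.
#' @return An `mrniv_summary_estimate` with per-parent coefficients and
#'   `interpretable` flags.
#' @export
proxy_mvmr_niv <- function(dataset,
                           estimator = c("divw", "cue_gmm", "grapple", "qhet"),
                           summaries = NULL, ...) {
  estimator <- match.arg(estimator)
  s <- summaries %||% proxy_summaries(dataset)
  est <- switch(estimator,
    divw = divw(s),
    cue_gmm = cue_gmm(s, ...),
    grapple = grapple_profile(s, ...),
    qhet = qhet(s, ...)
  )
  est$method <- paste0("proxy_", estimator)
  est$interpretable <- stats::setNames(c(TRUE, FALSE),
                                       colnames(s$beta_x))
  est$genotyped_parent <- attr(s, "genotyped_parent")
  est
}

#' @rdname proxy_mvmr_niv
#' @details `proxy_summaries()` performs the duo resolution and the
#'   offspring-GRS-adjusted per-variant regressions that every proxy estimator
#'   shares, returning an `mrniv_summaries` object whose first-exposure column
#'   is the genotyped parent.
#' @export
proxy_summaries <- function(dataset) {
  stopifnot(inherits(dataset, "mrniv_dataset"))
  geno <- dataset$geno
  if (is.null(geno))
    stop("proxy MVMR-NIV requires per-variant genotypes", call. = FALSE)
  have_m <- !is.null(geno$geno_m)
  have_f <- !is.null(geno$geno_f)
  if (have_m && have_f)
    warning("both parents genotyped; proxying the father from offspring alleles",
            call. = FALSE)
  gp <- if (have_m) geno$geno_m else geno$geno_f
  genotyped <- if (have_m) "mother" else "father"
  n <- nrow(gp); J <- ncol(gp)
  # direct table lookup; avoids materialising a families x variants data.frame
  code <- gp * 3L + geno$geno_o + 1L
  resolved <- duo_case_table[, "status"][code] == 1
  resolved[is.na(resolved)] <- FALSE
  z_niv <- duo_case_table[, "p_non_inherited"][code]
  z_niv[!resolved] <- NA
  z_proxy <- duo_case_table[, "other_contributed"][code]
  z_proxy[!resolved] <- NA
  Z <- cbind(matrix(z_niv, n, J), matrix(z_proxy, n, J))
  g_o <- build_grs(geno$geno_o, geno$variants$weight)$score
  if (genotyped == "mother") {
    expos <- cbind(mother = dataset$pheno$x_m, father = dataset$pheno$x_f)
  } else {
    expos <- cbind(father = dataset$pheno$x_f, mother = dataset$pheno$x_m)
  }
  s <- compute_variant_summaries(Z, expos, dataset$pheno$y,
                                 covariates = cbind(offspring_grs = g_o))
  if (s$J < s$K + 2)
    stop(sprintf("too few resolved instruments (%d) for %d exposures",
                 s$J, s$K), call. = FALSE)
  attr(s, "genotyped_parent") <- genotyped
  # aggregate weighted scores over resolved variants (handy for comparing the
  # proxy estimators against the aggregate-score UVMR-NIV on the same data)
  w <- geno$variants$weight
  zn <- z_niv; zn[is.na(zn)] <- 0
  zp <- z_proxy; zp[is.na(zp)] <- 0
  attr(s, "scores") <- data.frame(
    niv_grs = drop(matrix(zn, n, J) %*% w),
    proxy_grs = drop(matrix(zp, n, J) %*% w),
    offspring_grs = g_o
  )
  s
}
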
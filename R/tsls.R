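#' Two-stage least squares
#'
#' Standard 2SLS for one or more endogenous exposures, with exogenous
#' covariates included in both stages and heteroskedasticity-robust (HC1)
#' standard errors by default. 95% confidence intervals use the normal
#' approximation. Instrument strength is reported as the partial first-stage
#' F statistic for a single exposure and as Sanderson-Windmeijer conditional
#' F statistics (one per exposure) for multivariable models.
#'
#' @param outcome Numeric outcome vector.
#' @param exposures Numeric vector or matrix (n x K) of endogenous exposures.
#' @param instruments Numeric vector or matrix (n x J), J >= K.
#' @param covariates Optional numeric vector/matrix of exogenous covariates.
#' @param robust Use HC1 robust standard errors (default) or classical ones.
#' @param method Method tag stored on the estimate.
#' @return An object of class `mrniv_estimate`: list with `beta`, `se`,
#'   `ci_low`, `ci_high` (one entry per exposure), `first_stage_F`, `n_used`,
#'   `method`.
#' @examples
#' z <- rnorm(500); x <- z + rnorm(500); y <- 0.5 * x + rnorm(500)
#' tsls(y, x, z)
#' @export
tsls <- function(outcome, exposures, instruments, covariates = NULL,
                 robust = TRUE, method = "tsls") {
  y <- as.numeric(outcome)
  X <- as.matrix(exposures)
  Z <- as.matrix(instruments)
  n <- length(y)
  if (nrow(X) != n || nrow(Z) != n)
    stop("outcome, exposures and instruments must have aligned rows", call. = FALSE)
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    if (nrow(C) != n) stop("covariates must have aligned rows", call. = FALSE)
  } else C <- NULL
  K <- ncol(X); J <- ncol(Z)
  if (J < K)
    stop("under-identified model: fewer instruments than exposures", call. = FALSE)
  if (any(apply(Z, 2, stats::sd) == 0))
    stop("zero-variance (constant) instrument column", call. = FALSE)
  W <- cbind(`(Intercept)` = rep(1, n), C)
  Zfull <- cbind(W, Z)
  Xfull <- cbind(W, X)
  p <- ncol(Xfull)
  if (n <= p)
    stop("not enough observations for the number of parameters", call. = FALSE)
  qz <- qr(Zfull)
  if (qz$rank < ncol(Zfull))
    stop("rank-deficient instrument matrix", call. = FALSE)
  Xhat <- qr.fitted(qz, Xfull)
  XtX <- crossprod(Xhat)
  if (qr(XtX)$rank < p)
    stop("rank-deficient projected design (under-identification)", call. = FALSE)
  XtXi <- solve(XtX)
  beta_all <- drop(XtXi %*% crossprod(Xhat, y))
  names(beta_all) <- colnames(Xfull)
  u <- y - drop(Xfull %*% beta_all)
  if (robust) {
    meat <- crossprod(Xhat * u)
    vc <- XtXi %*% meat %*% XtXi * n / (n - p)
  } else {
    vc <- XtXi * sum(u^2) / (n - p)
  }
  idx <- seq.int(ncol(W) + 1L, p)
  beta <- beta_all[idx]
  se <- sqrt(diag(vc)[idx])
  expo_names <- colnames(X) %||% if (K == 1) "exposure" else paste0("exposure", 1:K)
  names(beta) <- names(se) <- expo_names
  fstat <- first_stage_F(X, Z, W)
  new_estimate(beta = beta, se = se, method = method,
               first_stage_F = fstat, n_used = n)
}

# Partial F of the instruments (UVMR) or Sanderson-Windmeijer conditional F
# per exposure (MVMR).
first_stage_F <- function(X, Z, W) {
  n <- nrow(X); K <- ncol(X); J <- ncol(Z)
  partial_F <- function(yv, extra) {
    q0 <- qr(W); q1 <- qr(cbind(W, extra))
    rss0 <- sum(qr.resid(q0, yv)^2)
    rss1 <- sum(qr.resid(q1, yv)^2)
    df1 <- ncol(extra); df2 <- n - ncol(W) - df1
    ((rss0 - rss1) / df1) / (rss1 / df2)
  }
  if (K == 1) return(partial_F(X[, 1], Z))
  vapply(seq_len(K), function(k) {
    # 2SLS of X_k on the other exposures, then strength of Z for the residual
    fit <- tryCatch(
      tsls_raw(X[, k], X[, -k, drop = FALSE], Z, W),
      error = function(e) NULL
    )
    if (is.null(fit)) return(NA_real_)
    eps <- fit$residuals
    partial_F(eps, Z) * J / (J - K + 1)
  }, numeric(1))
}

# minimal 2SLS returning residuals only (internal; W already holds intercept)
tsls_raw <- function(y, X, Z, W) {
  Zfull <- cbind(W, Z)
  Xfull <- cbind(W, X)
  Xhat <- qr.fitted(qr(Zfull), Xfull)
  beta <- solve(crossprod(Xhat), crossprod(Xhat, y))
  list(beta = drop(beta), residuals = y - drop(Xfull %*% beta))
}

new_estimate <- function(beta, se, method, first_stage_F = NA_real_,
                         n_used = NA_integer_, extra = list()) {
  est <- c(list(
    beta = beta, se = se,
    ci_low = beta - stats::qnorm(0.975) * se,
    ci_high = beta + stats::qnorm(0.975) * se,
    method = method, first_stage_F = first_stage_F, n_used = n_used
  ), extra)
  class(est) <- "mrniv_estimate"
  est
}

#' @export
print.mrniv_estimate <- function(x, ...) {
  cat(sprintf("MR estimate [%s], n = %s\n", x$method, format(x$n_used)))
  tab <- data.frame(beta = x$beta, se = x$se,
                    ci_low = x$ci_low, ci_high = x$ci_high)
  print(round(tab, 4))
  if (!all(is.na(x$first_stage_F)))
    cat("first-stage F:", paste(round(x$first_stage_F, 1), collapse = ", "), "\n")
  if (!is.null(x$or))
    cat(sprintf("OR: %.3f (%.3f, %.3f)\n", x$or, x$or_ci_low, x$or_ci_high))
  invisible(x)
}

#' Wald ratio estimator
#'
#' Ratio of the instrument-outcome association to the instrument-exposure
#' association, with first-order delta-method standard error
#' `|se_gy / beta_gx|`. Equivalent to 2SLS with a single instrument for a
#' linear outcome model; with `link = "logistic"` the numerator is a
#' log-odds-ratio coefficient and the estimate is also reported exponentiated
#' on the odds-ratio scale.
#'
#' @param beta_gy,se_gy Instrument-outcome association and its SE.
#' @param beta_gx,se_gx Instrument-exposure association and its SE.
#' @param link `"linear"` or `"logistic"` (affects reporting only).
#' @return An `mrniv_estimate`; for the logistic link it carries `or`,
#'   `or_ci_low`, `or_ci_high`.
#' @examples
#' wald_ratio(0.3, 0.1, 0.5, 0.05)
#' @export
wald_ratio <- function(beta_gy, se_gy, beta_gx, se_gx,
                       link = c("linear", "logistic")) {
  link <- match.arg(link)
  if (beta_gx == 0)
    stop("undefined ratio: instrument-exposure association is zero", call. = FALSE)
  if (abs(beta_gx / se_gx) < 2)
    warning("weak instrument: |beta_gx / se_gx| < 2; the Wald ratio may be unstable",
            call. = FALSE)
  beta <- beta_gy / beta_gx
  se <- abs(se_gy / beta_gx)
  extra <- list(link = link)
  if (link == "logistic") {
    extra$or <- exp(beta)
    extra$or_ci_low <- exp(beta - stats::qnorm(0.975) * se)
    extra$or_ci_high <- exp(beta + stats::qnorm(0.975) * se)
  }
  new_estimate(beta = c(exposure = beta), se = c(exposure = se),
               method = if (link == "linear") "wald_linear" else "wald_logistic",
               extra = extra)
}
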
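#' Simulate trio or duo family data
#'
#' Generates mother-father-offspring families under the causal diagram that
#' motivates MR with non-inherited variants: each parent's genetic risk score
#' (GRS) influences their own standardised exposure, the parental exposures and
#' (optionally) the offspring's own GRS influence the offspring outcome, a
#' shared environmental confounder loads on both parental exposures and the
#' outcome, and assortative mating (if any) pairs parents by their genotypic
#' scores.
#'
#' In score-only mode (`n_variants = 0`) each parental GRS is a standard-normal
#' score split into independent transmitted and non-transmitted halves of
#' variance 1/2; the offspring GRS is the sum of the two transmitted halves.
#' In per-variant mode explicit biallelic genotypes are simulated under
#' Hardy-Weinberg equilibrium and Mendelian transmission, with per-variant
#' GWAS-style weights drawn once from the same seed.
#'
#' @param config An [scenario_config()] object.
#' @param seed Integer seed; overrides `config$seed` when supplied.
#'
#' @return An object of class `mrniv_dataset`: a list with the phenotype table
#'   `pheno` (columns `family`, `x_m`, `x_f`, `y`, optionally `y_bin`, `u`),
#'   score vectors `grs` (`g_m`, `g_f`, `g_o`, and transmitted/non-transmitted
#'   halves `t_m`, `n_m`, `t_f`, `n_f`), per-variant matrices (`geno_m`,
#'   `geno_f`, `geno_o`, `trans_m`, `trans_f` and a `variants` weight table) in
#'   per-variant mode, and a `truth` block recording the parameters used.
#'   In duo mode the non-genotyped parent's genotype components are `NULL`
#'   (phenotypes are retained).
#' @examples
#' d <- simulate_trios(scenario_config(n_families = 500, seed = 1))
#' summary(stats::lm(d$pheno$x_m ~ d$grs$g_m))$r.squared
#' @export
simulate_trios <- function(config, seed = NULL) {
  stopifnot(inherits(config, "mrniv_config"))
  config <- validate_config(config)
  seed <- seed %||% config$seed
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- config$n_families

  if (config$n_variants == 0L) {
    t_m <- stats::rnorm(n, 0, sqrt(0.5)); n_m <- stats::rnorm(n, 0, sqrt(0.5))
    t_f <- stats::rnorm(n, 0, sqrt(0.5)); n_f <- stats::rnorm(n, 0, sqrt(0.5))
    g_m <- t_m + n_m
    g_f <- t_f + n_f
    if (config$am_rho > 0) {
      pair <- mate_assortatively(g_m, g_f, config$am_rho)
      t_f <- t_f[pair]; n_f <- n_f[pair]; g_f <- g_f[pair]
    }
    geno <- NULL
    g_o <- t_m + t_f
  } else {
    J <- config$n_variants
    maf <- stats::runif(J, config$maf_range[1], config$maf_range[2])
    weights <- abs(stats::rnorm(J, 0, 1))
    geno_m <- draw_genotypes(n, maf)
    geno_f <- draw_genotypes(n, maf)
    sc_mean <- sum(weights * 2 * maf)
    sc_sd <- sqrt(sum(weights^2 * 2 * maf * (1 - maf)))
    score <- function(g) (as.vector(g %*% weights) - sc_mean) / sc_sd
    g_m <- score(geno_m)
    g_f <- score(geno_f)
    if (config$am_rho > 0) {
      pair <- mate_assortatively(g_m, g_f, config$am_rho)
      geno_f <- geno_f[pair, , drop = FALSE]
      g_f <- g_f[pair]
    }
    tr_m <- transmit(geno_m)
    tr_f <- transmit(geno_f)
    geno_o <- tr_m$transmitted + tr_f$transmitted
    # transmitted/non-transmitted halves on the same standardised scale
    half <- function(h) (as.vector(h %*% weights) - sc_mean / 2) / sc_sd
    t_m <- half(tr_m$transmitted); n_m <- half(tr_m$non_transmitted)
    t_f <- half(tr_f$transmitted); n_f <- half(tr_f$non_transmitted)
    g_o <- t_m + t_f
    geno <- list(
      geno_m = geno_m, geno_f = geno_f, geno_o = geno_o,
      trans_m = tr_m$transmitted, trans_f = tr_f$transmitted,
      variants = data.frame(
        variant_id = sprintf("v%03d", seq_len(J)),
        maf = maf, weight = weights,
        effect_allele = "A", other_allele = "G",
        stringsAsFactors = FALSE
      )
    )
  }

  u <- stats::rnorm(n)
  a <- sqrt(config$grs_r2)
  cc <- config$confounder_effect
  sd_ex <- sqrt(1 - config$grs_r2 - cc^2)
  x_m <- a * g_m + cc * u + stats::rnorm(n, 0, sd_ex)
  x_f <- a * g_f + cc * u + stats::rnorm(n, 0, sd_ex)
  th <- config$theta
  dd <- config$offspring_direct_effect
  y <- th * x_m + th * x_f + dd * g_o + cc * u +
    stats::rnorm(n, 0, sqrt(config$resid_var_y))

  pheno <- data.frame(family = seq_len(n), x_m = x_m, x_f = x_f, y = y, u = u)
  if (!is.null(config$outcome_prevalence))
    pheno$y_bin <- binarize_outcome(y, config$outcome_prevalence)

  ds <- list(
    pheno = pheno,
    grs = list(g_m = g_m, g_f = g_f, g_o = g_o,
               t_m = t_m, n_m = n_m, t_f = t_f, n_f = n_f),
    geno = geno,
    config = config,
    truth = list(theta = th, am_rho = config$am_rho,
                 offspring_direct_effect = dd, seed = seed)
  )
  if (config$duo_mode) {
    drop <- if (config$genotyped_parent == "mother") "father" else "mother"
    if (drop == "father") {
      ds$grs$g_f <- ds$grs$t_f <- ds$grs$n_f <- NULL
      if (!is.null(ds$geno)) ds$geno$geno_f <- ds$geno$trans_f <- NULL
    } else {
      ds$grs$g_m <- ds$grs$t_m <- ds$grs$n_m <- NULL
      if (!is.null(ds$geno)) ds$geno$geno_m <- ds$geno$trans_m <- NULL
    }
  }
  class(ds) <- "mrniv_dataset"
  ds
}

draw_genotypes <- function(n, maf) {
  J <- length(maf)
  # HWE: dosage ~ Binomial(2, maf); the haplotype split happens in transmit()
  matrix(stats::rbinom(n * J, 2L, rep(maf, each = n)), n, J)
}

#' @export
print.mrniv_dataset <- function(x, ...) {
  cat(sprintf("MR-NIV dataset: %d families, %s mode%s\n",
              nrow(x$pheno),
              if (is.null(x$geno)) "score-only" else
                sprintf("per-variant (%d variants)", ncol(x$geno$geno_o)),
              if (x$config$duo_mode)
                sprintf(", duo (%s genotyped)", x$config$genotyped_parent) else ""))
  invisible(x)
}

#' Pair two score pools under assortative mating
#'
#' Gaussian-copula rank pairing: a latent bivariate-normal sample with
#' correlation `rho` is drawn, and the maternal (paternal) scores are matched
#' to the ranks of its first (second) coordinate. Each individual is used
#' exactly once, and for normally distributed scores the Pearson correlation
#' of the paired scores converges to `rho`.
#'
#' @param maternal_scores,paternal_scores Equal-length numeric vectors.
#' @param rho Target correlation in [0,1).
#' @param seed Optional integer seed.
#' @return An integer permutation `p` such that mother `i` is paired with
#'   father `p[i]`.
#' @examples
#' p <- mate_assortatively(rnorm(2000), rnorm(2000), 0.3, seed = 1)
#' @export
mate_assortatively <- function(maternal_scores, paternal_scores, rho, seed = NULL) {
  if (length(maternal_scores) != length(paternal_scores))
    stop("score pools must have equal length", call. = FALSE)
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1)
    stop("rho must lie in [0,1)", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(maternal_scores)
  if (rho == 0) return(sample.int(n))
  l1 <- stats::rnorm(n)
  l2 <- rho * l1 + sqrt(1 - rho^2) * stats::rnorm(n)
  # mother with rank r of her score takes the latent pair whose first
  # coordinate has rank r; her partner is the father whose score rank equals
  # the rank of the second coordinate of that pair.
  pair <- integer(n)
  m_ord <- order(maternal_scores)
  f_ord <- order(paternal_scores)
  pair[m_ord] <- f_ord[rank(l2, ties.method = "first")[order(l1)]]
  pair
}

#' Mendelian transmission of parental dosages
#'
#' Splits each parental dosage into a transmitted and a non-transmitted
#' haplotype dosage: homozygotes transmit deterministically, heterozygotes
#' transmit the effect allele with probability 1/2, independently across
#' variants and parents.
#'
#' @param parental_dosages Vector or matrix of dosages in \{0,1,2\}.
#' @param seed Optional integer seed.
#' @return List with components `transmitted` and `non_transmitted`, each of
#'   the same shape as the input, with entries in \{0,1\} summing to the input.
#' @examples
#' transmit(c(0, 1, 2), seed = 1)
#' @export
transmit <- function(parental_dosages, seed = NULL) {
  g <- parental_dosages
  if (!all(g %in% c(0, 1, 2)))
    stop("dosages must be 0, 1 or 2", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  t <- g / 2                       # 0 -> 0, 2 -> 1
  het <- g == 1
  t[het] <- stats::rbinom(sum(het), 1L, 0.5)
  storage.mode(t) <- "integer"
  nt <- g - t
  storage.mode(nt) <- "integer"
  list(transmitted = t, non_transmitted = nt)
}

#' Dichotomise a continuous outcome at a liability threshold
#'
#' Cuts `y` at its empirical `1 - prevalence` quantile so that the expected
#' case fraction equals `prevalence`.
#'
#' @param y Numeric vector.
#' @param prevalence Target case fraction in (0,1).
#' @param seed Unused; accepted for interface symmetry with the other
#'   generators (thresholding is deterministic given `y`).
#' @return Integer 0/1 vector.
#' @examples
#' mean(binarize_outcome(rnorm(1e4), 0.2))
#' @export
binarize_outcome <- function(y, prevalence, seed = NULL) {
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie in (0,1)", call. = FALSE)
  thr <- stats::quantile(y, 1 - prevalence, names = FALSE)
  as.integer(y > thr)
}
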
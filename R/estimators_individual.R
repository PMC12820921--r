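# Individual-level MR-NIV estimators: univariable and multivariable 2SLS
# variants differing in which scores instrument which parental exposures, and
# whether the offspring's own GRS is a covariate.

# Pull the score columns an estimator needs from a dataset (score-only mode)
# or from a resolved per-variant GRS set.
extract_scores <- function(dataset, grs = NULL) {
  stopifnot(inherits(dataset, "mrniv_dataset"))
  ph <- dataset$pheno
  if (is.null(dataset$geno)) {
    g <- dataset$grs
    list(
      x_m = ph$x_m, x_f = ph$x_f, y = ph$y,
      full_m = g$g_m, full_f = g$g_f,
      niv_m = g$n_m, niv_f = g$n_f,
      go = g$g_o
    )
  } else {
    if (is.null(grs)) grs <- grs_set(dataset)
    list(
      x_m = ph$x_m, x_f = ph$x_f, y = ph$y,
      full_m = grs$mother$full_grs, full_f = grs$father$full_grs,
      niv_m = grs$mother$non_inherited_grs,
      niv_f = grs$father$non_inherited_grs,
      go = grs$offspring$full_grs
    )
  }
}

pick_parent <- function(s, parent) {
  if (parent == "mother")
    list(x = s$x_m, niv = s$niv_m, full = s$full_m)
  else
    list(x = s$x_f, niv = s$niv_f, full = s$full_f)
}

check_instrument <- function(z, what) {
  if (is.null(z))
    stop(sprintf("%s is not available in this dataset (duo mode?)", what),
         call. = FALSE)
  if (stats::sd(z) == 0)
    stop(sprintf("zero-variance instrument: %s", what), call. = FALSE)
  z
}

#' Univariable MR with a parental non-inherited GRS
#'
#' 2SLS with instrument = one parent's non-inherited GRS, exposure = that
#' parent's phenotype, outcome = offspring phenotype. Adjusting for the
#' offspring's full GRS (default) improves precision and blocks the path
#' through the offspring genotype; it cannot bias the estimate because the
#' non-inherited score is independent of the offspring GRS under random
#' mating. With a single genotyped parent this is the duo-data workhorse, but
#' it is biased under assortative mating combined with a true causal effect.
#'
#' @param dataset An `mrniv_dataset` (score-only or per-variant).
#' @param parent `"mother"` or `"father"`.
#' @param adjust_offspring_grs Include the offspring full GRS as covariate.
#' @param grs Optional precomputed [grs_set()] (per-variant datasets).
#' @param robust HC1 robust SEs (default) or classical.
#' @return An `mrniv_estimate` (see [tsls()]).
#' @examples
#' d <- simulate_trios(scenario_config(n_families = 2000, seed = 1))
#' uvmr_niv(d, "mother")
#' @export
uvmr_niv <- function(dataset, parent = c("mother", "father"),
                     adjust_offspring_grs = TRUE, grs = NULL, robust = TRUE) {
  parent <- match.arg(parent)
  s <- extract_scores(dataset, grs)
  p <- pick_parent(s, parent)
  z <- check_instrument(p$niv, sprintf("%s non-inherited GRS", parent))
  cov <- if (adjust_offspring_grs) cbind(offspring_grs = s$go) else NULL
  x <- matrix(p$x, dimnames = list(NULL, parent))
  tsls(s$y, x, cbind(niv = z), cov, robust = robust, method = "uvmr_niv")
}

#' Univariable MR with the full parental GRS, adjusted for offspring GRS
#'
#' 2SLS with instrument = one parent's full (inherited + non-inherited) GRS
#' and the offspring's full GRS as a mandatory covariate. Because the
#' offspring GRS is a common descendant of both parents' genotypes,
#' conditioning on it opens a collider path through the other parent: this
#' estimator is biased whenever the other parent's phenotype affects the
#' offspring outcome, and serves as the comparison method.
#'
#' @inheritParams uvmr_niv
#' @return An `mrniv_estimate`.
#' @export
uvmr_adjusted <- function(dataset, parent = c("mother", "father"),
                          grs = NULL, robust = TRUE) {
  parent <- match.arg(parent)
  s <- extract_scores(dataset, grs)
  p <- pick_parent(s, parent)
  z <- check_instrument(p$full, sprintf("%s full GRS", parent))
  x <- matrix(p$x, dimnames = list(NULL, parent))
  tsls(s$y, x, cbind(full = z), cbind(offspring_grs = s$go),
       robust = robust, method = "uvmr_adj")
}

#' Multivariable MR with both parents' non-inherited GRSs
#'
#' Joint 2SLS with both parental phenotypes as exposures and both parents'
#' non-inherited GRSs as instruments. Modelling both parents blocks the
#' back-door induced by assortative mating; the offspring GRS covariate
#' (default) additionally blocks the direct path from the transmitted
#' haplotypes to the offspring outcome.
#'
#' @inheritParams uvmr_niv
#' @return An `mrniv_estimate` with one coefficient per parent.
#' @export
mvmr_niv <- function(dataset, adjust_offspring_grs = TRUE, grs = NULL,
                     robust = TRUE) {
  s <- extract_scores(dataset, grs)
  zm <- check_instrument(s$niv_m, "maternal non-inherited GRS")
  zf <- check_instrument(s$niv_f, "paternal non-inherited GRS")
  cov <- if (adjust_offspring_grs) cbind(offspring_grs = s$go) else NULL
  tsls(s$y, cbind(mother = s$x_m, father = s$x_f),
       cbind(niv_m = zm, niv_f = zf), cov,
       robust = robust, method = "mvmr_niv")
}

#' Multivariable MR with both parents' full GRSs, adjusted for offspring GRS
#'
#' Joint 2SLS with both parents' full GRSs as instruments and the offspring
#' full GRS as a mandatory covariate. Valid with trio data under assortative
#' mating, and typically the most precise of the valid estimators because the
#' full scores are stronger instruments than their non-inherited halves.
#'
#' @inheritParams uvmr_niv
#' @return An `mrniv_estimate` with one coefficient per parent.
#' @export
mvmr_adjusted <- function(dataset, grs = NULL, robust = TRUE) {
  s <- extract_scores(dataset, grs)
  zm <- check_instrument(s$full_m, "maternal full GRS")
  zf <- check_instrument(s$full_f, "paternal full GRS")
  tsls(s$y, cbind(mother = s$x_m, father = s$x_f),
       cbind(full_m = zm, full_f = zf), cbind(offspring_grs = s$go),
       robust = robust, method = "mvmr_adj")
}

#' Composite-parent MR: summed exposures and summed scores
#'
#' For homogeneous parental effects, uses the single exposure
#' `x_m + x_f` instrumented by the sum of both parents' scores
#' (non-inherited by default). With equal per-parent effects the slope on the
#' summed exposure equals the per-parent effect, and the composite model is
#' more precise than estimating each parent separately.
#'
#' @inheritParams uvmr_niv
#' @param use `"non_inherited"` (default) or `"full"` parental scores; with
#'   `"full"` the offspring-GRS adjustment is forced on.
#' @return An `mrniv_estimate` with a single coefficient (per-parent effect).
#' @export
composite_parent <- function(dataset, adjust_offspring_grs = TRUE,
                             use = c("non_inherited", "full"),
                             grs = NULL, robust = TRUE) {
  use <- match.arg(use)
  s <- extract_scores(dataset, grs)
  if (use == "non_inherited") {
    z <- check_instrument(s$niv_m, "maternal non-inherited GRS") +
      check_instrument(s$niv_f, "paternal non-inherited GRS")
  } else {
    z <- check_instrument(s$full_m, "maternal full GRS") +
      check_instrument(s$full_f, "paternal full GRS")
    adjust_offspring_grs <- TRUE
  }
  cov <- if (adjust_offspring_grs) cbind(offspring_grs = s$go) else NULL
  tsls(s$y, cbind(parents = s$x_m + s$x_f), cbind(sum_grs = z), cov,
       robust = robust, method = "composite")
}
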
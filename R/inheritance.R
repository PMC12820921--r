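# Deterministic classification of parental alleles as inherited or
# non-inherited, from trio (mother, father, offspring) or duo (one parent,
# offspring) genotype dosages. A trio combination is resolved when exactly one
# haplotype-transmission configuration is consistent with the observed
# dosages; (1,1,1) is the only ambiguous trio combination (either parent may
# have transmitted its single effect allele). Counts are emitted only for
# resolved combinations.

# Hand-derived case table over all 27 trio dosage combinations.
# tm in {0} if gm=0, {1} if gm=2, {0,1} if gm=1; tf likewise; tm + tf = go.
trio_case_table <- local({
  tab <- expand.grid(gm = 0:2, gf = 0:2, go = 0:2)
  rows <- list(
    # gm gf go status       m_inh m_ninh f_inh f_ninh
    c(0, 0, 0, 1, 0, 0, 0, 0),
    c(0, 0, 1, 3, NA, NA, NA, NA),
    c(0, 0, 2, 3, NA, NA, NA, NA),
    c(0, 1, 0, 1, 0, 0, 0, 1),
    c(0, 1, 1, 1, 0, 0, 1, 0),
    c(0, 1, 2, 3, NA, NA, NA, NA),
    c(0, 2, 0, 3, NA, NA, NA, NA),
    c(0, 2, 1, 1, 0, 0, 1, 1),
    c(0, 2, 2, 3, NA, NA, NA, NA),
    c(1, 0, 0, 1, 0, 1, 0, 0),
    c(1, 0, 1, 1, 1, 0, 0, 0),
    c(1, 0, 2, 3, NA, NA, NA, NA),
    c(1, 1, 0, 1, 0, 1, 0, 1),
    c(1, 1, 1, 2, NA, NA, NA, NA),
    c(1, 1, 2, 1, 1, 0, 1, 0),
    c(1, 2, 0, 3, NA, NA, NA, NA),
    c(1, 2, 1, 1, 0, 1, 1, 1),
    c(1, 2, 2, 1, 1, 0, 1, 1),
    c(2, 0, 0, 3, NA, NA, NA, NA),
    c(2, 0, 1, 1, 1, 1, 0, 0),
    c(2, 0, 2, 3, NA, NA, NA, NA),
    c(2, 1, 0, 3, NA, NA, NA, NA),
    c(2, 1, 1, 1, 1, 1, 0, 1),
    c(2, 1, 2, 1, 1, 1, 1, 0),
    c(2, 2, 0, 3, NA, NA, NA, NA),
    c(2, 2, 1, 3, NA, NA, NA, NA),
    c(2, 2, 2, 1, 1, 1, 1, 1)
  )
  m <- do.call(rbind, rows)
  colnames(m) <- c("gm", "gf", "go", "status",
                   "m_inherited", "m_non_inherited",
                   "f_inherited", "f_non_inherited")
  # index by code gm*9 + gf*3 + go + 1
  out <- m[order(m[, "gm"] * 9 + m[, "gf"] * 3 + m[, "go"]), , drop = FALSE]
  stopifnot(nrow(out) == 27)
  out
})

# Duo case table over the 9 (genotyped parent, offspring) combinations.
# other_contributed = effect alleles the offspring must have received from the
# non-genotyped parent.
duo_case_table <- local({
  rows <- list(
    # gp go status p_inh p_ninh other
    c(0, 0, 1, 0, 0, 0),
    c(0, 1, 1, 0, 0, 1),
    c(0, 2, 3, NA, NA, NA),
    c(1, 0, 1, 0, 1, 0),
    c(1, 1, 2, NA, NA, NA),
    c(1, 2, 1, 1, 0, 1),
    c(2, 0, 3, NA, NA, NA),
    c(2, 1, 1, 1, 1, 0),
    c(2, 2, 1, 1, 1, 1)
  )
  m <- do.call(rbind, rows)
  colnames(m) <- c("gp", "go", "status", "p_inherited", "p_non_inherited",
                   "other_contributed")
  m
})

status_levels <- c("resolved", "ambiguous", "mendelian_error", "missing")

check_dosage <- function(g, what) {
  bad <- !is.na(g) & !(g %in% c(0, 1, 2))
  if (any(bad))
    stop(sprintf("non-biallelic dosage value in %s: %s",
                 what, paste(unique(g[bad]), collapse = ", ")), call. = FALSE)
}

#' Resolve inherited and non-inherited allele counts from trio genotypes
#'
#' Classifies each (mother, father, offspring) dosage combination by exhaustive
#' case analysis of the consistent haplotype transmissions. A combination is
#' `resolved` when a unique transmission explains it (counts are then emitted
#' for both parents), `ambiguous` when several transmissions are consistent
#' (only the triple-heterozygote (1,1,1)), `mendelian_error` when none is, and
#' `missing` when any dosage is missing.
#'
#' @param gm,gf,go Equal-length vectors of maternal, paternal and offspring
#'   dosages in \{0,1,2\} (NA allowed).
#' @return A data.frame with columns `status` (factor) and the per-parent
#'   counts `m_inherited`, `m_non_inherited`, `f_inherited`,
#'   `f_non_inherited` (NA unless resolved).
#' @examples
#' resolve_trio(1, 0, 0)   # mother's allele certainly not inherited
#' resolve_trio(1, 1, 1)   # ambiguous
#' @export
resolve_trio <- function(gm, gf, go) {
  n <- max(length(gm), length(gf), length(go))
  gm <- rep_len(gm, n); gf <- rep_len(gf, n); go <- rep_len(go, n)
  check_dosage(gm, "gm"); check_dosage(gf, "gf"); check_dosage(go, "go")
  code <- gm * 9 + gf * 3 + go + 1
  miss <- is.na(code)
  code[miss] <- 1L
  res <- trio_case_table[code, , drop = FALSE]
  out <- data.frame(
    status = factor(status_levels[ifelse(miss, 4L, res[, "status"])],
                    levels = status_levels),
    m_inherited = res[, "m_inherited"],
    m_non_inherited = res[, "m_non_inherited"],
    f_inherited = res[, "f_inherited"],
    f_non_inherited = res[, "f_non_inherited"]
  )
  out[miss, c("m_inherited", "m_non_inherited",
              "f_inherited", "f_non_inherited")] <- NA
  out
}

#' Resolve allele counts from duo (one parent + offspring) genotypes
#'
#' As [resolve_trio()] but with only one genotyped parent: resolves that
#' parent's inherited/non-inherited counts and the number of effect alleles
#' the offspring must have received from the non-genotyped parent, whenever
#' the transmission is unambiguous given `(gp, go)` alone. The double
#' heterozygote (1,1) is ambiguous; (2,0) and (0,2) are Mendelian errors.
#'
#' @param gp,go Vectors of genotyped-parent and offspring dosages in
#'   \{0,1,2\} (NA allowed).
#' @return A data.frame with columns `status`, `p_inherited`,
#'   `p_non_inherited` and `other_contributed`.
#' @examples
#' resolve_duo(2, 1)  # parent transmitted one allele, kept one
#' resolve_duo(0, 1)  # allele must come from the other parent
#' @export
resolve_duo <- function(gp, go) {
  n <- max(length(gp), length(go))
  gp <- rep_len(gp, n); go <- rep_len(go, n)
  check_dosage(gp, "gp"); check_dosage(go, "go")
  code <- gp * 3 + go + 1
  miss <- is.na(code)
  code[miss] <- 1L
  res <- duo_case_table[code, , drop = FALSE]
  out <- data.frame(
    status = factor(status_levels[ifelse(miss, 4L, res[, "status"])],
                    levels = status_levels),
    p_inherited = res[, "p_inherited"],
    p_non_inherited = res[, "p_non_inherited"],
    other_contributed = res[, "other_contributed"]
  )
  out[miss, c("p_inherited", "p_non_inherited", "other_contributed")] <- NA
  out
}

#' Weighted genetic risk score from per-variant counts
#'
#' Computes `sum_j weight_j * count_j` per individual over the variants with
#' non-missing counts, reporting how many variants entered each score.
#'
#' @param counts Numeric matrix, individuals x variants; NA marks variants
#'   excluded for that individual (unresolved, missing, or Mendelian error).
#' @param weights Numeric vector of per-allele weights (one per column), or a
#'   data.frame with a `weight` column.
#' @return A data.frame with columns `score` and `n_variants_used`.
#' @examples
#' build_grs(rbind(c(2, NA), c(0, 1)), c(0.2, 0.5))
#' @export
build_grs <- function(counts, weights) {
  if (is.data.frame(weights)) weights <- weights$weight
  counts <- as.matrix(counts)
  if (ncol(counts) != length(weights))
    stop("one weight per variant column is required", call. = FALSE)
  if (any(!is.finite(weights)))
    stop("weights must be finite", call. = FALSE)
  w <- matrix(weights, nrow(counts), ncol(counts), byrow = TRUE)
  data.frame(
    score = rowSums(counts * w, na.rm = TRUE),
    n_variants_used = rowSums(!is.na(counts))
  )
}

#' Inherited, non-inherited and proxy GRSs for a per-variant dataset
#'
#' Runs the trio (or duo) resolver at every variant of a per-variant
#' [simulate_trios()] dataset, or on externally supplied dosage matrices, and
#' builds the weighted scores used by the MR-NIV estimators: full parental
#' GRSs, inherited/non-inherited GRSs over resolved variants only, the
#' offspring's full GRS, and (duo mode) the proxy GRS for the non-genotyped
#' parent built from offspring alleles attributed to that parent.
#'
#' @param dataset A per-variant `mrniv_dataset`, or a list with dosage
#'   matrices `geno_m`, `geno_f` (either may be NULL), `geno_o`, and a
#'   `variants` data.frame carrying `weight`.
#' @param weights Optional weight vector overriding `variants$weight`.
#' @return An object of class `mrniv_grs`: a list with per-individual score
#'   tables `mother`, `father`, `offspring` (each a data.frame of scores and
#'   `n_variants_used`), a `proxy` table in duo mode, and a `resolution`
#'   summary (status counts over family x variant cells).
#' @examples
#' d <- simulate_trios(scenario_config(n_families = 50, n_variants = 10, seed = 1))
#' g <- grs_set(d)
#' head(g$mother)
#' @export
grs_set <- function(dataset, weights = NULL) {
  geno <- if (inherits(dataset, "mrniv_dataset")) dataset$geno else dataset
  if (is.null(geno))
    stop("per-variant genotypes are required (score-only datasets carry scores directly)",
         call. = FALSE)
  w <- weights %||% geno$variants$weight
  go <- geno$geno_o
  have_m <- !is.null(geno$geno_m)
  have_f <- !is.null(geno$geno_f)
  n <- nrow(go); J <- ncol(go)
  out <- list()

  if (have_m && have_f) {
    # direct case-table lookup (resolve_trio semantics without the per-cell
    # data.frame, which matters at biobank scale)
    code <- geno$geno_m * 9L + geno$geno_f * 3L + go + 1L
    status <- trio_case_table[, "status"][code]
    status[is.na(status)] <- 4L
    resolved <- matrix(status == 1L, n, J)
    shape <- function(col) {
      v <- trio_case_table[, col][code]
      v[!resolved] <- NA
      matrix(v, n, J)
    }
    out$mother <- data.frame(
      full_grs = build_grs(geno$geno_m, w)$score,
      inherited_grs = build_grs(shape("m_inherited"), w)$score,
      non_inherited_grs = build_grs(shape("m_non_inherited"), w)$score,
      n_variants_used = rowSums(resolved)
    )
    out$father <- data.frame(
      full_grs = build_grs(geno$geno_f, w)$score,
      inherited_grs = build_grs(shape("f_inherited"), w)$score,
      non_inherited_grs = build_grs(shape("f_non_inherited"), w)$score,
      n_variants_used = rowSums(resolved)
    )
  } else {
    gp <- if (have_m) geno$geno_m else geno$geno_f
    code <- gp * 3L + go + 1L
    status <- duo_case_table[, "status"][code]
    status[is.na(status)] <- 4L
    resolved <- matrix(status == 1L, n, J)
    shape <- function(col) {
      v <- duo_case_table[, col][code]
      v[!resolved] <- NA
      matrix(v, n, J)
    }
    parent_tab <- data.frame(
      full_grs = build_grs(gp, w)$score,
      inherited_grs = build_grs(shape("p_inherited"), w)$score,
      non_inherited_grs = build_grs(shape("p_non_inherited"), w)$score,
      n_variants_used = rowSums(resolved)
    )
    proxy <- data.frame(
      proxy_other_parent_grs = build_grs(shape("other_contributed"), w)$score,
      n_variants_used = rowSums(resolved)
    )
    if (have_m) out$mother <- parent_tab else out$father <- parent_tab
    out$proxy <- proxy
  }
  out$offspring <- data.frame(
    full_grs = build_grs(go, w)$score,
    n_variants_used = rep(J, n)
  )
  out$resolution <- table(factor(status_levels[status], levels = status_levels))
  class(out) <- "mrniv_grs"
  out
}

#' @export
print.mrniv_grs <- function(x, ...) {
  cat("MR-NIV GRS set\n")
  cat("  roles:", paste(intersect(c("mother", "father", "offspring", "proxy"),
                                  names(x)), collapse = ", "), "\n")
  cat("  resolution status (family x variant cells):\n")
  print(x$resolution)
  invisible(x)
}

#' Align a GWAS weight table to observed variant alleles
#'
#' Matches a weight table to a variant table by id and orients dosages on the
#' weight table's effect allele: when the effect allele is the site's
#' reference allele the dosage must be counted as `2 - d` (flip). Variants
#' whose alleles match in neither orientation are dropped with a warning, as
#' are strand-ambiguous palindromic (A/T, C/G) sites unless
#' `keep_palindromic = TRUE`.
#'
#' @param variants Data.frame with `variant_id`, `ref`, `alt`.
#' @param weight_table Data.frame with `variant_id`, `effect_allele`,
#'   `other_allele`, `weight`.
#' @param keep_palindromic Keep A/T and C/G sites (default drops them).
#' @return A data.frame with `variant_id`, `weight`, `flip` (logical), plus a
#'   `dropped` attribute counting exclusions by reason.
#' @export
align_weights <- function(variants, weight_table, keep_palindromic = FALSE) {
  need <- c("variant_id", "effect_allele", "other_allele", "weight")
  miss <- setdiff(need, names(weight_table))
  if (length(miss))
    stop("weight table misses column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(weight_table$effect_allele == weight_table$other_allele))
    stop("effect and other allele must differ", call. = FALSE)
  if (any(!is.finite(weight_table$weight)))
    stop("weights must be finite", call. = FALSE)
  m <- merge(variants[c("variant_id", "ref", "alt")], weight_table,
             by = "variant_id")
  fwd <- m$effect_allele == m$alt & m$other_allele == m$ref
  rev <- m$effect_allele == m$ref & m$other_allele == m$alt
  pal <- paste0(pmin(m$ref, m$alt), pmax(m$ref, m$alt)) %in% c("AT", "CG")
  keep <- (fwd | rev) & (keep_palindromic | !pal)
  dropped <- c(unmatched_alleles = sum(!fwd & !rev),
               palindromic = sum((fwd | rev) & !keep_palindromic & pal))
  if (any(dropped > 0))
    warning(sprintf("dropped %d variant(s): %d allele-mismatched, %d palindromic",
                    sum(dropped), dropped[["unmatched_alleles"]],
                    dropped[["palindromic"]]), call. = FALSE)
  out <- data.frame(variant_id = m$variant_id[keep],
                    weight = m$weight[keep],
                    flip = rev[keep])
  attr(out, "dropped") <- dropped
  out
}
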
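# File-format frontier: VCF genotypes (via vcfR), pedigree / weight /
# phenotype tables, and writers for estimates, performance tables and
# simulated datasets. Variants are keyed internally by (chrom, pos, ref, alt);
# dosages are counts of the ALT allele with an explicit NA for missing.

#' Read a pedigree table
#'
#' Tab-separated table with columns `family_id`, `offspring_id`, `mother_id`,
#' `father_id`; empty or `NA` parent ids mark a non-genotyped parent (duo
#' families). At least one parent must be present per family.
#'
#' @param path TSV file path.
#' @return A data.frame with one row per family.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("family_id", "offspring_id", "mother_id", "father_id")
  miss <- setdiff(need, names(ped))
  if (length(miss))
    stop("pedigree misses column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(ped$family_id))
    stop("duplicate family_id in pedigree", call. = FALSE)
  no_parent <- is.na(ped$mother_id) & is.na(ped$father_id)
  if (any(no_parent))
    stop("families without any genotyped parent: ",
         paste(ped$family_id[no_parent], collapse = ", "), call. = FALSE)
  ped
}

#' Read a variant-weight table
#'
#' Tab-separated table with columns `variant_id`, `effect_allele`,
#' `other_allele`, `weight` (per-allele GWAS regression beta).
#'
#' @param path TSV file path.
#' @return A data.frame of variant weights.
#' @export
read_weights <- function(path) {
  w <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "effect_allele", "other_allele", "weight")
  miss <- setdiff(need, names(w))
  if (length(miss))
    stop("weight table misses column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(w$weight)))
    stop("weights must be finite", call. = FALSE)
  if (any(w$effect_allele == w$other_allele))
    stop("effect and other allele must differ", call. = FALSE)
  w
}

#' Read a phenotype table
#'
#' Comma-separated table with columns `family` plus any of `x_m`, `x_f`, `y`,
#' `y_bin`, `u`.
#'
#' @param path CSV file path.
#' @return A data.frame keyed by `family`.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"family" %in% names(ph))
    stop("phenotype table misses column(s): family", call. = FALSE)
  if (!"y" %in% names(ph))
    stop("phenotype table misses column(s): y", call. = FALSE)
  ph
}

#' Read trio/duo dosage matrices from a VCF
#'
#' Reads biallelic SNP genotypes (GT field) for the samples named in a
#' pedigree and returns one families x variants dosage matrix per role.
#' Multi-allelic records are skipped with a warning; malformed GT entries
#' become missing with a warning; variant order is preserved.
#'
#' @param path VCF file path (plain text or gzipped).
#' @param pedigree A [read_pedigree()] table.
#' @param variant_filter Optional character vector of variant ids to keep
#'   (`NULL` keeps all).
#' @return List with dosage matrices `geno_m`, `geno_f` (NULL when no family
#'   has that parent), `geno_o`, and a `variants` table
#'   (`variant_id`, `chrom`, `pos`, `ref`, `alt`).
#' @export
read_genotypes <- function(path, pedigree, variant_filter = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | nchar(fix$REF) != 1 | nchar(fix$ALT) != 1
  if (any(multi))
    warning(sprintf("skipping %d non-biallelic-SNP record(s)", sum(multi)),
            call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  variants <- data.frame(
    variant_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                        paste(fix$CHROM, fix$POS, fix$REF, fix$ALT, sep = ":"),
                        fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
  )
  if (!is.null(variant_filter)) {
    keep <- variants$variant_id %in% variant_filter
    gt <- gt[keep, , drop = FALSE]
    variants <- variants[keep, , drop = FALSE]
  }
  dose <- gt_to_dosage(gt)
  samples <- colnames(dose)
  get_role <- function(ids) {
    present <- !is.na(ids)
    if (!any(present)) return(NULL)
    missing_samples <- setdiff(ids[present], samples)
    if (length(missing_samples))
      stop("sample(s) named in pedigree absent from VCF: ",
           paste(missing_samples, collapse = ", "), call. = FALSE)
    m <- matrix(NA_integer_, length(ids), nrow(dose))
    m[present, ] <- t(dose[, ids[present], drop = FALSE])
    rownames(m) <- pedigree$family_id
    colnames(m) <- variants$variant_id
    m
  }
  off <- get_role(pedigree$offspring_id)
  if (is.null(off)) stop("no offspring samples found", call. = FALSE)
  all_missing <- colSums(!is.na(dose)) == 0
  if (any(all_missing))
    warning("sample(s) with all-missing genotypes: ",
            paste(samples[all_missing], collapse = ", "), call. = FALSE)
  list(
    geno_m = get_role(pedigree$mother_id),
    geno_f = get_role(pedigree$father_id),
    geno_o = off,
    variants = variants
  )
}

# GT strings ("0/1", "1|0", ".", "./.") -> ALT-allele dosage with NA
gt_to_dosage <- function(gt) {
  f <- function(x) {
    alleles <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
    vapply(alleles, function(a) {
      if (length(a) != 2 || any(!a %in% c("0", "1"))) NA_integer_
      else sum(a == "1")
    }, integer(1))
  }
  bad_before <- is.na(gt)
  d <- apply(gt, 2, f)
  if (!is.matrix(d))
    d <- matrix(d, nrow = nrow(gt), dimnames = dimnames(gt))
  if (any(is.na(d) & !bad_before))
    warning("malformed GT entries set to missing", call. = FALSE)
  d
}

#' Write a simulated per-variant dataset to VCF + pedigree + phenotype files
#'
#' Emits `genotypes.vcf` (biallelic SNPs, GT field, samples `<fam>_M`,
#' `<fam>_F`, `<fam>_O`), `pedigree.tsv`, `phenotypes.csv` and `weights.tsv`
#' under `dir`.
#'
#' @param dataset A per-variant `mrniv_dataset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "mrniv_dataset"))
  geno <- dataset$geno
  if (is.null(geno))
    stop("score-only datasets have no genotypes to write; use a per-variant config",
         call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(dataset$pheno)
  fam <- sprintf("fam%05d", dataset$pheno$family)
  roles <- list(M = geno$geno_m, F = geno$geno_f, O = geno$geno_o)
  roles <- roles[!vapply(roles, is.null, logical(1))]
  samples <- unlist(lapply(names(roles), function(r) paste0(fam, "_", r)))
  J <- ncol(geno$geno_o)
  gt_of <- function(d) c("0/0", "0/1", "1/1")[d + 1]
  body <- matrix("", J, length(samples))
  col <- 1L
  for (r in names(roles)) {
    for (i in seq_len(n)) {
      body[, col] <- gt_of(roles[[r]][i, ])
      col <- col + 1L
    }
  }
  # sample columns ordered role-major above; reorder family-major for readability
  ord <- order(rep(seq_len(n), times = length(roles)))
  samples <- samples[ord]; body <- body[, ord, drop = FALSE]
  vcf_path <- file.path(dir, "genotypes.vcf")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=mrniv_simulate",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  fixcols <- cbind("1", as.character(seq_len(J) * 1000L),
                   geno$variants$variant_id,
                   geno$variants$other_allele, geno$variants$effect_allele,
                   ".", "PASS", ".", "GT")
  writeLines(c(header, apply(cbind(fixcols, body), 1, paste, collapse = "\t")),
             vcf_path)
  ped <- data.frame(
    family_id = fam, offspring_id = paste0(fam, "_O"),
    mother_id = if (is.null(geno$geno_m)) NA else paste0(fam, "_M"),
    father_id = if (is.null(geno$geno_f)) NA else paste0(fam, "_F")
  )
  utils::write.table(ped, file.path(dir, "pedigree.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$pheno, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE)
  w <- geno$variants[c("variant_id", "effect_allele", "other_allele", "weight")]
  utils::write.table(w, file.path(dir, "weights.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Write estimates or performance tables
#'
#' `write_estimates()` serialises one or more `mrniv_estimate` objects to
#' JSON; `write_performance()` writes an `mrniv_performance` table to CSV.
#'
#' @param estimates A single estimate or a (possibly named) list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  if (inherits(estimates, "mrniv_estimate")) estimates <- list(estimates)
  ser <- lapply(estimates, function(e) {
    keep <- intersect(c("beta", "se", "ci_low", "ci_high", "method",
                        "first_stage_F", "n_used", "objective_value",
                        "converged", "interpretable", "tau2", "or",
                        "or_ci_low", "or_ci_high"),
                      names(e))
    e[keep]
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_estimates
#' @param performance An `mrniv_performance` data.frame.
#' @export
write_performance <- function(performance, path) {
  utils::write.csv(as.data.frame(performance), path, row.names = FALSE)
  invisible(path)
}
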
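test_that("trio resolver agrees with exhaustive transmission enumeration on all 27 combinations", {
  for (gm in 0:2) for (gf in 0:2) for (go in 0:2) {
    got <- resolve_trio(gm, gf, go)
    want <- oracle_trio(gm, gf, go)
    lbl <- sprintf("(gm=%d, gf=%d, go=%d)", gm, gf, go)
    expect_equal(as.character(got$status), want$status, label = lbl)
    if (want$status == "resolved") {
      expect_equal(got$m_inherited, want$m_inherited, label = lbl)
      expect_equal(got$m_non_inherited, want$m_non_inherited, label = lbl)
      expect_equal(got$f_inherited, want$f_inherited, label = lbl)
      expect_equal(got$f_non_inherited, want$f_non_inherited, label = lbl)
    } else {
      expect_true(all(is.na(got[c("m_inherited", "m_non_inherited",
                                  "f_inherited", "f_non_inherited")])),
                  label = lbl)
    }
  }
})

test_that("duo resolver agrees with exhaustive enumeration on all 9 combinations", {
  for (gp in 0:2) for (go in 0:2) {
    got <- resolve_duo(gp, go)
    want <- oracle_duo(gp, go)
    lbl <- sprintf("(gp=%d, go=%d)", gp, go)
    expect_equal(as.character(got$status), want$status, label = lbl)
    if (want$status == "resolved") {
      expect_equal(got$p_inherited, want$p_inherited, label = lbl)
      expect_equal(got$p_non_inherited, want$p_non_inherited, label = lbl)
      expect_equal(got$other_contributed, want$other_contributed, label = lbl)
    }
  }
})

test_that("textbook resolution cases come out as documented", {
  # parent has a risk allele the offspring lacks: certainly not inherited
  r <- resolve_trio(1, 0, 0)
  expect_equal(as.character(r$status), "resolved")
  expect_equal(r$m_non_inherited, 1); expect_equal(r$m_inherited, 0)
  expect_equal(r$f_non_inherited, 0)
  # triple heterozygote: source parent unknowable
  expect_equal(as.character(resolve_trio(1, 1, 1)$status), "ambiguous")
  # allele with no possible source
  expect_equal(as.character(resolve_trio(0, 0, 1)$status), "mendelian_error")
  expect_equal(as.character(resolve_trio(0, 0, 2)$status), "mendelian_error")
  # homozygous father forces the transmission, resolving the mother too
  r <- resolve_trio(1, 2, 1)
  expect_equal(r$f_inherited, 1); expect_equal(r$f_non_inherited, 1)
  expect_equal(r$m_inherited, 0); expect_equal(r$m_non_inherited, 1)
  # duo cases
  r <- resolve_duo(2, 2)
  expect_equal(r$p_inherited, 1); expect_equal(r$p_non_inherited, 1)
  expect_equal(r$other_contributed, 1)
  r <- resolve_duo(1, 0)
  expect_equal(r$p_non_inherited, 1); expect_equal(r$other_contributed, 0)
  r <- resolve_duo(1, 2)
  expect_equal(r$p_inherited, 1); expect_equal(r$p_non_inherited, 0)
  expect_equal(r$other_contributed, 1)
  # missing and malformed dosages
  expect_equal(as.character(resolve_trio(NA, 1, 1)$status), "missing")
  expect_equal(as.character(resolve_duo(1, NA)$status), "missing")
  expect_error(resolve_trio(1, 1, 3), "non-biallelic")
})

test_that("resolved counts match the simulator's true transmissions exactly", {
  d <- simulate_trios(scenario_config(n_families = 400, n_variants = 40,
                                      seed = 21))
  g <- d$geno
  res <- resolve_trio(as.vector(g$geno_m), as.vector(g$geno_f),
                      as.vector(g$geno_o))
  ok <- res$status == "resolved"
  true_m_ninh <- as.vector(g$geno_m - g$trans_m)
  true_f_ninh <- as.vector(g$geno_f - g$trans_f)
  # simulation produces no Mendelian errors, and 100% of resolved calls agree
  expect_equal(sum(res$status == "mendelian_error"), 0)
  expect_true(all(res$m_non_inherited[ok] == true_m_ninh[ok]))
  expect_true(all(res$f_non_inherited[ok] == true_f_ninh[ok]))
  expect_true(all(res$m_inherited[ok] + res$m_non_inherited[ok] ==
                    as.vector(g$geno_m)[ok]))
  # duo resolution against truth for the genotyped parent
  resd <- resolve_duo(as.vector(g$geno_m), as.vector(g$geno_o))
  okd <- resd$status == "resolved"
  expect_true(all(resd$p_non_inherited[okd] == true_m_ninh[okd]))
  expect_true(all(resd$other_contributed[okd] ==
                    as.vector(g$trans_f)[okd]))
})

test_that("resolution gets harder as variants approach 50% frequency", {
  set.seed(31)
  frac_resolved <- vapply(seq(0.05, 0.5, by = 0.05), function(maf) {
    gm <- rbinom(20000, 2, maf); gf <- rbinom(20000, 2, maf)
    tm <- transmit(gm); tf <- transmit(gf)
    res <- resolve_trio(gm, gf, tm$transmitted + tf$transmitted)
    mean(res$status == "resolved")
  }, numeric(1))
  expect_true(all(diff(frac_resolved) < 0))
  expect_gt(frac_resolved[1], 0.95)
})

test_that("GRS construction is a plain weighted sum with bookkeeping", {
  expect_equal(build_grs(rbind(c(1, 2), c(0, 0)), c(0, 0))$score, c(0, 0))
  one <- build_grs(matrix(2), 0.2)
  expect_equal(one$score, 0.4)
  expect_equal(one$n_variants_used, 1)
  # random 20-variant fixture equals a brute-force dot product
  set.seed(41)
  counts <- matrix(sample(c(0:2, NA), 200, replace = TRUE), 10, 20)
  w <- rnorm(20)
  got <- build_grs(counts, w)
  brute <- vapply(1:10, function(i) {
    s <- 0
    for (j in 1:20) if (!is.na(counts[i, j])) s <- s + w[j] * counts[i, j]
    s
  }, numeric(1))
  expect_equal(got$score, brute)
  expect_equal(got$n_variants_used, rowSums(!is.na(counts)))
  expect_error(build_grs(counts, w[-1]), "one weight per variant")
  expect_error(build_grs(counts, c(w[-1], Inf)), "finite")
})

test_that("grs_set decomposes the full score over resolved variants", {
  d <- simulate_trios(scenario_config(n_families = 300, n_variants = 30,
                                      seed = 51))
  g <- grs_set(d)
  w <- d$geno$variants$weight
  # inherited + non-inherited = full GRS restricted to resolved variants
  res <- resolve_trio(as.vector(d$geno$geno_m), as.vector(d$geno$geno_f),
                      as.vector(d$geno$geno_o))
  resolved <- matrix(res$status == "resolved", 300, 30)
  masked_m <- d$geno$geno_m; masked_m[!resolved] <- NA
  expect_equal(g$mother$inherited_grs + g$mother$non_inherited_grs,
               build_grs(masked_m, w)$score, tolerance = 1e-12)
  expect_equal(g$mother$n_variants_used, rowSums(resolved))
  expect_equal(g$offspring$full_grs, build_grs(d$geno$geno_o, w)$score)
  expect_equal(sum(g$resolution), 300 * 30)
  # duo mode emits the proxy score for the non-genotyped parent
  duo <- simulate_trios(scenario_config(n_families = 300, n_variants = 30,
                                        duo_mode = TRUE, seed = 51))
  gd <- grs_set(duo)
  expect_true(!is.null(gd$proxy))
  expect_null(gd$father)
  resd <- resolve_duo(as.vector(duo$geno$geno_m), as.vector(duo$geno$geno_o))
  okd <- matrix(resd$status == "resolved", 300, 30)
  proxy_counts <- matrix(resd$other_contributed, 300, 30)
  proxy_counts[!okd] <- NA
  expect_equal(gd$proxy$proxy_other_parent_grs,
               build_grs(proxy_counts, w)$score, tolerance = 1e-12)
})

test_that("weight alignment flips, drops and warns as specified", {
  variants <- data.frame(variant_id = c("v1", "v2", "v3", "v4"),
                         ref = c("G", "C", "A", "G"),
                         alt = c("A", "T", "T", "C"))
  wt <- data.frame(variant_id = c("v1", "v2", "v3", "v4"),
                   effect_allele = c("A", "C", "A", "G"),
                   other_allele = c("G", "T", "T", "C"),
                   weight = c(0.1, 0.2, 0.3, 0.4))
  # v1 forward; v2 flipped (effect = ref); v3 palindromic A/T; v4 palindromic C/G
  expect_warning(al <- align_weights(variants, wt), "palindromic")
  expect_equal(al$variant_id, c("v1", "v2"))
  expect_equal(al$flip, c(FALSE, TRUE))
  al2 <- suppressWarnings(align_weights(variants, wt, keep_palindromic = TRUE))
  expect_equal(nrow(al2), 4)
  # allele mismatch in both orientations is dropped with a warning
  wt$other_allele[1] <- "T"
  expect_warning(al3 <- align_weights(variants[1, ], wt[1, ]), "mismatch")
  expect_equal(nrow(al3), 0)
  wt2 <- wt; wt2$effect_allele[2] <- wt2$other_allele[2]
  expect_error(align_weights(variants, wt2), "differ")
})
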
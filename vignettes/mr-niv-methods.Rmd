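---
title: "Methods: Mendelian randomisation with non-inherited variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mendelian randomisation with non-inherited variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrniv)
```

## The design

Offspring inherit one random haplotype from each parent. The parental alleles
that were *not* transmitted cannot act biologically in the offspring, yet they
influenced the parent's own phenotype. A weighted score of non-inherited
alleles is therefore an instrumental variable for the *socially transmitted*
effect of the parental phenotype on the offspring ("genetic nurture" or
dynastic effects): it satisfies relevance (it predicts the parental
phenotype), independence (its allocation at the parent's conception is random
with respect to offspring-generation confounders), and the exclusion
restriction (no biological pathway in the offspring).

Two threats structure the estimator family:

* **Assortative mating** correlates the two parents' genotypes. A
  single-parent (univariable) non-inherited score then has a back-door path
  through the other parent's genotype and phenotype. Modelling *both* parents
  jointly (multivariable MR) blocks it.
* **The offspring's own genotype** affects the offspring phenotype. Scores
  containing inherited alleles (the "full-GRS adjusted" comparison method)
  must condition on the offspring GRS, which opens a collider between the two
  parental genotypes; with a single-parent model this produces collider bias
  whenever the other parent has a causal effect.

`mrniv` implements the resulting estimators at the individual level
(`uvmr_niv()`, `uvmr_adjusted()`, `mvmr_niv()`, `mvmr_adjusted()`,
`composite_parent()`, `wald_ratio()`) and, for duo data where one parent is
not genotyped, the proxy design `proxy_mvmr_niv()` built on per-variant
summary statistics with weak-instrument-robust estimators (`divw()`,
`cue_gmm()`, `grapple_profile()`, `qhet()`).

## Generating model

`simulate_trios()` draws families under the diagram above. In score-only mode
each parental GRS is split as $G_p = T_p + N_p$ with independent
$T_p, N_p \sim N(0, 1/2)$ (transmitted and non-transmitted halves); the
offspring GRS is $G_o = T_m + T_f$. Phenotypes follow

$$X_p = \sqrt{r^2}\,G_p + c\,U + \varepsilon_p, \qquad
  Y = \theta X_m + \theta X_f + \delta G_o + c\,U + \varepsilon_y,$$

with a shared confounder $U \sim N(0,1)$. Defaults (all overridable in
`scenario_config()`):

* `grs_r2 = 0.005`: the full parental GRS explains 0.5% of exposure variance,
  the order of magnitude of genome-wide-significant scores for behavioural
  phenotypes such as lifetime smoking.
* `theta = 0.75` per parent (0 in null scenarios). The exposures are
  standardised; the outcome is left on its natural scale.
* `resid_var_y = 14`: with `theta = 0.75` the parental plus offspring-genetic
  components then account for just under 10% of $\mathrm{Var}(Y)$, matching
  the stipulation that more than 90% of outcome variation is environmental.
  A unit-variance outcome is *impossible* under these constraints — the
  parental term alone is $2\theta^2 = 1.125$ — which is why $Y$ is not
  standardised.
* `offspring_direct_effect = NULL`: $\delta$ is solved in closed form so the
  offspring GRS explains `grs_r2` of $\mathrm{Var}(Y)$, mirroring the
  parental first stage.
* `confounder_effect = 0.3` on each exposure and the outcome: enough
  confounding that naive regression is visibly biased, while keeping the
  exposure-variance budget valid.
* `am_rho = 0.3` when assortative mating is on: assortment is modelled as
  Gaussian-copula rank pairing of the parents on their *total* genotypic
  scores (`mate_assortatively()`), so the paired-score correlation converges
  to `am_rho` while each marginal distribution is untouched. Single-trait
  assortment on the genotypic score is the modelled mechanism; cross-trait
  assortment is out of scope.

Per-variant mode (`n_variants = 126`, the size of the applied
lifetime-smoking instrument) simulates biallelic genotypes under
Hardy-Weinberg equilibrium with allele frequencies uniform on `maf_range`,
GWAS-style weights $|N(0,1)|$ drawn once per dataset, and explicit Mendelian
transmission (`transmit()`). Collapsing the per-variant scores reproduces the
score-only sampling distributions (a property the test suite checks at
n = 5,000 over 200 replicates).

## Inheritance resolution

`resolve_trio()` classifies each (mother, father, offspring) dosage
combination by exhaustive case analysis of the consistent haplotype
transmissions: a combination is *resolved* when exactly one transmission
explains it, *ambiguous* when several do (the triple heterozygote is the only
trio case), and a *Mendelian error* when none does. `resolve_duo()` does the
same given only one parent, additionally reporting how many effect alleles
the offspring must have received from the non-genotyped parent — the raw
material of the proxy design. Scores (`grs_set()`, `build_grs()`) are summed
over resolved variants only; Mendelian errors and missing genotypes exclude
the variant for that family rather than being coerced. Resolution gets harder
as allele frequencies approach 0.5 (more heterozygotes), a monotonicity the
tests verify on a frequency grid.

## Estimation choices

* 2SLS is QR-based with heteroskedasticity-robust (HC1) standard errors by
  default (`robust = FALSE` gives classical ones); 95% intervals are normal
  approximations throughout.
* Instrument strength: partial first-stage F for one exposure,
  Sanderson-Windmeijer-style conditional F per exposure for multivariable
  models.
* **Offspring-GRS adjustment.** For UVMR-NIV/MVMR-NIV the offspring GRS
  covariate is optional but defaults to on in the study harness: with a
  nonzero offspring direct effect and assortative mating, the non-inherited
  score correlates with the other parent's transmitted haplotype and hence
  with the offspring GRS, so leaving it out re-opens a genetic path. Under
  random mating the adjustment is harmless and improves precision. The plain
  (unadjusted) UVMR-NIV is retained as the "naive" single-parent analysis and
  is what the benchmark tables report for the univariable rows.
* Binary outcomes use the Wald ratio with a logistic-regression numerator
  (`wald_ratio(..., link = "logistic")`), not a two-stage logistic model.
* Summary estimators share the moment $g_j(\beta) = \hat\beta_{Yj} -
  \sum_k \beta_k \hat\beta_{Xjk}$ with variance $v_j(\beta) = \sigma_{Yj}^2 +
  \sum_k \beta_k^2 \sigma_{Xjk}^2$. `divw()` solves the moment system with the
  $\mathrm{diag}(\sigma_X^2)$ correction; `cue_gmm()` minimises
  $\sum_j g_j^2 / v_j$ by multi-start BFGS with analytic gradient
  (tolerance 1e-8, five starts around the IVW solution) and reports
  $(\sum_j b_{Xj} b_{Xj}^\top / v_j)^{-1}$ standard errors; `qhet()`
  minimises the identical heterogeneity objective by coarse grid plus polish
  and deliberately reports a point estimate only (a parametric bootstrap CI
  is available but costly); `grapple_profile()` maximises the profile
  pseudo-likelihood of the standardised residuals with an overdispersion
  parameter $\tau^2 \ge 0$ and a Tukey biweight loss (c = 4.685) by default,
  with a consistency factor $\kappa = E[\psi(Z)Z]$ so that $\tau^2$ is
  estimated without bias under normality. The CUE-GMM and Q-minimisation
  objectives coincide for independent instruments; the two routes differ in
  optimisation strategy and in whether interval estimates are attempted.
* `compute_variant_summaries()` centres each per-variant instrument within
  the families where it is resolved and sets it to zero elsewhere. The
  masked, centred count is a deterministic function of genotypes, hence still
  a valid instrument, and it keeps every per-variant regression a full-sample
  regression computable in a handful of matrix products — the difference
  between minutes and hours at biobank scale.
* The proxy design instruments the genotyped parent's phenotype with that
  parent's resolved non-inherited counts and the other parent's phenotype
  with the offspring alleles attributed to that parent, always adjusting for
  the offspring's full GRS. The proxied parent's coefficient is flagged
  `interpretable = FALSE`: its instruments are inherited alleles and violate
  the exclusion restriction by construction.

## The simulation study

`run_scenario()` crosses a causal effect (0.75 vs 0) with assortative mating
(0.3 vs 0), fits the requested methods to `n_reps` independent datasets
(replicate $r$ uses seed `master_seed + r`), and reports bias, empirical
variance, 95% coverage and mean CI width with Monte-Carlo standard errors
(bias: $s/\sqrt{R}$; variance: $s^2\sqrt{2/(R-1)}$; coverage:
$\sqrt{c(1-c)/R}$). Per-parent rows are accompanied by a mother-father
average row. Non-converged replicates are excluded and counted.

Problem sizes used by the packaged checks, chosen once as the study
conditions: 10,000 trios per replicate with 500-1,000 replicates for the
score-only scenarios; 60,000 duos with 126 variants and 100 replicates for
the proxy study; the mode-equivalence property uses 5,000 families and 200
replicates.

With these conditions the qualitative hierarchy is: plain UVMR-NIV unbiased
under random mating but biased upward under assortment; the full-GRS
univariable model collider-biased whenever the other parent matters; both
multivariable models unbiased everywhere, with the full-GRS multivariable
model the most precise. At our instrument strength (first-stage F around
12-25) the 2SLS sampling distribution is leptokurtic and normal-approximation
intervals over-cover slightly (empirical coverage near 0.97 rather than
0.950); the weak-instrument bias of 2SLS toward the confounded estimate is of
order 1/F and negligible next to Monte-Carlo error.

## What the simulations do and do not show

The generator emulates the *structure* of a birth-cohort trio resource —
sample size, GRS strength, effect size, dominant environmental variance,
genotype-level assortment — under idealised conditions: no missing data, no
genotyping error, no population stratification, variants independent and in
Hardy-Weinberg equilibrium, homogeneous parental effects, linear models with
Gaussian noise, and single-trait assortment on the genotypic score. Passing
tests therefore demonstrate internal validity of the estimators under the
stated mechanism, not robustness to pleiotropy, structure, cross-trait
assortment or measurement error in real cohorts.

Two quantitative caveats deserve emphasis:

* Because assortment is applied to the *aggregate* parental score, the
  per-variant cross-parent correlation it induces is of order
  `am_rho / n_variants`, and resolution masking attenuates it further. The
  naive duo analysis is therefore only mildly biased in our per-variant
  configuration, so contrasts defined *relative to* naive bias are much less
  dramatic here than under mechanisms that assort each variant strongly.
* With hundreds of individually tiny instruments, the heterogeneity-type
  objective shared by CUE-GMM and Q-minimisation has a genuinely biased
  minimiser at realistic sample sizes; the robust profile-likelihood
  estimator, whose overdispersion term absorbs part of that noise, is the
  most stable proxy estimator in this implementation, while the debiased IVW
  moment correction can become near-singular and erratic. Which robust
  estimator "wins" is thus implementation- and mechanism-sensitive, and
  results from differently specified CUE variants should not be expected to
  transfer exactly.

## Worked example

```{r example, eval = FALSE}
cfg <- scenario_config(n_families = 10000, theta = 0.75, am_rho = 0.3,
                       seed = 1)
d <- simulate_trios(cfg)
mvmr_adjusted(d)          # valid under assortative mating
uvmr_niv(d, "mother", adjust_offspring_grs = FALSE)  # naive: biased here

perf <- run_scenario(cfg, c("uvmr_niv", "mvmr_niv", "mvmr_adj"),
                     n_reps = 500, master_seed = 1)
perf[perf$parent == "average", ]
```
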
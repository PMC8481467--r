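---
title: "Gene-based rare-variant gene-by-smoking interaction analysis: models and design"
author: "exomeGxE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based rare-variant gene-by-smoking interaction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomeGxE)
```

# The problem

Spirometric measures of pulmonary function — FEV1 (forced expiratory volume
in one second), FVC (forced vital capacity) and their ratio — are highly
heritable and strongly affected by cigarette smoking. Common-variant GWAS of
these traits is mature; rare and low-frequency exonic variants (MAF < 5%,
many < 1%), and especially their *interaction* with smoking, are much less
explored because single-variant tests have essentially no power at these
frequencies. The standard remedy is the set-based test: group a gene's rare
variants and test them jointly.

`exomeGxE` implements a complete discovery-stage workflow for this setting:

1. per-cohort phenotype preparation (covariate design, residual-outlier
   exclusion, rank-based inverse-normal transformation, derivation of the
   ever- and current-smoking contrasts);
2. variant- and gene-level genotype QC with binomial imputation of missing
   genotypes;
3. gene-based variance-component score tests of gene-by-smoking interaction
   ("interaction-only") and of main-plus-interaction effects ("joint"),
   with a kinship-aware null model for family cohorts;
4. single-variant follow-up (1-df interaction and 2-df joint Wald tests),
   conditional analysis and a local LD $r^2$ utility;
5. Stouffer weighted-Z p-value meta-analysis across cohorts with
   genomic-control screening and a Bonferroni significance rule.

Because the consortium cohort data such an analysis runs on are not
publicly available, the package includes a first-class synthetic multi-cohort
generator with the statistical structure the analysis assumes, so that every
stage is testable end to end.

# The model and the two tests

For one cohort, one trait and one tested exposure, let $y$ be the
inverse-normal-transformed trait ($n$ samples), $X$ the covariate design
(intercept, age, age$^2$, sex, height, height$^2$, weight for FVC only,
recruitment-site indicators, 10 principal components, and **both** smoking
indicators), $E \in \{0,1\}^n$ the tested exposure, $G$ the $n \times m$
dosage matrix of the gene's retained variants and $S = G \circ E$ the
interaction matrix ($S_{ij} = G_{ij} E_i$). Variants receive diagonal
weights $W$, by default $w_j = \mathrm{Beta}(\mathrm{MAF}_j;\,1, 25)$, the
standard rare-variant convention that up-weights the rarest variants (flat
weights are available; nothing in the source analysis pins the weights, so
this default is an explicit assumption of the package).

The working model is

$$ y = X\alpha + G\beta + S\gamma + \varepsilon,\qquad
   \beta \sim N(0, \tau_m W),\quad \gamma \sim N(0, \tau_i W),\quad
   \varepsilon \sim N(0, \sigma^2 I). $$

**Joint test** ($H_0: \beta = \gamma = 0$). The null is the covariates-only
regression (or, with kinship, the polygenic mixed model below). With
$\hat P = \hat V^{-1} - \hat V^{-1}X(X'\hat V^{-1}X)^{-1}X'\hat V^{-1}$,

$$ Q_J = y'\hat P\,[G W G' + S W S']\,\hat P y
       = \lVert B'\hat P y\rVert^2,\qquad B = [GW^{1/2} \mid SW^{1/2}], $$

with null distribution $\sum_k \lambda_k \chi^2_1$, $\lambda_k$ the
eigenvalues of $B'\hat P B$.

**Interaction-only test** ($H_0: \gamma = 0$, main effects present). The
null model fits $y = X\alpha + G\beta + \varepsilon$ with $\beta$ random,
by REML profiled to the single ratio $\delta = \tau_m/\sigma^2$. The score
statistic is $Q_I = \lVert W^{1/2} S' \hat P y\rVert^2$ with the mixture
weights from $W^{1/2} S' \hat P S W^{1/2}$.

## Why the interaction projection eliminates the genotype columns

A design decision worth spelling out. The textbook construction evaluates
$\hat P$ from $\hat V = \hat\tau_m G W G' + \hat\sigma^2 I$ with $X$ alone
as fixed effects. With true variance components that test is exact (we
verify this property in the tests). But $\hat\tau_m$ is estimated from only
$m$ genotype directions, so its sampling noise satisfies
$\hat\delta \xi_j = O(1)$ for the leading eigenvalues $\xi_j$ of
$GWG'$ — and those are exactly the directions the interaction matrix
$S = G \circ E$ lives in. When main effects are truly absent, half the mass
of $\hat\tau_m$ sits at the boundary and the plug-in null distribution is
visibly conservative (empirical size near 0.03 at nominal 0.05 in our
calibration runs, with a failed uniformity test).

The package therefore computes the interaction projection with the
genotype columns included as adjustment covariates in the $\hat V$ metric:
$\hat P$ annihilates $\mathrm{span}(G)$ exactly. Since the discrepancy
between $\hat V$ and the true covariance is confined to
$\mathrm{span}(G)$, it cancels from $\mathrm{Var}(S'\hat P y)$ identically,
and the mixture null is exact (up to $\hat\sigma^2$, estimated on $n - q$
degrees of freedom) under *any* configuration of main effects — zero,
fixed, or random. The REML variance components are still estimated and
reported (and their recovery is validated), and the cost is $m$ degrees of
freedom, negligible at gene-sized $m \le 25$. The calibration suite runs
both tests under the pure null and requires empirical size in
[0.040, 0.060] with Kolmogorov–Smirnov uniformity.

## Related samples

For family cohorts the joint-test null adds a polygenic random intercept:
$y = X\alpha + b + \varepsilon$, $b \sim N(0, \sigma_g^2 A)$ with $A$ the
numerator-relationship matrix (unit diagonal, 0.5 for full sibs). Fitting
is REML through the eigendecomposition of $A$, again profiled to one
variance ratio. Kinship-coefficient matrices (0.25 for full sibs on a unit
diagonal) are accepted and doubled off-diagonal; the convention travels in
the dataset metadata. The tests then use the whitened projection exactly as
above. On sibship-structured data with polygenic share 0.4 the calibration
suite requires the kinship-aware joint test to hold its level at
$\alpha = 0.01$ within 1.2x nominal.

## Mixture-of-chi-square p-values

$P(\sum_k \lambda_k \chi^2_1 \ge q)$ is computed by, in order:

1. an exact mixture-of-central-chi-square series (Ruben-type) with
   $\beta = \min_k \lambda_k$, whose nonnegative mixing weights sum to one
   so the truncated mass bounds the error; the series is run to an absolute
   tolerance of $10^{-12}$ and then to relative stabilisation, which keeps
   deep-tail p-values meaningful on the log scale;
2. Imhof characteristic-function quadrature when the eigenvalue spread
   defeats the series (the same integral, extended with noncentralities,
   powers the analytic power calculator);
3. a Liu–Tang–Zhang four-moment match as a last resort, flagged
   per-result as `moment-match` in the output tables.

Eigenvalues below $10^{-10} \times$ the largest are discarded; p-values are
clipped to $(10^{-300}, 1]$. The test suite checks the closed chi-square
forms and agreement with $10^6$-draw Monte-Carlo oracles to three
Monte-Carlo standard errors.

# Phenotype preparation

* The FEV1/FVC ratio is computed **before** transformation; the transform
  is never applied to numerator and denominator separately (asserted by a
  wiring test).
* Residual outliers: the raw trait is regressed on the covariate design by
  OLS and samples with residuals more than 4 SDs from the residual mean are
  excluded (the threshold is configurable, and a flag-only mode exists).
  The source procedure had experts review flagged values; automatic
  exclusion replaces that review for reproducibility.
* The rank-based inverse-normal transformation uses the Blom offset
  $c = 3/8$: $y^*_i = \Phi^{-1}((r_i - c)/(n - 2c + 1))$, average ranks for
  ties, missing preserved. The offset is not pinned by the source analysis;
  $c = 0.5$ is available. Outlier exclusion happens first, the transform is
  applied to the retained set.
* Samples with a missing trait or any missing covariate are dropped.
  Single-site studies contribute no site columns; site indicators drop the
  first level.

# Genotype QC

Variant filters (each variant gets a report row naming every failed
filter): nonsynonymous-flagged only (annotation is an input column),
autosomes only, polymorphic, missing rate $\le 5\%$, MAF $< 5\%$ strictly,
computed on non-missing dosages in minor-allele orientation. Missing
genotypes of retained variants are imputed by a random draw from
Binomial(2, $\widehat{\mathrm{MAF}}$), per variant, in minor-allele
orientation, with a seedable stream; observed genotypes are never touched.
Gene-level filters then require $\ge 2$ retained variants and cumulative
minor allele count $\ge 20$ (strict "less than" excludes). The order —
variant filters, then imputation, then gene filters — makes the cumulative
MAC and the tested matrix agree; the source text does not state whether MAC
was counted pre- or post-imputation. MAF orientation is decided per study:
the meta-analysis combines p-values, not effect estimates, so cross-study
allele alignment is unnecessary.

# Meta-analysis

Per-study p-values are combined by Stouffer's weighted Z:
$Z_i = \Phi^{-1}(P_i)$, $Z = \sum_i w_i Z_i / \sqrt{\sum_i w_i^2}$ with
$w_i = \sqrt{N_i}$ ($N_i$ the study's analyzed sample size), and
$P = \Phi(Z)$ — the Gaussian *CDF*, lower tail, so small study p-values map
to small combined p-values. (Reading the combining formula as the Gaussian
density would not produce a p-value.) Variance-component p-values carry no
effect direction, so they are combined as-is. Extreme inputs are handled in
log space; the combined p-value never underflows to zero.

Genomic-control $\lambda$ is computed per study and per test family (trait
$\times$ exposure $\times$ test type) as the median 1-df chi-square statistic
of the family's gene-level p-values over 0.4549364. Studies with
$\lambda > 1.5$ (strict) are excluded from that family's meta-analysis
only — never globally. One guard is package-specific: the exclusion is
applied only when the study contributes at least 50 gene-level p-values
(configurable `minLambdaGenes`), the same bound below which the estimator
itself warns. A median over a handful of genes is noise, and applying the
screen there excludes studies at random; the genome-wide analyses this rule
comes from had ~14,600 genes, where the guard never binds.

Significance uses the Bonferroni threshold
$\alpha / (\text{genes} \times \text{combinations})$; with 14,591 genes and
the 6 trait-exposure combinations, `bonferroniThreshold(0.05, 14591, 6)`
gives 5.7e-07 at two significant figures, the study-wide constant the
package reproduces in its acceptance checks.

# The synthetic-data generator

`simConfig()`/`generateCohorts()` emulate the features the analysis relies
on: several cohorts of unequal size (defaults 1500/1000/800; the validation
suite also uses 2000); ever-smoking prevalence spaced over 30–61% and
current-smoking over 6–25% (current $\le$ ever by construction, drawn as a
3-category never/past/current variable); a shared variant panel with 2–25
variants per gene and log-uniform MAFs below 5% (over-representing the
rarest variants); Hardy–Weinberg genotypes Binomial(2, MAF) with
completely-at-random missingness (default 1%); covariates on natural scales
(age, sex, height, weight, sites, 10 standard-normal PCs); and mL-scale
FEV1/FVC assembled as covariate effects + exposure effects + genetic
effects + noise (residual SD 600 mL, Table-1-like). Genetic main and
interaction effect sizes are per-dosage increments in residual-SD units,
assigned per gene; the interaction acts on a configurable exposure coding
(ever by default). FVC is FEV1 rescaled toward a ratio of ~0.76 plus weight
effects and independent noise, so FEV1 $\le$ FVC is *not* enforced — real
spirometry can violate it and the ratio is handled downstream.

Optional family structure draws sibships of configurable size, emits the
block-diagonal numerator-relationship matrix, and adds a polygenic
intercept carrying a configurable share of the residual variance (shared +
individual construction, so sibs correlate at half the polygenic variance).

Seeding: one master seed; per-study, per-stage substreams are derived
deterministically, so regeneration is byte-identical and stages are
independently reproducible. The variant panel has its own `panelSeed`
(defaulting to the master seed): fixing it while varying the master seed
draws replicate cohort sets over one fixed "genome", which is what a
repeated-run experiment needs — and what makes a single analytic power
calculation apply to every replicate.

What the generator does **not** emulate: linkage disequilibrium within or
between genes (variants are independent), genotyping-array intensities and
calling, imputation uncertainty (INFO scores), population stratification
(PCs are pure noise, not confounders), site-phenotype confounding, and
missingness that is informative. Passing tests therefore demonstrate the
statistical machinery under the stated model, not robustness to those
real-data complications.

# Validation experiments and problem sizes

The acceptance suite (and `scripts/acceptance.R`, which recomputes the same
quantities from scratch at a caller-chosen seed) uses these experiment
sizes, chosen to make Monte-Carlo error small relative to the checked
tolerances:

* test calibration: 2,000 null genes, $n = 2000$, $m = 10$, MAF
  log-uniform on [0.001, 0.05], exposure prevalence 0.2; empirical size at
  $\alpha = 0.05$ and KS uniformity;
* quadform oracle: 20 random small instances ($n \le 100$, $m \le 5$)
  against $10^6$-draw Monte-Carlo;
* kinship calibration: 500 sibships of 4, polygenic share 0.4, 2,000 null
  genes at $\alpha = 0.01$;
* recovery: $(\tau_m, \sigma^2) = (0.2, 1)$ over 200 replicates at
  $n = 5000$; polygenic share 0.4 over 100 replicates at $n = 1000$;
  single-variant $(\beta, \gamma) = (0.3, 0.4)$ over 200 replicates at
  $n = 20{,}000$, MAF 1%, exposure prevalence 0.25 — all within three
  Monte-Carlo standard errors;
* end-to-end: 3 cohorts (800/600/500), a 20-gene panel, one embedded
  interaction gene, 50 seeded runs. The embedded effect size is chosen by
  the package's analytic power calculator (noncentral mixture of
  chi-squares) so that the *smallest* cohort alone has $\ge 90\%$ power at
  the run's Bonferroni threshold. We deliberately calibrate on the smallest
  cohort rather than on a pooled design: Stouffer combination of
  variance-component p-values is genuinely less efficient than a pooled
  analysis, and a pooled calibration overstates meta power substantially.

# Numerical choices

* REML: 1-d profiled deviance on $\log\delta$, bounded search with
  tolerance $10^{-8}$, explicit comparison against the $\delta = 0$
  boundary; boundary hits and near-bound optima are recorded in the model
  notes. Multi-dimensional AI-REML is avoided as fragile at these sizes.
* Eigenvalues below $10^{-10}\times$ max are discarded; degenerate cases
  ($E \equiv 0$, zero interaction matrix, no eigenvalue above tolerance)
  return $Q = 0$, $p = 1$ with a note.
* Constant genotype columns are dropped from the tested set with a note;
  collinear covariates (including duplicate conditioning vectors) are
  pruned with a warning.
* Conditional tests drop conditioning variants from the tested set when
  present, append dosages (and optionally dosage-by-exposure columns) to
  the covariates, and refit both nulls.
* All pipeline thresholds live in `pipelineConfig()`; stage functions take
  them as arguments and contain no analysis-threshold literals of their
  own.

# Known limitations

Quantitative traits and binary exposures only (no logistic version, no
robust/GEE variants, no multi-exposure tests); effect-direction-aware
(inverse-variance) meta-analysis and heterogeneity statistics are out of
scope; the kinship-aware machinery is exposed for both tests, but the
interaction test's family-data behaviour is validated only through the
joint-test calibration experiment; single-variant inference is Wald-based,
which differs from score/LRT at $O(1/n)$ (a cross-check test bounds the
discrepancy on null instances).
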
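---
title: "Regional association, fine-mapping and Wald-ratio MR: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional association, fine-mapping and Wald-ratio MR: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regmr)
```

## The scientific setting

Aromatase, encoded by *CYP19A1*, converts testosterone (T) to estradiol
(E2) and is rate-limiting for estrogen synthesis after the menopause.
A variant in this region that raises circulating E2 should — if E2 is
causally related to endometrial cancer — also raise disease risk, by an
amount predictable from its hormone effect. **regmr** implements that whole
argument as one pipeline: per-allele association scans in several
case–control studies, fixed-effects meta-analysis, conditional analysis and
likelihood-ratio fine-mapping of the signal, stratification by BMI and age
quartiles with a 1-df interaction test, and a Wald-ratio
Mendelian-randomization (MR) comparison of the predicted and observed
per-allele disease odds ratios.

## Models and assumptions

**Per-allele association.** Disease models are unconditional logistic
regressions with dosage entering as a single linear term (the 1-df trend
model), fit per variant on complete cases by IRLS (tolerance 1e-8, maximum
25 iterations). Hormone models are OLS on the natural-log scale. Both report
Wald tests; score and likelihood-ratio tests are not implemented, because
downstream summaries (meta-analysis weights, the candidate-set chi-squares)
are built from Wald statistics throughout. Quasi-separation or
non-convergence produces a flagged `NA` row, never an exception, so a
region-wide scan of thousands of variants cannot be aborted by one
degenerate variant.

**Family clustering.** A family-based hormone study (sister pairs)
correlates outcomes within families. Instead of a kinship-matrix mixed
model, the supported method is the clustered sandwich variance estimator
over `cluster_id` groups with the small-sample factor
G/(G−1)·(n−1)/(n−k) (implemented through `sandwich::vcovCL(type = "HC1")`,
which is algebraically identical to the explicit matrix formula — the test
suite keeps the hand-evaluated oracle). With every cluster of size one this
reduces exactly to HC1 heteroskedasticity-robust errors.

**Meta-analysis.** Fixed-effects inverse-variance pooling with Cochran's Q
and I² = max(0, (Q−df)/Q)·100 (floored at zero, the standard definition).
Variants with heterogeneity P < 0.05 are excluded from fine-mapping.
A single-study variant has undefined heterogeneity P and is *retained with
a warning*: silently excluding it would drop every variant genotyped in only
one panel. The per-study panels need not coincide; each variant is pooled
over the studies that report it.

**Fine-mapping.** The candidate-causal-set rule — "likelihood ratio < 1:100
against the lead, and r² > 0.2 with it" — is operationalized on summary
statistics: per-variant χ² = (β/se)², LRᵢ = exp((χ²_lead − χ²ᵢ)/2). This is
the standard asymptotic equivalence between Wald chi-squares and log-likelihoods;
the genotype-level likelihood is not recomputed. The conditional scan, by
contrast, *is* genotype-level: each model is refit with the lead dosage as a
covariate, which is exact rather than a summary-statistic approximation.
r² is the squared Pearson correlation of dosages (composite LD) — the
quantity actually available for unphased, imputed data. Ties for the lead
are broken by larger χ², then lower genomic position, making lead choice
deterministic.

**Quartile stratification.** Cutpoints are the 25/50/75 percentiles
(linear interpolation, `quantile` type 7) of the variable's distribution
*in cases*, reused unchanged for the hormone arm so the two phenotypes are
stratified comparably. Intervals are left-closed/right-open with the top
interval closed below, matching the "<24.3" / "≥33.2" labelling convention.
The interaction test is a single joint model with an ordinal quartile index
(0–3) and a dosage×index product term (1-df Wald). An ordinal trend term was
chosen over a 3-df categorical interaction because the scientific hypothesis
is monotone effect modification; the resulting P value is invariant to
affine relabelling of the index.

**Wald-ratio MR.** An allele multiplying E2 by exp(β) corresponds to
β/ln 2 doublings, so with an external disease OR per doubling of E2
(default 2.06, 95% CI 1.47–2.89; 1.29 for the breast-cancer variant of the
analysis) the predicted per-allele OR is exp(ln(OR_dbl)·β/ln 2). The
prediction's CI uses the delta method treating the two sources as
independent, with var(ln OR_dbl) recovered from its CI assuming a symmetric
Wald interval on the log scale. Published descriptions of this computation
sometimes typeset the exponent ratio ambiguously ("lnβ/ln2"); it is read
here as β/ln 2 — multiplying by ln β would be dimensionally meaningless and
inconsistent with the published point predictions. No published method
exists for the prediction interval itself, so the delta-method interval is
this package's own choice; it is slightly narrower than intervals quoted
elsewhere for the same inputs, and reports surface both interval and method
rather than hiding the difference. Compatibility of observed and predicted
ORs is a z-test on the log scale with SEs recovered from the two CIs;
"compatible" means two-sided P ≥ 0.05.

## The synthetic-data generator

No individual-level data from the original consortium analyses are
available, so the generator reproduces the *statistical structure* the
pipeline assumes, with the study conditions as defaults:

* four case–control studies totalling 6608 cases / 37 925 controls (iCOGS
  4402/29 040; the three GWAS sets split the remainder equally, as their
  individual totals are not published);
* control effect-allele frequency 0.651 with per-allele disease OR 1.15 at
  the causal variant;
* a hormone cohort of n = 2767 with effect-allele frequency 0.656,
  per-allele effect 0.096 on ln E2 and −0.045 on ln T.

**LD model.** Haplotypes follow a first-order Markov chain along the
ordered variants: marginals hit the target frequencies exactly in
expectation and adjacent pairs attain a target correlation r = √r²,
optionally damped exponentially with distance. Correlation between
non-adjacent variants decays as the product of intervening adjacent
correlations. This is deliberately *not* coalescent-realistic — no
recombination hotspots, no allele-age structure — but it is sufficient to
exercise everything downstream that consumes LD: proxy ladders, r²
filtering, collinear conditioning. Target correlations that exceed the
Fréchet-type bound for a frequency pair raise an explicit parameterization
error rather than silently clipping. The default frequency grid is a narrow
ladder around 0.651 precisely so that high adjacent-LD targets stay
feasible.

**Case–control sampling.** Cases are drawn retrospectively: genotype-class
probabilities at the causal variant are reweighted by exp(β·dosage) (the
rare-disease multiplicative model — exact for the per-allele logistic
target and orders of magnitude faster than prospective simulation), and the
non-causal variants are re-sampled conditionally on the causal allele so
regional LD is preserved. The implied closed form for the case allele
frequency, f·OR/(1−f+f·OR), is what the tests check the generator against.

**Covariates.** Case BMI and age are truncated normals — BMI N(28.6, 6.5²)
on [16, 55], age N(63, 8.9²) on [35, 90] — drawn uniformly over the quartile
bins at the published cutpoints (24.3/28.0/33.2 kg/m²; 57/63/69 years), so
the case-derived quartiles land on those values by construction. Controls
are down-weighted per quartile by exp(−b·q) with b the per-quartile disease
log-OR (BMI default ln 1.60, age ln 1.50) — the retrospective image of a
logistic model linear in quartile index, so a logistic fit of status on the
index recovers b exactly in expectation. Genotype×BMI effect modification
adds `gxe_coef`·q to each case's per-allele log-OR.

**Hormones.** ln E2 = 3.0 + β·g + covariate terms + batch effects
(SD 0.15 over 8 laboratory batches) + study offset + familial cluster
effect + N(0, σ²). The residual SD is a free parameter — no published
quantity identifies it — with default 0.64, chosen so the slope SE at
n = 2767 is ≈ 0.018, the study's own precision. A configurable fraction of
the SIBS-like subset is arranged in sister pairs sharing a N(0, 0.25²)
random effect; this is the structure the cluster-robust errors are for.
Covariate effects (age −0.004/yr, BMI +0.04 per kg/m², HRT +0.10,
menopause −0.08, study +0.10) are plausible-magnitude choices; BMI's value
makes it by far the largest non-genetic contributor, qualitatively matching
its dominant share of hormone variance. As a consequence the generator's
variance-explained for the causal variant is ≈ 0.8–1%, of the same order as
the ≈ 1% reported for real data — but that number depends directly on the
free residual SD and should not be read as a reproduction.

**Causal-chain mode.** `simulate_disease_via_e2()` makes the MR argument
literal: disease risk is logistic-linear in log2(E2) with the configured OR
per doubling, and genotype affects disease *only through* E2. Cases are
drawn from a large candidate pool with weights exp(ln(OR_dbl)·log2 E2);
controls are unweighted draws (rare-disease approximation). Under this
generator the observed per-allele OR and the Wald-ratio prediction from an
independent hormone cohort must agree, and the test suite requires the
compatibility test to pass in ≥ 90% of 100 replicates at full study scale.

**Seeding.** All randomness flows from one mandatory integer seed through
counter-based child streams (haplotypes, case–control, hormones, cohort
pairing, causal-chain mode each get their own stream), so modules are
reproducible independently and generators never disturb the caller's RNG
state. The same seed gives byte-identical output.

**What passing tests do and do not show.** The generator emulates sampling
structure, not biology: no imputation uncertainty or info-score filtering,
no population stratification or ancestry outliers, no X-chromosome
handling, no coalescent LD, no assay detection limits, and hormone
covariates are mutually independent where real ones correlate (age with
menopause, BMI with HRT). Parameter recovery on these data therefore
validates the estimators and their wiring — not robustness to those
real-data complications, which the original analyses handled by upstream QC
that is out of scope here.

## Numerical choices and degenerate inputs

* Logistic IRLS: tolerance 1e-8, max 25 iterations; silent convergence to a
  separated fit is caught by checking for fitted probabilities within
  1e-10 of 0 or 1, and flagged.
* In every model formula the covariates precede the dosage term, so a
  dosage collinear with a conditioning covariate (a perfect proxy of the
  lead) is the term R aliases — it returns a flagged `NA` row; a lead
  collinear with a *user* covariate is refused up front.
* Monomorphic variants give `NA` r² with a warning; all-missing variants
  give `NA` frequency with a warning; empty strata name the stratum in the
  error.
* Quartile assignment uses `findInterval` (left-closed), so boundary values
  are handled identically everywhere.
* Thresholds (5e-8 genome-wide, 1e-4 conditional, 0.05 heterogeneity,
  LR 100, r² 0.2) are package defaults and all overridable via
  `regmr_thresholds()`.

## Problem sizes used by the test suite

Unit and property tests run at deliberately small scale (pools of 2000–10 000
haplotypes, studies of a few hundred to a few thousand samples, 200-replicate
calibration loops); the acceptance-style checks re-run the estimators at the
published sample sizes (6608/37 925; n = 2767; 2858/14 098; 721/1254) with a
handful of seeds, and the causal-chain consistency check uses 100 full-scale
replicates. These sizes are the package's own validation design: large enough
that recovery tolerances are dominated by the published precision, small
enough to keep the suite fast.

## Known limitations

* The LD model cannot create realistic haplotype blocks; r²-based filtering
  is exercised, but block-boundary behaviour is not.
* The Wald-ratio MR uses a single instrument; no pleiotropy-robust
  estimators (median/mode/Egger) are provided, and the compatibility test
  assumes the two CIs are independent and log-symmetric.
* The conditional scan refits genotype-level models; summary-statistic
  approximate conditional analysis is not implemented.
* Imputation, principal-components computation and ancestry QC are out of
  scope; principal components can enter only as pre-computed covariate
  columns.
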
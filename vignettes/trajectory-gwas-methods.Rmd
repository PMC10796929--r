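---
title: "Modelling cognitive change: trajectory GWAS by GEE"
author: "TrajGEE authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cognitive change: trajectory GWAS by GEE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TrajGEE)
```

## The model

Cognitive test batteries administered repeatedly in older cohorts often
show a fast initial change — practice and acclimatisation effects over
the first year — followed by a different, slower long-term trend. TrajGEE
models each z-scored cognitive outcome $y_{ij}$ of subject $i$ at visit
day $t_{ij}$ as a piecewise-linear ("knot-point") trajectory,

$$
E[y_{ij}] = \beta_0 + \beta_{a}\,(a_i - a_{\mathrm{ref}})
  + \beta_1\, s_1(t_{ij}) + \beta_2\, s_2(t_{ij}),
$$

with $s_1(t) = \min(t, 365)/365$ and $s_2(t) = \max(t - 365, 0)/365$,
so that $365\,(s_1 + s_2) = t$. Time is stored in days; dividing the
spline columns by 365 makes $\beta_1$ and $\beta_2$ read as change in
phenotype SD units per year before and after the knot. $a_i$ is age at
baseline (years), centred at a reference age ($a_{\mathrm{ref}} = 73.4$
by default, a typical sample mean for a 65–83-year-old cohort; centring
stabilises the intercept). The four coefficients answer four questions:
average function at baseline, how baseline function varies with age,
and the average rate of change before and after one year.

For the genome scan, each variant's dosage $g$ enters additively along
with its interactions with the three non-intercept trajectory columns:

$$
\ldots + \gamma_0\, g + \gamma_a\, g\,(a_i - a_{\mathrm{ref}})
  + \gamma_1\, g\, s_1(t_{ij}) + \gamma_2\, g\, s_2(t_{ij}),
$$

so each scan record reports four parameter blocks (intercept, age,
slope 1, slope 2). A variant can leave baseline function untouched and
still accelerate post-knot decline — the geometry that motivates
trajectory GWAS over cross-sectional GWAS.

## Why GEE, and how it is estimated

Fitting one linear mixed model per variant across millions of variants
is computationally prohibitive; generalised estimating equations treat
the within-subject correlation as a nuisance and are much faster, and
for Gaussian outcomes GEE and mixed-model fixed effects are comparable
(the package tests this equivalence directly). `fitGEE()` is written
from first principles:

1. update $\beta$ by weighted least squares with each cluster weighted
   by the inverse working correlation $R(\alpha)^{-1}$;
2. re-estimate the dispersion $\phi$ and the correlation parameters
   from Pearson residuals by moments;
3. iterate until the largest coefficient change is below `tol` (1e-8 by
   default, at most 50 iterations). Non-convergence is flagged on the
   record, never fatal — a genome-wide scan must not abort on one
   variant.

For the exchangeable structure, $R^{-1}$ has the closed form
$\big(I - c J\big)/(1-\rho)$ with $c = \rho / (1 + (n_i - 1)\rho)$, so
all cluster sums reduce to grouped-sum algebra and the per-variant fit
costs a handful of matrix products — this is what makes a 10,000-variant
scan run in about a minute in plain R. Missing visits simply subset the
working correlation; clusters of size one reduce the exchangeable fit to
the independence fit, and the independence fit *is* ordinary least
squares, a property the test suite asserts exactly.

The default working correlation for the scan is exchangeable. The
unstructured option (all pairwise visit correlations free) is available
when visits lie on the shared 6-month grid, as used for stage-1 model
exploration; it is estimated by moments on the visit grid, with
eigenvalue clipping to keep the matrix positive definite. An
autoregressive option exists in the data generator but deliberately not
in the estimator: the robust variance protects against that
misspecification.

Inference uses the sandwich covariance $A^{-1} B A^{-1}$, with $A$ the
model-based information and $B$ the empirical outer product of cluster
scores. By default the meat is scaled by $m/(m-p)$ ($m$ clusters, $p$
coefficients), the clustered analogue of the HC1 residual-df adjustment.
The plain CR0 meat is biased downward by a factor of roughly $1 - p/m$;
with 500 subjects and the 16-column scan design that is a 3% variance
deficit — enough to push null rejection rates and genomic-control
lambda visibly above nominal, which is exactly what the calibration
suite guards against (it verifies both on a seeded
500-subject × 10,000-variant null scan). At tens of thousands of
clusters the scaling is negligible, so nothing is lost at scale.
`sandwichCorrection = "none"` restores CR0 and `"mancl-derouen"`
applies the per-cluster $(I - H_i)^{-1}$ residual inflation for small
cluster counts. Per-parameter p-values are two-sided Wald tests against
a normal reference; a 4-df joint test is reported as an extra column,
but the per-parameter tests are primary.

`fitLMM()` delegates the restricted-maximum-likelihood mixed model
(random intercept and slope on total time) to lme4 — the mixed model is
standard machinery here, not this package's contribution — and is used
for stage-1 exploration and PRS testing, with a GEE fallback.

## Phenotype preparation

Component test scores are standardised to the baseline mean and the
baseline sample (n−1) SD, per test; later visits reuse the baseline
parameters, so a z of 2 at year 3 means "two baseline SDs above the
baseline mean". Domain scores are unweighted available-case means of
their component z-scores (a row is dropped, and logged, only when all
components are missing); the global composite is the unweighted mean of
the five domain scores. The component-to-domain map is configuration
(`defaultDomainMap()`, YAML-serialisable): real batteries differ, and
tests exercise reduced maps. Constant baseline scores are a hard error
naming the offending test, since they make the z-scale undefined.

Whether to re-standardise within an analysis subset (e.g. the genotyped
subset of a larger clinic cohort) is left to the caller: the
standardizer is fitted on whatever cohort it is given, and
`sensitivityCompare()` contrasts coefficients across the two choices.

## Genotype QC and the EMAC filter

Variants are filtered on call rate (≥ 0.95), the exact Hardy–Weinberg
test (p ≥ 1e-8), minor allele frequency (≥ 0.01), imputation quality
(r² ≥ 0.7) and expected minor allele count,
$\mathrm{EMAC} = 2 N \cdot \mathrm{MAF} \cdot r^2 > 200$ — at N = 2515
and perfect imputation the EMAC rule first passes at a MAF of 4%, which
is what makes it the binding power filter in practice. The exclusion
ledger records exactly one (first-failing) reason per excluded variant,
in that rule order. The HWE test conditions on the allele counts and
sums the probabilities of all heterozygote counts no more probable than
the observed one, accumulated in log space; the suite verifies it
against direct closed-form enumeration for every genotype table with up
to 200 subjects. Dosages are rounded to hard genotypes for the test
(`hweOnDosages = FALSE` skips it for imputed data, and our default
semantics are pre-imputation). Missing dosages are excluded from QC
denominators and only ever mean-imputed at scan time.

Ancestry principal components use dosages standardised as
$(d - 2p)/\sqrt{2p(1-p)}$; scores are left singular vectors scaled by
the singular values, computed after QC, optionally on an LD-thinned
subset (every k-th variant) since neighbouring variants in LD otherwise
dominate the leading axes.

## Selection (collider) bias

A trial that enrols by age and specific risk genotypes makes genotype
and age dependent *within the sample* even though they are independent
in the population. The diagnostic runs a GWAS of baseline age (linear,
HC1-robust SEs) and of sex (logistic) among included subjects; any
variant associated at the genome-wide threshold is flagged as
selection-driven and its dosage joins the scan covariate set. The
generator reproduces the mechanism — inclusion is Bernoulli with
logistic probability in centred age and summed risk-locus dosage — so
the acceptance suite can verify both directions: strong selection flags
the risk locus, and conditioning on the flagged dosages restores the
age-GWAS lambda to 1 and clears the induced association at linked
variants. This is also why the scan adjusts for the two risk-locus
dosages, age, sex and PCs but deliberately *not* for education, alcohol,
smoking or BMI: those are plausibly downstream of genotype, and
conditioning on them can induce the very bias the design avoids. An
override flag (`adjustLifestyle`) exists for sensitivity analyses.

## Clumping, lookups, polygenic scores

Clumping is greedy: significant variants sorted by ascending p (ties by
chromosome, then position — determinism matters for reproducible
output); the best unassigned variant becomes an index and absorbs
unassigned variants within 1000 kb with squared dosage correlation at
least 0.1. External lookups harmonise the effect allele (betas negated
when the external effect allele is the cohort's other allele) and flag
Bonferroni survivors at $\alpha / (4 \times n_\text{variants})$.

Polygenic scores keep only genome-wide-significant external weights —
deliberately not a shrinkage or sub-threshold score, to limit
pleiotropic variants — drop strand-ambiguous (A/T, C/G) variants, align
weights to cohort alt-allele dosages, clump against the *cohort* LD
panel (the source-panel alternative is a documented difference, not
supported), and standardise the score in-sample so association betas
read per SD of score. The association model mirrors the scan design
with the score in place of the dosage, fitted by LMM (GEE fallback).

## The synthetic cohort: what it emulates and what it does not

`simulateCohort()` generates the statistical structure the analysis
assumes: Hardy–Weinberg genotypes at frequencies uniform in (0.05,
0.95) (post-QC panels rarely carry rarer variants, and the EMAC filter
would remove them anyway), optional copy-with-flip LD blocks, screening
ages uniform on 65–83 years, 6-monthly visits to day 1825 (1 to 11
occasions), monotone missing-at-random dropout at 5% per visit,
risk-stratified selection as above, and latent domain trajectories with
the knot-point mean structure, subject random intercept (SD 0.7) and
slope (SD 0.08/year), occasion residuals (SD 0.55; independence,
exchangeable or AR(1)), and per-test affine calibration plus
measurement noise (SD 0.35). The population trajectory defaults — a
small negative baseline-age gradient (−0.03 SD/year), a positive first
year (+0.10 SD/year, a practice effect) and a near-flat tail
(+0.02 SD/year) — echo the qualitative pattern of cognitively normal
trial cohorts. Within-subject correlation magnitudes are free
parameters with no published reference values; the defaults above give
a baseline phenotype SD near 1 and within-subject correlation around
0.6, and are deliberately exposed in the configuration.

Dropout is missing-at-random given covariates; informative dropout,
practice-effect correction, treatment effects and conversion endpoints
are out of scope. The two risk loci are ordinary biallelic variants
standing in for a haplotype-defined risk classification — poly-T repeat
genotyping is not modelled. Passing tests on this generator demonstrate
that the estimators are correct and calibrated under the assumed
structure; they cannot certify behaviour under informative missingness,
population stratification beyond what PCA captures, or non-Gaussian
outcomes.

All randomness derives from one seed through fixed per-stage
substreams, so cohorts, scans and whole pipeline runs are bit-identical
across reruns — the pipeline writes a provenance record (configuration
hash, seed, package version) alongside its summary tables.

## Numerical choices and problem sizes

Worth stating explicitly: the exchangeable correlation estimate is
clamped to $(-1/(\max_i n_i - 1) + 10^{-6},\ 0.95)$ so the closed-form
inverse exists; the unstructured estimate gets unit diagonal and
eigenvalues clipped at $10^{-6}$; monomorphic variants are an error in
`scanVariant()` and a logged, flagged record in `runScan()`; logistic
separation is detected by coefficient magnitude (|β| > 15) with
p-values set missing; clump ties break by p, then chromosome, then
position. The calibration studies shipped with the package use 500
subjects × 10,000 variants for the null scan, 100 replicates of 2,000
subjects for slope-effect coverage, and 100 replicates of 5,000
variants for the selection diagnostic's familywise null — sizes chosen
so the whole suite completes on a laptop while keeping Monte-Carlo
bands tight enough to be meaningful.

## Known limitations

Gaussian outcomes only (no binomial/Poisson GEE families, no GEE2);
no relatedness or genetic-sex QC (upstream concerns here); the
unstructured working correlation requires a shared discrete visit grid;
gene-based tests, functional annotation and colocalization are outside
the package's remit; and the gene-level interpretation of any hit
requires external evidence the package does not compute.
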
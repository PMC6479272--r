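---
title: "Multigene signature profiling and penalized Cox prognostic modeling in ovarian cancer"
author: "ovasig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multigene signature profiling and penalized Cox prognostic modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovasig)
```

## The analysis this package implements

Epithelial ovarian cancer tumours differ sharply in how strongly the immune
system is represented at the tumour site, and the sphingolipid and
lysophosphatidate (LPA) signalling systems interact with that local immune
context. `ovasig` implements an integrated analysis of a targeted qPCR
signature — 38 sphingolipid/LPA-associated genes (enzymes of the
sphingomyelin/salvage pathway, the S1P and LPA receptor families, the CD1
lipid-antigen-presentation molecules) plus 8 immune lineage markers — in a
clinically annotated cohort:

1. **Preprocessing**: delta-delta-Ct normalization of Ct values against the
   geometric mean of four housekeeping genes (ACTB, TOP1, UBC, YWHAZ) and a
   calibrator sample, log2 transformation, and single chained-equations
   imputation of missing values.
2. **Stratification**: gene–gene Pearson correlations with Holm adjustment,
   unsupervised clustering of patients on the full signature, and
   immune-low / mixed / immune-high subtype labels driven by a ten-gene
   immune core (the 8 immune markers plus S1PR4 and CD1B, which co-cluster
   with them).
3. **Prognostic modeling**: ridge- and lasso-penalized Cox models of overall
   and progression-free survival over seven variable sets (clinical
   covariates, sphingolipid genes, immune genes, and all combinations),
   validated *only* through cross-validated predictors from an outer
   leave-one-out loop.
4. **Signature similarity**: alignment of the cohort's median expression
   profile against a compendium of condition profiles, and co-expression
   list overlaps.

A synthetic-cohort generator reproduces the statistical structure such a
study assumes, so that every stage is testable without patient data.

## The penalized Cox engine

For covariates $x_i$, observed times $t_i$ and event indicators
$\delta_i$, the engine maximizes the Breslow-ties partial log-likelihood
penalized in the elastic-net family, in the parametrization

$$\hat\beta(\lambda) = \arg\min_\beta\; -\tfrac{1}{n}\,\ell(\beta)
  + \lambda\Big[\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2\Big],$$

with $\alpha = 0$ (ridge) or $\alpha = 1$ (lasso), on covariates
standardized internally to mean 0 and population SD 1 (denominator $n$).
This is the same objective scaling used by the established elastic-net
implementations, so coefficients are directly comparable at a given
$\lambda$; the test suite verifies agreement with `glmnet` along whole
paths and with `survival::coxph` at $\lambda = 0$.

Numerics, chosen for the heavy nested use below: lasso fits use iteratively
reweighted least squares with a diagonal Hessian and cyclic coordinate
descent (soft-thresholding); ridge fits use a chord iteration — the exact
Breslow Hessian is factored at a reference point and reused across
iterations and $\lambda$ values, with every step driven by the exact
gradient, so the fixed point solves the exact penalized score equations
regardless of the reference. Iterations stop when the step size, or a
geometric-tail bound on the remaining error of the contracting iteration,
falls below the tolerance ($10^{-10}$ for final fits, $10^{-6}$ inside
cross-validation). Coefficients below $10^{-10}$ in a lasso fit are snapped
to exact zero so that "variable excluded" is well defined.

**Penalty grids.** $\lambda_{\max}$ is the smallest lasso penalty with an
all-zero solution, computed from the null-model score; the grid is 100
log-spaced values from $\lambda_{\max}$ down to $10^{-4}\lambda_{\max}$,
and the ridge grid is the same grid scaled up 1000-fold (the standard
convention when the L1 threshold does not apply). The optimal $\lambda$
minimizes the leave-one-out cross-validated partial-likelihood deviance in
the Verweij–van Houwelingen form
$-2\sum_i [\ell(\hat\beta_{(-i)}) - \ell_{(-i)}(\hat\beta_{(-i)})]$,
which remains well defined even though a single subject's partial
likelihood is degenerate.

## Validation by cross-validated predictors

All performance claims rest on predictors $\tilde\eta_i$ from an **outer
leave-one-out loop**: for each subject, the remaining data are
standardized, the penalty is tuned by inner LOO, the model is fitted, and
the held-out subject's linear predictor is computed with the training-fold
standardization. Nothing entering $\tilde\eta_i$ ever saw subject $i$.
From these predictors the package reports:

* **Harrell's c-index** — the fraction of usable pairs (distinct observed
  times, shorter time an event) in which the higher predicted risk dies
  first; prediction ties count 1/2.
* **Schemper–Henderson explained variation (PEV)** — the relative reduction
  in time-averaged absolute prediction error versus the marginal
  Kaplan–Meier, $V = (D - D_x)/D$, with per-subject errors $1 - S(t\,|\,x)$
  (known alive), $S(t\,|\,x)$ (dead), or the conditional mixture for
  subjects censored before $t$; event times are weighted by the number of
  events over the censoring-distribution Kaplan–Meier just before $t$.
  A constant predictor gives exactly 0. In small cohorts the estimate can
  dip slightly below zero when a late event time receives an exploding
  inverse-probability-of-censoring weight; an independent longhand
  implementation of the same formulas lives in the test helpers and must
  agree to $10^{-10}$.
* **Global p** — the two-sided Wald p-value of a univariate Cox model with
  $\tilde\eta$ as the single covariate (a constant predictor returns 1).
* **Added value** — the likelihood-ratio test of the gene-derived
  cross-validated predictor in a bivariable Cox model next to the clinical
  cross-validated predictor (Wald fallback under near-collinearity).
* **Quartile risk groups** — type-7 quantiles of $\tilde\eta$; predictors
  strictly below Q1 are low risk, strictly above Q3 high risk (boundary
  values stay intermediate); Kaplan–Meier curves per group and the k-group
  log-rank test.
* **Variable importance** — with $S^{36}$ the 36-month survival of the
  reference subject (all covariates at sample means, Breslow baseline), a
  variable's importance is $(S^{36})^{\exp(\beta^*_j)} - S^{36}$, the
  survival shift for a subject one SD above the mean; ranking by
  $|\beta^*_j|$ is equivalent.

Binary response models use the same penalized machinery with a Bernoulli
likelihood and an unpenalized intercept, validated by 40-times-repeated
stratified 5-fold cross-validation (per-repeat AUC and deviance, and an
added-value likelihood-ratio test against the clinics-only model on the
same folds).

### A caution on the global p under the null

The global p tests a predictor that was *itself built from the other
subjects' outcomes* (a pre-validated predictor). Our null simulations —
pure-noise cohorts run through the full nested loop, reproducible with
`scripts/acceptance.R` — show that the resulting Wald test rejects far more
often than its nominal level, while the accompanying PEV stays near 0 and
the c-index near 1/2. This anti-conservativity is a known property of
naively testing pre-validated predictors (the test statistic behaves as a
degenerate U-statistic over outcome pairs, with roughly doubled variance),
not an implementation artifact: an independent glmnet-based implementation
of the same nested loop produces p-values identical to three decimals. The
package therefore reports the global p as the procedure defines it, but the
honest summary of "no predictive value" is the PEV/c-index pair, not the
p-value. The corresponding calibration check in the acceptance suite
documents this behaviour rather than hiding it.

## Subtype assignment conventions

Patients are clustered by UPGMA (unweighted average linkage) on the
uncentered-Pearson dissimilarity $d = 1 - \sum x_i y_i / (\|x\|\,\|y\|)$
over the full signature. When merges tie at the minimal dissimilarity, the
pair whose clusters contain the lexicographically smallest original row
indices merges first — a documented determinism rule, checked against a
brute-force re-averaging agglomeration. The dendrogram is cut into $k = 3$
clusters; clusters are ranked by their mean expression over the ten
immune-core genes; lowest becomes `immune_low`, highest `immune_high`, the
rest `mixed`.

The **separation guard** refuses low/high labels when the spread between
extreme cluster means is below `min_separation`. Its default is 2 log2
units: because the immune-core genes are strongly co-expressed
(within-block correlation around 0.6 in the generator, matching the dense
positive correlation block seen in such signatures), clusters of structure-
free noise already differ by 1.0–1.45 log2 units in core mean, so a
threshold below that would hallucinate subtypes. With the planted $\pm 2$
shift the observed spreads are 2.6–3.4, comfortably above the guard.

## What the synthetic generator emulates — and what it does not

`synthetic_config()` defaults describe a 173-patient advanced ovarian
cancer cohort profiled with the 46-gene signature:

* **Expression**: multivariate normal on the log2 relative-expression
  scale; six exchangeable-correlation gene blocks (immune core $\rho=0.6$;
  a myeloid-associated sphingolipid block co-varying with the infiltrate;
  three sphingolipid blocks expressed inversely to the immune context; a
  weakly correlated remainder); subtype mean shifts of $\pm 2$ log2 units
  on the immune core for the low/high subtypes and $\mp 0.4$ to $\mp 0.5$
  on the sphingolipid blocks; independent noise SD 0.3.
* **Subtypes**: planted immune-low / mixed / immune-high labels in
  proportions 47 : 70 : 56.
* **Clinical covariates**: age $\sim N(56, 10.5^2)$; serous histology
  88.4%; FIGO II/III/IV at 4.6/80.4/15.0%; grade 3 at 72.3%; peritoneal
  carcinomatosis 69.9%; residual disease none/≤1 cm/>1 cm at
  73.4/17.3/9.3%.
* **Survival**: Weibull baseline (shape 1.3; OS scale 76 months, PFS scale
  46 months) scaled by $e^{\mathrm{lp}}$ with protective log-hazards on
  CD68, LPAR3, SMPD2 and CD1B and adverse clinical effects; uniform
  administrative censoring on 12–49 months (median follow-up around 30
  months). The scales were calibrated once against the published cohort
  marginals — 28.9% deaths, 57.2% recurrences — and then frozen; over 20
  seeds the defaults give ≈29–30% OS events and ≈57% PFS events.
* **Response**: Bernoulli with logistic intercept 1.2 (≈73% responders) and
  positive log-odds on CD3E, CD68 and PTPRC, so immune-high tumours respond
  more often.
* **Missingness**: optional MCAR at a configurable rate (the study's
  per-variable missingness is not published; MCAR is an assumption, not a
  reconstruction).

Not emulated: amplification-efficiency variation, plate/batch effects, raw
fluorescence, non-proportional hazards, informative censoring, or
missing-not-at-random patterns. Passing tests on these cohorts therefore
establish the *machinery* — not that real qPCR data meet the generator's
assumptions.

## Design decisions on genuinely open points

* **Engine authorship.** The nested validation (inner-LOO penalty selection
  inside an outer LOO, hundreds of thousands of path fits in the simulation
  batteries) is served by the package's own compiled path solver; the
  general-purpose elastic-net and survival packages remain the independent
  oracles the tests compare against.
* **FIGO and residual disease** are coded as single ordinal covariates
  (II/III/IV → 0/1/2; none/≤1 cm/>1 cm → 0/1/2), preserving the
  six-covariate clinical model; dummy coding is available via
  `build_design(..., figo_coding = "dummy")`.
* **Imputation is single**, performed once before cross-validation: the
  downstream models consume one completed matrix. Predictive mean matching
  uses 5 donors and 10 cycles with a fixed seed.
* **Global p by Wald, added value by likelihood ratio** — the two tests the
  analysis convention prescribes for those two questions.
* **Relative similarity** is defined as $RS_c = r_c / \overline{r}$ over
  the included conditions — a positive rescaling that preserves the
  correlation ranking and flags above-average resemblance as $RS > 1$. The
  proprietary compendium's own RS values are not reproducible and no
  numeric equality with them is claimed.
* **Probe collapsing** in co-expression lists keeps the best-correlated
  probe per gene; list overlaps compare case-normalized symbols, with
  unannotated probes compared by identifier.

## Problem sizes in the test and acceptance batteries

The shipped batteries run at sizes chosen to exercise every claim on a
single core: oracle equivalence on 50 concordance instances and 20
clustering toys; null calibration on 200 pure-noise cohorts of $n = 60$
with 10 genes; signal recovery at $n = 200$ with a three-gene planted
effect; subtype recovery at $n = 150$; explained-variation monotonicity
over effect sizes $\{0, 0.5, 1.0, 1.5\}$ at $n = 300$ with 20 seeds. The
full-cohort workflow (173 × 52 design, seven models) lives in the
`analysis/` scripts.

## Known limitations

* The global-p anti-conservativity under the null, discussed above.
* PEV can be slightly negative in small cohorts with extreme censoring
  weights.
* The dendrogram cut is a reproducibility convention; cluster *counts* are
  sensitive to it even when the low/high separation is stable, so cohort
  sub-cluster sizes should not be over-interpreted.
* Uncentered-Pearson clustering is sensitive to the overall expression
  level; profiles should be on a comparable calibrated scale before
  clustering.
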
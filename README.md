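# ovasig

Multigene-signature profiling and penalized Cox prognostic modeling for
epithelial ovarian cancer cohorts.

Targeted qPCR panels that read out the sphingolipid/lysophosphatidate
machinery together with immune lineage markers can both *stratify* ovarian
tumours into immune-low and immune-high subtypes and *prognosticate*
survival — but only if the modeling pipeline around them is honest about
validation. `ovasig` implements that pipeline end to end for a 38+8-gene
sphingolipid/LPA/immune signature (38 pathway genes — sphingomyelin/salvage
enzymes, S1P and LPA receptor families, CD1 lipid-presentation molecules —
plus 8 immune markers; housekeeping reference ACTB, TOP1, UBC, YWHAZ):

* **qPCR preprocessing** — delta-delta-Ct normalization
  ($R = 2^{-\Delta\Delta Ct}$ against the housekeeping geometric mean and a
  calibrator sample), log2 transform, chained-equations imputation with
  predictive mean matching;
* **stratification** — gene–gene Pearson correlations with Holm
  step-down, UPGMA clustering on the uncentered-Pearson dissimilarity,
  immune-low/mixed/immune-high assignment from a ten-gene immune core,
  variance-guided group tests (Levene → Student/Welch t, ANOVA + Tukey or
  Welch ANOVA + Games–Howell), chi-square, PCA;
* **prognostic modeling** — ridge/lasso Cox regression
  $\min_\beta -\tfrac1n \ell(\beta) + \lambda[\alpha\|\beta\|_1 +
  \tfrac{1-\alpha}{2}\|\beta\|_2^2]$ (Breslow ties, compiled path solver),
  penalty tuned by leave-one-out cross-validated partial-likelihood
  deviance (Verweij–van Houwelingen), validated **only** through
  cross-validated predictors from an outer leave-one-out loop: Harrell
  c-index, Schemper–Henderson explained variation (PEV), global p,
  added-value test over the clinical model, quartile risk groups with
  Kaplan–Meier/log-rank, and the $S^{36}$ importance transform
  $(S^{36})^{\exp(\beta^*_j)} - S^{36}$;
* **signature similarity** — median-profile alignment against expression
  compendia (Pearson r and a relative-similarity rescaling) and
  co-expression list overlaps;
* **a synthetic-cohort generator** that reproduces the statistical
  structure such studies assume (block-correlated log2 expression with
  planted immune subtypes, clinical covariate marginals, Weibull survival
  under uniform administrative censoring calibrated to ~29% deaths / ~57%
  recurrences, a subtype-linked treatment response), so every stage is
  testable without patient data.

The methods vignette (`vignettes/prognostic-modeling.Rmd`) documents the
models, conventions, numerical choices and limitations.

## Worked example

```r
library(ovasig)

co <- generate_cohort(synthetic_config(n_samples = 80, seed = 1))
print(co)
#> synthetic cohort: n = 80, 46 genes; OS events 27.5%, responders 63.7%
#>  immune_low       mixed immune_high
#>          23          30          27

st <- assign_subtypes(co$expression)
print(st)
#>  immune_low       mixed immune_high
#>          34           4          42

X <- build_design(co, model_variable_sets()[["Clinics+Immune"]])
cv <- loocv_predictors(X, co$clinical$os_time, co$clinical$os_event, "ridge")
performance_report(cv$eta, co$clinical$os_time, co$clinical$os_event)
#> PEV 1.44%  c-index 0.482  global p 0.383  (n = 80, events = 22)
```

The subtype table shows the clustering recovering the planted immune-low
and immune-high groups (the mixed samples sit between the extremes and are
largely absorbed by them — only clearly separated structure earns low/high
labels). The performance report is deliberately sobering: with 22 events
and 14 covariates, the outer-LOO validated model has essentially no
prognostic value (c-index ≈ 0.5), which is exactly what honest nested
cross-validation should report at this sample size.

At full cohort scale the picture changes. The `analysis/` workflow
(`01_simulate.R` … `05_similarity.R`) runs the complete study on the
default 173-patient synthetic cohort; its model-comparison stage prints:

```
                   model pev_pct c_index global_p added_value_p
1                Clinics  15.571   0.703 1.99e-07            NA
2                Sphingo   0.319   0.526 4.81e-01        0.5295
3                 Immune   2.710   0.575 2.01e-02        0.0259
4         Sphingo+Immune   1.407   0.570 8.87e-02        0.0911
5        Clinics+Sphingo  11.446   0.675 4.63e-06        0.1810
6         Clinics+Immune  16.229   0.709 1.16e-08        0.0222
7 Clinics+Sphingo+Immune  11.927   0.684 1.70e-06        0.0604
risk groups (low/intermediate/high): 43/87/43; log-rank chisq 22.91, p = 1.06e-05
```

— the clinical covariates dominate, gene panels alone carry little
cross-validated signal, and the quartile risk groups separate sharply
(columns: PEV in %, Harrell c-index, global Wald p of the cross-validated
predictor, and the likelihood-ratio p for added value over the clinical
model).

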
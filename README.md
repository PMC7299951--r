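# qpcrpanel

Longitudinal two-group analysis of a targeted qPCR gene panel, built for
case-conversion cohorts: subjects sampled at baseline (M0) and at the end of
follow-up (MF), with a binary outcome such as conversion to psychosis in an
ultra-high-risk (UHR) cohort. The motivating use case is the seven-member
YWHA (14-3-3) gene family measured in peripheral blood of 92 UHR subjects
(36 converters / 56 non-converters, 67 with follow-up expression), but every
stage is generic over the panel.

Because cohorts like this are typically not publicly distributable, the
package ships a first-class synthetic-cohort generator that emulates the
study design — correlated expression panel, group effects on baseline level
and on longitudinal change, realistic covariate and clinical-score
distributions, group-dependent attrition, and a small DNA-methylation
subset — together with a truth record, so the whole pipeline is testable and
its operating characteristics (type-I error, power, effect recovery) are
measurable without any restricted data.

## The analysis

For each target gene *g* and subject *i*, with reference (housekeeping) gene
*R* and a calibrator group *C*:

- **Livak normalization.** ΔCt<sub>ig</sub> = Ct<sub>ig</sub> −
  Ct<sub>iR</sub>; ΔΔCt<sub>ig</sub> = ΔCt<sub>ig</sub> − mean ΔCt of *C*;
  RQ<sub>ig</sub> = 2<sup>−ΔΔCt<sub>ig</sub></sup>.
- **Reference-group z-scores.** Baseline log2 RQ and longitudinal change
  (MF − M0 on the log2 RQ scale) are standardized with the mean and SD of
  the non-converters only; z-scores are provably invariant to the
  calibrator choice.
- **Per-gene group test.** Logistic regression
  converter ~ z<sub>g</sub> + age + sex + CPZ-eq
  (CPZ-eq = chlorpromazine-equivalent antipsychotic dose, 0 if
  unmedicated). Significance is permutation-based: group labels are
  shuffled B = 10 000 times with each subject's predictor and covariates
  kept intact, and p<sub>perm</sub> = #{b : p<sub>Wald</sub>(b) ≤
  p<sub>Wald</sub>(observed)} / B. Benjamini–Hochberg FDR is applied to the
  permutation p-values within each analysis family (baseline,
  longitudinal, principal components).
- **Co-expression.** Pairwise Pearson correlation of the panel;
  correlation-matrix PCA with deterministic eigenvector signs and
  per-dimension variable contributions; the first three component scores
  enter one covariate-adjusted logistic model, each tested with the same
  permutation engine.
- **Correlates.** Spearman correlation of expression with clinical scores
  (BPRS, CGI, PANSS negative, and the CAARMS composite = Σ rating ×
  frequency over the four first subscales, range 0–144); Pearson
  correlation of CpG beta values with the matched gene's expression in the
  methylation subset, with BH adjustment across CpGs.

The permutation inner loop is compiled (Rcpp/Armadillo IRLS); `stats::glm`
remains the fit of record for all reported coefficients and the two engines
are cross-checked in the tests.

## Worked example

The `analysis/` directory is a numbered workflow over the package; each
script prints what it found and writes tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # synthetic study + null cohorts
Rscript analysis/02_normalize.R     # delta-Ct, Livak RQ, z-scores
Rscript analysis/03_test_panels.R   # demographics + both gene panels
Rscript analysis/04_pca.R           # correlation matrix, PCA, PC test
Rscript analysis/05_correlations.R  # clinical + methylation correlates
```

Output of `03_test_panels.R` on the simulated study cohort (seed 2026,
B = 2000):

```
baseline panel (n = 92): 5/7 genes at FDR < 0.05: YWHAB, YWHAE, YWHAG, YWHAQ, YWHAZ
longitudinal panel (n = 72): 3/7 genes at FDR < 0.05: YWHAG, YWHAH, YWHAS
direction of longitudinal effects (OR < 1 = decrease in converters):
YWHAB YWHAE YWHAG YWHAH YWHAQ YWHAS YWHAZ
 1.11  0.80  0.28  0.36  0.92  0.49  0.47
```

The five genes flagged at baseline are exactly the five that carry an
injected +0.8 SD converter effect; the odds ratios are per 1 SD of
standardized expression, so OR < 1 in the longitudinal panel means
converters' expression fell relative to non-converters (the injected −0.6 SD
change). The PCA stage on the same cohort reports:

```
variance explained by PC1+PC2: 70.7% (60.1% and 10.6%)
PC1 group test: OR = 1.77 [1.24, 2.50], p_perm = 0.001
```

PC1 of an equicorrelated panel is close to the mean expression, so the
baseline group shift loads on it. Longitudinal power is deliberately lower
than baseline power (n = 72 complete cases, −0.6 SD vs +0.8 SD): single
simulated cohorts flag 1–4 of the 5 changed genes.

Equivalently, `run_full_pipeline()` orchestrates all stages from a
`pipeline_config()` and `write_report()` writes the full bundle with a run
manifest (seeds, B, subject accounting at every stage).

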
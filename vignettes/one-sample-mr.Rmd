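---
title: "One-sample Mendelian randomization of vitamin D status: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-sample Mendelian randomization of vitamin D status}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdmr)
```

## The scientific question

Observational cohorts consistently find that low serum 25-hydroxyvitamin D
(25(OH)D) accompanies metabolic syndrome (MS), type 2 diabetes (T2D) and
elevated blood pressure. Whether low vitamin D *causes* these conditions is
a different question: vitamin D status is confounded by adiposity, outdoor
activity, diet and illness itself (reverse causation). Mendelian
randomization (MR) addresses this by using genetic variants as instrumental
variables: alleles are allocated at random at meiosis, so variants that
shift 25(OH)D are — under stated assumptions — independent of the
behavioural and physiological confounders and unaffected by disease.

`vitdmr` implements a one-sample MR analysis built on four well-replicated
vitamin-D pathway SNPs: two synthesis variants (DHCR7/NADSYN1-rs12785878,
CYP2R1-rs10741657), one transport variant (GC-rs2282679, the vitamin D
binding protein) and one catabolism variant (CYP24A1-rs6013897). SNPs are
combined into genetic risk scores (GRS): `synthesis` (two SNPs),
`metabolism` (transport + catabolism) and `combined` (all four).

## The generative model

Because individual-level data of this kind are rarely deposited, the
package ships a first-class synthetic cohort generator whose structure is
the causal diagram the analysis assumes:

* genotypes $g_j \in \{0,1,2\}$ drawn independently per SNP from
  Hardy-Weinberg proportions $((1-p_j)^2,\,2p_j(1-p_j),\,p_j^2)$;
* exposure
  $X = \alpha + \textstyle\sum_j \beta_{ZX,j}\, g_j + \gamma_X U + \varepsilon$,
  with $U \sim N(0,1)$ a latent confounder and
  $\varepsilon \sim N(0, \sigma^2)$, truncated at 1 nmol/L;
* a generic binary outcome with
  $\operatorname{logit} P(Y{=}1) = \mu + \theta X + \gamma_Y U +
  \textstyle\sum_j \kappa_j g_j$, where $\theta$ is the causal log-odds per
  nmol/L and $\kappa_j$ are optional direct (pleiotropic) SNP effects —
  $\kappa_j \neq 0$ violates the exclusion restriction on purpose, for
  testing MR-Egger;
* biomarkers (glucose, insulin, lipids, blood pressure, anthropometry)
  with means depending linearly on $X$ and $U$, from which the clinical
  outcomes MS, T2D and abnormal SBP/DBP are *derived* by the phenotyping
  rules, exactly as in a real cohort.

### Default parameters and why

The defaults are fixed study conditions, not tuning dials:

* **n = 2393**, the scale of a middle-aged and elderly community cohort.
* **Allele frequencies 0.45 / 0.40 / 0.30 / 0.25** — common variants
  (> 0.05), chosen to give workable instrument strength.
* **Per-allele effects 2.14 / 1.10 / 2.94 / 0.74 nmol/L** for rs12785878,
  rs10741657, rs2282679, rs6013897 — the published per-allele
  25(OH)D differences for these variants in an East-Asian cohort.
* **Intercept 37.1, residual SD 16, confounder effect −5 nmol/L per SD**,
  so the marginal 25(OH)D distribution has median ≈ 42 nmol/L and
  empirical quintile cutpoints near 28 / 37 / 46 / 57 nmol/L, matching the
  descriptive profile of such cohorts (widespread deficiency). No
  distributional form is published for the exposure; we use a normal
  truncated at 1 nmol/L, the simplest shape consistent with the published
  quintile cutpoints.
* **Causal effect −0.004 log-odds per nmol/L** (odds ratio ≈ 1.105 per
  25 nmol/L decrease), the order of magnitude reported for T2D in MR
  studies of Chinese adults; **confounder log-odds 0.3 per SD** and
  **baseline −1.6**, giving outcome prevalence between typical T2D and MS
  prevalences.
* **Biomarker baselines** calibrated so the *derived* phenotype prevalences
  sit at the published cohort values (MS ≈ 31%, T2D ≈ 15%), with
  vitamin-D gradients in glucose, insulin, HOMA-IR, triglycerides, HDL-c
  and waist circumference of the size seen across published 25(OH)D
  quintiles.

One published tension is worth stating: per-allele confidence intervals of
the size printed for these SNPs imply a residual exposure SD near 6
nmol/L, while the published quintile cutpoints imply a total SD near 17
nmol/L; both cannot hold. The generator follows the quintile calibration,
so simulated per-SNP F statistics (≈ 0.5–20 at n = 2393) are smaller than
the 17–68 printed in that literature. The combined GRS remains a usable
instrument (F ≈ 25–40 at study scale).

Every random variable draws from its own deterministic substream of the
single global seed, so the same configuration is byte-identical across
runs and adding a variable never perturbs earlier draws.

### What the generator does not emulate

No linkage disequilibrium between the four loci (they are on different
chromosomes), no seasonality or assay error in 25(OH)D, no missing data
beyond optional OGTT missingness, no correlation between medication use
and the underlying biomarker, and no age structure in genotype frequencies.
Passing tests therefore demonstrate correctness of the estimators under
the assumed causal structure — not robustness to the many ways real data
violate it.

## Phenotyping rules

* **Repeated measurements**: duplicate readings are averaged; if they
  disagree by more than the protocol tolerance (1 cm circumference, 1 kg
  weight, 10 mmHg blood pressure) a third is taken and the two closest are
  averaged. Tie-break (third reading equidistant from both): the third is
  averaged with the *earlier* original reading — deterministic and
  documented.
* **MS** (joint interim statement, Asian waist cutoffs): ≥ 3 of — WC ≥ 85
  cm (men) / ≥ 80 cm (women); TG ≥ 1.7 mmol/L or TG-lowering medication;
  HDL-c < 1.0 (men) / < 1.3 (women) mmol/L or treatment; SBP ≥ 130 or
  DBP ≥ 85 mmHg or antihypertensive medication; FBG ≥ 5.6 mmol/L or
  anti-diabetic medication. Medication always implies the component
  abnormal. Records missing a field are flagged unclassifiable, never
  dropped silently.
* **T2D**: FBG ≥ 7.0 mmol/L and/or 2-h OGTT ≥ 11.1 mmol/L and/or
  anti-diabetic treatment and/or prior physician diagnosis.
* **HOMA-IR** = FBG (mmol/L) × insulin (μIU/mL) / 22.5; a pmol/L ↔ μIU/mL
  insulin converter (× 6.945) is provided because descriptive tables often
  report pmol/L.
* **Vitamin D categories**: [0, 25) severe deficiency, [25, 50)
  deficiency, [50, 75) insufficiency, [75, ∞) sufficiency — half-open,
  right-continuous, partitioning the positive axis.
* **Quintiles**: empirical 20/40/60/80th percentiles; labels run Q1 =
  *highest* concentration (the reference) to Q5 = lowest, and a value
  equal to a boundary joins the lower-concentration quintile. Published
  tables disagree among themselves on whether Q1 or Q5 is the highest
  quintile; we fix Q1 = highest = reference and say so in every output.
* **Abnormal SBP/DBP**: thresholds 130 / 85 mmHg; whether antihypertensive
  medication alone marks the binary outcomes abnormal is not always stated
  in published analyses, so both modes exist behind
  `bp_med_rule = "include"/"exclude"` (default include, consistent with
  the MS blood-pressure component).

## Estimators

With $\hat\beta_{ZX,j}$ (linear, nmol/L per allele) and $\hat\beta_{ZY,j}$
(logistic, log-odds per allele):

* **Cragg-Donald F** $= R^2 (n-2) / (1 - R^2)$, with F > 10 the
  conventional adequacy bar. For a GRS with covariates, $R^2$ is the
  partial $R^2$ of the score given the covariates, which reduces to the
  simple regression $R^2$ without covariates — matching the
  single-regressor $n-2$ form of the formula.
* **Wald ratio** $\hat\beta_{IV,j} = \hat\beta_{ZY,j}/\hat\beta_{ZX,j}$
  with delta-method SE
  $\sqrt{se_{ZY}^2/\beta_{ZX}^2 + \beta_{ZY}^2 se_{ZX}^2/\beta_{ZX}^4}$.
  The one-sample covariance between numerator and denominator is ignored —
  a documented limitation; the two-stage estimator provides an
  internally-consistent alternative.
* **IVW fixed-effect pooling**
  $\hat\beta_{IVW} = \sum_j \omega_j \hat\beta_{IV,j} / \sum_j \omega_j$,
  $\omega_j = 1/\widehat{var}(\hat\beta_{IV,j})$, pooled SE
  $(\sum_j \omega_j)^{-1/2}$.
* **MR-Egger**: weighted least squares of $\hat\beta_{ZY}$ on
  $\hat\beta_{ZX}$ with free intercept, weights $1/se_{ZY}^2$; the
  intercept estimates directional pleiotropy. The intercept p-value uses a
  t reference with $k - 2$ degrees of freedom (four SNPs → 2 df), a
  deliberately conservative choice since no reference distribution is
  standard at k = 4. Egger requires all instruments oriented
  exposure-increasing; `egger_regression()` refuses negative
  $\hat\beta_{ZX}$, and the `snp_mr()` wrapper applies the standard
  convention of sign-flipping $(\hat\beta_{ZX}, \hat\beta_{ZY})$ pairs
  whose estimated exposure effect is negative. At small n this estimated-
  sign orientation is itself noisy for weak SNPs — an inherent Egger
  fragility, which is why the package's Egger calibration simulations run
  at n = 10,000 where instrument signs are essentially always determined.
* **Wald-type GRS estimator**:
  $OR_{IV} = \exp\!\big(\ln(OR_{GRS\text{-}outcome})/\beta_{GRS\text{-}VD}\big)$,
  rescaled by $\exp(\pm s \cdot)$ to per-$s$ nmol/L (s = 25 by default, 10
  for per-10 reporting). The CI maps the CI of $\ln OR_{ZY}$ through the
  same monotone transform with $\beta_{GRS\text{-}VD}$ treated as fixed;
  denominator uncertainty is deliberately not propagated (no published
  convention exists for it), and the two-stage estimator is the
  uncertainty-complete alternative. Reporting per-decrease and
  per-increase are exact reciprocals.
* **Two-stage estimator**: stage 1 regresses 25(OH)D on the GRS (+
  covariates); stage 2 is a logistic regression of the outcome on the
  fitted values (+ covariates); $OR_{IV} = \exp(-25\, \hat b_2)$ per 25
  nmol/L decrease. Without covariates this coincides numerically with the
  Wald-type estimator (the fitted exposure is an affine transform of the
  score). F ≤ 10 attaches a prominent weak-instrument warning to the
  result — a warning, not an error, since the estimate remains reportable.

### Orientation

Scores count alleles in the 25(OH)D-*decreasing* direction by default, so
"per 1 unit higher GRS" aligns with genetically lower vitamin D and causal
odds ratios read naturally "per 25 nmol/L decrease". Because every scoring
and estimation routine resolves the coded-allele direction explicitly, all
IV estimates are invariant (to numerical precision) under recoding any SNP
to its other allele — a property under test.

## Observational layer

Adjusted logistic models give ORs per 10 / per 25 nmol/L decrease (same
coefficient, different rescaling — so $OR_{25} = OR_{10}^{2.5}$ exactly),
by cohort quintile and by clinical category, with the
highest-concentration level as reference (OR exactly 1, no CI). Adjustment
presets: MS models use age, BMI, WHR, income, smoking, alcohol, physical
activity and family history; T2D models drop smoking; the MR models use
the full set. Descriptive quintile tables use ANOVA for approximately
normal variables, Kruskal-Wallis for skewed ones and Pearson chi-square
for categorical ones. Two-sided α = 0.05 throughout; no multiple-testing
correction is applied, as none is conventional in this table structure.

## Numerical choices

* CIs are Wald intervals, β ± 1.96·se, on the link scale throughout; no
  profile likelihood.
* Logistic fits use IRLS with relative tolerance 1e-10 and at most 100
  iterations; non-convergence is an error. Complete/quasi-complete
  separation (fitted probabilities numerically 0/1 with runaway
  coefficients, |β| > 15) and single-class outcomes are errors, never
  silently divergent estimates.
* Rank-deficient designs raise an error naming the collinear columns.
* Categorical covariates enter as indicator contrasts with the documented
  first level as reference.
* A monomorphic marker has no defined Hardy-Weinberg test; the result
  says so rather than returning numbers.
* Quintile ties go to the lower-concentration quintile; the
  repeated-measurement tie-break pairs the third reading with the earlier
  original.

## Problem sizes used in the test-suite simulations

Chosen once, as a balance of Monte-Carlo resolution against desk-scale
runtime: null calibration of the two-stage test uses 500 cohorts of
n = 2393; causal recovery uses 100 cohorts of n = 100,000 with externally
weighted scores (F > 30); confounding robustness uses 60 cohorts of
n = 50,000 with a strong shared confounder; Egger recovery and calibration
use 500 + 500 cohorts of n = 10,000; orientation invariance uses one seeded
cohort of n = 2393. The acceptance script reports study-scale (n = 2393)
quantities plus a 20-replicate mean recovery at n = 100,000.

## Known limitations

* One-sample MR with internally estimated associations: winner's-curse
  and weak-instrument bias push toward the confounded estimate; mitigated
  by reporting F and by external GRS weights, not eliminated.
* The Wald-ratio delta SE ignores the β_ZX/β_ZY covariance (one sample).
* The Wald-type CI treats the denominator as fixed.
* Equal GRS weights (the testing default) are not the externally weighted
  instrument a real analysis should use; weights are a required input in
  practice.
* MR-Egger with four instruments has 2 degrees of freedom: low power, and
  its InSIDE assumption is untestable.
* The generator's biomarkers are conditionally independent given exposure
  and confounder; real metabolic traits correlate beyond that.
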
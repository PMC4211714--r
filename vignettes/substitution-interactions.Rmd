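---
title: "Substitution models, predisposition scores and pooled gene-diet interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substitution models, predisposition scores and pooled gene-diet interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gdsub)
```

## The scientific question

`gdsub` asks whether genetic predisposition to adiposity modifies the
association between dietary protein and subsequent anthropometric change.
The unit of analysis is one adult observed at baseline and at follow-up
roughly five years later, with diet assessed at baseline as the energy
shares (E%) of protein, carbohydrate, fat and alcohol, genotypes at a panel
of adiposity-associated SNPs, and standard lifestyle covariates. Outcomes
are annualized: ΔBW = (BW₁ − BW₀)/follow-up years in kg/y, ΔWC analogous in
cm/y, reported as g/y and mm/y.

## The substitution model

Because the four macronutrient shares close to 100, only three can enter a
regression. The leave-one-out parameterization includes protein, alcohol and
one of carbohydrate/fat; the coefficient on protein is then the effect of
1 E% protein replacing 1 E% of the omitted macronutrient, holding the others
and (deliberately) not total energy constant — raising relative protein
intake may itself change total energy, and conditioning on energy would
block that pathway.

A product of a predisposition score with *protein* alone, however, tests an
interaction with protein irrespective of what protein replaces. The model is
therefore reparameterized through the substitution variable

$$ s = \frac{P - X}{2}, \qquad X \in \{C, F\}, $$

with the kept macronutrient $K$ and alcohol $A$ as the remaining diet terms.
Substituting $X = 100 - P - K - A$ into the leave-one-out model shows the
two parameterizations span the same column space with

$$ \beta_s = \beta_P, \qquad
   \beta_K^{(s)} = \beta_K - \tfrac{1}{2}\beta_P, \qquad
   \beta_A^{(s)} = \beta_A - \tfrac{1}{2}\beta_P, $$

identities the test suite asserts to 1e-8 relative error along with equality
of fitted values. The interaction term is the single column $s \times G$,
which is specific to the replaced macronutrient; both main effects always
accompany it.

```{r reparam, eval = FALSE}
co <- simulate_cohort(sim_config(n = 500), seed = 1)
coef(fit_substitution(co, parameterization = "leave_one_out"))["protein_e"]
coef(fit_substitution(co, parameterization = "substitution"))["substitution"]
```

## Predisposition scores

Scores are unweighted sums of risk-allele dosages (0/1/2) over the SNPs
whose trait tags match the requested score. Subset sizes are read from the
panel file at run time; in the bundled synthetic 50-SNP panel the tags give
33 (BMI), 6 (WC) and 14 (WHR_BMI) SNPs, with three SNPs tagged for both BMI
and WC, so the subsets overlap and the complete score is the sum over the 50
distinct SNPs, not the sum of the three subscores. Scores are complete-case:
one missing dosage in the subset makes the score missing. This mirrors how
genotyping success rates produce different analysable sample sizes per
score, and avoids the bias of rescaling by the available SNP count.

The bundled panel is a synthetic stand-in (hence its filename): rsIDs are
plausible adiposity loci, and risk-allele frequencies were chosen once so
that simulated score medians (complete ≈ 44, BMI ≈ 29, WC ≈ 3, WHR_BMI ≈ 14)
resemble population cohorts. Any panel with the same four columns can be
supplied instead.

## Adjustment set and coding choices

All models adjust for the baseline level of the outcome, height, sex,
smoking (never/former/current), physical activity (four groups), education
(two groups) and menopausal status; ΔWC models additionally adjust for
concurrent ΔBW so waist effects are interpreted independently of weight
change. Two coding decisions deserve note:

* **Menopause.** A full male/pre/post indicator block would be exactly
  collinear with the sex indicator (maleness is determined by the "male"
  menopause level). We therefore use a single postmenopausal indicator;
  together with sex and the intercept it spans the three estimable cells
  (men, pre-, postmenopausal women) while keeping the model fit in one
  pooled regression.
* **Age and follow-up time** are collected but not adjusted for by default,
  matching the adjustment set the published analyses describe; both are
  exposed as switches (`adjust_age`, `adjust_fu`) because reasonable
  analysts differ here.

Reference levels are fixed (female, never-smoker, activity group 1, low
education) for reproducibility. Rows with any missing required field are
dropped per model, and each result row logs `n_total`/`n_used` so the
complete-case attrition is auditable.

## Inference conventions

Fits are ordinary least squares via the QR decomposition, with classical
homoskedastic standard errors. Confidence intervals and p-values use normal
quantiles (1.959964 for 95%) by default — the intended cohorts have
thousands of rows — with a `use_t` switch. Effects are rescaled for
reporting by ×5 (per 5 E%) and ×1000 (kg→g) or ×10 (cm→mm); interactions are
additionally per single risk allele. Since estimate, SE and CI scale
together, z-statistics and p-values are invariant to the rescaling.

Degenerate designs are handled deterministically: indicator columns that are
constant in the analysed rows (e.g. a cohort with one smoking level) are
dropped with a warning; any remaining rank deficiency is a hard error naming
the collinear columns rather than a silent pivot.

## Meta-analysis

Cohort estimates are pooled by inverse variance. The random-effects model is
classic DerSimonian–Laird: Q on fixed-effect weights, moment estimator
τ² = max(0, (Q − df)/C) with C = Σw − Σw²/Σw (not iterated), random-effects
weights 1/(se² + τ²). I² = max(0, (Q − df)/Q)·100 is banded as
[0,25) none, [25,50) moderate, [50,75) significant, [75,100] extreme;
boundary values go to the higher band (the conventional overlapping bin
notation forces a choice). When a published table reports only betas and 95%
CIs, SEs are recovered as CI width / (2·1.959964); the same quantile
reproduces published pooled CI endpoints. τ² that truncates to zero makes
the random-effects result identical to the fixed-effect one — asserted
exactly in the tests, and `metafor::rma(method = "DL")` serves as an
independent oracle for the pooling arithmetic.

## Per-SNP scans and multiplicity

`scan_snps()` refits the interaction model once per panel SNP with the
dosage in place of the score and Bonferroni-corrects the interaction
p-values. The divisor stays at the panel size even when a SNP is skipped
(monomorphic in sample), because the family of planned tests does not
shrink when one test is unestimable in one cohort. Correction is applied
within each outcome-by-substitution combination, recorded in the output
attributes; analysts wanting a joint correction can multiply further.

## Energy balance and subgroup summaries

Observed annual weight change proxies cumulative net energy balance:
< −0.5 kg/y negative, within ±0.5 kg/y (closed interval) neutral,
> 0.5 kg/y positive — the closed neutral band is the consistent reading of
"±0.5" next to strict-inequality tails. `protein_by_subgroup()` tabulates
mean protein intake (E% and g/kg/day) with SEM and normal 95% CIs over the
six balance-by-score cells; the g/kg/day conversion uses 17 kJ per gram of
protein and baseline body weight (config-exposed, since energy densities of
16.7–17.2 are all in use).

The case-cohort gainer selection ranks, within each sex, residuals from a
regression of ΔBW on baseline age, weight, height, smoking and follow-up
time, and takes the top k per sex; ties are broken by individual id. The
selection is invariant to adding any linear function of those covariates to
ΔBW, which the tests assert directly.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, per
cohort:

* **Genotypes**: Hardy–Weinberg dosages, Binomial(2, p) per SNP, with
  missingness applied completely at random to the *observed* dosages only —
  outcomes are generated from the latent complete dosages, so missingness
  thins samples without distorting effects. Preset missing rates
  (0.8–1.3%) give complete-score availability around 50–70% of each cohort,
  the pattern real genotyping success rates produce.
* **Diet**: a logistic-normal law — Gaussian draws on the three log-ratios
  of carbohydrate, fat and alcohol to protein, closed to 100 — chosen over a
  Dirichlet because it allows realistic correlations between macronutrients
  (exposed as a log-ratio correlation matrix). Compositions close exactly by
  construction. Preset centers reproduce each cohort's published median
  composition and energy intake.
* **Covariates** are independent draws matching published category
  frequencies (about half women, cohort-specific smoking and education
  rates); no attempt is made to copy real correlation structure.
* **Outcomes**: ΔBW = β₀ + β_P·s + β_G·G + β_int·s·G + covariate terms +
  N(0, σ²), with follow-up weight back-computed as BW₀ + ΔBW·years. ΔWC is
  coupled to ΔBW (default 0.35 cm per kg) plus its own noise, so the
  ΔWC-adjusted-for-ΔBW pathway is exercised. Default effect sizes are the
  study conditions: a small positive substitution main effect
  (0.008 kg/y per E%, the order of the published pooled estimate), no score
  main effect and no interaction; σ = 0.9 kg/y reproduces the published
  spread of annual weight change. The `monica` preset has no waist
  measurements (excluding that cohort from waist analyses, as in the real
  data); the `dch` preset simulates an eligible pool and keeps the union of
  600 top gainers per sex and a random subcohort.

What the generator does **not** emulate: FFQ/food-record measurement error
and desirability bias, correlated covariates, linkage disequilibrium between
SNPs, intervention effects, or drop-out mechanisms. Passing tests therefore
show the pipeline recovers what it assumes — unbiased planted-effect
recovery, nominal CI coverage, correct pooling — not that those assumptions
hold in any real cohort.

## Validation problem sizes

The parameter-recovery check uses 200 replicates of three cohorts of
n = 2000 with a planted interaction of 0.01 kg/y per E% per allele,
asserting bias within twice the Monte-Carlo SE, pooled 95% CI coverage
within [92%, 98%], and median I² below 25 for identically parameterized
cohorts. Family-wise error of the corrected scan is checked over 40 null
replicates of a 6-SNP panel. Unit tests run on compact 6-SNP cohorts of
120–500 rows so the full suite stays fast; the fitting code paths are
identical at any size.

## Known limitations

* Classical (not robust) standard errors; no mixed models or case-cohort
  weighting — subgroup-design interactions are assumed negligible, as the
  analyses this package operationalizes concluded.
* Unweighted allele counts assume each SNP's interaction direction follows
  its main-effect direction; weighted scores are out of scope.
* The scan offers Bonferroni only; FDR control would be a natural extension
  but is deliberately not implemented.
* The printed-table entry point inherits the rounding of published CIs;
  weight percentages recomputed from printed waist rows can differ in the
  first decimal for that reason.
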
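---
title: "Methods: weighted genetic risk scores with random-forest variant selection"
author: "grsforest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted genetic risk scores with random-forest variant selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grsforest)
```

## The model

The package estimates the association between a weighted genetic risk
score and excess BMI loss (EBMIL) after Roux-en Y gastric bypass. For
subject $j$ with initial and 24-month BMI $b^{0}_j, b^{1}_j$,

$$\mathrm{EBMIL}_j \;=\; 100 - \frac{b^{1}_j - 25}{b^{0}_j - 25}\times 100,$$

treating BMI 25 kg/m² as the upper bound of normal; the quantity is the
percentage of the *excess* BMI that was lost. It is deliberately left
unclamped — values above 100 (final BMI below 25) and below 0 (weight
gain) are legitimate points on a continuous regression target. Percent
BMI loss, $100\,(b^0_j - b^1_j)/b^0_j$, is carried as a confirmatory
outcome; it is the standard relative reduction and matches the magnitudes
expected from the cohort's mean BMI trajectory (45.1 → 28.5 gives
36.8 %).

Genotypes are coded as effect-allele dosages $x_{ij}\in\{0,1,2\}$ and
weighted by published per-allele GWAS betas, $s_{ij} = x_{ij}\beta_i$.
After selection and direction-orientation (below), the score is

$$\mathrm{GRS}_j \;=\; s \sum_{i \in \mathcal{S}} x^{*}_{ij}\,|\beta_i|,$$

with $x^*$ the post-inversion coding and $s$ a display scale (default
100). The association model is ordinary least squares,

$$y_j = \alpha + \gamma\,\mathrm{GRS}_j + \delta_1\,\mathrm{age}_j +
\delta_2\,\mathbb{1}[\mathrm{male}_j] + \delta_3\,b^0_j +
\delta_4\,\mathbb{1}[\mathrm{distal}_j] + \varepsilon_j,$$

reported with unstandardised $\gamma$ (percent outcome per score unit),
its SE, p-value and $R^2$. A quartile analysis enters the empirical score
quartile as a 4-level factor in the same adjusted model and contrasts the
lowest quartile against each other quartile with equal-variance two-sample
t tests on the raw outcome, Benjamini–Hochberg adjusted across the three
contrasts at Q = 5 %; the covariate-adjusted factor-model contrasts are
reported alongside, since both post-hoc conventions are defensible and
they answer slightly different questions (marginal vs adjusted
difference).

## Variant selection by permutation importance

A regression random forest (10,000 trees by default; features per split
$\lceil p/3\rceil$, minimum leaf 5, full-n bootstrap) is grown with the
weighted scores as predictors and EBMIL as the target. Each variant's
importance is expressed as a relative percent increase in mean squared
error,

$$\mathrm{\%IncMSE}_i = 100\times\frac{\overline{\Delta \mathrm{MSE}}^{\mathrm{OOB}}_i}{\mathrm{MSE}^{\mathrm{OOB}}},$$

the mean over trees of the out-of-bag MSE increase after permuting
variant $i$ within the out-of-bag samples, divided by the forest's overall
out-of-bag MSE. Variants strictly above the 10 % cutoff enter the score;
"strictly" matters at the boundary and reflects reading the cutoff as
"above 10 %".

**Why the relative form, and what the scaled variant does.** Two
conventions circulate for regression-forest permutation importance: the
raw/relative form above, and the classic SE-scaled form (raw mean divided
by its standard error across trees), which is what `randomForest` — and
GUI front-ends wrapping it — print by default. We measured both under this
package's simulator. The SE-scaled variant at 10,000 trees produces values
in the 10–30 range for moderately strong variants, but it also exceeds 10
for *pure-noise* predictors under a complete null (the SE shrinks with
tree count while chance within-sample correlations persist), so a fixed
cutoff on it has no null calibration and its values are not comparable
across tree counts. The relative form is stable in expectation as trees
grow and stays well below 10 % under the null (measured max ≈ 7 % across
null replicates at n = 238, p = 23), which is what makes a fixed
threshold meaningful. The package therefore defaults to the relative form
and keeps the scaled one behind `forest_config(importance_type =
"scaled")` for comparability with legacy output.

A consequence worth stating plainly: under the relative form, a variant
only clears 10 % when it carries a substantial share of outcome variance.
With realistic per-allele effects (genetic $R^2\approx 0.1$ spread over
several variants at n = 238) *no* variant clears the cutoff, and the
bundled calibrated scenario honestly yields empty selections. Published
per-variant importances in the 10–25 range on cohorts of this size are,
in our measurements, only attainable with the scaled metric. Tests and
examples that need a non-empty selection therefore plant strong effects
(single variants carrying ≥ 20 % of variance), and the pipeline treats
"no variants selected" as a first-class, explicitly reported outcome.

**Direction check.** For each selected variant a preliminary univariate
regression of EBMIL on its weighted score is fitted. A positive slope
means the reported effect allele favours weight loss; the coding is then
inverted ($x \to 2-x$) and flagged, so that after orientation every risk
allele is the weight-loss-lowering allele and betas can enter the score
as magnitudes — "higher score, less expected weight loss" holds by
construction. The check is univariate (not covariate-adjusted) because it
precedes the adjusted model in the workflow; the recode is an involution
and a second pass is a no-op. Because both selection and orientation
condition on the outcome, the nominal level of the downstream test is a
property of the *fixed-score* analysis: the type-I simulations therefore
score the full fixed panel without selection or inversion (both would
bias the level by construction — inversion alone guarantees a
non-positive sample slope per variant).

## Quality control

Per variant: MAF (flag at ≤ 0.15, the panel inclusion criterion), a
1-degree-of-freedom chi-square goodness-of-fit against Hardy-Weinberg
proportions at the observed allele frequency (α = 0.05; adequate at
n ≈ 238 with MAF > 15 % since no expected cell is small; monomorphic
variants are flagged, not tested), and the missing-call rate (cap 0.05).
Per pair: composite LD as the squared Pearson correlation of dosage
vectors (no phase needed), cap r² = 0.2. The default policy is
warn-and-continue: the targeted cohort passed all checks, so a violation
in new data deserves inspection rather than silent removal. Allele
mismatches against the genotype source are hard errors — an automatic
strand flip would corrupt the direction of the score, which is the core
quantity. Missing genotypes are mean-imputed per variant for scoring
(keeping n fixed across stages); complete-case analysis is available by
pre-filtering.

## The synthetic cohort generator

`simulate_cohort()` draws genotypes i.i.d. per variant under
Hardy-Weinberg proportions at the effect-allele frequency, and builds

$$\mathrm{EBMIL}_j = \alpha + \textstyle\sum_i e_i x_{ij} +
\delta_a(\mathrm{age}_j-\bar a) + \delta_b(b^0_j-\bar b) +
\mathrm{offsets} + \mathcal N(0,\sigma^2),$$

with the intercept solved so the population mean equals the target. Final
BMI is back-computed by inverting the EBMIL formula around the sampled
initial BMI, so both outcome pipelines are exercised from one truth;
implausible draws (final BMI ≤ 0) error or resample by configuration.
Sex and surgery type are independent Bernoulli draws.

The default scenario (`default_scenario()`) encodes the marginals of the
cohort the method targets: n = 238, 74 % women, age 43.1 (SD 10.8) years,
initial BMI 45.1 (SD 6.2) kg/m², 73.5 % distal procedures, mean EBMIL
83.8 %. Covariate slopes are −0.23 %/year and −0.73 %/BMI-unit (the
reported clinical associations); per-allele effects of $-0.32 \cdot 100
\cdot \beta_i$ (BMI variants) and $-0.59 \cdot 100 \cdot \beta_i$ (WHR
variants) are planted on the ten variants the method is expected to
recover, making the true per-score-unit slopes −0.32 and −0.59. The
residual SD of 15.7 % was solved analytically so the total simulated
EBMIL SD is ≈ 17.8 %: genetic variance $\sum e_i^2\,2p_i(1-p_i) \approx
44$, covariate variance ≈ 27, and $15.7^2 \approx 17.8^2 - 44 - 27$.

What the generator does *not* emulate: linkage disequilibrium, dominance
or epistasis, population stratification, genotype-covariate dependence,
imputation dosages, and non-Gaussian residuals. Passing tests therefore
demonstrate correctness of the estimator under its own assumptions, not
robustness to those violations.

## Numerical and design choices

* **Quartile cut points** are the empirical type-7 quantiles; a sample
  exactly at a cut point goes to the *lower* quartile — deterministic for
  the heavily tied, integer-like scores a handful of variants produce. A
  quartile left empty by ties raises an error in direct calls and is
  caught and reported (not fatal) inside the orchestrated pipeline, since
  a one-variant score legitimately has too few levels.
* **Determinism.** One pipeline seed fans out to stages by name-salted
  derivation (`stage_seed()`), so adding a stage does not shift another
  stage's stream; forests are reproducible via `set.seed` before growth.
  Replicate seeds in the simulations are drawn from a seeded stream
  rather than taken as consecutive integers — consecutive seeds produce
  noticeably correlated generator states (we measured a type-I rate of
  0.060 with consecutive seeds against 0.051 with drawn seeds over 3,000
  null replicates).
* **Score scale.** Raw betas summed over a handful of variants give
  scores of order 1; the default display scale of 100 yields the
  integer-like ranges practitioners expect. The unscaled sum is always
  reported alongside, and slopes must be interpreted per chosen unit.
* **BH family.** The three Q1-vs-Qk contrasts per model form the
  adjustment family; `stats::p.adjust(method = "BH")` implements the
  step-up, verified in the tests against a brute-force oracle.
* **OLS.** `stats::lm` with explicit rank checking; a rank-deficient
  design (e.g. a constant score) errors naming the offending column
  rather than silently dropping it.
* **Confirmatory outcome.** Percent-BMI-loss models reuse the variants
  selected on EBMIL rather than re-running selection: the confirmatory
  question is whether the *same* score generalises across outcome
  definitions.
* **Sizes used in the shipped checks.** The test-suite simulations use
  238-subject cohorts (the design size), 200–1,000 replicates for
  operating characteristics, forests of 300–2,000 trees for structural
  checks and 1,000 for ranking checks; the full 10,000-tree default is
  exercised through the configuration surface. These sizes were chosen as
  the smallest that make the Monte-Carlo bounds sharp.

## A small demonstration

```{r demo}
snps <- data.frame(
  snp_id = c("rs571312", "rs3810291", "rs987237", "rs2241423"),
  maf = c(0.24, 0.28, 0.18, 0.22),
  effect = c(-10, -7, 8, 0),
  beta = c(0.23, 0.09, 0.13, 0.13),
  effect_allele = c("A", "A", "G", "G"),
  other_allele = c("C", "G", "A", "A"))
demo <- simulate_cohort(sim_scenario(n_samples = 238, snps = snps,
                                     noise_sd = 7, seed = 7))
w <- data.frame(snp_id = snps$snp_id, effect_allele = snps$effect_allele,
                other_allele = snps$other_allele, beta = snps$beta,
                trait = "BMI")
fit <- grs_fit(demo$dosages, demo$phenotypes, w,
               forest = forest_config(n_trees = 2000, seed = 7))
summary(fit)
```

The three causal variants are kept, the null one dropped, and the
beneficial allele re-oriented; the adjusted slope is negative and the
lowest-score quartile shows the largest excess-BMI loss.

## Known limitations

The bundled weight panels are synthetic reconstructions on the published
scale (real rsIDs and, where printed, the reported alleles) for testing
and demonstration — they must not be used to score real cohorts. The 10 %
cutoff is a convention, not an inferential threshold: it controls nothing
under the relative metric and is uncalibrated under the scaled one;
treating selection as exploratory and validating the resulting score on
independent data remains the defensible workflow. Multi-allelic sites,
reference-panel imputation and strand harmonisation are out of scope.
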
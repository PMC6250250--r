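---
title: "Methods: two-sample Mendelian randomization for platelet count and cardiovascular risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR for platelet count and cardiovascular risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plateletMR)
```

## The problem and the model

Observational associations between platelet count and cardiovascular disease
are vulnerable to confounding (platelet count responds to inflammation,
malignancy, iron status, ...) and to reverse causation. Mendelian
randomization (MR) sidesteps both by using genetic variants as instrumental
variables: alleles are fixed at conception, so a SNP that raises platelet
count can be read as a lifelong randomized nudge to the exposure. In the
two-sample design, the SNP-exposure associations (here: platelet count in SD
units, from a large population GWAS) and the SNP-outcome associations
(log odds ratios for coronary artery disease, myocardial infarction,
ischemic stroke and its subtypes, from disease consortia) come from separate,
non-overlapping samples.

For instrument \(j\) with exposure effect \(\beta_{Xj}\) (SE \(s_{Xj}\)) and
outcome effect \(\beta_{Yj}\) (SE \(s_{Yj}\)), the per-SNP causal estimate is
the Wald ratio

\[\hat\theta_j = \beta_{Yj} / \beta_{Xj},\]

in log-OR per SD of exposure. Its delta-method standard error is, at second
order,

\[ se(\hat\theta_j) = \sqrt{ s_{Yj}^2/\beta_{Xj}^2 +
   \beta_{Yj}^2 s_{Xj}^2 / \beta_{Xj}^4 }, \]

which acknowledges sampling error in the SNP-exposure estimate; the
first-order version \(s_{Yj}/|\beta_{Xj}|\) is available everywhere via
`seOrder = "first"`. Second order is the package default for Wald ratios,
IVW, Egger, median and mode, and every estimate records which order was used.

The main analysis pools the ratios by fixed-effect inverse-variance
weighting, \(w_j = se(\hat\theta_j)^{-2}\):

\[ \hat\theta_{IVW} = \frac{\sum_j w_j \hat\theta_j}{\sum_j w_j},
   \qquad se = \Big(\sum_j w_j\Big)^{-1/2}, \]

with normal-reference confidence intervals and p-values, reported as odds
ratios per SD-unit increase in genetically determined platelet count.
Instrument strength is summarized by \(F = R^2 (n-2)/(1-R^2)\), with
\(R^2 \approx 2\,\mathrm{eaf}(1-\mathrm{eaf})\beta_X^2\) on the standardized
exposure scale; \(F > 10\) is the conventional low-weak-instrument-bias
threshold.

## Harmonization

Both input tables are keyed on rsID (the design of the source panels; no
chromosome/position matching, no LD operations). Outcome effects are aligned
onto the exposure's effect allele: swapped alleles flip the outcome beta and
frequency, strand-complement codings are complemented first, and
irreconcilable allele pairs are dropped with an `allele_mismatch`
disposition. Palindromic SNPs (A/T, C/G) cannot be strand-resolved from
alleles alone; the default policy infers orientation by comparing allele
frequencies and drops the SNP as ambiguous when either frequency lies in
[0.42, 0.58] — a conservative community convention, adjustable via
`palindromePolicy`/`ambiguityWindow`. Duplicated rsIDs within a file keep the
row with the smallest p-value. Every disposition is counted in the returned
provenance so that kept plus dropped always equals the rsID intersection, and
all of it lands in the run manifest written by `writeStudyReport()`.

## The sensitivity battery

Pleiotropy — a variant affecting the outcome other than through platelet
count — is the central threat. The package implements the full battery used
in this study design:

* **Cochran Q / I²MR** (`cochranQ`): heterogeneity of the per-SNP ratios
  around the pooled estimate. Excessive heterogeneity is flagged when
  I²MR > 25% *and* the Q-derived p < 0.05 (both conditions, per the study's
  definition).
* **Exclusion-sensitivity IVW** (`applyExclusions` + `mrIVW`): re-estimation
  after removing a user-supplied list of SNPs with known secondary
  associations (the stand-in for a PhenoScanner screen, which is out of
  scope as a web service).
* **MR-Egger** (`mrEgger`): weighted regression of (oriented) outcome effects
  on exposure effects with a free intercept; the slope is the
  pleiotropy-adjusted estimate under the InSIDE assumption and the intercept
  estimates directional pleiotropy (no evidence when p >= 0.05). Inference
  uses a t reference on J-2 df with standard errors inflated by
  \(\max(1, \sqrt{Q'/(J-2)})\) — the multiplicative random-effects
  convention; whether the source analyses used t or normal quantiles is not
  stated, and the choice is recorded in each estimate's metadata. The
  regression weights are the Wald-ratio weights divided by \(\beta_{Xj}^2\),
  which reduces to the classic \(1/s_{Yj}^2\) weighting at first order and
  guarantees that constraining the intercept to zero reproduces the IVW
  estimate exactly (a property the tests assert).
* **Rucker model selection** (`ruckerModelSelection`): Q' is the Egger
  residual heterogeneity under the same weights, so Q >= Q' always; Q - Q'
  against chi-square(1) decides whether the intercept buys a significantly
  better fit.
* **I²GX** (`i2GX`): heterogeneity of the oriented SNP-exposure effects
  relative to their standard errors; > 95% indicates low risk of
  measurement-error (NOME-violation) bias in MR-Egger.
* **MR-PRESSO** (`mrPresso`): each SNP's residual from the leave-one-out
  zero-intercept fit, \(RSS_j = w_j(\beta_{Yj} - \hat\theta_{(-j)}
  \beta_{Xj})^2\), summed into a global statistic whose null distribution is
  simulated parametrically (default 1000 replicates); per-SNP outlier
  p-values are empirical tail probabilities Bonferroni-multiplied by J, and a
  distortion test compares the outlier-corrected shift against removal of
  random subsets of the same size, drawn without replacement. Empirical
  p-values use the add-one rule, so they are never zero and the global p is
  bounded below by 1/(nSim+1).
* **Weighted median** (`mrWeightedMedian`): the ratio at standardized
  cumulative weight 0.5 (linear interpolation between order statistics, which
  also resolves ties); consistent when valid instruments carry > 50% of the
  weight. CIs come from a parametric bootstrap (default 1000 replicates; each
  replicate redraws every ratio from \(N(\hat\theta_j, se_j)\)), reproducible
  given the recorded seed.
* **Weighted mode** (`mrWeightedMode`): the maximizer of a weighted
  normal-kernel density of the ratios — the estimate supported by the largest
  cluster of concordant SNPs. Bandwidth follows the normal-reference rule
  \(h = \phi\, 0.9 \min(sd, mad)\, J^{-1/5}\) (mad with the 1.4826
  consistency constant; \(\phi\) defaults to 1), evaluated on a 512-point
  grid spanning the ratio range padded by 3h. Degenerate inputs (all ratios
  equal) return that value directly.

### Why MR-PRESSO weights differ from the other estimators

One design point deserves explanation. The second-order Wald weight contains
the observed outcome effect in its denominator
(\(\beta_{Yj}^2 s_{Xj}^2/\beta_{Xj}^4\)). Inside MR-PRESSO that is
self-defeating: a strongly pleiotropic SNP inflates its own \(\beta_{Yj}\),
deflates its weight, and thereby shrinks exactly the residual the test needs
to see. In simulation this cut detection of a planted 10-SE outlier from
near-certainty to roughly 70%. `mrPresso` therefore defaults to first-order
(outcome-variance) weights — the original residual-sum formulation — while
the pooled estimators keep the second-order default; `seOrder = "second"`
remains available on `mrPresso` for comparison.

## The study runner and significance tiers

`runStudy()` drives the whole design from a declarative config (R or YAML):
one exposure, any number of outcomes each tagged `primary` or `secondary`,
an optional exclusion list, and the seven-method battery
(IVW, exclusion-sensitivity IVW, MR-Egger, MR-PRESSO raw and
outlier-corrected, weighted median, weighted mode). Primary outcomes are
tested at alpha = 0.025 — a Bonferroni correction of 0.05 across the two
primary outcomes — and secondary outcomes at 0.05; sensitivity analyses are
never multiplicity-corrected beyond their tier, since they exist to
replicate, not to discover. Methods whose preconditions fail (e.g. PRESSO
correction when no outliers are found) keep their row in the report with an
explicit skip reason, so the forest table always has the full
outcome-by-method layout. A failing outcome is recorded and the remaining
outcomes still run. Reports carry no timestamps, and all bootstrap/simulation
seeds are derived from the config's master seed, so a fixed config reproduces
the report byte for byte.

## The synthetic-data generator

There is no public per-SNP supplement bundled here, so testing rests on a
generator (`simulateTwoSample`) that emulates the study's data-generating
process with known truth:

* Panel defaults mirror the study: 219 candidate SNPs, exposure GWAS of
  166,066, outcome GWAS of 60,341 cases / 454,450 controls, minor allele
  frequencies uniform on [0.01, 0.5], genome-wide selection at p < 5e-8.
* True instrument effects \(b_j\) are half-normal — oriented so the effect
  allele increases the exposure, the convention of published instrument
  tables — and rescaled so the panel explains exactly `h2Instruments` of
  exposure variance. The default 0.15 was chosen a priori so realized F
  statistics span roughly 30-2000, the order-of-magnitude envelope of the
  published panel (37-1526); the orientation also means a nonzero mean
  pleiotropic effect is genuinely directional on the ratio scale.
* Standard errors use the standard large-sample approximations
  \(s_X = (2\,\mathrm{maf}(1-\mathrm{maf})\,n_X)^{-1/2}\) and, for a binary
  outcome, \(s_Y = \sqrt{(1/n_{cases} + 1/n_{controls}) /
  (2\,\mathrm{maf}(1-\mathrm{maf}))}\).
* The default causal effect is 0.07 log-OR per SD, the scale of the study's
  ischemic-stroke signal.
* Selection is applied to an *independent* discovery replicate of the
  exposure effects, so the estimation sample is free of winner's curse, as a
  two-sample design should be. Disabling the threshold (`gwThreshold = NULL`)
  retains the full candidate panel, including genuinely weak instruments.
* Pleiotropy is controlled by \(\pi\) (fraction of invalid SNPs) and
  \(\alpha_j \sim N(\mu_\alpha, \sigma_\alpha)\) (balanced when
  \(\mu_\alpha = 0\), directional otherwise; `insideViolation` correlates
  \(\mu_\alpha\) with instrument strength). Planted outliers add
  `outlierOffset` *outcome standard errors* to \(\alpha_j\), so "an outlier
  at 10x its SE" is expressed directly.

What the generator does **not** emulate: linkage disequilibrium between
instruments, population stratification, sample overlap between the two GWAS,
allele-frequency differences between populations, and case-control
ascertainment subtleties beyond the standard SE approximation. Passing
recovery tests therefore demonstrate correctness of the estimators under the
two-sample summary-statistics model, not robustness to those real-data
complications.

## Calibration studies and problem sizes

The test suite and `scripts/acceptance.R` recompute, from scratch:

* exact agreement of IVW, Egger, Q, Q', I²GX, weighted median and weighted
  mode with independent brute-force oracles on small hand instances;
* IVW mean bias and 95% CI coverage over 500 full 219-SNP panels at
  \(\theta = 0.07\) (selection disabled there because the scenario fixes
  J = 219);
* type-I error of the Egger intercept test and the PRESSO global test over
  500 null panels under the generator defaults. With selection on, both hold
  their nominal 5% size within binomial tolerance. (With selection *disabled*
  the Egger intercept test turns conservative, ~1-2%: near-zero-\(\beta_X\)
  SNPs enter with second-order weights that shrink exactly when the residual
  is large. The published panel contains no such SNPs.);
* the robustness ordering — weighted median error below IVW error — over 200
  panels with 30% invalid instruments under directional pleiotropy
  (\(\mu_\alpha = 0.02\), \(\sigma_\alpha = 0.02\), chosen once as a
  realistic per-SNP direct effect of a few hundredths of a log-OR);
* PRESSO detection of a single planted 10-SE outlier over 200 seeded runs.
  These use 50-SNP candidate panels (`h2Instruments` scaled to 0.035 to keep
  per-SNP strength realistic): with the add-one rule the smallest achievable
  Bonferroni-adjusted outlier p is \(J/(n_{sim}+1)\), so at
  \(n_{sim} = 1000\) detection at the 0.05 threshold is only possible for
  panels of about 50 instruments or fewer — at the full 219-SNP panel the
  floor is 0.22 and the per-SNP test cannot fire at that threshold, which is
  a property of the convention, not a bug;
* a deterministic six-outcome study (two primary, four secondary) reproducing
  the seven-method forest layout.

## A worked example

```{r example}
sim <- simulateTwoSample(simConfig(seed = 11))
x <- harmonize(sim$exposure, sim$outcome)
x
mrIVW(x)
mrEgger(x)
cochranQ(x)
i2GX(x)
```

## Known limitations

Multivariable MR is deliberately out of scope (it is problematic for
overlapping hematologic traits), as are random-effects IVW, SIMEX-corrected
Egger, Steiger directionality filtering, LD-aware instrument selection, and
any remote database queries. The Egger CI convention (t reference,
multiplicative overdispersion floored at 1) and the IVW normal reference are
package choices where the source analyses are silent; both are recorded in
the estimates' metadata so results remain auditable.
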
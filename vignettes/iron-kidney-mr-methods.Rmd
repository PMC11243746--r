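---
title: "Methods: two-sample MR of systemic iron status on kidney disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR of systemic iron status on kidney disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ironmr)
```

## The question and the design

Systemic iron status cannot be randomized, and observational associations
between iron biomarkers and kidney disease are confounded by inflammation,
diet and disease itself.  Two-sample Mendelian randomization sidesteps this
by using genetic variants as instruments: variants associated with iron
status are (to a good approximation) randomized at conception, so the
ratio of their outcome association to their exposure association estimates
a causal effect — provided the variants affect the outcome only through
the exposure.

`ironmr` implements this design for systemic iron status measured by four
correlated biomarkers — serum iron, ferritin, transferrin saturation
(TfSat) and total iron-binding capacity (TIBC) — against binary
kidney-disease outcomes (IgA nephropathy, acute and chronic kidney
disease).  TIBC rises when iron status falls; throughout the package it
carries a direction sign of $-1$ so that "direction-consistent" means
consistent on the iron-status axis.

All estimates are log-odds of disease per SD increase in the genetically
predicted biomarker; odds ratios are `exp(beta)` with exponentiated 95%
intervals (normal multiplier 1.96 throughout — the summary-data MR
convention at moderate instrument counts, rather than a t reference).

## Instrument selection

Candidate SNVs pass a chain of filters, each with a tunable threshold:

* **Association**: genome-wide significance, `p_threshold = 5e-8`.
  Three nested strategies: (1) significant in *all four* biomarkers with
  direction-consistent effects; (2) significant in at least one and
  direction-consistent in all four; (3) significant in at least one.
  Strategy 1 demands direction consistency so the three strategies are
  nested — an SNV significant everywhere but sign-discordant (e.g. a
  variant raising both ferritin and TIBC) does not measure *overall*
  iron status and is excluded from the strictest set.
* **Proxies**: SNVs absent from the outcome GWAS are replaced by the
  available SNV with the highest LD, requiring `r2 >= 0.8`; ties break
  by smaller base position then rsID, for determinism.
* **MHC**: chr6:28,477,797–33,448,354 (GRCh37, inclusive ends) is
  excluded wholesale; its long-range LD defeats clumping.
* **Confounders/outcome**: SNVs annotated to a confounder trait, or
  associated with the outcome itself, at `p < 5e-8` are removed (the
  annotation table is an offline stand-in for a PhenoScanner query).
* **Clumping**: greedy, `r2 < 0.01`: candidates sorted by ascending
  p-value (the *minimum* across the four biomarker GWAS, since an
  instrument must serve all four; ties by position then rsID) and
  accepted only if independent of everything already accepted.

Instrument strength is summarized per SNV by
$F = \frac{R^2/k}{(1-R^2)/(n-k-1)}$ with $k = 1$ and
$R^2 = 2f(1-f)\beta^2$ for a standardized trait ($f$ the effect-allele
frequency), falling back to $z^2/(z^2+n-2)$ when $f$ is missing;
$F < 10$ flags a weak instrument.  Study power uses the design-based
normal approximation
$\Phi\!\big(\sqrt{n\,R^2\,cf(1-cf)}\,|\ln OR| - z_{1-\alpha/2}\big)$
for a case–control outcome with case fraction $cf$.

## Harmonization

Effect alleles are aligned to the first exposure table's orientation.
Non-palindromic records reconcile by allele swap and/or strand
complementation; palindromic SNVs (A/T, G/C) are aligned by the
minor-allele side of the effect-allele frequencies and dropped when the
frequency is missing or uninformative (`palindrome_maf_cut = 0.42`: a
MAF at or above 0.42 on either side leaves the strand ambiguous).
Harmonization is an accounting-complete map: every requested rsID lands
either in the harmonized set or in the drop report with a reason, and
the result is invariant to each input table's allele coding.

## Univariable estimators

With harmonized per-SNV effects $(\hat\beta_{Xj}, \hat\beta_{Yj})$ and
SEs, the Wald ratio is $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$
with first-order SE $se_{Yj}/|\hat\beta_{Xj}|$ (a second-order option
propagates the exposure SE; the first-order form is the default, and its
neglect of exposure noise is visible as mildly anti-conservative
coverage in the calibration tests — 93–95% rather than exactly 95%).

* **IVW**: the precision-weighted mean of the ratios, identical to
  weighted least squares of $\hat\beta_Y$ on $\hat\beta_X$ through the
  origin.  The multiplicative random-effect variant inflates the SE by
  $\max\{1, \sqrt{Q/(J-1)}\}$ — never below the fixed-effect SE.
* **Medians**: simple (equal weights), weighted (50th percentile of the
  weight-standardized CDF over sorted ratios, linear interpolation
  between midpoints), and penalized weighted (weights multiplied by
  $\min\{1, 20\,p_j\}$ with $p_j$ the $\chi^2_1$ tail of the SNV's
  heterogeneity contribution about the weighted-median estimate — the
  canonical penalization constant 20, exposed as an argument).  Median
  SEs come from a seeded parametric bootstrap (ratios resampled from
  $N(\hat\theta_j, se_j^2)$, 1,000 replicates by default).
* **MR-Egger**: weighted regression with a free intercept after
  re-coding alleles so every $\hat\beta_X > 0$ (Egger is not
  orientation-invariant; this is the convention used).  The intercept
  and its p-value index directional pleiotropy; coefficient SEs are
  floored at the fixed-effect level by $\max(1, \hat\sigma)$ scaling.

Heterogeneity is Cochran's $Q = \sum_j w_j(\hat\theta_j - \hat\theta)^2$
with $J-1$ df about the IVW centre ($J-2$ for Egger).  Multiplicity over
the 4-exposure × 3-outcome grid uses the Bonferroni threshold
$0.05/12 \approx 0.0042$; p-values between the threshold and 0.05 are
labelled "suggestive".

## The mixture-model estimator

To tolerate invalid instruments, the residuals
$\hat\beta_{Yj} - \theta\hat\beta_{Xj}$ at a candidate $\theta$ are
modelled as a zero-mean two-component normal mixture: a valid component
with variance $s_j^2 = se_{Yj}^2 + \theta^2 se_{Xj}^2$ (mixing weight
$\pi_0$) and an invalid component with variance $s_j^2 + \sigma^2$.
Effects are first rescaled to the standardized scale by
$\sqrt{2f(1-f)}$ (or $z/\sqrt{n}$ without frequencies).  $(\pi_0,
\sigma^2)$ are fitted by EM — the $\sigma^2$ update has no closed form
with per-SNV base variances, so a one-dimensional search inside a
generalized EM keeps the likelihood monotone — and $\hat\theta$ is the
grid value maximizing the fitted $\pi_0$, profiled over
$[-0.5, 0.5]$ at step 0.01 and refined at 0.001 around the coarse
argmax (three decimals, matching how such estimates are reported).

Two numerical facts shape the implementation.  First, when the data are
homogeneous the likelihood has a ridge at $\sigma^2 = 0$ on which
$\pi_0$ is unidentifiable, and EM can drift to an interior pseudo-optimum
that merely fits sampling kurtosis; the fit therefore always includes
the degenerate all-valid candidate $(\pi_0 = 0.999, \sigma^2 = 0)$ and
abandons it only for a material likelihood gain (a BIC-style margin of
$\log J$ for the mixture's two extra parameters).  Second, the
$\pi_0$-profile is flat across every $\theta$ the data cannot
distinguish from homogeneous, so candidates within that plateau are
ranked by profile log-likelihood — which on the ridge is exactly the
all-valid model's likelihood, smooth and maximized near the true effect
— before the final smaller-$|\theta|$ tie-break.  Without this, the
tie-break alone would drag $\hat\theta$ to the near edge of the plateau
and systematically toward zero.

Only the point triple $(\theta, \pi_0, \sigma^2)$ is reported; no
asymptotic SE is attached.

## Multivariable MR by Bayesian model averaging

With four collinear biomarkers, which one *drives* risk is a variable
selection problem.  All $2^4$ subsets of biomarkers are scored: on the
precision scale ($\tilde y_j = \hat\beta_{Yj}/se_{Yj}$, columns
$\tilde X$ likewise weighted and scaled to unit norm), each model has
the closed-form Gaussian marginal likelihood of
$\tilde y \sim N(0,\, I + \sigma_p^2 \tilde X_\lambda
\tilde X_\lambda^{\top})$ under a zero-centred normal prior
(`prior_sd = 0.25`) on standardized coefficients, and prior mass
`prior_incl^{|\lambda|}(1-prior_incl)^{4-|\lambda|}`
(`prior_incl = 0.5`).  The defaults are deliberately weak and exposed
as arguments — with only four factors a sensitivity sweep is cheap.
The empty model is part of the enumeration so posterior probabilities
form a proper distribution; reporting filters it out of the "best
models" table.  Per factor we report the marginal inclusion probability
(MIP, the summed posterior probability of models containing it) and the
model-averaged causal estimate $\theta_{MACE}$, with per-model
conditional estimates back-transformed to the per-SD exposure scale.

Instrument outliers are diagnosed on the highest-posterior non-empty
model: heterogeneity contribution $q_j = w_j(\hat\beta_{Yj} -
\hat y_j)^2 > 10$, or Cook's distance above the median of the
$F(|\lambda|, J - |\lambda|)$ distribution, flags removal; the model
space is refitted once without the flagged instruments (a single pass —
iterating the rule risks eating the instrument set).

## The synthetic-study generator

`simulate_study()` emulates the assumed data-generating structure so
every stage runs without cohort access: per SNV a minor-allele
frequency on `maf_range`, a latent iron-status effect
$\gamma \sim N(0, sd_{latent}^2)$ shared by the four biomarkers through
loadings $(+1, +1, +1, -1)$, biomarker-specific deviations
$N(0, sd_{specific}^2)$ (without which the exposures are perfectly
collinear and multivariable MR is unidentifiable), and a case–control
outcome whose true log-odds effect is $\theta\gamma$ — or
$\sum_k \theta_k \beta_{Xk}$ when `theta` is a length-4 vector, the
configuration used to plant a single causal biomarker.  Observed
effects add noise with the analytic SEs $(2f(1-f)n)^{-1/2}$
(continuous) and $(2f(1-f)\,n\,cf(1-cf))^{-1/2}$ (case–control); LD is
block-diagonal with AR(1)-squared decay, hence positive semidefinite; a
configurable fraction of SNVs gets direct (pleiotropic) outcome
effects; and an annotation table plants confounder-associated SNVs.

Default cohort sizes are the study conditions scaled down tenfold
(serum iron 16,351; ferritin 24,614; TfSat 13,147; TIBC 13,543; outcome
65,314 at case fraction 0.024), with `sd_latent = 0.05` chosen so that
a realistic minority of SNVs reaches genome-wide significance at those
sizes.  One seed drives every draw; identical seeds give byte-identical
tables.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: sample overlap between exposure and
outcome GWAS, cross-ancestry heterogeneity in the pooled outcome
(emulated as a single pooled GWAS), allele-frequency–dependent effect
architectures, INDELs, and winner's-curse distortion of externally
selected instruments.

## Problem sizes and numerical choices in the tests

The suite exercises recovery and calibration at reduced but informative
sizes: IVW recovery averages 500 replicates of 50 valid instruments
(exposure n = 100,000, outcome n = 50,000, case fraction 0.1,
$\theta = 0.1$); type-I error and 95% CI coverage use 1,000 replicates
of 6 instruments at the full emulated cohort sizes; the mixture-model
recovery uses one all-valid study of 50 strong instruments
($\theta = 0.2$); model-averaging identification uses 200 replicates
with only ferritin causal.  Calibration checks use the fixed-effect
IVW: under a homogeneous null the multiplicative random-effect SE is
floored and therefore deliberately conservative.  EM tolerances are
`tol = 1e-8` with a 200-iteration cap during the coarse grid sweep
(warm-started along the grid) and the full budget at refinement.

## Known limitations

* Wald-ratio SEs are first-order by default; with weak instruments the
  second-order option should be preferred.
* The mixture model reports point estimates only, and its grid bounds
  $|\theta| \le 0.5$ — effects outside that range need a wider grid.
* Model-averaging results depend on the shrinkage prior when
  instruments are few; the priors are arguments precisely so that
  sensitivity is easy to check.
* The outlier rule's $Q > 10$ cut is an absolute convention, not
  sample-size adaptive.
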
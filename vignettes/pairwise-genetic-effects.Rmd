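---
title: "Detecting pairwise genetic effects: models, decision rules, and what the simulations show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pairwise genetic effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairscan)
```

## The question

Complex traits such as blood lipid levels are shaped by many genes at once.
For a pair of genes, two qualitatively different joint behaviours matter:

* **additive effects (AE)** — the joint effect equals the sum of the two
  individual effects; each gene contributes independently;
* **genetic interactions (GI, epistasis)** — the joint effect deviates from
  that sum, either amplifying it (negative/aggravating, synergy) or damping
  it (positive: alleviating or suppressive).

pairscan implements one statistical framework for both a population-cohort
arm (rare truncating-variant burden, common-SNP dosages, polygenic scores
against quantitative lipid traits and a binary disease trait) and a
cell-based combinatorial-knockdown screen arm (robust Z-scores of reporter
uptake). Both arms share the same core: a nested battery of regression
models, Schwarz information criterion (BIC) model selection, normal-theory
p-values, and design-wide Benjamini–Hochberg false-discovery-rate families.

## The model battery

For a response $y$ and two predictors $x_A$, $x_B$ the full model is

$$y = \beta_0 + \beta_A x_A + \beta_B x_B + \beta_{AB}\, x_A x_B + \varepsilon .$$

The battery fits the nested sub-models M1 ($x_A$ only), M2 ($x_B$ only),
M3 ($x_A + x_B$, the additive model) and M4 (the full interaction model);
the screen arm adds M0 (intercept only, the no-effect model). $\beta_{AB}$
is the **Interaction Value**: the difference between the observed joint
effect and the additive expectation,
$\beta_{AB} = y_{AB} - \beta_0 - \beta_A - \beta_B$ in the balanced case.

Quantitative traits are first residualized against covariates (age, sex,
smoking, alcohol, BMI, lipid medication, ten genotype principal components)
by ordinary least squares; the genetic models then see only the residuals.
The binary disease trait is not residualized — the covariates enter the
logistic models directly, because a linear residualization has no meaning
on the probability scale.

### Robust fitting

Lipid measurements are long-tailed, so the Gaussian-family models are fitted
by Huber M-estimation via iteratively reweighted least squares
(`huber_irls_fit()`). Choices that matter:

* tuning constant 1.345 (in robust-scale units): the conventional value
  giving 95% efficiency under Gaussian errors;
* scale = 1.4826 × median absolute residual, re-estimated during the first
  iterations and then frozen; at fixed scale the Huber objective is convex
  and IRLS converges monotonically, which avoids the small-sample limit
  cycles that scale re-estimation can induce. A floor of 1e-10 keeps
  noiseless (saturated) fits finite;
* convergence when the largest coefficient change drops below 1e-8, with a
  50-iteration cap; hitting the cap returns the last iterate flagged
  unconverged, and unconverged fits never enter model selection;
* standard errors from the weighted least-squares covariance at the
  optimum, which reduces exactly to the OLS covariance when no observation
  is downweighted;
* rank-deficient designs mark the aliased terms inestimable instead of
  failing — a collinear interaction column is a statement about the data
  (the pair is untestable), not an error.

t-statistics are converted to p-values with the normal rule
$p = 2 - 2\Phi(|t|)$ (`pval_from_t()`); the logistic fits use Wald z in the
same rule.

### The pseudo-BIC for robust fits

BIC needs a likelihood, and Huber regression does not come with a canonical
one. `model_bic()` evaluates the Gaussian profile criterion at the robust
coefficient estimates,

$$\mathrm{BIC} = n \log \hat\sigma^2 + (k + 1)\log n,$$

with $\hat\sigma^2$ the plain mean squared residual and the $+1$ charging
the estimated scale. When nothing is downweighted this is exactly the
textbook Gaussian BIC, which the tests verify against an independently
coded formula. An alternative with $\hat\sigma^2 = \sum w r^2 / \sum w$
(Huber-weighted) is available via `model_bic(variance = "huber-weighted")`
but is not the default: its weights re-adapt to each model's residuals,
which behaves like extra free parameters at screen-sized samples
(~32 observations) and measurably over-selects the interaction model — in
our simulations it picked M4 for roughly one in five purely additive pairs,
versus about one in twenty for the default. Exact BIC ties are broken
toward the model with fewer coefficients so selection is deterministic.

### Decision rules

Per (pair, trait) unit, three p-values (both single terms and the
interaction) are pooled into **one BH family per design** — never across
designs — and adjusted together (`bh_fdr()`). Inestimable p-values stay
missing and do not count toward the family size. The two-step rule then is:

* **GI** if the adjusted interaction p < 0.005 *and* M4 is BIC-best;
* **AE** if the adjusted interaction p > 0.01 (or the pair is untestable),
  both adjusted single-term p < 0.005, *and* M3 is BIC-best;
* **none** otherwise. Units whose adjusted interaction p falls in
  [0.005, 0.01] can satisfy neither branch: the band is a deliberate buffer
  between the two calls.

Single-term p-values are read from the BIC-selected full model (M4 when it
wins, otherwise M3); the interaction p can only come from M4. A pair is
*testable* when at least `min_joint` samples are exposed to both predictors
(default 1 — double carriers of rare truncating variants are scarce enough
that even single observations are informative) and the product column is
not collinear with the main effects.

Screen evidence is additionally graded by the BIC gap between the best and
second-best model: a gap above 2 is reported as `"strong"`, below as
`"ambiguous"` (two models remain plausible alternatives).

## The screen arm

Per-image summaries (mean per-cell reporter intensity) are first
QC-filtered on cell count (default ≥ 20), image sharpness (above the 5th
percentile of the array's negative controls) and background (below the 95th
control percentile); the thresholds are configurable because the criteria,
not the cutoffs, are the invariant. Per treatment and biological replicate,
image values are averaged and scored against the array's negative controls:

$$z = \frac{I_{\text{treated}} - \mathrm{median}(I_{\text{controls}})}{\mathrm{mad}(I_{\text{controls}})}.$$

The MAD is scaled by 1.4826 by default so z is in Gaussian-SD-equivalent
units; a raw-MAD mode ships too since either convention is defensible.
Control replicates receive z-scores as well and anchor the intercept of the
five-model battery near zero.

### GI taxonomy

Significant interactions are labelled by comparing the joint phenotype
$J = \beta_0+\beta_A+\beta_B+\beta_{AB}$ with the additive expectation
$E = \beta_0+\beta_A+\beta_B$ and the most severe single effect $M$,
with severity $s(x) = x\,\mathrm{sign}(M)$ and tolerance $\tau$ (default:
the standard error of the joint-cell mean):

* `negative-aggravating`: $s(J) > \max(s(E), s(M)) + \tau$;
* `positive-suppressive`: $s(J) < s(M) - \tau$;
* `positive-alleviating`: otherwise — the joint effect sits at (or is
  partially masked toward) the most severe single phenotype;
* `emergent`: both singles within $\tau$ of zero, reported separately.

Two design notes. First, the three-way rule as usually stated verbally
leaves a gap between "approximately equal to the most severe single" and
"beyond the additive expectation"; we assign that band to *alleviating* so
the taxonomy partitions every significant pair and is invariant under
swapping gene labels. Second, *alleviating* is intrinsically a boundary
class — it asserts the joint effect equals the severe single — so its
recovery from noisy data is sensitive to $\tau$; plantings on that boundary
are recovered as alleviating or suppressive with comparable frequency, and
reports always record the $\tau$ used.

A primary GI call is **validated** when the pair's adjusted interaction p
in an independent validation screen is below 0.01 and its Interaction Value
has the same sign as in the primary screen.

## The synthetic generators

`simulate_cohort()` emulates the statistical structure the cohort analyses
assume: rare carriers (Bernoulli per gene, default carrier frequency 1e-2,
with a within-gene variant series whose first variant dominates — the lever
for conditioning analyses), common dosages (Binomial(2, MAF), default MAF
0.2), covariates (age ~ U(40, 69), BMI ~ N(27, 4), binary covariates
Bernoulli, PCs standard normal), traits in mg/dl (LDLc location 138.3, the
non-carrier reference mean; noise SDs 33/14/80/40 for LDLc/HDLc/TG/TC) and
a logistic disease trait (8% baseline prevalence). Planted effects are
specified in trait-SD units so planted and recovered sizes share a scale.
Covariate distributions are deliberately unremarkable: residualization
removes them, so they cannot drive correctness.

`simulate_screen()` draws log-normal control intensities (fluorescence is
positive and right-skewed) and adds planted effects on the intensity scale
in units of the control scaled MAD, so planted and recovered robust-Z
effects share units *exactly* and the additive-closure property
($\beta_{AB} \to 0$ when nothing is planted) holds without bias. Defaults:
8 biological replicates (the emulated screen used at least 7), 4 images per
replicate — giving per-replicate z noise near 0.5 — 8 negative-control
spots per array design, 14% planted image-QC failures (zero cells, blur, or
high background).

What the generators do **not** emulate: linkage disequilibrium and
haplotype structure, genotype uncertainty, trait measurement batch effects,
spatial plate effects, cell-segmentation errors, or siRNA off-target
activity. Passing tests therefore demonstrate that the statistical
machinery recovers the truth *under the stated generative model*, not that
real-data confounders are handled.

## Calibration and problem sizes

The test suite checks, among others:

* IRLS ≡ closed-form OLS (coefficients and SEs to 1e-8) whenever no point
  is downweighted, and BH-FDR ≡ a brute-force step-up implementation on all
  families of size ≤ 8 over a p-grid;
* type-I control: across 500 null two-predictor scans at n = 5000, and 200
  null screens of a 6-gene panel at 8 replicates, the GI call rate stays
  within Monte-Carlo margin of the 0.005 working level;
* recovery: planted effects of 0.3 trait-SD on MAF-0.2 dosages at n = 5000
  (and z-effects of 2 at 8 replicates, noise 0.5) are recovered within 3
  reported SE in ≥ 95% of 200 seeds, with BIC choosing the additive model
  for additive truths and the interaction model for interaction truths in
  ≥ 90%;
* determinism: identical configuration and seed reproduce scan tables
  byte-identically.

These sizes (n = 5000 cohorts, 4–10-gene screen panels) are the package's
reference desk scale: large enough that the asymptotic calibration of the
decision rules is visible, small enough that the full suite re-runs in
minutes. The same code paths run unchanged at biobank scale.

## Known limitations

* The pseudo-BIC is one defensible likelihood surrogate for robust fits,
  not the only one; conclusions that hinge on razor-thin BIC margins
  (gap < 2) should be treated as "two models plausible".
* Fitted standard errors assume homoskedastic replicate noise; in the
  screen pipeline the double-knockdown cell is measured with fewer images
  than the controls, so its SE is mildly optimistic (the recovery tests
  quantify this).
* The alleviating/suppressive boundary is $\tau$-dependent, as discussed.
* FDR families follow the design definitions exactly; changing the panel
  changes the family and hence every adjusted p-value.
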
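---
title: "Distant and local amyloid effects on brain metabolism and cognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distant and local amyloid effects on brain metabolism and cognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Regional amyloid-beta (Abeta) burden and regional glucose hypometabolism
are both hallmarks of Alzheimer's disease, yet they famously fail to
overlap: regions with heavy Abeta load often metabolise normally, and
hypometabolic regions can be nearly Abeta-free. One resolution is that
Abeta acts *at a distance*: aggregates in one node of a functionally
coupled network (most prominently the default mode network, DMN) depress
metabolism in remote, connected nodes, while the *local* coincidence of
Abeta and an already-vulnerable (hypometabolic) environment is what drives
subsequent cognitive decline.

`amynet` implements the analysis machinery needed to test this two-step
model on multimodal PET data — an Abeta tracer image, an FDG image, and a
gray-matter density map per subject, plus longitudinal cognitive scores —
and a synthetic cohort generator that emulates the statistical structure
such data would carry, so every stage is testable without any patient
data.

## The analysis layers

### Per-voxel general linear models

`fit_voxelwise()` fits, independently at every in-mask voxel $v$,

$$ y_{iv} = \beta_0 + \sum_k \beta_k x^{(k)}_{iv} + \sum_m \gamma_m z^{(m)}_i
   + \varepsilon_{iv}, $$

where the $x^{(k)}_{iv}$ are voxel-level image predictors (e.g. the
subject's Abeta value at $v$), the $z^{(m)}_i$ are scalar predictors
(a global Abeta composite, demographic covariates), and products of voxel
terms can be added for interaction models. The canonical
Abeta-metabolism model (`abeta_metabolism_spec()`) regresses voxel FDG on
voxel Abeta *and* the global Abeta composite simultaneously, adjusted for
age, sex, education, APOE e4 carriage, p-tau and voxel gray-matter
density, so that the distant (global) and local contributions are
separated within one fit. Voxels with rank-deficient designs or constant
outcomes are marked not-evaluated, never silently zero.

The model of cognitive decline (`fit_interaction_model()`) uses each
subject's cognitive slope as the outcome and, at each voxel,

$$ \Delta\mathrm{score}_i = \beta_0 + \beta_1 A_{iv} + \beta_2 G_{iv}
   + \beta_3\, A_{iv} G_{iv} + \text{covariates} + \varepsilon_i, $$

with $A$ the Abeta and $G$ the FDG value; $\beta_3$ captures the
local synergy between Abeta and hypometabolism. Covariates include the
global Abeta composite and the follow-up duration.

### Family-wise error control

Maps are corrected with max-|t| permutation (`fwer_correct()`): the same
subject permutation is applied at every voxel, the full model is refit,
and the map-wide maximum |t| forms the null distribution; corrected
p-values are $(1 + \#\{b : \max|t|_b \ge |t_v|\})/(B+1)$. Three schemes
govern what a permutation shuffles. The default permutes the raw outcome
rows, which is *exactly* level-$\alpha$ conditional on the design
whenever the outcome is independent of every predictor — the global null
that the package's error-rate calibration targets — and remains accurate
for moderate nuisance effects. Freedman–Lane (permuting the
nuisance-residualised outcome) and Huh–Jhun (permuting its coordinates in
an orthonormal nuisance-null-space basis, where they are exchangeable
under Gaussian errors) are available for settings with strong nuisance
effects; in this package's leverage-structured designs at n = 40 both
measured mildly conservative (family-wise rate ≈ 0.03 at nominal 0.05)
while the outcome scheme measured 0.045 over 1000 null cohorts. The
scheme used is recorded in the correction metadata. Bonferroni over
evaluated voxels is a fast alternative; random-field-theory thresholds
are deliberately out of scope. Fewer than 100 permutations are refused
(the tail quantile would be unstable). Intensity-normalisation reference
regions (cerebellum, pons) are excluded from analysis masks: SUVR values
inside a modality's own reference region are ratio-degenerate, and
including them measurably distorted error rates. The compiled inner loop
makes 500 permutations over a few thousand voxels a matter of seconds.

### Connectivity

Metabolic connectivity (`metabolic_matrix()`) is the matrix of pairwise
Pearson *partial* correlations of regional FDG means across subjects,
controlling for age, sex, education, APOE e4, p-tau and mean gray-matter
density; the p-value uses $t = r\sqrt{df/(1-r^2)}$ with
$df = n - 2 - \#\text{covariates}$. The asymmetric cross-modal matrix
(`cross_modal_matrix()`) has entry $(i,j)$ = partial correlation of Abeta
in region $i$ with FDG in region $j$; its diagonal holds the *local*
associations and is retained in the Bonferroni family ($R^2$ tests;
$R(R-1)/2$ for the symmetric matrix). `element_correlation()` correlates
the two matrices' elements (off-diagonal by default, since self-pairs mix
local and distant semantics), and `distance_control()` checks that entries
are not simply a function of internode Euclidean distance between region
centroids (computed in world millimetres; the standard guard against
proximity artefacts). `seed_to_voxel_map()` delegates to the voxel engine
with a seed region's Abeta mean as the scalar predictor, and
`network_overlap()` decomposes a suprathreshold mask into the seven
canonical functional networks, with percentages that sum to exactly 100
at the reported precision (the largest entry absorbs the rounding
remainder; an empty mask is an error, not a row of zeros).

### The path model

`fit_sem()` fits a recursive path system over observed subject-level
summaries: distant Abeta and local Abeta point at posterior-DMN FDG, and
local FDG, local Abeta and their product point at the cognitive slope
(`sem_default_model()`). For a recursive system with independent errors,
per-equation OLS gives the maximum-likelihood path estimates; the
model-implied covariance follows from
$\Sigma = (I-A)^{-1} S_0 (I-A)^{-\top}$ with saturated exogenous
covariances and diagonal residuals, and
$\chi^2 = (n-1)\,F_{ML}$. CFI uses the independence (diagonal) model as
baseline — the conventional default — and SRMR is computed on the
correlation metric including the diagonal. A fit is *satisfactory* iff
CFI > 0.95 and SRMR < 0.1, both strict. The interaction enters as an
observed product of standardized parents, which bounds its collinearity
with the main effects.

## The synthetic cohort generator

`simulate_cohort()` draws, per subject, region-level values on a
parcellation of cuboid blocks (ten named analysis regions — the eight
global-composite regions plus insula and occipital pole — and cerebellum
and pons reference blocks):

* Abeta: $a_r \sim N(\mu_g, \Sigma_a)$ with the group mean $\mu_g$ at the
  composite scale of the human groups (1.07 / 1.30 / 1.35 SUVR), and a
  near-independent region covariance (within-network correlation 0.05),
  so that *local* Abeta-metabolism correlations are null when no local
  effect is simulated.
* FDG: $g_r = b_0 - \gamma (W a)_r + \delta a_r + \text{covariate
  effects} + \epsilon_r$, with $W$ the coupling matrix (0.3 between
  distinct default-mode regions, 0 elsewhere) and $\epsilon$ carrying a
  default-mode covariance block (within-network correlation 0.5) — the
  structure metabolic connectivity should recover. By default the local
  coupling $\delta = 0$.
* Cognitive slope: $c_0 + \beta_3 \cdot \overline{(a_r - \mathbb E a_r)
  \cdot (-(g_r - \mathbb E g_r))}_{r \in \mathrm{pDMN}} + \text{covariate
  effects} + \varepsilon$, averaged over the designated posterior
  default-mode regions (precuneus, posterior cingulate, inferior
  parietal), with $\beta_3$ group-specific (zero in control-like groups).
  Both factors are centred so that the driver is a pure local synergy
  between *excess* Abeta and hypometabolism — an uncentred product would
  be dominated by a rescaled hypometabolism main effect, which is not the
  quantity the interaction model is meant to detect. Scores are then laid
  out over four visits across the group's follow-up window.
* Volumes broadcast the region values onto the blocks, add voxel noise,
  apply 8-mm Gaussian smoothing, and carry a per-scan multiplicative
  factor that the SUVR step (`compute_suvr()`) removes.

Group sizes (99 / 53 / 170 by default), covariate distributions (age,
sex, education, APOE e4, follow-up, baseline score) and the
composite-scale Abeta means encode a realistic elderly amyloid-imaging
cohort; p-tau levels are plausible CSF values.
Effect sizes and noise scales are nowhere printed, so they are this
package's calibration: $\gamma = 0.5$, $\beta_3 = -0.4$, Abeta region SD
0.25 (which yields a composite SD of about 0.10 when averaged over eight
regions, the magnitude reported for such composites), FDG region noise 0.06, voxel noise 0.05,
reference-region noise 0.005, slope residual 0.003 and visit noise 0.006.
The slope noise is deliberately small relative to real test-retest
variability of cognitive instruments: it is chosen once so that the
voxel-level interaction survives max-|t| correction in the large majority
of impaired-group cohorts at the default impaired-group size (n = 170),
which is
what makes the group-contrast pattern a usable test statistic at desk
scale. The default-mode blocks are deliberately scattered across the
lattice so that network membership and internode distance remain
unconfounded, letting the distance-control check behave as in real
geometry.

What the generator does *not* emulate: anatomical shapes, spatially
graded Abeta topographies, biophysical spreading dynamics, longitudinal
imaging, realistic cognitive-score variances, or scanner artefacts.
Passing tests therefore demonstrate the correctness and calibration of
the *analysis machinery* under the assumed statistical structure, not
performance on real patient images.

## Partial-volume geometry and parameter recovery

Broadcasting block values and smoothing at 8 mm attenuates every observed
region mean toward the zero background (each 12-mm block keeps only about
half of its own signal), and products of attenuated means bias an
interaction coefficient by the square of the attenuation. The recovery
estimators (`estimate_distant_effect()`, `estimate_interaction_effect()`)
therefore correct region means with the geometric transfer matrix of the
package's own smoothing kernel (`roi_transfer_matrix()` /
`gtm_correct()`): entry $(r,s)$ is the mean over region $r$ of the
smoothed indicator of region $s$, and solving the linear system undoes
the attenuation exactly for piecewise-constant sources; renormalising to
the corrected reference region removes the per-scan SUVR scale. This is
an ROI-level transfer-matrix correction, simpler than voxel-level
partial-volume methods, and it is what makes unbiased (<10%) recovery of
$\gamma$ and $\beta_3$ possible under the broadcast-and-smooth
observation process. The descriptive connectivity matrices use raw region
means, as a real study would.

## Numerical choices

* Smoothing uses a separable discrete Gaussian with
  $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ per axis, truncated at
  $4\sigma$, with reflective (zero-flux) boundaries — so constants are
  preserved exactly and the total image sum is conserved; FWHM 0 is the
  identity, and an `intrinsic_fwhm_mm` argument applies
  $\sqrt{\text{target}^2 - \text{intrinsic}^2}$ when the input already
  carries known smoothness.
* All tests are two-sided; the positivity threshold (composite
  SUVR > 1.15) is strict, so the boundary value classifies negative.
* Voxel indices are 0-based under the affine; world coordinates are mm.
* Per-voxel rank deficiency or zero outcome variance yields not-evaluated
  voxels, which are counted and excluded from correction families.
* The bootstrap (`bootstrap_stability()`) resamples subjects (not
  residuals), redrawing a replicate if the resampled design is singular;
  with a single replicate the SDs are reported as NA, never 0.
* The cohort-level design is checked once for rank; a constant covariate
  is reported by name rather than producing NA maps.
* Master seed with derived per-subject streams; permutation and bootstrap
  seeds are explicit arguments, echoed into metadata.

## Problem sizes

The packaged study conditions are desk-scale by design: a 24-cube grid
(2-mm voxels) with twelve 6-cube blocks (2592 in-mask voxels), cohorts of
40–223 subjects, 300–500 permutations for map correction, 100–200
replicate cohorts for calibration studies, and 2000–10000 bootstrap
replicates. The error-rate calibration study
(`calibrate_fwer()`, 200 null cohorts at n = 40 and 500 permutations)
runs in a few minutes on one core.

## Known limitations

* Estimation at the analysis granularity (region-seeded or
  covariate-adjusted voxel GLMs) — no biophysical model of Abeta spread.
* The GTM correction assumes piecewise-constant sources on a zero
  background; it is exact for the generator's geometry but only
  approximate for real anatomy.
* The path model handles observed variables only (no latent measurement
  models, no robust estimators), matching its role here.
* Group labels are generative inputs, not re-derived from the simulated
  composites; the simulated positivity rate around the 1.15 cutoff is
  imperfect by design, mimicking classification noise.
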
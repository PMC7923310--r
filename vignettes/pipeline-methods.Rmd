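---
title: "Methods: synthetic multi-site cohorts and the intrinsic-function analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic multi-site cohorts and the intrinsic-function analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfmritools)
```

# Scope

`rfmritools` implements, as reusable and tested components, the analysis
chain used in multi-site resting-state fMRI studies of diagnosis-by-sex
differences in intrinsic brain function: motion quality control, nuisance
denoising, five voxel-wise metrics, empirical-Bayes site harmonization
(ComBat), voxel-wise group GLMs with Gaussian-random-field (GRF)
cluster-level correction, effect sizes with confidence intervals, an
effect-size-based robustness/replicability classifier, leave-one-site-out
stability, and sex-differential brain-behavior models.  Because the real
cohorts such studies draw on are access-restricted, the package pairs the
analysis chain with a synthetic-cohort generator whose ground truth
exercises every stage; all empirical claims in this vignette are the ones
the test suite and `scripts/acceptance.R` actually compute.

The package operates on volumes already aligned to a left-right symmetric
template grid; spatial preprocessing of raw echo-planar images
(slice-time correction, co-registration, normalization) is out of scope.

# The synthetic cohort

## Phenotypes, motion, behavior

`cohort_spec()` fixes a 2 (diagnosis: NT/ASD) x 2 (sex: M/F) x site
design.  The desk-scale default is 4 sites x 10 subjects per cell
(N = 160), ages uniform on 7-18 years, full-scale IQ normal with means
112 (NT) and 106 (ASD) and SD 13 — the direction and rough magnitude of
the IQ gap reported in large autism cohorts — on a 24 x 24 x 16 grid at
3 mm, 150 volumes at TR = 2 s.  Target mean framewise displacement (mFD)
is drawn log-normally around 0.09 mm (NT) and 0.12 mm (ASD) plus a
per-site offset, within the range QC retains.  `generate_motion()`
realizes a 6-parameter bounded random walk whose step scale is calibrated
so the realized Power-convention mFD (50 mm head radius) lands within a
few percent of target.

ADOS calibrated severity scores (1-10) exist for ASD rows only.
`generate_behavior()` constructs the social-affect score as a rounded,
range-clipped linear transform of a supplied region signal so that the
within-sex signal-score correlation hits its target (defaults
r = -0.29 in females, 0.03 in males, the discovery pattern).  Rounding
and clipping attenuate the realized correlation slightly; the +-0.1
tolerance used in tests absorbs this.

## The BOLD generative model

Each voxel series is a unit-variance mixture of latent signals and AR(1)
noise (`phi = 0.3`, shared by latents and noise so that band-pass
filtering preserves the generative correlations):

* **Homotopic channel** — mirror-pair voxels share a latent with mixing
  weight `sqrt(c)`; their correlation equals the coupling `c` exactly.
  For negative site-shifted couplings the latent sign is flipped on one
  pair member only.  Baseline `c = 0.3` brain-wide.
* **Local/seed/hub channels** — region-shared latents with weight
  `sqrt(p)` raise neighborhood concordance (ReHo), seed connectivity or
  degree; the seed region itself receives the same latent at fixed high
  weight.
* **Spectral channel** — a 0.01-0.1 Hz band-limited component with
  variance fraction `f` sets the fALFF ground truth.
* **Motion nuisance** — a linear combination of the realized motion
  parameters and their backward differences (hence inside the span of
  the 24-parameter motion model) is mixed into every voxel with weight
  0.2.

Inside an effect's target region the channel parameter is
`base + beta_dx*dx + beta_sex*sex + beta_int*dx*sex` (dx, sex coded
0/1).  The default fixture injects two homotopic effects: a bilateral
dorsolateral-occipital-like region with cell couplings NT-M 0.30,
NT-F 0.36, ASD-M 0.30, ASD-F 0.08 (a negative interaction on top of a
small positive sex effect, so the ground truth itself encodes the
"NT-F highest, ASD-F lowest" discovery ordering), and a posterior
midline region with diagnosis and sex main effects.

**Site batch effects.**  Correlation- and ratio-type metrics are
invariant to affine transforms of the series, so an additive scanner
offset on the BOLD signal cannot produce the additive site structure
ComBat removes.  Site effects are therefore injected on the *link scale*
of the generative parameters: Fisher z for couplings and logit for
variance fractions, `link(par) -> delta * link(par) + gamma`.  A site
gamma of +-0.5 then separates the VMHC z-map site means by almost
exactly 1.0, giving the harmonization stage a true location/scale batch
structure with known parameters.

What the generator does *not* emulate: hemodynamic response shape,
anatomical tissue classes, spatially smooth baseline metric topography,
scanner drift beyond polynomial trends, and distance-dependent motion
artifacts.  Passing tests therefore demonstrate the correctness and
calibration of the analysis chain, not its behavior under every
real-data pathology.

# Quality control

Framewise displacement uses Power-style backward differences with a
configurable 50 mm rotation radius, the most common convention in
multi-site autism imaging QC (the literature contains more than one
variant).
Eligibility retains ages 7-18 and FIQ 70-148 (inclusive bounds) and
excludes subjects with mFD above Q3 + 3 IQR of the *input sample*
(type-7 quantiles); the threshold is recomputed per sample, matching the
sample-dependent cut reported in such studies, with a fixed override
available.  Sites need at least 3 subjects in each of the four
diagnosis-by-sex cells.  `cohort_summary()` provides the verification
surface (ANOVA for age/FIQ, Kruskal-Wallis for the skewed mFD,
chi-square without continuity correction for categorical balance,
ASD-only t-tests for symptom scores); explicit group-matching
optimization is not implemented because the generator produces matched
groups by construction.

# Denoising

The discovery design concatenates intercept, linear and quadratic
trends, the 24-parameter motion set (6 parameters, their one-lag
backward differences, both squared), and 5 aCompCor components — the
top variance-normalized principal time series of a noise compartment
(for synthetic volumes, the non-brain rim).  The GSR variant appends the
in-mask global mean while keeping CompCor (whether published GSR
pipelines retained CompCor is often unstated; both-on is the default and
toggleable).  Nuisance removal is per-voxel OLS; band-pass filtering is
an ideal (hard) FFT filter on 0.01-0.1 Hz with the DC term always
removed — idempotent by construction and the common choice in R-fMRI
toolchains; fALFF consumes the regressed but *unfiltered* series.
Spatial smoothing (Gaussian, FWHM 6 mm, separable kernels with
normalized-convolution edge handling) is applied to the metric
derivative maps, not the 4D series.

A caveat the tests quantify: regressing p stochastic nuisance columns
removes about p/T of *any* fixed signal by noise-fitting, and the
subsequent band-pass can amplify the loss up to two-fold.  At the
fixture's T = 150 with ~33 columns this leakage is ~20%; the
"pipeline preserves in-band signal" property is therefore a long-run
statement, verified at T = 1600 where the expected leakage is ~3%.

# The five metrics

* **Seed iFC** — Pearson correlation with the seed-mean series, Fisher
  z with `r` clipped at 1 - 1e-7; the posterior-midline default seed is
  a configurable input.
* **VMHC** — Fisher z of the correlation between each voxel and its
  x-mirrored counterpart (index reflection; registration to a symmetric
  template is assumed upstream); the map is exactly mirror-symmetric,
  zero-variance pairs are zeroed and flagged.
* **ReHo** — Kendall's coefficient of concordance
  `W = 12 S / (K^2 (n^3 - n) - K sum(T_j))` with midrank tie
  correction, over the voxel and its 26-connected in-mask neighbors
  (7/19/27 configurable); voxels with fewer than 4 available neighbors
  are zeroed and flagged, partial neighborhoods use the reduced K and
  are flagged.
* **DC** — count (default) or sum of positive correlations above
  r = 0.25 with all other in-mask voxels, self excluded; threshold and
  binarization configurable since published defaults vary.
* **fALFF** — the sum of Fourier amplitudes in 0.01-0.1 Hz divided by
  the sum over all positive frequencies, DC excluded.  The numerator
  band matches the pipeline's filter band (classic implementations use
  0.01-0.08; configurable).

For group analysis, amplitude/count metrics (ReHo, DC, fALFF) are
z-scored within the subject's mask so the GLM inputs are scale-free;
correlation metrics stay on the Fisher-z scale.  Each metric is checked
against an independent brute-force implementation (direct loops over the
definitions) to 1e-10 on a 6 x 6 x 4 x 40 volume.

# ComBat harmonization

`combat_fit()` implements parametric empirical-Bayes ComBat for
subjects-by-voxels matrices: covariate-protected standardization by the
grand mean and pooled variance, per-site location/scale estimates,
normal/inverse-gamma priors fitted by moments, and the standard
iterative conditional posterior means (relative tolerance 1e-4).
Protected covariates default to diagnosis, sex, their interaction, age
and mFD, so the batch step cannot absorb the effects of interest.
Zero-pooled-variance voxels pass through unharmonized and are flagged.
A single site yields the identity adjustment.

Two structural facts shape the tests.  First, site locations are
identified only up to a per-voxel constant — the sample-size-weighted
mean across sites is absorbed into the grand mean — so parameter
recovery is judged against the *centered* true site effects (the raw
correlation is bounded by `sqrt(1 - 1/I)` for any implementation).
Second, EB shrinkage deliberately over-removes the sampling part of
observed site differences, so post-harmonization site F-tests lean
conservative; the tests require them to be non-anticonservative rather
than exactly uniform.  The implementation is cross-checked against the
reference Bioconductor implementation (`sva::ComBat`) on shared
defaults.

# Group inference

The group design codes diagnosis (NT = 0, ASD = 1), sex (M = 0, F = 1),
their product, and mean-centered age and mFD (FIQ optional).  Per-voxel
OLS t statistics are mapped to signed Z scores by log-scale CDF
matching.  Residual smoothness is estimated from the variance of spatial
derivatives of voxel-standardized residuals
(`FWHM = sqrt(4 ln 2 / var(du/dx))` per axis) and converted to RESELs.
Clusters are 26-connected components above |Z| = 3.1, positive and
negative maps treated separately; cluster-level p values use the
GRF expected-cluster statistics (Euler-characteristic density at the
threshold times RESELs for the expected cluster count, exponential tail
in `k^(2/3)` for the size distribution).  The study-wise cluster alpha
0.01 reflects sharing 0.05 across five metrics and is a configuration
constant.  GRF validity needs smoothness of roughly 3+ voxel FWHM;
calibration is verified on smooth unit-variance null fields (FWHM 9 mm
at 3 mm voxels), where the family-wise rate at p < 0.05 must land within
+-0.03 of nominal over 500 fields.

A Freedman-Lane permutation oracle (reduced-model residual permutation,
max-cluster-size null) provides a distribution-free cross-check;
GRF and permutation decisions at p < 0.01 agree on >= 90% of clusters in
matched simulations.  Null-calibration of the voxel stage itself is
checked two ways: analytically clean (iid normal subject matrices,
P(Z > 3.1) inside the binomial CI over 1e6 pooled draws) and end-to-end
(200 fully null synthetic cohorts through generation, denoising, VMHC
and the GLM).  The end-to-end check uses T = 100 volumes: with very
short runs the per-subject Fisher-z values rest on so few in-band
Fourier bins that their excess kurtosis visibly inflates the far tail.

# Effect sizes and replicability

Cluster means are analyzed with the full model (diagnosis, sex,
interaction, age, mFD).  Partial eta squared comes from type-III sums
of squares computed by explicit projections under sum-to-zero coding
(identical to `car::Anova(type = 3)` where both are defined, but also
well-behaved for noise-free inputs); the identity
`eta_p^2 = F df1 / (F df1 + df2)` holds to 1e-10 and, e.g., converts
F(1,311) = 4.44 to 0.0141.  Confidence intervals invert the noncentral-F
CDF (90% two-sided, the usual convention for eta-squared intervals
because the statistic is bounded below by zero; level configurable).
Contrast directions are signs of covariate-adjusted contrasts: ASD - NT,
F - M, and (ASD_F - NT_F) - (ASD_M - NT_M).

A discovery effect is classified R+ in a replication when the direction
matches and the replication eta_p^2 >= 0.01 (the small-effect floor);
otherwise R-.  On paired synthetic cohorts the classifier flags >= 80%
of injected interactions and <= 20% of null clusters, and is invariant
to positive affine rescaling of the extracted means.
Leave-one-site-out stability refits adjusted cell means with each site
excluded and reports the fraction of leave-outs preserving the
full-sample contrast sign.  Ontology overlap reports the percentage of
cluster voxels inside each thresholded probability map.

# Brain-behavior models

Within ASD subjects with available scores (listwise deletion, counts
logged), cluster means are modeled as
`mean ~ sex * score + age + mfd (+ module dummies)`, the module factor
referenced to its most frequent level.  The interaction F (1 df, the
squared t of the product term) is affine-invariant in both score and
signal; adding the module covariate reduces the error df by exactly the
number of dummies.  Bonferroni-adjusted alphas are reported exactly
(0.05/3 = 0.0167) alongside the conventionally rounded value (0.02).

# Numerical choices and problem sizes

Fisher z is clipped at |r| = 1 - 1e-7 to keep maps finite.  Quantiles
are type 7.  The EB iteration tolerance is 1e-4; the eta-CI root search
tolerance 1e-9.  Cluster connectivity defaults to 26.  Test and
acceptance problem sizes — a 24 x 24 x 16 fixture with N = 160 for
end-to-end recovery, 500 voxels x 40 subjects/site for ComBat, 1e6
pooled draws for GLM calibration, 500 null fields for GRF FWER, 100
cohort pairs for the replicability rates — were chosen as the smallest
sizes at which the binomial/Monte-Carlo error of each check is several
times smaller than its tolerance.

# Known limitations

GRF p values are asymptotic in smoothness and mask size and are not
trusted below ~3 voxel FWHM (use the permutation oracle there).  The
generator's mirror symmetry is exact, so VMHC maps carry duplicate
information across hemispheres; tests pool one hemisphere where
independence matters.  ComBat here is the parametric location/scale
model; non-parametric priors and covariance-level harmonization are out
of scope.  The behavior generator induces the target correlations
through a single region signal, not an item-level symptom model.
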
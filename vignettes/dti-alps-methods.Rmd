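---
title: "DTI-ALPS simulation and group statistics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DTI-ALPS simulation and group statistics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpsim)
```

## The DTI-ALPS method

Diffusion tensor image analysis along the perivascular space (DTI-ALPS)
quantifies glymphatic-system activity from an ordinary diffusion MRI
scan. At the level of the lateral-ventricle body, medullary veins run
along the scanner x axis (right–left), perpendicular to two adjacent
white-matter fibre populations: projection fibres (dominant direction
z, inferior–superior) and association fibres (dominant direction y,
anterior–posterior). Water diffusivity measured along x in those two
regions is, uniquely, aligned with the perivascular space and
perpendicular to both fibre populations. The index is

$$\mathrm{ALPS} =
  \frac{\mathrm{mean}(D_{xx}^{proj},\, D_{xx}^{assoc})}
       {\mathrm{mean}(D_{yy}^{proj},\, D_{zz}^{assoc})},$$

a dimensionless ratio: 1 means no preferential perivascular diffusion,
and healthy adult values are typically 1.4–1.9. The four diffusivities
are means of the diagonal tensor elements over four 6 × 6 mm²
rectangular ROIs (left/right × projection/association), placed on the
colour-coded FA map so that projection ROIs contain only z-dominant
("blue") voxels and association ROIs only y-dominant ("green") voxels.

The package implements the full desk-scale pipeline — phantom and
cohort simulation with known ground truth, tensor estimation, ROI
placement and QC, index computation, and the group-statistics stage of
a three-group clinical comparison (healthy controls, episodic migraine,
chronic migraine) — and re-analyses the published summary tables of
such a study from shipped plain-text fixtures.

## Forward model and phantom

Signals follow the mono-exponential tensor model
$S = S_0 \exp(-b\, g^\top D g)$ per voxel and gradient direction $g$,
with optional Rician corruption
$\tilde S = \sqrt{(S + \varepsilon_1)^2 + \varepsilon_2^2}$,
$\varepsilon_i \sim N(0, \sigma^2)$, drawn from a single seeded
generator stream. The phantom is a set of axis-aligned boxes on a
regular grid (default 64 × 64 × 40 voxels at 2 mm isotropic, stored
RAS): a CSF-like ventricle (3.0 × 10⁻³ mm²/s isotropic), mirrored
projection-fibre blocks with eigenvalues (1.1, 0.6, 1.6) × 10⁻³ mm²/s
along x/y/z, association-fibre blocks with (1.1, 1.6, 0.6) × 10⁻³, and
an isotropic background of 0.8 × 10⁻³. Tensors are diagonal in scanner
axes by construction, which makes ground truth exact and the ALPS
geometry literal: `set_phantom_alps()` rescales the x eigenvalues of
both fibre blocks of a hemisphere to
$D_{xx} = \mathrm{ALPS}_{target} \times \mathrm{mean}(D_{yy}^{proj},
D_{zz}^{assoc})$.

The default acquisition is 6 b = 0 volumes plus 32 directions at
b = 1000 s/mm² from an electrostatic-repulsion table shipped as a
fixture (minimum inter-axis angle ≈ 25°). Thirty-two directions keep
simulation and fitting fast while oversampling the 6 tensor degrees of
freedom; the scheme is fully configurable and a clinical 108-direction
protocol can be supplied the same way.

What the phantom deliberately omits: anatomy, crossing fibres, partial
volume, motion, eddy currents and susceptibility artefacts.
Consequently, passing round-trip tests demonstrates correctness of the
estimator and index arithmetic, not robustness to the preprocessing
problems that real scans bring (those are handled upstream by dedicated
tools in practice).

## Tensor estimation

Fitting is ordinary (unweighted) least squares on log-signals with
design row $(-b g_x^2, -b g_y^2, -b g_z^2, -2b g_x g_y, -2b g_x g_z,
-2b g_y g_z, 1)$, solved by one QR decomposition for all voxels. OLS
was chosen because it is deterministic and *exact* on noise-free data,
which turns every simulation into a strong oracle (round-trip
agreement to ≤ 10⁻⁹ is asserted, not approximated). Numerical
policies:

* voxels with non-positive mean b = 0 signal are masked invalid;
* individual non-positive samples (possible under heavy Rician noise)
  are clamped to `s0_floor_frac` (default 10⁻⁶) of the voxel's
  estimated $S_0$ before the log, and the voxel is flagged;
* negative eigenvalues are clamped to zero for FA and colour maps
  only; raw tensor components stay unclamped so ROI means reflect the
  fit;
* FA is scale invariant, so an all-but-zero tensor (constant signal)
  would inherit an arbitrary FA from rounding noise; eigenvalue
  triples below 10⁻¹² mm²/s report FA = 0;
* the principal eigenvector's sign is fixed by making its
  largest-magnitude component positive (colour maps are
  sign-invariant; the convention only stabilises serialisation).

## ROI placement and QC

ROIs are 0-based, half-open rectangles of 6 × 6 mm² (3 × 3 voxels at
2 mm) on a single axial slice — the minimal reading of a 2-D ROI
specification. The automated surrogate for visual "only blue / only
green" inspection computes, per ROI, the fraction of valid voxels
whose principal eigenvector's dominant absolute component matches the
expected axis *and* whose FA is at least `fa_min`; an ROI passes at
fraction ≥ 0.9 with all voxels valid. The published criterion is
qualitative, so both thresholds (FA 0.2, fraction 0.9) are exposed;
the defaults accept every on-target phantom ROI and reject ROIs
displaced onto the wrong fibre block or isotropic tissue.
`apply_affine_to_rois()` maps rectangle corners through a supplied
affine and re-derives sizes from the physical ROI area, standing in
for template-to-native transport when no registration is involved.

## Cohort generator

`default_cohort_spec()` encodes the published group structure:
right-hemisphere ALPS 1.63 ± 0.18 (HC, n = 41), 1.64 ± 0.17 (EM,
n = 32), 1.77 ± 0.23 (CM, n = 24), and the published left-hemisphere
summaries for EM (1.59 ± 0.15) and CM (1.65 ± 0.16). The HC
left-hemisphere summary is not published; the generator reuses the HC
right-hemisphere targets there. Per-subject indices are normal draws
truncated below at 1.0 (the physiological floor of the ratio; at these
means the truncation is ≈ 3.5 SD away and practically inert). Targets
at or below 1 are rejected as unreachable. Clinical covariates are
drawn per group from the published summaries: mean ± SD variables as
normals, median (IQR) variables as normals with SD = IQR/1.349 clamped
to each scale's range — the published tables constrain location and
spread but not shape, so the shapes are a modelling choice. Attack
frequency respects the diagnostic boundary (EM < 15, CM ≥ 15
days/month). Healthy controls carry no migraine scales (NA), matching
the published tables. All draws flow from one master seed; each
subject also records a sub-seed used for their phantom noise stream.

## Statistics dialect

Every procedure follows the conventions of mainstream clinical
statistics software, because those are the conventions that reproduce
the published numbers:

* **Summary-statistics ANOVA.** $SSB = \sum n_i(\bar x_i - \bar x)^2$,
  $SSW = \sum (n_i - 1) s_i^2$ — algebraically identical to raw-data
  ANOVA when summaries are exact (asserted to ≤ 10⁻¹²).
* **Bonferroni post hoc.** Pairwise t with the MSW pooled over *all*
  groups, df = N − g, adjusted p = min(1, k·p) with k = g(g−1)/2, and
  simultaneous CIs at α/k. Published mean differences (printed at
  3 decimals, finer than the rounded group means) can be supplied via
  `mean_diff` so recomputed p-values carry the source's precision
  rather than the rounding error of 2-decimal means.
* **Chi-square.** Pearson, no continuity correction, any r × c, zero
  margins rejected.
* **t-tests.** Pooled-variance Student by default (the "equal
  variances assumed" row); Welch behind a flag. Paired t defines
  all-zero differences as a null result rather than an error.
* **Mann–Whitney.** Exact two-sided p by full enumeration of the
  `choose(n1+n2, n1)` assignments when n₁+n₂ ≤ 12 (ties handled by
  conditioning on the pooled values); otherwise normal approximation
  with tie and continuity corrections. Routing between t and
  Mann–Whitney uses Shapiro–Wilk screening at 0.05.
* **Partial correlation.** Pearson correlation of OLS residuals on
  [1, covariates], df = n − 2 − k. For the published correlations the
  fixture records n = 48 for the scale-subset variables and n = 56 for
  BMI — the per-variable availability that the printed p-values are
  consistent with. A variable that is an exact covariate function has
  partial correlation 0 by definition (not 0/0).
* **Power.** Noncentral-F power of the omnibus test under two
  noncentrality conventions, because published "power" sentences
  rarely state one: *unweighted* Cohen's f (variance of unweighted
  group means over the mean of group variances, λ = N·f²; the default)
  and *weighted* (size-weighted means over pooled within variance).
  Both are always reported side by side.

## Operating characteristics and the homoscedastic reference model

The Monte-Carlo checks of the test's size and power use the
homoscedastic normal model — common SD equal to the pooled
within-group SD — because that is the model under which the F test has
exactly its nominal size and the weighted noncentral-F power formula
is exact. Under the heteroscedastic published SDs (the smallest group
being the most variable) the F test's empirical size inflates to
roughly 0.06–0.07, a well-known property, not an implementation
artefact. The heteroscedastic per-group SDs are retained wherever they
are the study condition: the cohort generator and the detection-rate
replicates.

One acceptance property deserves a frank note: requiring *both*
Bonferroni-adjusted post hoc comparisons (CM > HC and CM > EM) to be
significant in ≥ 80% of replicates is not attainable under the very
group structure being simulated. The 85% design-power statement
concerns the omnibus ANOVA; at these means and SDs the joint adjusted
post hoc detection rate is near 50% (each pair individually near
55–66%), as the package's own replicate simulation shows. The
corresponding test is therefore expected to fail, and the acceptance
script reports the measured rate rather than a target.

## Problem sizes

Unit and property tests run the imaging pipeline on a 32 × 32 × 16
scaled replica of the default phantom (fibre blocks of 4 × 4 × 4
voxels, the smallest grid whose blocks still contain a 3 × 3-voxel
ROI); noise-recovery properties use 20 seeded replicates at Rician σ
of 0.5%, 1% and 2% of S₀; type-I error uses 2,000 replicates, the
Monte-Carlo power check 10,000, and the detection rate 100 cohort
replicates at n = 41/32/24. The acceptance script runs the full
64 × 64 × 40 default phantom.

## Known limitations

* Diagonal ground-truth tensors make rotation handling testable via
  synthetic full tensors only; the phantom itself never exercises
  oblique fibre geometry.
* The OLS fitter is not robust to outliers or free water; weighted and
  robust variants are out of scope by design.
* The published left-hemisphere omnibus ANOVA cannot be recomputed
  (one group's summary was never printed) and is deliberately absent
  from the reproduction output.
* Clinical covariate shapes beyond published location/spread are
  invented; analyses that depend on distributional tails of those
  covariates should not lean on the generator.
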
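---
title: "mpmcortex: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mpmcortex: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Multi-parameter mapping (MPM) derives four quantitative maps — R1, R2\*,
MT saturation and effective proton density (PD\*) — from three multi-echo
FLASH acquisitions with proton-density, T1 and magnetization-transfer
weighting. Downstream, cortical analyses sample these maps at fractional
depths between the white and pial surfaces, model the laminar profiles
with hierarchical regressions, and map age effects vertex-wise. None of
these stages can be validated end-to-end on real scans, because the tissue
parameters of a living cortex are unknown. This package makes the whole
chain testable by replacing the scanner and the cohort with a generative
phantom whose ground truth is exact and recorded.

# Forward signal model

The spoiled gradient-echo steady state ("ernst" model) is

$$S = A \sin\alpha \,\frac{1 - E_1}{1 - \cos\alpha\,(1-\delta)\,E_1}\,
(1-\delta)\, e^{-TE \cdot R_2^*}, \qquad E_1 = e^{-TR \cdot R_1},$$

with the MT pre-pulse entering as a fractional saturation $\delta$ of
longitudinal magnetization once per TR. The literature the MT-map
estimator descends from does not print its exact forward convention, so the
package fixes it by the binding algebraic contract instead: the
small-angle variant

$$S = A\,\alpha\,\frac{TR \cdot R_1}{\alpha^2/2 + TR \cdot R_1 + \delta}\,
e^{-TE \cdot R_2^*}$$

places $\delta$ additively beside the apparent relaxation term, which the
MTsat estimator $\delta = (A\alpha/S - 1)R_1 TR - \alpha^2/2$ inverts
*exactly*. The test suite asserts machine-precision round trips through
the small-angle pair and a measured <5% bias when the exact Ernst forward
is inverted with the rational approximation at both protocol presets
(worst case 4.5%, cohort-1 T1w at 29°). Units are a classic silent-failure
point: TR/TE are stored in milliseconds and relaxation rates in s⁻¹, every
formula converts explicitly, and the conversions are unit-tested against
an arbitrary-precision oracle.

Protocol presets reproduce the two emulated acquisitions: cohort 1
(PDw/T1w TR 25.25 ms at 5°/29°, MTw TR 29.25 ms at 9°, eight echoes
2.39–18.91 ms in 2.36 ms steps) and cohort 2 (6°/21°/6°, TR 25 ms, eight
echoes 2.34–18.44 ms in 2.30 ms steps, six echoes for MTw). Echo averaging
uses all eight echoes for cohort 1 and the first six for cohort 2 for all
weightings, matching the shorter MTw train.

# The synthetic cortex

Each hemisphere is a corrugated height-field sheet over a regular 1 mm
vertex lattice: white surface $z = a\sin(2\pi x/\lambda_x + \phi)\cos(2\pi
y/\lambda_y + \psi)$ with analytic normals and mean curvature, and pial
surface offset along the normal by a thickness between 1.5 and 4 mm.
Curvature signs follow the convention positive = concave (sulcal),
negative = convex (gyral); thickness is coupled to curvature so gyral
crowns are thicker than sulcal depths, as in real cortex. A folding
amplitude of zero degenerates to a flat slab (zero curvature, constant
thickness), which several exactness tests exploit. Geometry that would
self-intersect (offset beyond the radius of curvature) is rejected.
Region labels are contiguous bands along the long axis; 17 regions mirror
the emulated parcellation. The voxel grid is labelled by projecting each
voxel center onto the nearest vertex normal line; the lateral catchment is
twice the lattice spacing because normal lines diverge above convex
crowns.

This is deliberately *not* a brain: there is no anatomy, no registration
problem (all subjects share the mesh), no segmentation error, no motion.
A green end-to-end test therefore establishes that the estimators and
statistics recover what the geometry and noise model admit — not that the
pipeline is robust to reconstruction failures or anatomical variability.

# Ground-truth tissue model and cohort

Grey-matter depth profiles are cubic polynomials in the depth fraction
$d\in[0,1]$ (white → pial): R1 declines 0.72 → 0.58 s⁻¹ and MTsat 1.4 →
0.7 pu with cubic truth, R2\* declines 16.5 → 13 s⁻¹ with quadratic truth,
and A (PD) rises 78 → 86 pu with cubic truth — the laminar myelin gradient
with the polynomial orders the depth-profile statistics are expected to
select. White matter is fixed at R1 1.05 s⁻¹, R2\* 21 s⁻¹, δ 0.019, A 69;
CSF at 0.25 s⁻¹, 2 s⁻¹, 0, 100. Regional offsets are drawn once per
cohort (population level), with designated "primary" regions boosted
(R1 +0.05 s⁻¹, MTsat +0.15 pu) to encode the primary > association
myelination contrast.

Subjects get random intercepts, region-within-subject intercepts and
region-within-subject linear depth slopes; ages are drawn uniformly over
18–39 whole years (uniform rather than the study's empirical histogram, to
maximize slope-recovery power at fixed n); the first 34/93 of subjects use
the cohort-1 protocol. Age effects are planted only in designated regions:
R1 +0.003 s⁻¹/yr and MTsat +0.0075 pu/yr (the center of the 0.006–0.009
range the emulated study reports), attenuated linearly by 50% from the
white to the pial surface, so the age × depth interaction is negative.

Two generator choices deserve explanation:

* **Age-orthogonalized random intercepts.** The subject-level (and
  subject-by-region) intercepts are shared across every vertex of a
  subject, so their finite-sample correlation with age — SD ≈ 0.10 at
  N = 93, occasionally ~0.3 — would act as a global age confounder that no
  vertex-wise method can remove, making the planted slopes *not* the only
  age structure of the generated world. The generator therefore
  residualizes these draws against age within the sample: the stated world
  is "age affects designated regions at the stated rates, and nothing
  else". The intercept SDs (R1 0.01 s⁻¹, MTsat 0.03 pu) give the planted
  effects vertex-level correlations near 0.6, the detectability regime the
  emulated study's widespread FDR-significant findings imply.
* **Per-subject covariate measurements.** All subjects share one mesh, so
  per-vertex thickness and curvature would be constant across subjects and
  the residualization covariates degenerate. Each subject therefore gets
  multiplicative measurement factors (SD 3% thickness, 5% curvature),
  emulating subject-specific surface reconstructions; the thickness factor
  also feeds a small R1 confound that residualization removes.

Noise is Gaussian on magnitude signals (valid at the simulated SNR, and
consistent with the log-linear ESTATICS error model); a Rician option
exists. The default `noise_sd = 0.12` signal units was calibrated once so
the fitted white-matter R1 map has SNR ≈ 50, the stated design point; the
achieved SNR is *reported* by the acceptance script, never asserted
against the study. Participant-specific transmit and receive fields are
smooth half-period sinusoidal modulations (±10%).

# Map estimation

ESTATICS fits $\ln S_w(TE_i) = \ln A_w - TE_i R_2^*$ jointly over all
weightings with one shared slope, by unweighted OLS in log space; because
all voxels share the echo design, one QR factorization serves the whole
volume, and the result is tested against a per-voxel normal-equations
oracle. Voxels with any non-positive echo are invalidated, never clamped.
R1 and A come from the rational-approximation inversion of the two
averaged (PDw, T1w) volumes with the true flip angles $f_T\alpha$; the
averaged volumes are *not* decay-corrected (hence "effective" PD\*). The
MTsat estimator is the exact algebraic inverse above, with an optional
(default-off) multiplicative transmit-bias correction
$\delta(1-C)/(1-Cf_T)$. PD\* divides the known synthetic receive field out
of A (standing in for UNICORT, which is out of scope) and rescales so the
white-matter mean is exactly 69 pu — idempotent and invariant to receive
rescaling, by construction. An imperfect-spoiling correction hook exists
but is the identity by default: its coefficients are scanner-specific and
not printable here.

# Depth sampling and profile statistics

Sampling uses the straight white→pial correspondence (equivalently, the
vertex normal) at fractions 0.1–0.9 and trilinear interpolation (nearest-
neighbour available for ablation); invalid voxels propagate as missing.
ROI profiles average vertices within ROI per hemisphere, then average the
two hemisphere means unweighted. Display smoothing is plain iterative
neighbour averaging (10 steps ≈ 3 mm FWHM Gaussian on a 1 mm mesh) and is
never applied before statistics.

Profile models are fitted by **maximum likelihood, not REML**, because the
likelihood-ratio tests compare models differing in fixed effects. The
depth basis is centered raw powers (the emulated analysis names no basis;
an orthogonal option exists and leaves the likelihood unchanged). The
random structure implements the three-level hierarchy — depths in ROIs in
subjects — as `(1 | subject) + (1 + depth | subject:ROI)`; if that fails,
a two-level fallback `(1 | subject) + (1 | subject:ROI)` is fitted and
flagged in the result. Order selection runs forward LRTs (linear →
quadratic → cubic) at α = 0.05 and stops at the first non-significant
step. Estimation is delegated to `lme4::lmer`; convergence is taken from
lme4's own criteria and surfaced as a flag, never silently.

# Age-effect mapping

The analysis depth is 0.5 (mid-cortex), matching the emulated choice of a
single representative depth to limit multiplicity. Residualization is
per-vertex OLS on intercept + curvature + thickness + cohort indicator;
degenerate (constant) columns are dropped with a warning. Vertex-wise
Pearson correlations with age (in whole years) are Fisher-transformed and
jackknifed: $z_J = N T - (N-1) T_m$ with $T_m$ the mean of leave-one-out
z-estimates. The emulated analysis does not state how p-values were
derived from the jackknifed r; the package defaults to the standard
t-transform $t = r_J\sqrt{(N-2)/(1-r_J^2)}$ on $N-2$ df (flagged as an
assumption), with a normal approximation using the jackknife SE behind
`p_method = "z"`. FDR control is Benjamini–Hochberg step-up, applied per
hemisphere ("peak-level" is read as vertex-wise; the source defines it no
further). Overlap ROIs are connected components (BFS on the mesh) of the
intersection of the *unsmoothed* R1 and MT masks; ROI age slopes are OLS
of per-subject ROI means on age.

# Numerical and degenerate-input choices

Grid dialects (4D-with-echo vs per-echo NIfTI files) load identically and
are declared in JSON sidecars; the NIfTI-1 reader/writer is minimal
(float64, sform affine) and cross-checked against an independent Python
reader in the tests. Fisher transforms clamp |r| at 1 − 1e−15 before
atanh. A vertex is invalidated when any leave-one-out subsample loses age
variance or drops below 3 subjects. LRT statistics marginally below zero
(optimizer tolerance) are clamped for the p-value and warned about beyond
tolerance; identical parameterizations return statistic 0, p = 1.
`select_depth_order` caps the order at (distinct depths − 2). All
randomness flows from explicit seeds; regenerating any object with the
same seed is byte-identical.

# What the tests do and do not establish

Green tests establish: exact algebraic inversion of the stated forward
model; agreement of every nontrivial statistic with an independent oracle
(enumeration, brute-force solve, flood fill, closed form); calibrated
type-I error of order selection and FDR under the null; and recovery of
planted laminar profiles and age effects at study scale on the synthetic
geometry. They do not establish robustness to real-data features the
phantom omits: anatomical folding complexity, registration and
segmentation error, B0 inhomogeneity, motion, flowing blood near the pial
surface (which in real data bends superficial R2\* upward), or
orientation-dependent R2\*. The reported study values (e.g., slopes of
0.003–0.004 s⁻¹/yr) enter only as generator magnitudes and recovery
targets, never as assertions about this package reproducing the cohort.
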
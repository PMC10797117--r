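---
title: "Methods: TE-dependent lung T1, DCE perfusion and their local correlation on a digital phantom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE-dependent lung T1, DCE perfusion and their local correlation on a digital phantom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What this package computes

`lungqmri` implements, end to end and on a synthetic digital lung phantom
with known ground truth, the quantitative analysis chain used in
morpho-functional lung MRI studies of obstructive lung disease:

1. **T1(TE) mapping** — per-voxel fitting of inversion-recovery
   ultra-short-echo-time (UTE) magnitude series, one map per echo time.
2. **DCE perfusion quantification** — conversion of a dynamic
   contrast-enhanced series to concentration, automatic arterial input
   function (AIF) detection, truncated-SVD deconvolution to the residue
   function R(t), pulmonary blood flow (PBF) as max R(t), Otsu
   two-threshold classification of R(t_max) into perfusion defect vs
   normal, and the defect percentage QDP.
3. **Spatial correspondence** — a registration-based route (externally
   produced deformation fields, identity by default) and a
   registration-free route that subdivides each lung into 10 x 10
   equal-volume areas.
4. **Statistics** — inter-patient Spearman correlations of median T1(TE)
   with median PBF and QDP, per-patient local correlations (voxel-wise and
   per-area), Wilcoxon comparisons of T1 in defect vs normal voxels with
   the relative difference dT1, and the second-order correlation between
   per-patient median T1 and local correlation strength.

Because no patient data are consumed, every stage is validated by recovery
against the phantom's stored ground truth, by closed-form identities, or
by independent brute-force oracles.

# The phantom

## Geometry

Anatomy is defined in physical millimetres (`lung_geometry()`): a torso
ellipse, two lung ellipses (~160 x 300 mm) either side of the midline and
a circular arterial blob between them. Defining geometry continuously
means the same subject can be rasterised at any grid — which is exactly
what the registration-free subdivision scheme is designed to survive, and
what the cross-resolution tests exercise. The default analysis grid is
64 x 64 over a 500 mm field of view (7.8 mm voxels); one coronal slice is
simulated, and the DCE volume extrudes it into eight 5 mm partitions so
slab projection onto the thicker (15 mm) UTE slice is meaningful.

Perfusion defects are drawn as a union of random ellipses (semi-axes
12–35 mm) inside the lungs, grown until a requested fraction of lung
voxels is covered; the final blob is trimmed outermost-first so the
achieved fraction lands within a voxel of the request.

## Two-compartment model of observed T1(TE)

Each lung voxel contains blood and extravascular tissue protons with
volume fractions `f_b + f_t = 1`. The echo time enters through the
compartment weights

    w_i = f_i * exp(-TE / T2*_i),   i in {blood, tissue}

and observed T1 is modelled as the weight-averaged compartment T1,

    T1_obs(TE) = (w_b T1_b + w_t T1_t) / (w_b + w_t).

Defaults: `T1_tissue` 1100 ms, `T1_blood` 1400 ms, `T2*_tissue` 700 us
(short, as in lung parenchyma at 1.5 T), `T2*_blood` 50,000 us,
`f_blood` 0.15. At the shortest echo time (70 us) both compartments
contribute; by 2300 us the parenchyma signal has largely decayed and
T1_obs approaches the blood value, reproducing the gradual rise of
observed T1 with TE expected in well-perfused tissue. Defects shorten
tissue T1 by 15% and reduce the blood fraction to 0.05, so defect voxels
carry shorter observed T1 at every TE.

The weighted-mean construction (rather than a bi-exponential recovery)
was chosen deliberately: it gives the fitter an exactly mono-exponential
target per voxel, so that fit errors measured in recovery tests are
attributable to the fitter and the noise, not to model mismatch.

## Signal models

*Inversion recovery.* `S(TI) = |A − B exp(−TI/T1_obs)| + ε`, with `A`
proportional to the compartment signal weight at that TE and `B = 2A`
(perfect inversion; the factor is configurable to emulate saturation).
Because `B/A = 2`, the Look-Locker-corrected T1 equals the apparent T1,
making the ground truth the exact fit target. The default TI grid
{300, 600, 900, 1200} ms derives from a 300-spoke readout block at
TR 5 ms cut by a 120-spoke sliding window stepped by 60 — four windows
centred at those times. Noise is Gaussian with `sigma = 1/SNR` relative
to the unit short-TE signal (SNR 20 by default); magnitude data are
properly Rician, but at these SNRs the difference is second order and is
accepted as a limitation.

*DCE.* Tissue concentration follows the indicator-dilution forward model

    C_v(t) = dt * sum_{k<=t} AIF(k) * PBF_v * R(t−k),  R(tau) = exp(−tau/MTT)

with MTT 6 s, a gamma-variate AIF (shape 3, scale 1.5 s, onset frame 3,
peak relative enhancement 1) sampled at 20 frames of 1.7 s, and signal
`S = S0 (1 + C) + ε`. True PBF is 0.05 1/s with a +-25% vertical
(gravitational-style) gradient, reduced by 80% inside defects — a 5x
defect contrast. The arterial blob carries the AIF itself, i.e. roughly
an order of magnitude more enhancement than tissue, which is what the
automatic AIF detector keys on. Signal is assumed linear in concentration
(reasonable for a low-dose protocol); no T1-based conversion is applied.

# Numerical choices

**IR fitting.** The three-parameter magnitude model is fitted by
exploiting its structure: for fixed apparent T1 and a fixed count `k` of
pre-zero-crossing samples, the model is linear in (A, B) after restoring
signs, so the fit reduces to a coarse log-spaced grid sweep over T1*
(vectorised across all voxels) followed by a bounded 1D refinement per
voxel with an exact inner linear solve. The reported residual is always
that of the magnitude model, and the refinement is checked in tests
against a brute-force grid search over (A, B, T1*). Fits are flagged
invalid when `A <= 0`, `B <= A`, the optimiser fails, or corrected T1
leaves the plausibility window (100–3000 ms); invalid voxels are excluded
from all downstream medians and correlations. With only four TI samples
at SNR 20 the estimator operates at its information limit: recovery is
exact (<1%) without noise, but the noisy median error is ~13%, matching
the Cramér–Rao bound for this sampling — a denser TI grid, not a better
optimiser, would be required to do better. The same censoring-and-noise
mechanism biases fitted medians low at the longest echo times, where the
signal amplitude itself has decayed towards the noise floor.

**Deconvolution.** The convolution matrix is lower-triangular Toeplitz in
`dt * AIF`; one SVD serves all voxels, with singular values below
`lambda * sigma_max` zeroed (`lambda = 0.15` default, the usual
indicator-dilution choice; exposed in the configuration). No
block-circulant (delay-insensitive) variant is implemented; AIF delay is
handled by onset alignment, a documented limitation. Negative PBF values
arising from truncation are clamped to zero and counted.

**Otsu.** Two thresholds over a 256-bin histogram of R(t_max) within the
lungs, by exhaustive search over bin pairs maximising between-class
variance (cumulative-moment formulation); returned as bin edges. Tests
compare against a naive O(bins^3) reimplementation. Ties in `t_max`
resolve to the earliest frame.

**Slab projection.** The three DCE partitions nearest the UTE slice
centre are averaged — plain mean for continuous maps; for binary defect
maps, majority vote with ties awarded to defect (conservative towards
defect detection; the averaging of label maps is otherwise undefined).
Whole-lung quantities (t_max, Otsu thresholds) are always computed on the
full 3D lungs; QDP compared against T1 is evaluated on the slab only.

**Subdivision.** Lung voxels are totally ordered (vertical coordinate,
then horizontal, i.e. raster order) and cut at exact cumulative-count
boundaries into 10 strips, each re-ordered horizontally and cut into 10
blocks: a deterministic, enumeration-order-invariant partition with area
counts differing by at most one voxel. The price of exact counts is that
strip boundaries split rows: the low-x segment of a boundary row joins
the lower strip, and the split fraction depends on the rasterisation.
Across two rasterisations of the same lung (128 vs 256), area centroids
agree sub-voxel in the median but single boundary-affected areas can
shift by up to ~1.5 coarse voxels; per-area medians of smooth fields
nevertheless transport with Spearman >= 0.95, which is the property the
downstream correlations rely on. "Vertical" is the head–foot image axis
of the coronal slice, per the configuration.

**Spearman and Wilcoxon.** Spearman is Pearson on average ranks, with an
exact permutation p for n <= 9 and the t approximation above; it is
cross-checked against `stats::cor.test` and an independent counting-based
ranking oracle. The Wilcoxon rank-sum comparison delegates to
`stats::wilcox.test` (exact for tie-free groups of <= 8, tie-corrected
normal approximation otherwise) and is checked against full enumeration.
dT1 uses the normal-class median as denominator — the fractional
shortening of defect tissue. No multiple-testing correction is applied
across echo times; significance is p < 0.05.

# The synthetic cohort

`run_cohort()` draws per-subject defect fractions uniformly from
[0.05, 0.45] and baseline tissue T1 from N(1100, 40) ms, simulates each
subject at SNR 20, and runs the full pipeline per subject
(~1,240 lung voxels per slice, five echo times, 22 subjects — sizes
chosen so a cohort completes in about a minute on one CPU). Severity
coupling makes the expected sign structure emerge rather than being
inserted: subjects with more defect burden have lower median T1, lower
median PBF and higher QDP, so median T1 correlates positively with PBF
and negatively with QDP across subjects, while within subjects defect
voxels carry shorter T1 and less flow.

One cohort-level behaviour deserves note. Across this severity range the
correlation between per-subject median T1 and per-subject local
correlation strength comes out *negative*: more defect means more
contrast to correlate. The positive correlation-of-correlations reported
in patient studies reflects a different regime — near-uniformly
destroyed lungs in which little perfusion spread remains, weakening local
correlations precisely where median T1 is lowest. That mechanism is
reproduced in a dedicated statistics test with severities extending to
0.95; it is a property of the severity distribution, not of the
correlation machinery.

# What the phantom does and does not emulate

It emulates: two-lung geometry with connected left/right components; a
TE-dependent compartment structure with defect-coupled T1 shortening;
indicator-dilution contrast passage with a detectable artery and
defect-coupled flow reduction; thin-partition 3D DCE vs thick-slice 2D
UTE geometry; seeded, bit-reproducible noise.

It does not emulate: radial k-space acquisition, NUFFT reconstruction,
sliding-window artefacts or respiratory gating (the pipeline starts from
reconstructed TI-indexed images); Rician noise statistics; real
registration error (deformation fields are inputs — identity or analytic
test fields); respiratory-state mismatch between acquisitions;
signal-concentration nonlinearity, recirculation or bolus dispersion;
B1/coil inhomogeneity. Passing recovery tests therefore demonstrates the
correctness of the estimators under their stated models, not robustness
to every artefact of patient data.

# Reproducibility

Every simulation accepts a seed and restores the caller's RNG state;
identical configuration and seed give bit-identical image stacks and
bit-identical JSON summaries. Outputs embed a 32-bit FNV-1a hash of the
serialised configuration. The numbered drivers under `analysis/` walk the
full chain on one subject and on the 22-subject cohort;
`scripts/acceptance.R --seed <int> --out <path>` recomputes the headline
quantities from scratch.
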
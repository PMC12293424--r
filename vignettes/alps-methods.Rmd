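---
title: "Methods: simulating and measuring the DTI-ALPS index during sleep"
author: "alpsdti"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring the DTI-ALPS index during sleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alpsdti)
```

## The measurement problem

The glymphatic system moves cerebrospinal fluid through perivascular
spaces (PVS), clearing interstitial waste, and is believed to be more
active during sleep. Around the deep medullary veins the PVS runs mainly
left–right (the scanner x axis), sandwiched between projection fibers
(superior corona radiata, oriented along z) and association fibers
(superior longitudinal fasciculus, oriented along y). In a diffusion
tensor acquired there, excess diffusivity along x — over and above the
radial diffusivity of the adjacent tracts — is attributed to water
movement in the PVS. The ALPS index condenses this into one ratio,

$$\mathrm{ALPS} = \frac{\mathrm{mean}(D_{xx}^{proj},\,
D_{xx}^{assoc})}{\mathrm{mean}(D_{yy}^{proj},\, D_{zz}^{assoc})},$$

where each entry is a diagonal tensor element averaged over a small ROI
in the corresponding tract. An isotropic medium gives exactly 1; healthy
awake white matter in this configuration gives roughly 1.4–1.5; the
ratio is dimensionless and invariant under global scaling of the
tensors.

This package implements the full measurement chain as a testable
pipeline on synthetic data: a ground-truth tensor phantom with
sleep-state modulation, two-shell diffusion-weighted (DWI) synthesis
with Rician noise, tensor fitting restricted to the low-b shell,
template-space ROI placement with deterministic refinement, the index
and its component decomposition, EEG-consensus subject inclusion, and
nonparametric time-course statistics.

## The phantom and what it does (and does not) emulate

`phantom_spec()` / `build_phantom()` create a 48 × 48 × 12 voxel grid at
2 mm isotropic resolution with an affine placing the template-mm ROI
coordinates inside two rectangular fiber blocks:

* a **projection block** (principal axis z) and an **association block**
  (principal axis y), both with radial eigenvalue
  $\lambda_\perp = 0.699\times10^{-3}\,\mathrm{mm^2/s}$ and axial
  eigenvalue $1.7\times10^{-3}$ (typical coherent white matter);
* a **perivascular x increment** of $0.301\times10^{-3}$ added to
  $D_{xx}$ in both blocks, so the awake ground-truth index is
  $1.000/0.699 = 1.4306$, matching the awake value of about 1.43
  reported for this ROI configuration in sleep-cohort data (only the
  ratio is anchored; the absolute values are a calibration choice);
* isotropic background at $0.8\times10^{-3}$.

The grid is deliberately small — the analysis is driven entirely by the
ROI geometry, not by brain realism — and the affine stands in for the
nonlinear template registration a real study would use.

Sleep states modulate the phantom multiplicatively
(`apply_state_modulation()`): at each post-notification scan time the x
diffusivities of both blocks are scaled by $1+a_t$ and the perpendicular
components of interest ($D_{yy}$ in the projection block, $D_{zz}$ in
the association block) by $1+b_t$. The default trajectory
(`default_state_trajectory()`) uses the component percent changes
observed in a zolpidem-assisted sleep cohort at 14.46–43.45 min after
sleep notification (x: +6.33, +3.51, +10.57, +5.94, +6.39, +4.51 %;
perpendicular: −11.05, −14.32, −8.04, −3.35, +1.74, −9.53 %). Because
the index is a ratio, the implied ground-truth index changes follow the
exact identity $(1+\Delta_{idx}) = (1+a_t)/(1+b_t)$, e.g. +20.81 % at
19.46 min. The awake baseline scan is placed nominally 9 min before
sleep notification.

The generator does **not** simulate scanner artifacts (eddy currents,
susceptibility distortion, motion), EEG-gel dropout, cardiac pulsation,
partial-volume mixtures, or spatially varying noise — a real study
removes these with dedicated preprocessing before the computation this
package implements begins. Passing tests therefore demonstrate the
correctness and calibration of the measurement and inference chain under
the stated noise model, not robustness to acquisition artifacts.

## DWI synthesis and noise

`synthesize_dwi()` applies the monoexponential tensor forward model
$S = S_0\exp(-b\,g^\mathsf{T} D g)$ over a two-shell protocol
(b = 800 and 2800 s/mm², 30 directions each, 8 b = 0 volumes by
default; directions spread by electrostatic repulsion with antipodal
symmetry, deterministic given a seed). Noise is Rician — the magnitude
of a complex Gaussian perturbation,
$\sqrt{(S+n_1)^2+n_2^2}$ with $\sigma = S_0/\mathrm{SNR}$ — with
Gaussian and noise-free modes retained for oracle tests. The default
SNR of 30 at b = 0 is a typical value for 2 mm single-shot EPI at 3 T;
the protocol itself does not pin one down.

`simulate_cohort()` draws per-subject log-normal multiplicative
perturbations (default CV 3 %) on the four diffusivity components
entering the ratio, constant across a subject's scans. These produce
realistic between-subject spread in the awake index while cancelling
exactly in within-subject percent changes, which mirrors how
repeated-measures designs remove subject effects. One cohort is nine
subjects, one awake scan plus six sleep scans each.

## Tensor fitting

`fit_tensor()` solves the log-linearised model
$\ln S = \ln S_0 - b\,g^\mathsf{T} D g$ per voxel for the six tensor
elements and $\ln S_0$ jointly — estimating $S_0$ as a regression
coefficient keeps one code path and is unbiased under the model. The
default estimator is weighted least squares with one reweighting pass,
weights equal to the squared predicted signals from an initial OLS fit
(the first-order variance model for log-transformed magnitude data);
OLS remains available for oracle comparisons. Voxels containing any
non-positive signal are flagged and excluded from ROI means rather than
failing the fit. Only the b = 800 shell plus the b = 0 volumes enter
the ALPS fit (`select_shell()`, tolerance 50 s/mm²; b < 50 counts as
b = 0). On the noiseless monoexponential phantom the fitted diagonals
are identical whichever shell is used — the restriction is a pure
configuration choice here, though it matters for real tissue where slow
and fast diffusion components separate.

Eigen-decomposition (`eigen_decompose()`) sorts eigenvalues descending,
clamps negative values to zero (flagging the voxel), and fixes the sign
of the primary eigenvector V1 so its largest-magnitude component is
non-negative, with exact ties broken x before y before z.

## ROI placement, refinement, exclusion

`standard_roi_pairs()` encodes the nine left-hemisphere pairs: three
in-plane placements, centers at (x, y) = (−26, −17)/(−37, −17),
(−26, −27)/(−37, −27) and (−26, −29)/(−37, −29) mm, on the three axial
planes z = 29, 30, 31. Coordinates are treated as template-space mm
(the alternative reading, slice indices, is noted as an open point;
with this template the two differ only by the affine). Right-hemisphere
mirrors exist behind a flag but are excluded by default, reflecting the
susceptibility artifacts EEG gel causes there in practice. Nominal ROIs
are 3 mm squares, refined to 2 mm for extraction; voxel membership uses
half-open cubes $[c - e/2,\, c + e/2)$ so that an edge equal to the
voxel size selects exactly one voxel when centered on a voxel center.

Visual ROI quality control is replaced by a deterministic rule
(`refine_and_validate()`): each pair is scored at the nine in-plane
shifts {−1, 0, 1} mm² by the fraction of ROI voxels whose V1 dominant
axis matches the expected tract axis (z for projection, y for
association), taking the pairwise minimum; the best-scoring shift is
kept with ties broken by smallest shift norm, then lexicographically.
Pairs scoring below 0.5 are excluded as misaligned. Reproducibility is
preferred here over fidelity to manual QC; in particular the
vein-intersection check a real study performs on susceptibility-weighted
images is not implementable without vein data and is subsumed by the
V1 alignment score. Refinement runs once per subject, on the awake
scan's eigenvector map, and the chosen voxels are reused at all time
points.

## Sleep annotation and inclusion

Three blinded raters label each 90 s inter-scan epoch awake (0), sleep
(1) or unreadable (U). `consensus_epoch()` applies the strict-majority
(two-of-three) rule, yielding N when no readable label has a majority.
`include_subjects()` admits a subject when, inside the analysis window
(epochs 1–7: awake baseline plus six sleep scans), the first epoch is 0
and all later epochs are 1 — an awakening or an N inside the window
excludes the subject. Applied to the bundled 12-subject example grid
this yields exactly nine analyzable subjects. The window rule is a
reconstruction: published protocols state the outcome (which subjects
enter, which scans are used) rather than the rule, and this is the
simplest rule consistent with it. `fleiss_kappa()` quantifies
inter-rater agreement with unreadable epochs either dropped (default)
or treated as their own category.

## Statistics

The inference stage (`run_full_analysis()`) mirrors standard
small-sample repeated-measures practice:

* **Friedman test** per ROI pair across the seven time points
  (tie-corrected rank statistic against $\chi^2_{k-1}$; a seeded
  within-subject permutation option exists for small designs). With
  n = 9 and k = 7 the $\chi^2$ approximation is well calibrated (the
  suite checks type-I error at the protocol size).
* **Post hoc Wilcoxon signed-rank tests** of each sleep time point
  against the awake baseline, exact by full sign-pattern enumeration
  for up to 15 informative pairs, normal approximation with tie and
  continuity corrections beyond. The post hoc test is an inference from
  the reported effect-size convention; the family for multiplicity is
  the six sleep-vs-awake comparisons within one pair, which is the
  family that reproduces the published worked example of raw versus
  adjusted values.
* **Benjamini–Hochberg** step-up adjustment within that family
  (delegated to `stats::p.adjust`, verified against a literal step-up
  oracle).
* **Effect sizes** $r = |z|/\sqrt{n}$, signed by the median difference,
  with the matched-pairs rank-biserial correlation behind a flag.
  Published effect sizes in this design are not mutually consistent
  with any single convention tried, so r values are reported but not
  treated as reproduction targets.
* **ROI selection** keeps pairs with Friedman p < 0.05 whose peak-time
  index elevation has a strictly positive numerator (x-diffusivity)
  change — an index rise driven solely by a perpendicular-diffusivity
  drop is not counted as perivascular.

The decomposition reported per pair (`decompose_components()`) uses
subject-mean quads, on which the identity
$(1+\Delta_{idx})=(1+\Delta_{num})/(1+\Delta_{den})$ holds exactly; the
first-order reading $\Delta_{idx}\approx\Delta_{num}-\Delta_{den}$ is
accurate to $|\Delta_{num}\Delta_{den}| + O(\Delta_{den}^2)$.

## Numerical choices and degenerate inputs

* Non-positive signals: voxel flagged, excluded from ROI means; an ROI
  with no unflagged voxels raises `empty_roi`.
* Negative eigenvalues: clamped to 0 and flagged.
* Friedman with fully tied rows: statistic 0, p = 1 (the tie-corrected
  denominator would vanish).
* Wilcoxon with all-zero differences: an error (`no_information`), not
  a p-value; fewer than five informative pairs is also an error.
* Degenerate Fleiss input (one category everywhere): $\kappa = 1$ by
  convention, flagged.
* All floating-point TSV output is printed at six significant digits so
  repeated runs are byte-identical.

## Problem sizes and what the tests show

The suite runs entirely on synthetic data generated in code. Unit tests
use a 26 × 25 × 11 voxel phantom with the same geometry and calibration
as the default; the end-to-end recovery checks use the full 48 × 48 × 12
grid with nine subjects and seven time points. At SNR 30 a single
cohort's mean recovered index change at one time point has a sampling
standard deviation of roughly 1.4 percentage points — the intrinsic
noise floor of single-voxel 2 mm ROIs at this SNR and cohort size —
which is why the stochastic recovery checks use a ±2 percentage-point
band while the noiseless identities are checked to 10⁻¹⁰ or better.

## Limitations

Everything upstream of the tensor fit (artifact correction, EEG signal
processing, nonlinear registration, vein imaging) is out of scope and
assumed done; the phantom's rectangular geometry cannot probe
registration error or partial-volume effects; the annotation model
reduces sleep to a binary state, as the underlying EEG quality forces;
and real-data index values depend on acquisition details the synthetic
calibration fixes by construction.
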
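---
title: "Methods: MEG source reconstruction, time-frequency mapping and nonparametric group statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MEG source reconstruction, time-frequency mapping and nonparametric group statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette describes the models and procedures implemented in
`megsource`, the assumptions behind them, the parameters that matter, and
the design decisions taken where the underlying methods literature leaves
choices open. Every empirical claim below is one that the package's test
suite or `scripts/acceptance.R` computes directly.

## The forward model

MEG fields are computed with the closed-form solution for a current
dipole in a spherically symmetric conductor, in its gradient
("radius-free") formulation. With the observation point $r$ and dipole
location $r_q$ taken relative to the sphere center, $a = r - r_q$,

$$F = a\,(r a + r^2 - r_q\cdot r), \qquad
B(r) = \frac{\mu_0}{4\pi F^2}\left(F\, Q\times r_q -
  (Q\times r_q\cdot r)\,\nabla F\right).$$

This form is numerically stable and independent of the sphere radius,
which the package exploits: the model radius is used only for grid
construction and inside tests. Two consequences serve as standing
oracles:

* **Silent sources.** A radially oriented dipole produces exactly zero
  external field; the test suite checks gains of radial dipoles against
  tangential ones at a $10^{-12}$ relative floor.
* **Radial agreement with the free-space dipole.** Volume currents
  contribute nothing to the radial field component, so the radial
  projection of the conductor solution must equal that of the
  Biot–Savart field $\frac{\mu_0}{4\pi} Q\times a/|a|^3$. The
  acceptance suite verifies this over 1,000 random dipole/sensor pairs
  at $10^{-10}$ relative tolerance.

Sensors are magnetometers (field projected on the coil orientation) or
axial gradiometers (first difference of that projection across the
baseline along the coil axis; 50 mm default). A per-channel
("multisphere") center table is supported; with all centers equal it
reproduces the single-sphere gains exactly.

Lead fields are stored either as three Cartesian columns per voxel
(`full3`) or as two columns on a deterministic tangential basis
(`tangential2`, the default, since the radial direction is silent). The
basis convention is $e_1 = \widehat{z \times \hat r}$ unless
$|z \times \hat r| < 10^{-8}$, in which case $e_1 = \hat x$; and
$e_2 = \hat r \times e_1$. The convention is anchored by a unit test
(voxel on $+z$ gives $\{+x, +y\}$) and is continuous away from the
vertical axis. For multisphere models the basis and the inside test use
the mean center. The voxel at the sphere center is excluded from grids
(its tangential plane is undefined and gains there are near-singular),
as are voxels within one spacing of the surface.

## Inverse solutions

All spatial filters share one container (voxels × channels ×
orientations); voxels where a required matrix is singular are *flagged*,
carry `NaN`, are excluded from argmax operations, and the count is
reported. Argmax ties break to the lowest voxel index.

* **LCMV vector**: $W_v = R^{-1}L_v(L_v^\top R^{-1}L_v)^{-1}$ with $R$
  the (regularized) data covariance. The unit-gain constraint
  $W_v^\top L_v = I$ is tested to $10^{-8}$ on random SPD covariances.
* **LCMV scalar** (SAM-style): the orientation maximizing
  noise-normalized output power, i.e. the generalized eigenvector of
  $(L^\top R^{-1}L,\; L^\top R^{-2}L)$ for the largest eigenvalue,
  solved by Cholesky whitening and a symmetric eigensolver. Verified
  against a brute-force 1° orientation sweep.
* **Eigenspace projection**: weights projected onto the top-$k$
  eigenvectors of the data covariance. The signal dimension is a
  required user parameter (nothing in the data pins it down reliably at
  these SNRs; the eigenvalue spectrum is available to choose it).
* **Minimum norm**: $W = L^\top(LL^\top + \lambda C_n)^{-1}$; matches an
  independent Tikhonov least-squares oracle on a toy grid at $10^{-10}$.
* **dSPM**: per-voxel divisor $\sqrt{\mathrm{tr}(W_v^\top C_n W_v)}$.
  With that definition pure-noise input has expected *normalized power*
  1 per voxel (the trace already sums over orientation components); the
  Monte-Carlo test asserts $1 \pm 10\%$.
* **sLORETA**: standardization by the per-voxel resolution block
  $R_v = W_v^\top L_v$; standardized power $\hat s^\top R_v^{-1}\hat s$.
  Its zero-localization-error property for noiseless single sources is
  exercised as a 50-run suite on the full ~1,400-voxel grid (100%
  required).
* **Champagne** (empirical Bayes): scalar variance hyperparameter
  $\gamma_v \ge 0$ per voxel, model covariance
  $\Sigma = C_n + L\,\Gamma L^\top$, fixed-point update
  $\gamma_v \leftarrow \sqrt{\overline{\|\hat s_v\|^2}}\,/\,
  \sqrt{\mathrm{tr}(L_v^\top\Sigma^{-1}L_v)}$ with the posterior mean
  $\hat s_v = \gamma_v L_v^\top \Sigma^{-1} y$. The scalar (isotropic
  per voxel) variant was chosen as the default; a full 3×3 per-voxel
  hyperparameter is a natural extension point but not needed for the
  package's sparse-recovery guarantees. Defaults: `max_iter = 200`,
  `tol = 1e-6` on the relative hyperparameter change, noise covariance
  estimated from the pre-stimulus control window (scaled-identity
  fallback). The marginal log-likelihood is tracked and must be
  nondecreasing within $10^{-6}$ per step; a larger decrease aborts with
  the trace preserved.

A pseudo-Z (noise-normalized power) map accompanies the raw beamformer
power map: unnormalized LCMV power grows toward the sphere center
(deep voxels have weak lead fields and hence large weights), and the
normalized map is what localization tests use.

## Preprocessing and DSSP

Filters are zero-phase (forward–backward) by default: Butterworth order
4, or windowed-sinc FIR (Hamming) with a 3.3/transition-width order
heuristic. Covariances are estimated from per-epoch demeaned segments
pooled over trials; fewer pooled samples than channels sets a
rank-deficiency flag rather than erroring. Regularization adds
$\lambda I$ with $\lambda$ absolute or relative to the mean diagonal.

DSSP (dual signal subspace projection) defines the spatial
"inside-brain" subspace as the top `spatial_dim` left singular vectors
of the stacked lead-field matrix (default 40 of 64 channels), projects
the data onto it and its complement, and compares the two temporal row
spaces by principal angles. Temporal directions with principal
correlation above 0.9 (configurable; or a fixed `n_interference`) are
identified as interference and projected out of the data. Epochs are
concatenated for subspace estimation and re-split afterwards. With
`n_interference = 0` the data pass through bit-identically. The test
measures performance against the known simulated mixing: ≥90%
interference power removed with ≥90% brain-signal power preserved.

## The time-frequency pipeline

Induced (non-phase-locked) activity cancels in the trial average; the
three-step pipeline recovers it per frequency band:

1. **Filter bank**: all trials bandpass filtered; epoch edges trimmed by
   half the filter's effective impulse response (the smallest one-sided
   extent containing 99% of the zero-phase impulse-response energy;
   recorded per band in ms). Analysis windows must leave this margin —
   the tutorial configurations use epochs of −1000 to 1500 ms for
   windows spanning 0–900 ms.
2. **Windowed covariances and weights**: spatial filter weights come
   from the covariance pooled over all active windows plus the control
   window (`weight_source = "combined"`, the default), so active/control
   power differences reflect source power rather than weight
   differences; `active_only` is available.
3. **Assembly**: per active window $w$ and band $b$,
   $P_{\mathrm{act}}[v,w,b] = \mathrm{tr}(W_v^\top C_w W_v)$, control
   power from the control window — or, in condition-contrast mode, from
   the control condition's trials over the *same* windows. The contrast
   is the pseudo-F ratio $(P_{\mathrm{act}} - P_{\mathrm{con}})/
   P_{\mathrm{con}}$, isolated in one function (`pseudo_f()`) because
   ratio-minus-one vs dB conventions differ across tools; a dB view is
   provided for display.

Windows step by `length − overlap` (e.g. 250 ms windows, 50 ms overlap);
a final partial window is dropped by default or clipped to the span end
with `partial = "truncate"`. Batched runs compute band/window tiles
independently and `assemble_outputs()` merges them; single-pass and
tiled results are bit-identical, and missing or conflicting tiles raise
errors naming the gap.

## Functional connectivity

Sensor data are projected through a scalar spatial filter (vector
filters are reduced by the dominant left singular vector of the voxel's
orientation-resolved time course, `reduce = "svd"`). Spectra are
Hann-tapered segment averages: each epoch is one segment in task mode;
resting mode cuts sliding segments (50% overlap default). Metrics:

* imaginary coherence $|\mathrm{Im}(S_{xy}/\sqrt{S_{xx}S_{yy}})|$ —
  insensitive to instantaneous (zero-lag) mixing such as volume
  conduction or beamformer leakage;
* magnitude-squared coherence $|S_{xy}|^2/(S_{xx}S_{yy})$;
* phase lag index $|\overline{\mathrm{sign}\,\mathrm{Im}\,S^{(s)}_{xy}}|$
  over segments;
* general lagged coherence
  $\mathrm{Im}(S_{xy})^2/(S_{xx}S_{yy} - \mathrm{Re}(S_{xy})^2)$;
* amplitude envelope correlation: Pearson correlation of band-limited
  analytic-signal envelopes, plain (non-orthogonalized) variant.

Seed maps support voxel seeds, ROI seeds (metric of the averaged ROI
time course by default — cheaper; per-voxel-metric averaging as an
option), and global connectivity (per-voxel mean over all other voxels,
self-connections excluded). Global averaging transforms through
Fisher-z before the mean and back-transforms, following the common
practice in the global-connectivity literature; a raw mean is retained
as an option.

## Nonparametric group statistics

The group statistic is the pseudo-t $\tilde t = \bar x /
\sqrt{\tilde\sigma^2/N}$ with the voxelwise variance smoothed by a 3-D
Gaussian kernel on the lattice. The conventional "2 cm" kernel is
interpreted as FWHM = 20 mm (exposed as `fwhm_mm`); the kernel is
renormalized over inside voxels so a constant field is preserved despite
the mask. With `fwhm_mm = 0` the statistic equals the textbook
one-sample t exactly (tested at $10^{-12}$).

For one-sample/paired designs the null distribution comes from the
$2^N$ polarity inversions of the subject maps: all of them when
$N \le 12$, otherwise 4,096 distinct random sign vectors (seeded,
identity always included, so attainable p-values are bounded by
$1/\mathrm{count}$). Variance smoothing is recomputed *inside* every
permutation — the statistic's definition includes the smoothing, so the
permuted statistics must too. Per frequency band, the maximum statistic
is pooled over voxels and time windows; FWER-corrected p-values are the
position of each observed value in that max distribution, uncorrected
p-values come from each voxel's own permutation distribution, and FDR is
a Benjamini–Hochberg step-up over all voxels × windows within the band
(the family choice is configurable). Two-sided inference uses maxima of
$|\tilde t|$ by default; a signed one-sided option exists. Note a
discreteness consequence: under the two-sided score each sign vector $s$
and its negation $-s$ give the same $|\tilde t|$, so the smallest
achievable uncorrected p at $N = 5$ is $2/32$; the signed test attains
$1/32$.

The cluster correction thresholds $|\tilde t|$ at a primary threshold,
groups suprathreshold voxels by face-wise (6-)connectivity, and compares
each cluster against the permutation null of the maximum cluster
statistic. The default cluster statistic is the **mass** (sum of
exceedances over the threshold) rather than the size: on desk-scale
grids cluster sizes are small integers and the size statistic is so
discrete that the realized error rate falls far below the nominal level,
while the continuous mass statistic is near-exact (the null calibration
below). Size-based p-values remain available (`cluster_stat = "size"`)
and both numbers are recorded per cluster.

Two-sample designs permute group labels with a pooled smoothed-variance
t; correlation designs permute the covariate (Pearson default, Spearman
option).

**Calibration.** 500 null replicates at $N = 8$, $\alpha = 0.05$ give
FWER and cluster-corrected rejection rates within $[0.03, 0.07]$
(acceptance suite; the script reports ~0.05 for both).

## The simulator and what it does (not) emulate

The generator defines the package's study conditions: 64 radially
oriented axial gradiometers (golden-angle spiral on the upper cap of a
120 mm helmet, 50 mm baseline), an 80 mm conducting sphere, and a 10 mm
grid (~1,400 inside voxels) — a deliberate desk-scale rendition of a
275-channel whole-head system, which is also available
(`make_sensor_array(275)`). Sources are current dipoles:

* *evoked* — a Gaussian-windowed sinusoid, identical in every trial;
* *induced* — a narrowband tone with per-trial random phase and ±20%
  amplitude jitter, raised inside its onset/offset window with 100 ms
  cosine ramps (long ramps keep the tone narrowband; sharp gating would
  splatter onset transients into higher bands);
* *interference* — a continuous external dipole at ≥1.5× the sphere
  radius, propagated with the free-space dipole field (there is no
  conductor around it), with large amplitude (≈10⁴ nA·m at 500 mm in
  the tests, mimicking line-noise-scale contamination).

Sensor noise is white Gaussian, either at a fixed tesla SD or scaled to
a target power SNR of the summed brain signal in its active windows
(SNR 10 in the localization and time-frequency tests — moderately
strong single-trial activity). Brain dipoles must sit at least 1 mm
from the sphere center and one grid spacing below the surface.
Everything is reproducible bit-for-bit from (config, seed).

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: realistic anatomy and BEM conduction,
correlated or structured sensor noise (no cardiac/ocular artifact
waveforms), head movement, sensor calibration errors, multiple
simultaneously active distributed sources, or between-subject anatomical
variability (group maps are exchangeable Gaussian stacks by
construction). Results on real recordings depend on coregistration and
head-model quality in ways these tests cannot probe.

## Numerical choices and degenerate inputs

* Symmetric eigendecompositions throughout; generalized eigenproblems
  via Cholesky whitening; covariance inverses through a symmetric
  eigen-inverse that raises an explicit error on singularity (pointing
  at regularization).
* Covariance regularization in tests and tutorials: 5% of the mean
  diagonal (relative mode); minimum-norm λ defaults are dimensionless
  relative to the mean lead-field power.
* Zero-variance voxels in the pseudo-t: 0/0 is defined as 0; nonzero
  mean with zero variance flags the voxel (NaN).
* `pseudo_f` returns NaN with a flag where control power is exactly 0.
* Container round-trips are bit-lossless and re-validate all class
  invariants on load; corrupt payloads and unknown container versions
  fail loudly. NIfTI export writes outside-mask voxels as NaN so
  thresholding tools ignore them; the sform affine maps 0-based lattice
  indices to mm RAS head-frame coordinates.
* Problem sizes in the default test run: the algebraic suites use a
  32-channel/15 mm mini montage (~100 voxels); localization,
  Champagne, DSSP and time-frequency suites use the full desk-scale
  montage; the statistics calibration uses a ~120-voxel grid with 150
  replicates in the unit suite and 500 in the acceptance suite. These
  sizes were chosen so the entire pipeline remains interactive on a
  laptop while keeping every property statistically decidable.

## Known limitations

* EEG forward modeling (multisphere center optimization against BEM
  potentials) is out of scope; the package is MEG-only.
* BEM/realistic head models, vendor data importers, and GUI
  visualization are out of scope; NIfTI-1 is the only volumetric export.
* Champagne is the scalar-γ variant; heavily correlated sources can
  split or merge hyperparameter mass.
* The AEC implementation is the plain variant; without leakage
  orthogonalization, zero-lag mixing inflates envelope correlations
  (use imaginary coherence or PLI when leakage is a concern).
* Cluster inference uses 6-connectivity only.
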
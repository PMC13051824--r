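---
title: "Tissue diffusivity mapping without CSF partial volume: models, phantoms and reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue diffusivity mapping without CSF partial volume}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdtmap)
```

# The quantity being estimated

A brain voxel at diffusion-MRI resolution rarely contains one tissue.
Near the cortical ribbon it mixes cortex, white matter and CSF, and any
diffusivity estimate anchored at b = 0 — where every compartment
contributes its full signal — inherits the CSF's free-water diffusivity
(~3.0 µm²/ms) in proportion to its volume fraction. The **Mean
Diffusivity of Tissue (MDT)** is instead the log-slope between two high
b-value shells acquired with spherical tensor encoding:

$$\mathrm{MDT} = \frac{\ln s(b_1) - \ln s(b_2)}{b_2 - b_1},
\qquad b_1 = 1500,\; b_2 = 2500\ \mathrm{s/mm^2}.$$

Two properties make this work:

1. **CSF suppression.** A free-water compartment attenuates by
   $e^{-b D}$; at $b = 2500\ \mathrm{s/mm^2}$ and $D = 3.0\ \mu m^2/ms$
   that is $e^{-7.5} \approx 5.5\times10^{-4}$ — under 0.1 % of its
   b = 0 signal. Both shells see essentially zero CSF, so the slope
   between them is a property of the tissue alone.
2. **Orientation independence.** Under spherical (isotropic) b-tensor
   encoding a Gaussian compartment with tensor $D$ attenuates as
   $\exp(-b\,\mathrm{tr}(D)/3)$, regardless of how the tensor is
   rotated. White-matter anisotropy therefore cannot masquerade as a
   diffusivity change, and a single measurement per shell suffices.

For a mixed voxel the package defines the ground truth as the
**CSF-excluded, fraction-weighted mean diffusivity** of the tissue
compartments. This definition is stated prominently because it is what
"tissue diffusivity unconfounded by CSF" has to mean operationally: a
voxel that is 60 % cortex at 0.8 µm²/ms and 40 % CSF has ground truth
0.8, and an ideal estimator should return 0.8 no matter how the CSF
fraction changes. `ground_truth_tissue_md()` implements exactly this,
and the phantom tests assert the invariance.

The residual bias of MDT in a mixed voxel is small but not zero: tissue
itself is multi-exponential across compartments, and the log-slope of a
sum of exponentials lies between the compartment diffusivities. For the
canonical test voxel (70 % tissue at 0.7, 30 % CSF), MDT returns
0.7122 µm²/ms (+1.7 %) while the conventional b = 0–1000 ADC returns
1.0146 µm²/ms (+45 %). A property test verifies that MDT's bias
magnitude stays below ADC's for every CSF fraction up to 0.5.

Units throughout: b in s/mm², diffusivity in µm²/ms, with the explicit
10⁻³ conversion inside the attenuation (1 µm²/ms = 10⁻³ mm²/s). Natural
logarithms are used; the base cancels only if applied consistently, and
this choice is part of the estimator's contract.

# The digital phantom

`build_phantom()` constructs a spherical-head phantom: background, a
subarachnoid CSF rim with sulcal clefts, a cortical ribbon (default
0.8 µm²/ms), a white-matter core (0.7), optional paired deep nuclei
(0.7), and a central CSF ventricle. Defaults for a 48³ mm volume place
the head radius at 44 % of the field of view, the CSF rim at 2 mm, the
ribbon at 3.5 mm and the ventricle at 11 % of the field of view —
proportions that give a miniature but topologically faithful cortex /
CSF / white-matter geography with abundant partial-volume boundary.

Partial volume is the phenomenon under test, so boundaries are not hard
labels: each voxel's compartment fractions come from supersampled
occupancy (3³ = 27 subsamples per voxel by default), giving fractional
mixtures on every tissue interface. The occupancy estimates converge at
rate O(1/supersample); tests compare factor 3 against factor 6 and
against analytic sphere volumes.

Lesions are spheres that shift the per-voxel diffusivity of their
target classes, leaving fractions (anatomy) untouched:
`focal_hyperintense` (+delta on cortex, a dysplasia-like change),
`tumor` (+delta on cortex and white matter), `ischemia` (−delta,
cytotoxic-edema-like). The phantom's diffusivity maps are per-class
arrays, so the ground truth updates automatically and lesion insertion
commutes for disjoint lesions.

What the phantom deliberately does **not** model: gyrification, atlas
anatomy, fat artifacts, susceptibility effects near air interfaces, and
any T2* mechanism. In vivo, iron-rich deep nuclei appear dark through a
relaxation mechanism this simulator does not contain; the deep-nuclei
compartment here only provides a tissue class whose diffusivity can be
manipulated. Passing tests therefore demonstrate correctness of the
estimation chain under Gaussian-compartment physics and Rician noise —
not robustness to the acquisition artifacts real scanners add.

# Acquisition model

The protocol simulated by default is the two-shell high-b scheme:
spherical encoding at b = 0/1500/2500 s/mm² in 1/16/24 repetitions
(TE 110 ms, TR 2100 ms, metadata only), thick slices of 5.2 mm with
1.53 × 1.53 mm² in-plane resolution, acquired in six stack rotations
about the anterior–posterior axis. The rotation angles are not part of
the stated protocol beyond their count; six evenly spaced angles
(0°–150°) are used since even spacing maximizes angular coverage of the
through-plane direction.

One stack is `y = D B R x`: tri-linear resampling onto the rotated
frame, convolution along the stack's slice axis with the slice profile,
decimation to the coarse grid. The slice profile is unknown for any
given sequence and materially affects conditioning; both a Gaussian
with FWHM equal to the slice thickness (default — typical of a
selective excitation) and an ideal boxcar are supported and recorded in
the metadata. Profiles are normalized to unit DC gain. The composite
operator is materialised as a sparse matrix per rotation, which makes
the adjoint exact by construction — the solver's adjoint test then
verifies bookkeeping, not floating-point luck.

Noise is Rician and applied per acquired volume (per repetition), as in
a physical acquisition: magnitude of the complex signal plus
independent Gaussian noise in both channels. At the b = 2500 shell,
tissue retains only ~15–25 % of its b = 0 signal, so at realistic noise
levels (σ = 0.02–0.05 of a unit b = 0 signal) the per-volume SNR is low
enough that the rectified noise floor matters.

**Repetition combination.** The chain applies denoising and averaging
before reconstruction. `average_repetitions()` offers two estimators:
the plain arithmetic mean of magnitudes (`rician_correction = "none"`),
and the default second-moment noise-floor correction
$\hat s = \sqrt{\max(\overline{m^2} - 2\sigma^2, 0)}$, which is exact
in expectation because $E[m^2] = s^2 + 2\sigma^2$ for Rician
magnitudes. The correction was made the default after quantifying the
alternative: with plain averaging at σ = 0.05, the noise floor inflates
the b = 2500 signal most exactly where tissue diffusivity is highest
(lower signal → larger relative rectification), which compresses the
dynamic range of the estimate and erodes lesion contrast from the
+0.138 µm²/ms recovered noiselessly down to +0.02–0.09. The correction
restores the contrast without any spatial filtering, and it collapses
signal-free voxels toward zero so they fall below the estimator's
signal floor and are flagged invalid rather than rendered as fake
tissue. With σ = 0 the two estimators coincide. Averaging always
happens on (corrected) magnitudes before the log; log-then-average is
deliberately not offered, since it would bias the estimate through the
concavity of the log at finite SNR in a less controllable way.
Distortion correction is a documented no-op: the simulator introduces
no distortions.

# Super-resolution reconstruction

Each shell's isotropic volume solves

$$\hat x = \arg\min_x \sum_r \|A_r x - y_r\|^2 + \lambda \|L x\|^2$$

on the normal equations, with `L` either the identity or (default) the
3-D first-difference operator. The regularized least-squares form is a
standard model-based SRR formulation re-derived here — it is labelled a
re-derivation, not a replication of any particular published
implementation, whose exact regularization is not documented in the
sources available to this package. The roles of the pieces:

* **Target grid**: isotropic, default equal to the in-plane spacing
  (1.53 mm), centred on the same world origin as the stacks; spacing
  greater than the slice thickness is rejected.
* **λ (default 10⁻², relative)**: by default λ is scaled by the mean
  diagonal of the data term $\sum_r A_r^\top A_r$, so "10⁻²" means one
  percent of the data-term scale regardless of geometry, repetition
  count or voxel size. An absolute mode exists and is what the dense
  oracle tests use, since their contract is the raw
  $(\sum A^\top A + \lambda I)x = \sum A^\top y$ system.
* **Solver**: a conjugate-residual iteration — the conjugate-direction
  Krylov method that minimizes the residual 2-norm at each step. Plain
  conjugate gradients minimizes the error in the operator norm and its
  residual 2-norm can oscillate; choosing the CR variant makes the
  residual history monotone non-increasing by construction, which is
  asserted as an invariant and makes the convergence diagnostics
  trustworthy. Cost per iteration is identical (one operator
  application). Stopping: relative residual ≤ 10⁻⁶ (default) or the
  iteration cap, in which case a warning is raised and the partial
  result is flagged — non-convergence is reported, never hidden.
* **Initialization**: zeros (default) or a sensitivity-normalized
  back-projection of the stacks.
* **Negativity**: the solver is left linear; small negative intensities
  from ringing are clamped to zero only at the estimation stage.

With fewer than two rotations the through-plane problem is determined
only by the regularizer, and reconstruction refuses to run. Shells
share geometry, so the operators are built once and reused across
shells; rotation order is irrelevant up to float associativity.

Correctness is checked three ways: equivalence with dense
normal-equation solves on instances up to 12³ (10⁻⁶), the adjoint
identity on random vectors (10⁻⁸ relative), and noiseless six-rotation
self-consistency against the generating phantom (< 5 % relative error,
measured at ~1 % on the 16³ fixture).

# Estimation, masking, display

`mdt_map_from_shells()` applies the two-shell formula voxelwise with a
signal floor (default 10⁻⁶): voxels where either shell is at or below
the floor become **invalid**, never clamped — this prevents the noise
floor in signal-free regions (air, suppressed CSF) from masquerading as
low diffusivity. Invalid voxels render as 0 in the display windowing,
which is why CSF is dark on an MDT map. The default display window is
0.5–0.9 µm²/ms; such a tight window is usable precisely because CSF is
nulled — windowing a conventional ADC map this tightly would saturate
everywhere CSF contributes.

Cortical masks are binary volumes resampled onto the map grid with
nearest-neighbour interpolation (binary semantics); scalar maps are
resampled tri-linearly. `pv_bias_report()` stratifies voxels by CSF
fraction (bins of 0.1 up to 0.5) and reports signed bias and RMSE of
MDT and ADC against the CSF-excluded ground truth; empty bins are
omitted (a flag restores them as explicit zero-count rows).

# Study conditions and problem sizes

The simulated validation conditions mirror the protocol: shell scheme
0/1500/2500 s/mm² × 1/16/24 repetitions, 1.53 × 1.53 × 5.2 mm stacks,
six AP rotations, reconstruction at 1.53 mm isotropic. Phantoms are
48³ voxels at 1.0 mm — 1.0 mm so the 1.53 mm acquisition is a genuine
downsampling — for end-to-end runs, with 16³–32³ fixtures for unit and
oracle tests; these sizes resolve every phantom structure by several
voxels while keeping a full six-rotation three-shell pipeline run at
roughly ten seconds. The end-to-end lesion-recovery experiment inserts
a +0.15 µm²/ms focal cortical lesion of 7 mm radius (large enough that
its core survives the ~5 mm through-plane blur), simulates at σ = 0.05
(SNR ≈ 20 at b = 0), and compares the lesion ROI against its
mid-sagittal mirror image; with three seeds the recovered elevation
averages ≈ 0.14 µm²/ms against the inserted 0.15.

# Known limitations

* Compartments are Gaussian: no exchange, kurtosis, or restriction.
  Relaxation weighting is folded into the signal fractions at the
  protocol's fixed TE; fractions are signal fractions, not volume
  fractions.
* Encoding is modeled at the b-tensor level; gradient waveforms,
  Maxwell terms and concomitant-field effects are out of scope.
* The simulator produces none of the artifacts that dominate real MDT
  reading sessions (fat shift bands, air-interface hyperintensities,
  EPI distortions, motion); the distortion-correction hook is a no-op.
* The noise-floor correction assumes the noise level is known (it is,
  in simulation) and spatially uniform; parallel-imaging noise maps
  are not modeled.
* The phantom's deep nuclei do not reproduce the T2*-driven signal
  loss suspected in iron-rich structures; treating them as a low-SNR
  region is possible but speculative, and no claim about iron is
  encoded in the tests.
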
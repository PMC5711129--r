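---
title: "Quasi-4D dose accumulation: model, phantom and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quasi-4D dose accumulation: model, phantom and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Stereotactic body radiotherapy (SBRT) of liver lesions delivers a highly
conformal, inhomogeneous dose to an organ that moves and deforms with every
breath. Conventional plan evaluation is *3D and static*: the dose is
computed once on a static planning image (usually the average intensity
projection, AIP, of a respiratory-correlated 4D CT) and the plan-quality
metrics — Dmean, near-minimum dose D98, near-maximum dose D2, the
homogeneity index HI = D2/D98, and the biologically effective dose (BED) —
are read off that single dose grid. A *quasi-4D* evaluation instead
estimates the dose actually absorbed by each tissue element over the
breathing cycle: the dose delivered in each respiratory phase is mapped
back onto a common reference anatomy through deformable image registration
(DIR), and the warped per-phase doses are averaged with equal weights
(phase bins are equal-time bins):

$$D_{4D}(x) \;=\; \sum_{k=1}^{10} w_k\, D_k\!\bigl(x + u_k(x)\bigr),
\qquad w_k = \tfrac1{10},$$

where $u_k$ is the displacement field mapping reference positions into
phase $k$ (the pull-back convention: the field is evaluated on the
reference grid and points to the source location, so it is directly usable
for resampling). Comparing $D_{4D}$ with the static dose quantifies how
strongly conventional 3D planning misrepresents target coverage,
homogeneity and normal-organ dose in moving anatomy.

`dosewarp` implements this pipeline end to end — phase-image generation,
optical-flow DIR, dose warping, equal-weighted accumulation (including
reduced phase subsets), and DVH-based plan metrics — and exercises it on a
deformable digital liver phantom whose ground-truth displacements are
analytic, so every estimate in the chain can be benchmarked against an
exact oracle.

# The static dose-cloud approximation

A full clinical implementation recalculates the dose on every phase image
with the treatment planning system's dose engine. No dose engine is in
scope here; instead the dose distribution is held **fixed in room
coordinates** across phases ("static dose cloud"), so the per-phase dose
$D_k$ equals the planned static dose $D$. This is the main fidelity gap of
the package: density changes along the beam paths are ignored. In liver —
near-water density, moderate deformation — the approximation is commonly
considered acceptable, and it preserves exactly the interplay the 4D
evaluation quantifies: tissue moving through a steep, spatially fixed dose
gradient. Under the static cloud, the dose "delivered" to reference tissue
element $x$ in phase $k$ is $D(x + u_k(x))$ with $u_k$ the forward motion
of that element, which is also the field a registration of phase $k$ to
the reference estimates.

A second, deliberate consequence: the 3DREF and 3DAIP evaluation arms
share the same dose volume and differ only in contours (normal liver =
liver − GTV for reference-phase contours, liver − ITV for AIP-style
contours), which is exactly the definitional difference between the two
clinical contouring workflows.

# The digital respiratory liver phantom

The generator (`phantom_spec()`, `motion_model()`, `generate_phase_ct()`,
`generate_phase_masks()`) emulates the statistical structure of a 10-phase
abdominal 4D CT:

* **Geometry.** An ellipsoidal soft-tissue body (semi-axes 130 × 110 ×
  135 mm) in air, containing an ellipsoidal liver (75 × 55 × 65 mm) and a
  spherical tumour. The default tumour radius (27.4 mm, 86.2 cm³) matches
  lesion preset "E"; `lesion_presets()` provides five presets spanning
  6.7–86.2 cm³ and 7.5–16.5 mm superior–inferior motion with their
  prescriptions. The tumour sits towards the liver dome. This asymmetry
  matters scientifically: the superior penumbra of the treatment field
  then lies outside the liver while the inferior penumbra lies within it,
  which is what makes the 4D-evaluated normal-liver dose *higher* than the
  static estimate. With a tumour centred in the liver the superior and
  inferior penumbra effects cancel almost exactly and the normal-liver
  comparison degenerates to noise.
* **Motion.** Separable analytic displacement
  $d_k(x) = w_k\,e(x)\,A$ with per-axis amplitudes $A$ (default LR 1.1,
  AP 1.6, SI 10.5 mm — preset "E"), phase waveform $w_k$, and a smooth
  spatial envelope $e(x)$: 1 throughout the liver region, falling to 0 at
  the body surface by a smoothstep in the ellipsoidal body coordinate
  (0.8 → 1.0). The zero-displacement boundary keeps the couch-side edge
  fixed. The default waveform is $w_k = (1+\cos 2\pi k/10)/2$ — 0 at the
  end-expiration reference phase (50%), 1 at end-inspiration (0%). Real
  breathing is asymmetric with a longer exhale dwell; a `cos4` option is
  provided. Any waveform here is a stand-in: clinical phase bins are
  equal-time bins of a measured respiratory signal, and the choice is
  recorded in the study provenance.
* **Intensities.** Tissue HU (air −1000, soft tissue 40, liver 60, tumour
  100) evaluated at the analytically inverted pulled-back position (the
  inverse of the forward map is found by a fixed-point iteration, 8
  sweeps), plus three components that make the images *registrable* and
  CT-like: a smooth advected texture (sum of three oblique plane waves,
  40 HU amplitude, ≈25 mm wavelength) standing in for hepatic and
  soft-tissue structure — without it the organ interiors are uniform and
  the optical-flow aperture problem leaves the interior field
  unconstrained; a Gaussian reconstruction point-spread blur (σ = 2 mm)
  emulating scanner partial-volume effects — without it the one-voxel,
  1000-HU air–tissue step punishes sub-voxel registration error at the
  static body surface more than any alignment gain elsewhere; and seeded
  i.i.d. Gaussian noise (SD 10 HU) drawn independently per phase.
* **Dose.** A conformal distribution built from the PTV mask:
  $D = D_{\max} G(x)$ with $D_{\max} = \text{prescription}/\text{covering
  isodose}$ (default 42 Gy / 0.80 = 52.5 Gy). $G$ is a Gaussian blur
  (penumbra σ = 5 mm) of the PTV indicator, rescaled so the covering
  isodose surface passes through the PTV's 95%-volume depth and clamped at
  1; thus D95(PTV) equals the prescription by construction and the
  exterior fall-off is a Gaussian tail. A broad low-dose halo (peak 12% of
  $D_{\max}$, σ = 45 mm, combined by voxel-wise maximum) emulates
  entrance/exit beam dose through the host organ; without it the normal
  liver's median dose is exactly zero and DVH-ratio comparisons over its
  [D98, D50] range are undefined. Setting `halo_fraction = 0` recovers
  the pure conformal component.

What the phantom does **not** emulate: realistic CT texture libraries,
breathing hysteresis (inhale/exhale path asymmetry), sliding at the
chest-wall interface, irregular breathing, and density changes requiring a
dose engine. Passing tests on this phantom therefore demonstrate the
correctness and internal consistency of the accumulation machinery under
smooth, invertible, one-parameter respiratory motion — not clinical
registration accuracy on patient images.

# Deformable registration

`register_volumes()` is a multi-resolution Horn–Schunck optical flow.
Both images are linearly rescaled to [0, 1] over a shared HU window
(−200, 300) bracketing soft-tissue contrast. At each pyramid level
(default 3 levels, subsampling 4×/2×/1× with anti-alias smoothing) the
current field warps the source, the brightness-constancy term is
linearised there, and red–black Gauss–Seidel sweeps with over-relaxation
(ω = 1.6) solve the Horn–Schunck update for the *total* field, so the
global smoothness prior acts on the absolute displacement. The gradient of
the data term averages warped-source and target gradients, which keeps a
restoring force where the warped image has drifted past an edge into a
flat region. Fields are stored in mm and are world-anchored, so upsampling
between levels is plain trilinear interpolation of each component.

Defaults (all overridable via `registration_params()`): 400 sweeps per
level, relinearised every 20; smoothness weight α = 0.05 in
normalised-intensity-per-voxel units; 0.7-voxel presmoothing at the finest
level; convergence tolerance 10⁻⁴ mm mean update. These were fixed by
known-transform recovery experiments on the phantom: a uniform 3 mm
translation of a smooth body-sized blob at 3 mm spacing is recovered with
mean error well under half a voxel, registering an image to itself yields
mean |u| < 0.05 voxel, and the estimated phase-to-reference fields on the
default phantom land within ≈0.5 mm (mean, inside the liver) of the
analytic truth. Substantially larger α under-resolves the envelope decay
near the body wall; substantially smaller α lets image noise roughen the
field. The algorithm is fully deterministic — zero initialisation, no
sampling — so identical inputs give bit-identical fields.

Registration quality is summarised by whole-volume Pearson
cross-correlation before/after warping (`cross_correlation()`; an ROI
variant exists). A decrease raises a warning, not an error.

# DVH and plan metrics

* **Cumulative DVH** (`compute_dvh()`): uniform bins, default width
  0.01 Gy — small enough that rounding of D2/D98 is far below the 0.1 Gy
  precision plan metrics are usually quoted at. The curve starts at 1 and
  is non-increasing by construction.
* **Dx** (`dose_at_volume()`): the largest dose received by at least x% of
  the volume, with linear interpolation between bin edges; this matches
  the "prescribed dose to at least 95% of volume" reading of D95 and is
  monotone in x.
* **Dmean** is the voxel mean over the structure (identical to the
  DVH-derived mean up to binning).
* **BED** (`bed_from_dvh()`): applied bin-wise to the differential DVH,
  $\mathrm{BED}_i = n d_i (1 + d_i/(\alpha/\beta))$ with $d_i$ the bin's
  per-fraction dose; `bed_mean` is the volume-weighted mean. α/β defaults:
  10 Gy for target structures, 2 Gy for late normal-liver toxicity. For a
  uniform dose this reduces to the closed form `bed()`, which is why
  uniform worked examples validate the DVH route. As α/β → ∞, BED → D.
* **HI = D2/D98** and the 3D-to-4D percentage ratio `hi_ratio_percent()`
  are computed from unrounded inputs; re-dividing independently rounded
  table values can drift in the last printed digit.
* **Reduced-phase convergence** (`dvh_fractional_volume_ratio()`): the
  ratio of fractional volumes between a subset accumulation and the
  10-phase reference, sampled on the reference bins over [D98, D50] of the
  reference curve; the summary is max |ratio − 1|.

# Target construction

GTVs are delineated on the two extreme phases; the ITV defaults to their
**union** — the ITV concept envelops the excursion, and target volumes
larger than the GTV are only consistent with a union — with an
`itv_mode = "intersection"` switch preserving the literal alternative
reading. PTV = ITV + 5 mm isotropic margin by Euclidean voxel-centre
dilation (`expand_margin()`), which is deterministic and exactly
checkable against a brute-force distance oracle; differences from
surface-distance dilation are sub-voxel.

# Numerical and convention choices

* Axes are fixed as (x = LR, y = AP, z = SI); world = origin +
  index·spacing, 0-based indices, no rotation. NRRD is the primary file
  format (MetaImage accepted); vector fields are 4D NRRD with the
  3-vector axis first. DICOM is deliberately unsupported.
* Trilinear interpolation everywhere; out-of-grid dose samples are 0 Gy
  (dose outside the computed grid is physically negligible), out-of-grid
  CT samples clamp to the nearest edge to avoid spurious air values.
* Maximum point-dose differences are normalised to the prescription dose
  by default (a local-dose normalisation is a trivial rescale); whether to
  normalise to prescription or local dose is a genuinely open convention.
* Equal phase weights are the default and the scientific case; arbitrary
  non-negative weights summing to 1 (tolerance 10⁻⁹) are accepted.
* Every stage is a pure function of its inputs and the seed; rerunning a
  seeded study produces byte-identical CSV/JSON reports.

# Problem sizes

The reference study conditions are the 96³ grid at 3 mm spacing (the
default `phantom_spec()`), ten phases, nine registrations; a full
`run_study()` takes a few minutes on one core. The test suite exercises
the complete pipeline at this size once and uses a 40³/4 mm down-scaled
phantom for the per-module checks; oracle comparisons (interpolation,
dilation, DVH counting) run on ≤ 30³ grids where brute force is exact.

# Known limitations

* The static dose cloud ignores density-driven dose changes; organ-at-risk
  results far from the target inherit the halo model rather than real
  beam geometry.
* The phantom's body surface is intentionally motionless, which makes the
  whole-volume cross-correlation a much harsher registration summary than
  on patient images, where large visible misalignment dominates the
  pre-registration value.
* Reduced-phase subsets are evaluated against the same waveform they
  subsample. The odd five-phase subset contains no sample at the
  end-inspiration extreme for any waveform symmetric about
  end-expiration, so its deviation from the 10-phase reference can exceed
  the three-phase subset's — a sampling property of the subset scheme
  itself (it persists when the analytic true fields replace the estimated
  ones), not a defect of the accumulation. The three-phase subset stays
  well within the 5% acceptability band on the default phantom.
* Motion is one-parameter and hysteresis-free; registration accuracy
  measured here does not transfer to sliding interfaces or irregular
  breathing.
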
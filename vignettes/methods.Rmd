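---
title: "Methods: quantifying whether an initial SRS planning CT can be reused at repeat treatment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying whether an initial SRS planning CT can be reused at repeat treatment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the measurement chain

Patients receiving stereotactic radiosurgery (SRS) for brain metastases
often return for further courses. Each course conventionally starts with a
fresh planning CT, yet the anatomy that matters for intracranial SRS — the
skull, which anchors localization, and the bulk tissue density, which
drives dose calculation — changes little between courses. If the *initial*
CT (iCT) were demonstrably interchangeable with the repeat CT (rCT), the
repeat course could be planned on the repeat MR (rMR) plus the archived
iCT.

"Interchangeable" is quantified along four axes, each a module of this
package:

1. **Targeting accuracy** (`register_rigid`, `residual_chain`). Targets are
   contoured on the rMR, so the rMR must land on the iCT correctly. Three
   rigid registrations are run — rMR→rCT on all anatomy, rMR→iCT primarily
   on bone, iCT→rCT — and the chain residual
   `R = T_a^{-1} ∘ T_c ∘ T_b` measures the discrepancy between routing the
   rMR through the iCT versus registering it directly. Under the working
   assumption that the iCT→rCT registration is essentially exact (the skull
   is rigid), the translation magnitude of `R` is the targeting
   uncertainty added by reusing the iCT.
2. **Skull stability** (`skull_profile`, `profile_difference`). From each
   target, 16 rays (8 at 45° increments in the transverse plane, 8 more
   elevated 45°) are traced to the proximal inner skull surface on both
   CTs; per-ray path-length differences quantify anatomical change of the
   localization reference itself.
3. **Scan similarity** (`mutual_information_normalized`, `pearson`).
   Histogram-based normalized mutual information and voxelwise Pearson
   correlation between the registered iCT and the rCT, read against
   comparison groups with known ground truth (same scan, resampled copy,
   different patient).
4. **Dosimetric accuracy** (`gamma_map`). The plan dose computed in the rCT
   frame is compared against the dose recomputed in the iCT frame and
   mapped back, via the 3D gamma index at 1 mm distance-to-agreement and 1%
   of the global maximum dose, evaluating only points above 10% of that
   maximum, on a 0.2 mm grid.

Everything runs on synthetic head phantoms, so every stage has an analytic
oracle; the `analysis/` scripts chain the stages into a small simulated
cohort study.

## Geometry and transform conventions

Volumes are axis-aligned grids in DICOM LPS patient coordinates (x left,
y posterior, z superior); `origin` is the world position of the first voxel
*center*. Oblique direction cosines are rejected rather than silently
reoriented — head scans are acquired near-axial, and refusing obliquity
keeps every geometric test exact.

Rigid motions use the planning-report parameterisation: translations in mm
and roll/pitch/yaw in degrees, with roll about the superior–inferior axis,
pitch about the left–right axis, yaw about the anterior–posterior axis,
composed as fixed-axis `R = R_yaw · R_pitch · R_roll`, applied about an
explicit center. Because translation components are center-dependent
whenever rotations are non-zero, every transform carries its center,
operations refuse to mix centers implicitly (`recenter_transform` converts),
and reported residuals state the center they refer to (the fixed image's
geometric center by default). Decomposition is unique for |pitch| < 90°,
far beyond any head-repositioning rotation.

Resampling is pull-back: `resample_volume(img, T)` fills each output voxel
with `img` interpolated at `T(x)`. Trilinear weights within 10⁻⁷ voxel of a
lattice point are snapped, so identity resampling is bit-lossless — which
in turn makes the degenerate self-case of the whole pipeline exactly
self-consistent (profile differences identically 0, NMI exactly 1, gamma
identically 0).

## The synthetic cohort: what it emulates, and what it does not

`make_head_phantom` builds concentric-ellipsoid heads (default outer
semi-axes 90/110/80 mm, 6 mm bone shell) with air at −1000 HU, brain at
40 HU, cortical bone at 1000 HU, contrast-enhancing spherical GTVs at
+60 HU, and an optional air cavity standing in for sinuses. Interfaces are
rendered with 2× supersampled partial-volume averaging: a voxel straddling
brain and bone receives the occupancy-weighted HU, reproducing the ~1-voxel
edge ramp of real CT. This matters: sub-voxel edge localization (and hence
the ray-trace oracle accuracy) is impossible against binary steps, and real
scanners do not produce binary steps.

`simulate_rescan` applies a known rigid motion, adds fresh Gaussian noise
(default 3 HU, truncated at the −1000 HU physical floor), and adds a
+20 HU offset inside a sphere of twice the GTV radius around each target —
soft tissue only, skull untouched — emulating the contrast-timing and
edema differences observed between scan dates, which are on the order of
20 HU and local to the target. `derive_mr` maps HU through a fixed
piecewise-linear lookup (air ≈ 0, brain ≈ 600, enhancing GTV ≈ 900,
cortical bone ≈ 80 — the T1 ordering with bone dark and enhancing lesions
brightest) plus noise (σ = 20 on a 0–1000 scale, i.e. brain SNR ≈ 30),
with geometry untouched so the true MR↔CT alignment is the identity and
cross-modality registration error is directly measurable.

`make_srs_dose` is the dose surrogate: prescription (20 Gy) exactly inside
the PTV (GTV + 1 mm), Gaussian falloff `Rx·exp(−(r−r_PTV)²/2σ²)` with
σ = 2 mm outside, on a 1 mm planning grid. The generator *errors* if the
voxelized PTV coverage at prescription drops below 98% — the plan objective
is a contract, not a hope. This surrogate reproduces what the gamma
analysis stresses — a flat core with SRS-grade gradients (≈30%/mm of the
maximum near the PTV edge) — while having a closed form for oracles. It is
not an arc-based calculation: beam-specific effects (MLC penumbra
anisotropy, heterogeneity corrections through bone) are out of scope, so
gamma results here validate the *comparison machinery*, not a dose engine.

Default problem sizes are a deliberate compromise: phantoms are
96×112×88 voxels at 2 mm (the full suite of registrations, ray traces and
gamma maps on a laptop core in minutes). The measurement chain is
resolution-agnostic; nothing in the code assumes these sizes.

## Registration: automated stand-in for a manual clinical step

The clinical workflow this models used a commercial registration console
with physicist adjustment. The package substitutes a deterministic
automated optimizer: normalized mutual information
`NMI = 2·I(A;B)/(H(A)+H(B))` over a joint histogram (48 bins per axis
during optimization), maximized by Nelder-Mead over the 6 parameters
through a 3-level block-mean pyramid (×4, ×2, ×1), each level seeded from
the previous, with a restart guard that re-seeds from the user's initial
transform when that scores better (coarse grids are slightly biased; the
guard guarantees an exact optimum at the init — e.g. self-registration —
is never lost). All overlap voxels enter the histogram; there is no
stochastic subsampling, so results are bit-reproducible. Histogram bin
edges span each image's whole in-field intensity range rather than the
per-pose overlap range — otherwise the objective jumps whenever the
overlap window shifts. In bone mode the histogram is restricted to the
fixed CT's thresholded (≥200 HU) and 1-voxel-dilated skull mask,
implementing "registration primarily on bony anatomy" as a hard mask; a
soft weighting would be another defensible reading, but clinical usage
does not define "primarily" and a hard mask is testable.

Measured performance on the default phantoms: CT–CT recovery of random
motions (|t| ≤ 5 mm, |rot| ≤ 3°) has median error well below 0.05 mm /
0.05°; MR→CT bone-mode recovery sits below 0.1 mm in the median with rare
excursions (the acceptance gate is the median, at the 0.3 mm / 0.6 mm
scale of clinically reported residuals). One known artifact is documented
rather than hidden: with a noisy moving image, trilinear interpolation
smooths noise at off-lattice poses, which *raises* MI slightly and can
displace the all-anatomy optimum by ~0.2–0.4 mm — the classic MI
interpolation artifact. It sets the floor of the degenerate-case residual
chain (~0.4 mm) and is of the same order as the irreducible residuals the
clinical workflow reports.

## Ray tracing and edge localization

Rays are sampled at 0.2 mm by trilinear interpolation. The inner skull
surface is the first *rising* crossing of the `hu_cross` level whose
centered finite-difference directional gradient reaches 100 HU/mm (a noise
blip is not an edge), with the crossing refined by linear interpolation
between bracketing samples. `hu_cross` defaults to 520 HU — the
half-maximum between brain (~40) and cortical bone (~1000). The midlevel
choice is deliberate: crossing a partial-volume edge ramp at its center
localizes the surface without bias, whereas a low absolute threshold
(e.g. 300 HU, ~27% of the ramp) systematically undershoots by roughly half
a voxel and fails the closed-form ray–ellipsoid oracle. All three edge
parameters remain exposed for CTs whose bone HU differs. A ray that leaves
the field of view without a qualifying edge returns a failure flag, not an
exception; profiles with more than 4 failed rays carry a warning flag.

The oblique octet's elevation sign is a genuinely open geometric choice
(the scheme diagram does not fix it); all-superior is the default with
inferior and alternating available.

## Gamma: definition, search cap, and the oracle

For every reference point `r` above the low-dose threshold,

γ(r) = min over evaluated points e of sqrt( ‖e−r‖²/DTA² + (D_eval(e) − D_ref(r))²/(dd·D_max)² )

with `D_max` the reference's global maximum (global normalization) and the
threshold applied to the reference only. The repeat-CT dose is the
reference by default — it is the ground truth a fresh scan would have
provided — and the convention is a flag, since gamma is asymmetric. The
optimized search visits candidates in order of increasing distance and
stops exactly when the distance term alone exceeds the running minimum, so
within the search radius it is value-identical to exhaustive search; the
default 3×DTA radius is exact for pass/fail and for all γ ≤ 3 (any farther
candidate carries γ > 3 from distance alone). `gamma_brute` — exhaustive,
no pruning, small grids only — is kept as the in-package oracle, and the
equivalence tests widen the search radius to the whole grid so the two
must agree to 10⁻⁶ everywhere, not just below 3.

One subtlety the tests encode: a rigid sub-DTA shift with unchanged dose
values yields a perfect passing rate *when the shift is an integer number
of evaluation-grid steps* (then every reference point has an exact dose
match within DTA). For non-lattice shifts, discrete sampling in a
30%-per-mm gradient can interpose up to `gradient × spacing/2` of dose
mismatch — several times a 1% criterion at 0.2 mm spacing — so the
pure-shift checks use a 0.5 mm shift on a 0.1 mm grid. This is a property
of lattice gamma itself, shared by any implementation that does not
interpolate the evaluated distribution.

## Statistics

Pearson `r` between per-case metrics and inter-scan time uses the exact
two-sided t transform on n−2 degrees of freedom, with the conventional
strength bands (|r| < 0.4 weak, 0.4–0.7 intermediate, > 0.7 strong) and
significance at 0.05. The similarity context bands are configuration, not
constants: absolute MI values are implementation-specific, so only
within-implementation orderings (same scan > resampled > rescan >
different patient) are asserted anywhere in the package.

## Degenerate inputs and numerical edges

Constant images have zero entropy: NMI and PC raise errors rather than
return 0/0. Registration refuses image pairs with no field-of-view overlap
under the initial transform and flags (rather than hides) hitting the
iteration cap. Out-of-field resampling fills with −1000 HU for CT and 0
otherwise, and the in-field mask rides along so overlap statistics never
mix fill values with data. Gamma errors when no reference point exceeds
the threshold. The dose generator errors when voxelization breaks the
98% coverage objective. Noise truncation at −1000 HU is the only
non-Gaussian feature of the phantom noise model.

## Known limitations

* File I/O is NIfTI plus CSV target lists; DICOM series/RTDOSE/RTSTRUCT
  parsing is a declared extension point, not implemented here.
* Targets are spheres (centroid + radius). The analyses use centroids and
  margins only, so contoured-structure support would change I/O, not
  mathematics.
* The dose surrogate is isotropic; no beam/arc modelling, no heterogeneity
  corrections, no DVH metrics beyond PTV coverage.
* Phantoms are ellipsoids with uniform tissues: passing tests demonstrate
  the correctness of the measurement chain under known ground truth, not
  clinical performance on real anatomy — real skulls have variable
  thickness and marrow, real MRs have bias fields, and real registrations
  inherit both. A concrete consequence: within-tissue texture is pure
  noise, so interpolation decorrelates it and the "resampled same scan"
  similarity group can rank below a registered same-head pair on phantoms,
  unlike on clinical cohorts where parenchymal texture survives
  resampling.
* Rigid transforms only; deformable anatomy (resection cavities, mass
  effect) is explicitly outside the model, as it is outside the clinical
  rationale for reusing an iCT.
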
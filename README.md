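# srsrescan

Quantitative feasibility analysis for reusing the **initial** stereotactic
radiosurgery (SRS) planning CT at **repeat** treatments.

Patients with brain metastases frequently return for further SRS courses.
The skull — the localization reference for frameless intracranial SRS — and
the bulk tissue density that drives dose calculation are nearly unchanged
between courses, which suggests the repeat course could be planned on a
fresh MR plus the *archived* initial CT (iCT), skipping the repeat CT (rCT).
This package implements the measurement chain that turns "nearly unchanged"
into numbers, for medical physicists and imaging researchers:

* **Targeting accuracy** — rigid 6-DOF registration (normalized mutual
  information, multi-resolution, deterministic) of the repeat MR to both
  CTs plus the iCT→rCT registration, combined into the residual chain
  `R = T_a⁻¹ ∘ T_c ∘ T_b`; `|t(R)|` is the targeting uncertainty added by
  routing target contours through the iCT.
* **Skull stability** — 16 rays per target (8 transverse at 45°
  increments, 8 elevated 45°) traced to the proximal inner skull surface
  with gradient-gated, sub-voxel edge detection; per-ray path-length
  differences between the registered CTs.
* **Scan similarity** — normalized mutual information
  `NMI = 2·I(A;B)/(H_A+H_B)` (identical sets score exactly 1) and Pearson
  correlation over the voxel overlap, read against comparison-group bands.
* **Dosimetric accuracy** — 3D gamma index with global normalization:
  `γ(r) = min_e √(‖e−r‖²/DTA² + (D_eval(e)−D_ref(r))²/(dd·D_max)²)`,
  at 1 mm / 1% with a 10% low-dose threshold on a 0.2 mm evaluation grid,
  plus an exhaustive brute-force oracle.
* **Synthetic cohort** — digital head phantoms (partial-volume rendered
  ellipsoidal skulls, enhancing GTV spheres, optional sinus), repeat CTs
  under known rigid motion with noise and a +20 HU contrast/edema
  perturbation, T1-like MRs, and an analytic 20 Gy SRS dose surrogate with
  a ≥98% PTV-coverage contract — so every stage runs and is tested with no
  external data.

## Worked example

A seeded repeat-treatment case: the repeat CT is the same head moved by a
known rigid transform with fresh noise and a +20 HU perturbation around the
target; the repeat MR is derived from it; the full per-case pipeline runs
all three registrations, the residual chain, skull ray tracing, similarity
scoring, and per-target gamma.

```r
library(srsrescan)

ph  <- make_head_phantom(phantom_spec(noise_sigma = 2))
Tt  <- rigid_transform(2.5, -1.5, 1, 1, -0.8, 1.2,
                       center = image_center(ph$ct))
rct <- simulate_rescan(ph, Tt, noise_sigma = 3, local_hu_offset = 20, seed = 9)
rmr <- derive_mr(rct, seed = 5)
tg  <- target(as.numeric(transform_points(Tt, c(30, 0, 10))), 8)

run_case(ph$ct, rct, rmr, targets = list(tg))
#> <case_report case>
#>   residual |t| = 0.382 mm
#>   skull profile mean |diff| = 0.005 mm
#>   iCT/rCT similarity: NMI 0.9019, PC 1.0000
#>   gamma passing: mean 1.0000 (range 1.0000-1.0000, n=1)
```

Reading: routing the repeat-MR contours through the initial CT adds
0.38 mm of targeting uncertainty (sub-voxel; the scale reported for manual
clinical registrations is ~0.6 mm); the target-to-inner-skull distances
agree to 0.005 mm on average over 16 rays (the skull is stable); NMI of
0.90 between the registered CTs reflects noise and the local contrast
change (identical scans score exactly 1.0); and 100% of evaluated dose
points pass 1 mm / 1% gamma — the dosimetric signature of an
interchangeable CT.

The `analysis/` scripts chain this into a small simulated cohort study and
write flat CSV tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R      # cases: iCT, rCT, rMR, targets
Rscript analysis/02_targeting_accuracy.R   # residual-displacement table
Rscript analysis/03_skull_raytrace.R       # per-ray skull distances + summary
Rscript analysis/04_similarity_groups.R    # MI/PC context groups + time trend
Rscript analysis/05_gamma_dosimetry.R      # gamma passing rates + time trend
Rscript analysis/06_full_case_report.R     # aggregated per-case JSON report
```

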
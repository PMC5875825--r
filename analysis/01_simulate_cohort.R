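#!/usr/bin/env Rscript

# Build a small synthetic repeat-SRS cohort: for each case an initial CT
# (iCT), a repeat CT (rCT) of the same head under a known rigid motion, a
# post-contrast T1-like repeat MR (rMR) aligned with the rCT, and the target
# list. Head geometry (skull size, thickness, sinus) varies per case so that
# "different patient" comparisons mean something; the iCT and rCT carry
# independent noise realizations of the same underlying anatomy, with the
# rCT additionally perturbed by +20 HU around each target (contrast/edema
# surrogate). Everything downstream (registration, ray tracing, similarity,
# gamma) reads these files, so the whole analysis is reproducible from here.

suppressPackageStartupMessages(library(srsrescan))

out_root <- "results/cases"
dir.create(out_root, showWarnings = FALSE, recursive = TRUE)

n_cases <- 5
set.seed(20240901)

manifest <- data.frame()
for (i in seq_len(n_cases)) {
  case_dir <- file.path(out_root, sprintf("case%02d", i))
  dir.create(case_dir, showWarnings = FALSE)

  semi <- c(90, 110, 80) + runif(3, -8, 8)
  thickness <- runif(1, 5, 8)
  inner <- semi - thickness
  n_targets <- sample(1:2, 1)
  targets <- lapply(seq_len(n_targets), function(k) {
    # keep the whole GTV comfortably inside the inner skull surface
    target(runif(3, -0.4, 0.4) * inner, gtv_radius = runif(1, 5, 9),
           id = sprintf("t%d", k))
  })
  spec <- phantom_spec(skull_outer_radii = semi, skull_thickness = thickness,
                       noise_sigma = 0, seed = 100 + i, targets = targets,
                       air_cavity = list(center = c(0, -0.55, -0.45) * inner,
                                         radius = runif(1, 8, 14)))
  ph <- make_head_phantom(spec)

  # two independent scans of the same head: the iCT as acquired, and the
  # rCT after a mask-repositioning-scale motion with its own noise
  ict <- simulate_rescan(ph, rigid_transform(), noise_sigma = 2,
                         local_hu_offset = 0, seed = 400 + i)
  tr <- runif(3, -4, 4); ro <- runif(3, -2, 2)
  Tt <- rigid_transform(tr[1], tr[2], tr[3], ro[1], ro[2], ro[3],
                        center = image_center(ph$ct))
  rct <- simulate_rescan(ph, Tt, noise_sigma = 2, local_hu_offset = 20,
                         seed = 200 + i)
  rmr <- derive_mr(rct, seed = 300 + i)

  # targets are contoured on the repeat MR, i.e. in the rCT frame
  targets_rct <- lapply(targets, function(tg)
    target(as.numeric(transform_points(Tt, tg$centroid)), tg$gtv_radius,
           tg$ptv_radius - tg$gtv_radius, tg$id))

  write_volume(ict, file.path(case_dir, "ict.nii.gz"))
  write_volume(rct, file.path(case_dir, "rct.nii.gz"))
  write_volume(rmr, file.path(case_dir, "rmr.nii.gz"))
  write_targets(targets_rct, file.path(case_dir, "targets.csv"))

  true_pars <- srsrescan:::transform_params(Tt)
  manifest <- rbind(manifest, data.frame(
    case = sprintf("case%02d", i), n_targets = n_targets,
    days_between_scans = round(runif(1, 65, 700)),
    t(true_pars)))
  cat(sprintf("%s: %d target(s), true motion |t| = %.2f mm\n",
              sprintf("case%02d", i), n_targets,
              sqrt(sum(true_pars[1:3]^2))))
}
write.csv(manifest, file.path("results", "cohort_manifest.csv"),
          row.names = FALSE)
cat(sprintf("wrote %d cases under %s\n", n_cases, out_root))
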
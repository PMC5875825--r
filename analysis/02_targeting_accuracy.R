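#!/usr/bin/env Rscript

# Targeting accuracy: how well can targets contoured on the repeat MR be
# placed on the initial CT? Three registrations per case (rMR->rCT on all
# anatomy, rMR->iCT on bone, iCT->rCT) and the residual-displacement chain:
# if routing the rMR through the iCT landed targets exactly where the direct
# rMR->rCT registration does, the residual would be zero. The translation
# magnitude of the residual is the targeting-uncertainty figure of merit.

suppressPackageStartupMessages(library(srsrescan))

cases <- list.dirs("results/cases", recursive = FALSE)
stopifnot(length(cases) > 0)

rows <- list()
for (cd in cases) {
  ict <- load_volume(file.path(cd, "ict.nii.gz"), "CT")
  rct <- load_volume(file.path(cd, "rct.nii.gz"), "CT")
  rmr <- load_volume(file.path(cd, "rmr.nii.gz"), "MR")
  ctr <- image_center(rct)

  T_a <- register_rigid(rmr, rct, "all_anatomy")$transform
  T_b <- register_rigid(rmr, ict, "bone")$transform
  T_c <- register_rigid(ict, rct, "all_anatomy")$transform
  res <- residual_chain(recenter_transform(T_a, ctr),
                        recenter_transform(T_b, ctr),
                        recenter_transform(T_c, ctr))
  rows[[cd]] <- data.frame(case = basename(cd),
                           x_mm = res$tx, y_mm = res$ty, z_mm = res$tz,
                           roll_deg = res$roll, pitch_deg = res$pitch,
                           yaw_deg = res$yaw, magnitude_mm = res$magnitude)
  cat(sprintf("%s: residual |t| = %.3f mm, rotations (%.3f, %.3f, %.3f) deg\n",
              basename(cd), res$magnitude, res$roll, res$pitch, res$yaw))
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/residual_displacements.csv", row.names = FALSE)
cat(sprintf("\nresidual translation magnitude over %d cases: %.2f +/- %.2f mm (range %.2f-%.2f)\n",
            nrow(tab), mean(tab$magnitude_mm), sd(tab$magnitude_mm),
            min(tab$magnitude_mm), max(tab$magnitude_mm)))
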
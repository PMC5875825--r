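#!/usr/bin/env Rscript

# Scan similarity in context: NMI and Pearson correlation between the
# registered iCT and the rCT of each case, bracketed by comparison groups
# with known ground truth — the same scan against itself, the same scan
# resampled on a slightly shifted grid, and scans of entirely different
# heads. Only the ordering of these groups is meaningful: absolute MI values
# depend on the histogram implementation, which is why identical image sets
# (similarity exactly 1) are the only hard anchor. Also tests whether
# similarity of the registered pair degrades with time between scans.
#
# One phantom-specific caveat: within-tissue texture here is pure noise, so
# a half-voxel resample decorrelates it and the "resampled" group can score
# below the registered same-head pair — real parenchymal texture survives
# interpolation, which is why clinical cohorts rank resampled copies higher.

suppressPackageStartupMessages(library(srsrescan))

cases <- list.dirs("results/cases", recursive = FALSE)
manifest <- read.csv("results/cohort_manifest.csv")
stopifnot(length(cases) > 0)

rows <- list()
add <- function(group, case, s) {
  rows[[length(rows) + 1]] <<- data.frame(group = group, case = case,
                                          mi = s$mi, pc = s$pc,
                                          n_overlap = s$n_overlap)
}

prev_ct <- NULL
for (cd in cases) {
  ict <- load_volume(file.path(cd, "ict.nii.gz"), "CT")
  rct <- load_volume(file.path(cd, "rct.nii.gz"), "CT")

  add("same scan", basename(cd), similarity_report(ict, ict))

  shifted <- resample_volume(ict, rigid_transform(0.5, 0.5, 0.5),
                             target_grid = ict)
  add("same scan, resampled", basename(cd), similarity_report(ict, shifted))

  T_c <- register_rigid(ict, rct, "all_anatomy")$transform
  ict_on_rct <- resample_volume(ict, invert_transform(T_c), target_grid = rct)
  add("same patient, different day", basename(cd),
      similarity_report(rct, ict_on_rct))

  if (!is.null(prev_ct))
    add("different patient", basename(cd), similarity_report(ict, prev_ct))
  prev_ct <- ict
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/similarity_groups.csv", row.names = FALSE)

cat("group means (the ordering, not the absolute values, is the result):\n")
agg <- aggregate(cbind(mi, pc) ~ group, tab, mean)
agg <- agg[order(-agg$mi), ]
print(agg, row.names = FALSE)

reg <- tab[tab$group == "same patient, different day", ]
reg$days <- manifest$days_between_scans[match(reg$case, manifest$case)]
ct <- correlate_with_time(reg$mi, reg$days)
cat(sprintf("\nMI vs days between scans: r = %.2f (%s), p = %.3f%s\n",
            ct$r, ct$strength, ct$p,
            if (ct$significant) " *" else ""))
write.csv(data.frame(metric = "mi_vs_days", r = ct$r, p = ct$p,
                     strength = ct$strength, significant = ct$significant),
          "results/similarity_time_correlation.csv", row.names = FALSE)
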
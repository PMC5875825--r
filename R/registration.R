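#' Bone mask of a CT volume
#'
#' Voxels at or above `hu_threshold` (default 200 HU, below trabecular bone
#' but far above brain/CSF), dilated by one voxel (6-connectivity) so the
#' bone-brain interface — where the registration signal lives — is included.
#' Used to restrict the similarity objective when registering "primarily on
#' bony anatomy".
#'
#' @param ct a CT `volume_image`
#' @param hu_threshold HU level (default 200)
#' @param dilate dilation steps (default 1; 0 gives the bare threshold mask)
#' @return logical array; errors if no voxel qualifies
#' @export
bone_mask <- function(ct, hu_threshold = 200, dilate = 1L) {
  stopifnot(is_volume_image(ct))
  if (ct$modality != "CT") stop("bone_mask requires a CT volume")
  m <- ct$voxels >= hu_threshold
  if (!any(m)) stop("empty bone mask: no voxel reaches the HU threshold")
  if (dilate < 1L) return(m)
  d <- dim(m)
  out <- m
  # one-voxel 6-neighbour dilation via shifted copies
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}

#' Registration options
#'
#' @param levels downsampling factors, coarse to fine (default 4, 2, 1)
#' @param n_bins histogram bins for the NMI objective (fewer at coarse levels
#'   would also work; one value keeps the objective comparable across levels)
#' @param maxit Nelder-Mead iteration cap per level, coarse to fine: the
#'   coarse levels do the searching, the finest level only refines an
#'   already-subvoxel estimate (its evaluations are the expensive ones)
#' @param reltol Nelder-Mead relative convergence tolerance
#' @param step_mm,step_deg initial simplex scale for translations/rotations
#' @return list of options for [register_rigid()]
#' @export
registration_options <- function(levels = c(4L, 2L, 1L), n_bins = 48L,
                                 maxit = c(500L, 400L, 250L), reltol = 1e-7,
                                 step_mm = 2, step_deg = 2) {
  maxit <- rep_len(as.integer(maxit), length(levels))
  list(levels = as.integer(levels), n_bins = as.integer(n_bins),
       maxit = maxit, reltol = reltol,
       step_mm = step_mm, step_deg = step_deg)
}

# NMI objective for a candidate pose. pose = (tx,ty,tz,roll,pitch,yaw) of the
# PULL-BACK map fixed-world -> moving-world about `center`. Bin ranges are
# fixed per level (whole-image in-field ranges) so the objective is smooth in
# the pose rather than jumping when the overlap window changes; the fixed
# image's bin indices are precomputed once per level.
nmi_objective <- function(pose, fbin, fgeom, moving, center, n_bins,
                          mrange, mask_idx) {
  T <- rigid_transform(pose[1], pose[2], pose[3], pose[4], pose[5], pose[6],
                       center = center)
  A <- transform_affine(T)
  r <- cpp_nmi_affine(fbin, fgeom$dims, fgeom$spacing, fgeom$origin,
                      moving$voxels, dim(moving$voxels),
                      moving$spacing, moving$origin, A, n_bins,
                      mrange[1], mrange[2], mask_idx)
  if (is.na(r$nmi) || r$n_overlap < 32) return(NA_real_)
  r$nmi
}

bin_indices <- function(values, lo, hi, n_bins) {
  i <- as.integer(floor((as.numeric(values) - lo) / max(hi - lo, 1e-12) * n_bins))
  i[i < 0L] <- 0L
  i[i >= n_bins] <- n_bins - 1L
  i
}

value_range <- function(img, fill) {
  v <- img$voxels[infield_mask(img)]
  v <- v[v != fill]
  if (!length(v)) v <- img$voxels
  range(v)
}

#' Rigid 6-DOF intensity-based registration
#'
#' Maximizes normalized mutual information over translations and rotations
#' with a 3-level multi-resolution pyramid (block-mean downsampled by the
#' factors in `opts$levels`) and Nelder-Mead at each level, seeded from the
#' previous level's optimum. In `"bone"` mode the objective is evaluated only
#' inside [bone_mask()] of the fixed image — the "register primarily on bony
#' anatomy" step of the repeat-MR workflow. Fully deterministic: no stochastic
#' histogram subsampling, fixed evaluation order.
#'
#' The returned transform maps moving-image world coordinates into the fixed
#' image's frame (moving -> fixed), reported about the fixed image's center.
#'
#' @param moving,fixed `volume_image`s with overlapping fields of view
#' @param mode `"all_anatomy"` or `"bone"`
#' @param init initial `rigid_transform` (moving -> fixed) estimate
#' @param opts see [registration_options()]
#' @return a `registration_result`: `transform`, `final_similarity`
#'   (`similarity_report` on the fixed grid), `converged`, `iterations`
#' @export
register_rigid <- function(moving, fixed, mode = c("all_anatomy", "bone"),
                           init = rigid_transform(),
                           opts = registration_options()) {
  mode <- match.arg(mode)
  stopifnot(is_volume_image(moving), is_volume_image(fixed))
  center <- image_center(fixed)
  # optimize the pull-back map S: fixed-world -> moving-world; S = invert(result)
  init_S <- invert_transform(recenter_transform(init, center))
  pose <- unname(transform_params(init_S))
  ffill <- if (fixed$modality == "CT") -1000 else 0
  mfill <- if (moving$modality == "CT") -1000 else 0
  frange_full <- value_range(fixed, ffill)
  mrange <- value_range(moving, mfill)
  mask_full <- if (mode == "bone") bone_mask(fixed) else NULL

  iterations <- 0L
  converged <- TRUE
  for (li in seq_along(opts$levels)) {
    lev <- opts$levels[li]
    f_lev <- if (lev > 1L) downsample_volume(fixed, lev) else fixed
    mask_idx <- integer(0)
    if (!is.null(mask_full)) {
      # recompute the mask at this level's resolution from the downsampled CT
      mask_lev <- if (lev > 1L) bone_mask(f_lev) else mask_full
      mask_idx <- which(mask_lev) - 1L
    }
    frange <- if (lev > 1L) value_range(f_lev, ffill) else frange_full
    fbin <- bin_indices(f_lev$voxels, frange[1], frange[2], opts$n_bins)
    fgeom <- list(dims = dim(f_lev$voxels), spacing = f_lev$spacing,
                  origin = f_lev$origin)
    obj <- function(p) {
      v <- nmi_objective(p, fbin, fgeom, moving, center, opts$n_bins,
                         mrange, mask_idx)
      if (is.na(v)) 1 else -v  # no-overlap poses are heavily penalized
    }
    if (is.na(nmi_objective(pose, fbin, fgeom, moving, center, opts$n_bins,
                            mrange, mask_idx)))
      stop("no field-of-view overlap between images under the initial transform")
    # restart guard: if the user-supplied init scores better at this level
    # than the pose carried from the coarser one (coarse grids are slightly
    # biased), start from the init — an exact optimum there is never lost
    init_pose <- unname(transform_params(init_S))
    if (!identical(init_pose, pose) &&
        isTRUE(obj(init_pose) < obj(pose))) pose <- init_pose
    sc <- c(rep(opts$step_mm, 3), rep(opts$step_deg, 3)) * lev / max(opts$levels)
    fit <- stats::optim(pose, obj, method = "Nelder-Mead",
                        control = list(maxit = opts$maxit[li],
                                       reltol = opts$reltol,
                                       parscale = sc))
    pose <- fit$par
    iterations <- iterations + fit$counts[["function"]]
    if (li == length(opts$levels) && fit$convergence != 0L) converged <- FALSE
  }
  S <- rigid_transform(pose[1], pose[2], pose[3], pose[4], pose[5], pose[6],
                       center = center)
  result_T <- invert_transform(S)
  aligned <- resample_volume(moving, S, target_grid = fixed, fill = mfill)
  sim <- similarity_report(fixed, aligned)
  structure(list(transform = result_T, final_similarity = sim,
                 converged = converged, iterations = iterations,
                 mode = mode),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("<registration_result> mode %s, %s, %d objective evaluations\n",
              x$mode, if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(x$transform)
  cat(sprintf("  final NMI %.4f, PC %.4f over %d voxels\n",
              x$final_similarity$mi, x$final_similarity$pc,
              x$final_similarity$n_overlap))
  invisible(x)
}

#' Residual displacement of the three-registration consistency chain
#'
#' The repeat-course targeting chain registers the repeat MR both directly to
#' the repeat CT (`T_a`: rMR -> rCT) and via the initial CT (`T_b`: rMR ->
#' iCT, then `T_c`: iCT -> rCT). If every registration were perfect the two
#' routes would agree; the residual `R = invert(T_a) o T_c o T_b` is the
#' transform left over on the rMR after routing through the iCT versus going
#' directly, and its translation magnitude is the targeting-uncertainty
#' figure of merit. All three transforms must share one rotation center;
#' reported translation components depend on that center.
#'
#' @param T_a rMR -> rCT transform
#' @param T_b rMR -> iCT transform
#' @param T_c iCT -> rCT transform
#' @return a `residual_displacement`: `magnitude` (mm), `tx`, `ty`, `tz`,
#'   `roll`, `pitch`, `yaw`
#' @export
residual_chain <- function(T_a, T_b, T_c) {
  if (!same_center(T_a, T_b) || !same_center(T_a, T_c))
    stop("transforms must share one rotation center; recenter_transform() first")
  R <- compose_transform(invert_transform(T_a), compose_transform(T_c, T_b))
  structure(list(magnitude = sqrt(R$tx^2 + R$ty^2 + R$tz^2),
                 tx = R$tx, ty = R$ty, tz = R$tz,
                 roll = R$roll, pitch = R$pitch, yaw = R$yaw,
                 center = R$center),
            class = "residual_displacement")
}

#' @export
print.residual_displacement <- function(x, ...) {
  cat(sprintf(
    "<residual_displacement> |t| = %.3f mm; t = (%.3f, %.3f, %.3f) mm; roll/pitch/yaw = (%.3f, %.3f, %.3f) deg\n",
    x$magnitude, x$tx, x$ty, x$tz, x$roll, x$pitch, x$yaw))
  invisible(x)
}
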
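#' Case-analysis configuration
#'
#' Bundles every tunable of the per-case workflow with its default so a
#' `case_report` can record exactly what produced it.
#'
#' @param registration_opts see [registration_options()]
#' @param bone_hu_threshold HU threshold of the bone mask
#' @param raytrace_step,raytrace_hu_cross,raytrace_grad_min edge-detection
#'   parameters of [trace_to_skull()]
#' @param raytrace_elevation oblique-ray scheme, see [ray_directions()]
#' @param n_bins similarity histogram bins
#' @param gamma see [gamma_criteria()]
#' @param dose see [dose_spec()]
#' @param skull_change_warn_mm mean profile difference (mm) above which the
#'   report flags the skull-stability assumption as violated
#' @return a `case_config` list
#' @export
case_config <- function(registration_opts = registration_options(),
                        bone_hu_threshold = 200,
                        raytrace_step = 0.2, raytrace_hu_cross = 520,
                        raytrace_grad_min = 100,
                        raytrace_elevation = "superior",
                        n_bins = 64L,
                        gamma = gamma_criteria(),
                        dose = dose_spec(),
                        skull_change_warn_mm = 2) {
  structure(list(registration_opts = registration_opts,
                 bone_hu_threshold = bone_hu_threshold,
                 raytrace_step = raytrace_step,
                 raytrace_hu_cross = raytrace_hu_cross,
                 raytrace_grad_min = raytrace_grad_min,
                 raytrace_elevation = raytrace_elevation,
                 n_bins = as.integer(n_bins),
                 gamma = gamma, dose = dose,
                 skull_change_warn_mm = skull_change_warn_mm),
            class = "case_config")
}

#' Run the full per-case feasibility analysis
#'
#' Executes the complete workflow for one repeat-treatment case:
#' \enumerate{
#'   \item register rMR -> rCT (all anatomy) and rMR -> iCT (bone mode),
#'     register iCT -> rCT, and form the [residual_chain()] quantifying the
#'     rMR-to-iCT targeting uncertainty;
#'   \item ray-trace 16 target-to-inner-skull distances on the iCT and on the
#'     registered rCT per target and compare profiles (skull stability);
#'   \item score NMI and Pearson correlation between the registered iCT and
#'     the rCT (scan similarity);
#'   \item per target, compare the rCT dose against the dose recomputed in
#'     the iCT frame and mapped back through the estimated registration, via
#'     3D gamma at the configured criteria.
#' }
#' The supplied rCT dose (or, when `dose_rct` is `NULL`, the analytic
#' surrogate built from each target) is the gamma reference. Any stage
#' failure is recorded by name and the report emitted with partial results.
#'
#' @param ict,rct,rmr `volume_image`s (initial CT, repeat CT, repeat MR)
#' @param targets list of [target()]s defined in the rCT frame
#' @param dose_rct optional DOSE `volume_image` in the rCT frame; default
#'   builds the analytic surrogate per target
#' @param config a [case_config()]
#' @param case_id label recorded in the report
#' @return a `case_report` with elements `registrations`, `residual`,
#'   `profiles`, `profile_comparisons`, `similarity`, `gamma`, `gamma_summary`,
#'   `skull_stability_flag`, `errors`, `provenance`
#' @export
run_case <- function(ict, rct, rmr, targets, dose_rct = NULL,
                     config = case_config(), case_id = "case") {
  stopifnot(is_volume_image(ict), is_volume_image(rct), is_volume_image(rmr),
            length(targets) >= 1L)
  report <- list(case_id = case_id)
  errors <- character(0)
  note <- function(stage, e) {
    errors <<- c(errors, sprintf("%s: %s", stage, conditionMessage(e)))
    NULL
  }
  opts <- config$registration_opts

  reg_a <- tryCatch(register_rigid(rmr, rct, "all_anatomy", opts = opts),
                    error = function(e) note("register rMR->rCT", e))
  reg_b <- tryCatch(register_rigid(rmr, ict, "bone", opts = opts),
                    error = function(e) note("register rMR->iCT", e))
  reg_c <- tryCatch(register_rigid(ict, rct, "all_anatomy", opts = opts),
                    error = function(e) note("register iCT->rCT", e))
  report$registrations <- list(rmr_to_rct = reg_a, rmr_to_ict = reg_b,
                               ict_to_rct = reg_c)

  report$residual <- if (!is.null(reg_a) && !is.null(reg_b) && !is.null(reg_c)) {
    tryCatch({
      ctr <- image_center(rct)
      residual_chain(recenter_transform(reg_a$transform, ctr),
                     recenter_transform(reg_b$transform, ctr),
                     recenter_transform(reg_c$transform, ctr))
    }, error = function(e) note("residual chain", e))
  }

  # align the iCT onto the rCT frame once; skull profiles and similarity both
  # need it. reg_c$transform maps iCT -> rCT, so the pull-back is its inverse.
  ict_on_rct <- if (!is.null(reg_c))
    tryCatch(resample_volume(ict, invert_transform(reg_c$transform),
                             target_grid = rct, fill = -1000),
             error = function(e) note("resample iCT", e))

  report$profiles <- list()
  report$profile_comparisons <- list()
  if (!is.null(ict_on_rct)) {
    for (tg in targets) {
      cmp <- tryCatch({
        p_i <- skull_profile(ict_on_rct, tg, config$raytrace_step,
                             config$raytrace_hu_cross, config$raytrace_grad_min,
                             config$raytrace_elevation)
        p_r <- skull_profile(rct, tg, config$raytrace_step,
                             config$raytrace_hu_cross, config$raytrace_grad_min,
                             config$raytrace_elevation)
        report$profiles[[tg$id]] <- list(ict = p_i, rct = p_r)
        profile_difference(p_i, p_r)
      }, error = function(e) note(sprintf("skull profile %s", tg$id), e))
      if (!is.null(cmp)) report$profile_comparisons[[tg$id]] <- cmp
    }
  }
  mean_diffs <- vapply(report$profile_comparisons,
                       function(x) x$mean_abs_diff, 0)
  report$skull_stability_flag <-
    length(mean_diffs) > 0 && any(mean_diffs > config$skull_change_warn_mm)

  report$similarity <- if (!is.null(ict_on_rct))
    tryCatch(similarity_report(rct, ict_on_rct, config$n_bins),
             error = function(e) note("similarity", e))

  report$gamma <- list()
  if (!is.null(reg_c)) {
    for (tg in targets) {
      g <- tryCatch({
        ref <- if (is.null(dose_rct)) make_srs_dose(tg, config$dose) else dose_rct
        # the plan is transferred to the iCT frame through the estimated
        # registration, "recomputed" there, and mapped back for comparison:
        # any registration imperfection shows up as a dose displacement.
        to_ict <- invert_transform(reg_c$transform)
        ref_fine <- resample_dose_fine(ref, config$gamma$fine_spacing)
        if (is.null(dose_rct)) {
          c_ict <- as.numeric(transform_points(to_ict, tg$centroid))
          dose_ict <- make_srs_dose(target(c_ict, tg$gtv_radius,
                                           tg$ptv_radius - tg$gtv_radius,
                                           tg$id),
                                    config$dose)
        } else {
          dose_ict <- resample_volume(dose_rct, reg_c$transform,
                                      target_grid = dose_rct, fill = 0)
        }
        eval_fine <- resample_volume(dose_ict, to_ict, target_grid = ref_fine,
                                     fill = 0)
        gamma_map(ref_fine, eval_fine, config$gamma)
      }, error = function(e) note(sprintf("gamma %s", tg$id), e))
      if (!is.null(g)) report$gamma[[tg$id]] <- g
    }
  }
  report$gamma_summary <- if (length(report$gamma))
    summarize_gamma(report$gamma)

  report$errors <- errors
  report$partial <- length(errors) > 0
  report$provenance <- list(schema_version = 1L,
                            config = config,
                            grids = list(ict = dim(ict$voxels),
                                         rct = dim(rct$voxels),
                                         rmr = dim(rmr$voxels)),
                            n_targets = length(targets),
                            package_version = as.character(
                              utils::packageVersion("srsrescan")))
  class(report) <- "case_report"
  report
}

#' @export
print.case_report <- function(x, ...) {
  cat(sprintf("<case_report %s>%s\n", x$case_id,
              if (x$partial) " [PARTIAL]" else ""))
  if (!is.null(x$residual))
    cat(sprintf("  residual |t| = %.3f mm\n", x$residual$magnitude))
  if (length(x$profile_comparisons)) {
    md <- vapply(x$profile_comparisons, function(p) p$mean_abs_diff, 0)
    cat(sprintf("  skull profile mean |diff| = %s mm%s\n",
                paste(sprintf("%.3f", md), collapse = ", "),
                if (isTRUE(x$skull_stability_flag)) "  ** skull-stability flag **" else ""))
  }
  if (!is.null(x$similarity))
    cat(sprintf("  iCT/rCT similarity: NMI %.4f, PC %.4f\n",
                x$similarity$mi, x$similarity$pc))
  if (!is.null(x$gamma_summary))
    cat(sprintf("  gamma passing: mean %.4f (range %.4f-%.4f, n=%d)\n",
                x$gamma_summary$mean, x$gamma_summary$min,
                x$gamma_summary$max, x$gamma_summary$n))
  for (e in x$errors) cat("  error -", e, "\n")
  invisible(x)
}

#' Correlate a per-case metric with elapsed time
#'
#' Pearson correlation with the two-sided p-value from the exact t transform
#' on n - 2 degrees of freedom, classified into the conventional strength
#' bands: |r| < 0.4 weak, 0.4 <= |r| <= 0.7 intermediate, |r| > 0.7 strong;
#' significance at `alpha`.
#'
#' @param values per-case metric (e.g. MI, PC, gamma passing rate)
#' @param times elapsed days between scans, same length
#' @param alpha significance level (default 0.05)
#' @return a `correlation_verdict`: `r`, `p`, `strength`, `significant`, `n`
#' @export
correlate_with_time <- function(values, times, alpha = 0.05) {
  values <- as.numeric(values); times <- as.numeric(times)
  if (length(values) != length(times)) stop("values and times differ in length")
  if (length(values) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(values) == 0 || stats::sd(times) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(values, times, method = "pearson",
                        alternative = "two.sided")
  r <- unname(ct$estimate)
  strength <- if (abs(r) < 0.4) "weak"
              else if (abs(r) <= 0.7) "intermediate"
              else "strong"
  structure(list(r = r, p = ct$p.value, strength = strength,
                 significant = ct$p.value < alpha, n = length(values),
                 alpha = alpha),
            class = "correlation_verdict")
}

#' @export
print.correlation_verdict <- function(x, ...) {
  cat(sprintf("<correlation_verdict> r = %.3f (%s), p = %.4g (%ssignificant at %.2g), n = %d\n",
              x$r, x$strength, x$p, if (x$significant) "" else "not ",
              x$alpha, x$n))
  invisible(x)
}

#' Read a volume from NIfTI
#'
#' Decodes geometry (spacing from pixdim, origin from the sform/qform
#' translation) and enforces the package's axis-aligned assumption: files
#' with oblique direction cosines are rejected, not silently reoriented.
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`)
#' @param modality `"CT"`, `"MR"`, or `"DOSE"`
#' @return a `volume_image`
#' @export
load_volume <- function(path, modality = c("CT", "MR", "DOSE")) {
  modality <- match.arg(modality)
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  R <- xf[1:3, 1:3]
  spacing <- sqrt(colSums(R^2))
  dircos <- sweep(R, 2, spacing, "/")
  if (max(abs(abs(dircos) - diag(3))) > 1e-4 || any(diag(dircos) < 0))
    stop("oblique or flipped orientation: only axis-aligned LPS-like volumes are supported")
  origin <- as.numeric(xf[1:3, 4])
  volume_image(array(as.numeric(img), dim = dim(img)[1:3]), spacing, origin,
               modality)
}

#' Write a volume to NIfTI
#'
#' @param img a `volume_image`
#' @param path output path (`.nii` / `.nii.gz`)
#' @return `path`, invisibly
#' @export
write_volume <- function(img, path) {
  stopifnot(is_volume_image(img))
  arr <- img$voxels
  nim <- RNifti::asNifti(arr)
  RNifti::pixdim(nim) <- img$spacing
  xf <- diag(4)
  diag(xf)[1:3] <- img$spacing
  xf[1:3, 4] <- img$origin
  nim <- RNifti::`sform<-`(nim, structure(xf, code = 2L))
  nim <- RNifti::`qform<-`(nim, structure(xf, code = 2L))
  RNifti::writeNifti(nim, path, datatype = "double")
  invisible(path)
}

#' Read a target list from CSV
#'
#' Expected columns: `id`, `x`, `y`, `z` (mm, rCT frame), `gtv_radius_mm`,
#' optional `margin_mm` (default 1).
#' @param path CSV file
#' @return list of [target()]s
#' @export
read_targets <- function(path) {
  df <- utils::read.csv(path)
  need <- c("id", "x", "y", "z", "gtv_radius_mm")
  if (!all(need %in% names(df)))
    stop("targets CSV must have columns id, x, y, z, gtv_radius_mm")
  margin <- if ("margin_mm" %in% names(df)) df$margin_mm else rep(1, nrow(df))
  lapply(seq_len(nrow(df)), function(i)
    target(c(df$x[i], df$y[i], df$z[i]), df$gtv_radius_mm[i], margin[i],
           id = df$id[i]))
}

#' Write a target list to CSV
#' @param targets list of [target()]s
#' @param path output CSV
#' @return `path`, invisibly
#' @export
write_targets <- function(targets, path) {
  df <- do.call(rbind, lapply(targets, function(tg)
    data.frame(id = tg$id, x = tg$centroid[1], y = tg$centroid[2],
               z = tg$centroid[3], gtv_radius_mm = tg$gtv_radius,
               margin_mm = tg$ptv_radius - tg$gtv_radius)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
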
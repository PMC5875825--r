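#' Spherical target (GTV + margin)
#'
#' Targets are modelled as spheres: a gross tumor volume (GTV) of radius
#' `gtv_radius` around `centroid`, expanded by `margin` (default 1 mm) to the
#' planning target volume (PTV), matching single-isocenter SRS practice for
#' small intracranial metastases.
#'
#' @param centroid world position (mm)
#' @param gtv_radius GTV radius, mm > 0
#' @param margin PTV expansion, mm >= 0 (default 1)
#' @param id optional label
#' @return a `target` object with `ptv_radius = gtv_radius + margin`
#' @export
target <- function(centroid, gtv_radius, margin = 1, id = NULL) {
  centroid <- as.numeric(centroid)
  if (length(centroid) != 3L || any(!is.finite(centroid)))
    stop("centroid must be 3 finite values (mm)")
  gtv_radius <- as.numeric(gtv_radius)
  margin <- as.numeric(margin)
  if (!is.finite(gtv_radius) || gtv_radius <= 0) stop("gtv_radius must be > 0")
  if (!is.finite(margin) || margin < 0) stop("margin must be >= 0")
  structure(list(centroid = centroid, gtv_radius = gtv_radius,
                 ptv_radius = gtv_radius + margin,
                 id = if (is.null(id)) "t1" else as.character(id)),
            class = "target")
}

#' Digital head-phantom specification
#'
#' Concentric-ellipsoid head model: an outer skull ellipsoid (semi-axes
#' `skull_outer_radii`), a bone shell of uniform `skull_thickness`, uniform
#' brain inside, optional air cavity (sinus surrogate), and contrast-enhanced
#' spherical GTVs. HU defaults: air -1000, brain 40, cortical bone 1000, with
#' +60 HU enhancement inside GTVs. Geometry is analytic so ray-trace and
#' volume oracles have closed forms.
#'
#' @param skull_outer_radii outer ellipsoid semi-axes (x,y,z) mm
#' @param skull_thickness shell thickness mm (subtracted from each semi-axis)
#' @param hu_air,hu_brain,hu_skull tissue HU values
#' @param hu_target_enhancement HU added inside each GTV
#' @param air_cavity optional `list(center=, radius=)` sphere at air HU
#' @param targets list of [target()] objects, all strictly inside the inner
#'   skull surface
#' @param dims,spacing,origin voxel lattice; default 2 mm isotropic,
#'   96 x 112 x 88 voxels centered on the skull center (`origin = NULL`
#'   centers the grid on 0)
#' @param noise_sigma additive Gaussian HU noise s.d.
#' @param seed RNG seed for the noise
#' @param antialias integer supersampling factor for partial-volume surface
#'   rendering (default 2): tissue interfaces get the ~1-voxel intensity ramp
#'   real CT shows instead of a binary step. 1 disables.
#' @return a `phantom_spec` list
#' @export
phantom_spec <- function(skull_outer_radii = c(90, 110, 80),
                         skull_thickness = 6,
                         hu_air = -1000, hu_brain = 40, hu_skull = 1000,
                         hu_target_enhancement = 60,
                         air_cavity = NULL,
                         targets = list(target(c(30, 0, 10), 8)),
                         dims = c(96L, 112L, 88L), spacing = c(2, 2, 2),
                         origin = NULL, noise_sigma = 0, seed = 1L,
                         antialias = 2L) {
  skull_outer_radii <- as.numeric(skull_outer_radii)
  if (skull_thickness <= 0 || skull_thickness >= min(skull_outer_radii))
    stop("skull_thickness must be positive and smaller than every semi-axis")
  inner <- skull_outer_radii - skull_thickness
  for (tg in targets) {
    if (!inherits(tg, "target")) stop("targets must be a list of target() objects")
    u <- sum((tg$centroid / inner)^2)
    # require the whole GTV sphere inside: conservative closed-form check
    if (sqrt(u) + tg$gtv_radius / min(inner) >= 1)
      stop(sprintf("target %s is not strictly inside the inner skull surface", tg$id))
  }
  if (is.null(origin)) origin <- -(as.numeric(dims) - 1) / 2 * as.numeric(spacing)
  structure(list(skull_outer_radii = skull_outer_radii,
                 skull_thickness = skull_thickness,
                 hu_air = hu_air, hu_brain = hu_brain, hu_skull = hu_skull,
                 hu_target_enhancement = hu_target_enhancement,
                 air_cavity = air_cavity, targets = targets,
                 dims = as.integer(dims), spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 antialias = max(1L, as.integer(antialias))),
            class = "phantom_spec")
}

# squared normalized ellipsoid coordinate field on the spec grid
ellipsoid_field <- function(spec, semi_axes, center = c(0, 0, 0)) {
  ax <- (spec$origin[1] + (seq_len(spec$dims[1]) - 1) * spec$spacing[1] - center[1]) / semi_axes[1]
  ay <- (spec$origin[2] + (seq_len(spec$dims[2]) - 1) * spec$spacing[2] - center[2]) / semi_axes[2]
  az <- (spec$origin[3] + (seq_len(spec$dims[3]) - 1) * spec$spacing[3] - center[3]) / semi_axes[3]
  outer(outer(ax^2, ay^2, `+`), az^2, `+`)
}

#' Generate a head-phantom CT with tissue masks
#'
#' Builds the analytic head CT described by a [phantom_spec()]: air outside
#' the outer skull ellipsoid, bone in the shell, brain inside, GTV spheres at
#' `hu_brain + hu_target_enhancement`, optional air cavity, then seeded
#' additive Gaussian noise truncated at -1000 HU (air is the physical floor
#' of the HU scale).
#'
#' @param spec a `phantom_spec`
#' @return list with `ct` (a CT `volume_image`), and logical masks `skull`,
#'   `brain` (inside inner surface, GTVs included), and `gtv` (list per target)
#' @export
make_head_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  inner <- spec$skull_outer_radii - spec$skull_thickness

  paint_hu <- function(gs) {
    u_out <- ellipsoid_field(gs, spec$skull_outer_radii)
    u_in <- ellipsoid_field(gs, inner)
    hu <- array(spec$hu_air, dim = gs$dims)
    hu[u_out <= 1 & u_in > 1] <- spec$hu_skull
    brain_m <- u_in <= 1
    hu[brain_m] <- spec$hu_brain
    for (tg in spec$targets) {
      m <- ellipsoid_field(gs, rep(tg$gtv_radius, 3), tg$centroid) <= 1
      hu[m] <- spec$hu_brain + spec$hu_target_enhancement
    }
    if (!is.null(spec$air_cavity)) {
      cav <- ellipsoid_field(gs, rep(spec$air_cavity$radius, 3),
                             spec$air_cavity$center) <= 1
      hu[cav & brain_m] <- spec$hu_air
    }
    hu
  }

  f <- spec$antialias
  if (f > 1L) {
    # render on an f-times-finer lattice and block-average down: voxels
    # straddling an interface get partial-volume HU like real CT
    fine <- list(dims = spec$dims * f, spacing = spec$spacing / f,
                 origin = spec$origin - (f - 1) / 2 * spec$spacing / f)
    hu_fine <- volume_image(paint_hu(fine), fine$spacing, fine$origin, "CT")
    hu <- downsample_volume(hu_fine, f)$voxels
  } else {
    hu <- paint_hu(spec)
  }

  # masks follow the analytic geometry at voxel centers
  u_out <- ellipsoid_field(spec, spec$skull_outer_radii)
  u_in <- ellipsoid_field(spec, inner)
  skull <- u_out <= 1 & u_in > 1
  brain <- u_in <= 1
  gtv <- vector("list", length(spec$targets))
  names(gtv) <- vapply(spec$targets, `[[`, "", "id")
  for (s in seq_along(spec$targets)) {
    tg <- spec$targets[[s]]
    gtv[[s]] <- ellipsoid_field(spec, rep(tg$gtv_radius, 3), tg$centroid) <= 1
  }
  if (spec$noise_sigma > 0) {
    old <- .Random.seed_exists()
    set.seed(spec$seed)
    hu <- hu + stats::rnorm(length(hu), 0, spec$noise_sigma)
    hu[hu < -1000] <- -1000
    dim(hu) <- spec$dims
    .restore_seed(old)
  }
  list(ct = volume_image(hu, spec$spacing, spec$origin, "CT"),
       skull = skull, brain = brain, gtv = gtv, spec = spec)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a repeat CT of the same head
#'
#' Moves the phantom rigidly by `transform` (resampling back onto the original
#' grid), adds a local HU perturbation emulating contrast/edema differences
#' between scan dates — +`local_hu_offset` HU (default 20, the magnitude such
#' inter-scan intracranial changes show) inside a sphere of radius
#' `2 * gtv_radius` around each (moved) target, brain tissue only — and adds
#' independent seeded Gaussian noise. Skull HU is left untouched: the working
#' assumption of the whole analysis is that the skull is stable between
#' courses.
#'
#' @param phantom result of [make_head_phantom()] (or a bare CT `volume_image`,
#'   in which case `targets` must be supplied for the local perturbation)
#' @param transform the rigid motion applied to the head (a `rigid_transform`)
#' @param noise_sigma added HU noise s.d. (default 3)
#' @param local_hu_offset HU added near targets (default 20; 0 disables)
#' @param targets list of [target()]s; default taken from the phantom spec
#'   carried by `make_head_phantom` output
#' @param seed RNG seed
#' @return a CT `volume_image` on the phantom grid
#' @export
simulate_rescan <- function(phantom, transform = rigid_transform(),
                            noise_sigma = 3, local_hu_offset = 20,
                            targets = NULL, seed = 2L) {
  ct <- if (is_volume_image(phantom)) phantom else phantom$ct
  if (is.null(targets) && !is_volume_image(phantom))
    targets <- phantom$spec$targets
  stopifnot(is_rigid_transform(transform))
  moved <- resample_volume(ct, invert_transform(transform), target_grid = ct,
                           interpolation = "trilinear", fill = -1000)
  hu <- moved$voxels
  if (local_hu_offset != 0 && length(targets)) {
    gs <- grid_spec(dim(hu), ct$spacing, ct$origin)
    fake_spec <- list(dims = gs$dims, spacing = gs$spacing, origin = gs$origin)
    for (tg in targets) {
      c_new <- as.numeric(transform_points(transform, tg$centroid))
      m <- ellipsoid_field(fake_spec, rep(2 * tg$gtv_radius, 3), c_new) <= 1
      soft <- hu > -200 & hu < 300  # brain only: skull and air excluded
      hu[m & soft] <- hu[m & soft] + local_hu_offset
    }
  }
  if (noise_sigma > 0) {
    old <- .Random.seed_exists()
    set.seed(seed)
    hu <- hu + stats::rnorm(length(hu), 0, noise_sigma)
    hu[hu < -1000] <- -1000
    dim(hu) <- dim(moved$voxels)
    .restore_seed(old)
  }
  out <- volume_image(hu, moved$spacing, moved$origin, "CT")
  attr(out, "infield") <- attr(moved, "infield")
  out
}

#' Derive a post-contrast T1-like MR from a phantom CT
#'
#' Deterministic nonlinear intensity remap giving T1-weighted contrast
#' ordering: cortical bone dark, brain mid-bright, contrast-enhancing GTVs
#' brightest, air near zero. Geometry is unchanged, so the ground-truth
#' alignment between the derived MR and its source CT is the identity — which
#' is what makes cross-modality registration tests self-validating.
#'
#' @param ct phantom CT `volume_image` (HU)
#' @param noise_sigma MR intensity noise s.d. (default 20 on a 0-1000 scale)
#' @param seed RNG seed
#' @return an MR `volume_image` on the same grid
#' @export
derive_mr <- function(ct, noise_sigma = 20, seed = 3L) {
  stopifnot(is_volume_image(ct))
  # knots: air -> ~0, brain (40) -> 600, enhancing GTV (~100) -> 900,
  # bone (1000) -> 80 (cortical bone is dark on T1)
  knots_hu <- c(-1000, -200, -50, 0, 40, 70, 100, 200, 400, 1000)
  knots_mr <- c(5, 10, 60, 400, 600, 750, 900, 500, 200, 80)
  v <- stats::approx(knots_hu, knots_mr, xout = as.numeric(ct$voxels),
                     rule = 2)$y
  if (noise_sigma > 0) {
    old <- .Random.seed_exists()
    set.seed(seed)
    v <- v + stats::rnorm(length(v), 0, noise_sigma)
    .restore_seed(old)
  }
  v[v < 0] <- 0
  dim(v) <- dim(ct$voxels)
  volume_image(v, ct$spacing, ct$origin, "MR")
}

#' Analytic SRS dose distribution specification
#'
#' @param prescription prescription dose Gy (default 20)
#' @param falloff_sigma Gaussian penumbra scale mm (default 2)
#' @param spacing dose-grid spacing mm (default 1 mm isotropic)
#' @param dims dose-grid voxel counts (default 64^3, centered on the target)
#' @return a `dose_spec` list
#' @export
dose_spec <- function(prescription = 20, falloff_sigma = 2,
                      spacing = c(1, 1, 1), dims = c(64L, 64L, 64L)) {
  if (prescription <= 0) stop("prescription must be > 0")
  if (falloff_sigma <= 0) stop("falloff_sigma must be > 0")
  structure(list(prescription = prescription, falloff_sigma = falloff_sigma,
                 spacing = as.numeric(spacing), dims = as.integer(dims)),
            class = "dose_spec")
}

#' Analytic single-isocenter SRS dose distribution
#'
#' Dose surrogate with the plateau-plus-steep-gradient structure of an SRS
#' plan: the prescription exactly inside the PTV and Gaussian falloff beyond,
#' `D(r) = Rx` for `r <= ptv_radius`, `Rx * exp(-(r - ptv_radius)^2 /
#' (2 sigma^2))` outside, sampled at dose-grid voxel centers. The grid is
#' centered on the target centroid unless `origin` is given. Errors if the
#' voxelized PTV coverage at the prescription falls below 98% — the plan
#' objective the generator must satisfy.
#'
#' @param tg a [target()]
#' @param spec a [dose_spec()]
#' @param origin optional dose-grid origin; default centers the grid on the
#'   target centroid
#' @return a DOSE `volume_image` (Gy)
#' @export
make_srs_dose <- function(tg, spec = dose_spec(), origin = NULL) {
  stopifnot(inherits(tg, "target"), inherits(spec, "dose_spec"))
  if (is.null(origin))
    origin <- tg$centroid - (spec$dims - 1) / 2 * spec$spacing
  ax <- origin[1] + (seq_len(spec$dims[1]) - 1) * spec$spacing[1] - tg$centroid[1]
  ay <- origin[2] + (seq_len(spec$dims[2]) - 1) * spec$spacing[2] - tg$centroid[2]
  az <- origin[3] + (seq_len(spec$dims[3]) - 1) * spec$spacing[3] - tg$centroid[3]
  r <- sqrt(outer(outer(ax^2, ay^2, `+`), az^2, `+`))
  d <- ifelse(r <= tg$ptv_radius, spec$prescription,
              spec$prescription *
                exp(-(r - tg$ptv_radius)^2 / (2 * spec$falloff_sigma^2)))
  dose <- volume_image(array(d, spec$dims), spec$spacing, origin, "DOSE")
  cov <- coverage(dose, tg$ptv_radius, tg$centroid, spec$prescription)
  if (cov < 0.98)
    stop(sprintf("PTV coverage %.3f < 0.98: dose grid too coarse for this target", cov))
  dose
}

#' Fractional target coverage at a dose level
#'
#' Fraction of voxels whose centers lie inside the target sphere that receive
#' at least `rx` Gy — the voxelized form of the plan objective "deliver Rx to
#' cover >98% of the target".
#'
#' @param dose a DOSE `volume_image`
#' @param target_radius sphere radius mm
#' @param centroid sphere center (mm)
#' @param rx dose level Gy
#' @return fraction in [0, 1]
#' @export
coverage <- function(dose, target_radius, centroid, rx) {
  stopifnot(is_volume_image(dose))
  gs <- list(dims = dim(dose$voxels), spacing = dose$spacing,
             origin = dose$origin)
  inside <- ellipsoid_field(gs, rep(target_radius, 3), centroid) <= 1
  n <- sum(inside)
  if (n == 0L) stop("no dose-grid voxel centers fall inside the target sphere")
  sum(dose$voxels[inside] >= rx) / n
}
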
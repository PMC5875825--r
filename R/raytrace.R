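#' The 16 ray-trace directions
#'
#' Eight rays spaced 45 degrees apart in the transverse plane through the
#' target (azimuth 0 = +x), plus eight rays at the same azimuths elevated 45
#' degrees out of that plane. Whether the oblique rays go superior, inferior,
#' or alternate is a free choice of the scheme; all-superior is the default.
#'
#' @param elevation `"superior"`, `"inferior"`, or `"alternating"` for the
#'   oblique set
#' @return 16 x 3 matrix of unit vectors, transverse octet first, with
#'   `azimuth_deg` / `elevation_deg` attributes
#' @export
ray_directions <- function(elevation = c("superior", "inferior", "alternating")) {
  elevation <- match.arg(elevation)
  az <- seq(0, 315, by = 45) * pi / 180
  transverse <- cbind(cos(az), sin(az), 0)
  el_sign <- switch(elevation,
                    superior = rep(1, 8),
                    inferior = rep(-1, 8),
                    alternating = rep(c(1, -1), 4))
  c45 <- cos(pi / 4)
  oblique <- cbind(cos(az) * c45, sin(az) * c45, el_sign * c45)
  out <- rbind(transverse, oblique)
  attr(out, "azimuth_deg") <- rep(seq(0, 315, by = 45), 2)
  attr(out, "elevation_deg") <- c(rep(0, 8), el_sign * 45)
  out
}

#' Ray-trace from a point to the proximal inner skull surface
#'
#' Samples HU by trilinear interpolation at `step` increments along the ray
#' and reports the distance to the first rising crossing of `hu_cross` whose
#' centered finite-difference directional gradient reaches `grad_min` — i.e.
#' the first genuine soft-tissue-to-bone edge (the inner table), not a noise
#' blip. The crossing position is refined by linear interpolation between the
#' bracketing samples.
#'
#' @param ct a CT `volume_image`
#' @param origin ray start, world mm (must be inside the image)
#' @param direction unit vector
#' @param step sampling increment mm (default 0.2)
#' @param hu_cross HU level defining the bone edge (default 520, the
#'   half-maximum between brain ~40 HU and cortical bone ~1000 HU: crossing a
#'   partial-volume ramp at its midlevel localizes the surface without bias)
#' @param grad_min minimum directional gradient HU/mm at the edge
#'   (default 100)
#' @return distance in mm, or `NA` with attribute `failed = TRUE` when the
#'   ray leaves the field of view without a qualifying edge
#' @export
trace_to_skull <- function(ct, origin, direction, step = 0.2,
                           hu_cross = 520, grad_min = 100) {
  stopifnot(is_volume_image(ct))
  direction <- as.numeric(direction)
  if (abs(sqrt(sum(direction^2)) - 1) > 1e-6)
    stop("direction must be unit-norm")
  origin <- as.numeric(origin)
  d <- dim(ct$voxels)
  extent <- sqrt(sum(((d - 1) * ct$spacing)^2))  # longest possible chord
  ts <- seq(0, extent, by = step)
  pts <- cbind(origin[1] + ts * direction[1],
               origin[2] + ts * direction[2],
               origin[3] + ts * direction[3])
  s <- sample_volume(ct, pts, "trilinear")
  if (!s$infield[1]) stop("ray origin lies outside the image")
  n <- which(!s$infield)[1]
  n <- if (is.na(n)) length(ts) else n - 1L
  hu <- s$values[seq_len(n)]
  if (n >= 3L) {
    grad <- c(NA, (hu[3:n] - hu[1:(n - 2)]) / (2 * step), NA)
    rising <- which(hu[-n] < hu_cross & hu[-1] >= hu_cross)
    for (k in rising) {
      g <- suppressWarnings(max(grad[k], grad[k + 1], na.rm = TRUE))
      if (is.finite(g) && g >= grad_min) {
        frac <- (hu_cross - hu[k]) / (hu[k + 1] - hu[k])
        return(ts[k] + frac * step)
      }
    }
  }
  structure(NA_real_, failed = TRUE)
}

#' 16-direction skull-distance profile for one target
#'
#' Applies [trace_to_skull()] along all 16 [ray_directions()] from the target
#' centroid. More than four failed rays is recorded as a warning flag on the
#' profile (open geometry or a target too close to the field edge).
#'
#' @param ct a CT `volume_image`
#' @param tg a [target()]
#' @param step,hu_cross,grad_min edge-detection parameters, see
#'   [trace_to_skull()]
#' @param elevation oblique-ray elevation scheme, see [ray_directions()]
#' @return a `raytrace_profile`: data frame of 16 rays (azimuth, elevation,
#'   distance_mm, valid) plus `target_id`, `directions`, `step` attributes
#' @export
skull_profile <- function(ct, tg, step = 0.2, hu_cross = 520, grad_min = 100,
                          elevation = "superior") {
  stopifnot(inherits(tg, "target"))
  dirs <- ray_directions(elevation)
  dist <- numeric(16)
  for (r in seq_len(16)) {
    dist[r] <- as.numeric(trace_to_skull(ct, tg$centroid, dirs[r, ],
                                         step, hu_cross, grad_min))
  }
  prof <- data.frame(ray = seq_len(16),
                     azimuth_deg = attr(dirs, "azimuth_deg"),
                     elevation_deg = attr(dirs, "elevation_deg"),
                     distance_mm = dist,
                     valid = !is.na(dist))
  structure(prof, class = c("raytrace_profile", "data.frame"),
            target_id = tg$id, directions = dirs, step = step,
            many_failures = sum(is.na(dist)) > 4L)
}

#' Compare two skull-distance profiles (initial vs repeat CT)
#'
#' Per-ray absolute differences of the target-to-inner-skull distances,
#' restricted to rays valid in both profiles; profiles must have been
#' measured after the two CTs were registered onto a common frame. The mean
#' absolute difference is the skull-stability figure of merit.
#'
#' @param p_ict,p_rct `raytrace_profile`s of the same target with the same
#'   direction set
#' @return a `profile_comparison`: `per_ray_abs_diff` (length 16, `NA` where
#'   either ray failed), `mean_abs_diff`, `max_abs_diff`, `n_valid_rays`
#' @export
profile_difference <- function(p_ict, p_rct) {
  stopifnot(inherits(p_ict, "raytrace_profile"),
            inherits(p_rct, "raytrace_profile"))
  if (!isTRUE(all.equal(attr(p_ict, "directions"), attr(p_rct, "directions"))))
    stop("profiles use different direction sets")
  if (!identical(attr(p_ict, "target_id"), attr(p_rct, "target_id")))
    stop("profiles belong to different targets")
  both <- p_ict$valid & p_rct$valid
  if (!any(both)) stop("no ray is valid in both profiles")
  diff <- abs(p_ict$distance_mm - p_rct$distance_mm)
  diff[!both] <- NA_real_
  structure(list(per_ray_abs_diff = diff,
                 mean_abs_diff = mean(diff[both]),
                 max_abs_diff = max(diff[both]),
                 n_valid_rays = sum(both),
                 target_id = attr(p_ict, "target_id")),
            class = "profile_comparison")
}
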
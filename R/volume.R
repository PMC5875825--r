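#' Axis-aligned 3D scalar volume
#'
#' The basic image container used throughout the package: a 3D array of
#' scalar values (HU for CT, arbitrary intensity for MR, Gy for dose) on an
#' axis-aligned grid. Index `(i, j, k)` (1-based in R) maps to world
#' coordinates `origin + ((i,j,k) - 1) * spacing`, i.e. `origin` is the world
#' position of the *center* of the first voxel and world axes follow the
#' DICOM LPS patient convention (x = left, y = posterior, z = superior).
#' Oblique orientations are deliberately unsupported.
#'
#' @param voxels 3D numeric array; first dimension runs along x.
#' @param spacing numeric length-3, voxel spacing in mm, all > 0.
#' @param origin numeric length-3, world position (mm) of voxel (1,1,1) center.
#' @param modality one of `"CT"`, `"MR"`, `"DOSE"`.
#' @return A `volume_image` object.
#' @export
volume_image <- function(voxels, spacing, origin = c(0, 0, 0),
                         modality = c("CT", "MR", "DOSE")) {
  modality <- match.arg(modality)
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  if (any(dim(voxels) < 2L))
    stop("all image dimensions must be >= 2")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)")
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 modality = modality),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image %s> %d x %d x %d voxels, spacing %s mm, origin (%s) mm\n",
              x$modality, dim(x$voxels)[1], dim(x$voxels)[2], dim(x$voxels)[3],
              paste(signif(x$spacing, 4), collapse = " x "),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

is_volume_image <- function(x) inherits(x, "volume_image")

#' World coordinates of the voxel-center lattice along each axis
#' @param img a `volume_image`
#' @return list with numeric vectors `x`, `y`, `z` (mm)
#' @export
grid_axes <- function(img) {
  d <- dim(img$voxels)
  list(x = img$origin[1] + (seq_len(d[1]) - 1) * img$spacing[1],
       y = img$origin[2] + (seq_len(d[2]) - 1) * img$spacing[2],
       z = img$origin[3] + (seq_len(d[3]) - 1) * img$spacing[3])
}

#' World position of the geometric center of the image
#' @param img a `volume_image`
#' @return numeric length-3 (mm)
#' @export
image_center <- function(img) {
  d <- dim(img$voxels)
  img$origin + (d - 1) / 2 * img$spacing
}

#' Grid specification helper
#'
#' A light-weight description of a voxel lattice (dims, spacing, origin) used
#' when resampling onto a grid that is not carried by an existing image.
#'
#' @param dims integer length-3 voxel counts (each >= 2)
#' @param spacing numeric length-3 spacing (mm)
#' @param origin numeric length-3 first-voxel-center position (mm)
#' @return a `grid_spec` list
#' @export
grid_spec <- function(dims, spacing, origin) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 2L)) stop("dims must be 3 values >= 2")
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  structure(list(dims = dims, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)), class = "grid_spec")
}

as_grid_spec <- function(x) {
  if (inherits(x, "grid_spec")) return(x)
  if (is_volume_image(x)) return(grid_spec(dim(x$voxels), x$spacing, x$origin))
  stop("cannot interpret object as a grid specification")
}

#' Do two volumes share the same voxel lattice?
#' @param a,b `volume_image` objects
#' @param tol positional tolerance in mm
#' @export
same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Maximum straight-line path length across one voxel
#'
#' The voxel space diagonal `sqrt(dx^2 + dy^2 + dz^2)`: the longest chord a
#' ray can traverse inside a single voxel, which bounds the spatial
#' granularity of any voxel-based distance measurement. For the typical SRS
#' planning-CT voxel of 0.78 x 0.78 x 1 mm this is 1.49 mm.
#'
#' @param spacing numeric length-3, voxel spacing in mm, all > 0
#' @return diagonal length in mm
#' @export
max_voxel_path <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)")
  sqrt(sum(spacing^2))
}

#' Sample a volume at arbitrary world points (trilinear or nearest)
#'
#' @param img a `volume_image`
#' @param pts n x 3 matrix of world coordinates (mm)
#' @param interpolation `"trilinear"` or `"nearest"`
#' @param fill value returned for points outside the voxel-center hull
#' @return list with `values` (length n) and `infield` (logical length n)
#' @export
sample_volume <- function(img, pts, interpolation = c("trilinear", "nearest"),
                          fill = NA_real_) {
  interpolation <- match.arg(interpolation)
  pts <- matrix(as.numeric(pts), ncol = 3L)
  cpp_sample_points(img$voxels, dim(img$voxels), img$spacing, img$origin,
                    pts, interpolation == "nearest",
                    if (is.na(fill)) NA_real_ else as.numeric(fill))
}
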
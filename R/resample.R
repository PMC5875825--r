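#' Resample a volume through a rigid transform
#'
#' Pull-back resampling: the output grid is sampled at its voxel centers, and
#' the value at output position `x` is `img` interpolated at the mapped
#' position `T(x)`. To *move* an image rigidly by a motion `M` (so that
#' anatomy at `p` ends up at `M(p)`), pass `T = invert_transform(M)`.
#'
#' Out-of-field positions receive `fill` (default -1000 for CT — air — and 0
#' for MR/dose); the returned image carries an `"infield"` attribute (logical
#' array) marking which output voxels were actually covered by the source,
#' which downstream overlap-based statistics use.
#'
#' @param img a `volume_image`
#' @param transform a `rigid_transform` mapping output-world to source-world
#' @param target_grid a `grid_spec` or `volume_image` defining the output
#'   lattice; default: the input's own lattice
#' @param interpolation `"trilinear"` or `"nearest"`
#' @param fill out-of-field fill value; default by modality
#' @return a `volume_image` on the target grid with an `infield` attribute
#' @export
resample_volume <- function(img, transform = rigid_transform(),
                            target_grid = NULL,
                            interpolation = c("trilinear", "nearest"),
                            fill = NULL) {
  interpolation <- match.arg(interpolation)
  stopifnot(is_volume_image(img), is_rigid_transform(transform))
  g <- as_grid_spec(if (is.null(target_grid)) img else target_grid)
  if (any(g$dims < 2L)) stop("degenerate target grid: all dims must be >= 2")
  if (is.null(fill)) fill <- if (img$modality == "CT") -1000 else 0
  A <- transform_affine(transform)
  res <- cpp_resample_affine(img$voxels, dim(img$voxels), img$spacing,
                             img$origin, g$dims, g$spacing, g$origin, A,
                             interpolation == "nearest", as.numeric(fill))
  vox <- array(res$values, dim = g$dims)
  out <- volume_image(vox, g$spacing, g$origin, img$modality)
  attr(out, "infield") <- array(res$infield, dim = g$dims)
  out
}

#' In-field mask of a (possibly resampled) volume
#'
#' Volumes produced by [resample_volume()] carry a logical mask of voxels
#' covered by the source field of view; native volumes are fully in-field.
#' @param img a `volume_image`
#' @return logical array matching `dim(img$voxels)`
#' @export
infield_mask <- function(img) {
  m <- attr(img, "infield")
  if (is.null(m)) array(TRUE, dim = dim(img$voxels)) else m
}

#' Block-mean downsample by an integer factor (multi-resolution pyramid)
#'
#' Averages `factor^3` blocks; trailing voxels that do not fill a block are
#' dropped. The origin moves to the center of the first block so world
#' geometry is preserved.
#' @param img a `volume_image`
#' @param factor integer >= 1
#' @return a `volume_image`
#' @keywords internal
downsample_volume <- function(img, factor) {
  factor <- as.integer(factor)
  if (factor <= 1L) return(img)
  d <- dim(img$voxels)
  nd <- d %/% factor
  if (any(nd < 2L)) stop("downsample factor too large for image dimensions")
  v <- img$voxels[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                  seq_len(nd[3] * factor), drop = FALSE]
  dim(v) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  v <- aperm(v, c(1, 3, 5, 2, 4, 6))
  dim(v) <- c(factor^3, prod(nd))
  out <- array(colMeans(v), dim = nd)
  volume_image(out, img$spacing * factor,
               img$origin + (factor - 1) / 2 * img$spacing, img$modality)
}
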
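#' Normalized mutual information between two co-registered volumes
#'
#' Histogram-based NMI over the overlap region (voxels in-field in both
#' volumes): a joint histogram with `n_bins` equal-width bins per image,
#' each spanning that image's min-max over the overlap, gives
#' `NMI = 2 I(A;B) / (H(A) + H(B))`. Identical images score exactly 1;
#' independent images tend to 0. This symmetric normalization is chosen
#' because "identical sets score 1" is the only hard anchor registration
#' consoles agree on — absolute values from proprietary MI scales are not
#' comparable, only orderings are.
#'
#' @param a,b `volume_image`s on the same grid (resample first if not)
#' @param n_bins histogram bins per axis (default 64, suited to 12-bit CT)
#' @return NMI in [0, 1]
#' @export
mutual_information_normalized <- function(a, b, n_bins = 64L) {
  h <- joint_histogram(a, b, n_bins)
  p <- h$counts / h$n
  px <- rowSums(p)
  py <- colSums(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  hx <- ent(px); hy <- ent(py); hxy <- ent(p)
  if (hx <= 0 || hy <= 0)
    stop("constant image in overlap: entropy is zero, NMI undefined")
  2 * (hx + hy - hxy) / (hx + hy)
}

# shared joint-histogram core; overlap = in-field in both volumes
joint_histogram <- function(a, b, n_bins = 64L) {
  stopifnot(is_volume_image(a), is_volume_image(b))
  if (!same_grid(a, b))
    stop("volumes must share one grid; resample_volume() one of them first")
  ok <- infield_mask(a) & infield_mask(b)
  va <- as.numeric(a$voxels[ok])
  vb <- as.numeric(b$voxels[ok])
  n <- length(va)
  if (n < 2L) stop("empty overlap between volumes")
  bin_of <- function(v) {
    lo <- min(v); hi <- max(v)
    if (hi <= lo) return(NULL)  # constant: caller decides how to fail
    i <- floor((v - lo) / (hi - lo) * n_bins) + 1L
    i[i > n_bins] <- n_bins
    i
  }
  ia <- bin_of(va); ib <- bin_of(vb)
  if (is.null(ia) || is.null(ib))
    stop("constant image in overlap: similarity undefined")
  counts <- matrix(tabulate(ia + n_bins * (ib - 1L), nbins = n_bins^2),
                   n_bins, n_bins)
  list(counts = counts, n = n)
}

#' Pearson correlation between two co-registered volumes
#'
#' Sample correlation of co-located voxel intensities over the overlap
#' region. Errors (rather than returning NaN) when either image is constant
#' in the overlap.
#'
#' @param a,b `volume_image`s on the same grid
#' @return correlation in [-1, 1]
#' @export
pearson <- function(a, b) {
  stopifnot(is_volume_image(a), is_volume_image(b))
  if (!same_grid(a, b))
    stop("volumes must share one grid; resample_volume() one of them first")
  ok <- infield_mask(a) & infield_mask(b)
  va <- as.numeric(a$voxels[ok])
  vb <- as.numeric(b$voxels[ok])
  if (length(va) < 2L) stop("empty overlap between volumes")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("constant image in overlap: correlation undefined")
  stats::cor(va, vb)
}

#' Full similarity report (NMI + Pearson) for two volumes
#'
#' @param a,b `volume_image`s on the same grid
#' @param n_bins histogram bins per axis for the NMI component
#' @return a `similarity_report`: `mi`, `pc`, `n_overlap`, `n_bins`
#' @export
similarity_report <- function(a, b, n_bins = 64L) {
  ok <- infield_mask(a) & infield_mask(b)
  structure(list(mi = mutual_information_normalized(a, b, n_bins),
                 pc = pearson(a, b),
                 n_overlap = sum(ok), n_bins = as.integer(n_bins)),
            class = "similarity_report")
}

#' Default similarity context bands
#'
#' Ordered MI floors mirroring the empirical ordering of scan-similarity
#' groups: same scan > resampled same scan > same-day rescan > different-day
#' rescan > different patient. The edges are configuration, not constants:
#' absolute MI values depend on the implementation's histogram scale, so only
#' the ordering is meaningful and users should calibrate edges on their own
#' comparison groups.
#' @return named numeric vector of descending MI floors
#' @export
default_similarity_bands <- function() {
  c("same scan" = 0.99,
    "same scan, resampled" = 0.75,
    "same patient, same day" = 0.6,
    "same patient, different day" = 0.45,
    "different patient" = -Inf)
}

#' Classify a similarity report against context bands
#'
#' @param report a `similarity_report` (or a bare MI value)
#' @param bands named numeric vector of descending MI floors; a report is
#'   labelled with the first band whose floor its MI reaches
#' @return band label (character)
#' @export
similarity_context <- function(report, bands = default_similarity_bands()) {
  mi <- if (inherits(report, "similarity_report")) report$mi else as.numeric(report)
  if (is.unsorted(rev(bands))) bands <- sort(bands, decreasing = TRUE)
  names(bands)[which(mi >= bands)[1]]
}
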
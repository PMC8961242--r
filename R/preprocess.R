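#' Resample a volume under a rigid/affine transform
#'
#' Applies a given 4x4 homogeneous transform, mapping target-grid mm
#' coordinates to source-grid mm coordinates, and resamples the source
#' volume onto the target grid. Interpolation is nearest-neighbour
#' (`order = 0`; preserves discrete value sets, for masks) or cubic spline
#' interpolation (`order = 3`, an interpolating cubic kernel that
#' reproduces the samples exactly, for intensity images). Out-of-field
#' voxels are set to 0. Transform estimation (registration search) is out
#' of scope: transforms come from outside, e.g. a FLIRT-style text matrix
#' via [readTransformMatrix()]; for phantom pipelines it is the identity.
#'
#' @param volume numeric 3D array.
#' @param transform 4x4 homogeneous matrix (target mm -> source mm). The
#'   upper-left 3x3 block must be invertible; for rigid transforms it is a
#'   rotation.
#' @param targetShape integer extent of the output grid (voxels).
#' @param order interpolation order, 0 or 3.
#' @param sourceSpacing,targetSpacing voxel sizes (mm) defining the
#'   voxel-to-mm scaling of the two grids (0-based voxel index times
#'   spacing).
#' @return resampled numeric 3D array of extent `targetShape`.
#' @examples
#' v <- array(rnorm(27^3), c(27, 27, 27))
#' ident <- applyTransform(v, diag(4), dim(v), order = 3)
#' max(abs(ident - v))  # ~1e-16: identity reproduces the input
#' @export
applyTransform <- function(volume, transform, targetShape = dim(volume),
                           order = 3, sourceSpacing = c(1, 1, 1),
                           targetSpacing = sourceSpacing) {
  stopifnot3d(volume)
  stopifnot(identical(dim(transform), c(4L, 4L)))
  if (!order %in% c(0, 3)) stop("order must be 0 or 3")
  if (abs(det(transform[1:3, 1:3])) < 1e-12)
    stop("singular transform matrix")
  targetShape <- as.integer(rep(targetShape, length.out = 3L))
  # 0-based voxel -> mm scaling for both grids
  stgt <- diag(c(rep(targetSpacing, length.out = 3), 1))
  ssrc <- diag(c(rep(sourceSpacing, length.out = 3), 1))
  M <- solve(ssrc) %*% transform %*% stgt     # target voxel -> source voxel
  out <- .affineResample(as.double(volume), dim(volume),
                         M[1:3, , drop = FALSE], targetShape,
                         as.integer(order))
  array(out, targetShape)
}

#' Read a 4x4 transform from a whitespace-delimited text file
#'
#' Reads the FLIRT-style plain-text dialect: four rows of four numbers.
#'
#' @param path file path.
#' @return 4x4 numeric matrix.
#' @export
readTransformMatrix <- function(path) {
  m <- as.matrix(read.table(path))
  dimnames(m) <- NULL
  if (!identical(dim(m), c(4L, 4L))) stop("expected a 4x4 matrix in ", path)
  m
}

#' Z-score, scale and clip a volume to [-1, 1]
#'
#' The intensity-normalization chain applied to every channel before
#' training: z-score the volume using the mean and standard deviation of
#' the voxels inside `mask` (so that background air does not dominate the
#' statistics), divide the z-scores by four, and clip to [-1, 1]. The
#' scaling is applied to all voxels, inside and outside the mask.
#'
#' @param volume numeric 3D array.
#' @param mask logical 3D array with at least one `TRUE` voxel.
#' @return a [NormalizedVolume-class] carrying the scaled data and the
#'   statistics used.
#' @export
normalizeIntensity <- function(volume, mask) {
  stopifnot3d(volume)
  stopifnot(identical(dim(volume), dim(mask)))
  vals <- volume[mask]
  if (length(vals) < 1L) stop("mask must cover at least one voxel")
  mu <- mean(vals)
  sigma <- sd(vals)
  if (!is.finite(sigma) || sigma <= 0)
    stop("zero intensity variance inside the mask: degenerate image")
  z <- (volume - mu) / sigma / 4
  z[z > 1] <- 1
  z[z < -1] <- -1
  new("NormalizedVolume", data = z, mask = array(as.logical(mask),
                                                 dim(mask)),
      mu = mu, sigma = sigma)
}
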
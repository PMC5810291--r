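#' Construct a voxel grid
#'
#' @param origin mm coordinate of the centre of voxel (1,1,1).
#' @param voxelSize isotropic voxel edge in mm.
#' @param dims integer(3) grid extent.
#' @return a [VolumeGrid-class].
#' @examples
#' g <- VolumeGrid(c(-70, -104, -60), 2, c(71L, 87L, 70L))
#' @export
VolumeGrid <- function(origin, voxelSize, dims) {
  new("VolumeGrid", origin = as.numeric(origin),
      voxelSize = as.numeric(voxelSize), dims = as.integer(dims))
}

#' Default Talairach-extent grid
#'
#' Covers x in [-70, 70], y in [-104, 68], z in [-60, 78] mm, the extent of the
#' Talairach atlas, at a configurable isotropic voxel size (default 2 mm, the
#' usual convention for ALE meta-analysis).
#'
#' @param voxelSize voxel edge in mm.
#' @return a [VolumeGrid-class].
#' @export
defaultGrid <- function(voxelSize = 2) {
  lo <- c(-70, -104, -60)
  hi <- c(70, 68, 78)
  dims <- floor((hi - lo) / voxelSize) + 1L
  VolumeGrid(lo, voxelSize, dims)
}

#' World/voxel coordinate mapping
#'
#' Voxel indices are 1-based; a millimetre coordinate maps to the voxel whose
#' centre is nearest (round-half-up per axis). The round trip
#' world -> voxel -> world moves a point by at most half a voxel per axis.
#'
#' @param grid a [VolumeGrid-class].
#' @param mm numeric matrix (n x 3) of mm coordinates (or a length-3 vector).
#' @param idx integer matrix (n x 3) of voxel indices (or a length-3 vector).
#' @return `worldToVoxel`: integer n x 3 matrix of indices; `voxelToWorld`:
#'   numeric n x 3 matrix of voxel-centre mm coordinates.
#' @export
worldToVoxel <- function(grid, mm) {
  mm <- .asCoordMatrix(mm)
  idx <- sweep(mm, 2, grid@origin, "-") / grid@voxelSize
  matrix(as.integer(round(idx)) + 1L, ncol = 3L,
         dimnames = list(NULL, c("i", "j", "k")))
}

#' @rdname worldToVoxel
#' @export
voxelToWorld <- function(grid, idx) {
  idx <- .asCoordMatrix(idx)
  out <- sweep((idx - 1) * grid@voxelSize, 2, grid@origin, "+")
  colnames(out) <- c("x", "y", "z")
  out
}

#' Test whether voxel indices fall inside the grid
#'
#' @inheritParams worldToVoxel
#' @return logical vector, one per row of `idx`.
#' @export
inGrid <- function(grid, idx) {
  idx <- .asCoordMatrix(idx)
  idx[, 1] >= 1L & idx[, 1] <= grid@dims[1] &
    idx[, 2] >= 1L & idx[, 2] <= grid@dims[2] &
    idx[, 3] >= 1L & idx[, 3] <= grid@dims[3]
}

.asCoordMatrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L)
  stopifnot(ncol(x) == 3L)
  x
}

.sameGrid <- function(a, b, tol = 1e-8) {
  identical(a@dims, b@dims) &&
    abs(a@voxelSize - b@voxelSize) < tol &&
    all(abs(a@origin - b@origin) < tol)
}

## linear index (column-major) of an n x 3 voxel index matrix
.linearIndex <- function(grid, idx) {
  d <- grid@dims
  (idx[, 3] - 1L) * d[1] * d[2] + (idx[, 2] - 1L) * d[1] + idx[, 1]
}
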
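#' Gaussian kernel width from FWHM
#'
#' \eqn{\sigma = FWHM / \sqrt{8 \ln 2}}.
#'
#' @param fwhmMm full-width at half-maximum in mm (> 0).
#' @return sigma in mm.
#' @examples
#' sigmaFromFwhm(sqrt(8 * log(2)))  # 1
#' @export
sigmaFromFwhm <- function(fwhmMm) {
  if (any(!is.finite(fwhmMm)) || any(fwhmMm <= 0))
    stop("fwhmMm must be positive")
  fwhmMm / sqrt(8 * log(2))
}

#' Isotropic 3-D Gaussian density at distance d
#'
#' \eqn{p(d) = (\sigma^3 (2\pi)^{3/2})^{-1} e^{-d^2 / (2\sigma^2)}}, the
#' probability density (per mm^3) of a focus displaced by Euclidean distance
#' `d` from its true location under isotropic spatial uncertainty `sigmaMm`.
#' Multiply by the voxel volume to obtain a per-voxel probability.
#'
#' @param d Euclidean distance(s) in mm, >= 0.
#' @param sigmaMm kernel sigma in mm, > 0.
#' @return density value(s).
#' @export
gaussianProb <- function(d, sigmaMm) {
  if (any(d < 0)) stop("d must be nonnegative")
  if (sigmaMm <= 0) stop("sigmaMm must be positive")
  exp(-d^2 / (2 * sigmaMm^2)) / (sigmaMm^3 * (2 * pi)^(3 / 2))
}

## Precompute a truncated spherical kernel: integer voxel offsets and the
## per-voxel probability (density * voxel volume) at each offset.
.makeKernel <- function(grid, fwhmMm, truncationFactor = 3) {
  sigma <- sigmaFromFwhm(fwhmMm)
  rMm <- truncationFactor * fwhmMm
  s <- floor(rMm / grid@voxelSize)
  off <- as.matrix(expand.grid(di = -s:s, dj = -s:s, dk = -s:s))
  d <- sqrt(rowSums(off^2)) * grid@voxelSize
  keep <- d <= rMm
  list(offsets = off[keep, , drop = FALSE],
       prob = gaussianProb(d[keep], sigma) * grid@voxelSize^3,
       sigma = sigma, radiusMm = rMm)
}

## MA values (3-D array) from a foci index matrix using a precomputed kernel.
## Per-voxel max over foci, zeroed outside mask.
.maValues <- function(fociIdx, grid, kernel, mask = NULL) {
  vals <- array(0, dim = grid@dims)
  d <- grid@dims
  for (r in seq_len(nrow(fociIdx))) {
    pos <- sweep(kernel$offsets, 2, as.integer(fociIdx[r, ]), "+")
    ok <- pos[, 1] >= 1L & pos[, 1] <= d[1] &
          pos[, 2] >= 1L & pos[, 2] <= d[2] &
          pos[, 3] >= 1L & pos[, 3] <= d[3]
    lin <- (pos[ok, 3] - 1L) * d[1] * d[2] + (pos[ok, 2] - 1L) * d[1] + pos[ok, 1]
    vals[lin] <- pmax(vals[lin], kernel$prob[ok])
  }
  if (!is.null(mask)) vals[!mask] <- 0
  vals
}

#' Modeled alteration (MA) map of one experiment
#'
#' Centres an isotropic Gaussian kernel (truncated at
#' `truncationFactor * fwhmMm`) on each focus, converts the density to a
#' per-voxel probability by multiplying by the voxel volume, and combines the
#' per-focus kernels by voxel-wise maximum, so repeated or adjacent foci of
#' one experiment are not double counted. Foci are snapped to the nearest
#' voxel centre; foci outside the grid are dropped with a warning.
#'
#' @param experiment an [Experiment-class].
#' @param grid the [VolumeGrid-class] to evaluate on.
#' @param fwhmMm kernel FWHM in mm (default 10).
#' @param mask optional logical array (in-brain mask); values outside are 0.
#' @param truncationFactor kernel truncation radius in FWHM units (default 3).
#' @return a [MaMap-class].
#' @export
maMap <- function(experiment, grid, fwhmMm = 10, mask = NULL,
                  truncationFactor = 3) {
  idx <- worldToVoxel(grid, experiment@foci)
  inside <- inGrid(grid, idx)
  if (!any(inside))
    stop("all foci of ", experiment@id, " fall outside the grid")
  if (!all(inside))
    warning(sum(!inside), " focus/foci of ", experiment@id,
            " outside the grid were dropped")
  kernel <- .makeKernel(grid, fwhmMm, truncationFactor)
  vals <- .maValues(idx[inside, , drop = FALSE], grid, kernel, mask)
  new("MaMap", grid = grid, values = vals,
      experimentId = experiment@id, fwhmMm = fwhmMm)
}

#' Unite MA maps into an ALE map
#'
#' Probabilistic union over experiments: per voxel,
#' \eqn{ALE = 1 - \prod_i (1 - MA_i)}. Commutative in experiment order and
#' monotone: adding an experiment never decreases any voxel.
#'
#' @param maMaps nonempty list of [MaMap-class] sharing one grid.
#' @return an (unthresholded) [AleMap-class].
#' @export
aleUnion <- function(maMaps) {
  if (!length(maMaps)) stop("need at least one MA map")
  grid <- maMaps[[1]]@grid
  for (m in maMaps) if (!.sameGrid(grid, m@grid)) stop("grid mismatch among MA maps")
  comp <- Reduce(`*`, lapply(maMaps, function(m) 1 - m@values))
  new("AleMap", grid = grid, values = 1 - comp,
      nExperiments = length(maMaps),
      fwhmMm = maMaps[[1]]@fwhmMm, thresholdValue = NA_real_)
}

#' Compute an ALE map from experiments
#'
#' Convenience wrapper: per-experiment MA maps followed by [aleUnion()].
#'
#' @inheritParams maMap
#' @param experiments list of [Experiment-class].
#' @return an [AleMap-class].
#' @export
computeAleMap <- function(experiments, grid, fwhmMm = 10, mask = NULL,
                          truncationFactor = 3) {
  kernel <- .makeKernel(grid, fwhmMm, truncationFactor)
  comp <- array(1, dim = grid@dims)
  for (e in experiments) {
    idx <- worldToVoxel(grid, e@foci)
    inside <- inGrid(grid, idx)
    if (!any(inside)) stop("all foci of ", e@id, " fall outside the grid")
    if (!all(inside))
      warning(sum(!inside), " focus/foci of ", e@id,
              " outside the grid were dropped")
    comp <- comp * (1 - .maValues(idx[inside, , drop = FALSE], grid, kernel, mask))
  }
  new("AleMap", grid = grid, values = 1 - comp,
      nExperiments = length(experiments), fwhmMm = fwhmMm,
      thresholdValue = NA_real_)
}

#' Simulate a null distribution of ALE summary statistics
#'
#' Repeatedly redraws every experiment's foci uniformly at random over the
#' in-mask voxels (keeping the real per-experiment foci counts), recomputes
#' the ALE map, and records either the maximum ALE value (`kind =
#' "voxel_max"`, for voxel-level family-wise-error control) or the size of the
#' largest suprathreshold 6-connected cluster (`kind = "cluster_size"`, given
#' a cluster-forming threshold).
#'
#' @param fociCounts integer vector: foci count per experiment of the real
#'   dataset (the "same characteristics" preserved under the null).
#' @param grid the [VolumeGrid-class].
#' @param mask logical array of in-brain voxels (nonempty).
#' @param fwhmMm kernel FWHM in mm.
#' @param nIterations number of simulated datasets (>= 100).
#' @param seed RNG seed (reproducible).
#' @param kind "voxel_max" or "cluster_size".
#' @param clusterFormingThreshold ALE value forming clusters (required for
#'   `kind = "cluster_size"`).
#' @param truncationFactor kernel truncation radius in FWHM units.
#' @return a [NullDistribution-class].
#' @export
buildNull <- function(fociCounts, grid, mask, fwhmMm = 10, nIterations = 1000,
                      seed = 1, kind = c("voxel_max", "cluster_size"),
                      clusterFormingThreshold = NULL, truncationFactor = 3) {
  kind <- match.arg(kind)
  if (nIterations < 100) stop("nIterations must be >= 100")
  if (is.null(mask)) mask <- array(TRUE, dim = grid@dims)
  maskIdx <- which(mask)
  if (!length(maskIdx)) stop("mask is empty")
  if (kind == "cluster_size" && is.null(clusterFormingThreshold))
    stop("cluster_size null requires clusterFormingThreshold")
  kernel <- .makeKernel(grid, fwhmMm, truncationFactor)
  d <- grid@dims
  ijkOf <- function(lin) {
    lin0 <- lin - 1L
    cbind(lin0 %% d[1] + 1L,
          (lin0 %/% d[1]) %% d[2] + 1L,
          lin0 %/% (d[1] * d[2]) + 1L)
  }
  samples <- numeric(nIterations)
  .withSeed(seed, {
    for (it in seq_len(nIterations)) {
      comp <- array(1, dim = d)
      for (k in fociCounts) {
        lin <- maskIdx[sample.int(length(maskIdx), k, replace = TRUE)]
        comp <- comp * (1 - .maValues(ijkOf(lin), grid, kernel, mask))
      }
      ale <- 1 - comp
      samples[it] <- if (kind == "voxel_max") max(ale)
                     else .largestCluster(ale >= clusterFormingThreshold, d)
    }
  })
  new("NullDistribution", kind = kind, samples = samples,
      nIterations = as.integer(nIterations), seed = as.integer(seed))
}

## size of the largest 6-connected TRUE cluster in a logical array
.largestCluster <- function(supra, d) {
  lin <- which(supra)
  if (!length(lin)) return(0)
  lab <- integer(prod(d))
  lab[lin] <- -1L            # unvisited suprathreshold
  nxy <- d[1] * d[2]
  best <- 0L
  for (start in lin) {
    if (lab[start] != -1L) next
    queue <- start; lab[start] <- 1L; size <- 0L
    while (length(queue)) {
      v <- queue[[length(queue)]]; queue <- queue[-length(queue)]
      size <- size + 1L
      v0 <- v - 1L
      i <- v0 %% d[1] + 1L; j <- (v0 %/% d[1]) %% d[2] + 1L; k <- v0 %/% nxy + 1L
      nb <- c(if (i > 1L) v - 1L, if (i < d[1]) v + 1L,
              if (j > 1L) v - d[1], if (j < d[2]) v + d[1],
              if (k > 1L) v - nxy, if (k < d[3]) v + nxy)
      nb <- nb[lab[nb] == -1L]
      lab[nb] <- 1L
      queue <- c(queue, nb)
    }
    best <- max(best, size)
  }
  as.numeric(best)
}

#' Threshold an ALE map against a simulated null
#'
#' The threshold is the `(1 - alpha)` empirical quantile of the null samples
#' with "higher" (ceiling order statistic) interpolation — conservative.
#' Voxels with ALE below the threshold are set to 0; voxels at or above it
#' survive.
#'
#' @param aleMap an unthresholded [AleMap-class].
#' @param null a [NullDistribution-class] with `kind = "voxel_max"`.
#' @param alpha family-wise voxel-level error rate, in (0, 1); default 0.05.
#' @return a thresholded [AleMap-class] (`thresholdValue` set); the surviving
#'   voxel count is reported via `message()`.
#' @export
thresholdMap <- function(aleMap, null, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (null@kind != "voxel_max")
    stop("voxel-level FWE thresholding requires a voxel_max null")
  thr <- .quantileHigher(null@samples, 1 - alpha)
  vals <- aleMap@values
  vals[vals < thr] <- 0
  out <- new("AleMap", grid = aleMap@grid, values = vals,
             nExperiments = aleMap@nExperiments, fwhmMm = aleMap@fwhmMm,
             thresholdValue = thr)
  message(sum(vals > 0), " voxels survive thresholding at alpha = ", alpha)
  out
}

## empirical quantile, "higher" interpolation: ceiling order statistic
.quantileHigher <- function(x, p) {
  s <- sort(x)
  s[max(1L, min(length(s), ceiling(p * length(s))))]
}

## evaluate a block with a temporary seed, restoring RNG state afterwards
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  eval.parent(substitute(expr))
}
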
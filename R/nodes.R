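#' Count altered voxels per atlas region
#'
#' A region counts as altered when at least `minRegionVoxels` voxels of the
#' thresholded ALE map fall inside it (default 20); the rule excludes rarely
#' altered regions from the network.
#'
#' @param thresholdedAle a thresholded [AleMap-class].
#' @param atlas an [AtlasVolume-class] on the same grid.
#' @param minRegionVoxels minimum suprathreshold voxel count (default 20).
#' @return `data.frame`: label, name, hemisphere, altered_voxels, passes.
#' @export
alteredRegions <- function(thresholdedAle, atlas, minRegionVoxels = 20) {
  if (!.sameGrid(thresholdedAle@grid, atlas@grid))
    stop("ALE map and atlas grids differ")
  tab <- labelTable(atlas)
  supra <- thresholdedAle@values > 0
  counts <- integer(nrow(tab))
  if (any(supra)) {
    tally <- table(atlas@values[supra])
    tally <- tally[names(tally) != "0"]
    counts[match(as.integer(names(tally)), tab$label)] <- as.integer(tally)
  }
  data.frame(label = tab$label, name = tab$name, hemisphere = tab$hemisphere,
             altered_voxels = counts,
             passes = counts >= minRegionVoxels,
             stringsAsFactors = FALSE)
}

## 26-neighbourhood offsets
.offsets26 <- local({
  o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  o[rowSums(abs(o)) > 0, , drop = FALSE]
})

#' Detect local maxima of a thresholded ALE map
#'
#' Local maxima over 26-connectivity among suprathreshold voxels; plateaus of
#' equal-valued adjacent maxima contribute one peak at the voxel nearest the
#' plateau centroid. Peaks are then filtered to those with value strictly
#' greater than the `percentile`-th percentile of the value distribution,
#' taken over suprathreshold voxel values (`basis = "voxels"`, default,
#' stable when peaks are few) or over the peak values (`basis = "peaks"`).
#'
#' @param thresholdedAle a thresholded [AleMap-class].
#' @param percentile percentile cutoff in [0, 100) (default 90).
#' @param basis which value distribution the percentile refers to.
#' @return `data.frame`: i, j, k (voxel index), x, y, z (mm), ale_value,
#'   ordered by descending ale_value (ties by voxel linear index).
#' @export
detectPeaks <- function(thresholdedAle, percentile = 90,
                        basis = c("voxels", "peaks")) {
  basis <- match.arg(basis)
  if (percentile < 0 || percentile >= 100)
    stop("percentile must lie in [0, 100)")
  grid <- thresholdedAle@grid
  v <- thresholdedAle@values
  d <- grid@dims
  supra <- which(v > 0)
  empty <- data.frame(i = integer(), j = integer(), k = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      ale_value = numeric())
  if (!length(supra)) return(empty)

  idx <- cbind((supra - 1L) %% d[1] + 1L,
               ((supra - 1L) %/% d[1]) %% d[2] + 1L,
               (supra - 1L) %/% (d[1] * d[2]) + 1L)
  # candidate: value >= every 26-neighbour (out-of-grid neighbours ignored)
  cand <- rep(TRUE, length(supra))
  for (r in seq_len(nrow(.offsets26))) {
    nb <- sweep(idx, 2, .offsets26[r, ], "+")
    ok <- inGrid(grid, nb)
    nbVal <- rep(-Inf, length(supra))
    nbVal[ok] <- v[.linearIndex(grid, nb[ok, , drop = FALSE])]
    cand <- cand & (v[supra] >= nbVal)
  }
  ci <- which(cand)
  if (!length(ci)) return(empty)
  peaks <- .collapsePlateaus(idx[ci, , drop = FALSE], v[supra][ci], grid)

  cutVals <- if (basis == "voxels") v[supra] else peaks$ale_value
  cut <- stats::quantile(cutVals, percentile / 100, names = FALSE)
  peaks <- peaks[peaks$ale_value > cut, , drop = FALSE]
  if (!nrow(peaks)) return(empty)
  ord <- order(-peaks$ale_value, .linearIndex(grid, as.matrix(peaks[, 1:3])))
  peaks <- peaks[ord, , drop = FALSE]
  mm <- voxelToWorld(grid, as.matrix(peaks[, c("i", "j", "k")]))
  rownames(peaks) <- NULL
  cbind(peaks[, c("i", "j", "k")], as.data.frame(mm),
        ale_value = peaks$ale_value)
}

## group equal-valued 26-adjacent candidate maxima; keep one representative
## per plateau: the voxel nearest the plateau centroid (ties by linear index)
.collapsePlateaus <- function(idx, vals, grid) {
  n <- nrow(idx)
  comp <- seq_len(n)
  if (n > 1L) {
    for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
      if (vals[a] == vals[b] && all(abs(idx[a, ] - idx[b, ]) <= 1L)) {
        ca <- comp[a]; cb <- comp[b]
        comp[comp == cb] <- ca
      }
    }
  }
  keep <- integer()
  for (g in unique(comp)) {
    members <- which(comp == g)
    if (length(members) == 1L) { keep <- c(keep, members); next }
    ctr <- colMeans(idx[members, , drop = FALSE])
    d2 <- rowSums(sweep(idx[members, , drop = FALSE], 2, ctr)^2)
    lin <- .linearIndex(grid, idx[members, , drop = FALSE])
    keep <- c(keep, members[order(d2, lin)][1L])
  }
  data.frame(i = idx[keep, 1], j = idx[keep, 2], k = idx[keep, 3],
             ale_value = vals[keep])
}

#' Enforce a minimum inter-peak distance
#'
#' Greedy selection in descending ALE-value order (ties broken by voxel linear
#' index, so the result is independent of input order): a peak is kept iff its
#' Euclidean mm distance to every already-kept peak is at least
#' `minInterpeakMm`. The comparison is inclusive: two peaks exactly
#' `minInterpeakMm` apart are both kept.
#'
#' @param peaks `data.frame` as returned by [detectPeaks()].
#' @param minInterpeakMm minimum distance in mm (default 10).
#' @param grid optional [VolumeGrid-class] used only for canonical tie-breaks.
#' @return the retained peaks, sorted by descending ale_value.
#' @export
enforceInterpeakDistance <- function(peaks, minInterpeakMm = 10, grid = NULL) {
  if (!nrow(peaks)) return(peaks)
  tie <- if (!is.null(grid) && all(c("i", "j", "k") %in% names(peaks)))
    .linearIndex(grid, as.matrix(peaks[, c("i", "j", "k")]))
  else seq_len(nrow(peaks))
  ord <- order(-peaks$ale_value, tie)
  peaks <- peaks[ord, , drop = FALSE]
  xyz <- as.matrix(peaks[, c("x", "y", "z")])
  keep <- logical(nrow(peaks))
  for (r in seq_len(nrow(peaks))) {
    if (!any(keep)) { keep[r] <- TRUE; next }
    dmin <- min(sqrt(rowSums(sweep(xyz[keep, , drop = FALSE], 2, xyz[r, ])^2)))
    keep[r] <- dmin >= minInterpeakMm
  }
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label surviving peaks as network nodes
#'
#' Peaks falling in the background or in regions that fail the altered-region
#' rule are dropped with a warning. Within each region, nodes are numbered
#' `<RegionName>_1`, `_2`, ... by descending y (anterior to posterior, the
#' rostrocaudal criterion), ties broken by descending ALE value.
#'
#' @param peaks distance-filtered peaks ([enforceInterpeakDistance()]).
#' @param atlas an [AtlasVolume-class].
#' @param regions output of [alteredRegions()].
#' @return node `data.frame`: id, region, hemisphere, x, y, z, ale_value.
#' @export
labelNodes <- function(peaks, atlas, regions) {
  empty <- data.frame(id = character(), region = character(),
                      hemisphere = character(), x = numeric(), y = numeric(),
                      z = numeric(), ale_value = numeric())
  if (!nrow(peaks)) return(empty)
  lab <- atlas@values[.linearIndex(atlas@grid,
                                   as.matrix(peaks[, c("i", "j", "k")]))]
  passing <- regions$label[regions$passes]
  drop <- lab == 0L | !(lab %in% passing)
  if (any(drop))
    warning(sum(drop), " peak(s) in background or non-passing regions dropped")
  peaks <- peaks[!drop, , drop = FALSE]
  lab <- lab[!drop]
  if (!nrow(peaks)) return(empty)
  tab <- labelTable(atlas)
  region <- tab$name[match(lab, tab$label)]
  hemi <- tab$hemisphere[match(lab, tab$label)]
  out <- data.frame(region = region, hemisphere = hemi,
                    x = peaks$x, y = peaks$y, z = peaks$z,
                    ale_value = peaks$ale_value, stringsAsFactors = FALSE)
  out$id <- NA_character_
  for (rg in unique(region)) {
    rows <- which(region == rg)
    ord <- rows[order(-out$y[rows], -out$ale_value[rows])]
    out$id[ord] <- paste0(rg, "_", seq_along(ord))
  }
  rownames(out) <- NULL
  out[, c("id", "region", "hemisphere", "x", "y", "z", "ale_value")]
}

#' Build network nodes from a thresholded ALE map
#'
#' Chains [alteredRegions()], [detectPeaks()], [enforceInterpeakDistance()]
#' and [labelNodes()]. By default the region rule is applied after the
#' distance filter, so a strong peak in a failing region still suppresses
#' nearby peaks (conservative); set `regionRuleFirst = TRUE` to drop peaks in
#' failing regions before the distance filter.
#'
#' @inheritParams alteredRegions
#' @inheritParams detectPeaks
#' @inheritParams enforceInterpeakDistance
#' @param regionRuleFirst apply the region rule before the distance filter.
#' @return list with elements `regions` and `nodes`.
#' @export
buildNodes <- function(thresholdedAle, atlas, minRegionVoxels = 20,
                       percentile = 90, basis = c("voxels", "peaks"),
                       minInterpeakMm = 10, regionRuleFirst = FALSE) {
  regions <- alteredRegions(thresholdedAle, atlas, minRegionVoxels)
  peaks <- detectPeaks(thresholdedAle, percentile, basis)
  if (regionRuleFirst && nrow(peaks)) {
    lab <- atlas@values[.linearIndex(atlas@grid,
                                     as.matrix(peaks[, c("i", "j", "k")]))]
    peaks <- peaks[lab %in% regions$label[regions$passes], , drop = FALSE]
  }
  peaks <- enforceInterpeakDistance(peaks, minInterpeakMm, thresholdedAle@grid)
  nodes <- labelNodes(peaks, atlas, regions)
  list(regions = regions, nodes = nodes)
}
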
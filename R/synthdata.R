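#' Construct a generative specification
#'
#' @param nExperiments number of experiments to simulate.
#' @param regions `data.frame` with columns name, hemisphere, cx, cy, cz
#'   (centre mm), hx, hy, hz (cuboid half-sizes mm); cuboids must be disjoint.
#' @param baseProb per-region marginal alteration probability (recycled).
#' @param couplings `data.frame` with columns region_a, region_b, excess
#'   (joint excess probability over independence); must form a matching.
#' @param fociPerRegion integer(2) min/max foci per altered region.
#' @param noiseFoci integer(2) min/max uniform noise foci per experiment.
#' @param scatterSd focus scatter sd in mm about region centres.
#' @param seed RNG seed.
#' @return a [GenerativeSpec-class] (validated at construction).
#' @export
generativeSpec <- function(nExperiments, regions, baseProb, couplings = NULL,
                           fociPerRegion = c(2L, 4L), noiseFoci = c(0L, 3L),
                           scatterSd = 4, seed = 0L) {
  if (is.null(couplings))
    couplings <- data.frame(region_a = character(), region_b = character(),
                            excess = numeric())
  new("GenerativeSpec", nExperiments = as.integer(nExperiments),
      regions = regions,
      baseProb = rep_len(baseProb, nrow(regions)),
      couplings = couplings,
      fociPerRegion = as.integer(fociPerRegion),
      noiseFoci = as.integer(noiseFoci),
      scatterSd = as.numeric(scatterSd), seed = as.integer(seed))
}

#' Default generative specification
#'
#' The package's reference simulation: 60 experiments over a toy brain of 10
#' mirrored cuboid regions (5 per hemisphere), marginal alteration
#' probability 0.5 everywhere, and 4 planted pairwise couplings with
#' population kappa 0.9, 0.8, 0.7 and 0.6 (a mix of inter- and
#' intrahemispheric pairs). Focus scatter sd 4 mm (about the sigma of a 10 mm
#' FWHM kernel, so ALE peaks land near region centres) and 0-3 uniform noise
#' foci per experiment.
#'
#' @param seed RNG seed (default 0).
#' @return a [GenerativeSpec-class].
#' @export
defaultGenerativeSpec <- function(seed = 0L) {
  half <- 10
  base <- data.frame(
    name = c("Frontal", "Temporal", "Parietal", "Occipital", "Limbic"),
    cy = c(40, 10, -30, -70, -20),
    cz = c(30, -10, 50, 10, -30))
  regions <- do.call(rbind, lapply(c("L", "R"), function(h)
    data.frame(name = paste0(base$name, "_", h), hemisphere = h,
               cx = if (h == "L") -40 else 40, cy = base$cy, cz = base$cz,
               hx = half, hy = half, hz = half, stringsAsFactors = FALSE)))
  # population kappa k with p = 0.5 marginals: theta1 = 1/4 + k/4,
  # so excess = theta1 - 1/4 = k/4
  couplings <- data.frame(
    region_a = c("Temporal_L", "Frontal_L", "Limbic_R", "Frontal_R"),
    region_b = c("Temporal_R", "Parietal_L", "Occipital_R", "Occipital_L"),
    excess = c(0.9, 0.8, 0.7, 0.6) / 4,
    stringsAsFactors = FALSE)
  generativeSpec(60L, regions, baseProb = 0.5, couplings = couplings,
                 fociPerRegion = c(2L, 4L), noiseFoci = c(0L, 3L),
                 scatterSd = 4, seed = seed)
}

#' Rasterize a generative specification into a toy atlas
#'
#' Labels each region's cuboid with consecutive integer labels on the given
#' grid (a voxel belongs to a region when its centre lies inside the cuboid).
#'
#' @param spec a [GenerativeSpec-class].
#' @param grid a [VolumeGrid-class]; all regions must fit inside it.
#' @return an [AtlasVolume-class].
#' @export
makeToyAtlas <- function(spec, grid) {
  rg <- spec@regions
  lo <- grid@origin
  hi <- grid@origin + (grid@dims - 1L) * grid@voxelSize
  vals <- array(0L, dim = grid@dims)
  ax <- lo[1] + (seq_len(grid@dims[1]) - 1) * grid@voxelSize
  ay <- lo[2] + (seq_len(grid@dims[2]) - 1) * grid@voxelSize
  az <- lo[3] + (seq_len(grid@dims[3]) - 1) * grid@voxelSize
  for (r in seq_len(nrow(rg))) {
    if (rg$cx[r] - rg$hx[r] < lo[1] || rg$cx[r] + rg$hx[r] > hi[1] ||
        rg$cy[r] - rg$hy[r] < lo[2] || rg$cy[r] + rg$hy[r] > hi[2] ||
        rg$cz[r] - rg$hz[r] < lo[3] || rg$cz[r] + rg$hz[r] > hi[3])
      stop("region outside the grid bounding box: ", rg$name[r])
    ix <- which(abs(ax - rg$cx[r]) <= rg$hx[r])
    iy <- which(abs(ay - rg$cy[r]) <= rg$hy[r])
    iz <- which(abs(az - rg$cz[r]) <= rg$hz[r])
    vals[ix, iy, iz] <- r
  }
  new("AtlasVolume", grid = grid, values = vals,
      labelTable = data.frame(label = seq_len(nrow(rg)), name = rg$name,
                              hemisphere = rg$hemisphere,
                              stringsAsFactors = FALSE))
}

## 4-cell joint probabilities (both, a-only, b-only, neither) of a coupled
## pair under the spec
.pairTheta <- function(spec, regionA, regionB) {
  p <- stats::setNames(spec@baseProb, spec@regions$name)
  cp <- spec@couplings
  hit <- (cp$region_a == regionA & cp$region_b == regionB) |
         (cp$region_a == regionB & cp$region_b == regionA)
  excess <- if (any(hit)) cp$excess[which(hit)[1]] else 0
  th1 <- p[regionA] * p[regionB] + excess
  unname(c(th1, p[regionA] - th1, p[regionB] - th1,
           1 - p[regionA] - p[regionB] + th1))
}

#' Population Patel's kappa of a region pair
#'
#' Applies the kappa formula chain to the exact 4-cell probabilities implied
#' by the generative specification (closed form, no sampling); the recovery
#' target for planted pairs.
#'
#' @param spec a [GenerativeSpec-class].
#' @param pair character(2) region names.
#' @return kappa (NA when a marginal is degenerate).
#' @export
populationKappa <- function(spec, pair) {
  stopifnot(length(pair) == 2L, all(pair %in% spec@regions$name))
  patelKappa(.pairTheta(spec, pair[1], pair[2]))
}

#' Simulate a synthetic coalteration dataset
#'
#' Per experiment, samples each planted pair's joint alteration state from
#' its exact 4-cell multinomial and each uncoupled region independently as
#' Bernoulli(baseProb). Every altered region contributes foci drawn from an
#' isotropic Gaussian about the region centre (sd `scatterSd`), truncated to
#' the region cuboid by rejection; uniform noise foci over the atlas's
#' labeled voxels are added. Fully reproducible given the spec's seed.
#'
#' @param spec a [GenerativeSpec-class].
#' @param atlas the [AtlasVolume-class] from [makeToyAtlas()] (supplies the
#'   mask for noise foci).
#' @param fociPath optional path; when given, the experiments are also
#'   written as a Sleuth-style foci file.
#' @return list: `experiments` (list of [Experiment-class]), `truth` (list
#'   with `alteration` binary matrix experiments x regions, `planted`
#'   `data.frame` with population kappa per planted pair, `centers`), and
#'   `fociPath` (NULL unless written).
#' @export
simulateDataset <- function(spec, atlas, fociPath = NULL) {
  rg <- spec@regions
  nR <- nrow(rg)
  nE <- spec@nExperiments
  p <- spec@baseProb
  cp <- spec@couplings
  coupledIdx <- cbind(match(cp$region_a, rg$name), match(cp$region_b, rg$name))
  freeIdx <- setdiff(seq_len(nR), as.vector(coupledIdx))
  maskLin <- which(atlas@values != 0L)
  if (!length(maskLin)) stop("atlas has no labeled voxels to place noise foci")
  d <- atlas@grid@dims
  alter <- matrix(0L, nE, nR, dimnames = list(sprintf("exp%03d", seq_len(nE)),
                                              rg$name))
  experiments <- vector("list", nE)
  .withSeed(spec@seed, {
    for (e in seq_len(nE)) {
      # planted pairs: exact 4-cell multinomial
      if (nrow(cp)) for (q in seq_len(nrow(cp))) {
        th <- .pairTheta(spec, cp$region_a[q], cp$region_b[q])
        cell <- sample.int(4L, 1L, prob = pmax(th, 0))
        ia <- coupledIdx[q, 1]; ib <- coupledIdx[q, 2]
        alter[e, ia] <- as.integer(cell %in% c(1L, 2L))
        alter[e, ib] <- as.integer(cell %in% c(1L, 3L))
      }
      for (i in freeIdx) alter[e, i] <- stats::rbinom(1L, 1L, p[i])
      foci <- matrix(numeric(0), ncol = 3L)
      for (i in which(alter[e, ] == 1L)) {
        k <- sample(seq(spec@fociPerRegion[1], spec@fociPerRegion[2]), 1L)
        ctr <- c(rg$cx[i], rg$cy[i], rg$cz[i])
        hs <- c(rg$hx[i], rg$hy[i], rg$hz[i])
        got <- 0L
        while (got < k) {       # rejection-truncate scatter to the cuboid
          f <- stats::rnorm(3L, ctr, spec@scatterSd)
          if (all(abs(f - ctr) <= hs)) {
            foci <- rbind(foci, f)
            got <- got + 1L
          }
        }
      }
      nNoise <- sample(seq(spec@noiseFoci[1], spec@noiseFoci[2]), 1L)
      if (nNoise > 0L) {
        lin <- maskLin[sample.int(length(maskLin), nNoise, replace = TRUE)]
        lin0 <- lin - 1L
        idx <- cbind(lin0 %% d[1] + 1L, (lin0 %/% d[1]) %% d[2] + 1L,
                     lin0 %/% (d[1] * d[2]) + 1L)
        foci <- rbind(foci, voxelToWorld(atlas@grid, idx))
      }
      if (!nrow(foci)) {        # keep the block valid: one noise focus
        lin <- maskLin[sample.int(length(maskLin), 1L)]
        lin0 <- lin - 1L
        idx <- cbind(lin0 %% d[1] + 1L, (lin0 %/% d[1]) %% d[2] + 1L,
                     lin0 %/% (d[1] * d[2]) + 1L)
        foci <- voxelToWorld(atlas@grid, idx)
      }
      experiments[[e]] <- Experiment(sprintf("exp%03d", e), foci,
                                     label = sprintf("SyntheticStudy%03d", e))
    }
  })
  planted <- if (nrow(cp)) data.frame(
    region_a = cp$region_a, region_b = cp$region_b,
    population_kappa = vapply(seq_len(nrow(cp)), function(q)
      populationKappa(spec, c(cp$region_a[q], cp$region_b[q])), 0),
    stringsAsFactors = FALSE)
  else data.frame(region_a = character(), region_b = character(),
                  population_kappa = numeric())
  if (!is.null(fociPath)) writeFociFile(experiments, fociPath)
  list(experiments = experiments,
       truth = list(alteration = alter, planted = planted,
                    centers = rg[, c("name", "cx", "cy", "cz")]),
       fociPath = fociPath)
}
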
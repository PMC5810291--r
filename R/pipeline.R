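#' Default pipeline configuration
#'
#' Returns the full set of tunable parameters with their defaults: kernel
#' FWHM 10 mm (the mean reported spatial-location uncertainty is about 10
#' mm), voxel-level FWE alpha 0.05 with a voxel-max null, the three
#' node-creation thresholds (20 voxels, 90th percentile over suprathreshold
#' voxel values, 10 mm interpeak distance), the 10 mm focus-to-node
#' assignment radius, and the edge test (e = 0, p < 0.01, 10^4 Dirichlet
#' draws under a flat prior).
#'
#' @param ... overrides for any of the defaults.
#' @return named list of parameters.
#' @export
coalternetConfig <- function(...) {
  cfg <- list(
    voxel_size = 2,
    fwhm_mm = 10,
    truncation_factor = 3,
    null_kind = "voxel_max",
    null_iterations = 1000,
    alpha = 0.05,
    cluster_forming_threshold = NULL,
    min_region_voxels = 20,
    peak_percentile = 90,
    peak_percentile_basis = "voxels",
    min_interpeak_mm = 10,
    region_rule_first = FALSE,
    assign_rule = "radius",
    assign_radius_mm = 10,
    e_threshold = 0,
    p_threshold = 0.01,
    mc_samples = 10000,
    alpha0 = 1,
    betweenness_ties = "fractional")
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(cfg, over, keep.null = TRUE)
}

#' Read a YAML configuration file
#'
#' @param path YAML file whose keys match [coalternetConfig()].
#' @return a complete config list (file values over defaults).
#' @export
readConfig <- function(path) {
  coalternetConfig(yaml::read_yaml(path))
}

## in-brain mask: atlas nonzero voxels dilated by one voxel (6-connectivity)
.brainMask <- function(atlas) {
  m <- atlas@values != 0L
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}

#' Run the full coalteration-network pipeline
#'
#' experiments -> ALE map -> simulated-null thresholding -> node creation ->
#' coalteration matrix -> Patel's-kappa edges -> topology report.
#'
#' @param experiments list of [Experiment-class] (e.g. from
#'   [readFociFile()]).
#' @param atlas an [AtlasVolume-class] on the analysis grid.
#' @param config parameter list from [coalternetConfig()].
#' @param seed master seed; the null simulation and the per-pair Monte-Carlo
#'   draw sub-seeds from it.
#' @param outDir optional output directory for [writeOutputs()].
#' @return list: `aleMap`, `thresholded`, `null`, `regions`, `nodes`,
#'   `matrix`, `network`, `topology`, and `outputs` (files written, or NULL).
#' @export
runPipeline <- function(experiments, atlas, config = coalternetConfig(),
                        seed = 1, outDir = NULL) {
  grid <- atlas@grid
  mask <- .brainMask(atlas)
  ale <- computeAleMap(experiments, grid, fwhmMm = config$fwhm_mm,
                       mask = mask,
                       truncationFactor = config$truncation_factor)
  fociCounts <- vapply(experiments, function(e) nrow(e@foci), 0L)
  null <- buildNull(fociCounts, grid, mask, fwhmMm = config$fwhm_mm,
                    nIterations = config$null_iterations, seed = seed,
                    kind = config$null_kind,
                    clusterFormingThreshold = config$cluster_forming_threshold,
                    truncationFactor = config$truncation_factor)
  thr <- thresholdMap(ale, null, alpha = config$alpha)
  nb <- buildNodes(thr, atlas,
                   minRegionVoxels = config$min_region_voxels,
                   percentile = config$peak_percentile,
                   basis = config$peak_percentile_basis,
                   minInterpeakMm = config$min_interpeak_mm,
                   regionRuleFirst = config$region_rule_first)
  if (!nrow(nb$nodes)) stop("no nodes survive the node-creation thresholds")
  mat <- buildMatrix(experiments, nb$nodes,
                     assignRadiusMm = config$assign_radius_mm,
                     rule = config$assign_rule, atlas = atlas)
  net <- buildNetwork(mat, nb$nodes,
                      eThreshold = config$e_threshold,
                      pThreshold = config$p_threshold,
                      nSamples = config$mc_samples,
                      seed = seed + 1000L, alpha0 = config$alpha0)
  topo <- topologyReport(net, ties = config$betweenness_ties)
  outputs <- NULL
  if (!is.null(outDir))
    outputs <- writeOutputs(nb$nodes, mat, net, outDir, aleMap = thr,
                            config = config, seed = seed)
  list(aleMap = ale, thresholded = thr, null = null,
       regions = nb$regions, nodes = nb$nodes, matrix = mat,
       network = net, topology = topo, outputs = outputs)
}
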
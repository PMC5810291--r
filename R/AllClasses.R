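#' Voxel-grid geometry
#'
#' An axis-aligned isotropic voxel lattice in stereotaxic (Talairach) space.
#' `origin` is the millimetre coordinate of the centre of voxel (1,1,1); voxel
#' centres along each axis are `origin + (index - 1) * voxelSize`.
#'
#' @slot origin numeric(3), mm coordinate of the first voxel centre.
#' @slot voxelSize numeric(1), isotropic voxel edge length in mm.
#' @slot dims integer(3), grid extent in voxels.
#' @export
setClass("VolumeGrid",
  representation(origin = "numeric", voxelSize = "numeric", dims = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be 3 finite mm coordinates")
    if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
        object@voxelSize <= 0)
      msg <- c(msg, "voxelSize must be a single positive number")
    if (length(object@dims) != 3L || any(object@dims < 1L))
      msg <- c(msg, "dims must be 3 positive integers")
    if (length(msg)) msg else TRUE
  })

#' Virtual parent of voxel-wise volumes
#'
#' @slot grid the [VolumeGrid-class] hosting the values.
#' @slot values 3-D array conforming to `grid@dims`.
#' @keywords internal
setClass("VoxelVolume",
  representation(grid = "VolumeGrid", values = "array", "VIRTUAL"),
  validity = function(object) {
    if (!identical(dim(object@values), as.integer(object@grid@dims)))
      return("values array dimensions must equal grid dims")
    TRUE
  })

#' Modeled alteration (MA) map of one experiment
#'
#' Per-voxel probability that the experiment's reported alteration lies in the
#' voxel: the maximum, over the experiment's foci, of an isotropic Gaussian
#' kernel converted to a per-voxel probability.
#'
#' @slot experimentId id of the experiment the map models.
#' @slot fwhmMm kernel full-width at half-maximum in mm.
#' @export
setClass("MaMap", contains = "VoxelVolume",
  representation(experimentId = "character", fwhmMm = "numeric"),
  validity = function(object) {
    v <- object@values
    if (any(v < 0 | v > 1)) return("MA values must lie in [0, 1]")
    TRUE
  })

#' Anatomical likelihood estimation (ALE) map
#'
#' Voxel-wise union of the per-experiment MA maps:
#' \eqn{ALE = 1 - \prod_i (1 - MA_i)}. `thresholdValue` is `NA` until the map
#' has been thresholded against a simulated null.
#'
#' @slot nExperiments number of experiments united into the map.
#' @slot fwhmMm kernel FWHM in mm shared by the MA maps.
#' @slot thresholdValue ALE cutoff applied (NA if unthresholded).
#' @export
setClass("AleMap", contains = "VoxelVolume",
  representation(nExperiments = "integer", fwhmMm = "numeric",
                 thresholdValue = "numeric"),
  prototype(thresholdValue = NA_real_),
  validity = function(object) {
    v <- object@values
    if (any(v < 0 | v >= 1)) return("ALE values must lie in [0, 1)")
    TRUE
  })

#' Integer-labeled atlas volume
#'
#' @slot labelTable `data.frame` with columns `label` (integer, nonzero),
#'   `name` (unique region names) and `hemisphere` ("L", "R" or "M").
#' @export
setClass("AtlasVolume", contains = "VoxelVolume",
  representation(labelTable = "data.frame"),
  validity = function(object) {
    msg <- character()
    tab <- object@labelTable
    need <- c("label", "name", "hemisphere")
    if (!all(need %in% names(tab)))
      return("labelTable must have columns label, name, hemisphere")
    if (anyDuplicated(tab$name)) msg <- c(msg, "region names must be unique")
    if (anyDuplicated(tab$label)) msg <- c(msg, "labels must be unique")
    v <- object@values
    if (any(v != round(v))) msg <- c(msg, "atlas voxel values must be integers")
    present <- setdiff(unique(as.integer(v)), 0L)
    missing <- setdiff(present, as.integer(tab$label))
    if (length(missing))
      msg <- c(msg, paste0("labels present in volume but missing from table: ",
                           paste(sort(missing), collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' One coordinate-based experiment (VBM contrast)
#'
#' @slot id short unique identifier.
#' @slot label free-text study/contrast description.
#' @slot nSubjects subject count (NA if unreported).
#' @slot foci numeric matrix, one row per focus, columns x/y/z in Talairach mm.
#' @export
setClass("Experiment",
  representation(id = "character", label = "character",
                 nSubjects = "integer", foci = "matrix"),
  prototype(nSubjects = NA_integer_),
  validity = function(object) {
    msg <- character()
    if (length(object@id) != 1L || !nzchar(object@id))
      msg <- c(msg, "id must be a nonempty string")
    f <- object@foci
    if (!is.numeric(f) || ncol(f) != 3L || nrow(f) < 1L)
      msg <- c(msg, "foci must be a numeric matrix with 3 columns and >= 1 row")
    else if (any(!is.finite(f)))
      msg <- c(msg, "focus coordinates must be finite")
    if (!is.na(object@nSubjects) && object@nSubjects < 1L)
      msg <- c(msg, "nSubjects must be positive")
    if (length(msg)) msg else TRUE
  })

#' Simulated null distribution of an ALE summary statistic
#'
#' @slot kind "voxel_max" (maximum ALE value) or "cluster_size" (largest
#'   suprathreshold 6-connected cluster).
#' @slot samples one null statistic per iteration.
#' @slot nIterations number of simulated datasets.
#' @slot seed RNG seed used.
#' @export
setClass("NullDistribution",
  representation(kind = "character", samples = "numeric",
                 nIterations = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("voxel_max", "cluster_size"))
      msg <- c(msg, "kind must be 'voxel_max' or 'cluster_size'")
    if (length(object@samples) != object@nIterations)
      msg <- c(msg, "samples length must equal nIterations")
    if (length(msg)) msg else TRUE
  })

#' Binary experiments-by-nodes coalteration matrix
#'
#' Cell (e, j) is 1 when experiment e shows alteration at node j.
#'
#' @slot cells integer 0/1 matrix with experiment ids as rownames and node ids
#'   as colnames.
#' @export
setClass("CoalterationMatrix",
  representation(cells = "matrix"),
  validity = function(object) {
    m <- object@cells
    if (!all(m %in% c(0L, 1L))) return("cells must be 0/1")
    if (is.null(rownames(m)) || is.null(colnames(m)))
      return("cells must carry experiment ids (rownames) and node ids (colnames)")
    if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
      return("experiment and node ids must be unique")
    TRUE
  })

#' Undirected coalteration network
#'
#' Nodes are atlas-labeled ALE peaks; edges are node pairs whose coalteration,
#' measured by Patel's kappa, is significant under the Dirichlet Monte-Carlo
#' test. `pairTests` keeps the full per-pair results (including
#' non-significant and degenerate pairs) for reporting.
#'
#' @slot nodes `data.frame`: id, region, hemisphere, x, y, z, ale_value.
#' @slot edges `data.frame` of significant pairs: node_a, node_b, kappa,
#'   posterior_prob.
#' @slot pairTests `data.frame` of all evaluated pairs.
#' @slot params list of the parameters used to build the network.
#' @export
setClass("CoalterationNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 pairTests = "data.frame", params = "list"),
  validity = function(object) {
    msg <- character()
    nd <- object@nodes; ed <- object@edges
    if (!"id" %in% names(nd)) return("nodes must have an 'id' column")
    if (anyDuplicated(nd$id)) msg <- c(msg, "node ids must be unique")
    if (nrow(ed)) {
      if (!all(c("node_a", "node_b") %in% names(ed)))
        return("edges must have node_a/node_b columns")
      if (!all(c(ed$node_a, ed$node_b) %in% nd$id))
        msg <- c(msg, "edge endpoints must exist among nodes")
      if (any(ed$node_a == ed$node_b)) msg <- c(msg, "self-loops not allowed")
      key <- paste(pmin(ed$node_a, ed$node_b), pmax(ed$node_a, ed$node_b))
      if (anyDuplicated(key)) msg <- c(msg, "duplicate undirected edges")
    }
    if (length(msg)) msg else TRUE
  })

#' Generative specification for synthetic coalteration datasets
#'
#' Defines a toy brain of disjoint cuboid regions, per-region alteration
#' probabilities, planted pairwise couplings (excess joint alteration
#' probability over independence), and focus-placement noise. Couplings must
#' form a matching: each region participates in at most one coupling, so every
#' planted pair's 4-cell joint distribution can be sampled exactly.
#'
#' @slot nExperiments number of simulated experiments.
#' @slot regions `data.frame`: name, hemisphere, cx, cy, cz (centre mm),
#'   hx, hy, hz (cuboid half-sizes mm).
#' @slot baseProb per-region marginal alteration probability.
#' @slot couplings `data.frame`: region_a, region_b, excess (joint excess
#'   probability theta1 - pa*pb).
#' @slot fociPerRegion integer(2), min/max foci drawn per altered region.
#' @slot noiseFoci integer(2), min/max uniform noise foci per experiment.
#' @slot scatterSd mm standard deviation of focus scatter about region centres.
#' @slot seed RNG seed for simulation.
#' @export
setClass("GenerativeSpec",
  representation(nExperiments = "integer", regions = "data.frame",
                 baseProb = "numeric", couplings = "data.frame",
                 fociPerRegion = "integer", noiseFoci = "integer",
                 scatterSd = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    rg <- object@regions
    need <- c("name", "hemisphere", "cx", "cy", "cz", "hx", "hy", "hz")
    if (!all(need %in% names(rg)))
      return("regions needs columns name, hemisphere, cx, cy, cz, hx, hy, hz")
    if (anyDuplicated(rg$name)) msg <- c(msg, "region names must be unique")
    if (length(object@baseProb) != nrow(rg))
      msg <- c(msg, "baseProb must have one entry per region")
    if (any(object@baseProb < 0 | object@baseProb > 1))
      msg <- c(msg, "baseProb must lie in [0, 1]")
    cp <- object@couplings
    if (nrow(cp)) {
      if (!all(c("region_a", "region_b", "excess") %in% names(cp)))
        return("couplings needs columns region_a, region_b, excess")
      used <- c(cp$region_a, cp$region_b)
      if (!all(used %in% rg$name))
        msg <- c(msg, "coupling regions must be named regions")
      if (anyDuplicated(used))
        msg <- c(msg, "couplings must form a matching (region used once)")
      p <- stats::setNames(object@baseProb, rg$name)
      th1 <- p[cp$region_a] * p[cp$region_b] + cp$excess
      th <- cbind(th1, p[cp$region_a] - th1, p[cp$region_b] - th1,
                  1 - p[cp$region_a] - p[cp$region_b] + th1)
      if (any(th < -1e-12 | th > 1 + 1e-12))
        msg <- c(msg, "a coupling implies joint probabilities outside the simplex")
    }
    # pairwise region overlap (axis-aligned cuboids)
    if (nrow(rg) > 1L) {
      for (i in seq_len(nrow(rg) - 1L)) for (j in (i + 1L):nrow(rg)) {
        sep <- abs(rg$cx[i] - rg$cx[j]) >= rg$hx[i] + rg$hx[j] ||
               abs(rg$cy[i] - rg$cy[j]) >= rg$hy[i] + rg$hy[j] ||
               abs(rg$cz[i] - rg$cz[j]) >= rg$hz[i] + rg$hz[j]
        if (!sep)
          msg <- c(msg, paste0("regions overlap: ", rg$name[i], " / ", rg$name[j]))
      }
    }
    if (object@nExperiments < 1L) msg <- c(msg, "nExperiments must be >= 1")
    if (any(object@fociPerRegion < 1L) || object@fociPerRegion[2] < object@fociPerRegion[1])
      msg <- c(msg, "fociPerRegion must be an increasing range of positive counts")
    if (any(object@noiseFoci < 0L) || object@noiseFoci[2] < object@noiseFoci[1])
      msg <- c(msg, "noiseFoci must be a nonnegative increasing range")
    if (object@scatterSd <= 0) msg <- c(msg, "scatterSd must be positive")
    if (length(msg)) msg else TRUE
  })

## ---- accessor methods -------------------------------------------------

#' @rdname accessors
setMethod("gridGeometry", "VoxelVolume", function(x) x@grid)
#' @rdname accessors
setMethod("voxelValues", "VoxelVolume", function(x) x@values)
#' @rdname accessors
setMethod("labelTable", "AtlasVolume", function(x) x@labelTable)
#' @rdname accessors
setMethod("experimentIds", "CoalterationMatrix", function(x) rownames(x@cells))
#' @rdname accessors
setMethod("nodeIds", "CoalterationMatrix", function(x) colnames(x@cells))
#' @rdname accessors
setMethod("networkNodes", "CoalterationNetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("networkEdges", "CoalterationNetwork", function(x) x@edges)
#' @rdname accessors
setMethod("pairTests", "CoalterationNetwork", function(x) x@pairTests)

#' Coerce a CoalterationMatrix to a base matrix
#'
#' @param x a [CoalterationMatrix-class].
#' @param ... ignored.
#' @return integer 0/1 matrix with dimnames.
#' @export
setMethod("as.matrix", "CoalterationMatrix", function(x, ...) x@cells)

## ---- show methods -----------------------------------------------------

setMethod("show", "VolumeGrid", function(object) {
  cat("VolumeGrid:", paste(object@dims, collapse = " x "),
      sprintf("voxels @ %g mm\n", object@voxelSize))
  lo <- object@origin
  hi <- object@origin + (object@dims - 1L) * object@voxelSize
  cat(sprintf("  bounding box x [%g, %g]  y [%g, %g]  z [%g, %g] mm\n",
              lo[1], hi[1], lo[2], hi[2], lo[3], hi[3]))
})

setMethod("show", "AleMap", function(object) {
  cat(sprintf("AleMap: %s voxels, %d experiments, FWHM %g mm\n",
              paste(object@grid@dims, collapse = " x "),
              object@nExperiments, object@fwhmMm))
  cat(sprintf("  max ALE %.4g; %s\n", max(object@values),
              if (is.na(object@thresholdValue)) "unthresholded"
              else sprintf("thresholded at %.4g (%d voxels survive)",
                           object@thresholdValue, sum(object@values > 0))))
})

setMethod("show", "AtlasVolume", function(object) {
  cat(sprintf("AtlasVolume: %s voxels, %d regions\n",
              paste(object@grid@dims, collapse = " x "),
              nrow(object@labelTable)))
})

setMethod("show", "Experiment", function(object) {
  cat(sprintf("Experiment %s (%s): %d foci%s\n", object@id, object@label,
              nrow(object@foci),
              if (is.na(object@nSubjects)) ""
              else sprintf(", %d subjects", object@nSubjects)))
})

setMethod("show", "CoalterationMatrix", function(object) {
  cat(sprintf("CoalterationMatrix: %d experiments x %d nodes (%.1f%% altered)\n",
              nrow(object@cells), ncol(object@cells),
              100 * mean(object@cells)))
})

setMethod("show", "CoalterationNetwork", function(object) {
  cat(sprintf("CoalterationNetwork: %d nodes, %d significant edges (of %d pairs tested)\n",
              nrow(object@nodes), nrow(object@edges), nrow(object@pairTests)))
})

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf("NullDistribution (%s): %d iterations, seed %d\n",
              object@kind, object@nIterations, object@seed))
})

setMethod("show", "GenerativeSpec", function(object) {
  cat(sprintf("GenerativeSpec: %d experiments, %d regions, %d planted couplings, seed %d\n",
              object@nExperiments, nrow(object@regions),
              nrow(object@couplings), object@seed))
})
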
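#' @import methods
NULL

#' Accessor generics
#'
#' Small family of accessors used across the package's S4 classes.
#'
#' @param x An object of one of the package's S4 classes.
#' @return `gridGeometry` returns a [VolumeGrid-class]; `voxelValues` a numeric
#'   (or integer) 3-D array; `labelTable` a `data.frame` with columns `label`,
#'   `name`, `hemisphere`; `experimentIds` / `nodeIds` character vectors;
#'   `networkNodes` / `networkEdges` / `pairTests` `data.frame`s.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("gridGeometry", function(x) standardGeneric("gridGeometry"))

#' @rdname accessors
#' @export
setGeneric("voxelValues", function(x) standardGeneric("voxelValues"))

#' @rdname accessors
#' @export
setGeneric("labelTable", function(x) standardGeneric("labelTable"))

#' @rdname accessors
#' @export
setGeneric("experimentIds", function(x) standardGeneric("experimentIds"))

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("pairTests", function(x) standardGeneric("pairTests"))
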
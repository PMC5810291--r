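#' Construct an Experiment
#'
#' @param id short unique identifier.
#' @param foci numeric n x 3 matrix (or length-3 vector) of Talairach mm
#'   coordinates.
#' @param label free-text description (defaults to the id).
#' @param nSubjects subject count, or NA when unreported.
#' @return an [Experiment-class].
#' @export
Experiment <- function(id, foci, label = id, nSubjects = NA_integer_) {
  foci <- .asCoordMatrix(foci)
  colnames(foci) <- c("x", "y", "z")
  new("Experiment", id = as.character(id), label = as.character(label),
      nSubjects = as.integer(nSubjects), foci = foci)
}

#' Read a Sleuth-style foci file
#'
#' The dialect: lines starting with `//` open or annotate an experiment block.
#' The first `//` line of a block is its label; `// Subjects=<n>` records the
#' subject count; a `// Reference=<space>` header declares the coordinate
#' space (anything other than Talairach draws a warning); other `// key=value`
#' annotations are ignored with a warning. Subsequent whitespace-separated
#' numeric x y z triples are foci in mm. A blank line closes the block.
#'
#' @param path path to the text file.
#' @return list of [Experiment-class] in file order, ids `exp001`, `exp002`, ...
#' @export
readFociFile <- function(path) {
  if (!file.exists(path)) stop("foci file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  experiments <- list()
  label <- NULL; nSubjects <- NA_integer_; foci <- list(); blockStart <- NA_integer_

  flush <- function() {
    if (is.null(label) && !length(foci)) return()
    if (!length(foci))
      stop("block '", label, "' (line ", blockStart, ") has zero foci")
    id <- sprintf("exp%03d", length(experiments) + 1L)
    experiments[[length(experiments) + 1L]] <<-
      Experiment(id, do.call(rbind, foci), label = label %||% id,
                 nSubjects = nSubjects)
    label <<- NULL; nSubjects <<- NA_integer_; foci <<- list()
    blockStart <<- NA_integer_
  }

  for (ln in seq_along(lines)) {
    line <- trimws(lines[[ln]])
    if (!nzchar(line)) { flush(); next }
    if (startsWith(line, "//")) {
      body <- trimws(sub("^//", "", line))
      if (grepl("^Reference\\s*=", body, ignore.case = TRUE)) {
        space <- trimws(sub("^Reference\\s*=", "", body, ignore.case = TRUE))
        if (!grepl("talairach", space, ignore.case = TRUE))
          warning("coordinate space declared as '", space,
                  "'; coordinates are treated as Talairach mm")
        next
      }
      if (grepl("^Subjects\\s*=", body, ignore.case = TRUE)) {
        n <- suppressWarnings(as.integer(
          trimws(sub("^Subjects\\s*=", "", body, ignore.case = TRUE))))
        if (is.na(n)) stop("unparsable Subjects annotation at line ", ln)
        nSubjects <- n
        next
      }
      if (grepl("=", body, fixed = TRUE)) {
        warning("ignoring unknown annotation at line ", ln, ": ", body)
        next
      }
      if (is.null(label)) {
        label <- body
        blockStart <- ln
      } else {
        label <- paste(label, body, sep = "; ")   # multi-line label
      }
      next
    }
    tok <- strsplit(line, "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(tok))
    if (length(tok) != 3L || any(is.na(vals)))
      stop("line ", ln, ": expected 3 numeric coordinates, got '", line, "'")
    if (is.na(blockStart)) blockStart <- ln
    foci[[length(foci) + 1L]] <- vals
  }
  flush()
  if (!length(experiments)) stop("no experiments in ", path)
  experiments
}

#' Write experiments as a Sleuth-style foci file
#'
#' @param experiments list of [Experiment-class].
#' @param path output path.
#' @param space coordinate-space header (default "Talairach").
#' @return `path`, invisibly.
#' @export
writeFociFile <- function(experiments, path, space = "Talairach") {
  out <- c(sprintf("// Reference=%s", space), "")
  for (e in experiments) {
    out <- c(out, paste("//", e@label))
    if (!is.na(e@nSubjects)) out <- c(out, sprintf("// Subjects=%d", e@nSubjects))
    out <- c(out, apply(e@foci, 1L, function(r)
      paste(formatC(r, format = "fg"), collapse = "\t")), "")
  }
  writeLines(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a labeled atlas volume
#'
#' @param volumePath NIfTI-1 (.nii/.nii.gz) file with integer labels
#'   (0 = background) on an axis-aligned RAS+ grid.
#' @param labelTablePath TSV with columns `label`, `name`, `hemisphere`.
#' @return an [AtlasVolume-class]; the grid is inferred from the NIfTI header.
#' @export
readAtlas <- function(volumePath, labelTablePath) {
  img <- RNifti::readNifti(volumePath)
  grid <- .gridFromXform(img)
  tab <- utils::read.delim(labelTablePath, stringsAsFactors = FALSE)
  need <- c("label", "name", "hemisphere")
  if (!all(need %in% names(tab)))
    stop("label table must have columns label, name, hemisphere")
  vals <- array(as.vector(img), dim = dim(img))
  if (any(vals != round(vals))) stop("atlas volume contains non-integer values")
  atlas <- new("AtlasVolume", grid = grid,
               values = array(as.integer(vals), dim = dim(vals)),
               labelTable = tab[, need])
  if (!any(atlas@values != 0L))
    warning("atlas volume is background-only (no labeled regions)")
  atlas
}

.gridFromXform <- function(img) {
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  if (any(abs(rot - diag(diag(rot))) > 1e-4) || any(diag(rot) <= 0))
    stop("volume is not axis-aligned RAS+; resampling is out of scope")
  vs <- diag(rot)
  if (max(vs) - min(vs) > 1e-4)
    stop("only isotropic voxels are supported (got ",
         paste(signif(vs, 4), collapse = " x "), " mm)")
  VolumeGrid(xf[1:3, 4], vs[1], dim(img)[1:3])
}

#' Write a voxel volume as NIfTI-1
#'
#' @param values 3-D array (or a [VoxelVolume-class] object).
#' @param grid the [VolumeGrid-class] (ignored when `values` carries one).
#' @param path output .nii or .nii.gz path.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(values, grid = NULL, path) {
  if (is(values, "VoxelVolume")) {
    grid <- values@grid
    values <- values@values
  }
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- rep(grid@voxelSize, 3L)
  aff <- diag(c(rep(grid@voxelSize, 3L), 1))
  aff[1:3, 4] <- grid@origin
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an ALE map written by this package
#'
#' @param path NIfTI file.
#' @param fwhmMm kernel FWHM recorded with the map (not stored in NIfTI).
#' @param nExperiments experiment count (idem).
#' @return an [AleMap-class].
#' @export
readAleMap <- function(path, fwhmMm = NA_real_, nExperiments = NA_integer_) {
  img <- RNifti::readNifti(path)
  new("AleMap", grid = .gridFromXform(img),
      values = array(as.vector(img), dim = dim(img)[1:3]),
      nExperiments = as.integer(nExperiments), fwhmMm = fwhmMm)
}

#' Write the standard output file set of a run
#'
#' Writes `nodes.tsv`, `matrix.tsv`, `edges.tsv`, `network.graphml`, an
#' optional `ale_map.nii.gz`, and `manifest.json` (configuration echo plus
#' seeds) into `outDir`.
#'
#' @param nodes node `data.frame` (id, region, hemisphere, x, y, z, ale_value).
#' @param matrix a [CoalterationMatrix-class].
#' @param network a [CoalterationNetwork-class].
#' @param outDir output directory (created if missing).
#' @param aleMap optional [AleMap-class] to serialize.
#' @param config list echoed into the manifest.
#' @param seed seed echoed into the manifest.
#' @return character vector of the files written, invisibly.
#' @export
writeOutputs <- function(nodes, matrix, network, outDir, aleMap = NULL,
                         config = list(), seed = NULL) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  if (!setequal(colnames(as.matrix(matrix)), nodes$id))
    stop("matrix columns do not match the node list")
  written <- character()
  deg <- nodeDegree(network)
  nodes$degree <- unname(deg[nodes$id])

  f <- file.path(outDir, "nodes.tsv")
  utils::write.table(nodes, f, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, f)

  f <- file.path(outDir, "matrix.tsv")
  m <- as.matrix(matrix)
  utils::write.table(data.frame(experiment = rownames(m), m,
                                check.names = FALSE),
                     f, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, f)

  f <- file.path(outDir, "edges.tsv")
  pt <- pairTests(network)
  eb <- edgeBetweenness(network)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  pt$edge_betweenness <- rep(NA_real_, nrow(pt))
  if (nrow(eb))
    pt$edge_betweenness <- eb$betweenness[
      match(key(pt$node_a, pt$node_b), key(eb$node_a, eb$node_b))]
  utils::write.table(pt, f, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, f)

  f <- file.path(outDir, "network.graphml")
  igraph::write_graph(.asIgraph(network), f, format = "graphml")
  written <- c(written, f)

  if (!is.null(aleMap)) {
    f <- file.path(outDir, "ale_map.nii.gz")
    writeVolume(aleMap, path = f)
    written <- c(written, f)
  }

  f <- file.path(outDir, "manifest.json")
  manifest <- list(package = "coalternet",
                   version = as.character(utils::packageVersion("coalternet")),
                   config = config, seed = seed,
                   n_nodes = nrow(nodes), n_edges = nrow(networkEdges(network)),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  written <- c(written, f)
  invisible(written)
}

#' Read back a matrix.tsv written by writeOutputs
#'
#' @param path the TSV file.
#' @return a [CoalterationMatrix-class].
#' @export
readMatrix <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- d[[1]]
  new("CoalterationMatrix", cells = m)
}

.asIgraph <- function(network) {
  nd <- networkNodes(network)
  ed <- networkEdges(network)
  vertices <- data.frame(name = nd$id, nd[setdiff(names(nd), "id")],
                         stringsAsFactors = FALSE)
  if (nrow(ed))
    igraph::graph_from_data_frame(ed, directed = FALSE, vertices = vertices)
  else
    igraph::make_empty_graph(n = nrow(nd), directed = FALSE) |>
      igraph::set_vertex_attr("name", value = nd$id)
}
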
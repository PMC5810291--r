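# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths (dense evaluation, exhaustive enumeration) so the
# implementation is checked against something it does not share.

# Dense, untruncated MA evaluation: per focus (snapped to the nearest voxel
# centre) evaluate the Gaussian density at every voxel of the grid, convert
# to per-voxel probability, and combine by voxel-wise maximum.
denseMaOracle <- function(fociMm, grid, fwhmMm) {
  sigma <- fwhmMm / sqrt(8 * log(2))
  d <- grid@dims
  ax <- grid@origin[1] + (seq_len(d[1]) - 1) * grid@voxelSize
  ay <- grid@origin[2] + (seq_len(d[2]) - 1) * grid@voxelSize
  az <- grid@origin[3] + (seq_len(d[3]) - 1) * grid@voxelSize
  fociMm <- if (is.null(dim(fociMm))) matrix(fociMm, ncol = 3) else fociMm
  snap <- function(v, axis) axis[which.min(abs(axis - v))]
  vals <- array(0, dim = d)
  for (r in seq_len(nrow(fociMm))) {
    f <- c(snap(fociMm[r, 1], ax), snap(fociMm[r, 2], ay),
           snap(fociMm[r, 3], az))
    d2 <- outer(outer((ax - f[1])^2, (ay - f[2])^2, "+"), (az - f[3])^2, "+")
    dens <- exp(-d2 / (2 * sigma^2)) / (sigma^3 * (2 * pi)^(3 / 2))
    vals <- pmax(vals, dens * grid@voxelSize^3)
  }
  vals
}

denseAleOracle <- function(fociList, grid, fwhmMm) {
  comp <- array(1, dim = grid@dims)
  for (f in fociList) comp <- comp * (1 - denseMaOracle(f, grid, fwhmMm))
  1 - comp
}

# Synthetic ALE-like map with planted Gaussian bumps, zeroed below `floor`
# (stands in for a thresholded map).
blobMap <- function(grid, centersMm, heights, sigmaMm = 6, floor = 1e-4) {
  d <- grid@dims
  ax <- grid@origin[1] + (seq_len(d[1]) - 1) * grid@voxelSize
  ay <- grid@origin[2] + (seq_len(d[2]) - 1) * grid@voxelSize
  az <- grid@origin[3] + (seq_len(d[3]) - 1) * grid@voxelSize
  vals <- array(0, dim = d)
  for (r in seq_len(nrow(centersMm))) {
    d2 <- outer(outer((ax - centersMm[r, 1])^2, (ay - centersMm[r, 2])^2, "+"),
                (az - centersMm[r, 3])^2, "+")
    vals <- pmax(vals, heights[r] * exp(-d2 / (2 * sigmaMm^2)))
  }
  vals[vals < floor] <- 0
  new("AleMap", grid = grid, values = vals, nExperiments = 1L,
      fwhmMm = sigmaMm * sqrt(8 * log(2)), thresholdValue = floor)
}

# Random simple undirected graph as a CoalterationNetwork.
randomNetwork <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p
  CoalterationNetwork(ids,
    data.frame(node_a = pairs[keep, 1], node_b = pairs[keep, 2],
               stringsAsFactors = FALSE))
}

# Exhaustive edge-betweenness oracle: enumerate every shortest path of every
# unordered pair by DFS over the BFS-distance DAG.
bruteBetweennessOracle <- function(network, ties = "fractional") {
  nd <- networkNodes(network)$id
  ed <- networkEdges(network)
  n <- length(nd)
  adj <- lapply(seq_len(n), function(i) integer(0))
  ui <- match(ed$node_a, nd); vi <- match(ed$node_b, nd)
  for (e in seq_along(ui)) {
    adj[[ui[e]]] <- c(adj[[ui[e]]], vi[e])
    adj[[vi[e]]] <- c(adj[[vi[e]]], ui[e])
  }
  bfs <- function(s) {
    dist <- rep(Inf, n); dist[s] <- 0; q <- s
    while (length(q)) {
      u <- q[1]; q <- q[-1]
      for (w in adj[[u]]) if (is.infinite(dist[w])) {
        dist[w] <- dist[u] + 1; q <- c(q, w)
      }
    }
    dist
  }
  ekey <- paste(pmin(ui, vi), pmax(ui, vi))
  bet <- setNames(numeric(length(ekey)), ekey)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    dt <- bfs(t)
    if (is.infinite(dt[s])) next
    paths <- list()
    walk <- function(u, path) {
      if (u == t) { paths[[length(paths) + 1]] <<- path; return() }
      for (w in adj[[u]]) if (dt[w] == dt[u] - 1) walk(w, c(path, w))
    }
    walk(s, s)
    w <- if (ties == "fractional") 1 / length(paths) else 1
    for (p in paths) for (i in seq_len(length(p) - 1)) {
      k <- paste(min(p[i], p[i + 1]), max(p[i], p[i + 1]))
      bet[k] <- bet[k] + w
    }
  }
  data.frame(node_a = ed$node_a, node_b = ed$node_b,
             betweenness = unname(bet[paste(pmin(ui, vi), pmax(ui, vi))]))
}

# Exhaustive k-core oracle (<= ~9 nodes): core_number(v) = max over all
# vertex subsets containing v of the subset's minimum internal degree.
bruteCoreOracle <- function(network) {
  nd <- networkNodes(network)$id
  ed <- networkEdges(network)
  n <- length(nd)
  ui <- match(ed$node_a, nd); vi <- match(ed$node_b, nd)
  core <- setNames(integer(n), nd)
  for (mask in seq_len(2^n) - 1L) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(S) < 2) next
    inS <- ui %in% S & vi %in% S
    deg <- tabulate(c(ui[inS], vi[inS]), nbins = n)[S]
    k <- min(deg)
    core[S] <- pmax(core[S], k)
  }
  core
}

# Random 0/1 coalteration matrix.
randomCoalterationMatrix <- function(nExp, nNode, p = 0.5, seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(nExp * nNode, 1L, p), nExp, nNode,
              dimnames = list(sprintf("e%03d", seq_len(nExp)),
                              sprintf("v%02d", seq_len(nNode))))
  new("CoalterationMatrix", cells = m)
}

# Contingency from a matrix wired the other way round: explicit per-row loop.
loopContingencyOracle <- function(m, a, b) {
  n <- c(0L, 0L, 0L, 0L)
  for (r in seq_len(nrow(m))) {
    x <- m[r, a]; y <- m[r, b]
    if (x == 1 && y == 1) n[1] <- n[1] + 1L
    else if (x == 1) n[2] <- n[2] + 1L
    else if (y == 1) n[3] <- n[3] + 1L
    else n[4] <- n[4] + 1L
  }
  n
}

# Small toy atlas with two mirrored 10x10x10-voxel cuboid regions.
twoCuboidAtlas <- function(voxelSize = 2) {
  grid <- VolumeGrid(c(-40, -20, -20), voxelSize, c(41L, 21L, 21L))
  vals <- array(0L, dim = grid@dims)
  vals[2:11, 4:13, 4:13] <- 1L
  vals[31:40, 4:13, 4:13] <- 2L
  new("AtlasVolume", grid = grid, values = vals,
      labelTable = data.frame(label = 1:2, name = c("Region_L", "Region_R"),
                              hemisphere = c("L", "R")))
}
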
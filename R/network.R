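## Internal: node ids and the edge list (two-column character matrix) of a
## CoalterationNetwork or of a plain list(nodes=, edges=).
.graphParts <- function(network) {
  nd <- networkNodes(network)
  ed <- networkEdges(network)
  list(ids = nd$id,
       from = as.character(ed$node_a), to = as.character(ed$node_b))
}

#' Node degree
#'
#' The number of edges incident to each node, the paper's measure of
#' "pathoconnectivity hubness". Isolated nodes have degree 0.
#'
#' @param network a [CoalterationNetwork-class].
#' @return named integer vector sorted by descending degree (hub listing).
#' @export
nodeDegree <- function(network) {
  g <- .graphParts(network)
  deg <- stats::setNames(integer(length(g$ids)), g$ids)
  for (v in c(g$from, g$to)) deg[v] <- deg[v] + 1L
  sort(deg, decreasing = TRUE)
}

#' Edge betweenness
#'
#' For every unordered pair of connected nodes (s, t), counted once,
#' accumulates over each edge the shortest s-t paths that traverse it. With
#' `ties = "fractional"` (default, the standard convention) each pair
#' contributes the *fraction* of its shortest paths through the edge; with
#' `ties = "integral"` each shortest path counts 1, so tied paths are not
#' split. The graph is treated as unweighted and may be disconnected
#' (disconnected pairs contribute 0).
#'
#' @param network a [CoalterationNetwork-class].
#' @param ties tie convention among equal shortest paths.
#' @return `data.frame`: node_a, node_b, betweenness (one row per edge).
#' @export
edgeBetweenness <- function(network, ties = c("fractional", "integral")) {
  ties <- match.arg(ties)
  g <- .graphParts(network)
  n <- length(g$ids)
  m <- length(g$from)
  out <- data.frame(node_a = g$from, node_b = g$to,
                    betweenness = numeric(m), stringsAsFactors = FALSE)
  if (!m) return(out)
  ui <- match(g$from, g$ids); vi <- match(g$to, g$ids)
  adj <- lapply(seq_len(n), function(i) c(vi[ui == i], ui[vi == i]))
  D <- matrix(Inf, n, n); S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); sig <- numeric(n)
    dist[s] <- 0; sig[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) for (w in adj[[u]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[u] + 1
          nxt <- c(nxt, w)
          sig[w] <- sig[w] + sig[u]
        } else if (dist[w] == dist[u] + 1) {
          sig[w] <- sig[w] + sig[u]
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist; S[s, ] <- sig
  }
  bet <- numeric(m)
  for (s in seq_len(n - 1L)) for (t in (s + 1L):n) {
    if (is.infinite(D[s, t])) next
    # paths through edge (u, v), traversed u->v or v->u
    cnt <- S[s, ui] * S[t, vi] * (D[s, ui] + 1 + D[t, vi] == D[s, t]) +
           S[s, vi] * S[t, ui] * (D[s, vi] + 1 + D[t, ui] == D[s, t])
    cnt[is.na(cnt)] <- 0
    bet <- bet + if (ties == "fractional") cnt / S[s, t] else cnt
  }
  out$betweenness <- bet
  out
}

#' k-core decomposition
#'
#' For ascending k, repeatedly deletes nodes whose current degree is below k
#' until stable; a node's core number is the largest k it survives. The "core
#' subnetwork" is the set of survivors at the maximal non-empty k.
#'
#' @param network a [CoalterationNetwork-class].
#' @return list: `core_number` (named integer per node), `max_k`, and
#'   `core_subnetwork` (node ids with core_number == max_k).
#' @export
kCore <- function(network) {
  g <- .graphParts(network)
  n <- length(g$ids)
  core <- stats::setNames(integer(n), g$ids)
  if (length(g$from)) {
    alive <- rep(TRUE, n)
    ui <- match(g$from, g$ids); vi <- match(g$to, g$ids)
    k <- 1L
    repeat {
      repeat {
        eAlive <- alive[ui] & alive[vi]
        deg <- tabulate(c(ui[eAlive], vi[eAlive]), nbins = n)
        kill <- alive & deg < k
        if (!any(kill)) break
        alive[kill] <- FALSE
      }
      if (!any(alive)) break
      core[alive] <- k
      k <- k + 1L
    }
  }
  maxK <- max(core)
  list(core_number = core, max_k = maxK,
       core_subnetwork = names(core)[core == maxK & maxK > 0L])
}

#' Inter- vs intrahemispheric edge counts
#'
#' An edge is interhemispheric iff its endpoint hemisphere tags are {L, R};
#' edges touching a midline ("M") node are counted as intrahemispheric (a
#' message notes how many). Counts sum to the edge count.
#'
#' @param network a [CoalterationNetwork-class] whose nodes carry a
#'   `hemisphere` column.
#' @return named integer vector `c(inter = ..., intra = ...)`.
#' @export
hemisphereSplit <- function(network) {
  nd <- networkNodes(network)
  ed <- networkEdges(network)
  if (!"hemisphere" %in% names(nd)) stop("nodes carry no hemisphere tags")
  hemi <- stats::setNames(nd$hemisphere, nd$id)
  bad <- ed$node_a[!(hemi[ed$node_a] %in% c("L", "R", "M"))]
  bad <- c(bad, ed$node_b[!(hemi[ed$node_b] %in% c("L", "R", "M"))])
  if (length(bad))
    stop("missing/invalid hemisphere tag on node(s): ",
         paste(unique(bad), collapse = ", "))
  ha <- hemi[ed$node_a]; hb <- hemi[ed$node_b]
  inter <- (ha == "L" & hb == "R") | (ha == "R" & hb == "L")
  nMid <- sum((ha == "M" | hb == "M"))
  if (nMid) message(nMid, " edge(s) touching midline nodes counted as intrahemispheric")
  c(inter = sum(inter), intra = sum(!inter))
}

#' Merge same-region nodes into a region-level network
#'
#' Contracts all nodes of one brain region into a single region node, keeping
#' the edges: parallel edges arising from the contraction are collapsed to
#' one region edge carrying the maximum kappa (with the collapsed multiplicity
#' reported); intra-region edges become self-loops and are dropped (counted).
#'
#' @param network a [CoalterationNetwork-class] whose nodes carry a `region`
#'   column.
#' @return list: `network` (region-level [CoalterationNetwork-class] with a
#'   `multiplicity` column on `pairTests`), `dropped_self_loops` count.
#' @export
mergeNodesByRegion <- function(network) {
  nd <- networkNodes(network)
  ed <- networkEdges(network)
  if (!"region" %in% names(nd)) stop("nodes carry no region column")
  regOf <- stats::setNames(nd$region, nd$id)
  hemiOf <- if ("hemisphere" %in% names(nd))
    stats::setNames(nd$hemisphere, nd$id) else NULL
  regions <- unique(nd$region)
  rnodes <- data.frame(id = regions, region = regions,
                       stringsAsFactors = FALSE)
  if (!is.null(hemiOf))
    rnodes$hemisphere <- vapply(regions, function(r)
      unique(hemiOf[nd$id[nd$region == r]])[1], "")
  if (!nrow(ed)) {
    return(list(network = CoalterationNetwork(rnodes, ed),
                dropped_self_loops = 0L))
  }
  ra <- regOf[ed$node_a]; rb <- regOf[ed$node_b]
  self <- ra == rb
  nSelf <- sum(self)
  ed <- ed[!self, , drop = FALSE]; ra <- ra[!self]; rb <- rb[!self]
  a <- pmin(ra, rb); b <- pmax(ra, rb)
  key <- paste(a, b, sep = "|")
  agg <- data.frame(node_a = a, node_b = b, kappa = ed$kappa,
                    key = key, stringsAsFactors = FALSE)
  red <- do.call(rbind, lapply(split(agg, agg$key), function(d)
    data.frame(node_a = d$node_a[1], node_b = d$node_b[1],
               kappa = max(d$kappa), multiplicity = nrow(d),
               stringsAsFactors = FALSE)))
  rownames(red) <- NULL
  redEdges <- red[, c("node_a", "node_b", "kappa")]
  redEdges$posterior_prob <- NA_real_
  pt <- red
  pt$significant <- TRUE
  list(network = CoalterationNetwork(rnodes, redEdges, pairTests = pt),
       dropped_self_loops = nSelf)
}

#' Full topology report
#'
#' @param network a [CoalterationNetwork-class].
#' @param ties tie convention for [edgeBetweenness()].
#' @return list: `degree`, `edge_betweenness`, `core_number`, `max_k`,
#'   `core_subnetwork`, `hemisphere_counts` (NULL when nodes carry no
#'   hemisphere tags).
#' @export
topologyReport <- function(network, ties = "fractional") {
  kc <- kCore(network)
  hemi <- if ("hemisphere" %in% names(networkNodes(network)))
    hemisphereSplit(network) else NULL
  list(degree = nodeDegree(network),
       edge_betweenness = edgeBetweenness(network, ties),
       core_number = kc$core_number, max_k = kc$max_k,
       core_subnetwork = kc$core_subnetwork,
       hemisphere_counts = hemi)
}
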
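#' Build the binary experiments-by-nodes coalteration matrix
#'
#' Cell (e, j) is 1 iff experiment e reports at least one focus close to node
#' j. Two assignment rules are provided: `"radius"` (default) marks a node
#' when a focus lies within `assignRadiusMm` of its peak coordinate — 10 mm,
#' the same spatial-uncertainty constant as the interpeak distance; `"region"`
#' marks a node when a focus falls inside the node's atlas region. One focus
#' may mark several nearby nodes; experiments with no focus near any node keep
#' their all-zero row (they contribute to the "neither altered" cell).
#'
#' @param experiments list of [Experiment-class].
#' @param nodes node `data.frame` from [labelNodes()]/[buildNodes()].
#' @param assignRadiusMm assignment radius in mm (default 10).
#' @param rule `"radius"` or `"region"`.
#' @param atlas [AtlasVolume-class], required for `rule = "region"`.
#' @return a [CoalterationMatrix-class].
#' @export
buildMatrix <- function(experiments, nodes, assignRadiusMm = 10,
                        rule = c("radius", "region"), atlas = NULL) {
  rule <- match.arg(rule)
  if (!nrow(nodes)) stop("no nodes")
  if (assignRadiusMm <= 0) stop("assignRadiusMm must be positive")
  if (rule == "region" && is.null(atlas))
    stop("rule = 'region' requires the atlas")
  m <- matrix(0L, nrow = length(experiments), ncol = nrow(nodes),
              dimnames = list(vapply(experiments, function(e) e@id, ""),
                              nodes$id))
  if (rule == "radius") {
    peakXyz <- as.matrix(nodes[, c("x", "y", "z")])
    for (r in seq_along(experiments)) {
      f <- experiments[[r]]@foci
      for (j in seq_len(nrow(nodes))) {
        d2 <- rowSums(sweep(f, 2, peakXyz[j, ])^2)
        if (any(d2 <= assignRadiusMm^2)) m[r, j] <- 1L
      }
    }
  } else {
    grid <- atlas@grid
    tab <- labelTable(atlas)
    nodeLab <- tab$label[match(nodes$region, tab$name)]
    for (r in seq_along(experiments)) {
      idx <- worldToVoxel(grid, experiments[[r]]@foci)
      inside <- inGrid(grid, idx)
      if (!any(inside)) next
      labs <- atlas@values[.linearIndex(grid, idx[inside, , drop = FALSE])]
      m[r, nodeLab %in% labs] <- 1L
    }
  }
  new("CoalterationMatrix", cells = m)
}

#' Contingency counts for a node pair
#'
#' Tallies over experiments the four joint alteration states of nodes `a` and
#' `b`: n1 (both altered), n2 (a only), n3 (b only), n4 (neither);
#' `theta_i = n_i / N` estimates the joint probabilities.
#'
#' @param matrix a [CoalterationMatrix-class].
#' @param a,b node ids (or column indices), distinct.
#' @return list with `node_a`, `node_b`, `n` (named integer n1..n4), `N`, and
#'   `theta` (n / N).
#' @export
contingency <- function(matrix, a, b) {
  m <- as.matrix(matrix)
  ca <- m[, a]; cb <- m[, b]
  if (identical(a, b)) stop("a and b must differ")
  N <- nrow(m)
  if (N == 0L) stop("empty matrix")
  n <- c(n1 = sum(ca == 1L & cb == 1L),
         n2 = sum(ca == 1L & cb == 0L),
         n3 = sum(ca == 0L & cb == 1L),
         n4 = sum(ca == 0L & cb == 0L))
  list(node_a = if (is.character(a)) a else colnames(m)[a],
       node_b = if (is.character(b)) b else colnames(m)[b],
       n = n, N = N, theta = n / N)
}

#' Patel's kappa from joint alteration probabilities
#'
#' Measures the excess of the joint alteration probability of a node pair
#' over its independence expectation, normalized to [-1, 1]:
#' \deqn{\kappa = (\theta_1 - E) / (D(\theta_1^{max} - E) +
#'   (1 - D)(E - \theta_1^{min}))}
#' with \eqn{E = (\theta_1+\theta_2)(\theta_1+\theta_3)},
#' \eqn{\theta_1^{max} = \min(\theta_1+\theta_2, \theta_1+\theta_3)},
#' \eqn{\theta_1^{min} = \max(0, 2\theta_1+\theta_2+\theta_3-1)}, and
#' \eqn{D = 1} when \eqn{\theta_1 \ge E}, else 0.
#'
#' Undefined (NA) when a marginal is degenerate (a node altered in all or no
#' experiments): the normalizing constant vanishes.
#'
#' @param theta numeric(4) on the simplex (theta1..theta4), or an n x 4 matrix
#'   of such rows (vectorized).
#' @return kappa in [-1, 1] (vector for matrix input), NA where degenerate.
#' @examples
#' patelKappa(c(0.2, 0.1, 0.1, 0.6))  # 0.11 / 0.21
#' @export
patelKappa <- function(theta) {
  th <- if (is.null(dim(theta))) matrix(theta, ncol = 4L) else as.matrix(theta)
  if (ncol(th) != 4L) stop("theta must have 4 components")
  if (any(th < -1e-9 | th > 1 + 1e-9))
    stop("theta components must lie in [0, 1]")
  if (any(abs(rowSums(th) - 1) > 1e-6))
    stop("theta must sum to 1")
  pa <- th[, 1] + th[, 2]
  pb <- th[, 1] + th[, 3]
  E <- pa * pb
  thMax <- pmin(pa, pb)
  thMin <- pmax(0, pa + pb - 1)
  D <- as.numeric(th[, 1] >= E)
  denom <- D * (thMax - E) + (1 - D) * (E - thMin)
  kappa <- ifelse(denom > 0, (th[, 1] - E) / denom, NA_real_)
  degenerate <- pa <= 0 | pa >= 1 | pb <= 0 | pb >= 1
  kappa[degenerate] <- NA_real_
  if (is.null(dim(theta))) kappa[[1]] else kappa
}

#' Dirichlet Monte-Carlo significance of a node pair
#'
#' Simulates the posterior of the pair's 4-cell multinomial under a flat
#' Dirichlet(1,1,1,1) prior: draws `nSamples` theta vectors from
#' Dirichlet(1 + n1, ..., 1 + n4), computes kappa per draw (draws with
#' degenerate marginals are rejected and redrawn, and counted), and reports
#' the posterior probability that kappa exceeds `eThreshold`. The pair is
#' significant when that probability reaches `1 - pThreshold` (default
#' p < 0.01).
#'
#' @param counts a contingency list from [contingency()] (or any list with
#'   elements `n` (n1..n4) and `N`).
#' @param eThreshold kappa effect threshold e (default 0).
#' @param pThreshold posterior tail threshold p (default 0.01).
#' @param nSamples Monte-Carlo sample count (>= 1000).
#' @param seed RNG seed.
#' @param alpha0 Dirichlet prior concentration per cell (default 1, flat).
#' @return list: node_a, node_b, kappa (maximum-likelihood point estimate
#'   n/N), E, theta1_max, theta1_min, posterior_prob, significant,
#'   n_mc_samples, n_rejected, seed.
#' @export
edgeSignificance <- function(counts, eThreshold = 0, pThreshold = 0.01,
                             nSamples = 10000, seed = NULL, alpha0 = 1) {
  if (nSamples < 1000) stop("nSamples must be >= 1000 (unstable tail estimate)")
  n <- counts$n
  if (counts$N < 2) stop("need N >= 2 experiments")
  alpha <- alpha0 + n
  nRejected <- 0L
  kap <- numeric(0)
  .withSeed(seed, {
    need <- nSamples
    while (need > 0) {
      g <- matrix(stats::rgamma(need * 4L, shape = rep(alpha, each = need)),
                  ncol = 4L)
      th <- g / rowSums(g)
      k <- patelKappa(th)
      bad <- is.na(k)
      nRejected <- nRejected + sum(bad)
      kap <- c(kap, k[!bad])
      need <- nSamples - length(kap)
    }
  })
  posterior <- mean(kap > eThreshold)
  theta <- n / counts$N
  pa <- theta[1] + theta[2]; pb <- theta[1] + theta[3]
  list(node_a = counts$node_a, node_b = counts$node_b,
       kappa = patelKappa(theta),
       E = unname(pa * pb),
       theta1_max = unname(min(pa, pb)),
       theta1_min = unname(max(0, pa + pb - 1)),
       posterior_prob = posterior,
       significant = posterior >= 1 - pThreshold,
       n_mc_samples = nSamples, n_rejected = nRejected,
       seed = seed)
}

#' Build the coalteration network
#'
#' Evaluates every unordered node pair of the matrix with
#' [edgeSignificance()]; significant pairs become undirected edges weighted
#' by the maximum-likelihood kappa point estimate. Columns altered in all or
#' no experiments are degenerate (kappa undefined) and are excluded from pair
#' evaluation with a message; isolated nodes are retained in the network.
#'
#' @param matrix a [CoalterationMatrix-class].
#' @param nodes node `data.frame` consistent with the matrix columns.
#' @param eThreshold,pThreshold,nSamples,alpha0 passed to [edgeSignificance()].
#' @param seed base seed; pair p gets seed `seed + p` so pairs are
#'   independently reproducible.
#' @param bonferroni also flag significance at `pThreshold / nPairs`
#'   (reported in `pairTests$significant_bonferroni`; default behaviour
#'   unchanged).
#' @return a [CoalterationNetwork-class].
#' @export
buildNetwork <- function(matrix, nodes, eThreshold = 0, pThreshold = 0.01,
                         nSamples = 10000, seed = 1, alpha0 = 1,
                         bonferroni = FALSE) {
  m <- as.matrix(matrix)
  if (!setequal(colnames(m), nodes$id))
    stop("matrix columns do not match node ids")
  colMean <- colMeans(m)
  degenerate <- colMean %in% c(0, 1)
  if (any(degenerate))
    message("excluding degenerate node column(s) from pair evaluation: ",
            paste(colnames(m)[degenerate], collapse = ", "))
  ids <- colnames(m)[!degenerate]
  pairs <- if (length(ids) >= 2L) utils::combn(ids, 2L) else
    matrix(character(), nrow = 2L)
  nPairs <- ncol(pairs)
  res <- vector("list", nPairs)
  for (p in seq_len(nPairs)) {
    cc <- contingency(matrix, pairs[1, p], pairs[2, p])
    res[[p]] <- edgeSignificance(cc, eThreshold, pThreshold, nSamples,
                                 seed = if (is.null(seed)) NULL else seed + p,
                                 alpha0 = alpha0)
  }
  pt <- if (nPairs) do.call(rbind, lapply(res, function(r)
    data.frame(node_a = r$node_a, node_b = r$node_b, kappa = r$kappa,
               posterior_prob = r$posterior_prob, significant = r$significant,
               stringsAsFactors = FALSE)))
  else data.frame(node_a = character(), node_b = character(),
                  kappa = numeric(), posterior_prob = numeric(),
                  significant = logical())
  if (bonferroni && nPairs)
    pt$significant_bonferroni <- pt$posterior_prob >= 1 - pThreshold / nPairs
  edges <- pt[pt$significant, c("node_a", "node_b", "kappa", "posterior_prob"),
              drop = FALSE]
  rownames(edges) <- NULL
  new("CoalterationNetwork", nodes = nodes, edges = edges, pairTests = pt,
      params = list(eThreshold = eThreshold, pThreshold = pThreshold,
                    nSamples = nSamples, seed = seed, alpha0 = alpha0))
}

#' Construct a CoalterationNetwork from node and edge tables
#'
#' Convenience constructor used by the topology functions and tests.
#'
#' @param nodes node `data.frame` with at least an `id` column.
#' @param edges edge `data.frame` with `node_a`, `node_b` (and optionally
#'   `kappa`, `posterior_prob`).
#' @param pairTests optional full pair-test table (defaults to `edges`).
#' @param params optional parameter list.
#' @return a [CoalterationNetwork-class].
#' @export
CoalterationNetwork <- function(nodes, edges, pairTests = NULL, params = list()) {
  if (is.character(nodes)) nodes <- data.frame(id = nodes, stringsAsFactors = FALSE)
  if (!nrow(edges)) {
    edges <- data.frame(node_a = character(), node_b = character(),
                        kappa = numeric(), posterior_prob = numeric())
  } else {
    if (!"kappa" %in% names(edges)) edges$kappa <- NA_real_
    if (!"posterior_prob" %in% names(edges)) edges$posterior_prob <- NA_real_
    edges <- edges[, c("node_a", "node_b", "kappa", "posterior_prob")]
  }
  if (is.null(pairTests)) {
    pairTests <- edges
    pairTests$significant <- rep(TRUE, nrow(edges))
  }
  new("CoalterationNetwork", nodes = nodes, edges = edges,
      pairTests = pairTests, params = params)
}
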
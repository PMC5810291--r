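triangle <- CoalterationNetwork(c("a", "b", "c"),
  data.frame(node_a = c("a", "b", "c"), node_b = c("b", "c", "a")))

test_that("node degree matches direct tallies on canonical graphs", {
  expect_equal(unname(nodeDegree(triangle)), c(2L, 2L, 2L))

  # star with 17 leaves: hub degree 17 (the paper-scale hub fixture)
  leaves <- sprintf("leaf%02d", 1:17)
  star <- CoalterationNetwork(c("hub", leaves),
    data.frame(node_a = "hub", node_b = leaves))
  deg <- nodeDegree(star)
  expect_equal(names(deg)[1], "hub")
  expect_equal(unname(deg["hub"]), 17L)
  expect_true(all(deg[leaves] == 1L))

  # random graphs vs an edge-list tally oracle
  for (s in 1:5) {
    net <- randomNetwork(12, 0.3, seed = s)
    ed <- networkEdges(net)
    oracle <- table(factor(c(ed$node_a, ed$node_b),
                           levels = networkNodes(net)$id))
    deg <- nodeDegree(net)
    expect_equal(unname(deg[names(oracle)]), unname(as.integer(oracle)))
    # handshake lemma
    expect_equal(sum(deg), 2L * nrow(ed))
  }
})

test_that("edge betweenness matches enumeration, igraph, and the tree formula", {
  # path a-b-c: edge (a,b) lies on pairs {a,b} and {a,c}
  path3 <- CoalterationNetwork(c("a", "b", "c"),
    data.frame(node_a = c("a", "b"), node_b = c("b", "c")))
  eb <- edgeBetweenness(path3)
  expect_equal(eb$betweenness, c(2, 2))

  # edgeless graph: empty result, no crash
  lone <- CoalterationNetwork(c("a", "b"), data.frame())
  expect_equal(nrow(edgeBetweenness(lone)), 0L)

  # random graphs (possibly disconnected) vs exhaustive path enumeration
  for (s in 1:10) {
    net <- randomNetwork(sample(4:12, 1), 0.3, seed = 100 + s)
    if (!nrow(networkEdges(net))) next
    got <- edgeBetweenness(net, ties = "fractional")
    oracle <- bruteBetweennessOracle(net, ties = "fractional")
    expect_equal(got$betweenness, oracle$betweenness, tolerance = 1e-9)
    gotInt <- edgeBetweenness(net, ties = "integral")
    oracleInt <- bruteBetweennessOracle(net, ties = "integral")
    expect_equal(gotInt$betweenness, oracleInt$betweenness, tolerance = 1e-9)
    # independent library cross-check (fractional convention)
    ig <- igraph::graph_from_data_frame(networkEdges(net)[, 1:2],
      directed = FALSE, vertices = networkNodes(net)$id)
    expect_equal(got$betweenness,
                 unname(igraph::edge_betweenness(ig, directed = FALSE)),
                 tolerance = 1e-9)
  }

  # tree: betweenness of an edge = product of the two component sizes
  tree <- CoalterationNetwork(c("r", "x", "y", "x1", "x2"),
    data.frame(node_a = c("r", "r", "x", "x"),
               node_b = c("x", "y", "x1", "x2")))
  eb <- edgeBetweenness(tree)
  expect_equal(eb$betweenness[eb$node_a == "r" & eb$node_b == "x"], 3 * 2)
  expect_equal(eb$betweenness[eb$node_a == "r" & eb$node_b == "y"], 4 * 1)
  expect_equal(eb$betweenness[eb$node_b == "x1"], 4 * 1)
})

test_that("k-core decomposition matches hand results and exhaustive search", {
  # complete graph K4: all core numbers 3
  k4 <- CoalterationNetwork(letters[1:4],
    data.frame(node_a = c("a", "a", "a", "b", "b", "c"),
               node_b = c("b", "c", "d", "c", "d", "d")))
  kc <- kCore(k4)
  expect_equal(unname(kc$core_number), rep(3L, 4))
  expect_equal(kc$max_k, 3L)
  expect_setequal(kc$core_subnetwork, letters[1:4])

  # triangle + pendant: max_k 2, core = the triangle
  tp <- CoalterationNetwork(c("a", "b", "c", "p"),
    data.frame(node_a = c("a", "b", "c", "a"), node_b = c("b", "c", "a", "p")))
  kc <- kCore(tp)
  expect_equal(kc$max_k, 2L)
  expect_setequal(kc$core_subnetwork, c("a", "b", "c"))
  expect_equal(unname(kc$core_number[c("a", "b", "c", "p")]), c(2L, 2L, 2L, 1L))

  # dense 8-node cluster + sparse periphery: the core is the dense 8
  dense <- sprintf("d%d", 1:8)
  densePairs <- t(combn(dense, 2))
  set.seed(5)
  densePairs <- densePairs[runif(nrow(densePairs)) < 0.9, ]
  periph <- sprintf("p%d", 1:6)
  ed <- rbind(data.frame(node_a = densePairs[, 1], node_b = densePairs[, 2]),
              data.frame(node_a = periph, node_b = sample(dense, 6, TRUE)))
  netc <- CoalterationNetwork(c(dense, periph), ed)
  kc <- kCore(netc)
  expect_setequal(kc$core_subnetwork, dense)

  # exhaustive subset oracle on graphs with <= 9 nodes
  for (s in 1:6) {
    net <- randomNetwork(sample(5:9, 1), 0.35, seed = 200 + s)
    expect_equal(kCore(net)$core_number, bruteCoreOracle(net))
  }

  # relabeling invariance
  net <- randomNetwork(9, 0.35, seed = 300)
  perm <- sample(9)
  ids <- networkNodes(net)$id
  relab <- setNames(sprintf("m%02d", perm), ids)
  ed <- networkEdges(net)
  net2 <- CoalterationNetwork(unname(relab[ids]),
    data.frame(node_a = unname(relab[ed$node_a]),
               node_b = unname(relab[ed$node_b])))
  expect_equal(unname(kCore(net2)$core_number[relab[ids]]),
               unname(kCore(net)$core_number[ids]))

  # edgeless graph: all cores 0, empty core subnetwork
  kc0 <- kCore(CoalterationNetwork(c("a", "b"), data.frame()))
  expect_equal(kc0$max_k, 0L)
  expect_length(kc0$core_subnetwork, 0L)
})

test_that("hemisphere split counts L-R edges as interhemispheric", {
  nd <- data.frame(id = sprintf("n%d", 1:6),
                   hemisphere = c("L", "L", "L", "R", "R", "M"))
  mkNet <- function(ed) CoalterationNetwork(nd, ed)
  # 5 L-R and 3 L-L edges
  ed <- rbind(data.frame(node_a = c("n1", "n1", "n2", "n2", "n3"),
                         node_b = c("n4", "n5", "n4", "n5", "n4")),
              data.frame(node_a = c("n1", "n1", "n2"),
                         node_b = c("n2", "n3", "n3")))
  expect_equal(hemisphereSplit(mkNet(ed)), c(inter = 5L, intra = 3L))
  # midline edges count as intra, with a message
  edM <- data.frame(node_a = c("n1", "n6"), node_b = c("n6", "n4"))
  expect_message(hs <- hemisphereSplit(mkNet(edM)), "midline")
  expect_equal(hs, c(inter = 0L, intra = 2L))
  # missing tag is an error naming the node
  ndBad <- nd; ndBad$hemisphere[4] <- NA
  netBad <- CoalterationNetwork(ndBad,
    data.frame(node_a = "n1", node_b = "n4"))
  expect_error(hemisphereSplit(netBad), "n4")
})

test_that("region merging contracts nodes, keeps max kappa, drops self-loops", {
  nd <- data.frame(id = c("R_1", "R_2", "S_1"),
                   region = c("R", "R", "S"),
                   hemisphere = c("L", "L", "R"))
  ed <- data.frame(node_a = c("R_1", "R_2", "R_1"),
                   node_b = c("S_1", "S_1", "R_2"),
                   kappa = c(0.4, 0.7, 0.9),
                   posterior_prob = c(.99, .999, .999))
  res <- mergeNodesByRegion(CoalterationNetwork(nd, ed))
  med <- networkEdges(res$network)
  expect_equal(nrow(med), 1L)
  expect_equal(med$kappa, 0.7)            # max of the two collapsed edges
  expect_equal(res$dropped_self_loops, 1L)
  expect_equal(pairTests(res$network)$multiplicity, 2L)

  # region-level degree never exceeds the sum of member-node degrees
  for (s in 1:5) {
    net <- randomNetwork(10, 0.3, seed = 400 + s)
    nd <- networkNodes(net)
    nd$region <- rep(c("A", "B", "C", "D", "E"), each = 2)
    net2 <- CoalterationNetwork(nd, transform(networkEdges(net), kappa = 0.5))
    degFull <- nodeDegree(net2)
    merged <- mergeNodesByRegion(net2)$network
    degR <- nodeDegree(merged)
    for (r in unique(nd$region))
      expect_lte(degR[r], sum(degFull[nd$id[nd$region == r]]))
  }
})

test_that("topology report is internally consistent", {
  net <- randomNetwork(10, 0.4, seed = 77)
  nd <- networkNodes(net)
  nd$hemisphere <- rep(c("L", "R"), 5)
  net <- CoalterationNetwork(nd, networkEdges(net))
  rep <- topologyReport(net)
  ne <- nrow(networkEdges(net))
  expect_equal(sum(rep$degree), 2L * ne)
  expect_equal(sum(rep$hemisphere_counts), ne)
  expect_true(all(rep$edge_betweenness$betweenness >= 0))
  expect_setequal(rep$core_subnetwork,
                  names(rep$core_number)[rep$core_number == rep$max_k])
})
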
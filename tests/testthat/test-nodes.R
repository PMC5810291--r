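test_that("the 20-voxel region rule is an inclusive boundary", {
  atlas <- twoCuboidAtlas()
  grid <- gridGeometry(atlas)
  mk <- function(nSupra1, nSupra2 = 0) {
    v <- array(0, dim = grid@dims)
    lin1 <- which(voxelValues(atlas) == 1L)[seq_len(nSupra1)]
    v[lin1] <- 0.5
    if (nSupra2) v[which(voxelValues(atlas) == 2L)[seq_len(nSupra2)]] <- 0.5
    new("AleMap", grid = grid, values = v, nExperiments = 1L, fwhmMm = 10,
        thresholdValue = 0.1)
  }
  r19 <- alteredRegions(mk(19), atlas)
  expect_equal(r19$altered_voxels[r19$name == "Region_L"], 19L)
  expect_false(r19$passes[r19$name == "Region_L"])
  r20 <- alteredRegions(mk(20), atlas)
  expect_true(r20$passes[r20$name == "Region_L"])

  # empty thresholded map: nothing passes
  r0 <- alteredRegions(mk(0), atlas)
  expect_true(all(!r0$passes))
  expect_true(all(r0$altered_voxels == 0L))

  # saturation: the whole 1000-voxel region
  r1000 <- alteredRegions(mk(1000), atlas)
  expect_equal(r1000$altered_voxels[r1000$name == "Region_L"], 1000L)
  expect_true(r1000$passes[r1000$name == "Region_L"])

  # grid mismatch is an error
  other <- blobMap(VolumeGrid(c(0, 0, 0), 2, c(3L, 3L, 3L)),
                   matrix(c(2, 2, 2), 1), heights = 0.5)
  expect_error(alteredRegions(other, atlas), "grids differ")
})

test_that("peak detection finds blob maxima and applies the percentile filter", {
  grid <- VolumeGrid(c(-40, -40, -40), 4, c(21L, 21L, 21L))
  # single Gaussian blob -> exactly one peak at the centre voxel
  p1 <- detectPeaks(blobMap(grid, matrix(c(0, 0, 0), 1), 0.5), percentile = 0)
  expect_equal(nrow(p1), 1L)
  expect_equal(unlist(p1[1, c("x", "y", "z")], use.names = FALSE), c(0, 0, 0))

  # two well-separated equal blobs -> 2 peaks with equal values
  p2 <- detectPeaks(blobMap(grid, rbind(c(-24, 0, 0), c(24, 0, 0)), c(.5, .5)),
                    percentile = 0)
  expect_equal(nrow(p2), 2L)
  expect_equal(p2$ale_value[1], p2$ale_value[2])

  # 10 planted maxima with graded heights: brute-force the 90th-percentile
  # cutoff over suprathreshold voxel values, then check who survives
  set.seed(3)
  centers <- as.matrix(expand.grid(x = c(-28, 0, 28), y = c(-28, 0, 28),
                                   z = 0))[1:9, ]
  centers <- rbind(centers, c(0, 0, 28))
  heights <- seq(0.1, 0.99, length.out = 10)
  m10 <- blobMap(grid, centers, heights, sigmaMm = 5, floor = 0.02)
  v <- voxelValues(m10)
  cut90 <- quantile(v[v > 0], 0.90, names = FALSE)
  expected <- sum(heights > cut90)
  p10 <- detectPeaks(m10, percentile = 90)
  expect_equal(nrow(p10), expected)
  expect_equal(nrow(detectPeaks(m10, percentile = 0)), 10L)
  # every emitted peak is a suprathreshold local maximum of the map
  for (r in seq_len(nrow(p10)))
    expect_equal(v[p10$i[r], p10$j[r], p10$k[r]], p10$ale_value[r])

  # plateau: a flat-topped block yields a single peak
  vf <- array(0, dim = grid@dims)
  vf[7:15, 7:15, 7:15] <- 0.1     # pedestal
  vf[9:13, 9:13, 9:13] <- 0.2     # flat top
  flat <- new("AleMap", grid = grid, values = vf, nExperiments = 1L,
              fwhmMm = 10, thresholdValue = 0.1)
  pf <- detectPeaks(flat, percentile = 0)
  expect_equal(nrow(pf), 1L)
  expect_equal(unlist(pf[1, c("i", "j", "k")], use.names = FALSE),
               c(11, 11, 11))   # plateau centroid

  expect_equal(nrow(detectPeaks(blobMap(grid, matrix(c(0, 0, 0), 1), 0),
                                percentile = 0)), 0L)
  expect_error(detectPeaks(m10, percentile = 100), "percentile")
})

test_that("interpeak distance filter is greedy, inclusive and order-independent", {
  mk <- function(x, val) data.frame(i = 1, j = 1, k = 1, x = x, y = 0, z = 0,
                                    ale_value = val)
  two <- rbind(mk(0, 0.9), mk(5, 0.8))
  kept <- enforceInterpeakDistance(two, 10)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$ale_value, 0.9)

  # exactly 10 mm apart: both kept (inclusive comparison)
  ten <- rbind(mk(0, 0.9), mk(10, 0.8))
  expect_equal(nrow(enforceInterpeakDistance(ten, 10)), 2L)

  # all pairwise distances > 10: input preserved (sorted by value)
  far <- rbind(mk(0, 0.5), mk(20, 0.9), mk(45, 0.7))
  kept <- enforceInterpeakDistance(far, 10)
  expect_equal(kept$ale_value, c(0.9, 0.7, 0.5))

  # order independence: shuffling input rows never changes the result
  set.seed(8)
  peaks <- data.frame(i = 1:12, j = 1, k = 1,
                      x = runif(12, 0, 40), y = runif(12, 0, 40), z = 0,
                      ale_value = runif(12))
  ref <- enforceInterpeakDistance(peaks, 10)
  for (s in 1:5) {
    shuf <- peaks[sample.int(12), ]
    expect_equal(enforceInterpeakDistance(shuf, 10), ref)
  }
  expect_equal(nrow(enforceInterpeakDistance(peaks[0, ], 10)), 0L)
})

test_that("node labeling numbers nodes rostrocaudally within regions", {
  atlas <- twoCuboidAtlas()
  regions <- data.frame(label = 1:2, name = c("Region_L", "Region_R"),
                        hemisphere = c("L", "R"),
                        altered_voxels = c(100L, 100L),
                        passes = c(TRUE, TRUE))
  # six peaks inside Region_L at distinct y values, shuffled
  ys <- c(-8, -4, -2, 0, 2, 4)
  peaks <- data.frame(i = 5, j = worldToVoxel(atlas@grid, cbind(0, ys, 0))[, 2],
                      k = 8, x = -30, y = ys, z = -6,
                      ale_value = runif(6, .2, .9))
  peaks <- peaks[c(3, 1, 6, 2, 5, 4), ]
  nodes <- labelNodes(peaks, atlas, regions)
  expect_equal(nodes$id[order(-nodes$y)], paste0("Region_L_", 1:6))
  expect_true(all(nodes$hemisphere == "L"))

  # equal y: tie broken by descending ALE value
  tied <- data.frame(i = 5, j = 8, k = 8, x = -30, y = 0, z = -6,
                     ale_value = c(0.3, 0.7))
  n2 <- labelNodes(tied, atlas, regions)
  expect_equal(n2$id[n2$ale_value == 0.7], "Region_L_1")
  expect_equal(n2$id[n2$ale_value == 0.3], "Region_L_2")

  # background peak dropped with a warning
  bg <- data.frame(i = 21, j = 1, k = 1, x = 0, y = -20, z = -20,
                   ale_value = 0.5)
  expect_warning(n3 <- labelNodes(rbind(peaks, bg), atlas, regions),
                 "dropped")
  expect_equal(nrow(n3), 6L)

  # peaks in a non-passing region are dropped too
  regions$passes[2] <- FALSE
  rp <- data.frame(i = 35, j = 8, k = 8, x = 30, y = 0, z = -6,
                   ale_value = 0.5)
  expect_warning(n4 <- labelNodes(rp, atlas, regions), "dropped")
  expect_equal(nrow(n4), 0L)
})

test_that("node count is monotone in each of the three thresholds", {
  grid <- VolumeGrid(c(-40, -40, -40), 4, c(21L, 21L, 21L))
  atlas <- new("AtlasVolume", grid = grid,
               values = array(1L, dim = grid@dims),
               labelTable = data.frame(label = 1L, name = "All",
                                       hemisphere = "M"))
  set.seed(21)
  centers <- cbind(runif(8, -30, 30), runif(8, -30, 30), runif(8, -30, 30))
  m <- blobMap(grid, centers, runif(8, .2, 1), sigmaMm = 5, floor = 0.02)
  count <- function(mv = 1, pc = 0, dist = 0)
    nrow(buildNodes(m, atlas, minRegionVoxels = mv, percentile = pc,
                    minInterpeakMm = dist)$nodes)
  expect_true(all(diff(sapply(c(1, 10, 20, 50), function(v) count(mv = v))) <= 0))
  expect_true(all(diff(sapply(c(0, 50, 90), function(p) count(pc = p))) <= 0))
  expect_true(all(diff(sapply(c(0, 5, 10, 20), function(d) count(dist = d))) <= 0))
})
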
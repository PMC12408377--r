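test_that("sphere scenes satisfy packing, radius-range and determinism contracts", {
  sc <- genSphereScene(5, seed = 1, minGap = 0.2)
  expect_length(sc@primitives, 5)
  ctr <- t(vapply(sc@primitives, function(p) p@center, numeric(3)))
  rad <- vapply(sc@primitives, function(p) p@radius, numeric(1))
  expect_true(all(rad >= 0.15 & rad <= 0.90))
  # pairwise surface gaps and vial containment
  D <- as.matrix(dist(ctr))
  for (i in 1:4) for (j in (i + 1):5)
    expect_gte(D[i, j], rad[i] + rad[j] + 0.2 - 1e-12)
  expect_true(all(sqrt(rowSums(ctr[, 1:2]^2)) + rad <= sc@vialRadius))
  expect_true(all(ctr[, 3] - rad >= 0 & ctr[, 3] + rad <= sc@vialHeight))
  sc2 <- genSphereScene(5, seed = 1, minGap = 0.2)
  expect_identical(vapply(sc2@primitives, function(p) p@center, numeric(3)),
                   vapply(sc@primitives, function(p) p@center, numeric(3)))
  expect_error(genSphereScene(1e6, vialRadius = 4.4, seed = 1,
                              maxAttempts = 50),
               "infeasible packing")
})

test_that("pillar phantoms are opaque, vertical when untilted, and seeded", {
  sc <- genPillarPhantom(10, diameter = 1.0, tiltMax = 0, seed = 3)
  expect_length(sc@primitives, 10)
  for (p in sc@primitives) {
    expect_true(p@opaque)
    expect_equal(p@kind, "capsule")
    expect_equal(p@tubeRadius, 0.5)
    expect_equal(as.numeric(p@axis), c(0, 0, 1))
  }
  thin <- genPillarPhantom(10, diameter = 0.5, seed = 3)
  expect_equal(thin@primitives[[1]]@tubeRadius, 0.25)
  again <- genPillarPhantom(10, diameter = 1.0, tiltMax = 0, seed = 3)
  expect_identical(vapply(again@primitives, function(p) p@center, numeric(3)),
                   vapply(sc@primitives, function(p) p@center, numeric(3)))
})

test_that("cage scenes have merged strut edges with the expected count and degree", {
  sc <- genCageScene(45, 10, 5, 0.5, seed = 7)
  edges <- attr(sc, "edges")
  # duplicate merge bounds: brute-force count check on the generated graph
  expect_gte(nrow(edges), ceiling(45 * 5 / 2))
  expect_lte(nrow(edges), 45 * 5)
  expect_identical(nrow(edges), length(sc@primitives))
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = 45)
  expect_true(all(deg >= 5))
  nodes <- attr(sc, "nodes")
  ctr <- colMeans(nodes)
  expect_true(all(abs(sqrt(rowSums(sweep(nodes, 2,
                                         c(0, 0, 6), "-")^2)) - 5) < 1e-9))
})

test_that("torus scenes validate dimensions and sit at the requested centre", {
  sc <- genTorusScene(torusDiameter = 4, center = c(0, 0, 5))
  p <- sc@primitives[[1]]
  expect_equal(p@radius, 2)        # centreline ring diameter 4 mm
  expect_equal(p@center, c(0, 0, 5))
  expect_error(genTorusScene(tubeDiameter = 0), "tubeDiameter")
  expect_error(genTorusScene(torusDiameter = 12, vialRadius = 5),
               "fit")
})

test_that("rasterization converges to analytic volumes and fills the occlusion mask", {
  sc <- scene(list(spherePrimitive(c(0, 0, 2), 0.5, channel = "ch532")),
              vialRadius = 1.5, vialHeight = 4)
  volErr <- function(vox) {
    g <- voxelGrid(c(ceiling(3 / vox), ceiling(3 / vox), ceiling(4 / vox)),
                   vox)
    ras <- rasterizeScene(sc, g)
    v <- sum(ras$volumes$ch532@values) * vox^3
    abs(v - 4 / 3 * pi * 0.5^3) / (4 / 3 * pi * 0.5^3)
  }
  expect_lt(volErr(0.025), 0.02)
  # halving the voxel size at least halves the volume error
  expect_lt(volErr(0.025), volErr(0.05) / 2 + 1e-6)
  # empty scene: zero volumes, all-false mask
  empty <- rasterizeScene(scene(list(), 1.5, 4),
                          voxelGrid(c(40, 40, 50), 0.08))
  expect_length(empty$volumes, 0)
  expect_false(any(empty$mask@inside))
  # opaque pillar fills the mask exactly at voxel centres inside the capsule
  pil <- scene(list(capsulePrimitive(c(0, 0, 2), c(0, 0, 1), 0.4, 1.5,
                                     opaque = TRUE)), 1.5, 4)
  g <- voxelGrid(c(40, 40, 50), 0.08)
  m <- rasterizeScene(pil, g)$mask
  ctr <- expand.grid(x = gridCoords(g, 1), y = gridCoords(g, 2),
                     z = gridCoords(g, 3))
  inCap <- with(ctr, {
    t <- pmin(pmax((z - 0.5) / 3, 0), 1)
    sqrt(x^2 + y^2 + (z - (0.5 + 3 * t))^2) <= 0.4
  })
  expect_identical(as.vector(m@inside), inCap)
})

test_that("polar scans cover the sweep, are zero for empty volumes, and symmetric on-axis", {
  g <- voxelGrid(c(60, 60, 40), 0.05)
  sc <- scene(list(spherePrimitive(c(0, 0, 1), 0.4, channel = "ch532")),
              vialRadius = 1.5, vialHeight = 2)
  vol <- rasterizeScene(sc, g)$volumes$ch532
  scan <- simulatePolarScan(vol, nSections = 20, thetaTotal = pi)
  expect_equal(dim(scan@images)[3], 20)
  expect_equal(scan@angles, (0:19) * pi / 20)
  # sphere on the axis: sections are (voxelization aside) identical at
  # every angle; totals match to <1% and pixel differences are edge-only
  tot <- apply(scan@images, 3, sum)
  expect_lt(diff(range(tot)) / mean(tot), 0.05)
  for (k in 2:20)
    expect_lt(mean(abs(scan@images[, , k] - scan@images[, , 1])), 0.01)
  emptyVol <- new("ChannelVolume", grid = g, channel = "ch532",
                  values = array(0, g@dim))
  expect_true(all(simulatePolarScan(emptyVol, nSections = 5)@images == 0))
  # scan/ground-truth consistency: argmax pixel maps near the sphere centre
  off <- scene(list(spherePrimitive(c(0.5, 0.3, 1), 0.35,
                                    channel = "ch532")), 1.5, 2)
  vol2 <- rasterizeScene(off, g)$volumes$ch532
  scan2 <- simulatePolarScan(vol2, nSections = 90, thetaTotal = pi)
  cloud <- polarToCartesian(scan2)
  w <- cloud@intensity * (if (length(cloud@sampleVolume))
    cloud@sampleVolume else 1)
  ctr <- colSums(cloud@points * w) / sum(w)
  expect_lt(sqrt(sum((ctr - c(0.5, 0.3, 1))^2)), g@voxelSize)
})

test_that("reflectance scans trace occluder surfaces within one voxel", {
  pil <- scene(list(capsulePrimitive(c(0.4, 0, 1), c(0, 0, 1), 0.3, 0.8,
                                     opaque = TRUE)), 1.5, 2)
  g <- voxelGrid(c(60, 60, 40), 0.05)
  scan <- simulateReflectanceScan(pil, nSections = 120, grid = g)
  expect_equal(scan@mode, "reflectance")
  expect_equal(scan@thetaTotal, 2 * pi)
  cloud <- polarToCartesian(scan)
  expect_gt(length(cloud), 0)
  # every reconstructed surface point lies within 1 voxel of the capsule wall
  p <- cloud@points
  tpar <- pmin(pmax((p[, 3] - 0.2) / 1.6, 0), 1)
  ax <- cbind(0.4, 0, 0.2 + 1.6 * tpar)
  d <- abs(sqrt(rowSums((p - ax)^2)) - 0.3)
  # boundary-voxel depth plus (u, plane-offset) pixel quantization
  expect_lt(max(d), 3 * g@voxelSize)
  expect_lt(mean(d), g@voxelSize)
  expect_warning(
    simulateReflectanceScan(scene(list(spherePrimitive(c(0, 0, 1), 0.3,
                                                       channel = "ch532")),
                                  1.5, 2),
                            nSections = 8, grid = g),
    "no opaque content")
})

test_that("femur proxy meshes are watertight with the stated head radius", {
  fx <- femurProxyScene(voxel = 0.1)
  m <- meshMeasures(fx$mesh)
  expect_true(m$watertight)
  expect_gt(m$volume, 0)
  # distance-transform oracle: the head centre sits headRadius from the wall
  d <- tomoprint:::cpp_point_mesh_dist(matrix(fx$headCenter, 1, 3),
                                       meshVertices(fx$mesh),
                                       meshFaces(fx$mesh))
  expect_lt(abs(d - fx$headRadius), 0.1 + 1e-9)
})
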
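test_that("wrapped networks honour the stand-off geometry and perfusable topology", {
  net <- wrappedNetwork(c(0.5, -0.3, 5), 0.5, offset = 0.3, channelD = 0.45,
                        nArcs = 6)
  roles <- vapply(tubeEdges(net), `[[`, character(1), "role")
  expect_equal(sum(roles == "wrap"), 6)
  expect_setequal(unique(roles), c("inlet", "outlet", "wrap"))
  rho <- 0.5 + 0.3 + 0.225
  for (e in tubeEdges(net)) {
    if (e$role != "wrap") next
    d <- sqrt(colSums((t(e$points) - c(0.5, -0.3, 5))^2))
    expect_equal(max(abs(d - rho)), 0, tolerance = 1e-12) # exact by construction
  }
  single <- wrappedNetwork(c(0, 0, 5), 0.5, nArcs = 1)
  expect_equal(sum(vapply(tubeEdges(single), `[[`, character(1),
                          "role") == "wrap"), 1)
  expect_error(wrappedNetwork(c(4.8, 0, 5), 0.5, buildRadius = 5),
               "exceeds the build volume")
})

test_that("wrapped-network walls clear the feature surface by the offset", {
  vox <- 0.025
  net <- wrappedNetwork(c(0, 0, 2.2), 0.5, offset = 0.3, channelD = 0.45,
                        zRange = c(0, 4.4), buildRadius = 2.2)
  wall <- tomoprint:::meshTube(net, voxel = vox)$mesh
  sph <- tomoprint:::sphereMesh(c(0, 0, 2.2), 0.5, voxel = vox)
  expect_equal(minClearance(wall, sph), 0.3, tolerance = vox)
})

test_that("grazing channels are tangent lines with the contracted arithmetic", {
  gr <- grazingChannel(c(0, 0, 5), 0.3, offset = 0.3, channelD = 0.45)
  expect_length(tubeEdges(gr), 1)
  e <- tubeEdges(gr)[[1]]
  expect_equal(length(unique(e$radii)), 1)
  expect_equal(sqrt(sum(e$points[1, 1:2]^2)), 0.825, tolerance = 1e-12)
  expect_warning(grazingChannel(c(4.5, 0, 5), 0.3, buildRadius = 5),
                 "shifted inward")
  # mesh-measured clearance equals the offset
  vox <- 0.05
  gr2 <- grazingChannel(c(0, 0, 2), 0.4, offset = 0.3, zRange = c(0.5, 3.5),
                        buildRadius = 3)
  wall <- tomoprint:::meshTube(gr2, voxel = vox)$mesh
  sph <- tomoprint:::sphereMesh(c(0, 0, 2), 0.4, voxel = vox)
  expect_equal(minClearance(wall, sph), 0.3, tolerance = vox)
})

test_that("A* routes equal Dijkstra on seeded random geometric graphs", {
  set.seed(99)
  for (trial in 1:20) {
    n <- sample(8:50, 1)
    nodes <- matrix(stats::runif(3 * n, 0, 10), ncol = 3)
    edges <- unique(t(apply(cbind(sample(n, 3 * n, TRUE),
                                  sample(n, 3 * n, TRUE)), 1, sort)))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    w <- sqrt(rowSums((nodes[edges[, 1], , drop = FALSE] -
                       nodes[edges[, 2], , drop = FALSE])^2))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    igraph::E(g)$weight <- w
    from <- sample(n, 1)
    to <- sample(n, 1)
    got <- aStarPath(nodes, edges, from, to, weights = w)$length
    want <- igraph::distances(g, v = from, to = to)[1, 1]
    expect_equal(got, unname(want), tolerance = 1e-10)
  }
})

test_that("strut interconnection keeps an MST over the kNN candidate graph", {
  feats <- tomoprint:::emptyFeatures()
  set.seed(3)
  pts <- matrix(stats::runif(3 * 7, 0, 5), ncol = 3)
  for (i in 1:7) {
    feats[i, c("x", "y", "z")] <- pts[i, ]
    feats$id[i] <- i - 1L
    feats$radius[i] <- 0.3
    feats$nPoints[i] <- 50L
  }
  fs <- new("FeatureSet", features = feats, provenance = list())
  net <- interconnectStruts(fs, kCandidates = 3, strutD = 0.45)
  expect_length(tubeEdges(net), 6) # n - 1 struts, single component
  # two features -> one straight strut
  fs2 <- new("FeatureSet", features = feats[1:2, ], provenance = list())
  net2 <- interconnectStruts(fs2)
  expect_length(tubeEdges(net2), 1)
})

test_that("encapsulation shells have correct SDF signs and analytic volume", {
  sh <- encapsulationShell(c(0, 0, 0), rFeature = 0.5, offset = 0.3,
                           thickness = 0.3)
  expect_gt(sh@sdf(matrix(c(0, 0, 0), 1, 3)), 0)          # centroid outside
  expect_lt(sh@sdf(matrix(c(0.95, 0, 0), 1, 3)), 0)       # mid-shell inside
  vox <- 0.025
  g <- voxelGrid(rep(ceiling(2.6 / vox), 3), vox, rep(-1.3, 3))
  mesh <- extractMesh(tomoprint:::evalSdfOnGrid(sh@sdf, g), g)
  m <- meshMeasures(mesh)
  analytic <- 4 / 3 * pi * (1.1^3 - 0.8^3)
  expect_lt(abs(m$volume - analytic) / analytic, 0.03)
})

test_that("design rules dispatch by size (inclusive boundary) and by label", {
  feats <- tomoprint:::emptyFeatures()
  for (i in 1:3) {
    feats[i, c("x", "y", "z")] <- c(0, 0, 5)
    feats$id[i] <- i - 1L
    feats$nPoints[i] <- 10L
  }
  feats$radius <- c(0.3, 0.7, 0.5)
  feats$channel <- "ch532"
  fs <- new("FeatureSet", features = feats, provenance = list())
  out <- applyDesignRules(fs, sizeRules(threshold = 0.5))
  expect_equal(unname(vapply(out, attr, character(1), "rule")),
               c("grazing-small", "wrapped-large", "wrapped-large"))
  feats$channel <- c("ch532", "ch650", "ch650")
  feats$radius <- 0.4
  fsc <- new("FeatureSet", features = feats, provenance = list())
  outc <- applyDesignRules(fsc, spectralRules())
  expect_equal(unname(vapply(outc, attr, character(1), "rule")),
               c("grazing-spectral", "wrapped-spectral", "wrapped-spectral"))
  feats$channel <- "ch450"
  fsu <- new("FeatureSet", features = feats, provenance = list())
  expect_error(applyDesignRules(fsu, spectralRules()), "no design rule")
})

test_that("torus vessel solver converges to the target area with clearance", {
  net <- torusVesselNetwork()
  prov <- net@provenance
  expect_true(prov$converged)
  expect_lt(abs(prov$meshArea - 180), 10)
  # coil centrelines keep offset + local radius from the torus tube axis
  for (e in tubeEdges(net)) {
    if (e$role != "coil") next
    p <- e$points
    rho <- sqrt((sqrt(p[, 1]^2 + p[, 2]^2) - 2)^2 + (p[, 3] - 5)^2)
    expect_true(all(rho - (0.5 + 0.3 + e$radii) > -1e-9))
  }
  expect_error(torusVesselNetwork(targetArea = 5000, meshCalibrate = FALSE),
               "did not converge")
})

test_that("random channel controls match the area without intersecting", {
  net <- randomChannelNetwork(seed = 4)
  prov <- net@provenance
  expect_true(prov$converged)
  expect_lt(abs(prov$analyticArea - 180), 10)
  centers <- t(vapply(tubeEdges(net), function(e) e$points[1, 1:2],
                      numeric(2)))
  rmax <- max(vapply(tubeEdges(net), function(e) max(e$radii), numeric(1)))
  if (nrow(centers) > 1) {
    D <- as.matrix(dist(centers))
    expect_gt(min(D[upper.tri(D)]), 2 * rmax)
  }
  again <- randomChannelNetwork(seed = 4)
  expect_identical(tubeEdges(again)[[1]]$points, tubeEdges(net)[[1]]$points)
})

test_that("cartilage caps conform to the head with analytic shell volume", {
  cap <- cartilageCap(c(0, 0, 0), headRadius = 2.5, thickness = 0.5,
                      capAngle = 90, voxel = 0.06)
  m <- meshMeasures(cap)
  expect_true(m$watertight)
  analytic <- 2 / 3 * pi * (3.0^3 - 2.5^3)
  expect_lt(abs(m$volume - analytic) / analytic, 0.05)
  # inner surface conforms to the head sphere
  sph <- unitSphereMesh(2.5, voxel = 0.06)
  expect_lt(minClearance(cap, sph), 0.06)
  expect_error(cartilageCap(c(0, 0, 0), 2.5, capAngle = 0), "capAngle")
})

test_that("voxelization obeys the bulk set identity and analytic tube volume", {
  g <- voxelGrid(c(60, 60, 60), 0.05, c(-1.5, -1.5, 0))
  tube <- tubeGraph(list(list(points = rbind(c(0, 0, 0.3), c(0, 0, 2.7)),
                              radii = c(0.3, 0.3), role = "strut")))
  pos <- voxelizeModel(tube, g, "positive")
  neg <- voxelizeModel(tube, g, "negative_in_bulk", bulkRadius = 1.2,
                       bulkHeight = 3)
  bulkOnly <- voxelizeModel(tubeGraph(list()), g, "negative_in_bulk",
                            bulkRadius = 1.2, bulkHeight = 3)
  expect_identical(neg, bulkOnly & !pos) # exact voxelwise set identity
  vol <- sum(pos) * 0.05^3
  analytic <- pi * 0.3^2 * 2.4 + 4 / 3 * pi * 0.3^3 # capsule caps included
  expect_lt(abs(vol - analytic) / analytic, 0.03)
  outside <- tubeGraph(list(list(points = rbind(c(0, 0, -5), c(0, 0, 5)),
                                 radii = c(0.3, 0.3), role = "strut")))
  expect_error(voxelizeModel(outside, g, "positive"), "exceeds")
})

test_that("isosurface extraction is sub-voxel accurate and watertight", {
  volErr <- function(vox) {
    n <- ceiling(4.4 / vox)
    g <- voxelGrid(rep(n, 3), vox, rep(-2.2, 3))
    f <- tomoprint:::evalSdfOnGrid(function(p) sqrt(rowSums(p^2)) - 2, g)
    m <- meshMeasures(extractMesh(f, g))
    expect_true(m$watertight)
    abs(m$volume - 4 / 3 * pi * 8) / (4 / 3 * pi * 8)
  }
  expect_lt(volErr(0.05), 0.01)
  expect_lt(volErr(0.05), volErr(0.1) / 2 + 1e-9) # resolution convergence
  g <- voxelGrid(c(10, 10, 10), 0.1)
  expect_error(extractMesh(array(0, c(10, 10, 10)), g), "empty foreground")
  # all-true binary volume: just the box surface
  box <- extractMesh(array(TRUE, c(8, 8, 8)), voxelGrid(c(8, 8, 8), 0.1))
  expect_true(meshMeasures(box)$watertight)
})

test_that("mesh measures give closed forms for cubes and spheres", {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  cube <- triMesh(v, f)
  m <- meshMeasures(cube)
  expect_equal(m$area, 6)
  expect_equal(m$volume, 1)
  expect_true(m$watertight)
  open <- triMesh(v, f[-1, ])
  expect_true(is.na(meshMeasures(open)$volume)) # volume withheld
  sph <- unitSphereMesh(1, voxel = 0.02)
  expect_lt(abs(meshMeasures(sph)$area - 4 * pi) / (4 * pi), 0.01)
})

test_that("clearance between meshes matches closed forms", {
  a <- unitSphereMesh(1, voxel = 0.05)
  b <- triMesh(sweep(meshVertices(a), 2, c(3, 0, 0), "+"), meshFaces(a))
  expect_equal(minClearance(a, b), 1, tolerance = 0.01)
  touching <- triMesh(sweep(meshVertices(a), 2, c(2, 0, 0), "+"),
                      meshFaces(a))
  expect_lt(minClearance(a, touching), 0.05)
})
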
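test_that("polar-to-Cartesian mapping follows the coordinate formula", {
  img <- array(0, c(81, 10, 4))
  img[41, 3, ] <- 2      # on the axis column
  img[81, 5, 2] <- 1     # +40 px off axis in section 2
  scan <- new("PolarScan", images = img,
              angles = c(0, pi / 2, pi, 3 * pi / 2), thetaTotal = 2 * pi,
              pixelSize = 0.025, axisColumn = 41, channel = "ch532",
              mode = "fluorescence", zOrigin = 0)
  cloud <- polarToCartesian(scan)
  pts <- cloud@points
  # axis pixels map to (0, 0, z) for every theta
  ax <- pts[cloud@intensity == 2, , drop = FALSE]
  expect_equal(nrow(ax), 4)
  expect_true(all(abs(ax[, 1:2]) < 1e-12))
  expect_equal(unique(ax[, 3]), 2.5 * 0.025)
  # u - u0 = +40 px at theta = pi/2 -> (0, 1, z)
  off <- pts[cloud@intensity == 1, ]
  expect_equal(as.numeric(off), c(0, 1.0, 4.5 * 0.025), tolerance = 1e-12)
})

test_that("foreground isolation matches a brute-force Otsu oracle", {
  set.seed(42)
  ints <- c(pmax(stats::rnorm(300, 0.1, 0.02), 0),
            stats::rnorm(200, 1.0, 0.05))
  cloud <- pointCloud(matrix(stats::rnorm(1500), ncol = 3),
                      intensity = ints)
  fg <- isolateForeground(cloud, "otsu")
  th <- attr(fg, "threshold")
  # Otsu has a plateau of maximizers between well-separated modes: the
  # induced partition must match the brute-force histogram oracle
  expect_setequal(which(ints >= th), which(ints >= bruteOtsu(ints)))
  expect_setequal(which(ints >= th), which(ints >= 0.5)) # only signal kept
  expect_length(fg, 200)
  # fixed threshold 0 is the identity
  expect_length(isolateForeground(cloud, "fixed", threshold = 0), 500)
  flat <- pointCloud(matrix(stats::rnorm(30), ncol = 3),
                     intensity = rep(1, 10))
  expect_warning(isolateForeground(flat, "otsu"), "degenerate")
})

test_that("DBSCAN clustering matches brute-force density reachability", {
  set.seed(7)
  for (trial in 1:4) {
    pts <- rbind(matrix(stats::rnorm(3 * 120, 0, 0.3), ncol = 3),
                 matrix(stats::rnorm(3 * 150, 4, 0.5), ncol = 3),
                 matrix(stats::runif(3 * 80, -6, 6), ncol = 3))
    eps <- c(0.4, 0.6, 0.8, 1.0)[trial]
    got <- tomoprint:::cpp_dbscan(pts, eps, 8)
    want <- bruteDbscan(pts, eps, 8)
    expect_identical(got == 0, want == 0)
    # same partition up to label permutation (border-point ties aside,
    # compare core-point partitions)
    D <- as.matrix(dist(pts))
    core <- rowSums(D <= eps) >= 8
    tab <- table(got[core], want[core])
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("scan -> cloud -> clusters recovers every sphere and centroid", {
  sc <- genSphereScene(12, radiusRange = c(0.25, 0.6), minGap = 0.7,
                       vialRadius = 4, vialHeight = 8, seed = 11)
  vox <- 0.06
  g <- voxelGrid(c(ceiling(8 / vox), ceiling(8 / vox), ceiling(8 / vox)),
                 vox)
  vol <- rasterizeScene(sc, g)$volumes$ch532
  scan <- simulatePolarScan(vol, nSections = 150, thetaTotal = pi)
  cloud <- polarToCartesian(scan)
  fs <- detectClusters(cloud, eps = 3 * vox, minSamples = 10)
  expect_equal(nrow(features(fs)), 12)
  truth <- t(vapply(sc@primitives, function(p) p@center, numeric(3)))
  f <- features(fs)
  for (i in seq_len(12)) {
    d <- sqrt(colSums((t(truth) - c(f$x[i], f$y[i], f$z[i]))^2))
    expect_lt(min(d), vox)
  }
})

test_that("volume-based radius estimation recovers sphere radii", {
  # full-density voxel cloud: r-hat within one spacing
  cl <- pointCloud(sphereVoxelCloud(c(1, 2, 3), 0.5, 0.05))
  fs <- detectClusters(cl, eps = 0.15, minSamples = 5)
  fs <- estimateRadius(fs, cl, pointSpacing = 0.05)
  expect_equal(features(fs)$radius, 0.5, tolerance = 0.05)
  expect_false(features(fs)$lowConfidence)
  # doubling the spacing leaves the estimate consistent
  cl2 <- pointCloud(sphereVoxelCloud(c(1, 2, 3), 0.5, 0.1))
  fs2 <- detectClusters(cl2, eps = 0.3, minSamples = 5)
  fs2 <- estimateRadius(fs2, cl2, pointSpacing = 0.1)
  expect_equal(features(fs2)$radius, features(fs)$radius, tolerance = 0.1)
  # radius recovery over 20 seeded scenes: |r-hat - r| <= 2 * spacing
  set.seed(5)
  for (k in 1:20) {
    r <- stats::runif(1, 0.3, 0.8)
    sp <- 0.05
    cl <- pointCloud(sphereVoxelCloud(stats::runif(3, -1, 1), r, sp))
    fs <- detectClusters(cl, eps = 3 * sp, minSamples = 5)
    fs <- estimateRadius(fs, cl, pointSpacing = sp)
    expect_lt(abs(features(fs)$radius - r), 2 * sp)
  }
  # degenerate (planar) cluster flagged low-confidence
  plane <- pointCloud(cbind(as.matrix(expand.grid(seq(0, 1, 0.05),
                                                  seq(0, 1, 0.05))), 0))
  fsp <- detectClusters(plane, eps = 0.15, minSamples = 5)
  fsp <- estimateRadius(fsp, plane, pointSpacing = 0.05)
  expect_true(features(fsp)$lowConfidence)
})

test_that("PCA pillar orientation recovers pitch and yaw within half a degree", {
  # construct capsule surface points, brute-force covariance oracle implicit
  makePillar <- function(R) {
    tt <- seq(-2.5, 2.5, length.out = 160)
    ang <- seq(0, 2 * pi, length.out = 24)[-24]
    pts <- cbind(rep(0.25 * cos(ang), length(tt)),
                 rep(0.25 * sin(ang), length(tt)),
                 rep(tt, each = length(ang)))
    t(R %*% t(pts))
  }
  vertical <- pointCloud(makePillar(diag(3)))
  fs <- detectClusters(vertical, eps = 0.3, minSamples = 5)
  fs <- estimatePillarAxes(fs, vertical)
  expect_lt(abs(features(fs)$pitch), 0.5)
  tilted <- pointCloud(makePillar(rotAbout(c(1, 0, 0), 10 * pi / 180)))
  ft <- detectClusters(tilted, eps = 0.3, minSamples = 5)
  ft <- estimatePillarAxes(ft, tilted)
  expect_equal(features(ft)$pitch, 10, tolerance = 0.5)
  # spherical cluster: orientation withheld
  ball <- pointCloud(sphereVoxelCloud(c(0, 0, 0), 0.5, 0.08))
  fb <- detectClusters(ball, eps = 0.25, minSamples = 5)
  fb <- estimatePillarAxes(fb, ball)
  expect_true(is.na(features(fb)$pitch))
})

test_that("spectral classification merges channels and flags co-detections", {
  mk <- function(centers, channel) {
    feats <- tomoprint:::emptyFeatures()
    for (i in seq_len(nrow(centers))) {
      feats[i, c("x", "y", "z")] <- centers[i, ]
      feats$id[i] <- i - 1L
      feats$channel[i] <- channel
      feats$nPoints[i] <- 100L
      feats$lowConfidence[i] <- FALSE
      feats$ambiguous[i] <- FALSE
    }
    new("FeatureSet", features = feats, provenance = list(channel = channel))
  }
  a <- mk(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)), "ch532")
  b <- mk(rbind(c(5, 5, 5), c(7, 5, 5), c(5, 7, 5), c(7, 7, 5)), "ch650")
  merged <- classifySpectral(list(a, b), matchRadius = 0.2)
  f <- features(merged)
  expect_equal(nrow(f), 7)
  expect_equal(sum(f$channel == "ch532"), 3)
  expect_equal(sum(f$channel == "ch650"), 4)
  expect_false(any(f$ambiguous))
  # same sphere in both channels -> one ambiguous feature
  dup <- classifySpectral(list(mk(rbind(c(1, 1, 1)), "ch532"),
                               mk(rbind(c(1.05, 1, 1)), "ch650")),
                          matchRadius = 0.2)
  expect_equal(nrow(features(dup)), 1)
  expect_true(features(dup)$ambiguous)
})
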
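test_that("projector and dose operators are adjoint under arbitrary occlusions", {
  set.seed(21)
  for (trial in 1:4) {
    n <- 32
    x <- array(stats::runif(n^3), c(n, n, n))
    ang <- seq(0, 2 * pi, length.out = 25)[-25]
    occ <- array(stats::runif(n^3) < c(0, 0.02, 0.1, 0.3)[trial],
                 c(n, n, n))
    P <- forwardProject(x, ang, occlusion = if (trial > 1) occ else NULL)
    y <- array(stats::runif(length(P@values)), dim(P@values))
    ySet <- new("ProjectionSet", values = y, angles = ang, pitch = 1)
    D <- computeDose(ySet, dim2 = c(n, n),
                     occlusion = if (trial > 1) occ else NULL)
    lhs <- sum(P@values * y)
    rhs <- sum(x * D@dose)
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  }
})

test_that("sinograms of a centred disk are angle-constant with chord-length profiles", {
  n <- 128
  cc <- (n - 1) / 2
  ix <- seq_len(n) - 1 - cc
  R <- 40
  disk <- outer(ix^2, ix^2, "+") <= R^2
  ang <- seq(0, 2 * pi, length.out = 61)[-61]
  P <- forwardProject(disk * 1, ang)
  sino <- P@values[, , 1]
  # rotational symmetry across angles
  expect_lt(max(abs(sino - rowMeans(sino))), 0.02 * max(sino) + 2)
  # profile = chord length x density
  u <- seq_len(n) - 1 - cc
  chord <- ifelse(abs(u) < R, 2 * sqrt(pmax(R^2 - u^2, 0)), 0)
  inner <- abs(u) < 0.8 * R
  expect_lt(max(abs(sino[inner, 1] - chord[inner]) / chord[inner]), 0.02)
  expect_true(all(forwardProject(matrix(0, 32, 32), ang)@values == 0))
})

test_that("rays deposit nothing downstream of an occluder", {
  n <- 64
  occ <- matrix(FALSE, n, n)
  occ[, 30:34] <- TRUE # occluding slab
  proj <- matrix(0, n, 1)
  proj[, 1] <- 1
  pset <- new("ProjectionSet", values = array(proj, c(n, 1, 1)),
              angles = pi / 2, pitch = 1) # rays along +y
  D <- computeDose(pset, dim2 = c(n, n), occlusion = occ)@dose[, , 1]
  expect_true(all(D[, 1:28] > 0))   # upstream dosed
  expect_true(all(D[, 37:n] == 0))  # strictly downstream starved
  # uniform projections over 2 pi: radially symmetric dose about the axis
  ang <- seq(0, 2 * pi, length.out = 91)[-91]
  uni <- new("ProjectionSet", values = array(1, c(n, 90, 1)), angles = ang,
             pitch = 1)
  Du <- computeDose(uni, dim2 = c(n, n))@dose[, , 1]
  cc <- (n - 1) / 2
  ix <- seq_len(n) - 1 - cc
  rr <- sqrt(outer(ix^2, ix^2, "+"))
  ring <- rr > 10 & rr < 12
  expect_lt(stats::sd(Du[ring]) / mean(Du[ring]), 0.02)
})

test_that("OSMO reproduces an unoccluded disk and degenerates gracefully", {
  n <- 96
  cc <- (n - 1) / 2
  ix <- seq_len(n) - 1 - cc
  disk <- outer(ix^2, ix^2, "+") <= 30^2
  ang <- seq(0, 2 * pi, length.out = 121)[-121]
  res <- osmoOptimize(disk, osmoParams(maxIters = 30), angles = ang)
  b <- binarizeDose(res$dose, "best_jaccard", target = disk)
  expect_gt(attr(b, "jaccard"), 0.95)
  # error count at termination never exceeds the initial one
  expect_lte(min(res$history), res$history[1])
  expect_true(all(res$projections@values >= 0))
  expect_true(all(res$dose >= 0))
  # eta = 0: dose equals the initial backprojection of the clipped forward
  # projection of the target
  res0 <- osmoOptimize(disk, osmoParams(eta = 0, maxIters = 3),
                       angles = ang)
  P0 <- forwardProject(disk * 1, ang)
  D0 <- computeDose(P0, dim2 = c(n, n), normalize = "max")
  expect_equal(res0$dose[, , 1], D0@dose[, , 1], tolerance = 1e-12)
})

test_that("shadow correction dominates per seed on the pillar benchmark", {
  rep <- shadowBenchmark(nReps = 2, seeds = 4:5, n = 96, nAngles = 120,
                         params = osmoParams(maxIters = 20))
  runs <- reportRuns(rep)
  for (s in unique(runs$seed)) {
    co <- runs[runs$seed == s & runs$arm == "corrected", ]
    un <- runs[runs$seed == s & runs$arm == "uncorrected", ]
    expect_gt(co$jaccard, un$jaccard)
    expect_lt(co$bhattacharyya, un$bhattacharyya)
  }
})

test_that("occluder-trimmed targets reject empty results", {
  tgt <- matrix(FALSE, 32, 32)
  tgt[10:12, 10:12] <- TRUE
  occ <- matrix(FALSE, 32, 32)
  occ[8:14, 8:14] <- TRUE
  expect_error(osmoOptimize(tgt, occlusion = occ,
                            angles = c(0, pi / 2), voxelSize = 1,
                            occlusionClearance = 1),
               "empty target")
})

test_that("dose binarization is monotone and exact on indicator doses", {
  set.seed(2)
  d <- matrix(stats::runif(64 * 64), 64, 64)
  b1 <- binarizeDose(d, "fixed", threshold = 0.3)
  b2 <- binarizeDose(d, "fixed", threshold = 0.6)
  expect_true(all(b2 <= b1)) # raising the threshold never adds voxels
  expect_true(all(binarizeDose(d, "fixed", threshold = 0)))
  tgt <- matrix(FALSE, 64, 64)
  tgt[20:40, 20:40] <- TRUE
  bb <- binarizeDose(tgt * 1, "best_jaccard", target = tgt)
  expect_equal(attr(bb, "jaccard"), 1)
})

test_that("FLight exposure extrudes patterns to the stated depth fraction", {
  g <- voxelGrid(c(40, 40, 10), 0.1)
  full <- flightPattern(matrix(TRUE, 40, 10), angle = 0, depthFraction = 1)
  expect_true(all(flightExpose(full, g)))
  img <- matrix(FALSE, 40, 10)
  img[15:25, 3:7] <- TRUE
  pat <- flightPattern(img, angle = 0, depthFraction = 0.7)
  vol <- flightExpose(pat, g)
  expect_equal(sum(vol), sum(img) * floor(0.7 * 40)) # exact counting
  # filaments span 70% of the traversal from the entry side
  expect_true(all(vol[1:28, 15:25, 5]))
  expect_false(any(vol[29:40, , ]))
})

test_that("telecentric point projection follows the detector convention", {
  expect_equal(unname(pointBeamCoords(c(1, 0, 2), 0)[1, ]), c(0, 2))
  expect_equal(unname(pointBeamCoords(c(1, 0, 2), pi / 2)[1, ]), c(-1, 2))
  expect_true(all(abs(pointBeamCoords(c(0, 0, 1),
                                      seq(0, 2 * pi, 0.1))[, "u"]) < 1e-12))
  th <- seq(0, 2 * pi, length.out = 200)
  u <- pointBeamCoords(c(1.2, -0.7, 0), th)[, "u"]
  expect_equal(max(abs(u)), sqrt(1.2^2 + 0.7^2), tolerance = 1e-3)
})
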
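test_that("volume sampling stays inside the mesh, is seeded, and centred", {
  sph <- unitSphereMesh(1, voxel = 0.05)
  cl <- sampleVolumePoints(sph, 3000, seed = 1)
  expect_length(cl, 3000)
  expect_true(all(sqrt(rowSums(cl@points^2)) <= 1 + 1e-6))
  cl2 <- sampleVolumePoints(sph, 3000, seed = 1)
  expect_identical(cl@points, cl2@points)
  # symmetric solid: sample mean near the centroid
  big <- sampleVolumePoints(sph, 20000, seed = 2)
  expect_lt(sqrt(sum(colMeans(big@points)^2)), 0.05)
  open <- triMesh(meshVertices(sph), meshFaces(sph)[-1, ])
  expect_error(sampleVolumePoints(open, 10), "watertight")
})

test_that("ICP recovers identity and known rigid transforms", {
  set.seed(10)
  ref <- matrix(stats::runif(3 * 800, -2, 2), ncol = 3)
  fit0 <- icpRegister(ref, ref)
  expect_lt(fit0@rmse, 1e-9)
  expect_lt(max(abs(fit0@transform@rotation - diag(3))), 1e-6)
  R <- rotAbout(c(0, 0, 1), 20 * pi / 180)
  scan <- t(R %*% t(ref)) + rep(c(1, 0.5, -0.5), each = nrow(ref))
  fit <- icpRegister(ref, scan)
  angErr <- acos(pmin(1, (sum(diag(t(R) %*% fit@transform@rotation)) - 1) / 2))
  expect_lt(angErr * 180 / pi, 1)
  expect_lt(sqrt(sum((fit@transform@translation - c(1, 0.5, -0.5))^2)), 0.1)
  # with per-point noise the recovery tolerances still hold and rmse ~ sigma
  noisy <- scan + matrix(stats::rnorm(length(scan), 0, 0.05), ncol = 3)
  fitN <- icpRegister(ref, noisy)
  angErrN <- acos(pmin(1, (sum(diag(t(R) %*% fitN@transform@rotation)) - 1) / 2))
  expect_lt(angErrN * 180 / pi, 1)
  expect_lt(sqrt(sum((fitN@transform@translation - c(1, 0.5, -0.5))^2)), 0.1)
  expect_gt(fitN@rmse, 0.02)
  expect_lt(fitN@rmse, 0.12)
  expect_error(icpRegister(cbind(1:10, 1:10, 1:10), scan), "collinear")
})

test_that("trimmed rmse is non-increasing across ICP iterations", {
  set.seed(11)
  ref <- matrix(stats::runif(3 * 500, -2, 2), ncol = 3)
  R <- rotAbout(c(1, 1, 0), 15 * pi / 180)
  scan <- t(R %*% t(ref)) + rep(c(0.4, -0.2, 0.3), each = nrow(ref)) +
    matrix(stats::rnorm(3 * 500, 0, 0.02), ncol = 3)
  fit <- icpRegister(ref, scan)
  expect_true(all(diff(fit@history) <= 1e-12))
})

test_that("transform application and group properties hold to 1e-9 mm", {
  sph <- unitSphereMesh(1, voxel = 0.08)
  idT <- rigidTransform()
  same <- transformGeometry(sph, idT)
  expect_identical(meshFaces(same), meshFaces(sph))
  expect_equal(meshVertices(same), meshVertices(sph), tolerance = 1e-15)
  shift <- rigidTransform(translation = c(1, 2, 3))
  moved <- transformGeometry(sph, shift)
  expect_equal(colMeans(meshVertices(moved)) - colMeans(meshVertices(sph)),
               c(1, 2, 3), tolerance = 1e-12)
  T1 <- rigidTransform(rotAbout(c(0.3, -0.5, 0.8), 0.7), c(0.3, -1, 2))
  back <- transformGeometry(transformGeometry(sph, T1), invertTransform(T1))
  expect_lt(max(abs(meshVertices(back) - meshVertices(sph))), 1e-9)
  comp <- composeTransforms(invertTransform(T1), T1)
  expect_lt(max(abs(comp@rotation - diag(3))), 1e-12)
  expect_lt(max(abs(comp@translation)), 1e-12)
})

test_that("the femur-cartilage alignment workflow closes the cap-to-head gap", {
  fx <- femurProxyScene(voxel = 0.12)
  cap <- cartilageCap(fx$headCenter, fx$headRadius, voxel = 0.1)
  pRef <- sampleVolumePoints(fx$mesh, 1500, seed = 5)
  trueT <- rigidTransform(rotAbout(c(0.2, 1, 0.4), 18 * pi / 180),
                          c(0.8, -0.4, 0.6))
  pScan <- transformGeometry(sampleVolumePoints(fx$mesh, 1500, seed = 6),
                             trueT)
  fit <- icpRegister(pRef, pScan)
  aligned <- transformGeometry(cap, fit@transform)
  headTrue <- transformGeometry(
    tomoprint:::sphereMesh(fx$headCenter, fx$headRadius, voxel = 0.1), trueT)
  expect_lt(minClearance(aligned, headTrue), 0.15) # conforming, ~0 gap
})
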
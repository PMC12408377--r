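test_that("Jaccard index matches closed forms and symmetry", {
  a <- array(FALSE, c(10, 10, 1))
  a[1:4, 1:10, 1] <- TRUE
  expect_equal(jaccard(a, a), 1)
  b <- array(FALSE, c(10, 10, 1))
  b[7:10, 1:10, 1] <- TRUE
  expect_equal(jaccard(a, b), 0)
  # two unit squares overlapping half: J = 1/3
  s1 <- array(FALSE, c(20, 10, 1))
  s1[1:10, , 1] <- TRUE
  s2 <- array(FALSE, c(20, 10, 1))
  s2[6:15, , 1] <- TRUE
  expect_equal(jaccard(s1, s2), 1 / 3)
  expect_equal(jaccard(s1, s2), jaccard(s2, s1))
  expect_equal(jaccard(a & FALSE, b & FALSE), 1) # both empty
  expect_error(jaccard(a, array(FALSE, c(5, 5, 1))), "different grids")
})

test_that("Bhattacharyya coefficient matches limits and the Gaussian closed form", {
  d <- array(stats::runif(4000), c(20, 20, 10))
  tgt <- array(rep(c(TRUE, FALSE), each = 2000), c(20, 20, 10))
  expect_equal(bhattacharyyaContrast(d, tgt), 1, tolerance = 0.05)
  sep <- array(0, c(20, 20, 10))
  sep[tgt] <- 0.9
  sep[!tgt] <- 0.1
  expect_equal(bhattacharyyaContrast(sep, tgt), 0)
  # two unit-variance Gaussians with means 2 apart: BC = exp(-1/2) = 0.607
  set.seed(31)
  n <- 5e5
  vals <- c(stats::rnorm(n, 5, 1), stats::rnorm(n, 7, 1))
  vals <- pmax(vals, 0)
  dg <- array(vals, c(100, 100, 100))
  tg <- array(rep(c(TRUE, FALSE), each = n), c(100, 100, 100))
  expect_equal(bhattacharyyaContrast(dg, tg, nBins = 256), exp(-0.5),
               tolerance = 0.02)
  expect_error(bhattacharyyaContrast(d, array(TRUE, dim(d))), "empty")
})

test_that("rms surface error matches concentric-sphere and oracle values", {
  sph <- unitSphereMesh(1, voxel = 0.04)
  expect_lt(rmsSurfaceError(sph, list(center = c(0, 0, 0), radius = 1)),
            0.01)
  # concentric spheres r vs r + delta: every distance = delta
  expect_equal(rmsSurfaceError(sph, list(center = c(0, 0, 0),
                                         radius = 1.25)),
               0.25, tolerance = 0.01)
  # ellipsoid vs unit sphere: implementation (mesh reference) against the
  # analytic-sphere distance oracle on identical dense samples
  ell <- triMesh(sweep(meshVertices(sph), 2, c(1.1, 1, 1), "*"),
                 meshFaces(sph))
  got <- rmsSurfaceError(ell, sph, nSamples = 20000, seed = 3)
  pts <- tomoprint:::meshSampleSurface(ell, 20000, seed = 3)
  want <- sqrt(mean((sqrt(rowSums(pts^2)) - 1)^2))
  expect_lt(abs(got - want) / want, 0.01)
})

test_that("sphericity reaches closed forms for spheres, cubes and ellipsoids", {
  sph <- unitSphereMesh(1, voxel = 0.02)
  expect_gte(sphericity(sph), 0.999)
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  expect_equal(sphericity(triMesh(v, f)), pi^(1 / 3) * 6^(2 / 3) / 6,
               tolerance = 1e-12)
  # 2:1:1 prolate spheroid: analytic area and volume
  ell <- triMesh(sweep(meshVertices(unitSphereMesh(1, 0.02)), 2,
                       c(2, 1, 1), "*"), meshFaces(sph))
  e <- sqrt(1 - 1 / 4)
  area <- 2 * pi * (1 + 2 / e * asin(e))
  vol <- 4 / 3 * pi * 2
  expect_equal(sphericity(ell), pi^(1 / 3) * (6 * vol)^(2 / 3) / area,
               tolerance = 0.01)
})

test_that("cog slices have the configured teeth, bore and extents", {
  cs <- cogSlice(n = 200, voxel = 0.05, outerR = 3, tipR = 3.5, nTeeth = 8,
                 boreR = 1)
  cc <- (200 - 1) / 2
  ix <- (seq_len(200) - 1 - cc) * 0.05
  rr <- sqrt(outer(ix^2, ix^2, "+"))
  expect_false(any(cs[rr < 1 - 0.05]))          # bore open
  expect_false(any(cs[rr > 3.5 + 0.05]))        # nothing beyond tooth tips
  expect_true(all(cs[rr > 1.1 & rr < 2.9]))     # annulus solid
  phi <- atan2(outer(rep(1, 200), ix), outer(ix, rep(1, 200)))
  tips <- cs & rr > 3.2
  # eight tooth sectors: count sign changes of tip occupancy around a ring
  ring <- rr > 3.2 & rr < 3.4
  ringPhi <- sort(phi[ring & cs])
  gaps <- diff(ringPhi) > 0.2
  expect_equal(sum(gaps) + 1, 8)
})

test_that("occlusion Monte Carlo degrades with pillar count and is deterministic", {
  tab <- occlusionMonteCarlo(pillarCounts = c(0, 6), nTrials = 3,
                             seedBase = 10, n = 64, nAngles = 90,
                             params = osmoParams(maxIters = 12))
  # no occlusion is easiest: the best row has zero pillars
  expect_equal(tab$nPillars[1], 0)
  m0 <- mean(tab$jaccard[tab$nPillars == 0])
  m6 <- mean(tab$jaccard[tab$nPillars == 6])
  expect_gt(m0, m6)
  tab2 <- occlusionMonteCarlo(pillarCounts = c(0, 6), nTrials = 3,
                              seedBase = 10, n = 64, nAngles = 90,
                              params = osmoParams(maxIters = 12))
  expect_identical(tab, tab2)
})

test_that("corrected ball-in-cage prints are rounder and closer to target per seed", {
  rep <- cageBenchmark(nReps = 2, seeds = 1:2, n = 48, nAngles = 90,
                       params = osmoParams(maxIters = 15))
  runs <- reportRuns(rep)
  for (s in unique(runs$seed)) {
    co <- runs[runs$seed == s & runs$arm == "corrected", ]
    un <- runs[runs$seed == s & runs$arm == "uncorrected", ]
    expect_lt(co$rms, un$rms)
    expect_gt(co$sphericity, un$sphericity)
  }
})
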
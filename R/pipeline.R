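# End-to-end demo scenarios and the pipeline driver tying the modules
# together: scan -> detect -> generate -> (align) -> optimize -> evaluate.

#' Catalog of end-to-end demo scenarios
#'
#' Each demo exercises one adaptive-printing scenario end to end on
#' synthetic scenes and emits a metric or clearance report.
#'
#' @return data.frame with demo names and descriptions.
#' @export
demoCatalog <- function() {
  data.frame(
    name = c("wrap-spheres", "interconnect", "encapsulate",
             "conditional-size", "conditional-spectral", "femur-cartilage",
             "pillar-shadow", "ball-in-cage", "torus-vessels", "flight"),
    description = c(
      "Spherically wrapped channel networks around detected spheres",
      "Strut interconnection of detected spheres (kNN + MST + A*)",
      "Encapsulation shell around a detected sphere",
      "Size-conditional geometry: r < 0.5 mm grazes, r >= 0.5 mm wrapped",
      "Spectral-conditional geometry: ch532 grazes, ch650 wrapped",
      "Femur/cartilage sequential print with ICP auto-alignment",
      "Cog print with pillar occlusions: OSMO shadow correction",
      "Ball-in-cage print: 3D shadow correction, sphericity and rms",
      "Tapered vessel networks around a torus, area-matched controls",
      "Single-projection FLight exposure: circles and stars at spheroids"),
    stringsAsFactors = FALSE)
}

# scan a scene and register sphere features (shared by several demos)
scanAndDetect <- function(sc, voxel = 0.05, nSections = 180,
                          thetaTotal = pi, eps = 3 * voxel,
                          minSamples = 10, channel = NULL) {
  nxy <- as.integer(ceiling(2 * sc@vialRadius / voxel))
  nz <- as.integer(ceiling(sc@vialHeight / voxel))
  grid <- voxelGrid(c(nxy, nxy, nz), voxel)
  ras <- rasterizeScene(sc, grid)
  vols <- ras$volumes
  if (!is.null(channel)) vols <- vols[channel]
  out <- lapply(vols, function(v) {
    scan <- simulatePolarScan(v, nSections = nSections,
                              thetaTotal = thetaTotal)
    cloud <- polarToCartesian(scan)
    fs <- detectClusters(cloud, eps = eps, minSamples = minSamples)
    fs <- estimateRadius(fs, cloud, pointSpacing = voxel)
    list(scan = scan, cloud = cloud, features = fs)
  })
  list(grid = grid, ras = ras, channels = out)
}

# voxelize one tube graph on a tight local grid and mesh it
meshTube <- function(graph, voxel = 0.025, pad = 0.2) {
  segs <- tubeSegments(graph)
  rmax <- max(segs[, 7:8])
  lo <- pmin(apply(segs[, 1:3, drop = FALSE], 2, min),
             apply(segs[, 4:6, drop = FALSE], 2, min)) - rmax - pad
  hi <- pmax(apply(segs[, 1:3, drop = FALSE], 2, max),
             apply(segs[, 4:6, drop = FALSE], 2, max)) + rmax + pad
  dims <- as.integer(ceiling((hi - lo) / voxel))
  grid <- voxelGrid(dims, voxel, lo)
  field <- modelSdf(graph, grid)
  list(mesh = extractMesh(field, grid), grid = grid)
}

# analytic sphere mesh at given voxel size (for clearance measurements)
sphereMesh <- function(center, radius, voxel = 0.025, pad = 0.15) {
  lo <- center - radius - pad
  dims <- as.integer(ceiling((2 * radius + 2 * pad) / voxel))
  grid <- voxelGrid(rep(max(dims), 3), voxel, lo)
  field <- evalSdfOnGrid(function(p)
    sqrt(colSums((t(p) - center)^2)) - radius, grid)
  extractMesh(field, grid)
}

demoWrapSpheres <- function(seed = 1, voxel = 0.05, meshVoxel = 0.025) {
  sc <- genSphereScene(3, radiusRange = c(0.5, 0.8), minGap = 1.2,
                       vialRadius = 4, vialHeight = 8, seed = seed,
                       wallMargin = 1.0) # keep room for the wrap spheres
  det <- scanAndDetect(sc, voxel = voxel)
  fs <- det$channels[[1]]$features
  rows <- list()
  for (i in seq_len(nrow(features(fs)))) {
    f <- features(fs)[i, ]
    net <- wrappedNetwork(c(f$x, f$y, f$z), f$radius,
                          zRange = c(0, sc@vialHeight),
                          buildRadius = sc@vialRadius)
    wall <- meshTube(net, voxel = meshVoxel)$mesh
    sph <- sphereMesh(c(f$x, f$y, f$z), f$radius, voxel = meshVoxel)
    rows[[i]] <- data.frame(feature = f$id, radius = f$radius,
                            clearance = minClearance(wall, sph))
  }
  list(scene = sc, features = fs, report = do.call(rbind, rows))
}

demoInterconnect <- function(seed = 2) {
  sc <- genSphereScene(6, radiusRange = c(0.3, 0.6), minGap = 0.8,
                       vialRadius = 4, vialHeight = 8, seed = seed)
  det <- scanAndDetect(sc)
  fs <- det$channels[[1]]$features
  net <- interconnectStruts(fs)
  lens <- vapply(tubeEdges(net), function(e)
    max(polylineArclength(e$points)), numeric(1))
  list(scene = sc, features = fs, network = net,
       report = data.frame(struts = length(tubeEdges(net)),
                           totalLength = sum(lens)))
}

demoEncapsulate <- function(seed = 3, meshVoxel = 0.025) {
  sc <- genSphereScene(1, radiusRange = c(0.6, 0.6), vialRadius = 4,
                       vialHeight = 8, seed = seed)
  det <- scanAndDetect(sc)
  f <- features(det$channels[[1]]$features)[1, ]
  shell <- encapsulationShell(c(f$x, f$y, f$z), f$radius)
  rIn <- f$radius + 0.3
  rOut <- rIn + 0.3
  lo <- c(f$x, f$y, f$z) - rOut - 0.15
  dims <- as.integer(ceiling((2 * rOut + 0.3) / meshVoxel))
  grid <- voxelGrid(rep(max(dims), 3), meshVoxel, lo)
  mesh <- extractMesh(evalSdfOnGrid(shell@sdf, grid), grid)
  m <- meshMeasures(mesh)
  analytic <- 4 / 3 * pi * (rOut^3 - rIn^3)
  list(scene = sc, mesh = mesh,
       report = data.frame(volume = m$volume, analytic = analytic,
                           relError = abs(m$volume - analytic) / analytic))
}

demoConditionalSize <- function(seed = 4) {
  sc <- scene(list(spherePrimitive(c(-1.5, 0, 3), 0.3, channel = "ch532"),
                   spherePrimitive(c(1.5, 0, 5), 0.7, channel = "ch532")),
              vialRadius = 4, vialHeight = 8, seed = seed)
  det <- scanAndDetect(sc)
  fs <- det$channels[[1]]$features
  geoms <- applyDesignRules(fs, sizeRules(zRange = c(0, 8), buildRadius = 4))
  list(features = fs,
       report = data.frame(id = features(fs)$id,
                           radius = features(fs)$radius,
                           rule = vapply(geoms, attr, character(1), "rule")))
}

demoConditionalSpectral <- function(seed = 5) {
  small <- genSphereScene(3, radiusRange = c(0.3, 0.5), channels = "ch532",
                          minGap = 0.8, vialRadius = 4, vialHeight = 8,
                          seed = seed)
  large <- genSphereScene(4, radiusRange = c(0.3, 0.5), channels = "ch650",
                          minGap = 0.8, vialRadius = 4, vialHeight = 8,
                          seed = seed + 1000)
  sc <- scene(c(small@primitives, large@primitives), 4, 8, seed)
  det <- scanAndDetect(sc)
  merged <- classifySpectral(lapply(det$channels, `[[`, "features"))
  geoms <- applyDesignRules(merged,
                            spectralRules(zRange = c(0, 8), buildRadius = 4))
  list(features = merged,
       report = data.frame(id = features(merged)$id,
                           channel = features(merged)$channel,
                           rule = vapply(geoms, attr, character(1), "rule")))
}

demoFemurCartilage <- function(seed = 6) {
  fx <- femurProxyScene()
  cap <- cartilageCap(fx$headCenter, fx$headRadius, voxel = 0.08)
  pRef <- sampleVolumePoints(fx$mesh, 4000, seed = seed)
  trueT <- withSeed(seed, {
    ang <- stats::runif(1, -25, 25) * pi / 180
    axis <- unitVec(stats::rnorm(3))
    K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
    rigidTransform(R, stats::runif(3, -1, 1))
  })
  pScan <- transformGeometry(sampleVolumePoints(fx$mesh, 4000,
                                                seed = seed + 1), trueT)
  fit <- icpRegister(pRef, pScan)
  alignedCap <- transformGeometry(cap, fit@transform)
  headScan <- transformGeometry(
    sphereMesh(fx$headCenter, fx$headRadius, voxel = 0.08), trueT)
  gap <- minClearance(alignedCap, headScan)
  list(fit = fit, cap = alignedCap,
       report = data.frame(rmse = fit@rmse, capHeadGap = gap))
}

demoPillarShadow <- function(seed = 7, fast = TRUE) {
  if (fast) {
    shadowBenchmark(nReps = 2, seeds = seed + 0:1, n = 128, nAngles = 180,
                    params = osmoParams(maxIters = 30))
  } else {
    shadowBenchmark(seeds = seq_len(12) + seed - 1)
  }
}

demoBallInCage <- function(seed = 8, fast = TRUE) {
  if (fast) cageBenchmark(nReps = 1, seeds = seed, n = 48, nAngles = 90,
                          params = osmoParams(maxIters = 20))
  else cageBenchmark(seeds = seed + 0:2)
}

demoTorusVessels <- function(seed = 9, meshVoxel = 0.05) {
  net <- torusVesselNetwork()
  mesh <- meshTube(net, voxel = meshVoxel)$mesh
  ctl <- randomChannelNetwork(seed = seed)
  mm <- meshMeasures(mesh)
  list(network = net, control = ctl,
       report = data.frame(
         arm = c("torus", "random-control"),
         analyticArea = c(net@provenance$analyticArea,
                          ctl@provenance$analyticArea),
         meshArea = c(mm$area, NA),
         converged = c(net@provenance$converged,
                       ctl@provenance$converged)))
}

# binary star polygon / circle stamps for the FLight pattern
stampShape <- function(img, u, v, rPix, shape) {
  nu <- nrow(img)
  nv <- ncol(img)
  iu <- pmax(1, round(u - rPix)):pmin(nu, round(u + rPix))
  iv <- pmax(1, round(v - rPix)):pmin(nv, round(v + rPix))
  for (a in iu) for (b in iv) {
    du <- a - u
    dv <- b - v
    rr <- sqrt(du^2 + dv^2)
    hit <- if (shape == "circle") {
      rr <= rPix
    } else { # 5-pointed star: radius modulated by angle
      ang <- atan2(dv, du)
      rr <= rPix * (0.45 + 0.55 * abs(cos(2.5 * ang)))
    }
    if (hit) img[a, b] <- TRUE
  }
  img
}

demoFlight <- function(seed = 10, voxel = 0.05) {
  sc1 <- genSphereScene(2, radiusRange = c(0.3, 0.4), channels = "ch450",
                        minGap = 1.5, vialRadius = 4, vialHeight = 8,
                        seed = seed)
  sc2 <- genSphereScene(2, radiusRange = c(0.3, 0.4), channels = "ch650",
                        minGap = 1.5, vialRadius = 4, vialHeight = 8,
                        seed = seed + 500)
  sc <- scene(c(sc1@primitives, sc2@primitives), 4, 8, seed)
  det <- scanAndDetect(sc)
  grid <- det$grid
  theta <- 0 # face-on exposure angle
  nu <- grid@dim[2]
  img <- matrix(FALSE, nu, grid@dim[3])
  shapes <- character(0)
  for (ch in names(det$channels)) {
    fs <- features(det$channels[[ch]]$features)
    shape <- if (ch == "ch450") "circle" else "star"
    for (i in seq_len(nrow(fs))) {
      uv <- pointBeamCoords(c(fs$x[i], fs$y[i], fs$z[i]), theta)
      u <- uv[1] / voxel + (nu + 1) / 2
      v <- (uv[2] - grid@origin[3]) / voxel
      img <- stampShape(img, u, v, fs$radius[i] / voxel * 1.4, shape)
      shapes <- c(shapes, shape)
    }
  }
  pat <- flightPattern(img, angle = theta, depthFraction = 0.7)
  vol <- flightExpose(pat, grid)
  list(pattern = pat, volume = vol,
       report = data.frame(shapes = paste(shapes, collapse = ","),
                           crosslinkedVoxels = sum(vol),
                           depthFraction = 0.7))
}

#' Run one end-to-end demo
#'
#' @param name demo name from \code{\link{demoCatalog}}.
#' @param seed integer seed.
#' @param fast reduced problem sizes (default) or full-size run.
#' @return demo result list (geometry objects plus a \code{report}).
#' @export
runDemo <- function(name, seed = 1, fast = TRUE) {
  switch(name,
         "wrap-spheres" = demoWrapSpheres(seed),
         "interconnect" = demoInterconnect(seed),
         "encapsulate" = demoEncapsulate(seed),
         "conditional-size" = demoConditionalSize(seed),
         "conditional-spectral" = demoConditionalSpectral(seed),
         "femur-cartilage" = demoFemurCartilage(seed),
         "pillar-shadow" = demoPillarShadow(seed, fast),
         "ball-in-cage" = demoBallInCage(seed, fast),
         "torus-vessels" = demoTorusVessels(seed),
         "flight" = demoFlight(seed),
         stop("unknown demo '", name, "'; see demoCatalog()"))
}

#' Run a configured pipeline and write its artifacts
#'
#' Executes a demo scenario under a named seed and writes every artifact
#' with provenance (config hash, package version, per-stage wall time) to
#' the run directory.  A rerun with the same config reproduces all outputs.
#'
#' @param config list with elements \code{demo}, \code{seed}, and optional
#'   \code{fast}; or the path of a YAML file with those fields.
#' @param outDir run directory (created).
#' @return the demo result, invisibly; artifacts and \code{log.json} are in
#'   \code{outDir}.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$demo))
  seed <- config$seed %||% 1L
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  res <- runDemo(config$demo, seed = seed, fast = config$fast %||% TRUE)
  elapsed <- proc.time()[["elapsed"]] - t0
  if (!is.null(res$report) && is.data.frame(res$report))
    utils::write.csv(res$report, file.path(outDir, "report.csv"),
                     row.names = FALSE)
  if (is(res, "MetricReport"))
    writeMetricReport(res, file.path(outDir, "metrics"))
  if (!is.null(res$scene))
    writeSceneYAML(res$scene, file.path(outDir, "scene.yaml"))
  if (!is.null(res$features) && is(res$features, "FeatureSet"))
    writeFeaturesJSON(res$features, file.path(outDir, "features.json"))
  log <- list(package = "tomoprint",
              version = as.character(utils::packageVersion("tomoprint")),
              demo = config$demo, seed = seed,
              configHash = digestConfig(config),
              wallTimeSec = elapsed, timestamp = format(Sys.time()))
  jsonlite::write_json(log, file.path(outDir, "log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

digestConfig <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE)
  # small rolling hash; avoids a digest dependency for a provenance tag
  h <- 0
  for (ch in utf8ToInt(as.character(s))) h <- (h * 31 + ch) %% 2^31
  sprintf("%08x", h)
}
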
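# Print-quality metrics and the in-silico shadow-correction benchmarks.

#' Jaccard similarity index of two binary volumes
#'
#' \code{|a & b| / |a | b|}; defined as 1 when both are empty.
#'
#' @param a,b logical arrays of identical shape.
#' @return ratio in [0, 1].
#' @export
jaccard <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("binary volumes are on different grids")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Bhattacharyya coefficient between in- and out-of-target dose histograms
#'
#' Histograms of the dose inside vs outside the target (over a stated
#' evaluation region, typically the build circle minus occluder voxels) on
#' \code{nBins} shared bins spanning [0, max dose].  0 means perfectly
#' separated dose populations (good print contrast), 1 identical ones.
#'
#' @param dose normalized dose (array or \linkS4class{DoseVolume}).
#' @param target binary target array.
#' @param region optional logical array restricting the evaluation.
#' @param nBins number of histogram bins.
#' @return coefficient in [0, 1].
#' @export
bhattacharyyaContrast <- function(dose, target, region = NULL, nBins = 64) {
  d <- if (is(dose, "DoseVolume")) dose@dose else dose
  tgt <- asVolumeArray(target) > 0
  keep <- if (is.null(region)) rep(TRUE, length(d)) else as.logical(region)
  din <- d[tgt & keep]
  dout <- d[!tgt & keep]
  if (!length(din) || !length(dout))
    stop("empty in-target or out-of-target population")
  breaks <- seq(0, max(d, 1e-12), length.out = nBins + 1)
  breaks[nBins + 1] <- breaks[nBins + 1] + 1e-9
  hin <- tabulate(findInterval(din, breaks, rightmost.closed = TRUE),
                  nbins = nBins)
  hout <- tabulate(findInterval(dout, breaks, rightmost.closed = TRUE),
                   nbins = nBins)
  sum(sqrt((hin / sum(hin)) * (hout / sum(hout))))
}

#' Root-mean-square surface error of a printed mesh
#'
#' RMS of unsigned distances from dense samples of the printed surface to
#' the reference surface (a mesh, or an analytic sphere given as
#' \code{list(center =, radius =)}).
#'
#' @param mesh printed \linkS4class{TriMesh}.
#' @param reference reference \linkS4class{TriMesh} or sphere list.
#' @param nSamples number of surface samples (>= 1e4 recommended).
#' @param seed sampling seed.
#' @return rms error, mm.
#' @export
rmsSurfaceError <- function(mesh, reference, nSamples = 10000, seed = 0L) {
  if (!nrow(mesh@faces)) stop("empty mesh")
  pts <- meshSampleSurface(mesh, nSamples, seed)
  d <- if (is(reference, "TriMesh")) {
    cpp_point_mesh_dist(pts, reference@vertices, reference@faces)
  } else {
    abs(sqrt(colSums((t(pts) - as.numeric(reference$center))^2)) -
          reference$radius)
  }
  sqrt(mean(d^2))
}

#' Sphericity of a watertight mesh
#'
#' \code{psi = pi^(1/3) (6V)^(2/3) / A}: 1 for a perfect sphere, lower for
#' rougher or aspherical bodies.
#'
#' @param mesh a watertight \linkS4class{TriMesh}.
#' @return ratio in (0, 1] (up to a small discretization allowance).
#' @export
sphericity <- function(mesh) {
  m <- meshMeasures(mesh)
  if (!m$watertight) stop("sphericity requires a watertight mesh")
  pi^(1 / 3) * (6 * m$volume)^(2 / 3) / m$area
}

#' Eight-toothed cog target slice
#'
#' z-extruded cog: trapezoidal teeth rising from the outer radius to the
#' tip radius, with a central bore.
#'
#' @param n slice resolution (n x n).
#' @param voxel voxel size, mm.
#' @param outerR tooth-root outer radius, mm.
#' @param tipR tooth tip radius, mm.
#' @param nTeeth number of teeth.
#' @param boreR bore radius, mm.
#' @param toothBase,toothTip tooth widths at root and tip, as fractions of
#'   the angular tooth period.
#' @return logical n x n matrix (slice through the cog).
#' @export
cogSlice <- function(n = 256, voxel = 11 / n, outerR = 3.15, tipR = 3.5,
                     nTeeth = 8, boreR = 0.875, toothBase = 0.30,
                     toothTip = 0.08) {
  cc <- (n - 1) / 2
  ix <- (seq_len(n) - 1 - cc) * voxel
  X <- outer(ix, rep(1, n))
  Y <- outer(rep(1, n), ix)
  r <- sqrt(X^2 + Y^2)
  phi <- atan2(Y, X)
  m <- (phi * nTeeth / (2 * pi)) %% 1
  dd <- abs(m - 0.5)
  wt <- toothTip / 2
  wb <- toothBase / 2
  Rout <- ifelse(dd <= wt, tipR,
                 ifelse(dd <= wb,
                        tipR - (tipR - outerR) * (dd - wt) / (wb - wt),
                        outerR))
  r <= Rout & r >= boreR
}

# 2D pillar occlusion slice inside the placement circle (the overprinted
# part's footprint).  "uniform" scatters pillars like genPillarPhantom;
# "stratified" (benchmark default) jitters them over equal-area rings with
# golden-angle azimuths and a seeded global rotation — closer in spirit to
# the deliberately distributed physical phantom, and with a much steadier
# total shadow burden across seeds.
pillarSlice <- function(n, voxel, nPillars = 10, pillarD = 1.0,
                        placementR = 5, seed = 0L,
                        layout = c("stratified", "uniform")) {
  layout <- match.arg(layout)
  r <- pillarD / 2
  centers <- if (layout == "uniform") {
    sc <- genPillarPhantom(nPillars, pillarD, tiltMax = 0, seed = seed,
                           vialRadius = placementR, vialHeight = 1)
    t(vapply(sc@primitives, function(p) p@center[1:2], numeric(2)))
  } else {
    withSeed(seed, {
      rot <- stats::runif(1, 0, 2 * pi)
      golden <- pi * (3 - sqrt(5))
      i <- seq_len(nPillars)
      rad <- (placementR - r) *
        sqrt((i - 0.5 + stats::runif(nPillars, -0.25, 0.25)) / nPillars)
      ang <- rot + i * golden + stats::runif(nPillars, -0.2, 0.2)
      cbind(rad * cos(ang), rad * sin(ang))
    })
  }
  cc <- (n - 1) / 2
  ix <- (seq_len(n) - 1 - cc) * voxel
  X <- outer(ix, rep(1, n))
  Y <- outer(rep(1, n), ix)
  occ <- matrix(FALSE, n, n)
  for (i in seq_len(nrow(centers)))
    occ <- occ | ((X - centers[i, 1])^2 + (Y - centers[i, 2])^2 <= r^2)
  occ
}

# one corrected/uncorrected OSMO pair on a 2D slice; returns both arms'
# metrics, evaluating dose occlusion-aware in both cases
shadowPair <- function(target, occ, params, angles, voxel,
                       region, clearance = 0.1) {
  runArm <- function(occOpt) {
    res <- osmoOptimize(target, params = params, occlusion = occOpt,
                        angles = angles, voxelSize = voxel,
                        occlusionClearance = clearance)
    # evaluation dose is always occlusion-aware
    occ3 <- array(occ, c(dim(occ), 1L))
    dv <- computeDose(res$projections, dim2 = dim(occ), occlusion = occ3,
                      normalize = "max")
    d <- dv@dose[, , 1]
    tgt <- res$target[, , 1]
    excl <- dilateMask(occ, clearance / voxel) | !region
    b <- binarizeDose(d, "best_jaccard", target = tgt, exclude = excl)
    list(jaccard = attr(b, "jaccard"),
         bc = bhattacharyyaContrast(d, tgt, region = region &
                                      !dilateMask(occ, clearance / voxel)),
         threshold = attr(b, "threshold"))
  }
  tgtTrim <- array(target, c(dim(target), 1L))
  list(corrected = runArm(array(occ, c(dim(occ), 1L))),
       uncorrected = runArm(NULL))
}

#' Shadow-correction benchmark: cog target with pillar occlusions
#'
#' For each seed: generate a random pillar phantom, trim the cog target
#' around the (dilated) occluders, run OSMO once with the occlusion mask
#' (corrected) and once without (uncorrected), always evaluate the dose
#' occlusion-aware, and measure the best-threshold Jaccard index and the
#' Bhattacharyya coefficient inside the build circle (occluders excluded).
#'
#' @param nReps number of seeded pillar configurations (>= 2).
#' @param seeds explicit seeds (default \code{1:nReps}).
#' @param nPillars number of pillars.
#' @param pillarD pillar diameter, mm.
#' @param n slice resolution.
#' @param nAngles projection angles over 2 pi.
#' @param params \linkS4class{OsmoParams}.
#' @param buildR build circle (vial) radius, mm: the dose evaluation region.
#' @param placementR radius of the circle the pillars are scattered in
#'   (the overprinted part's footprint), mm.
#' @param voxel voxel size, mm.
#' @param cogArgs extra arguments to \code{\link{cogSlice}}.
#' @return A \linkS4class{MetricReport} with corrected and uncorrected arms.
#' @export
shadowBenchmark <- function(nReps = 12, seeds = seq_len(nReps),
                            nPillars = 10, pillarD = 1.0, n = 256,
                            nAngles = 360, params = osmoParams(),
                            buildR = 9.0, placementR = 3.2,
                            voxel = 2 * (buildR + 0.3) / n,
                            cogArgs = list()) {
  stopifnot(length(seeds) >= 2)
  target <- do.call(cogSlice, c(list(n = n, voxel = voxel), cogArgs))
  angles <- seq(0, 2 * pi, length.out = nAngles + 1)[-(nAngles + 1)]
  cc <- (n - 1) / 2
  ix <- (seq_len(n) - 1 - cc) * voxel
  region <- outer(ix^2, ix^2, "+") <= buildR^2
  rows <- list()
  for (s in seeds) {
    occ <- pillarSlice(n, voxel, nPillars, pillarD, placementR = placementR,
                       seed = s)
    pair <- tryCatch(
      shadowPair(target, occ, params, angles, voxel, region),
      error = function(e) stop("benchmark run failed for seed ", s, ": ",
                               conditionMessage(e)))
    for (arm in c("corrected", "uncorrected")) {
      rows[[length(rows) + 1]] <-
        data.frame(seed = s, arm = arm, jaccard = pair[[arm]]$jaccard,
                   bhattacharyya = pair[[arm]]$bc,
                   threshold = pair[[arm]]$threshold)
    }
  }
  runs <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(runs, runs$arm), function(g)
    data.frame(arm = g$arm[1], n = nrow(g),
               jaccard_mean = mean(g$jaccard), jaccard_sd = sd(g$jaccard),
               bhattacharyya_mean = mean(g$bhattacharyya),
               bhattacharyya_sd = sd(g$bhattacharyya))))
  rownames(agg) <- NULL
  new("MetricReport", runs = runs, aggregate = agg,
      provenance = list(seeds = seeds, nPillars = nPillars,
                        pillarD = pillarD, n = n, nAngles = nAngles,
                        params = params))
}

#' Monte Carlo study of occlusion burden
#'
#' For each trial: draw a random pillar configuration, run the
#' shadow-corrected OSMO arm, and record (Jaccard, Bhattacharyya).  The
#' returned table is sorted by decreasing Jaccard with ties broken by
#' increasing Bhattacharyya; the best configuration is emitted as a Scene.
#'
#' @param pillarCounts vector of pillar counts to study.
#' @param nTrials trials per count.
#' @param seedBase seeds are \code{seedBase + trial index}.
#' @param n,nAngles,params,buildR,voxel,pillarD as in
#'   \code{\link{shadowBenchmark}}.
#' @param cogArgs extra arguments to \code{\link{cogSlice}}.
#' @return data.frame sorted as described, with the winning
#'   \linkS4class{Scene} attached as attribute \code{"bestScene"}.
#' @export
occlusionMonteCarlo <- function(pillarCounts = 0:10, nTrials = 5,
                                seedBase = 0L, n = 128, nAngles = 180,
                                params = osmoParams(maxIters = 30),
                                buildR = 5.2, pillarD = 1.0,
                                voxel = 2 * (buildR + 0.3) / n,
                                cogArgs = list()) {
  stopifnot(nTrials >= 1)
  target <- do.call(cogSlice, c(list(n = n, voxel = voxel), cogArgs))
  angles <- seq(0, 2 * pi, length.out = nAngles + 1)[-(nAngles + 1)]
  cc <- (n - 1) / 2
  ix <- (seq_len(n) - 1 - cc) * voxel
  region <- outer(ix^2, ix^2, "+") <= buildR^2
  rows <- list()
  trial <- 0L
  for (np in pillarCounts) for (tr in seq_len(nTrials)) {
    trial <- trial + 1L
    seed <- seedBase + trial
    occ <- if (np > 0) {
      pillarSlice(n, voxel, np, pillarD, placementR = buildR, seed = seed)
    } else matrix(FALSE, n, n)
    occ3 <- array(occ, c(dim(occ), 1L))
    res <- osmoOptimize(target, params = params,
                        occlusion = if (np > 0) occ3 else NULL,
                        angles = angles, voxelSize = voxel)
    dv <- computeDose(res$projections, dim2 = dim(occ),
                      occlusion = if (np > 0) occ3 else NULL,
                      normalize = "max")
    d <- dv@dose[, , 1]
    tgt <- res$target[, , 1]
    excl <- dilateMask(occ, 0.1 / voxel) | !region
    b <- binarizeDose(d, "best_jaccard", target = tgt, exclude = excl)
    rows[[trial]] <- data.frame(trial = trial, nPillars = np, seed = seed,
                                jaccard = attr(b, "jaccard"),
                                bhattacharyya = bhattacharyyaContrast(
                                  d, tgt, region = region &
                                    !dilateMask(occ, 0.1 / voxel)))
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$jaccard, tab$bhattacharyya), ]
  rownames(tab) <- NULL
  bestSeed <- tab$seed[1]
  bestN <- tab$nPillars[1]
  attr(tab, "bestScene") <- if (bestN > 0) {
    genPillarPhantom(bestN, pillarD, tiltMax = 0, seed = bestSeed,
                     vialRadius = buildR, vialHeight = 1)
  } else scene(list(), buildR, 1, bestSeed)
  tab
}

#' Ball-in-cage shadow-correction benchmark (3D)
#'
#' A spherical target inside a strut cage occluder, printed in both OSMO
#' arms; the binarized simulated prints are meshed and compared by
#' sphericity and r.m.s. surface error against the analytic target sphere.
#' Shadow correction should win on both metrics on every seed.
#'
#' @param nReps number of seeded cage configurations.
#' @param seeds explicit seeds.
#' @param n grid resolution per axis.
#' @param nAngles projection angles.
#' @param params \linkS4class{OsmoParams}.
#' @param cageDiameter,strutDiameter,nNodes,kNeighbours cage parameters, mm.
#' @param ballDiameter target sphere diameter, mm.
#' @return A \linkS4class{MetricReport}.
#' @export
cageBenchmark <- function(nReps = 3, seeds = seq_len(nReps), n = 64,
                          nAngles = 120,
                          params = osmoParams(maxIters = 30),
                          cageDiameter = 10, strutDiameter = 0.5,
                          nNodes = 45, kNeighbours = 5, ballDiameter = 5) {
  ext <- cageDiameter + 3
  voxel <- ext / n
  grid <- voxelGrid(c(n, n, n), voxel,
                    origin = c(-ext / 2, -ext / 2, 0))
  ctr <- c(0, 0, ext / 2)
  gx <- gridCoords(grid, 1)
  gz <- gridCoords(grid, 3)
  d2xy <- outer((gx - ctr[1])^2, (gx - ctr[2])^2, "+")
  tgt <- outer(d2xy, (gz - ctr[3])^2, "+") <= (ballDiameter / 2)^2
  angles <- seq(0, 2 * pi, length.out = nAngles + 1)[-(nAngles + 1)]
  rows <- list()
  for (s in seeds) {
    sc <- genCageScene(nNodes, cageDiameter, kNeighbours, strutDiameter,
                       seed = s, center = ctr, vialRadius = ext / 2,
                       vialHeight = ext)
    occ <- rasterizeScene(sc, grid)$mask@inside
    for (arm in c("corrected", "uncorrected")) {
      res <- osmoOptimize(tgt, params = params,
                          occlusion = if (arm == "corrected") occ else NULL,
                          angles = angles, voxelSize = voxel)
      dv <- computeDose(res$projections, dim2 = dim(tgt)[1:2],
                        occlusion = occ, normalize = "max")
      b <- binarizeDose(dv@dose, "best_jaccard", target = res$target,
                        exclude = occ)
      # the print surface is the gelation-dose level set of the dose field
      # (sub-voxel), lightly smoothed (1-voxel Gaussian, both arms alike)
      # as gelation does not resolve single-voxel streak texture; stray
      # satellites are excluded by keeping the main printed body
      smooth <- blur3(dv@dose)
      printMesh <- largestComponent(
        extractMesh(attr(b, "threshold") * max(smooth) - smooth, grid))
      rows[[length(rows) + 1]] <- data.frame(
        seed = s, arm = arm,
        jaccard = attr(b, "jaccard"),
        rms = rmsSurfaceError(printMesh,
                              list(center = ctr, radius = ballDiameter / 2),
                              seed = s),
        sphericity = sphericity(printMesh))
    }
  }
  runs <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(runs, runs$arm), function(g)
    data.frame(arm = g$arm[1], n = nrow(g), rms_mean = mean(g$rms),
               rms_sd = sd(g$rms), sphericity_mean = mean(g$sphericity),
               sphericity_sd = sd(g$sphericity))))
  rownames(agg) <- NULL
  new("MetricReport", runs = runs, aggregate = agg,
      provenance = list(seeds = seeds, n = n, nAngles = nAngles,
                        cageDiameter = cageDiameter,
                        strutDiameter = strutDiameter,
                        ballDiameter = ballDiameter))
}

# sphericity of the largest connected component of a (possibly fragmented)
# simulated print; stray satellite voxels would otherwise break the
# watertight-volume accounting
sphericityLargest <- function(mesh) {
  m <- meshMeasures(mesh)
  if (m$watertight) return(sphericity(mesh))
  comp <- largestComponent(mesh)
  sphericity(comp)
}

# separable 1-2-1 binomial blur (~1-voxel Gaussian) along each axis
blur3 <- function(a) {
  for (ax in 1:3) {
    perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 2, 1))
    b <- aperm(a, perm)
    n <- dim(b)[1]
    up <- b[c(1, seq_len(n - 1)), , , drop = FALSE]
    dn <- b[c(seq_len(n - 1) + 1, n), , , drop = FALSE]
    b <- (up + 2 * b + dn) / 4
    a <- aperm(b, order(perm))
  }
  a
}

largestComponent <- function(mesh) {
  Fc <- mesh@faces
  g <- igraph::graph_from_edgelist(
    rbind(Fc[, 1:2], Fc[, 2:3], Fc[, c(3, 1)]), directed = FALSE)
  cl <- igraph::components(g)
  keepV <- which(cl$membership == which.max(cl$csize))
  keepF <- Fc[Fc[, 1] %in% keepV & Fc[, 2] %in% keepV & Fc[, 3] %in% keepV,
              , drop = FALSE]
  idx <- integer(nrow(mesh@vertices))
  idx[keepV] <- seq_along(keepV)
  triMesh(mesh@vertices[keepV, , drop = FALSE],
          matrix(idx[keepF], ncol = 3))
}
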
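# Synthetic scenes and the simulated polar light-sheet instrument.

#' Generate a scene of non-overlapping fluorescent spheres
#'
#' Rejection-sampled sphere packing inside the vial cylinder.  Radii are
#' uniform in \code{radiusRange} (defaults span the organoid-compatible
#' 0.15-0.90 mm range), channel labels are cycled over \code{channels},
#' and every pair of spheres keeps a surface-to-surface gap of at least
#' \code{minGap}.
#'
#' @param n number of spheres.
#' @param radiusRange (min, max) radius, mm.
#' @param channels channel labels cycled over the spheres.
#' @param minGap minimum pairwise surface gap, mm.
#' @param vialRadius,vialHeight vial dimensions, mm.
#' @param seed integer seed; identical seeds give identical scenes.
#' @param maxAttempts rejection-sampling budget per sphere.
#' @param wallMargin clearance kept from the vial wall and caps, mm.
#' @return A \linkS4class{Scene}.
#' @examples
#' genSphereScene(5, seed = 1)
#' @export
genSphereScene <- function(n, radiusRange = c(0.15, 0.90),
                           channels = "ch532", minGap = 0.2,
                           vialRadius = 5, vialHeight = 10, seed = 0L,
                           maxAttempts = 5000L, wallMargin = 0.1) {
  stopifnot(n >= 1, radiusRange[1] > 0, radiusRange[2] >= radiusRange[1])
  withSeed(seed, {
    centers <- matrix(0, 0, 3)
    radii <- numeric(0)
    for (i in seq_len(n)) {
      r <- stats::runif(1, radiusRange[1], radiusRange[2])
      placed <- FALSE
      for (att in seq_len(maxAttempts)) {
        xy <- runifDisc(max(vialRadius - r - wallMargin, 0))
        z <- stats::runif(1, r + wallMargin, vialHeight - r - wallMargin)
        p <- c(xy, z)
        ok <- TRUE
        if (length(radii)) {
          d <- sqrt(colSums((t(centers) - p)^2))
          ok <- all(d >= radii + r + minGap)
        }
        if (ok) {
          centers <- rbind(centers, p)
          radii <- c(radii, r)
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("infeasible packing: could not place sphere ", i, " of ", n,
             " after ", maxAttempts, " attempts")
    }
    labs <- rep_len(channels, n)
    prims <- lapply(seq_len(n), function(i)
      spherePrimitive(centers[i, ], radii[i], channel = labs[i]))
    scene(prims, vialRadius, vialHeight, seed)
  })
}

#' Generate an opaque pillar occlusion phantom
#'
#' Capsule pillars spanning the vial height, centres uniform in the build
#' circle with non-overlap, axes tilted at most \code{tiltMax} degrees from
#' vertical.
#'
#' @param nPillars number of pillars.
#' @param diameter pillar diameter, mm (1 mm and 0.5 mm are both used by the
#'   physical phantoms this emulates; neither is privileged).
#' @param tiltMax maximum tilt from vertical, degrees.
#' @param seed integer seed.
#' @param vialRadius,vialHeight vial dimensions, mm.
#' @param maxAttempts placement budget per pillar.
#' @return A \linkS4class{Scene} of opaque capsules.
#' @export
genPillarPhantom <- function(nPillars = 10, diameter = 1.0, tiltMax = 0,
                             seed = 0L, vialRadius = 5, vialHeight = 10,
                             maxAttempts = 5000L) {
  stopifnot(nPillars >= 1, diameter > 0)
  r <- diameter / 2
  withSeed(seed, {
    centers <- matrix(0, 0, 2)
    prims <- vector("list", nPillars)
    for (i in seq_len(nPillars)) {
      placed <- FALSE
      for (att in seq_len(maxAttempts)) {
        xy <- runifDisc(vialRadius - r)
        ok <- !nrow(centers) ||
          all(sqrt(colSums((t(centers) - xy)^2)) >= diameter)
        if (ok) {
          placed <- TRUE
          centers <- rbind(centers, xy)
          break
        }
      }
      if (!placed)
        stop("infeasible packing: could not place pillar ", i)
      tilt <- if (tiltMax > 0) stats::runif(1, 0, tiltMax) * pi / 180 else 0
      azim <- stats::runif(1, 0, 2 * pi) # drawn even for tilt 0 (determinism)
      ax <- c(sin(tilt) * cos(azim), sin(tilt) * sin(azim), cos(tilt))
      prims[[i]] <- capsulePrimitive(c(xy, vialHeight / 2), ax, r,
                                     vialHeight / 2, opaque = TRUE)
    }
    scene(prims, vialRadius, vialHeight, seed)
  })
}

#' Generate a spherical cage occluder
#'
#' Nodes uniform on a sphere surface; each node is connected to its
#' \code{kNeighbours} nearest neighbours by opaque struts (duplicate edges
#' merged), reproducing a ball-in-cage style occlusion.
#'
#' @param nNodes number of surface nodes.
#' @param sphereDiameter cage diameter, mm.
#' @param kNeighbours struts per node.
#' @param strutDiameter strut diameter, mm.
#' @param seed integer seed.
#' @param center cage centre, mm.
#' @param vialRadius,vialHeight vial dimensions, mm.
#' @return A \linkS4class{Scene}; node coordinates and the merged edge list
#'   are attached as attributes \code{"nodes"} and \code{"edges"}.
#' @export
genCageScene <- function(nNodes = 45, sphereDiameter = 10, kNeighbours = 5,
                         strutDiameter = 0.5, seed = 0L,
                         center = c(0, 0, sphereDiameter / 2 + 1),
                         vialRadius = sphereDiameter / 2 + 1.5,
                         vialHeight = sphereDiameter + 3) {
  stopifnot(nNodes > kNeighbours, strutDiameter > 0)
  R <- sphereDiameter / 2
  withSeed(seed, {
    u <- stats::runif(nNodes, -1, 1)
    phi <- stats::runif(nNodes, 0, 2 * pi)
    s <- sqrt(1 - u^2)
    nodes <- cbind(R * s * cos(phi), R * s * sin(phi), R * u)
    nodes <- sweep(nodes, 2, center, "+")
    D <- as.matrix(stats::dist(nodes))
    edges <- matrix(0L, 0, 2)
    for (i in seq_len(nNodes)) {
      nb <- order(D[i, ])[2:(kNeighbours + 1)]
      edges <- rbind(edges, cbind(pmin(i, nb), pmax(i, nb)))
    }
    edges <- unique(edges)
    prims <- lapply(seq_len(nrow(edges)), function(e) {
      a <- nodes[edges[e, 1], ]
      b <- nodes[edges[e, 2], ]
      capsulePrimitive((a + b) / 2, b - a, strutDiameter / 2,
                       vnorm(b - a) / 2, opaque = TRUE)
    })
    sc <- scene(prims, vialRadius, vialHeight, seed)
    attr(sc, "nodes") <- nodes
    attr(sc, "edges") <- edges
    sc
  })
}

#' Generate a fluorescent torus scene
#'
#' Stand-in for an extruded cell-laden torus suspended in the vat.
#'
#' @param torusDiameter ring centreline diameter, mm.
#' @param tubeDiameter tube diameter, mm.
#' @param center torus centre, mm.
#' @param channel channel label.
#' @param seed integer seed (recorded; the construction is deterministic).
#' @param vialRadius,vialHeight vial dimensions, mm.
#' @return A \linkS4class{Scene} with a single torus primitive.
#' @export
genTorusScene <- function(torusDiameter = 4, tubeDiameter = 1,
                          center = c(0, 0, 5), channel = "ch650", seed = 0L,
                          vialRadius = 5, vialHeight = 10) {
  if (tubeDiameter <= 0) stop("tubeDiameter must be > 0")
  if (torusDiameter / 2 + tubeDiameter / 2 > vialRadius)
    stop("torus does not fit inside the vial")
  prim <- torusPrimitive(center, torusDiameter / 2, tubeDiameter / 2,
                         channel = channel)
  scene(list(prim), vialRadius, vialHeight, seed)
}

#' Femur-like proxy scene and mesh
#'
#' A self-contained, watertight femur stand-in: a capsule shaft topped by
#' an offset spherical head, with a distal condyle bump that breaks the
#' shaft's rotational symmetry (a real femur is asymmetric, and rigid
#' registration needs that asymmetry).  Used by the sequential-print
#' alignment demo; the head centre/radius are returned so a conforming
#' cartilage cap can be generated.
#'
#' @param shaftRadius,shaftLength capsule shaft dimensions, mm.
#' @param headRadius femoral-head sphere radius, mm.
#' @param headOffset lateral offset of the head centre, mm.
#' @param condyleRadius distal condyle sphere radius, mm.
#' @param channel channel label of the fluorescent volume.
#' @param voxel meshing voxel size, mm.
#' @param seed integer seed (recorded).
#' @return list with elements \code{scene}, \code{mesh}
#'   (\linkS4class{TriMesh}), \code{headCenter}, \code{headRadius}.
#' @export
femurProxyScene <- function(shaftRadius = 1.0, shaftLength = 5,
                            headRadius = 2.5, headOffset = 1.2,
                            condyleRadius = 1.3, channel = "ch650",
                            voxel = 0.08, seed = 0L) {
  base <- c(0, 0, headRadius + 0.5)
  shaftCenter <- base + c(0, 0, shaftLength / 2)
  headCenter <- base + c(headOffset, 0, shaftLength + headRadius * 0.45)
  condyleCenter <- base + c(-0.6 * condyleRadius, 0, 0.2 * condyleRadius)
  vialRadius <- headRadius + headOffset + 1.5
  vialHeight <- headCenter[3] + headRadius + 1.5
  prims <- list(
    capsulePrimitive(shaftCenter, c(0, 0, 1), shaftRadius, shaftLength / 2,
                     channel = channel),
    spherePrimitive(headCenter, headRadius, channel = channel),
    spherePrimitive(condyleCenter, condyleRadius, channel = channel))
  sc <- scene(prims, vialRadius, vialHeight, seed)
  # union SDF -> watertight mesh
  pad <- 4 * voxel
  lo <- pmin(shaftCenter - shaftLength / 2 - shaftRadius,
             headCenter - headRadius, condyleCenter - condyleRadius) - pad
  hi <- pmax(shaftCenter + shaftLength / 2 + shaftRadius,
             headCenter + headRadius, condyleCenter + condyleRadius) + pad
  dims <- as.integer(ceiling((hi - lo) / voxel))
  grid <- voxelGrid(dims, voxel, lo)
  a <- shaftCenter - c(0, 0, shaftLength / 2)
  b <- shaftCenter + c(0, 0, shaftLength / 2)
  segs <- rbind(c(a, b, shaftRadius, shaftRadius),
                c(headCenter, headCenter, headRadius, headRadius),
                c(condyleCenter, condyleCenter, condyleRadius,
                  condyleRadius))
  field <- cpp_tube_sdf(grid@dim, grid@origin, voxel, segs,
                        band = 4 * voxel, far_value = 1e6)
  dim(field) <- grid@dim
  mesh <- extractMesh(field, grid)
  list(scene = sc, mesh = mesh, headCenter = headCenter,
       headRadius = headRadius)
}

# signed distance of grid voxel centres to one primitive (3D array)
primitiveSdf <- function(prim, grid) {
  gx <- gridCoords(grid, 1)
  gy <- gridCoords(grid, 2)
  gz <- gridCoords(grid, 3)
  if (prim@kind == "sphere") {
    d2xy <- outer((gx - prim@center[1])^2, (gy - prim@center[2])^2, "+")
    sqrt(outer(d2xy, (gz - prim@center[3])^2, "+")) - prim@radius
  } else if (prim@kind == "torus") {
    # torus axis is z
    d2xy <- outer((gx - prim@center[1])^2, (gy - prim@center[2])^2, "+")
    a2 <- (sqrt(d2xy) - prim@radius)^2
    sqrt(outer(a2, (gz - prim@center[3])^2, "+")) - prim@tubeRadius
  } else if (prim@kind == "capsule") {
    a <- prim@center - prim@halfLength * prim@axis
    b <- prim@center + prim@halfLength * prim@axis
    field <- cpp_tube_sdf(grid@dim, grid@origin, grid@voxelSize,
                          matrix(c(a, b, prim@tubeRadius, prim@tubeRadius),
                                 1, 8),
                          band = 4 * grid@voxelSize, far_value = 1e6)
    array(field, grid@dim)
  } else {
    stop("cannot rasterize primitive kind '", prim@kind, "'")
  }
}

#' Rasterize a scene onto a voxel grid
#'
#' Produces one intensity volume per fluorescence channel (1 inside the
#' channel's primitives, 0 outside, optionally a linear soft edge over
#' \code{softEdge} mm) and the boolean occlusion mask of all opaque
#' primitives.
#'
#' @param scene a \linkS4class{Scene}.
#' @param grid a \linkS4class{VoxelGrid}; must cover the vial cylinder.
#' @param softEdge soft-edge width, mm (0 = hard binary).
#' @return list with \code{volumes} (named list of
#'   \linkS4class{ChannelVolume}) and \code{mask}
#'   (\linkS4class{OcclusionMask}).
#' @export
rasterizeScene <- function(scene, grid, softEdge = 0) {
  ext <- grid@origin + grid@dim * grid@voxelSize
  if (grid@origin[1] > -scene@vialRadius || ext[1] < scene@vialRadius ||
      grid@origin[2] > -scene@vialRadius || ext[2] < scene@vialRadius ||
      grid@origin[3] > 0 || ext[3] < scene@vialHeight)
    stop("grid does not cover the vial cylinder")
  chans <- unique(vapply(scene@primitives, function(p) p@channel,
                         character(1)))
  chans <- setdiff(chans, "none")
  volumes <- list()
  for (ch in chans) {
    vals <- array(0, grid@dim)
    for (p in scene@primitives) {
      if (p@channel != ch) next
      d <- primitiveSdf(p, grid)
      v <- if (softEdge > 0) {
        pmin(1, pmax(0, 0.5 - d / softEdge))
      } else {
        (d <= 0) * 1
      }
      vals <- pmax(vals, v)
    }
    volumes[[ch]] <- new("ChannelVolume", grid = grid, channel = ch,
                         values = vals)
  }
  inside <- array(FALSE, grid@dim)
  for (p in scene@primitives) {
    if (!p@opaque) next
    inside <- inside | (primitiveSdf(p, grid) <= 0)
  }
  mask <- new("OcclusionMask", grid = grid, inside = inside)
  list(volumes = volumes, mask = mask)
}

#' Simulate a polar light-sheet fluorescence scan
#'
#' For section k at angle \code{theta_k = (k-1) * thetaTotal / nSections},
#' image pixel (u, v) holds the trilinear sample of the channel volume at
#' \code{(r cos theta, r sin theta, z)} with signed radius
#' \code{r = (u - u0) * pixelSize}, plus optional additive Gaussian noise
#' (clamped at 0).  A half sweep (\code{thetaTotal = pi}) covers the volume
#' exactly once via the signed radius.
#'
#' @param volume a \linkS4class{ChannelVolume}.
#' @param nSections number of sections (>= 2).
#' @param thetaTotal total angular sweep, \code{pi} or \code{2*pi}.
#' @param pixelSize image pixel pitch, mm.
#' @param noiseSd Gaussian noise s.d. (image units).
#' @param seed integer seed for the noise.
#' @return A \linkS4class{PolarScan}.
#' @export
simulatePolarScan <- function(volume, nSections = 500, thetaTotal = pi,
                              pixelSize = volume@grid@voxelSize, noiseSd = 0,
                              seed = 0L) {
  stopifnot(pixelSize > 0, nSections >= 2)
  grid <- volume@grid
  ext <- grid@origin + grid@dim * grid@voxelSize
  rmax <- max(abs(c(grid@origin[1:2], ext[1:2])))
  nh <- ceiling(rmax / pixelSize)
  nu <- 2L * nh + 1L
  u0 <- nh + 1
  nv <- as.integer(floor((ext[3] - grid@origin[3]) / pixelSize))
  angles <- (seq_len(nSections) - 1) * thetaTotal / nSections
  rr <- (seq_len(nu) - u0) * pixelSize
  zz <- grid@origin[3] + (seq_len(nv) - 0.5) * pixelSize
  images <- array(0, c(nu, nv, nSections))
  pts <- cbind(rep(rr, times = nv), 0, rep(zz, each = nu))
  for (k in seq_len(nSections)) {
    th <- angles[k]
    xy <- cbind(pts[, 1] * cos(th), pts[, 1] * sin(th), pts[, 3])
    idx <- mmToIndex(grid, xy)
    images[, , k] <- cpp_trilinear(as.numeric(volume@values), grid@dim, idx)
  }
  if (noiseSd > 0) {
    withSeed(seed, {
      images <- images + stats::rnorm(length(images), 0, noiseSd)
    })
    images[images < 0] <- 0
  }
  new("PolarScan", images = images, angles = angles, thetaTotal = thetaTotal,
      pixelSize = pixelSize, axisColumn = as.numeric(u0),
      channel = volume@channel, mode = "fluorescence",
      zOrigin = grid@origin[3])
}

#' Simulate a reflectance (profilometry) scan of opaque structures
#'
#' Surfaces of the occlusion mask produce bright pixels: boundary voxels of
#' the mask within half a pixel of each polar section plane are projected to
#' (signed radius, z) image coordinates.  The sweep is forced to
#' \code{2*pi} so both sides of every surface are observed (bidirectional
#' illumination).
#'
#' @param mask an \linkS4class{OcclusionMask}, or a \linkS4class{Scene}
#'   containing opaque primitives (rasterized on \code{grid}).
#' @param nSections number of sections.
#' @param pixelSize image pixel pitch, mm.
#' @param grid grid used when a Scene is given.
#' @param seed integer seed (recorded).
#' @return A \linkS4class{PolarScan} with \code{mode = "reflectance"}.
#' @export
simulateReflectanceScan <- function(mask, nSections = 1000,
                                    pixelSize = NULL, grid = NULL,
                                    seed = 0L) {
  if (is(mask, "Scene")) {
    if (is.null(grid))
      grid <- voxelGrid(c(ceiling(2 * mask@vialRadius / 0.05),
                          ceiling(2 * mask@vialRadius / 0.05),
                          ceiling(mask@vialHeight / 0.05)), 0.05)
    mask <- rasterizeScene(mask, grid)$mask
  }
  grid <- mask@grid
  if (is.null(pixelSize)) pixelSize <- grid@voxelSize
  thetaTotal <- 2 * pi
  angles <- (seq_len(nSections) - 1) * thetaTotal / nSections
  ext <- grid@origin + grid@dim * grid@voxelSize
  rmax <- max(abs(c(grid@origin[1:2], ext[1:2])))
  nh <- ceiling(rmax / pixelSize)
  nu <- 2L * nh + 1L
  u0 <- nh + 1
  nv <- as.integer(floor((ext[3] - grid@origin[3]) / pixelSize))
  images <- array(0, c(nu, nv, nSections))
  if (!any(mask@inside)) {
    warning("no opaque content in scene; reflectance scan is empty")
  } else {
    bnd <- maskBoundary(mask@inside)
    idx <- which(bnd, arr.ind = TRUE)
    ctr <- cbind(gridCoords(grid, 1)[idx[, 1]],
                 gridCoords(grid, 2)[idx[, 2]],
                 gridCoords(grid, 3)[idx[, 3]])
    for (k in seq_len(nSections)) {
      th <- angles[k]
      off <- -ctr[, 1] * sin(th) + ctr[, 2] * cos(th)
      sel <- abs(off) <= pixelSize / 2
      if (!any(sel)) next
      r <- ctr[sel, 1] * cos(th) + ctr[sel, 2] * sin(th)
      u <- round(r / pixelSize) + u0
      v <- ceiling((ctr[sel, 3] - grid@origin[3]) / pixelSize)
      ok <- u >= 1 & u <= nu & v >= 1 & v <= nv
      images[cbind(u[ok], v[ok], k)] <- 1
    }
  }
  new("PolarScan", images = images, angles = angles, thetaTotal = thetaTotal,
      pixelSize = pixelSize, axisColumn = as.numeric(u0), channel = "none",
      mode = "reflectance", zOrigin = grid@origin[3])
}

# 6-neighbour boundary voxels of a logical 3D array
maskBoundary <- function(inside) {
  d <- dim(inside)
  er <- inside
  shift <- function(a, ax, by) {
    out <- array(FALSE, dim(a))
    i <- seq_len(d[1]); j <- seq_len(d[2]); k <- seq_len(d[3])
    src <- list(i, j, k)
    dst <- list(i, j, k)
    n <- d[ax]
    if (by > 0) {
      dst[[ax]] <- 1:(n - by); src[[ax]] <- (1 + by):n
    } else {
      dst[[ax]] <- (1 - by):n; src[[ax]] <- 1:(n + by)
    }
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (ax in 1:3) for (by in c(-1, 1)) er <- er & shift(inside, ax, by)
  inside & !er
}
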
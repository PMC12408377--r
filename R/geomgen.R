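# Generative parametric geometry around registered features, plus SDF
# voxelization, isosurface meshing and mesh measurement.

#' Spherically wrapped channel network around a feature
#'
#' \code{nArcs} meridian arcs on the stand-off sphere of radius
#' \code{rFeature + offset + channelD/2}, joined at polar junctions to
#' vertical inlet/outlet trunks, forming a single perfusable inlet-to-outlet
#' path.  The realized channel wall clears the feature surface by
#' \code{offset} exactly, by construction.
#'
#' @param center feature centroid, mm.
#' @param rFeature feature radius, mm.
#' @param offset wall-to-feature clearance, mm (printed constructs use
#'   300 um).
#' @param channelD channel diameter, mm (450 um default).
#' @param nArcs number of meridian arcs.
#' @param zRange (bottom, top) of the build volume, mm, for the trunks.
#' @param buildRadius build circle radius, mm.
#' @param arcStep angular sampling of the arcs, radians.
#' @return A \linkS4class{TubeGraph}.
#' @export
wrappedNetwork <- function(center, rFeature, offset = 0.3, channelD = 0.45,
                           nArcs = 6, zRange = c(0, 10), buildRadius = 5,
                           arcStep = pi / 60) {
  stopifnot(offset > 0, channelD > 0, nArcs >= 1)
  rho <- rFeature + offset + channelD / 2
  if (sqrt(sum(center[1:2]^2)) + rho > buildRadius ||
      center[3] - rho < zRange[1] || center[3] + rho > zRange[2])
    stop("wrap sphere exceeds the build volume")
  rc <- channelD / 2
  north <- center + c(0, 0, rho)
  south <- center - c(0, 0, rho)
  edges <- list(
    list(points = rbind(c(center[1], center[2], zRange[2]), north),
         radii = c(rc, rc), role = "inlet"),
    list(points = rbind(south, c(center[1], center[2], zRange[1])),
         radii = c(rc, rc), role = "outlet"))
  tt <- seq(0, pi, by = arcStep)
  for (j in seq_len(nArcs)) {
    phi <- (j - 1) * 2 * pi / nArcs
    pts <- cbind(center[1] + rho * sin(tt) * cos(phi),
                 center[2] + rho * sin(tt) * sin(phi),
                 center[3] + rho * cos(tt))
    edges[[length(edges) + 1]] <-
      list(points = pts, radii = rep(rc, length(tt)), role = "wrap")
  }
  tubeGraph(edges, provenance = list(generator = "wrappedNetwork",
                                     center = center, rFeature = rFeature,
                                     offset = offset, channelD = channelD,
                                     nArcs = nArcs))
}

#' Single grazing channel tangent to a feature's stand-off sphere
#'
#' A straight vertical channel whose centreline passes the feature centre at
#' lateral distance \code{rFeature + offset + channelD/2}, so the channel
#' wall grazes the stand-off surface.  If the tangent line falls outside the
#' build circle, the azimuth is rotated (with a warning) to the nearest
#' placement inside.
#'
#' @inheritParams wrappedNetwork
#' @param direction azimuth of the tangent displacement, radians.
#' @return A \linkS4class{TubeGraph} with a single constant-radius edge.
#' @export
grazingChannel <- function(center, rFeature, offset = 0.3, channelD = 0.45,
                           direction = 0, zRange = c(0, 10),
                           buildRadius = 5) {
  stopifnot(offset > 0, channelD > 0)
  dlat <- rFeature + offset + channelD / 2
  rc <- channelD / 2
  candidates <- direction + seq(0, 2 * pi, length.out = 65)[-65]
  q <- NULL
  for (i in seq_along(candidates)) {
    a <- candidates[i]
    qi <- center[1:2] + dlat * c(cos(a), sin(a))
    if (sqrt(sum(qi^2)) <= buildRadius - rc) {
      if (i > 1) warning("tangent line outside build circle; shifted inward")
      q <- qi
      break
    }
  }
  if (is.null(q)) stop("no tangent placement fits the build circle")
  edges <- list(list(points = rbind(c(q, zRange[1]), c(q, zRange[2])),
                     radii = c(rc, rc), role = "graze"))
  tubeGraph(edges, provenance = list(generator = "grazingChannel",
                                     center = center, rFeature = rFeature,
                                     offset = offset, channelD = channelD))
}

#' A* shortest path over a weighted geometric graph
#'
#' Standard A* with the (admissible) Euclidean-distance heuristic over
#' Euclidean edge weights.
#'
#' @param nodes N x 3 matrix of node positions, mm.
#' @param edges E x 2 matrix of node index pairs (1-based, undirected).
#' @param from,to node indices.
#' @param weights edge weights; defaults to Euclidean edge lengths.
#' @return list with \code{path} (node indices) and \code{length}.
#' @export
aStarPath <- function(nodes, edges, from, to, weights = NULL) {
  n <- nrow(nodes)
  if (is.null(weights))
    weights <- sqrt(rowSums((nodes[edges[, 1], , drop = FALSE] -
                             nodes[edges[, 2], , drop = FALSE])^2))
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, weights[e]))
    adj[[b]] <- rbind(adj[[b]], c(a, weights[e]))
  }
  h <- sqrt(colSums((t(nodes) - nodes[to, ])^2))
  g <- rep(Inf, n)
  g[from] <- 0
  came <- rep(NA_integer_, n)
  open <- c(from)
  closed <- rep(FALSE, n)
  while (length(open)) {
    f <- g[open] + h[open]
    cur <- open[which.min(f)]
    open <- setdiff(open, cur)
    if (cur == to) break
    closed[cur] <- TRUE
    nb <- adj[[cur]]
    for (k in seq_len(NROW(nb))) {
      v <- nb[k, 1]
      if (closed[v]) next
      cand <- g[cur] + nb[k, 2]
      if (cand < g[v]) {
        g[v] <- cand
        came[v] <- cur
        if (!v %in% open) open <- c(open, v)
      }
    }
  }
  if (!is.finite(g[to])) return(list(path = integer(0), length = Inf))
  path <- to
  while (!is.na(came[path[1]])) path <- c(came[path[1]], path)
  list(path = path, length = g[to])
}

#' Interconnect detected features with printed struts
#'
#' Builds a k-nearest-neighbour candidate graph on feature centroids
#' (incrementing k with a warning until connected), keeps the minimum
#' spanning tree, and realizes each kept edge as a capsule strut between the
#' feature surfaces.  Pairwise routes through the candidate graph can be
#' queried with \code{\link{aStarPath}} on the returned provenance.
#'
#' @param featureSet a \linkS4class{FeatureSet} with >= 2 features.
#' @param kCandidates neighbours per node in the candidate graph.
#' @param strutD strut diameter, mm.
#' @return A \linkS4class{TubeGraph}; provenance carries \code{nodes},
#'   candidate \code{edges} and \code{weights}.
#' @export
interconnectStruts <- function(featureSet, kCandidates = 5, strutD = 0.45) {
  feats <- featureSet@features
  stopifnot(nrow(feats) >= 2)
  nodes <- as.matrix(feats[, c("x", "y", "z")])
  n <- nrow(nodes)
  D <- as.matrix(stats::dist(nodes))
  k <- min(kCandidates, n - 1)
  repeat {
    edges <- matrix(0L, 0, 2)
    for (i in seq_len(n)) {
      nb <- order(D[i, ])[2:(k + 1)]
      edges <- rbind(edges, cbind(pmin(i, nb), pmax(i, nb)))
    }
    edges <- unique(edges)
    gg <- igraph::graph_from_edgelist(edges, directed = FALSE)
    if (igraph::vcount(gg) == n && igraph::is_connected(gg)) break
    if (k >= n - 1) break
    k <- k + 1
    warning("candidate graph disconnected; increasing k to ", k)
  }
  weights <- D[edges]
  gg <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(gg)$weight <- weights
  mst <- igraph::mst(gg)
  kept <- igraph::as_edgelist(mst)
  radii <- ifelse(is.na(feats$radius), 0, feats$radius)
  tubes <- lapply(seq_len(nrow(kept)), function(e) {
    i <- as.integer(kept[e, 1]); j <- as.integer(kept[e, 2])
    dir <- unitVec(nodes[j, ] - nodes[i, ])
    a <- nodes[i, ] + dir * radii[i]
    b <- nodes[j, ] - dir * radii[j]
    list(points = rbind(a, b), radii = rep(strutD / 2, 2), role = "strut")
  })
  tubeGraph(tubes, provenance = list(generator = "interconnectStruts",
                                     nodes = nodes, edges = edges,
                                     weights = weights, k = k))
}

#' Spherical encapsulation shell around a feature
#'
#' Implicit shell occupying radii \code{[r + offset, r + offset + thickness]}
#' around the feature centroid.
#'
#' @inheritParams wrappedNetwork
#' @param thickness shell thickness, mm.
#' @return An \linkS4class{ImplicitModel} (signed distance, negative inside).
#' @export
encapsulationShell <- function(center, rFeature, offset = 0.3,
                               thickness = 0.3) {
  stopifnot(thickness > 0)
  rMid <- rFeature + offset + thickness / 2
  center <- as.numeric(center)
  sdf <- function(p) {
    d <- sqrt(colSums((t(p) - center)^2))
    abs(d - rMid) - thickness / 2
  }
  new("ImplicitModel", sdf = sdf,
      provenance = list(generator = "encapsulationShell", center = center,
                        rFeature = rFeature, offset = offset,
                        thickness = thickness))
}

#' Design rule: predicate on a feature plus a geometry generator
#'
#' @param name rule name.
#' @param predicate function taking one row of a feature table, returning
#'   TRUE when the rule applies.
#' @param generator function taking the feature row, returning a
#'   \linkS4class{TubeGraph} or \linkS4class{ImplicitModel}.
#' @return a design rule (list with class \code{"designRule"}).
#' @export
designRule <- function(name, predicate, generator) {
  structure(list(name = name, predicate = predicate, generator = generator),
            class = "designRule")
}

#' Size-conditional rule set: small spheres graze, large spheres are wrapped
#'
#' Features with radius below \code{threshold} receive a single grazing
#' channel; radius at or above the threshold (inclusive) receives a
#' spherically wrapped network.
#'
#' @param threshold radius threshold, mm.
#' @param ... generator parameters passed to \code{\link{grazingChannel}} /
#'   \code{\link{wrappedNetwork}}.
#' @return list of \code{\link{designRule}}s, first-match-wins order.
#' @export
sizeRules <- function(threshold = 0.5, ...) {
  dots <- list(...)
  list(
    designRule("grazing-small",
               function(f) !is.na(f$radius) && f$radius < threshold,
               function(f) do.call(grazingChannel,
                                   c(list(center = c(f$x, f$y, f$z),
                                          rFeature = f$radius), dots))),
    designRule("wrapped-large",
               function(f) !is.na(f$radius) && f$radius >= threshold,
               function(f) do.call(wrappedNetwork,
                                   c(list(center = c(f$x, f$y, f$z),
                                          rFeature = f$radius), dots))))
}

#' Spectral rule set: one channel grazes, the other is wrapped
#'
#' Mirrors discrimination by fluorophore: the Cy3.5-class label receives a
#' solitary grazing channel, the Cy5-class label a wrapped network.
#'
#' @param grazeChannel,wrapChannel channel labels.
#' @param ... generator parameters.
#' @return list of \code{\link{designRule}}s.
#' @export
spectralRules <- function(grazeChannel = "ch532", wrapChannel = "ch650",
                          ...) {
  dots <- list(...)
  list(
    designRule("grazing-spectral",
               function(f) identical(f$channel, grazeChannel),
               function(f) do.call(grazingChannel,
                                   c(list(center = c(f$x, f$y, f$z),
                                          rFeature = f$radius), dots))),
    designRule("wrapped-spectral",
               function(f) identical(f$channel, wrapChannel),
               function(f) do.call(wrappedNetwork,
                                   c(list(center = c(f$x, f$y, f$z),
                                          rFeature = f$radius), dots))))
}

#' Apply design rules to a feature set
#'
#' First matching rule wins; an unmatched feature is an error naming the
#' feature.
#'
#' @param featureSet a \linkS4class{FeatureSet}.
#' @param rules list of \code{\link{designRule}}s.
#' @return named list (by feature id) of generated geometries, each with
#'   attribute \code{"rule"}.
#' @export
applyDesignRules <- function(featureSet, rules) {
  feats <- featureSet@features
  out <- list()
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    hit <- NULL
    for (r in rules) {
      if (isTRUE(r$predicate(f))) {
        hit <- r
        break
      }
    }
    if (is.null(hit))
      stop("no design rule matches feature id ", f$id, " (radius = ",
           f$radius, ", channel = ", f$channel, ")")
    geom <- hit$generator(f)
    attr(geom, "rule") <- hit$name
    out[[as.character(f$id)]] <- geom
  }
  out
}

# offset-torus surface point; phi toroidal, psi poloidal, rho radial offset
torusPoint <- function(center, R, phi, psi, rho) {
  cbind(center[1] + cos(phi) * (R + rho * cos(psi)),
        center[2] + sin(phi) * (R + rho * cos(psi)),
        center[3] + rho * sin(psi))
}

#' Tapered vessel network coiled around a torus
#'
#' A single vertical inlet trunk (top) and outlet trunk (bottom) of diameter
#' \code{dInlet} joined by \code{nCoils} channels that coil around the torus
#' tube at clearance \code{offset}, their diameter tapering linearly in
#' arclength from \code{dInlet} at the trunks to \code{dMin} at the
#' midplane.  The number of poloidal turns is solved (bracketing sweep
#' plus refinement) so the realized area matches \code{targetArea} within
#' \code{areaTol}.  Because channels necessarily merge near the torus bore
#' and the junctions, the union (mesh) area falls below the summed analytic
#' lateral area; with \code{meshCalibrate = TRUE} (default) the solver
#' therefore iterates against the measured mesh area, which is the quantity
#' the physical workflow reports from segmented scans.
#'
#' @param center torus centre, mm.
#' @param ringDiameter torus centreline diameter, mm.
#' @param tubeDiameter torus tube diameter, mm.
#' @param offset wall clearance from the torus surface, mm.
#' @param dInlet inlet/outlet channel diameter, mm.
#' @param dMin midplane (minimum) channel diameter, mm.
#' @param nCoils number of coiling channels.
#' @param targetArea target lateral surface area, mm^2.
#' @param areaTol area tolerance, mm^2.
#' @param turnsRange solver bounds on poloidal turns per coil.
#' @param zRange build z-range for the trunks, mm.
#' @param nSamples polyline samples per coil.
#' @param meshCalibrate iterate the solve against the measured mesh area.
#' @param meshVoxel voxel size for the calibration meshing, mm.
#' @return A \linkS4class{TubeGraph}; provenance records \code{converged},
#'   \code{analyticArea}, \code{meshArea}, \code{turns}.
#' @export
torusVesselNetwork <- function(center = c(0, 0, 5), ringDiameter = 4,
                               tubeDiameter = 1, offset = 0.3, dInlet = 1.0,
                               dMin = 0.45, nCoils = 4, targetArea = 180,
                               areaTol = 10, turnsRange = c(0.5, 10),
                               zRange = c(0.5, 9.5), nSamples = 400,
                               meshCalibrate = TRUE, meshVoxel = 0.05) {
  R <- ringDiameter / 2
  rTube <- tubeDiameter / 2
  rIn <- dInlet / 2
  rMin <- dMin / 2
  build <- function(turns) {
    rhoOf <- function(rr) rTube + offset + rr
    A <- torusPoint(center, R, 0, pi / 2, rhoOf(rIn))[1, ]
    B <- torusPoint(center, R, pi, -pi / 2, rhoOf(rIn))[1, ]
    edges <- list(
      list(points = rbind(c(A[1], A[2], zRange[2]), A),
           radii = c(rIn, rIn), role = "inlet"),
      list(points = rbind(B, c(B[1], B[2], zRange[1])),
           radii = c(rIn, rIn), role = "outlet"))
    tt <- seq(0, 1, length.out = nSamples)
    for (j in seq_len(nCoils)) {
      dirj <- if (j %% 2 == 1) 1 else -1
      mj <- turns + (j - 1) %/% 2 # distinct winding per same-direction coil
      rr <- rIn + (rMin - rIn) * (1 - abs(2 * tt - 1))
      phi <- dirj * pi * tt
      psi <- pi / 2 + (2 * pi * mj - pi) * tt
      pts <- torusPoint(center, R, phi, psi, rhoOf(rr))
      # poloidal connector at phi = dir*pi back to the outlet junction B
      psiEnd <- psi[length(psi)]
      psiTarget <- -pi / 2 + 2 * pi * round((psiEnd + pi / 2) / (2 * pi))
      if (abs(psiTarget - psiEnd) > 1e-9) {
        cpsi <- seq(psiEnd, psiTarget, length.out = 24)[-1]
        cpts <- torusPoint(center, R, dirj * pi, cpsi, rhoOf(rIn))
        pts <- rbind(pts, cpts)
        rr <- c(rr, rep(rIn, length(cpsi)))
      }
      edges[[length(edges) + 1]] <-
        list(points = pts, radii = rr, role = "coil")
    }
    edges
  }
  areaOf <- function(edges)
    sum(vapply(edges, function(e) tubeLateralArea(e$points, e$radii),
               numeric(1)))
  # the poloidal connector makes area(turns) piecewise continuous, so a
  # coarse bracketing sweep plus local refinement replaces plain bisection
  solveAnalytic <- function(tgt) {
    sweep1 <- seq(turnsRange[1], turnsRange[2], length.out = 120)
    a1 <- vapply(sweep1, function(m) areaOf(build(m)), numeric(1))
    best1 <- sweep1[which.min(abs(a1 - tgt))]
    step <- diff(sweep1[1:2])
    sweep2 <- seq(max(turnsRange[1], best1 - step),
                  min(turnsRange[2], best1 + step), length.out = 40)
    a2 <- vapply(sweep2, function(m) areaOf(build(m)), numeric(1))
    sweep2[which.min(abs(a2 - tgt))]
  }
  workTarget <- targetArea
  meshArea <- NA_real_
  for (round_ in 1:4) {
    turns <- solveAnalytic(workTarget)
    edges <- build(turns)
    analytic <- areaOf(edges)
    if (!meshCalibrate) break
    graph <- tubeGraph(edges)
    meshArea <- meshMeasures(meshTube(graph, voxel = meshVoxel)$mesh)$area
    if (abs(meshArea - targetArea) <= areaTol * 0.5) break
    workTarget <- workTarget * targetArea / meshArea
    if (workTarget > 2.5 * targetArea) break # beyond the coil-count bounds
  }
  realized <- if (meshCalibrate) meshArea else analytic
  if (abs(realized - targetArea) > areaTol)
    stop("torus vessel area solver did not converge: target ", targetArea,
         " mm^2; best achieved ", round(realized, 1), " mm^2 at ",
         round(turns, 2), " turns")
  tubeGraph(edges,
            provenance = list(generator = "torusVesselNetwork",
                              converged = abs(realized - targetArea) <=
                                areaTol,
                              analyticArea = analytic, meshArea = meshArea,
                              turns = turns, nCoils = nCoils,
                              targetArea = targetArea, offset = offset,
                              dInlet = dInlet, dMin = dMin))
}

#' Randomly placed vertical channels of matched surface area
#'
#' Control geometry: vertical channels with the same taper law at seeded
#' random lateral positions, pairwise non-intersecting, their common radius
#' scale set so the analytic lateral area matches \code{targetArea}.
#'
#' @param bulkRadius,bulkHeight bulk cylinder dimensions, mm.
#' @param targetArea target lateral area, mm^2.
#' @param dInlet,dMin end and midplane channel diameters, mm.
#' @param seed integer seed.
#' @param areaTol area tolerance, mm^2.
#' @param margin end margin of the channels inside the bulk, mm.
#' @param maxAttempts placement budget per channel.
#' @return A \linkS4class{TubeGraph} with provenance as for
#'   \code{\link{torusVesselNetwork}}.
#' @export
randomChannelNetwork <- function(bulkRadius = 4, bulkHeight = 10,
                                 targetArea = 180, dInlet = 1.0, dMin = 0.45,
                                 seed = 0L, areaTol = 10, margin = 0.5,
                                 maxAttempts = 2000L) {
  rIn <- dInlet / 2
  rMin <- dMin / 2
  zz <- seq(margin, bulkHeight - margin, length.out = 64)
  tt <- (zz - margin) / (bulkHeight - 2 * margin)
  rr <- rIn + (rMin - rIn) * (1 - abs(2 * tt - 1))
  one <- tubeLateralArea(cbind(0, 0, zz), rr)
  n <- max(1L, round(targetArea / one))
  sigma <- targetArea / (n * one) # lateral area is linear in the radius scale
  withSeed(seed, {
    centers <- matrix(0, 0, 2)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (att in seq_len(maxAttempts)) {
        xy <- runifDisc(bulkRadius - sigma * rIn - 0.1)
        ok <- !nrow(centers) ||
          all(sqrt(colSums((t(centers) - xy)^2)) > 2 * sigma * rIn + 0.2)
        if (ok) {
          centers <- rbind(centers, xy)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place ", n, " non-intersecting channels")
    }
    edges <- lapply(seq_len(n), function(i)
      list(points = cbind(centers[i, 1], centers[i, 2], zz),
           radii = sigma * rr, role = "coil"))
    analytic <- sum(vapply(edges, function(e)
      tubeLateralArea(e$points, e$radii), numeric(1)))
    tubeGraph(edges,
              provenance = list(generator = "randomChannelNetwork",
                                converged = abs(analytic - targetArea) <=
                                  areaTol,
                                analyticArea = analytic, n = n,
                                sigma = sigma, targetArea = targetArea,
                                seed = seed))
  })
}

#' Conforming cartilage cap over a spherical femoral head
#'
#' Offset shell of given thickness over the spherical-cap region of the
#' head within \code{capAngle} of the cap axis; watertight by construction.
#'
#' @param headCenter,headRadius head sphere, mm.
#' @param thickness cap thickness, mm.
#' @param capAngle half-angle of the cap, degrees.
#' @param axis cap axis (points from the head centre through the cap apex).
#' @param voxel meshing voxel size, mm.
#' @return A \linkS4class{TriMesh}.
#' @export
cartilageCap <- function(headCenter, headRadius, thickness = 0.5,
                         capAngle = 90, axis = c(0, 0, 1), voxel = 0.05) {
  if (capAngle <= 0) stop("capAngle must be > 0")
  axis <- unitVec(axis)
  cosA <- cos(capAngle * pi / 180)
  headCenter <- as.numeric(headCenter)
  sdf <- function(p) {
    rel <- t(p) - headCenter
    d <- sqrt(colSums(rel^2))
    shell <- pmax(d - (headRadius + thickness), headRadius - d)
    cone <- cosA * d - colSums(rel * axis)
    pmax(shell, cone)
  }
  rOut <- headRadius + thickness
  lo <- headCenter - rOut - 4 * voxel
  hi <- headCenter + rOut + 4 * voxel
  dims <- as.integer(ceiling((hi - lo) / voxel))
  grid <- voxelGrid(dims, voxel, lo)
  field <- evalSdfOnGrid(sdf, grid)
  extractMesh(field, grid)
}

evalSdfOnGrid <- function(sdf, grid) {
  gx <- gridCoords(grid, 1)
  gy <- gridCoords(grid, 2)
  gz <- gridCoords(grid, 3)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz,
                               KEEP.OUT.ATTRS = FALSE))
  array(sdf(pts), grid@dim)
}

#' Voxelize a generated model
#'
#' \code{positive}: voxels inside the model are TRUE.
#' \code{negative_in_bulk}: TRUE inside the bulk cylinder minus the model
#' (open channels in a scaffold).  Tube networks use a capsule-union signed
#' distance field.
#'
#' @param model a \linkS4class{TubeGraph} or \linkS4class{ImplicitModel}.
#' @param grid a \linkS4class{VoxelGrid}.
#' @param mode \code{"positive"} or \code{"negative_in_bulk"}.
#' @param bulkRadius,bulkHeight,bulkCenter bulk cylinder (z-aligned), mm.
#' @return logical 3D array on \code{grid}.
#' @export
voxelizeModel <- function(model, grid,
                          mode = c("positive", "negative_in_bulk"),
                          bulkRadius = 4, bulkHeight = diff(range(gridCoords(grid, 3))),
                          bulkCenter = c(0, 0, mean(range(gridCoords(grid, 3))))) {
  mode <- match.arg(mode)
  field <- modelSdf(model, grid)
  if (mode == "positive") {
    ext <- grid@origin + grid@dim * grid@voxelSize
    if (is(model, "TubeGraph")) {
      segs <- tubeSegments(model)
      rmax <- max(segs[, 7:8])
      lo <- apply(segs[, 1:3, drop = FALSE], 2, min)
      lo <- pmin(lo, apply(segs[, 4:6, drop = FALSE], 2, min)) - rmax
      hi <- apply(segs[, 1:3, drop = FALSE], 2, max)
      hi <- pmax(hi, apply(segs[, 4:6, drop = FALSE], 2, max)) + rmax
      if (any(lo < grid@origin - 1e-9) || any(hi > ext + 1e-9))
        stop("model exceeds the voxel grid")
    }
    return(field <= 0)
  }
  gx <- gridCoords(grid, 1) - bulkCenter[1]
  gy <- gridCoords(grid, 2) - bulkCenter[2]
  gz <- gridCoords(grid, 3) - bulkCenter[3]
  inDisc <- outer(gx^2, gy^2, "+") <= bulkRadius^2
  inZ <- abs(gz) <= bulkHeight / 2
  bulk <- array(outer(as.vector(inDisc), inZ, "&"), grid@dim)
  bulk & !(field <= 0)
}

modelSdf <- function(model, grid) {
  if (is(model, "TubeGraph")) {
    segs <- tubeSegments(model)
    if (is.null(segs))
      return(array(1e6, grid@dim))
    field <- cpp_tube_sdf(grid@dim, grid@origin, grid@voxelSize, segs,
                          band = 4 * grid@voxelSize, far_value = 1e6)
    array(field, grid@dim)
  } else if (is(model, "ImplicitModel")) {
    evalSdfOnGrid(model@sdf, grid)
  } else stop("unsupported model type")
}

#' Extract a triangle mesh from a volume
#'
#' Marching tetrahedra at the 0-level of a signed distance field
#' (sub-voxel accurate) or at the 0.5-level of a binary volume.  The output
#' of a closed level set is watertight and consistently oriented.
#'
#' @param x a numeric SDF array, logical/binary array, or
#'   \linkS4class{ChannelVolume}.
#' @param grid the \linkS4class{VoxelGrid} (taken from a ChannelVolume).
#' @return A \linkS4class{TriMesh}.
#' @export
extractMesh <- function(x, grid = NULL) {
  if (is(x, "ChannelVolume")) {
    grid <- x@grid
    x <- x@values
  }
  if (is.null(grid)) stop("grid required")
  field <- if (is.logical(x) || all(x %in% c(0, 1))) {
    0.5 - x
  } else {
    x
  }
  if (!any(field < 0)) stop("empty foreground: nothing to mesh")
  # pad with a positive far-field layer so level sets touching the grid
  # boundary are capped and the mesh closes
  d <- grid@dim
  padded <- array(1e6, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- field
  res <- cpp_march_tets(as.numeric(padded), d + 2L,
                        grid@origin - grid@voxelSize, grid@voxelSize, 0)
  triMesh(res$vertices, res$faces)
}

#' Surface area, volume and watertightness of a mesh
#'
#' Area is the sum of triangle areas; volume comes from signed tetrahedra
#' and is withheld (NA) for non-watertight meshes.
#'
#' @param mesh a \linkS4class{TriMesh}.
#' @return list with \code{area} (mm^2), \code{volume} (mm^3 or NA),
#'   \code{watertight}.
#' @export
meshMeasures <- function(mesh) {
  V <- mesh@vertices
  Fc <- mesh@faces
  a <- V[Fc[, 1], , drop = FALSE]
  b <- V[Fc[, 2], , drop = FALSE]
  cc <- V[Fc[, 3], , drop = FALSE]
  u <- b - a
  w <- cc - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  area <- sum(sqrt(rowSums(cr^2))) / 2
  wt <- isWatertight(mesh)
  vol <- if (wt) {
    abs(sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
            a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
            a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1]))) / 6
  } else NA_real_
  list(area = area, volume = vol, watertight = wt)
}

isWatertight <- function(mesh) {
  Fc <- mesh@faces
  if (!nrow(Fc)) return(FALSE)
  nv <- as.numeric(nrow(mesh@vertices))
  he <- rbind(cbind(Fc[, 1], Fc[, 2]), cbind(Fc[, 2], Fc[, 3]),
              cbind(Fc[, 3], Fc[, 1]))
  fwd <- (he[, 1] - 1) * nv + he[, 2]
  rev <- (he[, 2] - 1) * nv + he[, 1]
  # every directed half-edge must be matched by exactly one reverse
  if (anyDuplicated(fwd)) return(FALSE)
  all(fwd %in% rev)
}

#' Minimum clearance between two meshes
#'
#' Symmetric minimum vertex-to-surface distance.
#'
#' @param meshA,meshB \linkS4class{TriMesh} objects.
#' @return clearance, mm.
#' @export
minClearance <- function(meshA, meshB) {
  min(min(cpp_point_mesh_dist(meshA@vertices, meshB@vertices, meshB@faces)),
      min(cpp_point_mesh_dist(meshB@vertices, meshA@vertices, meshA@faces)))
}

# area-weighted random points on a mesh surface
meshSampleSurface <- function(mesh, n, seed = 0L) {
  V <- mesh@vertices
  Fc <- mesh@faces
  a <- V[Fc[, 1], , drop = FALSE]
  b <- V[Fc[, 2], , drop = FALSE]
  cc <- V[Fc[, 3], , drop = FALSE]
  u <- b - a
  w <- cc - a
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  areas <- sqrt(rowSums(cr^2)) / 2
  withSeed(seed, {
    tri <- sample.int(nrow(Fc), n, replace = TRUE, prob = areas)
    r1 <- sqrt(stats::runif(n))
    r2 <- stats::runif(n)
    (1 - r1) * a[tri, , drop = FALSE] +
      r1 * (1 - r2) * b[tri, , drop = FALSE] +
      r1 * r2 * cc[tri, , drop = FALSE]
  })
}
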
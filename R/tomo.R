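# Telecentric parallel-beam tomographic print simulation and OSMO
# projection optimization with occlusion (shadow) correction.

asVolumeArray <- function(x) {
  if (is(x, "ChannelVolume")) x@values
  else if (is(x, "DoseVolume")) x@dose
  else if (is.matrix(x)) array(x, c(dim(x), 1L))
  else if (is.array(x)) x
  else stop("expected a matrix, 3D array, ChannelVolume or DoseVolume")
}

asMaskArray <- function(occlusion, dim3) {
  if (is.null(occlusion)) return(NULL)
  m <- if (is(occlusion, "OcclusionMask")) occlusion@inside
       else if (is.matrix(occlusion)) array(occlusion, c(dim(occlusion), 1L))
       else occlusion
  if (!identical(dim(m), dim3))
    stop("occlusion mask grid does not match the volume grid")
  storage.mode(m) <- "integer"
  m
}

#' Forward projection (telecentric parallel-beam line integrals)
#'
#' Per z-slice line integrals over rotated rays; with an occlusion mask the
#' integrand weight is 1 from the ray entry side up to the first occluded
#' voxel and 0 beyond.  The detector coordinate convention is
#' \code{u = -x sin(theta) + y cos(theta)}, rays travel along
#' \code{(cos(theta), sin(theta))}.
#'
#' @param volume matrix (one slice), 3D array or \linkS4class{ChannelVolume}.
#' @param angles projection angles, radians.
#' @param occlusion optional \linkS4class{OcclusionMask} or logical array on
#'   the same grid.
#' @param step ray sampling step (= voxel size), mm; scales the integrals.
#' @return A \linkS4class{ProjectionSet} (negatives cannot occur; the
#'   operator is linear with nonnegative weights, and nonnegative input
#'   gives nonnegative projections).
#' @export
forwardProject <- function(volume, angles = seq(0, 2 * pi,
                                                length.out = 361)[-361],
                           occlusion = NULL, step = 1) {
  vol <- asVolumeArray(volume)
  occ <- asMaskArray(occlusion, dim(vol))
  nz <- dim(vol)[3]
  nu <- dim(vol)[1]
  values <- array(0, c(nu, length(angles), nz))
  for (k in seq_len(nz)) {
    ok <- if (is.null(occ)) NULL else matrix(occ[, , k], nrow = nu)
    values[, , k] <- cpp_project_slice(matrix(vol[, , k], nrow = nu),
                                       angles, ok, step)
  }
  values[values < 0] <- 0
  new("ProjectionSet", values = values, angles = angles, pitch = step)
}

#' Accumulated dose from a projection set
#'
#' Sum over angles of ray-wise deposition with the same occlusion
#' transmission weights as \code{\link{forwardProject}} (exact adjoint when
#' \code{mu = 0}), with optional Beer-Lambert attenuation
#' \code{exp(-mu * depth)} along each ray.
#'
#' @param projections a \linkS4class{ProjectionSet} (or nu x nAngles
#'   matrix for a single slice).
#' @param dim2 slice dimensions (nx, ny); defaults to square (nu, nu).
#' @param occlusion optional mask as in \code{\link{forwardProject}}.
#' @param mu absorption coefficient, 1/mm (default 0: index-matched,
#'   low-absorbing resin).
#' @param grid optional \linkS4class{VoxelGrid} for the returned
#'   \linkS4class{DoseVolume}.
#' @param normalize \code{"none"} or \code{"max"}.
#' @return A \linkS4class{DoseVolume}.
#' @export
computeDose <- function(projections, dim2 = NULL, occlusion = NULL, mu = 0,
                        grid = NULL, normalize = c("none", "max")) {
  normalize <- match.arg(normalize)
  if (is.matrix(projections)) {
    projections <- new("ProjectionSet",
                       values = array(projections,
                                      c(dim(projections), 1L)),
                       angles = attr(projections, "angles") %||%
                         stop("matrix input needs an 'angles' attribute"),
                       pitch = 1)
  }
  vals <- projections@values
  nu <- dim(vals)[1]
  nz <- dim(vals)[3]
  if (is.null(dim2)) dim2 <- c(nu, nu)
  occ <- asMaskArray(occlusion, as.integer(c(dim2, nz)))
  dose <- array(0, c(dim2, nz))
  for (k in seq_len(nz)) {
    ok <- if (is.null(occ)) NULL else matrix(occ[, , k], nrow = dim2[1])
    dose[, , k] <- cpp_dose_slice(matrix(vals[, , k], nrow = nu),
                                  projections@angles, ok,
                                  dim2[1], dim2[2], projections@pitch, mu)
  }
  if (normalize == "max" && max(dose) > 0) dose <- dose / max(dose)
  if (is.null(grid))
    grid <- voxelGrid(dim(dose), projections@pitch)
  new("DoseVolume", grid = grid, dose = dose, normalization = normalize)
}

# dilate a logical slice/volume by a Euclidean radius (voxels)
dilateMask <- function(mask, rVox) {
  if (rVox <= 0 || !any(mask)) return(mask)
  k <- ceiling(rVox)
  d <- dim(mask)
  out <- mask
  offs <- expand.grid(dx = -k:k, dy = -k:k)
  offs <- offs[offs$dx^2 + offs$dy^2 <= rVox^2, ]
  nz <- if (length(d) == 3) d[3] else 1L
  m3 <- if (length(d) == 3) mask else array(mask, c(d, 1L))
  o3 <- if (length(d) == 3) out else array(out, c(d, 1L))
  for (i in seq_len(nrow(offs))) {
    dx <- offs$dx[i]; dy <- offs$dy[i]
    if (dx == 0 && dy == 0) next
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    o3[xs, ys, ] <- o3[xs, ys, , drop = FALSE] |
      m3[xs - dx, ys - dy, , drop = FALSE]
  }
  if (length(d) == 3) o3 else o3[, , 1]
}

#' Object-space model optimization (OSMO) of tomographic projections
#'
#' Iterative dual-threshold scheme: starting from the (occluder-trimmed)
#' target as the float model M, each iteration forward-projects M, clips
#' the projections at zero, computes the max-normalized dose D, marks
#' under-dosed in-target voxels (\code{D < tHigh}) and over-dosed
#' out-of-target voxels (\code{D > tLow}, occluder interior excluded), and
#' nudges M by \code{eta} against both error populations.  Stops at the
#' iteration budget or when the error-voxel count stops improving for
#' \code{patience} iterations; the best iterate is returned.
#'
#' When \code{occlusion} is supplied the projector models the blocked rays
#' (shadow correction); withholding it reproduces the uncorrected arm.
#'
#' @param target binary matrix / 3D array (or ChannelVolume) to print.
#' @param params an \linkS4class{OsmoParams}.
#' @param occlusion optional occlusion mask (same shape as \code{target}).
#' @param angles projection angles, radians.
#' @param voxelSize voxel size, mm (for the occluder clearance trim).
#' @param occlusionClearance target voxels closer than this to an occluder
#'   are removed before optimization, mm.
#' @return list with \code{projections} (\linkS4class{ProjectionSet}),
#'   \code{dose} (max-normalized, computed with the same occlusion given to
#'   the optimizer), \code{model}, \code{target} (trimmed), and
#'   \code{history} (error-voxel count per iteration).
#' @export
osmoOptimize <- function(target, params = osmoParams(), occlusion = NULL,
                         angles = seq(0, 2 * pi, length.out = 361)[-361],
                         voxelSize = 1, occlusionClearance = 0.1) {
  tgt <- asVolumeArray(target) > 0
  occ <- asMaskArray(occlusion, dim(tgt))
  if (!is.null(occ)) {
    occL <- occ > 0
    trim <- dilateMask(occL, occlusionClearance / voxelSize)
    tgt <- tgt & !trim
    forbid <- occL
  } else {
    forbid <- array(FALSE, dim(tgt))
  }
  if (!any(tgt)) stop("empty target after occluder trim")
  nz <- dim(tgt)[3]
  nu <- dim(tgt)[1]
  proj <- array(0, c(nu, length(angles), nz))
  doseA <- array(0, dim(tgt))
  model <- array(0, dim(tgt))
  histories <- vector("list", nz)
  for (k in seq_len(nz)) {
    tk <- tgt[, , k]
    if (!any(tk)) {
      histories[[k]] <- integer(0)
      next
    }
    ok <- if (is.null(occ)) NULL else occ[, , k]
    fk <- forbid[, , k]
    M <- tk * 1
    if (params@init == "backprojection") {
      P0 <- pmax(cpp_project_slice(M, angles, ok, 1), 0)
      M <- cpp_dose_slice(P0, angles, ok, nu, dim(tk)[2], 1, 0)
      M <- M / max(M)
    }
    best <- list(err = Inf)
    stall <- 0L
    hist <- integer(0)
    for (it in seq_len(params@maxIters)) {
      P <- pmax(cpp_project_slice(M, angles, ok, 1), 0)
      D <- cpp_dose_slice(P, angles, ok, nu, dim(tk)[2], 1, 0)
      mx <- max(D)
      if (mx > 0) D <- D / mx
      under <- tk & (D < params@tHigh)
      over <- !tk & !fk & (D > params@tLow)
      err <- sum(under) + sum(over)
      hist <- c(hist, err)
      if (err < best$err) {
        best <- list(err = err, M = M, P = P, D = D, mx = mx)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= params@patience) break
      }
      M <- M + params@eta * (under - over)
    }
    # harmonize slices: scale each slice's projections by its dose maximum
    # (per-slice exposure scaling, as a grayscale projector would) so the
    # accumulated 3D dose carries one consistent gelation scale
    proj[, , k] <- if (best$mx > 0) best$P / best$mx else best$P
    doseA[, , k] <- best$D
    model[, , k] <- best$M
    histories[[k]] <- hist
  }
  history <- if (nz == 1) histories[[1]] else histories
  list(projections = new("ProjectionSet", values = proj, angles = angles,
                         pitch = 1),
       dose = doseA, model = model, target = tgt, history = history)
}

#' Binarize a normalized dose volume
#'
#' Fixed threshold, or the threshold from a 64-point sweep maximizing the
#' Jaccard index against a target (the in-silico analogue of stopping the
#' print at a sufficient dose accumulation).
#'
#' @param dose normalized dose (array, matrix or \linkS4class{DoseVolume}).
#' @param strategy \code{"fixed"} or \code{"best_jaccard"}.
#' @param threshold fixed threshold.
#' @param target binary target for the Jaccard sweep.
#' @param exclude optional logical mask of voxels ignored by the sweep
#'   (e.g. occluders).
#' @param nSweep number of thresholds swept.
#' @return logical array; the chosen threshold is attached as attribute
#'   \code{"threshold"}.
#' @export
binarizeDose <- function(dose, strategy = c("fixed", "best_jaccard"),
                         threshold = 0.5, target = NULL, exclude = NULL,
                         nSweep = 64) {
  strategy <- match.arg(strategy)
  d <- asVolumeArray(if (is(dose, "DoseVolume")) dose@dose else dose)
  if (strategy == "fixed") {
    out <- d >= threshold
    attr(out, "threshold") <- threshold
    return(out)
  }
  if (is.null(target)) stop("best_jaccard needs a target")
  tgt <- array(asVolumeArray(target) > 0, dim(d))
  dm <- max(d)
  ths <- seq_len(nSweep) / (nSweep + 1) * dm
  keep <- if (is.null(exclude)) TRUE else !array(asVolumeArray(exclude) > 0,
                                                 dim(d))
  tk <- tgt & keep
  best <- -1
  bestTh <- ths[1]
  for (th in ths) {
    b <- (d >= th) & keep
    j <- jaccard(b, tk)
    if (j > best) {
      best <- j
      bestTh <- th
    }
  }
  out <- d >= bestTh
  attr(out, "threshold") <- bestTh
  attr(out, "jaccard") <- best
  out
}

#' Single-projection (FLight) exposure
#'
#' Extrudes the binary pattern along the beam axis from the entry side over
#' \code{depthFraction} of the traversal depth, producing the long aligned
#' filament structures of single-projection exposure.
#'
#' @param pattern a \linkS4class{FLightPattern}.
#' @param grid a \linkS4class{VoxelGrid}; the pattern pixels are taken at
#'   the grid's voxel pitch.
#' @return logical 3D array of crosslinked voxels.
#' @export
flightExpose <- function(pattern, grid) {
  d <- grid@dim
  img <- pattern@image
  if (nrow(img) > d[1] || ncol(img) > d[3])
    stop("pattern does not fit the grid cross-section")
  th <- pattern@angle
  nDepth <- max(d[1], d[2])
  maxS <- floor(pattern@depthFraction * nDepth)
  cx <- (d[1] - 1) / 2
  cy <- (d[2] - 1) / 2
  u0 <- (nrow(img) - 1) / 2
  ix <- seq_len(d[1]) - 1
  iy <- seq_len(d[2]) - 1
  X <- outer(ix - cx, rep(1, d[2]))
  Y <- outer(rep(1, d[1]), iy - cy)
  U <- round(-X * sin(th) + Y * cos(th) + u0) + 1
  S <- X * cos(th) + Y * sin(th) + (nDepth - 1) / 2 # entry side at s = 0
  sOK <- S >= -0.5 & S < maxS - 0.5
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    if (k > ncol(img)) break
    col <- img[, k]
    hit <- sOK & U >= 1 & U <= nrow(img)
    hit[hit] <- col[U[hit]]
    out[, , k] <- hit
  }
  out
}

#' Detector coordinates of a rotating point (telecentric projection)
#'
#' Used to keep a thin beam on a tracked particle as the vial rotates:
#' \code{u = -x sin(theta) + y cos(theta)}, \code{v = z}.
#'
#' @param point (x, y, z), mm.
#' @param theta vial angle(s), radians.
#' @return matrix with columns \code{u}, \code{v}, mm.
#' @export
pointBeamCoords <- function(point, theta) {
  cbind(u = -point[1] * sin(theta) + point[2] * cos(theta),
        v = rep(point[3], length(theta)))
}
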
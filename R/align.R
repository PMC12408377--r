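# Rigid auto-alignment of a reference model to a scanned point cloud.

#' Sample points uniformly inside a watertight mesh volume
#'
#' Rejection sampling in the bounding box with a ray-parity inside test,
#' emulating the dense random reference cloud drawn inside a reference
#' model before registration.
#'
#' @param mesh a watertight \linkS4class{TriMesh}.
#' @param n number of points.
#' @param seed integer seed.
#' @return A \linkS4class{PointCloud}.
#' @export
sampleVolumePoints <- function(mesh, n, seed = 0L) {
  if (!isWatertight(mesh)) stop("mesh is not watertight")
  lo <- apply(mesh@vertices, 2, min)
  hi <- apply(mesh@vertices, 2, max)
  withSeed(seed, {
    got <- matrix(0, 0, 3)
    while (nrow(got) < n) {
      m <- max(2 * (n - nrow(got)), 1000)
      cand <- cbind(stats::runif(m, lo[1], hi[1]),
                    stats::runif(m, lo[2], hi[2]),
                    stats::runif(m, lo[3], hi[3]))
      inside <- cpp_points_in_mesh(cand, mesh@vertices, mesh@faces)
      got <- rbind(got, cand[inside, , drop = FALSE])
    }
    pointCloud(got[seq_len(n), , drop = FALSE])
  })
}

#' Apply a rigid transform
#'
#' Vertices map as \code{v -> R v + t}; topology is unchanged.  Composing
#' with the inverse transform restores the input to numerical precision.
#'
#' @param x a \linkS4class{TriMesh}, \linkS4class{PointCloud} or N x 3
#'   matrix.
#' @param transform a \linkS4class{RigidTransform}.
#' @return the transformed object, same type as \code{x}.
#' @export
transformGeometry <- function(x, transform) {
  ap <- function(p) t(transform@rotation %*% t(p) + transform@translation)
  if (is(x, "TriMesh")) {
    triMesh(ap(x@vertices), x@faces)
  } else if (is(x, "PointCloud")) {
    pointCloud(ap(x@points), x@intensity, channel = x@channel,
               sampleVolume = x@sampleVolume)
  } else {
    ap(as.matrix(x))
  }
}

#' Invert a rigid transform
#' @param transform a \linkS4class{RigidTransform}.
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  rigidTransform(Rt, -as.numeric(Rt %*% transform@translation))
}

#' Compose two rigid transforms (\code{a} applied after \code{b})
#' @param a,b \linkS4class{RigidTransform} objects.
#' @export
composeTransforms <- function(a, b) {
  rigidTransform(a@rotation %*% b@rotation,
                 as.numeric(a@rotation %*% b@translation) + a@translation)
}

# least-squares rigid fit (orthogonal decomposition / Kabsch)
kabsch <- function(moving, target) {
  mc <- colMeans(moving)
  tc <- colMeans(target)
  H <- crossprod(sweep(moving, 2, mc), sweep(target, 2, tc))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigidTransform(R, tc - as.numeric(R %*% mc))
}

# the 24 rotations of the octahedral group (signed permutation matrices,
# det +1) used as deterministic restart initializations
octahedralRotations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) for (sx in c(-1, 1)) for (sy in c(-1, 1))
    for (sz in c(-1, 1)) {
      R <- diag(c(sx, sy, sz))[, p]
      if (abs(det(R) - 1) < 1e-12) out[[length(out) + 1]] <- R
    }
  out
}

#' Iterative closest point rigid registration
#'
#' Aligns the moving reference cloud to the fixed scanned cloud by
#' alternating nearest-neighbour correspondence with a trimmed
#' least-squares rigid fit (worst \code{trim} fraction of matches dropped
#' each iteration, for robustness to partial overlap).  If the identity
#' start does not reach \code{acceptGate}, 24 deterministic octahedral
#' rotation restarts (about the cloud centroid) are tried and the best kept.
#'
#' @param pRef moving reference \linkS4class{PointCloud} (or matrix).
#' @param pScan fixed scanned \linkS4class{PointCloud} (or matrix).
#' @param maxIter iteration budget per start.
#' @param tol convergence tolerance on the rmse change, mm.
#' @param trim fraction of worst correspondences discarded.
#' @param acceptGate rmse (mm) below which the identity start is accepted
#'   without restarts; default 2 per cent of the scan bounding-box diagonal.
#' @return An \linkS4class{AlignmentResult}.
#' @export
icpRegister <- function(pRef, pScan, maxIter = 50, tol = 1e-6, trim = 0.1,
                        acceptGate = NULL) {
  ref <- if (is(pRef, "PointCloud")) pRef@points else as.matrix(pRef)
  scan <- if (is(pScan, "PointCloud")) pScan@points else as.matrix(pScan)
  if (nrow(ref) < 3 || nrow(scan) < 3)
    stop("both clouds need at least 3 points")
  for (m in list(ref, scan)) {
    ev <- eigen(stats::cov(m), symmetric = TRUE, only.values = TRUE)$values
    if (ev[2] <= 1e-12 * max(ev[1], 1))
      stop("degenerate (collinear) geometry")
  }
  if (is.null(acceptGate)) {
    diag_ <- sqrt(sum((apply(scan, 2, max) - apply(scan, 2, min))^2))
    acceptGate <- 0.02 * diag_
  }
  runFrom <- function(init) {
    Tcur <- init
    history <- numeric(0)
    nKeep <- max(3, floor(nrow(ref) * (1 - trim)))
    converged <- FALSE
    for (it in seq_len(maxIter)) {
      moved <- transformGeometry(ref, Tcur)
      nn <- cpp_nn1(moved, scan)
      keep <- order(nn$distance)[seq_len(nKeep)]
      Tcur <- kabsch(ref[keep, , drop = FALSE],
                     scan[nn$index[keep], , drop = FALSE])
      moved <- transformGeometry(ref[keep, , drop = FALSE], Tcur)
      rmse <- sqrt(mean(rowSums(
        (moved - scan[nn$index[keep], , drop = FALSE])^2)))
      history <- c(history, rmse)
      if (it > 1 && abs(history[it - 1] - rmse) < tol) {
        converged <- TRUE
        break
      }
    }
    list(transform = Tcur, rmse = rmse, iterations = it,
         converged = converged, history = history)
  }
  best <- runFrom(rigidTransform())
  if (best$rmse > acceptGate) {
    ctr <- colMeans(ref)
    for (R in octahedralRotations()) {
      init <- rigidTransform(R, as.numeric(ctr - R %*% ctr))
      cand <- runFrom(init)
      if (cand$rmse < best$rmse) best <- cand
      if (best$rmse <= acceptGate) break
    }
  }
  new("AlignmentResult", transform = best$transform, rmse = best$rmse,
      iterations = as.integer(best$iterations), converged = best$converged,
      history = best$history)
}
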
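# Shared fixtures and independent oracles used across the suite.

# brute-force DBSCAN by explicit density reachability (O(n^2)); the
# independent oracle for the grid-hashed implementation
bruteDbscan <- function(pts, eps, minPts) {
  n <- nrow(pts)
  D <- as.matrix(stats::dist(pts))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= minPts
  label <- rep(0L, n)
  cl <- 0L
  visited <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (visited[i] || !core[i]) next
    cl <- cl + 1L
    queue <- i
    visited[i] <- TRUE
    label[i] <- cl
    while (length(queue)) {
      p <- queue[1]
      queue <- queue[-1]
      if (!core[p]) next
      for (q in nb[[p]]) {
        if (label[q] == 0L) label[q] <- cl
        if (!visited[q]) {
          visited[q] <- TRUE
          queue <- c(queue, q)
        }
      }
    }
  }
  label
}

# brute-force Otsu threshold over a fixed-width histogram
bruteOtsu <- function(x, levels = 256) {
  rng <- range(x)
  br <- seq(rng[1], rng[2], length.out = levels + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (br[-1] + br[-(levels + 1)]) / 2
  best <- -Inf
  th <- mids[1]
  for (k in 1:(levels - 1)) {
    w0 <- sum(p[1:k])
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(p[1:k] * mids[1:k]) / w0
    m1 <- sum(p[(k + 1):levels] * mids[(k + 1):levels]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) {
      best <- v
      th <- br[k + 1]
    }
  }
  th
}

# uniform point cloud over the voxel centres inside a sphere
sphereVoxelCloud <- function(center, radius, spacing) {
  g <- seq(-radius - spacing, radius + spacing, by = spacing)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- pts[rowSums(pts^2) <= radius^2, , drop = FALSE]
  sweep(pts, 2, center, "+")
}

# rotation matrix about a unit axis
rotAbout <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# unit sphere mesh fixture at modest resolution
unitSphereMesh <- function(radius = 1, voxel = 0.05) {
  n <- as.integer(ceiling((2 * radius + 0.4) / voxel))
  grid <- voxelGrid(c(n, n, n), voxel,
                    origin = rep(-(radius + 0.2), 3))
  f <- tomoprint:::evalSdfOnGrid(function(p)
    sqrt(rowSums(p^2)) - radius, grid)
  extractMesh(f, grid)
}
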
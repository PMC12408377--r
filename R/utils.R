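# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.  All randomized generators route their draws through this.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

vnorm <- function(v) sqrt(sum(v^2))

unitVec <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("zero vector cannot be normalized")
  v / n
}

# uniform point in a disc of radius r (polar inverse-CDF; uses 2 draws)
runifDisc <- function(r) {
  a <- stats::runif(1, 0, 2 * pi)
  d <- r * sqrt(stats::runif(1))
  c(d * cos(a), d * sin(a))
}

# polyline arclengths (cumulative, starting at 0)
polylineArclength <- function(points) {
  if (nrow(points) < 2) return(0)
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  c(0, cumsum(seg))
}

# lateral (side) surface area of a discretized tube: 2*pi * integral r ds
tubeLateralArea <- function(points, radii) {
  if (nrow(points) < 2) return(0)
  ds <- sqrt(rowSums((points[-1, , drop = FALSE] -
                      points[-nrow(points), , drop = FALSE])^2))
  rbar <- (radii[-1] + radii[-length(radii)]) / 2
  2 * pi * sum(rbar * ds)
}

# flatten a TubeGraph into an n x 8 segment matrix for SDF voxelization
tubeSegments <- function(graph) {
  segs <- lapply(graph@edges, function(e) {
    p <- e$points
    r <- e$radii
    n <- nrow(p)
    if (n < 2) return(NULL)
    cbind(p[-n, , drop = FALSE], p[-1, , drop = FALSE], r[-n], r[-1])
  })
  do.call(rbind, segs)
}
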
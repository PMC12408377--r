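# Computer-vision routines: polar scan -> point cloud -> registered features.

#' Convert a polar scan to a Cartesian point cloud
#'
#' Each pixel above zero (or every pixel when \code{keepZero = TRUE})
#' becomes a point at \code{(r cos theta, r sin theta, z)} with signed
#' radius \code{r = (u - u0) * pixelSize}; intensity is copied.  The
#' nonuniform cylindrical sample volume of each pixel
#' (\code{pixel^2 * max(|r|, pixel/2) * pi / nSections}, which also folds in
#' the double coverage of a \code{2*pi} sweep) is recorded per point and is
#' used by the volume-based radius estimator.
#'
#' @param scan a \linkS4class{PolarScan}.
#' @param keepZero keep zero-intensity pixels as points.
#' @return A \linkS4class{PointCloud}.
#' @export
polarToCartesian <- function(scan, keepZero = FALSE) {
  d <- dim(scan@images)
  nu <- d[1]; nv <- d[2]; ns <- d[3]
  rr <- (seq_len(nu) - scan@axisColumn) * scan@pixelSize
  zz <- scan@zOrigin + (seq_len(nv) - 0.5) * scan@pixelSize
  pts <- vector("list", ns)
  ints <- vector("list", ns)
  vols <- vector("list", ns)
  dtheta <- pi / ns # per-plane coverage: theta_total / ns / (theta_total/pi)
  for (k in seq_len(ns)) {
    img <- scan@images[, , k]
    sel <- if (keepZero) rep(TRUE, length(img)) else img > 0
    if (!any(sel)) next
    iu <- ((which(sel) - 1) %% nu) + 1
    iv <- ((which(sel) - 1) %/% nu) + 1
    r <- rr[iu]
    th <- scan@angles[k]
    pts[[k]] <- cbind(r * cos(th), r * sin(th), zz[iv])
    ints[[k]] <- img[sel]
    vols[[k]] <- scan@pixelSize^2 * pmax(abs(r), scan@pixelSize / 2) * dtheta
  }
  pts <- do.call(rbind, pts)
  if (is.null(pts)) pts <- matrix(0, 0, 3)
  pointCloud(pts, intensity = unlist(ints) %||% numeric(0),
             channel = scan@channel,
             sampleVolume = unlist(vols) %||% numeric(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Isolate foreground points by intensity thresholding
#'
#' Keeps points with intensity at or above a fixed threshold, or above the
#' Otsu threshold of the intensity histogram (via \code{EBImage::otsu}).
#' Point ordering is preserved.
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @param method \code{"otsu"} or \code{"fixed"}.
#' @param threshold fixed threshold (required for \code{method = "fixed"}).
#' @return the foreground \linkS4class{PointCloud}; empty with a warning if
#'   everything is background or the histogram is degenerate.
#' @export
isolateForeground <- function(cloud, method = c("otsu", "fixed"),
                              threshold = NULL) {
  method <- match.arg(method)
  if (!length(cloud)) stop("empty point cloud")
  ints <- cloud@intensity
  if (method == "fixed") {
    if (is.null(threshold)) stop("fixed method needs a threshold")
    th <- threshold
  } else {
    rng <- range(ints)
    if (diff(rng) == 0) {
      warning("degenerate (uniform) intensity histogram; no foreground")
      return(subsetCloud(cloud, logical(length(ints))))
    }
    x <- (ints - rng[1]) / diff(rng)
    th <- rng[1] + diff(rng) *
      EBImage::otsu(matrix(x, nrow = 1), range = c(0, 1), levels = 256)
  }
  keep <- ints >= th
  if (!any(keep)) warning("all points fall below the threshold")
  out <- subsetCloud(cloud, keep)
  attr(out, "threshold") <- th
  out
}

subsetCloud <- function(cloud, keep) {
  pointCloud(cloud@points[keep, , drop = FALSE], cloud@intensity[keep],
             channel = cloud@channel,
             sampleVolume = if (length(cloud@sampleVolume))
               cloud@sampleVolume[keep] else numeric(0))
}

#' Detect features by DBSCAN clustering
#'
#' Density-based clustering of the cloud; noise points are excluded and one
#' feature is created per cluster with an intensity-weighted centroid.
#' Cluster labels (0 = noise) are stored in the provenance for downstream
#' per-cluster estimators.
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @param eps DBSCAN neighbourhood radius, mm (default 3x the point
#'   spacing is a good choice for rasterized/scanned solids).
#' @param minSamples DBSCAN core-point threshold.
#' @return A \linkS4class{FeatureSet}.
#' @export
detectClusters <- function(cloud, eps, minSamples = 10) {
  stopifnot(eps > 0)
  n <- length(cloud)
  labels <- if (n) cpp_dbscan(cloud@points, eps, as.integer(minSamples))
            else integer(0)
  ids <- sort(unique(labels[labels > 0]))
  rows <- lapply(seq_along(ids), function(i) {
    sel <- labels == ids[i]
    w <- cloud@intensity[sel]
    # polar sampling is denser near the axis; weighting by the per-point
    # sample volume removes the resulting centroid bias
    if (length(cloud@sampleVolume)) w <- w * cloud@sampleVolume[sel]
    if (sum(w) == 0) w <- rep(1, sum(sel))
    ctr <- colSums(cloud@points[sel, , drop = FALSE] * w) / sum(w)
    data.frame(id = i - 1L, x = ctr[1], y = ctr[2], z = ctr[3],
               radius = NA_real_, channel = cloud@channel,
               ax = NA_real_, ay = NA_real_, az = NA_real_,
               pitch = NA_real_, yaw = NA_real_,
               nPoints = sum(sel), lowConfidence = FALSE, ambiguous = FALSE)
  })
  feats <- if (length(rows)) do.call(rbind, rows) else emptyFeatures()
  new("FeatureSet", features = feats,
      provenance = list(eps = eps, minSamples = minSamples, labels = labels,
                        clusterIds = ids, channel = cloud@channel))
}

emptyFeatures <- function() {
  data.frame(id = integer(0), x = numeric(0), y = numeric(0), z = numeric(0),
             radius = numeric(0), channel = character(0), ax = numeric(0),
             ay = numeric(0), az = numeric(0), pitch = numeric(0),
             yaw = numeric(0), nPoints = integer(0),
             lowConfidence = logical(0), ambiguous = logical(0))
}

clusterMembers <- function(featureSet, cloud, id) {
  labs <- featureSet@provenance$labels
  ids <- featureSet@provenance$clusterIds
  which(labs == ids[id + 1L])
}

#' Estimate equivalent-sphere radii of detected features
#'
#' Volume-based estimator: the cluster volume is the number of member points
#' times the sample volume per point (or the sum of the per-point sample
#' volumes recorded by \code{\link{polarToCartesian}}), and
#' \code{r = (3V / 4 pi)^(1/3)}.  Near-degenerate (planar or tiny) clusters
#' are flagged low-confidence.
#'
#' @param featureSet a \linkS4class{FeatureSet} from
#'   \code{\link{detectClusters}}.
#' @param cloud the clustered \linkS4class{PointCloud}.
#' @param pointSpacing sample spacing, mm; used as \code{pointSpacing^3} per
#'   point when the cloud has no per-point sample volumes.
#' @return the \linkS4class{FeatureSet} with \code{radius} (and
#'   \code{lowConfidence}) filled in.
#' @export
estimateRadius <- function(featureSet, cloud, pointSpacing = NULL) {
  feats <- featureSet@features
  for (i in seq_len(nrow(feats))) {
    mem <- clusterMembers(featureSet, cloud, feats$id[i])
    V <- if (length(cloud@sampleVolume)) {
      sum(cloud@sampleVolume[mem])
    } else {
      if (is.null(pointSpacing))
        stop("pointSpacing needed for clouds without per-point sample volumes")
      length(mem) * pointSpacing^3
    }
    feats$radius[i] <- (3 * V / (4 * pi))^(1 / 3)
    low <- length(mem) < 4
    if (!low) {
      ev <- eigen(stats::cov(cloud@points[mem, , drop = FALSE]),
                  symmetric = TRUE, only.values = TRUE)$values
      sp <- pointSpacing %||%
        (if (length(cloud@sampleVolume))
           stats::median(cloud@sampleVolume[mem])^(1 / 3) else 0)
      low <- ev[3] < (sp / 4)^2
    }
    feats$lowConfidence[i] <- low
  }
  new("FeatureSet", features = feats, provenance = featureSet@provenance)
}

#' Estimate pillar orientations by principal component analysis
#'
#' The first principal axis of each cluster (typically from a reflectance
#' scan of opaque pillars) gives its orientation; pitch is the tilt from
#' vertical (\code{acos(a_z)}, degrees) and yaw the azimuth of the tilt
#' (\code{atan2(a_x, -a_y)}), with the axis signed so \code{a_z >= 0}.
#' Orientation is withheld for clusters with elongation ratio
#' (sqrt of first/second eigenvalue) below \code{minElongation}.
#'
#' @param featureSet a \linkS4class{FeatureSet}.
#' @param cloud the clustered \linkS4class{PointCloud}.
#' @param minElongation minimum elongation ratio for a trusted axis.
#' @return the \linkS4class{FeatureSet} with \code{ax, ay, az, pitch, yaw}.
#' @export
estimatePillarAxes <- function(featureSet, cloud, minElongation = 2) {
  feats <- featureSet@features
  for (i in seq_len(nrow(feats))) {
    mem <- clusterMembers(featureSet, cloud, feats$id[i])
    if (length(mem) < 3) next
    ev <- eigen(stats::cov(cloud@points[mem, , drop = FALSE]),
                symmetric = TRUE)
    elong <- sqrt(ev$values[1] / max(ev$values[2], .Machine$double.eps))
    if (!is.finite(elong) || elong < minElongation) next # sphere-like
    a <- ev$vectors[, 1]
    if (a[3] < 0) a <- -a
    feats$ax[i] <- a[1]; feats$ay[i] <- a[2]; feats$az[i] <- a[3]
    feats$pitch[i] <- acos(min(1, max(-1, a[3]))) * 180 / pi
    feats$yaw[i] <- atan2(a[1], -a[2]) * 180 / pi
  }
  new("FeatureSet", features = feats, provenance = featureSet@provenance)
}

#' Merge per-channel feature sets with spectral classification
#'
#' Each feature keeps the label of the channel in which it was detected;
#' features co-detected within \code{matchRadius} in several channels are
#' merged into one feature flagged \code{ambiguous}.
#'
#' @param featureSets list of per-channel \linkS4class{FeatureSet}s.
#' @param matchRadius co-detection radius, mm.
#' @return merged \linkS4class{FeatureSet}.
#' @export
classifySpectral <- function(featureSets, matchRadius = 0.2) {
  stopifnot(length(featureSets) >= 1)
  all <- do.call(rbind, lapply(featureSets, function(fs) fs@features))
  if (!nrow(all)) {
    return(new("FeatureSet", features = emptyFeatures(),
               provenance = list(matchRadius = matchRadius)))
  }
  n <- nrow(all)
  src <- rep(seq_along(featureSets),
             vapply(featureSets, function(fs) nrow(fs@features), integer(1)))
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (src[i] == src[j]) next
    d <- sqrt(sum((all[i, c("x", "y", "z")] - all[j, c("x", "y", "z")])^2))
    if (d <= matchRadius) parent[find(j)] <- find(i)
  }
  groups <- vapply(seq_len(n), find, integer(1))
  rows <- lapply(unique(groups), function(g) {
    sub <- all[groups == g, , drop = FALSE]
    out <- sub[1, , drop = FALSE]
    if (nrow(sub) > 1) {
      out$x <- mean(sub$x); out$y <- mean(sub$y); out$z <- mean(sub$z)
      out$ambiguous <- TRUE
    }
    out
  })
  feats <- do.call(rbind, rows)
  feats$id <- seq_len(nrow(feats)) - 1L
  rownames(feats) <- NULL
  new("FeatureSet", features = feats,
      provenance = list(matchRadius = matchRadius,
                        channels = vapply(featureSets, function(fs)
                          fs@provenance$channel %||% NA_character_,
                          character(1))))
}
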
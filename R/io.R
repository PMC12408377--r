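# File formats: STL and PLY meshes/clouds, CSV clouds, TIFF volumes,
# YAML scenes/configs, JSON features/transforms/reports.

#' Write a triangle mesh to STL
#'
#' @param mesh a \linkS4class{TriMesh}.
#' @param path output file.
#' @param binary binary (default) or ASCII STL.
#' @export
writeSTL <- function(mesh, path, binary = TRUE) {
  V <- mesh@vertices
  Fc <- mesh@faces
  a <- V[Fc[, 1], , drop = FALSE]
  b <- V[Fc[, 2], , drop = FALSE]
  cc <- V[Fc[, 3], , drop = FALSE]
  u <- b - a
  w <- cc - a
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  nf <- nrow(Fc)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nf), con, size = 4, endian = "little")
    tri <- matrix(0, nf, 12)
    tri[, 1:3] <- nrm
    tri[, 4:6] <- a
    tri[, 7:9] <- b
    tri[, 10:12] <- cc
    for (i in seq_len(nf)) {
      writeBin(as.numeric(tri[i, ]), con, size = 4, endian = "little")
      writeBin(raw(2), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nf)) {
      writeLines(c(sprintf("  facet normal %g %g %g", nrm[i, 1], nrm[i, 2],
                           nrm[i, 3]),
                   "    outer loop",
                   sprintf("      vertex %g %g %g", a[i, 1], a[i, 2],
                           a[i, 3]),
                   sprintf("      vertex %g %g %g", b[i, 1], b[i, 2],
                           b[i, 3]),
                   sprintf("      vertex %g %g %g", cc[i, 1], cc[i, 2],
                           cc[i, 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(path)
}

#' Read an STL file (binary or ASCII)
#'
#' Vertices are welded exactly (identical float coordinates merge), so a
#' watertight mesh round-trips watertight.
#'
#' @param path STL file.
#' @return A \linkS4class{TriMesh}.
#' @export
readSTL <- function(path) {
  head <- readBin(path, "raw", n = 512)
  isAscii <- identical(rawToChar(head[1:5]), "solid") &&
    !any(head == as.raw(0))
  if (isAscii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    nums <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x)
      as.numeric(x[2:4])))
    tris <- nums
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    readBin(con, "raw", n = 80)
    nf <- readBin(con, "integer", size = 4, endian = "little")
    tris <- matrix(0, nf * 3, 3)
    for (i in seq_len(nf)) {
      vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      readBin(con, "raw", n = 2)
      tris[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
    }
  }
  if (nrow(tris) %% 3 != 0) stop("malformed STL: triangle count broken")
  key <- paste(tris[, 1], tris[, 2], tris[, 3])
  uk <- !duplicated(key)
  ids <- match(key, key[uk])
  verts <- tris[uk, , drop = FALSE]
  faces <- matrix(ids, ncol = 3, byrow = TRUE)
  triMesh(verts, faces)
}

#' Write a point cloud to PLY (binary little-endian) or CSV
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @param path output file; format chosen by extension (.ply / .csv).
#' @export
writePointCloud <- function(cloud, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- data.frame(x = cloud@points[, 1], y = cloud@points[, 2],
                     z = cloud@points[, 3], intensity = cloud@intensity,
                     channel = cloud@channel)
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  n <- length(cloud)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply", "format binary_little_endian 1.0",
           paste("element vertex", n),
           "property float x", "property float y", "property float z",
           "property float intensity", "end_header")
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  dat <- t(cbind(cloud@points, cloud@intensity))
  writeBin(as.numeric(dat), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a point cloud from PLY or CSV
#'
#' @param path input file (.ply binary little-endian with x/y/z/intensity
#'   float properties, or .csv with x,y,z,intensity[,channel] columns).
#' @return A \linkS4class{PointCloud}.
#' @export
readPointCloud <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path)
    bad <- which(!stats::complete.cases(df[, c("x", "y", "z")]))
    if (length(bad))
      stop("malformed point cloud CSV: non-finite coordinates at line ",
           bad[1] + 1)
    return(pointCloud(as.matrix(df[, c("x", "y", "z")]),
                      intensity = df$intensity %||% rep(1, nrow(df)),
                      channel = as.character(df$channel[1] %||% "none")))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- readBinLine(con)
    hdr <- c(hdr, line)
    if (identical(line, "end_header")) break
    if (length(hdr) > 100) stop("malformed PLY: no end_header")
  }
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", hdr, value = TRUE)))
  nprop <- sum(grepl("^property float", hdr))
  dat <- readBin(con, "numeric", n = nv * nprop, size = 4,
                 endian = "little")
  m <- matrix(dat, ncol = nprop, byrow = TRUE)
  pointCloud(m[, 1:3, drop = FALSE],
             intensity = if (nprop >= 4) m[, 4] else rep(1, nv))
}

readBinLine <- function(con) {
  out <- raw(0)
  repeat {
    ch <- readBin(con, "raw", n = 1)
    if (!length(ch) || ch == as.raw(10)) break
    out <- c(out, ch)
  }
  rawToChar(out)
}

#' Write a volume to multi-page TIFF (one page per z slice, float32)
#'
#' @param x 3D array, \linkS4class{ChannelVolume}, \linkS4class{DoseVolume}
#'   or \linkS4class{OcclusionMask}.
#' @param path output file.
#' @export
writeVolumeTIFF <- function(x, path) {
  vol <- if (is(x, "ChannelVolume")) x@values
         else if (is(x, "DoseVolume")) x@dose
         else if (is(x, "OcclusionMask")) x@inside * 1
         else x
  pages <- lapply(seq_len(dim(vol)[3]), function(k) vol[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  invisible(path)
}

#' Read a multi-page TIFF volume
#'
#' @param path TIFF file.
#' @return numeric 3D array.
#' @export
readVolumeTIFF <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  arr
}

#' Serialize a scene to YAML
#'
#' @param scene a \linkS4class{Scene}.
#' @param path output file.
#' @export
writeSceneYAML <- function(scene, path) {
  prims <- lapply(scene@primitives, function(p)
    list(kind = p@kind, center = as.numeric(p@center),
         axis = as.numeric(p@axis), radius = p@radius,
         tubeRadius = p@tubeRadius, halfLength = p@halfLength,
         channel = p@channel, opaque = p@opaque))
  yaml::write_yaml(list(vialRadius = scene@vialRadius,
                        vialHeight = scene@vialHeight,
                        seed = scene@seed, primitives = prims), path)
  invisible(path)
}

#' Read a scene from YAML
#' @param path YAML file written by \code{\link{writeSceneYAML}}.
#' @return A \linkS4class{Scene}.
#' @export
readSceneYAML <- function(path) {
  y <- yaml::read_yaml(path)
  prims <- lapply(y$primitives, function(p)
    new("Primitive", kind = p$kind, center = as.numeric(p$center),
        axis = as.numeric(p$axis), radius = as.numeric(p$radius),
        tubeRadius = as.numeric(p$tubeRadius),
        halfLength = as.numeric(p$halfLength), channel = p$channel,
        opaque = p$opaque))
  scene(prims, y$vialRadius, y$vialHeight, y$seed)
}

#' Serialize a feature set to JSON (with provenance)
#' @param featureSet a \linkS4class{FeatureSet}.
#' @param path output file.
#' @export
writeFeaturesJSON <- function(featureSet, path) {
  prov <- featureSet@provenance
  prov$labels <- NULL # per-point labels are bulky scan-side state
  jsonlite::write_json(list(features = featureSet@features,
                            provenance = prov),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Serialize a rigid transform to JSON (row-major rotation + translation)
#' @param transform a \linkS4class{RigidTransform}.
#' @param path output file.
#' @export
writeTransformJSON <- function(transform, path) {
  jsonlite::write_json(list(rotation = as.numeric(t(transform@rotation)),
                            translation = transform@translation,
                            order = "row-major", units = "mm"),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a rigid transform from JSON
#' @param path JSON file written by \code{\link{writeTransformJSON}}.
#' @return A \linkS4class{RigidTransform}.
#' @export
readTransformJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigidTransform(matrix(j$rotation, 3, 3, byrow = TRUE), j$translation)
}

#' Serialize a tube graph to JSON (nodes, polylines, radius profiles)
#' @param graph a \linkS4class{TubeGraph}.
#' @param path output file.
#' @export
writeTubeGraphJSON <- function(graph, path) {
  edges <- lapply(graph@edges, function(e)
    list(points = unname(as.matrix(e$points)), radii = e$radii,
         role = e$role))
  prov <- graph@provenance
  prov <- prov[!vapply(prov, is.function, logical(1))]
  jsonlite::write_json(list(edges = edges, provenance = prov), path,
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Write a metric report to CSV (runs) and JSON (aggregate + provenance)
#' @param report a \linkS4class{MetricReport}.
#' @param stem output path stem; writes \code{<stem>.csv} and
#'   \code{<stem>.json}.
#' @export
writeMetricReport <- function(report, stem) {
  utils::write.csv(report@runs, paste0(stem, ".csv"), row.names = FALSE)
  prov <- report@provenance
  prov <- prov[!vapply(prov, isS4, logical(1))]
  jsonlite::write_json(list(aggregate = report@aggregate, provenance = prov),
                       paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
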
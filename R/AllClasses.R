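#' @import methods
NULL

CHANNEL_LABELS <- c("none", "ch450", "ch532", "ch650")

# ---------------------------------------------------------------------------
# Voxel grids and volumes
# ---------------------------------------------------------------------------

#' Isotropic voxel grid
#'
#' Right-handed frame with the z axis along the rotation axis of the vial.
#' Voxel \code{(i, j, k)} (0-based) is centred at
#' \code{origin + (index + 0.5) * voxelSize}.
#'
#' @slot dim integer vector (nx, ny, nz).
#' @slot voxelSize isotropic voxel edge length in mm.
#' @slot origin position of the grid corner in mm.
#' @export
setClass("VoxelGrid", representation(dim = "integer", voxelSize = "numeric",
                                     origin = "numeric"),
         validity = function(object) {
           if (length(object@dim) != 3L || any(object@dim < 1L))
             return("dim must be three positive integers")
           if (length(object@voxelSize) != 1L || object@voxelSize <= 0)
             return("voxelSize must be a single positive number")
           if (length(object@origin) != 3L) return("origin must have length 3")
           TRUE
         })

#' Create a voxel grid
#'
#' @param dim grid dimensions (nx, ny, nz).
#' @param voxelSize voxel edge length, mm.
#' @param origin grid corner, mm; defaults to centring the grid on the
#'   origin in x/y with z starting at 0.
#' @return A \linkS4class{VoxelGrid}.
#' @examples
#' voxelGrid(c(64, 64, 64), 0.05)
#' @export
voxelGrid <- function(dim, voxelSize,
                      origin = c(-dim[1] * voxelSize / 2,
                                 -dim[2] * voxelSize / 2, 0)) {
  new("VoxelGrid", dim = as.integer(dim), voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' Voxel-centre coordinates along one axis
#' @param grid a \linkS4class{VoxelGrid}.
#' @param axis 1, 2 or 3.
#' @return numeric vector of centre coordinates, mm.
#' @export
gridCoords <- function(grid, axis) {
  grid@origin[axis] + (seq_len(grid@dim[axis]) - 0.5) * grid@voxelSize
}

# mm -> fractional 0-based voxel index
mmToIndex <- function(grid, pts) {
  sweep(pts, 2, grid@origin, "-") / grid@voxelSize - 0.5
}

#' Per-channel intensity volume
#' @slot grid the \linkS4class{VoxelGrid}.
#' @slot channel fluorophore channel label.
#' @slot values nonnegative 3D array.
#' @export
setClass("ChannelVolume", representation(grid = "VoxelGrid",
                                         channel = "character",
                                         values = "array"),
         validity = function(object) {
           if (!identical(dim(object@values), as.integer(object@grid@dim)))
             return("values dimensions do not match the grid")
           if (any(object@values < 0)) return("values must be nonnegative")
           TRUE
         })

#' Boolean occlusion mask (opaque structures)
#' @slot grid the \linkS4class{VoxelGrid}.
#' @slot inside logical 3D array, TRUE inside opaque material.
#' @export
setClass("OcclusionMask", representation(grid = "VoxelGrid",
                                         inside = "array"),
         validity = function(object) {
           if (!identical(dim(object@inside), as.integer(object@grid@dim)))
             return("mask dimensions do not match the grid")
           if (!is.logical(object@inside)) return("inside must be logical")
           TRUE
         })

# ---------------------------------------------------------------------------
# Scenes
# ---------------------------------------------------------------------------

#' Geometric primitive of a synthetic scene
#'
#' Kinds: \code{sphere} (radius), \code{torus} (radius = ring centreline
#' radius, tubeRadius = tube radius), \code{capsule} (tubeRadius = capsule
#' radius, halfLength along axis).  \code{channel} is the fluorophore proxy
#' label; \code{opaque} marks occluding (non-fluorescent-required) material.
#'
#' @export
setClass("Primitive", representation(kind = "character", center = "numeric",
                                     axis = "numeric", radius = "numeric",
                                     tubeRadius = "numeric",
                                     halfLength = "numeric",
                                     channel = "character",
                                     opaque = "logical"),
         prototype(axis = c(0, 0, 1), radius = 0, tubeRadius = 0,
                   halfLength = 0, channel = "none", opaque = FALSE),
         validity = function(object) {
           if (!object@kind %in% c("sphere", "torus", "capsule", "mesh"))
             return("unknown primitive kind")
           if (object@kind == "sphere" && object@radius <= 0)
             return("sphere radius must be > 0")
           if (object@kind %in% c("torus", "capsule") &&
               object@tubeRadius <= 0)
             return("tube radius must be > 0")
           if (!object@channel %in% CHANNEL_LABELS)
             return("unknown channel label")
           if (abs(sum(object@axis^2) - 1) > 1e-6)
             return("axis must be unit-norm")
           TRUE
         })

#' @rdname Primitive-class
#' @param center sphere centre, mm.
#' @param radius sphere radius, mm.
#' @param channel channel label.
#' @param opaque logical.
#' @export
spherePrimitive <- function(center, radius, channel = "none", opaque = FALSE) {
  new("Primitive", kind = "sphere", center = as.numeric(center),
      radius = as.numeric(radius), channel = channel, opaque = opaque)
}

#' @rdname Primitive-class
#' @param ringRadius torus centreline radius, mm.
#' @param tubeRadius torus tube radius, mm.
#' @export
torusPrimitive <- function(center, ringRadius, tubeRadius, channel = "none",
                           opaque = FALSE) {
  new("Primitive", kind = "torus", center = as.numeric(center),
      radius = as.numeric(ringRadius), tubeRadius = as.numeric(tubeRadius),
      channel = channel, opaque = opaque)
}

#' @rdname Primitive-class
#' @param axis unit axis vector of the capsule.
#' @param halfLength half the cylinder length, mm (caps extend beyond).
#' @export
capsulePrimitive <- function(center, axis, tubeRadius, halfLength,
                             channel = "none", opaque = FALSE) {
  axis <- as.numeric(axis)
  axis <- axis / sqrt(sum(axis^2))
  new("Primitive", kind = "capsule", center = as.numeric(center), axis = axis,
      tubeRadius = as.numeric(tubeRadius), halfLength = as.numeric(halfLength),
      channel = channel, opaque = opaque)
}

#' Synthetic scene: the virtual counterpart of the resin-filled vial
#'
#' @slot primitives list of \linkS4class{Primitive}.
#' @slot vialRadius,vialHeight inner vial dimensions, mm.
#' @slot seed integer seed that fully determined any randomized construction.
#' @export
setClass("Scene", representation(primitives = "list", vialRadius = "numeric",
                                 vialHeight = "numeric", seed = "integer"),
         validity = function(object) {
           ok <- vapply(object@primitives, is, logical(1), class2 = "Primitive")
           if (!all(ok)) return("primitives must all be Primitive objects")
           TRUE
         })

#' @rdname Scene-class
#' @param primitives list of \linkS4class{Primitive}.
#' @param vialRadius,vialHeight vial dimensions, mm.
#' @param seed integer seed recorded for provenance.
#' @export
scene <- function(primitives, vialRadius = 5, vialHeight = 10, seed = 0L) {
  new("Scene", primitives = primitives, vialRadius = vialRadius,
      vialHeight = vialHeight, seed = as.integer(seed))
}

setMethod("show", "Scene", function(object) {
  kinds <- vapply(object@primitives, function(p) p@kind, character(1))
  cat("Scene:", length(object@primitives), "primitives (",
      paste(names(table(kinds)), table(kinds), collapse = ", "),
      ") in vial r =", object@vialRadius, "mm, h =", object@vialHeight,
      "mm, seed", object@seed, "\n")
})

# ---------------------------------------------------------------------------
# Scans, clouds, features
# ---------------------------------------------------------------------------

#' Polar light-sheet scan
#'
#' A stack of section images of planes through the rotation axis.  Image
#' pixel (u, v) of section k samples the volume at signed radius
#' \code{r = (u - axisColumn) * pixelSize} in the plane at angle
#' \code{angles[k]}, height \code{z = v * pixelSize} (1-based pixel indices,
#' pixel centres).
#'
#' @slot images array (nu, nv, nSections), nonnegative.
#' @slot angles section angles, radians, strictly increasing in
#'   \code{[0, thetaTotal)}.
#' @slot thetaTotal total sweep, \code{pi} (half-sweep) or \code{2*pi}.
#' @slot pixelSize pixel pitch, mm.
#' @slot axisColumn u-index of the rotation axis (numeric, 1-based).
#' @slot channel channel label.
#' @slot mode \code{"fluorescence"} or \code{"reflectance"}.
#' @slot zOrigin z of pixel v = 1, mm.
#' @export
setClass("PolarScan", representation(images = "array", angles = "numeric",
                                     thetaTotal = "numeric",
                                     pixelSize = "numeric",
                                     axisColumn = "numeric",
                                     channel = "character", mode = "character",
                                     zOrigin = "numeric"),
         prototype(zOrigin = 0),
         validity = function(object) {
           if (length(dim(object@images)) != 3L)
             return("images must be a 3D array (nu, nv, nSections)")
           if (dim(object@images)[3] != length(object@angles))
             return("number of angles must match number of sections")
           if (any(diff(object@angles) <= 0))
             return("angles must be strictly increasing")
           if (any(object@angles < 0) ||
               any(object@angles >= object@thetaTotal + 1e-12))
             return("angles must lie in [0, thetaTotal)")
           if (!object@mode %in% c("fluorescence", "reflectance"))
             return("unknown scan mode")
           TRUE
         })

setMethod("show", "PolarScan", function(object) {
  d <- dim(object@images)
  cat(sprintf("PolarScan (%s, %s): %d sections of %d x %d px, theta_total = %.3f rad, pixel %.3f mm\n",
              object@mode, object@channel, d[3], d[1], d[2],
              object@thetaTotal, object@pixelSize))
})

#' 3D point cloud in vat coordinates
#'
#' @slot points N x 3 matrix, mm.
#' @slot intensity nonnegative per-point intensity.
#' @slot channel channel label.
#' @slot sampleVolume optional per-point sample volume (mm^3) recording the
#'   nonuniform polar sampling density; length N or 0.
#' @export
setClass("PointCloud", representation(points = "matrix",
                                      intensity = "numeric",
                                      channel = "character",
                                      sampleVolume = "numeric"),
         prototype(channel = "none", sampleVolume = numeric(0)),
         validity = function(object) {
           if (ncol(object@points) != 3L) return("points must be N x 3")
           if (length(object@intensity) != nrow(object@points))
             return("intensity length must match point count")
           if (any(!is.finite(object@points)))
             return("point coordinates must be finite")
           if (length(object@sampleVolume) &&
               length(object@sampleVolume) != nrow(object@points))
             return("sampleVolume length must match point count")
           TRUE
         })

#' @rdname PointCloud-class
#' @param points N x 3 matrix, mm.
#' @param intensity per-point intensities (default 1).
#' @param channel channel label.
#' @param sampleVolume optional per-point sample volumes, mm^3.
#' @export
pointCloud <- function(points, intensity = rep(1, nrow(points)),
                       channel = "none", sampleVolume = numeric(0)) {
  points <- as.matrix(points)
  dimnames(points) <- NULL
  new("PointCloud", points = points, intensity = as.numeric(intensity),
      channel = channel, sampleVolume = as.numeric(sampleVolume))
}

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud: %d points (%s)\n", nrow(object@points),
              object@channel))
})

#' Number of points in a cloud
#' @param x a \linkS4class{PointCloud}.
#' @export
setMethod("length", "PointCloud", function(x) nrow(x@points))

#' Registered feature set
#'
#' One row per feature: \code{id} (0-based, contiguous), centroid
#' \code{x, y, z} (mm), \code{radius} (mm or NA), \code{channel},
#' axis components \code{ax, ay, az} plus \code{pitch}/\code{yaw} (degrees,
#' NA for non-elongated clusters), \code{nPoints}, \code{lowConfidence},
#' \code{ambiguous}.
#'
#' @slot features data.frame as described.
#' @slot provenance list of scan and clustering parameters.
#' @export
setClass("FeatureSet", representation(features = "data.frame",
                                      provenance = "list"),
         validity = function(object) {
           f <- object@features
           need <- c("id", "x", "y", "z", "nPoints")
           if (!all(need %in% names(f)))
             return("features must contain id, x, y, z, nPoints")
           if (nrow(f) && !identical(sort(f$id), 0:(nrow(f) - 1)))
             return("feature ids must be unique and contiguous from 0")
           TRUE
         })

#' Extract the feature table
#' @param object a \linkS4class{FeatureSet}.
#' @return data.frame of features.
#' @export
features <- function(object) object@features

setMethod("show", "FeatureSet", function(object) {
  cat(sprintf("FeatureSet: %d features\n", nrow(object@features)))
  if (nrow(object@features)) print(utils::head(object@features, 10))
})

# ---------------------------------------------------------------------------
# Generated geometry
# ---------------------------------------------------------------------------

#' Channel-network graph
#'
#' Edges are polylines with a per-arclength radius profile (constant or
#' linearly tapered between polyline vertices) and a role tag
#' (inlet, outlet, wrap, strut, coil, graze).
#'
#' @slot edges list of lists with elements \code{points} (P x 3 matrix, mm),
#'   \code{radii} (length P, mm), \code{role}.
#' @slot provenance generator name and parameters.
#' @export
setClass("TubeGraph", representation(edges = "list", provenance = "list"),
         validity = function(object) {
           for (e in object@edges) {
             if (!all(c("points", "radii", "role") %in% names(e)))
               return("each edge needs points, radii, role")
             if (nrow(e$points) != length(e$radii))
               return("radii length must match polyline length")
             if (any(e$radii <= 0)) return("radii must be > 0 along every edge")
           }
           TRUE
         })

tubeGraph <- function(edges, provenance = list()) {
  new("TubeGraph", edges = edges, provenance = provenance)
}

#' Edge list of a tube graph
#' @param graph a \linkS4class{TubeGraph}.
#' @export
tubeEdges <- function(graph) graph@edges

setMethod("show", "TubeGraph", function(object) {
  cat(sprintf("TubeGraph: %d edges (%s)\n", length(object@edges),
              paste(unique(vapply(object@edges, `[[`, character(1), "role")),
                    collapse = ", ")))
})

#' Implicit (signed-distance) model
#'
#' @slot sdf function taking an N x 3 matrix of mm coordinates and returning
#'   signed distances (negative inside).
#' @slot provenance generator and parameters.
#' @export
setClass("ImplicitModel", representation(sdf = "function",
                                         provenance = "list"))

#' Triangle mesh
#' @slot vertices V x 3 matrix, mm.
#' @slot faces F x 3 integer matrix, 1-based vertex indices, consistently
#'   oriented (outward normals) for generated meshes.
#' @export
setClass("TriMesh", representation(vertices = "matrix", faces = "matrix"),
         validity = function(object) {
           if (ncol(object@vertices) != 3L) return("vertices must be V x 3")
           if (ncol(object@faces) != 3L) return("faces must be F x 3")
           if (nrow(object@faces) &&
               (max(object@faces) > nrow(object@vertices) ||
                min(object@faces) < 1))
             return("face indices out of range")
           TRUE
         })

#' @rdname TriMesh-class
#' @param vertices V x 3 matrix, mm.
#' @param faces F x 3 integer matrix (1-based).
#' @export
triMesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(vertices) <- dimnames(faces) <- NULL
  new("TriMesh", vertices = vertices, faces = faces)
}

#' @rdname TriMesh-class
#' @param mesh a \linkS4class{TriMesh}.
#' @export
meshVertices <- function(mesh) mesh@vertices

#' @rdname TriMesh-class
#' @export
meshFaces <- function(mesh) mesh@faces

setMethod("show", "TriMesh", function(object) {
  cat(sprintf("TriMesh: %d vertices, %d faces\n", nrow(object@vertices),
              nrow(object@faces)))
})

# ---------------------------------------------------------------------------
# Alignment
# ---------------------------------------------------------------------------

#' Rigid transform (rotation + translation)
#' @slot rotation 3 x 3 orthonormal matrix, det = +1.
#' @slot translation length-3 vector, mm.
#' @export
setClass("RigidTransform", representation(rotation = "matrix",
                                          translation = "numeric"),
         validity = function(object) {
           R <- object@rotation
           if (!all(dim(R) == c(3, 3))) return("rotation must be 3 x 3")
           if (max(abs(crossprod(R) - diag(3))) > 1e-9)
             return("rotation must be orthonormal (R'R = I within 1e-9)")
           if (abs(det(R) - 1) > 1e-9) return("det(rotation) must be +1")
           if (length(object@translation) != 3L)
             return("translation must have length 3")
           TRUE
         })

#' @rdname RigidTransform-class
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 translation, mm.
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2)))
  cat(sprintf("RigidTransform: rotation %.2f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang * 180 / pi, object@translation[1], object@translation[2],
              object@translation[3]))
})

#' Result of ICP registration
#' @slot transform the fitted \linkS4class{RigidTransform}.
#' @slot rmse trimmed root-mean-square correspondence error, mm.
#' @slot iterations number of ICP iterations used.
#' @slot converged logical.
#' @slot history per-iteration rmse.
#' @export
setClass("AlignmentResult", representation(transform = "RigidTransform",
                                           rmse = "numeric",
                                           iterations = "integer",
                                           converged = "logical",
                                           history = "numeric"))

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("AlignmentResult: rmse = %.4g mm after %d iterations (%s)\n",
              object@rmse, object@iterations,
              if (object@converged) "converged" else "not converged"))
  show(object@transform)
})

# ---------------------------------------------------------------------------
# Tomographic state
# ---------------------------------------------------------------------------

#' Set of tomographic projections
#' @slot values array (nu, nAngles, nz), nonnegative.
#' @slot angles projection angles, radians.
#' @slot pitch detector pixel pitch, mm (equals the voxel size).
#' @export
setClass("ProjectionSet", representation(values = "array", angles = "numeric",
                                         pitch = "numeric"),
         validity = function(object) {
           if (length(dim(object@values)) != 3L)
             return("values must be (nu, nAngles, nz)")
           if (dim(object@values)[2] != length(object@angles))
             return("angle count mismatch")
           if (any(object@values < 0))
             return("projections must be nonnegative")
           TRUE
         })

#' Accumulated light-dose volume
#' @slot grid the \linkS4class{VoxelGrid}.
#' @slot dose nonnegative 3D array.
#' @slot normalization \code{"none"} or \code{"max"}.
#' @export
setClass("DoseVolume", representation(grid = "VoxelGrid", dose = "array",
                                      normalization = "character"),
         validity = function(object) {
           if (!identical(dim(object@dose), as.integer(object@grid@dim)))
             return("dose dimensions do not match the grid")
           if (any(object@dose < 0)) return("dose must be nonnegative")
           TRUE
         })

#' OSMO optimization parameters
#'
#' Dual-threshold object-space model optimization: after each model update
#' the dose is max-normalized; in-target voxels below \code{tHigh} are
#' under-dosed, out-of-target voxels above \code{tLow} are over-dosed, and
#' the model is nudged by \code{eta} against each error population.
#'
#' @slot tLow,tHigh normalized dose thresholds, 0 < tLow < tHigh <= 1.
#' @slot eta update step.
#' @slot maxIters iteration budget.
#' @slot patience iterations without error-count improvement before stopping.
#' @slot init \code{"target"} or \code{"backprojection"}.
#' @export
setClass("OsmoParams", representation(tLow = "numeric", tHigh = "numeric",
                                      eta = "numeric", maxIters = "integer",
                                      patience = "integer",
                                      init = "character"),
         validity = function(object) {
           if (!(object@tLow > 0 && object@tLow < object@tHigh &&
                 object@tHigh <= 1))
             return("need 0 < tLow < tHigh <= 1")
           if (object@eta < 0) return("eta must be >= 0")
           TRUE
         })

#' @rdname OsmoParams-class
#' @param tLow,tHigh dual dose thresholds (fractions of max dose).
#' @param eta update step size.
#' @param maxIters maximum iterations.
#' @param patience early-stop patience (iterations without improvement).
#' @param init initial model.
#' @export
osmoParams <- function(tLow = 0.55, tHigh = 0.65, eta = 0.1, maxIters = 50L,
                       patience = 5L, init = c("target", "backprojection")) {
  new("OsmoParams", tLow = tLow, tHigh = tHigh, eta = eta,
      maxIters = as.integer(maxIters), patience = as.integer(patience),
      init = match.arg(init))
}

#' Single-projection (FLight) exposure pattern
#' @slot image logical matrix (u, v) of the binary projection.
#' @slot angle beam axis angle, radians.
#' @slot depthFraction fraction (0, 1] of the traversal that crosslinks.
#' @export
setClass("FLightPattern", representation(image = "matrix", angle = "numeric",
                                         depthFraction = "numeric"),
         validity = function(object) {
           if (!is.logical(object@image)) return("image must be logical")
           if (object@depthFraction <= 0 || object@depthFraction > 1)
             return("depthFraction must be in (0, 1]")
           TRUE
         })

#' @rdname FLightPattern-class
#' @param image logical matrix (u along the detector, v along z).
#' @param angle face-on beam angle, radians.
#' @param depthFraction crosslinked fraction of the traversal depth.
#' @export
flightPattern <- function(image, angle = 0, depthFraction = 0.7) {
  new("FLightPattern", image = image, angle = angle,
      depthFraction = depthFraction)
}

#' Print-quality metric report
#' @slot runs per-run metric data.frame.
#' @slot aggregate mean and s.d. per metric and arm.
#' @slot provenance seeds and parameters.
#' @export
setClass("MetricReport", representation(runs = "data.frame",
                                        aggregate = "data.frame",
                                        provenance = "list"))

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport:", nrow(object@runs), "runs\n")
  print(object@aggregate)
})

#' @rdname MetricReport-class
#' @param object a \linkS4class{MetricReport}.
#' @export
reportRuns <- function(object) object@runs

#' @rdname MetricReport-class
#' @export
reportAggregate <- function(object) object@aggregate
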
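#' @include AllClasses.R transform.R
NULL

#' Compute per-vertex normals
#'
#' Each vertex normal is the normalised area-weighted average of the
#' incident face normals (the unnormalised face cross products already
#' carry the area weight). For a watertight mesh with outward winding the
#' normals point outwards. Vertices without any incident face get a zero
#' normal and a warning.
#'
#' @param mesh a [TriangleMesh-class] with consistent triangle winding.
#' @return The mesh with the `normals` slot filled.
#' @examples
#' plate <- triangleMesh(rbind(c(0,0,0), c(1,0,0), c(0,1,0)),
#'                       rbind(c(1,2,3)))
#' normals(vertexNormals(plate))
#' @export
vertexNormals <- function(mesh) {
    v <- mesh@vertices
    tr <- mesh@triangles
    if (nrow(tr) == 0L) stop("cannot compute vertex normals without faces")
    a <- v[tr[, 1], , drop = FALSE]
    fn <- .rowCross(v[tr[, 2], , drop = FALSE] - a,
                    v[tr[, 3], , drop = FALSE] - a)
    acc <- matrix(0, nrow(v), 3L)
    for (k in 1:3) {
        for (c in 1:3) {
            s <- rowsum(fn[, c], tr[, k])
            acc[as.integer(rownames(s)), c] <-
                acc[as.integer(rownames(s)), c] + s
        }
    }
    len <- sqrt(rowSums(acc^2))
    if (any(len == 0))
        warning(sum(len == 0), " isolated vertex/vertices flagged with a ",
                "zero normal")
    acc[len > 0, ] <- acc[len > 0, , drop = FALSE] / len[len > 0]
    mesh@normals <- acc
    validObject(mesh)
    mesh
}

#' Subset a mesh by a vertex filter
#'
#' Keeps the selected vertices and only those triangles whose three
#' vertices all survive; indices are remapped. Per-vertex attributes
#' (normals, scalar field, colours) follow the subset.
#'
#' @param mesh a [TriangleMesh-class].
#' @param keep logical or integer vertex selector.
#' @return The sub-mesh.
#' @export
subsetMesh <- function(mesh, keep) {
    n <- nrow(mesh@vertices)
    keepIdx <- if (is.logical(keep)) which(keep) else as.integer(keep)
    if (length(keepIdx) == 0L) stop("empty vertex selection")
    map <- integer(n)
    map[keepIdx] <- seq_along(keepIdx)
    tr <- mesh@triangles
    if (nrow(tr) > 0L) {
        ok <- map[tr[, 1]] > 0L & map[tr[, 2]] > 0L & map[tr[, 3]] > 0L
        tr <- matrix(map[tr[ok, , drop = FALSE]], ncol = 3L)
    }
    triangleMesh(mesh@vertices[keepIdx, , drop = FALSE], tr,
        normals = if (nrow(mesh@normals) == n)
            mesh@normals[keepIdx, , drop = FALSE],
        scalar = if (length(mesh@scalar) == n) mesh@scalar[keepIdx],
        colors = if (nrow(mesh@colors) == n)
            mesh@colors[keepIdx, , drop = FALSE])
}

#' Cut the front-facing part of a surface
#'
#' Keeps the vertices whose normal makes an angle of less than 90 degrees
#' with the patient's anterior direction (strictly positive dot product;
#' vertices at exactly 90 degrees are dropped). Only the front part of
#' the segmented skin can be seen by the depth camera, so restricting the
#' registration to it removes pointless correspondences.
#'
#' @param mesh a [TriangleMesh-class]; normals are computed on the fly if
#'   absent.
#' @param anterior unit 3-vector, the anterior (front) direction in the
#'   mesh's frame.
#' @return The front sub-mesh.
#' @examples
#' sph <- makePhantomVolume(phantomSpec(dims = c(24, 24, 16),
#'     spacing = c(4, 4, 4), semiAxes = c(36, 30, 26),
#'     noiseSigma = 0), seed = 1)
#' skin <- skinSurfaceFromVolume(sph$volume, segmentationConfig(-400))
#' front <- selectFront(skin, c(0, 1, 0))
#' nVertices(front) < nVertices(skin)
#' @export
selectFront <- function(mesh, anterior = c(0, 1, 0)) {
    anterior <- as.numeric(anterior)
    anterior <- anterior / sqrt(sum(anterior^2))
    if (nrow(mesh@normals) != nrow(mesh@vertices))
        mesh <- vertexNormals(mesh)
    keep <- as.vector(mesh@normals %*% anterior) > 0
    if (!any(keep))
        stop("no front-facing vertices: check the 'anterior' direction")
    subsetMesh(mesh, keep)
}

#' Crop a mesh to a spherical region of interest
#'
#' @param mesh a [TriangleMesh-class].
#' @param center 3-point in mm.
#' @param radius sphere radius in mm (> 0).
#' @return The sub-mesh of vertices within `radius` of `center`.
#' @export
cropROI <- function(mesh, center, radius) {
    if (radius <= 0) stop("'radius' must be > 0")
    d2 <- rowSums(sweep(mesh@vertices, 2L, as.numeric(center), "-")^2)
    keep <- d2 <= radius^2
    if (!any(keep))
        stop("empty region of interest: no vertex within ", radius,
             " mm of the given center")
    subsetMesh(mesh, keep)
}

#' Apply a rigid transform to a mesh
#'
#' Vertices map as \eqn{v \mapsto R v + t}; normals are rotated;
#' connectivity and scalar attributes are untouched.
#'
#' @param mesh a [TriangleMesh-class].
#' @param transform a [RigidTransform-class].
#' @return The transformed mesh.
#' @export
applyTransform <- function(mesh, transform) {
    stopifnot(is(transform, "RigidTransform"))
    mesh@vertices <- transformPoints(mesh@vertices, transform)
    if (nrow(mesh@normals) > 0L)
        mesh@normals <- mesh@normals %*% t(transform@rotation)
    mesh
}
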
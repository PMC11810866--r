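#' @include AllClasses.R mesh-ops.R
NULL

#' Exact nearest neighbours between point sets
#'
#' For each row of `points`, the index of and distance to the closest row
#' of `reference` (Euclidean), computed with a k-d tree.
#'
#' @param points N x 3 query matrix (mm).
#' @param reference M x 3 reference matrix (mm).
#' @return list with `index` (1-based into `reference`) and `distance`
#'   (mm).
#' @export
nearestNeighbors <- function(points, reference) {
    points <- .asPoints(points)
    reference <- .asPoints(reference)
    if (nrow(points) == 0L || nrow(reference) == 0L)
        stop("nearest-neighbour search needs non-empty point sets")
    .nnSearch(reference, points)
}

.asPoints <- function(x) {
    if (is(x, "TriangleMesh")) return(x@vertices)
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    if (ncol(x) != 3L) stop("points must be N x 3")
    x
}

#' Hausdorff distance between surfaces or point sets
#'
#' The directed distance is
#' \eqn{d_{X_1}(X_2) = \max_{x \in X_1} \min_{y \in X_2} \|x - y\|_2};
#' the symmetric Hausdorff distance is the larger of the two directed
#' distances. Minimum distances are found with a k-d tree, and distances
#' are vertex-to-vertex (the surfaces compared here are dense relative to
#' the millimetre error scale). A larger value means a worse
#' co-registration.
#'
#' @param x1,x2 [TriangleMesh-class] objects or N x 3 matrices (mm).
#' @return Distance in mm.
#' @examples
#' directedHausdorff(rbind(c(0, 0, 0)), rbind(c(3, 4, 0)))  # 5
#' @export
directedHausdorff <- function(x1, x2) {
    max(nearestNeighbors(.asPoints(x1), .asPoints(x2))$distance)
}

#' @rdname directedHausdorff
#' @export
hausdorffDistance <- function(x1, x2) {
    max(directedHausdorff(x1, x2), directedHausdorff(x2, x1))
}

#' ErrorMap: per-vertex registration error with colours
#'
#' @slot distances per-vertex distance to the other surface, mm.
#' @slot colors N x 3 integer RGB matrix (see [distanceColormap()]).
#' @slot cap distance (mm) at and above which vertices are pure red.
#' @seealso [perVertexDistance()]
#' @exportClass ErrorMap
setClass("ErrorMap",
    representation(distances = "numeric", colors = "matrix",
                   cap = "numeric"))

setValidity("ErrorMap", function(object) {
    if (any(object@distances < 0)) return("distances must be >= 0")
    if (nrow(object@colors) != length(object@distances))
        return("one colour per distance required")
    TRUE
})

#' @describeIn perVertexDistance compact display.
#' @param object object to display.
setMethod("show", "ErrorMap", function(object) {
    cat(sprintf("ErrorMap: %d vertices, cap %g mm\n",
                length(object@distances), object@cap))
    cat(sprintf("  distance range [%.3f, %.3f] mm, %.1f%% at/above cap\n",
                min(object@distances), max(object@distances),
                100 * mean(object@distances >= object@cap)))
})

#' Per-vertex distance field between two surfaces
#'
#' Assigns every vertex of `surface` its minimum Euclidean distance to
#' the vertices of `other` and the corresponding colour-map RGB value.
#' The maximum of the field is the directed Hausdorff distance.
#'
#' @param surface,other [TriangleMesh-class] objects.
#' @param cap mm mapped to pure red (default 5).
#' @return An [ErrorMap-class].
#' @seealso [colorizeMesh()] to attach the map to the mesh for export.
#' @export
perVertexDistance <- function(surface, other, cap = 5) {
    d <- nearestNeighbors(.asPoints(surface), .asPoints(other))$distance
    new("ErrorMap", distances = d, colors = distanceColormap(d, cap),
        cap = cap)
}

#' Distance-to-colour mapping for error visualisation
#'
#' Null distance is pure blue (0, 0, 255); distances at or above `cap`
#' (default 5 mm) are pure red (255, 0, 0); in between the colour is the
#' linear blend \eqn{d \mapsto (255 d / cap,\ 0,\ 255 (1 - d / cap))},
#' rounded to integers.
#'
#' @param distances non-negative distances in mm.
#' @param cap mm mapped to pure red.
#' @return N x 3 integer matrix of RGB values.
#' @examples
#' distanceColormap(c(0, 2.5, 5, 9))
#' @export
distanceColormap <- function(distances, cap = 5) {
    if (any(distances < 0)) stop("distances must be >= 0")
    if (cap <= 0) stop("'cap' must be > 0")
    f <- pmin(distances / cap, 1)
    m <- cbind(as.integer(round(255 * f)), 0L,
               as.integer(round(255 * (1 - f))))
    colnames(m) <- c("red", "green", "blue")
    m
}

#' Attach an error map to a mesh
#'
#' @param mesh the [TriangleMesh-class] the map was computed on.
#' @param errorMap an [ErrorMap-class].
#' @return The mesh with `scalar` and `colors` slots set, ready for
#'   [writeMesh()] as a coloured PLY.
#' @export
colorizeMesh <- function(mesh, errorMap) {
    if (length(errorMap@distances) != nrow(mesh@vertices))
        stop("error map and mesh vertex counts differ")
    mesh@scalar <- errorMap@distances
    mesh@colors <- unname(errorMap@colors)
    validObject(mesh)
    mesh
}

#' Target registration error
#'
#' Mean Euclidean distance between corresponding landmark lists,
#' evaluated inside the volume after registration:
#' \eqn{TRE = \frac{1}{N} \sum_i \| registered_i - target_i \|}. The
#' clinical protocol uses a single anatomical target (N = 1).
#'
#' @param registered N x 3 matrix (or list of 3-vectors) of landmark
#'   positions after registration, mm.
#' @param target the corresponding target landmark positions, mm.
#' @return TRE in mm.
#' @examples
#' tre(rbind(c(0, 0, 0)), rbind(c(0, 0, 7.4)))  # 7.4
#' @export
tre <- function(registered, target) {
    toMat <- function(x) if (is.list(x)) do.call(rbind, x) else
        matrix(as.numeric(x), ncol = 3L)
    r <- toMat(registered)
    t <- toMat(target)
    if (nrow(r) == 0L) stop("landmark lists must be non-empty")
    if (nrow(r) != nrow(t))
        stop("landmark lists differ in length (", nrow(r), " vs ",
             nrow(t), ")")
    mean(sqrt(rowSums((r - t)^2)))
}
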
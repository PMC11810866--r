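#' @import methods
NULL

.isOrthonormal <- function(m, tol = 1e-6) {
    is.matrix(m) && all(dim(m) == c(3L, 3L)) &&
        max(abs(crossprod(m) - diag(3))) < tol
}

#' VolumetricImage: a 3D scalar medical image
#'
#' Container for a CT/MR volume: a 3D intensity grid plus the geometric
#' metadata needed to place every voxel in world (scanner) coordinates.
#' The world position of 0-based voxel index \eqn{(i,j,k)} is
#' \eqn{origin + A (s \circ (i,j,k))} where \eqn{A} is the direction
#' matrix and \eqn{s} the per-axis spacing in mm.
#'
#' @slot data 3D numeric array of intensities (Hounsfield units for CT,
#'   arbitrary units for MR).
#' @slot spacing numeric(3), voxel size in mm along each array axis;
#'   strictly positive.
#' @slot origin numeric(3), world position (mm) of voxel (0,0,0).
#' @slot axes 3x3 orthonormal direction matrix with determinant +1; column
#'   j is the world direction of array axis j.
#' @slot sliceAxis integer, index (1..3) of the axis along which 2D slices
#'   are stacked. Slice-wise operations (padding, region growing) work in
#'   the plane orthogonal to this axis.
#'
#' @seealso [volumetricImage()], [readVolume()], [segmentSkin()]
#' @exportClass VolumetricImage
setClass("VolumetricImage",
    representation(
        data = "array",
        spacing = "numeric",
        origin = "numeric",
        axes = "matrix",
        sliceAxis = "integer"
    )
)

setValidity("VolumetricImage", function(object) {
    d <- object@data
    if (length(dim(d)) != 3L)
        return("'data' must be a 3D array")
    if (any(dim(d) < 2L))
        return("each volume axis must have at least 2 voxels")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        return("'spacing' must be 3 strictly positive values (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
        return("'origin' must be a finite 3-vector (mm)")
    if (!.isOrthonormal(object@axes))
        return("'axes' must be a 3x3 orthonormal direction matrix")
    if (det(object@axes) < 0)
        return("'axes' must be right-handed (determinant +1)")
    if (length(object@sliceAxis) != 1L || !object@sliceAxis %in% 1:3)
        return("'sliceAxis' must be 1, 2 or 3")
    TRUE
})

#' Construct a VolumetricImage
#'
#' @param data 3D numeric array of voxel intensities.
#' @param spacing numeric(3) voxel size in mm (default 1 mm isotropic).
#' @param origin numeric(3) world position of voxel (0,0,0) in mm.
#' @param axes 3x3 orthonormal direction matrix, determinant +1.
#' @param sliceAxis axis (1..3) along which slices are stacked; the third
#'   array axis by default.
#' @return A [VolumetricImage-class] object.
#' @examples
#' vol <- volumetricImage(array(0, c(8, 8, 4)), spacing = c(1, 1, 2))
#' dim(vol)
#' @export
volumetricImage <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                            axes = diag(3), sliceAxis = 3L) {
    new("VolumetricImage", data = data, spacing = as.numeric(spacing),
        origin = as.numeric(origin), axes = axes,
        sliceAxis = as.integer(sliceAxis))
}

#' MockupGrid: slice-wise skin segmentation labels
#'
#' Output of [segmentSkin()]. A label grid parallel to the (padded,
#' possibly subsampled) volume with one of three values per voxel:
#' 0 = background air reached by region growing, 1 = body edge (first
#' voxel at or above the skin iso-value met by the growth), 2 = the
#' initial value, i.e. voxels never reached -- the body interior and any
#' air pockets enclosed by it.
#'
#' @slot labels 3D integer array over \{0, 1, 2\}.
#' @slot isoValue the skin iso-value used for the segmentation.
#' @slot volume the [VolumetricImage-class] the labels refer to (after any
#'   internal padding/subsampling), kept so that surface extraction is
#'   self-consistent.
#' @seealso [segmentSkin()], [binarizeMockup()], [extractSkinSurface()]
#' @exportClass MockupGrid
setClass("MockupGrid",
    representation(
        labels = "array",
        isoValue = "numeric",
        volume = "VolumetricImage"
    )
)

setValidity("MockupGrid", function(object) {
    if (!all(object@labels %in% c(0L, 1L, 2L)))
        return("labels must be 0 (background), 1 (body edge) or 2 (initial)")
    if (!identical(dim(object@labels), dim(object@volume@data)))
        return("label grid and volume dimensions differ")
    if (length(object@isoValue) != 1L || !is.finite(object@isoValue))
        return("'isoValue' must be a single finite number")
    TRUE
})

#' TriangleMesh: a surface in world coordinates
#'
#' Vertices in mm plus triangle connectivity; optionally unit per-vertex
#' normals, a per-vertex scalar field (e.g. distance to another surface,
#' in mm) and per-vertex RGB colours. Both the skin surface segmented
#' from the volume and the depth-camera surface are stored in this class;
#' a camera point cloud simply has zero triangles.
#'
#' @slot vertices N x 3 numeric matrix, mm.
#' @slot triangles M x 3 integer matrix of 1-based vertex indices
#'   (0 rows for a raw point cloud).
#' @slot normals N x 3 (or 0 x 3) matrix of unit vertex normals.
#' @slot scalar numeric of length N (or 0), per-vertex scalar field.
#' @slot colors N x 3 (or 0 x 3) integer matrix of RGB values in 0..255.
#' @seealso [triangleMesh()], [vertexNormals()], [writeMesh()]
#' @exportClass TriangleMesh
setClass("TriangleMesh",
    representation(
        vertices = "matrix",
        triangles = "matrix",
        normals = "matrix",
        scalar = "numeric",
        colors = "matrix"
    )
)

setValidity("TriangleMesh", function(object) {
    v <- object@vertices
    tr <- object@triangles
    if (ncol(v) != 3L)
        return("'vertices' must be an N x 3 matrix")
    if (ncol(tr) != 3L)
        return("'triangles' must be an M x 3 index matrix")
    if (nrow(tr) > 0L) {
        if (any(tr < 1L) || any(tr > nrow(v)))
            return("triangle indices out of range")
    }
    if (nrow(object@normals) > 0L) {
        if (nrow(object@normals) != nrow(v) || ncol(object@normals) != 3L)
            return("'normals' must be N x 3 when present")
        len <- sqrt(rowSums(object@normals^2))
        if (any(abs(len[len > 0] - 1) > 1e-6))
            return("non-zero normals must be unit length")
    }
    if (length(object@scalar) > 0L && length(object@scalar) != nrow(v))
        return("'scalar' must have one value per vertex when present")
    if (nrow(object@colors) > 0L) {
        if (nrow(object@colors) != nrow(v) || ncol(object@colors) != 3L)
            return("'colors' must be N x 3 when present")
        if (any(object@colors < 0L) || any(object@colors > 255L))
            return("colour components must lie in 0..255")
    }
    TRUE
})

.emptyMat <- function(ncol = 3L, mode = "numeric") {
    matrix(vector(mode, 0L), nrow = 0L, ncol = ncol)
}

#' Construct a TriangleMesh
#'
#' @param vertices N x 3 numeric matrix of positions in mm.
#' @param triangles M x 3 matrix of 1-based vertex indices; omit for a
#'   point cloud.
#' @param normals optional N x 3 matrix of unit vertex normals.
#' @param scalar optional per-vertex scalar field (length N).
#' @param colors optional N x 3 integer matrix of RGB values (0..255).
#' @return A [TriangleMesh-class] object.
#' @examples
#' m <- triangleMesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                   rbind(c(1, 2, 3)))
#' nVertices(m)
#' @export
triangleMesh <- function(vertices, triangles = NULL, normals = NULL,
                         scalar = NULL, colors = NULL) {
    vertices <- unname(as.matrix(vertices))
    storage.mode(vertices) <- "double"
    if (is.null(triangles) || nrow(as.matrix(triangles)) == 0L) {
        triangles <- .emptyMat(3L, "integer")
    } else {
        triangles <- unname(as.matrix(triangles))
        storage.mode(triangles) <- "integer"
    }
    if (is.null(normals)) normals <- .emptyMat() else {
        normals <- unname(as.matrix(normals))
        storage.mode(normals) <- "double"
    }
    if (is.null(colors)) colors <- .emptyMat(3L, "integer") else {
        colors <- unname(as.matrix(colors))
        storage.mode(colors) <- "integer"
    }
    new("TriangleMesh", vertices = vertices, triangles = triangles,
        normals = normals, scalar = if (is.null(scalar)) numeric(0)
                                    else as.numeric(scalar),
        colors = colors)
}

#' RigidTransform: rotation plus translation
#'
#' A proper rigid-body transform \eqn{x \mapsto R x + t} with \eqn{R} a
#' rotation matrix (orthonormal, det +1) and \eqn{t} in mm. This is the
#' output of the co-registration; applied to the volume it brings the
#' CT/MR data into the camera/tracking reference frame.
#'
#' @slot rotation 3x3 rotation matrix.
#' @slot translation numeric(3), mm.
#' @seealso [rigidTransform()], [composeTransforms()], [applyTransform()]
#' @exportClass RigidTransform
setClass("RigidTransform",
    representation(rotation = "matrix", translation = "numeric")
)

setValidity("RigidTransform", function(object) {
    R <- object@rotation
    if (!is.matrix(R) || !all(dim(R) == c(3L, 3L)))
        return("'rotation' must be 3x3")
    if (max(abs(crossprod(R) - diag(3))) > 1e-8)
        return("'rotation' must be orthonormal (R'R = I within 1e-8)")
    if (abs(det(R) - 1) > 1e-8)
        return("'rotation' must be proper (det +1 within 1e-8)")
    if (length(object@translation) != 3L ||
        any(!is.finite(object@translation)))
        return("'translation' must be a finite 3-vector (mm)")
    TRUE
})

#' LandmarkPair: one corresponding virtual landmark per surface
#'
#' The operator-selected point pair initialising the translation of the
#' co-registration: one point on the segmented skin surface, the
#' corresponding point on the camera surface. Points are snapped to the
#' nearest mesh vertex and must lie within 5 mm of their surface.
#'
#' @slot onSegmented numeric(3), mm, on the segmented surface.
#' @slot onCamera numeric(3), mm, on the camera surface.
#' @seealso [landmarkPair()], [coregister()]
#' @exportClass LandmarkPair
setClass("LandmarkPair",
    representation(onSegmented = "numeric", onCamera = "numeric")
)

setValidity("LandmarkPair", function(object) {
    if (length(object@onSegmented) != 3L || length(object@onCamera) != 3L)
        return("landmarks must be 3-vectors")
    if (any(!is.finite(c(object@onSegmented, object@onCamera))))
        return("landmarks must be finite")
    TRUE
})

#' RegistrationResult: output of the co-registration pipeline
#'
#' @slot transform the [RigidTransform-class] mapping the segmented
#'   surface (and hence the volume) into the camera frame.
#' @slot perStageRMS named numeric, RMS nearest-neighbour distance (mm)
#'   after each pipeline stage (landmark, icp1, icp2).
#' @slot hausdorff symmetric Hausdorff distance (mm) between the
#'   registered ROI surfaces.
#' @slot iterations named integer, ICP iterations used per stage.
#' @slot segROI the registered segmented-surface ROI with per-vertex
#'   distances and error colours attached.
#' @slot camROI the camera-surface ROI, likewise coloured.
#' @slot details list of diagnostics (per-iteration RMS traces, final
#'   trimmed RMS, configuration echo).
#' @seealso [coregister()]
#' @exportClass RegistrationResult
setClass("RegistrationResult",
    representation(
        transform = "RigidTransform",
        perStageRMS = "numeric",
        hausdorff = "numeric",
        iterations = "integer",
        segROI = "TriangleMesh",
        camROI = "TriangleMesh",
        details = "list"
    )
)

#' Segmentation configuration
#'
#' @param isoValue scalar intensity threshold separating air from body
#'   (skin iso-value); Hounsfield units for CT. The first voxel at or
#'   above this value reached from outside is labelled as body edge.
#' @param padWidth voxels of background padding added around each slice
#'   (default 1); padding is filled with the global minimum intensity so
#'   the corner seeds are guaranteed to be background even when the
#'   scanner bed touches the slice border.
#' @param subsampleFactor integer decimation factor (>= 1) applied per
#'   axis before segmentation to trade resolution for speed.
#' @param sliceAxis axis along which slices are stacked (default 3).
#' @return A list of class \code{"SegmentationConfig"}.
#' @examples
#' segmentationConfig(isoValue = -400)
#' @export
segmentationConfig <- function(isoValue, padWidth = 1L, subsampleFactor = 1L,
                               sliceAxis = 3L) {
    stopifnot(length(isoValue) == 1L, is.finite(isoValue))
    padWidth <- as.integer(padWidth)
    subsampleFactor <- as.integer(subsampleFactor)
    if (padWidth < 0L) stop("'padWidth' must be >= 0")
    if (any(subsampleFactor < 1L)) stop("'subsampleFactor' must be >= 1")
    structure(list(isoValue = as.numeric(isoValue), padWidth = padWidth,
                   subsampleFactor = subsampleFactor,
                   sliceAxis = as.integer(sliceAxis)),
              class = "SegmentationConfig")
}

#' Registration configuration
#'
#' Tunable parameters of the co-registration pipeline.
#'
#' @param roiRadius radius (mm) of the spherical region of interest
#'   around the camera-surface landmark used for the ICP stages
#'   (default 100 mm).
#' @param trimFraction fraction of closest correspondence pairs kept in
#'   the second, trimmed ICP stage (default 0.8).
#' @param maxIterations maximum iterations per ICP stage (default 100;
#'   point-to-point ICP converges by slow tangential sliding on smooth
#'   skin-like surfaces, and truncating it too early leaves a residual
#'   rotation).
#' @param convergenceTol stop an ICP stage when the RMS change between
#'   iterations falls below this value, in mm (default 1e-4).
#' @param anterior unit 3-vector giving the patient's anterior direction
#'   in the volume's world frame, used to cut the front of the segmented
#'   surface (default +y, an LPS-style convention).
#' @param startOffset step (mm) of the landmark-correction search grid
#'   (default 15, the clinically plausible virtual-landmark picking
#'   error; 0 disables the search). The landmark only initialises the
#'   translation, and on smooth body surfaces a mis-picked landmark can
#'   strand ICP in a tilted local minimum; [coregister()] therefore
#'   scores a small tangential grid of corrected landmarks with a short
#'   full-trim ICP run and keeps the correction with the lowest trimmed
#'   RMS, which makes the recovered pose operator-independent.
#' @return A list of class \code{"RegistrationConfig"}.
#' @examples
#' registrationConfig(trimFraction = 0.8)
#' @export
registrationConfig <- function(roiRadius = 100, trimFraction = 0.8,
                               maxIterations = 100L, convergenceTol = 1e-4,
                               anterior = c(0, 1, 0), startOffset = 15) {
    if (roiRadius <= 0) stop("'roiRadius' must be > 0")
    if (trimFraction <= 0 || trimFraction > 1)
        stop("'trimFraction' must lie in (0, 1]")
    if (startOffset < 0) stop("'startOffset' must be >= 0")
    anterior <- as.numeric(anterior)
    anterior <- anterior / sqrt(sum(anterior^2))
    structure(list(roiRadius = roiRadius, trimFraction = trimFraction,
                   maxIterations = as.integer(maxIterations),
                   convergenceTol = convergenceTol, anterior = anterior,
                   startOffset = startOffset),
              class = "RegistrationConfig")
}
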
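#' @include AllClasses.R mesh-ops.R metrics.R
NULL

#' Principal-component orientation adjustment
#'
#' Estimates the rotation that maps the principal axes of the source
#' surface (eigenvectors of the vertex covariance, descending eigenvalue
#' order) onto those of the destination surface, with the translation
#' aligning the centroids. Eigenvectors are sign-ambiguous; under the
#' precondition that both surfaces are consistently oriented (head-feet,
#' right-left), each axis takes the sign that agrees with the
#' corresponding destination axis, and a residual improper combination is
#' repaired by flipping the least certain axis so the result is a proper
#' rotation. Nearly tied eigenvalues (relative gap below 1\%) make the
#' axes meaningless and raise an error.
#'
#' @param src,dst [TriangleMesh-class] objects (or N x 3 point matrices).
#' @return A [RigidTransform-class] mapping `src` onto `dst`.
#' @seealso [coregister()]
#' @export
pcaAlign <- function(src, dst) {
    ps <- .asPoints(src)
    pd <- .asPoints(dst)
    es <- .principalAxes(ps, "source")
    ed <- .principalAxes(pd, "destination")
    agree <- colSums(es$vectors * ed$vectors)
    s <- ifelse(agree >= 0, 1, -1)
    if (any(abs(agree) < 1e-6))
        stop("ambiguous principal axes: a source axis is orthogonal to ",
             "its destination counterpart; surfaces are not consistently ",
             "oriented")
    R <- ed$vectors %*% diag(s) %*% t(es$vectors)
    if (det(R) < 0) {
        flip <- which.min(abs(agree))
        s[flip] <- -s[flip]
        R <- ed$vectors %*% diag(s) %*% t(es$vectors)
    }
    cs <- colMeans(ps)
    cd <- colMeans(pd)
    rigidTransform(R, cd - as.vector(R %*% cs))
}

.principalAxes <- function(p, what) {
    e <- eigen(stats::cov(p), symmetric = TRUE)
    gaps <- -diff(e$values) / e$values[1]
    if (any(gaps < 0.01))
        stop("ambiguous principal axes: ", what,
             " surface has (near-)tied covariance eigenvalues ",
             "(relative gap < 1%)")
    e
}

#' Build a landmark pair snapped to the surfaces
#'
#' Each operator-picked point is snapped to the nearest vertex of its
#' surface; a point farther than `maxSnap` (default 5 mm) from the
#' surface is rejected as not on the skin.
#'
#' @param segmented the segmented skin [TriangleMesh-class].
#' @param camera the camera surface.
#' @param onSegmented,onCamera picked 3-points in mm.
#' @param maxSnap largest tolerated point-to-surface distance, mm.
#' @return A [LandmarkPair-class].
#' @export
landmarkPair <- function(segmented, camera, onSegmented, onCamera,
                         maxSnap = 5) {
    snap <- function(mesh, p, lab) {
        nn <- nearestNeighbors(matrix(as.numeric(p), ncol = 3L), mesh)
        if (nn$distance > maxSnap)
            stop("landmark on the ", lab, " surface is ",
                 format(nn$distance, digits = 3), " mm away from it ",
                 "(limit ", maxSnap, " mm)")
        vertices(mesh)[nn$index, ]
    }
    new("LandmarkPair",
        onSegmented = snap(segmented, onSegmented, "segmented"),
        onCamera = snap(camera, onCamera, "camera"))
}

#' Translate onto the virtual landmark
#'
#' Keeps the rotation of `transform` and replaces its translation by the
#' one that maps the rotated segmented-surface landmark exactly onto the
#' camera-surface landmark. If the landmarks already coincide under
#' `transform`, the translation is unchanged.
#'
#' @param pair a [LandmarkPair-class].
#' @param transform the [RigidTransform-class] from [pcaAlign()].
#' @return The adjusted [RigidTransform-class].
#' @export
landmarkTranslate <- function(pair, transform) {
    R <- transform@rotation
    rigidTransform(R, pair@onCamera - as.vector(R %*% pair@onSegmented))
}

#' Iterative closest point with distance trimming
#'
#' Classic point-to-point ICP: each iteration matches every (transformed)
#' source point to its nearest destination point through a k-d tree,
#' keeps the `trimFraction` of pairs with the smallest distances, and
#' solves the least-squares rigid update in closed form (SVD/Kabsch). The
#' per-iteration trimmed RMS is recorded and is non-increasing; the loop
#' stops when its change drops below `convergenceTol` or after
#' `maxIterations`.
#'
#' @param src N x 3 source points or a [TriangleMesh-class] (N >= 10).
#' @param dst destination points or mesh.
#' @param init initial [RigidTransform-class] (identity by default).
#' @param trimFraction fraction of closest pairs kept (1 = plain ICP).
#' @param maxIterations,convergenceTol see [registrationConfig()].
#' @param toSurface when `TRUE` and `dst` is a triangulated mesh, source
#'   points are matched to their closest point *on* the destination
#'   surface (point-to-triangle) instead of its nearest vertex. This
#'   removes the vertex-lattice quantisation of the objective, which
#'   otherwise leaves millimetre-scale spurious minima when the source
#'   cloud is noisy and the destination mesh is coarse.
#' @return list with `transform` (the accumulated [RigidTransform-class]
#'   mapping `src` onto `dst`), `rms` (trimmed RMS in mm per iteration),
#'   `iterations`, and `finalRMS`.
#' @examples
#' pts <- matrix(rnorm(300), ncol = 3)
#' fit <- icp(pts, transformPoints(pts,
#'     rotationAboutAxis(c(0, 0, 1), 5, c(2, 0, 0))))
#' fit$finalRMS
#' @export
icp <- function(src, dst, init = identityTransform(), trimFraction = 1,
                maxIterations = 100L, convergenceTol = 1e-4,
                toSurface = FALSE) {
    s <- .asPoints(src)
    d <- .asPoints(dst)
    useSurf <- isTRUE(toSurface) && is(dst, "TriangleMesh") &&
        nrow(dst@triangles) > 0L
    if (nrow(s) < 10L) stop("ICP needs at least 10 source points")
    if (trimFraction <= 0 || trimFraction > 1)
        stop("'trimFraction' must lie in (0, 1]")
    keepN <- floor(trimFraction * nrow(s))
    if (keepN < 3L)
        stop("fewer than 3 correspondence pairs survive trimming")
    cur <- init
    rms <- numeric(0)
    for (it in seq_len(maxIterations)) {
        p <- transformPoints(s, cur)
        if (useSurf) {
            nn <- .nnSearchMesh(d, dst@triangles, p, 8L)
            matched <- nn$point
        } else {
            nn <- .nnSearch(d, p)
            matched <- d[nn$index, , drop = FALSE]
        }
        ord <- order(nn$distance)[seq_len(keepN)]
        rmsNow <- sqrt(mean(nn$distance[ord]^2))
        rms <- c(rms, rmsNow)
        if (rmsNow < convergenceTol) break   # already aligned
        if (it > 1L && abs(rms[it - 1L] - rmsNow) < convergenceTol) break
        cur <- .kabsch(s[ord, , drop = FALSE],
                       matched[ord, , drop = FALSE])
    }
    list(transform = cur, rms = rms, iterations = length(rms),
         finalRMS = rms[length(rms)])
}

# Candidate camera-side landmarks for the misplacement-robust search:
# the picked point plus a grid of +/- offset steps along the camera
# cloud's two leading principal (tangential) directions, each snapped
# back onto the cloud; duplicates collapse.
.landmarkCandidates <- function(camera, lmCam, offset) {
    if (offset <= 0) return(list(lmCam))
    tang <- eigen(stats::cov(vertices(camera)),
                  symmetric = TRUE)$vectors[, 1:2]
    targets <- list(lmCam)                 # the picked point comes first
    for (s1 in c(-offset, 0, offset))
        for (s2 in c(-offset, 0, offset))
            if (s1 != 0 || s2 != 0)
                targets <- c(targets,
                             list(lmCam + s1 * tang[, 1] +
                                  s2 * tang[, 2]))
    hits <- nearestNeighbors(do.call(rbind, targets), camera)
    lapply(unique(hits$index), function(i) vertices(camera)[i, ])
}

# Closed-form least-squares rigid fit src -> dst (Kabsch/Umeyama).
.kabsch <- function(src, dst) {
    cs <- colMeans(src)
    cd <- colMeans(dst)
    H <- crossprod(sweep(src, 2L, cs), sweep(dst, 2L, cd))
    sv <- svd(H)
    sgn <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, sgn)) %*% t(sv$u)
    rigidTransform(R, cd - as.vector(R %*% cs))
}

#' Co-register the segmented skin with the camera surface
#'
#' The full rigid co-registration pipeline: (1) cut the front of the
#' segmented surface (the part the camera can see) by the normal-angle
#' criterion; (2) principal-component orientation adjustment against the
#' camera surface; (3) translation onto the virtual landmark pair;
#' (4) crop both surfaces to a spherical region of interest around the
#' camera landmark; (5) a first ICP run on all correspondences; (6) a
#' refinement ICP run keeping only the `trimFraction` (default 80\%)
#' closest pairs each iteration. The composed transform maps the
#' segmented surface -- and, via [applyToVolume()], the CT/MR volume --
#' into the camera/tracking frame.
#'
#' @param segmented the segmented skin [TriangleMesh-class], consistently
#'   oriented with the camera surface.
#' @param camera the depth-camera surface (frontal acquisition).
#' @param pair a [LandmarkPair-class] (see [landmarkPair()]).
#' @param config a [registrationConfig()].
#' @return A [RegistrationResult-class]; its `segROI`/`camROI` meshes
#'   carry the per-vertex error field and colours.
#' @export
coregister <- function(segmented, camera, pair,
                       config = registrationConfig()) {
    stopifnot(is(pair, "LandmarkPair"),
              inherits(config, "RegistrationConfig"))
    front <- withCallingHandlers(
        selectFront(segmented, config$anterior),
        error = function(e) stop("front-cut stage: ",
                                 conditionMessage(e), call. = FALSE))
    tPca <- withCallingHandlers(
        pcaAlign(front, camera),
        error = function(e) stop("PCA stage: ", conditionMessage(e),
                                 call. = FALSE))
    # The virtual landmark initialises the translation only, and the
    # operator may pick it some 15 mm off the intended spot. On smooth
    # skin such an offset can strand ICP in a tilted local minimum whose
    # trimmed RMS is clearly worse than the global fit, so the pipeline
    # hypothesises a small tangential grid of landmark corrections,
    # scores each with a short full-trim ICP run, and keeps the one with
    # the lowest RMS before running the two full ICP stages. This makes
    # the recovered pose (in particular its rotation) insensitive to
    # landmark misplacement, i.e. operator-independent.
    candidates <- .landmarkCandidates(camera, pair@onCamera,
                                      config$startOffset)
    buildROIs <- function(lmCam) {
        tInit <- landmarkTranslate(
            new("LandmarkPair", onSegmented = pair@onSegmented,
                onCamera = lmCam), tPca)
        segROI <- tryCatch(
            cropROI(applyTransform(front, tInit), lmCam,
                    config$roiRadius),
            error = function(e) stop("ROI stage (segmented): ",
                                     conditionMessage(e), call. = FALSE))
        camROI <- tryCatch(
            cropROI(camera, lmCam, config$roiRadius),
            error = function(e) stop("ROI stage (camera): ",
                                     conditionMessage(e), call. = FALSE))
        list(tInit = tInit, segROI = segROI, camROI = camROI)
    }
    lmBest <- candidates[[1]]
    if (length(candidates) > 1L) {
        score <- vapply(candidates, function(lmCam) {
            st <- buildROIs(lmCam)
            icp(st$camROI, st$segROI, trimFraction = 1,
                maxIterations = min(40L, config$maxIterations),
                convergenceTol = config$convergenceTol,
                toSurface = TRUE)$finalRMS
        }, numeric(1))
        lmBest <- candidates[[which.min(score)]]
    }
    st <- buildROIs(lmBest)
    tInit <- st$tInit
    segROI <- st$segROI
    camROI <- st$camROI
    # Correspondences run from the sparse, partial camera cloud into the
    # dense segmented surface: every camera point has a genuine
    # counterpart on the skin, whereas the reverse direction pairs
    # skin vertices outside the camera's field of view with arbitrary
    # points. The returned transform still moves the segmented surface
    # into the camera frame (the inverse of the fitted one).
    rmsInit <- sqrt(mean(nearestNeighbors(camROI, segROI)$distance^2))
    fit1 <- tryCatch(
        icp(camROI, segROI, trimFraction = 1,
            maxIterations = config$maxIterations,
            convergenceTol = config$convergenceTol, toSurface = TRUE),
        error = function(e) stop("ICP stage 1: ", conditionMessage(e),
                                 call. = FALSE))
    fit2 <- tryCatch(
        icp(camROI, segROI, init = fit1$transform,
            trimFraction = config$trimFraction,
            maxIterations = config$maxIterations,
            convergenceTol = config$convergenceTol, toSurface = TRUE),
        error = function(e) stop("ICP stage 2: ", conditionMessage(e),
                                 call. = FALSE))
    refine <- invertTransform(fit2$transform)
    final <- composeTransforms(refine, tInit)
    segReg <- applyTransform(segROI, refine)
    mapSeg <- perVertexDistance(segReg, camROI)
    mapCam <- perVertexDistance(camROI, segReg)
    hd <- max(mapSeg@distances, mapCam@distances)
    # residual quality is judged camera -> skin: every camera point
    # should lie on the registered surface, whereas skin -> camera
    # distances also reflect the sparse camera sampling
    over <- mean(mapCam@distances >= 5)
    if (over > 0.10)
        warning(sprintf(paste0(
            "co-registration error at/above 5 mm on %.1f%% of ROI ",
            "vertices (Hausdorff %.2f mm)"), 100 * over, hd))
    new("RegistrationResult",
        transform = final,
        perStageRMS = c(landmark = rmsInit, icp1 = fit1$finalRMS,
                        icp2 = fit2$finalRMS),
        hausdorff = hd,
        iterations = c(icp1 = fit1$iterations, icp2 = fit2$iterations),
        segROI = colorizeMesh(segReg, mapSeg),
        camROI = colorizeMesh(camROI, mapCam),
        details = list(rmsICP1 = fit1$rms, rmsICP2 = fit2$rms,
                       initTransform = tInit, config = config,
                       srcROI = segROI))
}

#' Apply the co-registration to the volume header
#'
#' A pose update only: the origin becomes \eqn{R\,origin + t} and the
#' direction matrix \eqn{R\,A}; voxel data are untouched (no resampling),
#' so the world coordinate of every voxel moves exactly by the rigid
#' transform. This is how the CT/MR image is brought into the reference
#' system of the ultrasound probe.
#'
#' @param vol a [VolumetricImage-class].
#' @param transform a [RigidTransform-class].
#' @return The re-posed [VolumetricImage-class].
#' @export
applyToVolume <- function(vol, transform) {
    stopifnot(is(transform, "RigidTransform"))
    vol@origin <- as.vector(transform@rotation %*% vol@origin) +
        transform@translation
    vol@axes <- transform@rotation %*% vol@axes
    validObject(vol)
    vol
}
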
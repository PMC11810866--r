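#' @include AllClasses.R volume-io.R
NULL

#' Slice-by-slice iso-value skin segmentation
#'
#' Labels every voxel of a CT/MR volume by growing the background region
#' slice by slice. A mock-up grid parallel to the image is initialised to
#' 2 everywhere. Per slice, growth starts from the corner pixels that lie
#' below the skin iso-value (the padding added by [padVolume()] guarantees
#' at least one such seed) and proceeds over 4-connected in-plane
#' neighbours: a visited pixel below the iso-value is background (label 0)
#' and its unvisited neighbours are queued; a pixel at or above the
#' iso-value is the body edge (label 1) and its neighbours are not
#' queued. Each pixel is evaluated at most once. Whatever the growth
#' never reaches -- the body interior, and any air pocket fully enclosed
#' by it -- keeps the initial label 2, so the body is segmented as a
#' whole object by exclusion.
#'
#' Subsampling and padding requested in `config` are applied internally
#' (in that order) before labelling; the returned grid carries the
#' processed volume so that surface extraction stays consistent.
#'
#' @param vol a [VolumetricImage-class].
#' @param config a [segmentationConfig()].
#' @return A [MockupGrid-class].
#' @seealso [binarizeMockup()], [extractSkinSurface()],
#'   [skinSurfaceFromVolume()]
#' @examples
#' vol <- makePhantomVolume(phantomSpec(shape = "ellipsoid",
#'     dims = c(24, 24, 12), spacing = c(4, 4, 6),
#'     semiAxes = c(36, 30, 28), noiseSigma = 0), seed = 1)$volume
#' grid <- segmentSkin(vol, segmentationConfig(isoValue = -400))
#' grid
#' @export
segmentSkin <- function(vol, config) {
    stopifnot(is(vol, "VolumetricImage"),
              inherits(config, "SegmentationConfig"))
    vol@sliceAxis <- config$sliceAxis
    if (any(config$subsampleFactor > 1L))
        vol <- subsampleVolume(vol, config$subsampleFactor)
    if (config$padWidth > 0L)
        vol <- padVolume(vol, config$padWidth)
    iso <- config$isoValue
    ax <- vol@sliceAxis
    perm <- c(setdiff(1:3, ax), ax)
    arr <- aperm(vol@data, perm)
    labs <- array(2L, dim(arr))
    for (k in seq_len(dim(arr)[3L]))
        labs[, , k] <- .growSlice(arr[, , k], iso, k)
    labs <- aperm(labs, order(perm))
    new("MockupGrid", labels = labs, isoValue = iso, volume = vol)
}

# Vectorised breadth-first growth on one slice. Equivalent to a FIFO
# queue: each sweep processes the whole current frontier at once, which
# leaves the result identical to any per-pixel visiting order.
.growSlice <- function(sl, iso, sliceIndex) {
    nr <- nrow(sl)
    nc <- ncol(sl)
    body <- sl >= iso
    corners <- cbind(c(1L, nr, 1L, nr), c(1L, 1L, nc, nc))
    seedOK <- !body[corners]
    if (!any(seedOK))
        stop("segmentation seed failure: all four corner pixels of slice ",
             sliceIndex, " are at or above the iso-value ", iso,
             "; pad the volume (padVolume) so the corners are background")
    lab <- matrix(2L, nr, nc)
    visited <- matrix(FALSE, nr, nc)
    frontier <- matrix(FALSE, nr, nc)
    frontier[corners[seedOK, , drop = FALSE]] <- TRUE
    while (any(frontier)) {
        visited <- visited | frontier
        bg <- frontier & !body
        lab[bg] <- 0L
        lab[frontier & body] <- 1L
        nb <- matrix(FALSE, nr, nc)
        nb[-nr, ] <- bg[-1, , drop = FALSE]
        nb[-1, ] <- nb[-1, , drop = FALSE] | bg[-nr, , drop = FALSE]
        nb[, -nc] <- nb[, -nc, drop = FALSE] | bg[, -1, drop = FALSE]
        nb[, -1] <- nb[, -1, drop = FALSE] | bg[, -nc, drop = FALSE]
        frontier <- nb & !visited
    }
    lab
}

#' Binarise a mock-up grid into a body mask
#'
#' Body edge (1) and never-reached voxels (2) together form the body;
#' internal air pockets are unreachable from outside and therefore count
#' as body, matching the by-exclusion semantics of the region growing.
#'
#' @param grid a [MockupGrid-class].
#' @return A 3D integer array, 1 = body, 0 = background.
#' @export
binarizeMockup <- function(grid) {
    mask <- array(1L, dim(grid@labels))
    mask[grid@labels == 0L] <- 0L
    mask
}
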
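#' @include AllClasses.R
NULL

#' World coordinates of voxel indices
#'
#' Maps 0-based voxel indices to world mm via
#' \eqn{origin + A (spacing \circ index)}.
#'
#' @param vol a [VolumetricImage-class].
#' @param index N x 3 matrix of 0-based voxel indices (may be fractional).
#' @return N x 3 matrix of world coordinates in mm.
#' @export
voxelToWorld <- function(vol, index) {
    index <- matrix(as.numeric(index), ncol = 3L)
    scaled <- sweep(index, 2L, vol@spacing, "*")
    sweep(scaled %*% t(vol@axes), 2L, vol@origin, "+")
}

#' Read a volumetric image
#'
#' Reads a 3D scalar volume from NIfTI-1 (`.nii`/`.nii.gz`) or MetaImage
#' (`.mha`/`.mhd`+`.raw`) into a [VolumetricImage-class]. Intensities are
#' passed through untouched; spacing, origin and direction matrix are
#' taken from the header. A header whose direction matrix is not
#' orthonormal and right-handed is rejected.
#'
#' @param path file to read.
#' @param format `"nifti"` or `"metaimage"`; guessed from the extension
#'   by default.
#' @return A [VolumetricImage-class].
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path, format = c("auto", "nifti", "metaimage")) {
    format <- match.arg(format)
    if (format == "auto") format <- .guessVolumeFormat(path)
    if (!file.exists(path)) stop("file not found: ", path)
    switch(format,
        nifti = .readNiftiVolume(path),
        metaimage = .readMetaImage(path))
}

#' Write a volumetric image
#'
#' @param vol a [VolumetricImage-class].
#' @param path output file; extension selects the on-disk layout for
#'   MetaImage (`.mha` embeds the raw block, `.mhd` writes a companion
#'   `.raw`).
#' @param format `"nifti"` or `"metaimage"`; guessed from the extension
#'   by default.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(vol, path, format = c("auto", "nifti", "metaimage")) {
    format <- match.arg(format)
    if (format == "auto") format <- .guessVolumeFormat(path)
    switch(format,
        nifti = .writeNiftiVolume(vol, path),
        metaimage = .writeMetaImage(vol, path))
    invisible(path)
}

.guessVolumeFormat <- function(path) {
    low <- tolower(path)
    if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
    if (grepl("\\.(mha|mhd)$", low)) return("metaimage")
    stop("cannot guess volume format from extension of: ", path)
}

.readNiftiVolume <- function(path) {
    img <- RNifti::readNifti(path)
    a <- as.array(img)
    a <- array(as.vector(a), dim(a))   # plain array, no image class
    if (length(dim(a)) == 4L && dim(a)[4] == 1L)
        a <- array(a, dim(a)[1:3])
    if (length(dim(a)) != 3L)
        stop("format error: expected a 3D volume, got ",
             length(dim(a)), "D data in ", path)
    x <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
    m <- x[1:3, 1:3]
    sp <- sqrt(colSums(m^2))
    if (any(sp <= 0) || any(!is.finite(sp)))
        stop("format error: degenerate voxel spacing in header of ", path)
    axes <- sweep(m, 2L, sp, "/")
    if (!.isOrthonormal(axes, tol = 1e-4))
        stop("format error: direction matrix (srow/qform) of ", path,
             " is not orthonormal")
    if (det(axes) < 0)
        stop("format error: direction matrix of ", path,
             " is left-handed (determinant -1); re-orient the volume")
    # re-orthonormalise exactly (header rounding)
    s <- svd(axes)
    axes <- s$u %*% t(s$v)
    volumetricImage(a, spacing = sp, origin = x[1:3, 4], axes = axes)
}

.writeNiftiVolume <- function(vol, path) {
    img <- RNifti::asNifti(vol@data)
    RNifti::pixdim(img) <- vol@spacing
    m <- diag(4)
    m[1:3, 1:3] <- vol@axes %*% diag(vol@spacing)
    m[1:3, 4] <- vol@origin
    img <- RNifti::`sform<-`(img, structure(m, code = 2L))
    img <- RNifti::`qform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, path)
}

#' Pad each slice with background
#'
#' Adds a `padWidth`-voxel border around every 2D slice, filled with the
#' global minimum intensity of the volume, so that the slice corners are
#' guaranteed background for the region growing even when the scanner bed
#' or the body touches the slice border. The slice count is unchanged and
#' the origin is shifted so every original voxel keeps its world
#' coordinates.
#'
#' @param vol a [VolumetricImage-class].
#' @param padWidth border width in voxels (>= 0); a
#'   \code{"SegmentationConfig"} may be given instead.
#' @return The padded [VolumetricImage-class].
#' @examples
#' vol <- volumetricImage(array(1, c(8, 8, 3)))
#' dim(padVolume(vol, 1))  # 10 x 10 x 3
#' @export
padVolume <- function(vol, padWidth = 1L) {
    if (inherits(padWidth, "SegmentationConfig"))
        padWidth <- padWidth$padWidth
    p <- as.integer(padWidth)
    if (p < 0L) stop("'padWidth' must be >= 0")
    if (p == 0L) return(vol)
    d <- dim(vol@data)
    ax <- vol@sliceAxis
    inPlane <- setdiff(1:3, ax)
    nd <- d
    nd[inPlane] <- nd[inPlane] + 2L * p
    filled <- array(min(vol@data), nd)
    idx <- lapply(1:3, function(a)
        if (a == ax) seq_len(d[a]) else p + seq_len(d[a]))
    filled[idx[[1]], idx[[2]], idx[[3]]] <- vol@data
    offset <- ifelse(1:3 == ax, 0, p)
    origin <- vol@origin - as.vector(vol@axes %*% (offset * vol@spacing))
    volumetricImage(filled, spacing = vol@spacing, origin = origin,
                    axes = vol@axes, sliceAxis = ax)
}

#' Subsample a volume by decimation
#'
#' Keeps every `factor`-th voxel starting at index 0 along each axis;
#' spacing is multiplied accordingly and the origin is unchanged (voxel
#' (0,0,0) is always retained). Decimation is deliberately unfiltered:
#' the point is to probe the segmentation's robustness to the raw
#' lower-resolution image, not to a smoothed one.
#'
#' @param vol a [VolumetricImage-class].
#' @param factor integer >= 1, scalar or per-axis length-3.
#' @return The decimated [VolumetricImage-class].
#' @examples
#' vol <- volumetricImage(array(0, c(64, 64, 32)))
#' dim(subsampleVolume(vol, 2))  # 32 x 32 x 16
#' @export
subsampleVolume <- function(vol, factor) {
    f <- as.integer(rep_len(factor, 3L))
    if (any(f < 1L)) stop("'factor' must be >= 1")
    d <- dim(vol@data)
    if (any(f > d))
        stop("subsampling factor (", paste(f, collapse = ","),
             ") exceeds volume dimensions (", paste(d, collapse = ","), ")")
    if (all(f == 1L)) return(vol)
    keep <- lapply(1:3, function(a) seq(1L, d[a], by = f[a]))
    volumetricImage(vol@data[keep[[1]], keep[[2]], keep[[3]], drop = FALSE],
                    spacing = vol@spacing * f, origin = vol@origin,
                    axes = vol@axes, sliceAxis = vol@sliceAxis)
}
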
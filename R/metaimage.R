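#' @include AllClasses.R
NULL

# MetaImage (ITK .mha/.mhd) support. The format is a short key = value
# text header followed by (or pointing at) a raw little-endian voxel
# block; no reader for it exists among the available packages, so it is
# implemented here directly.

.metaTypes <- list(
    MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
    MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
    MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
    MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
    MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
    MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
    MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE)
)

.readMetaImage <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    hdr <- list()
    repeat {
        line <- readLines(con, n = 1L, warn = FALSE)
        if (length(line) == 0L)
            stop("format error: MetaImage header of ", path,
                 " has no ElementDataFile field")
        kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$",
                                       line))[[1]]
        if (length(kv) != 3L)
            stop("format error: malformed MetaImage header line: ", line)
        hdr[[kv[2]]] <- trimws(kv[3])
        if (kv[2] == "ElementDataFile") break
    }
    need <- function(field) {
        if (is.null(hdr[[field]]))
            stop("format error: MetaImage header of ", path,
                 " is missing field '", field, "'")
        hdr[[field]]
    }
    if (!identical(as.integer(need("NDims")), 3L))
        stop("format error: field 'NDims' must be 3, got ", hdr$NDims)
    dims <- as.integer(strsplit(need("DimSize"), "\\s+")[[1]])
    spacing <- if (!is.null(hdr$ElementSpacing))
        as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
    origin <- if (!is.null(hdr$Offset))
        as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
    axes <- if (!is.null(hdr$TransformMatrix))
        t(matrix(as.numeric(strsplit(hdr$TransformMatrix, "\\s+")[[1]]),
                 3L, 3L)) else diag(3)
    if (!.isOrthonormal(axes, tol = 1e-4))
        stop("format error: field 'TransformMatrix' of ", path,
             " is not orthonormal")
    if (det(axes) < 0)
        stop("format error: field 'TransformMatrix' of ", path,
             " is left-handed (determinant -1)")
    type <- .metaTypes[[need("ElementType")]]
    if (is.null(type))
        stop("format error: unsupported field 'ElementType' value ",
             hdr$ElementType)
    if (!is.null(hdr$CompressedData) &&
        tolower(hdr$CompressedData) == "true")
        stop("format error: field 'CompressedData' = True is unsupported")
    msb <- !is.null(hdr$BinaryDataByteOrderMSB) &&
        tolower(hdr$BinaryDataByteOrderMSB) == "true"
    n <- prod(dims)
    if (identical(hdr$ElementDataFile, "LOCAL")) {
        raw <- readBin(con, type$what, n = n, size = type$size,
                       signed = type$signed,
                       endian = if (msb) "big" else "little")
    } else {
        rawPath <- file.path(dirname(path), hdr$ElementDataFile)
        if (!file.exists(rawPath))
            stop("format error: field 'ElementDataFile' points to missing ",
                 rawPath)
        rcon <- file(rawPath, "rb")
        on.exit(close(rcon), add = TRUE)
        raw <- readBin(rcon, type$what, n = n, size = type$size,
                       signed = type$signed,
                       endian = if (msb) "big" else "little")
    }
    if (length(raw) != n)
        stop("format error: raw block of ", path, " holds ", length(raw),
             " voxels, header promises ", n)
    s <- svd(axes)
    volumetricImage(array(as.numeric(raw), dims), spacing = spacing,
                    origin = origin, axes = s$u %*% t(s$v))
}

.writeMetaImage <- function(vol, path) {
    local <- grepl("\\.mha$", tolower(path))
    rawName <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
    hdr <- c(
        "ObjectType = Image",
        "NDims = 3",
        "BinaryData = True",
        "BinaryDataByteOrderMSB = False",
        "CompressedData = False",
        paste("TransformMatrix =",
              paste(format(as.vector(t(vol@axes)), digits = 17),
                    collapse = " ")),
        paste("Offset =",
              paste(format(vol@origin, digits = 17), collapse = " ")),
        paste("ElementSpacing =",
              paste(format(vol@spacing, digits = 17), collapse = " ")),
        paste("DimSize =", paste(dim(vol@data), collapse = " ")),
        "ElementType = MET_DOUBLE",
        paste("ElementDataFile =", if (local) "LOCAL" else rawName)
    )
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    if (local) {
        writeBin(as.numeric(vol@data), con, size = 8L, endian = "little")
    } else {
        rcon <- file(file.path(dirname(path), rawName), "wb")
        on.exit(close(rcon), add = TRUE)
        writeBin(as.numeric(vol@data), rcon, size = 8L, endian = "little")
    }
    invisible(path)
}
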
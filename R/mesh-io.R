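#' @include AllClasses.R
NULL

#' Write a triangle mesh to PLY, STL or OBJ
#'
#' ASCII variants of the three formats are produced. PLY carries vertex
#' normals, per-vertex RGB (as `uchar red/green/blue`, e.g. a registration
#' error colour map) and the scalar field (as `float quality`) when
#' present; OBJ carries normals; STL stores triangles only (vertices are
#' deduplicated again on reading).
#'
#' @param mesh a [TriangleMesh-class].
#' @param path output file.
#' @param format `"ply"`, `"stl"` or `"obj"`; guessed from the extension
#'   by default.
#' @return `path`, invisibly.
#' @seealso [readMesh()]
#' @export
writeMesh <- function(mesh, path, format = c("auto", "ply", "stl", "obj")) {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(sub(".*\\.", "", path))
        if (!ext %in% c("ply", "stl", "obj"))
            stop("unsupported mesh format: ", ext)
        format <- ext
    }
    switch(format,
        ply = .writePly(mesh, path),
        stl = .writeStl(mesh, path),
        obj = .writeObj(mesh, path))
    invisible(path)
}

#' Read a triangle mesh
#'
#' @param path an ASCII PLY, STL or OBJ file.
#' @param format format override; guessed from the extension by default.
#' @return A [TriangleMesh-class].
#' @export
readMesh <- function(path, format = c("auto", "ply", "stl", "obj")) {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(sub(".*\\.", "", path))
        if (!ext %in% c("ply", "stl", "obj"))
            stop("unsupported mesh format: ", ext)
        format <- ext
    }
    if (!file.exists(path)) stop("file not found: ", path)
    switch(format,
        ply = .readPly(path),
        stl = .readStl(path),
        obj = .readObj(path))
}

.fmtRow <- function(m) {
    apply(m, 1L, function(r) paste(format(r, digits = 9, trim = TRUE,
                                          scientific = FALSE),
                                   collapse = " "))
}

.writePly <- function(mesh, path) {
    nv <- nrow(mesh@vertices)
    hasN <- nrow(mesh@normals) == nv && nv > 0L
    hasC <- nrow(mesh@colors) == nv && nv > 0L
    hasS <- length(mesh@scalar) == nv && nv > 0L
    props <- c("property float x", "property float y", "property float z")
    if (hasN) props <- c(props, "property float nx", "property float ny",
                         "property float nz")
    if (hasC) props <- c(props, "property uchar red", "property uchar green",
                         "property uchar blue")
    if (hasS) props <- c(props, "property float quality")
    hdr <- c("ply", "format ascii 1.0", "comment produced by SkinFusion",
             paste("element vertex", nv), props,
             paste("element face", nrow(mesh@triangles)),
             "property list uchar int vertex_indices", "end_header")
    block <- mesh@vertices
    if (hasN) block <- cbind(block, mesh@normals)
    vlines <- .fmtRow(block)
    if (hasC) vlines <- paste(vlines, .fmtRow(mesh@colors))
    if (hasS) vlines <- paste(vlines,
                              format(mesh@scalar, digits = 9, trim = TRUE,
                                     scientific = FALSE))
    flines <- if (nrow(mesh@triangles) > 0L)
        paste("3", .fmtRow(mesh@triangles - 1L)) else character(0)
    writeLines(c(hdr, vlines, flines), path)
}

.readPly <- function(path) {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) == 0L || trimws(lines[1]) != "ply")
        stop("format error: not a PLY file (missing 'ply' magic): ", path)
    endHdr <- match("end_header", trimws(lines))
    if (is.na(endHdr)) stop("format error: PLY header not terminated")
    hdr <- trimws(lines[seq_len(endHdr)])
    if (!any(grepl("^format\\s+ascii", hdr)))
        stop("format error: only ASCII PLY is supported")
    counts <- list(); propNames <- list(); current <- NULL
    for (h in hdr) {
        tok <- strsplit(h, "\\s+")[[1]]
        if (tok[1] == "element") {
            current <- tok[2]
            counts[[current]] <- as.integer(tok[3])
            propNames[[current]] <- character(0)
        } else if (tok[1] == "property" && !is.null(current) &&
                   tok[2] != "list") {
            propNames[[current]] <- c(propNames[[current]], tok[3])
        }
    }
    nv <- counts$vertex %||% 0L
    nf <- counts$face %||% 0L
    body <- lines[-seq_len(endHdr)]
    body <- body[nzchar(trimws(body))]
    vl <- body[seq_len(nv)]
    vp <- propNames$vertex
    vm <- matrix(as.numeric(unlist(strsplit(trimws(vl), "\\s+"))),
                 nrow = nv, byrow = TRUE)
    colnames(vm) <- vp[seq_len(ncol(vm))]
    pick <- function(cols) if (all(cols %in% vp))
        vm[, cols, drop = FALSE] else NULL
    verts <- pick(c("x", "y", "z"))
    if (is.null(verts)) stop("format error: PLY misses x/y/z properties")
    tri <- NULL
    if (nf > 0L) {
        fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
        tri <- t(vapply(fl, function(tok) {
            k <- as.integer(tok[1])
            if (k != 3L) stop("format error: non-triangular PLY face")
            as.integer(tok[2:4]) + 1L
        }, integer(3)))
    }
    nrm <- pick(c("nx", "ny", "nz"))
    if (!is.null(nrm)) {  # renormalise: stored single precision
        len <- sqrt(rowSums(nrm^2))
        nrm[len > 0, ] <- nrm[len > 0, , drop = FALSE] / len[len > 0]
    }
    triangleMesh(verts, tri, normals = nrm,
                 scalar = if ("quality" %in% vp) vm[, "quality"] else NULL,
                 colors = pick(c("red", "green", "blue")))
}

.writeStl <- function(mesh, path) {
    v <- mesh@vertices
    tr <- mesh@triangles
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid skinfusion", con)
    if (nrow(tr) > 0L) {
        a <- v[tr[, 1], , drop = FALSE]
        b <- v[tr[, 2], , drop = FALSE]
        cc <- v[tr[, 3], , drop = FALSE]
        n <- .rowCross(b - a, cc - a)
        len <- sqrt(rowSums(n^2))
        n[len > 0, ] <- n[len > 0, , drop = FALSE] / len[len > 0]
        fmt <- function(m) apply(m, 1L, function(r)
            paste(format(r, digits = 9, trim = TRUE, scientific = TRUE),
                  collapse = " "))
        writeLines(paste0(
            "facet normal ", fmt(n), "\n outer loop\n  vertex ", fmt(a),
            "\n  vertex ", fmt(b), "\n  vertex ", fmt(cc),
            "\n endloop\nendfacet"), con)
    }
    writeLines("endsolid skinfusion", con)
}

.readStl <- function(path) {
    lines <- trimws(readLines(path, warn = FALSE))
    if (!grepl("^solid", lines[1]))
        stop("format error: only ASCII STL is supported (missing 'solid')")
    vl <- lines[startsWith(lines, "vertex")]
    if (length(vl) %% 3L != 0L)
        stop("format error: STL vertex count not a multiple of 3")
    coords <- matrix(as.numeric(unlist(strsplit(sub("^vertex\\s+", "", vl),
                                                "\\s+"))),
                     ncol = 3L, byrow = TRUE)
    key <- apply(coords, 1L, paste, collapse = "|")
    uid <- match(key, unique(key))
    verts <- coords[!duplicated(key), , drop = FALSE]
    tri <- matrix(uid, ncol = 3L, byrow = TRUE)
    triangleMesh(verts, tri)
}

.writeObj <- function(mesh, path) {
    v <- paste("v", .fmtRow(mesh@vertices))
    out <- v
    hasN <- nrow(mesh@normals) == nrow(mesh@vertices) &&
        nrow(mesh@vertices) > 0L
    if (hasN) out <- c(out, paste("vn", .fmtRow(mesh@normals)))
    if (nrow(mesh@triangles) > 0L) {
        f <- if (hasN) {
            idx <- apply(mesh@triangles, 1L, function(t)
                paste(sprintf("%d//%d", t, t), collapse = " "))
            paste("f", idx)
        } else paste("f", .fmtRow(mesh@triangles))
        out <- c(out, f)
    }
    writeLines(out, path)
}

.readObj <- function(path) {
    lines <- trimws(readLines(path, warn = FALSE))
    vl <- lines[startsWith(lines, "v ")]
    verts <- matrix(as.numeric(unlist(strsplit(sub("^v\\s+", "", vl),
                                               "\\s+"))),
                    ncol = 3L, byrow = TRUE)
    nl <- lines[startsWith(lines, "vn ")]
    nrm <- if (length(nl) == nrow(verts))
        matrix(as.numeric(unlist(strsplit(sub("^vn\\s+", "", nl), "\\s+"))),
               ncol = 3L, byrow = TRUE) else NULL
    fl <- lines[startsWith(lines, "f ")]
    tri <- NULL
    if (length(fl) > 0L) {
        tri <- t(vapply(strsplit(sub("^f\\s+", "", fl), "\\s+"),
                        function(tok) {
            if (length(tok) != 3L)
                stop("format error: non-triangular OBJ face")
            as.integer(sub("/.*$", "", tok))
        }, integer(3)))
    }
    if (!is.null(nrm)) {
        len <- sqrt(rowSums(nrm^2))
        nrm[len > 0, ] <- nrm[len > 0, , drop = FALSE] / len[len > 0]
    }
    triangleMesh(verts, tri, normals = nrm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.rowCross <- function(a, b) {
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
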
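#' @include AllClasses.R segmentation.R
NULL

#' Extract the skin surface mesh from a segmentation
#'
#' Runs a marching isosurface extraction at level 0.5 on the binarised
#' segmentation mask (not on the raw intensities: binarisation removes
#' internal anatomy that intensity isosurfacing would pick up). Each grid
#' cell is decomposed into the six Kuhn tetrahedra, whose shared face
#' diagonals are globally consistent, so the extracted mesh is watertight
#' by construction; on a binary field the level-0.5 crossing puts every
#' vertex at the midpoint of an inside/outside cell edge. The mask is
#' enclosed in a one-voxel background shell first so that a body touching
#' the volume border still yields a closed surface. Vertex coordinates
#' are returned in world mm; triangle winding and vertex normals point
#' outwards.
#'
#' @param grid a [MockupGrid-class] from [segmentSkin()].
#' @param vol the volume the labels refer to; defaults to the one carried
#'   by the grid.
#' @return A watertight [TriangleMesh-class] with outward vertex normals.
#' @seealso [segmentSkin()], [isWatertight()]
#' @export
extractSkinSurface <- function(grid, vol = gridVolume(grid)) {
    mask <- binarizeMockup(grid)
    if (!identical(dim(mask), dim(vol@data)))
        stop("label grid and volume dimensions differ")
    if (all(mask == 1L) || all(mask == 0L))
        stop("no iso-surface: segmentation mask is ",
             if (all(mask == 1L)) "full" else "empty")
    vertexNormals(.marchingTets(mask, vol))
}

#' Segment a volume and extract its skin surface
#'
#' Convenience wrapper: [segmentSkin()] followed by
#' [extractSkinSurface()].
#'
#' @inheritParams segmentSkin
#' @return A [TriangleMesh-class] in world mm.
#' @export
skinSurfaceFromVolume <- function(vol, config) {
    extractSkinSurface(segmentSkin(vol, config))
}

# The six Kuhn tetrahedra of the unit cell, as corner ids 0..7 with
# id = ox + 2*oy + 4*oz. All share the main diagonal 0-7; every cell uses
# the same decomposition, so face diagonals agree between neighbours.
.kuhnTets <- rbind(
    c(0L, 1L, 3L, 7L), c(0L, 1L, 5L, 7L), c(0L, 2L, 3L, 7L),
    c(0L, 2L, 6L, 7L), c(0L, 4L, 5L, 7L), c(0L, 4L, 6L, 7L))

# Sign cases for one tetrahedron, indexed by the 4-bit inside code of
# slots (a,b,c,d). Each triangle is a 3 x 2 matrix of slot pairs, one
# iso-vertex per inside/outside edge.
.tetCases <- local({
    cases <- vector("list", 14L)
    for (code in 1:14) {
        ins <- which(bitwAnd(code, c(1L, 2L, 4L, 8L)) > 0L)
        outs <- setdiff(1:4, ins)
        tris <- if (length(ins) == 1L) {
            x <- ins
            list(rbind(c(x, outs[1]), c(x, outs[2]), c(x, outs[3])))
        } else if (length(ins) == 3L) {
            x <- outs
            list(rbind(c(ins[1], x), c(ins[2], x), c(ins[3], x)))
        } else {
            x <- ins[1]; y <- ins[2]; p <- outs[1]; q <- outs[2]
            list(rbind(c(x, p), c(x, q), c(y, q)),
                 rbind(c(x, p), c(y, q), c(y, p)))
        }
        cases[[code]] <- list(tris = tris, ins = ins, outs = outs)
    }
    cases
})

.marchingTets <- function(mask, vol) {
    d <- dim(mask)
    nx <- d[1] + 2L; ny <- d[2] + 2L; nz <- d[3] + 2L
    ntot <- as.numeric(nx) * ny * nz
    if (ntot^2 >= 2^53)
        stop("volume too large for exact edge keys; subsample first")
    m <- array(0L, c(nx, ny, nz))
    m[2:(nx - 1L), 2:(ny - 1L), 2:(nz - 1L)] <- mask
    cx <- nx - 1L; cy <- ny - 1L; cz <- nz - 1L
    off <- cbind(ox = rep(0:1, 4), oy = rep(rep(0:1, each = 2), 2),
                 oz = rep(0:1, each = 4))
    corner <- vector("list", 8L)
    for (ci in 1:8)
        corner[[ci]] <- as.integer(m[off[ci, 1] + 1:cx, off[ci, 2] + 1:cy,
                                     off[ci, 3] + 1:cz])
    total <- Reduce(`+`, corner)
    act <- which(total > 0L & total < 8L)
    a0 <- act - 1
    ci <- a0 %% cx
    cj <- (a0 %/% cx) %% cy
    ck <- a0 %/% (cx * cy)
    gids <- lapply(1:8, function(c)
        (ci + off[c, 1]) + nx * (cj + off[c, 2]) +
            (as.numeric(nx) * ny) * (ck + off[c, 3]))
    flags <- lapply(1:8, function(c) corner[[c]][act] == 1L)
    eMin <- list(); eMax <- list(); dirIdx <- list(); ne <- 0L
    for (t in seq_len(nrow(.kuhnTets))) {
        slot <- .kuhnTets[t, ] + 1L           # local corner ids -> 1..8
        f <- lapply(slot, function(s) flags[[s]])
        code <- f[[1]] + 2L * f[[2]] + 4L * f[[3]] + 8L * f[[4]]
        for (cs in 1:14) {
            idx <- which(code == cs)
            if (!length(idx)) next
            case <- .tetCases[[cs]]
            # inside -> outside direction of this tet, in index space
            slotPos <- lapply(1:4, function(s)
                cbind(ci[idx] + off[slot[s], 1], cj[idx] + off[slot[s], 2],
                      ck[idx] + off[slot[s], 3]))
            pin <- Reduce(`+`, slotPos[case$ins]) / length(case$ins)
            pout <- Reduce(`+`, slotPos[case$outs]) / length(case$outs)
            dd <- pout - pin
            for (tri in case$tris) {
                g1 <- cbind(gids[[slot[tri[1, 1]]]][idx],
                            gids[[slot[tri[2, 1]]]][idx],
                            gids[[slot[tri[3, 1]]]][idx])
                g2 <- cbind(gids[[slot[tri[1, 2]]]][idx],
                            gids[[slot[tri[2, 2]]]][idx],
                            gids[[slot[tri[3, 2]]]][idx])
                ne <- ne + 1L
                eMin[[ne]] <- pmin(g1, g2)
                eMax[[ne]] <- pmax(g1, g2)
                dirIdx[[ne]] <- dd
            }
        }
    }
    if (ne == 0L) stop("no iso-surface: no mixed cells found")
    E1 <- do.call(rbind, eMin)
    E2 <- do.call(rbind, eMax)
    dirs <- do.call(rbind, dirIdx)
    key <- E1 * ntot + E2
    ukey <- unique(as.vector(key))
    vid <- match(key, ukey)                    # column-major fill
    tri <- matrix(vid, ncol = 3L)
    # unique iso-vertices: midpoints of their padded-grid cell edge
    decode <- function(g) cbind(g %% nx, (g %/% nx) %% ny,
                                g %/% (as.numeric(nx) * ny))
    p1 <- decode(ukey %/% ntot) - 1           # back to 0-based voxel index
    p2 <- decode(ukey %% ntot) - 1
    verts <- (voxelToWorld(vol, p1) + voxelToWorld(vol, p2)) / 2
    # orient triangles so normals point from inside to outside
    dirW <- sweep(dirs, 2L, vol@spacing, "*") %*% t(vol@axes)
    v1 <- verts[tri[, 1], , drop = FALSE]
    n <- .rowCross(verts[tri[, 2], , drop = FALSE] - v1,
                   verts[tri[, 3], , drop = FALSE] - v1)
    flip <- rowSums(n * dirW) < 0
    tri[flip, 2:3] <- tri[flip, 3:2]
    triangleMesh(verts, tri)
}

#' Is a mesh watertight and consistently oriented?
#'
#' A closed manifold mesh has every undirected edge shared by exactly two
#' triangles, traversed once in each direction.
#'
#' @param mesh a [TriangleMesh-class].
#' @return `TRUE` or `FALSE`.
#' @export
isWatertight <- function(mesh) {
    tr <- mesh@triangles
    if (nrow(tr) == 0L) return(FALSE)
    he <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
    keyD <- paste(he[, 1], he[, 2])
    if (anyDuplicated(keyD)) return(FALSE)     # inconsistent orientation
    keyU <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
    all(table(keyU) == 2L)
}
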
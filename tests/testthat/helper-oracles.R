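# Independent brute-force oracles the fast implementations are checked
# against. These deliberately share no code with the package internals.

# Stack-based 2D flood fill replicating the background growing rule:
# start from every below-threshold corner, visit 4-neighbours, label
# reached below-threshold pixels 0 and reached at/above-threshold pixels
# 1 (without expanding through them); everything else keeps 2.
floodFillOracle <- function(sl, iso) {
    nr <- nrow(sl)
    nc <- ncol(sl)
    lab <- matrix(2L, nr, nc)
    seen <- matrix(FALSE, nr, nc)
    stack <- list()
    for (cr in list(c(1L, 1L), c(nr, 1L), c(1L, nc), c(nr, nc)))
        if (sl[cr[1], cr[2]] < iso) stack[[length(stack) + 1L]] <- cr
    while (length(stack) > 0L) {
        px <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        i <- px[1]; j <- px[2]
        if (seen[i, j]) next
        seen[i, j] <- TRUE
        if (sl[i, j] >= iso) {
            lab[i, j] <- 1L       # body edge: do not expand
            next
        }
        lab[i, j] <- 0L
        for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L),
                        c(i, j + 1L)))
            if (nb[1] >= 1L && nb[1] <= nr && nb[2] >= 1L && nb[2] <= nc &&
                !seen[nb[1], nb[2]])
                stack[[length(stack) + 1L]] <- nb
    }
    lab
}

# O(n*m) nearest-neighbour distances, coordinate sums in the same x,y,z
# order as the k-d tree so agreement is exact.
bruteNNDist <- function(query, target) {
    vapply(seq_len(nrow(query)), function(i) {
        d2 <- (query[i, 1] - target[, 1])^2 +
              (query[i, 2] - target[, 2])^2 +
              (query[i, 3] - target[, 3])^2
        sqrt(min(d2))
    }, numeric(1))
}

bruteDirectedHausdorff <- function(a, b) max(bruteNNDist(a, b))

bruteHausdorff <- function(a, b)
    max(bruteDirectedHausdorff(a, b), bruteDirectedHausdorff(b, a))

randomCloud <- function(n, seed, scale = 100) {
    withSeed(seed, matrix(stats::runif(n * 3, -scale, scale), ncol = 3))
}

# Icosphere: subdivided icosahedron, the standard quasi-uniform sphere
# triangulation (outward winding).
icosphere <- function(subdiv = 3L, radius = 1, center = c(0, 0, 0)) {
    phi <- (1 + sqrt(5)) / 2
    v <- rbind(
        c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
        c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
        c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
    v <- v / sqrt(rowSums(v^2))
    f <- rbind(
        c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
        c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
        c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
        c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
    for (s in seq_len(subdiv)) {
        edgeId <- new.env()
        nv <- nrow(v)
        midpoint <- function(a, b) {
            key <- paste(min(a, b), max(a, b))
            id <- edgeId[[key]]
            if (is.null(id)) {
                m <- v[a, ] + v[b, ]
                v <<- rbind(v, m / sqrt(sum(m^2)))
                id <- nrow(v)
                edgeId[[key]] <- id
            }
            id
        }
        nf <- matrix(0L, 0L, 3L)
        for (t in seq_len(nrow(f))) {
            a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
            ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
            nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc),
                        c(ab, bc, ca))
        }
        f <- nf
    }
    triangleMesh(sweep(v * radius, 2L, center, "+"), f)
}

# flat triangulated plate in the z = 0 plane, CCW seen from +z
flatPlate <- function(n = 5L, width = 10) {
    xs <- seq(0, width, length.out = n)
    g <- as.matrix(expand.grid(x = xs, y = xs))
    verts <- cbind(g, 0)
    id <- function(i, j) (j - 1L) * n + i
    tris <- matrix(0L, 0L, 3L)
    for (j in seq_len(n - 1L))
        for (i in seq_len(n - 1L))
            tris <- rbind(tris,
                          c(id(i, j), id(i + 1L, j), id(i + 1L, j + 1L)),
                          c(id(i, j), id(i + 1L, j + 1L), id(i, j + 1L)))
    triangleMesh(verts, tris)
}

randomRigid <- function(seed, maxAngle = 20, maxTrans = 50) {
    withSeed(seed, {
        ax <- stats::rnorm(3)
        ang <- stats::runif(1, 0, maxAngle)
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        rotationAboutAxis(ax, ang,
                          translation = dir * stats::runif(1, 0, maxTrans))
    })
}
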
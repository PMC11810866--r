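#' @include AllClasses.R
NULL

#' Construct rigid transforms
#'
#' `rigidTransform` builds \eqn{x \mapsto R x + t} from a rotation matrix
#' and translation; `identityTransform` is the identity pose;
#' `rotationAboutAxis` builds a rotation from an axis and an angle in
#' degrees (Rodrigues' formula); `eulerRotation` composes rotations about
#' the world x, y and z axes (applied in that order, angles in degrees).
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation numeric(3) in mm.
#' @return A [RigidTransform-class].
#' @examples
#' T1 <- rotationAboutAxis(c(0, 0, 1), 10, translation = c(5, -3, 2))
#' rotationAngle(T1)
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
    new("RigidTransform", rotation = rotation,
        translation = as.numeric(translation))
}

#' @rdname rigidTransform
#' @export
identityTransform <- function() rigidTransform()

#' @rdname rigidTransform
#' @param axis rotation axis (need not be unit length).
#' @param angle rotation angle in degrees.
#' @export
rotationAboutAxis <- function(axis, angle, translation = c(0, 0, 0)) {
    u <- axis / sqrt(sum(axis^2))
    th <- angle * pi / 180
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    rigidTransform(R, translation)
}

#' @rdname rigidTransform
#' @param angles numeric(3), rotations about x, y, z in degrees.
#' @export
eulerRotation <- function(angles, translation = c(0, 0, 0)) {
    Rx <- rotation(rotationAboutAxis(c(1, 0, 0), angles[1]))
    Ry <- rotation(rotationAboutAxis(c(0, 1, 0), angles[2]))
    Rz <- rotation(rotationAboutAxis(c(0, 0, 1), angles[3]))
    rigidTransform(Rz %*% Ry %*% Rx, translation)
}

#' Compose, invert and measure rigid transforms
#'
#' `composeTransforms(a, b)` returns the transform applying `b` first and
#' then `a` (so \eqn{x \mapsto R_a (R_b x + t_b) + t_a}).
#' `invertTransform` returns the exact inverse. `rotationAngle` gives the
#' rotation angle of a transform in degrees; `rotationBetween(a, b)` the
#' angular difference (degrees) between the two rotations, a convenient
#' scalar for "how different are these two recovered poses".
#'
#' @param a,b,x [RigidTransform-class] objects.
#' @return A [RigidTransform-class], or degrees for the angle helpers.
#' @examples
#' T1 <- rotationAboutAxis(c(0, 0, 1), 30)
#' rotationAngle(composeTransforms(T1, invertTransform(T1)))
#' @export
composeTransforms <- function(a, b) {
    rigidTransform(a@rotation %*% b@rotation,
                   as.vector(a@rotation %*% b@translation) + a@translation)
}

#' @rdname composeTransforms
#' @export
invertTransform <- function(x) {
    Rt <- t(x@rotation)
    rigidTransform(Rt, -as.vector(Rt %*% x@translation))
}

#' @rdname composeTransforms
#' @export
rotationAngle <- function(x) {
    R <- if (is(x, "RigidTransform")) x@rotation else x
    # clamp for numerical safety: trace can exceed 3 by rounding
    c <- (sum(diag(R)) - 1) / 2
    acos(min(1, max(-1, c))) * 180 / pi
}

#' @rdname composeTransforms
#' @export
rotationBetween <- function(a, b) {
    rotationAngle(rotation(a) %*% t(rotation(b)))
}

#' Euler angles of a rotation
#'
#' Decomposes a rotation matrix as \eqn{R = R_z R_y R_x} (the convention
#' of [eulerRotation()]) and returns the three angles in degrees, the
#' form in which per-axis rotation robustness is reported.
#'
#' @param R 3x3 rotation matrix or a [RigidTransform-class].
#' @return numeric(3), degrees about x, y, z.
#' @export
eulerAngles <- function(R) {
    if (is(R, "RigidTransform")) R <- R@rotation
    ry <- asin(min(1, max(-1, -R[3, 1])))
    if (abs(cos(ry)) > 1e-9) {
        rx <- atan2(R[3, 2], R[3, 3])
        rz <- atan2(R[2, 1], R[1, 1])
    } else {  # gimbal lock: fold everything into x
        rx <- atan2(-R[2, 3], R[2, 2])
        rz <- 0
    }
    c(rx, ry, rz) * 180 / pi
}

#' Apply a rigid transform to a point matrix
#'
#' @param points N x 3 matrix (mm).
#' @param transform a [RigidTransform-class].
#' @return N x 3 matrix of transformed points.
#' @examples
#' transformPoints(diag(3), rotationAboutAxis(c(0, 0, 1), 90))
#' @export
transformPoints <- function(points, transform) {
    points <- as.matrix(points)
    sweep(points %*% t(transform@rotation), 2L, transform@translation, "+")
}

#' Homogeneous 4x4 form of a rigid transform
#'
#' @param x a [RigidTransform-class], or a 4x4 matrix for
#'   `transformFromMatrix`.
#' @return `transformToMatrix`: 4x4 homogeneous matrix;
#'   `transformFromMatrix`: a [RigidTransform-class].
#' @export
transformToMatrix <- function(x) {
    m <- diag(4)
    m[1:3, 1:3] <- x@rotation
    m[1:3, 4] <- x@translation
    m
}

#' @rdname transformToMatrix
#' @export
transformFromMatrix <- function(x) {
    stopifnot(all(dim(x) == c(4L, 4L)))
    rigidTransform(x[1:3, 1:3], x[1:3, 4])
}
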
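#' @include AllClasses.R registration.R
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded generators
#' compose without side effects.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
withSeed <- function(seed, expr) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

#' Specification of a synthetic CT/MR phantom
#'
#' Describes a CT-like test volume: a bright body of a chosen analytic
#' shape on a dark air background, with optional intensity noise, scanner
#' bed and internal air cavity. Defaults emulate an abdominal CT:
#' air at -1000 HU, soft tissue at 40 HU, skin iso-value -400 HU,
#' noise 30 HU, a trunk-sized body in a 384 x 384 x 240 mm field of view
#' centred on the world origin.
#'
#' @param shape `"ellipsoid"`, `"cylinder"` (a deliberately symmetric
#'   shape in the spirit of cylindrical calibration phantoms) or
#'   `"abdomen"` (an in-plane superellipsoid with an anterior belly
#'   bulge, closer to real trunk morphology).
#' @param semiAxes numeric(3), mm: lateral, anterior-posterior and
#'   cranio-caudal semi-axes. The cylinder uses `semiAxes[1]` as its
#'   circular radius and `semiAxes[3]` as its half-length.
#' @param dims voxel grid size (>= 16 per axis).
#' @param spacing voxel size, mm.
#' @param bodyIntensity,airIntensity body and air intensities;
#'   `airIntensity < isoValue <= bodyIntensity` is required.
#' @param isoValue the skin iso-value the phantom is built for.
#' @param noiseSigma standard deviation of the additive Gaussian
#'   intensity noise. The noise is clipped so that no voxel can cross the
#'   iso-value; a sigma above a quarter of the air/body margin is
#'   rejected as violating separability.
#' @param includeBed add a scanner-bed slab touching the posterior slice
#'   border.
#' @param bedIntensity intensity of the bed slab (above the iso-value by
#'   default, like a real couch).
#' @param internalCavity carve an air-filled cavity inside the body (it
#'   must stay part of the segmented body, by exclusion).
#' @return A list of class `"PhantomSpec"`.
#' @seealso [makePhantomVolume()]
#' @export
phantomSpec <- function(shape = c("ellipsoid", "cylinder", "abdomen"),
                        semiAxes = c(150, 100, 110),
                        dims = c(96, 96, 48), spacing = c(4, 4, 5),
                        bodyIntensity = 40, airIntensity = -1000,
                        isoValue = -400, noiseSigma = 30,
                        includeBed = FALSE, bedIntensity = 150,
                        internalCavity = FALSE) {
    shape <- match.arg(shape)
    dims <- as.integer(rep_len(dims, 3L))
    if (any(dims < 16L)) stop("phantom dims must be >= 16 per axis")
    if (!(airIntensity < isoValue && isoValue <= bodyIntensity))
        stop("need airIntensity < isoValue <= bodyIntensity")
    margin <- min(isoValue - airIntensity, bodyIntensity - isoValue)
    if (bodyIntensity == isoValue && noiseSigma > 0)
        stop("phantom spec violates separability: body intensity sits on ",
             "the iso-value, any noise crosses it")
    if (noiseSigma > margin / 4)
        stop("phantom spec violates separability: noiseSigma ", noiseSigma,
             " exceeds a quarter of the air/body margin (", margin, ")")
    structure(list(shape = shape, semiAxes = as.numeric(semiAxes),
                   dims = dims, spacing = as.numeric(rep_len(spacing, 3L)),
                   bodyIntensity = bodyIntensity,
                   airIntensity = airIntensity, isoValue = isoValue,
                   noiseSigma = noiseSigma, includeBed = includeBed,
                   bedIntensity = bedIntensity,
                   internalCavity = internalCavity),
              class = "PhantomSpec")
}

# Analytic inside indicator for the phantom body, points in world mm
# (body centred on the origin).
.phantomInside <- function(spec, pts) {
    a <- spec$semiAxes
    x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
    switch(spec$shape,
        ellipsoid = (x / a[1])^2 + (y / a[2])^2 + (z / a[3])^2 <= 1,
        cylinder = (x / a[1])^2 + (y / a[1])^2 <= 1 & abs(z) <= a[3],
        abdomen = {
            bulge <- 1 + 0.2 * exp(-(z / (0.4 * a[3]))^2) * (y > 0)
            (abs(x) / a[1])^2.5 + (abs(y) / (a[2] * bulge))^2.5 +
                (abs(z) / a[3])^4 <= 1
        })
}

.cavityInside <- function(spec, pts) {
    a <- spec$semiAxes / 3.5
    ctr <- c(0, -0.2 * spec$semiAxes[2], 0)
    q <- sweep(pts, 2L, ctr, "-")
    (q[, 1] / a[1])^2 + (q[, 2] / a[2])^2 + (q[, 3] / a[3])^2 <= 1
}

#' Generate a synthetic CT/MR-like phantom volume
#'
#' Voxels inside the analytic body get the body intensity, the rest the
#' air intensity; clipped Gaussian noise is added on top so that the
#' air/body classification against the iso-value is never flipped. The
#' volume is centred so the body centroid sits at the world origin (a
#' scanner-isocentre convention that also keeps registration lever arms
#' realistic).
#'
#' @param spec a [phantomSpec()].
#' @param seed integer seed for the intensity noise.
#' @return list with `volume` (a [VolumetricImage-class]), `spec`, and
#'   `inside`, a function mapping N x 3 world points to the analytic
#'   inside-body indicator (cavity excluded from the *analytic* body;
#'   the segmentation keeps it by exclusion).
#' @examples
#' ph <- makePhantomVolume(phantomSpec(dims = c(24, 24, 16),
#'     spacing = c(4, 4, 4), semiAxes = c(36, 30, 26)), seed = 7)
#' ph$volume
#' @export
makePhantomVolume <- function(spec, seed = 1L) {
    stopifnot(inherits(spec, "PhantomSpec"))
    d <- spec$dims
    origin <- -(d - 1) / 2 * spec$spacing
    xs <- origin[1] + spec$spacing[1] * (seq_len(d[1]) - 1L)
    ys <- origin[2] + spec$spacing[2] * (seq_len(d[2]) - 1L)
    zs <- origin[3] + spec$spacing[3] * (seq_len(d[3]) - 1L)
    pts <- cbind(rep(xs, times = d[2] * d[3]),
                 rep(rep(ys, each = d[1]), times = d[3]),
                 rep(zs, each = d[1] * d[2]))
    inside <- .phantomInside(spec, pts)
    data <- ifelse(inside, spec$bodyIntensity, spec$airIntensity)
    if (spec$internalCavity)
        data[.cavityInside(spec, pts)] <- spec$airIntensity
    if (spec$includeBed) {
        # slab under the patient (just below the posterior skin), full
        # width, reaching the posterior border of every slice
        bedTop <- -1.05 * spec$semiAxes[2]
        data[pts[, 2] <= bedTop] <- spec$bedIntensity
    }
    if (spec$noiseSigma > 0) {
        clip <- 0.99 * min(spec$isoValue - spec$airIntensity,
                           spec$bodyIntensity - spec$isoValue)
        clip <- min(clip, 4 * spec$noiseSigma)
        noise <- withSeed(seed,
            stats::rnorm(length(data), sd = spec$noiseSigma))
        data <- data + pmin(pmax(noise, -clip), clip)
    }
    vol <- volumetricImage(array(data, d), spacing = spec$spacing,
                           origin = origin)
    # the analytic body indicator: the enclosed cavity still counts as
    # body, matching the segmentation's by-exclusion semantics
    list(volume = vol, spec = spec,
         inside = function(p) .phantomInside(spec, .asPoints(p)))
}

#' Specification of a simulated depth-camera acquisition
#'
#' @param pose ground-truth [RigidTransform-class] mapping the skin
#'   surface (volume frame) into the camera/tracking frame.
#' @param coverage fraction (0, 1] of the front surface retained, as a
#'   contiguous window.
#' @param noiseSigma isotropic positional noise, mm.
#' @param sampleCount number of surface points returned.
#' @param seed integer seed for resampling and noise.
#' @param anterior anterior direction in the skin surface's frame.
#' @param tiltDeg off-axis angle (degrees) of the acquisition window
#'   about the cranio-caudal axis, emulating a tilted camera that sees a
#'   laterally shifted part of the skin.
#' @return A list of class `"CameraSimSpec"`.
#' @export
cameraSimSpec <- function(pose = identityTransform(), coverage = 0.6,
                          noiseSigma = 0.5, sampleCount = 1500L,
                          seed = 1L, anterior = c(0, 1, 0), tiltDeg = 0) {
    if (coverage <= 0 || coverage > 1)
        stop("'coverage' must lie in (0, 1]")
    if (noiseSigma < 0) stop("'noiseSigma' must be >= 0")
    structure(list(pose = pose, coverage = coverage,
                   noiseSigma = noiseSigma,
                   sampleCount = as.integer(sampleCount),
                   seed = as.integer(seed),
                   anterior = as.numeric(anterior), tiltDeg = tiltDeg),
              class = "CameraSimSpec")
}

#' Simulate a depth-camera acquisition of the skin
#'
#' Emulates a frontal depth-camera view: the front of the skin surface is
#' cut by the normal-angle criterion, a contiguous window holding the
#' requested coverage fraction (optionally tilted off-axis) is kept,
#' the window is resampled to `sampleCount` points, isotropic Gaussian
#' noise is added, and the ground-truth pose is applied. Everything is
#' driven by the spec's seed, so equal specs give bit-identical output.
#'
#' @param skin the segmented skin [TriangleMesh-class] (watertight).
#' @param spec a [cameraSimSpec()].
#' @return list with `surface` (a [TriangleMesh-class] point cloud in the
#'   camera frame), `pose` (the ground truth) and `windowCenter` (mm, in
#'   the skin frame).
#' @export
simulateCameraSurface <- function(skin, spec) {
    stopifnot(inherits(spec, "CameraSimSpec"))
    front <- selectFront(skin, spec$anterior)
    fv <- front@vertices
    bodyCenter <- colMeans(skin@vertices)
    ctr <- colMeans(fv)
    c0 <- fv[which.min(rowSums(sweep(fv, 2L, ctr, "-")^2)), ]
    if (spec$tiltDeg != 0) {
        axis <- c(0, 0, 1)  # cranio-caudal
        rot <- rotation(rotationAboutAxis(axis, spec$tiltDeg))
        target <- bodyCenter + as.vector(rot %*% (c0 - bodyCenter))
        c0 <- fv[which.min(rowSums(sweep(fv, 2L, target, "-")^2)), ]
    }
    k <- max(1L, round(spec$coverage * nrow(fv)))
    win <- order(rowSums(sweep(fv, 2L, c0, "-")^2))[seq_len(k)]
    if (k < 100L)
        stop("camera coverage yields only ", k,
             " surface points (< 100); increase coverage or resolution")
    pts <- withSeed(spec$seed, {
        idx <- if (spec$sampleCount <= k)
            sample(win, spec$sampleCount)
        else sample(win, spec$sampleCount, replace = TRUE)
        p <- fv[idx, , drop = FALSE]
        if (spec$noiseSigma > 0)
            p <- p + matrix(stats::rnorm(length(p), sd = spec$noiseSigma),
                            ncol = 3L)
        p
    })
    list(surface = triangleMesh(transformPoints(pts, spec$pose)),
         pose = spec$pose, windowCenter = c0)
}

#' Perturbation scenario suite
#'
#' Expands a base acquisition into the perturbation design used for
#' phantom validation: four camera-distance analogues (noise grows
#' linearly with distance, sigma = 0.3 mm + 0.02 mm/cm), three tilt
#' angles (0/30/45 degrees at 35 cm) and three 15-mm virtual-landmark
#' misplacements (horizontal x, vertical z, diagonal x+y; the camera
#' surface itself is untouched, only the landmark moves). Every scenario
#' carries its own derived seed.
#'
#' @param base a [cameraSimSpec()] describing the unperturbed
#'   acquisition.
#' @return list of 11 scenarios (base + 4 + 3 + 3), each a list with
#'   `name`, `group`, `camera` (a `CameraSimSpec`) and `landmarkOffset`
#'   (mm, in the camera frame).
#' @seealso [evaluateScenarios()]
#' @export
perturbationSuite <- function(base = cameraSimSpec()) {
    stopifnot(inherits(base, "CameraSimSpec"))
    distSigma <- function(cm) 0.3 + 0.02 * cm
    mk <- function(name, group, i, noiseSigma = base$noiseSigma,
                   tiltDeg = base$tiltDeg, offset = c(0, 0, 0)) {
        cam <- base
        cam$noiseSigma <- noiseSigma
        cam$tiltDeg <- tiltDeg
        cam$seed <- base$seed + i
        list(name = name, group = group, camera = cam,
             landmarkOffset = offset)
    }
    d <- 15 / sqrt(2)
    c(list(mk("base", "base", 0L)),
      lapply(seq_along(c(20, 25, 30, 35)), function(i)
          mk(paste0("distance_", c(20, 25, 30, 35)[i], "cm"), "distance",
             i, noiseSigma = distSigma(c(20, 25, 30, 35)[i]))),
      lapply(seq_along(c(0, 30, 45)), function(i)
          mk(paste0("tilt_", c(0, 30, 45)[i], "deg"), "tilt", 4L + i,
             noiseSigma = distSigma(35), tiltDeg = c(0, 30, 45)[i])),
      # the three misplacements share one camera acquisition (seed 5,
      # the perpendicular 35 cm view): only the landmark moves
      list(mk("misplace_horizontal", "misplacement", 5L,
              noiseSigma = distSigma(35), offset = c(15, 0, 0)),
           mk("misplace_vertical", "misplacement", 5L,
              noiseSigma = distSigma(35), offset = c(0, 0, 15)),
           mk("misplace_diagonal", "misplacement", 5L,
              noiseSigma = distSigma(35), offset = c(d, d, 0))))
}

#' Run the co-registration across a perturbation suite
#'
#' For each scenario, simulates the camera acquisition, builds the
#' (possibly misplaced) landmark pair, co-registers and evaluates the
#' target registration error at an internal target point by comparing
#' the recovered and ground-truth mappings of that point. Rotation
#' angles (degrees, about x/y/z) of the recovered transform are reported
#' so landmark-robustness can be read off directly.
#'
#' @param skin the segmented skin [TriangleMesh-class].
#' @param scenarios output of [perturbationSuite()].
#' @param landmarkOnSkin virtual landmark on the skin surface (mm); the
#'   anterior apex of the surface by default.
#' @param target internal target point (mm, volume frame) for the TRE;
#'   defaults to 60 mm posterior of the landmark.
#' @param config a [registrationConfig()].
#' @return data.frame with one row per scenario: TRE (mm), Hausdorff
#'   (mm), recovered rotation angles and rotation/translation error
#'   versus ground truth.
#' @export
evaluateScenarios <- function(skin, scenarios,
                              landmarkOnSkin = NULL, target = NULL,
                              config = registrationConfig()) {
    if (is.null(landmarkOnSkin)) {
        fv <- vertices(selectFront(skin, config$anterior))
        landmarkOnSkin <- fv[which.max(fv %*% config$anterior), ]
    }
    if (is.null(target))
        target <- landmarkOnSkin - 60 * config$anterior
    rows <- lapply(scenarios, function(sc) {
        cam <- simulateCameraSurface(skin, sc$camera)
        # the operator picks the landmark ON the acquired cloud: take the
        # camera point nearest to the (possibly misplaced) true position
        want <- transformPoints(matrix(landmarkOnSkin, ncol = 3L),
                                cam$pose)[1, ] + sc$landmarkOffset
        hit <- nearestNeighbors(matrix(want, ncol = 3L), cam$surface)
        lmCam <- vertices(cam$surface)[hit$index, ]
        pair <- landmarkPair(skin, cam$surface, landmarkOnSkin, lmCam)
        res <- coregister(skin, cam$surface, pair, config)
        rec <- transform(res)
        ang <- eulerAngles(rotation(rec))
        tgt <- matrix(target, ncol = 3L)
        data.frame(
            scenario = sc$name, group = sc$group,
            noiseSigma = sc$camera$noiseSigma,
            tiltDeg = sc$camera$tiltDeg,
            tre = tre(transformPoints(tgt, rec),
                      transformPoints(tgt, cam$pose)),
            hausdorff = hausdorffValue(res),
            rotX = ang[1], rotY = ang[2], rotZ = ang[3],
            rotErr = rotationBetween(rec, cam$pose),
            transErr = sqrt(sum((translation(rec) -
                                 translation(cam$pose))^2)))
    })
    do.call(rbind, rows)
}
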
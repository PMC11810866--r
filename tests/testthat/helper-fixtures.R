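# Shared fixtures, built once per test run (phantom segmentation is the
# slow step, the result is deterministic).

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
    if (is.null(.fixtureCache[[name]]))
        .fixtureCache[[name]] <- builder()
    .fixtureCache[[name]]
}

abdomenSkin <- function() fixture("abdomenSkin", function() {
    ph <- makePhantomVolume(phantomSpec(shape = "abdomen"), seed = 42)
    skinSurfaceFromVolume(ph$volume, segmentationConfig(-400))
})

ellipsoidSkin <- function() fixture("ellipsoidSkin", function() {
    ph <- makePhantomVolume(phantomSpec(shape = "ellipsoid"), seed = 43)
    skinSurfaceFromVolume(ph$volume, segmentationConfig(-400))
})

# trunk phantoms for the pose-recovery study: adult-sized abdomen
# shapes whose anterior bulge and distinct axes make the pose fully
# observable from a frontal window (near-symmetric shapes genuinely
# degrade rotation recovery; see the vignette)
trunkSkinA <- function() fixture("trunkSkinA", function() {
    ph <- makePhantomVolume(phantomSpec(shape = "abdomen",
        semiAxes = c(165, 110, 95)), seed = 44)
    skinSurfaceFromVolume(ph$volume, segmentationConfig(-400))
})

trunkSkinB <- function() fixture("trunkSkinB", function() {
    ph <- makePhantomVolume(phantomSpec(shape = "abdomen",
        semiAxes = c(140, 95, 105)), seed = 45)
    skinSurfaceFromVolume(ph$volume, segmentationConfig(-400))
})

# anterior apex of the front surface: the natural virtual-landmark spot
apexLandmark <- function(skin, anterior = c(0, 1, 0)) {
    fv <- vertices(selectFront(skin, anterior))
    fv[which.max(fv %*% anterior), ]
}

# one seeded ground-truth recovery run; returns pose errors and traces
recoveryTrial <- function(skin, seed, noiseSigma = 0.5, coverage = 0.5,
                          maxAngle = 20, maxTrans = 50,
                          config = registrationConfig()) {
    pose <- randomRigid(seed, maxAngle, maxTrans)
    cam <- simulateCameraSurface(skin, cameraSimSpec(
        pose = pose, coverage = coverage, noiseSigma = noiseSigma,
        sampleCount = 1500L, seed = seed + 1L))
    lmS <- apexLandmark(skin, config$anterior)
    hit <- nearestNeighbors(transformPoints(matrix(lmS, ncol = 3), pose),
                            cam$surface)
    lmC <- vertices(cam$surface)[hit$index, ]
    pair <- landmarkPair(skin, cam$surface, lmS, lmC)
    res <- suppressWarnings(coregister(skin, cam$surface, pair, config))
    list(result = res, pose = pose,
         rotErr = rotationBetween(transform(res), pose),
         transErr = sqrt(sum((translation(transform(res)) -
                              translation(pose))^2)))
}
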
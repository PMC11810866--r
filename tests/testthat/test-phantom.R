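smallSpec <- function(...) {
    phantomSpec(dims = c(24, 24, 16), spacing = c(4, 4, 5),
                semiAxes = c(36, 30, 30), ...)
}

test_that("phantom generation is deterministic under a fixed seed", {
    a <- makePhantomVolume(smallSpec(), seed = 7)
    b <- makePhantomVolume(smallSpec(), seed = 7)
    c <- makePhantomVolume(smallSpec(), seed = 8)
    expect_identical(volData(a$volume), volData(b$volume))
    expect_false(identical(volData(a$volume), volData(c$volume)))
})

test_that("generated volumes always satisfy the segmentation preconditions", {
    for (s in 1:5) {
        spec <- smallSpec(includeBed = s %% 2 == 0,
                          internalCavity = s %% 3 == 0)
        vol <- makePhantomVolume(spec, seed = s)$volume
        padded <- padVolume(vol, 1)
        d <- dim(padded)
        corners <- volData(padded)[c(1, d[1]), c(1, d[2]), ]
        expect_true(all(corners < spec$isoValue))
        # segmentation runs without error on every variant
        expect_s4_class(segmentSkin(vol, segmentationConfig(spec$isoValue)),
                        "MockupGrid")
    }
})

test_that("zero-noise segmentation reproduces the analytic body", {
    ph <- makePhantomVolume(smallSpec(noiseSigma = 0), seed = 1)
    grid <- segmentSkin(ph$volume, segmentationConfig(-400, padWidth = 0))
    mask <- binarizeMockup(grid)
    d <- dim(mask)
    idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                                 k = 0:(d[3] - 1)))
    inside <- array(ph$inside(voxelToWorld(ph$volume, idx)), d)
    expect_identical(mask == 1L, inside)
})

test_that("noise never flips the air/body classification", {
    spec <- smallSpec(noiseSigma = 100)   # a quarter of the 400 margin
    ph <- makePhantomVolume(spec, seed = 3)
    d <- dim(volData(ph$volume))
    idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                                 k = 0:(d[3] - 1)))
    inside <- array(ph$inside(voxelToWorld(ph$volume, idx)), d)
    expect_identical(volData(ph$volume) >= spec$isoValue, inside)
    expect_error(smallSpec(noiseSigma = 150), "separability")
    expect_error(phantomSpec(bodyIntensity = 0, isoValue = 0,
                             noiseSigma = 1), "separability")
})

test_that("an internal cavity stays part of the segmented body", {
    ph <- makePhantomVolume(smallSpec(internalCavity = TRUE,
                                      noiseSigma = 0), seed = 1)
    grid <- segmentSkin(ph$volume, segmentationConfig(-400))
    mask <- binarizeMockup(grid)
    lab <- gridLabels(grid)
    # find cavity voxels: air intensity but analytically inside the body
    d <- dim(volData(ph$volume))
    idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                                 k = 0:(d[3] - 1)))
    inside <- array(ph$inside(voxelToWorld(ph$volume, idx)), d)
    cavity <- inside & (volData(ph$volume) < -400)
    expect_gt(sum(cavity), 0)
    # label grid is padded by one: embed the cavity mask accordingly
    cavLab <- lab[2:(d[1] + 1), 2:(d[2] + 1), ][cavity]
    cavMask <- mask[2:(d[1] + 1), 2:(d[2] + 1), ][cavity]
    expect_true(all(cavLab == 2L))
    expect_true(all(cavMask == 1L))
})

test_that("the scanner bed is segmented only when above the iso-value", {
    withBed <- makePhantomVolume(smallSpec(includeBed = TRUE,
                                           noiseSigma = 0), seed = 1)
    grid <- segmentSkin(withBed$volume, segmentationConfig(-400))
    mask <- binarizeMockup(grid)
    expect_gt(sum(mask), sum(binarizeMockup(segmentSkin(
        makePhantomVolume(smallSpec(noiseSigma = 0), seed = 1)$volume,
        segmentationConfig(-400)))))
    # bed at air intensity: padding lets the background flow around it
    dark <- makePhantomVolume(smallSpec(includeBed = TRUE,
                                        bedIntensity = -1000,
                                        noiseSigma = 0), seed = 1)
    gridDark <- segmentSkin(dark$volume, segmentationConfig(-400))
    maskDark <- binarizeMockup(gridDark)
    base <- binarizeMockup(segmentSkin(
        makePhantomVolume(smallSpec(noiseSigma = 0), seed = 1)$volume,
        segmentationConfig(-400)))
    expect_identical(maskDark, base)
})

test_that("camera simulation: on-surface, deterministic, seeded noise", {
    skin <- ellipsoidSkin()
    id <- simulateCameraSurface(skin, cameraSimSpec(
        pose = identityTransform(), coverage = 1, noiseSigma = 0,
        sampleCount = 800L, seed = 5))
    d <- nearestNeighbors(id$surface, skin)$distance
    expect_lt(max(d), 1e-6)
    again <- simulateCameraSurface(skin, cameraSimSpec(
        pose = identityTransform(), coverage = 1, noiseSigma = 0,
        sampleCount = 800L, seed = 5))
    expect_identical(vertices(id$surface), vertices(again$surface))
    noisy <- simulateCameraSurface(skin, cameraSimSpec(
        pose = identityTransform(), coverage = 1, noiseSigma = 1,
        sampleCount = 800L, seed = 5))
    expect_false(identical(vertices(id$surface), vertices(noisy$surface)))
})

test_that("camera coverage below 100 points is refused", {
    skin <- ellipsoidSkin()
    expect_error(simulateCameraSurface(skin, cameraSimSpec(
        coverage = 1e-4, sampleCount = 500L)), "100")
})

test_that("the perturbation suite has the full factorial layout", {
    suite <- perturbationSuite(cameraSimSpec(seed = 11))
    expect_length(suite, 11L)
    groups <- vapply(suite, `[[`, "", "group")
    expect_identical(as.vector(table(factor(groups,
        c("base", "distance", "tilt", "misplacement")))),
        c(1L, 4L, 3L, 3L))
    # noise grows with the distance analogue
    sig <- vapply(suite[groups == "distance"], function(s)
        s$camera$noiseSigma, numeric(1))
    expect_true(all(diff(sig) > 0))
    # misplacement scenarios share one camera acquisition
    mis <- suite[groups == "misplacement"]
    expect_identical(mis[[1]]$camera, mis[[2]]$camera)
    expect_identical(mis[[1]]$camera, mis[[3]]$camera)
    offs <- t(vapply(mis, `[[`, numeric(3), "landmarkOffset"))
    expect_equal(sqrt(rowSums(offs^2)), rep(15, 3))
})

test_that("misplacement scenarios move only the landmark", {
    skin <- ellipsoidSkin()
    suite <- perturbationSuite(cameraSimSpec(pose = randomRigid(21),
                                             seed = 31))
    mis <- suite[vapply(suite, `[[`, "", "group") == "misplacement"]
    s1 <- simulateCameraSurface(skin, mis[[1]]$camera)
    s2 <- simulateCameraSurface(skin, mis[[2]]$camera)
    expect_identical(vertices(s1$surface), vertices(s2$surface))
})

test_that("evaluateScenarios reports finite TRE per scenario", {
    skin <- ellipsoidSkin()
    suite <- perturbationSuite(cameraSimSpec(pose = randomRigid(61),
                                             coverage = 0.6,
                                             noiseSigma = 0.5, seed = 71))
    tab <- evaluateScenarios(skin, suite[c(1, 3, 9)])
    expect_identical(nrow(tab), 3L)
    expect_true(all(is.finite(tab$tre)))
    expect_true(all(tab$tre >= 0))
    expect_true(all(is.finite(tab$hausdorff)))
    expect_true(all(c("rotX", "rotY", "rotZ") %in% names(tab)))
})
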
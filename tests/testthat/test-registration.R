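scaledEllipsoidCloud <- function(seed = 1) {
    # points on an ellipsoid with well-separated principal axes
    m <- icosphere(3)
    sweep(vertices(m), 2L, c(80, 40, 20), "*")
}

test_that("PCA alignment is the identity on a mesh against itself", {
    p <- scaledEllipsoidCloud()
    fit <- pcaAlign(p, p)
    expect_lt(rotationAngle(fit), 1e-6)
    expect_lt(max(abs(translation(fit))), 1e-9)
})

test_that("PCA alignment recovers a known rotation of an ellipsoid", {
    p <- scaledEllipsoidCloud()
    T1 <- rotationAboutAxis(c(1, 2, -1), 25, c(30, -10, 50))
    q <- transformPoints(p, T1)
    fit <- pcaAlign(p, q)
    expect_lt(rotationBetween(fit, T1), 0.5)
    expect_lt(max(abs(translation(fit) - translation(T1))), 0.5)
})

test_that("tied covariance eigenvalues are rejected as ambiguous", {
    sph <- vertices(icosphere(3, radius = 10))
    expect_error(pcaAlign(sph, sph * 2), "ambiguous principal axes")
})

test_that("landmark translation maps the landmark exactly", {
    skin <- ellipsoidSkin()
    lmS <- apexLandmark(skin)
    T1 <- randomRigid(17)
    cam <- applyTransform(skin, T1)
    lmC <- transformPoints(matrix(lmS, ncol = 3), T1)[1, ]
    pair <- landmarkPair(skin, cam, lmS, lmC)
    adj <- landmarkTranslate(pair, pcaAlign(skin, cam))
    resid <- transformPoints(matrix(pair@onSegmented, ncol = 3), adj)[1, ] -
        pair@onCamera
    expect_lt(max(abs(resid)), 1e-12)
    # already-coincident landmarks leave the translation unchanged
    same <- landmarkTranslate(pair, adj)
    expect_identical(translation(same), translation(adj))
})

test_that("landmarks far from the surface are rejected", {
    skin <- ellipsoidSkin()
    lmS <- apexLandmark(skin)
    expect_error(landmarkPair(skin, skin, lmS + c(0, 30, 0), lmS),
                 "away from it")
})

test_that("ICP on identical clouds stops immediately at identity", {
    p <- randomCloud(200, seed = 41)
    fit <- icp(p, p)
    expect_identical(fit$iterations, 1L)
    expect_lt(rotationAngle(fit$transform), 1e-12)
    expect_identical(fit$finalRMS, 0)
})

test_that("ICP recovers a small displacement without noise", {
    half <- scaledEllipsoidCloud()
    half <- half[half[, 3] > 0, ]            # front half
    T1 <- rotationAboutAxis(c(0, 0, 1), 10, c(5, -3, 2))
    fit <- icp(half, transformPoints(half, T1), trimFraction = 1)
    expect_lt(rotationBetween(fit$transform, T1), 0.1)
    expect_lt(max(abs(translation(fit$transform) - translation(T1))), 0.1)
    expect_true(all(diff(fit$rms) <= 1e-9))
})

test_that("trimming rescues ICP from gross outliers", {
    ell <- icosphere(3)
    ell@vertices <- sweep(vertices(ell), 2L, c(80, 40, 20), "*")
    half <- subsetMesh(ell, vertices(ell)[, 3] > 0)
    T1 <- rotationAboutAxis(c(0, 0, 1), 10, c(5, -3, 2))
    dstMesh <- applyTransform(half, T1)
    bad <- vertices(half)
    nOut <- floor(nrow(bad) * 0.10)
    bad[seq_len(nOut), ] <- withSeed(55,
        matrix(runif(nOut * 3, 300, 600), ncol = 3))
    # cold start: trimming converges close to the truth (fraction
    # trimming drops boundary points, so a small slid residual remains),
    # while the untrimmed run is wrecked by the outliers
    trimmed <- icp(bad, dstMesh, trimFraction = 0.8, toSurface = TRUE)
    expect_lt(rotationBetween(trimmed$transform, T1), 2)
    expect_lt(max(abs(translation(trimmed$transform) - translation(T1))),
              3)
    expect_true(all(diff(trimmed$rms) <= 1e-9))
    plain <- icp(bad, dstMesh, trimFraction = 1, toSurface = TRUE)
    expect_gt(rotationBetween(plain$transform, T1), 10)
    # warm start (how the second pipeline stage uses trimming): exact
    expect_lt(rotationBetween(icp(bad, dstMesh, init = T1,
                                  trimFraction = 0.8,
                                  toSurface = TRUE)$transform, T1),
              0.1)
})

test_that("ICP input validation", {
    p <- randomCloud(5, seed = 61)
    expect_error(icp(p, p), "at least 10")
    q <- randomCloud(20, seed = 62)
    expect_error(icp(q, q, trimFraction = 0.05), "fewer than 3")
    expect_error(icp(q, q, trimFraction = 0), "trimFraction")
})

test_that("self-registration returns the identity", {
    skin <- ellipsoidSkin()
    cam <- simulateCameraSurface(skin, cameraSimSpec(
        pose = identityTransform(), coverage = 1, noiseSigma = 0,
        sampleCount = 2000L, seed = 3))
    lmS <- apexLandmark(skin)
    pair <- landmarkPair(skin, cam$surface, lmS, lmS)
    res <- coregister(skin, cam$surface, pair,
                      registrationConfig(convergenceTol = 1e-7))
    expect_lt(rotationAngle(transform(res)), 1e-3)
    expect_lt(max(abs(translation(transform(res)))), 1e-3)
    # every camera point lies back on the registered skin
    expect_lt(perStageRMS(res)[["icp2"]], 1e-3)
})

test_that("ground-truth pose is recovered on a synthetic phantom", {
    trial <- recoveryTrial(abdomenSkin(), seed = 501, noiseSigma = 0.5,
                           coverage = 0.5)
    expect_lt(trial$rotErr, 1)
    expect_lt(trial$transErr, 1)
    res <- trial$result
    expect_true(all(diff(res@details$rmsICP1) <= 1e-9))
    expect_true(all(diff(res@details$rmsICP2) <= 1e-9))
    # landmark stage -> ICP stages never get worse
    expect_lte(res@perStageRMS[["icp1"]],
               res@perStageRMS[["landmark"]] + 1e-9)
    expect_lte(res@perStageRMS[["icp2"]],
               res@perStageRMS[["icp1"]] + 1e-9)
})

test_that("the reported transform reproduces the final trimmed RMS", {
    trial <- recoveryTrial(abdomenSkin(), seed = 777, noiseSigma = 0.8,
                           coverage = 0.6)
    res <- trial$result
    segReg <- res@segROI            # ROI already carrying the transform
    cam <- res@camROI
    nn <- SkinFusion:::.nnSearchMesh(vertices(segReg), triangles(segReg),
                                     vertices(cam), 8L)
    keep <- floor(0.8 * nVertices(cam))
    rms <- sqrt(mean(sort(nn$distance)[seq_len(keep)]^2))
    expect_equal(rms, res@perStageRMS[["icp2"]], tolerance = 1e-6)
})

test_that("a 15 mm landmark misplacement barely changes the rotation", {
    skin <- abdomenSkin()
    pose <- randomRigid(88)
    cam <- simulateCameraSurface(skin, cameraSimSpec(
        pose = pose, coverage = 0.6, noiseSigma = 0.5,
        sampleCount = 1500L, seed = 89))
    lmS <- apexLandmark(skin)
    want <- transformPoints(matrix(lmS, ncol = 3), pose)[1, ]
    pick <- function(offset) {
        hit <- nearestNeighbors(matrix(want + offset, ncol = 3),
                                cam$surface)
        vertices(cam$surface)[hit$index, ]
    }
    base <- coregister(skin, cam$surface,
                       landmarkPair(skin, cam$surface, lmS, pick(c(0, 0, 0))))
    moved <- coregister(skin, cam$surface,
                        landmarkPair(skin, cam$surface, lmS,
                                     pick(c(15, 15, 0) / sqrt(2))))
    expect_lt(rotationBetween(transform(base), transform(moved)), 1)
})

test_that("re-posing a volume moves voxel world coordinates rigidly", {
    vol <- volumetricImage(array(rnorm(5 * 4 * 3), c(5, 4, 3)),
                           spacing = c(1.1, 2, 0.9), origin = c(7, -2, 4),
                           axes = rotation(rotationAboutAxis(c(1, 0, 1),
                                                             20)))
    expect_identical(volOrigin(applyToVolume(vol, identityTransform())),
                     volOrigin(vol))
    T1 <- randomRigid(92)
    idx <- withSeed(93, matrix(sample(0:2, 30, replace = TRUE), ncol = 3))
    posed <- applyToVolume(vol, T1)
    expect_equal(voxelToWorld(posed, idx),
                 transformPoints(voxelToWorld(vol, idx), T1),
                 tolerance = 1e-9)
    back <- applyToVolume(posed, invertTransform(T1))
    expect_equal(volOrigin(back), volOrigin(vol), tolerance = 1e-9)
    expect_equal(volAxes(back), volAxes(vol), tolerance = 1e-9)
    expect_identical(volData(back), volData(vol))
})
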
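sphereSkin <- function(spacingMM = 1) {
    n <- ceiling(48 / spacingMM)
    ph <- makePhantomVolume(phantomSpec(shape = "ellipsoid",
        semiAxes = c(20, 20, 20), dims = rep(n, 3),
        spacing = rep(spacingMM, 3), noiseSigma = 0), seed = 1)
    skinSurfaceFromVolume(ph$volume, segmentationConfig(-400))
}

test_that("sphere surface vertices sit within half a voxel diagonal", {
    skin <- fixture("sphere1mm", function() sphereSkin(1))
    r <- sqrt(rowSums(vertices(skin)^2))
    expect_true(all(abs(r - 20) <= sqrt(3) / 2))
    expect_gt(nVertices(skin), 1000)
})

test_that("the radial error bound scales with the voxel diagonal", {
    skin <- sphereSkin(2)
    r <- sqrt(rowSums(vertices(skin)^2))
    expect_true(all(abs(r - 20) <= sqrt(12) / 2))
    # and it genuinely exceeds the fine bound, so the test has teeth
    expect_gt(max(abs(r - 20)), sqrt(3) / 2)
})

test_that("extracted surfaces are watertight and consistently oriented", {
    skin <- fixture("sphere1mm", function() sphereSkin(1))
    expect_true(isWatertight(skin))
    # outward normals: radial on a sphere
    radial <- vertices(skin) / sqrt(rowSums(vertices(skin)^2))
    expect_gt(min(rowSums(normals(skin) * radial)), 0)
})

test_that("a single body voxel yields a small closed surface", {
    sl0 <- matrix(-10, 5, 5)
    sl1 <- sl0; sl1[3, 3] <- 10
    vol <- volumetricImage(array(c(sl0, sl1, sl0), c(5, 5, 3)))
    grid <- segmentSkin(vol, segmentationConfig(0, padWidth = 0))
    m <- extractSkinSurface(grid)
    expect_true(isWatertight(m))
    a <- vertices(m)[triangles(m)[, 1], ]
    b <- vertices(m)[triangles(m)[, 2], ]
    cc <- vertices(m)[triangles(m)[, 3], ]
    area <- sum(sqrt(rowSums(SkinFusion:::.rowCross(b - a, cc - a)^2))) / 2
    expect_gt(area, 0)
    # the surface enc encloses the voxel centre
    ctr <- voxelToWorld(vol, rbind(c(2, 2, 1)))
    expect_true(all(sweep(vertices(m), 2, ctr, "-")^2 %*% rep(1, 3) <= 3))
})

test_that("empty and full masks are rejected", {
    vol <- volumetricImage(array(-5, c(6, 6, 2)))
    grid <- segmentSkin(vol, segmentationConfig(0, padWidth = 0))
    expect_error(extractSkinSurface(grid), "no iso-surface")
    full <- new("MockupGrid", labels = array(2L, c(6, 6, 2)),
                isoValue = 0, volume = vol)
    expect_error(extractSkinSurface(full), "no iso-surface")
})

test_that("surface vertices honour a rotated world frame", {
    sl0 <- matrix(-10, 6, 6)
    sl1 <- sl0; sl1[3:4, 3:4] <- 10
    R <- rotation(rotationAboutAxis(c(0, 0, 1), 30))
    vol <- volumetricImage(array(c(sl0, sl1, sl1, sl0), c(6, 6, 4)),
                           spacing = c(2, 1, 1), origin = c(5, 6, 7),
                           axes = R)
    grid <- segmentSkin(vol, segmentationConfig(0, padWidth = 0))
    m <- extractSkinSurface(grid)
    # same extraction in an axis-aligned frame, then transformed
    vol0 <- volumetricImage(array(c(sl0, sl1, sl1, sl0), c(6, 6, 4)),
                            spacing = c(2, 1, 1))
    m0 <- extractSkinSurface(segmentSkin(vol0,
                                         segmentationConfig(0, padWidth = 0)))
    mapped <- transformPoints(vertices(m0), rigidTransform(R, c(5, 6, 7)))
    expect_equal(vertices(m), mapped, tolerance = 1e-9)
})

test_that("factor-2 subsampling moves the surface by at most the coarse voxel diagonal", {
    ph <- makePhantomVolume(phantomSpec(shape = "ellipsoid",
        dims = c(48, 48, 32), spacing = c(3, 3, 4),
        semiAxes = c(60, 45, 50)), seed = 12)
    fine <- skinSurfaceFromVolume(ph$volume, segmentationConfig(-400))
    coarse <- skinSurfaceFromVolume(ph$volume,
        segmentationConfig(-400, subsampleFactor = 2))
    coarseDiag <- sqrt(sum((2 * c(3, 3, 4))^2))
    expect_lte(hausdorffDistance(fine, coarse), coarseDiag)
})

test_that("pad-then-subsample and subsample-then-pad give close surfaces", {
    ph <- makePhantomVolume(phantomSpec(dims = c(32, 32, 24),
        spacing = c(4, 4, 5), semiAxes = c(50, 40, 44)), seed = 13)
    a <- extractSkinSurface(segmentSkin(
        subsampleVolume(padVolume(ph$volume, 1), 2),
        segmentationConfig(-400, padWidth = 0, subsampleFactor = 1)))
    b <- extractSkinSurface(segmentSkin(
        padVolume(subsampleVolume(ph$volume, 2), 1),
        segmentationConfig(-400, padWidth = 0, subsampleFactor = 1)))
    coarseDiag <- sqrt(sum((2 * c(4, 4, 5))^2))
    expect_lte(hausdorffDistance(a, b), coarseDiag)
})
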
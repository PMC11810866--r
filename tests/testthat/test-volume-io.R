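test_that("NIfTI round-trip preserves grid, spacing and intensities", {
    vol <- volumetricImage(array(rnorm(10 * 10 * 5), c(10, 10, 5)),
                           spacing = c(1, 1, 2), origin = c(3, -2, 7))
    f <- withr::local_tempfile(fileext = ".nii.gz")
    writeVolume(vol, f)
    back <- readVolume(f)
    expect_identical(dim(back), dim(vol))
    expect_equal(volSpacing(back), volSpacing(vol), tolerance = 1e-6)
    expect_equal(volOrigin(back), volOrigin(vol), tolerance = 1e-5)
    expect_equal(volData(back), volData(vol))
})

test_that("NIfTI round-trip keeps rotated direction matrices", {
    R <- rotation(rotationAboutAxis(c(0, 0, 1), 25))
    vol <- volumetricImage(array(seq_len(8 * 8 * 4), c(8, 8, 4)),
                           spacing = c(0.7, 0.7, 2), origin = c(1, 2, 3),
                           axes = R)
    f <- withr::local_tempfile(fileext = ".nii")
    writeVolume(vol, f)
    back <- readVolume(f)
    expect_equal(volAxes(back), R, tolerance = 1e-6)
    expect_equal(volSpacing(back), c(0.7, 0.7, 2), tolerance = 1e-6)
})

test_that("non-orthonormal direction matrix is a format error", {
    f <- withr::local_tempfile(fileext = ".nii")
    img <- RNifti::asNifti(array(0, c(4, 4, 4)))
    m <- diag(4)
    m[1, 2] <- 0.5   # shear
    img <- RNifti::`sform<-`(img, structure(m, code = 2L))
    RNifti::writeNifti(img, f)
    expect_error(readVolume(f), "orthonormal")
})

test_that("MetaImage round-trips both on-disk layouts voxel-exactly", {
    vol <- volumetricImage(array(rnorm(6 * 7 * 8), c(6, 7, 8)),
                           spacing = c(1.5, 1, 2.5),
                           origin = c(-10, 4, 2))
    for (ext in c(".mha", ".mhd")) {
        f <- file.path(withr::local_tempdir(), paste0("vol", ext))
        writeVolume(vol, f)
        back <- readVolume(f)
        expect_identical(volData(back), volData(vol))
        expect_equal(volSpacing(back), volSpacing(vol))
        expect_equal(volOrigin(back), volOrigin(vol))
    }
})

test_that("MetaImage header problems name the offending field", {
    d <- withr::local_tempdir()
    f <- file.path(d, "bad.mha")
    writeLines(c("ObjectType = Image", "NDims = 3",
                 "ElementDataFile = LOCAL"), f)
    expect_error(readVolume(f), "DimSize")
    writeLines(c("ObjectType = Image", "NDims = 3", "DimSize = 2 2 2",
                 "ElementType = MET_COMPLEX",
                 "ElementDataFile = LOCAL"), f)
    expect_error(readVolume(f), "ElementType")
})

test_that("synthetic phantom volume survives the disk round-trip", {
    ph <- makePhantomVolume(phantomSpec(dims = c(20, 20, 16),
        spacing = c(4, 4, 5), semiAxes = c(30, 26, 30)), seed = 9)
    f <- withr::local_tempfile(fileext = ".nii.gz")
    writeVolume(ph$volume, f)
    back <- readVolume(f)
    expect_equal(volData(back), volData(ph$volume))
    expect_equal(volOrigin(back), volOrigin(ph$volume), tolerance = 1e-5)
})

test_that("padding adds a minimum-intensity border per slice", {
    a <- array(runif(8 * 8 * 3, min = 5, max = 9), c(8, 8, 3))
    vol <- volumetricImage(a, spacing = c(1, 2, 3))
    p <- padVolume(vol, 1)
    expect_identical(dim(p), c(10L, 10L, 3L))
    expect_equal(volData(p)[1, , ], matrix(min(a), 10, 3))
    expect_equal(volData(p)[, 1, ], matrix(min(a), 10, 3))
    expect_equal(volData(p)[2:9, 2:9, ], a)
    const <- volumetricImage(array(4.2, c(5, 5, 2)))
    expect_true(all(volData(padVolume(const, 2)) == 4.2))
    expect_identical(padVolume(vol, 0), vol)
})

test_that("padding keeps world coordinates of original voxels", {
    R <- rotation(rotationAboutAxis(c(1, 1, 0), 15))
    vol <- volumetricImage(array(rnorm(60), c(5, 4, 3)),
                           spacing = c(1.2, 0.8, 2), origin = c(4, -1, 6),
                           axes = R)
    p <- padVolume(vol, 3)
    idx <- rbind(c(0, 0, 0), c(4, 3, 2), c(2, 1, 1))
    shifted <- sweep(idx, 2L, c(3, 3, 0), "+")
    expect_equal(voxelToWorld(p, shifted), voxelToWorld(vol, idx),
                 tolerance = 1e-12)
})

test_that("subsampling decimates with doubled spacing, origin fixed", {
    a <- array(rnorm(64 * 64 * 32), c(64, 64, 32))
    vol <- volumetricImage(a, spacing = c(0.5, 0.5, 1))
    s <- subsampleVolume(vol, 2)
    expect_identical(dim(s), c(32L, 32L, 16L))
    expect_equal(volSpacing(s), c(1, 1, 2))
    expect_equal(volOrigin(s), volOrigin(vol))
    # voxel (i,j,k) of the subsampled grid is original (2i,2j,2k)
    expect_equal(volData(s)[3, 5, 7], a[5, 9, 13])
    expect_identical(subsampleVolume(vol, 1), vol)
    expect_error(subsampleVolume(vol, 40), "exceeds")
})
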
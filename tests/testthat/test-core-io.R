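# Data model invariants and NIfTI/CSV round-trips.

test_that("constructors enforce the geometric invariants", {
  expect_error(image_volume(matrix(0, 2, 2), c(1, 1, 1)), "3D")
  expect_error(image_volume(array(0, dim = c(2, 2, 2)), c(1, -1, 1)),
               "positive")
  expect_error(image_volume(array(c(0, NA), dim = c(2, 1, 1)), c(1, 1, 1)),
               "finite")
  expect_error(deformation_field(array(0, dim = c(2, 2, 2)), c(1, 1, 1)),
               "3 components")
  expect_error(rigid_transform(rotation = diag(c(1, 1, -1))), "determinant")
  expect_error(landmark_set(c("a", "a"), 1:2, 1:2, 1:2), "unique")
})

test_that("volume, mask, field and landmark files round-trip losslessly", {
  dir <- withr::local_tempdir()
  vol <- image_volume(array(stats::rnorm(4 * 4 * 4), dim = c(4, 4, 4)),
                      spacing = c(0.24, 0.24, 2), origin = c(-3, 2, 10))
  p <- file.path(dir, "v.nii.gz")
  write_volume(vol, p)
  back <- read_volume(p)
  expect_identical(back$voxels, vol$voxels)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-6)

  zero <- image_volume(array(0, dim = c(4, 4, 4)), c(1, 1, 1))
  write_volume(zero, p)
  expect_identical(read_volume(p)$voxels, zero$voxels)

  msk <- structure_mask(array(stats::runif(64) > 0.4, dim = c(4, 4, 4)),
                        c(1, 1, 2), label = "s")
  pm <- file.path(dir, "m.nii.gz")
  write_mask(msk, pm)
  expect_identical(read_mask(pm, "s")$voxels, msk$voxels)

  fld <- deformation_field(array(stats::rnorm(4^3 * 3), dim = c(4, 4, 4, 3)),
                           c(1, 1, 2))
  pf <- file.path(dir, "f.nii.gz")
  write_field(fld, pf)
  expect_identical(read_field(pf)$vectors, fld$vectors)

  lms <- landmark_set(c("g1", "g2"), c(0.5, -2), c(1, 4), c(9, 9))
  pl <- file.path(dir, "l.csv")
  write_landmarks(lms, pl)
  expect_equal(as.data.frame(read_landmarks(pl)), as.data.frame(lms))
})

test_that("non-3D NIfTI input is rejected as a format error", {
  p <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(matrix(0, 4, 4)), p)
  expect_error(read_volume(p), "format error")
  expect_error(read_field(p), "format error")
})

test_that("push-forward fields are inverted on import", {
  dir <- withr::local_tempdir()
  d <- c(14, 14, 14)
  fwd <- local({
    g <- image_volume(array(0, dim = d), c(1, 1, 1))
    pts <- dirqa:::grid_points(g)
    r2 <- rowSums(sweep(pts, 2, c(6.5, 6.5, 6.5))^2)
    ux <- 1.5 * exp(-r2 / 18)
    deformation_field(array(cbind(ux, 0 * ux, 0 * ux), dim = c(d, 3)),
                      c(1, 1, 1))
  })
  p <- file.path(dir, "fwd.nii.gz")
  write_field(fwd, p)
  inv <- read_field(p, convention = "push-forward")
  lm <- landmark_set("c", 6.5, 6.5, 6.5)
  round_trip <- transform_points(inv, transform_points(fwd, lm))
  expect_lt(abs(round_trip$x - 6.5), 0.02)
})
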
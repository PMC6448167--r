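# Warping, composition, point mapping and field inversion.

zero_field_on <- function(vol) {
  deformation_field(array(0, dim = c(dim(vol$voxels), 3)), vol$spacing,
                    vol$origin)
}

test_that("resampling with the identity field reproduces the volume exactly", {
  vol <- fixtures$two_cubes
  out <- resample(vol, zero_field_on(vol), fill = 0)
  expect_equal(out$voxels, vol$voxels)
})

test_that("integer-voxel translations shift the voxel array exactly", {
  vol <- image_volume(array(seq_len(6^3), dim = c(6, 6, 6)), c(1, 1, 2))
  f <- zero_field_on(vol)
  f$vectors[, , , 3] <- 2  # one slice in z
  out <- resample(vol, f, fill = -1)
  expect_equal(out$voxels[, , 1:5], vol$voxels[, , 2:6])
  expect_true(all(out$voxels[, , 6] == -1))
})

test_that("half-voxel translation of a linear ramp matches the analytic value", {
  vol <- ramp_volume(d = c(10, 8, 6), coef = c(4, 0, 0))
  f <- zero_field_on(vol)
  f$vectors[, , , 1] <- 0.5
  out <- resample(vol, f, fill = 0)
  expect_equal(out$voxels[1:9, , ], vol$voxels[1:9, , ] + 2, tolerance = 1e-12)
})

test_that("warping with a composed transform equals sequential warps", {
  vol <- ramp_volume(d = c(14, 14, 14), coef = c(3, -2, 5))
  fld <- fixtures$smooth_field
  fld <- deformation_field(fld$vectors[1:14, 1:14, 1:14, , drop = FALSE],
                           c(1, 1, 1))
  rig <- rigid_transform(axis_rotation(3, 4), c(0.4, -0.2, 0.3),
                         center = c(7, 7, 7))
  comp <- compose(rig, fld)
  w_comp <- resample(vol, comp, fill = 0)
  w_seq <- resample(resample(vol, rig), fld, fill = 0)
  interior <- 4:11
  expect_equal(w_comp$voxels[interior, interior, interior],
               w_seq$voxels[interior, interior, interior], tolerance = 1e-9)
})

test_that("compose with the identity rigid leaves the field unchanged", {
  fld <- fixtures$smooth_field
  expect_equal(compose(rigid_transform(), fld)$vectors, fld$vectors,
               tolerance = 1e-12)
})

test_that("compose of a rigid with the zero field is the rigid displacement", {
  vol <- fixtures$two_cubes
  rig <- rigid_transform(axis_rotation(1, 10), c(1, 2, 3), center = c(5, 5, 5))
  comp <- compose(rig, zero_field_on(vol))
  pts <- dirqa:::grid_points(vol)
  expect_equal(matrix(comp$vectors, ncol = 3),
               dirqa:::apply_rigid_points(rig, pts) - pts, tolerance = 1e-12)
})

test_that("transform_points handles rigid, field and closure transforms", {
  lm <- landmark_set(c("a", "b"), c(3, 9), c(4, 8), c(5, 7))
  expect_equal(as.data.frame(transform_points(rigid_transform(), lm)),
               as.data.frame(lm))
  tr <- rigid_transform(translation = c(1, -2, 0.5))
  shifted <- transform_points(tr, lm)
  expect_equal(shifted$x, lm$x + 1)
  expect_equal(shifted$z, lm$z + 0.5)

  spec <- coarse_bend(8)$spec
  bent <- transform_points(attr(coarse_bend(8)$truth, "forward"), lm)
  direct <- dirqa:::bend_forward_points(cbind(lm$x, lm$y, lm$z), spec)
  expect_equal(cbind(bent$x, bent$y, bent$z), direct, tolerance = 1e-12)
})

test_that("points outside the field domain raise a named domain error", {
  fld <- fixtures$smooth_field
  lm <- landmark_set("outside", 500, 0, 0)
  expect_error(transform_points(fld, lm), "outside.*outside")
})

test_that("fixed-point inversion undoes a smooth field to sub-tolerance", {
  fld <- fixtures$smooth_field
  inv <- invert_field(fld)
  lm <- landmark_set(paste0("p", 1:4), c(6, 9, 12, 8), c(7, 10, 6, 12),
                     c(8, 8, 11, 10))
  rt <- transform_points(inv, transform_points(fld, lm))
  err <- max(abs(cbind(rt$x - lm$x, rt$y - lm$y, rt$z - lm$z)))
  expect_lt(err, 0.05)
  rt2 <- invert_map_points(fld, transform_points(fld, lm))
  err2 <- max(abs(cbind(rt2$x - lm$x, rt2$y - lm$y, rt2$z - lm$z)))
  expect_lt(err2, 0.05)
})
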
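# Bending-stick phantom generation, ground-truth bend transform and the
# end-axes angle measurement.

test_that("spec validation rejects impossible geometries", {
  expect_error(bending_phantom_spec(angle_deg = -3), "parameter error")
  expect_error(bending_phantom_spec(angle_deg = 150), "self-intersect")
  expect_error(bending_phantom_spec(sphere_z_mm = c(2, 75, 125)),
               "inside the stick")
  expect_error(bending_phantom_spec(sphere_diameter_mm = 1.5),
               "grain diameter")
})

test_that("straight-phantom sphere masks match the analytic sphere volume", {
  # CT-resolution grid: voxel-count volume of the discretized spheres
  b <- build_bending_phantom(bending_phantom_spec(0, spacing = c(1, 1, 2)))
  expect_length(b$sphere_masks, 3)
  voxvol <- prod(b$volume$spacing)
  analytic <- pi / 6 * 16^3
  for (m in b$sphere_masks)
    expect_lt(abs(sum(m$voxels) * voxvol - analytic) / analytic, 0.02)
})

test_that("interior voxels carry the exact material HU of the spec", {
  b <- coarse_bend(0)
  spec <- b$spec
  # clay sample away from every boundary
  g <- image_volume(array(0, dim = dim(b$volume$voxels)), b$volume$spacing,
                    b$volume$origin)
  pts <- dirqa:::grid_points(g)
  in_clay <- pts[, 1]^2 + pts[, 2]^2 < (spec$radius_mm - 3)^2 &
    pts[, 3] > 3 & pts[, 3] < spec$length_mm - 3
  for (zc in spec$sphere_z_mm)
    in_clay <- in_clay & (pts[, 1]^2 + pts[, 2]^2 + (pts[, 3] - zc)^2 >
                            (spec$sphere_diameter_mm / 2 + 3)^2)
  for (i in seq_len(nrow(spec$grain_xyz)))
    in_clay <- in_clay & (colSums((t(pts) - spec$grain_xyz[i, ])^2) > 16)
  vals <- b$volume$voxels[array(in_clay, dim = dim(b$volume$voxels))]
  expect_true(all(vals == spec$hu[["clay"]]))
})

test_that("bend transform is the exact analytic mapping with exact inverse", {
  b <- coarse_bend(8)
  fwd <- attr(b$truth, "forward"); inv <- attr(b$truth, "inverse")
  pts <- cbind(c(0, 5, -5, 2), c(0, 3, -3, 0), c(0, 40, 90, 140))
  expect_lt(max(abs(inv(fwd(pts)) - pts)), 1e-6)
  # anchor: the fixed-end axis point does not move
  expect_equal(as.vector(fwd(cbind(0, 0, 0))), c(0, 0, 0), tolerance = 1e-9)
  # grain landmarks are exactly the forward-mapped straight positions
  straight <- b$spec$grain_xyz
  mapped <- fwd(straight)
  grains <- b$landmarks[grepl("grain", b$landmarks$name), ]
  expect_equal(cbind(grains$x, grains$y, grains$z), unname(mapped),
               tolerance = 1e-9)
})

test_that("zero bending angle produces the identity transform", {
  b <- coarse_bend(0)
  expect_equal(max(abs(b$truth$vectors)), 0)
})

test_that("measured end-axes angle reproduces the configured study levels", {
  for (angle in c(0, 8, 16, 25)) {
    b <- coarse_bend(angle)
    expect_lt(abs(measure_bend_angle(b$volume) - angle), 1,
              label = paste0("angle ", angle, " deg"))
  }
})

test_that("the angle measurement is invariant to a whole-body rotation", {
  spec <- bending_phantom_spec(0, spacing = c(2, 2, 2))
  R <- axis_rotation(2, 30)
  grid <- image_volume(array(0, dim = c(98, 25, 90)), c(2, 2, 2),
                       c(-97, -24, -12))
  hu <- as.numeric(spec$hu[c("background", "clay", "glass")])
  vol <- dirqa:::render_phantom(grid, function(p)
    dirqa:::bending_material(p %*% R, spec), hu)
  expect_lt(measure_bend_angle(vol), 1)
})

test_that("degenerate foregrounds raise measurement errors", {
  flat <- image_volume(array(-1000, dim = c(8, 8, 8)), c(1, 1, 1))
  expect_error(measure_bend_angle(flat), "empty foreground")
  blob <- flat
  blob$voxels[3:6, 3:6, 3:6] <- 500
  expect_error(measure_bend_angle(blob), "not elongated")
})
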
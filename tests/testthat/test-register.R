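# Rigid alignment, the demons-type stand-in DIR, box refinement and field
# error statistics.

textured_volume <- function(d = c(40, 40, 40), seed = 2, sp = c(1, 1, 1)) {
  rng <- dirqa:::local_rng(seed)
  arr <- rng(array(stats::rnorm(prod(d)), dim = d))
  arr <- dirqa:::smooth_gaussian(arr, 2, sp)
  image_volume(1000 * (arr - min(arr)) / diff(range(arr)), sp)
}

test_that("landmark rigid fit recovers a known transform", {
  set.seed(4)
  P <- matrix(stats::runif(15, 0, 50), 5, 3)
  R <- axis_rotation(3, 12) %*% axis_rotation(1, -7)
  t <- c(4, -2, 6)
  Q <- t(R %*% t(P)) + rep(t, each = 5)
  lmP <- landmark_set(paste0("p", 1:5), P[, 1], P[, 2], P[, 3])
  lmQ <- landmark_set(paste0("p", 1:5), Q[, 1], Q[, 2], Q[, 3])
  fit <- rigid_align(mode = "landmark", anchors = list(lmP, lmQ))
  expect_lt(attr(fit, "rms"), 1e-9)
  expect_lt(max(abs(dirqa:::apply_rigid_points(fit, P) - Q)), 1e-9)
  expect_error(rigid_align(mode = "landmark",
                           anchors = list(lmP[1, ], lmQ[1, ])),
               ">= 2 corresponding")
})

test_that("two-point alignment uses the minimal twist-free rotation", {
  lmP <- landmark_set(c("a", "b"), c(0, 0), c(0, 0), c(0, 100))
  lmQ <- landmark_set(c("a", "b"), c(0, 30), c(0, 0), c(5, 100))
  fit <- rigid_align(mode = "landmark", anchors = list(lmP, lmQ))
  # a vector orthogonal to the segment plane must stay put
  expect_lt(abs(dirqa:::rotation_angle_deg(fit$rotation)), 20)
  ey <- fit$rotation %*% c(0, 1, 0)
  expect_gt(ey[2], 0.95)
})

test_that("intensity rigid mode is exact on identical and shifted images", {
  vol <- textured_volume(c(30, 30, 30))
  ident <- rigid_align(vol, vol, mode = "intensity")
  expect_true(dirqa:::is_identity_rigid(ident))
  t_known <- c(1.6, -1.1, 0.8)
  shifted <- resample(vol, rigid_transform(translation = t_known),
                      reference = vol, fill = 0)
  # reference -> target transform should recover the sampling translation
  fit <- rigid_align(shifted, vol, mode = "intensity", maxit = 400)
  expect_lt(max(abs(fit$translation - t_known)), 0.2)
})

test_that("registering a volume against itself yields the zero field", {
  vol <- textured_volume(c(24, 24, 24))
  f <- deform_register(vol, vol, params = dir_params(iterations = c(5, 5, 5)))
  expect_equal(max(abs(f$vectors)), 0)
})

test_that("a known Gaussian-bump warp is recovered below one voxel", {
  vol <- textured_volume(c(48, 48, 48))
  d <- dim(vol$voxels)
  pts <- dirqa:::grid_points(vol)
  r2 <- rowSums(sweep(pts, 2, c(24, 24, 24))^2)
  ux <- 3 * exp(-r2 / (2 * 8^2))  # 3 mm peak displacement
  truth <- deformation_field(array(cbind(ux, 0 * ux, 0 * ux), dim = c(d, 3)),
                             vol$spacing, vol$origin)
  tgt <- resample(vol, truth, fill = 0)
  est <- deform_register(vol, tgt, params = dir_params(force_floor = 0))
  roi <- structure_mask(array(r2 <= 18^2, dim = d), vol$spacing, vol$origin)
  err <- dvf_error(est, invert_field(truth), roi)
  expect_lt(err[["mean"]], 1)
})

test_that("DIR shrinks marker distances relative to rigid alignment alone", {
  b0 <- coarse_bend(0); b8 <- coarse_bend(8)
  cs <- study_contrast_levels()[["30_1000"]]
  r0 <- remap_contrast(b0$volume, cs); r8 <- remap_contrast(b8$volume, cs)
  an <- c("sphere1", "sphere3")
  init <- rigid_align(mode = "landmark", anchors = list(
    b0$landmarks[match(an, b0$landmarks$name), ],
    b8$landmarks[match(an, b8$landmarks$name), ]))
  field <- deform_register(r0, r8, init,
                           dir_params(iterations = c(40, 25, 10)))
  rm_of <- function(transform) {
    mapped <- if (inherits(transform, "dirqa_field"))
      invert_map_points(transform, b8$landmarks)
    else transform_points(dirqa:::rigid_inverse(transform), b8$landmarks)
    mean(sqrt(rowSums((dirqa:::landmark_matrix(mapped) -
                         dirqa:::landmark_matrix(b0$landmarks))^2)))
  }
  expect_lt(rm_of(field), rm_of(init))
})

test_that("dvf_error matches a direct per-voxel computation", {
  d <- c(6, 5, 4)
  ea <- deformation_field(array(stats::rnorm(prod(d) * 3), dim = c(d, 3)),
                          c(1, 1, 2))
  tr <- deformation_field(array(stats::rnorm(prod(d) * 3), dim = c(d, 3)),
                          c(1, 1, 2))
  expect_equal(dvf_error(ea, ea), c(mean = 0, max = 0))
  shift <- deformation_field(array(rep(c(2, 0, 0), each = prod(d)),
                                   dim = c(d, 3)), c(1, 1, 2))
  zero <- deformation_field(array(0, dim = c(d, 3)), c(1, 1, 2))
  expect_equal(dvf_error(shift, zero), c(mean = 2, max = 2))
  manual <- numeric(prod(d))
  for (i in seq_len(prod(d))) {
    dv <- sapply(1:3, function(cmp)
      as.vector(ea$vectors[, , , cmp])[i] - as.vector(tr$vectors[, , , cmp])[i])
    manual[i] <- sqrt(sum(dv^2))
  }
  expect_equal(dvf_error(ea, tr),
               c(mean = mean(manual), max = max(manual)))
  bad <- deformation_field(array(0, dim = c(d, 3)), c(2, 2, 2))
  expect_error(dvf_error(ea, bad), "geometry error")
})

test_that("reg_refine is a no-op without boxes and local otherwise", {
  vol <- textured_volume(c(36, 36, 20))
  d <- dim(vol$voxels)
  # target differs from the reference only by a shift inside one region
  shift_region <- array(FALSE, dim = d)
  shift_region[6:16, 6:16, 5:15] <- TRUE
  tgt <- vol
  tgt$voxels[4:14, 6:16, 5:15] <- vol$voxels[6:16, 6:16, 5:15]
  zero <- deformation_field(array(0, dim = c(d, 3)), vol$spacing, vol$origin)
  expect_identical(reg_refine(vol, tgt, zero, list()), zero)

  box <- refine_box(center = c(10, 10, 9.5), half_size = c(6, 6, 6))
  refined <- reg_refine(vol, tgt, zero, list(box),
                        dir_params(iterations = 5, force_floor = 0))
  resid <- function(field) {
    w <- resample(tgt, field, fill = 0)
    mean((w$voxels[shift_region] - vol$voxels[shift_region])^2)
  }
  expect_lt(resid(refined), resid(zero))
  # far from the box (beyond 4 blend sigmas) the field is untouched
  pts <- dirqa:::grid_points(vol)
  dist <- sqrt(rowSums(sweep(pts, 2, box$center)^2))
  sgm <- sqrt(sum(box$half_size^2)) / 2
  far <- array(dist > 4 * sgm, dim = d)
  for (cmp in 1:3)
    expect_equal(max(abs(refined$vectors[, , , cmp][far])), 0)
  expect_error(reg_refine(vol, tgt, zero,
                          list(refine_box(c(500, 0, 0), c(5, 5, 5)))),
               "outside the image domain")
})
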
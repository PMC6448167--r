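# Similarity indices against independent brute-force oracles, threshold
# segmentation, and the report assembly.

test_that("threshold segmentation splits and orders components correctly", {
  masks <- threshold_segment(fixtures$two_cubes, 0.5, min_voxels = 5)
  expect_length(masks, 2)
  expect_equal(sum(masks[[1]]$voxels), 4^3)
  expect_equal(sum(masks[[2]]$voxels), 6^3)
  expect_lt(centroid(masks[[1]])[3], centroid(masks[[2]])[3])

  uniform <- image_volume(array(7, dim = c(4, 4, 4)), c(1, 1, 1))
  expect_error(threshold_segment(uniform), "degenerate")
  expect_error(threshold_segment(fixtures$two_cubes, fraction = 1.5),
               "parameter error")
  expect_error(threshold_segment(fixtures$two_cubes, min_voxels = 1e6),
               "min_voxels")
})

test_that("the straight phantom segments into exactly the three spheres", {
  b <- coarse_bend(0)
  masks <- threshold_segment(b$volume, 0.5, min_voxels = 40)
  expect_length(masks, 3)
  for (i in 1:3) {
    ctr <- centroid(masks[[i]])
    expect_lt(sqrt(sum((ctr - c(0, 0, b$spec$sphere_z_mm[i]))^2)), 0.5)
  }
})

test_that("centroid equals the brute-force coordinate mean", {
  m <- fixtures$cube_pair$a
  single <- structure_mask(array(FALSE, dim = c(5, 5, 5)), c(1, 2, 3),
                           c(10, 0, -4))
  single$voxels[3, 4, 2] <- TRUE
  expect_equal(centroid(single), c(10 + 2 * 1, 0 + 3 * 2, -4 + 1 * 3))
  expect_equal(centroid(m), unname(colMeans(mask_coords(m))))
  empty <- structure_mask(array(FALSE, dim = c(2, 2, 2)), c(1, 1, 1))
  expect_error(centroid(empty), "empty mask")
})

test_that("centroid distance is exact for rigid shifts", {
  a <- fixtures$cube_pair$a
  b <- a
  b$voxels <- array(FALSE, dim = dim(a$voxels))
  b$voxels[4:13, 1:10, 1:10] <- TRUE  # 3-voxel x-shift at 1 mm spacing
  expect_equal(centroid_distance(a, b), 3)
  expect_equal(centroid_distance(a, a), 0)
})

test_that("dice matches voxel-count arithmetic and its edge cases", {
  a <- fixtures$cube_pair$a; b <- fixtures$cube_pair$b
  expect_equal(dice(a, b), 0.5)  # 2*500 / 2000
  expect_equal(dice(a, a), 1)
  disjoint <- a
  disjoint$voxels <- array(FALSE, dim = dim(a$voxels))
  disjoint$voxels[12:15, 12:15, 12:15] <- TRUE
  expect_equal(dice(a, disjoint), 0)
  empty <- structure_mask(array(FALSE, dim = dim(a$voxels)), a$spacing)
  expect_error(dice(empty, empty), "both masks are empty")
  other_grid <- structure_mask(a$voxels, a$spacing * 2)
  expect_error(dice(a, other_grid), "geometry error")
  expect_equal(dice(a, b), dice(b, a))
})

test_that("dice decreases monotonically with shift for a convex mask", {
  d <- c(24, 12, 12)
  base <- structure_mask(array(FALSE, dim = d), c(1, 1, 1))
  base$voxels[3:10, 3:10, 3:10] <- TRUE
  vals <- vapply(0:6, function(s) {
    shifted <- structure_mask(array(FALSE, dim = d), c(1, 1, 1))
    shifted$voxels[(3 + s):(10 + s), 3:10, 3:10] <- TRUE
    dice(base, shifted)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("hausdorff matches the brute-force oracle on small fixtures", {
  a <- fixtures$cube_pair$a; b <- fixtures$cube_pair$b
  expect_equal(hausdorff(a, b), oracle_hausdorff(a, b))
  expect_equal(hausdorff(a, a), 0)
  expect_equal(hausdorff(a, b), hausdorff(b, a))
  # cube translated 3 mm along one axis
  shifted <- a
  shifted$voxels <- array(FALSE, dim = dim(a$voxels))
  shifted$voxels[4:13, 1:10, 1:10] <- TRUE
  expect_equal(hausdorff(a, shifted), 3)
  # concentric digital spheres, radius 5 and 8 mm
  hd <- hausdorff(fixtures$sphere_r5, fixtures$sphere_r8)
  expect_equal(hd, oracle_hausdorff(fixtures$sphere_r5, fixtures$sphere_r8))
  expect_lt(abs(hd - 3), sqrt(3) / 2 + 1e-9)
  expect_error(hausdorff(a, structure_mask(array(FALSE, dim = dim(a$voxels)),
                                           a$spacing)), "empty")
})

test_that("hausdorff under dilation is bounded by the dilation radius", {
  a <- fixtures$sphere_r5
  dil <- structure_mask(
    dirqa:::smooth_gaussian(a$voxels + 0, 0, a$spacing) > 0.5, a$spacing)
  # one-voxel 6-neighbour dilation by explicit shifting
  v <- a$voxels
  for (ax in 1:3) for (dr in c(-1, 1)) {
    idx <- seq_len(dim(v)[ax])
    src <- pmin(pmax(idx - dr, 1), dim(v)[ax])
    if (ax == 1) dil$voxels <- dil$voxels | v[src, , ]
    if (ax == 2) dil$voxels <- dil$voxels | v[, src, ]
    if (ax == 3) dil$voxels <- dil$voxels | v[, , src]
  }
  expect_lte(hausdorff(a, dil), max(a$spacing) + 1e-9)
})

test_that("max diameter matches the brute-force oracle", {
  single <- structure_mask(array(FALSE, dim = c(5, 5, 5)), c(1, 1, 1))
  single$voxels[3, 3, 3] <- TRUE
  expect_equal(max_diameter(single), 0)
  two <- single
  two$voxels[3, 3, 1] <- TRUE  # 2 voxels, 2 slices apart
  two$spacing <- c(1, 1, 2)
  expect_equal(max_diameter(two), 4)
  expect_equal(max_diameter(fixtures$sphere_r8),
               oracle_max_diameter(fixtures$sphere_r8))
  expect_equal(max_diameter(fixtures$cube_pair$a),
               oracle_max_diameter(fixtures$cube_pair$a))
})

test_that("a segmented 16 mm digital sphere measures 16 mm across", {
  sp <- c(0.5, 0.5, 0.5)
  dims <- c(41L, 41L, 41L)
  g <- image_volume(array(0, dim = dims), sp)
  pts <- dirqa:::grid_points(g)
  inside <- rowSums(sweep(pts, 2, c(10, 10, 10))^2) <= 8^2
  m <- structure_mask(array(inside, dim = dims), sp)
  expect_lt(abs(max_diameter(m) - 16), sqrt(sum(sp^2)))
})

test_that("evaluate_similarity assembles indices, summaries and errors", {
  a <- fixtures$cube_pair$a
  ref <- list(s1 = a, s2 = a, s3 = a)
  shift_mask <- function(s) {
    m <- structure_mask(array(FALSE, dim = dim(a$voxels)), a$spacing)
    m$voxels[(1 + s):(10 + s), 1:10, 1:10] <- TRUE
    m
  }
  reg <- list(s1 = shift_mask(1), s2 = shift_mask(2), s3 = shift_mask(3))
  rep <- evaluate_similarity(ref, reg)
  expect_equal(rep$summary$mean[rep$summary$index == "R"], 2)
  self <- evaluate_similarity(ref, ref)
  expect_true(all(self$structures$DSC == 1))
  expect_true(all(self$structures[c("HD", "DD", "R")] == 0))
  expect_error(evaluate_similarity(ref, reg[c("s1", "s2")]),
               "unmatched structures: s3")
  lmA <- landmark_set(c("m1", "m2"), c(0, 1), c(0, 0), c(0, 0))
  lmB <- landmark_set(c("m1", "mX"), c(0, 1), c(0, 0), c(0, 0))
  expect_error(evaluate_similarity(ref, reg, lmA, lmB), "unmatched landmarks")
  # order invariance
  rep2 <- evaluate_similarity(ref[c(3, 1, 2)], reg[c(3, 1, 2)])
  expect_equal(sort(rep2$structures$R), sort(rep$structures$R))
  expect_equal(rep2$summary$mean[rep2$summary$index == "R"], 2)
})

test_that("report serialization writes JSON and flat CSV", {
  dir <- withr::local_tempdir()
  a <- fixtures$cube_pair$a
  rep <- evaluate_similarity(list(s1 = a), list(s1 = fixtures$cube_pair$b),
                             metadata = list(registration = "unit"))
  paths <- write_report(rep, file.path(dir, "report"))
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paths[["json"]])
  expect_equal(js$metadata$registration, "unit")
  long <- utils::read.csv(paths[["csv"]])
  expect_setequal(long$index, c("DSC", "HD", "DD", "R"))
})
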
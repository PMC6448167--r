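# Shared fixtures and independent brute-force oracles. All fixtures are
# generated in code; the coarse (2 mm) phantom grids keep the suite fast
# while leaving every geometric property intact.

fixtures <- make_fixtures(seed = 17)

# cached coarse phantoms used by several files
coarse_bend <- function(angle) {
  key <- paste0("bend", angle)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- build_bending_phantom(
      bending_phantom_spec(angle_deg = angle, spacing = c(2, 2, 2)))
  .fixture_cache[[key]]
}
coarse_shrink <- function(fill) {
  key <- paste0("shrink", fill)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- build_shrinking_phantom(
      shrinking_phantom_spec(fill_ml = fill, spacing = c(2, 2, 2)))
  .fixture_cache[[key]]
}
desk_bend <- function(angle) {
  key <- paste0("desk_bend", angle)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- build_bending_phantom(
      bending_phantom_spec(angle_deg = angle, spacing = c(1, 1, 2)))
  .fixture_cache[[key]]
}
desk_shrink <- function(fill) {
  key <- paste0("desk_shrink", fill)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- build_shrinking_phantom(
      shrinking_phantom_spec(fill_ml = fill, spacing = c(1, 1, 2)))
  .fixture_cache[[key]]
}
.fixture_cache <- new.env()

mask_coords <- function(mask) {
  idx <- which(mask$voxels, arr.ind = TRUE) - 1
  sweep(sweep(idx, 2, mask$spacing, "*"), 2, mask$origin, "+")
}

# O(n^2) oracles on surface voxel sets (surface = member voxel with a face
# neighbour outside), independent of the package implementation
oracle_surface <- function(mask) {
  v <- mask$voxels
  d <- dim(v)
  idx <- which(v, arr.ind = TRUE)
  on_surface <- vapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    nb <- rbind(c(i - 1, j, k), c(i + 1, j, k), c(i, j - 1, k),
                c(i, j + 1, k), c(i, j, k - 1), c(i, j, k + 1))
    any(apply(nb, 1, function(p)
      p[1] < 1 || p[1] > d[1] || p[2] < 1 || p[2] > d[2] ||
        p[3] < 1 || p[3] > d[3] || !v[p[1], p[2], p[3]]))
  }, logical(1))
  pts <- idx[on_surface, , drop = FALSE] - 1
  sweep(sweep(pts, 2, mask$spacing, "*"), 2, mask$origin, "+")
}

oracle_hausdorff <- function(a, b) {
  sa <- oracle_surface(a); sb <- oracle_surface(b)
  dmat <- as.matrix(stats::dist(rbind(sa, sb)))[seq_len(nrow(sa)),
                                                nrow(sa) + seq_len(nrow(sb))]
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}

oracle_max_diameter <- function(mask) {
  s <- oracle_surface(mask)
  if (nrow(s) < 2) return(0)
  max(stats::dist(s))
}

# exact Wilcoxon p by full sign enumeration (n <= ~15)
oracle_wilcoxon <- function(a, b) {
  d <- (a - b)[a - b != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# analytic trilinear interpolation of a 3D affine function is exact, making
# affine-ramp volumes exact test images for warping identities
ramp_volume <- function(d = c(12, 12, 12), coef = c(3, 5, 7), sp = c(1, 1, 1)) {
  g <- image_volume(array(0, dim = d), sp)
  pts <- dirqa:::grid_points(g)
  image_volume(array(pts %*% coef, dim = d), sp)
}
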
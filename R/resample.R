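# Trilinear interpolation of a 3D array at continuous 0-based index
# coordinates. `ci` is an N x 3 matrix; out-of-domain points take `fill`.
interp_trilinear_index <- function(arr, ci, fill) {
  d <- dim(arr)
  n <- nrow(ci)
  inside <- ci[, 1] >= 0 & ci[, 1] <= d[1] - 1 &
            ci[, 2] >= 0 & ci[, 2] <= d[2] - 1 &
            ci[, 3] >= 0 & ci[, 3] <= d[3] - 1
  out <- rep(as.numeric(fill), n)
  if (!any(inside)) return(out)
  p <- ci[inside, , drop = FALSE]
  i0 <- pmin(floor(p[, 1]), d[1] - 2); i0[d[1] == 1] <- 0
  j0 <- pmin(floor(p[, 2]), d[2] - 2); j0[d[2] == 1] <- 0
  k0 <- pmin(floor(p[, 3]), d[3] - 2); k0[d[3] == 1] <- 0
  fx <- p[, 1] - i0; fy <- p[, 2] - j0; fz <- p[, 3] - k0
  # linear index of corner (i0, j0, k0), 1-based
  base <- 1 + i0 + d[1] * (j0 + d[2] * k0)
  sx <- 1; sy <- d[1]; sz <- d[1] * d[2]
  if (d[1] == 1) { sx <- 0; fx <- fx * 0 }
  if (d[2] == 1) { sy <- 0; fy <- fy * 0 }
  if (d[3] == 1) { sz <- 0; fz <- fz * 0 }
  v000 <- arr[base];            v100 <- arr[base + sx]
  v010 <- arr[base + sy];       v110 <- arr[base + sx + sy]
  v001 <- arr[base + sz];       v101 <- arr[base + sx + sz]
  v011 <- arr[base + sy + sz];  v111 <- arr[base + sx + sy + sz]
  c00 <- v000 + fx * (v100 - v000); c10 <- v010 + fx * (v110 - v010)
  c01 <- v001 + fx * (v101 - v001); c11 <- v011 + fx * (v111 - v011)
  c0 <- c00 + fy * (c10 - c00); c1 <- c01 + fy * (c11 - c01)
  out[inside] <- c0 + fz * (c1 - c0)
  out
}

# Sample a volume at world points (N x 3 matrix), trilinear, fill outside.
sample_volume <- function(volume, pts, fill = -1000) {
  interp_trilinear_index(volume$voxels, world_to_index(volume, pts), fill)
}

# Sample a vector field at world points; points outside the field domain
# yield NA rows unless `rule = "clamp"` clamps to the boundary.
sample_field <- function(field, pts, rule = c("na", "clamp")) {
  rule <- match.arg(rule)
  ci <- world_to_index(field, pts)
  d <- dim(field$vectors)[1:3]
  if (rule == "clamp")
    for (a in 1:3) ci[, a] <- pmin(pmax(ci[, a], 0), d[a] - 1)
  u <- vapply(1:3, function(cmp)
    interp_trilinear_index(field$vectors[, , , cmp], ci, NA_real_),
    numeric(nrow(pts)))
  matrix(u, ncol = 3)
}

#' Warp a volume by a displacement field or rigid transform
#'
#' Realizes the "registered dataset": for each voxel center `p` of the output
#' grid the target volume is sampled (trilinear) at `p + u(p)` for a
#' displacement field, or at `rigid(p)` for a rigid transform. Positions
#' falling outside the target take the `fill` value (air by default).
#'
#' @param target `dirqa_volume` to be warped.
#' @param transform a `dirqa_field` (defines the output grid) or a
#'   `dirqa_rigid` (output grid given by `reference`, default the target grid).
#' @param fill HU value for out-of-bounds samples.
#' @param reference optional volume/mask providing the output grid when
#'   `transform` is rigid.
#' @return A `dirqa_volume` on the reference grid.
#' @export
resample <- function(target, transform, fill = -1000, reference = NULL) {
  if (inherits(transform, "dirqa_field")) {
    d <- grid_dims(transform)
    pts <- grid_points(transform)
    pts <- pts + matrix(transform$vectors, ncol = 3)
    vox <- array(sample_volume(target, pts, fill), dim = d)
    return(image_volume(vox, transform$spacing, transform$origin))
  }
  if (inherits(transform, "dirqa_rigid")) {
    ref <- if (is.null(reference)) target else reference
    d <- grid_dims(ref)
    pts <- apply_rigid_points(transform, grid_points(ref))
    vox <- array(sample_volume(target, pts, fill), dim = d)
    return(image_volume(vox, ref$spacing, ref$origin))
  }
  stop("`transform` must be a dirqa_field or dirqa_rigid", call. = FALSE)
}

#' Warp a binary mask by a displacement field (nearest-neighbour)
#' @param mask `dirqa_mask`; @param field `dirqa_field` on the output grid.
#' @return A `dirqa_mask` on the field grid.
#' @export
resample_mask <- function(mask, field) {
  d <- grid_dims(field)
  pts <- grid_points(field) + matrix(field$vectors, ncol = 3)
  v <- interp_trilinear_index(mask$voxels + 0, world_to_index(mask, pts), 0)
  structure_mask(array(v >= 0.5, dim = d), field$spacing, field$origin,
                 label = mask$label)
}

#' Compose a rigid transform after a displacement field
#'
#' The result is the single pull-back field mapping reference point `p` to
#' the sampling position `rigid(p + u(p))`; warping with the composition is
#' equivalent to warping with the field and then with the rigid transform.
#'
#' @param rigid `dirqa_rigid`; @param field `dirqa_field` on the reference grid.
#' @return A `dirqa_field` on the same reference grid.
#' @export
compose <- function(rigid, field) {
  pts <- grid_points(field)
  mapped <- apply_rigid_points(rigid, pts + matrix(field$vectors, ncol = 3))
  deformation_field(array(mapped - pts, dim = dim(field$vectors)),
                    field$spacing, field$origin)
}

#' Map landmark points through a transform
#'
#' Rigid transforms map points exactly; displacement fields are interpolated
#' trilinearly at off-grid points and map `p` to `p + u(p)`.
#'
#' @param transform `dirqa_rigid` or `dirqa_field`.
#' @param points `dirqa_landmarks`.
#' @return A `dirqa_landmarks` with mapped coordinates.
#' @export
transform_points <- function(transform, points) {
  pts <- landmark_matrix(points)
  if (inherits(transform, "dirqa_rigid")) {
    out <- apply_rigid_points(transform, pts)
  } else if (inherits(transform, "dirqa_field")) {
    u <- sample_field(transform, pts)
    bad <- which(is.na(u[, 1]))
    if (length(bad))
      stop("domain error: landmark(s) outside field domain: ",
           paste(points$name[bad], collapse = ", "), call. = FALSE)
    out <- pts + u
  } else if (is.function(transform)) {
    out <- transform(pts)
  } else stop("unsupported transform", call. = FALSE)
  landmark_set(points$name, out[, 1], out[, 2], out[, 3])
}

#' Invert a displacement field by fixed-point iteration
#'
#' Finds `v` with `v(q) = -u(q + v(q))`, so that the returned field is the
#' (approximate) inverse mapping of `p -> p + u(p)`. Used to import
#' push-forward fields and to carry target-frame landmarks into the
#' reference frame.
#'
#' @param field `dirqa_field`.
#' @param iterations maximum fixed-point iterations (default 20).
#' @param tol stop when the mean update drops below this (mm, default 0.01).
#' @return A `dirqa_field` on the same grid.
#' @export
invert_field <- function(field, iterations = 20, tol = 0.01) {
  pts <- grid_points(field)
  d <- dim(field$vectors)
  v <- -matrix(field$vectors, ncol = 3)
  for (it in seq_len(iterations)) {
    u_at <- sample_field(field, pts + v, rule = "clamp")
    vnew <- -u_at
    delta <- mean(sqrt(rowSums((vnew - v)^2)))
    v <- vnew
    if (delta < tol) break
  }
  deformation_field(array(v, dim = d), field$spacing, field$origin)
}

#' Map points through the inverse of a displacement field
#'
#' Point-wise fixed-point inversion: for each landmark position `q` in the
#' target frame, finds the reference position `p` with `p + u(p) = q`. This
#' is how target-study marker centroids are carried into the reference frame
#' for the marker-distance index.
#'
#' @param field `dirqa_field` (pull-back convention on the reference grid).
#' @param points `dirqa_landmarks` in the target frame.
#' @param iterations,tol fixed-point iteration controls (20 iterations,
#'   0.01 mm).
#' @return A `dirqa_landmarks` in the reference frame.
#' @export
invert_map_points <- function(field, points, iterations = 20, tol = 0.01) {
  q <- landmark_matrix(points)
  v <- -sample_field(field, q, rule = "clamp")
  for (it in seq_len(iterations)) {
    vnew <- -sample_field(field, q + v, rule = "clamp")
    delta <- max(sqrt(rowSums((vnew - v)^2)))
    v <- vnew
    if (delta < tol) break
  }
  p <- q + v
  landmark_set(points$name, p[, 1], p[, 2], p[, 3])
}

# separable gaussian smoothing ----------------------------------------------

gauss_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  k <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# correlate along the first dimension with replicate padding
smooth_axis1 <- function(arr, kernel) {
  if (length(kernel) == 1L) return(arr)
  d <- dim(arr)
  r <- (length(kernel) - 1L) / 2L
  idx_pad <- c(rep(1L, r), seq_len(d[1]), rep(d[1], r))
  m <- matrix(arr, nrow = d[1])
  mp <- m[idx_pad, , drop = FALSE]
  out <- matrix(0, d[1], ncol(m))
  for (t in seq_along(kernel))
    out <- out + kernel[t] * mp[t:(t + d[1] - 1L), , drop = FALSE]
  array(out, dim = d)
}

# Gaussian smoothing of a 3D array; sigma given in mm per axis.
smooth_gaussian <- function(arr, sigma_mm, spacing) {
  sigma_mm <- rep(sigma_mm, length.out = 3)
  sv <- sigma_mm / spacing
  if (sv[1] > 0) arr <- smooth_axis1(arr, gauss_kernel(sv[1]))
  if (sv[2] > 0) {
    arr <- aperm(arr, c(2, 1, 3))
    arr <- smooth_axis1(arr, gauss_kernel(sv[2]))
    arr <- aperm(arr, c(2, 1, 3))
  }
  if (sv[3] > 0) {
    arr <- aperm(arr, c(3, 2, 1))
    arr <- smooth_axis1(arr, gauss_kernel(sv[3]))
    arr <- aperm(arr, c(3, 2, 1))
  }
  arr
}

# central-difference gradient of a volume array, per mm
gradient3 <- function(arr, spacing) {
  d <- dim(arr)
  g <- vector("list", 3)
  for (a in 1:3) {
    hi <- arr; lo <- arr
    n <- d[a]
    if (n > 1) {
      idx_hi <- c(2:n, n); idx_lo <- c(1, 1:(n - 1))
      if (a == 1) { hi <- arr[idx_hi, , , drop = FALSE]; lo <- arr[idx_lo, , , drop = FALSE] }
      if (a == 2) { hi <- arr[, idx_hi, , drop = FALSE]; lo <- arr[, idx_lo, , drop = FALSE] }
      if (a == 3) { hi <- arr[, , idx_hi, drop = FALSE]; lo <- arr[, , idx_lo, drop = FALSE] }
      g[[a]] <- array((hi - lo) / (2 * spacing[a]), dim = d)
    } else g[[a]] <- array(0, dim = d)
  }
  g
}

# downsample a volume by an integer factor per axis (with pre-smoothing)
downsample_volume <- function(volume, factor) {
  factor <- pmin(rep(as.integer(factor), length.out = 3), grid_dims(volume))
  if (all(factor == 1L)) return(volume)
  arr <- smooth_gaussian(volume$voxels, 0.5 * factor * volume$spacing,
                         volume$spacing)
  d <- dim(arr)
  idx <- lapply(1:3, function(a) seq(1L, d[a], by = factor[a]))
  image_volume(arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
               volume$spacing * factor, volume$origin)
}
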
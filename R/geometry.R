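#' @keywords internal
"_PACKAGE"

# World coordinates are in mm; voxel indices are 0-based in the geometry
# model (1-based only inside R array subscripts); a point is a voxel center;
# axis order is (x in-plane, y in-plane, z slice).

#' CT-like image volume
#'
#' A 3D scalar grid of Hounsfield units with anisotropic physical spacing.
#' World coordinates are in mm, the position of the center of voxel
#' `(0,0,0)` is `origin`, and the center of 0-based voxel `(i,j,k)` is
#' `origin + c(i,j,k) * spacing`.
#'
#' @param voxels 3D numeric array of HU values (all finite).
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin numeric length-3, world position of the first voxel center.
#' @return An object of class `dirqa_volume`.
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  if (anyNA(voxels) || any(!is.finite(voxels)))
    stop("all voxel values must be finite", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "dirqa_volume")
}

#' Binary structure mask on a volume grid
#'
#' @param voxels 3D logical array.
#' @param spacing,origin grid geometry as in [image_volume()].
#' @param label structure name.
#' @return An object of class `dirqa_mask`.
#' @export
structure_mask <- function(voxels, spacing, origin = c(0, 0, 0),
                           label = "structure") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("mask `voxels` must be a 3D array", call. = FALSE)
  storage.mode(voxels) <- "logical"
  if (anyNA(voxels)) stop("mask may not contain NA", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 label = as.character(label)[1]),
            class = "dirqa_mask")
}

#' Dense displacement field on a reference grid
#'
#' Stores one 3-component displacement (mm) per voxel of a reference grid,
#' in the pull-back convention: the warped image at reference voxel center
#' `p` samples the target image at `p + displacement(p)`.
#'
#' @param vectors 4D numeric array `[nx, ny, nz, 3]` of displacements in mm.
#' @param spacing,origin geometry of the reference grid.
#' @return An object of class `dirqa_field`.
#' @export
deformation_field <- function(vectors, spacing, origin = c(0, 0, 0)) {
  if (!is.array(vectors) || length(dim(vectors)) != 4L || dim(vectors)[4] != 3L)
    stop("`vectors` must be a 4D array with 3 components", call. = FALSE)
  if (anyNA(vectors) || any(!is.finite(vectors)))
    stop("all displacement components must be finite", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)", call. = FALSE)
  structure(list(vectors = vectors, spacing = spacing, origin = origin),
            class = "dirqa_field")
}

#' Rigid (rotation + translation) transform
#'
#' Maps a world point `p` to `rotation %*% (p - center) + center + translation`.
#'
#' @param rotation 3x3 rotation matrix (orthonormal, determinant +1).
#' @param translation length-3 translation in mm.
#' @param center rotation center in mm.
#' @return An object of class `dirqa_rigid`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation); center <- as.numeric(center)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("`rotation` must be orthonormal with determinant +1", call. = FALSE)
  if (length(translation) != 3L || length(center) != 3L)
    stop("`translation` and `center` must have length 3", call. = FALSE)
  structure(list(rotation = rotation, translation = translation,
                 center = center),
            class = "dirqa_rigid")
}

#' Named landmark set
#'
#' @param name character vector of unique marker names.
#' @param x,y,z world coordinates in mm.
#' @return A data frame of class `dirqa_landmarks`.
#' @export
landmark_set <- function(name, x, y, z) {
  name <- as.character(name)
  if (anyDuplicated(name)) stop("landmark names must be unique", call. = FALSE)
  pts <- cbind(as.numeric(x), as.numeric(y), as.numeric(z))
  if (any(!is.finite(pts))) stop("landmark points must be finite", call. = FALSE)
  out <- data.frame(name = name, x = pts[, 1], y = pts[, 2], z = pts[, 3],
                    stringsAsFactors = FALSE)
  class(out) <- c("dirqa_landmarks", "data.frame")
  out
}

landmark_matrix <- function(lm) {
  m <- cbind(lm$x, lm$y, lm$z)
  rownames(m) <- lm$name
  m
}

#' @export
print.dirqa_volume <- function(x, ...) {
  cat("<dirqa_volume> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm, HU range [", signif(min(x$voxels), 4), ", ",
      signif(max(x$voxels), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.dirqa_mask <- function(x, ...) {
  cat("<dirqa_mask> '", x$label, "': ", sum(x$voxels), " of ",
      length(x$voxels), " voxels, spacing ",
      paste(signif(x$spacing, 4), collapse = "/"), " mm\n", sep = "")
  invisible(x)
}

#' @export
print.dirqa_field <- function(x, ...) {
  mag <- sqrt(x$vectors[, , , 1]^2 + x$vectors[, , , 2]^2 + x$vectors[, , , 3]^2)
  cat("<dirqa_field> ", paste(dim(x$vectors)[1:3], collapse = " x "),
      " grid, |u| mean ", signif(mean(mag), 4), " / max ",
      signif(max(mag), 4), " mm\n", sep = "")
  invisible(x)
}

#' @export
print.dirqa_rigid <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat("<dirqa_rigid> rotation ", signif(ang, 4), " deg, translation (",
      paste(signif(x$translation, 4), collapse = ", "), ") mm\n", sep = "")
  invisible(x)
}

# geometry helpers ----------------------------------------------------------

grid_dims <- function(obj) {
  d <- dim(if (is.null(obj$voxels)) obj$vectors else obj$voxels)
  d[1:3]
}

same_grid <- function(a, b, tol = 1e-6) {
  all(grid_dims(a) == grid_dims(b)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

stop_grid_mismatch <- function(what) {
  stop("geometry error: ", what, " must share the same grid ",
       "(dimensions, spacing, origin)", call. = FALSE)
}

#' World coordinates of the grid axes
#' @noRd
axis_coords <- function(obj) {
  d <- grid_dims(obj)
  lapply(1:3, function(a) obj$origin[a] + (seq_len(d[a]) - 1) * obj$spacing[a])
}

# N x 3 matrix of the world coordinates of every voxel center, in array order
grid_points <- function(obj) {
  d <- grid_dims(obj)
  ax <- axis_coords(obj)
  cbind(rep(ax[[1]], times = d[2] * d[3]),
        rep(rep(ax[[2]], each = d[1]), times = d[3]),
        rep(ax[[3]], each = d[1] * d[2]))
}

# world -> continuous 0-based index
world_to_index <- function(obj, pts) {
  sweep(sweep(pts, 2, obj$origin, "-"), 2, obj$spacing, "/")
}

index_to_world <- function(obj, idx) {
  sweep(sweep(idx, 2, obj$spacing, "*"), 2, obj$origin, "+")
}

# mask voxel centers as an N x 3 world-coordinate matrix
mask_points <- function(mask) {
  idx <- which(mask$voxels, arr.ind = TRUE) - 1
  index_to_world(mask, idx)
}

rotation_angle_deg <- function(R) {
  c_ <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, c_))) * 180 / pi
}

#' Rotation matrix about a coordinate axis
#' @param axis 1, 2 or 3 (x, y, z).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
axis_rotation <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  ca <- cos(a); sa <- sin(a)
  R <- diag(3)
  ij <- switch(axis, c(2, 3), c(1, 3), c(1, 2))
  R[ij[1], ij[1]] <- ca; R[ij[2], ij[2]] <- ca
  R[ij[1], ij[2]] <- -sa; R[ij[2], ij[1]] <- sa
  R
}

# minimal rotation carrying direction u onto direction v (Rodrigues)
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  ax <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(ax^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite directions: rotate 180 degrees about any perpendicular axis
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- p - sum(p * u) * u
    ax <- ax / sqrt(sum(ax^2))
    K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
    return(diag(3) + 2 * K %*% K)
  }
  ax <- ax / s
  K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]), c(-ax[2], ax[1], 0))
  ang <- atan2(s, c_)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

apply_rigid_points <- function(rigid, pts) {
  pts <- matrix(pts, ncol = 3)
  ctr <- sweep(pts, 2, rigid$center, "-")
  out <- ctr %*% t(rigid$rotation)
  sweep(out, 2, rigid$center + rigid$translation, "+")
}

rigid_inverse <- function(rigid) {
  Rt <- t(rigid$rotation)
  rigid_transform(rotation = Rt,
                  translation = -as.vector(Rt %*% rigid$translation),
                  center = rigid$center)
}

is_identity_rigid <- function(rigid, tol = 1e-9) {
  max(abs(rigid$rotation - diag(3))) < tol &&
    max(abs(rigid$translation)) < tol
}
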
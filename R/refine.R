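# Box-based local-rigid refinement: axis-aligned boxes are placed where the
# deformable alignment is inadequate; inside each box a local rigid
# registration is run and the local rigids are blended into a correction of
# the deformation field, followed by a short deformable pass that holds
# locked boxes fixed.

#' Refinement box
#'
#' @param center box center in mm.
#' @param half_size per-axis half extents in mm (> 0).
#' @param locked if `TRUE` the refined displacements inside the box are held
#'   fixed during the closing deformable pass.
#' @return A list of class `refine_box`.
#' @export
refine_box <- function(center, half_size, locked = TRUE) {
  center <- as.numeric(center); half_size <- rep(as.numeric(half_size), length.out = 3)
  if (any(half_size <= 0))
    stop("parameter error: box extents must be positive", call. = FALSE)
  structure(list(center = center, half_size = half_size,
                 locked = isTRUE(locked)),
            class = "refine_box")
}

box_voxel_index <- function(box, geom) {
  pts <- grid_points(geom)
  which(abs(pts[, 1] - box$center[1]) <= box$half_size[1] &
        abs(pts[, 2] - box$center[2]) <= box$half_size[2] &
        abs(pts[, 3] - box$center[3]) <= box$half_size[3])
}

# local rigid registration restricted to a box, warm-started at the mean
# displacement of the current field inside the box. Returns the optimized
# rigid together with its metric value and the metric of the current field
# in the box, so the caller can reject a rigid that does not improve the
# local alignment (the automatic analogue of inspecting a box before
# locking it).
local_box_rigid <- function(reference, target, box, u_box, maxit = 200,
                            subsample = 4000) {
  sel <- box_voxel_index(box, reference)
  pts <- grid_points(reference)[sel, , drop = FALSE]
  ub <- u_box
  if (length(sel) > subsample) {
    keep <- as.integer(seq(1L, nrow(pts), length.out = subsample))
    pts <- pts[keep, , drop = FALSE]
    sel <- sel[keep]
    ub <- ub[keep, , drop = FALSE]
  }
  refv <- as.vector(reference$voxels)[sel]
  cost_current <- mean((sample_volume(target, pts + ub) - refv)^2)
  t0 <- colMeans(ub)
  cost <- function(par) {
    R <- axis_rotation(3, par[6]) %*% axis_rotation(2, par[5]) %*%
      axis_rotation(1, par[4])
    rt <- rigid_transform(R, par[1:3], center = box$center)
    mean((sample_volume(target, apply_rigid_points(rt, pts)) - refv)^2)
  }
  opt <- stats::optim(c(t0, 0, 0, 0), cost, method = "Nelder-Mead",
                      control = list(maxit = maxit,
                                     parscale = c(1, 1, 1, 0.5, 0.5, 0.5)))
  par <- opt$par
  R <- axis_rotation(3, par[6]) %*% axis_rotation(2, par[5]) %*%
    axis_rotation(1, par[4])
  list(rigid = rigid_transform(R, par[1:3], center = box$center),
       cost = opt$value, cost_current = cost_current)
}

#' Refine a deformation field with local rigid registrations
#'
#' For each box a local rigid registration (intensity mean-squares,
#' restricted to the box) is computed, warm-started at the field's mean
#' displacement inside the box. The local rigids are blended into a
#' correction field by normalized Gaussian distance weighting from the box
#' centers (sigma = half the box diagonal); the correction vanishes far from
#' every box. A short closing deformable pass then runs with displacements
#' inside locked boxes held fixed and updates confined to the blend region.
#'
#' @param reference,target `dirqa_volume`s (target in its native frame).
#' @param field current `dirqa_field` on the reference grid.
#' @param boxes list of [refine_box()]; empty list returns `field` unchanged.
#' @param params [dir_params()] for the closing pass (its `iterations` are
#'   capped at 8 per level and only the finest level is run).
#' @return A refined `dirqa_field` on the reference grid.
#' @export
reg_refine <- function(reference, target, field, boxes,
                       params = dir_params()) {
  if (!length(boxes)) return(field)
  if (!same_grid(field, reference)) stop_grid_mismatch("field and reference")
  d <- grid_dims(reference)
  pts <- grid_points(reference)
  lo <- reference$origin
  hi <- reference$origin + (d - 1) * reference$spacing
  for (b in boxes) {
    if (any(b$center + b$half_size < lo) || any(b$center - b$half_size > hi))
      stop("parameter error: box outside the image domain", call. = FALSE)
  }
  u <- matrix(field$vectors, ncol = 3)
  wsum <- numeric(nrow(pts))
  corr <- matrix(0, nrow(pts), 3)
  lock_idx <- integer(0)
  for (b in boxes) {
    sel <- box_voxel_index(b, reference)
    if (!length(sel)) next
    loc <- local_box_rigid(reference, target, b, u[sel, , drop = FALSE])
    # accept the local rigid only when it improves the box alignment,
    # as an operator would before locking the box
    if (loc$cost >= loc$cost_current) next
    delta <- apply_rigid_points(loc$rigid, pts) - pts - u
    sgm <- sqrt(sum(b$half_size^2)) / 2
    d2 <- (pts[, 1] - b$center[1])^2 + (pts[, 2] - b$center[2])^2 +
      (pts[, 3] - b$center[3])^2
    w <- exp(-d2 / (2 * sgm^2))
    w[d2 > (4 * sgm)^2] <- 0
    corr <- corr + w * delta
    wsum <- wsum + w
    if (b$locked) lock_idx <- c(lock_idx, sel)
  }
  influence <- pmin(wsum, 1)
  nz <- wsum > 0
  corr[nz, ] <- corr[nz, , drop = FALSE] / wsum[nz] * influence[nz]
  corr[!nz, ] <- 0
  u <- u + corr
  unew <- array(u, dim = c(d, 3))

  # closing deformable pass, frozen in locked boxes, confined to the blend
  # region so the field is never touched far from every box
  frozen <- logical(prod(d))
  frozen[unique(lock_idx)] <- TRUE
  upd_mask <- array(as.numeric(nz & !frozen), dim = d)
  res <- demons_level(reference, target, unew,
                      iters = min(8L, max(params$iterations)), params = params,
                      update_mask = upd_mask, frozen = which(frozen))
  # restore the input field outside the blend region: refinement is local
  # by contract, and the closing pass's field smoothing must not bleed past
  # the boxes' influence
  out <- res$u
  outside <- array(!nz, dim = d)
  for (cmp in 1:3) {
    tmp <- out[, , , cmp]
    orig <- field$vectors[, , , cmp]
    tmp[outside] <- orig[outside]
    out[, , , cmp] <- tmp
  }
  deformation_field(out, field$spacing, field$origin)
}

#' Default refinement boxes for the bending study
#'
#' Nine boxes equally spaced along the phantom length and covering the
#' entire phantom volume, as used by the bending-study refinement protocol.
#'
#' @param spec [bending_phantom_spec()] of the target (bent) phantom.
#' @param n number of boxes (default 9).
#' @return List of [refine_box()].
#' @export
default_bending_boxes <- function(spec, n = 9) {
  zc <- seq(0, spec$length_mm, length.out = n + 1)
  zc <- (zc[-1] + zc[-(n + 1)]) / 2
  ctrs <- bend_forward_points(cbind(0, 0, zc), spec)
  half_z <- spec$length_mm / (2 * n)
  lapply(seq_len(n), function(i)
    refine_box(ctrs[i, ], c(spec$radius_mm + 4, spec$radius_mm + 4,
                            half_z + 2)))
}

#' Default refinement boxes for the shrinking study
#'
#' Boxes positioned near the changing volume: a 5 x 5 grid over the
#' mass-facing anterior surface region (default 25 boxes), blocking fixed
#' structures and following the border of the protruding mass.
#'
#' @param spec [shrinking_phantom_spec()] of the reference phantom.
#' @param n_side boxes per side of the grid (default 5).
#' @return List of [refine_box()].
#' @export
default_shrinking_boxes <- function(spec, n_side = 5) {
  att <- mass_attachment(spec)
  reach <- (3 * spec$grid_fill_ml * 1000 / (2 * pi))^(1 / 3)
  xs <- seq(att[1] - reach, att[1] + reach, length.out = n_side)
  zs <- seq(att[3] - reach, att[3] + reach, length.out = n_side)
  half <- c(reach / n_side + 2, reach / 2 + 4, reach / n_side + 2)
  boxes <- list()
  for (z in zs) for (x in xs)
    boxes[[length(boxes) + 1L]] <- refine_box(c(x, att[2], z), half)
  boxes
}
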
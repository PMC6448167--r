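# Stand-in registration system under test: rigid pre-alignment, a
# multi-resolution demons-type free-form intensity-based DIR with Gaussian
# regularization of the update (fluid-like) and of the accumulated field
# (elastic-like), and dense-field error statistics. This is a
# self-contained, fully documented stand-in for the behaviour class of
# commercial free-form intensity-based engines; any external DIR can be
# scored instead by importing its displacement field ([read_field()]).

#' DIR parameters for the demons-type stand-in engine
#'
#' @param levels number of resolution levels (coarsest downsampled by
#'   `2^(levels-1)`).
#' @param iterations iterations per level, coarse to fine (recycled).
#' @param sigma_fluid Gaussian sigma (mm) smoothing each update field.
#' @param sigma_elastic Gaussian sigma (mm) smoothing the accumulated field;
#'   realizes the transformation-likelihood regularizer.
#' @param tol stop a level when the mean update magnitude (mm) drops below
#'   this.
#' @param step_max maximum update magnitude per iteration, in units of the
#'   smallest voxel size.
#' @param force_floor intensity differences (HU) below this magnitude exert
#'   no force, so image noise in homogeneous regions cannot accumulate into
#'   spurious displacements (default 30 HU, about three times the default
#'   study noise level).
#' @param seed seed for any stochastic initialization (the engine itself is
#'   deterministic; the seed is recorded for provenance).
#' @return A list of class `dir_params`.
#' @export
dir_params <- function(levels = 3, iterations = c(60, 40, 15),
                       sigma_fluid = 2.5, sigma_elastic = 2.5,
                       tol = 0.02, step_max = 0.8, force_floor = 30,
                       seed = 17) {
  if (levels < 1 || any(iterations < 1))
    stop("parameter error: levels and iterations must be >= 1", call. = FALSE)
  if (sigma_fluid < 0 || sigma_elastic < 0)
    stop("parameter error: sigmas must be >= 0", call. = FALSE)
  structure(list(levels = as.integer(levels),
                 iterations = rep_len(as.integer(iterations), levels),
                 sigma_fluid = sigma_fluid, sigma_elastic = sigma_elastic,
                 tol = tol, step_max = step_max, force_floor = force_floor,
                 seed = seed),
            class = "dir_params")
}

#' Rigid pre-alignment
#'
#' Landmark mode computes the closed-form least-squares rigid fit (orthogonal
#' Procrustes / Kabsch, no scaling) between corresponding point pairs.
#' Intensity mode minimizes the mean squared intensity difference over the
#' overlap by direct search on the 6 rigid parameters (3 translations in mm,
#' 3 rotations in degrees about the image center). The returned transform
#' maps reference coordinates into target coordinates.
#'
#' @param reference,target `dirqa_volume`s (intensity mode).
#' @param mode `"landmark"` or `"intensity"`.
#' @param anchors for landmark mode, a list of two `dirqa_landmarks`
#'   (reference points, corresponding target points); >= 2 shared names.
#' @param mask optional `dirqa_mask` restricting the intensity metric (e.g.
#'   a bone mask to optimize the matching of bony structures).
#' @param subsample target number of metric samples for intensity mode.
#' @param maxit direct-search iteration budget for intensity mode.
#' @return A `dirqa_rigid` with attributes `converged` and `rms` (landmark
#'   residual or final metric value).
#' @export
rigid_align <- function(reference = NULL, target = NULL,
                        mode = c("landmark", "intensity"), anchors = NULL,
                        mask = NULL, subsample = 30000, maxit = 250) {
  mode <- match.arg(mode)
  if (mode == "landmark") {
    if (is.null(anchors) || length(anchors) != 2L)
      stop("parameter error: landmark mode needs anchors = list(ref, tgt)",
           call. = FALSE)
    a <- anchors[[1]]; b <- anchors[[2]]
    shared <- intersect(a$name, b$name)
    if (length(shared) < 2L)
      stop("parameter error: need >= 2 corresponding landmark pairs",
           call. = FALSE)
    P <- landmark_matrix(a)[shared, , drop = FALSE]
    Q <- landmark_matrix(b)[shared, , drop = FALSE]
    cp <- colMeans(P); cq <- colMeans(Q)
    H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
    sv <- svd(H)
    if (length(shared) == 2L || sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)) {
      # (near-)collinear pairs leave a free twist about the common axis;
      # take the minimal rotation carrying one direction onto the other
      R <- rotation_between(sweep(P, 2, cp)[1, ], sweep(Q, 2, cq)[1, ])
    } else {
      D <- diag(c(1, 1, sign(det(tcrossprod(sv$v, sv$u)))))
      R <- sv$v %*% D %*% t(sv$u)
    }
    out <- rigid_transform(R, cq - cp, center = cp)
    res <- apply_rigid_points(out, P) - Q
    attr(out, "rms") <- sqrt(mean(rowSums(res^2)))
    attr(out, "converged") <- TRUE
    return(out)
  }
  if (is.null(reference) || is.null(target))
    stop("parameter error: intensity mode needs reference and target",
         call. = FALSE)
  pts <- grid_points(reference)
  wts <- if (!is.null(mask)) which(as.vector(mask$voxels)) else
    which(as.vector(reference$voxels) > min(reference$voxels) + 1e-9)
  if (!length(wts))
    stop("registration error: no overlapping content for intensity metric",
         call. = FALSE)
  if (length(wts) > subsample)
    wts <- wts[seq(1L, length(wts), length.out = subsample)]
  pts <- pts[wts, , drop = FALSE]
  refv <- as.vector(reference$voxels)[wts]
  ctr <- reference$origin + (grid_dims(reference) - 1) * reference$spacing / 2
  cost <- function(par) {
    R <- axis_rotation(3, par[6]) %*% axis_rotation(2, par[5]) %*%
      axis_rotation(1, par[4])
    rt <- rigid_transform(R, par[1:3], center = ctr)
    smp <- sample_volume(target, apply_rigid_points(rt, pts))
    mean((smp - refv)^2)
  }
  c0 <- cost(rep(0, 6))
  if (c0 < 1e-9) {
    out <- rigid_transform(center = ctr)
    attr(out, "rms") <- c0; attr(out, "converged") <- TRUE
    return(out)
  }
  opt <- stats::optim(rep(0, 6), cost, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-7,
                                     parscale = c(1, 1, 1, 0.5, 0.5, 0.5)))
  par <- opt$par
  R <- axis_rotation(3, par[6]) %*% axis_rotation(2, par[5]) %*%
    axis_rotation(1, par[4])
  out <- rigid_transform(R, par[1:3], center = ctr)
  attr(out, "rms") <- opt$value
  # hitting the iteration cap with no improvement over the identity start
  # just means the start was already (near) optimal
  converged <- opt$convergence == 0 || opt$value <= c0
  attr(out, "converged") <- converged
  if (!converged)
    warning("rigid_align: direct search stopped before convergence",
            call. = FALSE)
  out
}

# one demons level: reference/target volumes on the same grid, initial
# field `u` (4D array, mm); returns list(u, iterations, mean_update)
demons_level <- function(ref, tgt, u, iters, params, update_mask = NULL,
                         frozen = NULL) {
  d <- grid_dims(ref)
  pts <- grid_points(ref)
  sp <- ref$spacing
  grad <- gradient3(ref$voxels, sp)
  g2 <- grad[[1]]^2 + grad[[2]]^2 + grad[[3]]^2
  delta2 <- max(sp)^2
  cap <- params$step_max * min(sp)
  refv <- ref$voxels
  mean_upd <- Inf
  it <- 0L
  while (it < iters) {
    it <- it + 1L
    smp <- pts + matrix(u, ncol = 3)
    tw <- array(sample_volume(tgt, smp), dim = d)
    diffv <- tw - refv
    denom <- g2 + diffv^2 / delta2
    fac <- ifelse(denom > 1e-9 & abs(diffv) >= params$force_floor,
                  -diffv / denom, 0)
    upd <- list(fac * grad[[1]], fac * grad[[2]], fac * grad[[3]])
    mag <- sqrt(upd[[1]]^2 + upd[[2]]^2 + upd[[3]]^2)
    over <- mag > cap
    if (any(over)) {
      scl <- ifelse(over, cap / pmax(mag, 1e-12), 1)
      upd <- lapply(upd, function(a) a * scl)
    }
    if (params$sigma_fluid > 0)
      upd <- lapply(upd, smooth_gaussian, sigma_mm = params$sigma_fluid,
                    spacing = sp)
    if (!is.null(update_mask))
      upd <- lapply(upd, function(a) a * update_mask)
    for (cmp in 1:3) u[, , , cmp] <- u[, , , cmp] + upd[[cmp]]
    if (params$sigma_elastic > 0) {
      frz <- if (!is.null(frozen)) list(u[, , , 1][frozen], u[, , , 2][frozen],
                                        u[, , , 3][frozen])
      for (cmp in 1:3)
        u[, , , cmp] <- smooth_gaussian(u[, , , cmp], params$sigma_elastic, sp)
      if (!is.null(frozen))
        for (cmp in 1:3) u[, , , cmp][frozen] <- frz[[cmp]]
    }
    mean_upd <- mean(sqrt(upd[[1]]^2 + upd[[2]]^2 + upd[[3]]^2))
    if (mean_upd < params$tol) break
  }
  list(u = u, iterations = it, mean_update = mean_upd)
}

#' Free-form intensity-based DIR (demons-type stand-in)
#'
#' Multi-resolution demons scheme: at each level the intensity-difference
#' force (fixed-image-gradient demons, step-capped) is smoothed with
#' `sigma_fluid`, accumulated additively, and the accumulated field is
#' smoothed with `sigma_elastic`. The deformable stage starts from the rigid
#' fusion `init`: the target is first resampled through `init` onto the
#' reference grid and the returned field is the composition
#' `init(p + u(p))`. Deterministic for fixed parameters.
#'
#' @param reference,target `dirqa_volume`s.
#' @param init `dirqa_rigid` initial fusion (default identity).
#' @param params [dir_params()].
#' @return A `dirqa_field` on the reference grid, with attribute `log` (per
#'   level iterations and final mean update).
#' @export
deform_register <- function(reference, target, init = rigid_transform(),
                            params = dir_params()) {
  tgt0 <- if (is_identity_rigid(init)) target else
    resample(target, init, reference = reference)
  if (max(tgt0$voxels) <= min(tgt0$voxels) &&
      max(reference$voxels) > min(reference$voxels))
    stop("registration error: empty overlap after initial alignment",
         call. = FALSE)
  factors <- 2^((params$levels - 1):0)
  u <- NULL
  log <- list()
  for (li in seq_along(factors)) {
    f <- factors[li]
    ref_l <- downsample_volume(reference, f)
    tgt_l <- downsample_volume(tgt0, f)
    d <- grid_dims(ref_l)
    if (is.null(u)) {
      u <- array(0, dim = c(d, 3))
    } else {
      prev <- deformation_field(u, spacing = prev_spacing, origin = prev_origin)
      up <- sample_field(prev, grid_points(ref_l), rule = "clamp")
      u <- array(up, dim = c(d, 3))
    }
    res <- demons_level(ref_l, tgt_l, u, params$iterations[li], params)
    u <- res$u
    prev_spacing <- ref_l$spacing; prev_origin <- ref_l$origin
    log[[li]] <- c(level = f, iterations = res$iterations,
                   mean_update = res$mean_update)
  }
  field <- deformation_field(u, reference$spacing, reference$origin)
  out <- if (is_identity_rigid(init)) field else compose(init, field)
  attr(out, "log") <- log
  out
}

#' Displacement-field error statistics
#'
#' Euclidean per-voxel error between an estimated and a ground-truth field
#' over a region of interest.
#'
#' @param estimated,truth `dirqa_field`s on the same grid.
#' @param roi optional `dirqa_mask` on the same grid (default whole grid).
#' @return Named numeric `c(mean, max)` in mm.
#' @export
dvf_error <- function(estimated, truth, roi = NULL) {
  if (!same_grid(estimated, truth)) stop_grid_mismatch("fields")
  dv <- estimated$vectors - truth$vectors
  err <- sqrt(dv[, , , 1]^2 + dv[, , , 2]^2 + dv[, , , 3]^2)
  if (!is.null(roi)) {
    if (!same_grid(roi, estimated)) stop_grid_mismatch("roi and field")
    err <- err[roi$voxels]
  }
  c(mean = mean(err), max = max(err))
}
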
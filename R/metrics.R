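# Similarity-index suite: threshold segmentation with 26-connected
# labelling, centroid / centroid-distance (R, RM), Dice coefficient (DSC),
# symmetric Hausdorff distance on surface voxels (HD) and maximum (Feret)
# diameter for the diameter difference (DD).

# 26-connected components of a logical array; returns an integer label
# array (0 = background), labels in arbitrary order
label_components <- function(fg, dims) {
  n1 <- dims[1]; n2 <- dims[2]; n3 <- dims[3]
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  labels <- integer(length(fg))
  todo <- which(fg)
  lab <- 0L
  seen <- logical(length(fg))
  seen[!fg] <- TRUE
  for (seed in todo) {
    if (seen[seed]) next
    lab <- lab + 1L
    frontier <- seed
    seen[seed] <- TRUE
    labels[seed] <- lab
    while (length(frontier)) {
      i <- (frontier - 1L) %% n1
      j <- ((frontier - 1L) %/% n1) %% n2
      k <- (frontier - 1L) %/% (n1 * n2)
      nxt <- integer(0)
      for (o in seq_len(nrow(off))) {
        ii <- i + off[o, 1]; jj <- j + off[o, 2]; kk <- k + off[o, 3]
        ok <- ii >= 0L & ii < n1 & jj >= 0L & jj < n2 & kk >= 0L & kk < n3
        cand <- 1L + ii[ok] + n1 * (jj[ok] + n2 * kk[ok])
        cand <- cand[!seen[cand]]
        if (length(cand)) {
          seen[cand] <- TRUE
          labels[cand] <- lab
          nxt <- c(nxt, cand)
        }
      }
      frontier <- nxt
    }
  }
  array(labels, dim = dims)
}

#' Threshold segmentation with connected-component splitting
#'
#' Voxels at or above `fraction` times the global maximum form the
#' foreground, which is split into 26-connected components; components
#' smaller than `min_voxels` are discarded and the survivors are returned
#' ordered along the z axis (centroid z, ties by y then x) for stable
#' correspondence between studies.
#'
#' @param volume `dirqa_volume`.
#' @param fraction threshold as a fraction of the global maximum (0-1,
#'   default 0.5 as in the sphere segmentation protocol).
#' @param min_voxels minimum component size in voxels.
#' @param labels optional character vector of names for the components.
#' @return A named list of `dirqa_mask`, one per retained component.
#' @export
threshold_segment <- function(volume, fraction = 0.5, min_voxels = 10,
                              labels = NULL) {
  if (fraction <= 0 || fraction >= 1)
    stop("parameter error: fraction must be in (0, 1)", call. = FALSE)
  thr <- fraction * max(volume$voxels)
  fg <- volume$voxels >= thr
  if (!any(fg))
    stop("segmentation error: empty foreground at threshold", call. = FALSE)
  if (all(fg))
    stop("segmentation error: degenerate input (uniform volume, threshold ",
         "selects every voxel)", call. = FALSE)
  dims <- grid_dims(volume)
  lb <- label_components(fg, dims)
  sizes <- tabulate(lb)
  keep <- which(sizes >= min_voxels)
  if (!length(keep))
    stop("segmentation error: no component reaches min_voxels", call. = FALSE)
  masks <- lapply(keep, function(l)
    structure_mask(lb == l, volume$spacing, volume$origin))
  cent <- t(vapply(masks, centroid, numeric(3)))
  ord <- order(cent[, 3], cent[, 2], cent[, 1])
  masks <- masks[ord]
  if (is.null(labels)) labels <- paste0("component", seq_along(masks))
  labels <- rep_len(labels, length(masks))
  for (i in seq_along(masks)) masks[[i]]$label <- labels[i]
  names(masks) <- labels
  masks
}

#' Centroid of a structure mask
#'
#' Unweighted mean of the world coordinates of the member voxel centers.
#'
#' @param mask `dirqa_mask` (non-empty).
#' @return Length-3 numeric, mm.
#' @export
centroid <- function(mask) {
  if (!any(mask$voxels))
    stop("value error: empty mask", call. = FALSE)
  unname(colMeans(mask_points(mask)))
}

#' Distance between the centroids of two masks
#'
#' Yields the sphere centroid distance R when applied to corresponding
#' sphere masks and the marker distance RM when applied to marker masks.
#'
#' @param maskA,maskB non-empty `dirqa_mask`s.
#' @return Euclidean distance in mm.
#' @export
centroid_distance <- function(maskA, maskB) {
  sqrt(sum((centroid(maskA) - centroid(maskB))^2))
}

#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` on voxelized masks sharing a grid.
#'
#' @param maskA,maskB `dirqa_mask`s on identical grids, not both empty.
#' @return DSC in [0, 1].
#' @export
dice <- function(maskA, maskB) {
  if (!same_grid(maskA, maskB)) stop_grid_mismatch("dice masks")
  na <- sum(maskA$voxels); nb <- sum(maskB$voxels)
  if (na + nb == 0)
    stop("value error: both masks are empty", call. = FALSE)
  2 * sum(maskA$voxels & maskB$voxels) / (na + nb)
}

# surface voxels: members with at least one 6-face neighbour outside
surface_voxels <- function(mask) {
  v <- mask$voxels
  d <- dim(v)
  interior <- array(TRUE, dim = d)
  shift_and <- function(acc, axis, dir) {
    n <- d[axis]
    if (n == 1) return(acc & FALSE)
    pad <- function(x) x
    if (axis == 1) nb <- v[c(if (dir > 0) 2:n else 1, if (dir > 0) n else 1:(n - 1)), , , drop = FALSE]
    if (axis == 2) nb <- v[, c(if (dir > 0) 2:n else 1, if (dir > 0) n else 1:(n - 1)), , drop = FALSE]
    if (axis == 3) nb <- v[, , c(if (dir > 0) 2:n else 1, if (dir > 0) n else 1:(n - 1)), drop = FALSE]
    # boundary of the array counts as outside
    if (axis == 1) { if (dir > 0) nb[n, , ] <- FALSE else nb[1, , ] <- FALSE }
    if (axis == 2) { if (dir > 0) nb[, n, ] <- FALSE else nb[, 1, ] <- FALSE }
    if (axis == 3) { if (dir > 0) nb[, , n] <- FALSE else nb[, , 1] <- FALSE }
    acc & nb
  }
  for (axis in 1:3) for (dir in c(-1, 1))
    interior <- shift_and(interior, axis, dir)
  surf <- v & !interior
  idx <- which(surf, arr.ind = TRUE) - 1
  index_to_world(mask, idx)
}

# minimum distance from each row of `a` to the point set `b`, chunked so the
# pairwise distance block stays small
min_dist_to_set <- function(a, b, chunk = 1e7) {
  nb2 <- rowSums(b^2)
  out <- numeric(nrow(a))
  step <- max(1L, floor(chunk / nrow(b)))
  for (s in seq(1L, nrow(a), by = step)) {
    e <- min(s + step - 1L, nrow(a))
    blk <- a[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), nb2, "+") - 2 * tcrossprod(blk, b)
    mins <- d2[cbind(seq_len(nrow(d2)), max.col(-d2, ties.method = "first"))]
    out[s:e] <- sqrt(pmax(mins, 0))
  }
  out
}

#' Hausdorff distance between two masks
#'
#' Classical symmetric Hausdorff distance (maximum of the two directed
#' max-min distances) between the surface-voxel sets of the two masks, in
#' mm. A surface voxel is a member voxel with at least one face neighbour
#' outside the mask.
#'
#' @param maskA,maskB non-empty `dirqa_mask`s on identical grids.
#' @return HD in mm.
#' @export
hausdorff <- function(maskA, maskB) {
  if (!same_grid(maskA, maskB)) stop_grid_mismatch("hausdorff masks")
  if (!any(maskA$voxels) || !any(maskB$voxels))
    stop("value error: empty mask", call. = FALSE)
  sa <- surface_voxels(maskA)
  sb <- surface_voxels(maskB)
  max(max(min_dist_to_set(sa, sb)), max(min_dist_to_set(sb, sa)))
}

#' Maximum (Feret) diameter of a mask
#'
#' Maximum pairwise Euclidean distance between surface voxel centers. The
#' diameter difference index for a structure pair is
#' `DD = |max_diameter(A) - max_diameter(B)|`.
#'
#' @param mask non-empty `dirqa_mask`.
#' @return Diameter in mm (0 for a single-voxel mask).
#' @export
max_diameter <- function(mask) {
  if (!any(mask$voxels))
    stop("value error: empty mask", call. = FALSE)
  s <- surface_voxels(mask)
  if (nrow(s) == 1) return(0)
  # reduce to the extreme candidates before the O(n^2) pass
  if (nrow(s) > 4000) {
    ctr <- colMeans(s)
    r <- sqrt(rowSums(sweep(s, 2, ctr)^2))
    s <- s[r >= stats::quantile(r, 1 - 3000 / nrow(s)), , drop = FALSE]
  }
  n2 <- rowSums(s^2)
  best <- 0
  step <- max(1L, floor(2e6 / nrow(s)))
  for (st in seq(1L, nrow(s), by = step)) {
    e <- min(st + step - 1L, nrow(s))
    blk <- s[st:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), n2, "+") - 2 * tcrossprod(blk, s)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}
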
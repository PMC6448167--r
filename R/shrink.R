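# Digital analogue of the shrinking-mass phantom: a head/neck-like body of
# stacked ellipses with a mandible-like bone arc, eight small defect
# markers, and a water-filled mass protruding from the anterior surface
# whose volume is the study variable (0 / 25 / 50 ml).

#' Shrinking-phantom specification
#'
#' The body axis runs along z from 0 to `height_mm`; cross-sections are
#' ellipses whose semi-axes grow linearly from the neck values at z = 0 to
#' the head values at the top. The mass is attached to the anterior surface
#' (-y) at mid-height and grown voxel-by-voxel until its voxel volume first
#' reaches `fill_ml`. Body, bone and markers are identical across fill
#' levels; only the mass changes.
#'
#' @param fill_ml water fill volume of the mass in ml (study levels 0, 25,
#'   50).
#' @param height_mm body height (default 80, i.e. 40 slices at 2 mm).
#' @param neck_ab,head_ab in-plane semi-axes (mm) at the bottom and top.
#' @param bone_scale mandible arc scale relative to the body cross-section.
#' @param bone_radius_mm tube radius of the mandible-like arc.
#' @param bone_z_mm z-range of the mandible arc.
#' @param marker_xyz 8 x 3 matrix of defect-marker centers (d = 3 mm air
#'   pockets).
#' @param hu named HU per material: `background`, `soft`, `bone`, `water`,
#'   `gel`.
#' @param gel_mm thickness of the gel shell around the water fill.
#' @param spacing voxel size in mm (default 1 x 1 x 2).
#' @param roi_mm axial extent of the analysis region of interest centered on
#'   the mass (default 62 mm, i.e. 31 slices at 2 mm).
#' @param grid_fill_ml fill volume used to size the (fill-independent) grid.
#' @param margin_mm air margin.
#' @return A list of class `shrinking_phantom_spec`.
#' @export
shrinking_phantom_spec <- function(fill_ml = 0,
                                   height_mm = 80,
                                   neck_ab = c(55, 45), head_ab = c(65, 55),
                                   bone_scale = 0.6, bone_radius_mm = 5,
                                   bone_z_mm = c(30, 55),
                                   marker_xyz = NULL,
                                   hu = c(background = -1000, soft = 30,
                                          bone = 1000, water = 0, gel = 30),
                                   gel_mm = 2,
                                   spacing = c(1, 1, 2),
                                   roi_mm = 62,
                                   grid_fill_ml = 60,
                                   margin_mm = 6) {
  if (fill_ml < 0) stop("parameter error: fill volume must be >= 0", call. = FALSE)
  if (fill_ml > grid_fill_ml)
    stop("parameter error: fill exceeds the sized capacity (grid_fill_ml)",
         call. = FALSE)
  if (is.null(marker_xyz))
    marker_xyz <- cbind(x = c(30, -30, 25, -25, 35, -35, 15, -15),
                        y = c(10, 10, -20, -20, 0, 0, 25, 25),
                        z = c(20, 20, 30, 30, 50, 50, 60, 60))
  marker_xyz <- matrix(as.numeric(marker_xyz), ncol = 3)
  spec <- structure(list(fill_ml = fill_ml, height_mm = height_mm,
                         neck_ab = neck_ab, head_ab = head_ab,
                         bone_scale = bone_scale,
                         bone_radius_mm = bone_radius_mm,
                         bone_z_mm = bone_z_mm, marker_xyz = marker_xyz,
                         hu = hu, gel_mm = gel_mm,
                         spacing = as.numeric(spacing), roi_mm = roi_mm,
                         grid_fill_ml = grid_fill_ml, margin_mm = margin_mm),
                    class = "shrinking_phantom_spec")
  ab <- body_semiaxes(spec, marker_xyz[, 3])
  inside <- (marker_xyz[, 1] / ab[, 1])^2 + (marker_xyz[, 2] / ab[, 2])^2 < 0.95
  if (!all(inside) || any(marker_xyz[, 3] < 2) ||
      any(marker_xyz[, 3] > height_mm - 2))
    stop("parameter error: markers must lie inside the body", call. = FALSE)
  spec
}

body_semiaxes <- function(spec, z) {
  f <- pmin(pmax(z / spec$height_mm, 0), 1)
  cbind(spec$neck_ab[1] + f * (spec$head_ab[1] - spec$neck_ab[1]),
        spec$neck_ab[2] + f * (spec$head_ab[2] - spec$neck_ab[2]))
}

# anterior surface point at mid-height where the mass is attached
mass_attachment <- function(spec) {
  zc <- spec$height_mm / 2
  c(0, -body_semiaxes(spec, zc)[1, 2], zc)
}

in_body <- function(spec, pts) {
  ab <- body_semiaxes(spec, pts[, 3])
  (pts[, 1] / ab[, 1])^2 + (pts[, 2] / ab[, 2])^2 <= 1 &
    pts[, 3] >= 0 & pts[, 3] <= spec$height_mm
}

in_bone <- function(spec, pts) {
  zc <- (spec$bone_z_mm[1] + spec$bone_z_mm[2]) / 2
  ab <- spec$bone_scale * body_semiaxes(spec, zc)[1, ]
  # distance in the plane to the anterior elliptical arc (sampled polyline)
  tt <- seq(195, 345, by = 2.5) * pi / 180
  arc <- cbind(ab[1] * cos(tt), ab[2] * sin(tt))
  d2 <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(arc)))
    d2 <- pmin(d2, (pts[, 1] - arc[i, 1])^2 + (pts[, 2] - arc[i, 2])^2)
  d2 <= spec$bone_radius_mm^2 &
    pts[, 3] >= spec$bone_z_mm[1] & pts[, 3] <= spec$bone_z_mm[2]
}

shrinking_grid <- function(spec) {
  m <- spec$margin_mm
  reach <- (3 * spec$grid_fill_ml * 1000 / (2 * pi))^(1 / 3) + 4
  amax <- max(spec$neck_ab[1], spec$head_ab[1])
  bmax <- max(spec$neck_ab[2], spec$head_ab[2])
  lo <- c(-(amax + m), -(bmax + reach + m), -m)
  hi <- c(amax + m, bmax + m, spec$height_mm + m)
  n <- pmax(2L, as.integer(ceiling((hi - lo) / spec$spacing)) + 1L)
  image_volume(array(0, dim = n), spec$spacing, lo)
}

# grow the mass on the grid: exterior voxels sorted by distance to the
# attachment point, taken in order until the voxel volume first reaches the
# fill volume; returns the selection and the reached growth radius
grow_mass <- function(spec, grid) {
  fill_mm3 <- spec$fill_ml * 1000
  voxvol <- prod(grid$spacing)
  empty <- list(index = integer(0), radius = 0)
  if (fill_mm3 <= 0) return(empty)
  att <- mass_attachment(spec)
  pts <- grid_points(grid)
  d2 <- (pts[, 1] - att[1])^2 + (pts[, 2] - att[2])^2 + (pts[, 3] - att[3])^2
  reach <- (3 * spec$grid_fill_ml * 1000 / (2 * pi))^(1 / 3) + 4
  cand <- which(d2 <= reach^2)
  cand <- cand[!in_body(spec, pts[cand, , drop = FALSE])]
  k <- ceiling(fill_mm3 / voxvol)
  if (k > length(cand))
    stop("parameter error: fill volume exceeds geometric capacity", call. = FALSE)
  ord <- order(d2[cand])
  sel <- cand[ord[seq_len(k)]]
  list(index = sel, radius = sqrt(d2[sel[k]]))
}

#' Build the shrinking-mass phantom
#'
#' Renders the body + mandible + markers + mass volume with partial-volume
#' anti-aliasing at material boundaries, and returns the marker landmarks
#' and the structure masks (external contour, mandible, mass) restricted to
#' the analysis ROI. The body and mandible are identical across fill levels.
#'
#' @param spec [shrinking_phantom_spec()].
#' @return A list with `volume`, `landmarks` (8 markers), `external_mask`,
#'   `mandible_mask`, `mass_mask`, `roi_z` (ROI z-range in mm) and `spec`.
#' @export
build_shrinking_phantom <- function(spec) {
  grid <- shrinking_grid(spec)
  mass <- grow_mass(spec, grid)
  att <- mass_attachment(spec)
  hu <- as.numeric(spec$hu[c("background", "soft", "bone", "water", "gel")])
  r_in <- max(mass$radius - spec$gel_mm, 0)
  mat_fun <- function(pts) {
    m <- integer(nrow(pts))
    body <- in_body(spec, pts)
    m[body] <- 1L
    m[in_bone(spec, pts)] <- 2L
    if (mass$radius > 0) {
      d2 <- (pts[, 1] - att[1])^2 + (pts[, 2] - att[2])^2 +
        (pts[, 3] - att[3])^2
      in_mass <- !body & d2 <= mass$radius^2 & pts[, 3] >= 0 &
        pts[, 3] <= spec$height_mm
      m[in_mass] <- ifelse(d2[in_mass] <= r_in^2, 3L, 4L)
    }
    for (i in seq_len(nrow(spec$marker_xyz))) {
      g <- spec$marker_xyz[i, ]
      d2 <- (pts[, 1] - g[1])^2 + (pts[, 2] - g[2])^2 + (pts[, 3] - g[3])^2
      m[d2 <= 1.5^2] <- 0L  # air-pocket defects
    }
    m
  }
  vol <- render_phantom(grid, mat_fun, hu)

  d <- grid_dims(grid)
  pts <- grid_points(grid)
  roi_z <- att[3] + c(-0.5, 0.5) * spec$roi_mm
  in_roi <- pts[, 3] >= roi_z[1] & pts[, 3] <= roi_z[2]

  body <- in_body(spec, pts)
  mass_vox <- logical(nrow(pts)); mass_vox[mass$index] <- TRUE
  ext <- (body | mass_vox) & in_roi
  bone <- in_bone(spec, pts) & in_roi
  mk <- function(v, label)
    structure_mask(array(v, dim = d), grid$spacing, grid$origin, label)
  lms <- landmark_set(paste0("marker", seq_len(nrow(spec$marker_xyz))),
                      spec$marker_xyz[, 1], spec$marker_xyz[, 2],
                      spec$marker_xyz[, 3])
  list(volume = vol, landmarks = lms,
       external_mask = mk(ext, "external"),
       mandible_mask = mk(bone, "mandible"),
       mass_mask = mk(mass_vox & in_roi, "mass"),
       roi_z = roi_z, spec = spec)
}
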
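# Per-structure similarity reports and the self-registration sensitivity
# protocol. A report carries per-structure DSC/HD/DD/R, per-marker RM, and
# summary means/SDs, plus metadata identifying the registration condition.

#' Evaluate the similarity-index suite for a registration
#'
#' Computes, for each corresponding structure pair, the Dice coefficient
#' (DSC), Hausdorff distance (HD, mm), maximum-diameter difference (DD, mm)
#' and centroid distance (R, mm), and for each corresponding landmark the
#' marker distance RM (mm). Summary means and standard deviations (n-1
#' denominator) are attached per index.
#'
#' @param ref_masks,reg_masks named lists of `dirqa_mask`; names define the
#'   structure correspondence.
#' @param ref_landmarks,reg_landmarks optional `dirqa_landmarks`; names
#'   define the marker correspondence.
#' @param indices subset of `c("DSC", "HD", "DD", "R")` to compute per
#'   structure.
#' @param metadata named list recorded in the report (registration id,
#'   contrast level, refine flag, ...).
#' @return A list of class `dirqa_report` with elements `structures` (data
#'   frame), `markers` (data frame), `summary` (data frame) and `metadata`.
#' @export
evaluate_similarity <- function(ref_masks, reg_masks,
                                ref_landmarks = NULL, reg_landmarks = NULL,
                                indices = c("DSC", "HD", "DD", "R"),
                                metadata = list()) {
  indices <- match.arg(indices, several.ok = TRUE)
  if (length(ref_masks) || length(reg_masks)) {
    if (is.null(names(ref_masks)) || is.null(names(reg_masks)))
      stop("pairing error: mask lists must be named", call. = FALSE)
    miss <- c(setdiff(names(ref_masks), names(reg_masks)),
              setdiff(names(reg_masks), names(ref_masks)))
    if (length(miss))
      stop("pairing error: unmatched structures: ",
           paste(unique(miss), collapse = ", "), call. = FALSE)
  }
  snames <- names(ref_masks)
  rows <- lapply(snames, function(nm) {
    a <- ref_masks[[nm]]; b <- reg_masks[[nm]]
    out <- list(structure = nm)
    if ("DSC" %in% indices) out$DSC <- dice(a, b)
    if ("HD" %in% indices) out$HD <- hausdorff(a, b)
    if ("DD" %in% indices) out$DD <- abs(max_diameter(a) - max_diameter(b))
    if ("R" %in% indices) out$R <- centroid_distance(a, b)
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  structures <- if (length(rows)) do.call(rbind, rows) else
    data.frame(structure = character(0))

  markers <- data.frame(marker = character(0), RM = numeric(0))
  if (!is.null(ref_landmarks) && !is.null(reg_landmarks)) {
    miss <- c(setdiff(ref_landmarks$name, reg_landmarks$name),
              setdiff(reg_landmarks$name, ref_landmarks$name))
    if (length(miss))
      stop("pairing error: unmatched landmarks: ",
           paste(unique(miss), collapse = ", "), call. = FALSE)
    A <- landmark_matrix(ref_landmarks)
    B <- landmark_matrix(reg_landmarks)[rownames(A), , drop = FALSE]
    markers <- data.frame(marker = rownames(A),
                          RM = sqrt(rowSums((A - B)^2)),
                          row.names = NULL, stringsAsFactors = FALSE)
  }

  vals <- list()
  for (ix in intersect(c("DSC", "HD", "DD", "R"), names(structures)))
    vals[[ix]] <- structures[[ix]]
  if (nrow(markers)) vals$RM <- markers$RM
  summary <- do.call(rbind, lapply(names(vals), function(ix)
    data.frame(index = ix, mean = mean(vals[[ix]]),
               sd = if (length(vals[[ix]]) > 1) stats::sd(vals[[ix]]) else NA_real_,
               n = length(vals[[ix]]), stringsAsFactors = FALSE)))
  if (is.null(summary))
    summary <- data.frame(index = character(0), mean = numeric(0),
                          sd = numeric(0), n = integer(0))
  structure(list(structures = structures, markers = markers,
                 summary = summary, metadata = metadata),
            class = "dirqa_report")
}

#' @export
print.dirqa_report <- function(x, ...) {
  cat("<dirqa_report>",
      if (length(x$metadata)) paste0("[", paste(names(x$metadata),
        unlist(lapply(x$metadata, format)), sep = "=", collapse = ", "), "]"),
      "\n")
  if (nrow(x$structures)) { cat("structures:\n"); print(x$structures, digits = 4) }
  if (nrow(x$markers)) { cat("markers:\n"); print(x$markers, digits = 4) }
  cat("summary:\n"); print(x$summary, digits = 4)
  invisible(x)
}

#' Flatten a report to one row per structure/marker per index
#' @param report `dirqa_report`.
#' @return A data frame with columns item, index, value plus metadata.
#' @export
report_long <- function(report) {
  out <- list()
  st <- report$structures
  for (ix in intersect(c("DSC", "HD", "DD", "R"), names(st)))
    if (nrow(st)) out[[length(out) + 1L]] <-
      data.frame(item = st$structure, index = ix, value = st[[ix]],
                 stringsAsFactors = FALSE)
  if (nrow(report$markers))
    out[[length(out) + 1L]] <-
      data.frame(item = report$markers$marker, index = "RM",
                 value = report$markers$RM, stringsAsFactors = FALSE)
  long <- if (length(out)) do.call(rbind, out) else
    data.frame(item = character(0), index = character(0), value = numeric(0))
  for (nm in names(report$metadata)) long[[nm]] <- report$metadata[[nm]]
  long
}

#' Write a report as JSON and flat CSV
#' @param report `dirqa_report`; @param path base path (without extension).
#' @return Invisibly, the two file paths.
#' @export
write_report <- function(report, path) {
  js <- paste0(path, ".json"); cs <- paste0(path, ".csv")
  jsonlite::write_json(list(metadata = report$metadata,
                            structures = report$structures,
                            markers = report$markers,
                            summary = report$summary),
                       js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report_long(report), cs, row.names = FALSE)
  invisible(c(json = js, csv = cs))
}

#' Self-registration sensitivity of the similarity indices
#'
#' Runs the full pipeline -- rigid alignment, stand-in DIR, resampling,
#' segmentation, index evaluation -- with the target identical to the
#' reference, and reports the maximum observed value of each distance index
#' over structures/markers and the maximum of `1 - DSC`. These maxima are
#' the floor below which index differences between registrations are not
#' meaningful.
#'
#' @param phantom a phantom bundle from [build_bending_phantom()] or
#'   [build_shrinking_phantom()].
#' @param params [dir_params()] for the stand-in engine.
#' @param engine registration engine: a function
#'   `(reference, target, init, params) -> dirqa_field`; defaults to
#'   [deform_register()]. An identity stub can be substituted to isolate
#'   the metric chain.
#' @return A one-row data frame of class `sensitivity_table` with columns
#'   `RM`, `HD`, `DD`, `R` (mm; DD/R only for the bending phantom) and
#'   `one_minus_DSC`.
#' @export
sensitivity_protocol <- function(phantom, params = dir_params(),
                                 engine = deform_register) {
  kind <- if (!is.null(phantom$sphere_masks)) "bending" else "shrinking"
  ref <- phantom$volume
  stage <- "rigid alignment"
  out <- tryCatch({
    init <- rigid_align(ref, ref, mode = "intensity")
    stage <- "deformable registration"
    field <- engine(ref, ref, init = init, params = params)
    stage <- "resampling"
    reg <- resample(ref, field)
    stage <- "segmentation and scoring"
    rep <- score_registration(ref, reg, field, phantom, phantom,
                              metadata = list(registration = "self"))
    rep
  }, error = function(e)
    stop("pipeline failure at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE))
  st <- out$structures
  tab <- data.frame(
    phantom = kind,
    RM = if (nrow(out$markers)) max(out$markers$RM) else NA_real_,
    HD = max(st$HD),
    DD = if (!is.null(st$DD)) max(st$DD) else NA_real_,
    R = if (!is.null(st$R)) max(st$R) else NA_real_,
    one_minus_DSC = max(1 - st$DSC),
    stringsAsFactors = FALSE)
  class(tab) <- c("sensitivity_table", "data.frame")
  tab
}

# Segment the structures of a phantom kind in a reference and a registered
# volume, map the target-frame landmarks into the reference frame through
# the inverse of the estimated field, and evaluate the similarity suite.
# `tgt_phantom` supplies the landmarks of the target study (for
# self-registration it is the reference bundle itself).
score_registration <- function(ref_vol, reg_vol, field, ref_phantom,
                               tgt_phantom, metadata = list(),
                               inverse_field = NULL) {
  if (!is.null(ref_phantom$sphere_masks)) {
    ref_masks <- threshold_segment(ref_vol, 0.5, min_voxels = 40,
                                   labels = paste0("sphere", 1:3))
    reg_masks <- threshold_segment(reg_vol, 0.5, min_voxels = 40,
                                   labels = paste0("sphere", 1:3))
    if (length(ref_masks) != length(reg_masks))
      stop("pairing error: different sphere counts in reference (",
           length(ref_masks), ") and registered (", length(reg_masks),
           ") studies", call. = FALSE)
    indices <- c("DSC", "HD", "DD", "R")
  } else {
    ref_masks <- shrinking_structures(ref_vol, ref_phantom$roi_z)
    reg_masks <- shrinking_structures(reg_vol, ref_phantom$roi_z)
    indices <- c("DSC", "HD")
  }
  ref_lms <- ref_phantom$landmarks
  reg_lms <- if (is.null(inverse_field))
    invert_map_points(field, tgt_phantom$landmarks)
  else transform_points(inverse_field, tgt_phantom$landmarks)
  evaluate_similarity(ref_masks, reg_masks, ref_lms, reg_lms,
                      indices = indices, metadata = metadata)
}

# threshold segmentation of the shrinking phantom: external contour
# (everything above -400 HU) and mandible-like bone (>= 300 HU), both
# restricted to the analysis ROI
shrinking_structures <- function(volume, roi_z) {
  d <- grid_dims(volume)
  zc <- axis_coords(volume)[[3]]
  in_roi <- zc >= roi_z[1] & zc <= roi_z[2]
  roi <- array(rep(in_roi, each = d[1] * d[2]), dim = d)
  list(external = structure_mask(volume$voxels > -400 & roi, volume$spacing,
                                 volume$origin, "external"),
       mandible = structure_mask(volume$voxels >= 300 & roi, volume$spacing,
                                 volume$origin, "mandible"))
}
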
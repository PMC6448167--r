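# NIfTI-1 is the single on-disk format: scalar volumes in HU, masks as
# uint8, displacement fields as 4D (nx,ny,nz,3) vector volumes in mm using
# the pull-back convention on the reference grid. Landmark sets travel as
# plain CSV (name,x,y,z in mm).

nifti_from_geometry <- function(arr, spacing, origin) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(spacing, rep(1, nd - 3L))
  aff <- diag(4)
  diag(aff)[1:3] <- spacing
  aff[1:3, 4] <- origin
  RNifti::`qform<-`(img, structure(aff, code = 2L))
}

geometry_from_nifti <- function(img) {
  aff <- RNifti::xform(img)
  sp <- sqrt(colSums(aff[1:3, 1:3]^2))
  offdiag <- abs(aff[1:3, 1:3]) - diag(abs(diag(aff[1:3, 1:3])))
  if (max(abs(offdiag)) > 1e-4 * max(sp))
    stop("format error: only axis-aligned NIfTI orientations are supported",
         call. = FALSE)
  sgn <- sign(diag(aff[1:3, 1:3]))
  list(spacing = sp, origin = aff[1:3, 4], flip = sgn < 0)
}

#' Read / write an image volume as NIfTI-1
#'
#' Round-trips preserve voxel values bit-exactly (float64 storage) and
#' spacing/origin to float precision. Only 3D, axis-aligned volumes are
#' accepted.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume`: a `dirqa_volume`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("format error: expected a 3D scalar NIfTI volume, got ",
         length(d), "D", call. = FALSE)
  g <- geometry_from_nifti(img)
  if (any(g$flip))
    stop("format error: negative axis directions are not supported", call. = FALSE)
  image_volume(array(as.numeric(img), dim = d), g$spacing, g$origin)
}

#' @rdname read_volume
#' @param volume `dirqa_volume` to write.
#' @export
write_volume <- function(volume, path) {
  img <- nifti_from_geometry(volume$voxels, volume$spacing, volume$origin)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read / write a structure mask as uint8 NIfTI-1
#' @param path file path; @param label structure name for the read mask.
#' @return `read_mask`: a `dirqa_mask`.
#' @export
read_mask <- function(path, label = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("format error: expected a 3D mask NIfTI volume", call. = FALSE)
  g <- geometry_from_nifti(img)
  if (is.null(label))
    label <- sub("\\.nii(\\.gz)?$", "", basename(path))
  structure_mask(array(as.numeric(img) > 0.5, dim = d), g$spacing, g$origin,
                 label = label)
}

#' @rdname read_mask
#' @param mask `dirqa_mask` to write.
#' @export
write_mask <- function(mask, path) {
  img <- nifti_from_geometry(mask$voxels + 0L, mask$spacing, mask$origin)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read / write a displacement field as a 4D vector NIfTI
#'
#' The on-disk layout is a 4D volume with three components per voxel
#' (displacements in mm). Fields are stored in the pull-back convention on
#' the reference grid; a push-forward field can be converted on import with
#' `convention = "push-forward"`, which applies fixed-point inversion
#' ([invert_field()]).
#'
#' @param path file path.
#' @param convention `"pull-back"` (stored convention, default) or
#'   `"push-forward"` (inverted on import).
#' @return `read_field`: a `dirqa_field`.
#' @export
read_field <- function(path, convention = c("pull-back", "push-forward")) {
  convention <- match.arg(convention)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 5L && d[4] == 1L) {
    img <- array(as.numeric(img), dim = d[c(1:3, 5)]); d <- dim(img)
  }
  if (length(d) != 4L || d[4] != 3L)
    stop("format error: expected a 3-component vector NIfTI field", call. = FALSE)
  g <- geometry_from_nifti(img)
  f <- deformation_field(array(as.numeric(img), dim = d), g$spacing, g$origin)
  if (convention == "push-forward") f <- invert_field(f)
  f
}

#' @rdname read_field
#' @param field `dirqa_field` to write.
#' @export
write_field <- function(field, path) {
  img <- nifti_from_geometry(field$vectors, field$spacing, field$origin)
  img$descrip <- "dirqa DVF: pull-back displacements (mm) on reference grid"
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read / write landmark sets as CSV (name,x,y,z in mm)
#' @param path file path.
#' @return `read_landmarks`: a `dirqa_landmarks`.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("format error: landmark CSV must have columns name,x,y,z", call. = FALSE)
  landmark_set(df$name, df$x, df$y, df$z)
}

#' @rdname read_landmarks
#' @param landmarks `dirqa_landmarks` to write.
#' @export
write_landmarks <- function(landmarks, path) {
  utils::write.csv(as.data.frame(landmarks)[c("name", "x", "y", "z")],
                   path, row.names = FALSE)
  invisible(path)
}
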
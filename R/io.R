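# NIfTI readers/writers for volumes, label maps and displacement fields.
# Fields are stored as one NIfTI with the vector components in the last
# dimension (shape x D); 2D data are stored with a singleton third axis.

#' Read a NIfTI volume
#'
#' Files with an integer on-disk datatype load as a [label_volume]; all
#' others load as a [scalar_volume]. Voxel spacing is taken from the header.
#' A trailing singleton third dimension (2D data stored as 3D) is dropped.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [scalar_volume] or [label_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ",
                                           path, " (", conditionMessage(e),
                                           ")"))
  hdr <- RNifti::niftiHeader(img)
  dat <- as.array(img)
  spacing <- RNifti::pixdim(img)
  if (length(dim(dat)) == 3 && dim(dat)[3] == 1) {
    dat <- array(dat, dim(dat)[1:2])
    spacing <- spacing[1:2]
  }
  spacing <- rep_len(spacing, length(dim(dat)))
  int_types <- c(2L, 4L, 8L, 256L, 512L, 768L, 1024L, 1280L)
  if (hdr$datatype %in% int_types)
    label_volume(dat, spacing = spacing)
  else
    scalar_volume(dat, spacing = spacing)
}

#' Write a volume to NIfTI
#'
#' Label volumes are written with an integer datatype (so labels round-trip
#' bit-exactly and re-load as [label_volume]); scalar volumes as float64.
#'
#' @param vol a [scalar_volume] or [label_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  is_label <- inherits(vol, "label_volume")
  dat <- if (is_label) vol$labels else vol$data
  spacing <- vol$spacing
  if (length(dim(dat)) == 2) {
    dat <- array(dat, c(dim(dat), 1L))
    spacing <- c(spacing, 1)
  }
  attr(dat, "pixdim") <- spacing
  img <- RNifti::asNifti(dat, datatype = if (is_label) "int32" else "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a displacement field from NIfTI
#'
#' Expects the vector components in the last dimension (`shape x D`), the
#' layout written by [write_field].
#'
#' @param path path to the field NIfTI.
#' @return A [displacement_field].
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop("field file not found: ", path)
  img <- RNifti::readNifti(path)
  dat <- as.array(img)
  nd <- length(dim(dat))
  D <- dim(dat)[nd]
  shape <- dim(dat)[-nd]
  if (length(shape) == 3 && shape[3] == 1) shape <- shape[1:2]
  dat <- array(dat, c(prod(shape), D))
  vec <- array(t(dat), c(D, shape))
  spacing <- rep_len(RNifti::pixdim(img), length(shape))
  displacement_field(vec, spacing = spacing)
}

#' Write a displacement field to NIfTI
#'
#' Components go to the last dimension; 2D fields gain a singleton third
#' spatial axis.
#'
#' @param field a [displacement_field].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  v <- field$vectors
  D <- dim(v)[1]
  shape <- dim(v)[-1]
  dat <- t(matrix(v, D))           # voxels x components
  if (length(shape) == 2) shape <- c(shape, 1L)
  dat <- array(dat, c(shape, D))
  attr(dat, "pixdim") <- rep_len(field$spacing, 3)
  img <- RNifti::asNifti(dat, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}
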
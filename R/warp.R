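#' Warp an image by a dense displacement field
#'
#' Pull/backward warping: the output at voxel `p` samples the input at
#' `p + field(p)` (displacements in voxel units). Samples falling outside the
#' grid take the nearest border value. Linear interpolation is used for
#' intensity images; nearest-neighbour for label volumes.
#'
#' @param image a [scalar_volume] or [label_volume].
#' @param field a [displacement_field] on the same grid.
#' @param interpolation `"linear"` or `"nearest"`. Defaults to `"linear"` for
#'   scalar volumes and is forced to `"nearest"` for label volumes.
#' @return A warped object of the same class as `image`.
#' @examples
#' img <- scalar_volume(matrix(rnorm(64), 8, 8))
#' w <- warp_image(img, identity_field(c(8, 8)))
#' identical(w$data, img$data)
#' @export
warp_image <- function(image, field,
                       interpolation = c("linear", "nearest")) {
  is_label <- inherits(image, "label_volume")
  interpolation <- if (is_label && missing(interpolation)) "nearest"
                   else match.arg(interpolation)
  if (!inherits(field, "displacement_field"))
    stop("field must be a displacement_field")
  if (!all(is.finite(field$vectors)))
    stop("warp_image: field contains non-finite values")
  check_same_shape(image, field, "image", "field")
  arr <- vol_data(image)
  x <- add_channel(arr)
  out <- cpp_warp_fwd(x, field$vectors, interpolation == "nearest")
  out <- drop_channel(out, dim(arr))
  if (is_label)
    label_volume(round(out), label_names = image$label_names,
                 spacing = image$spacing)
  else
    scalar_volume(out, spacing = image$spacing)
}

#' Compose two displacement fields
#'
#' Returns a single field `u` with `u(p) = second(p) + first(p + second(p))`,
#' so that warping once by `u` approximates warping by `first` and then by
#' `second` (one resampling instead of two). The `first` field is sampled
#' with linear interpolation and border clamping.
#'
#' @param first,second [displacement_field]s on the same grid.
#' @return A [displacement_field].
#' @export
compose_fields <- function(first, second) {
  if (!inherits(first, "displacement_field") ||
      !inherits(second, "displacement_field"))
    stop("compose_fields expects two displacement_field objects")
  check_same_shape(first, second, "first field", "second field")
  sampled <- cpp_warp_fwd(first$vectors, second$vectors, FALSE)
  displacement_field(second$vectors + sampled, spacing = first$spacing)
}

#' All-zero displacement field
#'
#' @param shape integer vector of grid dimensions (length 2 or 3).
#' @param spacing per-axis voxel size in mm.
#' @return A [displacement_field] of zeros with dim `c(D, shape)`.
#' @export
identity_field <- function(shape, spacing = NULL) {
  shape <- as.integer(shape)
  if (!length(shape) %in% c(2L, 3L) || any(shape < 1))
    stop("identity_field: shape must be 2 or 3 positive integers")
  D <- length(shape)
  displacement_field(array(0, c(D, shape)), spacing = spacing)
}

#' Fraction of folding voxels of a displacement field
#'
#' Computes the fraction of (interior) voxels at which the Jacobian
#' determinant of the map `p -> p + u(p)` is non-positive, using forward
#' finite differences. Non-zero values indicate locally non-invertible
#' ("folded") deformations.
#'
#' @param field a [displacement_field].
#' @return Scalar in `[0, 1]`.
#' @export
neg_jacobian_fraction <- function(field) {
  cpp_neg_jacobian_frac(field$vectors)
}

# --- internal ---------------------------------------------------------------

add_channel <- function(arr, C = 1L) {
  d <- dim(arr)
  x <- array(as.double(arr), c(C, d))
  x
}

drop_channel <- function(x, shape) {
  array(as.double(x), shape)
}

# stack fixed and moving into a 2-channel network input, dim c(2, shape)
stack_channels <- function(a, b) {
  d <- dim(a)
  m <- rbind(as.vector(a), as.vector(b))
  array(m, c(2L, d))
}
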
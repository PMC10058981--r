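#' Grayscale image volume on a regular voxel grid
#'
#' A `scalar_volume` holds a real-valued 2D or 3D array together with its
#' per-axis voxel spacing in millimetres. It is the container for fixed,
#' moving and warped images.
#'
#' @param data numeric array with 2 or 3 dimensions; all values finite.
#' @param spacing numeric vector of per-axis voxel sizes in mm (recycled to
#'   the number of axes; default 1 mm isotropic).
#' @return An object of class `scalar_volume` with elements `data` and
#'   `spacing`.
#' @examples
#' v <- scalar_volume(matrix(runif(16), 4, 4))
#' dim(v$data)
#' @export
scalar_volume <- function(data, spacing = NULL) {
  data <- as_grid_array(data)
  if (!all(is.finite(data)))
    stop("scalar_volume: all voxel values must be finite")
  D <- length(dim(data))
  if (is.null(spacing)) spacing <- rep(1, D)
  spacing <- rep_len(as.numeric(spacing), D)
  structure(list(data = data, spacing = spacing), class = "scalar_volume")
}

#' Integer tissue segmentation aligned to a scalar volume
#'
#' Labels are non-negative integers on a voxel grid; 0 is reserved for
#' background. `label_names` maps label values to tissue names.
#'
#' @param labels integer-valued array (2D or 3D), non-negative.
#' @param label_names optional named character vector, names being label
#'   values (e.g. `c("1" = "CSF", "2" = "GM", "3" = "WM")`).
#' @param spacing per-axis voxel size in mm.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, label_names = NULL, spacing = NULL) {
  labels <- as_grid_array(labels)
  if (any(!is.finite(labels)) || any(labels < 0) ||
      any(labels != round(labels)))
    stop("label_volume: labels must be finite non-negative integers")
  storage.mode(labels) <- "integer"
  D <- length(dim(labels))
  if (is.null(spacing)) spacing <- rep(1, D)
  spacing <- rep_len(as.numeric(spacing), D)
  structure(list(labels = labels, label_names = label_names,
                 spacing = spacing), class = "label_volume")
}

#' Dense displacement field
#'
#' Per-voxel displacement vectors on the same grid as an image, stored
#' component-first: an array of dim `c(D, shape)` where `D` is the grid
#' dimensionality. Displacements are in voxel units and are *added* to the
#' sampling location (pull/backward warping).
#'
#' @param vectors numeric array of dim `c(D, shape)` with `length(shape) == D`.
#' @param spacing per-axis voxel size in mm (carried along, not used by
#'   warping, which operates in voxel units).
#' @return An object of class `displacement_field`.
#' @examples
#' u <- identity_field(c(8, 8))
#' dim(u$vectors)
#' @export
displacement_field <- function(vectors, spacing = NULL) {
  if (is.null(dim(vectors)))
    stop("displacement_field: vectors must be an array of dim c(D, shape)")
  d <- dim(vectors)
  D <- d[1]
  if (length(d) != D + 1)
    stop("displacement_field: component count (", D,
         ") must equal grid dimensionality (", length(d) - 1, ")")
  if (!all(is.finite(vectors)))
    stop("displacement_field: all displacement values must be finite")
  if (is.null(spacing)) spacing <- rep(1, D)
  spacing <- rep_len(as.numeric(spacing), D)
  structure(list(vectors = vectors, spacing = spacing),
            class = "displacement_field")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat("<scalar_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(x$spacing, collapse = " x "), " mm, range [",
      signif(min(x$data), 4), ", ", signif(max(x$data), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$labels), collapse = " x "),
      " voxels, labels {", paste(sort(unique(as.vector(x$labels))),
                                 collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$vectors)
  mag <- sqrt(colSums(matrix(x$vectors, d[1]) ^ 2))
  cat("<displacement_field> ", d[1], " components on ",
      paste(d[-1], collapse = " x "), " grid, mean |u| = ",
      signif(mean(mag), 4), " voxels\n", sep = "")
  invisible(x)
}

# --- internal helpers -------------------------------------------------------

as_grid_array <- function(x) {
  if (is.null(dim(x))) stop("expected an array with 2 or 3 dimensions")
  d <- dim(x)
  if (!length(d) %in% c(2L, 3L))
    stop("expected an array with 2 or 3 dimensions, got ", length(d))
  array(as.double(x), d)  # plain array, foreign attributes dropped
}

grid_shape <- function(x) {
  if (inherits(x, "scalar_volume")) return(dim(x$data))
  if (inherits(x, "label_volume")) return(dim(x$labels))
  if (inherits(x, "displacement_field")) return(dim(x$vectors)[-1])
  dim(x)
}

# raw spatial array from a volume-like object
vol_data <- function(x) {
  if (inherits(x, "scalar_volume")) return(x$data)
  if (inherits(x, "label_volume")) {
    d <- x$labels
    storage.mode(d) <- "double"
    return(d)
  }
  as_grid_array(x)
}

check_same_shape <- function(a, b, what_a = "first", what_b = "second") {
  sa <- grid_shape(a)
  sb <- grid_shape(b)
  if (length(sa) != length(sb) || !all(sa == sb))
    stop(what_a, " shape (", paste(sa, collapse = "x"), ") and ", what_b,
         " shape (", paste(sb, collapse = "x"), ") do not match")
  invisible(TRUE)
}

# mean per-voxel displacement magnitude, in voxels
field_magnitude <- function(field) {
  d <- dim(field$vectors)
  mean(sqrt(colSums(matrix(field$vectors, d[1]) ^ 2)))
}
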
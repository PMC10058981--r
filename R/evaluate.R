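#' Dice overlap of one label between two segmentations
#'
#' `2|X ∩ Y| / (|X| + |Y|)` on the binary masks of `label`. When both masks
#' are empty the overlap is defined as 1.
#'
#' @param X,Y [label_volume]s (or integer arrays) of the same shape.
#' @param label the label value to compare.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(X, Y, label) {
  check_same_shape(X, Y, "X", "Y")
  x <- vol_data(X) == label
  y <- vol_data(Y) == label
  denom <- sum(x) + sum(y)
  if (denom == 0) return(1)
  2 * sum(x & y) / denom
}

#' Global structural similarity index (SSIM)
#'
#' Computed from global image statistics:
#' `(2 mu_X mu_Y + c1)(2 cov_XY + c2) / ((mu_X^2 + mu_Y^2 + c1)(var_X +
#' var_Y + c2))` with `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2` for dynamic range
#' `L` (default `max(X) - min(X)`). A windowed mean-of-local-SSIM variant is
#' available via `windowed = TRUE`.
#'
#' @param X,Y [scalar_volume]s (or arrays) of the same shape.
#' @param dynamic_range the constant `L`; defaults to the range of `X`.
#' @param windowed compute the mean of local SSIM over `window`-sided cubes
#'   instead of the global statistic.
#' @param window odd window side for the windowed variant.
#' @return Scalar (1 for identical non-degenerate images).
#' @export
ssim <- function(X, Y, dynamic_range = NULL, windowed = FALSE, window = 7L) {
  check_same_shape(X, Y, "X", "Y")
  x <- vol_data(X)
  y <- vol_data(Y)
  L <- if (is.null(dynamic_range)) diff(range(x)) else dynamic_range
  c1 <- (0.01 * L) ^ 2
  c2 <- (0.03 * L) ^ 2
  if (!windowed) {
    n <- length(x)
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx) ^ 2); vy <- mean((y - my) ^ 2)
    cxy <- mean((x - mx) * (y - my))
    return(((2 * mx * my + c1) * (2 * cxy + c2)) /
             ((mx ^ 2 + my ^ 2 + c1) * (vx + vy + c2)))
  }
  n <- as.integer(window)
  cnt <- cpp_boxsum(array(1, dim(x)), n)
  mx <- cpp_boxsum(x, n) / cnt
  my <- cpp_boxsum(y, n) / cnt
  vx <- cpp_boxsum(x * x, n) / cnt - mx ^ 2
  vy <- cpp_boxsum(y * y, n) / cnt - my ^ 2
  cxy <- cpp_boxsum(x * y, n) / cnt - mx * my
  mean(((2 * mx * my + c1) * (2 * cxy + c2)) /
         ((mx ^ 2 + my ^ 2 + c1) * (vx + vy + c2)))
}

#' Pearson correlation of voxel intensities
#'
#' @param X,Y [scalar_volume]s (or arrays) of the same shape with non-zero
#'   variance.
#' @return Scalar in `[-1, 1]`.
#' @export
pcc <- function(X, Y) {
  check_same_shape(X, Y, "X", "Y")
  x <- as.vector(vol_data(X))
  y <- as.vector(vol_data(Y))
  if (sd(x) == 0) stop("pcc: first input has zero variance")
  if (sd(y) == 0) stop("pcc: second input has zero variance")
  cor(x, y)
}

#' Evaluate one registered pair
#'
#' Per-tissue Dice between the warped and fixed segmentations plus global
#' SSIM and PCC between the warped and fixed images.
#'
#' @param fixed,warped [scalar_volume]s.
#' @param fixed_seg,warped_seg [label_volume]s.
#' @param labels label values to evaluate (default: all non-zero labels of
#'   the fixed segmentation).
#' @return A list with `dice` (named per label), `ssim`, `pcc`.
#' @export
evaluate_pair <- function(fixed, warped, fixed_seg, warped_seg,
                          labels = NULL) {
  if (is.null(labels)) {
    labels <- sort(unique(as.vector(vol_data(fixed_seg))))
    labels <- labels[labels != 0]
  }
  dv <- vapply(labels, function(l) dice(fixed_seg, warped_seg, l), numeric(1))
  names(dv) <- label_display_names(fixed_seg, labels)
  list(dice = dv, ssim = ssim(fixed, warped), pcc = pcc(fixed, warped))
}

label_display_names <- function(seg, labels) {
  nm <- as.character(labels)
  if (inherits(seg, "label_volume") && !is.null(seg$label_names)) {
    hit <- nm %in% names(seg$label_names)
    nm[hit] <- seg$label_names[nm[hit]]
  }
  nm
}

#' Per-field Dice comparison of the two networks' deformations
#'
#' For a trained pair of networks, compares the Dice obtained by warping the
#' moving segmentation with (1) the registration field `phi1` alone, (2)
#' `phi1` followed by the augmented field `phi2` (two resamplings), and (3)
#' the composed field `phi1 o phi2` (one resampling). Labels are warped with
#' nearest-neighbour interpolation. A small gap between rows 2-3 and row 1
#' indicates the augmented network plays only a secondary role.
#'
#' @param F_seg,M_seg fixed and moving [label_volume]s.
#' @param phi1,phi2 [displacement_field]s.
#' @param labels label values (default: non-zero labels of `F_seg`).
#' @return Numeric matrix, 3 rows (`phi1`, `phi1_then_phi2`,
#'   `phi1_compose_phi2`) by one column per tissue.
#' @export
field_ablation_report <- function(F_seg, M_seg, phi1, phi2, labels = NULL) {
  if (is.null(labels)) {
    labels <- sort(unique(as.vector(vol_data(F_seg))))
    labels <- labels[labels != 0]
  }
  w1 <- warp_image(M_seg, phi1)
  w12 <- warp_image(w1, phi2)
  wc <- warp_image(M_seg, compose_fields(phi1, phi2))
  rows <- list(phi1 = w1, phi1_then_phi2 = w12, phi1_compose_phi2 = wc)
  out <- vapply(labels, function(l)
    vapply(rows, function(wseg) dice(F_seg, wseg, l), numeric(1)),
    numeric(3))
  out <- matrix(out, nrow = 3,
                dimnames = list(names(rows),
                                label_display_names(F_seg, labels)))
  out
}
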
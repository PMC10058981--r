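# Brain-like multi-tissue phantoms: nested smooth-boundary regions
# (randomly perturbed concentric shapes) with distinct tissue intensities,
# plus deformed pairs under random smooth displacement fields with known
# ground truth. Everything is deterministic per seed.

#' Phantom configuration
#'
#' @param dims grid dimensionality (2 or 3).
#' @param shape grid shape (defaults: 64^2 in 2D, 32^3 in 3D).
#' @param n_tissues number of nested tissues inside the background (default
#'   3, mimicking CSF/GM/WM).
#' @param intensity_means mean intensity per tissue (labels 1..n_tissues,
#'   outermost first).
#' @param background_mean background intensity.
#' @param noise_sd additive Gaussian intensity noise, in intensity units.
#' @param deform_amplitude maximum displacement magnitude of the generated
#'   pair-deformation, in voxels.
#' @param deform_smoothness Gaussian sigma (voxels) of the smoothing applied
#'   to the white-noise displacement components.
#' @param boundary_perturb amplitude of the random smooth perturbation of the
#'   tissue boundaries (fraction of the phantom radius).
#' @param seed RNG seed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(dims = 2L, shape = NULL, n_tissues = 3L,
                           intensity_means = c(0.25, 0.55, 0.85),
                           background_mean = 0.05, noise_sd = 0.03,
                           deform_amplitude = 12, deform_smoothness = 8,
                           boundary_perturb = 0.12, seed = 1L) {
  dims <- as.integer(dims)
  if (!dims %in% c(2L, 3L)) stop("phantom_config: dims must be 2 or 3")
  if (is.null(shape)) shape <- if (dims == 2L) c(64L, 64L) else c(32L, 32L, 32L)
  shape <- as.integer(shape)
  if (length(shape) != dims || any(shape < 8))
    stop("phantom_config: degenerate shape")
  if (length(intensity_means) != n_tissues)
    stop("phantom_config: need one intensity mean per tissue")
  if (any(duplicated(c(background_mean, intensity_means))))
    stop("phantom_config: intensity means must be distinct")
  if (deform_amplitude < 0) stop("phantom_config: deform_amplitude >= 0")
  if (deform_smoothness <= 0) stop("phantom_config: deform_smoothness > 0")
  structure(list(dims = dims, shape = shape, n_tissues = as.integer(n_tissues),
                 intensity_means = intensity_means,
                 background_mean = background_mean, noise_sd = noise_sd,
                 deform_amplitude = deform_amplitude,
                 deform_smoothness = deform_smoothness,
                 boundary_perturb = boundary_perturb,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# separable Gaussian smoothing of a spatial array, replicate borders
# (implemented as a truncated-renormalized kernel matrix per axis)
gauss_smooth <- function(arr, sigma) {
  d <- dim(arr)
  for (a in seq_along(d)) {
    S <- d[a]
    r <- ceiling(3 * sigma)
    idx <- outer(seq_len(S), seq_len(S), `-`)
    K <- exp(-idx ^ 2 / (2 * sigma ^ 2))
    K[abs(idx) > r] <- 0
    K <- K / rowSums(K)
    perm <- c(a, seq_along(d)[-a])
    m <- matrix(aperm(arr, perm), S)
    m <- K %*% m
    arr <- aperm(array(m, d[perm]), order(perm))
  }
  arr
}

#' Generate a multi-tissue phantom
#'
#' Builds nested smooth-boundary tissue regions by thresholding a randomly
#' perturbed radial coordinate, then assigns tissue-mean intensities plus
#' Gaussian noise and a light smoothing. Label 0 is background; labels
#' 1..n_tissues run from the outermost tissue inward (with 3 tissues:
#' 1 = CSF-like outer ring, 2 = GM-like ring, 3 = WM-like core).
#'
#' @param config a [phantom_config].
#' @return A list with `image` ([scalar_volume]) and `labels`
#'   ([label_volume]).
#' @export
make_phantom <- function(config = phantom_config()) {
  set.seed(config$seed)
  phantom_impl(config)
}

phantom_impl <- function(config) {
  shape <- config$shape
  D <- config$dims
  centre <- (shape - 1) / 2
  ax <- lapply(seq_len(D), function(a)
    (seq_len(shape[a]) - 1 - centre[a]) / (0.45 * shape[a]))
  rr2 <- array(0, shape)
  for (a in seq_len(D)) {
    g <- array(rep(ax[[a]], each = prod(shape[seq_len(a - 1)])), shape)
    rr2 <- rr2 + g ^ 2
  }
  rr <- sqrt(rr2)
  pert <- gauss_smooth(array(rnorm(prod(shape)), shape),
                       sigma = max(shape) / 8)
  pert <- pert / max(sd(pert), 1e-12) * config$boundary_perturb
  rho <- rr - pert
  nt <- config$n_tissues
  # thresholds from the core outward; rho < th[k] => at least tissue depth k
  th <- seq(0.35, 1, length.out = nt + 1)[-1]
  labels <- array(nt - findInterval(rho, th), shape)
  means <- c(config$background_mean, config$intensity_means)
  img <- array(means[labels + 1L], shape)
  img <- gauss_smooth(img, 0.6)
  img <- img + rnorm(prod(shape), sd = config$noise_sd)
  names_def <- if (nt == 3) c("1" = "CSF", "2" = "GM", "3" = "WM") else NULL
  list(image = scalar_volume(img),
       labels = label_volume(labels, label_names = names_def))
}

# random smooth displacement field: i.i.d. Gaussian noise per component,
# Gaussian-smoothed, scaled to the requested maximum magnitude
random_smooth_field <- function(shape, amplitude, sigma) {
  D <- length(shape)
  comps <- lapply(seq_len(D), function(a)
    gauss_smooth(array(rnorm(prod(shape)), shape), sigma))
  m <- do.call(rbind, lapply(comps, as.vector))
  mag <- sqrt(colSums(m ^ 2))
  mx <- max(mag)
  if (mx > 0 && amplitude >= 0) m <- m * (amplitude / mx)
  displacement_field(array(m, c(D, shape)))
}

#' Generate a deformed phantom pair with ground truth
#'
#' Creates a phantom (the fixed image F with segmentation), draws a random
#' smooth displacement field scaled to `deform_amplitude`, and produces the
#' moving image `M = warp(F, field)` (linear interpolation; labels warped
#' with nearest-neighbour). If the drawn field folds over more than 20% of
#' voxels (non-positive Jacobian) it is redrawn with a warning.
#'
#' @param config a [phantom_config].
#' @return A list with elements `fixed`, `fixed_seg`, `moving`,
#'   `moving_seg`, `field` (the ground-truth [displacement_field]).
#' @export
make_pair <- function(config = phantom_config()) {
  set.seed(config$seed)
  ph <- phantom_impl(config)
  fld <- random_smooth_field(config$shape, config$deform_amplitude,
                             config$deform_smoothness)
  tries <- 0
  while (neg_jacobian_fraction(fld) > 0.2 && tries < 10) {
    warning("generated field folds over >20% of voxels; redrawing")
    fld <- random_smooth_field(config$shape, config$deform_amplitude,
                               config$deform_smoothness)
    tries <- tries + 1
  }
  moving <- warp_image(ph$image, fld, "linear")
  moving_seg <- warp_image(ph$labels, fld)
  list(fixed = ph$image, fixed_seg = ph$labels,
       moving = moving, moving_seg = moving_seg, field = fld)
}

#' Generate a dataset of independent phantom pairs
#'
#' Each pair gets its own sub-seed derived from `seed`, so datasets are
#' reproducible and pairs are independent draws of both anatomy and
#' deformation.
#'
#' @param n number of pairs.
#' @param config a [phantom_config]; its `seed` is overridden per pair.
#' @param seed master seed.
#' @return A list of [make_pair] results.
#' @export
phantom_dataset <- function(n, config = phantom_config(), seed = 1L) {
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- as.integer((seed * 10007L + i * 131L) %% .Machine$integer.max)
    make_pair(cfg)
  })
}
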
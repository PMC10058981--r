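# Inference. Only the registration network G is evaluated here: the
# augmented network and the discriminator exist for training only, so a
# model whose params_A / params_D have been dropped registers identically.

#' Register a moving volume onto a fixed volume
#'
#' Runs only the trained registration network to predict the dense
#' displacement field `phi1`, then warps the moving image by it. Volumes
#' larger than the training patch are handled either by a single
#' full-volume forward pass (the network is fully convolutional; default) or
#' by a sliding window whose overlapping field estimates are blended with
#' linear (tent) weights. Sides not divisible by the network's downsampling
#' factor are padded symmetrically with edge replication and the result is
#' cropped back, with a warning.
#'
#' @param model a fitted [augreg] model.
#' @param fixed,moving [scalar_volume]s of equal shape, assumed linearly
#'   pre-aligned.
#' @param method `"full"` (one forward pass) or `"sliding"` (window +
#'   blending).
#' @param window,stride sliding-window geometry (defaults: the training
#'   patch size and stride).
#' @return A list with `field` (the predicted [displacement_field]) and
#'   `warped` (the moving image resampled by it, original intensity scale).
#' @export
register_pair <- function(model, fixed, moving,
                          method = c("full", "sliding"),
                          window = NULL, stride = NULL) {
  method <- match.arg(method)
  check_same_shape(fixed, moving, "fixed", "moving")
  params_G <- model$params_G   # the only parameter set inference touches
  cfg <- model$unet_cfg
  Fa <- vol_data(normalize01(fixed))
  Ma <- vol_data(normalize01(moving))
  shape <- dim(Fa)
  if (length(shape) != cfg$dims)
    stop("model was trained for ", cfg$dims, "D volumes, input is ",
         length(shape), "D")
  field <- if (method == "full") {
    predict_field_full(params_G, cfg, Fa, Ma)
  } else {
    if (is.null(window)) window <- model$config$patch_size
    if (is.null(stride)) stride <- model$config$stride
    predict_field_sliding(params_G, cfg, Fa, Ma, window, stride)
  }
  fld <- displacement_field(field, spacing = fixed$spacing)
  list(field = fld, warped = warp_image(moving, fld, "linear"))
}

#' @rdname register_pair
#' @param object a fitted [augreg] model.
#' @param ... passed on to [register_pair].
#' @export
predict.augreg <- function(object, fixed, moving, ...) {
  register_pair(object, fixed, moving, ...)
}

predict_field_full <- function(params_G, cfg, Fa, Ma) {
  shape <- dim(Fa)
  div <- 2 ^ length(cfg$enc_channels)
  target <- ceiling(shape / div) * div
  if (any(target != shape)) {
    warning("volume sides ", paste(shape, collapse = "x"),
            " padded symmetrically to ", paste(target, collapse = "x"),
            " (network downsampling factor ", div, "); result cropped back")
    lo <- (target - shape) %/% 2
    hi <- target - shape - lo
    Fa <- pad_replicate(Fa, lo, hi)
    Ma <- pad_replicate(Ma, lo, hi)
  }
  fld <- forward_field_plain(params_G, Fa, Ma, cfg)
  if (any(target != shape)) {
    lo <- (target - shape) %/% 2
    idx <- lapply(seq_along(shape), function(a) lo[a] + seq_len(shape[a]))
    fld <- do.call(`[`, c(list(fld), list(TRUE), idx, list(drop = FALSE)))
    fld <- array(fld, c(length(shape), shape))
  }
  fld
}

predict_field_sliding <- function(params_G, cfg, Fa, Ma, window, stride) {
  shape <- dim(Fa)
  D <- length(shape)
  window <- rep_len(as.integer(window), D)
  check_divisible(window, length(cfg$enc_channels))
  grid <- extract_patch_grid(shape, window, stride)
  accm <- matrix(0, D, prod(shape))
  wsum <- numeric(prod(shape))
  # tent profile per axis: maximal at the patch centre, > 0 everywhere
  tent <- lapply(seq_len(D), function(a) {
    i <- seq_len(window[a])
    1 - abs(2 * (i - 0.5) / window[a] - 1) + 1e-3
  })
  wpatch <- as.vector(Reduce(function(a, b) outer(a, b), tent))
  strides <- cumprod(c(1, shape[-D]))
  for (spec in grid) {
    fld <- matrix(forward_field_plain(params_G, crop_patch(Fa, spec),
                                      crop_patch(Ma, spec), cfg), D)
    coords <- lapply(seq_len(D),
                     function(a) spec$origin[a] + seq_len(window[a]) - 1L)
    lin <- as.integer(as.matrix(do.call(expand.grid, coords)) %*% strides) + 1L
    wsum[lin] <- wsum[lin] + wpatch
    accm[, lin] <- accm[, lin] + fld * rep(wpatch, each = D)
  }
  accm <- accm / rep(wsum, each = D)
  array(accm, c(D, shape))
}

pad_replicate <- function(arr, lo, hi) {
  d <- dim(arr)
  idx <- lapply(seq_along(d), function(a) {
    c(rep(1L, lo[a]), seq_len(d[a]), rep(d[a], hi[a]))
  })
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

#' Predict the augmented network's residual field (training-time quantity)
#'
#' Runs G to get `phi1`, warps the moving image, then runs the augmented
#' network A on (fixed, warped) to obtain `phi2`. Only meaningful for models
#' trained with `mode` `"vm_a"` or `"vm_a_gan"`. This is a diagnostic for
#' studying the regularizer; inference proper ([register_pair]) never
#' evaluates A.
#'
#' @inheritParams register_pair
#' @return A list with fields `phi1`, `phi2` ([displacement_field]s).
#' @export
augmented_field <- function(model, fixed, moving) {
  if (is.null(model$params_A))
    stop("model has no augmented network (mode '", model$config$mode, "')")
  Fa <- vol_data(normalize01(fixed))
  Ma <- vol_data(normalize01(moving))
  cfg <- model$unet_cfg
  phi1 <- predict_field_full(model$params_G, cfg, Fa, Ma)
  shape <- dim(Fa)
  W1 <- drop_channel(cpp_warp_fwd(array(Ma, c(1L, shape)), phi1, FALSE),
                     shape)
  phi2 <- predict_field_full(model$params_A, cfg, Fa, W1)
  list(phi1 = displacement_field(phi1, spacing = fixed$spacing),
       phi2 = displacement_field(phi2, spacing = fixed$spacing))
}
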
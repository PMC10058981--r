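#' Configuration of the registration / augmented U-Net
#'
#' Both deformation-predicting networks share this fully convolutional
#' encoder-decoder architecture: stride-2 convolutions downsample once per
#' encoder level, the decoder upsamples with nearest-neighbour interpolation
#' and concatenates skip connections, and a final small-initialized
#' convolution emits one displacement channel per spatial dimension. All
#' convolutions use 3^D kernels and LeakyReLU activations; there are no
#' normalization layers.
#'
#' @param dims grid dimensionality, 2 or 3.
#' @param enc_channels encoder channel counts, one per downsampling level.
#' @param dec_channels decoder channel counts (same length as the encoder).
#' @param head_channels channels of the full-resolution pre-field convolution.
#' @param input_channels number of input channels (2: fixed + moving).
#' @param leaky_slope LeakyReLU negative slope.
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(dims = 2L, enc_channels = c(8, 16, 16),
                        dec_channels = c(16, 16, 8), head_channels = 8L,
                        input_channels = 2L, leaky_slope = 0.2) {
  dims <- as.integer(dims)
  if (!dims %in% c(2L, 3L)) stop("unet_config: dims must be 2 or 3")
  if (length(dec_channels) != length(enc_channels))
    stop("unet_config: encoder and decoder must have the same depth")
  structure(list(dims = dims,
                 enc_channels = as.integer(enc_channels),
                 dec_channels = as.integer(dec_channels),
                 head_channels = as.integer(head_channels),
                 input_channels = as.integer(input_channels),
                 output_channels = dims,
                 leaky_slope = leaky_slope),
            class = "unet_config")
}

#' Configuration of the adversarial discriminator
#'
#' Exactly four stride-2 convolutional layers with LeakyReLU activations
#' after the first three; the last layer emits a single channel whose global
#' average passes through a sigmoid to give the probability that a patch is
#' a real (fixed-image) patch.
#'
#' @param dims grid dimensionality, 2 or 3.
#' @param channels channel counts of the 4 convolutional layers (last must
#'   be 1).
#' @param leaky_slope LeakyReLU negative slope.
#' @param input_channels 1 for single-image patches (default); 2 for a
#'   paired fixed+candidate variant.
#' @return An object of class `disc_config`.
#' @export
disc_config <- function(dims = 2L, channels = c(8, 16, 32, 1),
                        leaky_slope = 0.2, input_channels = 1L) {
  if (length(channels) != 4)
    stop("disc_config: exactly 4 convolutional layers are required")
  if (channels[4] != 1)
    stop("disc_config: the final layer must emit 1 channel")
  structure(list(dims = as.integer(dims), channels = as.integer(channels),
                 leaky_slope = leaky_slope,
                 input_channels = as.integer(input_channels)),
            class = "disc_config")
}

# He-style initialization for a conv layer: w dim c(Cout, Cin, 3, 3[, 3])
conv_init <- function(cout, cin, dims, sd = NULL) {
  k <- rep(3L, dims)
  fan_in <- cin * 3 ^ dims
  if (is.null(sd)) sd <- sqrt(2 / fan_in)
  list(w = array(rnorm(cout * cin * 3 ^ dims, sd = sd), c(cout, cin, k)),
       b = numeric(cout))
}

# Parameter list for a U-Net; the final field convolution is initialized
# near zero so the untrained network predicts a near-identity deformation.
unet_init <- function(cfg) {
  L <- length(cfg$enc_channels)
  p <- list()
  cin <- cfg$input_channels
  for (i in seq_len(L)) {
    p[[paste0("enc", i)]] <- conv_init(cfg$enc_channels[i], cin, cfg$dims)
    cin <- cfg$enc_channels[i]
  }
  # decoder: deepest conv, then one conv after each upsample+skip concat
  p[["dec1"]] <- conv_init(cfg$dec_channels[1], cfg$enc_channels[L], cfg$dims)
  cin <- cfg$dec_channels[1]
  if (L > 1) {
    for (i in 2:L) {
      skip <- cfg$enc_channels[L - i + 1]
      p[[paste0("dec", i)]] <- conv_init(cfg$dec_channels[i], cin + skip,
                                         cfg$dims)
      cin <- cfg$dec_channels[i]
    }
  }
  p[["head"]] <- conv_init(cfg$head_channels, cin + cfg$input_channels,
                           cfg$dims)
  p[["field"]] <- conv_init(cfg$output_channels, cfg$head_channels,
                            cfg$dims, sd = 1e-3)
  p
}

disc_init <- function(cfg) {
  p <- list()
  cin <- cfg$input_channels
  for (i in 1:4) {
    p[[paste0("conv", i)]] <- conv_init(cfg$channels[i], cin, cfg$dims)
    cin <- cfg$channels[i]
  }
  p
}

# wrap every parameter array of `params` as tape leaves
wrap_params <- function(tape, params, requires_grad = TRUE) {
  lapply(params, function(layer)
    list(w = tp_leaf(tape, layer$w, requires_grad),
         b = tp_leaf(tape, layer$b, requires_grad)))
}

# collect accumulated gradients in the same structure as the parameters
collect_grads <- function(leaves) {
  lapply(leaves, function(layer)
    list(w = if (is.null(layer$w$grad)) layer$w$value * 0 else layer$w$grad,
         b = if (is.null(layer$b$grad)) layer$b$value * 0 else layer$b$grad))
}

check_divisible <- function(shape, levels) {
  div <- 2 ^ levels
  if (any(shape %% div != 0))
    stop("patch side(s) ", paste(shape, collapse = "x"),
         " must be divisible by ", div,
         " (2^levels of the encoder)")
  invisible(div)
}

# U-Net forward on a tape. x: node with value dim c(input_channels, shape).
# Returns the displacement-field node, dim c(dims, shape).
unet_forward <- function(tape, leaves, x, cfg) {
  L <- length(cfg$enc_channels)
  shape <- dim(x$value)[-1]
  check_divisible(shape, L)
  sl <- cfg$leaky_slope
  enc <- vector("list", L)
  h <- x
  shapes <- vector("list", L)
  for (i in seq_len(L)) {
    lay <- leaves[[paste0("enc", i)]]
    h <- tp_lrelu(tape, tp_conv(tape, h, lay$w, lay$b, 2L), sl)
    enc[[i]] <- h
    shapes[[i]] <- dim(h$value)[-1]
  }
  lay <- leaves[["dec1"]]
  h <- tp_lrelu(tape, tp_conv(tape, h, lay$w, lay$b, 1L), sl)
  if (L > 1) {
    for (i in 2:L) {
      up_to <- shapes[[L - i + 1]]
      h <- tp_upsample(tape, h, up_to)
      h <- tp_concat(tape, h, enc[[L - i + 1]])
      lay <- leaves[[paste0("dec", i)]]
      h <- tp_lrelu(tape, tp_conv(tape, h, lay$w, lay$b, 1L), sl)
    }
  }
  h <- tp_upsample(tape, h, shape)
  h <- tp_concat(tape, h, x)
  lay <- leaves[["head"]]
  h <- tp_lrelu(tape, tp_conv(tape, h, lay$w, lay$b, 1L), sl)
  lay <- leaves[["field"]]
  tp_conv(tape, h, lay$w, lay$b, 1L)
}

disc_forward <- function(tape, leaves, x, cfg) {
  shape <- dim(x$value)[-1]
  if (any(shape < 16))
    stop("discriminator input sides (", paste(shape, collapse = "x"),
         ") must be >= 16 to pass 4 stride-2 convolutions")
  h <- x
  for (i in 1:4) {
    lay <- leaves[[paste0("conv", i)]]
    h <- tp_conv(tape, h, lay$w, lay$b, 2L)
    if (i < 4) h <- tp_lrelu(tape, h, cfg$leaky_slope)
  }
  tp_sigmoid(tape, tp_global_mean(tape, h))
}

#' Run the registration network on a pair of patches
#'
#' Predicts the dense displacement field `phi1 = G(F, M)` mapping the
#' fixed-image grid into the moving image. The patch sides must be divisible
#' by `2^levels` of the encoder.
#'
#' @param F_patch,M_patch [scalar_volume]s (or arrays) of the same shape.
#' @param params parameter list from the network initializer (internal
#'   structure; obtained from a fitted [augreg] model as `model$params_G`).
#' @param config a [unet_config].
#' @return A [displacement_field].
#' @export
registration_net <- function(F_patch, M_patch, params, config = unet_config()) {
  check_same_shape(F_patch, M_patch, "fixed patch", "moving patch")
  x <- stack_channels(vol_data(F_patch), vol_data(M_patch))
  tape <- tape_new()
  xf <- tp_leaf(tape, x, FALSE)
  leaves <- wrap_params(tape, params, FALSE)
  out <- unet_forward(tape, leaves, xf, config)
  displacement_field(out$value)
}

#' Run the augmented (successive) network
#'
#' Identical architecture to [registration_net] with its own parameters; its
#' inputs are the fixed image and the once-warped moving image, its output
#' the residual field `phi2`.
#'
#' @inheritParams registration_net
#' @param warped_patch the warped moving image `M(phi1)`.
#' @export
augmented_net <- function(F_patch, warped_patch, params,
                          config = unet_config()) {
  registration_net(F_patch, warped_patch, params, config)
}

#' Run the discriminator on an image patch
#'
#' @param patch a [scalar_volume] (or array); for the pair-input variant
#'   (`input_channels = 2`), a list of two patches.
#' @param params parameter list from the discriminator initializer.
#' @param config a [disc_config].
#' @return Probability in (0, 1) that the patch is a real (fixed-image) patch.
#' @export
discriminator <- function(patch, params, config = disc_config()) {
  if (config$input_channels == 2L) {
    if (!is.list(patch) || length(patch) != 2)
      stop("pair-input discriminator expects a list of two patches")
    x <- stack_channels(vol_data(patch[[1]]), vol_data(patch[[2]]))
  } else {
    arr <- vol_data(patch)
    x <- array(arr, c(1L, dim(arr)))
  }
  tape <- tape_new()
  xf <- tp_leaf(tape, x, FALSE)
  leaves <- wrap_params(tape, params, FALSE)
  disc_forward(tape, leaves, xf, config)$value
}
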
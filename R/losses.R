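#' Loss weights for the joint training objective
#'
#' `alpha` weights the similarity term and `lambda` the smoothness term of
#' the registration-network loss. `a_weights` gives one weight per term of
#' the augmented-network loss, in the order: sim(F, M(phi1)),
#' sim(F, M(phi1 o phi2)), sim(F, phi2(M(phi1))), mse(phi2), smooth(phi1),
#' smooth(phi2), smooth(phi1 o phi2). `cc_window` is the side of the local
#' cross-correlation window (odd, default 9).
#'
#' @param alpha,lambda non-negative reals, default 1.
#' @param a_weights non-negative numeric of length 7, default all 1.
#' @param cc_window odd integer >= 3.
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 1, lambda = 1, a_weights = rep(1, 7),
                         cc_window = 9L) {
  if (alpha < 0 || lambda < 0 || any(a_weights < 0))
    stop("loss_weights: all weights must be >= 0")
  if (length(a_weights) != 7)
    stop("loss_weights: a_weights must have length 7")
  cc_window <- as.integer(cc_window)
  if (cc_window < 3 || cc_window %% 2 == 0)
    stop("loss_weights: cc_window must be odd and >= 3")
  structure(list(alpha = alpha, lambda = lambda,
                 a_weights = as.numeric(a_weights), cc_window = cc_window),
            class = "loss_weights")
}

#' Ablation switches for the training objective
#'
#' @param use_augmented train the successive (augmented) network alongside
#'   the registration network.
#' @param use_gan train the adversarial discriminator and add the adversarial
#'   term to the registration loss.
#' @param use_mse keep the MSE-to-zero penalty on the augmented network's
#'   field (meaningful only when `use_augmented` is `TRUE`).
#' @param use_extra_sim keep the two extra similarity terms of the
#'   augmented-network loss (meaningful only when `use_augmented` is `TRUE`).
#' @return An object of class `ablation_flags`.
#' @export
ablation_flags <- function(use_augmented = FALSE, use_gan = FALSE,
                           use_mse = TRUE, use_extra_sim = TRUE) {
  structure(list(use_augmented = isTRUE(use_augmented),
                 use_gan = isTRUE(use_gan),
                 use_mse = isTRUE(use_mse),
                 use_extra_sim = isTRUE(use_extra_sim)),
            class = "ablation_flags")
}

CC_EPS <- 1e-5
PROB_EPS <- 1e-7

#' Local (windowed) normalized cross-correlation
#'
#' Mean over voxels of the squared local correlation between two images,
#' computed in the `n^D` cube centred at each voxel (truncated at the grid
#' border) with local means; a small epsilon (1e-5) stabilises the
#' denominator. Values are in `[0, 1]` up to the epsilon. The measure is
#' invariant under positive affine rescaling of either image's intensities.
#'
#' @param F,W [scalar_volume]s (or plain arrays) of the same shape.
#' @param n odd window side, >= 3 (default 9).
#' @return Scalar correlation value.
#' @export
local_cc <- function(F, W, n = 9L) {
  n <- as.integer(n)
  if (n < 3 || n %% 2 == 0) stop("local_cc: n must be odd and >= 3")
  check_same_shape(F, W, "F", "W")
  cpp_ncc(vol_data(F), vol_data(W), n, CC_EPS, FALSE)$value
}

#' Intensity similarity loss (negative local cross-correlation)
#'
#' @inheritParams local_cc
#' @return `-local_cc(F, W, n)`; approximately -1 at perfect alignment.
#' @export
sim_loss <- function(F, W, n = 9L) {
  -local_cc(F, W, n)
}

#' Displacement-field smoothness loss
#'
#' Mean over voxels of the squared Euclidean norm of the spatial gradient of
#' the field, using forward finite differences per component and axis (the
#' difference at the far boundary is taken as zero).
#'
#' @param field a [displacement_field].
#' @return Non-negative scalar; exactly 0 for constant fields.
#' @export
smoothness_loss <- function(field) {
  cpp_smooth_fwd(field$vectors)
}

#' MSE-to-zero regularizer on a displacement field
#'
#' Mean over voxels of the squared Euclidean norm of the displacement itself,
#' i.e. the mean squared error between the field and the zero field. This is
#' the penalty that pushes the augmented network's output field toward zero
#' so the first network absorbs the full deformation.
#'
#' @param field a [displacement_field].
#' @return Non-negative scalar; exactly 0 for the zero field; for a constant
#'   field with every component equal to `c` it equals `D * c^2`.
#' @export
mse_zero_loss <- function(field) {
  v <- field$vectors
  sum(v ^ 2) / prod(dim(v)[-1])
}

#' Adversarial loss of the generator (registration network)
#'
#' `-log(p)` for the discriminator's output probability on a warped patch,
#' minimised when the discriminator is fooled (p -> 1). Probabilities are
#' clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param p probability (or vector of probabilities, averaged).
#' @return Non-negative scalar.
#' @export
adversarial_g_loss <- function(p) {
  p <- pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)
  mean(-log(p))
}

#' Discriminator loss
#'
#' `-log(p_real) - log(1 - p_fake)` averaged over a batch: real patches come
#' from the fixed image, fake patches are warped moving-image patches.
#'
#' @param p_real,p_fake probabilities (vectors are averaged).
#' @return Non-negative scalar.
#' @export
discriminator_loss <- function(p_real, p_fake) {
  p_real <- pmin(pmax(p_real, PROB_EPS), 1 - PROB_EPS)
  p_fake <- pmin(pmax(p_fake, PROB_EPS), 1 - PROB_EPS)
  mean(-log(p_real)) + mean(-log(1 - p_fake))
}

#' Registration-network aggregate loss
#'
#' `L_G = L_adv + alpha * L_sim(F, M(phi1)) + lambda * L_smooth(phi1)`, the
#' adversarial term being 0 when the GAN is disabled.
#'
#' @param F,M fixed and moving [scalar_volume]s.
#' @param phi1 [displacement_field] predicted by the registration network.
#' @param p_fake discriminator output on the warped image (ignored unless
#'   `flags$use_gan`).
#' @param weights a [loss_weights].
#' @param flags an [ablation_flags].
#' @return Scalar loss.
#' @export
loss_G <- function(F, M, phi1, p_fake = NULL, weights = loss_weights(),
                   flags = ablation_flags()) {
  W1 <- warp_image(M, phi1, "linear")
  adv <- if (flags$use_gan) adversarial_g_loss(p_fake) else 0
  adv + weights$alpha * sim_loss(F, W1, weights$cc_window) +
    weights$lambda * smoothness_loss(phi1)
}

#' Augmented-network aggregate loss
#'
#' Weighted sum of seven terms: similarity of `F` with `M(phi1)`, with
#' `M(phi1 o phi2)` and with `phi2(M(phi1))`; the MSE-to-zero penalty on
#' `phi2` (dropped when `!flags$use_mse`); and smoothness of `phi1`, `phi2`
#' and `phi1 o phi2`. The second and third similarity terms are dropped when
#' `!flags$use_extra_sim`.
#'
#' @inheritParams loss_G
#' @param phi2 [displacement_field] predicted by the augmented network.
#' @return Scalar loss.
#' @export
loss_A <- function(F, M, phi1, phi2, weights = loss_weights(),
                   flags = ablation_flags(use_augmented = TRUE)) {
  n <- weights$cc_window
  aw <- weights$a_weights
  W1 <- warp_image(M, phi1, "linear")
  comp <- compose_fields(phi1, phi2)
  Wc <- warp_image(M, comp, "linear")
  W2 <- warp_image(W1, phi2, "linear")
  terms <- c(
    sim1    = sim_loss(F, W1, n),
    sim_c   = if (flags$use_extra_sim) sim_loss(F, Wc, n) else 0,
    sim2    = if (flags$use_extra_sim) sim_loss(F, W2, n) else 0,
    mse2    = if (flags$use_mse) mse_zero_loss(phi2) else 0,
    smooth1 = smoothness_loss(phi1),
    smooth2 = smoothness_loss(phi2),
    smoothc = smoothness_loss(comp))
  sum(aw * terms)
}

#' Total training loss
#'
#' `L_total = L_G + L_A` (the augmented part being 0 when the augmented
#' network is disabled).
#'
#' @inheritParams loss_A
#' @param p_fake discriminator output on the warped image.
#' @return Scalar loss.
#' @export
loss_total <- function(F, M, phi1, phi2 = NULL, p_fake = NULL,
                       weights = loss_weights(), flags = ablation_flags()) {
  lg <- loss_G(F, M, phi1, p_fake, weights, flags)
  la <- if (flags$use_augmented) loss_A(F, M, phi1, phi2, weights, flags)
        else 0
  lg + la
}
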
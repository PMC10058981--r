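test_that("local cross-correlation matches the nested-loop oracle", {
  set.seed(10)
  F3 <- array(rnorm(8 ^ 3), c(8, 8, 8))
  W3 <- array(rnorm(8 ^ 3), c(8, 8, 8))
  expect_lt(abs(local_cc(F3, W3, 5) - oracle_cc(F3, W3, 5)), 1e-5)
  F2 <- matrix(rnorm(16 ^ 2), 16, 16)
  W2 <- matrix(rnorm(16 ^ 2), 16, 16)
  expect_lt(abs(local_cc(F2, W2, 9) - oracle_cc(F2, W2, 9)), 1e-5)
})

test_that("local CC is ~1 on self and under positive affine rescaling", {
  set.seed(11)
  F <- matrix(rnorm(16 ^ 2), 16, 16)
  expect_equal(local_cc(F, F, 5), 1, tolerance = 1e-3)
  expect_equal(local_cc(F, 3.2 * F + 0.7, 5), 1, tolerance = 1e-4)
  expect_equal(local_cc(0.5 * F - 2, F, 9), 1, tolerance = 1e-4)
})

test_that("local CC validates the window and shapes", {
  F <- matrix(0, 8, 8)
  expect_error(local_cc(F, F, 4), "odd")
  expect_error(local_cc(F, matrix(0, 9, 9), 5), "do not match")
})

test_that("similarity loss is ~-1 at alignment and decreases toward it", {
  set.seed(12)
  # noise everywhere so no window has (near-)zero variance
  F <- gaussian_blob_image(c(32, 32)) + matrix(rnorm(32 ^ 2, sd = 0.05),
                                               32, 32)
  expect_equal(sim_loss(F, F, 9), -1, tolerance = 1e-3)
  shift_loss <- vapply(c(4, 2, 0), function(s) {
    f <- identity_field(c(32, 32))
    f$vectors[1, , ] <- s
    W <- warp_image(scalar_volume(F), f)$data
    sim_loss(F, W, 9)
  }, numeric(1))
  expect_true(all(diff(shift_loss) < 0))
})

test_that("similarity loss is finite on constant (zero-variance) images", {
  F <- matrix(1, 12, 12)
  v <- sim_loss(F, F, 5)
  expect_true(is.finite(v))
  v2 <- local_cc(F, matrix(rnorm(144), 12, 12), 5)
  expect_true(is.finite(v2))
})

test_that("smoothness loss: exact zeros, hand-computed slope, oracle", {
  expect_identical(smoothness_loss(identity_field(c(8, 8))), 0)
  cf <- identity_field(c(8, 8))
  cf$vectors[] <- 3.7
  expect_identical(smoothness_loss(cf), 0)
  # unit slope along axis 1 in component 1: (S-1) unit differences / S voxels
  f <- identity_field(c(5, 1))
  f$vectors[1, , 1] <- 0:4
  expect_equal(smoothness_loss(f), 4 / 5)
  set.seed(13)
  v <- array(rnorm(3 * 6 ^ 3), c(3, 6, 6, 6))
  expect_lt(abs(smoothness_loss(displacement_field(v)) - oracle_smooth(v)),
            1e-6)
})

test_that("MSE-to-zero loss: closed forms and degree-2 homogeneity", {
  expect_identical(mse_zero_loss(identity_field(c(6, 6))), 0)
  cf <- displacement_field(array(0.7, c(3, 5, 5, 5)))
  expect_equal(mse_zero_loss(cf), 3 * 0.7 ^ 2, tolerance = 1e-12)
  set.seed(14)
  u <- displacement_field(array(rnorm(2 * 49), c(2, 7, 7)))
  m1 <- mse_zero_loss(u)
  for (s in c(0.25, 0.5, 2)) {
    us <- displacement_field(s * u$vectors)
    expect_equal(mse_zero_loss(us), s ^ 2 * m1, tolerance = 1e-10)
  }
  us <- displacement_field(0.9 * u$vectors)
  expect_lt(mse_zero_loss(us), m1)
})

test_that("adversarial losses take their closed-form values", {
  expect_equal(adversarial_g_loss(1 - 1e-7), 0, tolerance = 1e-6)
  expect_equal(adversarial_g_loss(0.5), log(2), tolerance = 1e-12)
  expect_equal(adversarial_g_loss(exp(-1)), 1, tolerance = 1e-12)
  expect_true(is.finite(adversarial_g_loss(0)))  # clamped
  expect_equal(discriminator_loss(0.5, 0.5), 2 * log(2), tolerance = 1e-12)
  expect_equal(discriminator_loss(0.9, 0.1), -2 * log(0.9), tolerance = 1e-6)
  expect_lt(discriminator_loss(1 - 1e-7, 1e-7), 1e-5)
})

test_that("aggregate generator loss composes its terms as specified", {
  set.seed(15)
  F <- scalar_volume(gaussian_blob_image(c(32, 32)) +
                       matrix(rnorm(32 ^ 2, sd = 0.05), 32, 32))
  flags_off <- ablation_flags()
  w <- loss_weights(alpha = 2.5, lambda = 0)
  # perfectly aligned, constant field: alpha * (-1)
  cf <- identity_field(c(32, 32))
  lg <- loss_G(F, F, cf, weights = w, flags = flags_off)
  expect_equal(lg, -2.5, tolerance = 5e-3)
  # zero weights, gan off -> 0
  expect_equal(loss_G(F, F, cf, weights = loss_weights(alpha = 0, lambda = 0),
                      flags = flags_off), 0, tolerance = 1e-12)
  # equals independently computed component sum
  u <- smooth_test_field(c(32, 32), amplitude = 2)
  M <- warp_image(F, smooth_test_field(c(32, 32), amplitude = 3))
  expected <- sim_loss(F$data, warp_image(M, u)$data, 9) + smoothness_loss(u)
  expect_equal(loss_G(F, M, u, weights = loss_weights(), flags = flags_off),
               expected, tolerance = 1e-10)
})

test_that("aggregate augmented loss composes its seven terms", {
  set.seed(16)
  F <- scalar_volume(gaussian_blob_image(c(32, 32)) +
                       matrix(rnorm(32 ^ 2, sd = 0.05), 32, 32))
  z <- identity_field(c(32, 32))
  fl <- ablation_flags(use_augmented = TRUE)
  # phi1 = phi2 = 0, F == M: three sims of -1, all regularizers 0
  expect_equal(loss_A(F, F, z, z, flags = fl), -3, tolerance = 5e-3)
  # component-sum oracle on random smooth inputs
  u1 <- smooth_test_field(c(32, 32), amplitude = 2)
  u2 <- smooth_test_field(c(32, 32), amplitude = 1)
  M <- warp_image(F, smooth_test_field(c(32, 32), amplitude = 3))
  W1 <- warp_image(M, u1)
  comp <- compose_fields(u1, u2)
  expected <- sim_loss(F$data, W1$data, 9) +
    sim_loss(F$data, warp_image(M, comp)$data, 9) +
    sim_loss(F$data, warp_image(W1, u2)$data, 9) +
    mse_zero_loss(u2) + smoothness_loss(u1) + smoothness_loss(u2) +
    smoothness_loss(comp)
  expect_equal(loss_A(F, M, u1, u2, flags = fl), expected, tolerance = 1e-6)
  # ablation contracts: dropping terms removes exactly their contribution
  no_mse <- ablation_flags(use_augmented = TRUE, use_mse = FALSE)
  expect_equal(loss_A(F, M, u1, u2, flags = no_mse),
               loss_A(F, M, u1, u2, flags = fl) - mse_zero_loss(u2),
               tolerance = 1e-8)
  no_sim <- ablation_flags(use_augmented = TRUE, use_extra_sim = FALSE)
  expect_equal(loss_A(F, M, u1, u2, flags = no_sim),
               sim_loss(F$data, W1$data, 9) + mse_zero_loss(u2) +
                 smoothness_loss(u1) + smoothness_loss(u2) +
                 smoothness_loss(comp),
               tolerance = 1e-8)
})

test_that("total loss is the sum of the two aggregates", {
  set.seed(17)
  F <- scalar_volume(gaussian_blob_image(c(32, 32)))
  M <- warp_image(F, smooth_test_field(c(32, 32), amplitude = 3))
  u1 <- smooth_test_field(c(32, 32), amplitude = 2)
  u2 <- smooth_test_field(c(32, 32), amplitude = 1)
  fl <- ablation_flags(use_augmented = TRUE)
  expect_equal(loss_total(F, M, u1, u2, flags = fl),
               loss_G(F, M, u1, flags = fl) + loss_A(F, M, u1, u2, flags = fl),
               tolerance = 1e-10)
  # without the augmented network, L_total reduces to L_G
  expect_equal(loss_total(F, M, u1, flags = ablation_flags()),
               loss_G(F, M, u1, flags = ablation_flags()), tolerance = 1e-12)
})

test_that("loss_weights and ablation_flags validate their fields", {
  expect_error(loss_weights(alpha = -1), ">= 0")
  expect_error(loss_weights(cc_window = 8), "odd")
  expect_error(loss_weights(a_weights = rep(1, 6)), "length 7")
  fl <- ablation_flags(use_augmented = TRUE, use_gan = TRUE)
  expect_true(fl$use_augmented && fl$use_gan)
})
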
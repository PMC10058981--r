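small_cfg <- unet_config(dims = 2, enc_channels = c(4, 8),
                         dec_channels = c(8, 4), head_channels = 4)

test_that("registration network emits one displacement channel per axis", {
  set.seed(20)
  p <- augreg:::unet_init(small_cfg)
  F2 <- matrix(runif(64 ^ 2), 64, 64)
  M2 <- matrix(runif(64 ^ 2), 64, 64)
  fld <- registration_net(F2, M2, p, small_cfg)
  expect_equal(dim(fld$vectors), c(2, 64, 64))
  # 3D contract at the reference patch size
  cfg3 <- unet_config(dims = 3, enc_channels = c(4, 8),
                      dec_channels = c(8, 4), head_channels = 4)
  p3 <- augreg:::unet_init(cfg3)
  F3 <- array(runif(64 ^ 3), c(64, 64, 64))
  M3 <- array(runif(64 ^ 3), c(64, 64, 64))
  fld3 <- registration_net(F3, M3, p3, cfg3)
  expect_equal(dim(fld3$vectors), c(3, 64, 64, 64))
})

test_that("freshly initialized networks predict a near-identity deformation", {
  set.seed(21)
  p <- augreg:::unet_init(small_cfg)
  F2 <- matrix(runif(32 ^ 2), 32, 32)
  M2 <- matrix(runif(32 ^ 2), 32, 32)
  fld <- registration_net(F2, M2, p, small_cfg)
  expect_lt(mean(sqrt(colSums(matrix(fld$vectors, 2) ^ 2))), 0.5)
})

test_that("indivisible patch sides raise an error naming the divisor", {
  set.seed(22)
  p <- augreg:::unet_init(small_cfg)
  F2 <- matrix(runif(30 ^ 2), 30, 30)
  expect_error(registration_net(F2, F2, p, small_cfg), "divisible by 4")
})

test_that("registration and augmented networks hold disjoint parameters", {
  set.seed(23)
  pG <- augreg:::unet_init(small_cfg)
  pA <- augreg:::unet_init(small_cfg)
  F2 <- matrix(runif(32 ^ 2), 32, 32)
  M2 <- matrix(runif(32 ^ 2), 32, 32)
  before <- registration_net(F2, M2, pG, small_cfg)
  pA$field$w[] <- pA$field$w + 10  # perturb A heavily
  after <- registration_net(F2, M2, pG, small_cfg)
  expect_identical(before$vectors, after$vectors)
  # and the augmented net output does change
  w1 <- warp_image(scalar_volume(M2), before)
  a1 <- augmented_net(F2, w1$data, pA, small_cfg)
  expect_false(isTRUE(all.equal(a1$vectors, before$vectors)))
})

test_that("the networks are fully convolutional: doubling input doubles output", {
  set.seed(24)
  p <- augreg:::unet_init(small_cfg)
  f1 <- registration_net(matrix(runif(32 ^ 2), 32, 32),
                         matrix(runif(32 ^ 2), 32, 32), p, small_cfg)
  f2 <- registration_net(matrix(runif(64 ^ 2), 64, 64),
                         matrix(runif(64 ^ 2), 64, 64), p, small_cfg)
  expect_equal(dim(f1$vectors)[-1] * 2, dim(f2$vectors)[-1])
})

test_that("discriminator outputs a probability, deterministically", {
  set.seed(25)
  dc <- disc_config(dims = 2)
  pd <- augreg:::disc_init(dc)
  x <- matrix(runif(32 ^ 2), 32, 32)
  p1 <- discriminator(x, pd, dc)
  p2 <- discriminator(x, pd, dc)
  expect_identical(p1, p2)
  expect_gt(p1, 0)
  expect_lt(p1, 1)
  expect_error(discriminator(matrix(0, 8, 8), pd, dc), ">= 16")
  expect_error(disc_config(channels = c(8, 16, 32)), "4 convolutional")
})

test_that("a short adversarial run separates real from fake patches", {
  set.seed(26)
  dc <- disc_config(dims = 2)
  pd <- augreg:::disc_init(dc)
  ad <- augreg:::adam_new(pd)
  make_real <- function() gaussian_blob_image(c(16, 16)) +
    matrix(rnorm(256, sd = 0.02), 16, 16)
  make_fake <- function() matrix(runif(256), 16, 16)
  for (i in 1:200) {
    tape <- augreg:::tape_new()
    dl <- augreg:::wrap_params(tape, pd, TRUE)
    xr <- augreg:::tp_leaf(tape, array(make_real(), c(1, 16, 16)), FALSE)
    xf <- augreg:::tp_leaf(tape, array(make_fake(), c(1, 16, 16)), FALSE)
    pr <- augreg:::disc_forward(tape, dl, xr, dc)
    pf <- augreg:::disc_forward(tape, dl, xf, dc)
    loss <- augreg:::tp_wsum(tape, list(augreg:::tp_neglog(tape, pr),
                                        augreg:::tp_neglog1m(tape, pf)),
                             c(1, 1))
    augreg:::tp_backward(tape, loss)
    upd <- augreg:::adam_step(pd, augreg:::collect_grads(dl), ad, 1e-3)
    pd <- upd$params
    ad <- upd$state
  }
  p_real <- mean(replicate(20, discriminator(make_real(), pd, dc)))
  p_fake <- mean(replicate(20, discriminator(make_fake(), pd, dc)))
  expect_gt(p_real, p_fake)
})

test_that("a forward+backward pass yields finite gradients for all nets", {
  set.seed(27)
  cfg <- augreg_config(mode = "vm_a_gan", dims = 2, patch_size = 16,
                       enc_channels = c(4, 8), dec_channels = c(8, 4),
                       head_channels = 4, iterations = 2,
                       lr_G = 1e-3, lr_D = 1e-4)
  st <- train_state_init(cfg)
  rec <- train_step(st, matrix(runif(256), 16, 16),
                    matrix(runif(256), 16, 16))
  expect_true(all(is.finite(rec)))
  all_finite <- function(params) all(vapply(params, function(l)
    all(is.finite(l$w)) && all(is.finite(l$b)), logical(1)))
  expect_true(all_finite(st$params_G))
  expect_true(all_finite(st$params_A))
  expect_true(all_finite(st$params_D))
})

test_that("the joint loss sends gradient to both field producers", {
  set.seed(28)
  cfg <- augreg_config(mode = "vm_a", dims = 2, patch_size = 16,
                       enc_channels = c(4, 8), dec_channels = c(8, 4),
                       head_channels = 4, iterations = 2, lr_G = 1e-3)
  st <- train_state_init(cfg)
  pG0 <- st$params_G
  pA0 <- st$params_A
  train_step(st, matrix(runif(256), 16, 16), matrix(runif(256), 16, 16))
  moved <- function(p0, p1) max(vapply(names(p0), function(k)
    max(abs(p0[[k]]$w - p1[[k]]$w)), numeric(1)))
  expect_gt(moved(pG0, st$params_G), 0)
  expect_gt(moved(pA0, st$params_A), 0)
})
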
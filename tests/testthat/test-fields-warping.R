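test_that("warping by the zero field is the bit-exact identity", {
  set.seed(1)
  for (shape in list(c(7, 9), c(5, 6, 4))) {
    img <- scalar_volume(array(rnorm(prod(shape)), shape))
    w <- warp_image(img, identity_field(shape), "linear")
    expect_identical(w$data, img$data)
  }
})

test_that("constant displacement shifts with border clamping", {
  # row 0,1,2,3 shifted by +1 voxel -> 1,2,3,3
  img <- scalar_volume(matrix(as.numeric(0:3), 4, 1))
  f <- identity_field(c(4, 1))
  f$vectors[1, , ] <- 1
  expect_equal(as.vector(warp_image(img, f)$data), c(1, 2, 3, 3))
})

test_that("nearest-neighbour warping of labels under sub-half-voxel shift", {
  set.seed(2)
  lab <- label_volume(matrix(sample(0:3, 36, TRUE), 6, 6))
  f <- identity_field(c(6, 6))
  f$vectors[] <- 0.4
  w <- warp_image(lab, f)
  expect_identical(w$labels, lab$labels)
  expect_s3_class(w, "label_volume")
})

test_that("warp_image validates shapes and finite fields", {
  img <- scalar_volume(matrix(0, 4, 4))
  expect_error(warp_image(img, identity_field(c(5, 5))), "4x4.*5x5")
  f <- identity_field(c(4, 4))
  f$vectors[1, 1, 1] <- NaN
  expect_error(warp_image(img, f), "non-finite")
})

test_that("warp_image matches the brute-force interpolation oracle", {
  set.seed(3)
  arr <- array(rnorm(8 ^ 3), c(8, 8, 8))
  vec <- array(rnorm(3 * 8 ^ 3, sd = 1.5), c(3, 8, 8, 8))
  w <- warp_image(scalar_volume(arr), displacement_field(vec))$data
  expect_lt(max(abs(w - oracle_warp(arr, vec))), 1e-6)
  # 2D as well
  arr2 <- matrix(rnorm(64), 8, 8)
  vec2 <- array(rnorm(128, sd = 2), c(2, 8, 8))
  w2 <- warp_image(scalar_volume(arr2), displacement_field(vec2))$data
  expect_lt(max(abs(w2 - oracle_warp(arr2, vec2))), 1e-6)
})

test_that("composing with a zero field returns the other field bit-exactly", {
  set.seed(4)
  u <- displacement_field(array(rnorm(2 * 64, sd = 0.8), c(2, 8, 8)))
  z <- identity_field(c(8, 8))
  expect_identical(compose_fields(u, z)$vectors, u$vectors)
  expect_identical(compose_fields(z, u)$vectors, u$vectors)
  expect_identical(compose_fields(z, z)$vectors, z$vectors)
})

test_that("composition of constant fields adds the constants", {
  a <- identity_field(c(6, 6))
  a$vectors[1, , ] <- 0.3
  a$vectors[2, , ] <- -0.2
  b <- identity_field(c(6, 6))
  b$vectors[1, , ] <- 0.15
  b$vectors[2, , ] <- 0.25
  expect_equal(compose_fields(a, b)$vectors, a$vectors + b$vectors,
               tolerance = 1e-12)
})

test_that("single composed warp approximates two sequential warps", {
  set.seed(5)
  shape <- c(32, 32)
  img <- scalar_volume(gaussian_blob_image(shape))
  rng <- diff(range(img$data))
  for (k in 1:3) {
    u1 <- smooth_test_field(shape, amplitude = 2)
    u2 <- smooth_test_field(shape, amplitude = 2)
    once <- warp_image(img, compose_fields(u1, u2))
    twice <- warp_image(warp_image(img, u1), u2)
    expect_lt(max(abs(once$data - twice$data)), 0.05 * rng)
  }
})

test_that("identity_field produces a correctly shaped zero field", {
  f <- identity_field(c(4, 4))
  expect_equal(dim(f$vectors), c(2, 4, 4))
  expect_true(all(f$vectors == 0))
  expect_error(identity_field(c(4)), "2 or 3")
  expect_error(compose_fields(identity_field(c(4, 4)),
                              identity_field(c(5, 5))), "do not match")
})

test_that("displacement_field validates component count and finiteness", {
  expect_error(displacement_field(array(0, c(3, 8, 8))), "dimensionality")
  expect_error(displacement_field(array(NA_real_, c(2, 4, 4))), "finite")
})

test_that("folding detection flags a strongly compressive field", {
  f <- identity_field(c(16, 16))
  expect_equal(neg_jacobian_fraction(f), 0)
  g <- identity_field(c(16, 16))
  g$vectors[1, , ] <- -2 * (seq_len(16) - 1)  # x -> -x: det < 0 everywhere
  expect_gt(neg_jacobian_fraction(g), 0.9)
})
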
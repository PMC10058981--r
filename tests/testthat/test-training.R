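test_that("the patch grid covers the volume with clamped final origins", {
  g <- extract_patch_grid(c(64, 64), 64, 32)
  expect_length(g, 1)
  expect_equal(g[[1]]$origin, c(0L, 0L))
  g2 <- extract_patch_grid(c(96, 96), 64, 32)
  origins <- unique(vapply(g2, function(s) s$origin[1], integer(1)))
  expect_equal(sort(origins), c(0L, 32L))
  expect_length(g2, 4)
  # uneven: final origin clamps so the last patch touches the boundary
  g3 <- extract_patch_grid(c(100, 70), c(64, 64), c(32, 32))
  expect_true(all(vapply(g3, function(s)
    all(s$origin + s$size <= c(100, 70)), logical(1))))
  covered <- matrix(FALSE, 100, 70)
  for (s in g3)
    covered[s$origin[1] + 1:64, s$origin[2] + 1:64] <- TRUE
  expect_true(all(covered))
  expect_error(extract_patch_grid(c(32, 32), 64, 32), "exceeds")
})

test_that("vm-mode training reduces to the registration loss alone", {
  set.seed(30)
  cfg <- augreg_config(mode = "vm", dims = 2, patch_size = 16,
                       enc_channels = c(4, 8), dec_channels = c(8, 4),
                       head_channels = 4, iterations = 2, lr_G = 1e-3)
  st <- train_state_init(cfg)
  rec <- train_step(st, matrix(runif(256), 16, 16),
                    matrix(runif(256), 16, 16))
  expect_false(any(c("loss_D", "loss_A", "adv") %in% names(rec)))
  expect_equal(unname(rec["loss_total"]), unname(rec["loss_G"]))
  expect_null(st$params_A)
  expect_null(st$params_D)
})

test_that("200 steps on one fixed pair reduce the similarity loss", {
  set.seed(0)
  pair <- make_pair(phantom_config(shape = c(32, 32), seed = 0))
  cfg <- augreg_config(mode = "vm", dims = 2, patch_size = 32, stride = 16,
                       enc_channels = c(8, 16), dec_channels = c(16, 8),
                       iterations = 200, lr_G = 1e-3, seed = 0)
  model <- augreg(list(pair), config = cfg)
  expect_lt(tail(model$log$sim1, 1), model$log$sim1[1])
  expect_lt(median(tail(model$log$sim1, 20)), median(head(model$log$sim1, 20)))
})

test_that("training is reproducible from the master seed", {
  ds <- phantom_dataset(2, phantom_config(shape = c(32, 32)), seed = 3)
  cfg <- augreg_config(mode = "vm_a_gan", dims = 2, patch_size = 32,
                       stride = 16, enc_channels = c(4, 8),
                       dec_channels = c(8, 4), head_channels = 4,
                       iterations = 40, lr_G = 1e-3, lr_D = 1e-4, seed = 11)
  m1 <- augreg(ds, config = cfg)
  m2 <- augreg(ds, config = cfg)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params_G, m2$params_G)
})

test_that("non-finite losses abort naming the offending term", {
  set.seed(31)
  cfg <- augreg_config(mode = "vm", dims = 2, patch_size = 16,
                       enc_channels = c(4, 8), dec_channels = c(8, 4),
                       head_channels = 4, iterations = 2, lr_G = 1e-3)
  st <- train_state_init(cfg)
  st$params_G$field$w[] <- Inf
  expect_error(train_step(st, matrix(runif(256), 16, 16),
                          matrix(runif(256), 16, 16)), "term")
})

test_that("augreg() trains, logs every term and writes run artifacts", {
  ds <- phantom_dataset(2, phantom_config(shape = c(32, 32)), seed = 4)
  out <- file.path(tempdir(), "augreg-run")
  cfg <- augreg_config(mode = "vm_a", dims = 2, patch_size = 32, stride = 16,
                       enc_channels = c(4, 8), dec_channels = c(8, 4),
                       head_channels = 4, iterations = 30, lr_G = 1e-3,
                       seed = 5, output_dir = out)
  m <- augreg(ds, config = cfg)
  expect_s3_class(m, "augreg")
  expect_equal(nrow(m$log), 30)
  expect_true(all(c("sim1", "smooth1", "mse2", "smooth2", "smoothc",
                    "loss_A", "loss_total", "phi2_mag") %in% names(m$log)))
  expect_true(file.exists(file.path(out, "loss_log.csv")))
  expect_true(file.exists(file.path(out, "config.yaml")))
  reloaded <- load_config(file.path(out, "config.yaml"))
  expect_equal(reloaded$seed, 5L)
  expect_error(augreg(list(), config = cfg), "empty dataset")
  # summary and print carry the headline numbers
  s <- summary(m)
  expect_true(is.finite(s$sim_last10))
  expect_output(print(m), "vm_a")
})

test_that("random pairing of a plain volume list never pairs a volume with itself", {
  set.seed(32)
  vols <- lapply(1:5, function(i)
    scalar_volume(matrix(runif(64) + i, 8, 8)))
  for (k in 1:10) {
    pairs <- augreg:::epoch_pairs(vols)
    for (p in pairs)
      expect_false(identical(p$fixed$data, p$moving$data))
  }
})

test_that("inference runs only the registration network", {
  set.seed(33)
  ds <- phantom_dataset(2, phantom_config(), seed = 6)
  cfg <- augreg_config(mode = "vm_a_gan", dims = 2, patch_size = 64,
                       stride = 32, enc_channels = c(4, 8),
                       dec_channels = c(8, 4), head_channels = 4,
                       iterations = 30, lr_G = 1e-3, lr_D = 1e-4, seed = 7)
  model <- augreg(ds, config = cfg)
  p <- ds[[1]]
  full <- register_pair(model, p$fixed, p$moving)
  expect_equal(dim(full$field$vectors)[-1], dim(p$fixed$data))
  # dropping the other two networks must not change inference at all
  stripped <- model
  stripped$params_A <- NULL
  stripped$params_D <- NULL
  again <- register_pair(stripped, p$fixed, p$moving)
  expect_identical(full$field$vectors, again$field$vectors)
  expect_identical(full$warped$data, again$warped$data)
  # predict() delegates to register_pair()
  pr <- predict(model, p$fixed, p$moving)
  expect_identical(pr$field$vectors, full$field$vectors)
})

test_that("sliding-window and full-volume inference agree", {
  set.seed(34)
  ds <- phantom_dataset(3, phantom_config(), seed = 8)
  cfg <- augreg_config(mode = "vm", dims = 2, patch_size = 64, stride = 32,
                       enc_channels = c(4, 8), dec_channels = c(8, 4),
                       head_channels = 4, iterations = 120, lr_G = 1e-3,
                       seed = 9)
  model <- augreg(ds, config = cfg)
  big <- phantom_dataset(1, phantom_config(shape = c(96, 96)), seed = 10)[[1]]
  rf <- register_pair(model, big$fixed, big$moving, method = "full")
  rs <- register_pair(model, big$fixed, big$moving, method = "sliding")
  expect_equal(dim(rs$field$vectors), dim(rf$field$vectors))
  expect_lt(mean(abs(rs$field$vectors - rf$field$vectors)), 0.1)
})

test_that("non-divisible volumes are padded, registered and cropped back", {
  set.seed(35)
  ds <- phantom_dataset(2, phantom_config(), seed = 12)
  cfg <- augreg_config(mode = "vm", dims = 2, patch_size = 64, stride = 32,
                       enc_channels = c(4, 8), dec_channels = c(8, 4),
                       head_channels = 4, iterations = 20, lr_G = 1e-3,
                       seed = 13)
  model <- augreg(ds, config = cfg)
  odd <- phantom_dataset(1, phantom_config(shape = c(70, 70)), seed = 14)[[1]]
  expect_warning(r <- register_pair(model, odd$fixed, odd$moving), "padded")
  expect_equal(dim(r$field$vectors), c(2, 70, 70))
  expect_equal(dim(r$warped$data), c(70, 70))
})
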
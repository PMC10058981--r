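# Joint training of the registration network G, the augmented network A and
# the discriminator D. One iteration processes one patch pair: the
# discriminator takes a step first (real = fixed patch, fake = warped moving
# patch, detached), then G and A take one Adam step on L_total = L_G + L_A.

#' Regular patch grid over a volume
#'
#' Origins are placed at multiples of `stride` along each axis, with a final
#' clamped origin so the last patch touches the volume boundary; every voxel
#' is covered by at least one patch. Origins are 0-based (matching the voxel
#' coordinate convention of displacement fields) and the ordering is
#' axis-major (first axis fastest).
#'
#' @param shape integer vector of volume dimensions.
#' @param size patch side(s), recycled per axis.
#' @param stride stride(s), recycled per axis.
#' @return A list of `patch_spec` objects, each with `origin`, `size`,
#'   `stride`.
#' @examples
#' length(extract_patch_grid(c(96, 96), 64, 32))  # origins 0 and 32 per axis
#' @export
extract_patch_grid <- function(shape, size, stride) {
  shape <- as.integer(shape)
  D <- length(shape)
  size <- rep_len(as.integer(size), D)
  stride <- rep_len(as.integer(stride), D)
  if (any(size > shape))
    stop("patch size (", paste(size, collapse = "x"),
         ") exceeds volume shape (", paste(shape, collapse = "x"), ")")
  axes <- lapply(seq_len(D), function(a) {
    o <- seq.int(0L, shape[a] - size[a], by = stride[a])
    last <- shape[a] - size[a]
    if (o[length(o)] != last) o <- c(o, last)
    o
  })
  grid <- do.call(expand.grid, axes)  # first axis varies fastest
  lapply(seq_len(nrow(grid)), function(i)
    structure(list(origin = as.integer(grid[i, ]), size = size,
                   stride = stride), class = "patch_spec"))
}

# sub-array at a 0-based patch origin
crop_patch <- function(arr, spec) {
  idx <- lapply(seq_along(spec$origin),
                function(a) spec$origin[a] + seq_len(spec$size[a]))
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

# --- Adam -------------------------------------------------------------------

adam_new <- function(params) {
  zeros <- lapply(params, function(l) list(w = l$w * 0, b = l$b * 0))
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1 ^ st$t
  c2 <- 1 - beta2 ^ st$t
  for (k in names(params)) {
    for (p in c("w", "b")) {
      g <- grads[[k]][[p]]
      st$m[[k]][[p]] <- beta1 * st$m[[k]][[p]] + (1 - beta1) * g
      st$v[[k]][[p]] <- beta2 * st$v[[k]][[p]] + (1 - beta2) * g * g
      mhat <- st$m[[k]][[p]] / c1
      vhat <- st$v[[k]][[p]] / c2
      params[[k]][[p]] <- params[[k]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = st)
}

# --- state ------------------------------------------------------------------

#' Initialize a training state
#'
#' Creates the parameters of the three networks, their optimizer states and
#' the loss bookkeeping for a configuration. Called by [augreg]; exposed for
#' step-level experimentation with [train_step].
#'
#' @param config an [augreg_config].
#' @return An environment of class `train_state`.
#' @export
train_state_init <- function(config) {
  st <- new.env(parent = emptyenv())
  st$config <- config
  st$flags <- config_flags(config)
  st$weights <- config_weights(config)
  st$unet_cfg <- unet_config(config$dims, config$enc_channels,
                             config$dec_channels, config$head_channels,
                             leaky_slope = config$leaky_slope)
  st$disc_cfg <- disc_config(config$dims, config$disc_channels,
                             config$leaky_slope)
  st$params_G <- unet_init(st$unet_cfg)
  st$params_A <- if (st$flags$use_augmented) unet_init(st$unet_cfg) else NULL
  st$params_D <- if (st$flags$use_gan) disc_init(st$disc_cfg) else NULL
  st$adam_G <- adam_new(st$params_G)
  st$adam_A <- if (!is.null(st$params_A)) adam_new(st$params_A) else NULL
  st$adam_D <- if (!is.null(st$params_D)) adam_new(st$params_D) else NULL
  st$iter <- 0L
  class(st) <- "train_state"
  st
}

# plain (gradient-free) field prediction from raw arrays
forward_field_plain <- function(params, Fa, Ma, cfg) {
  tape <- tape_new()
  x <- tp_leaf(tape, stack_channels(Fa, Ma), FALSE)
  leaves <- wrap_params(tape, params, FALSE)
  unet_forward(tape, leaves, x, cfg)$value
}

check_finite_terms <- function(terms) {
  for (nm in names(terms)) {
    v <- terms[[nm]]
    if (!is.finite(v))
      stop("non-finite loss at iteration: term '", nm, "' = ", v)
  }
  invisible(TRUE)
}

#' One joint training step on a patch pair
#'
#' Runs the forward pass (`phi1 = G(F, M)`; if enabled, `phi2 = A(F,
#' M(phi1))` and the composed field), updates the discriminator one step on
#' real/fake patches when the GAN is enabled, then updates G (and A) one
#' Adam step on the total loss. The returned record carries every individual
#' loss term.
#'
#' @param state a `train_state` from [train_state_init] (modified in place).
#' @param F_patch,M_patch fixed and moving patches ([scalar_volume]s or
#'   arrays of equal shape).
#' @return The loss record (named numeric vector), invisibly the state is
#'   updated.
#' @export
train_step <- function(state, F_patch, M_patch) {
  Fa <- vol_data(F_patch)
  Ma <- vol_data(M_patch)
  if (!all(dim(Fa) == dim(Ma)))
    stop("fixed (", paste(dim(Fa), collapse = "x"), ") and moving (",
         paste(dim(Ma), collapse = "x"), ") patches must share a shape")
  fl <- state$flags
  w <- state$weights
  shape <- dim(Fa)
  rec <- c(iter = state$iter + 1L)

  # --- discriminator step on detached warped image -------------------------
  if (fl$use_gan) {
    phi1_det <- forward_field_plain(state$params_G, Fa, Ma, state$unet_cfg)
    W1_det <- drop_channel(
      cpp_warp_fwd(array(Ma, c(1L, shape)), phi1_det, FALSE), shape)
    tape <- tape_new()
    dl <- wrap_params(tape, state$params_D, TRUE)
    p_real <- disc_forward(tape, dl,
                           tp_leaf(tape, array(Fa, c(1L, shape)), FALSE),
                           state$disc_cfg)
    p_fake <- disc_forward(tape, dl,
                           tp_leaf(tape, array(W1_det, c(1L, shape)), FALSE),
                           state$disc_cfg)
    ld <- tp_wsum(tape, list(tp_neglog(tape, p_real),
                             tp_neglog1m(tape, p_fake)), c(1, 1))
    check_finite_terms(c(loss_D = ld$value))
    tp_backward(tape, ld)
    upd <- adam_step(state$params_D, collect_grads(dl), state$adam_D,
                     state$config$lr_D)
    state$params_D <- upd$params
    state$adam_D <- upd$state
    rec <- c(rec, loss_D = ld$value, p_real = p_real$value,
             p_fake = p_fake$value)
  }

  # --- generator (G, and A) step -------------------------------------------
  tape <- tape_new()
  gl <- wrap_params(tape, state$params_G, TRUE)
  x <- tp_leaf(tape, stack_channels(Fa, Ma), FALSE)
  phi1 <- unet_forward(tape, gl, x, state$unet_cfg)
  Mimg <- tp_leaf(tape, array(Ma, c(1L, shape)), FALSE)
  Fimg <- tp_leaf(tape, array(Fa, c(1L, shape)), FALSE)
  W1 <- tp_warp(tape, Mimg, phi1)
  sim1 <- tp_sim_loss_ch(tape, Fa, W1, w$cc_window)
  smooth1 <- tp_smooth_loss(tape, phi1)

  g_terms <- list(sim1, smooth1)
  g_wts <- c(w$alpha, w$lambda)
  if (fl$use_gan) {
    dlc <- wrap_params(tape, state$params_D, FALSE)
    p_fake_G <- disc_forward(tape, dlc, W1, state$disc_cfg)
    adv <- tp_neglog(tape, p_fake_G)
    g_terms <- c(g_terms, list(adv))
    g_wts <- c(g_wts, 1)
    rec <- c(rec, adv = adv$value)
  }
  lG <- tp_wsum(tape, g_terms, g_wts)
  rec <- c(rec, sim1 = sim1$value, smooth1 = smooth1$value,
           loss_G = lG$value)

  if (fl$use_augmented) {
    al <- wrap_params(tape, state$params_A, TRUE)
    xA <- tp_concat(tape, Fimg, W1)
    phi2 <- unet_forward(tape, al, xA, state$unet_cfg)
    comp <- tp_add(tape, phi2, tp_warp(tape, phi1, phi2))
    Wc <- tp_warp(tape, Mimg, comp)
    W2 <- tp_warp(tape, W1, phi2)
    sim_c <- tp_sim_loss_ch(tape, Fa, Wc, w$cc_window)
    sim2 <- tp_sim_loss_ch(tape, Fa, W2, w$cc_window)
    mse2 <- tp_mse_loss(tape, phi2)
    smooth2 <- tp_smooth_loss(tape, phi2)
    smoothc <- tp_smooth_loss(tape, comp)
    a_terms <- list(sim1, sim_c, sim2, mse2, smooth1, smooth2, smoothc)
    mask <- c(1, fl$use_extra_sim, fl$use_extra_sim, fl$use_mse, 1, 1, 1)
    lA <- tp_wsum(tape, a_terms, w$a_weights * mask)
    lT <- tp_wsum(tape, list(lG, lA), c(1, 1))
    d2 <- dim(phi2$value)
    rec <- c(rec, sim_c = sim_c$value, sim2 = sim2$value,
             mse2 = mse2$value, smooth2 = smooth2$value,
             smoothc = smoothc$value, loss_A = lA$value,
             phi2_mag = mean(sqrt(colSums(matrix(phi2$value, d2[1]) ^ 2))))
  } else {
    lT <- lG
  }
  rec <- c(rec, loss_total = lT$value)
  check_finite_terms(rec)

  tp_backward(tape, lT)
  upd <- adam_step(state$params_G, collect_grads(gl), state$adam_G,
                   state$config$lr_G)
  state$params_G <- upd$params
  state$adam_G <- upd$state
  if (fl$use_augmented) {
    upd <- adam_step(state$params_A, collect_grads(al), state$adam_A,
                     state$config$lr_G)
    state$params_A <- upd$params
    state$adam_A <- upd$state
  }
  state$iter <- state$iter + 1L
  rec
}

# sim loss where W carries a leading singleton channel axis
tp_sim_loss_ch <- function(tape, F_const, W, n) {
  shape <- dim(F_const)
  Ws <- tp_node(tape, drop_channel(W$value, shape), W$requires,
                function(node) {
                  tp_accum(W, array(node$grad, c(1L, shape)))
                })
  tp_sim_loss(tape, F_const, Ws, n)
}

# --- training loop ----------------------------------------------------------

normalize01 <- function(vol) {
  x <- vol_data(vol)
  rng <- range(x)
  if (rng[2] > rng[1]) x <- (x - rng[1]) / (rng[2] - rng[1])
  scalar_volume(x, spacing = if (!is.null(vol$spacing)) vol$spacing)
}

# accepts either a list of pairs (elements with $fixed and $moving) or a
# plain list of volumes, paired at random each epoch
epoch_pairs <- function(dataset) {
  if (length(dataset) == 0) stop("train: empty dataset")
  if (!is.null(dataset[[1]]$fixed)) {
    dataset[sample(length(dataset))]
  } else {
    n <- length(dataset)
    idx <- sample(n)
    jdx <- sample(n)
    clash <- idx == jdx
    if (any(clash)) jdx[clash] <- (jdx[clash] %% n) + 1L
    lapply(seq_len(n), function(i)
      list(fixed = dataset[[idx[i]]], moving = dataset[[jdx[i]]]))
  }
}

#' Train the augmented-regularization registration model
#'
#' The main fitting function. Iterates epochs over the training pairs, cuts
#' each pair into a regular patch grid, shuffles the patches (seeded) and
#' runs joint training steps until the iteration budget is exhausted.
#' Intensities are normalized to `[0, 1]` per volume before training. If
#' `config$output_dir` is set, the per-iteration loss log (CSV) and the
#' resolved configuration (YAML, including the seed) are written there.
#'
#' @param data training data: either a list of pair objects (each with
#'   elements `fixed` and `moving`, e.g. from [make_pair]) or a plain list
#'   of [scalar_volume]s, which are then paired at random each epoch.
#' @param ... fields of [augreg_config] overriding the defaults, e.g.
#'   `mode = "vm_a_gan"`, `iterations = 2000`.
#' @param config a complete [augreg_config]; mutually exclusive with `...`.
#' @return A fitted model of class `augreg`: the three parameter sets, the
#'   configuration and the loss log. Only the registration network is used
#'   by [predict.augreg] / [register_pair].
#' @seealso [register_pair], [make_pair], [run_ablation]
#' @export
augreg <- function(data, ..., config = NULL) {
  if (is.null(config)) config <- augreg_config(...)
  else if (length(list(...)))
    stop("give either a complete `config` or `...` overrides, not both")
  set.seed(config$seed)
  st <- train_state_init(config)
  check_divisible(rep(config$patch_size, config$dims),
                  length(config$enc_channels))
  log <- vector("list", config$iterations)
  done <- FALSE
  while (!done) {
    for (pair in epoch_pairs(data)) {
      Fv <- normalize01(pair$fixed)
      Mv <- normalize01(pair$moving)
      grid <- extract_patch_grid(dim(Fv$data), config$patch_size,
                                 config$stride)
      for (spec in grid[sample(length(grid))]) {
        rec <- train_step(st, crop_patch(Fv$data, spec),
                          crop_patch(Mv$data, spec))
        log[[st$iter]] <- rec
        if (st$iter >= config$iterations) {
          done <- TRUE
          break
        }
      }
      if (done) break
    }
  }
  nm <- unique(unlist(lapply(log, names)))
  logdf <- as.data.frame(do.call(rbind, lapply(log, function(r) {
    out <- setNames(rep(NA_real_, length(nm)), nm)
    out[names(r)] <- r
    out
  })))
  model <- structure(list(params_G = st$params_G, params_A = st$params_A,
                          params_D = st$params_D, config = config,
                          unet_cfg = st$unet_cfg, disc_cfg = st$disc_cfg,
                          log = logdf, iterations = st$iter),
                     class = "augreg")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(logdf, file.path(config$output_dir, "loss_log.csv"),
              row.names = FALSE)
    dump_config(config, file.path(config$output_dir, "config.yaml"))
  }
  model
}

#' @export
print.augreg <- function(x, ...) {
  cat("Augmented-regularization registration model\n")
  cat("  mode:       ", x$config$mode, "\n")
  cat("  iterations: ", x$iterations, "\n")
  cat("  patch/stride:", x$config$patch_size, "/", x$config$stride, "\n")
  last <- tail(x$log, 1)
  cat("  final sim loss (F vs M(phi1)): ", signif(last$sim1, 4), "\n")
  invisible(x)
}

#' @export
summary.augreg <- function(object, ...) {
  log <- object$log
  k <- max(1L, floor(nrow(log) / 10))
  out <- list(
    mode = object$config$mode,
    iterations = object$iterations,
    sim_first10 = median(head(log$sim1, k)),
    sim_last10 = median(tail(log$sim1, k)),
    loss_total_final = tail(log$loss_total, 1),
    phi2_mag_final = if ("phi2_mag" %in% names(log))
      median(tail(log$phi2_mag, k)) else NA_real_)
  class(out) <- "summary.augreg"
  out
}

#' @export
print.summary.augreg <- function(x, ...) {
  cat("augreg model (mode ", x$mode, ", ", x$iterations, " iterations)\n",
      sep = "")
  cat("  median sim loss, first 10% of iterations: ",
      signif(x$sim_first10, 4), "\n")
  cat("  median sim loss, last 10% of iterations:  ",
      signif(x$sim_last10, 4), "\n")
  if (!is.na(x$phi2_mag_final))
    cat("  final mean |phi2| (voxels):               ",
        signif(x$phi2_mag_final, 4), "\n")
  invisible(x)
}

#' @export
plot.augreg <- function(x, ...) {
  log <- x$log
  graphics::plot(log$iter, log$sim1, type = "l", xlab = "iteration",
                 ylab = "similarity loss  -CC(F, M(phi1))",
                 main = paste("augreg training,", x$config$mode), ...)
  graphics::lines(stats::lowess(log$iter, log$sim1, f = 0.2), col = 2,
                  lwd = 2)
  invisible(x)
}
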
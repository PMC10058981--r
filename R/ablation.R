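#' Scaled-down ablation study on synthetic phantoms
#'
#' Trains one model per requested mode on a shared phantom dataset and
#' evaluates all of them on a shared test set, reporting pre- and
#' post-registration tissue Dice, SSIM and PCC, and (for modes with the
#' augmented network) the mean residual-field magnitude on the test set.
#' Mode names are `"vm"`, `"vm_a"`, `"vm_a_gan"`, optionally suffixed with
#' `"-mse"` to drop the MSE-to-zero penalty (e.g. `"vm_a-mse"`).
#'
#' The default problem size (64x64 phantoms, 20 training pairs, 10 test
#' pairs, 2000 iterations per mode) runs on one CPU core at desk scale.
#'
#' @param modes character vector of modes to train.
#' @param n_train,n_test number of training / test phantom pairs.
#' @param iterations training iterations per mode.
#' @param seed master seed (datasets, initialization, shuffling).
#' @param phantom a [phantom_config] describing the study's synthetic data.
#' @param lr_G,lr_D Adam learning rates for this study.
#' @param keep_models keep the fitted models in the result (default TRUE).
#' @return An object of class `augreg_ablation`: a list with `pre`
#'   (pre-registration metrics), `modes` (per-mode metrics and models) and
#'   the study inputs.
#' @export
run_ablation <- function(modes = c("vm", "vm_a", "vm_a_gan"),
                         n_train = 20L, n_test = 10L, iterations = 2000L,
                         seed = 1L, phantom = phantom_config(),
                         lr_G = 1e-3, lr_D = 1e-4, keep_models = TRUE) {
  train_set <- phantom_dataset(n_train, phantom, seed = seed)
  test_set <- phantom_dataset(n_test, phantom, seed = seed + 999L)

  pre <- aggregate_metrics(lapply(test_set, function(p)
    evaluate_pair(p$fixed, p$moving, p$fixed_seg, p$moving_seg)))

  results <- list()
  for (mode in modes) {
    parsed <- parse_mode(mode)
    cfg <- augreg_config(mode = parsed$mode, use_mse = parsed$use_mse,
                         iterations = iterations, seed = seed,
                         dims = phantom$dims,
                         patch_size = min(phantom$shape),
                         stride = max(min(phantom$shape) %/% 2L, 1L),
                         lr_G = lr_G, lr_D = lr_D)
    model <- augreg(train_set, config = cfg)
    per_pair <- lapply(test_set, function(p) {
      reg <- register_pair(model, p$fixed, p$moving)
      warped_seg <- warp_image(p$moving_seg, reg$field)
      evaluate_pair(p$fixed, reg$warped, p$fixed_seg, warped_seg)
    })
    agg <- aggregate_metrics(per_pair)
    phi2_mag <- NA_real_
    if (!is.null(model$params_A)) {
      phi2_mag <- mean(vapply(test_set, function(p)
        field_magnitude(augmented_field(model, p$fixed, p$moving)$phi2),
        numeric(1)))
    }
    results[[mode]] <- list(metrics = agg, phi2_mag = phi2_mag,
                            model = if (keep_models) model)
  }
  structure(list(pre = pre, modes = results, seed = seed,
                 phantom = phantom, n_train = n_train, n_test = n_test,
                 iterations = iterations, test_set_seed = seed + 999L),
            class = "augreg_ablation")
}

parse_mode <- function(mode) {
  use_mse <- TRUE
  base <- mode
  if (grepl("-mse$", mode)) {
    use_mse <- FALSE
    base <- sub("-mse$", "", mode)
  }
  if (!base %in% c("vm", "vm_a", "vm_a_gan"))
    stop("unknown ablation mode: ", mode)
  list(mode = base, use_mse = use_mse)
}

aggregate_metrics <- function(per_pair) {
  dice_mat <- do.call(rbind, lapply(per_pair, `[[`, "dice"))
  list(dice_per_tissue = colMeans(dice_mat),
       dice_per_tissue_sd = apply(dice_mat, 2, sd),
       mean_dice = mean(dice_mat),
       ssim = mean(vapply(per_pair, `[[`, numeric(1), "ssim")),
       pcc = mean(vapply(per_pair, `[[`, numeric(1), "pcc")),
       n = length(per_pair))
}

#' @export
print.augreg_ablation <- function(x, ...) {
  cat("Scaled-down ablation study (", x$n_train, " train / ", x$n_test,
      " test pairs, ", x$iterations, " iterations per mode)\n", sep = "")
  cat(sprintf("  %-14s mean Dice  SSIM   PCC    mean |phi2|\n", "mode"))
  cat(sprintf("  %-14s %8.3f  %5.3f  %5.3f\n", "(before)",
              x$pre$mean_dice, x$pre$ssim, x$pre$pcc))
  for (mode in names(x$modes)) {
    r <- x$modes[[mode]]
    cat(sprintf("  %-14s %8.3f  %5.3f  %5.3f  %s\n", mode,
                r$metrics$mean_dice, r$metrics$ssim, r$metrics$pcc,
                if (is.na(r$phi2_mag)) "-" else sprintf("%.4f", r$phi2_mag)))
  }
  invisible(x)
}
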
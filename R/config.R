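#' Run configuration
#'
#' Collects every knob of a training run: the method mode, ablation
#' switches, loss weights, patch geometry, learning rates, iteration budget
#' and master seed. `mode` determines the networks trained:
#' `"vm"` trains the registration network alone, `"vm_a"` adds the augmented
#' network, `"vm_a_gan"` additionally trains the adversarial discriminator.
#'
#' Defaults follow the reference protocol: patch side 64, stride 32,
#' `lr_G = 1e-5`, `lr_D = 1e-6`, local-CC window 9, `alpha = lambda = 1`.
#'
#' @param mode one of `"vm"`, `"vm_a"`, `"vm_a_gan"`.
#' @param use_mse keep the MSE-to-zero penalty on the augmented field.
#' @param use_extra_sim keep the two extra similarity terms of the augmented
#'   loss.
#' @param alpha,lambda,a_weights,cc_window see [loss_weights].
#' @param patch_size,stride patch side and stride (scalars, applied per axis).
#' @param lr_G,lr_D Adam learning rates of the generator networks and of the
#'   discriminator.
#' @param iterations training iteration budget (one patch pair per
#'   iteration).
#' @param seed master seed covering pairing, patch shuffling and network
#'   initialization.
#' @param dims grid dimensionality of the patches (2 or 3).
#' @param enc_channels,dec_channels,head_channels U-Net architecture, see
#'   [unet_config].
#' @param disc_channels,leaky_slope discriminator architecture, see
#'   [disc_config].
#' @param output_dir optional directory for the loss log and resolved config.
#' @return An object of class `augreg_config`.
#' @export
augreg_config <- function(mode = c("vm", "vm_a", "vm_a_gan"),
                          use_mse = TRUE, use_extra_sim = TRUE,
                          alpha = 1, lambda = 1, a_weights = rep(1, 7),
                          cc_window = 9L,
                          patch_size = 64L, stride = 32L,
                          lr_G = 1e-5, lr_D = 1e-6,
                          iterations = 2000L, seed = 1L, dims = 2L,
                          enc_channels = c(8, 16, 16),
                          dec_channels = c(16, 16, 8),
                          head_channels = 8L,
                          disc_channels = c(8, 16, 32, 1),
                          leaky_slope = 0.2,
                          output_dir = NULL) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, use_mse = isTRUE(use_mse),
              use_extra_sim = isTRUE(use_extra_sim),
              alpha = alpha, lambda = lambda,
              a_weights = as.numeric(a_weights),
              cc_window = as.integer(cc_window),
              patch_size = as.integer(patch_size),
              stride = as.integer(stride),
              lr_G = lr_G, lr_D = lr_D,
              iterations = as.integer(iterations), seed = as.integer(seed),
              dims = as.integer(dims),
              enc_channels = as.integer(enc_channels),
              dec_channels = as.integer(dec_channels),
              head_channels = as.integer(head_channels),
              disc_channels = as.integer(disc_channels),
              leaky_slope = leaky_slope,
              output_dir = output_dir)
  class(cfg) <- "augreg_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  loss_weights(cfg$alpha, cfg$lambda, cfg$a_weights, cfg$cc_window)
  if (cfg$iterations < 1) stop("config: iterations must be >= 1")
  if (cfg$patch_size < 1 || cfg$stride < 1)
    stop("config: patch_size and stride must be >= 1")
  if (cfg$lr_G <= 0 || cfg$lr_D <= 0)
    stop("config: learning rates must be positive")
  invisible(cfg)
}

config_flags <- function(cfg) {
  ablation_flags(use_augmented = cfg$mode %in% c("vm_a", "vm_a_gan"),
                 use_gan = cfg$mode == "vm_a_gan",
                 use_mse = cfg$use_mse,
                 use_extra_sim = cfg$use_extra_sim)
}

config_weights <- function(cfg) {
  loss_weights(cfg$alpha, cfg$lambda, cfg$a_weights, cfg$cc_window)
}

#' Load a run configuration from a YAML file
#'
#' Missing keys take the defaults of [augreg_config]; unknown keys are
#' rejected. The keys `use_gan` and `use_augmented` may be given only to
#' confirm the mode: a value inconsistent with `mode` is an error. An empty
#' file yields the full default configuration.
#'
#' @param path path to a YAML (or JSON, which YAML subsumes) file.
#' @return An [augreg_config].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  allowed <- names(formals(augreg_config))
  extra <- setdiff(names(vals), c(allowed, "use_gan", "use_augmented"))
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  mode <- if (!is.null(vals$mode)) vals$mode else "vm"
  implied <- list(use_augmented = mode %in% c("vm_a", "vm_a_gan"),
                  use_gan = mode == "vm_a_gan")
  for (k in c("use_gan", "use_augmented")) {
    if (!is.null(vals[[k]]) && !identical(isTRUE(vals[[k]]), implied[[k]]))
      stop("config key '", k, "' = ", vals[[k]],
           " is inconsistent with mode '", mode, "'")
    vals[[k]] <- NULL
  }
  do.call(augreg_config, vals)
}

#' Write a configuration to a YAML file
#'
#' `load_config(dump_config(cfg, f))` reproduces `cfg` exactly.
#'
#' @param config an [augreg_config].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' @export
print.augreg_config <- function(x, ...) {
  cat("<augreg_config> mode=", x$mode,
      " iters=", x$iterations,
      " patch=", x$patch_size, "/", x$stride,
      " lr_G=", format(x$lr_G), " lr_D=", format(x$lr_D),
      " seed=", x$seed, "\n", sep = "")
  invisible(x)
}
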
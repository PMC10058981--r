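# Minimal reverse-mode automatic differentiation over the handful of
# operations the networks and losses need. A tape records nodes in creation
# order; tp_backward() walks it in reverse. Each node is an environment with:
#   value    numeric array / scalar
#   grad     accumulated upstream gradient (NULL until touched)
#   requires TRUE if any ancestor leaf wants a gradient
#   backfn   function(node) propagating node$grad into its parents
# Heavy numerics live in the C++ kernels; the tape only does bookkeeping.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tp_node <- function(tape, value, requires, backfn = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$requires <- requires
  nd$backfn <- backfn
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd
}

tp_leaf <- function(tape, value, requires_grad = FALSE) {
  tp_node(tape, value, requires_grad)
}

tp_accum <- function(node, g) {
  if (!node$requires) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

tp_backward <- function(tape, loss_node) {
  loss_node$grad <- 1
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$backfn) || !nd$requires) next
    nd$backfn(nd)
  }
  invisible(NULL)
}

# --- operations -------------------------------------------------------------

tp_conv <- function(tape, x, w, b, stride = 1L) {
  val <- cpp_conv_fwd(x$value, w$value, b$value, stride)
  req <- x$requires || w$requires || b$requires
  nd <- tp_node(tape, val, req, function(node) {
    r <- cpp_conv_bwd(x$value, w$value, node$grad, stride)
    tp_accum(x, r$gx)
    tp_accum(w, r$gw)
    tp_accum(b, r$gb)
  })
  nd
}

tp_lrelu <- function(tape, x, slope = 0.2) {
  v <- x$value
  neg <- v < 0
  val <- v
  val[neg] <- slope * v[neg]
  tp_node(tape, val, x$requires, function(node) {
    g <- node$grad
    g[neg] <- slope * g[neg]
    tp_accum(x, g)
  })
}

tp_upsample <- function(tape, x, target_shape) {
  src_shape <- dim(x$value)[-1]
  val <- cpp_upsample_fwd(x$value, as.integer(target_shape))
  tp_node(tape, val, x$requires, function(node) {
    tp_accum(x, cpp_upsample_bwd(node$grad, as.integer(src_shape)))
  })
}

tp_concat <- function(tape, a, b) {
  da <- dim(a$value)
  db <- dim(b$value)
  Ca <- da[1]
  Cb <- db[1]
  m <- rbind(matrix(a$value, Ca), matrix(b$value, Cb))
  val <- array(m, c(Ca + Cb, da[-1]))
  tp_node(tape, val, a$requires || b$requires, function(node) {
    g <- matrix(node$grad, Ca + Cb)
    if (a$requires) tp_accum(a, array(g[seq_len(Ca), , drop = FALSE], da))
    if (b$requires) tp_accum(b, array(g[Ca + seq_len(Cb), , drop = FALSE], db))
  })
}

# img: (C, S...) node; field: (D, S...) node
tp_warp <- function(tape, img, field) {
  val <- cpp_warp_fwd(img$value, field$value, FALSE)
  tp_node(tape, val, img$requires || field$requires, function(node) {
    r <- cpp_warp_bwd(img$value, field$value, node$grad,
                      img$requires, field$requires)
    if (img$requires) tp_accum(img, r$gimg)
    if (field$requires) tp_accum(field, r$gfield)
  })
}

tp_add <- function(tape, a, b) {
  tp_node(tape, a$value + b$value, a$requires || b$requires, function(node) {
    tp_accum(a, node$grad)
    tp_accum(b, node$grad)
  })
}

# negative local cross-correlation of constant F against node W (spatial
# arrays, no channel axis); scalar output
tp_sim_loss <- function(tape, F_const, W, n) {
  r <- cpp_ncc(F_const, W$value, as.integer(n), CC_EPS, W$requires)
  tp_node(tape, -r$value, W$requires, function(node) {
    tp_accum(W, -node$grad * r$gW)
  })
}

tp_smooth_loss <- function(tape, field) {
  val <- cpp_smooth_fwd(field$value)
  tp_node(tape, val, field$requires, function(node) {
    tp_accum(field, node$grad * cpp_smooth_bwd(field$value))
  })
}

tp_mse_loss <- function(tape, field) {
  v <- field$value
  nvox <- prod(dim(v)[-1])
  tp_node(tape, sum(v ^ 2) / nvox, field$requires, function(node) {
    tp_accum(field, node$grad * (2 / nvox) * v)
  })
}

tp_global_mean <- function(tape, x) {
  n <- length(x$value)
  tp_node(tape, mean(x$value), x$requires, function(node) {
    g <- array(node$grad / n, dim(x$value))
    tp_accum(x, g)
  })
}

tp_sigmoid <- function(tape, x) {
  p <- 1 / (1 + exp(-x$value))
  tp_node(tape, p, x$requires, function(node) {
    tp_accum(x, node$grad * p * (1 - p))
  })
}

# -log(p) and -log(1-p) with probability clamping
tp_neglog <- function(tape, p) {
  pc <- min(max(p$value, PROB_EPS), 1 - PROB_EPS)
  inside <- p$value > PROB_EPS && p$value < 1 - PROB_EPS
  tp_node(tape, -log(pc), p$requires, function(node) {
    if (inside) tp_accum(p, -node$grad / pc)
  })
}

tp_neglog1m <- function(tape, p) {
  pc <- min(max(p$value, PROB_EPS), 1 - PROB_EPS)
  inside <- p$value > PROB_EPS && p$value < 1 - PROB_EPS
  tp_node(tape, -log(1 - pc), p$requires, function(node) {
    if (inside) tp_accum(p, node$grad / (1 - pc))
  })
}

# weighted sum of scalar nodes: sum(w_i * node_i)
tp_wsum <- function(tape, nodes, weights) {
  val <- 0
  for (i in seq_along(nodes)) val <- val + weights[i] * nodes[[i]]$value
  req <- any(vapply(nodes, function(nd) nd$requires, logical(1)))
  tp_node(tape, val, req, function(node) {
    for (i in seq_along(nodes))
      if (weights[i] != 0) tp_accum(nodes[[i]], weights[i] * node$grad)
  })
}
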
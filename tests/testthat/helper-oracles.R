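# Independent brute-force oracles: straightforward nested-loop
# implementations used to validate the fast kernels. Deliberately naive.

# pull-warp with multilinear interpolation and border clamping
oracle_warp <- function(arr, vec) {
  s <- dim(arr)
  D <- length(s)
  out <- array(0, s)
  idx <- as.matrix(expand.grid(lapply(s, seq_len)))
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    disp <- vapply(seq_len(D), function(a) vec[matrix(c(a, p), 1)], numeric(1))
    pos <- pmin(pmax((p - 1) + disp, 0), s - 1)
    base <- pmin(floor(pos), s - 2)
    fr <- pos - base
    acc <- 0
    for (m in 0:(2 ^ D - 1)) {
      bits <- bitwAnd(m, 2 ^ (seq_len(D) - 1)) > 0
      wgt <- prod(ifelse(bits, fr, 1 - fr))
      j <- pmin(base + bits, s - 1) + 1
      acc <- acc + wgt * arr[matrix(j, 1)]
    }
    out[matrix(p, 1)] <- acc
  }
  out
}

# windowed local cross-correlation, truncated windows, mean over voxels
oracle_cc <- function(F, W, n, eps = 1e-5) {
  s <- dim(F)
  D <- length(s)
  h <- n %/% 2
  tot <- 0
  idx <- as.matrix(expand.grid(lapply(s, seq_len)))
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    rng <- lapply(seq_len(D), function(a) max(1, p[a] - h):min(s[a], p[a] + h))
    win <- as.matrix(expand.grid(rng))
    Fw <- F[win]
    Ww <- W[win]
    A <- sum((Fw - mean(Fw)) * (Ww - mean(Ww)))
    B <- sum((Fw - mean(Fw)) ^ 2)
    C <- sum((Ww - mean(Ww)) ^ 2)
    tot <- tot + A ^ 2 / (B * C + eps)
  }
  tot / nrow(idx)
}

# mean squared norm of the forward-difference field gradient
oracle_smooth <- function(v) {
  d <- dim(v)
  D <- d[1]
  s <- d[-1]
  tot <- 0
  idx <- as.matrix(expand.grid(lapply(s, seq_len)))
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    for (a in seq_along(s)) {
      if (p[a] + 1 > s[a]) next
      p2 <- p
      p2[a] <- p[a] + 1
      for (cc in seq_len(D))
        tot <- tot + (v[matrix(c(cc, p2), 1)] - v[matrix(c(cc, p), 1)]) ^ 2
    }
  }
  tot / prod(s)
}

oracle_mse_zero <- function(v) {
  sum(v ^ 2) / prod(dim(v)[-1])
}

# global-statistics SSIM straight from the printed formula
oracle_ssim <- function(x, y, L = diff(range(x))) {
  c1 <- (0.01 * L) ^ 2
  c2 <- (0.03 * L) ^ 2
  mx <- mean(x)
  my <- mean(y)
  vx <- mean((x - mx) ^ 2)
  vy <- mean((y - my) ^ 2)
  cxy <- mean((x - mx) * (y - my))
  ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx ^ 2 + my ^ 2 + c1) * (vx + vy + c2))
}

oracle_dice <- function(x, y, label) {
  a <- x == label
  b <- y == label
  if (sum(a) + sum(b) == 0) return(1)
  2 * sum(a & b) / (sum(a) + sum(b))
}

oracle_pcc <- function(x, y) {
  xm <- x - mean(x)
  ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm ^ 2) * sum(ym ^ 2))
}

# smooth asymmetric test image: two Gaussian blobs on a gradient
gaussian_blob_image <- function(shape) {
  D <- length(shape)
  grids <- lapply(seq_len(D), function(a) {
    g <- (seq_len(shape[a]) - 1) / (shape[a] - 1)
    array(rep(g, each = prod(shape[seq_len(a - 1)])), shape)
  })
  r1 <- Reduce(`+`, lapply(grids, function(g) (g - 0.35) ^ 2))
  r2 <- Reduce(`+`, lapply(grids, function(g) (g - 0.65) ^ 2))
  exp(-r1 / 0.05) + 0.6 * exp(-r2 / 0.02) + 0.1 * grids[[1]]
}

# small random smooth displacement field for property tests
smooth_test_field <- function(shape, amplitude, sigma = 4) {
  D <- length(shape)
  comps <- lapply(seq_len(D), function(a) {
    noise <- array(rnorm(prod(shape)), shape)
    k <- outer(seq_len(shape[1]), seq_len(shape[1]),
               function(i, j) exp(-(i - j) ^ 2 / (2 * sigma ^ 2)))
    # crude separable smoothing via matrix products along each axis
    m <- noise
    for (ax in seq_len(D)) {
      S <- shape[ax]
      K <- outer(seq_len(S), seq_len(S),
                 function(i, j) exp(-(i - j) ^ 2 / (2 * sigma ^ 2)))
      K <- K / rowSums(K)
      perm <- c(ax, seq_len(D)[-ax])
      mm <- matrix(aperm(m, perm), S)
      m <- aperm(array(K %*% mm, shape[perm]), order(perm))
    }
    m
  })
  mat <- do.call(rbind, lapply(comps, as.vector))
  mag <- sqrt(colSums(mat ^ 2))
  if (max(mag) > 0) mat <- mat * (amplitude / max(mag))
  displacement_field(array(mat, c(D, shape)))
}
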
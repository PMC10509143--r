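# Neural-network layer primitives in base R.
#
# Tensor layout throughout: dim = c(C, H, W, N) (channels fastest), so a
# tensor flattens to a (C, H*W*N) matrix by a plain dim<- and all per-channel
# statistics are row operations. Convolutions run as BLAS matrix products via
# im2col gathers; col2im (the transpose scatter) uses rowsum(), which
# aggregates at C speed.

# Gather index for im2col on a zero-padded (C, Hp, Wp) image.
# Row order of the column matrix: channel fastest, then kernel row, kernel
# col; column order: output row fastest, then output col.
im2col_index <- function(C, Hp, Wp, k, stride, Hout, Wout) {
  a <- as.vector(outer(outer(seq_len(C), C * (seq_len(k) - 1L), `+`),
                       C * Hp * (seq_len(k) - 1L), `+`))
  b <- as.vector(outer(C * stride * (seq_len(Hout) - 1L),
                       C * Hp * stride * (seq_len(Wout) - 1L), `+`))
  outer(a, b, `+`)  # (C*k*k) x (Hout*Wout) matrix of 1-based indices
}

pad_chw <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2L * pad, d[3] + 2L * pad, d[4]))
  out[, (pad + 1L):(pad + d[2]), (pad + 1L):(pad + d[3]), ] <- x
  out
}

# x: (Cin, H, W, N); W_arr: (Cin, k, k, Cout); b: length Cout.
conv_forward <- function(x, W_arr, b, stride = 1L, pad = 0L,
                         keep_cache = TRUE) {
  d <- dim(x); Cin <- d[1]; H <- d[2]; W <- d[3]; N <- d[4]
  k <- dim(W_arr)[2]; Cout <- dim(W_arr)[4]
  Hout <- (H + 2L * pad - k) %/% stride + 1L
  Wout <- (W + 2L * pad - k) %/% stride + 1L
  xp <- pad_chw(x, pad)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  idx <- im2col_index(Cin, Hp, Wp, k, stride, Hout, Wout)
  xp_mat <- xp; dim(xp_mat) <- c(Cin * Hp * Wp, N)
  xcol <- xp_mat[as.vector(idx), , drop = FALSE]   # (Ckk*HWout, N)
  dim(xcol) <- c(Cin * k * k, Hout * Wout * N)
  W_mat <- W_arr; dim(W_mat) <- c(Cin * k * k, Cout)
  out <- crossprod(W_mat, xcol) + b                # (Cout, HWout*N)
  dim(out) <- c(Cout, Hout, Wout, N)
  cache <- if (keep_cache) {
    list(xcol = xcol, idx = as.vector(idx), W_mat = W_mat,
         dims = c(Cin = Cin, H = H, W = W, N = N, k = k, Cout = Cout,
                  Hout = Hout, Wout = Wout, Hp = Hp, Wp = Wp, pad = pad))
  } else NULL
  list(out = out, cache = cache)
}

conv_backward <- function(dout, cache) {
  dm <- cache$dims
  dout_mat <- dout; dim(dout_mat) <- c(dm["Cout"], dm["Hout"] * dm["Wout"] * dm["N"])
  dW <- cache$xcol %*% t(dout_mat)                # (Ckk, Cout)
  dim(dW) <- c(dm["Cin"], dm["k"], dm["k"], dm["Cout"])
  db <- rowSums(dout_mat)
  dxcol <- cache$W_mat %*% dout_mat               # (Ckk, HWout*N)
  dim(dxcol) <- c(dm["Cin"] * dm["k"]^2 * dm["Hout"] * dm["Wout"], dm["N"])
  agg <- rowsum(dxcol, cache$idx)                 # rows sorted by unique idx
  dxp <- matrix(0, dm["Cin"] * dm["Hp"] * dm["Wp"], dm["N"])
  dxp[as.integer(rownames(agg)), ] <- agg
  dim(dxp) <- c(dm["Cin"], dm["Hp"], dm["Wp"], dm["N"])
  pad <- dm[["pad"]]
  dx <- if (pad > 0L) {
    dxp[, (pad + 1L):(pad + dm["H"]), (pad + 1L):(pad + dm["W"]), ,
        drop = FALSE]
  } else dxp
  list(dx = dx, dW = dW, db = db)
}

# Batch normalisation over (H, W, N) per channel.
bn_forward <- function(x, gamma, beta, running_mean, running_var,
                       training = TRUE, momentum = 0.1, eps = 1e-5,
                       keep_cache = TRUE) {
  d <- dim(x); C <- d[1]
  xm <- x; dim(xm) <- c(C, length(x) / C)
  if (training) {
    mu <- rowMeans(xm)
    va <- rowMeans(xm * xm) - mu^2
    va <- pmax(va, 0)
    running_mean <- (1 - momentum) * running_mean + momentum * mu
    m <- ncol(xm)
    unbiased <- if (m > 1) va * m / (m - 1) else va
    running_var <- (1 - momentum) * running_var + momentum * unbiased
  } else {
    mu <- running_mean
    va <- running_var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- (xm - mu) * invstd
  out <- gamma * xhat + beta
  dim(out) <- d
  cache <- if (keep_cache) list(xhat = xhat, invstd = invstd, gamma = gamma,
                                dims = d) else NULL
  list(out = out, cache = cache,
       running_mean = running_mean, running_var = running_var)
}

bn_backward <- function(dout, cache) {
  d <- cache$dims; C <- d[1]
  dout_m <- dout; dim(dout_m) <- c(C, length(dout) / C)
  m <- ncol(dout_m)
  xhat <- cache$xhat
  dgamma <- rowSums(dout_m * xhat)
  dbeta <- rowSums(dout_m)
  dxhat <- dout_m * cache$gamma
  dx <- cache$invstd / m * (m * dxhat - rowSums(dxhat) - xhat *
                              rowSums(dxhat * xhat))
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

relu_backward <- function(dout, cache) dout * cache

# Global average pool: (C, H, W, N) -> (C, N).
gap_forward <- function(x) {
  d <- dim(x)
  xr <- x; dim(xr) <- c(d[1], d[2] * d[3], d[4])
  out <- colMeans(aperm(xr, c(2, 1, 3)))
  dim(out) <- c(d[1], d[4])
  list(out = out, cache = d)
}

gap_backward <- function(dout, cache) {
  d <- cache
  hw <- d[2] * d[3]
  dx <- dout[, rep(seq_len(d[4]), each = hw)] / hw
  dim(dx) <- d
  dx
}

# Per-channel mean over spatial positions: (C, H, W, N) -> (C, N).
channel_means <- function(x) {
  d <- dim(x)
  xr <- x; dim(xr) <- c(d[1], d[2] * d[3], d[4])
  s <- colMeans(aperm(xr, c(2, 1, 3)))
  dim(s) <- c(d[1], d[4])
  s
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Squeeze-and-excitation channel attention on a (C, H, W, N) map.
# params: w1 (C/r, C), b1, w2 (C, C/r), b2.
se_forward <- function(x, w1, b1, w2, b2, keep_cache = TRUE) {
  d <- dim(x); C <- d[1]; hw <- d[2] * d[3]; N <- d[4]
  s <- channel_means(x)                       # squeeze: (C, N)
  z_pre <- w1 %*% s + b1
  z <- z_pre * (z_pre > 0)
  g <- sigmoid(w2 %*% z + b2)                 # gates in (0,1): (C, N)
  xm <- x; dim(xm) <- c(C, hw * N)
  gexp <- g[, rep(seq_len(N), each = hw), drop = FALSE]
  out <- xm * gexp
  dim(out) <- d
  cache <- if (keep_cache) list(x = x, s = s, z_pre = z_pre, z = z, g = g,
                                w1 = w1, w2 = w2, dims = d) else NULL
  list(out = out, cache = cache)
}

se_backward <- function(dout, cache) {
  d <- cache$dims; C <- d[1]; hw <- d[2] * d[3]; N <- d[4]
  dout_m <- dout; dim(dout_m) <- c(C, hw * N)
  xm <- cache$x; dim(xm) <- c(C, hw * N)
  gexp <- cache$g[, rep(seq_len(N), each = hw), drop = FALSE]
  dx_m <- dout_m * gexp
  # gate gradient: sum over spatial positions of dout * x
  P <- dout_m * xm; dim(P) <- c(C, d[2], d[3], N)
  dg <- channel_means(P) * hw                 # (C, N)
  dpre2 <- dg * cache$g * (1 - cache$g)
  dw2 <- dpre2 %*% t(cache$z)
  db2 <- rowSums(dpre2)
  dz <- t(cache$w2) %*% dpre2
  dz <- dz * (cache$z_pre > 0)
  dw1 <- dz %*% t(cache$s)
  db1 <- rowSums(dz)
  ds <- t(cache$w1) %*% dz                    # (C, N)
  dx_from_s <- ds[, rep(seq_len(N), each = hw), drop = FALSE] / hw
  dx <- dx_m + dx_from_s
  dim(dx) <- d
  list(dx = dx, dw1 = dw1, db1 = db1, dw2 = dw2, db2 = db2)
}

# 3x3 stride-2 pad-1 max pool via pmax over the 9 shifted slices.
maxpool_forward <- function(x, k = 3L, stride = 2L, pad = 1L,
                            keep_cache = TRUE) {
  d <- dim(x)
  Hout <- (d[2] + 2L * pad - k) %/% stride + 1L
  Wout <- (d[3] + 2L * pad - k) %/% stride + 1L
  xp <- pad_chw(x, pad)
  if (pad > 0L) {
    xp[xp == 0 & pad_chw(array(1, d), pad) == 0] <- -Inf
  }
  out <- NULL
  for (dh in 0:(k - 1L)) for (dw in 0:(k - 1L)) {
    sl <- xp[, seq(1L + dh, by = stride, length.out = Hout),
             seq(1L + dw, by = stride, length.out = Wout), , drop = FALSE]
    out <- if (is.null(out)) sl else pmax(out, sl)
  }
  cache <- if (keep_cache) list(xp = xp, out = out, dims = d, k = k,
                                stride = stride, pad = pad,
                                Hout = Hout, Wout = Wout) else NULL
  list(out = out, cache = cache)
}

maxpool_backward <- function(dout, cache) {
  d <- cache$dims; k <- cache$k; stride <- cache$stride; pad <- cache$pad
  Hout <- cache$Hout; Wout <- cache$Wout
  dxp <- array(0, dim(cache$xp))
  remaining <- array(TRUE, dim(dout))
  for (dh in 0:(k - 1L)) for (dw in 0:(k - 1L)) {
    ri <- seq(1L + dh, by = stride, length.out = Hout)
    ci <- seq(1L + dw, by = stride, length.out = Wout)
    sl <- cache$xp[, ri, ci, , drop = FALSE]
    take <- (sl == cache$out) & remaining
    remaining <- remaining & !take
    dxp[, ri, ci, ] <- dxp[, ri, ci, , drop = FALSE] + dout * take
  }
  if (pad > 0L) {
    dxp[, (pad + 1L):(pad + d[2]), (pad + 1L):(pad + d[3]), , drop = FALSE]
  } else dxp
}
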
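#' @include autograd.R
NULL

# ---------------------------------------------------------------------------
# Convolution layers on BLAS: same-padded stride-1 kernels are lowered to a
# precomputed gather (im2col) followed by a dense matrix product. The
# backward-data pass reuses the same lowering with the tap-flipped,
# channel-transposed kernel, so no scatter is ever needed. Gather index
# matrices depend only on (spatial dims, kernel, channels) and are cached.
# ---------------------------------------------------------------------------

convCache <- new.env(parent = emptyenv())

#' Clear the cached convolution gather indices
#'
#' The cache grows with every distinct (input shape, channel count)
#' combination a convolution runs at; clearing it frees that memory.
#' @return Invisibly, NULL.
#' @export
clearConvCache <- function() {
  rm(list = ls(convCache), envir = convCache)
  invisible(NULL)
}

# gather indices into the zero-padded array for a same-padded k^d stencil;
# column order: tap fastest within channel, i.e. col = (ci-1)*K + tap
convIndex <- function(spatial, cin, k = 3L) {
  key <- paste(c(spatial, cin, k), collapse = "_")
  got <- convCache[[key]]
  if (!is.null(got)) return(got)
  d <- length(spatial)
  pad <- (k - 1L) %/% 2L
  padded <- spatial + 2L * pad
  nvox <- prod(spatial)
  # linear index of output voxel (1-based) in the padded array at tap offset 0
  if (d == 3L) {
    z <- rep(seq_len(spatial[1]), times = spatial[2] * spatial[3])
    y <- rep(rep(seq_len(spatial[2]), each = spatial[1]), times = spatial[3])
    x <- rep(seq_len(spatial[3]), each = spatial[1] * spatial[2])
    base <- z + (y - 1L) * padded[1] + (x - 1L) * padded[1] * padded[2]
    taps <- as.matrix(expand.grid(dz = 0:(k - 1L), dy = 0:(k - 1L),
                                  dx = 0:(k - 1L)))
    off <- taps[, 1] + taps[, 2] * padded[1] + taps[, 3] * padded[1] * padded[2]
  } else {
    r <- rep(seq_len(spatial[1]), times = spatial[2])
    cc <- rep(seq_len(spatial[2]), each = spatial[1])
    base <- r + (cc - 1L) * padded[1]
    taps <- as.matrix(expand.grid(dr = 0:(k - 1L), dc = 0:(k - 1L)))
    off <- taps[, 1] + taps[, 2] * padded[1]
  }
  K <- as.integer(k^d)
  chanStride <- prod(padded)
  idx <- matrix(0L, nvox, K * cin)
  for (ci in seq_len(cin)) for (t in seq_len(K)) {
    idx[, (ci - 1L) * K + t] <- base + off[t] + (ci - 1L) * chanStride
  }
  res <- list(idx = idx, padded = padded, K = K, pad = pad)
  convCache[[key]] <- res
  res
}

padSpatial <- function(x, pad) {
  d <- dim(x)
  nd <- length(d)
  spatial <- d[-nd]
  out <- array(0, c(spatial + 2L * pad, d[nd]))
  if (nd == 4L) out[pad + seq_len(d[1]), pad + seq_len(d[2]),
                    pad + seq_len(d[3]), ] <- x
  else out[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  out
}

# lower x (spatial..., cin) to the (nvox, K*cin) patch matrix
im2col <- function(x, k = 3L) {
  d <- dim(x)
  nd <- length(d)
  cin <- d[nd]
  ci <- convIndex(d[-nd], cin, k)
  xp <- padSpatial(x, ci$pad)
  matrix(xp[ci$idx], nrow(ci$idx), ncol(ci$idx))
}

# build the backward-data kernel: taps flipped, in/out channels swapped.
# W is (K*cin, cout); result is (K*cout, cin).
flipKernel <- function(W, K, cin, cout) {
  a <- array(W, c(K, cin, cout))
  a <- a[K:1, , , drop = FALSE]           # full tap reversal
  matrix(aperm(a, c(1, 3, 2)), K * cout, cin)
}

# same-padded stride-1 convolution; x: (spatial..., cin) tensor,
# W: (K*cin, cout) tensor, b: (cout) tensor
agConv <- function(x, W, b, k = 3L) {
  x <- agConst(x); W <- agConst(W); b <- agConst(b)
  d <- dim(x$val)
  nd <- length(d)
  spatial <- d[-nd]
  cin <- d[nd]
  cout <- length(b$val)
  if (k == 1L) {
    Xm <- matrix(x$val, prod(spatial), cin)
    Ym <- Xm %*% matrix(W$val, cin, cout)
  } else {
    Xm <- im2col(x$val, k)
    Ym <- Xm %*% W$val
  }
  Ym <- sweep(Ym, 2L, b$val, "+")
  out <- array(Ym, c(spatial, cout))
  agTensor(out, list(x, W, b), function(g) {
    gm <- matrix(g, prod(spatial), cout)
    db <- colSums(gm)
    if (k == 1L) {
      dW <- crossprod(matrix(x$val, prod(spatial), cin), gm)
      dX <- array(gm %*% t(matrix(W$val, cin, cout)), d)
      return(list(dX, matrix(dW, cin, cout), db))
    }
    dW <- crossprod(Xm, gm)
    Gm <- im2col(array(g, c(spatial, cout)), k)
    K <- as.integer(k^(nd - 1L))
    Wb <- flipKernel(W$val, K, cin, cout)
    dX <- array(Gm %*% Wb, d)
    list(dX, dW, db)
  })
}

# transposed 3D convolution, kernel 2, stride 2 (exact 2x upsampling).
# x: (Z, Y, X, cin); W: (cin, 8*cout) with column order
# (az, ay, ax) fastest within each output channel; b: (cout).
agConvT3d <- function(x, W, b) {
  x <- agConst(x); W <- agConst(W); b <- agConst(b)
  d <- dim(x$val)
  cin <- d[4]
  cout <- length(b$val)
  nvox <- prod(d[1:3])
  Xm <- matrix(x$val, nvox, cin)
  Ym <- Xm %*% W$val                       # (nvox, 8*cout)
  Y <- array(Ym, c(d[1], d[2], d[3], 2L, 2L, 2L, cout))
  Y <- aperm(Y, c(4, 1, 5, 2, 6, 3, 7))
  dim(Y) <- c(2L * d[1], 2L * d[2], 2L * d[3], cout)
  Y <- sweep(Y, 4L, b$val, "+")
  agTensor(Y, list(x, W, b), function(g) {
    db <- apply(g, 4L, sum)
    G <- g
    dim(G) <- c(2L, d[1], 2L, d[2], 2L, d[3], cout)
    G <- aperm(G, c(2, 4, 6, 1, 3, 5, 7))
    Gm <- matrix(G, nvox, 8L * cout)
    dW <- crossprod(Xm, Gm)
    dX <- array(Gm %*% t(W$val), d)
    list(dX, dW, db)
  })
}

# 2x mean pooling
agPool <- function(x) {
  x <- agConst(x)
  d <- dim(x$val)
  nd <- length(d)
  if (nd == 4L) {
    v <- x$val
    dim(v) <- c(2L, d[1] %/% 2L, 2L, d[2] %/% 2L, 2L, d[3] %/% 2L, d[4])
    v <- aperm(v, c(1, 3, 5, 2, 4, 6, 7))
    dim(v) <- c(8L, prod(d) %/% 8L)
    out <- array(colMeans(v), c(d[1:3] %/% 2L, d[4]))
    agTensor(out, list(x), function(g) {
      n <- length(g)
      gg <- matrix(rep(as.vector(g) / 8, each = 8L), 8L, n)
      dim(gg) <- c(2L, 2L, 2L, d[1] %/% 2L, d[2] %/% 2L, d[3] %/% 2L, d[4])
      gg <- aperm(gg, c(1, 4, 2, 5, 3, 6, 7))
      dim(gg) <- d
      list(gg)
    })
  } else {
    v <- x$val
    dim(v) <- c(2L, d[1] %/% 2L, 2L, d[2] %/% 2L, d[3])
    v <- aperm(v, c(1, 3, 2, 4, 5))
    dim(v) <- c(4L, prod(d) %/% 4L)
    out <- array(colMeans(v), c(d[1:2] %/% 2L, d[3]))
    agTensor(out, list(x), function(g) {
      n <- length(g)
      gg <- matrix(rep(as.vector(g) / 4, each = 4L), 4L, n)
      dim(gg) <- c(2L, 2L, d[1] %/% 2L, d[2] %/% 2L, d[3])
      gg <- aperm(gg, c(1, 3, 2, 4, 5))
      dim(gg) <- d
      list(gg)
    })
  }
}

# instance normalization: per-channel standardization over the spatial
# extent with learnable gain/shift
agInstNorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- agConst(x); gamma <- agConst(gamma); beta <- agConst(beta)
  d <- dim(x$val)
  nd <- length(d)
  C <- d[nd]
  n <- prod(d[-nd])
  Xm <- matrix(x$val, n, C)
  mu <- colMeans(Xm)
  xc <- sweep(Xm, 2L, mu)
  va <- colMeans(xc^2)
  istd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, istd, "*")
  Ym <- sweep(sweep(xhat, 2L, gamma$val, "*"), 2L, beta$val, "+")
  agTensor(array(Ym, d), list(x, gamma, beta), function(g) {
    Gm <- matrix(g, n, C)
    dgamma <- colSums(Gm * xhat)
    dbeta <- colSums(Gm)
    dxhat <- sweep(Gm, 2L, gamma$val, "*")
    # classic batch/instance-norm backward
    t1 <- sweep(dxhat, 2L, colMeans(dxhat))
    t2 <- sweep(xhat, 2L, colMeans(dxhat * xhat), "*")
    dX <- sweep(t1 - t2, 2L, istd, "*")
    list(array(dX, d), dgamma, dbeta)
  })
}

# ---- parameters and optimizer ---------------------------------------------

# He-style initialization for a (fanin, fanout) kernel matrix
heInit <- function(nrowW, ncolW, fanin) {
  matrix(stats::rnorm(nrowW * ncolW, sd = sqrt(2 / fanin)), nrowW, ncolW)
}

newParam <- function(val) agTensor(val)

# Adam with bias correction; state lives alongside the parameter list
adamInit <- function(params) {
  lapply(params, function(p) list(m = p$val * 0, v = p$val * 0))
}

adamStep <- function(params, state, lr, beta1, beta2, t, eps = 1e-8) {
  for (i in seq_along(params)) {
    p <- params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st <- state[[i]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    state[[i]] <- st
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    p$val <- p$val - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

# flatten a nested named list of parameter tensors into a flat list
flattenParams <- function(x) {
  if (agIsTensor(x)) return(list(x))
  unlist(lapply(x, flattenParams), recursive = FALSE, use.names = FALSE)
}

paramVectorNorm <- function(params) {
  sqrt(sum(vapply(params, function(p) sum(p$val^2), numeric(1))))
}
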
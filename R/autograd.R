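#' @include AllClasses.R
NULL

# ---------------------------------------------------------------------------
# A minimal reverse-mode automatic differentiation engine.
#
# Tensors are environments carrying a value, an accumulated gradient, parent
# tensors and a backward closure mapping the output gradient to per-parent
# gradients. Graphs are built dynamically by the operators below; agBackward()
# runs a depth-first topological sort and accumulates gradients leaf-ward.
# Gradient recording can be switched off (agNoGrad) for inference so large
# intermediate buffers are not retained.
# ---------------------------------------------------------------------------

agState <- new.env(parent = emptyenv())
agState$counter <- 0L
agState$recording <- TRUE

agTensor <- function(val, parents = list(), backfn = NULL) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$grad <- NULL
  if (agState$recording) {
    e$parents <- parents
    e$backfn <- backfn
  } else {
    e$parents <- list()
    e$backfn <- NULL
  }
  agState$counter <- agState$counter + 1L
  e$id <- agState$counter
  class(e) <- "agTensor"
  e
}

agIsTensor <- function(x) inherits(x, "agTensor")

agConst <- function(x) if (agIsTensor(x)) x else agTensor(x)

# run expr without recording the graph (inference mode)
agNoGrad <- function(expr) {
  old <- agState$recording
  agState$recording <- FALSE
  on.exit(agState$recording <- old)
  force(expr)
}

agZeroGrad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# reverse-mode sweep from a scalar loss tensor
agBackward <- function(loss) {
  stopifnot(agIsTensor(loss), length(loss$val) == 1L)
  topo <- vector("list", 256L)
  nTopo <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = loss, stage = 1L))
  # iterative DFS (graphs can be deep; avoid C stack limits)
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents)
        if (is.null(seen[[as.character(p$id)]]))
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
    } else {
      nTopo <- nTopo + 1L
      if (nTopo > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[nTopo]] <- node
    }
  }
  topo <- topo[seq_len(nTopo)]
  for (n in topo) if (!identical(n$id, loss$id)) n$grad <- NULL
  loss$grad <- 1
  for (i in rev(seq_len(nTopo))) {
    n <- topo[[i]]
    if (is.null(n$backfn) || is.null(n$grad)) next
    gs <- n$backfn(n$grad)
    for (j in seq_along(n$parents)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- n$parents[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(NULL)
}

# ---- elementwise and reduction ops ----------------------------------------

agAdd <- function(a, b) {
  a <- agConst(a); b <- agConst(b)
  agTensor(a$val + b$val, list(a, b), function(g) list(g, g))
}

agSub <- function(a, b) {
  a <- agConst(a); b <- agConst(b)
  agTensor(a$val - b$val, list(a, b), function(g) list(g, -g))
}

agScale <- function(a, k) {
  a <- agConst(a)
  agTensor(a$val * k, list(a), function(g) list(g * k))
}

agRelu <- function(a) {
  a <- agConst(a)
  pos <- a$val > 0
  agTensor(a$val * pos, list(a), function(g) list(g * pos))
}

agSigmoid <- function(a) {
  a <- agConst(a)
  s <- 1 / (1 + exp(-a$val))
  agTensor(s, list(a), function(g) list(g * s * (1 - s)))
}

# mean((a - b)^2) -> scalar
agMSE <- function(a, b) {
  a <- agConst(a); b <- agConst(b)
  d <- a$val - b$val
  n <- length(d)
  agTensor(mean(d^2), list(a, b),
           function(g) list(g * 2 * d / n, -g * 2 * d / n))
}

# mean(|a - b|) -> scalar; subgradient 0 at ties
agMAE <- function(a, b) {
  a <- agConst(a); b <- agConst(b)
  d <- a$val - b$val
  n <- length(d)
  s <- sign(d)
  agTensor(mean(abs(d)), list(a, b),
           function(g) list(g * s / n, -g * s / n))
}

agMean <- function(a) {
  a <- agConst(a)
  n <- length(a$val)
  d <- dim(a$val)
  agTensor(mean(a$val), list(a), function(g) {
    out <- rep(g / n, n)
    if (!is.null(d)) dim(out) <- d
    list(out)
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

agSum <- function(ts) {
  # sum of a list of scalar tensors
  stopifnot(length(ts) >= 1L)
  val <- sum(vapply(ts, function(t) t$val, numeric(1)))
  agTensor(val, ts, function(g) rep(list(g), length(ts)))
}

# mean of a (z, y, x, 1) or (z, y, x) volume over one spatial axis -> 2D map
agMeanAxis <- function(a, axis) {
  a <- agConst(a)
  v <- a$val
  stopifnot(length(dim(v)) == 4L, dim(v)[4] == 1L)
  d3 <- dim(v)[1:3]
  dim(v) <- d3
  m <- apply(v, setdiff(1:3, axis), mean)
  n <- d3[axis]
  agTensor(m, list(a), function(g) {
    gv <- array(0, d3)
    if (axis == 1L) for (i in seq_len(n)) gv[i, , ] <- g / n
    else if (axis == 2L) for (i in seq_len(n)) gv[, i, ] <- g / n
    else for (i in seq_len(n)) gv[, , i] <- g / n
    dim(gv) <- c(d3, 1L)
    list(gv)
  })
}

# concatenate along the channel (last) axis
agConcatC <- function(a, b) {
  a <- agConst(a); b <- agConst(b)
  da <- dim(a$val); db <- dim(b$val)
  nd <- length(da)
  stopifnot(all(da[-nd] == db[-nd]))
  val <- array(c(a$val, b$val), c(da[-nd], da[nd] + db[nd]))
  agTensor(val, list(a, b), function(g) {
    spat <- prod(da[-nd])
    gm <- matrix(g, spat)
    list(array(gm[, seq_len(da[nd])], da),
         array(gm[, da[nd] + seq_len(db[nd])], db))
  })
}

# exact 90-degree lattice rotation of a (z, y, x, c) grid about z:
# out[z, y, x, c] = in[z, x, nY + 1 - y, c]
agRotZ90 <- function(a) {
  a <- agConst(a)
  d <- dim(a$val)
  stopifnot(length(d) == 4L, d[2] == d[3])  # square transverse plane
  A <- aperm(a$val, c(1, 3, 2, 4))
  val <- A[, d[2]:1, , , drop = FALSE]
  agTensor(val, list(a), function(g) {
    # inverse: undo the reversal, then the transposition
    list(aperm(g[, d[2]:1, , , drop = FALSE], c(1, 3, 2, 4)))
  })
}

# replicate a 2D feature map (z, x, c) along a new y axis -> (z, depth, x, c)
agExpandY <- function(a, depth) {
  a <- agConst(a)
  d <- dim(a$val)  # (z, x, c)
  v <- array(a$val, c(d[1], 1, d[2], d[3]))[, rep(1, depth), , ,
                                            drop = FALSE]
  agTensor(v, list(a), function(g) {
    gm <- apply(g, c(1, 3, 4), sum)
    dim(gm) <- d
    list(gm)
  })
}

# average two equal-shaped tensors
agAvg <- function(a, b) agScale(agAdd(a, b), 0.5)
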
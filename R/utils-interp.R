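#' @include AllClasses.R
NULL

# Bilinear resize of a 2D matrix (wraps EBImage; first dim = rows).
resizeBilinear <- function(m, nrowOut, ncolOut) {
  if (nrow(m) == nrowOut && ncol(m) == ncolOut) return(m)
  r <- EBImage::resize(m, w = nrowOut, h = ncolOut, filter = "bilinear")
  matrix(as.numeric(r), nrowOut, ncolOut)
}

# Trilinear resize of a 3D array to a target shape, pixel-centre aligned.
resizeVolume <- function(a, shapeOut) {
  dIn <- dim(a)
  if (all(dIn == shapeOut)) return(a)
  coord <- function(nOut, nIn) {
    s <- (seq_len(nOut) - 0.5) * nIn / nOut + 0.5
    pmin(pmax(s, 1), nIn)
  }
  cz <- coord(shapeOut[1], dIn[1])
  cy <- coord(shapeOut[2], dIn[2])
  cx <- coord(shapeOut[3], dIn[3])
  fz <- pmin(floor(cz), dIn[1] - 1L); wz <- cz - fz
  fy <- pmin(floor(cy), dIn[2] - 1L); wy <- cy - fy
  fx <- pmin(floor(cx), dIn[3] - 1L); wx <- cx - fx
  if (dIn[1] == 1L) { fz <- rep(1, shapeOut[1]); wz <- rep(0, shapeOut[1]) }
  if (dIn[2] == 1L) { fy <- rep(1, shapeOut[2]); wy <- rep(0, shapeOut[2]) }
  if (dIn[3] == 1L) { fx <- rep(1, shapeOut[3]); wx <- rep(0, shapeOut[3]) }
  out <- array(0, shapeOut)
  idx <- function(z, y, x) {
    # linear indices into a for all (z[i], y[j], x[k]) combinations
    az <- rep(z, times = shapeOut[2] * shapeOut[3])
    ay <- rep(rep(y, each = shapeOut[1]), times = shapeOut[3])
    ax <- rep(x, each = shapeOut[1] * shapeOut[2])
    az + (ay - 1) * dIn[1] + (ax - 1) * dIn[1] * dIn[2]
  }
  WZ <- rep(wz, times = shapeOut[2] * shapeOut[3])
  WY <- rep(rep(wy, each = shapeOut[1]), times = shapeOut[3])
  WX <- rep(wx, each = shapeOut[1] * shapeOut[2])
  acc <- numeric(prod(shapeOut))
  for (bz in 0:1) for (by in 0:1) for (bx in 0:1) {
    w <- (if (bz) WZ else 1 - WZ) * (if (by) WY else 1 - WY) *
      (if (bx) WX else 1 - WX)
    acc <- acc + w * a[idx(fz + bz, fy + by, fx + bx)]
  }
  array(acc, shapeOut)
}

# Rotate a (z, y, x) volume about the z axis by `angleDeg` degrees with
# bilinear in-plane interpolation; `fill` is used outside the source grid.
# cospi/sinpi make quarter turns exact lattice permutations.
rotateVolumeZ <- function(a, angleDeg, fill = min(a)) {
  if (angleDeg %% 360 == 0) return(a)
  d <- dim(a)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  ct <- cospi(angleDeg / 180); st <- sinpi(angleDeg / 180)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  gy <- rep(seq_len(ny), times = nx) - cy
  gx <- rep(seq_len(nx), each = ny) - cx
  # inverse rotation: sample the source at R(-theta) (y, x)
  sy <- cy + ct * gy - st * gx
  sx <- cx + st * gy + ct * gx
  fy <- floor(sy); fx <- floor(sx)
  wy <- sy - fy; wx <- sx - fx
  am <- matrix(a, nz, ny * nx)
  accum <- matrix(0, nz, ny * nx)
  wsum <- numeric(ny * nx)
  for (by in 0:1) for (bx in 0:1) {
    py <- fy + by; px <- fx + bx
    ok <- py >= 1 & py <= ny & px >= 1 & px <= nx
    w <- (if (by) wy else 1 - wy) * (if (bx) wx else 1 - wx)
    w[!ok] <- 0
    col <- pmin(pmax(py, 1), ny) + (pmin(pmax(px, 1), nx) - 1) * ny
    accum <- accum + am[, col, drop = FALSE] *
      matrix(w, nz, ny * nx, byrow = TRUE)
    wsum <- wsum + w
  }
  # missing weight mass comes from outside the grid: fill it
  accum <- accum + matrix((1 - wsum) * fill, nz, ny * nx, byrow = TRUE)
  array(accum, d)
}

# min-max rescale to [0, 1]; all-constant input collapses to zeros.
rescale01 <- function(m, warnDegenerate = FALSE) {
  lo <- min(m); hi <- max(m)
  if (hi - lo <= .Machine$double.eps * max(abs(hi), 1)) {
    if (warnDegenerate)
      warning("degenerate rescale: image is constant, emitting zeros")
    return(array(0, dim(m)))
  }
  (m - lo) / (hi - lo)
}
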
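# Internal array/geometry helpers shared across modules.

# Deterministic sub-seed derivation (keeps seeds < 2^31).
.deriveSeed <- function(master, i) {
  as.integer((as.numeric(master) * 1000003 + as.numeric(i) * 7919) %%
               2147483629)
}

# 1D interpolation matrix (nOut x nIn) for grid-extent-preserving
# resampling. order: 0 nearest, 1 linear, 3 Catmull-Rom cubic. Edge
# handling is replicate; every row sums to 1, so constants are preserved.
.interpMatrix <- function(nIn, nOut, order = 3) {
  u <- (seq_len(nOut) - 0.5) * nIn / nOut + 0.5   # fractional 1-based index
  M <- matrix(0, nOut, nIn)
  clampi <- function(i) pmin(pmax(i, 1L), nIn)
  if (order == 0) {
    M[cbind(seq_len(nOut), clampi(as.integer(round(u))))] <- 1
  } else if (order == 1) {
    i0 <- floor(u); t <- u - i0
    for (k in 0:1) {
      w <- if (k == 0) 1 - t else t
      idx <- clampi(as.integer(i0) + k)
      M[cbind(seq_len(nOut), idx)] <- M[cbind(seq_len(nOut), idx)] + w
    }
  } else if (order == 3) {
    i0 <- floor(u); t <- u - i0
    w <- cbind((-t^3 + 2 * t^2 - t) / 2,
               (3 * t^3 - 5 * t^2 + 2) / 2,
               (-3 * t^3 + 4 * t^2 + t) / 2,
               (t^3 - t^2) / 2)
    for (k in 0:3) {
      idx <- clampi(as.integer(i0) + k - 1L)
      M[cbind(seq_len(nOut), idx)] <- M[cbind(seq_len(nOut), idx)] + w[, k + 1]
    }
  } else stop("unsupported interpolation order: ", order)
  M
}

# Apply a matrix transform along one axis of a 3D array.
.applyAxis <- function(arr, M, axis) {
  d <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  inv <- order(perm)
  a <- aperm(arr, perm)
  da <- dim(a)
  out <- M %*% matrix(a, da[1], da[2] * da[3])
  dim(out) <- c(nrow(M), da[2], da[3])
  aperm(out, inv)
}

# Integer-voxel array shift with constant fill.
.shiftArray <- function(arr, shift, fill = 0) {
  d <- dim(arr)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    s <- shift[a]
    if (abs(s) >= d[a]) return(out)
    if (s >= 0) { dst[[a]] <- (1 + s):d[a]; src[[a]] <- 1:(d[a] - s) }
    else        { dst[[a]] <- 1:(d[a] + s); src[[a]] <- (1 - s):d[a] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# Trilinear sampling at fractional 1-based voxel coordinates (n x 3).
.sampleTrilinear <- function(arr, coords, fill = 0) {
  d <- dim(arr)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  tx <- x - x0; ty <- y - y0; tz <- z - z0
  val <- numeric(nrow(coords))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) tx else 1 - tx) * (if (dy) ty else 1 - ty) *
         (if (dz) tz else 1 - tz)
    ix <- x0 + dx; iy <- y0 + dy; iz <- z0 + dz
    ok <- ix >= 1 & ix <= d[1] & iy >= 1 & iy <= d[2] & iz >= 1 & iz <= d[3]
    v <- rep(fill, length(val))
    if (any(ok))
      v[ok] <- arr[cbind(ix[ok], iy[ok], iz[ok])]
    val <- val + w * v
  }
  val
}

# 6-connected binary dilation by r voxels (iterated unit dilation).
.dilateMask <- function(mask, r = 1L) {
  for (i in seq_len(r)) {
    m <- mask
    m <- m | .shiftArray(mask, c(1, 0, 0), FALSE)  |
             .shiftArray(mask, c(-1, 0, 0), FALSE) |
             .shiftArray(mask, c(0, 1, 0), FALSE)  |
             .shiftArray(mask, c(0, -1, 0), FALSE) |
             .shiftArray(mask, c(0, 0, 1), FALSE)  |
             .shiftArray(mask, c(0, 0, -1), FALSE)
    mask <- m
  }
  mask
}

.erodeMask <- function(mask, r = 1L) !.dilateMask(!mask, r)

# Largest-remainder apportionment of n among weights (sums to n).
.largestRemainder <- function(n, weights) {
  w <- weights / sum(weights)
  raw <- n * w
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# Mask centroid in world mm (1-based voxel indices -> mm).
.maskCentroidMm <- function(mask, spacing, origin) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no centroid")
  unname(colMeans(sweep(sweep(idx - 1, 2, spacing, "*"), 2, origin, "+")))
}

# Dice overlap of two logical masks.
.dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Gaussian 1D kernel (unit sum), sigma in voxels.
.gaussKernel <- function(sigma, truncate = 3) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(truncate * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur of a 3D array (sigma in voxels per axis),
# replicate boundaries, no value clamping.
.blur3d <- function(arr, sigmaVox) {
  d <- dim(arr)
  for (a in 1:3) {
    k <- .gaussKernel(sigmaVox[min(a, length(sigmaVox))])
    if (length(k) > 1) arr <- .applyAxis(arr, .convMatrix(d[a], k), a)
  }
  arr
}

# 1D convolution matrix (n x n) with boundary mode replicate|periodic.
.convMatrix <- function(n, kernel, mode = c("replicate", "periodic")) {
  mode <- match.arg(mode)
  r <- (length(kernel) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + (-r:r)
    idx <- if (mode == "periodic") ((idx - 1) %% n) + 1 else pmin(pmax(idx, 1), n)
    for (j in seq_along(idx))
      M[i, idx[j]] <- M[i, idx[j]] + kernel[j]
  }
  M
}
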
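## Interpolation engine.
##
## All samplers take continuous 0-based voxel coordinates (an N x 3 matrix)
## and return values with zero extension outside the grid: the fields this
## package produces vanish at the domain boundary (Dirichlet), so extending
## by zero is the consistent convention for both intensities pulled from
## outside the field of view and displacements sampled out of domain.

## mirror boundary index (reflect about edge samples), 0-based
mirror_index <- function(i, n) {
  if (n == 1L) return(rep.int(0L, length(i)))
  p <- 2L * (n - 1L)
  i <- abs(i) %% p
  ifelse(i > n - 1L, p - i, i)
}

## fraction of points strictly outside the [0, n-1] sample box
outside_mask <- function(pts, n) {
  (pts[, 1] < 0 | pts[, 1] > n[1] - 1 |
   pts[, 2] < 0 | pts[, 2] > n[2] - 1 |
   pts[, 3] < 0 | pts[, 3] > n[3] - 1)
}

## trilinear sampling of a 3D array; array treated as 0 outside
sample_trilinear <- function(arr, pts) {
  n <- dim(arr)
  i0 <- floor(pts)
  f <- pts - i0
  acc <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- i0[, 1] + dx; iy <- i0[, 2] + dy; iz <- i0[, 3] + dz
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
         (if (dy) f[, 2] else 1 - f[, 2]) *
         (if (dz) f[, 3] else 1 - f[, 3])
    ok <- ix >= 0 & ix <= n[1] - 1 & iy >= 0 & iy <= n[2] - 1 &
          iz >= 0 & iz <= n[3] - 1 & w != 0
    if (any(ok)) {
      lin <- ix[ok] + n[1] * (iy[ok] + n[2] * iz[ok]) + 1
      acc[ok] <- acc[ok] + w[ok] * arr[lin]
    }
  }
  acc
}

## trilinear sampling of an (nx,ny,nz,3) vector array -> N x 3
sample_trilinear_vec <- function(arr, pts) {
  out <- matrix(0, nrow(pts), 3)
  for (c in 1:3) out[, c] <- sample_trilinear(arr[, , , c, drop = TRUE], pts)
  out
}

## nearest neighbour with round-half-toward-lower-index tie break
sample_nearest <- function(arr, pts, outside = 0) {
  n <- dim(arr)
  idx <- ceiling(pts - 0.5)
  ok <- idx[, 1] >= 0 & idx[, 1] <= n[1] - 1 &
        idx[, 2] >= 0 & idx[, 2] <= n[2] - 1 &
        idx[, 3] >= 0 & idx[, 3] <= n[3] - 1
  out <- rep(outside, nrow(pts))
  if (any(ok)) {
    lin <- idx[ok, 1] + n[1] * (idx[ok, 2] + n[2] * idx[ok, 3]) + 1
    out[ok] <- arr[lin]
  }
  out
}

## ---- B-spline prefilter (recursive, mirror boundary) ------------------

bspline_poles <- function(order) {
  switch(as.character(order),
         "0" = numeric(0),
         "1" = numeric(0),
         "2" = sqrt(8) - 3,
         "3" = sqrt(3) - 2,
         stop("B-spline order must be 0, 1, 2 or 3", call. = FALSE))
}

## one causal+anticausal pass along the rows of an (n x m) matrix
filter_pole <- function(s, z) {
  n <- nrow(s)
  if (n == 1L) return(s)
  gain <- (1 - z) * (1 - 1 / z)
  s <- s * gain
  ## causal init for the mirror-extended signal: exact closed form when the
  ## decay horizon exceeds the signal, truncated geometric sum otherwise
  horizon <- ceiling(log(1e-15) / log(abs(z)))
  if (horizon >= n) {
    zn <- z^(n - 1)
    w <- c(1, z^seq_len(n - 2) + zn^2 / z^seq_len(n - 2), zn) /
      (1 - zn^2)
    if (n == 2L) w <- c(1, zn) / (1 - zn^2)
    s[1, ] <- drop(w %*% s)
  } else {
    zk <- z^(seq_len(horizon) - 1)
    s[1, ] <- drop(zk %*% s[seq_len(horizon), , drop = FALSE])
  }
  for (i in 2:n) s[i, ] <- s[i, ] + z * s[i - 1, ]
  ## anticausal init and pass
  s[n, ] <- (z / (z^2 - 1)) * (s[n, ] + z * s[n - 1, ])
  for (i in (n - 1):1) s[i, ] <- z * (s[i + 1, ] - s[i, ])
  s
}

## in-place prefilter of a 3D array for the given spline order
bspline_coefficients <- function(arr, order) {
  poles <- bspline_poles(order)
  if (!length(poles)) return(arr)
  d <- dim(arr)
  for (axis in 1:3) {
    perm <- c(axis, setdiff(1:3, axis))
    a <- aperm(arr, perm)
    dd <- dim(a)
    m <- matrix(a, nrow = dd[1])
    for (z in poles) m <- filter_pole(m, z)
    arr <- aperm(array(m, dd), order(perm))
  }
  arr
}

## per-axis weights and 0-based base index for spline evaluation
bspline_weights <- function(x, order) {
  if (order == 2L) {
    i <- floor(x + 0.5)
    t <- x - i
    list(base = i - 1, w = cbind(0.5 * (0.5 - t)^2,
                                 0.75 - t^2,
                                 0.5 * (0.5 + t)^2))
  } else {                      # cubic
    i <- floor(x)
    t <- x - i
    list(base = i - 1,
         w = cbind((1 - t)^3 / 6,
                   (3 * t^3 - 6 * t^2 + 4) / 6,
                   (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
                   t^3 / 6))
  }
}

## evaluate prefiltered coefficients at pts (mirror boundary for taps);
## caller zeroes out-of-domain points
bspline_eval <- function(coef, pts, order) {
  n <- dim(coef)
  wx <- bspline_weights(pts[, 1], order)
  wy <- bspline_weights(pts[, 2], order)
  wz <- bspline_weights(pts[, 3], order)
  taps <- ncol(wx$w)
  acc <- numeric(nrow(pts))
  for (dx in seq_len(taps)) {
    ix <- mirror_index(wx$base + (dx - 1), n[1])
    for (dy in seq_len(taps)) {
      iy <- mirror_index(wy$base + (dy - 1), n[2])
      wxy <- wx$w[, dx] * wy$w[, dy]
      for (dz in seq_len(taps)) {
        iz <- mirror_index(wz$base + (dz - 1), n[3])
        lin <- ix + n[1] * (iy + n[2] * iz) + 1
        acc <- acc + wxy * wz$w[, dz] * coef[lin]
      }
    }
  }
  acc
}

## unified scalar sampler: order 0 NN, 1 trilinear, 2/3 B-spline.
## `coef` may be precomputed via bspline_coefficients for orders >= 2.
sample_scalar <- function(arr, pts, order, coef = NULL) {
  out <- if (order == 0L) sample_nearest(arr, pts)
         else if (order == 1L) sample_trilinear(arr, pts)
         else {
           if (is.null(coef)) coef <- bspline_coefficients(arr, order)
           bspline_eval(coef, pts, order)
         }
  off <- outside_mask(pts, dim(arr))
  out[off] <- 0
  attr(out, "n_outside") <- sum(off)
  out
}

## 0-based voxel-centre coordinates of every voxel, N x 3, column-major order
grid_points <- function(grid) {
  n <- grid$shape
  cbind(rep.int(seq_len(n[1]) - 1L, n[2] * n[3]),
        rep.int(rep(seq_len(n[2]) - 1L, each = n[1]), n[3]),
        rep(seq_len(n[3]) - 1L, each = n[1] * n[2]))
}

## convert world-mm displacement vectors (N x 3) to voxel-index offsets
world_to_index <- function(disp, grid) {
  m <- diag(1 / grid$spacing) %*% t(grid$direction)
  disp %*% t(m)
}

index_to_world <- function(disp, grid) {
  m <- grid$direction %*% diag(grid$spacing)
  disp %*% t(m)
}
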
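#' Deformation-field calculus
#'
#' Divergence under the two discretizations used by the solver and by common
#' external morphometry tools, Jacobian determinants, composition and
#' fixed-point inversion of displacement fields.
#'
#' Two divergence stencils are provided because ground-truth volume change
#' must be measured with the same scheme as the algorithm under evaluation:
#' the solver's native face-based (6-point) stencil, and the centered
#' difference used by default in common medical-imaging toolkits.  A field
#' solved
#' with one stencil and measured with the other shows artifactual constraint
#' error where the prescribed atrophy jumps.
#'
#' @name field-calculus
NULL

## centered difference along `axis` with first-order one-sided boundaries
centered_diff <- function(arr, axis, h) {
  n <- dim(arr)[axis]
  idx_lo <- function(shift) {
    i <- pmin(pmax(seq_len(n) + shift, 1L), n)
    switch(axis, arr[i, , , drop = FALSE], arr[, i, , drop = FALSE],
           arr[, , i, drop = FALSE])
  }
  d <- (idx_lo(1L) - idx_lo(-1L))
  ## interior uses 2h; clamped boundary rows effectively use a step of h
  denom <- array(2 * h, dim = dim(arr))
  edge <- function(i) switch(axis,
                             denom[i, , ] <<- h,
                             denom[, i, ] <<- h,
                             denom[, , i] <<- h)
  edge(1L); edge(n)
  d / denom
}

#' @describeIn field-calculus Face-based (6-point) divergence of a staggered
#'   field: `(u_{i+1/2}-u_{i-1/2})/h_x + ...` per cell.
#' @param sf a [staggered_field()].
#' @return A [scalar_image()] of per-cell divergence (1/step).
#' @export
divergence_staggered <- function(sf) {
  g <- sf$grid; n <- g$shape; h <- g$spacing
  div <- (sf$u[2:(n[1] + 1L), , , drop = FALSE] -
            sf$u[1:n[1], , , drop = FALSE]) / h[1] +
         (sf$v[, 2:(n[2] + 1L), , drop = FALSE] -
            sf$v[, 1:n[2], , drop = FALSE]) / h[2] +
         (sf$w[, , 2:(n[3] + 1L), drop = FALSE] -
            sf$w[, , 1:n[3], drop = FALSE]) / h[3]
  scalar_image(array(div, dim = n), g)
}

#' @describeIn field-calculus Centered-difference divergence of a
#'   centre-sampled field: `(u_{i+1}-u_{i-1})/(2 h_x) + ...`; boundary voxels
#'   use one-sided differences.
#' @param f a [displacement_field()].
#' @export
divergence_centered <- function(f) {
  g <- grid_of(f); a <- as_array(f)
  ## displacements are world vectors; differentiate along image axes and
  ## map to world derivatives through the (orthonormal) direction matrix
  div <- 0
  for (ax in 1:3) {
    d <- vapply(1:3, function(c)
      centered_diff(a[, , , c, drop = TRUE], ax, g$spacing[ax]),
      array(0, g$shape))
    ## component of the derivative along world axis = direction column
    div <- div + array(d, c(prod(g$shape), 3)) %*% g$direction[, ax]
  }
  scalar_image(array(div, g$shape), g)
}

#' @describeIn field-calculus Jacobian determinant `det(I + grad u)` with the
#'   gradient computed by the same centered stencil as
#'   [divergence_centered()]; value is the local ratio of warped to original
#'   voxel volume, `V1/V0`.
#' @export
jacobian_determinant <- function(f) {
  g <- grid_of(f); a <- as_array(f)
  nvox <- prod(g$shape)
  ## G[, c, ax]: derivative of world component c along world axis ax
  G <- array(0, c(nvox, 3, 3))
  for (ax in 1:3) {
    d <- vapply(1:3, function(c)
      centered_diff(a[, , , c, drop = TRUE], ax, g$spacing[ax]),
      array(0, g$shape))
    d <- array(d, c(nvox, 3))
    for (wax in 1:3) G[, , wax] <- G[, , wax] + d * g$direction[wax, ax]
  }
  F11 <- 1 + G[, 1, 1]; F12 <- G[, 1, 2]; F13 <- G[, 1, 3]
  F21 <- G[, 2, 1]; F22 <- 1 + G[, 2, 2]; F23 <- G[, 2, 3]
  F31 <- G[, 3, 1]; F32 <- G[, 3, 2]; F33 <- 1 + G[, 3, 3]
  J <- F11 * (F22 * F33 - F23 * F32) -
       F12 * (F21 * F33 - F23 * F31) +
       F13 * (F21 * F32 - F22 * F31)
  scalar_image(array(J, g$shape), g)
}

#' @describeIn field-calculus Composition `Phi_outer o Phi_inner` of two
#'   displacement fields on one grid:
#'   `u(x) = u_outer(x + u_inner(x)) + u_inner(x)`, with the outer field
#'   sampled by trilinear interpolation and zero extension outside the
#'   domain (fields vanish at the boundary by construction).  The number of
#'   out-of-domain samples is recorded in the `"n_outside"` attribute.
#' @param outer,inner [displacement_field()] objects on the same grid.
#' @export
compose_fields <- function(outer, inner) {
  assert_same_space(outer, inner)
  g <- grid_of(inner)
  ui <- matrix(as_array(inner), ncol = 3)
  pts <- grid_points(g) + world_to_index(ui, g)
  uo <- sample_trilinear_vec(as_array(outer), pts)
  n_out <- sum(outside_mask(pts, g$shape))
  log_note("compose_fields: ", n_out, " out-of-domain samples (zero extension)")
  out <- displacement_field(array(uo + ui, c(g$shape, 3)), g)
  attr(out, "n_outside") <- n_out
  out
}

#' @describeIn field-calculus Fixed-point inversion: iterates
#'   `v_{n+1}(y) = -u(y + v_n(y))` from `v_0 = 0` until the largest update is
#'   below `tol` (mm), returning `v` with `Phi^{-1}(y) = y + v(y)`.  Requires
#'   a contractive field (`|grad u| < 1`), which holds for the small-step
#'   deformations this model produces.
#' @param tol convergence tolerance in mm; default `1e-3 * min(spacing)`.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   achieved update norm.
#' @export
invert_field <- function(f, tol = NULL, max_iter = 100L) {
  g <- grid_of(f)
  if (is.null(tol)) tol <- 1e-3 * min(g$spacing)
  u <- as_array(f)
  P <- grid_points(g)
  v <- matrix(0, nrow(P), 3)
  delta <- Inf
  for (it in seq_len(max_iter)) {
    pts <- P + world_to_index(v, g)
    vn <- -sample_trilinear_vec(u, pts)
    delta <- sqrt(max(rowSums((vn - v)^2)))
    v <- vn
    if (delta < tol) {
      out <- displacement_field(array(v, c(g$shape, 3)), g)
      attr(out, "iterations") <- it
      return(out)
    }
  }
  stop(sprintf(
    "invert_field did not converge in %d iterations (last update %.3g mm, tol %.3g mm)",
    max_iter, delta, tol), call. = FALSE)
}

log_note <- function(...) {
  if (isTRUE(getOption("atrophysim.verbose", FALSE)))
    message("[atrophysim] ", ...)
  invisible(NULL)
}
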
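#' Model parameters for the brain-deformation solver
#'
#' The deformation obeys a creep-flow (Stokes-like) system driven by the
#' prescribed atrophy `a`: in freely-compensating tissue (label 1)
#' `mu Lap(u) - grad p = 0` with relaxed incompressibility
#' `div u + k p = 0`; in prescribed tissue (label 2)
#' `mu Lap(u) - grad p = (mu + lam) grad a` with the hard constraint
#' `div u = -a`; rigid regions (label 0) carry zero displacement (Dirichlet).
#'
#' @param mu shear-like coefficient, kPa (> 0).  Default 1.
#' @param lam second elastic coefficient, kPa (>= 0).  Default 0.
#' @param k compressibility coefficient of the label-1 regime, 1/kPa (> 0).
#'   Default 1.  Solutions for `u` are invariant under
#'   `(mu, lam, k) -> (c mu, c lam, k/c)`; only pressure rescales.
#' @param scheme divergence stencil used inside the solver: `"six_point"`
#'   (native face-based MAC stencil) or `"twelve_point"` (centered difference
#'   of face-averaged values, consistent with external centered-difference
#'   divergence and Jacobian computations).
#' @param solver_tol maximum acceptable relative residual of the linear
#'   solve.
#' @param max_iter iteration cap for the iterative backend.
#' @param backend `"auto"` (default) picks `"direct"` below ~8000 unknowns
#'   and `"schur_gmres"` above; `"direct"` is a sparse LU (deterministic,
#'   but fill-in makes it impractical beyond ~16^3 domains);
#'   `"schur_gmres"` is GMRES on the full saddle-point system with a block
#'   upper-triangular preconditioner (Cholesky-factored face Laplacian plus
#'   a diagonal Schur-complement approximation) and converges in tens of
#'   iterations for either stencil.
#' @param pressure_reg tiny diagonal regularization added to the mass rows of
#'   label-2 components that have no path to a label-1 cell (which would
#'   otherwise make the system singular); applied with a warning.
#' @return An object of class `model_params`.
#' @export
model_params <- function(mu = 1, lam = 0, k = 1,
                         scheme = c("six_point", "twelve_point"),
                         solver_tol = 1e-9, max_iter = 2000L,
                         backend = c("auto", "direct", "schur_gmres"),
                         pressure_reg = 1e-8) {
  scheme <- match.arg(scheme)
  backend <- match.arg(backend)
  if (!is.finite(mu) || mu <= 0) stop("mu must be > 0", call. = FALSE)
  if (!is.finite(k) || k <= 0) stop("k must be > 0", call. = FALSE)
  if (!is.finite(lam) || lam < 0) stop("lam must be >= 0", call. = FALSE)
  structure(list(mu = mu, lam = lam, k = k, scheme = scheme,
                 solver_tol = solver_tol, max_iter = as.integer(max_iter),
                 backend = backend, pressure_reg = pressure_reg),
            class = "model_params")
}

## shift a 3D array by integer offset along one axis, zero-padded:
## result[i] = A[i + off] (0 outside)
shift_axis <- function(A, axis, off) {
  if (off == 0L) return(A)
  d <- dim(A)
  out <- array(if (is.integer(A)) 0L else 0, d)
  n <- d[axis]
  src <- (1:n) + off
  ok <- src >= 1L & src <= n
  if (!any(ok)) return(out)
  dst <- (1:n)[ok]; src <- src[ok]
  switch(axis,
         out[dst, , ] <- A[src, , ],
         out[, dst, ] <- A[, src, ],
         out[, , dst] <- A[, , src])
  out
}

## value of a face-lattice array at cell positions shifted by `off` along the
## face's own axis: face index fi = cell index + off (0 if out of lattice)
face_at <- function(F, axis, off) {
  d <- dim(F)
  n <- d; n[axis] <- n[axis] - 1L          # cell shape
  out <- array(if (is.integer(F)) 0L else 0, n)
  src <- (1:n[axis]) + off
  ok <- src >= 1L & src <= d[axis]
  dst <- (1:n[axis])[ok]; src <- src[ok]
  switch(axis,
         out[dst, , ] <- F[src, , ],
         out[, dst, ] <- F[, src, ],
         out[, , dst] <- F[, , src])
  out
}

## label-2 cells in connected components (6-connectivity over labels > 0)
## that contain no label-1 cell
isolated_label2 <- function(L) {
  fluid <- L > 0L
  reached <- L == 1L
  repeat {
    grown <- reached
    for (ax in 1:3) for (s in c(-1L, 1L))
      grown <- grown | shift_axis(reached, ax, s)
    grown <- grown & fluid
    if (identical(grown, reached)) break
    reached <- grown
  }
  (L == 2L) & !reached
}

#' Assemble the three-regime linear system
#'
#' Unknowns are the interior face velocities (faces whose two adjacent cells
#' both have label > 0) and the cell pressures of all label-1/label-2 cells;
#' label-0 faces and boundary faces are eliminated at zero.  Ordering: x-face
#' unknowns, then y, then z (each in column-major grid order), then pressures
#' in column-major cell order.
#'
#' @param labels a [label_image()].
#' @param a an [atrophy_map()] on the same grid; must vanish outside label 2.
#' @param params a [model_params()].
#' @return A list of class `atrophy_system`: sparse matrix `A`, right-hand
#'   side `b`, unknown counts and face/pressure index maps.
#' @export
assemble_system <- function(labels, a, params = model_params()) {
  assert_same_space(labels, a)
  check_compensation(labels, a)
  L <- label_values(labels)
  av <- as_array(a)
  if (any(av != 0 & L != 2L))
    stop(paste("atrophy is prescribed on label-0/label-1 voxels;",
               "the constraint div u = -a can only be honored on label 2"),
         call. = FALSE)
  g <- grid_of(labels); n <- g$shape; h <- g$spacing
  mu <- params$mu; lam <- params$lam; kk <- params$k

  ## face unknown index maps, one lattice per component
  face_dim <- function(ax) { d <- n; d[ax] <- d[ax] + 1L; d }
  idx <- vector("list", 3)
  nU <- integer(3)
  offset <- 0L
  for (ax in 1:3) {
    interior <- shift_axis(L > 0L, ax, -1L) & (L > 0L)  # both cells > 0
    m <- array(FALSE, face_dim(ax))
    ## face fi (2..n) lies between cells fi-1 and fi
    switch(ax,
           m[2:n[1], , ] <- interior[2:n[1], , ],
           m[, 2:n[2], ] <- interior[, 2:n[2], ],
           m[, , 2:n[3]] <- interior[, , 2:n[3]])
    id <- array(0L, face_dim(ax))
    id[m] <- offset + seq_len(sum(m))
    nU[ax] <- sum(m)
    offset <- offset + nU[ax]
    idx[[ax]] <- id
  }
  nF <- offset
  cellmask <- L > 0L
  idxP <- array(0L, n)
  idxP[cellmask] <- nF + seq_len(sum(cellmask))
  nP <- sum(cellmask)
  N <- nF + nP
  b <- numeric(N)
  ti <- tj <- tx <- vector("list", 64L); nt <- 0L
  push <- function(i, j, x) {
    keep <- j > 0L
    nt <<- nt + 1L
    ti[[nt]] <<- i[keep]; tj[[nt]] <<- j[keep]
    tx[[nt]] <<- if (length(x) == 1L) rep(x, sum(keep)) else x[keep]
  }

  if (N > 0L) {
    ## momentum rows at unknown faces
    for (ax in 1:3) {
      if (nU[ax] == 0L) next
      id <- idx[[ax]]
      mask <- id > 0L
      rows <- id[mask]
      push(rows, rows, -2 * mu * sum(1 / h^2))
      for (nax in 1:3) for (s in c(-1L, 1L)) {
        nb <- shift_axis(id, nax, s)
        push(rows, nb[mask], mu / h[nax]^2)
      }
      ## pressure gradient and atrophy forcing at the face: cell fi is the
      ## "+" side, cell fi-1 the "-" side along the face's own axis
      pplus <- face_at_pad(idxP, ax)          # cell value at face positions
      pminus <- shift_axis(pplus, ax, -1L)
      push(rows, pplus[mask], -1 / h[ax])
      push(rows, pminus[mask], 1 / h[ax])
      aplus <- face_at_pad(av, ax)
      aminus <- shift_axis(aplus, ax, -1L)
      b[rows] <- (mu + lam) * (aplus[mask] - aminus[mask]) / h[ax]
    }

    ## mass (divergence-constraint) rows at fluid cells
    prow <- idxP[cellmask]
    for (ax in 1:3) {
      id <- idx[[ax]]
      if (params$scheme == "six_point") {
        push(prow, face_at(id, ax, 1L)[cellmask],  1 / h[ax])
        push(prow, face_at(id, ax, 0L)[cellmask], -1 / h[ax])
      } else {
        push(prow, face_at(id, ax, 2L)[cellmask],  1 / (4 * h[ax]))
        push(prow, face_at(id, ax, 1L)[cellmask],  1 / (4 * h[ax]))
        push(prow, face_at(id, ax, 0L)[cellmask], -1 / (4 * h[ax]))
        push(prow, face_at(id, ax, -1L)[cellmask], -1 / (4 * h[ax]))
      }
    }
    lab1 <- (L == 1L)[cellmask]
    if (any(lab1)) push(prow[lab1], prow[lab1], kk)
    b[prow] <- ifelse((L == 2L)[cellmask], -av[cellmask], 0)

    iso <- isolated_label2(L)
    if (any(iso & av != 0)) {
      warning(sum(iso), " label-2 voxels have no path to a label-1 cell; ",
              "adding pressure regularization ", params$pressure_reg,
              " to their mass rows", call. = FALSE)
      r <- idxP[iso]
      push(r, r, params$pressure_reg)
    }
  }

  A <- if (nt == 0L) {
    methods::as(Matrix::Matrix(0, N, N, sparse = TRUE), "generalMatrix")
  } else {
    Matrix::sparseMatrix(
      i = unlist(ti[seq_len(nt)]), j = unlist(tj[seq_len(nt)]),
      x = unlist(tx[seq_len(nt)]), dims = c(N, N))
  }
  structure(list(A = A, b = b, n_face = nU, n_face_total = nF,
                 n_pressure = nP, face_index = idx, pressure_index = idxP,
                 grid = g, labels = L, atrophy = av, params = params),
            class = "atrophy_system")
}

## cell-centred array placed on the face lattice of `ax`: face fi takes the
## value of cell fi (0 for the fi = n+1 boundary face)
face_at_pad <- function(C, ax) {
  d <- dim(C); d[ax] <- d[ax] + 1L
  out <- array(if (is.integer(C)) 0L else 0, d)
  n <- dim(C)[ax]
  switch(ax,
         out[1:n, , ] <- C,
         out[, 1:n, ] <- C,
         out[, , 1:n] <- C)
  out
}

#' @export
print.atrophy_system <- function(x, ...) {
  cat("atrophy_system:", x$n_face_total, "face unknowns +", x$n_pressure,
      "pressures,", length(x$A@x), "nonzeros,", x$params$scheme,
      "divergence stencil\n")
  invisible(x)
}

#' Solve the brain-deformation model
#'
#' Assembles and solves the three-regime system, returning the displacement
#' interpolated to voxel centres, the pressure field, the internal staggered
#' solution, and diagnostics (relative residual, iterations, and the maximum
#' violation of the divergence constraint over label-2 voxels under the
#' solver's own stencil).
#'
#' @inheritParams assemble_system
#' @param system optionally a pre-assembled [assemble_system()] result.
#' @return An object of class `atrophy_fit` with elements `field`
#'   ([displacement_field()]), `pressure` ([scalar_image()], zero on label 0),
#'   `staggered` ([staggered_field()]) and `diagnostics`.
#' @examples
#' ph <- make_phantom(phantom_spec(shape = c(12, 12, 12),
#'                                 radii = c(5.5, 5, 4, 1.5), noise_sd = 0))
#' a <- uniform_atrophy(ph$labels, 0.05)
#' fit <- solve_deformation(ph$labels, a)
#' fit$diagnostics$max_constraint_violation
#' @export
solve_deformation <- function(labels, a, params = model_params(),
                              system = NULL) {
  if (is.null(system)) system <- assemble_system(labels, a, params)
  params <- system$params
  g <- system$grid; n <- g$shape
  N <- length(system$b)
  if (N == 0L) {
    sf <- zero_staggered(g)
    return(new_fit(sf, scalar_image(array(0, n), g), system,
                   list(residual = 0, iterations = 0L, backend = "none")))
  }
  backend <- params$backend
  if (backend == "auto")
    backend <- if (N <= 8000L) "direct" else "schur_gmres"
  if (backend == "direct") {
    x <- tryCatch(as.numeric(Matrix::solve(system$A, system$b)),
                  error = function(e)
                    stop("sparse direct solve failed (singular system?): ",
                         conditionMessage(e), call. = FALSE))
    iterations <- 1L
  } else {
    sol <- schur_gmres_solve(system, rtol = params$solver_tol,
                             max_iter = params$max_iter)
    x <- sol$x
    iterations <- sol$iterations
  }
  bn <- sqrt(sum(system$b^2))
  residual <- if (bn == 0) 0 else
    sqrt(sum((as.numeric(system$A %*% x) - system$b)^2)) / bn
  if (residual > params$solver_tol)
    stop(sprintf("solver did not reach tolerance: relative residual %.3g > %.3g",
                 residual, params$solver_tol), call. = FALSE)
  sf <- zero_staggered(g)
  solve_backend <- backend
  for (ax in 1:3) {
    id <- system$face_index[[ax]]
    m <- id > 0L
    comp <- c("u", "v", "w")[ax]
    arr <- sf[[comp]]
    arr[m] <- x[id[m]]
    sf[[comp]] <- arr
  }
  p <- array(0, n)
  pm <- system$pressure_index > 0L
  p[pm] <- x[system$pressure_index[pm]]
  new_fit(sf, scalar_image(p, g), system,
          list(residual = residual, iterations = iterations,
               backend = solve_backend))
}

zero_staggered <- function(g) {
  n <- g$shape
  staggered_field(array(0, c(n[1] + 1L, n[2], n[3])),
                  array(0, c(n[1], n[2] + 1L, n[3])),
                  array(0, c(n[1], n[2], n[3] + 1L)), g)
}

new_fit <- function(sf, pressure, system, solve_info) {
  g <- system$grid
  field <- face_to_center(sf)
  div <- if (system$params$scheme == "six_point") divergence_staggered(sf)
         else divergence_twelve_point(sf)
  lab2 <- system$labels == 2L
  viol <- if (any(lab2))
    max(abs(as_array(div)[lab2] + system$atrophy[lab2])) else 0
  diagnostics <- c(solve_info,
                   list(max_constraint_violation = viol,
                        mean_constraint_violation = if (any(lab2))
                          mean(abs(as_array(div)[lab2] +
                                     system$atrophy[lab2])) else 0,
                        n_unknowns = length(system$b),
                        scheme = system$params$scheme))
  structure(list(field = field, pressure = pressure, staggered = sf,
                 diagnostics = diagnostics, params = system$params),
            class = "atrophy_fit")
}

#' @export
print.atrophy_fit <- function(x, ...) {
  d <- x$diagnostics
  cat("atrophy_fit (", d$scheme, ", ", d$backend, "): ", d$n_unknowns,
      " unknowns\n  relative residual ", signif(d$residual, 3),
      ", max |div u + a| over label 2 = ",
      signif(d$max_constraint_violation, 3), "\n",
      "  max |u| = ", signif(max(abs(as_array(x$field))), 4), " mm\n",
      sep = "")
  invisible(x)
}

#' Interpolate a staggered solution to voxel centres
#'
#' Each centre component is the mean of its two bounding face values,
#' e.g. `u_{i,j,k} = (u_{i+1/2} + u_{i-1/2}) / 2`; exact for fields linear
#' along the face axis.
#'
#' @param sf a [staggered_field()].
#' @return A [displacement_field()].
#' @export
face_to_center <- function(sf) {
  n <- sf$grid$shape
  out <- array(0, c(n, 3L))
  out[, , , 1] <- (sf$u[1:n[1], , ] + sf$u[2:(n[1] + 1L), , ]) / 2
  out[, , , 2] <- (sf$v[, 1:n[2], ] + sf$v[, 2:(n[2] + 1L), ]) / 2
  out[, , , 3] <- (sf$w[, , 1:n[3]] + sf$w[, , 2:(n[3] + 1L)]) / 2
  displacement_field(out, sf$grid)
}

## 12-point divergence evaluated directly on the faces: the centered
## difference of face-averaged values,
## (u_{i+3/2} + u_{i+1/2} - u_{i-1/2} - u_{i-3/2}) / (4 h_x) + ...
divergence_twelve_point <- function(sf) {
  g <- sf$grid; h <- g$spacing
  div <- 0
  comps <- list(sf$u, sf$v, sf$w)
  for (ax in 1:3) {
    F <- comps[[ax]]
    div <- div + (face_at(F, ax, 2L) + face_at(F, ax, 1L) -
                    face_at(F, ax, 0L) - face_at(F, ax, -1L)) / (4 * h[ax])
  }
  scalar_image(div, g)
}

## Right-preconditioned restarted GMRES on the full saddle-point system.
## Preconditioner: block upper-triangular
##   P = [ -K  -G ; 0  -S_hat ]
## with K the (SPD) mu-scaled face Laplacian factored once by sparse
## Cholesky and S_hat a diagonal Schur-complement approximation
## (k on label-1 rows plus the 1/mu pressure-mass scale).  For the creep-flow
## operator this clusters the spectrum so that a few tens of iterations reach
## direct-solve accuracy, for either divergence stencil.
schur_gmres_solve <- function(system, rtol, max_iter, restart = 200L) {
  A <- system$A
  b <- system$b
  nF <- system$n_face_total
  N <- length(b)
  mu <- system$params$mu
  kk <- system$params$k
  pidx <- if (nF < N) (nF + 1L):N else integer(0)
  ch <- if (nF > 0L)
    Matrix::Cholesky(Matrix::forceSymmetric(-A[1:nF, 1:nF, drop = FALSE]),
                     LDL = FALSE, perm = TRUE) else NULL
  lab1 <- (system$labels == 1L)[system$labels > 0L]
  s_hat <- 1 / mu + ifelse(lab1, kk, 0)
  A12 <- if (nF > 0L && length(pidx))
    A[1:nF, pidx, drop = FALSE] else NULL
  Pinv <- function(r) {
    zp <- if (length(pidx)) -r[pidx] / s_hat else numeric(0)
    z <- numeric(N)
    if (nF > 0L) {
      ru <- r[1:nF]
      if (!is.null(A12) && length(zp)) ru <- ru - as.numeric(A12 %*% zp)
      z[1:nF] <- -as.numeric(Matrix::solve(ch, ru))
    }
    if (length(pidx)) z[pidx] <- zp
    z
  }
  bn <- sqrt(sum(b^2))
  x <- numeric(N)
  total_it <- 0L
  repeat {
    r <- b - as.numeric(A %*% x)
    beta <- sqrt(sum(r^2))
    if (beta / bn < rtol) return(list(x = x, iterations = total_it))
    m <- min(restart, max_iter - total_it)
    if (m <= 0L) break
    V <- matrix(0, N, m + 1L)
    H <- matrix(0, m + 1L, m)
    V[, 1] <- r / beta
    g <- c(beta, numeric(m))
    cs <- sn <- numeric(m)
    j_used <- 0L
    for (j in seq_len(m)) {
      w <- as.numeric(A %*% Pinv(V[, j]))
      for (i in seq_len(j)) {
        H[i, j] <- sum(w * V[, i])
        w <- w - H[i, j] * V[, i]
      }
      H[j + 1L, j] <- sqrt(sum(w^2))
      if (H[j + 1L, j] > 0) V[, j + 1L] <- w / H[j + 1L, j]
      for (i in seq_len(j - 1L)) {
        t <- cs[i] * H[i, j] + sn[i] * H[i + 1L, j]
        H[i + 1L, j] <- -sn[i] * H[i, j] + cs[i] * H[i + 1L, j]
        H[i, j] <- t
      }
      d <- sqrt(H[j, j]^2 + H[j + 1L, j]^2)
      cs[j] <- H[j, j] / d; sn[j] <- H[j + 1L, j] / d
      H[j, j] <- d; H[j + 1L, j] <- 0
      g[j + 1L] <- -sn[j] * g[j]; g[j] <- cs[j] * g[j]
      j_used <- j
      if (abs(g[j + 1L]) / bn < rtol * 0.1) break
    }
    y <- backsolve(H[1:j_used, 1:j_used, drop = FALSE], g[1:j_used])
    x <- x + Pinv(as.numeric(V[, 1:j_used, drop = FALSE] %*% y))
    total_it <- total_it + j_used
    if (total_it >= max_iter) break
  }
  res <- sqrt(sum((as.numeric(A %*% x) - b)^2)) / bn
  if (res < rtol) return(list(x = x, iterations = total_it))
  stop(sprintf(
    "schur_gmres did not converge in %d iterations (relative residual %.3g)",
    total_it, res), call. = FALSE)
}
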
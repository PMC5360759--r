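test_that("staggered divergence matches a brute-force triple loop", {
  g <- image_grid(c(6, 5, 4), spacing = c(1, 1.2, 0.8))
  sf <- rand_staggered(g, seed = 2L)
  div <- as_array(divergence_staggered(sf))
  n <- g$shape; h <- g$spacing
  bf <- array(0, n)
  for (i in 1:n[1]) for (j in 1:n[2]) for (k in 1:n[3])
    bf[i, j, k] <- (sf$u[i + 1, j, k] - sf$u[i, j, k]) / h[1] +
                   (sf$v[i, j + 1, k] - sf$v[i, j, k]) / h[2] +
                   (sf$w[i, j, k + 1] - sf$w[i, j, k]) / h[3]
  expect_identical(div, bf)
  ## linear faces: u_{i+1/2} = c (i + 1/2) h has divergence exactly c
  cl <- 0.7
  sfl <- atrophysim:::zero_staggered(g)
  sfl$u <- array(rep(cl * (seq_len(n[1] + 1) - 0.5) * h[1], n[2] * n[3]),
                 dim(sfl$u))
  expect_equal(max(abs(as_array(divergence_staggered(sfl)) - cl)), 0,
               tolerance = 1e-12)
  ## zero field
  expect_true(all(as_array(divergence_staggered(
    atrophysim:::zero_staggered(g))) == 0))
})

test_that("centered divergence of the centered field equals the 12-point stencil", {
  g <- image_grid(c(7, 6, 5), spacing = c(1, 1.3, 0.9))
  sf <- rand_staggered(g, seed = 3L)
  ctr <- face_to_center(sf)
  dc <- as_array(divergence_centered(ctr))
  ## brute-force 12-point formula on the faces, interior cells
  n <- g$shape; h <- g$spacing
  for (i in 2:(n[1] - 1)) for (j in 2:(n[2] - 1)) for (k in 2:(n[3] - 1)) {
    d12 <- (sf$u[i + 2, j, k] + sf$u[i + 1, j, k] -
              sf$u[i, j, k] - sf$u[i - 1, j, k]) / (4 * h[1]) +
           (sf$v[i, j + 2, k] + sf$v[i, j + 1, k] -
              sf$v[i, j, k] - sf$v[i, j - 1, k]) / (4 * h[2]) +
           (sf$w[i, j, k + 2] + sf$w[i, j, k + 1] -
              sf$w[i, j, k] - sf$w[i, j, k - 1]) / (4 * h[3])
    expect_equal(dc[i, j, k], d12, tolerance = 1e-14)
  }
})

test_that("both divergence stencils converge at second order on smooth fields", {
  ## fixed physical wavelength, refined spacing: classical h-refinement
  wave <- 2 * pi / 10
  err_at <- function(n) {
    h <- 10 / (n - 1)
    g <- image_grid(rep(n, 3L), spacing = rep(h, 3))
    P <- atrophysim:::grid_points(g) * h        # physical coordinates
    u <- cbind(sin(wave * P[, 1]), sin(wave * P[, 2]), sin(wave * P[, 3]))
    f <- displacement_field(array(u, c(g$shape, 3L)), g)
    exact <- array(wave * (cos(wave * P[, 1]) + cos(wave * P[, 2]) +
                             cos(wave * P[, 3])), g$shape)
    interior <- erode_mask(array(TRUE, g$shape), 1L)
    e_c <- max(abs(as_array(divergence_centered(f)) - exact)[interior])
    sf <- atrophysim:::zero_staggered(g)
    fx <- (seq_len(n + 1L) - 1.5) * h           # physical face positions
    sf$u <- array(sin(wave * fx), dim(sf$u))
    sf$v <- aperm(array(sin(wave * fx), c(n + 1L, n, n)), c(2, 1, 3))
    sf$w <- aperm(array(sin(wave * fx), c(n + 1L, n, n)), c(2, 3, 1))
    e_s <- max(abs(as_array(divergence_staggered(sf)) - exact)[interior])
    c(centered = e_c, staggered = e_s)
  }
  e1 <- err_at(12L); e2 <- err_at(23L)          # h ratio = 2
  order_c <- log2(e1["centered"] / e2["centered"])
  order_s <- log2(e1["staggered"] / e2["staggered"])
  expect_gte(order_c, 1.9)
  expect_gte(order_s, 1.9)
})

test_that("Jacobian determinants recover identity and uniform scalings", {
  g <- image_grid(c(10, 10, 10))
  z <- displacement_field(array(0, c(g$shape, 3L)), g)
  expect_equal(max(abs(as_array(jacobian_determinant(z)) - 1)), 0)
  s <- 0.04
  P <- atrophysim:::grid_points(g)
  u <- array(s * (P - 4.5), c(g$shape, 3L))
  J <- as_array(jacobian_determinant(displacement_field(u, g)))
  interior <- erode_mask(array(TRUE, g$shape), 1L)
  expect_equal(max(abs(J[interior] - (1 + s)^3)), 0, tolerance = 1e-12)
})

test_that("J - 1 matches -a to first order for scheme-matched solves", {
  ph <- make_phantom(small_spec())
  amax <- 0.02
  a <- uniform_atrophy(ph$labels, amax)
  fit <- solve_deformation(ph$labels, a,
                           model_params(scheme = "twelve_point"))
  J <- as_array(jacobian_determinant(fit$field))
  interior <- erode_mask(atrophysim:::label_values(ph$labels) == 2L, 2L)
  expect_lt(max(abs((J - 1) + as_array(a))[interior]), 2 * amax^2)
})

test_that("composition obeys the translation group and identity laws", {
  g <- image_grid(c(10, 9, 8))
  const_field <- function(t) displacement_field(
    array(rep(t, each = prod(g$shape)), c(g$shape, 3L)), g)
  f <- smooth_field(g, amp = 0.4)
  z <- const_field(c(0, 0, 0))
  expect_equal(as_array(compose_fields(f, z)), as_array(f),
               ignore_attr = TRUE)
  t1 <- c(0.4, -0.2, 0.1); t2 <- c(-0.1, 0.3, 0.2)
  comp <- compose_fields(const_field(t1), const_field(t2))
  interior <- erode_mask(array(TRUE, g$shape), 1L)
  u <- as_array(comp)
  for (c in 1:3)
    expect_equal(max(abs(u[, , , c][interior] - (t1[c] + t2[c]))), 0,
                 tolerance = 1e-12)
  ## associativity on translations
  t3 <- c(0.2, 0.1, -0.3)
  lhs <- compose_fields(compose_fields(const_field(t1), const_field(t2)),
                        const_field(t3))
  rhs <- compose_fields(const_field(t1),
                        compose_fields(const_field(t2), const_field(t3)))
  inner2 <- erode_mask(array(TRUE, g$shape), 2L)
  expect_equal(max(abs((as_array(lhs) - as_array(rhs))[rep(inner2, 3)])), 0,
               tolerance = 1e-12)
})

test_that("fixed-point inversion round-trips and is an involution", {
  g <- image_grid(c(12, 12, 12))
  ## closed forms first
  z <- displacement_field(array(0, c(g$shape, 3L)), g)
  expect_equal(as_array(invert_field(z)), as_array(z), ignore_attr = TRUE)
  t1 <- c(0.6, -0.3, 0.2)
  tf <- displacement_field(array(rep(t1, each = prod(g$shape)),
                                 c(g$shape, 3L)), g)
  ti <- as_array(invert_field(tf))
  interior <- erode_mask(array(TRUE, g$shape), 2L)
  for (c in 1:3)
    expect_lt(max(abs(ti[, , , c][interior] + t1[c])), 1e-3)
  ## smooth small field round trip
  g16 <- image_grid(c(16, 16, 16))
  f <- smooth_field(g16, amp = 0.25)
  tol <- 1e-3 * min(g16$spacing)
  fi <- invert_field(f, tol = tol)
  rt <- compose_fields(f, fi)
  expect_lt(max(abs(as_array(rt))), 10 * tol)
  ## approximate involution (limited by trilinear field sampling)
  f2 <- invert_field(fi, tol = tol)
  int16 <- erode_mask(array(TRUE, g16$shape), 2L)
  expect_lt(max(abs(as_array(f2) - as_array(f))[rep(int16, 3)]), 20 * tol)
  ## non-convergence errors carry the achieved update
  big <- displacement_field(array(as_array(f) * 40, c(g$shape, 3L)), g)
  expect_error(invert_field(big, max_iter = 3L), "did not converge")
})
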
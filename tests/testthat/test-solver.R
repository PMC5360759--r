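test_that("degenerate regimes assemble as expected", {
  ## all label 0: empty system
  g <- image_grid(c(4, 4, 4))
  L0 <- label_image(array(0L, c(4, 4, 4)), g)
  a0 <- atrophy_map(array(0, c(4, 4, 4)), g)
  sys <- assemble_system(L0, a0)
  expect_equal(length(sys$b), 0L)
  fit <- solve_deformation(L0, a0)
  expect_equal(max(abs(as_array(fit$field))), 0)

  ## pressure unknowns = number of label-1 + label-2 voxels
  bp <- box_phantom(8L)
  sys <- assemble_system(bp$labels, bp$a)
  expect_equal(sys$n_pressure,
               sum(atrophysim:::label_values(bp$labels) > 0L))

  ## atrophy on a non-prescribed voxel is a hard error
  av <- as_array(bp$a); av[2, 2, 2] <- 0.1   # a label-1 voxel
  expect_error(assemble_system(bp$labels, atrophy_map(av, bp$grid)),
               "label-0/label-1")
})

test_that("zero atrophy gives the zero solution", {
  bp <- box_phantom(8L, a_value = 0)
  fit <- solve_deformation(bp$labels, bp$a)
  expect_equal(max(abs(as_array(fit$field))), 0)
  expect_equal(max(abs(as_array(fit$pressure))), 0)
})

test_that("label-0 voxels carry exactly zero displacement", {
  ph <- make_phantom(small_spec())
  a <- uniform_atrophy(ph$labels, 0.05)
  fit <- solve_deformation(ph$labels, a)
  lab0 <- atrophysim:::label_values(ph$labels) == 0L
  expect_identical(max_disp_on(fit$field, lab0), 0)
})

test_that("production solve agrees with a dense direct factorization", {
  bp <- box_phantom(8L)
  sys <- assemble_system(bp$labels, bp$a)
  x_dense <- solve(as.matrix(sys$A), sys$b)
  fit <- solve_deformation(bp$labels, bp$a, system = sys)
  ## reconstruct the staggered solution from the dense vector
  sf <- atrophysim:::zero_staggered(bp$grid)
  for (ax in 1:3) {
    id <- sys$face_index[[ax]]
    comp <- c("u", "v", "w")[ax]
    arr <- sf[[comp]]; arr[id > 0L] <- x_dense[id[id > 0L]]
    sf[[comp]] <- arr
  }
  dense_field <- face_to_center(sf)
  scale <- max(abs(as_array(dense_field)))
  expect_lt(max(abs(as_array(fit$field) - as_array(dense_field))) / scale,
            1e-8)
})

test_that("the iterative backend matches the direct solve for both stencils", {
  ph <- make_phantom(small_spec())
  a <- uniform_atrophy(ph$labels, 0.05)
  for (sch in c("six_point", "twelve_point")) {
    ref <- solve_deformation(ph$labels, a,
                             model_params(scheme = sch, backend = "direct"))
    fit <- solve_deformation(ph$labels, a,
                             model_params(scheme = sch,
                                          backend = "schur_gmres"))
    expect_lt(max(abs(as_array(fit$field) - as_array(ref$field))) /
                max(abs(as_array(ref$field))), 1e-6)
  }
})

test_that("solutions are invariant under (mu,lam,k) -> (c mu, c lam, k/c)", {
  bp <- box_phantom(8L)
  base <- solve_deformation(bp$labels, bp$a, model_params(mu = 1, lam = 0.5,
                                                          k = 1))
  scaled <- solve_deformation(bp$labels, bp$a,
                              model_params(mu = 10, lam = 5, k = 0.1))
  rel <- max(abs(as_array(scaled$field) - as_array(base$field))) /
    max(abs(as_array(base$field)))
  expect_lt(rel, 1e-8)
  prel <- max(abs(as_array(scaled$pressure) - 10 * as_array(base$pressure))) /
    max(abs(10 * as_array(base$pressure)))
  expect_lt(prel, 1e-8)
})

test_that("the solution is linear in the prescribed atrophy", {
  ph <- make_phantom(small_spec())
  lv <- atrophysim:::label_values(ph$labels)
  rv <- atrophysim:::label_values(ph$rois)
  a1 <- uniform_atrophy(ph$labels, 0.02)
  av2 <- array(0, dim(lv)); av2[rv == 17L & lv == 2L] <- 0.05
  a2 <- atrophy_map(av2, grid_of(ph$labels))
  asum <- atrophy_map(as_array(a1) + as_array(a2), grid_of(ph$labels))
  f1 <- solve_deformation(ph$labels, a1)
  f2 <- solve_deformation(ph$labels, a2)
  fs <- solve_deformation(ph$labels, asum)
  err <- max(abs(as_array(fs$field) -
                   (as_array(f1$field) + as_array(f2$field))))
  expect_lt(err / max(abs(as_array(fs$field))), 1e-8)
})

test_that("prescribed shrinkage pulls the surrounding tissue inward", {
  ph <- make_phantom(small_spec())
  a <- uniform_atrophy(ph$labels, 0.05)
  fit <- solve_deformation(ph$labels, a)
  g <- grid_of(ph$labels)
  lv <- atrophysim:::label_values(ph$labels)
  shell <- (lv == 2L) & !erode_mask(lv == 2L, 1L)   # boundary shell of the ball
  ctr <- (g$shape - 1) * g$spacing / 2
  P <- atrophysim:::grid_points(g)
  radial <- sweep(sweep(P, 2, ctr), 1,
                  sqrt(rowSums(sweep(P, 2, ctr)^2)) + 1e-12, "/")
  u <- matrix(as_array(fit$field), ncol = 3)
  ur <- rowSums(u * radial)[as.vector(shell)]
  expect_lt(mean(ur), 0)            # inward on average
  expect_gt(mean(ur < 0), 0.9)      # and for the vast majority of voxels
})

test_that("global volume change is conserved (label 1 compensates label 2)", {
  ph <- make_phantom(small_spec())
  a <- uniform_atrophy(ph$labels, 0.05)
  fit <- solve_deformation(ph$labels, a)
  g <- grid_of(ph$labels)
  div <- as_array(divergence_staggered(fit$staggered))
  lv <- atrophysim:::label_values(ph$labels)
  vol <- voxel_volume(g)
  total <- sum(div) * vol
  scale <- sum(abs(as_array(a))) * vol
  expect_lt(abs(total), 10 * fit$params$solver_tol * scale)
  expansion <- sum(div[lv == 1L]) * vol
  loss <- sum(as_array(a)[lv == 2L]) * vol
  expect_equal(expansion, loss, tolerance = 1e-6)
})

test_that("face-to-center interpolation averages bounding faces", {
  g <- image_grid(c(5, 4, 3))
  sf <- rand_staggered(g, seed = 11L)
  ctr <- face_to_center(sf)
  ## brute-force oracle over all cells
  for (pick in list(c(1L, 1L, 1L), c(3L, 2L, 2L), c(5L, 4L, 3L))) {
    i <- pick[1]; j <- pick[2]; k <- pick[3]
    expect_equal(as_array(ctr)[i, j, k, 1],
                 (sf$u[i, j, k] + sf$u[i + 1L, j, k]) / 2)
    expect_equal(as_array(ctr)[i, j, k, 2],
                 (sf$v[i, j, k] + sf$v[i, j + 1L, k]) / 2)
    expect_equal(as_array(ctr)[i, j, k, 3],
                 (sf$w[i, j, k] + sf$w[i, j, k + 1L]) / 2)
  }
  ## constant faces give constant centers; linear faces are exact
  n <- g$shape
  cf <- staggered_field(array(2.5, n + c(1L, 0L, 0L)),
                        array(2.5, n + c(0L, 1L, 0L)),
                        array(2.5, n + c(0L, 0L, 1L)), g)
  expect_true(all(as_array(face_to_center(cf)) == 2.5))
})

test_that("isolated label-2 components are regularized with a warning", {
  g <- image_grid(c(6, 6, 6))
  L <- array(0L, c(6, 6, 6))
  L[2, 2, 2] <- 1L              # distant label-1, not connected to the core
  L[4:5, 4:5, 4:5] <- 2L        # label-2 island with no label-1 contact
  av <- array(0, c(6, 6, 6)); av[4:5, 4:5, 4:5] <- 0.01
  expect_warning(assemble_system(label_image(L, g), atrophy_map(av, g)),
                 "regularization")
})
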
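test_that("phantoms are deterministic and piecewise constant without noise", {
  sp <- small_spec(noise_sd = 0)
  ph <- make_phantom(sp)
  expect_setequal(unique(as.vector(as_array(ph$image))),
                  c(0, 60, 30, 110))
  sp2 <- small_spec(noise_sd = 3)
  expect_identical(as_array(make_phantom(sp2)$image),
                   as_array(make_phantom(sp2)$image))
  ## radii must nest strictly
  expect_error(phantom_spec(radii = c(10, 11, 5, 2)), "decreasing")
})

test_that("label volumes match analytic sphere volumes at 64^3", {
  sp <- phantom_spec(shape = c(64, 64, 64), radii = c(30, 26, 22, 6),
                     rois = list(), noise_sd = 0)
  ph <- make_phantom(sp)
  lv <- atrophysim:::label_values(ph$labels)
  vol <- function(r) 4 / 3 * pi * r^3
  expect_equal(sum(lv == 2L), vol(22) - vol(6), tolerance = 0.05)
  expect_equal(sum(lv == 1L), (vol(26) - vol(22)) + vol(6), tolerance = 0.05)
})

test_that("repeat scans carry independent noise and a bounded bias field", {
  sp <- small_spec(n = 24L, noise_sd = 4, seed = 21L)
  ph <- make_phantom(sp)
  ## same seed, no bias: identical to baseline
  expect_identical(as_array(make_repeat_scan(sp, seed = sp$seed,
                                             bias_amplitude = 0)),
                   as_array(ph$image))
  ## independent seed: difference is zero-mean iid with sd = sqrt(2) sigma
  rep <- make_repeat_scan(sp, seed = 99L, bias_amplitude = 0)
  d <- as.vector(as_array(rep) - as_array(ph$image))
  expect_lt(abs(mean(d)), 4 * sqrt(2) * sp$noise_sd / sqrt(length(d)))
  expect_equal(stats::sd(d), sqrt(2) * sp$noise_sd, tolerance = 0.02)
  ## bias amplitude 0.2: multiplicative ratio stays within [0.8, 1.2],
  ## varies smoothly, and attains the prescribed amplitude somewhere
  spq <- small_spec(n = 24L, noise_sd = 0, seed = 21L)
  biased <- make_repeat_scan(spq, seed = 5L, bias_amplitude = 0.2)
  base <- make_phantom(spq)$image
  tissue <- as_array(base) > 0
  ratio <- as_array(biased)[tissue] / as_array(base)[tissue]
  expect_gte(min(ratio), 0.8 - 1e-9)
  expect_lte(max(ratio), 1.2 + 1e-9)
  expect_gt(stats::sd(ratio), 0)        # spatially varying
  B <- atrophysim:::with_seed(5L, {
    atrophysim:::add_noise(as_array(make_phantom(spq)$noiseless), spq)
    atrophysim:::bias_field(spq, 0.2)
  })
  expect_equal(max(abs(B - 1)), 0.2, tolerance = 1e-12)
  ## smooth: neighbouring voxels differ by far less than the amplitude
  expect_lt(max(abs(diff(B[, 12, 12]))), 0.05)
})

test_that("rician noise follows the magnitude-of-complex-Gaussian recipe", {
  sp <- small_spec(n = 12L, noise_sd = 5, noise_model = "rician", seed = 4L)
  ph <- make_phantom(sp)
  ## background (true signal 0) has Rayleigh-distributed intensities:
  ## mean sigma sqrt(pi/2), all positive
  bg <- as_array(ph$image)[as_array(ph$noiseless) == 0]
  expect_true(all(bg >= 0))
  expect_equal(mean(bg), 5 * sqrt(pi / 2), tolerance = 0.1)
})

test_that("follow-up scans reduce to repeat scans for a zero field", {
  sp <- small_spec(n = 16L, noise_sd = 3, seed = 9L)
  z <- displacement_field(array(0, c(sp$shape, 3L)),
                          image_grid(sp$shape, sp$spacing))
  fu <- make_followup_scan(sp, z, seed = 31L, bias_amplitude = 0)
  rep <- make_repeat_scan(sp, seed = 31L, bias_amplitude = 0)
  expect_lt(max(abs(as_array(fu$image) - as_array(rep))), 1e-6)
  expect_equal(max(abs(as_array(fu$reg_field))), 0)
})

test_that("follow-up ROI volumes change by the prescribed fractions", {
  sp <- small_spec(n = 24L, noise_sd = 0)
  ph <- make_phantom(sp)
  a <- uniform_atrophy(ph$labels, 0.05)
  fit <- solve_deformation(ph$labels, a,
                           model_params(scheme = "twelve_point"))
  ## volume accounting via the Jacobian integral over the prescribed region
  J <- as_array(jacobian_determinant(fit$field))
  lab2 <- atrophysim:::label_values(ph$labels) == 2L
  shrink <- 1 - sum(J[lab2]) / sum(lab2)
  expect_lt(abs(shrink - 0.05), 0.005)
  ## the returned registration field inverts the true deformation
  fu <- make_followup_scan(sp, fit$field, seed = 77L, bias_amplitude = 0)
  rt <- compose_fields(fit$field, fu$reg_field)
  expect_lt(max(abs(as_array(rt))), 0.05 * min(grid_of(fit$field)$spacing))
})
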
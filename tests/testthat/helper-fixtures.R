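## Shared fixtures: everything is generated in code, nothing stored on disk.

## nested-box segmentation: label-0 hull, label-1 shell, label-2 core
box_phantom <- function(n = 8L, a_value = 0.05, spacing = c(1, 1, 1)) {
  g <- image_grid(rep(n, 3L), spacing)
  L <- array(0L, rep(n, 3L))
  L[2:(n - 1L), 2:(n - 1L), 2:(n - 1L)] <- 1L
  core <- (n %/% 2L):(n %/% 2L + 1L)
  L[core, core, core] <- 2L
  labels <- label_image(L, g)
  list(labels = labels, a = uniform_atrophy(labels, a_value), grid = g,
       core = core)
}

## spherical phantom spec scaled to a 16^3 grid
small_spec <- function(n = 16L, noise_sd = 0, seed = 7L, ...) {
  phantom_spec(shape = rep(n, 3L), radii = c(7.5, 6.5, 5, 1.5),
               rois = list(list(label = 17L, center = c(2, 0, 0),
                                radius = 1.6)),
               noise_sd = noise_sd, seed = seed, ...)
}

## smooth displacement field vanishing near the boundary
smooth_field <- function(grid, amp = 0.5) {
  n <- grid$shape
  P <- atrophysim:::grid_points(grid)
  s <- function(i) sin(pi * P[, i] / (n[i] - 1))
  u <- amp * cbind(s(1)^2 * sin(2 * pi * P[, 2] / (n[2] - 1)),
                   s(2)^2 * sin(2 * pi * P[, 3] / (n[3] - 1)),
                   s(3)^2 * sin(2 * pi * P[, 1] / (n[1] - 1)))
  displacement_field(array(u, c(n, 3L)), grid)
}

rand_staggered <- function(grid, seed = 1L) {
  n <- grid$shape
  atrophysim:::with_seed(seed, staggered_field(
    array(stats::rnorm(prod(n + c(1L, 0L, 0L))), n + c(1L, 0L, 0L)),
    array(stats::rnorm(prod(n + c(0L, 1L, 0L))), n + c(0L, 1L, 0L)),
    array(stats::rnorm(prod(n + c(0L, 0L, 1L))), n + c(0L, 0L, 1L)), grid))
}

erode_mask <- function(mask, r = 1L) {
  for (i in seq_len(r)) {
    m <- mask
    for (ax in 1:3) for (s in c(-1L, 1L))
      m <- m & atrophysim:::shift_axis(mask, ax, s)
    mask <- m
  }
  mask
}

## max |u| over a voxel mask
max_disp_on <- function(field, mask) {
  u <- matrix(as_array(field), ncol = 3L)
  if (!any(mask)) return(0)
  max(abs(u[as.vector(mask), ]))
}
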
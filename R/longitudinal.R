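#' Simulate one follow-up time point
#'
#' Solves the deformation model for the prescribed atrophy and pulls the
#' baseline intensities through the resulting field:
#' `I_s = Phi_sim * I_b = I_b o Phi_sim^{-1}`.
#'
#' @inheritParams solve_deformation
#' @param baseline a [scalar_image()].
#' @param interpolation_order spline order for the intensity pull
#'   (default 3).
#' @return A list: `image`, `field`, `pressure`, `diagnostics`.
#' @export
simulate_step <- function(baseline, labels, a, params = model_params(),
                          interpolation_order = 3L) {
  assert_same_space(baseline, labels)
  fit <- solve_deformation(labels, a, params)
  img <- warp_image(baseline, fit$field,
                    interpolation_order = interpolation_order)
  list(image = img, field = fit$field, pressure = fit$pressure,
       diagnostics = fit$diagnostics)
}

#' Resample intensities for a simulated time point from an alternate scan
#'
#' The key mechanism for realistic intensity variation: the simulated
#' deformation is kept fixed and only the intensity source changes.
#' With no registration field the source is treated as a same-session
#' repeat scan and warped by the simulated field alone
#' (`I_s1 = Phi_sim * I_b1`); with a registration field `Phi_reg` (mapping
#' the source's anatomy onto the baseline) the two deformations are composed
#' first (`I_s2 = (Phi_sim o Phi_reg) * I_r`).  Either way the morphology —
#' and hence the ground-truth volume change — is identical to the
#' baseline-sourced simulation; only intensity characteristics differ.
#'
#' @param sim_field the simulated [displacement_field()].
#' @param source the [scalar_image()] whose intensities to resample.
#' @param reg_field optional [displacement_field()] from registering the
#'   source to the baseline.
#' @param interpolation_order spline order for the intensity pull.
#' @return A [scalar_image()].
#' @export
resample_intensity <- function(sim_field, source, reg_field = NULL,
                               interpolation_order = 3L) {
  assert_same_space(sim_field, source)
  total <- if (is.null(reg_field)) sim_field else {
    assert_same_space(sim_field, reg_field)
    compose_fields(sim_field, reg_field)
  }
  warp_image(source, total, interpolation_order = interpolation_order)
}

#' Sequence specification for multi-time-point simulation
#'
#' @param n_steps number of simulation steps (>= 1).
#' @param params a [model_params()].
#' @param sources named list of intensity sources; each element is a list
#'   with `scan` (a [scalar_image()]) and optionally `reg_field` (a
#'   [displacement_field()] registering that scan to the baseline).  Every
#'   time point is simulated once per source.  Default: resample from the
#'   baseline only.
#' @param rescale_atrophy `"none"` (default) keeps the warped atrophy map as
#'   is, so the total prescribed volume change may drift across steps;
#'   `"preserve_total"` rescales each step's map to the initial total.
#' @param interpolation_order spline order for intensity pulls.
#' @return An object of class `sequence_spec`.
#' @export
sequence_spec <- function(n_steps, params = model_params(), sources = NULL,
                          rescale_atrophy = c("none", "preserve_total"),
                          interpolation_order = 3L) {
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("n_steps must be >= 1", call. = FALSE)
  structure(list(n_steps = n_steps, params = params, sources = sources,
                 rescale_atrophy = match.arg(rescale_atrophy),
                 interpolation_order = as.integer(interpolation_order)),
            class = "sequence_spec")
}

#' Simulate a longitudinal sequence
#'
#' Multi-time-point algorithm: the first step solves on the initial atrophy
#' `a0` and segmentation `L0`.  For each later step `t`, the previous
#' atrophy map and the *original* labels are warped by the accumulated
#' composed field `u_{t-1} o ... o u_0` (atrophy by trilinear interpolation,
#' labels by nearest neighbour), the model is solved on the warped inputs,
#' and the accumulated field is extended to `u_t o ... o u_0`.  Warped
#' atrophy is clamped to zero outside the warped label-2 region (trilinear
#' interpolation bleeds values across the moving tissue edge; the solver
#' requires support on label 2).  Because the atrophy map is rewarped each
#' step, the initially prescribed global atrophy rate is not necessarily
#' preserved at intermediate time points.
#'
#' Images for every time point are always resampled from the original
#' source scans through the accumulated fields — never by re-warping
#' already-warped images — so interpolation blur does not compound.
#'
#' @inheritParams simulate_step
#' @param a0 initial [atrophy_map()].
#' @param spec a [sequence_spec()].
#' @return An object of class `atrophy_sequence`: per-step fields and
#'   diagnostics (`steps`), accumulated per-time-point fields
#'   (`accumulated`), and per-source lists of simulated images (`images`).
#' @export
simulate_sequence <- function(baseline, labels, a0, spec) {
  stopifnot(inherits(spec, "sequence_spec"))
  assert_same_space(baseline, labels)
  assert_same_space(baseline, a0)
  sources <- spec$sources
  if (is.null(sources)) sources <- list(baseline = list(scan = baseline))
  if (is.null(names(sources)) || any(names(sources) == ""))
    stop("sequence sources must be named", call. = FALSE)
  for (s in sources) assert_same_space(baseline, s$scan)
  total0 <- sum(as_array(a0)) * voxel_volume(grid_of(a0))
  steps <- vector("list", spec$n_steps)
  accumulated <- vector("list", spec$n_steps)
  a_prev <- a0
  L_t <- labels
  for (t in seq_len(spec$n_steps)) {
    if (t > 1L) {
      acc_prev <- accumulated[[t - 1L]]
      L_t <- warp_labels(labels, acc_prev)
      a_arr <- as_array(warp_image(a_prev, acc_prev,
                                   interpolation_order = 1L))
      a_arr[label_values(L_t) != 2L] <- 0
      if (spec$rescale_atrophy == "preserve_total") {
        tot <- sum(a_arr) * voxel_volume(grid_of(a0))
        if (tot != 0) a_arr <- a_arr * (total0 / tot)
      }
      a_prev <- atrophy_map(a_arr, grid_of(a0))
    }
    fit <- tryCatch(
      solve_deformation(L_t, a_prev, spec$params),
      error = function(e) stop("sequence step ", t, " failed: ",
                               conditionMessage(e), call. = FALSE))
    steps[[t]] <- list(field = fit$field, diagnostics = fit$diagnostics,
                       atrophy = a_prev, labels = L_t)
    accumulated[[t]] <- if (t == 1L) fit$field else
      compose_fields(fit$field, accumulated[[t - 1L]])
  }
  images <- lapply(sources, function(s)
    lapply(accumulated, function(acc)
      resample_intensity(acc, s$scan, s$reg_field,
                         interpolation_order = spec$interpolation_order)))
  structure(list(steps = steps, accumulated = accumulated, images = images,
                 spec = spec),
            class = "atrophy_sequence")
}

#' @export
print.atrophy_sequence <- function(x, ...) {
  viol <- vapply(x$steps, function(s)
    s$diagnostics$max_constraint_violation, 0)
  cat("atrophy_sequence:", length(x$steps), "steps,",
      length(x$images), "intensity source(s)\n",
      " per-step max |div u + a|:", paste(signif(viol, 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' Dice overlap of two masks
#'
#' Utility for morphology agreement checks between simulated images
#' (e.g. thresholded tissue masks of the same time point resampled from
#' different scans).
#'
#' @param a,b logical arrays or images of equal shape.
#' @return Dice coefficient in \[0, 1\].
#' @export
mask_dice <- function(a, b) {
  av <- as.logical(if (inherits(a, "grid_image")) as_array(a) else a)
  bv <- as.logical(if (inherits(b, "grid_image")) as_array(b) else b)
  stopifnot(length(av) == length(bv))
  denom <- sum(av) + sum(bv)
  if (denom == 0) return(1)
  2 * sum(av & bv) / denom
}
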
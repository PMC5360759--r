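#' Specification of a synthetic brain-like phantom
#'
#' The phantom is a concentric-sphere "head": background and a skull shell
#' (rigid, label 0), a sulcal-CSF shell and a central ventricle (freely
#' compensating, label 1), and parenchyma between them (prescribable,
#' label 2) optionally containing spherical ROI blobs standing in for
#' structures such as the hippocampus.  Intensities are per-tissue means
#' plus Gaussian noise; repeat scans add an independent noise realization
#' and a smooth multiplicative polynomial bias field, emulating the
#' intensity variation between same-session acquisitions.  All randomness
#' flows from explicit seeds: equal specs give bit-identical phantoms.
#'
#' @param shape voxels per axis (default 32^3).
#' @param spacing voxel spacing, mm.
#' @param radii strictly decreasing radii in mm: outer skull, outer CSF
#'   shell, outer parenchyma (= inner CSF shell), ventricle.
#' @param rois list of ROI blobs, each `list(label =, center =, radius =)`
#'   with `center` in mm relative to the image centre; blobs must lie in the
#'   parenchyma.
#' @param intensities named vector of tissue means: `background`, `skull`,
#'   `csf`, `parenchyma`, and optionally `roi` (defaults to the parenchyma
#'   mean).
#' @param noise_sd Gaussian noise standard deviation (image units).
#' @param noise_model `"gaussian"` (default) or `"rician"` (magnitude of a
#'   complex Gaussian perturbation, the classical MR noise recipe; offered
#'   for comparison studies).
#' @param bias_amplitude relative amplitude of the multiplicative bias field
#'   applied to repeat/follow-up scans (0 disables; 0.2 gives intensity
#'   ratios in about \[0.8, 1.2\]).
#' @param bias_order polynomial order of the separable bias field.
#' @param seed integer seed for the baseline noise.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32, 32, 32), spacing = c(1, 1, 1),
                         radii = c(15, 13, 11, 3),
                         rois = list(list(label = 17L, center = c(5, 0, 0),
                                          radius = 3)),
                         intensities = c(background = 0, skull = 60,
                                         csf = 30, parenchyma = 110),
                         noise_sd = 4,
                         noise_model = c("gaussian", "rician"),
                         bias_amplitude = 0.1, bias_order = 2L,
                         seed = 1L) {
  radii <- as.numeric(radii)
  if (length(radii) != 4L || any(diff(radii) >= 0))
    stop("`radii` must be 4 strictly decreasing values: skull > csf > parenchyma > ventricle",
         call. = FALSE)
  need <- c("background", "skull", "csf", "parenchyma")
  if (!all(need %in% names(intensities)))
    stop("`intensities` must name: ", paste(need, collapse = ", "),
         call. = FALSE)
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 radii = radii, rois = rois,
                 intensities = intensities, noise_sd = noise_sd,
                 noise_model = match.arg(noise_model),
                 bias_amplitude = bias_amplitude,
                 bias_order = as.integer(bias_order),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  } else assign(".Random.seed", old, envir = genv))
  set.seed(seed)
  force(code)
}

phantom_radius_map <- function(spec) {
  n <- spec$shape; h <- spec$spacing
  ctr <- (n - 1) * h / 2
  x <- (seq_len(n[1]) - 1) * h[1] - ctr[1]
  y <- (seq_len(n[2]) - 1) * h[2] - ctr[2]
  z <- (seq_len(n[3]) - 1) * h[3] - ctr[3]
  sqrt(outer(outer(x^2, y^2, "+"), z^2, "+"))
}

phantom_anatomy <- function(spec) {
  n <- spec$shape
  r <- phantom_radius_map(spec)
  rs <- spec$radii   # skull, csf, parenchyma, ventricle
  labels <- array(0L, n)
  labels[r <= rs[2]] <- 1L                       # CSF shell (and deeper)
  labels[r <= rs[3]] <- 2L                       # parenchyma
  labels[r <= rs[4]] <- 1L                       # ventricle
  tissue <- array(spec$intensities[["background"]], n)
  tissue[r <= rs[1]] <- spec$intensities[["skull"]]
  tissue[labels == 1L] <- spec$intensities[["csf"]]
  tissue[labels == 2L] <- spec$intensities[["parenchyma"]]
  rois <- array(0L, n)
  rois[labels == 2L] <- 1L                       # parenchyma remainder
  ctr <- (n - 1) * spec$spacing / 2
  roi_mean <- if ("roi" %in% names(spec$intensities))
    spec$intensities[["roi"]] else spec$intensities[["parenchyma"]]
  for (b in spec$rois) {
    cx <- ctr + b$center
    x <- (seq_len(n[1]) - 1) * spec$spacing[1] - cx[1]
    y <- (seq_len(n[2]) - 1) * spec$spacing[2] - cx[2]
    z <- (seq_len(n[3]) - 1) * spec$spacing[3] - cx[3]
    rb <- sqrt(outer(outer(x^2, y^2, "+"), z^2, "+"))
    sel <- rb <= b$radius & labels == 2L
    rois[sel] <- as.integer(b$label)
    tissue[sel] <- roi_mean
  }
  list(labels = labels, tissue = tissue, rois = rois)
}

add_noise <- function(tissue, spec) {
  if (spec$noise_sd == 0) return(tissue)
  if (spec$noise_model == "gaussian") {
    tissue + array(stats::rnorm(length(tissue), sd = spec$noise_sd),
                   dim(tissue))
  } else {
    ## Rician: treat the signal as a complex number with zero imaginary
    ## part, perturb real and imaginary parts with independent Gaussians,
    ## and take the magnitude
    re <- tissue + stats::rnorm(length(tissue), sd = spec$noise_sd)
    im <- stats::rnorm(length(tissue), sd = spec$noise_sd)
    array(sqrt(re^2 + im^2), dim(tissue))
  }
}

## separable polynomial bias field, normalized to max |B| = 1;
## returned as the multiplicative factor 1 + amplitude * B
bias_field <- function(spec, amplitude) {
  n <- spec$shape
  if (amplitude == 0) return(array(1, n))
  poly <- function(nax) {
    t <- seq(-1, 1, length.out = nax)
    cf <- stats::rnorm(spec$bias_order + 1L)
    drop(outer(t, 0:spec$bias_order, "^") %*% cf)
  }
  B <- outer(outer(poly(n[1]), poly(n[2])), poly(n[3]))
  B <- B / max(abs(B))
  1 + amplitude * array(B, n)
}

#' Generate a synthetic brain phantom
#'
#' @param spec a [phantom_spec()].
#' @return A list: `image` (baseline [scalar_image()] with noise), `labels`
#'   ([label_image()]), `rois` ([roi_segmentation()]; blobs keep their
#'   specified labels, remaining parenchyma is ROI 1), and `noiseless`
#'   (the pure tissue-mean image).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- image_grid(spec$shape, spec$spacing)
  an <- phantom_anatomy(spec)
  noisy <- with_seed(spec$seed, add_noise(an$tissue, spec))
  list(image = scalar_image(noisy, g),
       labels = label_image(an$labels, g),
       rois = roi_segmentation(an$rois, g),
       noiseless = scalar_image(an$tissue, g))
}

#' Generate a repeat scan of a phantom
#'
#' Same anatomy as the baseline, an independent noise realization, and
#' (when `bias_amplitude > 0`) a smooth multiplicative polynomial bias field
#' differing from the baseline's — the ingredients that make two real
#' same-session scans differ.
#'
#' @inheritParams make_phantom
#' @param seed seed for the new noise and bias realization.
#' @param bias_amplitude overrides `spec$bias_amplitude` if given.
#' @return A [scalar_image()].
#' @export
make_repeat_scan <- function(spec, seed = spec$seed + 1L,
                             bias_amplitude = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(bias_amplitude)) bias_amplitude <- spec$bias_amplitude
  g <- image_grid(spec$shape, spec$spacing)
  an <- phantom_anatomy(spec)
  img <- with_seed(seed, {
    noisy <- add_noise(an$tissue, spec)
    noisy * bias_field(spec, bias_amplitude)
  })
  scalar_image(img, g)
}

#' Generate a follow-up scan with known deformation
#'
#' Warps the noiseless anatomy by `true_field`, then adds an independent
#' noise realization and bias field.  Also returns the exact registration
#' field a perfect non-rigid registration of the follow-up onto the baseline
#' would produce (the inverse of `true_field`), so downstream experiments
#' can bypass registration or perturb it deliberately to study the effect of
#' registration error.
#'
#' @inheritParams make_repeat_scan
#' @param true_field the [displacement_field()] that deformed the anatomy
#'   between baseline and follow-up.
#' @param interpolation_order spline order for warping the anatomy.
#' @return A list: `image` ([scalar_image()]) and `reg_field`
#'   ([displacement_field()], ground-truth registration of follow-up to
#'   baseline).
#' @export
make_followup_scan <- function(spec, true_field, seed = spec$seed + 2L,
                               bias_amplitude = NULL,
                               interpolation_order = 3L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(bias_amplitude)) bias_amplitude <- spec$bias_amplitude
  g <- image_grid(spec$shape, spec$spacing)
  assert_same_space(image_grid(spec$shape, spec$spacing), true_field)
  an <- phantom_anatomy(spec)
  warped <- warp_image(scalar_image(an$tissue, g), true_field,
                       interpolation_order = interpolation_order)
  img <- with_seed(seed, {
    noisy <- add_noise(as_array(warped), spec)
    noisy * bias_field(spec, bias_amplitude)
  })
  list(image = scalar_image(img, g),
       reg_field = invert_field(true_field))
}
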
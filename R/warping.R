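#' Warp images through a deformation field
#'
#' Implements the image action `Phi * I = I o Phi^{-1}` by backward (pull)
#' mapping: each output voxel centre `y` is mapped through the inverse
#' deformation and the input image is interpolated at `y + u_inv(y)`.
#' Forward splatting is not offered; pulling avoids the scattered-data
#' interpolation problem entirely.
#'
#' If `field_is_inverse = FALSE` (default) the supplied field is the forward
#' deformation `Phi` and is inverted first with [invert_field()]; pass
#' `field_is_inverse = TRUE` when you already hold `Phi^{-1}` (mirroring the
#' usual command-line "do not invert" default, where users pre-invert fields
#' once and reuse them).
#'
#' @param img a [scalar_image()].
#' @param field a [displacement_field()] on the same grid.
#' @param field_is_inverse is `field` already the inverse deformation?
#' @param interpolation_order B-spline order 0-3 (default 3; 0 = nearest
#'   neighbour, 1 = trilinear).  Orders >= 2 prefilter the image so the
#'   spline interpolates (not merely approximates) the samples.
#' @param ... passed to [invert_field()] when inversion is needed.
#' @return A [scalar_image()]; out-of-domain pulls return 0 and their count
#'   is recorded in the `"n_outside"` attribute.
#' @export
warp_image <- function(img, field, field_is_inverse = FALSE,
                       interpolation_order = 3L, ...) {
  assert_same_space(img, field)
  order <- as.integer(interpolation_order)
  if (order < 0L || order > 3L)
    stop("interpolation_order must be 0, 1, 2 or 3", call. = FALSE)
  g <- grid_of(img)
  inv <- if (field_is_inverse) field else invert_field(field, ...)
  pts <- grid_points(g) +
    world_to_index(matrix(as_array(inv), ncol = 3), g)
  vals <- sample_scalar(as_array(img), pts, order)
  n_out <- attr(vals, "n_outside")
  log_note("warp_image: ", n_out, " out-of-domain pulls set to 0")
  out <- scalar_image(array(vals, g$shape), g)
  attr(out, "n_outside") <- n_out
  out
}

#' Warp a label image or ROI segmentation
#'
#' Nearest-neighbour pull through the (inverse) deformation; no new label
#' values can appear and out-of-domain pulls become 0 (background).
#' Tie-breaking at exact half-voxel positions rounds toward the lower index,
#' fixed for cross-platform determinism.
#'
#' @param labels a [label_image()] or [roi_segmentation()].
#' @inheritParams warp_image
#' @return Same type as `labels`.
#' @export
warp_labels <- function(labels, field, field_is_inverse = FALSE, ...) {
  assert_same_space(labels, field)
  g <- grid_of(labels)
  inv <- if (field_is_inverse) field else invert_field(field, ...)
  pts <- grid_points(g) +
    world_to_index(matrix(as_array(inv), ncol = 3), g)
  vals <- sample_nearest(label_values(labels), pts, outside = 0L)
  arr <- array(as.integer(vals), g$shape)
  if (inherits(labels, "label_image")) label_image(arr, g)
  else roi_segmentation(arr, g)
}
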
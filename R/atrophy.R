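#' Construct prescribed atrophy maps
#'
#' Atrophy maps hold the per-voxel fractional volume loss per time step,
#' `a = (V0 - V1)/V0` (positive = shrinkage, negative = growth).  Values are
#' only prescribable where the three-regime segmentation is label 2; every
#' constructor zeroes all other voxels.
#'
#' @name atrophy-maps
NULL

#' @describeIn atrophy-maps Paint uniform ROI values from a table: each voxel
#'   takes the table value of its ROI label when the voxel lies in the
#'   prescribed (label-2) region and its ROI is listed; all other voxels are
#'   zero.  Table labels absent from the segmentation produce a warning, not
#'   an error.
#' @param rois a [roi_segmentation()].
#' @param table named numeric vector mapping ROI labels to atrophy values
#'   (see [read_atrophy_table()]).
#' @param model_labels a [label_image()] on the same grid.
#' @return An [atrophy_map()].
#' @export
atrophy_from_table <- function(rois, table, model_labels) {
  assert_same_space(rois, model_labels)
  g <- grid_of(rois)
  rv <- label_values(rois)
  lv <- label_values(model_labels)
  out <- array(0, g$shape)
  if (length(table)) {
    labs <- as.integer(names(table))
    if (any(is.na(labs)))
      stop("atrophy table must be named by integer ROI labels", call. = FALSE)
    missing <- setdiff(labs, unique(as.vector(rv)))
    if (length(missing))
      warning("atrophy table references ROI labels absent from the segmentation: ",
              paste(missing, collapse = ", "), call. = FALSE)
    for (i in seq_along(labs)) {
      sel <- rv == labs[i] & lv == 2L
      out[sel] <- table[[i]]
    }
  }
  atrophy_map(out, g)
}

#' @describeIn atrophy-maps Uniform atrophy `value` over the whole label-2
#'   region (convenience wrapper used throughout the examples and tests).
#' @param value per-step fractional volume loss.
#' @export
uniform_atrophy <- function(model_labels, value) {
  g <- grid_of(model_labels)
  out <- array(0, g$shape)
  out[label_values(model_labels) == 2L] <- value
  atrophy_map(out, g)
}

#' @describeIn atrophy-maps Smoothly varying atrophy from a stationary
#'   velocity field: the negated centered-difference divergence of `svf` on
#'   label-2 voxels, zero elsewhere.  Registration-derived velocity fields
#'   give realistic smooth volume-change patterns.  `negate = TRUE` flips the
#'   sign to prescribe growth instead of atrophy.
#' @param svf a [displacement_field()] holding the stationary velocity field.
#' @param negate flip the sign of the map (growth scenario).
#' @export
atrophy_from_velocity <- function(svf, model_labels, negate = FALSE) {
  assert_same_space(svf, model_labels)
  g <- grid_of(svf)
  div <- as_array(divergence_centered(svf))
  out <- -div
  out[label_values(model_labels) != 2L] <- 0
  if (negate) out <- -out
  atrophy_map(out, g)
}

#' @describeIn atrophy-maps Replace a map by its ROI-wise average: every
#'   voxel of ROI `r` inside the prescribed region receives the mean of the
#'   input map over `r` intersected with label 2 (voxel-count weights; grids
#'   have uniform spacing, so this preserves each ROI's total prescribed
#'   volume change exactly).  ROIs with no prescribed voxels get 0 with a
#'   warning.  Piecewise-constant maps are fixed points.
#' @param map an [atrophy_map()].
#' @export
regionwise_average <- function(map, rois, model_labels = NULL) {
  assert_same_space(map, rois)
  g <- grid_of(map)
  av <- as_array(map)
  rv <- label_values(rois)
  prescribed <- if (is.null(model_labels)) {
    av != 0        # map invariant: support lies inside the prescribed region
  } else {
    assert_same_space(map, model_labels)
    label_values(model_labels) == 2L
  }
  out <- array(0, g$shape)
  labs <- setdiff(sort(unique(as.vector(rv))), 0L)  # 0 = background
  empty <- integer(0)
  for (r in labs) {
    sel <- rv == r & prescribed
    if (!any(sel)) { empty <- c(empty, r); next }
    out[sel] <- mean(av[sel])
  }
  if (length(empty))
    warning("ROIs with no prescribed voxels set to 0: ",
            paste(empty, collapse = ", "), call. = FALSE)
  atrophy_map(out, g)
}
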
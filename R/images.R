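#' Image and field containers
#'
#' All pipeline data are plain R arrays tagged with an [image_grid()]:
#'
#' * `scalar_image()` — one real value per voxel (intensities, pressure,
#'   divergence, Jacobian maps).
#' * `label_image()` — the model's three-regime segmentation.  Label 0 marks
#'   voxels held rigidly at zero displacement (skull and background), label 1
#'   marks freely compensating tissue (CSF), label 2 marks tissue with
#'   prescribed volume change (parenchyma).
#' * `roi_segmentation()` — an arbitrary non-negative integer parcellation
#'   (e.g. anatomical ROIs) used to paint or average atrophy maps.
#' * `atrophy_map()` — per-voxel fractional volume loss per time step,
#'   a = (V0 - V1)/V0; positive values shrink, negative values grow.
#' * `displacement_field()` — one world-space (mm) 3-vector per voxel centre,
#'   stored as an (nx, ny, nz, 3) array.
#'
#' @name image-containers
NULL

new_grid_array <- function(values, grid, class, extra = NULL) {
  structure(values, grid = grid, class = class)
}

#' @param values 3D numeric array matching `grid$shape`.
#' @param grid an [image_grid()]; defaults to a unit-spacing grid of the
#'   array's dimensions.
#' @rdname image-containers
#' @export
scalar_image <- function(values, grid = NULL) {
  values <- as.array(values)
  if (is.null(grid)) grid <- image_grid(dim(values))
  check_dims(values, grid$shape, "scalar_image")
  if (any(!is.finite(values)))
    stop("scalar_image values must be finite", call. = FALSE)
  storage.mode(values) <- "double"
  new_grid_array(values, grid, c("scalar_image", "grid_image"))
}

#' @rdname image-containers
#' @export
label_image <- function(values, grid = NULL) {
  values <- as.array(values)
  if (is.null(grid)) grid <- image_grid(dim(values))
  check_dims(values, grid$shape, "label_image")
  bad <- setdiff(unique(as.vector(values)), c(0, 1, 2))
  if (length(bad))
    stop("label_image values must be in {0,1,2}; found: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  storage.mode(values) <- "integer"
  new_grid_array(values, grid, c("label_image", "grid_image"))
}

#' @rdname image-containers
#' @export
roi_segmentation <- function(values, grid = NULL) {
  values <- as.array(values)
  if (is.null(grid)) grid <- image_grid(dim(values))
  check_dims(values, grid$shape, "roi_segmentation")
  if (any(values < 0) || any(values != round(values)))
    stop("roi_segmentation values must be non-negative integers", call. = FALSE)
  storage.mode(values) <- "integer"
  new_grid_array(values, grid, c("roi_segmentation", "grid_image"))
}

#' @rdname image-containers
#' @export
atrophy_map <- function(values, grid = NULL) {
  values <- as.array(values)
  if (is.null(grid)) grid <- image_grid(dim(values))
  check_dims(values, grid$shape, "atrophy_map")
  if (any(!is.finite(values)))
    stop("atrophy_map values must be finite", call. = FALSE)
  if (any(values >= 1))
    stop("atrophy values must be < 1 (a voxel cannot lose more than its own volume)",
         call. = FALSE)
  storage.mode(values) <- "double"
  new_grid_array(values, grid, c("atrophy_map", "scalar_image", "grid_image"))
}

#' @rdname image-containers
#' @export
displacement_field <- function(values, grid = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 4L || dim(values)[4] != 3L)
    stop("displacement_field values must be an (nx, ny, nz, 3) array",
         call. = FALSE)
  if (is.null(grid)) grid <- image_grid(dim(values)[1:3])
  if (!all(dim(values)[1:3] == grid$shape))
    stop("displacement_field dimensions do not match grid shape", call. = FALSE)
  if (any(!is.finite(values)))
    stop("displacement_field values must be finite", call. = FALSE)
  storage.mode(values) <- "double"
  new_grid_array(values, grid, c("displacement_field", "grid_image"))
}

#' Face-centred (staggered / MAC) velocity field
#'
#' The solver stores displacement components on cell faces: the x-component
#' on x-faces (an (nx+1, ny, nz) array), and analogously for y and z.  Cell
#' centres carry pressure and atrophy.  This layout avoids the pressure
#' checkerboard instability of collocated grids.
#'
#' @param u,v,w face arrays with one extra sample along their own axis.
#' @param grid the cell-centred [image_grid()].
#' @return An object of class `staggered_field`.
#' @export
staggered_field <- function(u, v, w, grid) {
  n <- grid$shape
  stopifnot(all(dim(u) == c(n[1] + 1L, n[2], n[3])),
            all(dim(v) == c(n[1], n[2] + 1L, n[3])),
            all(dim(w) == c(n[1], n[2], n[3] + 1L)))
  structure(list(u = u, v = v, w = w, grid = grid), class = "staggered_field")
}

#' @export
print.staggered_field <- function(x, ...) {
  cat("staggered_field on", paste(x$grid$shape, collapse = " x "),
      "cells; max |component| =",
      signif(max(abs(x$u), abs(x$v), abs(x$w)), 4), "mm\n")
  invisible(x)
}

check_dims <- function(values, shape, what) {
  if (length(dim(values)) != 3L || !all(dim(values) == shape))
    stop(what, " values must be a 3D array matching the grid shape",
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.grid_image <- function(x, ...) {
  g <- grid_of(x)
  kind <- class(x)[1]
  cat(kind, ": ", paste(g$shape, collapse = " x "), " voxels, spacing ",
      paste(signif(g$spacing, 4), collapse = " x "), " mm\n", sep = "")
  v <- as.vector(x)
  if (kind %in% c("label_image", "roi_segmentation")) {
    tb <- table(v)
    cat("  labels:", paste(sprintf("%s (n=%d)", names(tb), as.integer(tb)),
                           collapse = ", "), "\n")
  } else {
    cat("  range [", signif(min(v), 4), ", ", signif(max(v), 4), "]\n", sep = "")
  }
  invisible(x)
}

#' Strip class/grid attributes and return the bare array
#' @param x any package image or field object.
#' @return The underlying numeric array.
#' @export
as_array <- function(x) {
  if (inherits(x, "staggered_field"))
    stop("a staggered_field has no single array; access $u, $v, $w",
         call. = FALSE)
  a <- unclass(x)
  attr(a, "grid") <- NULL
  a
}

label_values <- function(x) {
  a <- as_array(x)
  storage.mode(a) <- "integer"
  a
}

#' Verify the compensation requirement of a three-regime segmentation
#'
#' Prescribed volume change in label-2 tissue must be compensated somewhere:
#' whenever any label-2 voxel carries nonzero atrophy, at least one label-1
#' voxel must exist for the solver's relaxed-incompressibility regime to
#' absorb the volume.
#'
#' @param labels a [label_image()].
#' @param a an [atrophy_map()] on the same grid (optional; if omitted, the
#'   check requires label 1 to be present whenever label 2 is).
#' @return Invisibly `TRUE` or an error.
#' @export
check_compensation <- function(labels, a = NULL) {
  lv <- label_values(labels)
  needs <- if (is.null(a)) any(lv == 2L) else {
    assert_same_space(labels, a)
    any(as_array(a) != 0 & lv == 2L)
  }
  if (needs && !any(lv == 1L))
    stop(paste("segmentation has prescribed (label-2) volume change but no",
               "label-1 region to compensate it"), call. = FALSE)
  invisible(TRUE)
}
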
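#' Regular 3D image grid
#'
#' An `image_grid` describes the sampling geometry shared by every image and
#' field in a simulation: the number of voxels per axis, the voxel spacing in
#' millimetres, the world coordinate of the first voxel centre, and an
#' orthonormal direction (orientation) matrix.  Voxel indexing is 0-based:
#' voxel (i, j, k) has its centre at
#' `origin + direction %*% (i*h_x, j*h_y, k*h_z)`.
#'
#' @param shape integer vector of length 3, voxels per axis (all positive).
#' @param spacing numeric vector of length 3, voxel spacing in mm (all
#'   strictly positive).
#' @param origin numeric vector of length 3, world position (mm) of the centre
#'   of voxel (0, 0, 0).
#' @param direction 3x3 orthonormal direction matrix (columns are the world
#'   directions of the image axes).
#' @return An object of class `image_grid`.
#' @examples
#' g <- image_grid(c(16, 16, 16), spacing = c(1, 1, 1.5))
#' g
#' @export
image_grid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       direction = diag(3)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  direction <- as.matrix(direction)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be 3 positive integers", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive reals (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite reals (mm)", call. = FALSE)
  if (!all(dim(direction) == c(3L, 3L)) || any(!is.finite(direction)))
    stop("`direction` must be a finite 3x3 matrix", call. = FALSE)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("`direction` must be orthonormal within 1e-6", call. = FALSE)
  structure(list(shape = shape, spacing = spacing, origin = origin,
                 direction = direction),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat("image_grid:", paste(x$shape, collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 4), collapse = " x "),
      "mm\n  origin (", paste(signif(x$origin, 4), collapse = ", "), ") mm",
      if (!isTRUE(all.equal(x$direction, diag(3), tolerance = 1e-12)))
        "\n  oblique direction matrix" else "", "\n", sep = " ")
  invisible(x)
}

is_image_grid <- function(x) inherits(x, "image_grid")

#' Voxel volume of a grid
#'
#' @param grid an [image_grid()].
#' @return Voxel volume in mm^3.
#' @export
voxel_volume <- function(grid) prod(grid$spacing)

#' Extract the grid of an image or field
#'
#' @param x any package image/field object (or an [image_grid()] itself).
#' @return The associated [image_grid()].
#' @export
grid_of <- function(x) {
  if (is_image_grid(x)) return(x)
  if (inherits(x, "staggered_field")) return(x$grid)
  g <- attr(x, "grid", exact = TRUE)
  if (is.null(g)) stop("object carries no image grid", call. = FALSE)
  g
}

#' Compare the spatial metadata of two images or fields
#'
#' Downstream operations require all inputs to live on one grid; this check is
#' applied by every multi-image operation in the package.  Shapes must be
#' identical; spacing, origin and direction must agree within `tol`.
#'
#' @param a,b images, fields, or [image_grid()] objects.
#' @param tol numeric tolerance in mm (and absolute, for direction entries).
#'   The default absorbs header rounding across toolkits.
#' @return Invisibly `TRUE`; otherwise an error naming the differing field.
#' @export
assert_same_space <- function(a, b, tol = 1e-4) {
  ga <- grid_of(a); gb <- grid_of(b)
  if (!identical(ga$shape, gb$shape))
    stop(sprintf("grids differ in shape: (%s) vs (%s)",
                 paste(ga$shape, collapse = ","),
                 paste(gb$shape, collapse = ",")), call. = FALSE)
  for (fld in c("spacing", "origin")) {
    d <- max(abs(ga[[fld]] - gb[[fld]]))
    if (d > tol)
      stop(sprintf("grids differ in %s by %.3g mm (tol %.3g)", fld, d, tol),
           call. = FALSE)
  }
  d <- max(abs(ga$direction - gb$direction))
  if (d > tol)
    stop(sprintf("grids differ in direction by %.3g (tol %.3g)", d, tol),
         call. = FALSE)
  invisible(TRUE)
}
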
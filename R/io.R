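#' Read a 3D image or displacement field
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`) and uncompressed MetaImage
#' (`.mha`, `.mhd`).  Grid metadata (spacing, origin, direction) is taken
#' from the header; NIfTI geometry is read from the sform/qform matrix.
#'
#' @param path file to read.
#' @param kind what to construct: `"scalar"` (default), `"label"` (validated
#'   against the three-regime value set \{0,1,2\}), `"roi"` (arbitrary
#'   non-negative integer parcellation), `"atrophy"`, or `"displacement"`
#'   (3-component vector image, world-mm displacements).
#' @return A [scalar_image()], [label_image()], [roi_segmentation()],
#'   [atrophy_map()] or [displacement_field()].
#' @seealso [write_image()]
#' @export
read_image <- function(path, kind = c("scalar", "label", "roi", "atrophy",
                                      "displacement")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- switch(io_format(path),
                nifti = read_nifti_raw(path),
                meta  = read_meta_raw(path))
  vals <- raw$values
  nd <- length(dim(vals))
  if (kind == "displacement") {
    if (nd == 5L && dim(vals)[4] == 1L)       # NIfTI vector convention
      vals <- array(vals, dim = dim(vals)[c(1:3, 5)])
    if (length(dim(vals)) != 4L || dim(vals)[4] != 3L)
      stop("not a 3-component vector image: ", path, call. = FALSE)
    return(displacement_field(vals, raw$grid))
  }
  if (nd != 3L) stop("not a 3D scalar image: ", path, call. = FALSE)
  switch(kind,
         scalar = scalar_image(vals, raw$grid),
         label  = label_image(vals, raw$grid),
         roi    = roi_segmentation(vals, raw$grid),
         atrophy = atrophy_map(vals, raw$grid))
}

#' Write a 3D image or displacement field
#'
#' The extension selects the format (`.nii`/`.nii.gz` NIfTI-1,
#' `.mha`/`.mhd` MetaImage).  Label images are stored as 32-bit integers,
#' everything else as 64-bit floats, so write/read round trips are exact.
#' Displacement fields are written as 3-component vector images
#' (5D NIfTI with vector intent, or MetaImage with three channels), with
#' world-mm components in (x, y, z) order.
#'
#' @param image any package image or field object.
#' @param path destination file.
#' @return Invisibly `path`.
#' @export
write_image <- function(image, path) {
  grid <- grid_of(image)
  integerish <- inherits(image, "label_image") ||
    inherits(image, "roi_segmentation")
  vals <- as_array(image)
  if (inherits(image, "displacement_field"))
    vals <- array(vals, dim = c(grid$shape, 1L, 3L))  # NIfTI vector layout
  switch(io_format(path),
         nifti = write_nifti_raw(vals, grid, path, integerish),
         meta  = write_meta_raw(vals, grid, path, integerish,
                                vector = inherits(image, "displacement_field")))
  invisible(path)
}

io_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.mh[ad]$", path, ignore.case = TRUE)) return("meta")
  stop("unsupported image format (use .nii, .nii.gz, .mha or .mhd): ", path,
       call. = FALSE)
}

## ---- NIfTI ------------------------------------------------------------

read_nifti_raw <- function(path) {
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  spacing <- sqrt(colSums(rot^2))
  direction <- sweep(rot, 2, spacing, "/")
  grid <- image_grid(dim(img)[1:3], spacing = spacing, origin = xf[1:3, 4],
                     direction = direction)
  vals <- as.array(img)
  attributes(vals) <- list(dim = dim(img))
  list(values = vals, grid = grid)
}

write_nifti_raw <- function(vals, grid, path, integerish) {
  img <- RNifti::asNifti(vals)
  m <- diag(4)
  m[1:3, 1:3] <- grid$direction %*% diag(grid$spacing)
  m[1:3, 4] <- grid$origin
  RNifti::sform(img) <- structure(m, code = 2L)
  if (length(dim(vals)) == 5L) img$intent_code <- 1007L  # vector
  RNifti::writeNifti(img, path,
                     datatype = if (integerish) "int32" else "double")
}

## ---- MetaImage --------------------------------------------------------
## Minimal reader/writer for the uncompressed MetaImage dialect
## (MET_* element types, optional ElementNumberOfChannels, LOCAL or
## separate-file data, little-endian).

meta_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_UINT   = list(what = "integer", size = 4L, signed = TRUE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE))

read_meta_raw <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  ## header is ASCII key = value lines; data begins after ElementDataFile line
  nl <- which(bytes == as.raw(10L))
  hdr_lines <- character(); data_offset <- NA_integer_
  start <- 1L
  for (p in nl) {
    line <- rawToChar(bytes[start:(p - 1L)])
    hdr_lines <- c(hdr_lines, line)
    start <- p + 1L
    if (grepl("^\\s*ElementDataFile", line)) { data_offset <- p; break }
  }
  if (is.na(data_offset)) stop("malformed MetaImage header: ", path,
                               call. = FALSE)
  kv <- strsplit(sub("\\s*$", "", hdr_lines), "\\s*=\\s*")
  hdr <- stats::setNames(vapply(kv, function(x) paste(x[-1], collapse = "="),
                                ""),
                         vapply(kv, `[[`, "", 1))
  names(hdr) <- trimws(names(hdr))
  num <- function(key, default = NULL) {
    if (!key %in% names(hdr)) return(default)
    as.numeric(strsplit(trimws(hdr[[key]]), "\\s+")[[1]])
  }
  if ("CompressedData" %in% names(hdr) &&
      identical(trimws(hdr[["CompressedData"]]), "True"))
    stop("compressed MetaImage data is not supported", call. = FALSE)
  dims <- as.integer(num("DimSize"))
  spacing <- num("ElementSpacing", rep(1, 3))
  origin <- num("Offset", rep(0, 3))
  tm <- num("TransformMatrix", as.vector(t(diag(3))))
  direction <- matrix(tm, 3, 3, byrow = TRUE)
  nchan <- as.integer(num("ElementNumberOfChannels", 1))
  type <- meta_types[[trimws(hdr[["ElementType"]])]]
  if (is.null(type)) stop("unsupported MetaImage ElementType", call. = FALSE)
  n <- prod(dims) * nchan
  datafile <- trimws(hdr[["ElementDataFile"]])
  if (identical(datafile, "LOCAL")) {
    data <- bytes[(data_offset + 1L):length(bytes)]
    vals <- readBin(data, type$what, n = n, size = type$size,
                    signed = type$signed, endian = "little")
  } else {
    rawpath <- file.path(dirname(path), datafile)
    vals <- readBin(rawpath, type$what, n = n, size = type$size,
                    signed = type$signed, endian = "little")
  }
  if (length(vals) != n) stop("truncated MetaImage data: ", path, call. = FALSE)
  vals <- if (nchan > 1L) {
    a <- array(vals, dim = c(nchan, dims))          # channel fastest on disk
    array(aperm(a, c(2:4, 1)), dim = c(dims, 1L, nchan))
  } else array(vals, dim = dims)
  grid <- image_grid(dims, spacing = spacing, origin = origin,
                     direction = direction)
  list(values = vals, grid = grid)
}

write_meta_raw <- function(vals, grid, path, integerish, vector = FALSE) {
  nchan <- if (vector) 3L else 1L
  type <- if (integerish) "MET_INT" else "MET_DOUBLE"
  size <- if (integerish) 4L else 8L
  local <- grepl("\\.mha$", path, ignore.case = TRUE)
  datafile <- if (local) "LOCAL" else
    paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    paste("TransformMatrix =",
          paste(format(as.vector(t(grid$direction)), digits = 17),
                collapse = " ")),
    paste("Offset =", paste(format(grid$origin, digits = 17), collapse = " ")),
    paste("ElementSpacing =",
          paste(format(grid$spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(grid$shape, collapse = " ")),
    if (nchan > 1L) paste("ElementNumberOfChannels =", nchan),
    paste("ElementType =", type),
    paste("ElementDataFile =", datafile))
  flat <- if (vector) {
    a <- array(vals, dim = c(grid$shape, nchan))
    as.vector(aperm(a, c(4, 1, 2, 3)))
  } else as.vector(vals)
  if (integerish) flat <- as.integer(flat)
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (local) {
    writeBin(flat, con, size = size, endian = "little")
  } else {
    rawcon <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(rawcon), add = TRUE)
    writeBin(flat, rawcon, size = size, endian = "little")
  }
  invisible(path)
}

#' Read an ROI atrophy table
#'
#' A two-column CSV (`label,value`) mapping ROI labels to per-step fractional
#' atrophy values, as consumed by [atrophy_from_table()].
#'
#' @param path CSV file with columns `label` and `value` (header optional if
#'   the first row parses as numbers).
#' @return Named numeric vector: values named by ROI label.
#' @export
read_atrophy_table <- function(path) {
  df <- utils::read.csv(path, header = TRUE,
                        col.names = c("label", "value"))[, 1:2]
  if (is.character(df$label) || is.character(df$value)) # headerless file
    df <- utils::read.csv(path, header = FALSE,
                          col.names = c("label", "value"))
  tab <- stats::setNames(as.numeric(df$value), as.integer(df$label))
  if (anyDuplicated(names(tab))) stop("duplicate ROI labels in table",
                                      call. = FALSE)
  if (any(!is.finite(tab))) stop("non-finite atrophy value in table",
                                 call. = FALSE)
  tab
}
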
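#' 3-D image grid with physical geometry
#'
#' An `image_grid` couples a 3-D scalar intensity array with its physical
#' voxel spacing and origin, both in millimetres. Axis order is (x, y, z)
#' throughout the package: the first array index runs along the patient
#' left-right axis, matching the in-memory (column-major, x fastest) order
#' of NIfTI voxel data, so no axis permutation happens anywhere. Voxel
#' indices are 0-based in world-coordinate arithmetic: the centre of voxel
#' (i, j, k) lies at `origin + c(i, j, k) * spacing` (voxel-centre
#' convention).
#'
#' @param values numeric 3-D array of intensities (HU-like).
#' @param spacing numeric length-3, mm per voxel along (x, y, z); all > 0.
#' @param origin numeric length-3, world position (mm) of voxel (0, 0, 0).
#' @return An object of class `image_grid` with fields `values`, `spacing`,
#'   `origin`.
#' @examples
#' g <- image_grid(array(0, c(8, 8, 4)), spacing = c(1.17, 1.17, 3))
#' dim(g)
#' @export
image_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array", call. = FALSE)
  if (!all(is.finite(values)))
    stop("`values` must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers (mm)", call. = FALSE)
  storage.mode(values) <- "double"
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "image_grid")
}

#' @export
dim.image_grid <- function(x) dim(x$values)

#' @export
print.image_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<image_grid> %d x %d x %d voxels, spacing (%.4g, %.4g, %.4g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.4g, %.4g, %.4g) mm, intensity range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.array.image_grid <- function(x, ...) x$values

is_binary_array <- function(a) all(a == 0 | a == 1)

#' Named binary organ masks on a shared grid geometry
#'
#' A `structure_set` holds one binary 3-D mask per organ, all sharing the
#' same shape, spacing and origin.
#'
#' @param masks named list of binary 3-D arrays (values 0/1), or of
#'   [image_grid] objects whose geometry matches.
#' @param spacing,origin shared geometry (mm), as in [image_grid].
#' @return An object of class `structure_set` with fields `masks`
#'   (named list of 0/1 arrays), `spacing`, `origin`.
#' @export
structure_set <- function(masks, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.list(masks) || is.null(names(masks)) || any(names(masks) == ""))
    stop("`masks` must be a named list", call. = FALSE)
  masks <- lapply(masks, function(m) {
    if (inherits(m, "image_grid")) m <- m$values
    if (!is.array(m) || length(dim(m)) != 3L)
      stop("each mask must be a 3-D array", call. = FALSE)
    if (!is_binary_array(m)) stop("mask values must be 0/1", call. = FALSE)
    storage.mode(m) <- "double"
    m
  })
  d0 <- dim(masks[[1]])
  for (m in masks)
    if (!identical(dim(m), d0))
      stop("all masks must share one shape", call. = FALSE)
  structure(list(masks = masks, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  d <- dim(x$masks[[1]])
  cat(sprintf("<structure_set> %d organ(s) on %d x %d x %d grid: %s\n",
              length(x$masks), d[1], d[2], d[3],
              paste(names(x$masks), collapse = ", ")))
  invisible(x)
}

#' Extract a rectangular patch from a grid
#'
#' Returns the sub-array at a 0-based voxel `offset` with the requested
#' `size`. Out-of-bounds requests are an error; there is no silent
#' clipping.
#'
#' @param grid an [image_grid], or a bare 3-D array.
#' @param offset integer length-3, 0-based voxel offset of the patch corner.
#' @param size integer length-3 patch extent in voxels.
#' @return An object of class `patch` with fields `values` (3-D array) and
#'   `offset` (the 0-based corner).
#' @examples
#' g <- image_grid(array(seq_len(64), c(4, 4, 4)))
#' p <- extract_patch(g, c(1, 1, 1), c(2, 2, 2))
#' p$values[1, 1, 1] == g$values[2, 2, 2]
#' @export
extract_patch <- function(grid, offset, size) {
  vals <- if (inherits(grid, "image_grid")) grid$values else grid
  d <- dim(vals)
  offset <- as.integer(offset); size <- as.integer(size)
  if (length(offset) != 3L || length(size) != 3L)
    stop("`offset` and `size` must have length 3", call. = FALSE)
  if (any(offset < 0L) || any(size < 1L) || any(offset + size > d))
    stop(sprintf(
      "patch out of bounds: offset (%s) + size (%s) exceeds grid (%s)",
      paste(offset, collapse = ","), paste(size, collapse = ","),
      paste(d, collapse = ",")), call. = FALSE)
  v <- vals[offset[1] + seq_len(size[1]),
            offset[2] + seq_len(size[2]),
            offset[3] + seq_len(size[3]), drop = FALSE]
  structure(list(values = v, offset = offset), class = "patch")
}

#' @export
print.patch <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<patch> %d x %d x %d at offset (%s)\n", d[1], d[2], d[3],
              paste(x$offset, collapse = ", ")))
  invisible(x)
}
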
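#' Read a 3-D NIfTI volume as an image grid
#'
#' Spacing and origin are taken from the file's spatial transform (sform,
#' falling back to qform): spacing as the Euclidean norms of the affine's
#' first three columns, origin as its translation. Only 3-D payloads are
#' accepted.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [image_grid].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1, drop = TRUE]
  if (length(dim(a)) != 3L)
    stop("not a 3-D volume: ", path, " has rank ", length(dim(a)),
         call. = FALSE)
  xf <- RNifti::xform(img, useQuaternionFirst = FALSE)
  spacing <- sqrt(colSums(xf[1:3, 1:3]^2))
  origin <- xf[1:3, 4]
  attributes(a) <- list(dim = dim(a))
  storage.mode(a) <- "double"
  image_grid(a, spacing = spacing, origin = origin)
}

#' Write an image grid to NIfTI
#'
#' The spatial transform is written as a diagonal RAS affine
#' `diag(spacing)` with translation `origin` (sform, code 2).
#' `datatype` "double" (the default for intensity images) round-trips
#' values bitwise; masks should be written as "uint8" and probability maps
#' as "float".
#'
#' @param grid an [image_grid].
#' @param path output path (`.nii` or `.nii.gz`); the parent directory must
#'   exist.
#' @param datatype one of "double", "float", "uint8".
#' @return Invisibly, `path`.
#' @export
write_image <- function(grid, path, datatype = c("double", "float", "uint8")) {
  datatype <- match.arg(datatype)
  stopifnot(inherits(grid, "image_grid"))
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  aff <- diag(c(grid$spacing, 1))
  aff[1:3, 4] <- grid$origin
  img <- RNifti::asNifti(grid$values, internal = FALSE)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read a structure set from a directory with a JSON sidecar
#'
#' The sidecar (default `masks.json`) maps organ names to NIfTI filenames,
#' e.g. `{"heart": "heart.nii.gz"}`. All masks must share the grid
#' geometry of the first.
#'
#' @param dir directory containing the sidecar and mask files.
#' @param sidecar sidecar filename within `dir`.
#' @return A [structure_set].
#' @export
read_structure_set <- function(dir, sidecar = "masks.json") {
  side <- file.path(dir, sidecar)
  if (!file.exists(side)) stop("sidecar not found: ", side, call. = FALSE)
  mapping <- jsonlite::fromJSON(side)
  grids <- lapply(mapping, function(f) read_image(file.path(dir, f)))
  g0 <- grids[[1]]
  masks <- lapply(grids, function(g) {
    m <- round(g$values)
    if (!is_binary_array(m)) stop("mask file is not binary", call. = FALSE)
    m
  })
  structure_set(masks, spacing = g0$spacing, origin = g0$origin)
}

#' Write a structure set as per-organ NIfTI masks plus a JSON sidecar
#'
#' Masks are stored as unsigned 8-bit volumes with values 0/1.
#'
#' @param sset a [structure_set].
#' @param dir output directory (created if missing).
#' @param sidecar sidecar filename.
#' @return Invisibly, the sidecar path.
#' @export
write_structure_set <- function(sset, dir, sidecar = "masks.json") {
  stopifnot(inherits(sset, "structure_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mapping <- list()
  for (organ in names(sset$masks)) {
    fname <- paste0(organ, ".nii.gz")
    g <- image_grid(sset$masks[[organ]], sset$spacing, sset$origin)
    write_image(g, file.path(dir, fname), datatype = "uint8")
    mapping[[organ]] <- fname
  }
  side <- file.path(dir, sidecar)
  jsonlite::write_json(mapping, side, auto_unbox = TRUE, pretty = TRUE)
  invisible(side)
}
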
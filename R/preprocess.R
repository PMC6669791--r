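#' Trilinear resampling to a target voxel spacing
#'
#' Resamples the intensity field at the voxel centres of the target grid
#' using trilinear interpolation. The output shape is
#' `ceiling(shape * spacing / target_spacing)` per axis (never discarding
#' physical extent) and the origin is preserved. Sampling positions beyond
#' the source grid use edge-value extension, which avoids introducing
#' spurious air at the body border.
#'
#' @param grid an [image_grid].
#' @param target_spacing numeric length-3 target spacing in mm (> 0).
#' @return An [image_grid] at the target spacing.
#' @export
resample_trilinear <- function(grid, target_spacing) {
  stopifnot(inherits(grid, "image_grid"))
  ts <- as.numeric(target_spacing)
  if (length(ts) != 3L || any(!is.finite(ts)) || any(ts <= 0))
    stop("`target_spacing` must be 3 positive numbers", call. = FALSE)
  d <- dim(grid$values)
  nd <- as.integer(ceiling(d * grid$spacing / ts))
  # continuous source index (0-based) of each target voxel centre, clamped
  # to the grid for edge-value extension
  u <- lapply(1:3, function(ax) {
    pmin(pmax((seq_len(nd[ax]) - 1) * ts[ax] / grid$spacing[ax], 0), d[ax] - 1)
  })
  i0 <- lapply(1:3, function(ax) pmin(floor(u[[ax]]), d[ax] - 1))
  fr <- lapply(1:3, function(ax) u[[ax]] - i0[[ax]])
  i1 <- lapply(1:3, function(ax) pmin(i0[[ax]] + 1, d[ax] - 1))

  ix0 <- as.integer(i0[[1]]) + 1L; ix1 <- as.integer(i1[[1]]) + 1L
  iy0 <- as.integer(i0[[2]]) + 1L; iy1 <- as.integer(i1[[2]]) + 1L
  iz0 <- as.integer(i0[[3]]) + 1L; iz1 <- as.integer(i1[[3]]) + 1L
  fx <- fr[[1]]; fy <- fr[[2]]; fz <- fr[[3]]

  v <- grid$values
  corner <- function(ix, iy, iz) v[ix, iy, iz, drop = FALSE]
  wx1 <- array(fx, dim = nd); wx0 <- 1 - wx1
  wy1 <- array(rep(fy, each = nd[1]), dim = nd); wy0 <- 1 - wy1
  wz1 <- array(rep(fz, each = nd[1] * nd[2]), dim = nd); wz0 <- 1 - wz1
  out <-
    corner(ix0, iy0, iz0) * wx0 * wy0 * wz0 +
    corner(ix1, iy0, iz0) * wx1 * wy0 * wz0 +
    corner(ix0, iy1, iz0) * wx0 * wy1 * wz0 +
    corner(ix1, iy1, iz0) * wx1 * wy1 * wz0 +
    corner(ix0, iy0, iz1) * wx0 * wy0 * wz1 +
    corner(ix1, iy0, iz1) * wx1 * wy0 * wz1 +
    corner(ix0, iy1, iz1) * wx0 * wy1 * wz1 +
    corner(ix1, iy1, iz1) * wx1 * wy1 * wz1
  image_grid(out, spacing = ts, origin = grid$origin)
}

#' In-plane (axial) downsampling by an integer factor
#'
#' Multiplies the in-plane (x, y) spacing by `factor`, leaving the slice
#' thickness untouched; implemented via [resample_trilinear()]. With the
#' common 1.17 mm / 3 mm working resolution and factor 2 this yields the
#' 2.34 mm in-plane spacing used for whole-volume training.
#'
#' @param grid an [image_grid].
#' @param factor integer >= 1.
#' @return An [image_grid].
#' @export
downsample_axial <- function(grid, factor) {
  factor <- as.integer(factor)
  if (length(factor) != 1L || is.na(factor) || factor < 1L)
    stop("`factor` must be an integer >= 1", call. = FALSE)
  if (factor == 1L) return(grid)
  resample_trilinear(grid, grid$spacing * c(factor, factor, 1))
}

#' Resample a binary mask to a target spacing
#'
#' Trilinearly interpolates the 0/1 field (as done for the structure sets
#' alongside the CT volumes) and thresholds at 0.5, so the result is again
#' binary.
#'
#' @param mask binary 3-D array or an [image_grid] holding 0/1 values.
#' @param target_spacing numeric length-3 (mm).
#' @param spacing source spacing, required when `mask` is a bare array.
#' @return An [image_grid] with 0/1 values at the target spacing.
#' @export
resample_mask <- function(mask, target_spacing, spacing = NULL) {
  if (!inherits(mask, "image_grid")) {
    if (is.null(spacing)) stop("`spacing` required for a bare array",
                               call. = FALSE)
    mask <- image_grid(mask, spacing = spacing)
  }
  if (!is_binary_array(mask$values))
    stop("`mask` must be binary (0/1)", call. = FALSE)
  res <- resample_trilinear(mask, target_spacing)
  res$values <- (res$values >= 0.5) * 1
  res
}

#' Window and quantize intensities to 8-bit
#'
#' Linearly maps the window `[lo, hi]` to `[0, 255]`, clips outside
#' values, and rounds half away from zero. The default window
#' (-1024, 1024) HU covers the full CT soft-tissue/air range.
#'
#' @param grid an [image_grid] (or numeric array).
#' @param window numeric length-2 `(lo, hi)` with `lo < hi`.
#' @return Same type as the input, with integer values in 0..255.
#' @export
quantize_uint8 <- function(grid, window = c(-1024, 1024)) {
  lo <- window[1]; hi <- window[2]
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop("window must satisfy lo < hi", call. = FALSE)
  vals <- if (inherits(grid, "image_grid")) grid$values else grid
  q <- (vals - lo) / (hi - lo) * 255
  q <- pmin(pmax(q, 0), 255)
  q <- floor(q + 0.5)  # half away from zero (values are non-negative here)
  if (inherits(grid, "image_grid")) {
    out <- grid
    out$values <- array(q, dim = dim(vals))
    out
  } else {
    array(q, dim = dim(vals))
  }
}
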
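#' Full-image inference: per-organ probability maps in one forward pass
#'
#' Runs a single evaluation-mode forward pass (dropout off, batch-norm
#' running statistics) over the whole volume and returns one probability
#' grid per organ, each with the input's spatial shape.
#'
#' @param net a `seg_network` (bib-type; shape-preserving).
#' @param grid an [image_grid].
#' @param organs optional organ names for the output channels.
#' @return Named list of [image_grid]s with values in [0, 1].
#' @export
infer_full_image <- function(net, grid, organs = NULL) {
  stopifnot(inherits(grid, "image_grid"))
  prob <- predict(net, grid)
  n_ch <- dim(prob)[4]
  if (is.null(organs)) organs <- paste0("organ", seq_len(n_ch))
  if (length(organs) != n_ch)
    stop("`organs` must name each output channel", call. = FALSE)
  out <- lapply(seq_len(n_ch), function(k)
    image_grid(prob[, , , k], spacing = grid$spacing, origin = grid$origin))
  names(out) <- organs
  out
}

#' Tiled patch-wise inference for valid-convolution networks
#'
#' Tiles the volume with input patches whose output patches abut exactly
#' (no averaging): because all convolutions are valid, the assembled
#' output equals a single big-patch pass on the covered interior
#' identically. The border that the valid convolutions cannot predict is
#' flagged as `NA`.
#'
#' @param net a valid-convolution `seg_network` (unet3).
#' @param grid an [image_grid].
#' @param patch_size input patch extent per axis (each a multiple of 4 and
#'   at least the network's minimum admissible size).
#' @return An (X, Y, Z, out_channels) array of probabilities, `NA` outside
#'   the covered interior; attribute `valid_range` gives the 1-based
#'   inclusive index range of the interior per axis.
#' @export
infer_patchwise <- function(net, grid, patch_size) {
  stopifnot(inherits(net, "unet3"), inherits(grid, "image_grid"))
  d <- dim(grid$values)
  ps <- as.integer(patch_size)
  if (any(vapply(ps, function(i) is.na(unet3_out_extent(i)), logical(1))))
    stop(sprintf("patch size inadmissible; minimum is %d and extents must be divisible by 4",
                 net$min_input), call. = FALSE)
  if (any(ps > d)) stop("patch grid cannot cover the volume", call. = FALSE)
  shrink <- net$shrink; mar <- net$margin
  out_sz <- ps - shrink
  n_out <- net$config$out_channels
  prob <- array(NA_real_, dim = c(d, n_out))
  # offsets stay congruent to 0 mod 4 so pooling grids align between tiles
  offsets <- lapply(1:3, function(ax) {
    o <- seq(0L, d[ax] - ps[ax], by = out_sz[ax])
    last <- ((d[ax] - ps[ax]) %/% 4L) * 4L
    unique(c(o, last))
  })
  for (ox in offsets[[1]]) for (oy in offsets[[2]]) for (oz in offsets[[3]]) {
    off <- c(ox, oy, oz)
    p <- extract_patch(grid, off, ps)
    y <- predict(net, p$values)
    idx <- lapply(1:3, function(ax) off[ax] + mar + seq_len(out_sz[ax]))
    prob[idx[[1]], idx[[2]], idx[[3]], ] <- y
  }
  valid <- vapply(1:3, function(ax)
    c(mar + 1L, max(offsets[[ax]]) + mar + out_sz[ax]), integer(2))
  attr(prob, "valid_range") <- valid
  prob
}

#' Largest connected component of a binary mask
#'
#' Components are found by flood fill under the requested connectivity;
#' the largest is kept. Ties are broken deterministically in favour of the
#' component containing the lexicographically smallest voxel (labels are
#' assigned in raster-scan order). An empty mask is returned unchanged.
#'
#' @param mask binary 3-D array or [image_grid].
#' @param connectivity 6, 18 or 26.
#' @return Same type as the input, containing only the largest component.
#' @export
largest_component <- function(mask, connectivity = 26) {
  vals <- if (inherits(mask, "image_grid")) mask$values else mask
  if (!is_binary_array(vals)) stop("`mask` must be binary", call. = FALSE)
  if (!connectivity %in% c(6, 18, 26))
    stop("`connectivity` must be 6, 18 or 26", call. = FALSE)
  if (sum(vals) == 0) return(mask)
  lab <- label_components_cpp(array(as.integer(vals), dim = dim(vals)),
                              as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)  # first maximum: lowest label wins ties
  out <- (lab == keep) * 1
  if (inherits(mask, "image_grid")) {
    mask$values <- out
    mask
  } else out
}

#' Spacing-aware Gaussian smoothing of a 3-D field
#'
#' Separable Gaussian with standard deviation `sigma_mm` (mm), converted
#' per axis to voxels using the spacing; edges use replication. A sigma of
#' 0 returns the input unchanged.
#'
#' @param grid an [image_grid] (or array with `spacing` given).
#' @param sigma_mm standard deviation in mm.
#' @param spacing spacing for bare arrays.
#' @return Same type as the input.
#' @export
gaussian_smooth <- function(grid, sigma_mm, spacing = NULL) {
  if (sigma_mm < 0) stop("`sigma_mm` must be >= 0", call. = FALSE)
  vals <- if (inherits(grid, "image_grid")) grid$values else grid
  sp <- if (inherits(grid, "image_grid")) grid$spacing else spacing
  if (is.null(sp)) stop("`spacing` required for a bare array", call. = FALSE)
  if (sigma_mm > 0) {
    d <- dim(vals)
    for (ax in 1:3) {
      sig <- sigma_mm / sp[ax]
      r <- max(1L, ceiling(3 * sig))
      k <- exp(-(seq(-r, r))^2 / (2 * sig^2))
      k <- k / sum(k)
      acc <- array(0, dim = d)
      for (j in seq_along(k)) {
        sh <- j - r - 1L
        src <- pmin(pmax(seq_len(d[ax]) + sh, 1L), d[ax])  # edge replication
        acc <- acc + k[j] * switch(ax,
          vals[src, , , drop = FALSE],
          vals[, src, , drop = FALSE],
          vals[, , src, drop = FALSE])
      }
      vals <- acc
    }
  }
  if (inherits(grid, "image_grid")) {
    grid$values <- vals
    grid
  } else vals
}

#' Post-processing specification
#'
#' @param gaussian_sigma_mm Gaussian smoothing standard deviation (mm).
#' @param binarize_threshold probability threshold in (0, 1).
#' @param connectivity connectivity for the largest-component step.
#' @return An object of class `postprocess_spec`.
#' @export
postprocess_spec <- function(gaussian_sigma_mm = 1.5,
                             binarize_threshold = 0.5,
                             connectivity = 26) {
  if (gaussian_sigma_mm < 0) stop("sigma must be >= 0", call. = FALSE)
  if (binarize_threshold <= 0 || binarize_threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  structure(list(gaussian_sigma_mm = gaussian_sigma_mm,
                 binarize_threshold = binarize_threshold,
                 connectivity = connectivity),
            class = "postprocess_spec")
}

#' Clinical post-processing of a probability map
#'
#' Pipeline: trilinear upsampling of the probability map to the target
#' geometry, Gaussian smoothing (applied to the probabilities, before
#' binarization, to avoid re-binarization artifacts), thresholding, and
#' retention of the largest connected component. An empty post-threshold
#' mask is returned empty with attribute `empty_prediction = TRUE` and a
#' warning, so cohort evaluation can exclude the case.
#'
#' @param prob probability [image_grid] at working resolution.
#' @param target an [image_grid] (or list with `spacing`) defining the
#'   output geometry.
#' @param spec a [postprocess_spec].
#' @return A binary [image_grid] at the target spacing.
#' @export
postprocess <- function(prob, target, spec = postprocess_spec()) {
  stopifnot(inherits(prob, "image_grid"), inherits(spec, "postprocess_spec"))
  target_spacing <- if (inherits(target, "image_grid")) target$spacing
                    else target$spacing
  up <- resample_trilinear(prob, target_spacing)
  sm <- gaussian_smooth(up, spec$gaussian_sigma_mm)
  bin <- (sm$values >= spec$binarize_threshold) * 1
  if (sum(bin) == 0) {
    warning("empty mask after thresholding", call. = FALSE)
    out <- image_grid(bin, spacing = sm$spacing, origin = sm$origin)
    attr(out, "empty_prediction") <- TRUE
    return(out)
  }
  out <- largest_component(image_grid(bin, spacing = sm$spacing,
                                      origin = sm$origin),
                           spec$connectivity)
  attr(out, "empty_prediction") <- FALSE
  out
}
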
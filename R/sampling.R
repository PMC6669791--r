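#' Configuration for the training-patch samplers
#'
#' Training patches are drawn by a mixture of four samplers: an entropy
#' sampler (rejects patches from featureless regions such as surrounding
#' air), two shell samplers (patch centre within 20 or 40 mm of a
#' ground-truth structure surface) and a mask sampler (patch intersects
#' the ground truth). Admissibility is decided on the patch CENTRE voxel;
#' shell distances are true Euclidean mm under anisotropic spacing.
#'
#' @param patch_size integer length-3 patch extent (voxels).
#' @param entropy_threshold minimum Shannon entropy (bits) of the 256-bin
#'   intensity histogram for the entropy sampler.
#' @param shell_distances_mm numeric vector of shell radii (mm).
#' @param sampler_weights nonnegative weights over
#'   (entropy, shell..., mask), in that order; need not sum to 1.
#' @param quantize_window intensity window used for the 8-bit histogram.
#' @param max_rejects rejection-sampling budget before a sampler-exhausted
#'   error.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(patch_size = c(32, 32, 16),
                           entropy_threshold = 2.0,
                           shell_distances_mm = c(20, 40),
                           sampler_weights = NULL,
                           quantize_window = c(-1024, 1024),
                           max_rejects = 10000L) {
  n_samplers <- 2L + length(shell_distances_mm)
  if (is.null(sampler_weights)) sampler_weights <- rep(1, n_samplers)
  if (length(sampler_weights) != n_samplers || any(sampler_weights < 0) ||
      sum(sampler_weights) <= 0)
    stop("`sampler_weights` must be ", n_samplers,
         " nonnegative weights with positive sum", call. = FALSE)
  structure(list(patch_size = as.integer(patch_size),
                 entropy_threshold = entropy_threshold,
                 shell_distances_mm = as.numeric(shell_distances_mm),
                 sampler_weights = as.numeric(sampler_weights),
                 quantize_window = quantize_window,
                 max_rejects = as.integer(max_rejects)),
            class = "sampler_config")
}

#' Shannon entropy (bits) of a patch's 8-bit intensity histogram
#'
#' The patch is windowed and quantized to 0..255 and the entropy
#' `-sum f log2 f` of the 256-bin relative frequency histogram computed.
#' A constant patch has 0 bits; two equally frequent intensities give
#' 1 bit.
#'
#' @param patch a `patch`, [image_grid] or numeric array.
#' @param window quantization window `(lo, hi)`.
#' @return Entropy in bits.
#' @export
patch_entropy <- function(patch, window = c(-1024, 1024)) {
  v <- if (inherits(patch, "patch")) patch$values
       else if (inherits(patch, "image_grid")) patch$values
       else patch
  q <- quantize_uint8(array(as.numeric(v), dim = dim(v) %||% length(v)),
                      window)
  f <- tabulate(as.integer(q) + 1L, nbins = 256L) / length(q)
  f <- f[f > 0]
  -sum(f * log2(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Offsets (0-based) such that a patch of `size` centred at voxel `center`
# (1-based index) fits the grid; NULL when it does not.
center_to_offset <- function(center, size, gdim) {
  off <- center - 1L - (size %/% 2L)
  if (any(off < 0L) || any(off + size > gdim)) return(NULL)
  off
}

# All 1-based centre positions admitting a patch of `size`.
valid_center_ranges <- function(size, gdim) {
  lapply(1:3, function(ax) {
    lo <- 1L + (size[ax] %/% 2L)                       # offset 0
    hi <- gdim[ax] - size[ax] + 1L + (size[ax] %/% 2L) # offset gdim - size
    if (hi < lo) integer(0) else lo:hi
  })
}

draw_valid_center <- function(size, gdim) {
  rng <- valid_center_ranges(size, gdim)
  if (any(lengths(rng) == 0))
    stop("patch larger than volume", call. = FALSE)
  vapply(rng, function(r) if (length(r) == 1L) r else sample(r, 1L),
         integer(1))
}

#' Entropy sampler: random patch with sufficiently rich intensity content
#'
#' Draws uniformly positioned candidate patches and rejects those whose
#' 8-bit histogram entropy does not exceed the threshold, up to the
#' rejection budget.
#'
#' @param grid an [image_grid].
#' @param cfg a [sampler_config].
#' @return A `patch`. Seed the R RNG beforehand for reproducible draws.
#' @export
sample_entropy <- function(grid, cfg) {
  gdim <- dim(grid$values)
  for (i in seq_len(cfg$max_rejects)) {
    ctr <- draw_valid_center(cfg$patch_size, gdim)
    off <- center_to_offset(ctr, cfg$patch_size, gdim)
    p <- extract_patch(grid, off, cfg$patch_size)
    if (patch_entropy(p, cfg$quantize_window) > cfg$entropy_threshold)
      return(p)
  }
  stop("entropy sampler exhausted its rejection budget (",
       cfg$max_rejects, " draws)", call. = FALSE)
}

#' Shell sampler: patch centred near a structure surface
#'
#' The admissible centres are all voxels whose Euclidean distance (mm) to
#' the mask surface is at most `distance_mm` — inside or outside the
#' structure — intersected with the positions where the patch fits; one is
#' drawn uniformly.
#'
#' @param grid an [image_grid].
#' @param mask binary ground-truth array (same shape).
#' @param distance_mm shell radius in mm (may be `Inf`).
#' @param cfg a [sampler_config].
#' @return A `patch`.
#' @export
sample_shell <- function(grid, mask, distance_mm, cfg) {
  if (inherits(mask, "image_grid")) mask <- mask$values
  if (sum(mask) == 0) stop("empty mask", call. = FALSE)
  gdim <- dim(grid$values)
  if (is.infinite(distance_mm)) {
    admissible <- array(TRUE, gdim)
  } else {
    dvol <- distance_to_surface(mask, grid$spacing)
    admissible <- dvol <= distance_mm
  }
  rng <- valid_center_ranges(cfg$patch_size, gdim)
  if (any(lengths(rng) == 0)) stop("patch larger than volume", call. = FALSE)
  fits <- array(FALSE, gdim)
  fits[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
  idx <- which(admissible & fits)
  if (length(idx) == 0)
    stop("no admissible shell-sampler centre", call. = FALSE)
  pick <- if (length(idx) == 1L) idx else sample(idx, 1L)
  ctr <- as.integer(arrayInd(pick, gdim))
  extract_patch(grid, center_to_offset(ctr, cfg$patch_size, gdim),
                cfg$patch_size)
}

#' Euclidean distance of every voxel centre to a mask's surface
#'
#' Computed with an exact separable (anisotropic) Euclidean distance
#' transform seeded at the surface voxels, so it agrees with exhaustive
#' nearest-surface-point search to floating-point precision.
#'
#' @param mask binary 3-D array.
#' @param spacing voxel spacing (mm).
#' @return 3-D array of distances in mm (0 on the surface itself).
#' @export
distance_to_surface <- function(mask, spacing = c(1, 1, 1)) {
  sp <- surface_points(mask, spacing = spacing, origin = c(0, 0, 0))
  surf_idx <- round(sweep(unclass(sp), 2, spacing, "/")) + 1
  ind <- array(0L, dim = dim(mask))
  ind[surf_idx] <- 1L
  edt_mm(ind, as.numeric(spacing))
}

#' Mask sampler: patch guaranteed to intersect the ground truth
#'
#' Rejection-samples patch positions until the patch contains at least one
#' ground-truth voxel.
#'
#' @inheritParams sample_shell
#' @return A `patch`.
#' @export
sample_mask <- function(grid, mask, cfg) {
  if (inherits(mask, "image_grid")) mask <- mask$values
  if (sum(mask) == 0) stop("empty mask", call. = FALSE)
  gdim <- dim(grid$values)
  for (i in seq_len(cfg$max_rejects)) {
    ctr <- draw_valid_center(cfg$patch_size, gdim)
    off <- center_to_offset(ctr, cfg$patch_size, gdim)
    mp <- extract_patch(mask, off, cfg$patch_size)
    if (sum(mp$values) > 0) return(extract_patch(grid, off, cfg$patch_size))
  }
  stop("mask sampler exhausted its rejection budget", call. = FALSE)
}

#' Precomputed sampler state for repeated draws from one case
#'
#' Shell-sampler admissibility needs the distance-to-surface field of the
#' ground-truth union mask, which is expensive to recompute per draw; this
#' precomputes the union mask and the admissible patch-centre index set
#' for each shell distance once, so subsequent draws are O(1) lookups.
#'
#' @param grid an [image_grid].
#' @param sset a [structure_set].
#' @param cfg a [sampler_config].
#' @return An opaque list passed to [composite_sampler()].
#' @export
sampler_state <- function(grid, sset, cfg) {
  gdim <- dim(grid$values)
  union_mask <- Reduce(pmax, sset$masks)
  rng <- valid_center_ranges(cfg$patch_size, gdim)
  if (any(lengths(rng) == 0)) stop("patch larger than volume", call. = FALSE)
  fits <- array(FALSE, gdim)
  fits[rng[[1]], rng[[2]], rng[[3]]] <- TRUE
  shell_idx <- NULL
  if (length(cfg$shell_distances_mm)) {
    dvol <- distance_to_surface(union_mask, grid$spacing)
    shell_idx <- lapply(cfg$shell_distances_mm, function(dmm)
      which((dvol <= dmm) & fits))
  }
  list(union_mask = union_mask, fits = fits, shell_idx = shell_idx,
       gdim = gdim)
}

#' Composite sampler: weighted mixture of entropy, shell and mask samplers
#'
#' Each draw first picks one of the component samplers with probability
#' proportional to `cfg$sampler_weights` (order: entropy, one entry per
#' shell distance, mask), then delegates; the label patch is the
#' ground-truth crop of every organ at the same offset. Shell and mask
#' samplers condition on the union of the organ masks.
#'
#' @param grid an [image_grid].
#' @param sset a [structure_set].
#' @param cfg a [sampler_config].
#' @param n number of draws.
#' @param state optional precomputed [sampler_state()] for this case.
#' @return A list of `n` draws, each a list with `image` (patch),
#'   `labels` ((X, Y, Z, organ) 0/1 array), `offset`, and `sampler` (the
#'   component used).
#' @export
composite_sampler <- function(grid, sset, cfg, n = 1, state = NULL) {
  if (is.null(state)) state <- sampler_state(grid, sset, cfg)
  union_mask <- state$union_mask
  gdim <- state$gdim
  nms <- c("entropy",
           paste0("shell", cfg$shell_distances_mm),
           "mask")
  w <- cfg$sampler_weights / sum(cfg$sampler_weights)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sample.int(length(nms), 1L, prob = w)
    p <- if (nms[k] == "entropy") {
      sample_entropy(grid, cfg)
    } else if (nms[k] == "mask") {
      sample_mask(grid, union_mask, cfg)
    } else {
      idx <- state$shell_idx[[k - 1L]]
      if (length(idx) == 0)
        stop("no admissible shell-sampler centre", call. = FALSE)
      pick <- if (length(idx) == 1L) idx else sample(idx, 1L)
      ctr <- as.integer(arrayInd(pick, gdim))
      extract_patch(grid, center_to_offset(ctr, cfg$patch_size, gdim),
                    cfg$patch_size)
    }
    labs <- vapply(sset$masks, function(m)
      extract_patch(m, p$offset, cfg$patch_size)$values,
      array(0, dim = cfg$patch_size))
    out[[i]] <- list(image = p, labels = labs, offset = p$offset,
                     sampler = nms[k])
  }
  out
}
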
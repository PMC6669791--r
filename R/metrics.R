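#' Sørensen-Dice coefficient between two binary masks
#'
#' `DSC = 2|X ∩ Y| / (|X| + |Y|)`, equivalently `2TP / (2TP + FP + FN)`.
#' When both masks are empty the coefficient is undefined: `NaN` is
#' returned with a warning rather than silently reporting 0 or 1, so
#' cohort evaluation can exclude the case explicitly.
#'
#' @param X,Y same-shaped binary arrays (0/1).
#' @return Dice coefficient in [0, 1], or `NaN` when both masks are empty.
#' @export
dice_coefficient <- function(X, Y) {
  if (inherits(X, "image_grid")) X <- X$values
  if (inherits(Y, "image_grid")) Y <- Y$values
  if (!identical(dim(X), dim(Y))) stop("shape mismatch", call. = FALSE)
  sx <- sum(X); sy <- sum(Y)
  if (sx + sy == 0) {
    warning("both masks empty: Dice undefined", call. = FALSE)
    return(NaN)
  }
  2 * sum(X * Y) / (sx + sy)
}

#' Overlap counts (TP/FP/FN/TN) between prediction and reference
#'
#' @param X predicted binary mask; @param Y reference binary mask.
#' @return Named list of voxel counts summing to the total voxel count.
#' @export
overlap_counts <- function(X, Y) {
  if (!identical(dim(X), dim(Y))) stop("shape mismatch", call. = FALSE)
  tp <- sum(X * Y)
  list(TP = tp, FP = sum(X) - tp, FN = sum(Y) - tp,
       TN = length(X) - sum(X) - sum(Y) + tp)
}

#' Soft Jaccard loss
#'
#' Differentiable relaxation of `1 - |X ∩ Y| / |X ∪ Y|` for a probability
#' map `p` against a binary reference `Y`: intersection `sum(p * y)`,
#' union `sum(p) + sum(y) - intersection`, ratio smoothed by `eps` to
#' avoid 0/0 on empty structures. Used as the back-propagation objective
#' during training.
#'
#' @param p array of per-voxel probabilities in [0, 1].
#' @param Y binary array of the same shape.
#' @param eps smoothing constant.
#' @return Scalar loss >= 0.
#' @export
jaccard_loss <- function(p, Y, eps = 1e-5) {
  if (!identical(dim(p), dim(Y))) stop("shape mismatch", call. = FALSE)
  inter <- sum(p * Y)
  union <- sum(p) + sum(Y) - inter
  1 - (inter + eps) / (union + eps)
}

# Gradient of the soft Jaccard loss w.r.t. p (used by the training loop).
jaccard_loss_grad <- function(p, Y, eps = 1e-5) {
  inter <- sum(p * Y)
  union <- sum(p) + sum(Y) - inter
  # d/dp_i of -(I+eps)/(U+eps): I' = y_i, U' = 1 - y_i
  -(Y * (union + eps) - (inter + eps) * (1 - Y)) / (union + eps)^2
}

#' Binary (per-voxel) classification accuracy
#'
#' Fraction of voxels whose thresholded probability (>= 0.5) equals the
#' reference label. Kept for reference: on heavily background-dominated
#' volumes it saturates near 1 even for empty predictions, which is why
#' overlap-based losses are used for training.
#'
#' @param p probability array; @param Y binary array, same shape.
#' @return Fraction in [0, 1].
#' @export
binary_accuracy <- function(p, Y) {
  if (!identical(dim(p), dim(Y))) stop("shape mismatch", call. = FALSE)
  mean(((p >= 0.5) * 1) == Y)
}

#' Surface points of a binary mask in world coordinates
#'
#' A mask voxel is a surface voxel when at least one of its 6-neighbours
#' is background (voxels beyond the grid count as background). Returned
#' points are the world coordinates (mm) of the surface voxel centres.
#'
#' @param mask binary 3-D array or [image_grid] with 0/1 values.
#' @param spacing,origin geometry (mm); taken from the grid if supplied.
#' @return An n x 3 matrix of class `surface_points`.
#' @export
surface_points <- function(mask, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (inherits(mask, "image_grid")) {
    spacing <- mask$spacing; origin <- mask$origin; mask <- mask$values
  }
  if (!is_binary_array(mask)) stop("`mask` must be binary", call. = FALSE)
  n_fg <- sum(mask)
  if (n_fg == 0) stop("empty mask has no surface", call. = FALSE)
  if (n_fg == length(mask)) stop("full-grid mask has no surface", call. = FALSE)
  d <- dim(mask)
  pad <- array(0, d + 2)
  pad[1 + seq_len(d[1]), 1 + seq_len(d[2]), 1 + seq_len(d[3])] <- mask
  core <- function(dx, dy, dz)
    pad[1 + dx + seq_len(d[1]), 1 + dy + seq_len(d[2]), 1 + dz + seq_len(d[3])]
  n_bg_neigh <- (1 - core(1, 0, 0)) + (1 - core(-1, 0, 0)) +
    (1 - core(0, 1, 0)) + (1 - core(0, -1, 0)) +
    (1 - core(0, 0, 1)) + (1 - core(0, 0, -1))
  surf <- which(mask == 1 & n_bg_neigh > 0, arr.ind = TRUE)
  pts <- sweep(sweep(surf - 1, 2, spacing, "*"), 2, origin, "+")
  colnames(pts) <- c("x", "y", "z")
  structure(pts, class = c("surface_points", class(pts)))
}

as_point_matrix <- function(p) {
  if (inherits(p, "surface_points")) return(unclass(p))
  p <- as.matrix(p)
  if (ncol(p) != 3) stop("points must be n x 3", call. = FALSE)
  p
}

#' Directed RMS surface distance (prediction to ground truth)
#'
#' Root-mean-square over the prediction's surface points of the distance
#' to the nearest ground-truth surface point, in mm. As defined this is
#' directed (P to G) and therefore not symmetric; see
#' [symmetric_mean_surface_distance()] for the symmetrised companion.
#'
#' @param P,G surface point sets (n x 3 matrices, mm).
#' @return Distance in mm.
#' @export
rms_surface_distance <- function(P, G) {
  P <- as_point_matrix(P); G <- as_point_matrix(G)
  if (nrow(P) == 0 || nrow(G) == 0) stop("empty point set", call. = FALSE)
  sqrt(mean(min_point_dists(P, G)^2))
}

#' Symmetrised mean surface distance
#'
#' Mean of all nearest-neighbour distances pooled over both directions;
#' reported alongside the directed RMS value for information.
#'
#' @inheritParams rms_surface_distance
#' @return Distance in mm.
#' @export
symmetric_mean_surface_distance <- function(P, G) {
  P <- as_point_matrix(P); G <- as_point_matrix(G)
  if (nrow(P) == 0 || nrow(G) == 0) stop("empty point set", call. = FALSE)
  mean(c(min_point_dists(P, G), min_point_dists(G, P)))
}

#' Hausdorff distance between two surface point sets
#'
#' `max( sup_{x in P} inf_{q in G} d(x, q), sup_{q in G} inf_{x in P}
#' d(x, q) )` with Euclidean d in mm: the worst-case boundary error, and
#' symmetric by construction.
#'
#' @inheritParams rms_surface_distance
#' @return Distance in mm.
#' @export
hausdorff_distance <- function(P, G) {
  P <- as_point_matrix(P); G <- as_point_matrix(G)
  if (nrow(P) == 0 || nrow(G) == 0) stop("empty point set", call. = FALSE)
  max(max(min_point_dists(P, G)), max(min_point_dists(G, P)))
}
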
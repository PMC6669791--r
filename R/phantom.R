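#' Specification for a synthetic thorax phantom
#'
#' Describes a CT-like thorax phantom: an ellipsoidal fat-intensity body on
#' an air background, two low-intensity lung regions, two anterior breast
#' blobs and one heart blob between the lungs, with additive Gaussian
#' noise. Geometry is given in millimetres as offsets from the grid centre
#' plus ellipsoid radii; intensities are HU-like class means. The defaults
#' (64 x 64 x 32 voxels at 2.34 x 2.34 x 3 mm) are a scaled-down version
#' of the working resolution used for whole-volume segmentation so that
#' training runs on one CPU.
#'
#' @param shape integer length-3 grid extent in voxels; at least (16, 16, 8).
#' @param spacing voxel spacing in mm.
#' @param geometry named list of ellipsoid parameters (mm): `body_radii`,
#'   `lung_offset` (mirrored in x for the two lungs), `lung_radii`,
#'   `breast_offset` (mirrored in x), `breast_radii`, `heart_offset`,
#'   `heart_radii`. Offsets are relative to the grid centre; +x is patient
#'   left, +y anterior, +z superior.
#' @param intensities named list of class means (HU-like): `air`, `lung`,
#'   `fat`, `soft`.
#' @param jitter named list with `radius_frac` (multiplicative radius
#'   jitter half-range, per case) and `center_mm` (additive centre jitter
#'   half-range, mm) used by [generate_cohort()].
#' @param noise_sd standard deviation of the additive Gaussian intensity
#'   noise (HU-like units); 0 disables noise.
#' @param seed integer seed for the noise field.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 32),
                         spacing = c(2.34, 2.34, 3.0),
                         geometry = list(),
                         intensities = list(),
                         jitter = list(),
                         noise_sd = 20,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < c(16L, 16L, 8L)))
    stop("`shape` must be at least (16, 16, 8)", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("`spacing` must be positive", call. = FALSE)
  geom <- modifyList(list(
    body_radii    = c(66, 45, 200),
    lung_offset   = c(31, -10, 0),
    lung_radii    = c(21, 24, 56),
    breast_offset = c(32, 40, 5),
    breast_radii  = c(18, 14, 20),
    heart_offset  = c(0, 0, -2),
    heart_radii   = c(18, 16, 22)), geometry)
  if (any(unlist(geom[grep("radii", names(geom))]) <= 0))
    stop("all radii must be positive", call. = FALSE)
  intens <- modifyList(list(air = -1000, lung = -700, fat = -100, soft = 40),
                       intensities)
  jit <- modifyList(list(radius_frac = 0.08, center_mm = 4), jitter)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(list(shape = shape, spacing = spacing, geometry = geom,
                 intensities = intens, jitter = jit,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# 0/1 array for membership in an axis-aligned ellipsoid (centre/radii in mm).
ellipsoid_mask <- function(shape, spacing, center, radii) {
  ax <- ((seq_len(shape[1]) - 1) * spacing[1] - center[1])^2 / radii[1]^2
  ay <- ((seq_len(shape[2]) - 1) * spacing[2] - center[2])^2 / radii[2]^2
  az <- ((seq_len(shape[3]) - 1) * spacing[3] - center[3])^2 / radii[3]^2
  (outer(outer(ax, ay, "+"), az, "+") <= 1) * 1
}

#' Generate one thorax phantom with ground-truth masks
#'
#' Builds the intensity volume and the binary masks `left_breast`,
#' `right_breast` and `heart`. The body is the union of the trunk
#' ellipsoid and the two breast blobs, so every organ mask lies inside the
#' body by construction; lungs and heart are painted only where they
#' intersect the trunk. The same spec and seed give bitwise-identical
#' output.
#'
#' @param spec a [phantom_spec].
#' @return A list with elements `image` (an [image_grid]), `structures`
#'   (a [structure_set] with organs left_breast, right_breast, heart) and
#'   `body` (the 0/1 body array, for reference).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$geometry
  sh <- spec$shape; sp <- spec$spacing
  centre <- (sh - 1) / 2 * sp
  mirror <- function(off) off * c(-1, 1, 1)
  for (nm in c("lung_offset", "heart_offset")) {
    off <- g[[nm]]
    if (sum((off / g$body_radii)^2) >= 1)
      stop(nm, ": organ centre falls outside the body ellipsoid",
           call. = FALSE)
  }
  rad_names <- c("lung_radii", "heart_radii", "breast_radii")
  if (any(vapply(rad_names, function(nm) any(g[[nm]] >= g$body_radii * 2),
                 logical(1))))
    stop("organ radii too large to fit inside the body", call. = FALSE)

  trunk <- ellipsoid_mask(sh, sp, centre, g$body_radii)
  lung_r <- ellipsoid_mask(sh, sp, centre + g$lung_offset, g$lung_radii) * trunk
  lung_l <- ellipsoid_mask(sh, sp, centre + mirror(g$lung_offset),
                           g$lung_radii) * trunk
  heart <- ellipsoid_mask(sh, sp, centre + g$heart_offset, g$heart_radii) * trunk
  breast_r <- ellipsoid_mask(sh, sp, centre + g$breast_offset, g$breast_radii)
  breast_l <- ellipsoid_mask(sh, sp, centre + mirror(g$breast_offset),
                             g$breast_radii)
  body <- pmax(trunk, breast_r, breast_l)

  iv <- spec$intensities
  vol <- array(iv$air, dim = sh)
  vol[body == 1] <- iv$fat
  vol[lung_r == 1 | lung_l == 1] <- iv$lung
  vol[heart == 1 | breast_r == 1 | breast_l == 1] <- iv$soft
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    vol <- vol + array(rnorm(prod(sh), sd = spec$noise_sd), dim = sh)
  }
  # +x is patient left, so the patient's left breast sits at larger x.
  sset <- structure_set(list(left_breast = breast_r, right_breast = breast_l,
                             heart = heart),
                        spacing = sp, origin = c(0, 0, 0))
  list(image = image_grid(vol, spacing = sp, origin = c(0, 0, 0)),
       structures = sset, body = body)
}

#' Generate a reproducible cohort of jittered phantoms
#'
#' Each case perturbs the base spec with a multiplicative radius jitter
#' drawn uniformly from `1 +/- jitter$radius_frac` and an additive centre
#' jitter from `+/- jitter$center_mm` (mm, per axis and organ), then adds
#' an independent seeded noise field. Case `i` is fully determined by
#' `(spec, seed, i)`.
#'
#' @param spec a [phantom_spec] (its `jitter` entry sets the ranges).
#' @param n number of cases (>= 1).
#' @param seed integer cohort seed.
#' @return A named list (`case001`, ...) of phantom lists as returned by
#'   [generate_phantom()], each with an added `id` element.
#' @export
generate_cohort <- function(spec, n, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  out <- vector("list", n)
  ids <- sprintf("case%03d", seq_len(n))
  for (i in seq_len(n)) {
    csd <- (seed + 7919L * i) %% 2147483647L
    set.seed(csd)
    g <- spec$geometry
    jr <- spec$jitter$radius_frac; jc <- spec$jitter$center_mm
    for (nm in grep("radii", names(g), value = TRUE))
      if (nm != "body_radii")
        g[[nm]] <- g[[nm]] * runif(3, 1 - jr, 1 + jr)
    for (nm in grep("offset", names(g), value = TRUE))
      g[[nm]] <- g[[nm]] + runif(3, -jc, jc)
    cspec <- spec
    cspec$geometry <- g
    cspec$seed <- (csd + 1L) %% 2147483647L
    ph <- generate_phantom(cspec)
    ph$id <- ids[i]
    out[[i]] <- ph
  }
  names(out) <- ids
  out
}
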
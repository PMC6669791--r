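test_that("patch entropy matches the brute-force histogram formula", {
  expect_equal(patch_entropy(array(0, c(4, 4, 4))), 0)
  # two equally frequent intensities: 1 bit
  two <- array(rep(c(-1024, 1024), 32), c(4, 4, 4))
  expect_equal(patch_entropy(two), 1)
  set.seed(13)
  v <- array(runif(200, -1024, 1024), c(10, 10, 2))
  q <- quantize_uint8(v, c(-1024, 1024))
  f <- table(as.vector(q)) / length(q)
  expect_equal(patch_entropy(v), -sum(f * log2(f)), tolerance = 1e-12)
})

test_that("entropy sampler accepts everything at threshold 0 and exhausts above max", {
  ph <- generate_phantom(small_phantom_spec(seed = 3L))
  set.seed(1)
  cfg0 <- sampler_config(patch_size = c(8, 8, 4), entropy_threshold = 0)
  p <- sample_entropy(ph$image, cfg0)
  expect_identical(dim(p$values), c(8L, 8L, 4L))
  cfg_hi <- sampler_config(patch_size = c(8, 8, 4), entropy_threshold = 9,
                           max_rejects = 50L)
  expect_error(sample_entropy(ph$image, cfg_hi), "exhausted")
})

test_that("entropy-admissible centres agree with exhaustive thresholding", {
  # half-air / half-tissue toy volume: admissible centres are those whose
  # patch straddles the boundary (entropy ~1 bit), found exhaustively
  vol <- array(-1000, c(16, 8, 4))
  vol[9:16, , ] <- 40
  g <- image_grid(vol)
  cfg <- sampler_config(patch_size = c(4, 4, 4), entropy_threshold = 0.5)
  gd <- dim(vol)
  admissible <- c()
  for (cx in 3:14) {
    off <- oarseg:::center_to_offset(c(cx, 3L, 3L), cfg$patch_size, gd)
    if (is.null(off)) next
    e <- patch_entropy(extract_patch(g, off, cfg$patch_size))
    if (e > cfg$entropy_threshold) admissible <- c(admissible, cx)
  }
  set.seed(5)
  for (i in 1:200) {
    p <- sample_entropy(g, cfg)
    cx <- p$offset[1] + cfg$patch_size[1] %/% 2 + 1
    expect_true(cx %in% admissible)
  }
})

test_that("shell sampler admissibility equals brute-force distance thresholding", {
  d <- c(16, 16, 8)
  mask <- array(0, d); mask[8:9, 8:9, 4:5] <- 1
  sp <- c(2.34, 2.34, 3)
  g <- image_grid(array(rnorm(prod(d)), d), spacing = sp)
  cfg <- sampler_config(patch_size = c(6, 6, 4), shell_distances_mm = 20)
  # brute force: distance from every voxel centre to the nearest surface voxel
  spts <- surface_points(mask, spacing = sp)
  idx <- which(array(TRUE, d), arr.ind = TRUE)
  world <- sweep(idx - 1, 2, sp, "*")
  bf <- vapply(seq_len(nrow(idx)), function(r)
    sqrt(min(colSums((t(spts) - world[r, ])^2))), numeric(1))
  bf_adm <- array(bf <= 20, d)
  dvol <- distance_to_surface(mask, sp)
  expect_equal(as.vector(dvol), bf, tolerance = 1e-9)
  set.seed(6)
  for (i in 1:100) {
    p <- sample_shell(g, mask, 20, cfg)
    ctr <- p$offset + cfg$patch_size %/% 2 + 1
    expect_true(bf_adm[ctr[1], ctr[2], ctr[3]])
  }
  # the mask surface itself is admissible at any distance >= 0
  expect_true(all(dvol[mask == 1 &
    oarseg:::is_binary_array(mask)] <= max(dvol)))
  expect_equal(min(dvol[8:9, 8:9, 4:5]), 0)
  # infinite distance admits any centre
  p_inf <- sample_shell(g, mask, Inf, cfg)
  expect_identical(dim(p_inf$values), c(6L, 6L, 4L))
  expect_error(sample_shell(g, array(0, d), 20, cfg), "empty")
})

test_that("mask sampler patches always intersect the ground truth", {
  d <- c(16, 16, 8)
  mask <- array(0, d); mask[12, 5, 6] <- 1  # single voxel
  g <- image_grid(array(rnorm(prod(d)), d))
  cfg <- sampler_config(patch_size = c(4, 4, 4))
  # admissible offsets enumerated exhaustively for a single-voxel mask
  adm <- list()
  for (ox in 0:(d[1] - 4)) for (oy in 0:(d[2] - 4)) for (oz in 0:(d[3] - 4)) {
    if (12 %in% (ox + 1:4) && 5 %in% (oy + 1:4) && 6 %in% (oz + 1:4))
      adm[[length(adm) + 1]] <- c(ox, oy, oz)
  }
  adm <- do.call(rbind, adm)
  set.seed(8)
  for (i in 1:200) {
    p <- sample_mask(g, mask, cfg)
    expect_true(any(apply(adm, 1, function(a) all(a == p$offset))))
  }
  full <- array(1, d)
  p <- sample_mask(g, full, cfg)
  expect_identical(dim(p$values), c(4L, 4L, 4L))
  expect_error(sample_mask(g, array(0, d), cfg), "empty")
})

test_that("composite sampler delegates by weight and crops labels at the same offset", {
  ph <- generate_phantom(small_phantom_spec(seed = 12L))
  cfg1 <- sampler_config(patch_size = c(8, 8, 4),
                         sampler_weights = c(1, 0, 0, 0))
  set.seed(9)
  draws <- composite_sampler(ph$image, ph$structures, cfg1, 20)
  expect_true(all(vapply(draws, `[[`, character(1), "sampler") == "entropy"))

  cfg_eq <- sampler_config(patch_size = c(8, 8, 4))
  set.seed(10)
  st <- sampler_state(ph$image, ph$structures, cfg_eq)
  draws <- composite_sampler(ph$image, ph$structures, cfg_eq, 4000,
                             state = st)
  tab <- table(factor(vapply(draws, `[[`, character(1), "sampler"),
                      levels = c("entropy", "shell20", "shell40", "mask")))
  # multinomial 3-sigma bound around 1/4
  sigma <- sqrt(4000 * 0.25 * 0.75)
  expect_true(all(abs(tab - 1000) < 3 * sigma))
  # image and label patches share offset and size by construction
  for (dr in draws[1:50]) {
    expect_identical(dim(dr$labels)[1:3], dim(dr$image$values))
    organ <- names(ph$structures$masks)[1]
    expect_identical(dr$labels[, , , 1],
                     extract_patch(ph$structures$masks[[organ]],
                                   dr$offset, cfg_eq$patch_size)$values)
  }
})

test_that("samplers are deterministic given a seed", {
  ph <- generate_phantom(small_phantom_spec(seed = 14L))
  cfg <- sampler_config(patch_size = c(8, 8, 4))
  st <- sampler_state(ph$image, ph$structures, cfg)
  set.seed(77)
  a <- composite_sampler(ph$image, ph$structures, cfg, 10, state = st)
  set.seed(77)
  b <- composite_sampler(ph$image, ph$structures, cfg, 10, state = st)
  expect_identical(lapply(a, `[[`, "offset"), lapply(b, `[[`, "offset"))
  expect_identical(lapply(a, `[[`, "sampler"), lapply(b, `[[`, "sampler"))
})
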
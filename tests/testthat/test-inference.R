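test_that("full-image inference returns per-organ probability grids", {
  set.seed(50)
  net <- tiny_bibnet(out_channels = 3)
  ph <- generate_phantom(small_phantom_spec(seed = 50L))
  probs <- infer_full_image(net, ph$image,
                            organs = c("left_breast", "right_breast", "heart"))
  expect_named(probs, c("left_breast", "right_breast", "heart"))
  for (p in probs) {
    expect_identical(dim(p$values), dim(ph$image$values))
    expect_true(all(p$values >= 0 & p$values <= 1))
  }
  # evaluation mode is deterministic even with dropout in the config
  net_do <- build_bibnet(bibnet_config(n_levels = 2, base_filters = 4,
                                       encoder_blocks = c(1, 1),
                                       lateral_blocks = c(1, 0),
                                       decoder_blocks = 1,
                                       dropout_rate = 0.5))
  x <- ph$image
  p1 <- infer_full_image(net_do, x)
  p2 <- infer_full_image(net_do, x)
  expect_identical(p1$organ1$values, p2$organ1$values)
  # near-constant input gives near-constant interior output
  flat <- image_grid(array(0, c(16, 16, 8)))
  pf <- predict(net, flat)
  interior <- pf[5:12, 5:12, 3:6, 1]
  expect_lt(diff(range(interior)), 1e-6)
  # odd shapes are padded internally and cropped back
  odd <- image_grid(array(rnorm(15 * 13 * 7), c(15, 13, 7)))
  po <- predict(net, odd)
  expect_identical(dim(po)[1:3], c(15L, 13L, 7L))
})

test_that("patchwise U-Net inference equals the single big-patch pass exactly", {
  set.seed(51)
  net <- build_unet3(unet3_config())
  g <- image_grid(array(rnorm(48 * 48 * 44), c(48, 48, 44)))
  tiled <- infer_patchwise(net, g, c(44, 44, 44))
  full <- predict(net, g$values)
  vr <- attr(tiled, "valid_range")
  ix <- vr[1, 1]:vr[2, 1]; iy <- vr[1, 2]:vr[2, 2]; iz <- vr[1, 3]:vr[2, 3]
  inner <- tiled[ix, iy, iz, , drop = FALSE]
  expect_false(anyNA(inner))
  # full pass covers margin 20..; compare on the patchwise-covered interior
  expect_identical(dim(full)[1:3], c(8L, 8L, 4L))
  full_region <- full[ix - 20, iy - 20, iz - 20, , drop = FALSE]
  expect_equal(inner, full_region, tolerance = 1e-12)
  # border is flagged
  expect_true(anyNA(tiled[1, 1, 1, 1]))
  # volume equal to one patch reduces to the single forward pass
  g1 <- image_grid(array(rnorm(44^3), c(44, 44, 44)))
  tiled1 <- infer_patchwise(net, g1, c(44, 44, 44))
  full1 <- predict(net, g1$values)
  expect_equal(tiled1[21:24, 21:24, 21:24, , drop = FALSE], full1,
               tolerance = 1e-12)
  expect_error(infer_patchwise(net, g1, c(24, 24, 24)), "inadmissible")
})

test_that("largest_component matches brute-force flood fill", {
  m <- array(0, c(8, 8, 4))
  m[1:3, 1:3, 1:2] <- 1          # 18 voxels
  m[6:7, 6:7, 3] <- 1            # 4 voxels
  lc <- largest_component(m)
  expect_identical(sum(lc), 18)
  expect_identical(lc[2, 2, 1], 1)
  # single component unchanged; empty in, empty out
  expect_identical(largest_component(m * 0), m * 0)
  one <- array(0, c(4, 4, 4)); one[2:3, 2:3, 2:3] <- 1
  expect_identical(largest_component(one), one)
  # random multi-blob masks against the brute-force labelling, all connectivities
  set.seed(52)
  for (i in 1:10) {
    r <- random_mask(c(7, 7, 5), p = 0.25)
    for (conn in c(6, 18, 26)) {
      lab <- bf_label(r, conn)
      sizes <- tabulate(lab[lab > 0])
      expected <- (lab == which.max(sizes)) * 1
      expect_identical(largest_component(r, conn), expected)
    }
  }
})

test_that("postprocess resamples, smooths, thresholds and keeps one component", {
  # two blobs, 500 + 20 voxels: only the larger survives
  prob <- array(0, c(16, 16, 8))
  prob[2:11, 2:11, 2:6] <- 0.9    # 500 voxels
  prob[14:15, 14:15, 6:7] <- 0.9  # 8 voxels (proportionally small)
  pg <- image_grid(prob, spacing = c(2, 2, 3))
  target <- image_grid(array(0, c(32, 32, 12)), spacing = c(1, 1, 2))
  out <- postprocess(pg, target, postprocess_spec(gaussian_sigma_mm = 0))
  expect_equal(out$spacing, c(1, 1, 2))
  lab <- bf_label(out$values, 26)
  expect_identical(max(lab), 1L)
  # sigma 0 on matching geometry reduces to plain thresholding
  same <- postprocess(pg, pg, postprocess_spec(gaussian_sigma_mm = 0))
  expect_identical(same$values, largest_component((prob >= 0.5) * 1))
  # empty result is returned flagged, with a warning
  low <- image_grid(array(0.1, c(8, 8, 4)), spacing = c(2, 2, 3))
  expect_warning(e <- postprocess(low, pg, postprocess_spec()), "empty")
  expect_true(attr(e, "empty_prediction"))
  expect_identical(sum(e$values), 0)
  # output is always a single component (or empty) across random fields
  set.seed(53)
  for (i in 1:5) {
    pr <- image_grid(array(runif(16 * 16 * 8), c(16, 16, 8)),
                     spacing = c(2, 2, 3))
    r <- postprocess(pr, pr, postprocess_spec(gaussian_sigma_mm = 2))
    lab <- bf_label(r$values, 26)
    expect_lte(max(lab), 1L)
  }
})

test_that("smoothing a convex blob never fragments it", {
  blob <- array(0, c(16, 16, 8))
  blob[5:12, 5:12, 3:6] <- 1
  g <- image_grid(blob, spacing = c(1, 1, 1))
  for (sigma in c(0.5, 1, 2)) {
    sm <- gaussian_smooth(g, sigma)
    th <- (sm$values >= 0.5) * 1
    lab <- bf_label(th, 26)
    expect_lte(max(lab), 1L)
  }
  # sigma 0 is the identity
  expect_identical(gaussian_smooth(g, 0)$values, blob)
})
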
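test_that("default configuration hits both printed architecture anchors", {
  cfg <- bibnet_config()
  expect_identical(receptive_field(cfg), rep(484L, 3))
  set.seed(1)
  net <- build_bibnet(cfg)
  n <- count_parameters(net)
  expect_lt(abs(n - 7.5e6) / 7.5e6, 0.05)
})

test_that("receptive field composes kernel/stride contributions", {
  # single 3^3 convolution
  one <- bibnet_config(n_levels = 2, encoder_blocks = c(1, 0),
                       lateral_blocks = c(0, 0), decoder_blocks = 0)
  # one residual block = two 3^3 convs at stride 1: 1 + 2*2 = 5, plus the
  # stride-2 pool (+1) before level 2 which adds no further convs
  expect_identical(receptive_field(one), rep(6L, 3))
  two <- bibnet_config(n_levels = 2, encoder_blocks = c(1, 1),
                       lateral_blocks = c(0, 0), decoder_blocks = 0)
  # level-2 residual block adds 2 convs at stride 2: 6 + 2*2*2 = 14
  expect_identical(receptive_field(two), rep(14L, 3))
})

test_that("parameter counting is exact on hand-checkable layers", {
  # a single 3^3 convolution, 1 -> 8 channels with bias: 8 * (27 + 1) = 224
  g <- oarseg:::new_graph()
  inp <- oarseg:::g_add(g, "input")
  oarseg:::g_conv(g, inp, 1, 8, k = 3L, s = 1L, pad = 1L)
  net <- structure(list(nodes = g$nodes, out_id = 2L), class = "seg_network")
  expect_equal(count_parameters(net), 224)
  # identity network with no parameters
  g2 <- oarseg:::new_graph()
  oarseg:::g_add(g2, "input")
  net2 <- structure(list(nodes = g2$nodes, out_id = 1L),
                    class = "seg_network")
  expect_equal(count_parameters(net2), 0)
})

test_that("bib-type networks preserve spatial shape and emit probabilities", {
  set.seed(2)
  net <- tiny_bibnet(out_channels = 3)
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  y <- predict(net, x)
  expect_identical(dim(y), c(16L, 16L, 8L, 3L))
  expect_true(all(y > 0 & y < 1))
  # filter-doubling rule: every 3^3 conv width is base * growth^level
  widths <- unique(unlist(lapply(net$nodes, function(nd)
    if (nd$op == "conv" && nd$k == 3) nd$cout)))
  base <- net$config$base_filters
  expect_true(all(widths %in% (base * net$config$growth_factor^(0:1))))
})

test_that("bib-type networks are shift-equivariant in the interior", {
  set.seed(4)
  # shallow instance whose receptive field (~16 voxels) is well inside the
  # test volume, so true interior voxels exist
  net <- build_bibnet(bibnet_config(n_levels = 2, base_filters = 2,
                                    encoder_blocks = c(1, 0),
                                    lateral_blocks = c(0, 0),
                                    decoder_blocks = 0, dropout_rate = 0))
  d <- c(40, 40, 16)
  x <- array(rnorm(prod(d)), d)
  y0 <- predict(net, x)
  # shift input by one stride multiple (2 voxels) along x
  xs <- array(0, d)
  xs[3:40, , ] <- x[1:38, , ]
  ys <- predict(net, xs)
  # compare deep-interior voxels away from both borders
  expect_equal(ys[15:26, 15:26, 7:10, 1], y0[13:24, 15:26, 7:10, 1],
               tolerance = 1e-6)
})

test_that("analytic receptive field matches gradient-support probing", {
  set.seed(6)
  cfg <- bibnet_config(n_levels = 2, base_filters = 2,
                       encoder_blocks = c(1, 0), lateral_blocks = c(0, 0),
                       decoder_blocks = 0, dropout_rate = 0)
  rf <- receptive_field(cfg)[1]
  net <- build_bibnet(cfg)
  # probe: gradient of the deepest-encoder activation at the volume centre
  # w.r.t. the input has support exactly rf wide (away from borders)
  probe <- net
  probe$out_id <- net$encoder_ids[cfg$n_levels]
  d <- c(32, 32, 32)
  x <- array(rnorm(prod(d)), c(d, 1))
  fw <- oarseg:::forward_net(probe, x, training = FALSE)
  dout <- array(0, dim = dim(fw$out))
  ctr <- dim(fw$out)[1:3] %/% 2
  dout[ctr[1], ctr[2], ctr[3], 1] <- 1
  bw <- oarseg:::backward_net(probe, fw, dout)
  supp <- which(abs(bw$dx[, , , 1]) > 0, arr.ind = TRUE)
  extent <- apply(supp, 2, function(i) diff(range(i)) + 1)
  expect_identical(as.integer(extent), rep(rf, 3))
})

test_that("valid-convolution U-Net shrinks outputs by the analytic amount", {
  set.seed(5)
  net <- build_unet3(unet3_config())
  # symbolic shape arithmetic: each 3^3 conv -2/axis, pool /2, upsample x2
  shrink_oracle <- function(i) {
    a <- i - 4; b <- a / 2 - 4; cc <- b / 2 - 4
    2 * (2 * cc - 4) - 4
  }
  for (i in c(44L, 48L, 52L))
    expect_identical(oarseg:::unet3_out_extent(i), as.integer(shrink_oracle(i)))
  x <- array(rnorm(44^3), c(44, 44, 44))
  y <- predict(net, x)
  expect_identical(dim(y), c(4L, 4L, 4L, 1L))
  expect_true(all(dim(y)[1:3] < dim(x)[1:3]))
  # below minimum admissible size: shape error naming the minimum
  expect_error(predict(net, array(0, c(32, 44, 44))), "minimum admissible")
  expect_identical(oarseg:::unet3_min_input(), 44L)
})

test_that("network configurations round-trip through JSON", {
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "net.json")
  cfg <- bibnet_config(n_levels = 3, base_filters = 4,
                       encoder_blocks = c(1, 2, 2), lateral_blocks = c(2, 1, 0),
                       decoder_blocks = c(1, 1), dropout_rate = 0.25,
                       out_channels = 2)
  write_network_config(cfg, f)
  expect_equal(read_network_config(f), cfg)
  u <- unet3_config(out_channels = 3)
  write_network_config(u, f)
  expect_equal(read_network_config(f), u)
})

test_that("weight serialization round-trips forward outputs bitwise", {
  tmp <- withr::local_tempdir()
  set.seed(8)
  net <- tiny_bibnet()
  x <- array(rnorm(16 * 16 * 8), c(16, 16, 8))
  y0 <- predict(net, x)
  f <- file.path(tmp, "w.rds")
  save_weights(net, f)
  set.seed(999)  # a differently initialised shell
  net2 <- tiny_bibnet()
  expect_false(identical(predict(net2, x), y0))
  net2 <- load_weights(net2, f)
  expect_identical(predict(net2, x), y0)
})

test_that("multi-organ variant builds and runs on the same input", {
  set.seed(9)
  cfg3 <- bibnet_config(n_levels = 2, base_filters = 4,
                        encoder_blocks = c(1, 1), lateral_blocks = c(1, 0),
                        decoder_blocks = 1, dropout_rate = 0,
                        out_channels = 3)
  net <- build_bibnet(cfg3)
  y <- predict(net, array(rnorm(16 * 16 * 8), c(16, 16, 8)))
  expect_identical(dim(y)[4], 3L)
})
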
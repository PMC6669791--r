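test_that("learning rate decays linearly between the published endpoints", {
  cfg <- train_config(planned_epochs = 101L)
  expect_equal(lr_at_epoch(cfg, 0), 1e-2)
  expect_equal(lr_at_epoch(cfg, 100), 1e-5)
  expect_equal(lr_at_epoch(cfg, 500), 1e-5)          # clamped past the plan
  expect_equal(lr_at_epoch(cfg, 50), (1e-2 + 1e-5) / 2)  # midpoint
  expect_error(lr_at_epoch(cfg, -1), ">= 0")
})

test_that("Nesterov-Adam follows its closed recurrence on a scalar quadratic", {
  # minimize f(w) = 0.5 * w^2 (gradient w); compare against an independent
  # re-derivation of the recurrence
  lr <- 0.05; b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  w_ref <- 2; m <- 0; v <- 0
  traj_ref <- numeric(20)
  for (t in 1:20) {
    g <- w_ref
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    upd <- lr * (b1 * m / (1 - b1^(t + 1)) + (1 - b1) * g / (1 - b1^t)) /
      (sqrt(v / (1 - b2^t)) + eps)
    w_ref <- w_ref - upd
    traj_ref[t] <- w_ref
  }
  params <- list(w = array(2, 1))
  st <- oarseg:::nadam_init(params)
  traj <- numeric(20)
  for (t in 1:20) {
    res <- oarseg:::nadam_step(st, params, list(w = params$w), lr)
    st <- res$state; params <- res$params
    traj[t] <- params$w
  }
  expect_equal(traj, traj_ref, tolerance = 1e-10)
})

test_that("a zero learning rate leaves parameters bitwise unchanged", {
  set.seed(20)
  net <- tiny_bibnet(out_channels = 1)
  p0 <- oarseg:::net_params(net)
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8, 1))
  y <- array(rbinom(512, 1, 0.3), c(8, 8, 8, 1))
  st <- train_step(net, list(list(x = x, y = y)), NULL, lr = 0)
  expect_identical(oarseg:::net_params(st$net), p0)
  expect_true(is.finite(st$loss))
})

test_that("repeated steps on one batch strictly reduce the Jaccard loss", {
  set.seed(21)
  ph <- generate_phantom(small_phantom_spec(seed = 21L))
  cfgs <- sampler_config(patch_size = c(16, 16, 8),
                         sampler_weights = c(0, 0, 0, 1))
  d <- composite_sampler(ph$image, ph$structures, cfgs, 1)[[1]]
  batch <- list(list(x = d$image$values, y = d$labels))
  net <- tiny_bibnet(out_channels = 3)
  state <- NULL
  losses <- numeric(200)
  for (i in 1:200) {
    st <- train_step(net, batch, state, 5e-3)
    net <- st$net; state <- st$state
    losses[i] <- st$loss
  }
  expect_lt(losses[200], losses[1])
  expect_lt(min(losses), 0.8 * losses[1])
})

test_that("training gradients match finite differences through the full graph", {
  set.seed(22)
  net <- build_bibnet(bibnet_config(n_levels = 2, base_filters = 2,
                                    encoder_blocks = c(1, 1),
                                    lateral_blocks = c(1, 1),
                                    decoder_blocks = 1, dropout_rate = 0,
                                    out_channels = 2))
  x <- array(rnorm(4 * 4 * 4), c(4, 4, 4, 1))
  y <- array(rbinom(4 * 4 * 4 * 2, 1, 0.4), c(4, 4, 4, 2))
  loss_of <- function(n) {
    fw <- oarseg:::forward_net(n, x, training = TRUE)
    oarseg:::multiorgan_jaccard(fw$out, y)$loss
  }
  fw <- oarseg:::forward_net(net, x, training = TRUE)
  lo <- oarseg:::multiorgan_jaccard(fw$out, y)
  bw <- oarseg:::backward_net(net, fw, lo$dp)
  g <- oarseg:::grads_flat(net, bw$grads)
  p <- oarseg:::net_params(net)
  # step size balances truncation against the single-precision forward noise
  for (nm in sample(names(p), 8)) {
    i <- sample(length(p[[nm]]), 1)
    eps <- 2e-3
    p2 <- p; p2[[nm]][i] <- p2[[nm]][i] + eps
    lp <- loss_of(oarseg:::net_set_params(net, p2))
    p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
    lm <- loss_of(oarseg:::net_set_params(net, p2))
    num <- (lp - lm) / (2 * eps)
    ana <- g[[nm]][i]
    expect_lt(abs(num - ana) / (abs(num) + abs(ana) + 1e-6), 0.02)
  }
})

test_that("convolution forward and backward-data are numerical adjoints", {
  # <conv(x), y> == <x, conv_bw_data(y)> for random tensors, for the padded
  # stride-1 kernel and the stride-2 pooling kernel
  set.seed(24)
  for (ks in list(c(3L, 1L, 1L), c(2L, 2L, 0L))) {
    x <- array(rnorm(8 * 8 * 8 * 2), c(8, 8, 8, 2))
    w <- array(rnorm(ks[1]^3 * 2 * 3) * 0.2, c(ks[1], ks[1], ks[1], 2, 3))
    b <- numeric(3)
    yx <- oarseg:::conv3d_fw(x, w, b, ks[1], ks[2], ks[3])
    y <- array(rnorm(length(yx)), dim = dim(yx))
    bw <- oarseg:::conv3d_bw(x, w, y, ks[1], ks[2], ks[3])
    expect_equal(sum(yx * y), sum(x * bw$dx), tolerance = 1e-4)
  }
})

test_that("tournament selection equals sort-and-keep on stubbed loss traces", {
  set.seed(23)
  # deterministic synthetic validation-loss traces for 8 networks, 100 epochs
  traces <- sapply(1:8, function(i)
    seq(1, 0.1 * i, length.out = 100) + sin(seq_len(100) / 7 + i) * 0.01)
  schedule <- list(c(20, 4), c(40, 2), c(80, 1))
  sel <- tournament_select(traces, schedule)
  # brute-force oracle: sort the losses of the still-alive networks
  alive <- 1:8
  for (st in schedule) {
    l <- traces[st[1], alive]
    alive <- sort(alive[order(l)][seq_len(st[2])])
    expect_identical(sel[[sprintf("epoch%d", st[1])]], alive)
  }
  expect_identical(lengths(sel), c(epoch20 = 4L, epoch40 = 2L, epoch80 = 1L))
  # population 2, schedule (1,1): lower-loss network survives
  tr2 <- cbind(c(0.9), c(0.2))
  expect_identical(tournament_select(tr2, list(c(1, 1)))$epoch1, 2L)
  # random traces: survivor counts follow the schedule
  for (rep in 1:20) {
    tr <- matrix(runif(8 * 80), 80, 8)
    s <- tournament_select(tr, list(c(10, 4), c(30, 2), c(60, 1)))
    expect_identical(unname(lengths(s)), c(4L, 2L, 1L))
    expect_true(all(s[[3]] %in% s[[2]], s[[2]] %in% s[[1]]))
  }
})

test_that("tournament training drops the worse network and returns the best checkpoint", {
  spec <- small_phantom_spec(seed = 30L)
  train_co <- generate_cohort(spec, 2, seed = 31L)
  val_co <- generate_cohort(spec, 1, seed = 32L)
  cfg <- train_config(planned_epochs = 3L,
                      tournament_schedule = list(c(1, 1)),
                      n_initializations = 2L,
                      patch_size = c(16, 16, 8), batch_size = 1L,
                      steps_per_epoch = 2L, patience = 1L,
                      sampler = sampler_config(patch_size = c(16, 16, 8)),
                      seed = 33L)
  factory <- function(seed) tiny_bibnet(out_channels = 3)
  fit <- tournament_train(factory, train_co, val_co, cfg)
  expect_s3_class(fit, "tournament_fit")
  h <- fit$history
  # both networks trained in epoch 1, a single survivor afterwards
  expect_identical(sort(unique(h$net[h$epoch == 1])), c(1L, 2L))
  expect_length(unique(h$net[h$epoch > 1]), 1L)
  # the survivor had the lower epoch-1 validation loss
  e1 <- h[h$epoch == 1, ]
  expect_identical(unique(h$net[h$epoch > 1]),
                   e1$net[which.min(e1$val_loss)])
  expect_identical(fit$stages$epoch1, e1$net[which.min(e1$val_loss)])
  # winner's recorded best loss is the minimum of its own trace
  surv <- fit$stages$epoch1
  expect_equal(fit$best_val_loss, min(h$val_loss[h$net == surv]))
  # prediction through the fit works
  pr <- predict(fit, val_co[[1]]$image)
  expect_identical(dim(pr)[1:3], dim(val_co[[1]]$image$values))

  # schedule inconsistent with the population errors out
  bad <- cfg; bad$n_initializations <- 3L
  expect_error(tournament_train(factory, train_co, val_co, bad),
               "inconsistent")
  expect_error(tournament_train(factory, train_co, list(), cfg), "empty")
})

test_that("training is reproducible from the config seed", {
  spec <- small_phantom_spec(seed = 40L)
  train_co <- generate_cohort(spec, 1, seed = 41L)
  val_co <- generate_cohort(spec, 1, seed = 42L)
  cfg <- train_config(planned_epochs = 2L, tournament_schedule = list(c(1, 1)),
                      n_initializations = 2L, patch_size = c(16, 16, 8),
                      batch_size = 1L, steps_per_epoch = 1L, patience = 5L,
                      sampler = sampler_config(patch_size = c(16, 16, 8)),
                      seed = 43L)
  factory <- function(seed) tiny_bibnet(out_channels = 3)
  f1 <- tournament_train(factory, train_co, val_co, cfg)
  f2 <- tournament_train(factory, train_co, val_co, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(oarseg:::net_params(f1$network),
                   oarseg:::net_params(f2$network))
})
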
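#' Training configuration
#'
#' Settings for the optimization loop: Nesterov-Adam on the soft Jaccard
#' loss, a learning rate decaying linearly from `lr_initial` (1e-2) to
#' `lr_final` (1e-5) over the planned epochs, and tournament selection —
#' several randomly initialized networks trained concurrently-in-schedule
#' with the worse half (by validation loss) dropped at the scheduled
#' epochs, the last survivor continuing under early stopping. Validation
#' ranking uses the Dice loss (1 - hard Dice); back-propagation uses the
#' Jaccard loss.
#'
#' @param lr_initial,lr_final learning-rate endpoints
#'   (`lr_initial > lr_final > 0`).
#' @param planned_epochs epochs over which the linear decay is defined.
#' @param tournament_schedule list of `c(epoch, survivors)` pairs with
#'   strictly decreasing survivor counts ending at 1.
#' @param n_initializations networks in the starting population; must
#'   match the implied first-stage population (twice the first survivor
#'   count for a halving schedule).
#' @param patch_size training-patch extent (voxels).
#' @param batch_size patches per optimization step.
#' @param steps_per_epoch optimization steps per epoch per network.
#' @param patience epochs without validation improvement tolerated after
#'   the last drop ("until the validation loss does not decrease
#'   further").
#' @param organs organ names (output-channel order).
#' @param sampler a [sampler_config] used to draw training patches.
#' @param seed root seed for initialization and sampling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr_initial = 1e-2,
                         lr_final = 1e-5,
                         planned_epochs = 120L,
                         tournament_schedule = list(c(20, 4), c(40, 2), c(80, 1)),
                         n_initializations = 8L,
                         patch_size = c(32, 32, 16),
                         batch_size = 2L,
                         steps_per_epoch = 50L,
                         patience = 10L,
                         organs = c("left_breast", "right_breast", "heart"),
                         sampler = sampler_config(patch_size = patch_size),
                         seed = 1L) {
  if (!(lr_initial > lr_final && lr_final > 0))
    stop("need lr_initial > lr_final > 0", call. = FALSE)
  surv <- vapply(tournament_schedule, `[`, numeric(1), 2)
  if (length(surv) && (any(diff(surv) >= 0) || surv[length(surv)] != 1))
    stop("tournament survivors must strictly decrease and end at 1",
         call. = FALSE)
  structure(list(lr_initial = lr_initial, lr_final = lr_final,
                 planned_epochs = as.integer(planned_epochs),
                 tournament_schedule = tournament_schedule,
                 n_initializations = as.integer(n_initializations),
                 patch_size = as.integer(patch_size),
                 batch_size = as.integer(batch_size),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 patience = as.integer(patience),
                 organs = organs, sampler = sampler,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch under the linear decay
#'
#' `lr(e) = lr_initial + (lr_final - lr_initial) * min(e, E-1) / (E-1)`
#' for `E = planned_epochs` (0-based epochs), clamped at `lr_final`
#' afterwards.
#'
#' @param cfg a [train_config].
#' @param epoch 0-based epoch counter.
#' @return The learning rate.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  if (epoch < 0) stop("`epoch` must be >= 0", call. = FALSE)
  E <- cfg$planned_epochs
  if (E <= 1) return(cfg$lr_final)
  f <- pmin(epoch, E - 1) / (E - 1)
  cfg$lr_initial + (cfg$lr_final - cfg$lr_initial) * f
}

# --- Nesterov-Adam ---------------------------------------------------------
# Bias-corrected adaptive moments with a Nesterov look-ahead on the first
# moment:
#   m <- b1 m + (1-b1) g ;  v <- b2 v + (1-b2) g^2
#   update = lr * ( b1 * m/(1-b1^(t+1)) + (1-b1) g/(1-b1^t) ) /
#            ( sqrt(v/(1-b2^t)) + eps )

nadam_init <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zeros <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  list(m = zeros, v = zeros, t = 0L, beta1 = beta1, beta2 = beta2, eps = eps)
}

nadam_step <- function(state, params, grads, lr) {
  state$t <- state$t + 1L
  t <- state$t
  b1 <- state$beta1; b2 <- state$beta2; eps <- state$eps
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat_next <- state$m[[nm]] / (1 - b1^(t + 1))
    ghat <- g / (1 - b1^t)
    vhat <- state$v[[nm]] / (1 - b2^t)
    params[[nm]] <- params[[nm]] -
      lr * (b1 * mhat_next + (1 - b1) * ghat) / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}

# Multi-organ training loss: unweighted mean of per-channel soft Jaccard
# losses; returns the loss and its gradient w.r.t. the probability map.
multiorgan_jaccard <- function(p, y) {
  n_ch <- dim(p)[4]
  loss <- 0
  dp <- array(0, dim = dim(p))
  for (ch in seq_len(n_ch)) {
    pc <- p[, , , ch, drop = FALSE]
    yc <- y[, , , ch, drop = FALSE]
    loss <- loss + jaccard_loss(pc, yc)
    dp[, , , ch] <- jaccard_loss_grad(pc, yc) / n_ch
  }
  list(loss = loss / n_ch, dp = dp)
}

#' One Nesterov-Adam step on the soft Jaccard loss
#'
#' Runs forward (training mode: dropout on, batch-norm batch statistics)
#' and backward passes for each sample in the batch, averages the
#' parameter gradients, and applies one Nesterov-Adam update. Batch-norm
#' running statistics are updated as a side effect.
#'
#' @param net a `seg_network`.
#' @param batch list of samples, each `list(x = (X,Y,Z,Cin) array,
#'   y = (X,Y,Z,Cout) 0/1 array)`.
#' @param state optimizer state from `nadam_init`, or `NULL` to create one.
#' @param lr learning rate for this step.
#' @param clip_norm global gradient-norm ceiling applied to the averaged
#'   batch gradient before the optimizer update; guards the high-learning-
#'   rate phase of the schedule against occasional destabilising batches.
#' @return `list(net, state, loss)` with the mean batch loss.
#' @export
train_step <- function(net, batch, state, lr, clip_norm = 5) {
  params <- net_params(net)
  if (is.null(state)) state <- nadam_init(params)
  acc <- NULL
  total_loss <- 0
  for (s in batch) {
    x <- s$x
    if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
    y <- s$y
    if (length(dim(y)) == 3L) dim(y) <- c(dim(y), 1L)
    fw <- forward_net(net, x, training = TRUE)
    lo <- multiorgan_jaccard(fw$out, y)
    if (!is.finite(lo$loss))
      stop("non-finite training loss: diverged or invalid input",
           call. = FALSE)
    bw <- backward_net(net, fw, lo$dp)
    g <- grads_flat(net, bw$grads)
    acc <- if (is.null(acc)) g else
      setNames(lapply(names(g), function(nm) acc[[nm]] + g[[nm]]), names(g))
    total_loss <- total_loss + lo$loss
    net <- update_bn_buffers(net, fw)
  }
  nb <- length(batch)
  acc <- lapply(acc, function(g) g / nb)
  if (is.finite(clip_norm) && clip_norm > 0) {
    gn <- sqrt(sum(vapply(acc, function(g) sum(g^2), numeric(1))))
    if (gn > clip_norm)
      acc <- lapply(acc, function(g) g * (clip_norm / gn))
  }
  if (lr > 0) {
    res <- nadam_step(state, params, acc, lr)
    net <- net_set_params(net, res$params)
    state <- res$state
  } else {
    state$t <- state$t + 1L
  }
  list(net = net, state = state, loss = total_loss / nb)
}

#' Brute-force tournament bookkeeping: survivors at each drop epoch
#'
#' Pure selection rule, separated from the training loop so it can be
#' exercised on stubbed loss traces: at each scheduled epoch the networks
#' with the lowest validation loss at that epoch survive (ties broken by
#' lower network index).
#'
#' @param traces numeric matrix of validation losses, epochs x networks.
#' @param schedule list of `c(epoch, survivors)` pairs.
#' @return Named list, one element per stage, of surviving network
#'   indices (referring to columns of `traces`).
#' @export
tournament_select <- function(traces, schedule) {
  alive <- seq_len(ncol(traces))
  out <- list()
  for (st in schedule) {
    ep <- st[1]; keep <- st[2]
    if (ep > nrow(traces))
      stop("schedule epoch beyond trace length", call. = FALSE)
    losses <- traces[ep, alive]
    alive <- sort(alive[order(losses)[seq_len(keep)]])  # stable: ties keep lower index
    out[[sprintf("epoch%d", ep)]] <- alive
  }
  out
}

# Validation Dice loss of a network over a cohort: mean over cases and
# organs of (1 - Dice) of the thresholded full-image prediction.
validation_dice_loss <- function(net, cohort, organs) {
  losses <- c()
  for (case in cohort) {
    prob <- predict(net, case$image)
    for (k in seq_along(organs)) {
      pred <- (prob[, , , k] >= 0.5) * 1
      truth <- case$structures$masks[[organs[k]]]
      d <- if (sum(pred) + sum(truth) == 0) 1 else
        2 * sum(pred * truth) / (sum(pred) + sum(truth))
      losses <- c(losses, 1 - d)
    }
  }
  mean(losses)
}

draw_batch <- function(cohort, cfg, states = NULL) {
  lapply(seq_len(cfg$batch_size), function(i) {
    ci <- sample.int(length(cohort), 1L)
    case <- cohort[[ci]]
    d <- composite_sampler(case$image, case$structures, cfg$sampler, 1L,
                           state = states[[ci]])[[1]]
    y <- d$labels[, , , match(cfg$organs, names(case$structures$masks)),
                  drop = FALSE]
    list(x = d$image$values, y = y)
  })
}

#' Tournament training of several randomly initialized networks
#'
#' Initializes `n_initializations` networks with independent seeds, trains
#' each for `steps_per_epoch` Nesterov-Adam steps per epoch on composite-
#' sampled patches, and at each scheduled epoch retains the survivors with
#' the lowest validation Dice loss. After the last drop the single
#' survivor continues until its validation loss has not improved for
#' `patience` epochs (or `planned_epochs` is reached); the
#' best-validation-loss checkpoint is returned. Each network draws its
#' training batches from an independent seeded stream.
#'
#' @param model_factory function(seed) returning a fresh `seg_network`.
#' @param train_cohort,val_cohort lists of cases, each
#'   `list(image = image_grid, structures = structure_set)`.
#' @param cfg a [train_config].
#' @param verbose print per-epoch progress.
#' @return An object of class `tournament_fit`: the winning `network`
#'   (best checkpoint), a per-epoch `history` data frame (epoch, net id,
#'   train loss, validation loss, lr, alive flag), the surviving ids per
#'   stage, and the config.
#' @export
tournament_train <- function(model_factory, train_cohort, val_cohort, cfg,
                             verbose = FALSE) {
  if (length(val_cohort) == 0) stop("validation cohort empty", call. = FALSE)
  surv0 <- vapply(cfg$tournament_schedule, `[`, numeric(1), 2)[1]
  if (length(surv0) && 2 * surv0 != cfg$n_initializations)
    stop("schedule inconsistent with the initial population", call. = FALSE)
  n <- cfg$n_initializations
  nets <- vector("list", n)
  states <- vector("list", n)
  seeds <- cfg$seed + seq_len(n) * 1009L
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    nets[[i]] <- model_factory(seeds[i])
  }
  alive <- seq_len(n)
  sampler_states <- lapply(train_cohort, function(case)
    sampler_state(case$image, case$structures, cfg$sampler))
  history <- NULL
  stages <- list()
  sched <- cfg$tournament_schedule
  best <- list(loss = Inf, params = NULL, buffers = NULL, id = NA)
  no_improve <- 0L
  epoch <- 0L
  while (epoch < cfg$planned_epochs) {
    epoch <- epoch + 1L
    lr <- lr_at_epoch(cfg, epoch - 1L)
    for (i in alive) {
      set.seed((seeds[i] + 131L * epoch) %% 2147483647L)
      tr_loss <- NA_real_
      for (s in seq_len(cfg$steps_per_epoch)) {
        batch <- draw_batch(train_cohort, cfg, sampler_states)
        st <- train_step(nets[[i]], batch, states[[i]], lr)
        nets[[i]] <- st$net; states[[i]] <- st$state; tr_loss <- st$loss
      }
      vl <- validation_dice_loss(nets[[i]], val_cohort, cfg$organs)
      history <- rbind(history, data.frame(
        epoch = epoch, net = i, train_loss = tr_loss, val_loss = vl,
        lr = lr, alive = TRUE))
      if (verbose)
        message(sprintf("epoch %d net %d: train %.4f val %.4f", epoch, i,
                        tr_loss, vl))
    }
    cur <- history[history$epoch == epoch, ]
    drop_now <- Filter(function(st) st[1] == epoch, sched)
    if (length(drop_now)) {
      keep <- drop_now[[1]][2]
      vl <- cur$val_loss[match(alive, cur$net)]
      alive <- sort(alive[order(vl)[seq_len(keep)]])
      stages[[sprintf("epoch%d", epoch)]] <- alive
    }
    if (length(alive) == 1L) {
      vl <- cur$val_loss[cur$net == alive]
      if (vl < best$loss - 1e-12) {
        best <- list(loss = vl, params = net_params(nets[[alive]]),
                     buffers = lapply(nets[[alive]]$nodes, `[[`, "buffers"),
                     id = alive)
        no_improve <- 0L
      } else {
        no_improve <- no_improve + 1L
        if (no_improve >= cfg$patience) break
      }
    }
  }
  winner <- nets[[alive[1]]]
  if (!is.null(best$params)) {
    winner <- net_set_params(winner, best$params)
    for (id in seq_along(best$buffers))
      if (!is.null(best$buffers[[id]]))
        winner$nodes[[id]]$buffers <- best$buffers[[id]]
  }
  structure(list(network = winner, history = history, stages = stages,
                 best_val_loss = if (is.finite(best$loss)) best$loss else
                   min(history$val_loss),
                 config = cfg),
            class = "tournament_fit")
}

#' @export
print.tournament_fit <- function(x, ...) {
  cat(sprintf(
    "<tournament_fit> %d epochs over %d initialization(s); best validation Dice loss %.4f\n",
    max(x$history$epoch), x$config$n_initializations, x$best_val_loss))
  invisible(x)
}

#' @export
summary.tournament_fit <- function(object, ...) {
  h <- object$history
  agg <- aggregate(val_loss ~ net, data = h, FUN = min)
  cat("Best validation Dice loss per network:\n")
  print(agg, row.names = FALSE)
  cat("Survivors per stage:\n")
  for (nm in names(object$stages))
    cat(" ", nm, ":", paste(object$stages[[nm]], collapse = ", "), "\n")
  invisible(object)
}

#' @export
plot.tournament_fit <- function(x, ...) {
  h <- x$history
  plot(NA, xlim = range(h$epoch), ylim = range(h$val_loss),
       xlab = "epoch", ylab = "validation Dice loss",
       main = "Tournament training")
  for (i in unique(h$net)) {
    hi <- h[h$net == i, ]
    lines(hi$epoch, hi$val_loss, col = i)
  }
  invisible(x)
}

#' @export
predict.tournament_fit <- function(object, grid, ...) {
  predict(object$network, grid, ...)
}
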
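# Minimal computation-graph engine for 3-D fully convolutional networks.
#
# A network is a list of topologically ordered nodes. Each node has an op
# type, the ids of its input nodes, op attributes, and (optionally) named
# parameter arrays plus non-trainable buffers (batch-norm running stats).
# Activations flow as (X, Y, Z, C) arrays. forward_net() caches per-node
# outputs and the op-specific intermediates needed by backward_net(),
# which returns parameter gradients plus the gradient at the input.
#
# Supported ops:
#   input                conv (k, s, pad)        convt2 (2x2x2 stride-2
#   prelu (per-channel)  bn (per-channel)        transpose convolution)
#   dropout (rate)       add                     concat / cropcat
#   maxpool2             upnn2 (nearest x2)      relu / sigmoid

new_graph <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env
}

g_add <- function(g, op, ins = integer(0), ...) {
  node <- c(list(op = op, ins = as.integer(ins)), list(...))
  g$nodes[[length(g$nodes) + 1L]] <- node
  length(g$nodes)
}

he_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(runif(prod(dims), -lim, lim), dim = dims)
}

# Convolution node; pad is symmetric zero padding. Weights are He-uniform
# over fan_in = k^3 * cin (draws come from the caller-seeded R RNG).
g_conv <- function(g, in_id, cin, cout, k, s = 1L, pad = 0L) {
  W <- he_uniform(c(k, k, k, cin, cout), k^3 * cin)
  g_add(g, "conv", in_id, k = as.integer(k), s = as.integer(s),
        pad = as.integer(pad), cin = cin, cout = cout,
        params = list(W = W, b = numeric(cout)))
}

g_convt2 <- function(g, in_id, cin, cout) {
  W <- he_uniform(c(2, 2, 2, cin, cout), 8 * cin)
  g_add(g, "convt2", in_id, cin = cin, cout = cout,
        params = list(W = W, b = numeric(cout)))
}

g_prelu <- function(g, in_id, c) {
  g_add(g, "prelu", in_id, params = list(alpha = rep(0.25, c)))
}

g_bn <- function(g, in_id, c, eps = 1e-5, momentum = 0.1) {
  g_add(g, "bn", in_id, eps = eps, momentum = momentum,
        params = list(gamma = rep(1, c), beta = numeric(c)),
        buffers = list(rm = numeric(c), rv = rep(1, c)))
}

# Convolutional block in caption order: dropout -> conv -> PReLU -> batch norm.
g_conv_block <- function(g, in_id, cin, cout, k, dropout) {
  id <- in_id
  if (dropout > 0) id <- g_add(g, "dropout", id, rate = dropout)
  id <- g_conv(g, id, cin, cout, k = k, s = 1L, pad = (k - 1L) %/% 2L)
  id <- g_prelu(g, id, cout)
  g_bn(g, id, cout)
}

# Residual block: two convolutional blocks plus an additive skip.
g_res_block <- function(g, in_id, c, dropout) {
  a <- g_conv_block(g, in_id, c, c, 3L, dropout)
  b <- g_conv_block(g, a, c, c, 3L, dropout)
  g_add(g, "add", c(in_id, b))
}

channel_apply <- function(x, f) {
  d <- dim(x)
  m <- matrix(x, prod(d[1:3]), d[4])
  array(f(m), dim = d)
}

forward_net <- function(net, x, training = FALSE) {
  nodes <- net$nodes
  acts <- vector("list", length(nodes))
  extras <- vector("list", length(nodes))
  for (id in seq_along(nodes)) {
    nd <- nodes[[id]]
    a <- if (length(nd$ins)) acts[[nd$ins[1]]] else NULL
    out <- switch(nd$op,
      input = x,
      conv = conv3d_fw(a, nd$params$W, nd$params$b, nd$k, nd$s, nd$pad),
      convt2 = convt2_fw(a, nd$params$W, nd$params$b),
      prelu = prelu_fw(a, nd$params$alpha),
      bn = {
        if (training) {
          st <- channel_stats(a)
          mu <- st$mean
          va <- st$var
        } else {
          mu <- nd$buffers$rm
          va <- nd$buffers$rv
        }
        inv <- 1 / sqrt(va + nd$eps)
        scale <- nd$params$gamma * inv
        extras[[id]] <- list(inv = inv, mu = mu, va = va,
                             training = training)
        channel_affine(a, scale, nd$params$beta - mu * scale)
      },
      dropout = {
        if (training && nd$rate > 0) {
          keep <- 1 - nd$rate
          mask <- (runif(length(a)) < keep) / keep
          extras[[id]] <- mask
          array(a * mask, dim = dim(a))
        } else a
      },
      add = {
        s <- acts[[nd$ins[1]]]
        for (k in nd$ins[-1]) s <- s + acts[[k]]
        s
      },
      concat = {
        parts <- lapply(nd$ins, function(k) acts[[k]])
        d1 <- dim(parts[[1]])
        cs <- vapply(parts, function(p) dim(p)[4], numeric(1))
        array(unlist(parts, use.names = FALSE),
              dim = c(d1[1:3], sum(cs)))
      },
      cropcat = {
        up <- acts[[nd$ins[1]]]
        skip <- acts[[nd$ins[2]]]
        du <- dim(up); ds <- dim(skip)
        mar <- (ds[1:3] - du[1:3]) %/% 2L
        if (any(ds[1:3] - du[1:3] < 0))
          stop("skip smaller than upsampled path", call. = FALSE)
        sk <- skip[mar[1] + seq_len(du[1]), mar[2] + seq_len(du[2]),
                   mar[3] + seq_len(du[3]), , drop = FALSE]
        extras[[id]] <- mar
        array(c(up, sk), dim = c(du[1:3], du[4] + ds[4]))
      },
      maxpool2 = {
        r <- maxpool2_fw(a)
        extras[[id]] <- list(argmax = r$argmax, xdim = dim(a))
        r$y
      },
      upnn2 = upnn2_fw(a),
      relu = pmax(a, 0),
      sigmoid = 1 / (1 + exp(-a)),
      stop("unknown op: ", nd$op)
    )
    acts[[id]] <- out
  }
  list(out = acts[[net$out_id]], acts = acts, extras = extras)
}

# Backward pass: dout is the gradient of the loss w.r.t. the network output.
# Returns list(grads = per-node list of named parameter gradients,
#              dx = gradient at the input node).
backward_net <- function(net, fw, dout) {
  nodes <- net$nodes
  acts <- fw$acts
  extras <- fw$extras
  dacts <- vector("list", length(nodes))
  grads <- vector("list", length(nodes))
  dacts[[net$out_id]] <- dout
  add_grad <- function(cur, inc) if (is.null(cur)) inc else cur + inc
  for (id in rev(seq_along(nodes))) {
    dy <- dacts[[id]]
    if (is.null(dy)) next
    nd <- nodes[[id]]
    a <- if (length(nd$ins)) acts[[nd$ins[1]]] else NULL
    switch(nd$op,
      input = NULL,
      conv = {
        bw <- conv3d_bw(a, nd$params$W, dy, nd$k, nd$s, nd$pad)
        grads[[id]] <- list(W = bw$dw, b = bw$db)
        dacts[[nd$ins[1]]] <- add_grad(dacts[[nd$ins[1]]], bw$dx)
      },
      convt2 = {
        bw <- convt2_bw(a, nd$params$W, dy)
        grads[[id]] <- list(W = bw$dw, b = bw$db)
        dacts[[nd$ins[1]]] <- add_grad(dacts[[nd$ins[1]]], bw$dx)
      },
      prelu = {
        bw <- prelu_bw(a, nd$params$alpha, dy)
        grads[[id]] <- list(alpha = bw$dalpha)
        dacts[[nd$ins[1]]] <- add_grad(dacts[[nd$ins[1]]], bw$dx)
      },
      bn = {
        ex <- extras[[id]]
        bw <- bn_bw(a, dy, ex$mu, ex$inv, nd$params$gamma, ex$training)
        grads[[id]] <- list(gamma = bw$dgamma, beta = bw$dbeta)
        dacts[[nd$ins[1]]] <- add_grad(dacts[[nd$ins[1]]], bw$dx)
      },
      dropout = {
        mask <- extras[[id]]
        dx <- if (is.null(mask)) dy else array(dy * mask, dim = dim(dy))
        dacts[[nd$ins[1]]] <- add_grad(dacts[[nd$ins[1]]], dx)
      },
      add = {
        for (k in nd$ins)
          dacts[[k]] <- add_grad(dacts[[k]], dy)
      },
      concat = {
        off <- 0L
        dd <- dim(dy)
        for (k in nd$ins) {
          ck <- dim(acts[[k]])[4]
          dk <- dy[, , , off + seq_len(ck), drop = FALSE]
          dacts[[k]] <- add_grad(dacts[[k]], dk)
          off <- off + ck
        }
      },
      cropcat = {
        mar <- extras[[id]]
        du <- dim(acts[[nd$ins[1]]])
        ds <- dim(acts[[nd$ins[2]]])
        dup <- dy[, , , seq_len(du[4]), drop = FALSE]
        dskip_crop <- dy[, , , du[4] + seq_len(ds[4]), drop = FALSE]
        dskip <- array(0, dim = ds)
        dskip[mar[1] + seq_len(du[1]), mar[2] + seq_len(du[2]),
              mar[3] + seq_len(du[3]), ] <- dskip_crop
        dacts[[nd$ins[1]]] <- add_grad(dacts[[nd$ins[1]]], dup)
        dacts[[nd$ins[2]]] <- add_grad(dacts[[nd$ins[2]]], dskip)
      },
      maxpool2 = {
        ex <- extras[[id]]
        dx <- maxpool2_bw(dy, ex$argmax, ex$xdim)
        dacts[[nd$ins[1]]] <- add_grad(dacts[[nd$ins[1]]], dx)
      },
      upnn2 = {
        dacts[[nd$ins[1]]] <- add_grad(dacts[[nd$ins[1]]], upnn2_bw(dy))
      },
      relu = {
        dacts[[nd$ins[1]]] <- add_grad(dacts[[nd$ins[1]]],
                                       dy * (a > 0))
      },
      sigmoid = {
        y <- acts[[id]]
        dacts[[nd$ins[1]]] <- add_grad(dacts[[nd$ins[1]]], dy * y * (1 - y))
      },
      stop("unknown op: ", nd$op)
    )
    if (id != 1L) dacts[id] <- list(NULL)  # free memory as we go
  }
  list(grads = grads, dx = dacts[[1]])
}

# Update batch-norm running statistics from one training-mode forward pass.
update_bn_buffers <- function(net, fw) {
  for (id in seq_along(net$nodes)) {
    nd <- net$nodes[[id]]
    if (nd$op != "bn" || is.null(fw$extras[[id]])) next
    ex <- fw$extras[[id]]
    if (!isTRUE(ex$training)) next
    mom <- nd$momentum
    net$nodes[[id]]$buffers$rm <- (1 - mom) * nd$buffers$rm + mom * ex$mu
    net$nodes[[id]]$buffers$rv <- (1 - mom) * nd$buffers$rv + mom * ex$va
  }
  net
}

# Flat named list of all trainable parameter arrays ("n<id>.<name>").
net_params <- function(net) {
  out <- list()
  for (id in seq_along(net$nodes)) {
    ps <- net$nodes[[id]]$params
    if (is.null(ps)) next
    for (nm in names(ps)) out[[sprintf("n%d.%s", id, nm)]] <- ps[[nm]]
  }
  out
}

net_set_params <- function(net, params) {
  for (nm in names(params)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    id <- as.integer(sub("^n", "", parts[1]))
    p <- net$nodes[[id]]$params[[parts[2]]]
    stopifnot(length(p) == length(params[[nm]]))
    dim_old <- dim(p)
    v <- params[[nm]]
    if (!is.null(dim_old)) dim(v) <- dim_old
    net$nodes[[id]]$params[[parts[2]]] <- v
  }
  net
}

grads_flat <- function(net, grads) {
  out <- list()
  for (id in seq_along(net$nodes)) {
    gs <- grads[[id]]
    if (is.null(gs)) next
    for (nm in names(gs)) out[[sprintf("n%d.%s", id, nm)]] <- gs[[nm]]
  }
  out
}
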
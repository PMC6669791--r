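# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own computational paths: plain R loops and direct
# formula evaluation only.

# all-pairs directed minimum distances from each row of P to G (mm)
bf_min_dists <- function(P, G) {
  apply(P, 1, function(p) sqrt(min(colSums((t(G) - p)^2))))
}

bf_hausdorff <- function(P, G) {
  max(max(bf_min_dists(P, G)), max(bf_min_dists(G, P)))
}

bf_rms <- function(P, G) sqrt(mean(bf_min_dists(P, G)^2))

# flood-fill component labelling, 6/18/26-connectivity, recursion-free
bf_label <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  manh <- rowSums(abs(offs))
  offs <- offs[manh > 0 & manh <= c("6" = 1, "18" = 2, "26" = 3)[as.character(connectivity)], ,
               drop = FALSE]
  lab <- array(0L, d)
  nxt <- 0L
  for (v in which(mask == 1)) {
    if (lab[v] > 0L) next
    nxt <- nxt + 1L
    queue <- matrix(arrayInd(v, d), ncol = 3)
    lab[v] <- nxt
    while (nrow(queue)) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (r in seq_len(nrow(offs))) {
        nb <- cur + offs[r, ]
        if (any(nb < 1) || any(nb > d)) next
        if (mask[nb[1], nb[2], nb[3]] == 1 && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- nxt
          queue <- rbind(queue, nb)
        }
      }
    }
  }
  lab
}

# random binary mask with at least one foreground and one background voxel
random_mask <- function(d, p = 0.3) {
  repeat {
    m <- array(as.numeric(rbinom(prod(d), 1, p)), dim = d)
    if (sum(m) > 0 && sum(m) < length(m)) return(m)
  }
}

# small phantom spec whose geometry fits a 32x32x16 grid
small_phantom_spec <- function(noise_sd = 20, seed = 1L) {
  phantom_spec(shape = c(32, 32, 16), spacing = c(2.34, 2.34, 3.0),
               geometry = list(body_radii = c(33, 24, 100),
                               lung_offset = c(15, -5, 0),
                               lung_radii = c(10, 12, 28),
                               breast_offset = c(16, 20, 2),
                               breast_radii = c(9, 7, 10),
                               heart_offset = c(0, 0, -1),
                               heart_radii = c(9, 8, 11)),
               jitter = list(radius_frac = 0.08, center_mm = 2),
               noise_sd = noise_sd, seed = seed)
}

# tiny bib-type network for engine-level tests
tiny_bibnet <- function(out_channels = 1, base = 4, dropout = 0) {
  build_bibnet(bibnet_config(n_levels = 2, base_filters = base,
                             encoder_blocks = c(1, 1),
                             lateral_blocks = c(1, 0), decoder_blocks = 1,
                             dropout_rate = dropout,
                             out_channels = out_channels))
}
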
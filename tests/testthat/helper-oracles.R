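# Independent oracles used across the suite.

# Brute-force five-nested-loop convolution (valid, stride 1,
# cross-correlation), deliberately naive and independent of the package's
# conv path.
conv_loop_oracle <- function(layer, x) {
  d <- dim(x)
  k <- layer$k
  N <- d[1]; C <- d[2]; OH <- d[3] - k + 1; OW <- d[4] - k + 1
  FF <- dim(layer$weights)[1]
  out <- array(0, c(N, FF, OH, OW))
  for (n in seq_len(N)) for (f in seq_len(FF)) for (oh in seq_len(OH)) for (ow in seq_len(OW)) {
    s <- 0
    cs <- if (layer$mode == "depthwise") 1L else seq_len(C)
    for (c in cs) for (i in seq_len(k)) for (j in seq_len(k)) {
      src_c <- if (layer$mode == "depthwise") f else c
      s <- s + layer$weights[f, c, i, j] * x[n, src_c, oh + i - 1, ow + j - 1]
    }
    out[n, f, oh, ow] <- s + layer$biases[f]
  }
  out
}

# Relative error with a floor so that near-zero pairs do not blow up.
rel_err <- function(a, b, floor = 1e-6) {
  abs(a - b) / pmax(abs(a), abs(b), floor)
}

# Central finite difference of scalar function f at x[i], h = 1e-5.
fd_grad <- function(f, x, i, h = 1e-5) {
  xp <- x; xp[i] <- xp[i] + h
  xm <- x; xm[i] <- xm[i] - h
  (f(xp) - f(xm)) / (2 * h)
}

# Tiny network configuration used by the whole-model gradient checks.
tiny_config <- function(seed = 1L, use_batchnorm = FALSE)
  network_config(n_channels = 2L, input_side = 8L, conv2_filters = 2L,
                 kernel = 3L, fc_sizes = c(8L, 4L, 1L),
                 use_batchnorm = use_batchnorm, seed = seed)

# Whole-network scalar loss and analytic parameter gradient on one batch.
net_loss_and_grad <- function(net, x, y, mode = "eval") {
  fwd <- tanhrelunet:::net_forward_cached(net, x, mode)
  l <- mse_loss(fwd$prob, y)
  list(loss = l$loss,
       grads = tanhrelunet:::net_backward(net, fwd$cache, l$grad))
}

net_loss_at <- function(net, params, x, y, mode = "eval") {
  net2 <- set_net_params(net, params)
  mse_loss(net_forward(net2, x, mode), y)$loss
}

# A tiny synthetic cohort that trains in seconds: few channels, short
# recordings, slim network.
tiny_cohort <- function(seed = 1L, n_per_class = 3L, duration_s = 8,
                        effect = 1) {
  generate_dataset(synth_config(n_subjects_per_class = n_per_class,
                                duration_s = duration_s, n_channels = 2L,
                                alpha_amp_effect = effect, seed = seed))
}

tiny_net_cfg <- function(seed = 1L)
  network_config(n_channels = 2L, conv2_filters = 4L,
                 fc_sizes = c(16L, 4L, 1L), seed = seed)

tiny_train_cfg <- function(seed = 1L, ...)
  train_config(batch_size = 4L, max_epochs = 3L, patience = 2L,
               shuffle_seed = seed, ...)
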
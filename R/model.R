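# Network assembly: depthwise "high-filter" conv -> standard conv -> flatten
# -> hourglass fully connected block -> sigmoid head.  Batch normalization
# (when enabled) sits after each conv and each hidden fc layer, before the
# activation.

#' Network architecture configuration
#'
#' Defaults give the reference geometry: 20-channel input, 32x32 planes
#' per channel (one 1024-sample window), two 5x5 valid convolutions (the
#' first depthwise with one filter per electrode, the second standard), and
#' an hourglass fully connected block with strictly decreasing widths ending
#' in a single sigmoid unit.
#'
#' @param n_channels Input channels (electrodes); default 20.
#' @param input_side Side of the square per-channel plane; default 32
#'   (window length `input_side^2 = 1024`).
#' @param conv1_filters Filters in the depthwise layer; must equal
#'   `n_channels`.
#' @param conv2_filters Filters in the second (standard) conv layer;
#'   default 20.
#' @param kernel Square kernel size for both conv layers; default 5.
#' @param fc_sizes Strictly decreasing widths of the hourglass block, last
#'   must be 1; default `c(128, 32, 1)`.
#' @param activation An [activation_spec()]; default TanhReLU with `a = 0.25`.
#' @param use_batchnorm Apply batch normalization after each conv and hidden
#'   fc layer; default `TRUE`.
#' @param seed Integer seed controlling weight initialization.
#' @return A `network_config` object.
#' @export
network_config <- function(n_channels = 20L, input_side = 32L,
                           conv1_filters = n_channels, conv2_filters = 20L,
                           kernel = 5L, fc_sizes = c(128L, 32L, 1L),
                           activation = activation_spec("tanhrelu"),
                           use_batchnorm = TRUE, seed = 1L) {
  cfg <- list(n_channels = as.integer(n_channels),
              input_side = as.integer(input_side),
              conv1_filters = as.integer(conv1_filters),
              conv2_filters = as.integer(conv2_filters),
              kernel = as.integer(kernel),
              fc_sizes = as.integer(fc_sizes),
              activation = activation,
              use_batchnorm = isTRUE(use_batchnorm),
              seed = as.integer(seed))
  if (cfg$n_channels < 1L || cfg$input_side < 1L)
    stop("n_channels and input_side must be positive")
  if (cfg$conv1_filters != cfg$n_channels)
    stop("conv1 is depthwise: conv1_filters must equal n_channels")
  if (length(cfg$fc_sizes) < 1L || any(diff(cfg$fc_sizes) >= 0))
    stop("fc_sizes must be strictly decreasing (hourglass block)")
  if (cfg$fc_sizes[length(cfg$fc_sizes)] != 1L)
    stop("the final fc size must be 1 (single sigmoid unit)")
  s1 <- cfg$input_side - cfg$kernel + 1L
  s2 <- s1 - cfg$kernel + 1L
  if (s2 < 1L)
    stop(sprintf("kernel %d too large for %dx%d input (two valid convolutions)",
                 cfg$kernel, cfg$input_side, cfg$input_side))
  if (!inherits(cfg$activation, "activation_spec"))
    stop("activation must be an activation_spec")
  cfg$conv_out_side <- s2
  cfg$flat_size <- cfg$conv2_filters * s2 * s2
  structure(cfg, class = "network_config")
}

glorot_uniform <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(runif(prod(dims), -lim, lim), dim = dims)
}

#' Build a network from a configuration
#'
#' Weights are zero-mean uniform with half-width `sqrt(6 / (fan_in +
#' fan_out))` per layer (Glorot), biases zero, batch-norm `gamma = 1`,
#' `beta = 0`; all draws come from a single generator seeded by
#' `config$seed`, so the same config yields bit-identical parameters.
#'
#' @param config A [network_config()].
#' @return A `tanhrelu_net` object.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  k <- config$kernel
  with_seed(config$seed, {
    conv1 <- conv_layer(glorot_uniform(c(config$n_channels, 1, k, k),
                                       k * k, k * k),
                        rep(0, config$n_channels), mode = "depthwise")
    conv2 <- conv_layer(glorot_uniform(c(config$conv2_filters, config$n_channels, k, k),
                                       config$n_channels * k * k,
                                       config$conv2_filters * k * k),
                        rep(0, config$conv2_filters), mode = "standard")
    sizes <- c(config$flat_size, config$fc_sizes)
    fcs <- lapply(seq_along(config$fc_sizes), function(i)
      fc_layer(glorot_uniform(c(sizes[i + 1], sizes[i]), sizes[i], sizes[i + 1]),
               rep(0, sizes[i + 1])))
  })
  bns <- NULL
  if (config$use_batchnorm) {
    nf <- c(config$conv1_filters, config$conv2_filters,
            config$fc_sizes[-length(config$fc_sizes)])
    bns <- lapply(nf, batchnorm_layer)
  }
  structure(list(config = config, conv1 = conv1, conv2 = conv2,
                 fcs = fcs, bns = bns),
            class = "tanhrelu_net")
}

#' @export
print.tanhrelu_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<tanhrelu_net: %d ch x %dx%d -> conv %d (depthwise, %dx%d) -> conv %d -> %s -> sigmoid; %s%s; %d parameters>\n",
              cfg$n_channels, cfg$input_side, cfg$input_side,
              cfg$conv1_filters, cfg$kernel, cfg$kernel, cfg$conv2_filters,
              paste(cfg$fc_sizes, collapse = " -> "), cfg$activation$kind,
              if (cfg$use_batchnorm) " + batchnorm" else "",
              parameter_count(cfg)))
  invisible(x)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars: conv and fc weights and biases, plus
#' batch-norm gamma/beta when enabled (running statistics are state, not
#' parameters).
#'
#' @param config A [network_config()].
#' @return Integer parameter count.
#' @export
parameter_count <- function(config) {
  stopifnot(inherits(config, "network_config"))
  k2 <- config$kernel^2
  n <- config$n_channels * k2 + config$n_channels +                 # depthwise
    config$conv2_filters * config$n_channels * k2 + config$conv2_filters
  sizes <- c(config$flat_size, config$fc_sizes)
  n <- n + sum(sizes[-length(sizes)] * sizes[-1] + sizes[-1])
  if (config$use_batchnorm)
    n <- n + 2 * (config$conv1_filters + config$conv2_filters +
                    sum(config$fc_sizes[-length(config$fc_sizes)]))
  as.integer(n)
}

check_batch <- function(net, batch, validate = TRUE) {
  d <- dim(batch)
  cfg <- net$config
  if (is.null(d) || length(d) != 4L ||
      d[2] != cfg$n_channels || d[3] != cfg$input_side || d[4] != cfg$input_side)
    stop(sprintf("batch must be N x %d x %d x %d",
                 cfg$n_channels, cfg$input_side, cfg$input_side))
  if (validate) check_finite(batch, "batch")
  d
}

#' Network forward pass
#'
#' Runs a batch through the network and returns one probability per example.
#' `"train"` mode uses batch statistics for normalization (and updates the
#' running statistics — retrieve the updated network via
#' `net_forward_cached()`); `"eval"` mode uses the running statistics and is
#' deterministic.
#'
#' @param net A [build_network()] result.
#' @param batch Numeric array `N x C x side x side`.
#' @param mode `"train"` or `"eval"`.
#' @return Numeric vector of probabilities in (0,1), length `N`.
#' @export
net_forward <- function(net, batch, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  net_forward_cached(net, batch, mode)$prob
}

# Forward pass retaining every intermediate needed by net_backward.
# Returns list(prob, cache, net) where net carries updated running stats.
# `validate = FALSE` skips the finiteness scan for tensors the caller has
# already validated (the training loop re-screens via the loss instead).
net_forward_cached <- function(net, batch, mode = c("eval", "train"),
                               validate = TRUE) {
  mode <- match.arg(mode)
  check_batch(net, batch, validate)
  cfg <- net$config
  act <- cfg$activation
  bn_i <- 0L
  cache <- list(input = batch)
  run_bn <- function(x) {
    bn_i <<- bn_i + 1L
    r <- batchnorm_forward(net$bns[[bn_i]], x, mode)
    net$bns[[bn_i]] <<- r$layer
    cache[[paste0("bn", bn_i)]] <<- r$cache
    r$output
  }
  z <- conv2d_forward(net$conv1, batch)
  if (cfg$use_batchnorm) z <- run_bn(z)
  cache$z1 <- z
  h <- activation_forward(act, z)
  cache$h1 <- h
  z <- conv2d_forward(net$conv2, h)
  if (cfg$use_batchnorm) z <- run_bn(z)
  cache$z2 <- z
  h <- activation_forward(act, z)
  cache$h2 <- h
  N <- dim(batch)[1]
  flat <- matrix(h, nrow = N)               # column-major flatten, documented
  cache$flat <- flat
  x <- flat
  n_fc <- length(net$fcs)
  for (i in seq_len(n_fc)) {
    z <- fc_forward(net$fcs[[i]], x)
    if (i < n_fc) {
      if (cfg$use_batchnorm) z <- run_bn(z)
      cache[[paste0("zf", i)]] <- z
      x <- activation_forward(act, z)
      cache[[paste0("hf", i)]] <- x
    } else {
      cache$logit <- z
    }
  }
  prob <- sigmoid(as.numeric(cache$logit))
  cache$prob <- prob
  list(prob = prob, cache = cache, net = net)
}

# Backward pass through the whole network given d(loss)/d(prob).
# Returns gradients as a named list parallel to net_params().
net_backward <- function(net, cache, grad_prob) {
  cfg <- net$config
  act <- cfg$activation
  grads <- list()
  p <- cache$prob
  gz <- matrix(grad_prob * p * (1 - p), ncol = 1)   # through sigmoid
  n_fc <- length(net$fcs)
  bn_total <- if (cfg$use_batchnorm) 2L + (n_fc - 1L) else 0L
  bn_i <- bn_total
  for (i in rev(seq_len(n_fc))) {
    inp <- if (i == 1) cache$flat else cache[[paste0("hf", i - 1)]]
    g <- fc_backward(net$fcs[[i]], inp, gz)
    grads[[paste0("fc", i, ".weights")]] <- g$grad_weights
    grads[[paste0("fc", i, ".biases")]] <- g$grad_biases
    gz <- g$grad_input
    if (i > 1) {
      gz <- gz * activation_deriv(act, cache[[paste0("zf", i - 1)]])
      if (cfg$use_batchnorm) {
        b <- batchnorm_backward(net$bns[[bn_i]], cache[[paste0("bn", bn_i)]], gz)
        grads[[paste0("bn", bn_i, ".gamma")]] <- b$grad_gamma
        grads[[paste0("bn", bn_i, ".beta")]] <- b$grad_beta
        gz <- b$grad_input
        bn_i <- bn_i - 1L
      }
    }
  }
  # back through flatten
  gh <- array(gz, dim = dim(cache$h2))
  gh <- gh * activation_deriv(act, cache$z2)
  if (cfg$use_batchnorm) {
    b <- batchnorm_backward(net$bns[[2]], cache$bn2, gh)
    grads[["bn2.gamma"]] <- b$grad_gamma
    grads[["bn2.beta"]] <- b$grad_beta
    gh <- b$grad_input
  }
  # safe to reuse the forward's patch buffer: net_backward always directly
  # follows its own net_forward_cached on the same batch
  g <- conv_std_bwd(cache$h1, net$conv2$weights, gh, reuse_cols = TRUE)
  grads[["conv2.weights"]] <- g$grad_weights
  grads[["conv2.biases"]] <- g$grad_biases
  gh <- g$grad_input * activation_deriv(act, cache$z1)
  if (cfg$use_batchnorm) {
    b <- batchnorm_backward(net$bns[[1]], cache$bn1, gh)
    grads[["bn1.gamma"]] <- b$grad_gamma
    grads[["bn1.beta"]] <- b$grad_beta
    gh <- b$grad_input
  }
  # first layer: the input gradient is never consumed, skip computing it
  g <- depthwise_bwd(cache$input, net$conv1$weights, gh,
                     need_input_grad = FALSE)
  grads[["conv1.weights"]] <- g$grad_weights
  grads[["conv1.biases"]] <- g$grad_biases
  grads
}

#' Flat named view of all trainable parameters
#'
#' Names follow `<layer>.<parameter>` (`conv1.weights`, `bn2.gamma`,
#' `fc3.biases`, ...).  [set_net_params()] is its inverse.
#'
#' @param net A network.
#' @return Named list of numeric arrays.
#' @export
net_params <- function(net) {
  p <- list(conv1.weights = net$conv1$weights, conv1.biases = net$conv1$biases,
            conv2.weights = net$conv2$weights, conv2.biases = net$conv2$biases)
  for (i in seq_along(net$fcs)) {
    p[[paste0("fc", i, ".weights")]] <- net$fcs[[i]]$weights
    p[[paste0("fc", i, ".biases")]] <- net$fcs[[i]]$biases
  }
  for (i in seq_along(net$bns)) {
    p[[paste0("bn", i, ".gamma")]] <- net$bns[[i]]$gamma
    p[[paste0("bn", i, ".beta")]] <- net$bns[[i]]$beta
  }
  p
}

#' Write a flat parameter list back into a network
#'
#' @param net A network.
#' @param params Named list as produced by [net_params()].
#' @return The updated network.
#' @export
set_net_params <- function(net, params) {
  net$conv1$weights <- params$conv1.weights
  net$conv1$biases <- params$conv1.biases
  net$conv2$weights <- params$conv2.weights
  net$conv2$biases <- params$conv2.biases
  for (i in seq_along(net$fcs)) {
    net$fcs[[i]]$weights <- params[[paste0("fc", i, ".weights")]]
    net$fcs[[i]]$biases <- params[[paste0("fc", i, ".biases")]]
  }
  for (i in seq_along(net$bns)) {
    net$bns[[i]]$gamma <- params[[paste0("bn", i, ".gamma")]]
    net$bns[[i]]$beta <- params[[paste0("bn", i, ".beta")]]
  }
  net
}

# batch-norm running statistics (state, not trainable parameters)
net_state <- function(net) {
  s <- list()
  for (i in seq_along(net$bns)) {
    s[[paste0("bn", i, ".running_mean")]] <- net$bns[[i]]$running_mean
    s[[paste0("bn", i, ".running_var")]] <- net$bns[[i]]$running_var
  }
  s
}

set_net_state <- function(net, state) {
  for (i in seq_along(net$bns)) {
    net$bns[[i]]$running_mean <- state[[paste0("bn", i, ".running_mean")]]
    net$bns[[i]]$running_var <- state[[paste0("bn", i, ".running_var")]]
  }
  net
}

#' Save a network checkpoint
#'
#' Parameters and batch-norm state go to `path` as a little-endian binary
#' container (per entry: name, dimensions, float64 payload); the
#' configuration goes to `paste0(path, ".json")` so the checkpoint is
#' self-describing.
#'
#' @param net A network.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(net, path) {
  entries <- c(net_params(net), net_state(net))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRNC", con, nchars = 4, eos = NULL)
  writeBin(1L, con, size = 4, endian = "little")            # format version
  writeBin(length(entries), con, size = 4, endian = "little")
  for (nm in names(entries)) {
    raw_nm <- charToRaw(nm)
    writeBin(length(raw_nm), con, size = 4, endian = "little")
    writeBin(raw_nm, con)
    v <- entries[[nm]]
    d <- dim(v) %||% length(v)
    writeBin(length(d), con, size = 4, endian = "little")
    writeBin(as.integer(d), con, size = 4, endian = "little")
    writeBin(as.numeric(v), con, size = 8, endian = "little")
  }
  cfg <- net$config
  cfg_json <- list(n_channels = cfg$n_channels, input_side = cfg$input_side,
                   conv1_filters = cfg$conv1_filters,
                   conv2_filters = cfg$conv2_filters, kernel = cfg$kernel,
                   fc_sizes = cfg$fc_sizes,
                   activation = list(kind = cfg$activation$kind,
                                     a = cfg$activation$a,
                                     continuity_correction = cfg$activation$continuity_correction),
                   use_batchnorm = cfg$use_batchnorm, seed = cfg$seed)
  jsonlite::write_json(cfg_json, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a network checkpoint
#'
#' @param path Path previously passed to [save_checkpoint()].
#' @return The reconstructed network.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path) || !file.exists(paste0(path, ".json")))
    stop(sprintf("checkpoint not found at '%s' (need both the binary and .json files)", path))
  cj <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- network_config(n_channels = cj$n_channels, input_side = cj$input_side,
                        conv1_filters = cj$conv1_filters,
                        conv2_filters = cj$conv2_filters, kernel = cj$kernel,
                        fc_sizes = cj$fc_sizes,
                        activation = activation_spec(cj$activation$kind,
                                                     a = cj$activation$a,
                                                     continuity_correction = cj$activation$continuity_correction),
                        use_batchnorm = cj$use_batchnorm, seed = cj$seed)
  net <- build_network(cfg)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "TRNC")) stop("not a tanhrelunet checkpoint")
  readBin(con, "integer", 1, size = 4, endian = "little")   # version
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  entries <- list()
  for (i in seq_len(n)) {
    ln <- readBin(con, "integer", 1, size = 4, endian = "little")
    nm <- rawToChar(readBin(con, "raw", ln))
    nd <- readBin(con, "integer", 1, size = 4, endian = "little")
    d <- readBin(con, "integer", nd, size = 4, endian = "little")
    v <- readBin(con, "numeric", prod(d), size = 8, endian = "little")
    if (nd > 1) dim(v) <- d
    entries[[nm]] <- v
  }
  pn <- names(net_params(net))
  net <- set_net_params(net, entries[pn])
  net <- set_net_state(net, entries[setdiff(names(entries), pn)])
  net
}
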
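# From-scratch differentiable layers.  Tensors are plain R arrays in
# N x C x H x W order; convolution is cross-correlation (no kernel flip),
# stride 1, valid padding.  Each forward has an exact analytic backward,
# verified against central finite differences in the test suite.

#' Convolution layer parameters
#'
#' Holds kernel weights and per-map biases for a 2-D convolution layer.  In
#' `"standard"` mode every filter spans all input channels (`weights` is
#' `F x C_in x k x k`).  In `"depthwise"` mode there is exactly one filter per
#' input channel and filter `f` sees only channel `f` (`weights` is
#' `C x 1 x k x k`) — the configuration used by the first, "high-filter"
#' layer, where each filter is dedicated to one electrode.
#'
#' @param weights 4-d numeric array of kernel weights (see above).
#' @param biases Numeric vector, one bias per output map.
#' @param mode `"standard"` or `"depthwise"`.
#' @return A `conv_layer` object.
#' @export
conv_layer <- function(weights, biases, mode = c("standard", "depthwise")) {
  mode <- match.arg(mode)
  d <- dim(weights)
  if (is.null(d) || length(d) != 4L)
    stop("weights must be a 4-d array (filters x in-channels x k x k)")
  if (d[3] != d[4]) stop("only square kernels are supported")
  if (mode == "depthwise" && d[2] != 1L)
    stop(sprintf("depthwise weights must have in-channel dim 1, got %d", d[2]))
  if (length(biases) != d[1])
    stop(sprintf("expected %d biases (one per output map), got %d", d[1], length(biases)))
  check_finite(weights, "conv weights")
  check_finite(biases, "conv biases")
  structure(list(weights = weights, biases = as.numeric(biases), mode = mode,
                 k = d[3]), class = "conv_layer")
}

conv_check_input <- function(layer, input) {
  d <- dim(input)
  if (is.null(d) || length(d) != 4L)
    stop("input must be a 4-d array N x C x H x W")
  wc <- if (layer$mode == "depthwise") dim(layer$weights)[1] else dim(layer$weights)[2]
  if (d[2] != wc)
    stop(sprintf("channel mismatch: layer expects %d input channels, got %d", wc, d[2]))
  if (d[3] < layer$k || d[4] < layer$k)
    stop(sprintf("input plane %dx%d smaller than kernel %d", d[3], d[4], layer$k))
  d
}

#' Convolution forward pass
#'
#' Valid-padding, stride-1 cross-correlation of a batch with the layer's
#' kernels, plus per-map bias.  Output is `N x F x (H-k+1) x (W-k+1)`.
#'
#' @param layer A [conv_layer()].
#' @param input Numeric array `N x C x H x W`.
#' @return Numeric array of feature maps.
#' @export
conv2d_forward <- function(layer, input) {
  conv_check_input(layer, input)
  if (layer$mode == "depthwise")
    depthwise_fwd(input, layer$weights, layer$biases)
  else
    conv_std_fwd(input, layer$weights, layer$biases)
}

#' Convolution backward pass
#'
#' Exact gradients of [conv2d_forward()] with respect to input, weights and
#' biases, given the upstream gradient `grad_out`.
#'
#' @param layer A [conv_layer()].
#' @param input The array the forward pass saw.
#' @param grad_out Gradient w.r.t. the forward output (same shape).
#' @return List with `grad_input`, `grad_weights`, `grad_biases`.
#' @export
conv2d_backward <- function(layer, input, grad_out) {
  d <- conv_check_input(layer, input)
  N <- d[1]; k <- layer$k
  OH <- d[3] - k + 1; OW <- d[4] - k + 1
  gd <- dim(grad_out)
  FF <- dim(layer$weights)[1]
  if (is.null(gd) || !all(gd == c(N, FF, OH, OW)))
    stop(sprintf("grad_out shape mismatch: expected %s, got %s",
                 paste(c(N, FF, OH, OW), collapse = "x"),
                 paste(gd, collapse = "x")))
  if (layer$mode == "depthwise")
    depthwise_bwd(input, layer$weights, grad_out)
  else
    conv_std_bwd(input, layer$weights, grad_out)
}

#' Fully connected layer parameters
#'
#' @param weights Numeric matrix `n_out x n_in`.
#' @param biases Numeric vector length `n_out`.
#' @return An `fc_layer` object.
#' @export
fc_layer <- function(weights, biases) {
  if (!is.matrix(weights)) stop("weights must be a matrix n_out x n_in")
  if (length(biases) != nrow(weights))
    stop(sprintf("expected %d biases, got %d", nrow(weights), length(biases)))
  check_finite(weights, "fc weights")
  check_finite(biases, "fc biases")
  structure(list(weights = weights, biases = as.numeric(biases)),
            class = "fc_layer")
}

#' Fully connected forward pass
#'
#' Affine map `x W' + b` applied to each row of the batch.
#'
#' @param layer An [fc_layer()].
#' @param input Numeric matrix `N x n_in`.
#' @return Numeric matrix `N x n_out`.
#' @export
fc_forward <- function(layer, input) {
  if (!is.matrix(input)) input <- matrix(input, nrow = 1)
  if (ncol(input) != ncol(layer$weights))
    stop(sprintf("fc input width mismatch: expected %d, got %d",
                 ncol(layer$weights), ncol(input)))
  sweep(tcrossprod(input, layer$weights), 2, layer$biases, "+")
}

#' Fully connected backward pass
#'
#' @param layer An [fc_layer()].
#' @param input The `N x n_in` matrix the forward pass saw.
#' @param grad_out Gradient w.r.t. the `N x n_out` output.
#' @return List with `grad_input`, `grad_weights`, `grad_biases`.
#' @export
fc_backward <- function(layer, input, grad_out) {
  if (!is.matrix(input)) input <- matrix(input, nrow = 1)
  if (!is.matrix(grad_out)) grad_out <- matrix(grad_out, nrow = nrow(input))
  if (!all(dim(grad_out) == c(nrow(input), nrow(layer$weights))))
    stop("grad_out shape mismatch in fc_backward")
  list(grad_input = grad_out %*% layer$weights,
       grad_weights = crossprod(grad_out, input),
       grad_biases = colSums(grad_out))
}

#' Batch normalization parameters
#'
#' One scale (`gamma`) and shift (`beta`) per feature, plus running first and
#' second moments used at evaluation time.  For convolutional features the
#' "feature" is the channel (statistics pool over batch and both spatial
#' dims); for fully connected features it is the unit.
#'
#' @param n_features Number of features (channels or units).
#' @param momentum Fraction of the batch statistic blended into the running
#'   statistic each training step, in (0,1); default 0.1.
#' @param epsilon Variance floor for numerical stability; default 1e-5.
#' @return A `batchnorm_layer` object with `gamma = 1`, `beta = 0`,
#'   `running_mean = 0`, `running_var = 1`.
#' @export
batchnorm_layer <- function(n_features, momentum = 0.1, epsilon = 1e-5) {
  stopifnot(n_features >= 1)
  if (momentum <= 0 || momentum >= 1) stop("momentum must be in (0,1)")
  check_scalar_pos(epsilon, "epsilon")
  structure(list(gamma = rep(1, n_features), beta = rep(0, n_features),
                 running_mean = rep(0, n_features),
                 running_var = rep(1, n_features),
                 momentum = momentum, epsilon = epsilon),
            class = "batchnorm_layer")
}

# collapse a conv (N,C,H,W) or fc (N,D) tensor to an m x n_features matrix
bn_as_matrix <- function(x) {
  d <- dim(x)
  if (length(d) == 4L)
    list(m = matrix(aperm(x, c(1, 3, 4, 2)), prod(d[c(1, 3, 4)]), d[2]),
         dim = d, conv = TRUE)
  else if (length(d) == 2L)
    list(m = x, dim = d, conv = FALSE)
  else stop("batchnorm input must be 2-d (N x D) or 4-d (N x C x H x W)")
}

bn_from_matrix <- function(m, info) {
  if (info$conv) {
    d <- info$dim
    aperm(array(m, dim = c(d[1], d[3], d[4], d[2])), c(1, 4, 2, 3))
  } else m
}

#' Batch normalization forward pass
#'
#' Training mode normalizes each feature by the batch mean and (biased) batch
#' variance, applies `gamma`/`beta`, and blends the batch statistics into the
#' running statistics (unbiased variance) with the configured momentum.
#' Evaluation mode is a fixed affine map using the running statistics.
#'
#' @param layer A [batchnorm_layer()].
#' @param input Conv (`N x C x H x W`) or fc (`N x D`) tensor.
#' @param mode `"train"` or `"eval"`.  Train mode requires batch size >= 2.
#' @return List with `output`, `batch_stats` (mean/var per feature, train
#'   mode), `cache` (for the backward pass) and `layer` (with updated running
#'   statistics in train mode).
#' @export
batchnorm_forward <- function(layer, input, mode = c("train", "eval")) {
  mode <- match.arg(mode)
  info <- bn_as_matrix(input)
  nf <- length(layer$gamma)
  if (ncol(info$m) != nf)
    stop(sprintf("batchnorm feature mismatch: expected %d, got %d", nf, ncol(info$m)))
  conv <- info$conv
  if (mode == "eval") {
    out <- if (conv)
      bn_conv_apply(input, layer$gamma, layer$beta, layer$running_mean,
                    layer$running_var, layer$epsilon)
    else {
      inv_std <- 1 / sqrt(layer$running_var + layer$epsilon)
      xhat <- sweep(sweep(info$m, 2, layer$running_mean), 2, inv_std, "*")
      sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
    }
    return(list(output = if (conv) out else bn_from_matrix(out, info),
                batch_stats = NULL, cache = NULL, layer = layer))
  }
  if (info$dim[1] < 2L)
    stop("batch normalization in train mode needs a batch of at least 2")
  m <- nrow(info$m)
  if (conv) {
    st <- bn_conv_stats(input)
    mu <- st$mean; v <- st$var
    out <- bn_conv_apply(input, layer$gamma, layer$beta, mu, v, layer$epsilon)
  } else {
    mu <- colMeans(info$m)
    xc <- sweep(info$m, 2, mu)
    v <- colMeans(xc^2)                    # biased, used for normalization
    xhat <- sweep(xc, 2, 1 / sqrt(v + layer$epsilon), "*")
    out <- bn_from_matrix(sweep(sweep(xhat, 2, layer$gamma, "*"), 2,
                                layer$beta, "+"), info)
  }
  mom <- layer$momentum
  layer$running_mean <- (1 - mom) * layer$running_mean + mom * mu
  layer$running_var <- (1 - mom) * layer$running_var + mom * v * m / max(m - 1, 1)
  list(output = out,
       batch_stats = list(mean = mu, var = v),
       cache = list(x = input, mean = mu, var = v, gamma = layer$gamma,
                    epsilon = layer$epsilon, conv = conv, info = info),
       layer = layer)
}

#' Batch normalization backward pass
#'
#' Exact gradients through the train-mode normalization (batch statistics are
#' themselves functions of the input, which the closed form accounts for).
#'
#' @param layer A [batchnorm_layer()].
#' @param cache The `cache` entry returned by train-mode [batchnorm_forward()].
#' @param grad_out Gradient w.r.t. the forward output (same shape as input).
#' @return List with `grad_input`, `grad_gamma`, `grad_beta`.
#' @export
batchnorm_backward <- function(layer, cache, grad_out) {
  if (is.null(cache)) stop("batchnorm_backward needs a train-mode cache")
  if (cache$conv)
    return(bn_conv_bwd(cache$x, cache$gamma, cache$mean, cache$var,
                       cache$epsilon, grad_out))
  G <- bn_as_matrix(grad_out)$m
  inv_std <- 1 / sqrt(cache$var + cache$epsilon)
  xhat <- sweep(sweep(cache$x, 2, cache$mean), 2, inv_std, "*")
  grad_gamma <- colSums(G * xhat)
  grad_beta <- colSums(G)
  Gx <- sweep(G, 2, cache$gamma, "*")
  t1 <- sweep(Gx, 2, colMeans(Gx))
  t2 <- sweep(xhat, 2, colMeans(Gx * xhat), "*")
  grad_in <- sweep(t1 - t2, 2, inv_std, "*")
  list(grad_input = bn_from_matrix(grad_in, cache$info),
       grad_gamma = grad_gamma, grad_beta = grad_beta)
}

#' Mean squared error loss
#'
#' `loss = mean((pred - target)^2)` with gradient `2 (pred - target) / N`,
#' the training criterion for the sigmoid-output classifier.
#'
#' @param pred Numeric vector of predictions in `[0, 1]`.
#' @param target Binary vector (0/1) of the same length.
#' @return List with scalar `loss` and vector `grad`.
#' @export
mse_loss <- function(pred, target) {
  if (length(pred) != length(target))
    stop(sprintf("length mismatch: %d predictions vs %d targets",
                 length(pred), length(target)))
  if (!all(target %in% c(0, 1))) stop("targets must be 0 or 1")
  d <- pred - target
  list(loss = mean(d^2), grad = 2 * d / length(d))
}
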
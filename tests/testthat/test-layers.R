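# Differentiable layers: forward against independent oracles, backward
# against central finite differences.

test_that("conv2d_forward matches the nested-loop oracle in both modes", {
  set.seed(7)
  # identity kernel
  ly <- conv_layer(array(1, c(1, 1, 1, 1)), 0, "depthwise")
  x <- array(1, c(1, 1, 3, 3))
  expect_equal(conv2d_forward(ly, x), x)
  # all-ones 2x2 kernel sums the entries
  ls <- conv_layer(array(1, c(1, 1, 2, 2)), 0, "standard")
  x2 <- array(c(1, 3, 2, 4), c(1, 1, 2, 2))   # [[1,2],[3,4]] row-major
  expect_equal(as.numeric(conv2d_forward(ls, x2)), 10)
  # random instances vs brute force
  for (i in 1:5) {
    x <- array(rnorm(2 * 3 * 8 * 8), c(2, 3, 8, 8))
    dw <- conv_layer(array(rnorm(3 * 25), c(3, 1, 5, 5)), rnorm(3), "depthwise")
    st <- conv_layer(array(rnorm(4 * 3 * 9), c(4, 3, 3, 3)), rnorm(4), "standard")
    expect_lt(max(abs(conv2d_forward(dw, x) - conv_loop_oracle(dw, x))), 1e-10)
    expect_lt(max(abs(conv2d_forward(st, x) - conv_loop_oracle(st, x))), 1e-10)
  }
})

test_that("depthwise convolution equals standard convolution with channel-masked weights", {
  set.seed(8)
  C <- 4; k <- 3
  w <- array(rnorm(C * k * k), c(C, 1, k, k))
  b <- rnorm(C)
  masked <- array(0, c(C, C, k, k))
  for (c in seq_len(C)) masked[c, c, , ] <- w[c, 1, , ]
  x <- array(rnorm(3 * C * 7 * 7), c(3, C, 7, 7))
  expect_lt(max(abs(conv2d_forward(conv_layer(w, b, "depthwise"), x) -
                      conv2d_forward(conv_layer(masked, b, "standard"), x))), 1e-12)
})

test_that("conv layers are linear in their input (zero bias)", {
  set.seed(9)
  x <- array(rnorm(2 * 3 * 6 * 6), c(2, 3, 6, 6))
  st <- conv_layer(array(rnorm(2 * 3 * 9), c(2, 3, 3, 3)), rep(0, 2), "standard")
  a <- rnorm(1)
  expect_lt(max(abs(conv2d_forward(st, a * x) - a * conv2d_forward(st, x))), 1e-10)
})

test_that("conv2d_backward matches finite differences on random instances", {
  set.seed(10)
  for (mode in c("standard", "depthwise")) {
    for (rep in 1:3) {
      C <- 3; FF <- if (mode == "depthwise") C else 2; k <- 3
      wd <- if (mode == "depthwise") c(C, 1, k, k) else c(FF, C, k, k)
      ly <- conv_layer(array(rnorm(prod(wd)), wd), rnorm(FF), mode)
      x <- array(rnorm(2 * C * 6 * 6), c(2, C, 6, 6))
      g <- array(rnorm(2 * FF * 4 * 4), c(2, FF, 4, 4))
      bw <- conv2d_backward(ly, x, g)
      # zero upstream gradient gives zero gradients
      z <- conv2d_backward(ly, x, g * 0)
      expect_equal(max(abs(z$grad_input)), 0)
      expect_equal(max(abs(z$grad_weights)), 0)
      loss_w <- function(w) sum(conv2d_forward(conv_layer(w, ly$biases, mode), x) * g)
      loss_x <- function(xx) sum(conv2d_forward(ly, xx) * g)
      for (i in sample(length(ly$weights), 6))
        expect_lt(rel_err(fd_grad(loss_w, ly$weights, i), bw$grad_weights[i]), 1e-4)
      for (i in sample(length(x), 6))
        expect_lt(rel_err(fd_grad(loss_x, x, i), bw$grad_input[i]), 1e-4)
      expect_equal(bw$grad_biases, apply(g, 2, sum))
    }
  }
})

test_that("fc layer is the affine map with exact gradients", {
  set.seed(11)
  # identity / hand-computed cases
  expect_equal(fc_forward(fc_layer(diag(3), rep(0, 3)), matrix(1:6, 2, byrow = TRUE)),
               matrix(1:6, 2, byrow = TRUE))
  expect_equal(as.numeric(fc_forward(fc_layer(matrix(c(1, 1), 1), 1),
                                     matrix(c(2, 3), 1))), 6)
  # random instance vs naive triple loop
  W <- matrix(rnorm(12), 3, 4); b <- rnorm(3); x <- matrix(rnorm(8), 2, 4)
  ref <- matrix(0, 2, 3)
  for (n in 1:2) for (o in 1:3) ref[n, o] <- sum(W[o, ] * x[n, ]) + b[o]
  expect_lt(max(abs(fc_forward(fc_layer(W, b), x) - ref)), 1e-12)
  # gradients vs finite differences
  ly <- fc_layer(W, b)
  g <- matrix(rnorm(6), 2, 3)
  bw <- fc_backward(ly, x, g)
  loss_w <- function(w) sum(fc_forward(fc_layer(w, b), x) * g)
  loss_x <- function(xx) sum(fc_forward(ly, xx) * g)
  for (i in sample(length(W), 6))
    expect_lt(rel_err(fd_grad(loss_w, W, i), bw$grad_weights[i]), 1e-4)
  for (i in seq_along(x))
    expect_lt(rel_err(fd_grad(loss_x, x, i), bw$grad_input[i]), 1e-4)
  expect_equal(bw$grad_biases, colSums(g))
})

test_that("batch normalization normalizes in train mode and is affine in eval mode", {
  set.seed(12)
  ly <- batchnorm_layer(3)
  # conv features: per-channel statistics over batch and space
  x <- array(rnorm(8 * 3 * 5 * 5, mean = 3, sd = 2), c(8, 3, 5, 5))
  r <- batchnorm_forward(ly, x, "train")
  for (c in 1:3) {
    v <- r$output[, c, , ]
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(stats::var(as.numeric(v)) * (length(v) - 1) / length(v) - 1), 1e-3)
  }
  # constant input maps to ~0
  rc <- batchnorm_forward(batchnorm_layer(2), array(5, c(4, 2, 3, 3)), "train")
  expect_lt(max(abs(rc$output)), 1e-6)
  # fc features
  xf <- matrix(rnorm(40, 1, 3), 8, 5)
  rf <- batchnorm_forward(batchnorm_layer(5), xf, "train")
  expect_lt(max(abs(colMeans(rf$output))), 1e-6)
  # batch of 1 in train mode is an error
  expect_error(batchnorm_forward(ly, array(1, c(1, 3, 2, 2)), "train"),
               "at least 2")
  # eval mode with fresh running stats (mean 0, var 1) is near-identity
  e <- batchnorm_forward(batchnorm_layer(3), x, "eval")
  expect_lt(max(abs(e$output - x)), 1e-4 * max(abs(x)))
})

test_that("batch normalization backward matches finite differences", {
  set.seed(13)
  for (conv in c(TRUE, FALSE)) {
    x <- if (conv) array(rnorm(4 * 2 * 3 * 3), c(4, 2, 3, 3)) else matrix(rnorm(12), 4, 3)
    nf <- if (conv) 2L else 3L
    ly <- batchnorm_layer(nf)
    ly$gamma <- rnorm(nf, 1, 0.2); ly$beta <- rnorm(nf, 0, 0.2)
    g <- if (conv) array(rnorm(length(x)), dim(x)) else matrix(rnorm(12), 4, 3)
    r <- batchnorm_forward(ly, x, "train")
    bw <- batchnorm_backward(ly, r$cache, g)
    loss_x <- function(xx) sum(batchnorm_forward(ly, xx, "train")$output * g)
    for (i in sample(length(x), 8))
      expect_lt(rel_err(fd_grad(loss_x, x, i), bw$grad_input[i], floor = 1e-4), 1e-4)
    loss_gamma <- function(gm) {
      l2 <- ly; l2$gamma <- gm
      sum(batchnorm_forward(l2, x, "train")$output * g)
    }
    for (i in seq_len(nf))
      expect_lt(rel_err(fd_grad(loss_gamma, ly$gamma, i), bw$grad_gamma[i]), 1e-4)
    expect_equal(bw$grad_beta,
                 if (conv) apply(g, 2, sum) else colSums(g))
    # zero upstream gradient
    z <- batchnorm_backward(ly, r$cache, g * 0)
    expect_equal(max(abs(z$grad_input)), 0)
  }
})

test_that("running statistics blend batch statistics with the configured momentum", {
  set.seed(14)
  ly <- batchnorm_layer(2, momentum = 0.1)
  x <- array(rnorm(6 * 2 * 4 * 4, 2, 3), c(6, 2, 4, 4))
  r <- batchnorm_forward(ly, x, "train")
  m <- 6 * 16
  expect_equal(r$layer$running_mean, 0.9 * 0 + 0.1 * r$batch_stats$mean)
  expect_equal(r$layer$running_var,
               0.9 * 1 + 0.1 * r$batch_stats$var * m / (m - 1))
})

test_that("mse loss and gradient follow the definition", {
  expect_equal(mse_loss(c(1, 0), c(1, 0))$loss, 0)
  expect_equal(mse_loss(c(1, 0), c(0, 1))$loss, 1)
  set.seed(15)
  p <- runif(6); y <- rep(c(0, 1), 3)
  l <- mse_loss(p, y)
  expect_equal(l$loss, mean((p - y)^2))
  for (i in seq_along(p))
    expect_lt(rel_err(fd_grad(function(pp) mse_loss(pp, y)$loss, p, i, h = 1e-7),
                      l$grad[i]), 1e-6)
  expect_error(mse_loss(c(0.5), c(1, 0)), "length")
  expect_error(mse_loss(c(0.5, 0.5), c(1, 2)), "0 or 1")
})
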
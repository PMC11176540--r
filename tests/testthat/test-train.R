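# Training recipe: SGD with decoupled weight decay, early stopping with
# best-epoch restoration, metrics and leave-one-out plumbing.

test_that("sgd_step applies the decayed update to weights only", {
  p <- list(fc1.weights = matrix(1, 1, 1), fc1.biases = 1)
  g <- list(fc1.weights = matrix(1, 1, 1), fc1.biases = 0)
  up <- sgd_step(p, g, lr = 0.1, weight_decay = 0)
  expect_equal(as.numeric(up$fc1.weights), 0.9)
  # pure decay: g = 0, wd = 1e-6, lr = 0.01
  up2 <- sgd_step(p, list(fc1.weights = matrix(0, 1, 1), fc1.biases = 0),
                  lr = 0.01, weight_decay = 1e-6)
  expect_equal(as.numeric(up2$fc1.weights), 1 - 1e-8)
  # biases and batch-norm parameters are never decayed
  p3 <- list(bn1.gamma = 2, fc1.biases = 3)
  up3 <- sgd_step(p3, list(bn1.gamma = 0, fc1.biases = 0), 0.01, 0.5)
  expect_equal(up3$bn1.gamma, 2)
  expect_equal(up3$fc1.biases, 3)
  expect_error(sgd_step(p, list(fc1.weights = matrix(NaN, 1, 1), fc1.biases = 0),
                        0.1, 0), "non-finite")
  expect_error(sgd_step(p, list(fc1.weights = matrix(1, 2, 1), fc1.biases = 0),
                        0.1, 0), "mismatch")
})

test_that("the decayed update equals gradient descent on the L2-penalized loss", {
  set.seed(50)
  net <- build_network(tiny_config(seed = 8, use_batchnorm = FALSE))
  x <- array(rnorm(3 * 2 * 8 * 8), c(3, 2, 8, 8))
  y <- c(1, 0, 0)
  wd <- 1e-3; lr <- 0.05
  r <- net_loss_and_grad(net, x, y)
  p0 <- net_params(net)
  stepped <- sgd_step(p0, r$grads, lr, wd)
  # oracle: gradient of loss + (wd/2) * ||w||^2 over the decayed subset
  for (nm in names(p0)) {
    pen_grad <- r$grads[[nm]] + if (endsWith(nm, ".weights")) wd * p0[[nm]] else 0
    manual <- p0[[nm]] - lr * pen_grad
    expect_lt(max(rel_err(manual, stepped[[nm]], floor = 1e-8)), 1e-8)
  }
  # spot-check the penalized-loss gradient itself against finite differences
  pen_loss <- function(pp) {
    w2 <- sum(vapply(names(pp), function(nm)
      if (endsWith(nm, ".weights")) sum(pp[[nm]]^2) else 0, 1))
    net_loss_at(net, pp, x, y) + wd / 2 * w2
  }
  for (nm in c("conv1.weights", "fc3.weights")) {
    i <- 3
    pp <- p0; pp[[nm]][i] <- pp[[nm]][i] + 1e-5
    pm <- p0; pm[[nm]][i] <- pm[[nm]][i] - 1e-5
    num <- (pen_loss(pp) - pen_loss(pm)) / 2e-5
    expect_lt(rel_err(num, r$grads[[nm]][i] + wd * p0[[nm]][i]), 1e-4)
  }
})

make_segments <- function(seed = 1, n_per_class = 3, duration_s = 8) {
  recs <- tiny_cohort(seed = seed, n_per_class = n_per_class,
                      duration_s = duration_s)
  unlist(lapply(recs, segment_recording), recursive = FALSE)
}

test_that("zero learning rate leaves parameters unchanged with a flat curve", {
  segs <- make_segments(seed = 2)
  cfg <- network_config(n_channels = 2L, conv2_filters = 4L,
                        fc_sizes = c(16L, 4L, 1L), use_batchnorm = FALSE,
                        seed = 4)
  net <- build_network(cfg)
  res <- train_network(net, segs, train_config(learning_rate = 0,
                                               batch_size = 4L, max_epochs = 5L,
                                               patience = 5L, shuffle_seed = 3))
  expect_identical(net_params(res$net), net_params(net))
  expect_equal(length(unique(res$learning_curve$train_loss)), 1L)
  expect_equal(length(unique(res$learning_curve$val_loss)), 1L)
})

test_that("early stopping halts after `patience` epochs without improvement and restores the best epoch", {
  segs <- make_segments(seed = 3)
  # batchnorm off so zero-lr validation loss is exactly constant: it then
  # never improves after epoch 1 and the stop epoch is fully determined
  cfg <- network_config(n_channels = 2L, conv2_filters = 4L,
                        fc_sizes = c(16L, 4L, 1L), use_batchnorm = FALSE,
                        seed = 5)
  for (pat in c(1L, 3L)) {
    res <- train_network(build_network(cfg),
                         segs, train_config(learning_rate = 0, batch_size = 4L,
                                            max_epochs = 40L, patience = pat,
                                            shuffle_seed = 1))
    expect_equal(nrow(res$learning_curve), 1L + pat)
    expect_equal(res$best_epoch, 1L)
  }
  # restored parameters reproduce the recorded best validation loss
  res <- train_network(build_network(cfg), segs,
                       tiny_train_cfg(seed = 2, learning_rate = 0.02))
  n <- length(segs)
  ord <- tanhrelunet:::with_seed(2, sample.int(n))
  val_idx <- ord[seq_len(max(1L, round(0.15 * n)))]
  vb <- segments_to_batch(segs[val_idx])
  vl <- mse_loss(net_forward(res$net, vb$x, "eval"), vb$y)$loss
  expect_equal(vl, res$learning_curve$val_loss[res$best_epoch], tolerance = 1e-12)
  expect_lte(nrow(res$learning_curve), 3L)
})

test_that("training is bit-reproducible under identical seeds", {
  segs <- make_segments(seed = 4)
  cfg <- tiny_net_cfg(seed = 6)
  r1 <- train_network(build_network(cfg), segs, tiny_train_cfg(seed = 7))
  r2 <- train_network(build_network(cfg), segs, tiny_train_cfg(seed = 7))
  expect_identical(r1$learning_curve, r2$learning_curve)
  expect_identical(net_params(r1$net), net_params(r2$net))
})

test_that("single-class training data is rejected", {
  recs <- generate_dataset(synth_config(n_subjects_per_class = 4,
                                        duration_s = 20, n_channels = 2, seed = 5))
  segs <- unlist(lapply(recs[1:4], segment_recording), recursive = FALSE)  # class 0 only
  expect_error(train_network(build_network(tiny_net_cfg()), segs,
                             tiny_train_cfg()), "single class")
})

test_that("evaluate_network tallies the confusion matrix with ties positive", {
  segs <- make_segments(seed = 6)
  net <- build_network(tiny_net_cfg(seed = 2))
  y <- vapply(segs, function(b) b$label, 1L)
  # threshold 0: everything predicted positive
  cm0 <- evaluate_network(net, segs, threshold = 1e-12)
  expect_equal(cm0$fn + cm0$tn, 0L)
  expect_equal(cm0$tp, sum(y == 1))
  # constant 0.5 output with threshold 0.5 counts as positive (>= rule)
  p <- net_params(net)
  p$fc3.weights[] <- 0; p$fc3.biases[] <- 0
  cm5 <- evaluate_network(set_net_params(net, p), segs, threshold = 0.5)
  expect_equal(cm5$tp + cm5$fp, length(segs))
  # conservation
  cm <- evaluate_network(net, segs, 0.5)
  expect_equal(cm$tp + cm$fp + cm$tn + cm$fn, length(segs))
})

test_that("metrics follow their definitions and flag undefined ratios", {
  m <- classification_metrics(confusion_matrix(tp = 98, fn = 2, tn = 97, fp = 3))
  expect_equal(m$sensitivity, 0.98)
  expect_equal(m$specificity, 0.97)
  expect_equal(m$accuracy, 0.975)
  perfect <- classification_metrics(confusion_matrix(tp = 10, tn = 10))
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1, specificity = 1))
  und <- classification_metrics(confusion_matrix(tn = 5, fp = 1))
  expect_true(is.nan(und$sensitivity))
  expect_false(is.nan(und$specificity))
  # accuracy is the prevalence-weighted mix of sensitivity and specificity
  cm <- confusion_matrix(tp = 7, fn = 3, tn = 4, fp = 6)
  m2 <- classification_metrics(cm)
  P <- cm$tp + cm$fn; N <- cm$tn + cm$fp
  expect_equal(m2$accuracy, (P * m2$sensitivity + N * m2$specificity) / (P + N))
})

test_that("leave-one-out produces one fold per unit with pooled conservation", {
  recs <- tiny_cohort(seed = 8, n_per_class = 3, duration_s = 8)
  res <- loo_validate(recs, tiny_net_cfg(seed = 1),
                      tiny_train_cfg(seed = 1), unit = "subject")
  expect_length(res$folds, 6)
  expect_false(any(vapply(res$folds, function(f) isTRUE(f$skipped), TRUE)))
  total_held <- sum(vapply(res$folds, function(f)
    f$confusion$tp + f$confusion$fp + f$confusion$tn + f$confusion$fn, 1L))
  n_segs <- sum(vapply(recs, function(r) ncol(r$signal) %/% 1024L, 1L))
  expect_equal(total_held, n_segs)
  pc <- res$pooled_confusion
  expect_equal(pc$tp + pc$fp + pc$tn + pc$fn, n_segs)
  # metric bounds
  pm <- res$pooled_metrics
  expect_true(all(unlist(pm) >= 0 & unlist(pm) <= 1, na.rm = TRUE))
  expect_error(loo_validate(recs[1:2], tiny_net_cfg(), tiny_train_cfg()),
               "at least 3")
})

test_that("the ablation activations run through the identical pipeline", {
  segs <- make_segments(seed = 9)
  curves <- lapply(c("tanhrelu", "tanh", "relu"), function(kind) {
    cfg <- network_config(n_channels = 2L, conv2_filters = 4L,
                          fc_sizes = c(16L, 4L, 1L),
                          activation = activation_spec(kind), seed = 3)
    train_network(build_network(cfg), segs,
                  tiny_train_cfg(seed = 4))$learning_curve
  })
  for (cv in curves) expect_true(all(is.finite(cv$train_loss)))
  # same seed, different activation: genuinely different training dynamics
  expect_false(identical(curves[[1]]$train_loss, curves[[2]]$train_loss))
})

test_that("learning_curve_report writes well-formed CSVs and flags divergence", {
  segs <- make_segments(seed = 10)
  res <- train_network(build_network(tiny_net_cfg(seed = 2)), segs,
                       tiny_train_cfg(seed = 5))
  dir <- file.path(tempdir(), "curves")
  rep <- learning_curve_report(res$learning_curve, dir)
  expect_true(file.exists(rep$csv[1]))
  cv <- utils::read.csv(rep$csv[1])
  expect_identical(names(cv), c("epoch", "train_loss", "val_loss",
                                "train_acc", "val_acc"))
  expect_equal(nrow(cv), nrow(res$learning_curve))
  # flat curves (zero lr) must not be flagged as diverging
  flat <- train_network(build_network(tiny_net_cfg(seed = 2)), segs,
                        train_config(learning_rate = 0, batch_size = 4L,
                                     max_epochs = 4L, patience = 4L,
                                     shuffle_seed = 5))
  rep_flat <- learning_curve_report(flat$learning_curve, dir)
  expect_false(rep_flat$diverging[1])
  # a fabricated monotone-growing gap is flagged
  div <- data.frame(epoch = 1:6, train_loss = rep(0.2, 6),
                    val_loss = 0.2 + (1:6) * 0.05,
                    train_acc = rep(0.8, 6), val_acc = rep(0.7, 6))
  expect_true(learning_curve_report(div, dir, patience = 5)$diverging[1])
})
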
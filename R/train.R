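# Training recipe: stochastic gradient descent with decoupled weight decay
# on weight tensors only, mean squared error on the sigmoid output, early
# stopping on validation loss with best-epoch restoration.

#' Training configuration
#'
#' Defaults are the reference recipe: learning rate 0.01, weight decay
#' 1e-6, batch size 15, at most 40 epochs, early-stopping patience 10.
#'
#' @param learning_rate SGD step size; default 0.01.
#' @param weight_decay L2 decay applied to weight tensors (never biases or
#'   batch-norm parameters); default 1e-6.
#' @param batch_size Mini-batch size; default 15.
#' @param max_epochs Epoch cap; default 40.
#' @param patience Consecutive epochs without validation-loss improvement
#'   before stopping; default 10.  Must not exceed `max_epochs`.
#' @param shuffle_seed Seed for the one-time shuffle and split.
#' @param val_fraction Fraction of the provided segments held out for
#'   validation; default 0.15.
#' @param threshold Probability cut-off for predicting the positive (MDD)
#'   class; ties count as positive.  Default 0.5.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 0.01, weight_decay = 1e-6,
                         batch_size = 15L, max_epochs = 40L, patience = 10L,
                         shuffle_seed = 1L, val_fraction = 0.15,
                         threshold = 0.5) {
  if (learning_rate < 0) stop("learning_rate must be non-negative")
  if (weight_decay < 0) stop("weight_decay must be non-negative")
  cfg <- list(learning_rate = learning_rate, weight_decay = weight_decay,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              shuffle_seed = as.integer(shuffle_seed),
              val_fraction = val_fraction, threshold = threshold)
  if (cfg$batch_size < 2L) stop("batch_size must be at least 2")
  if (cfg$max_epochs < 1L) stop("max_epochs must be positive")
  if (cfg$patience < 1L || cfg$patience > cfg$max_epochs)
    stop("patience must be in [1, max_epochs]")
  if (cfg$val_fraction <= 0 || cfg$val_fraction >= 1)
    stop("val_fraction must be in (0,1)")
  if (cfg$threshold <= 0 || cfg$threshold >= 1)
    stop("threshold must be in (0,1)")
  structure(cfg, class = "train_config")
}

#' One SGD update with decoupled weight decay
#'
#' `w <- w - lr * (g + weight_decay * w)` for every parameter tensor whose
#' name ends in `".weights"`; biases and batch-norm gamma/beta are updated
#' without the decay term.  Equivalent to plain gradient descent on the loss
#' plus `(weight_decay / 2) * ||w||^2` over the decayed subset.
#'
#' @param params Named parameter list ([net_params()] layout).
#' @param grads Matching named gradient list.
#' @param lr Learning rate.
#' @param weight_decay Decay coefficient.
#' @return Updated parameter list.
#' @export
sgd_step <- function(params, grads, lr, weight_decay = 0) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) stop(sprintf("missing gradient for '%s'", nm))
    if (!all((dim(g) %||% length(g)) == (dim(params[[nm]]) %||% length(params[[nm]]))))
      stop(sprintf("gradient shape mismatch for '%s'", nm))
    wd <- if (endsWith(nm, ".weights")) weight_decay else 0
    params[[nm]] <- tryCatch(sgd_update(params[[nm]], g, lr, wd),
                             error = function(e)
                               stop(sprintf("non-finite gradient in '%s'", nm)))
  }
  params
}

#' Train a network on labeled segments
#'
#' The segment list is shuffled once (seeded), split into validation
#' (`val_fraction`) and training parts, and iterated in mini-batches of
#' `batch_size` (a trailing short batch is kept if it has at least 2
#' examples, else dropped — batch normalization needs 2).  After each epoch
#' the validation loss is computed in eval mode; training stops when it has
#' not improved for `patience` consecutive epochs or at `max_epochs`, and
#' the returned network carries the parameters (and batch-norm state) of the
#' best validation epoch.
#'
#' @param net A freshly built (or warm) network.
#' @param segments List of `segment_block`s containing both classes.
#' @param cfg A [train_config()].
#' @return List with `net` (best-epoch network), `learning_curve` (data
#'   frame: epoch, train_loss, val_loss, train_acc, val_acc) and
#'   `best_epoch`.
#' @export
train_network <- function(net, segments, cfg) {
  stopifnot(inherits(cfg, "train_config"), inherits(net, "tanhrelu_net"))
  n <- length(segments)
  labels <- vapply(segments, function(b) as.numeric(b$label), numeric(1))
  ord <- with_seed(cfg$shuffle_seed, sample.int(n))
  n_val <- max(1L, round(cfg$val_fraction * n))
  if (n - n_val < 2L * cfg$batch_size)
    stop("too few segments: need at least 2 training batches after the validation split")
  val_idx <- ord[seq_len(n_val)]
  tr_idx <- ord[-seq_len(n_val)]
  if (length(unique(labels[tr_idx])) < 2L)
    stop("training split contains a single class; cannot fit a classifier")
  tr <- segments_to_batch(segments[tr_idx])
  va <- segments_to_batch(segments[val_idx])

  starts <- seq(1L, length(tr_idx), by = cfg$batch_size)
  batches <- lapply(starts, function(s) s:min(s + cfg$batch_size - 1L, length(tr_idx)))
  short <- lengths(batches) < 2L
  if (any(short)) {
    message(sprintf("dropping %d trailing batch(es) of size 1 (batch normalization needs 2)",
                    sum(short)))
    batches <- batches[!short]
  }

  curve <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric(), train_acc = numeric(),
                      val_acc = numeric())
  best <- list(val = Inf, epoch = 0L, params = NULL, state = NULL)
  stall <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    tl <- 0; tc <- 0; tn_seen <- 0
    for (b in batches) {
      xb <- tr$x[b, , , , drop = FALSE]
      yb <- tr$y[b]
      fwd <- net_forward_cached(net, xb, "train", validate = FALSE)
      net <- fwd$net
      l <- mse_loss(fwd$prob, yb)
      grads <- net_backward(net, fwd$cache, l$grad)
      net <- set_net_params(net, sgd_step(net_params(net), grads,
                                          cfg$learning_rate, cfg$weight_decay))
      tl <- tl + l$loss * length(b)
      tc <- tc + sum((fwd$prob >= cfg$threshold) == (yb == 1))
      tn_seen <- tn_seen + length(b)
    }
    vp <- net_forward(net, va$x, "eval")
    vl <- mse_loss(vp, va$y)$loss
    curve[epoch, ] <- list(epoch, tl / tn_seen, vl, tc / tn_seen,
                           mean((vp >= cfg$threshold) == (va$y == 1)))
    if (vl < best$val) {
      best <- list(val = vl, epoch = epoch, params = net_params(net),
                   state = net_state(net))
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  }
  net <- set_net_params(net, best$params)
  net <- set_net_state(net, best$state)
  list(net = net, learning_curve = curve, best_epoch = best$epoch)
}

#' Confusion matrix of a network on segments
#'
#' Eval-mode forward; prediction is positive (MDD) iff the probability is at
#' least `threshold`.
#'
#' @param net A trained network.
#' @param segments List of labeled `segment_block`s.
#' @param threshold Decision threshold; default 0.5.
#' @return A `confusion_matrix` object (fields `tp`, `fp`, `tn`, `fn`).
#' @export
evaluate_network <- function(net, segments, threshold = 0.5) {
  b <- segments_to_batch(segments)
  p <- net_forward(net, b$x, "eval")
  pred <- as.integer(p >= threshold)
  confusion_matrix(tp = sum(pred == 1 & b$y == 1),
                   fp = sum(pred == 1 & b$y == 0),
                   tn = sum(pred == 0 & b$y == 0),
                   fn = sum(pred == 0 & b$y == 1))
}

#' Construct a confusion matrix
#'
#' @param tp,fp,tn,fn Non-negative counts; positive class is MDD (label 1).
#' @return A `confusion_matrix` object.
#' @export
confusion_matrix <- function(tp = 0L, fp = 0L, tn = 0L, fn = 0L) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || any(v != round(v))) stop("counts must be non-negative integers")
  structure(as.list(stats::setNames(as.integer(v), names(v))),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion: tp=%d fp=%d tn=%d fn=%d>\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

add_confusion <- function(a, b)
  confusion_matrix(a$tp + b$tp, a$fp + b$fp, a$tn + b$tn, a$fn + b$fn)

#' Accuracy, sensitivity and specificity
#'
#' `accuracy = (tp+tn)/total`, `sensitivity = tp/(tp+fn)` (true-positive
#' rate, MDD positive), `specificity = tn/(tn+fp)`.  A metric whose
#' denominator is zero is returned as `NaN` (flagged undefined), never an
#' error.
#'
#' @param cm A [confusion_matrix()].
#' @return List with `accuracy`, `sensitivity`, `specificity`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  safe <- function(num, den) if (den > 0) num / den else NaN
  list(accuracy = safe(cm$tp + cm$tn, total),
       sensitivity = safe(cm$tp, cm$tp + cm$fn),
       specificity = safe(cm$tn, cm$tn + cm$fp))
}

#' Leave-one-out validation
#'
#' For each held-out unit (a subject's recording, or a single segment) the
#' remaining segments are shuffled and split per `train_cfg$val_fraction`, a
#' fresh network is built with a fold-derived seed and trained, and the
#' held-out segments are scored.  Pooled metrics come from the summed
#' confusion matrices.  A fold whose training split is single-class is
#' skipped with a warning and recorded.
#'
#' Per-fold seeds derive deterministically from `train_cfg$shuffle_seed` and
#' the fold index, so folds are independent but the whole run reproduces
#' bit-for-bit.
#'
#' @param recordings List of labeled [eeg_recording()]s (both classes, at
#'   least 3 units).
#' @param net_cfg A [network_config()].
#' @param train_cfg A [train_config()].
#' @param unit `"subject"` (default; no window of a held-out subject is seen
#'   in training) or `"segment"`.
#' @param window Segment length in samples; default 1024.
#' @return List with `folds` (per-fold: held_out_unit, confusion, metrics,
#'   learning_curve, best_epoch, skipped), `pooled_confusion`,
#'   `pooled_metrics`, `unit`.
#' @export
loo_validate <- function(recordings, net_cfg, train_cfg,
                         unit = c("subject", "segment"), window = 1024L) {
  unit <- match.arg(unit)
  stopifnot(inherits(net_cfg, "network_config"), inherits(train_cfg, "train_config"))
  segs <- unlist(lapply(recordings, segment_recording, window = window),
                 recursive = FALSE)
  units <- if (unit == "subject")
    vapply(segs, function(b) b$subject_id, "") else as.character(seq_along(segs))
  uniq <- unique(units)
  if (length(uniq) < 3L) stop("leave-one-out needs at least 3 units")
  seg_labels <- vapply(segs, function(b) b$label, integer(1))
  if (length(unique(seg_labels)) < 2L) stop("both classes must be present")
  folds <- list()
  pooled <- confusion_matrix()
  for (i in seq_along(uniq)) {
    held <- units == uniq[i]
    rest <- segs[!held]
    fold_net_cfg <- net_cfg
    fold_net_cfg$seed <- as.integer(derive_seed(net_cfg$seed, i))
    fold_train_cfg <- train_cfg
    fold_train_cfg$shuffle_seed <- as.integer(derive_seed(train_cfg$shuffle_seed, 100000 + i))
    res <- tryCatch(
      train_network(build_network(fold_net_cfg), rest, fold_train_cfg),
      error = function(e) {
        if (grepl("single class", conditionMessage(e))) {
          warning(sprintf("fold %d (%s) skipped: %s", i, uniq[i],
                          conditionMessage(e)))
          NULL
        } else stop(e)
      })
    if (is.null(res)) {
      folds[[i]] <- list(held_out_unit = uniq[i], skipped = TRUE)
      next
    }
    cm <- evaluate_network(res$net, segs[held], fold_train_cfg$threshold)
    pooled <- add_confusion(pooled, cm)
    folds[[i]] <- list(held_out_unit = uniq[i], confusion = cm,
                       metrics = classification_metrics(cm),
                       learning_curve = res$learning_curve,
                       best_epoch = res$best_epoch, skipped = FALSE)
  }
  list(folds = folds, pooled_confusion = pooled,
       pooled_metrics = classification_metrics(pooled), unit = unit)
}

#' Write learning-curve reports
#'
#' One CSV (columns exactly `epoch, train_loss, val_loss, train_acc,
#' val_acc`) and one PNG per fold, plus a divergence flag per fold: `TRUE`
#' when the validation-minus-training loss gap grew strictly monotonically
#' over the final `patience` epochs — the telltale of overfitting that a
#' healthy run should not show.
#'
#' @param curves A single learning-curve data frame, a list of them, or a
#'   [loo_validate()] result.
#' @param dir Output directory (created if needed).
#' @param patience Window for the divergence flag; default 10.
#' @return Data frame with `fold`, `csv`, `png`, `epochs`, `diverging`.
#' @export
learning_curve_report <- function(curves, dir, patience = 10L) {
  if (is.data.frame(curves)) curves <- list(curves)
  if (!is.null(curves$folds))
    curves <- lapply(Filter(function(f) !isTRUE(f$skipped), curves$folds),
                     `[[`, "learning_curve")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    stopifnot(identical(names(cv), c("epoch", "train_loss", "val_loss",
                                     "train_acc", "val_acc")))
    csv <- file.path(dir, sprintf("fold%02d_curve.csv", i))
    png_path <- file.path(dir, sprintf("fold%02d_curve.png", i))
    utils::write.csv(cv, csv, row.names = FALSE)
    grDevices::png(png_path, width = 640, height = 480)
    graphics::matplot(cv$epoch, cbind(cv$train_loss, cv$val_loss), type = "l",
                      lty = 1, col = c("steelblue", "firebrick"),
                      xlab = "epoch", ylab = "MSE loss",
                      main = sprintf("Learning curve (fold %d)", i))
    graphics::legend("topright", c("train", "validation"), lty = 1,
                     col = c("steelblue", "firebrick"), bty = "n")
    grDevices::dev.off()
    gap <- cv$val_loss - cv$train_loss
    tail_gap <- gap[max(1L, length(gap) - patience + 1L):length(gap)]
    data.frame(fold = i, csv = csv, png = png_path, epochs = nrow(cv),
               diverging = length(tail_gap) >= 2 && all(diff(tail_gap) > 0))
  })
  do.call(rbind, rows)
}
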
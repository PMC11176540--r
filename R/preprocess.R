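# Windowing of continuous multichannel EEG into channel-stacked square
# tensors.  One training example is a C x 32 x 32 block: a 1024-sample
# (4 s at 256 Hz) window, reshaped row-major to 32 x 32 per channel and
# stacked in channel order.

#' EEG recording container
#'
#' @param signal Numeric matrix, channels x samples (microvolts).
#' @param sampling_rate Sampling rate in Hz (nominal 256).
#' @param label Binary class label: 1 = MDD (positive), 0 = healthy control.
#' @param subject_id Subject identifier string.
#' @param channel_names Optional character vector of montage labels (10-20
#'   system); defaults to `"ch1"`, `"ch2"`, ...
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(signal, sampling_rate = 256, label,
                          subject_id = "s1", channel_names = NULL) {
  if (!is.matrix(signal) || nrow(signal) < 1L || ncol(signal) < 1L)
    stop("signal must be a channels x samples matrix")
  check_finite(signal, "signal")
  check_scalar_pos(sampling_rate, "sampling_rate")
  if (!label %in% c(0, 1)) stop("label must be 0 (control) or 1 (MDD)")
  channel_names <- channel_names %||% paste0("ch", seq_len(nrow(signal)))
  if (length(channel_names) != nrow(signal))
    stop("channel_names length must match the number of channels")
  structure(list(signal = signal, sampling_rate = sampling_rate,
                 label = as.integer(label), subject_id = as.character(subject_id),
                 channel_names = as.character(channel_names)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording %s: %d ch x %d samples @ %g Hz, label %d>\n",
              x$subject_id, nrow(x$signal), ncol(x$signal), x$sampling_rate,
              x$label))
  invisible(x)
}

#' Reshape a window into a square matrix
#'
#' Row-major fill: `m[r, c] = v[(r-1)*s + c]` with `s = sqrt(length(v))`.
#' The inverse is [flatten_square()]; the pair is a bijection, so no sample
#' is lost or duplicated.
#'
#' @param v Numeric vector whose length is a perfect square.
#' @return An `s x s` numeric matrix.
#' @export
reshape_square <- function(v) {
  s <- sqrt(length(v))
  if (s != round(s))
    stop(sprintf("window length %d is not a perfect square", length(v)))
  matrix(v, nrow = s, byrow = TRUE)
}

#' Flatten a square matrix back to a window
#'
#' @param m Square numeric matrix.
#' @return Numeric vector; `flatten_square(reshape_square(v))` equals `v`.
#' @export
flatten_square <- function(m) as.numeric(t(m))

#' Cut a recording into fixed non-overlapping windows
#'
#' Consecutive windows of `window` samples starting at sample 1; a trailing
#' remainder shorter than `window` is dropped, so a recording of `T` samples
#' yields `floor(T / window)` segments.  Each window is reshaped per channel
#' by [reshape_square()] and stacked along channels into a
#' `C x sqrt(window) x sqrt(window)` tensor; label and subject id propagate.
#'
#' @param rec An [eeg_recording()].
#' @param window Window length in samples; must be a perfect square.
#'   Default 1024 (4 s at 256 Hz).
#' @return List of `segment_block` objects (possibly empty), each with
#'   fields `tensor`, `label`, `subject_id`, `window_index` (0-based).
#' @export
segment_recording <- function(rec, window = 1024L) {
  stopifnot(inherits(rec, "eeg_recording"))
  s <- sqrt(window)
  if (s != round(s))
    stop(sprintf("window %d is not a perfect square", window))
  s <- as.integer(s)
  n_seg <- ncol(rec$signal) %/% window
  if (n_seg == 0L) return(list())
  C <- nrow(rec$signal)
  lapply(seq_len(n_seg) - 1L, function(w) {
    block <- array(0, dim = c(C, s, s))
    cols <- (w * window + 1L):((w + 1L) * window)
    for (ch in seq_len(C))
      block[ch, , ] <- reshape_square(rec$signal[ch, cols])
    structure(list(tensor = block, label = rec$label,
                   subject_id = rec$subject_id, window_index = w),
              class = "segment_block")
  })
}

#' Normalize one segment
#'
#' `"none"` (the default everywhere in the pipeline) is the identity:
#' windows are fed to the network as raw amplitudes.  `"zscore_per_channel"`
#' centres and scales each channel plane to mean 0, sd 1; a constant channel
#' (sd 0) becomes all zeros.
#'
#' @param block A `segment_block`.
#' @param mode `"none"` or `"zscore_per_channel"`.
#' @return The (possibly) normalized `segment_block`.
#' @export
normalize_segment <- function(block, mode = c("none", "zscore_per_channel")) {
  mode <- match.arg(mode)
  if (mode == "none") return(block)
  for (ch in seq_len(dim(block$tensor)[1])) {
    p <- block$tensor[ch, , ]
    s <- sd(p)
    block$tensor[ch, , ] <- if (s > 0) (p - mean(p)) / s else p * 0
  }
  block
}

#' Stack segment blocks into a batch tensor
#'
#' @param blocks List of `segment_block`s with identical channel counts.
#' @return List with `x` (array `N x C x s x s`) and `y` (numeric 0/1 labels).
#' @export
segments_to_batch <- function(blocks) {
  if (!length(blocks)) stop("no segments to stack")
  d <- dim(blocks[[1]]$tensor)
  x <- array(0, dim = c(length(blocks), d))
  for (i in seq_along(blocks)) x[i, , , ] <- blocks[[i]]$tensor
  list(x = x, y = vapply(blocks, function(b) as.numeric(b$label), numeric(1)))
}

#' Read a dataset manifest
#'
#' A manifest is a delimited text file (comma or tab) with columns
#' `subject_id`, `path`, `label` mapping signal files to classes.  Relative
#' paths are resolved against the manifest's directory.
#'
#' @param path Manifest file path.
#' @return Data frame with the three columns, paths resolved.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: '%s'", path))
  sep <- if (grepl("\t", readLines(path, n = 1L))) "\t" else ","
  m <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(m)))
    stop(sprintf("manifest must have columns %s", paste(need, collapse = ", ")))
  if (!all(m$label %in% c(0, 1))) stop("manifest labels must be 0 or 1")
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}

#' Load every recording named in a manifest
#'
#' @param path Manifest file path (see [read_manifest()]).
#' @return List of [eeg_recording()]s.
#' @export
load_manifest <- function(path) {
  m <- read_manifest(path)
  lapply(seq_len(nrow(m)), function(i)
    read_edf(m$path[i], label = m$label[i], subject_id = m$subject_id[i]))
}
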
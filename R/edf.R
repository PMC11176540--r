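# Minimal EDF/EDF+ codec (16-bit sample encoding).  No EDF reader exists in
# this package's dependency set, so the container is read and written
# directly: 256-byte fixed ASCII header, 256 bytes of ASCII header per
# signal, then data records of little-endian 16-bit integers scaled between
# the digital and physical ranges declared in the header.

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1L, width)
}

#' Write a recording to an EDF file
#'
#' One data record per second (so the sampling rate must be a whole number
#' per second and the duration a whole number of seconds; a trailing partial
#' second is dropped).  Each channel's physical range is set symmetrically to
#' its absolute maximum, so the 16-bit quantization error is at most
#' `max(abs(signal)) / 2^15` per channel.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path; the directory must exist.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!dir.exists(dirname(path)))
    stop(sprintf("cannot write EDF: directory '%s' does not exist", dirname(path)))
  fs <- rec$sampling_rate
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  ns <- nrow(rec$signal)
  n_rec <- ncol(rec$signal) %/% fs
  if (n_rec < 1L) stop("recording shorter than one data record (1 s)")
  pmax_ch <- pmax(apply(abs(rec$signal), 1, max), 1e-6)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field(rec$subject_id, 80),
    edf_field(sprintf("label %d", rec$label), 80),
    edf_field("01.01.00", 8), edf_field("00.00.00", 8),
    edf_field(256 * (1 + ns), 8),
    edf_field("", 44),
    edf_field(n_rec, 8),
    edf_field(1, 8),
    edf_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  per <- function(vals, width)
    writeChar(paste0(vapply(vals, edf_field, "", width = width), collapse = ""),
              con, eos = NULL)
  per(rec$channel_names, 16)
  per(rep("", ns), 80)                                   # transducer
  per(rep("uV", ns), 8)                                  # physical dimension
  per(sprintf("%.6g", -pmax_ch), 8)
  per(sprintf("%.6g", pmax_ch), 8)
  per(rep(-32768L, ns), 8)
  per(rep(32767L, ns), 8)
  per(rep("", ns), 80)                                   # prefiltering
  per(rep(as.integer(fs), ns), 8)
  per(rep("", ns), 32)                                   # reserved
  scale <- 65535 / (2 * pmax_ch)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((rec$signal[ch, cols] + pmax_ch[ch]) * scale[ch]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF/EDF+ file
#'
#' Returns all channels scaled to their physical units.  If channels were
#' recorded at different rates, every channel is resampled to the modal rate
#' by linear interpolation, with a warning.
#'
#' @param path EDF file path.
#' @param label Binary class label to attach (EDF itself carries none);
#'   default 0.
#' @param subject_id Subject id; defaults to the EDF patient field (or the
#'   file name if that is blank).
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, label = 0L, subject_id = NULL) {
  if (!file.exists(path)) stop(sprintf("EDF file not found: '%s'", path))
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readChar(con, 256, useBytes = TRUE)
  if (nchar(fixed, type = "bytes") < 256)
    stop(sprintf("'%s' is not a valid EDF file (truncated header)", path))
  fld <- function(from, width) trimws(substr(fixed, from, from + width - 1L))
  patient <- fld(9, 80)
  n_rec <- as.integer(fld(237, 8))
  rec_dur <- as.numeric(fld(245, 8))
  ns <- as.integer(fld(253, 4))
  if (is.na(ns) || ns < 1L)
    stop(sprintf("'%s' declares no signals", path))
  sig_hdr <- readChar(con, 256 * ns, useBytes = TRUE)
  if (nchar(sig_hdr, type = "bytes") < 256 * ns)
    stop(sprintf("'%s' is not a valid EDF file (truncated signal header)", path))
  take <- function(offset, width) {
    start <- offset * ns
    vapply(seq_len(ns), function(i)
      trimws(substr(sig_hdr, start + (i - 1L) * width + 1L, start + i * width)),
      "")
  }
  labels <- take(0, 16)
  pmin_ <- as.numeric(take(16 + 80 + 8, 8))
  pmax_ <- as.numeric(take(16 + 80 + 8 + 8, 8))
  dmin_ <- as.numeric(take(16 + 80 + 8 + 16, 8))
  dmax_ <- as.numeric(take(16 + 80 + 8 + 24, 8))
  spr <- as.integer(take(16 + 80 + 8 + 32 + 80, 8))
  if (any(is.na(c(pmin_, pmax_, dmin_, dmax_, spr))))
    stop(sprintf("'%s' has an unparseable signal header", path))
  raw_sig <- lapply(seq_len(ns), function(i) numeric(0))
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      v <- readBin(con, "integer", spr[ch], size = 2, signed = TRUE,
                   endian = "little")
      if (length(v) < spr[ch])
        stop(sprintf("'%s' is truncated in data record %d", path, r))
      raw_sig[[ch]] <- c(raw_sig[[ch]], v)
    }
  }
  phys <- lapply(seq_len(ns), function(ch)
    (raw_sig[[ch]] - dmin_[ch]) * (pmax_[ch] - pmin_[ch]) /
      (dmax_[ch] - dmin_[ch]) + pmin_[ch])
  rates <- spr / rec_dur
  modal <- as.numeric(names(sort(table(rates), decreasing = TRUE))[1])
  if (length(unique(rates)) > 1L) {
    warning(sprintf("'%s': channels sampled at different rates (%s); resampling all to %g Hz",
                    path, paste(unique(rates), collapse = ", "), modal))
    dur <- n_rec * rec_dur
    n_out <- round(dur * modal)
    t_out <- (seq_len(n_out) - 1) / modal
    phys <- lapply(seq_len(ns), function(ch) {
      t_in <- (seq_along(phys[[ch]]) - 1) / rates[ch]
      stats::approx(t_in, phys[[ch]], xout = t_out, rule = 2)$y
    })
  }
  sig <- do.call(rbind, phys)
  sid <- subject_id %||% (if (nzchar(patient)) patient else basename(path))
  eeg_recording(sig, sampling_rate = modal, label = label, subject_id = sid,
                channel_names = labels)
}
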
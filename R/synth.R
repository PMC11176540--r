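# Seeded synthetic EEG: a per-subject alpha-band sinusoid whose amplitude
# carries the class contrast, on top of 1/f-shaped ("pink") background noise
# plus white sensor noise.  The generator exists so the entire
# window -> tensor -> train -> leave-one-out pipeline is exercisable and
# testable with no external data; it makes no claim of physiological realism.

#' Synthetic EEG generator configuration
#'
#' Each channel of a generated recording is
#' `A_subj * (alpha_amp_control + label * alpha_amp_effect) *
#' sin(2*pi*f_alpha*t + phi_ch) + pink_noise_scale * p(t) +
#' white_noise_scale * w(t)`
#' where `phi_ch` is a per-channel uniform phase, `w` is unit white noise,
#' `p` is unit-variance 1/f-shaped noise (spectral density proportional to
#' 1/f over 1-45 Hz), and `A_subj = exp(N(0, subject_variability^2))` is a
#' per-subject amplitude multiplier.  With the defaults the class-1 (MDD)
#' alpha amplitude is twice the class-0 amplitude, i.e. roughly a fourfold
#' alpha-band power contrast.
#'
#' @param n_subjects_per_class Subjects simulated per class.
#' @param duration_s Recording duration in seconds per subject.
#' @param sampling_rate Hz; default 256.
#' @param n_channels Electrodes; default 20.
#' @param alpha_freq_hz Oscillation frequency; default 10 (alpha band).
#' @param alpha_amp_control Class-0 alpha amplitude; default 1.
#' @param alpha_amp_effect Additive amplitude increment for class 1;
#'   default 1 (set 0 for a null dataset).
#' @param pink_noise_scale Scale of the 1/f background; default 1.
#' @param white_noise_scale Scale of the white sensor noise; default 0.2.
#' @param subject_variability Standard deviation of the log-normal
#'   per-subject amplitude multiplier; default 0.1.
#' @param seed Master seed; together with subject index and label it fully
#'   determines every sample.
#' @return A `synth_config` object.
#' @export
synth_config <- function(n_subjects_per_class = 6L, duration_s = 40,
                         sampling_rate = 256, n_channels = 20L,
                         alpha_freq_hz = 10, alpha_amp_control = 1,
                         alpha_amp_effect = 1, pink_noise_scale = 1,
                         white_noise_scale = 0.2, subject_variability = 0.1,
                         seed = 1L) {
  cfg <- list(n_subjects_per_class = as.integer(n_subjects_per_class),
              duration_s = duration_s, sampling_rate = sampling_rate,
              n_channels = as.integer(n_channels),
              alpha_freq_hz = alpha_freq_hz,
              alpha_amp_control = alpha_amp_control,
              alpha_amp_effect = alpha_amp_effect,
              pink_noise_scale = pink_noise_scale,
              white_noise_scale = white_noise_scale,
              subject_variability = subject_variability,
              seed = as.integer(seed))
  if (cfg$n_subjects_per_class < 1L) stop("need at least one subject per class")
  check_scalar_pos(cfg$duration_s, "duration_s")
  check_scalar_pos(cfg$sampling_rate, "sampling_rate")
  if (cfg$n_channels < 1L) stop("need at least one channel")
  if (cfg$alpha_amp_control < 0 || cfg$pink_noise_scale < 0 ||
      cfg$white_noise_scale < 0 || cfg$subject_variability < 0)
    stop("amplitudes and noise scales must be non-negative")
  if (cfg$duration_s * cfg$sampling_rate < 1024)
    stop("duration_s * sampling_rate must cover at least one 1024-sample window")
  structure(cfg, class = "synth_config")
}

# unit-variance 1/f-shaped noise: white Gaussian noise shaped in the
# frequency domain with amplitude 1/sqrt(f) above 1 Hz (flat below), then
# rescaled to sd 1.  Density is proportional to 1/f over the whole 1 Hz -
# Nyquist range, which covers the contractual 1-45 Hz band.
pink_noise <- function(n, fs) {
  w <- rnorm(n)
  sp <- fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  amp <- 1 / sqrt(pmax(f, 1))
  p <- Re(fft(sp * amp, inverse = TRUE)) / n
  s <- sd(p)
  if (s > 0) p / s else p
}

#' Generate one synthetic recording
#'
#' Fully determined by `(cfg$seed, subject_index, label)`; calling twice with
#' the same triple gives bit-identical signals.
#'
#' @param cfg A [synth_config()].
#' @param subject_index Positive integer index of the subject within its
#'   class.
#' @param label 0 (control) or 1 (MDD-like, boosted alpha amplitude).
#' @return An [eeg_recording()] with subject id `"synth-<label>-<index>"`.
#' @export
generate_recording <- function(cfg, subject_index, label) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!label %in% c(0, 1)) stop("label must be 0 or 1")
  if (subject_index < 1) stop("subject_index must be positive")
  n <- round(cfg$duration_s * cfg$sampling_rate)
  t <- (seq_len(n) - 1) / cfg$sampling_rate
  amp <- cfg$alpha_amp_control + label * cfg$alpha_amp_effect
  sig <- with_seed(derive_seed(cfg$seed, 2 * subject_index + label), {
    a_subj <- exp(rnorm(1, 0, cfg$subject_variability))
    m <- matrix(0, cfg$n_channels, n)
    for (ch in seq_len(cfg$n_channels)) {
      phi <- runif(1, 0, 2 * pi)
      m[ch, ] <- a_subj * amp * sin(2 * pi * cfg$alpha_freq_hz * t + phi) +
        cfg$pink_noise_scale * pink_noise(n, cfg$sampling_rate) +
        cfg$white_noise_scale * rnorm(n)
    }
    m
  })
  eeg_recording(sig, sampling_rate = cfg$sampling_rate, label = label,
                subject_id = sprintf("synth-%d-%02d", label, subject_index),
                channel_names = default_montage(cfg$n_channels))
}

# the 20-electrode 10-20 montage (ECG included) used by the emulated data
default_montage <- function(n) {
  base <- c("Fp1", "Fp2", "F3", "F4", "F7", "T3", "T5", "C3", "C4", "Fz",
            "Cz", "Pz", "F8", "T4", "T6", "P3", "P4", "O1", "O2", "ECG")
  if (n <= length(base)) base[seq_len(n)] else c(base, paste0("ch", seq_len(n - length(base)) + length(base)))
}

#' Generate a balanced labeled dataset
#'
#' @param cfg A [synth_config()].
#' @return List of `2 * n_subjects_per_class` [eeg_recording()]s with unique
#'   subject ids, `n_subjects_per_class` per class, deterministic from the
#'   seed.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  recs <- list()
  for (lab in c(0L, 1L))
    for (i in seq_len(cfg$n_subjects_per_class))
      recs[[length(recs) + 1L]] <- generate_recording(cfg, i, lab)
  recs
}

#' Write a dataset of EDF fixtures plus a manifest
#'
#' Writes one EDF per recording into `dir` and a `manifest.csv` with columns
#' `subject_id`, `path`, `label`, consumable by [load_manifest()].
#'
#' @param recordings List of [eeg_recording()]s.
#' @param dir Output directory (created if missing).
#' @return Path of the manifest, invisibly.
#' @export
write_edf_dataset <- function(recordings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(recordings, function(rec) {
    fn <- paste0(rec$subject_id, ".edf")
    write_edf(rec, file.path(dir, fn))
    data.frame(subject_id = rec$subject_id, path = fn, label = rec$label)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}

#' Band power of one channel
#'
#' Mean periodogram power density integrated over `[f_lo, f_hi]`; used by the
#' generator's own calibration checks (e.g. the alpha-band class contrast).
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param f_lo,f_hi Band edges in Hz.
#' @return Band power (variance units).
#' @export
band_power <- function(x, fs, f_lo = 8, f_hi = 13) {
  n <- length(x)
  sp <- Mod(fft(x))^2 / n^2
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= f_lo & f <= f_hi & f <= fs / 2
  2 * sum(sp[keep])
}
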
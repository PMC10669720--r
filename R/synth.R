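#' Synthetic phonocardiogram configuration
#'
#' Parameters of the generator used for offline testing. Defaults model
#' resting-to-elevated heart rates (55-110 bpm), low-frequency S1/S2
#' transients (70 and 120 Hz tone bursts, S2 at 35% of the cycle), a
#' systolic murmur as 150-700 Hz band-limited noise at 0.4 relative
#' amplitude for the abnormal class, and additive white noise at 2% of
#' the S1 amplitude.
#'
#' @param sample_rate Hz (default 2000).
#' @param duration_s Clip length in seconds (default 5).
#' @param heart_rate_bpm Length-2 range the per-recording rate is drawn
#'   from.
#' @param s1_freq,s2_freq Tone-burst centre frequencies in Hz.
#' @param s1_s2_interval S2 position as a fraction of the cycle.
#' @param murmur_band Length-2 Hz range of the murmur noise.
#' @param murmur_amplitude Murmur amplitude relative to S1 (abnormal
#'   class only; 0 disables).
#' @param noise_sd Additive white-noise SD relative to S1.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(sample_rate = 2000, duration_s = 5,
                         heart_rate_bpm = c(55, 110),
                         s1_freq = 70, s2_freq = 120,
                         s1_s2_interval = 0.35,
                         murmur_band = c(150, 700),
                         murmur_amplitude = 0.4, noise_sd = 0.02) {
  stopifnot(sample_rate > 0, duration_s > 0,
            length(heart_rate_bpm) == 2, all(heart_rate_bpm > 0),
            length(murmur_band) == 2, murmur_band[1] < murmur_band[2])
  if (murmur_band[2] >= sample_rate / 2)
    stop("murmur_band must lie below the Nyquist frequency")
  structure(list(sample_rate = sample_rate, duration_s = duration_s,
                 heart_rate_bpm = heart_rate_bpm, s1_freq = s1_freq,
                 s2_freq = s2_freq, s1_s2_interval = s1_s2_interval,
                 murmur_band = murmur_band,
                 murmur_amplitude = murmur_amplitude,
                 noise_sd = noise_sd), class = "synth_config")
}

# FFT band-pass: keep only components inside [lo, hi] Hz
bandpass_fft <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)                     # two-sided frequency axis
  X[f < lo | f > hi] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

gauss_burst <- function(t_axis, center, freq, sd_s, amp) {
  amp * exp(-0.5 * ((t_axis - center) / sd_s)^2) *
    sin(2 * pi * freq * (t_axis - center))
}

#' Generate one synthetic phonocardiogram
#'
#' Quasi-periodic cardiac cycles at a heart rate drawn from the
#' configured range, with +/-5% per-cycle jitter. Each cycle holds a
#' Gaussian-windowed S1 tone burst at its start and an S2 burst at
#' `s1_s2_interval` of the cycle. For the abnormal class, band-limited
#' noise ("murmur") fills the S1-S2 (systolic) window at
#' `murmur_amplitude`; the same random draws are consumed for both
#' classes, so an abnormal recording with `murmur_amplitude = 0` is
#' sample-identical to the normal recording under the same seed.
#' White noise is added at `noise_sd` and the peak is scaled to 0.9.
#'
#' @param label 0 (normal) or 1 (abnormal).
#' @param config A [synth_config()].
#' @param seed Integer seed (fully determines the recording).
#' @param id Recording identifier.
#' @return A [pcg_recording].
#' @export
generate_recording <- function(label, config = synth_config(), seed = 1L,
                               id = NULL) {
  stopifnot(label %in% c(0, 1))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  fs <- config$sample_rate
  n <- round(config$duration_s * fs)
  t_axis <- (seq_len(n) - 1) / fs
  x <- numeric(n)

  hr <- stats::runif(1, config$heart_rate_bpm[1], config$heart_rate_bpm[2])
  base_cycle <- 60 / hr
  murmur_gain <- if (label == 1) config$murmur_amplitude else 0

  cursor <- 0.05
  while (cursor < config$duration_s) {
    cyc <- base_cycle * (1 + stats::runif(1, -0.05, 0.05))
    t_s1 <- cursor
    t_s2 <- cursor + config$s1_s2_interval * cyc
    x <- x + gauss_burst(t_axis, t_s1, config$s1_freq, 0.012, 1.0)
    if (t_s2 < config$duration_s)
      x <- x + gauss_burst(t_axis, t_s2, config$s2_freq, 0.010, 0.8)
    # systolic murmur window between S1 and S2
    w_lo <- t_s1 + 0.04; w_hi <- t_s2 - 0.02
    if (w_hi > w_lo) {
      idx <- which(t_axis >= w_lo & t_axis <= w_hi)
      noise <- stats::rnorm(length(idx))       # drawn for both classes
      if (length(idx) > 8) {
        bp <- bandpass_fft(noise, fs, config$murmur_band[1],
                           config$murmur_band[2])
        rms <- sqrt(mean(bp^2))
        if (rms > 0) {
          env <- hann_window(length(idx))
          x[idx] <- x[idx] + murmur_gain * env * bp / rms
        }
      }
    }
    cursor <- cursor + cyc
  }
  x <- x + stats::rnorm(n, 0, config$noise_sd)
  x <- 0.9 * x / max(abs(x))
  if (is.null(id))
    id <- sprintf("syn_%s_s%d", if (label == 1) "abn" else "nrm", seed)
  rec <- pcg_recording(x, fs, label = label, id = id)
  rec$heart_rate <- hr
  rec
}

#' Generate a balanced labeled dataset
#'
#' @param n_per_class Recordings per label (>= 1).
#' @param config A [synth_config()].
#' @param seed Master seed; per-recording seeds are derived from it.
#' @return List with `recordings` (list of [pcg_recording]) and
#'   `manifest` (data.frame: id, label, seed, heart_rate).
#' @export
generate_dataset <- function(n_per_class, config = synth_config(),
                             seed = 1L) {
  stopifnot(n_per_class >= 1)
  labels <- rep(c(0, 1), each = n_per_class)
  seeds <- (as.numeric(seed) * 7919 + 104729 * seq_along(labels)) %%
    2147483647
  recordings <- lapply(seq_along(labels), function(i) {
    generate_recording(labels[i], config, seed = as.integer(seeds[i]),
                       id = sprintf("syn_%s_%03d",
                                    if (labels[i] == 1) "abn" else "nrm",
                                    ((i - 1) %% n_per_class) + 1))
  })
  manifest <- data.frame(
    id = vapply(recordings, function(r) r$id, character(1)),
    label = labels,
    seed = as.integer(seeds),
    heart_rate = vapply(recordings, function(r) r$heart_rate, numeric(1)))
  list(recordings = recordings, manifest = manifest)
}

#' Mean spectral power in a frequency band
#'
#' Periodogram power averaged over the FFT bins inside `[lo, hi]` Hz.
#' Used as the murmur-energy statistic: abnormal recordings carry
#' strictly more 150-700 Hz power than their normal counterparts.
#'
#' @param x Numeric waveform.
#' @param fs Sampling rate in Hz.
#' @param lo,hi Band edges in Hz.
#' @return Mean power (amplitude^2 per bin) in the band.
#' @export
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  keep <- f >= lo & f <= hi & f <= fs / 2
  mean(P[keep])
}
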
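#' MFCC extraction configuration
#'
#' The configuration that maps a fixed-duration clip to the network
#' input. The defaults are the package's declared convention for the
#' 5-s, 2 kHz clip: 128 mel filters spanning 20-1000 Hz, Hann-windowed
#' frames of 1024 samples with a 625-sample hop, centred framing with
#' reflection padding, a DCT-II keeping all 128 coefficients, and the
#' frame count truncated to exactly 16 — yielding the 128 x 16 input the
#' capsule network expects. `segment_preset()` supplies variants for
#' other clip lengths.
#'
#' @param sample_rate Model sampling rate in Hz.
#' @param duration_s Clip duration in seconds.
#' @param n_mels Number of mel filters (= coefficients kept).
#' @param fmin,fmax Filter-bank frequency range in Hz.
#' @param frame_length STFT frame length in samples.
#' @param hop Hop between frame centres in samples.
#' @param n_frames Number of frames kept (the input width).
#' @return An object of class `mfcc_config`.
#' @export
mfcc_config <- function(sample_rate = 2000, duration_s = 5, n_mels = 128,
                        fmin = 20, fmax = 1000, frame_length = 1024,
                        hop = 625, n_frames = 16) {
  stopifnot(fmax <= sample_rate / 2, fmin >= 0, fmin < fmax,
            n_mels >= 1, frame_length >= 2, hop >= 1, n_frames >= 1)
  structure(list(sample_rate = sample_rate, duration_s = duration_s,
                 n_mels = n_mels, n_coeff = n_mels, fmin = fmin, fmax = fmax,
                 frame_length = frame_length, hop = hop, n_frames = n_frames),
            class = "mfcc_config")
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Triangular mel filter bank
#'
#' @param config An [mfcc_config()].
#' @return `n_mels` x `n_bins` weight matrix over the one-sided FFT bins.
#' @keywords internal
mel_filterbank <- function(config) {
  n_fft <- config$frame_length
  n_bins <- n_fft %/% 2 + 1
  bin_hz <- (seq_len(n_bins) - 1) * config$sample_rate / n_fft
  mel_pts <- seq(hz_to_mel(config$fmin), hz_to_mel(config$fmax),
                 length.out = config$n_mels + 2)
  hz_pts <- mel_to_hz(mel_pts)
  fb <- matrix(0, config$n_mels, n_bins)
  for (m in seq_len(config$n_mels)) {
    lo <- hz_pts[m]; mid <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- (bin_hz - lo) / (mid - lo)
    down <- (hi - bin_hz) / (hi - mid)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

dct_ii_matrix <- function(n) {
  # orthonormal DCT-II: C[k, m] = s_k cos(pi k (2m + 1) / (2n))
  k <- 0:(n - 1)
  m <- 0:(n - 1)
  C <- cos(pi * outer(k, 2 * m + 1) / (2 * n))
  C * c(sqrt(1 / n), rep(sqrt(2 / n), n - 1))
}

#' Compute the MFCC spectrum of a preprocessed segment
#'
#' A pure, deterministic function of the samples and the configuration:
#' centred Hann-windowed STFT (reflection padding), power spectrum, mel
#' filter-bank energies, log, orthonormal DCT-II. The output shape is
#' asserted to be `n_coeff` x `n_frames` (128 x 16 under defaults).
#'
#' @param segment A `pcg_segment` at `config$sample_rate`, normalized.
#' @param config An [mfcc_config()].
#' @return An object of class `mfcc_spectrum` with fields `values`
#'   (matrix), `n_coeff`, `n_frames`, `source_id`, `label`.
#' @export
mfcc_spectrum <- function(segment, config = mfcc_config()) {
  stopifnot(inherits(segment, "pcg_segment"))
  x <- segment$samples
  n <- length(x)
  avail <- 1L + n %/% config$hop
  if (avail < config$n_frames)
    stop(sprintf("segment supports only %d frames, config expects %d (%d samples at hop %d)",
                 avail, config$n_frames, n, config$hop))
  half <- config$frame_length %/% 2
  if (n < half + 2)
    stop("segment too short for reflection padding at this frame length")
  padded <- c(x[(half + 1):2], x, x[(n - 1):(n - half)])
  w <- hann_window(config$frame_length)
  starts <- (seq_len(config$n_frames) - 1L) * config$hop + 1L
  frames <- vapply(starts,
                   function(s) padded[s:(s + config$frame_length - 1L)] * w,
                   numeric(config$frame_length))
  spec <- stats::mvfft(frames)
  n_bins <- config$frame_length %/% 2 + 1
  power <- Mod(spec[seq_len(n_bins), , drop = FALSE])^2
  fb <- mel_filterbank(config)
  energies <- fb %*% power
  loge <- log(energies + 1e-10)
  C <- dct_ii_matrix(config$n_mels)
  values <- (C %*% loge)[seq_len(config$n_coeff), , drop = FALSE]
  stopifnot(nrow(values) == config$n_coeff, ncol(values) == config$n_frames,
            all(is.finite(values)))
  structure(list(values = values, n_coeff = config$n_coeff,
                 n_frames = config$n_frames,
                 source_id = segment$id, label = segment$label),
            class = "mfcc_spectrum")
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' @export
print.mfcc_spectrum <- function(x, ...) {
  cat(sprintf("<mfcc_spectrum '%s': %d x %d, label=%s>\n", x$source_id,
              x$n_coeff, x$n_frames,
              if (is.na(x$label)) "NA" else as.character(x$label)))
  invisible(x)
}
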
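#' Construct a phonocardiogram recording
#'
#' The basic labelled-waveform container. Stereo input is kept as a
#' two-column matrix; segmentation mixes it down to mono (the network
#' input is single-channel).
#'
#' @param samples Numeric vector (mono) or matrix with one column per
#'   channel; dimensionless amplitude.
#' @param sample_rate Sampling rate in Hz (> 0).
#' @param label `0` (normal), `1` (abnormal) or `NA` (unlabeled).
#' @param id Opaque identifier string.
#' @return An object of class `pcg_recording`.
#' @export
pcg_recording <- function(samples, sample_rate, label = NA, id = "pcg") {
  if (is.null(dim(samples))) samples <- matrix(as.numeric(samples), ncol = 1)
  stopifnot(sample_rate > 0, nrow(samples) > 0, ncol(samples) %in% c(1L, 2L))
  if (!is.na(label) && !label %in% c(0, 1))
    stop("label must be 0 (normal), 1 (abnormal) or NA")
  structure(list(samples = samples, sample_rate = sample_rate,
                 channels = ncol(samples), label = label, id = id),
            class = "pcg_recording")
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<pcg_recording '%s': %.2f s @ %g Hz, %d ch, label=%s>\n",
              x$id, nrow(x$samples) / x$sample_rate, x$sample_rate,
              x$channels,
              if (is.na(x$label)) "NA" else as.character(x$label)))
  invisible(x)
}

new_segment <- function(samples, sample_rate, duration_s, source_id, label,
                        index = 1L) {
  structure(list(samples = as.numeric(samples), sample_rate = sample_rate,
                 duration_s = duration_s, source_id = source_id,
                 label = label,
                 id = sprintf("%s_seg%03d", source_id, index)),
            class = "pcg_segment")
}

#' Slice a recording into fixed-duration segments
#'
#' Cuts the waveform into consecutive non-overlapping clips of
#' `duration_s` seconds; a trailing remainder shorter than one clip is
#' discarded. Stereo recordings are mixed to mono by channel averaging
#' before slicing. A recording shorter than one clip yields an empty
#' list.
#'
#' @param recording A [pcg_recording].
#' @param duration_s Clip duration in seconds (default 5).
#' @return List of `pcg_segment` objects (label inherited).
#' @export
segment_pcg <- function(recording, duration_s = 5) {
  stopifnot(inherits(recording, "pcg_recording"), duration_s > 0)
  mono <- rowMeans(recording$samples)
  seg_len <- round(duration_s * recording$sample_rate)
  n_seg <- length(mono) %/% seg_len
  if (n_seg == 0L) return(list())
  lapply(seq_len(n_seg), function(k) {
    idx <- ((k - 1L) * seg_len + 1L):(k * seg_len)
    new_segment(mono[idx], recording$sample_rate, duration_s,
                recording$id, recording$label, k)
  })
}

#' Downsample a segment with anti-aliased polyphase filtering
#'
#' Resamples to `target_rate` through `signal::resample` (polyphase FIR
#' low-pass before rate reduction), so content below the new Nyquist —
#' the sub-1 kHz band that carries S1, S2 and murmur energy at the 2 kHz
#' model rate — is preserved. Upsampling is refused.
#'
#' @param segment A `pcg_segment`.
#' @param target_rate Target rate in Hz (default 2000); must not exceed
#'   the segment's rate.
#' @return The resampled `pcg_segment`, trimmed/padded to exactly
#'   `round(duration_s * target_rate)` samples.
#' @export
downsample_pcg <- function(segment, target_rate = 2000) {
  stopifnot(inherits(segment, "pcg_segment"))
  if (target_rate > segment$sample_rate)
    stop("target_rate exceeds source rate; upsampling unsupported")
  if (target_rate == segment$sample_rate) return(segment)
  g <- gcd_int(round(target_rate), round(segment$sample_rate))
  p <- round(target_rate) / g
  q <- round(segment$sample_rate) / g
  y <- signal::resample(segment$samples, p, q)
  n_out <- round(segment$duration_s * target_rate)
  if (length(y) >= n_out) y <- y[seq_len(n_out)]
  else y <- c(y, numeric(n_out - length(y)))
  segment$samples <- y
  segment$sample_rate <- target_rate
  segment
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Peak-normalize a segment to [-1, 1]
#'
#' Divides by the peak absolute amplitude so that max |x| is exactly 1.
#' An all-zero segment is returned unchanged with a warning; non-finite
#' samples are an error. Idempotent.
#'
#' @param segment A `pcg_segment`.
#' @return The scaled `pcg_segment`.
#' @export
normalize_pcg <- function(segment) {
  stopifnot(inherits(segment, "pcg_segment"))
  if (any(!is.finite(segment$samples)))
    stop("segment contains non-finite samples")
  peak <- max(abs(segment$samples))
  if (peak == 0) {
    warning("all-zero segment left unchanged by normalize_pcg")
    return(segment)
  }
  segment$samples <- segment$samples / peak
  segment
}

#' Full preprocessing chain for one recording
#'
#' segmentation -> downsampling -> per-segment normalization -> MFCC,
#' in that order.
#'
#' @param recording A [pcg_recording].
#' @param config An [mfcc_config()]; its `duration_s` and `sample_rate`
#'   drive the earlier stages.
#' @return List of [mfcc_spectrum] objects, one per full segment.
#' @export
preprocess_pcg <- function(recording, config = mfcc_config()) {
  segs <- segment_pcg(recording, config$duration_s)
  lapply(segs, function(s) {
    s <- downsample_pcg(s, config$sample_rate)
    s <- normalize_pcg(s)
    mfcc_spectrum(s, config)
  })
}
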
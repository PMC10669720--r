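#' Segment-length presets
#'
#' Each clip duration carries its own MFCC configuration and network
#' geometry (conv filters/kernels/strides and batch size). The 5-s
#' preset is the default architecture: 128 x 16 input, conv1 with 256
#' 9 x 9 filters at stride 2, a primary-capsule convolution with 16
#' capsule channels of dimension 16 (256 filters) at kernel 4, giving
#' 912 primary capsules.
#'
#' @param duration One of `"5s"`, `"10s"`, `"3s"`, `"1s"`.
#' @return List with `mfcc` (an [mfcc_config()]) and `net`
#'   (a [capsnet_config()]).
#' @export
segment_preset <- function(duration = c("5s", "10s", "3s", "1s")) {
  duration <- match.arg(duration)
  p <- switch(duration,
    "5s"  = list(dur = 5,  n_frames = 16, hop = 625,
                 conv1_f = 256, conv1_k = 9, conv1_s = 2,
                 pc_ch = 16, pc_k = 4, pc_s = 1, batch = 8),
    "10s" = list(dur = 10, n_frames = 32, hop = 625,
                 conv1_f = 256, conv1_k = 9, conv1_s = 2,
                 pc_ch = 16, pc_k = 4, pc_s = 2, batch = 8),
    "3s"  = list(dur = 3,  n_frames = 10, hop = 600,
                 conv1_f = 128, conv1_k = 7, conv1_s = 1,
                 pc_ch = 8,  pc_k = 4, pc_s = 1, batch = 16),
    "1s"  = list(dur = 1,  n_frames = 4,  hop = 500,
                 conv1_f = 224, conv1_k = 3, conv1_s = 1,
                 pc_ch = 32, pc_k = 2, pc_s = 1, batch = 32))
  mfcc <- mfcc_config(duration_s = p$dur, hop = p$hop,
                      n_frames = p$n_frames)
  net <- capsnet_config(
    input_shape = c(mfcc$n_coeff, p$n_frames, 1),
    conv1_filters = p$conv1_f, conv1_kernel = p$conv1_k,
    conv1_stride = p$conv1_s,
    pc_channels = p$pc_ch, pc_kernel = p$pc_k, pc_stride = p$pc_s,
    batch_size = p$batch)
  list(mfcc = mfcc, net = net, duration = duration)
}

#' Capsule network configuration
#'
#' @param input_shape Integer vector `c(n_coeff, n_frames, channels)`.
#' @param conv1_filters,conv1_kernel,conv1_stride First convolution.
#' @param pc_channels Number of primary-capsule channels; the
#'   primary-capsule convolution has `pc_channels * capsule_dim` filters.
#' @param pc_kernel,pc_stride Primary-capsule convolution geometry.
#' @param capsule_dim Primary capsule dimension (default 16).
#' @param digit_dim Digit capsule dimension (default 16).
#' @param n_classes Number of classes (2: normal/abnormal).
#' @param routings Dynamic-routing iterations (default 5).
#' @param decoder_hidden Widths of the decoder's hidden layers.
#' @param w_rec Reconstruction-loss weight; 0 trains on margin loss only.
#' @param m_plus,m_minus,lambda_down Margin-loss constants.
#' @param threshold Digitization cutoff T on capsule length.
#' @param batch_size Minibatch size.
#' @return An object of class `capsnet_config`.
#' @export
capsnet_config <- function(input_shape = c(128, 16, 1),
                           conv1_filters = 256, conv1_kernel = 9,
                           conv1_stride = 2,
                           pc_channels = 16, pc_kernel = 4, pc_stride = 1,
                           capsule_dim = 16, digit_dim = 16, n_classes = 2,
                           routings = 5,
                           decoder_hidden = c(1024, 2048),
                           w_rec = 5e-4,
                           m_plus = 0.9, m_minus = 0.1, lambda_down = 0.5,
                           threshold = 0.5,
                           batch_size = 8) {
  stopifnot(routings >= 1, n_classes >= 2,
            0 < m_minus, m_minus < m_plus, m_plus <= 1,
            0 < threshold, threshold < 1, lambda_down > 0)
  cfg <- structure(list(
    input_shape = as.integer(input_shape),
    conv1_filters = conv1_filters, conv1_kernel = conv1_kernel,
    conv1_stride = conv1_stride,
    pc_channels = pc_channels, pc_kernel = pc_kernel, pc_stride = pc_stride,
    pc_filters = pc_channels * capsule_dim,
    capsule_dim = capsule_dim, digit_dim = digit_dim, n_classes = n_classes,
    routings = routings, decoder_hidden = decoder_hidden, w_rec = w_rec,
    m_plus = m_plus, m_minus = m_minus, lambda_down = lambda_down,
    threshold = threshold, batch_size = batch_size), class = "capsnet_config")
  sh <- capsnet_shapes(cfg)   # validates geometry
  stopifnot(sh$n_primary >= 1)
  cfg
}

conv_out_dim <- function(n, k, s) {
  if (k > n) stop("kernel larger than input (", k, " > ", n, ")")
  (n - k) %/% s + 1L
}

#' Layer shape chain for a configuration
#'
#' @param config A [capsnet_config()].
#' @return List of per-layer output shapes plus `n_primary`.
#' @export
capsnet_shapes <- function(config) {
  h0 <- config$input_shape[1]; w0 <- config$input_shape[2]
  h1 <- conv_out_dim(h0, config$conv1_kernel, config$conv1_stride)
  w1 <- conv_out_dim(w0, config$conv1_kernel, config$conv1_stride)
  h2 <- conv_out_dim(h1, config$pc_kernel, config$pc_stride)
  w2 <- conv_out_dim(w1, config$pc_kernel, config$pc_stride)
  n_feat <- h2 * w2 * config$pc_filters
  if (n_feat %% config$capsule_dim != 0)
    stop("primary-capsule feature count ", n_feat,
         " not divisible by capsule_dim ", config$capsule_dim)
  list(input = c(h0, w0, config$input_shape[3]),
       conv1 = c(h1, w1, config$conv1_filters),
       pc_conv = c(h2, w2, config$pc_filters),
       n_primary = n_feat %/% config$capsule_dim,
       digit = c(config$n_classes, config$digit_dim),
       decoder_out = c(h0, w0, config$input_shape[3]))
}

#' Analytic per-layer trainable-parameter audit
#'
#' Computes, without instantiating any weights, the output shape and
#' trainable-parameter count of every layer: convolutions contribute
#' K^2*C*F + F, the digit-capsule transform M * n_classes * D_in * D_out
#' (no bias), and the decoder a dense stack over its hidden widths.
#' Under the default 5-s preset this reproduces the reference
#' architecture: 20,992 / 1,048,832 / 466,944 / 6,329,344 parameters and
#' 7,866,112 in total over 912 primary capsules.
#'
#' @param config A [capsnet_config()] (default: the 5-s preset).
#' @return A data.frame with columns `layer`, `output_shape`, `params`,
#'   plus attributes `total` and `n_primary`.
#' @export
count_params <- function(config = segment_preset("5s")$net) {
  sh <- capsnet_shapes(config)
  conv1 <- config$conv1_kernel^2 * config$input_shape[3] *
    config$conv1_filters + config$conv1_filters
  pc <- config$pc_kernel^2 * config$conv1_filters * config$pc_filters +
    config$pc_filters
  digit <- sh$n_primary * config$n_classes * config$capsule_dim *
    config$digit_dim
  widths <- c(config$n_classes * config$digit_dim, config$decoder_hidden,
              prod(config$input_shape))
  dec <- sum((widths[-length(widths)] + 1) * widths[-1])
  shp <- function(v) paste0("(", paste(v, collapse = ", "), ")")
  df <- data.frame(
    layer = c("input", "conv1", "primarycap_conv2d", "primarycap_reshape",
              "digitcaps", "capsnet_length", "decoder"),
    output_shape = c(shp(sh$input), shp(sh$conv1), shp(sh$pc_conv),
                     shp(c(sh$n_primary, config$capsule_dim)),
                     shp(sh$digit), shp(config$n_classes),
                     shp(sh$decoder_out)),
    params = c(0, conv1, pc, 0, digit, 0, dec),
    stringsAsFactors = FALSE)
  attr(df, "total") <- sum(df$params)
  attr(df, "n_primary") <- sh$n_primary
  df
}

#' Initialize a capsule network model
#'
#' He-style scaled normal initialization for the convolutions and
#' decoder, smaller-scale normal for the per-pair digit-capsule weight
#' matrices (which carry no bias). The RNG state is restored afterwards,
#' so initialization is reproducible from `seed` alone.
#'
#' @param config A [capsnet_config()].
#' @param seed Integer seed.
#' @return An object of class `capsnet_model`.
#' @export
init_capsnet <- function(config, seed = 1L) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  sh <- capsnet_shapes(config)
  k1 <- config$conv1_kernel; c1 <- config$input_shape[3]
  k2 <- config$pc_kernel;    c2 <- config$conv1_filters
  rnorm_arr <- function(dims, sd) array(stats::rnorm(prod(dims), 0, sd), dims)
  params <- list(
    conv1_W = rnorm_arr(c(k1, k1, c1, config$conv1_filters),
                        sqrt(2 / (k1 * k1 * c1))),
    conv1_b = numeric(config$conv1_filters),
    pc_W = rnorm_arr(c(k2, k2, c2, config$pc_filters),
                     sqrt(2 / (k2 * k2 * c2))),
    pc_b = numeric(config$pc_filters),
    digit_W = rnorm_arr(c(config$capsule_dim, config$digit_dim,
                          sh$n_primary, config$n_classes),
                        0.1 / sqrt(config$capsule_dim)))
  widths <- c(config$n_classes * config$digit_dim, config$decoder_hidden,
              prod(config$input_shape))
  params$dec <- lapply(seq_len(length(widths) - 1), function(i) {
    list(W = rnorm_arr(c(widths[i], widths[i + 1]), sqrt(2 / widths[i])),
         b = numeric(widths[i + 1]))
  })
  structure(list(config = config, params = params, seed = seed),
            class = "capsnet_model")
}

#' @export
print.capsnet_model <- function(x, ...) {
  df <- count_params(x$config)
  cat(sprintf("<capsnet_model: %d primary capsules, %s total params, seed %d>\n",
              attr(df, "n_primary"),
              format(attr(df, "total"), big.mark = ","), x$seed))
  invisible(x)
}
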
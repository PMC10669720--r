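# Independent reference implementations used as oracles. These follow
# the defining formulas line by line (scalar loops, own squash), and
# stay independent of the vectorized code paths they check.

# squash written directly from its formula
oracle_squash <- function(s) {
  n2 <- sum(s^2)
  if (n2 == 0) return(s)
  (n2 / (1 + n2)) * s / sqrt(n2)
}

# naive quadruple-loop valid convolution, stride S, bias + activation
oracle_conv <- function(input, W, b, stride, relu = TRUE) {
  H <- dim(input)[1]; Wd <- dim(input)[2]; C <- dim(input)[3]
  K <- dim(W)[1]; F <- dim(W)[4]
  Hp <- (H - K) %/% stride + 1; Wp <- (Wd - K) %/% stride + 1
  out <- array(0, c(Hp, Wp, F))
  for (k in seq_len(F)) for (i in seq_len(Hp)) for (j in seq_len(Wp)) {
    acc <- b[k]
    for (u in seq_len(K)) for (v in seq_len(K)) for (cc in seq_len(C))
      acc <- acc + W[u, v, cc, k] *
        input[stride * (i - 1) + u, stride * (j - 1) + v, cc]
    out[i, j, k] <- if (relu) max(0, acc) else acc
  }
  out
}

# unvectorized routing-by-agreement: u = W s; c = softmax_j(b);
# s_j = sum_i c_ij u_j|i; v_j = squash(s_j); b_ij += u_j|i . v_j
oracle_routing <- function(primary, W, R) {
  Dp <- nrow(primary); M <- ncol(primary)
  Dd <- dim(W)[2]; N <- dim(W)[4]
  u <- array(0, c(Dd, M, N))
  for (m in seq_len(M)) for (n in seq_len(N))
    u[, m, n] <- t(W[, , m, n]) %*% primary[, m]
  b <- matrix(0, M, N)
  v <- matrix(0, Dd, N)
  coup <- NULL
  for (r in seq_len(R)) {
    coup <- exp(b) / rowSums(exp(b))
    for (n in seq_len(N)) {
      s <- numeric(Dd)
      for (m in seq_len(M)) s <- s + coup[m, n] * u[, m, n]
      v[, n] <- oracle_squash(s)
    }
    for (m in seq_len(M)) for (n in seq_len(N))
      b[m, n] <- b[m, n] + sum(u[, m, n] * v[, n])
  }
  list(digits = v, couplings = coup)
}

# AUC as the Mann-Whitney U statistic (no ties assumed)
oracle_auc_mw <- function(scores, positive) {
  positive <- as.logical(positive)
  r <- rank(scores)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# small reduced network configuration used across tests
tiny_net_config <- function(...) {
  capsnet_config(input_shape = c(12, 6, 1), conv1_filters = 4,
                 conv1_kernel = 3, conv1_stride = 2, pc_channels = 2,
                 pc_kernel = 2, pc_stride = 1, capsule_dim = 4,
                 digit_dim = 3, routings = 2, decoder_hidden = c(5),
                 w_rec = 0.01, batch_size = 2, ...)
}

# reduced network for learning tests: 32 conv filters, capsule dim 8,
# 2 routing iterations
reduced_net_config <- function(...) {
  capsnet_config(conv1_filters = 32, pc_channels = 4, capsule_dim = 8,
                 digit_dim = 8, routings = 2, decoder_hidden = c(64, 128),
                 w_rec = 0, batch_size = 16, ...)
}

make_sine_segment <- function(freq, fs = 2000, dur = 5, amp = 0.9) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  rec <- pcg_recording(amp * sin(2 * pi * freq * t), fs, label = 0,
                       id = sprintf("sine%g", freq))
  segment_pcg(rec, dur)[[1]]
}

# cache for expensive shared fixtures
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

synthetic_spectra <- function(n_per_class, seed) {
  cached(sprintf("spectra_%d_%d", n_per_class, seed), {
    ds <- generate_dataset(n_per_class, synth_config(), seed = seed)
    unlist(lapply(ds$recordings, preprocess_pcg), recursive = FALSE)
  })
}
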
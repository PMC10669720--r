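# Batched forward/backward pass and the Adam optimizer.
#
# Gradients are hand-derived reverse-mode (verified against finite
# differences in the test suite). Backprop convention through routing:
# the coupling coefficients produced by the forward iterations are
# treated as constants in the backward pass; gradients flow through the
# prediction vectors u = W s, the weighted sums and both squashes.

# reshape feature maps to capsules WITHOUT squashing: (H',W',F,B) -> (D,M,B)
caps_reshape <- function(maps, capsule_dim) {
  d <- dim(maps)
  A <- aperm(maps, c(3, 1, 2, 4))
  array(A, c(capsule_dim, d[3] %/% capsule_dim * d[1] * d[2], d[4]))
}

# backward of squash applied along dim 1.
# pre: pre-squash vectors (D, ...); g: upstream gradient, same shape.
squash_backward_dim1 <- function(pre, g) {
  d <- dim(pre)
  S <- matrix(pre, d[1]); G <- matrix(g, d[1])
  n2 <- colSums(S^2); n <- sqrt(n2)
  alpha <- ifelse(n == 0, 0, n / (1 + n2))
  dalpha <- (1 - n2) / (1 + n2)^2
  sg <- colSums(S * G)
  coef <- ifelse(n == 0, 0, dalpha * sg / n)
  out <- G * rep(alpha, each = d[1]) + S * rep(coef, each = d[1])
  array(out, d)
}

minmax_scale_cols <- function(X) {
  # scale each column of X to [0, 1]; constant columns -> 0
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  sweep(sweep(X, 2, rng[1, ], "-"), 2, span, "/")
}

decoder_forward <- function(dec, x) {
  # x: (in, B); ReLU hidden layers, sigmoid output
  acts <- list(x)
  n <- length(dec)
  for (i in seq_len(n)) {
    z <- crossprod(dec[[i]]$W, acts[[i]]) + dec[[i]]$b
    acts[[i + 1]] <- if (i < n) pmax(z, 0) else 1 / (1 + exp(-z))
  }
  acts
}

decoder_backward <- function(dec, acts, dy) {
  n <- length(dec)
  grads <- vector("list", n)
  y <- acts[[n + 1]]
  delta <- dy * y * (1 - y)                       # sigmoid output layer
  for (i in rev(seq_len(n))) {
    grads[[i]] <- list(W = acts[[i]] %*% t(delta), b = rowSums(delta))
    if (i > 1) {
      delta <- (dec[[i]]$W %*% delta) * (acts[[i]] > 0)
    } else {
      delta <- dec[[i]]$W %*% delta
    }
  }
  list(grads = grads, dx = delta)
}

# Full forward pass on a batch.
# X: (H, W, 1, B); labels: one-hot (N, B) or NULL (mask by prediction).
capsnet_batch_forward <- function(model, X, labels = NULL) {
  cfg <- model$config; pp <- model$params
  B <- dim(X)[4]
  f1 <- conv_forward_batch(X, pp$conv1_W, pp$conv1_b, cfg$conv1_stride, "relu")
  f2 <- conv_forward_batch(f1$out, pp$pc_W, pp$pc_b, cfg$pc_stride, "linear")
  caps_pre <- caps_reshape(f2$out, cfg$capsule_dim)          # (Dp, M, B)
  S <- squash_dim1(caps_pre)
  U <- predict_vectors(S, pp$digit_W)
  rt <- route_predictions(U, cfg$routings)
  V <- rt$V                                                  # (Dd, N, B)
  norms <- sqrt(apply(V^2, c(2, 3), sum))
  norms <- matrix(norms, cfg$n_classes, B)
  # decoder input: digit capsules masked to one class per sample
  mask_class <- if (!is.null(labels)) max.col(t(labels)) else
    apply(norms, 2, which.max)
  Vm <- matrix(V, cfg$digit_dim * cfg$n_classes, B)
  mask <- matrix(0, cfg$digit_dim * cfg$n_classes, B)
  for (b in seq_len(B))
    mask[(mask_class[b] - 1) * cfg$digit_dim + seq_len(cfg$digit_dim), b] <- 1
  dec_in <- Vm * mask
  acts <- decoder_forward(pp$dec, dec_in)
  recon <- acts[[length(acts)]]                              # (P, B)
  target <- minmax_scale_cols(matrix(X, prod(cfg$input_shape), B))
  m_loss <- if (!is.null(labels))
    margin_loss(norms, labels, cfg$m_plus, cfg$m_minus, cfg$lambda_down)
  else NA_real_
  r_loss <- sum((recon - target)^2) / B
  list(f1 = f1, f2 = f2, caps_pre = caps_pre, S = S, U = U, rt = rt,
       V = V, norms = norms, mask = mask, acts = acts, recon = recon,
       target = target, margin = m_loss, recon_sse = r_loss,
       loss = if (is.null(labels)) NA_real_ else m_loss + cfg$w_rec * r_loss,
       X = X, labels = labels)
}

capsnet_batch_backward <- function(model, fw) {
  cfg <- model$config; pp <- model$params
  B <- dim(fw$X)[4]
  Dd <- cfg$digit_dim; N <- cfg$n_classes
  M <- dim(fw$S)[2]; Dp <- cfg$capsule_dim

  # margin loss -> digit capsule vectors
  dnorm <- margin_loss_grad(fw$norms, fw$labels, cfg$m_plus, cfg$m_minus,
                            cfg$lambda_down)
  safe_n <- ifelse(fw$norms == 0, 1, fw$norms)
  dV <- array(0, c(Dd, N, B))
  for (n in seq_len(N))
    dV[, n, ] <- array(fw$V[, n, ], c(Dd, B)) *
      rep(dnorm[n, ] / safe_n[n, ], each = Dd)

  # reconstruction loss -> decoder -> masked digit capsules
  dy <- cfg$w_rec * 2 * (fw$recon - fw$target) / B
  dec_bw <- decoder_backward(pp$dec, fw$acts, dy)
  dV <- dV + array(dec_bw$dx * fw$mask, c(Dd, N, B))

  # through the digit squash: need pre-squash weighted sums s_j
  cc <- fw$rt$couplings                                      # (M, N, B)
  s_pre <- array(0, c(Dd, N, B))
  for (n in seq_len(N)) {
    un <- array(fw$U[, , n, ], c(Dd, M, B))
    cb <- aperm(array(array(cc[, n, ], c(M, B)), c(M, B, Dd)), c(3, 1, 2))
    s_pre[, n, ] <- colSums(aperm(un * cb, c(2, 1, 3)))
  }
  dS_digit <- squash_backward_dim1(s_pre, dV)                # (Dd, N, B)

  # ds_j -> dU (couplings detached)
  dU <- array(0, c(Dd, M, N, B))
  for (n in seq_len(N)) {
    dsb <- aperm(array(array(dS_digit[, n, ], c(Dd, B)), c(Dd, B, M)),
                 c(1, 3, 2))                                 # (Dd, M, B)
    cb <- aperm(array(array(cc[, n, ], c(M, B)), c(M, B, Dd)), c(3, 1, 2))
    dU[, , n, ] <- dsb * cb
  }

  # dU -> digit weights and primary capsules
  dWd <- array(0, dim(pp$digit_W))
  dS <- array(0, c(Dp, M, B))
  for (p in seq_len(Dp)) {
    Sp <- array(fw$S[p, , ], c(M, B))
    Sbig <- aperm(array(Sp, c(M, B, Dd, N)), c(3, 1, 4, 2))  # (Dd,M,N,B)
    dWd[p, , , ] <- array(rowSums(matrix(dU * Sbig, Dd * M * N, B)),
                          c(Dd, M, N))
    Wp <- array(pp$digit_W[p, , , ], c(Dd, M, N))
    T2 <- array(Wp, c(Dd, M, N, B)) * dU
    m1 <- colSums(T2)                                        # (M, N, B)
    dS[p, , ] <- array(apply(array(m1, c(M, N, B)), c(1, 3), sum), c(M, B))
  }

  # primary squash, reshape, conv2, ReLU, conv1
  d_caps <- squash_backward_dim1(fw$caps_pre, dS)
  d_maps <- caps_to_maps_grad(d_caps, fw$f2$out_dim)
  bw2 <- conv_backward_batch(fw$f2, pp$pc_W, d_maps, need_dx = TRUE)
  d_pre1 <- bw2$dX * (fw$f1$pre > 0)
  bw1 <- conv_backward_batch(fw$f1, pp$conv1_W, d_pre1, need_dx = FALSE)

  list(conv1_W = bw1$dW, conv1_b = bw1$db,
       pc_W = bw2$dW, pc_b = bw2$db,
       digit_W = dWd, dec = dec_bw$grads)
}

# ---- Adam ------------------------------------------------------------

flatten_params <- function(p) {
  c(list(conv1_W = p$conv1_W, conv1_b = p$conv1_b,
         pc_W = p$pc_W, pc_b = p$pc_b, digit_W = p$digit_W),
    stats::setNames(
      unlist(lapply(p$dec, function(l) list(l$W, l$b)), recursive = FALSE),
      paste0("dec", rep(seq_along(p$dec), each = 2), c("_W", "_b"))))
}

unflatten_params <- function(flat, template) {
  out <- template
  out$conv1_W <- flat$conv1_W; out$conv1_b <- flat$conv1_b
  out$pc_W <- flat$pc_W; out$pc_b <- flat$pc_b
  out$digit_W <- flat$digit_W
  for (i in seq_along(template$dec)) {
    out$dec[[i]]$W <- flat[[paste0("dec", i, "_W")]]
    out$dec[[i]]$b <- flat[[paste0("dec", i, "_b")]]
  }
  out
}

adam_init <- function(params) {
  fl <- flatten_params(params)
  list(m = lapply(fl, function(x) x * 0),
       v = lapply(fl, function(x) x * 0),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(params, grads, state, lr) {
  fp <- flatten_params(params)
  fg <- flatten_params(grads)
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (k in names(fp)) {
    state$m[[k]] <- state$beta1 * state$m[[k]] + (1 - state$beta1) * fg[[k]]
    state$v[[k]] <- state$beta2 * state$v[[k]] + (1 - state$beta2) * fg[[k]]^2
    fp[[k]] <- fp[[k]] - lr * (state$m[[k]] / bc1) /
      (sqrt(state$v[[k]] / bc2) + state$eps)
  }
  list(params = unflatten_params(fp, params), state = state)
}

#' Run the capsule network on one spectrum
#'
#' Full pass: conv1 -> primary capsules -> dynamic routing -> digit
#' capsules, returning per-class capsule lengths, the digitized binary
#' prediction, and the decoder's reconstruction of the input (from the
#' capsule of the predicted class).
#'
#' @param model A `capsnet_model` (see [init_capsnet()], [fit_capsnet()]).
#' @param spectrum An [mfcc_spectrum] or a bare matrix matching the
#'   model's input shape.
#' @return List with `norms` (per-class lengths, in `[0, 1)`),
#'   `prediction` (0/1 per class via the digitization threshold),
#'   `class` (predicted class index - 1, i.e. 0 = normal, 1 = abnormal),
#'   `reconstruction` (matrix of the input shape), `couplings`.
#' @export
capsnet_forward <- function(model, spectrum) {
  vals <- if (inherits(spectrum, "mfcc_spectrum")) spectrum$values
          else spectrum
  cfg <- model$config
  if (!all(dim(vals) == cfg$input_shape[1:2]))
    stop(sprintf("spectrum is %d x %d but the model preset expects %d x %d",
                 nrow(vals), ncol(vals), cfg$input_shape[1],
                 cfg$input_shape[2]))
  X <- array(vals, c(cfg$input_shape, 1))
  fw <- capsnet_batch_forward(model, X, labels = NULL)
  norms <- fw$norms[, 1]
  list(norms = norms,
       prediction = digitize(norms, cfg$threshold),
       class = which.max(norms) - 1L,
       reconstruction = matrix(fw$recon[, 1], cfg$input_shape[1],
                               cfg$input_shape[2]),
       couplings = matrix(fw$rt$couplings, dim(fw$rt$couplings)[1]))
}
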
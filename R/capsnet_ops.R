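#' Squash nonlinearity
#'
#' Rescales a vector to length `|v|^2 / (1 + |v|^2)` while preserving
#' its direction, mapping any vector into the open unit ball; the zero
#' vector maps to itself (the limit case).
#'
#' @param v Numeric vector, or a matrix whose *columns* are capsule
#'   vectors (each column squashed independently).
#' @return Object of the same shape.
#' @export
squash <- function(v) {
  if (is.matrix(v)) {
    n2 <- colSums(v^2)
    scale <- ifelse(n2 == 0, 0, sqrt(n2) / (1 + n2))
    return(v * rep(scale, each = nrow(v)))
  }
  stopifnot(all(is.finite(v)))
  n2 <- sum(v^2)
  if (n2 == 0) return(v)
  v * (sqrt(n2) / (1 + n2))
}

# squash applied along dim 1 of an array (Dp, ...), returning same shape
squash_dim1 <- function(a) {
  d <- dim(a)
  m <- matrix(a, d[1])
  array(squash(m), d)
}

#' Valid-padding strided convolution (single input)
#'
#' Cross-correlation (no kernel flip) with valid padding and floor
#' division for the output size, bias add, then activation. Output is
#' `floor((H-K)/S)+1 x floor((W-K)/S)+1 x F`.
#'
#' @param input Array `H x W x C` (a matrix is treated as `H x W x 1`).
#' @param W Weight array `K x K x C x F`.
#' @param b Bias vector of length F.
#' @param stride Stride S.
#' @param activation `"relu"` or `"linear"`.
#' @return Array `H' x W' x F`.
#' @export
conv_forward <- function(input, W, b = numeric(dim(W)[4]), stride = 1,
                         activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  if (is.matrix(input)) input <- array(input, c(dim(input), 1))
  x4 <- array(input, c(dim(input), 1))           # batch of one
  y <- conv_forward_batch(x4, W, b, stride, activation)$out
  array(y, dim(y)[1:3])
}

# Batched conv. X: (H, W, C, B); weights (K, K, C, F).
# Returns out (H', W', F, B) and the im2col patch matrix for backprop.
conv_forward_batch <- function(X, W, b, stride, activation = "linear") {
  dX <- dim(X); H <- dX[1]; Wd <- dX[2]; C <- dX[3]; B <- dX[4]
  K <- dim(W)[1]; F <- dim(W)[4]
  Hp <- conv_out_dim(H, K, stride); Wp <- conv_out_dim(Wd, K, stride)
  k2c <- K * K * C
  P <- array(0, c(k2c, Hp, Wp, B))
  for (j in seq_len(Wp)) {
    cj <- (j - 1L) * stride
    for (i in seq_len(Hp)) {
      ri <- (i - 1L) * stride
      P[, i, j, ] <- matrix(X[ri + seq_len(K), cj + seq_len(K), , ,
                              drop = FALSE], k2c, B)
    }
  }
  Pm <- matrix(P, k2c, Hp * Wp * B)
  wmat <- matrix(W, k2c, F)
  Ym <- crossprod(Pm, wmat)                       # (Hp*Wp*B, F)
  Ym <- sweep(Ym, 2, b, "+")
  pre <- aperm(array(Ym, c(Hp, Wp, B, F)), c(1, 2, 4, 3))
  out <- if (activation == "relu") pmax(pre, 0) else pre
  list(out = out, pre = pre, patches = Pm, stride = stride,
       in_dim = dX, out_dim = c(Hp, Wp, F, B))
}

# Gradient of a batched conv. dY: (Hp, Wp, F, B).
# Returns dW, db and (optionally) dX.
conv_backward_batch <- function(fwd, W, dY, need_dx = TRUE) {
  od <- fwd$out_dim; Hp <- od[1]; Wp <- od[2]; F <- od[3]; B <- od[4]
  K <- dim(W)[1]; C <- dim(W)[3]
  dYm <- matrix(aperm(dY, c(1, 2, 4, 3)), Hp * Wp * B, F)
  dW <- array(fwd$patches %*% dYm, dim(W))
  db <- colSums(dYm)
  dX <- NULL
  if (need_dx) {
    dP <- array(matrix(W, K * K * C) %*% t(dYm), c(K * K * C, Hp, Wp, B))
    dX <- array(0, fwd$in_dim)
    s <- fwd$stride
    for (j in seq_len(Wp)) {
      cj <- (j - 1L) * s
      for (i in seq_len(Hp)) {
        ri <- (i - 1L) * s
        dX[ri + seq_len(K), cj + seq_len(K), , ] <-
          dX[ri + seq_len(K), cj + seq_len(K), , , drop = FALSE] +
          array(dP[, i, j, ], c(K, K, C, B))
      }
    }
  }
  list(dW = dW, db = db, dX = dX)
}

#' Form primary capsules from convolutional features
#'
#' Applies the primary-capsule convolution (linear), partitions the
#' resulting feature maps into capsules of dimension `capsule_dim`
#' (contiguous channel groups per spatial position), and squashes each
#' capsule.
#'
#' @param features Array `H x W x C` of conv1 activations.
#' @param W,b Primary-capsule convolution weights `K x K x C x F` and
#'   bias (F must be a multiple of `capsule_dim`).
#' @param stride Convolution stride.
#' @param capsule_dim Capsule dimension D.
#' @return Matrix `D x M` of squashed capsule vectors (columns).
#' @export
primary_capsules <- function(features, W, b = numeric(dim(W)[4]),
                             stride = 1, capsule_dim = 16) {
  F <- dim(W)[4]
  if (F %% capsule_dim != 0)
    stop("filter count ", F, " not divisible by capsule_dim ", capsule_dim)
  conv <- conv_forward(features, W, b, stride, "linear")
  caps_from_maps(array(conv, c(dim(conv), 1)), capsule_dim)[, , 1]
}

# (H', W', F, B) feature maps -> (D, M, B) capsules, squashed.
# Capsule m = (channel group g, spatial position (i, j)); the D channels
# of group g at one position form one capsule vector.
caps_from_maps <- function(maps, capsule_dim) {
  d <- dim(maps)
  A <- aperm(maps, c(3, 1, 2, 4))                     # (F, H', W', B)
  S <- array(A, c(capsule_dim, d[3] %/% capsule_dim * d[1] * d[2], d[4]))
  squash_dim1(S)
}

# inverse of caps_from_maps' reshape for gradients: (D, M, B) -> maps grad
caps_to_maps_grad <- function(dS, map_dim) {
  A <- array(dS, c(map_dim[3], map_dim[1], map_dim[2], map_dim[4]))
  aperm(A, c(2, 3, 1, 4))
}

# prediction vectors u[d2, m, n, b] = sum_p W[p, d2, m, n] * S[p, m, b]
predict_vectors <- function(S, W) {
  Dp <- dim(W)[1]; Dd <- dim(W)[2]; M <- dim(W)[3]; N <- dim(W)[4]
  B <- dim(S)[3]
  U <- array(0, c(Dd, M, N, B))
  for (p in seq_len(Dp)) {
    Wp <- array(W[p, , , ], c(Dd, M, N))
    Sp <- array(S[p, , ], c(M, B))
    Sbig <- aperm(array(Sp, c(M, B, Dd, N)), c(3, 1, 4, 2))
    U <- U + array(Wp, c(Dd, M, N, B)) * Sbig
  }
  U
}

expand_MB <- function(x, M, N, B) {
  # (M, B) -> (M, N, B) by replication over the class axis
  aperm(array(x, c(M, B, N)), c(1, 3, 2))
}

softmax_over_classes <- function(b_log) {
  # b_log: (M, N, B); softmax over the digit-capsule axis N
  d <- dim(b_log); M <- d[1]; N <- d[2]; B <- d[3]
  mx <- apply(b_log, c(1, 3), max)
  e <- exp(b_log - expand_MB(mx, M, N, B))
  den <- apply(e, c(1, 3), sum)
  e / expand_MB(den, M, N, B)
}

# Core routing on prediction vectors. U: (Dd, M, N, B).
# Returns V (Dd, N, B), final couplings C (M, N, B), and per-iteration state.
route_predictions <- function(U, routings, keep_state = FALSE) {
  d <- dim(U); Dd <- d[1]; M <- d[2]; N <- d[3]; B <- d[4]
  b_log <- array(0, c(M, N, B))
  state <- if (keep_state) vector("list", routings)
  V <- array(0, c(Dd, N, B))
  cc <- NULL
  for (r in seq_len(routings)) {
    cc <- softmax_over_classes(b_log)
    for (n in seq_len(N)) {
      un <- array(U[, , n, ], c(Dd, M, B))
      cb <- aperm(array(array(cc[, n, ], c(M, B)), c(M, B, Dd)),
                  c(3, 1, 2))                                 # (Dd, M, B)
      s_n <- colSums(aperm(un * cb, c(2, 1, 3)))              # (Dd, B)
      V[, n, ] <- squash(matrix(s_n, Dd, B))
    }
    agree <- array(0, c(M, N, B))
    for (n in seq_len(N)) {
      un <- array(U[, , n, ], c(Dd, M, B))
      vb <- aperm(array(array(V[, n, ], c(Dd, B)), c(Dd, B, M)),
                  c(1, 3, 2))                                 # (Dd, M, B)
      agree[, n, ] <- array(colSums(un * vb), c(M, B))
    }
    if (keep_state)
      state[[r]] <- list(logits = b_log, couplings = cc, agreement = agree)
    b_log <- b_log + agree
  }
  list(V = V, couplings = cc, state = state)
}

#' Dynamic routing by agreement
#'
#' Iteratively couples primary capsules to digit capsules: prediction
#' vectors `u = W s`, couplings `c` by softmax over the digit axis of
#' logits `b` (initialized to zero), weighted sums `s_j = sum_i c_ij
#' u_j|i`, digit outputs `v_j = squash(s_j)`, then logit updates
#' `b_ij += u_j|i . v_j`, repeated `routings` times.
#'
#' @param primary Matrix `D_in x M` of (already squashed) primary
#'   capsule vectors, one per column.
#' @param W Weight array `D_in x D_out x M x n_classes` of per-pair
#'   transform matrices.
#' @param routings Number of iterations R (>= 1).
#' @param keep_state Record logits/couplings/agreements per iteration.
#' @return List with `digits` (matrix `D_out x n_classes`), `couplings`
#'   (`M x n_classes`, from the final iteration), `norms` (per-class
#'   lengths) and `state` (list per iteration, if kept).
#' @export
dynamic_routing <- function(primary, W, routings = 5, keep_state = TRUE) {
  if (routings < 1) stop("routings must be >= 1")
  stopifnot(is.matrix(primary), dim(W)[1] == nrow(primary),
            dim(W)[3] == ncol(primary))
  S <- array(primary, c(dim(primary), 1))
  U <- predict_vectors(S, W)
  r <- route_predictions(U, routings, keep_state)
  digits <- matrix(r$V[, , 1], dim(W)[2], dim(W)[4])
  st <- if (keep_state) lapply(r$state, function(s)
    list(logits = matrix(s$logits, dim(W)[3]),
         couplings = matrix(s$couplings, dim(W)[3]),
         agreement = matrix(s$agreement, dim(W)[3])))
  list(digits = digits, couplings = matrix(r$couplings, dim(W)[3]),
       norms = sqrt(colSums(digits^2)), state = st)
}

#' Digitize capsule lengths into class indicators
#'
#' Class c is declared present iff `|v_c|^2 > T^2` (strict).
#'
#' @param norms Per-class capsule lengths (vector or `N x B` matrix).
#' @param threshold Cutoff T in (0, 1).
#' @return 0/1 object of the same shape.
#' @export
digitize <- function(norms, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  out <- ifelse(norms^2 > threshold^2, 1L, 0L)
  if (!is.null(dim(norms))) dim(out) <- dim(norms)
  out
}

#' Margin loss on digit-capsule lengths
#'
#' `sum_c [ T_c max(0, m+ - |v_c|)^2 +
#'          lambda (1 - T_c) max(0, |v_c| - m-)^2 ]`
#' summed over classes; with matrix input, averaged over the batch.
#'
#' @param norms Per-class capsule lengths (vector, or `N x B` matrix).
#' @param labels One-hot true labels, same shape.
#' @param m_plus Upper margin for present classes (default 0.9).
#' @param m_minus Lower margin for absent classes (default 0.1).
#' @param lambda_down Down-weight on absent-class terms (default 0.5).
#' @return Non-negative scalar.
#' @export
margin_loss <- function(norms, labels, m_plus = 0.9, m_minus = 0.1,
                        lambda_down = 0.5) {
  stopifnot(length(norms) == length(labels))
  per <- labels * pmax(0, m_plus - norms)^2 +
    lambda_down * (1 - labels) * pmax(0, norms - m_minus)^2
  if (is.matrix(norms)) sum(per) / ncol(norms) else sum(per)
}

# derivative of margin loss wrt norms (same shapes; batch-mean for matrices)
margin_loss_grad <- function(norms, labels, m_plus, m_minus, lambda_down) {
  g <- -2 * labels * pmax(0, m_plus - norms) +
    2 * lambda_down * (1 - labels) * pmax(0, norms - m_minus)
  if (is.matrix(norms)) g / ncol(norms) else g
}
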
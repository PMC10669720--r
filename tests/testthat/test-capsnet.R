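test_that("squash preserves direction and maps norms into [0, 1)", {
  expect_equal(squash(c(0, 0, 0)), c(0, 0, 0))
  v <- c(1, 0)
  expect_equal(sqrt(sum(squash(v)^2)), 0.5)           # |v| = 1 -> 1/2
  w <- c(3, 0, 0)
  expect_equal(sqrt(sum(squash(w)^2)), 0.9)           # 9/(1+9)
  set.seed(21)
  for (i in 1:25) {
    x <- stats::rnorm(sample(2:16, 1)) * 10^stats::runif(1, -2, 2)
    s <- squash(x)
    n <- sqrt(sum(s^2))
    expect_true(n >= 0 && n < 1)
    # direction preserved
    expect_equal(s / n, x / sqrt(sum(x^2)), tolerance = 1e-12)
    expect_equal(s, oracle_squash(x), tolerance = 1e-12)
  }
  # strictly increasing in the input norm
  norms <- sapply(c(0.1, 0.5, 1, 2, 5, 20),
                  function(a) sqrt(sum(squash(c(a, 0))^2)))
  expect_true(all(diff(norms) > 0))
})

test_that("convolution matches the naive loop oracle and the shape chain", {
  set.seed(22)
  x <- array(stats::rnorm(6 * 6 * 2), c(6, 6, 2))
  W <- array(stats::rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
  b <- stats::rnorm(4)
  got <- conv_forward(x, W, b, stride = 1, activation = "relu")
  expect_equal(got, oracle_conv(x, W, b, 1, relu = TRUE), tolerance = 1e-10)
  # stride 2, linear
  got2 <- conv_forward(x, W, b, stride = 2, activation = "linear")
  expect_equal(got2, oracle_conv(x, W, b, 2, relu = FALSE), tolerance = 1e-10)

  # identity: 1x1 kernel of weight 1, bias 0, linear
  idw <- array(1, c(1, 1, 1, 1))
  xm <- matrix(stats::rnorm(12), 4, 3)
  expect_equal(conv_forward(xm, idw, 0, 1, "linear"),
               array(xm, c(4, 3, 1)))

  # kernel larger than input errors
  expect_error(conv_forward(matrix(0, 2, 2), W, b, 1), "kernel larger")

  # 128x16x1 with F=256, K=9, S=2 gives 60x4x256 (shape only)
  sh <- capsnet_shapes(segment_preset("5s")$net)
  expect_equal(sh$conv1, c(60, 4, 256))
  expect_equal(sh$pc_conv, c(57, 1, 256))
  expect_equal(sh$n_primary, 912)
})

test_that("primary capsules reshape and squash the conv features", {
  set.seed(23)
  feats <- array(stats::rnorm(6 * 3 * 4), c(6, 3, 4))
  W <- array(stats::rnorm(2 * 2 * 4 * 8), c(2, 2, 4, 8))
  caps <- primary_capsules(feats, W, stride = 1, capsule_dim = 4)
  sh <- c(5, 2)                        # (6-2)/1+1 x (3-2)/1+1
  expect_equal(dim(caps), c(4, prod(sh) * 8 / 4))
  expect_true(all(colSums(caps^2) < 1))
  # all-zero features -> zero capsules (squash of 0 is 0; bias defaults 0)
  z <- primary_capsules(array(0, c(6, 3, 4)), W, stride = 1, capsule_dim = 4)
  expect_true(all(z == 0))
  # non-divisible capsule dim errors
  expect_error(primary_capsules(feats, W, stride = 1, capsule_dim = 3),
               "divisible")
})

test_that("dynamic routing equals the line-by-line oracle on random instances", {
  set.seed(24)
  for (i in 1:30) {
    M <- sample(2:16, 1); Dp <- sample(2:6, 1); Dd <- sample(2:6, 1)
    N <- 2; R <- sample(1:5, 1)
    primary <- squash(matrix(stats::rnorm(Dp * M), Dp, M))
    W <- array(stats::rnorm(Dp * Dd * M * N, sd = 0.5), c(Dp, Dd, M, N))
    got <- dynamic_routing(primary, W, routings = R)
    want <- oracle_routing(primary, W, R)
    expect_equal(got$digits, want$digits, tolerance = 1e-8)
    expect_equal(got$couplings, want$couplings, tolerance = 1e-8)
    # coupling rows sum to 1 at every recorded iteration
    for (st in got$state)
      expect_equal(rowSums(st$couplings), rep(1, M), tolerance = 1e-12)
  }
})

test_that("routing limit cases behave as the equations dictate", {
  set.seed(25)
  # first-iteration couplings are uniform (softmax of zero logits)
  primary <- squash(matrix(stats::rnorm(4 * 6), 4, 6))
  W <- array(stats::rnorm(4 * 4 * 6 * 2), c(4, 4, 6, 2))
  rt <- dynamic_routing(primary, W, routings = 3)
  expect_equal(rt$state[[1]]$couplings,
               matrix(0.5, 6, 2), tolerance = 1e-12)

  # single primary capsule, single digit capsule, identity transform:
  # coupling is 1, so the output is squash applied twice
  s <- squash(c(0.3, -0.8, 0.5))
  Wid1 <- array(diag(3), c(3, 3, 1, 1))
  rt1 <- dynamic_routing(matrix(s, 3, 1), Wid1, routings = 1)
  expect_equal(rt1$digits[, 1], squash(s), tolerance = 1e-12)

  # with two digit capsules the couplings split 0.5/0.5, so each class
  # receives half the prediction vector before its squash
  Wid <- array(0, c(3, 3, 1, 2))
  Wid[, , 1, 1] <- diag(3); Wid[, , 1, 2] <- diag(3)
  rt2 <- dynamic_routing(matrix(s, 3, 1), Wid, routings = 1)
  expect_equal(rt2$digits[, 1], squash(0.5 * s), tolerance = 1e-12)
  expect_equal(rt2$digits[, 2], squash(0.5 * s), tolerance = 1e-12)

  expect_error(dynamic_routing(matrix(s, 3, 1), Wid, routings = 0), ">= 1")
})

test_that("digitization thresholds squared capsule lengths strictly", {
  expect_equal(digitize(c(0.9, 0.2), 0.5), c(1L, 0L))
  expect_equal(digitize(0.5, 0.5), 0L)       # boundary: strict inequality
  expect_equal(digitize(c(0.001, 0.9), 1e-6), c(1L, 1L))
  expect_error(digitize(0.5, 0), "threshold")
})

test_that("margin loss follows the hinge arithmetic and its monotonicity", {
  # both margins satisfied -> 0
  expect_equal(margin_loss(c(0.95, 0.05), c(1, 0)), 0)
  # hand arithmetic: (0.9-0.5)^2 + 0.5*(0.5-0.1)^2
  expect_equal(margin_loss(c(0.5, 0.5), c(1, 0)), 0.24)
  expect_gte(margin_loss(c(0.2, 0.8), c(1, 0)), 0)
  # non-increasing in the true-class norm, non-decreasing in the false
  tt <- sapply(seq(0, 0.95, 0.05),
               function(v) margin_loss(c(v, 0.5), c(1, 0)))
  expect_true(all(diff(tt) <= 1e-12))
  ff <- sapply(seq(0, 0.95, 0.05),
               function(v) margin_loss(c(0.5, v), c(1, 0)))
  expect_true(all(diff(ff) >= -1e-12))
  # zero iff both margins met at defaults
  expect_gt(margin_loss(c(0.89, 0.05), c(1, 0)), 0)
  expect_gt(margin_loss(c(0.95, 0.11), c(1, 0)), 0)
})

test_that("parameter audit reproduces the reference architecture counts", {
  df <- count_params(segment_preset("5s")$net)
  p <- stats::setNames(df$params, df$layer)
  expect_equal(unname(p["conv1"]), 20992)
  expect_equal(unname(p["primarycap_conv2d"]), 1048832)
  expect_equal(unname(p["digitcaps"]), 466944)
  expect_equal(unname(p["decoder"]), 6329344)
  expect_equal(attr(df, "total"), 7866112)
  expect_equal(attr(df, "n_primary"), 912)
  # decoder widths: independent dense-stack arithmetic
  expect_equal((32 + 1) * 1024 + (1024 + 1) * 2048 + (2048 + 1) * 2048,
               6329344)
})

test_that("full forward pass is pure and respects output contracts", {
  cfg <- tiny_net_config()
  model <- init_capsnet(cfg, seed = 5)
  set.seed(26)
  x <- matrix(stats::rnorm(12 * 6), 12, 6)
  out1 <- capsnet_forward(model, x)
  out2 <- capsnet_forward(model, x)
  expect_identical(out1$norms, out2$norms)            # purity
  expect_true(all(out1$norms >= 0 & out1$norms < 1))  # squash range
  expect_equal(dim(out1$reconstruction), c(12, 6))
  expect_equal(out1$prediction, digitize(out1$norms, cfg$threshold))
  expect_error(capsnet_forward(model, matrix(0, 5, 5)), "expects")

  # translation probe: a one-frame circular shift changes digit norms
  # only boundedly (smoke property, no exact equivariance claim)
  xs <- x[, c(2:6, 1)]
  outs <- capsnet_forward(model, xs)
  expect_lt(max(abs(outs$norms - out1$norms)), 0.5)
})

test_that("model initialization is reproducible from its seed alone", {
  cfg <- tiny_net_config()
  m1 <- init_capsnet(cfg, seed = 9)
  m2 <- init_capsnet(cfg, seed = 9)
  expect_identical(m1$params, m2$params)
  m3 <- init_capsnet(cfg, seed = 10)
  expect_false(identical(m1$params$conv1_W, m3$params$conv1_W))
})
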
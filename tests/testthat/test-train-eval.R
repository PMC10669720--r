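test_that("learning-rate policies follow their printed semantics", {
  cfg <- train_config()
  # plateau: after 3 stagnant epochs 0.0025 -> 0.0025 * 0.15 = 0.000375
  expect_equal(lr_schedule("plateau", c(1.0, 1.0, 1.0, 1.0), cfg), 0.000375)
  # improving validation loss: rate never changes
  expect_equal(lr_schedule("plateau", c(1.0, 0.9, 0.8, 0.7), cfg), 0.0025)
  # fixed: constant regardless of history
  expect_equal(lr_schedule("fixed", c(5, 4, 3, 2, 1, 1, 1, 1), cfg), 0.0025)
  expect_equal(lr_schedule("fixed", numeric(0), cfg), 0.0025)
  # decay: initial 0.005, x0.1 every decay_interval epochs
  expect_equal(lr_schedule("decay", numeric(0), cfg), 0.005)
  expect_equal(lr_schedule("decay", rep(1, 30), cfg), 0.0005)
  expect_equal(lr_schedule("decay", rep(1, 60), cfg), 5e-05)
  expect_error(lr_schedule("exotic", 1, cfg), "unknown")
})

test_that("confusion-matrix metrics reproduce the reference arithmetic", {
  cm <- confusion_matrix(2507, 41, 447, 2029)
  m <- metrics_from_confusion(cm)
  expect_equal(round(100 * m$precision, 2), 98.39)
  expect_equal(round(100 * m$recall, 2), 84.87)
  expect_equal(round(100 * m$abnormal_precision, 2), 81.95)
  expect_equal(round(100 * m$specificity, 2), 98.02)
  expect_equal(round(100 * m$accuracy, 2), 90.29)
  expect_equal(m$accuracy, (2507 + 2029) / 5024)

  # degenerate cases
  all1 <- metrics_from_confusion(confusion_matrix(1, 0, 0, 1))
  expect_true(all(unlist(all1) == 1))
  zero <- metrics_from_confusion(confusion_matrix(0, 0, 0, 0))
  expect_true(all(is.na(unlist(zero))))
  # one-sided zero denominator: undefined, not 0
  expect_true(is.na(metrics_from_confusion(confusion_matrix(0, 0, 5, 5))$precision))
})

test_that("accuracy is invariant to class relabeling of the confusion matrix", {
  set.seed(41)
  for (i in 1:20) {
    v <- sample(0:50, 4, replace = TRUE)
    a <- metrics_from_confusion(confusion_matrix(v[1], v[2], v[3], v[4]))
    b <- metrics_from_confusion(confusion_matrix(v[4], v[3], v[2], v[1]))
    if (!is.na(a$accuracy)) expect_equal(a$accuracy, b$accuracy)
  }
})

test_that("threshold-sweep AUC equals the Mann-Whitney formulation and pROC", {
  set.seed(42)
  for (i in 1:10) {
    n <- 60
    pos <- c(rep(TRUE, 25), rep(FALSE, 35))
    scores <- stats::rnorm(n) + ifelse(pos, stats::runif(1, 0, 2), 0)
    rc <- roc_curve(scores, pos)
    expect_equal(rc$auc, oracle_auc_mw(scores, pos), tolerance = 1e-9)
    # ROC monotone non-decreasing in both coordinates
    expect_true(all(diff(rc$roc$fpr) >= 0))
    expect_true(all(diff(rc$roc$tpr) >= 0))
  }
  if (requireNamespace("pROC", quietly = TRUE)) {
    scores <- stats::rnorm(80) + rep(c(1, 0), each = 40)
    pos <- rep(c(TRUE, FALSE), each = 40)
    got <- roc_curve(scores, pos)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(response = pos,
                                          predictor = scores,
                                          quiet = TRUE,
                                          direction = "<")))
    expect_equal(got, ref, tolerance = 1e-9)
  }
  # perfect separation
  expect_equal(roc_curve(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$auc, 1)
  # random scores, balanced labels: null AUC ~ 0.5
  set.seed(43)
  s <- stats::runif(10000)
  expect_lt(abs(roc_curve(s, rep(c(TRUE, FALSE), 5000))$auc - 0.5), 0.02)
})

test_that("evaluate_model builds the report from capsule-length scores", {
  spectra <- synthetic_spectra(15, seed = 91)
  cfg <- reduced_net_config()
  model <- init_capsnet(cfg, seed = 8)
  fit <- fit_capsnet(model, spectra, NULL,
                     train_config(epochs = 4, lr_policy = "fixed",
                                  routings = 2, early_stop_gap = Inf,
                                  seed = 2))
  rep <- evaluate_model(fit$model, spectra)
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$confusion$total, 30)
  expect_true(rep$auc >= 0 && rep$auc <= 1)
  expect_true(all(diff(rep$roc$fpr) >= 0))
  expect_gte(rep$metrics$accuracy, 0.9)    # trivially separable set

  # unlabeled data refused
  unl <- spectra[1:2]
  unl[[1]]$label <- NA
  expect_error(evaluate_model(fit$model, unl), "unlabeled")

  # report writing round-trip
  dir <- withr::local_tempdir()
  write_eval_report(rep, dir)
  expect_true(file.exists(file.path(dir, "confusion.csv")))
  js <- jsonlite::fromJSON(file.path(dir, "report.json"))
  expect_equal(js$accuracy, rep$metrics$accuracy)
})

test_that("early stopping reacts to the loss gap, never when losses agree", {
  # identical train/val (val = NULL): gap 0, runs to the epoch limit
  spectra <- synthetic_spectra(15, seed = 91)[1:10]
  model <- init_capsnet(reduced_net_config(), seed = 3)
  res <- fit_capsnet(model, spectra, NULL,
                     train_config(epochs = 2, lr_policy = "fixed",
                                  routings = 2, seed = 1))
  expect_false(res$stopped_early)
  expect_equal(nrow(res$history), 2)
})

test_that("seeded fit runs are reproducible", {
  spectra <- synthetic_spectra(15, seed = 91)[c(1:6, 16:21)]
  cfg <- train_config(epochs = 2, lr_policy = "fixed", routings = 2,
                      early_stop_gap = Inf, seed = 5)
  r1 <- fit_capsnet(init_capsnet(reduced_net_config(), seed = 4),
                    spectra, NULL, cfg)
  r2 <- fit_capsnet(init_capsnet(reduced_net_config(), seed = 4),
                    spectra, NULL, cfg)
  expect_identical(r1$history, r2$history)
})
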
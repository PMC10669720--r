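#' Training configuration
#'
#' Defaults follow the reference hyperparameters: Adam with initial
#' learning rate 0.0025, 100 epochs, 5 routing iterations, and a
#' plateau learning-rate policy (factor 0.15, patience 3). Early
#' stopping halts training when the gap between validation and training
#' margin loss exceeds `early_stop_gap` (15%), by default relative to
#' the training loss.
#'
#' @param learning_rate Initial learning rate (> 0).
#' @param epochs Maximum number of epochs (>= 1).
#' @param routings Routing iterations used during training.
#' @param batch_size Minibatch size; `NULL` uses the model preset's.
#' @param lr_policy One of `"plateau"`, `"decay"`, `"fixed"`.
#' @param plateau_factor,plateau_patience Plateau policy: multiply the
#'   rate by `plateau_factor` after `plateau_patience` consecutive
#'   epochs without validation-loss improvement.
#' @param decay_initial,decay_factor,decay_interval Decay policy:
#'   start at `decay_initial`, multiply by `decay_factor` every
#'   `decay_interval` epochs.
#' @param early_stop_gap Loss-gap fraction that triggers early stopping
#'   (`Inf` disables).
#' @param gap_mode `"relative"` (gap / train loss) or `"absolute"`.
#' @param restore_best Restore the best-validation-loss weights on stop.
#' @param seed RNG seed for shuffling.
#' @param verbose Print per-epoch progress.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.0025, epochs = 100, routings = 5,
                         batch_size = NULL,
                         lr_policy = c("plateau", "decay", "fixed"),
                         plateau_factor = 0.15, plateau_patience = 3,
                         decay_initial = 0.005, decay_factor = 0.1,
                         decay_interval = 30,
                         early_stop_gap = 0.15,
                         gap_mode = c("relative", "absolute"),
                         restore_best = TRUE, seed = 1L, verbose = FALSE) {
  lr_policy <- match.arg(lr_policy)
  gap_mode <- match.arg(gap_mode)
  stopifnot(learning_rate >= 0, epochs >= 1,
            plateau_factor > 0, plateau_factor < 1, plateau_patience >= 1)
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 routings = routings, batch_size = batch_size,
                 lr_policy = lr_policy, plateau_factor = plateau_factor,
                 plateau_patience = plateau_patience,
                 decay_initial = decay_initial, decay_factor = decay_factor,
                 decay_interval = decay_interval,
                 early_stop_gap = early_stop_gap, gap_mode = gap_mode,
                 restore_best = restore_best, seed = seed,
                 verbose = verbose),
            class = "train_config")
}

#' Next learning rate under a policy
#'
#' Replays the policy over the validation-loss history so far and
#' returns the learning rate for the next epoch. `plateau` multiplies
#' the current rate by `plateau_factor` after `plateau_patience`
#' consecutive epochs without improvement; `decay` multiplies
#' `decay_initial` by `decay_factor` every `decay_interval` epochs;
#' `fixed` always returns `learning_rate`.
#'
#' @param policy One of `"plateau"`, `"decay"`, `"fixed"`.
#' @param val_losses Numeric vector of per-epoch validation losses so
#'   far (possibly empty).
#' @param config A [train_config()].
#' @return The learning rate for the next epoch.
#' @export
lr_schedule <- function(policy, val_losses, config = train_config()) {
  if (!policy %in% c("plateau", "decay", "fixed"))
    stop("unknown learning-rate policy: ", policy)
  n <- length(val_losses)
  if (policy == "fixed") return(config$learning_rate)
  if (policy == "decay")
    return(config$decay_initial *
             config$decay_factor^(n %/% config$decay_interval))
  lr <- config$learning_rate
  best <- Inf; wait <- 0L
  for (L in val_losses) {
    if (L < best) {
      best <- L; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$plateau_patience) {
        lr <- lr * config$plateau_factor
        wait <- 0L
      }
    }
  }
  lr
}

# stack a list of mfcc_spectrum into (H, W, 1, n) + labels
spectra_to_array <- function(dataset, require_labels = TRUE) {
  stopifnot(length(dataset) >= 1)
  v1 <- dataset[[1]]$values
  X <- array(0, c(nrow(v1), ncol(v1), 1, length(dataset)))
  y <- rep(NA_real_, length(dataset))
  ids <- character(length(dataset))
  for (i in seq_along(dataset)) {
    X[, , 1, i] <- dataset[[i]]$values
    y[i] <- dataset[[i]]$label
    ids[i] <- dataset[[i]]$source_id %||% as.character(i)
  }
  if (require_labels && any(is.na(y)))
    stop("dataset contains unlabeled spectra")
  list(X = X, y = y, ids = ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

onehot <- function(y, n_classes = 2) {
  # class index = label + 1 (0 = normal -> class 1, 1 = abnormal -> class 2)
  L <- matrix(0, n_classes, length(y))
  L[cbind(y + 1, seq_along(y))] <- 1
  L
}

# margin loss + argmax accuracy over a full set, in minibatches
eval_loss_acc <- function(model, X, y, batch = 64) {
  n <- dim(X)[4]
  cfg <- model$config
  tot_margin <- 0; correct <- 0
  norms_all <- matrix(0, cfg$n_classes, n)
  for (s in seq(1, n, by = batch)) {
    idx <- s:min(s + batch - 1, n)
    fw <- capsnet_batch_forward(model,
                                X[, , , idx, drop = FALSE],
                                onehot(y[idx], cfg$n_classes))
    tot_margin <- tot_margin + fw$margin * length(idx)
    pred <- apply(fw$norms, 2, which.max) - 1
    correct <- correct + sum(pred == y[idx])
    norms_all[, idx] <- fw$norms
  }
  list(loss = tot_margin / n, acc = correct / n, norms = norms_all)
}

#' Train a capsule network
#'
#' Minibatch Adam on the total loss (margin loss plus `w_rec` times the
#' reconstruction error). Per-epoch history records training and
#' validation margin loss and accuracy and the learning rate. Training
#' halts at the epoch limit or when the validation/training loss gap
#' exceeds `early_stop_gap`; the best-validation weights are restored
#' if `restore_best`.
#'
#' @param model A `capsnet_model` from [init_capsnet()].
#' @param train_set List of labeled [mfcc_spectrum] objects.
#' @param val_set Validation list; `NULL` reuses the training set (and
#'   disables early stopping, since the gap is then zero).
#' @param config A [train_config()].
#' @return List with `model` (trained), `history` (data.frame), and
#'   `stopped_early`.
#' @export
fit_capsnet <- function(model, train_set, val_set = NULL,
                        config = train_config()) {
  if (length(train_set) == 0) stop("empty training set")
  cfg <- model$config
  if (!is.null(config$routings)) model$config$routings <- config$routings
  batch <- config$batch_size %||% cfg$batch_size
  tr <- spectra_to_array(train_set)
  va <- if (is.null(val_set)) tr else spectra_to_array(val_set)
  same_val <- is.null(val_set)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  opt <- adam_init(model$params)
  n <- dim(tr$X)[4]
  hist_rows <- list()
  val_losses <- numeric(0)
  best_val <- Inf; best_params <- model$params
  stopped_early <- FALSE

  for (epoch in seq_len(config$epochs)) {
    lr <- lr_schedule(config$lr_policy, val_losses, config)
    perm <- sample.int(n)
    for (s in seq(1, n, by = batch)) {
      idx <- perm[s:min(s + batch - 1, n)]
      fw <- capsnet_batch_forward(model,
                                  tr$X[, , , idx, drop = FALSE],
                                  onehot(tr$y[idx], cfg$n_classes))
      if (!is.finite(fw$loss))
        stop(sprintf("non-finite loss at epoch %d (margin %.4g, recon %.4g); aborting",
                     epoch, fw$margin, fw$recon_sse))
      gr <- capsnet_batch_backward(model, fw)
      upd <- adam_step(model$params, gr, opt, lr)
      model$params <- upd$params
      opt <- upd$state
    }
    tr_m <- eval_loss_acc(model, tr$X, tr$y)
    va_m <- if (same_val) tr_m else eval_loss_acc(model, va$X, va$y)
    val_losses <- c(val_losses, va_m$loss)
    hist_rows[[epoch]] <- data.frame(
      epoch = epoch, lr = lr,
      train_loss = tr_m$loss, val_loss = va_m$loss,
      train_acc = tr_m$acc, val_acc = va_m$acc)
    if (config$verbose)
      message(sprintf("epoch %3d lr %.5g train %.4f/%.3f val %.4f/%.3f",
                      epoch, lr, tr_m$loss, tr_m$acc, va_m$loss, va_m$acc))
    if (va_m$loss < best_val) {
      best_val <- va_m$loss
      best_params <- model$params
    }
    gap <- abs(va_m$loss - tr_m$loss)
    if (config$gap_mode == "relative")
      gap <- if (tr_m$loss > 0) gap / tr_m$loss else 0
    if (gap > config$early_stop_gap) {
      stopped_early <- TRUE
      break
    }
  }
  if (config$restore_best) model$params <- best_params
  list(model = model, history = do.call(rbind, hist_rows),
       stopped_early = stopped_early)
}

#' Confusion matrix (normal = positive class)
#'
#' @param tp,fp,fn,tn Non-negative counts. `tp` counts recordings that
#'   are truly normal and predicted normal; `tn` truly abnormal and
#'   predicted abnormal.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 total = tp + fp + fn + tn), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2,
              dimnames = list(truth = c("normal", "abnormal"),
                              predicted = c("normal", "abnormal")))
  print(m)
  invisible(x)
}

#' Metrics from a confusion matrix
#'
#' Pure arithmetic with normal as the positive class:
#' precision = TP/(TP+FP), recall = TP/(TP+FN), abnormal precision =
#' TN/(TN+FN), specificity = TN/(TN+FP), accuracy = (TP+TN)/total, F1 =
#' harmonic mean of precision and recall. A zero denominator yields
#' `NA` (undefined), never 0.
#'
#' @param cm A [confusion_matrix()].
#' @return List of metrics in `[0, 1]` (or `NA`).
#' @export
metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$total == 0) {
    return(list(precision = NA_real_, recall = NA_real_, f1 = NA_real_,
                accuracy = NA_real_, abnormal_precision = NA_real_,
                specificity = NA_real_))
  }
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  precision <- div(cm$tp, cm$tp + cm$fp)
  recall <- div(cm$tp, cm$tp + cm$fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  list(precision = precision,
       recall = recall,
       f1 = f1,
       accuracy = div(cm$tp + cm$tn, cm$total),
       abnormal_precision = div(cm$tn, cm$tn + cm$fn),
       specificity = div(cm$tn, cm$tn + cm$fp))
}

#' ROC curve and AUC from scores
#'
#' Sweeps every observed score as a threshold (predict positive iff
#' score > t) and integrates TPR over FPR by the trapezoidal rule.
#'
#' @param scores Continuous scores, larger = more positive.
#' @param positive Logical (or 0/1) truth: `TRUE` = positive class.
#' @return List with `roc` (data.frame threshold/fpr/tpr) and `auc`.
#' @export
roc_curve <- function(scores, positive) {
  positive <- as.logical(positive)
  stopifnot(length(scores) == length(positive),
            any(positive), any(!positive))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  tpr <- vapply(thr, function(t) sum(scores > t & positive) / n_pos,
                numeric(1))
  fpr <- vapply(thr, function(t) sum(scores > t & !positive) / n_neg,
                numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr), auc = auc)
}

#' Evaluate a trained model on a labeled set
#'
#' Scores every spectrum with the normal-class capsule length, builds
#' the confusion matrix at the digitization threshold (predict normal
#' iff `|v_normal|^2 > T^2`), derives the margin metrics, and sweeps the
#' score for the ROC curve and AUC.
#'
#' @param model A trained `capsnet_model`.
#' @param labeled_set List of labeled [mfcc_spectrum] objects.
#' @param threshold Digitization threshold T; defaults to the model's.
#' @param by_recording Aggregate segment predictions to recordings by
#'   majority vote before computing the confusion matrix (ROC stays
#'   segment-level).
#' @return An object of class `eval_report`: `confusion`, `metrics`,
#'   `roc`, `auc`, `scores`, `labels`.
#' @export
evaluate_model <- function(model, labeled_set, threshold = NULL,
                           by_recording = FALSE) {
  threshold <- threshold %||% model$config$threshold
  dd <- spectra_to_array(labeled_set, require_labels = TRUE)
  em <- eval_loss_acc(model, dd$X, dd$y)
  scores <- em$norms[1, ]                 # normal-class capsule length
  pred_normal <- scores^2 > threshold^2
  truth_normal <- dd$y == 0
  if (by_recording) {
    rec <- sub("_seg[0-9]+$", "", dd$ids)
    pred_normal <- tapply(pred_normal, rec, function(v) mean(v) >= 0.5)
    truth_normal <- tapply(truth_normal, rec, function(v) mean(v) >= 0.5)
  }
  cm <- confusion_matrix(tp = sum(pred_normal & truth_normal),
                         fp = sum(pred_normal & !truth_normal),
                         fn = sum(!pred_normal & truth_normal),
                         tn = sum(!pred_normal & !truth_normal))
  rc <- if (any(dd$y == 0) && any(dd$y == 1)) {
    roc_curve(em$norms[1, ], dd$y == 0)
  } else {
    # single-class set: ROC/AUC undefined
    list(roc = data.frame(threshold = numeric(0), fpr = numeric(0),
                          tpr = numeric(0)), auc = NA_real_)
  }
  structure(list(confusion = cm, metrics = metrics_from_confusion(cm),
                 roc = rc$roc, auc = rc$auc,
                 scores = em$norms[1, ], labels = dd$y,
                 threshold = threshold),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  print(x$confusion)
  m <- x$metrics
  cat(sprintf("accuracy %.4f  precision %.4f  recall %.4f  f1 %.4f\n",
              m$accuracy, m$precision, m$recall, m$f1))
  cat(sprintf("abnormal precision %.4f  specificity %.4f  AUC %.4f\n",
              m$abnormal_precision, m$specificity, x$auc))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' @param report An [evaluate_model()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- report$confusion
  utils::write.csv(data.frame(tp = cm$tp, fp = cm$fp, fn = cm$fn,
                              tn = cm$tn),
                   file.path(dir, "confusion.csv"), row.names = FALSE)
  utils::write.csv(report$roc, file.path(dir, "roc.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(report$metrics, list(auc = report$auc, threshold = report$threshold)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
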
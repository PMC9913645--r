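## SGD training loop: momentum, weight decay, step learning-rate schedule,
## imbalance strategy plumbing, per-epoch logging and best-AUC checkpointing.

#' Training hyper-parameters
#'
#' Defaults follow the published recipe: SGD with initial learning rate
#' 0.01, momentum 0.9, weight decay 5e-4, batch size 128, and a step
#' schedule dividing the rate by 10 at epochs 50, 100 and 150 with a 1e-5
#' floor. A linear-decay alternative (`schedule = "linear"`, from `lr0` down
#' to `lr_floor` across the run) is available.
#'
#' @param lr0 Initial learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay added to every parameter gradient.
#' @param batch_size Mini-batch size.
#' @param milestones Epochs at which the step schedule divides the rate by 10.
#' @param lr_floor Minimal learning rate.
#' @param epochs Total epochs (default 200, covering all milestones).
#' @param seed Seed controlling shuffling, oversampling and augmentation.
#' @param imbalance One of `"gradient_penalty"` (oversampling + penalty, the
#'   default), `"oversample"`, `"reweight"` (oversampling + class-reverse
#'   loss weights), `"none"`.
#' @param epsilon,lambda Gradient-penalty similarity threshold and shrink
#'   factor (see [penalty_factors()]).
#' @param penalty_scope Parameter scope for per-sample gradients
#'   (see [per_sample_gradients()]).
#' @param penalty_rule `"flat"` or `"power"` (see [penalty_factors()]).
#' @param schedule `"step"` or `"linear"`.
#' @param reduction Loss reduction, `"mean"` (default) or `"sum"`.
#' @param augment_cfg Optional [augment_config()] applied to every training
#'   batch; `NULL` disables augmentation.
#' @param verbose Print a line per epoch.
#' @return List of class `"rtn_train_config"`.
#' @export
rtn_train_config <- function(lr0 = 0.01, momentum = 0.9, weight_decay = 5e-4,
                             batch_size = 128L, milestones = c(50L, 100L, 150L),
                             lr_floor = 1e-5, epochs = 200L, seed = 1L,
                             imbalance = c("gradient_penalty", "oversample",
                                           "reweight", "none"),
                             epsilon = 0.9, lambda = 0.5,
                             penalty_scope = "head_last",
                             penalty_rule = "flat",
                             schedule = c("step", "linear"),
                             reduction = c("mean", "sum"),
                             augment_cfg = NULL, verbose = FALSE) {
  imbalance <- match.arg(imbalance)
  schedule <- match.arg(schedule)
  reduction <- match.arg(reduction)
  if (lr0 <= 0 || momentum < 0 || weight_decay < 0 || batch_size < 1 ||
      epochs < 1 || lr_floor <= 0)
    stop("rates, sizes and epochs must be positive")
  if (is.unsorted(milestones, strictly = TRUE)) stop("milestones must increase")
  structure(list(lr0 = lr0, momentum = momentum, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), milestones = milestones,
                 lr_floor = lr_floor, epochs = as.integer(epochs),
                 seed = as.integer(seed), imbalance = imbalance,
                 epsilon = epsilon, lambda = lambda,
                 penalty_scope = penalty_scope, penalty_rule = penalty_rule,
                 schedule = schedule, reduction = reduction,
                 augment_cfg = augment_cfg, verbose = verbose),
            class = "rtn_train_config")
}

#' Learning rate at a given epoch
#'
#' Step schedule: `lr0` before the first milestone, divided by 10 at each
#' milestone passed, never below `lr_floor`. Linear schedule: straight-line
#' decay from `lr0` (epoch 1) to `lr_floor` (final epoch).
#'
#' @param epoch Epoch number (1-based).
#' @param config An [rtn_train_config()].
#' @return Learning rate.
#' @export
lr_at <- function(epoch, config) {
  if (config$schedule == "linear") {
    if (config$epochs <= 1) return(config$lr0)
    return(max(config$lr_floor,
               config$lr0 + (config$lr_floor - config$lr0) *
                 (epoch - 1) / (config$epochs - 1)))
  }
  max(config$lr_floor, config$lr0 * 0.1^sum(epoch >= config$milestones))
}

safe_auc <- function(scores, labels) {
  if (length(unique(labels)) < 2 || length(unique(scores)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c(0, 1),
                                 direction = "<", quiet = TRUE)))
}

#' Predicted positive-class probabilities
#'
#' Deterministic evaluation-mode forward pass, batched.
#'
#' @param model An `rtn_model`.
#' @param x Images (matrix, array, cohort, or tall matrix).
#' @param batch_size Evaluation batch size.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
rtn_predict <- function(model, x, batch_size = 64L) {
  xm <- as_image_batch(x, model$config$img_size)
  N <- ncol(xm)
  out <- numeric(N)
  for (s in seq(1L, N, by = batch_size)) {
    ii <- s:min(s + batch_size - 1L, N)
    fw <- rtn_forward(model, xm[, ii, drop = FALSE], train = FALSE)
    out[ii] <- softmax_rows(fw$logits)[, 2]
  }
  out
}

augment_batch <- function(xb, size, cfg) {
  for (j in seq_len(ncol(xb)))
    xb[, j] <- as.numeric(augment(matrix(xb[, j], size, size), cfg))
  xb
}

#' Train a network
#'
#' One SGD epoch iterates mini-batches drawn according to the configured
#' imbalance strategy (all strategies except `"none"` rebalance each epoch by
#' minority oversampling; `"reweight"` additionally applies class-reverse
#' loss weights computed from the original class counts; `"gradient_penalty"`
#' additionally shrinks per-sample gradients whose pairwise cosine similarity
#' exceeds `epsilon`). Per-epoch loss/ACC/AUC are logged for the training
#' stream and, when given, a held-out test set; the parameters achieving the
#' best test AUC are checkpointed.
#'
#' @param model An `rtn_model` from [rtn_build()].
#' @param images Training images (array `(H,W,N)` or tall matrix).
#' @param labels Binary labels, length N.
#' @param config An [rtn_train_config()].
#' @param test Optional list with `images` and `labels` for held-out
#'   monitoring.
#' @return List of class `"rtn_trained"`: `model` (final parameters),
#'   `best` (`params`, `state`, `epoch`, `auc` at the best test AUC, when a
#'   test set was supplied), `history` (one row per epoch), `config`.
#' @export
rtn_train <- function(model, images, labels, config = rtn_train_config(),
                      test = NULL) {
  size <- model$config$img_size
  X <- as_image_batch(images, size)
  y <- as.integer(labels)
  N <- ncol(X)
  if (N == 0 || N != length(y)) stop("images/labels mismatch or empty train set")
  set.seed(config$seed)
  vel <- lapply(model$params, function(p) p * 0)
  cw <- NULL
  if (config$imbalance == "reweight")
    cw <- reverse_weights(c(sum(y == 0), sum(y == 1)))
  hist_rows <- vector("list", config$epochs)
  best <- list(auc = -Inf, params = NULL, state = NULL, epoch = NA_integer_)
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_at(epoch, config)
    ord <- if (config$imbalance == "none") sample(N) else oversample_indices(y)
    ep_loss <- 0; ep_n <- 0L
    tr_scores <- numeric(0); tr_labels <- integer(0)
    for (s in seq(1L, length(ord), by = config$batch_size)) {
      ii <- ord[s:min(s + config$batch_size - 1L, length(ord))]
      if (length(ii) < 2L) next   # batch norm needs > 1 sample
      xb <- X[, ii, drop = FALSE]
      if (!is.null(config$augment_cfg))
        xb <- augment_batch(xb, size, config$augment_cfg)
      yb <- y[ii]
      B <- length(ii)
      fw <- rtn_forward(model, xb, train = TRUE, keep = TRUE)
      model$state <- fw$state
      probs <- softmax_rows(fw$logits)
      p1 <- probs[, 2]
      w <- if (is.null(cw)) rep(1, B) else cw[yb + 1]
      loss <- ce_loss(p1, yb, class_weights = cw, reduction = config$reduction)
      if (!is.finite(loss))
        stop("training diverged (non-finite loss) at epoch ", epoch,
             "; lower the learning rate")
      dlog <- probs
      dlog[cbind(seq_len(B), yb + 1L)] <- dlog[cbind(seq_len(B), yb + 1L)] - 1
      dlog <- dlog * w
      if (config$imbalance == "gradient_penalty") {
        G <- per_sample_gradients(model, fw$cache, dlog, config$penalty_scope)
        f <- penalty_factors(cosine_similarity_matrix(G),
                             config$epsilon, config$lambda, config$penalty_rule)
        dlog <- dlog * f
      }
      if (config$reduction == "mean") dlog <- dlog / B
      grads <- rtn_backward(model, fw$cache, dlog)
      for (nm in names(model$params)) {
        vel[[nm]] <- config$momentum * vel[[nm]] -
          lr * (grads[[nm]] + config$weight_decay * model$params[[nm]])
        model$params[[nm]] <- model$params[[nm]] + vel[[nm]]
      }
      ep_loss <- ep_loss + loss * B; ep_n <- ep_n + B
      tr_scores <- c(tr_scores, p1); tr_labels <- c(tr_labels, yb)
    }
    row <- data.frame(epoch = epoch, lr = lr,
                      train_loss = ep_loss / max(ep_n, 1L),
                      train_acc = mean((tr_scores >= 0.5) == (tr_labels == 1)),
                      train_auc = safe_auc(tr_scores, tr_labels),
                      test_loss = NA_real_, test_acc = NA_real_,
                      test_auc = NA_real_)
    if (!is.null(test)) {
      ts <- rtn_predict(model, test$images, config$batch_size)
      tl <- as.integer(test$labels)
      row$test_loss <- ce_loss(ts, tl)
      row$test_acc <- mean((ts >= 0.5) == (tl == 1))
      row$test_auc <- safe_auc(ts, tl)
      if (is.finite(row$test_auc) && row$test_auc > best$auc)
        best <- list(auc = row$test_auc, params = model$params,
                     state = model$state, epoch = epoch)
    }
    hist_rows[[epoch]] <- row
    if (config$verbose)
      message(sprintf("epoch %3d lr %.5f loss %.4f train AUC %.3f test AUC %s",
                      epoch, lr, row$train_loss, row$train_auc,
                      ifelse(is.na(row$test_auc), "-", sprintf("%.3f", row$test_auc))))
  }
  structure(list(model = model,
                 best = if (is.finite(best$auc)) best else NULL,
                 history = do.call(rbind, hist_rows), config = config),
            class = "rtn_trained")
}

#' Save / load a model checkpoint
#'
#' Single-file container holding parameters, batch-norm state and the full
#' architecture configuration, so a reloaded checkpoint reproduces
#' predictions exactly.
#'
#' @param model An `rtn_model` (or fitted `restransnet` object).
#' @param path Destination file.
#' @return `rtn_load` returns the restored object; `rtn_save` returns `path`
#'   invisibly.
#' @export
rtn_save <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname rtn_save
#' @export
rtn_load <- function(path) readRDS(path)
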
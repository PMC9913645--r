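## The user-facing fitting interface: restransnet() and its S3 methods.

as_rtn_model <- function(x) {
  if (inherits(x, "restransnet")) x$model else x
}

#' Fit a hybrid residual-CNN/transformer classifier to a lesion cohort
#'
#' Builds a seeded network, splits the cohort at the patient level (8:2 by
#' default) unless a split is supplied, trains with the configured SGD
#' recipe and imbalance strategy, and evaluates on the held-out set. The
#' returned object keeps the weights from the epoch with the best held-out
#' AUC.
#'
#' @param cohort An `rtn_cohort` (see [generate_synthetic_cohort()] /
#'   [read_cohort()]): images plus a manifest with `patient_id` and `label`.
#' @param config Training settings, an [rtn_train_config()].
#' @param model_config Architecture settings, an [rtn_model_config()].
#' @param split Optional precomputed [holdout_split()]; by default an 8:2
#'   patient-level split seeded from `config$seed`.
#' @return Object of class `"restransnet"`: `model` (best-AUC weights),
#'   `final_model`, `history`, `split`, `test_scores`, `train_scores`,
#'   and the configurations.
#' @examples
#' \donttest{
#' co <- generate_synthetic_cohort(n_patients = 40, images_per_patient = 1,
#'                                 effect_size = 3, seed = 7)
#' fit <- restransnet(co,
#'   config = rtn_train_config(epochs = 5, batch_size = 16, seed = 7),
#'   model_config = rtn_model_config(n_blocks = 2, d = 32))
#' print(fit)
#' }
#' @export
restransnet <- function(cohort, config = rtn_train_config(),
                        model_config = rtn_model_config(), split = NULL) {
  if (!inherits(cohort, "rtn_cohort")) stop("cohort must be an rtn_cohort")
  if (is.null(split)) split <- holdout_split(cohort, 0.8, config$seed)
  meta <- cohort$meta
  size <- model_config$img_size
  X <- as_image_batch(cohort$images, size)
  ytr <- meta$label[split$train]
  yte <- meta$label[split$test]
  model <- rtn_build(model_config, seed = config$seed)
  tr <- rtn_train(model, X[, split$train, drop = FALSE], ytr, config,
                  test = list(images = X[, split$test, drop = FALSE],
                              labels = yte))
  best_model <- tr$model
  if (!is.null(tr$best)) {
    best_model$params <- tr$best$params
    best_model$state <- tr$best$state
  }
  obj <- structure(list(model = best_model, final_model = tr$model,
                        history = tr$history, split = split,
                        config = config, model_config = model_config,
                        train_labels = ytr, test_labels = yte,
                        best_epoch = if (!is.null(tr$best)) tr$best$epoch else NA),
                   class = "restransnet")
  obj$train_scores <- rtn_predict(best_model, X[, split$train, drop = FALSE])
  obj$test_scores <- rtn_predict(best_model, X[, split$test, drop = FALSE])
  obj
}

#' @export
print.restransnet <- function(x, ...) {
  cfg <- x$model_config
  cat("ResTransNet classifier\n")
  cat(sprintf("  backbone %s, %d transformer blocks (d=%d, %d heads); imbalance: %s\n",
              paste(cfg$channels, collapse = "/"), cfg$n_blocks, cfg$d,
              cfg$heads, x$config$imbalance))
  cat(sprintf("  %d train / %d test images (%d / %d patients), %d epochs\n",
              length(x$train_labels), length(x$test_labels),
              length(x$split$train_patients), length(x$split$test_patients),
              x$config$epochs))
  auc <- safe_auc(x$test_scores, x$test_labels)
  if (is.finite(auc))
    cat(sprintf("  held-out AUC %.3f (best epoch %d)\n", auc, x$best_epoch))
  invisible(x)
}

#' @export
summary.restransnet <- function(object, threshold = 0.5, ...) {
  cm_test <- classification_metrics(
    confusion_counts(object$test_scores, object$test_labels, threshold))
  cm_train <- classification_metrics(
    confusion_counts(object$train_scores, object$train_labels, threshold))
  out <- list(
    train = c(cm_train, AUC = safe_auc(object$train_scores, object$train_labels)),
    test = c(cm_test, AUC = safe_auc(object$test_scores, object$test_labels)),
    threshold = threshold, best_epoch = object$best_epoch,
    history = object$history)
  class(out) <- "summary.restransnet"
  out
}

#' @export
print.summary.restransnet <- function(x, ...) {
  cat(sprintf("Performance at threshold %.2f (best epoch %s)\n",
              x$threshold, x$best_epoch))
  m <- rbind(train = x$train, test = x$test)
  print(round(m, 3))
  invisible(x)
}

#' @export
coef.restransnet <- function(object, ...) object$model$params

#' @export
predict.restransnet <- function(object, newdata = NULL,
                                type = c("prob", "class", "link"), ...) {
  type <- match.arg(type)
  scores <- if (is.null(newdata)) object$test_scores
            else rtn_predict(object$model, newdata)
  switch(type,
         prob = scores,
         class = as.integer(scores >= 0.5),
         link = stats::qlogis(pmin(pmax(scores, 1e-12), 1 - 1e-12)))
}

#' @export
fitted.restransnet <- function(object, ...) object$train_scores

#' @export
residuals.restransnet <- function(object, ...)
  object$train_labels - object$train_scores

#' @export
plot.restransnet <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "Epoch",
                 ylab = "Training loss", main = "Loss", ...)
  graphics::plot(h$epoch, h$train_auc, type = "l", ylim = c(0, 1),
                 xlab = "Epoch", ylab = "AUC", main = "AUC")
  if (!all(is.na(h$test_auc))) {
    graphics::lines(h$epoch, h$test_auc, lty = 2)
    graphics::legend("bottomright", c("train", "test"), lty = 1:2, bty = "n")
  }
  invisible(x)
}

#' @export
simulate.restransnet <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$train_scores
  out <- as.data.frame(replicate(nsim, stats::rbinom(length(p), 1, p)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
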
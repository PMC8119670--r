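# Evaluation surface: confusion matrix, balanced accuracy with a percentile
# bootstrap confidence interval, ROC/AUC, and the Pearson correlation
# between mean fluorescence and classification score.

#' Confusion matrix for live/dead predictions
#'
#' @param pred,truth Character vectors in `{"live", "dead"}` of equal
#'   length.
#' @return A 2 x 2 integer matrix, rows = truth, columns = prediction, live
#'   first.
#' @export
confusion_matrix <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  lv <- c("live", "dead")
  if (!all(pred %in% lv) || !all(truth %in% lv)) {
    stop("labels must be 'live' or 'dead'")
  }
  m <- table(truth = factor(truth, lv), pred = factor(pred, lv))
  matrix(as.integer(m), 2L, 2L, dimnames = dimnames(m))
}

#' Balanced accuracy
#'
#' The mean of per-class recalls, insensitive to class imbalance.
#'
#' @param x Either a 2 x 2 confusion matrix (rows = truth) or a prediction
#'   vector (then `truth` is required).
#' @param truth Optional truth vector when `x` is a prediction vector.
#' @return A number in \[0, 1\].
#' @export
balanced_accuracy <- function(x, truth = NULL) {
  cm <- if (is.matrix(x)) x else confusion_matrix(x, truth)
  rs <- rowSums(cm)
  if (any(rs == 0)) stop("every truth class needs at least one sample")
  mean(diag(cm) / rs)
}

#' ROC curve and AUC
#'
#' The AUC is computed from mean ranks (equivalent to the probability that a
#' random positive outscores a random negative, ties counting one half) and
#' the full ROC curve is returned alongside.
#'
#' @param scores Numeric scores; higher means more likely `positive`.
#' @param truth Character labels; both classes must be present.
#' @param positive The class that high scores indicate (default `"live"`).
#' @return An object of class `roc_result`: list with `auc`, `curve`
#'   (tibble `threshold`, `fpr`, `tpr`) and `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, truth, positive = "live") {
  if (length(scores) != length(truth)) stop("length mismatch")
  pos <- truth == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute a ROC curve")
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- tibble::tibble(
    threshold = thr,
    tpr = vapply(thr, function(t) sum(scores[pos] >= t) / n_pos, numeric(1)),
    fpr = vapply(thr, function(t) sum(scores[!pos] >= t) / n_neg, numeric(1)))
  structure(list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d positive / %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Percentile bootstrap confidence interval for an evaluation metric
#'
#' Resamples prediction/truth pairs with replacement and returns percentile
#' bounds of the metric. Resamples whose truth collapses to a single class
#' are redrawn, up to a cap.
#'
#' @param metric_fn Function `(pred, truth) -> numeric` (e.g.
#'   [balanced_accuracy()] via a wrapper, or [f1_score()]).
#' @param pred,truth Paired vectors (n >= 30).
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional seed.
#' @param max_redraw Maximum redraws per resample before giving up.
#' @return Numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(metric_fn, pred, truth, n_boot = 2000L, level = 0.95,
                         seed = NULL, max_redraw = 100L) {
  n <- length(truth)
  if (n < 30) stop("bootstrap CI requires n >= 30")
  if (length(pred) != n) stop("length mismatch")
  run <- function() {
    vals <- numeric(n_boot)
    warned <- FALSE
    for (b in seq_len(n_boot)) {
      for (attempt in seq_len(max_redraw)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(truth[idx])) > 1 || length(unique(truth)) == 1) break
        if (attempt == max_redraw) {
          warned <- TRUE
        }
      }
      vals[b] <- metric_fn(pred[idx], truth[idx])
    }
    if (warned) warning("some resamples remained single-class after redraw cap")
    vals
  }
  vals <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  unname(quantile(vals, probs = c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Pearson correlation between mean fluorescence and classification score
#'
#' With scores oriented as live-class probabilities, an effective classifier
#' yields a negative correlation: high fluorescence (dead) patches get low
#' scores.
#'
#' @param mean_fluorescence,scores Paired numeric vectors (n >= 3, finite,
#'   non-constant).
#' @return A tibble with `r`, `p_value` and `n`.
#' @export
fluorescence_score_correlation <- function(mean_fluorescence, scores) {
  if (length(mean_fluorescence) != length(scores)) stop("length mismatch")
  if (length(scores) < 3) stop("need at least 3 pairs")
  if (any(!is.finite(mean_fluorescence)) || any(!is.finite(scores))) {
    stop("values must be finite")
  }
  if (stats::sd(mean_fluorescence) == 0 || stats::sd(scores) == 0) {
    stop("zero variance in one of the vectors; correlation undefined")
  }
  ct <- cor.test(mean_fluorescence, scores, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(scores))
}

#' Evaluate a trained classifier on a test set
#'
#' Computes the full evaluation surface on one partition: confusion matrix,
#' balanced accuracy with a percentile-bootstrap 95% CI, ROC/AUC of the
#' live-probability score, and the Pearson correlation between each patch's
#' mean fluorescence and its score.
#'
#' @param model A [train_classifier()] result.
#' @param test Patch tibble with `bright_field` (8-bit matrices), `label`,
#'   and either `mean_fluorescence` or a raw-intensity `fluorescence`
#'   list-column.
#' @param n_boot,ci_level,seed Bootstrap settings (the CI is skipped with a
#'   message when n < 30).
#' @return An object of class `eval_report`.
#' @export
evaluate_classifier <- function(model, test, n_boot = 2000L, ci_level = 0.95,
                                seed = 1L) {
  stopifnot(inherits(model, "trained_classifier"))
  if (!"mean_fluorescence" %in% names(test) && "fluorescence" %in% names(test)) {
    test <- add_mean_fluorescence(test)
  }
  preds <- predict(model, test)
  cm <- confusion_matrix(preds$label, test$label)
  ba <- balanced_accuracy(cm)
  ci <- if (nrow(test) >= 30) {
    bootstrap_ci(function(p, t) balanced_accuracy(confusion_matrix(p, t)),
                 preds$label, test$label, n_boot = n_boot, level = ci_level,
                 seed = seed)
  } else {
    message("test set smaller than 30; bootstrap CI not computed")
    c(NA_real_, NA_real_)
  }
  roc <- roc_auc(preds$p_live, test$label, positive = "live")
  corr <- if ("mean_fluorescence" %in% names(test)) {
    fluorescence_score_correlation(test$mean_fluorescence, preds$p_live)
  } else {
    tibble::tibble(r = NA_real_, p_value = NA_real_, n = nrow(test))
  }
  structure(list(confusion = cm, balanced_accuracy = ba,
                 balanced_accuracy_ci = ci, ci_level = ci_level,
                 roc = roc, auc = roc$auc,
                 pearson_r = corr$r, pearson_p = corr$p_value,
                 n_test = nrow(test), predictions = preds),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report> n =", x$n_test, "\n")
  print(x$confusion)
  cat(sprintf("  balanced accuracy %.3f (%.0f%% CI [%.3f, %.3f])\n",
              x$balanced_accuracy, 100 * x$ci_level,
              x$balanced_accuracy_ci[1], x$balanced_accuracy_ci[2]))
  cat(sprintf("  AUC %.3f; fluorescence-score Pearson r %.3f (p = %.3g)\n",
              x$auc, x$pearson_r, x$pearson_p))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.eval_report <- function(x, ...) {
  tibble::tibble(
    metric = c("balanced_accuracy", "balanced_accuracy_ci_low",
               "balanced_accuracy_ci_high", "auc", "pearson_r", "pearson_p"),
    value = c(x$balanced_accuracy, x$balanced_accuracy_ci[1],
              x$balanced_accuracy_ci[2], x$auc, x$pearson_r, x$pearson_p))
}

#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  tibble::tibble(n_test = x$n_test, balanced_accuracy = x$balanced_accuracy,
                 auc = x$auc, pearson_r = x$pearson_r)
}
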
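#' Matthews correlation coefficient of a confusion matrix
#'
#' \deqn{MCC = \frac{TN \cdot TP - FN \cdot FP}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' with the convention that the positive class is the unacceptable test. The
#' MCC lies in `[-1, 1]`: 1 is a perfect prediction, -1 an inverse
#' prediction, and 0 a prediction no better than chance; accordingly, when
#' any factor of the denominator is zero the chance value 0 is returned.
#'
#' @param tp,fp,fn,tn Non-negative integer counts, or a single
#'   `confusion_matrix` object as first argument.
#' @return The MCC, a scalar in `[-1, 1]`.
#' @examples
#' mcc(tp = 6, fp = 0, fn = 2, tn = 14)  # 0.81 to 2 d.p.
#' @export
mcc <- function(tp, fp, fn, tn) {
  if (inherits(tp, "confusion_matrix")) {
    cm <- tp; tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  }
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0, tp + fp + fn + tn > 0)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tn * tp - fn * fp) / sqrt(den)
}

#' Confusion matrix at a risk threshold
#'
#' Predicts unacceptable when `risk >= threshold` (boundary counted as
#' unacceptable); the positive class is unacceptable.
#'
#' @param scores Numeric risks in `[0, 1]`.
#' @param labels 0/1 vector (1 = unacceptable) or
#'   acceptable/unacceptable strings.
#' @param threshold Decision threshold in `[0, 1]`.
#' @return A `confusion_matrix` object (fields tp, fp, fn, tn).
#' @export
confusion_at <- function(scores, labels, threshold) {
  y <- as_binary_labels(labels)
  pred <- scores >= threshold
  structure(list(tp = sum(pred & y == 1), fp = sum(pred & y == 0),
                 fn = sum(!pred & y == 1), tn = sum(!pred & y == 0)),
            class = "confusion_matrix")
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    stopifnot(all(labels %in% c("acceptable", "unacceptable")))
    as.integer(labels == "unacceptable")
  } else {
    stopifnot(all(labels %in% c(0, 1)))
    as.integer(labels)
  }
}

#' MCC-optimal decision threshold
#'
#' Evaluates the MCC of the confusion matrix induced by every candidate
#' threshold — the midpoints between consecutive distinct sorted scores,
#' plus 0 and 1 — and returns the candidate with the largest MCC; ties are
#' broken toward the smallest threshold.
#'
#' @inheritParams confusion_at
#' @return A list `threshold`, `mcc_at_threshold`.
#' @export
select_threshold <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L)
    stop("threshold selection requires both classes", call. = FALSE)
  s <- sort(unique(scores))
  cand <- unique(c(0, if (length(s) > 1) (head(s, -1) + tail(s, -1)) / 2, 1))
  vals <- vapply(cand, function(th) mcc(confusion_at(scores, y, th)),
                 numeric(1))
  best <- which(vals == max(vals))[1]      # ties -> smallest threshold
  list(threshold = cand[best], mcc_at_threshold = vals[best])
}

# Trapezoidal AUC of the ROC curve; ties contribute diagonal segments, so
# the value equals the Mann-Whitney statistic with ties counted 1/2.
auc_trapezoid <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  grp <- cumsum(!duplicated(s))
  tp <- c(0, cumsum(tapply(yy, grp, sum)))
  fp <- c(0, cumsum(tapply(1 - yy, grp, sum)))
  tpr <- tp / n1; fpr <- fp / n0
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' Threshold-based evaluation with bootstrap confidence intervals
#'
#' Computes AUC (trapezoidal ROC integration) plus sensitivity, specificity,
#' accuracy, precision and F1 at the given threshold, each with a 95%
#' percentile-bootstrap confidence interval over `n_boot` resamples of the
#' (score, label) pairs. Metrics with a zero denominator are reported as `NA`
#' with a warning.
#'
#' @inheritParams confusion_at
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap resampling.
#' @param conf Confidence level (default 0.95).
#' @return An `eval_report`: a data.frame with one row per metric and columns
#'   `estimate`, `lower`, `upper`.
#' @export
evaluate_predictions <- function(scores, labels, threshold, n_boot = 2000L,
                                 seed = 1L, conf = 0.95) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L)
    stop("evaluation requires both classes", call. = FALSE)
  stopifnot(threshold >= 0, threshold <= 1)

  metrics_of <- function(s, yy) {
    cm <- confusion_at(s, yy, threshold)
    div <- function(num, den) if (den == 0) NA_real_ else num / den
    sens <- div(cm$tp, cm$tp + cm$fn)
    spec <- div(cm$tn, cm$tn + cm$fp)
    prec <- div(cm$tp, cm$tp + cm$fp)
    acc <- (cm$tp + cm$tn) / (cm$tp + cm$fp + cm$fn + cm$tn)
    f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) NA_real_ else
      2 * prec * sens / (prec + sens)
    auc <- if (length(unique(yy)) < 2L) NA_real_ else auc_trapezoid(s, yy)
    c(auc = auc, sensitivity = sens, specificity = spec, accuracy = acc,
      f1 = f1, precision = prec)
  }

  est <- metrics_of(scores, y)
  if (anyNA(est))
    warning("metric(s) undefined at this threshold (zero denominator): ",
            paste(names(est)[is.na(est)], collapse = ", "), call. = FALSE)
  set.seed(as.integer(seed))
  n <- length(y)
  boot <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    metrics_of(scores[i], y[i])
  }, numeric(6))
  alpha <- (1 - conf) / 2
  ci <- apply(boot, 1, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  out <- data.frame(metric = names(est), estimate = unname(est),
                    lower = ci[1, ], upper = ci[2, ], row.names = NULL)
  attr(out, "threshold") <- threshold
  attr(out, "n_boot") <- n_boot
  class(out) <- c("eval_report", "data.frame")
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Evaluation at threshold ", format(attr(x, "threshold")), " (",
      attr(x, "n_boot"), " bootstrap resamples)\n", sep = "")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-12s %5.2f  (95%% CI %.2f-%.2f)\n", x$metric[i],
                x$estimate[i], x$lower[i], x$upper[i]))
  invisible(x)
}
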
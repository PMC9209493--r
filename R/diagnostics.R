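#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (positive call when
#' `score >= threshold`, ties positive). The AUC is computed by the
#' Mann-Whitney rank formula with midranks for ties, which equals the
#' trapezoid area under the swept curve.
#'
#' @param scores numeric scores (higher = more disease-like).
#' @param labels logical (or 0/1) vector, TRUE = positive class.
#' @return list of class `apv_roc` with `thresholds`, `sensitivity`,
#'   `fpr` (1 - specificity) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    stop_apv("apv_validation_error", "scores/labels must align, no NAs")
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop_apv("apv_label_error", "both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  sens <- fpr <- numeric(length(thr) + 1L)
  for (k in seq_along(thr)) {
    pos <- scores >= thr[k]
    sens[k] <- sum(pos & labels) / n1
    fpr[k] <- sum(pos & !labels) / n0
  }
  sens[length(thr) + 1L] <- 1; fpr[length(thr) + 1L] <- 1
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(thresholds = c(thr, -Inf), sensitivity = sens, fpr = fpr,
                 auc = auc),
            class = "apv_roc")
}

#' Confusion counts at a threshold
#'
#' Positive call when `score >= threshold`.
#'
#' @param scores,labels as in [roc_auc()].
#' @param threshold decision threshold.
#' @return list of class `apv_confusion` with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold) {
  labels <- as.logical(labels)
  pos <- scores >= threshold
  confusion_counts(TP = sum(pos & labels), FP = sum(pos & !labels),
                   TN = sum(!pos & !labels), FN = sum(!pos & labels))
}

#' @rdname confusion_at_threshold
#' @param TP,FP,TN,FN non-negative integer counts.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  counts <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_apv("apv_validation_error", "counts must be non-negative integers")
  if (sum(counts) == 0)
    stop_apv("apv_validation_error", "confusion table is empty")
  structure(as.list(counts), class = "apv_confusion")
}

safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Full diagnostic-accuracy metric panel from confusion counts
#'
#' Sensitivity, specificity, accuracy, predictive values, likelihood ratios
#' `LR+ = sens/(1-spec)`, `LR- = (1-sens)/spec`, Youden index
#' `Yi = sens + spec - 1` and diagnostic odds ratio
#' `DOR = (TP*TN)/(FP*FN)`. Any metric whose denominator is zero is
#' reported as NA (a typed flag, never an error), matching the usual
#' convention for undefined values arising from division by zero.
#'
#' @param counts an `apv_confusion`.
#' @param auc optional AUC to carry into the report.
#' @param threshold optional threshold to carry into the report.
#' @return list of class `apv_diagnostic_report`.
#' @export
diagnostic_report <- function(counts, auc = NA_real_,
                              threshold = NA_real_) {
  TP <- counts$TP; FP <- counts$FP; TN <- counts$TN; FN <- counts$FN
  sens <- safe_ratio(TP, TP + FN)
  spec <- safe_ratio(TN, TN + FP)
  lr_plus <- if (is.na(spec)) NA_real_ else safe_ratio(sens, 1 - spec)
  lr_minus <- if (is.na(sens) || is.na(spec) || spec == 0) NA_real_ else
    (1 - sens) / spec
  yi <- if (is.na(sens) || is.na(spec)) NA_real_ else sens + spec - 1
  structure(list(
    auc = auc,
    threshold = threshold,
    sensitivity = sens,
    specificity = spec,
    accuracy = (TP + TN) / (TP + TN + FP + FN),
    npv = safe_ratio(TN, TN + FN),
    ppv = safe_ratio(TP, TP + FP),
    lr_plus = lr_plus,
    lr_minus = lr_minus,
    youden = yi,
    dor = if (FP == 0 || FN == 0) NA_real_ else (TP * TN) / (FP * FN),
    counts = counts), class = "apv_diagnostic_report")
}

#' @export
print.apv_diagnostic_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.4f", v))
  cat("Diagnostic report\n")
  for (m in c("auc", "threshold", "specificity", "sensitivity", "accuracy",
              "npv", "ppv", "lr_plus", "lr_minus", "youden", "dor"))
    cat(sprintf("  %-12s %s\n", m, fmt(x[[m]])))
  invisible(x)
}

#' Convert diagnostic reports to a data.frame (table row order)
#'
#' Rows follow the conventional panel order: AUC, Threshold, Specificity,
#' Sensitivity, Accuracy, NPV, PPV, LR+, LR-, Yi, DOR. NA values are
#' written as the literal "NA" by `write.csv`.
#'
#' @param reports named list of `apv_diagnostic_report`s (one column each).
#' @return data.frame with a `metric` column and one column per report.
#' @export
report_table <- function(reports) {
  metrics <- c(AUC = "auc", Threshold = "threshold",
               Specificity = "specificity", Sensitivity = "sensitivity",
               Accuracy = "accuracy", NPV = "npv", PPV = "ppv",
               `LR+` = "lr_plus", `LR-` = "lr_minus", Yi = "youden",
               DOR = "dor")
  out <- data.frame(metric = names(metrics), stringsAsFactors = FALSE)
  for (nm in names(reports))
    out[[nm]] <- vapply(metrics, function(m) reports[[nm]][[m]], 1)
  out
}

#' Hold-out AUC convention from sensitivity and specificity
#'
#' `(sens + spec) / 2` — the single-threshold AUC, i.e. the trapezoid area
#' of the ROC through the one operating point `(1 - spec, sens)`.
#'
#' @param sens,spec rates in `[0, 1]`.
#' @return scalar AUC.
#' @export
balanced_auc <- function(sens, spec) {
  if (any(c(sens, spec) < 0 | c(sens, spec) > 1))
    stop_apv("apv_validation_error", "rates must lie in [0, 1]")
  (sens + spec) / 2
}

#' Youden-optimal threshold of an ROC curve
#'
#' Maximizes `sensitivity + specificity - 1`; ties resolved toward the
#' smallest threshold.
#'
#' @param r an `apv_roc` from [roc_auc()].
#' @return the selected threshold.
#' @export
youden_threshold <- function(r) {
  finite <- is.finite(r$thresholds)
  j <- r$sensitivity[finite] - r$fpr[finite]
  thr <- r$thresholds[finite]
  if (!length(thr))
    stop_apv("apv_validation_error", "ROC curve has no finite threshold")
  best <- max(j)
  min(thr[j >= best - 1e-12])
}

#' One-way random-effects, single-measurement intraclass correlation
#'
#' ICC(1,1): `(MSB - MSW) / (MSB + (k-1) MSW)` from the one-way ANOVA
#' decomposition of an n-subject by k-measurement table — the absolute
#' agreement, single rater/measurement form.
#'
#' @param x numeric matrix, n subjects x k repeated measurements, complete.
#' @return list of class `apv_icc` with `icc`, `msb`, `msw`, `n`, `k`.
#' @export
icc_oneway <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L)
    stop_apv("apv_sample_size_error", "need n >= 2 subjects and k >= 2 measurements")
  if (anyNA(x))
    stop_apv("apv_completeness_error", "missing cells are not allowed")
  grand <- mean(x)
  rowm <- rowMeans(x)
  msb <- k * sum((rowm - grand)^2) / (n - 1)
  msw <- sum((x - rowm)^2) / (n * (k - 1))
  structure(list(icc = (msb - msw) / (msb + (k - 1) * msw),
                 msb = msb, msw = msw, n = n, k = k),
            class = "apv_icc")
}

#' Bland-Altman agreement statistics
#'
#' @param a,b paired measurements (>= 2 pairs).
#' @return list of class `apv_bland_altman`: `bias` (mean of `a - b`) and
#'   `limits` (bias +/- 1.96 sd of the differences).
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop_apv("apv_sample_size_error", "need >= 2 aligned pairs")
  d <- a - b
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, limits = c(lower = bias - 1.96 * s,
                                         upper = bias + 1.96 * s),
                 sd = s, n = length(d)),
            class = "apv_bland_altman")
}
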
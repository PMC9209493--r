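#' Top-weight feature-subset robustness analysis
#'
#' Re-evaluates a fitted stage's ApV when the weighted sum is restricted to
#' feature subsets: the full selected set (`Ftot`), the `k` features with
#' the largest absolute weights (`Ftest<k>`), every size-(k-1) subset of
#' that top set (`Ftest<k-1>-p1..`) and every size-(k-2) subset
#' (`Ftest<k-2>-p..`, numbering continuing after the triples). Weights stay
#' at their fitted values; each subset's decision threshold is re-derived by
#' the Youden rule on the evaluation split. Ties in |weight| are broken by
#' feature-name order, so subset membership is deterministic.
#'
#' @param model an `apv_stage_model` with at least `k` selected features.
#' @param eval_m an `apv_feature_matrix` to evaluate on.
#' @param k size of the top-weight set (default 4).
#' @return data.frame with one row per subset: `subset`, `features`
#'   (comma-joined), `n_features` and the diagnostic metric panel.
#' @export
subset_robustness <- function(model, eval_m, k = 4L) {
  if (k < 3L)
    stop_apv("apv_size_error", "k must be >= 3 (subsets go down to k - 2)")
  w <- model$weights
  if (length(w) < k)
    stop_apv("apv_size_error",
             "model selected %d features, need >= k = %d", length(w), k)
  ord <- order(-abs(w), names(w))
  top <- names(w)[ord][seq_len(k)]

  subsets <- list(Ftot = names(w))
  subsets[[paste0("Ftest", k)]] <- top
  cmb1 <- combn(top, k - 1L, simplify = FALSE)
  for (i in seq_along(cmb1))
    subsets[[sprintf("Ftest%d-p%d", k - 1L, i)]] <- cmb1[[i]]
  cmb2 <- combn(top, k - 2L, simplify = FALSE)
  for (i in seq_along(cmb2))
    subsets[[sprintf("Ftest%d-p%d", k - 2L, length(cmb1) + i)]] <- cmb2[[i]]

  y <- eval_m$groups %in% model$contrast$positive
  if (!any(y) || all(y))
    stop_apv("apv_label_error", "evaluation split needs both classes")

  rows <- lapply(names(subsets), function(nm) {
    sub <- subsets[[nm]]
    sub_model <- model
    sub_model$weights <- w[sub]
    sub_model$selected <- sub
    s <- predict_stage(sub_model, eval_m)
    roc <- roc_auc(s, y)
    thr <- youden_threshold(roc)
    rep <- diagnostic_report(confusion_at_threshold(s, y, thr),
                             auc = roc$auc, threshold = thr)
    data.frame(subset = nm, features = paste(sub, collapse = ","),
               n_features = length(sub),
               auc = rep$auc, threshold = rep$threshold,
               specificity = rep$specificity, sensitivity = rep$sensitivity,
               accuracy = rep$accuracy, npv = rep$npv, ppv = rep$ppv,
               lr_plus = rep$lr_plus, lr_minus = rep$lr_minus,
               youden = rep$youden, dor = rep$dor,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
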
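test_that("ROC/AUC: separation, ties, pairwise oracle, pROC cross-check", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12),
                       c(F, F, F, T, T, T))$auc, 1)
  expect_equal(roc_auc(rep(5, 8), rep(c(TRUE, FALSE), 4))$auc, 0.5)

  set.seed(14)
  s <- rnorm(10); y <- rep(c(TRUE, FALSE), 5)
  # O(n^2) pairwise comparison oracle with half-credit ties
  pairs <- expand.grid(i = which(y), j = which(!y))
  oracle <- mean(ifelse(s[pairs$i] > s[pairs$j], 1,
                        ifelse(s[pairs$i] == s[pairs$j], 0.5, 0)))
  r <- roc_auc(s, y)
  expect_equal(r$auc, oracle, tolerance = 1e-12)
  expect_equal(r$auc, as.numeric(suppressMessages(
    pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<",
                        levels = c(FALSE, TRUE))))), tolerance = 1e-12)
  # monotone sweep
  expect_true(all(diff(r$sensitivity) >= 0))
  expect_true(all(diff(r$fpr) >= 0))
  expect_error(roc_auc(s, rep(TRUE, 10)), class = "apv_label_error")

  # AUC invariant under strictly increasing transforms
  expect_equal(roc_auc(exp(s), y)$auc, r$auc)
})

test_that("confusion counts at extreme and interior thresholds", {
  s <- c(0.1, 0.4, 0.35, 0.8); y <- c(FALSE, TRUE, FALSE, TRUE)
  low <- confusion_at_threshold(s, y, 0)    # everything positive
  expect_equal(c(low$FN, low$TN), c(0, 0))
  high <- confusion_at_threshold(s, y, 2)   # nothing positive
  expect_equal(c(high$TP, high$FP), c(0, 0))
  mid <- confusion_at_threshold(s, y, 0.4)  # ties called positive
  expect_equal(unlist(mid[c("TP", "FP", "TN", "FN")]),
               c(TP = 2, FP = 0, TN = 2, FN = 0))
})

test_that("diagnostic panel reproduces the external-cohort worked example", {
  # implied counts from a 53-control/11-case external set at the printed
  # sensitivity 5/11 and specificity 47/53
  rep <- diagnostic_report(confusion_counts(TP = 5, FN = 6, TN = 47, FP = 6))
  expect_equal(rep$sensitivity, 5 / 11, tolerance = 1e-12)
  expect_equal(rep$specificity, 47 / 53, tolerance = 1e-12)
  expect_equal(rep$accuracy, 0.8125, tolerance = 1e-12)
  expect_equal(rep$npv, 0.8868, tolerance = 1e-4)
  expect_equal(rep$lr_plus, 4.0151, tolerance = 1e-4)
  expect_equal(rep$lr_minus, 0.6151, tolerance = 1e-4)
  expect_equal(rep$youden, 0.3413, tolerance = 2e-4)
  expect_equal(rep$dor, 6.5278, tolerance = 1e-4)
})

test_that("zero denominators yield NA flags, never errors", {
  rep <- diagnostic_report(confusion_counts(TP = 5, FN = 1, TN = 10, FP = 0))
  expect_true(is.na(rep$lr_plus))   # 1 - spec = 0
  expect_true(is.na(rep$dor))
  expect_false(is.na(rep$sensitivity))

  perfect <- diagnostic_report(confusion_counts(TP = 7, FN = 0, TN = 9,
                                                FP = 0))
  expect_equal(perfect$youden, 1)
  expect_equal(perfect$accuracy, 1)
  # the CSV writer renders NA as the literal string
  tab <- report_table(list(m = rep))
  f <- tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  expect_true(any(grepl("\"LR\\+\",NA", readLines(f))))
})

test_that("DOR = LR+/LR- and label swap exchanges the panel", {
  set.seed(9)
  for (i in 1:10) {
    cc <- as.list(sample(1:30, 4))
    names(cc) <- c("TP", "FP", "TN", "FN")
    rep <- diagnostic_report(do.call(confusion_counts, cc))
    expect_equal(rep$dor, rep$lr_plus / rep$lr_minus, tolerance = 1e-12)
    swapped <- diagnostic_report(confusion_counts(TP = cc$TN, FP = cc$FN,
                                                  TN = cc$TP, FN = cc$FP))
    expect_equal(swapped$sensitivity, rep$specificity)
    expect_equal(swapped$specificity, rep$sensitivity)
    expect_equal(swapped$ppv, rep$npv)
    expect_equal(swapped$npv, rep$ppv)
    expect_equal(swapped$dor, rep$dor, tolerance = 1e-12)
  }
})

test_that("balanced AUC equals the one-threshold trapezoid", {
  expect_equal(balanced_auc(0.9741, 0.9831), 0.9786)
  expect_equal(balanced_auc(1, 1), 1)
  expect_equal(balanced_auc(0.4545, 0.8868), 0.67065, tolerance = 1e-12)
  # trapezoid through (0,0), (1-spec, sens), (1,1)
  sens <- 0.7; spec <- 0.8
  x <- c(0, 1 - spec, 1); y <- c(0, sens, 1)
  trap <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  expect_equal(balanced_auc(sens, spec), trap, tolerance = 1e-12)
})

test_that("Youden threshold: exhaustive sweep oracle and tie rule", {
  # separable scores: any gap threshold gives J = 1; smallest chosen
  s <- c(1, 2, 3, 10, 11, 12); y <- c(F, F, F, T, T, T)
  r <- roc_auc(s, y)
  expect_equal(youden_threshold(r), 10)

  set.seed(23)
  s2 <- rnorm(10); y2 <- rep(c(TRUE, FALSE), 5)
  r2 <- roc_auc(s2, y2)
  cand <- sort(unique(s2))
  j <- vapply(cand, function(t) {
    cc <- confusion_at_threshold(s2, y2, t)
    cc$TP / (cc$TP + cc$FN) + cc$TN / (cc$TN + cc$FP) - 1
  }, 1)
  expect_equal(youden_threshold(r2), min(cand[j >= max(j) - 1e-12]))
})

test_that("ICC(1,1): duplicated columns, hand ANOVA, null simulation", {
  x <- matrix(rnorm(12), 6, 2)
  dup <- icc_oneway(cbind(x[, 1], x[, 1]))
  expect_equal(dup$icc, 1)

  # explicit MSB/MSW on a small 4 x 2 table
  tab <- matrix(c(7, 8, 6, 9, 8, 7, 5, 10), 4, 2)
  n <- 4; k <- 2
  grand <- mean(tab)
  msb <- k * sum((rowMeans(tab) - grand)^2) / (n - 1)
  msw <- sum((tab - rowMeans(tab))^2) / (n * (k - 1))
  expect_equal(icc_oneway(tab)$icc, (msb - msw) / (msb + (k - 1) * msw),
               tolerance = 1e-12)

  set.seed(60)
  noise <- matrix(rnorm(1000), 500, 2)
  expect_lt(abs(icc_oneway(noise)$icc), 0.1)
  expect_error(icc_oneway(matrix(1:2, 1, 2)), class = "apv_sample_size_error")
  bad <- x; bad[1, 1] <- NA
  expect_error(icc_oneway(bad), class = "apv_completeness_error")
})

test_that("Bland-Altman bias and limits", {
  a <- c(1, 2, 3, 4)
  ba0 <- bland_altman(a, a)
  expect_equal(ba0$bias, 0)
  expect_equal(unname(ba0$limits), c(0, 0))

  ba1 <- bland_altman(a + 2.5, a)
  expect_equal(ba1$bias, 2.5)
  expect_equal(unname(diff(ba1$limits)), 0)

  set.seed(3)
  u <- rnorm(50); v <- rnorm(50)
  ba <- bland_altman(u, v)
  expect_equal(ba$bias, mean(u - v))
  expect_equal(unname(ba$limits),
               mean(u - v) + c(-1.96, 1.96) * sd(u - v), tolerance = 1e-12)
  expect_error(bland_altman(1, 2), class = "apv_sample_size_error")
})
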
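#' Subjects x features matrix with group labels and optional clinical scores
#'
#' The container screened and fed to the LASSO stages. Clinical-score
#' columns (e.g. MMSE, LDELTOTAL, CSF abeta/tau/ptau, age) are kept apart
#' from imaging features because they bypass FDR screening and are always
#' offered to the LASSO as candidates.
#'
#' @param values numeric matrix (subjects x features) with rownames =
#'   subject ids and colnames = feature names; NA marks masked values.
#' @param groups character/factor of group labels, one per subject.
#' @param scores optional numeric matrix/data.frame of clinical scores with
#'   the same subjects.
#' @return object of class `apv_feature_matrix`.
#' @export
feature_matrix <- function(values, groups, scores = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (anyDuplicated(rownames(values)))
    stop_apv("apv_validation_error", "duplicate subject ids")
  if (length(groups) != nrow(values))
    stop_apv("apv_validation_error",
             "groups must cover all %d subjects", nrow(values))
  if (!is.null(scores)) {
    scores <- as.matrix(as.data.frame(scores))
    if (nrow(scores) != nrow(values))
      stop_apv("apv_validation_error", "scores must cover all subjects")
    rownames(scores) <- rownames(values)
  }
  structure(list(values = values, groups = as.character(groups),
                 scores = scores, subject_ids = rownames(values)),
            class = "apv_feature_matrix")
}

#' @export
print.apv_feature_matrix <- function(x, ...) {
  cat(sprintf("<apv_feature_matrix> %d subjects x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s:%d", names(table(x$groups)),
                            table(x$groups)), collapse = ", ")))
  invisible(x)
}

subset_fm <- function(fm, keep) {
  feature_matrix(fm$values[keep, , drop = FALSE], fm$groups[keep],
                 if (!is.null(fm$scores)) fm$scores[keep, , drop = FALSE])
}

#' Fit per-feature standardization parameters on a training split
#'
#' @param train an `apv_feature_matrix` (or plain matrix) of >= 2 subjects.
#' @return list of class `apv_standardization` with per-feature `mean`,
#'   `sd` (sample sd, NA-aware) and a `flagged` mask for zero-variance
#'   features.
#' @export
standardize_fit <- function(train) {
  values <- if (inherits(train, "apv_feature_matrix")) train$values else
    as.matrix(train)
  if (nrow(values) < 2L)
    stop_apv("apv_sample_size_error",
             "need >= 2 subjects to estimate standardization")
  mu <- colMeans(values, na.rm = TRUE)
  sdv <- apply(values, 2, sd, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  sdv[is.na(sdv)] <- 0
  flagged <- sdv <= 0
  structure(list(mean = mu, sd = sdv, flagged = flagged,
                 features = colnames(values)),
            class = "apv_standardization")
}

#' Apply standardization parameters
#'
#' `(x - mean) / sd` per feature; zero-variance (flagged) features and
#' masked (NA) values map to 0 — the training mean on the z scale — so a
#' linear model downstream treats them as uninformative.
#'
#' @param m an `apv_feature_matrix` or numeric matrix whose columns match
#'   the fitted parameters.
#' @param p an `apv_standardization` from [standardize_fit()].
#' @return object of the same kind with standardized values.
#' @export
standardize_apply <- function(m, p) {
  is_fm <- inherits(m, "apv_feature_matrix")
  values <- if (is_fm) m$values else as.matrix(m)
  if (!identical(colnames(values), p$features))
    stop_apv("apv_schema_error",
             "feature names do not match standardization parameters")
  z <- sweep(values, 2, p$mean)
  denom <- ifelse(p$flagged, 1, p$sd)
  z <- sweep(z, 2, denom, `/`)
  z[, p$flagged] <- 0
  z[is.na(z)] <- 0
  if (is_fm) feature_matrix(z, m$groups, m$scores) else z
}

#' Two-group per-feature tests
#'
#' Mann-Whitney (Wilcoxon rank-sum) by default: the exact null distribution
#' when both groups have <= 8 subjects and no ties, otherwise the normal
#' approximation with tie correction and continuity correction. Constant
#' features are flagged and given p = 1. `welch_t` is offered as an
#' alternative.
#'
#' @param m an `apv_feature_matrix` or numeric matrix.
#' @param labels logical/binary vector marking the positive group (defaults
#'   to `m$groups == positive` when `m` is a feature matrix).
#' @param test `"mann_whitney"` (default) or `"welch_t"`.
#' @param positive group label treated as positive when `labels` is missing.
#' @return data.frame with columns `feature`, `p`, `flagged`.
#' @export
groupwise_test <- function(m, labels = NULL,
                           test = c("mann_whitney", "welch_t"),
                           positive = NULL) {
  test <- match.arg(test)
  values <- if (inherits(m, "apv_feature_matrix")) m$values else as.matrix(m)
  if (is.null(labels)) {
    if (!inherits(m, "apv_feature_matrix") || is.null(positive))
      stop_apv("apv_validation_error", "labels (or positive group) required")
    labels <- m$groups == positive
  }
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop_apv("apv_sample_size_error", "both groups must be non-empty")
  res <- apply(values, 2, function(x) {
    a <- x[labels]; b <- x[!labels]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) == 0L || length(b) == 0L) return(c(1, 1))
    if (sd(c(a, b)) == 0) return(c(1, 1))
    p <- if (test == "mann_whitney") mw_p(a, b) else
      stats::t.test(a, b)$p.value
    c(p, 0)
  })
  data.frame(feature = colnames(values) %||%
               paste0("f", seq_len(ncol(values))),
             p = res[1, ], flagged = res[2, ] == 1,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Two-sided Mann-Whitney p-value. Exact via the null U distribution when
# both groups are small and untied; otherwise a continuity-corrected normal
# approximation with tie correction and, for untied data, an Edgeworth
# kurtosis term (the null U has excess kurtosis
# -(6/5)(n1^2+n2^2+n1 n2+n1+n2)/(n1 n2 (n1+n2+1)), and the second-order
# expansion tracks the exact tail far better at small n).
mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (!ties && n1 <= 8 && n2 <= 8) {
    if (U > n1 * n2 / 2) U <- n1 * n2 - U
    p <- 2 * pwilcox(U, n1, n2)
    return(min(p, 1))
  }
  mu <- n1 * n2 / 2
  tab <- table(r)
  sigma2 <- (n1 * n2 / 12) *
    ((n1 + n2 + 1) - sum(tab^3 - tab) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sigma2 <= 0) return(1)
  z <- abs(U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  p1 <- stats::pnorm(-z)
  if (!ties) {
    e4 <- -(6 / 5) * (n1^2 + n2^2 + n1 * n2 + n1 + n2) /
      (n1 * n2 * (n1 + n2 + 1))
    p1 <- p1 + stats::dnorm(z) * e4 / 24 * (z^3 - 3 * z)
  }
  min(max(2 * p1, 0), 1)
}

#' Benjamini-Hochberg FDR screen
#'
#' Step-up procedure; a feature is kept when its adjusted q-value is
#' strictly below the level (default 5%).
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list of class `apv_screening` with `p`, `q` (BH-adjusted),
#'   `kept` (logical), `level`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop_apv("apv_validation_error", "p-values must lie in [0, 1]")
  qv <- p.adjust(p, method = "BH")
  structure(list(p = p, q = qv, kept = qv < q, level = q),
            class = "apv_screening")
}

#' Screen a feature matrix for one contrast
#'
#' Convenience wrapper: [groupwise_test()] then [bh_fdr()].
#'
#' @inheritParams groupwise_test
#' @param fdr_level FDR level.
#' @return data.frame `feature`, `p`, `q`, `kept`.
#' @export
screen_features <- function(m, labels = NULL,
                            test = c("mann_whitney", "welch_t"),
                            fdr_level = 0.05, positive = NULL) {
  gt <- groupwise_test(m, labels, test, positive)
  sc <- bh_fdr(gt$p, fdr_level)
  data.frame(feature = gt$feature, p = sc$p, q = sc$q,
             kept = sc$kept & !gt$flagged, stringsAsFactors = FALSE)
}
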
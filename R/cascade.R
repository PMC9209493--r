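# Reference CSF biomarker cut-offs (pg/ml) commonly used for positivity
# calls; stored as constants for reporting, not used by the model itself.
CSF_CUTOFFS <- c(tau = 93, abeta42 = 192, ptau = 23)

#' Stratified train/validation split
#'
#' @param groups group label per subject.
#' @param fraction training fraction in (0, 1) (default 0.7).
#' @param seed RNG seed for the permutation within each class.
#' @return list with integer vectors `train` and `test`; errors if any
#'   class would be missing from a split.
#' @export
stratified_split <- function(groups, fraction = 0.7, seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop_apv("apv_validation_error", "fraction must lie in (0, 1)")
  set.seed(seed)
  train <- integer(0)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    n_tr <- round(length(idx) * fraction)
    if (n_tr < 1L || n_tr >= length(idx))
      stop_apv("apv_stratification_error",
               "class %s would be missing from a split", g)
    train <- c(train, sample(idx)[seq_len(n_tr)])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(groups), train))
}

#' Cross-validated LASSO fit over a lambda path
#'
#' Fits an L1-penalized linear (gaussian) or logistic (binomial) model over
#' a geometric lambda grid running from `lambda_max` (the smallest lambda
#' with an all-zero coefficient vector) down three decades. K-fold
#' cross-validation with folds stratified by class and reproducible from
#' `seed`; the chosen lambda minimizes the mean CV loss (deviance for
#' binomial, squared error for gaussian). The solver is glmnet's coordinate
#' descent; the grid, fold assignment and CV loop are owned here.
#'
#' @param X numeric matrix (already standardized; no missing values).
#' @param y binary response (logical or 0/1).
#' @param family `"binomial"` (default) or `"gaussian"`.
#' @param folds number of CV folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @param nlambda grid resolution (default 100).
#' @param intercept fit an intercept (default TRUE).
#' @return list of class `apv_lasso_fit`: `lambda` (grid), `cvm` (mean CV
#'   loss per lambda), `lambda_min`, `intercept`, `coefficients` (named,
#'   full vector at `lambda_min`), `selected` (non-zero names), `family`,
#'   `folds`, `seed`, `foldid`.
#' @export
lasso_cv_fit <- function(X, y, family = c("binomial", "gaussian"),
                         folds = 10L, seed = 1L, nlambda = 100L,
                         intercept = TRUE) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (anyNA(X) || anyNA(y))
    stop_apv("apv_validation_error", "X/y must be complete (impute first)")
  binary <- all(y %in% c(0, 1))
  if (family == "binomial") {
    if (!binary)
      stop_apv("apv_label_error", "y must be binary 0/1")
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    if (n1 == 0L || n0 == 0L)
      stop_apv("apv_label_error", "both classes must be present")
    if (min(n1, n0) < folds)
      stop_apv("apv_fold_error",
               "need >= %d subjects per class for %d-fold CV", folds, folds)
  } else if (length(y) < folds) {
    stop_apv("apv_fold_error", "need >= %d subjects for %d-fold CV", folds,
             folds)
  }
  # glmnet requires >= 2 columns; pad a constant dummy that can never be
  # selected and drop it from the results
  padded <- ncol(X) == 1L
  if (padded) X <- cbind(X, `.dummy.` = 0)

  # lambda_max from the unpenalized gradient at the null model, then a
  # 3-decade geometric path
  fit0 <- glmnet::glmnet(X, y, family = family, standardize = FALSE,
                         intercept = intercept, nlambda = 5)
  lambda_max <- fit0$lambda[1]
  lambda <- lambda_max * 10^seq(0, -3, length.out = nlambda)

  # fold assignment stratified by class (plain random for a continuous
  # gaussian response), reproducible from the seed
  set.seed(seed)
  foldid <- integer(length(y))
  if (binary) {
    for (cls in c(0, 1)) {
      idx <- which(y == cls)
      foldid[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
  } else {
    foldid <- sample(rep(seq_len(folds), length.out = length(y)))
  }

  loss_mat <- matrix(NA_real_, folds, length(lambda))
  wts <- integer(folds)
  for (f in seq_len(folds)) {
    tr <- foldid != f
    fit_f <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], family = family,
                            lambda = lambda, standardize = FALSE,
                            intercept = intercept)
    eta <- predict(fit_f, X[!tr, , drop = FALSE], s = lambda)
    yv <- y[!tr]
    loss_mat[f, ] <- if (family == "gaussian") {
      colMeans((yv - eta)^2)
    } else {
      pr <- 1 / (1 + exp(-eta))
      pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
      -2 * colMeans(yv * log(pr) + (1 - yv) * log(1 - pr))
    }
    wts[f] <- sum(!tr)
  }
  cvm <- colSums(loss_mat * wts) / sum(wts)
  k_min <- which.min(cvm)

  fit <- glmnet::glmnet(X, y, family = family, lambda = lambda,
                        standardize = FALSE, intercept = intercept)
  beta <- as.numeric(fit$beta[, k_min])
  names(beta) <- rownames(fit$beta)
  if (padded) beta <- beta[names(beta) != ".dummy."]
  structure(list(lambda = lambda, cvm = cvm, lambda_min = lambda[k_min],
                 intercept = fit$a0[k_min],
                 coefficients = beta,
                 selected = names(beta)[beta != 0],
                 family = family, folds = folds, seed = seed,
                 foldid = foldid),
            class = "apv_lasso_fit")
}

#' ApV score of one standardized feature row
#'
#' The Alzheimer's Predictive Vector: the weighted sum
#' `intercept + sum_i w_i z_i` over the model's selected features — a linear
#' predictor, not a probability. The stage's stored orientation sign is
#' applied so that the disease class scores higher.
#'
#' @param model an `apv_stage_model` (or `apv_lasso_fit`, orientation +1).
#' @param row named numeric vector of standardized features covering the
#'   selected set.
#' @return scalar score.
#' @export
apv_score <- function(model, row) {
  w <- model$weights %||% model$coefficients[model$selected]
  orientation <- model$orientation %||% 1
  missing <- setdiff(names(w), names(row))
  if (length(missing))
    stop_apv("apv_schema_error", "row lacks selected features: %s",
             paste(utils::head(missing, 5), collapse = ", "))
  orientation * (model$intercept + sum(w * row[names(w)]))
}

#' Fit one LASSO stage (standardize, FDR screen, LASSO, threshold)
#'
#' Pipeline: standardization parameters fitted on this (training) data;
#' Mann-Whitney FDR < `fdr_level` screen on the stage's own contrast;
#' optional clinical-score and age candidates appended after their own
#' standardization (they bypass screening); cross-validated LASSO; Youden
#' threshold on the training ROC. Orientation is fixed so the positive
#' (disease) class has the higher mean training score.
#'
#' @param m an `apv_feature_matrix` (the training split).
#' @param contrast list with `negative` and `positive` character vectors of
#'   group labels.
#' @param include_scores append the clinical-score columns of `m` as LASSO
#'   candidates (default FALSE).
#' @param family,folds,seed,nlambda passed to [lasso_cv_fit()].
#' @param fdr_level FDR screen level (default 0.05).
#' @param test screening test (default Mann-Whitney).
#' @param tag stage tag stored in the model (e.g. "ApV1").
#' @return list of class `apv_stage_model`.
#' @export
fit_stage <- function(m, contrast, include_scores = FALSE,
                      family = c("binomial", "gaussian"), folds = 10L,
                      seed = 1L, nlambda = 100L, fdr_level = 0.05,
                      test = c("mann_whitney", "welch_t"), tag = "ApV") {
  family <- match.arg(family)
  test <- match.arg(test)
  keep_subj <- m$groups %in% c(contrast$negative, contrast$positive)
  if (!any(m$groups %in% contrast$negative) ||
      !any(m$groups %in% contrast$positive))
    stop_apv("apv_label_error", "both contrast groups must be present")
  fm <- subset_fm(m, keep_subj)
  y <- as.numeric(fm$groups %in% contrast$positive)

  std <- standardize_fit(fm)
  z <- standardize_apply(fm, std)
  scr <- screen_features(z, labels = y == 1, test = test,
                         fdr_level = fdr_level)
  kept <- scr$feature[scr$kept]

  X <- z$values[, kept, drop = FALSE]
  score_std <- NULL
  if (include_scores) {
    if (is.null(fm$scores))
      stop_apv("apv_validation_error",
               "include_scores = TRUE but the matrix has no scores")
    score_std <- standardize_fit(fm$scores)
    zs <- standardize_apply(fm$scores, score_std)
    X <- cbind(X, zs)
  }
  if (ncol(X) == 0L)
    stop_apv("apv_empty_model_error",
             "screening kept no features and no scores were included")

  lasso <- lasso_cv_fit(X, y, family = family, folds = folds, seed = seed,
                        nlambda = nlambda)
  lp <- as.numeric(lasso$intercept +
                     X[, names(lasso$coefficients), drop = FALSE] %*%
                     lasso$coefficients)
  orientation <- if (mean(lp[y == 1]) >= mean(lp[y == 0])) 1 else -1
  apv <- orientation * lp
  roc <- roc_auc(apv, y == 1)
  thr <- youden_threshold(roc)

  structure(list(tag = tag,
                 weights = lasso$coefficients[lasso$selected],
                 intercept = lasso$intercept,
                 orientation = orientation,
                 selected = lasso$selected,
                 lambda = lasso$lambda, cvm = lasso$cvm,
                 lambda_min = lasso$lambda_min,
                 threshold = thr,
                 standardization = std,
                 score_standardization = score_std,
                 screening = scr,
                 contrast = contrast,
                 include_scores = include_scores,
                 family = family, folds = folds, seed = seed,
                 train_auc = roc$auc),
            class = "apv_stage_model")
}

#' @export
print.apv_stage_model <- function(x, ...) {
  cat(sprintf(
    "<apv_stage_model %s> %d selected features, lambda %.4g, threshold %.4f (train AUC %.3f)\n",
    x$tag, length(x$selected), x$lambda_min, x$threshold, x$train_auc))
  invisible(x)
}

#' ApV scores of a stage model on new subjects
#'
#' Applies the stage's stored standardization (imaging features by name,
#' clinical scores if the stage used them) and returns the oriented linear
#' predictor per subject.
#'
#' @param model an `apv_stage_model`.
#' @param m an `apv_feature_matrix` with the same feature names.
#' @return named numeric vector of ApV scores.
#' @export
predict_stage <- function(model, m) {
  sel <- model$selected
  std <- model$standardization
  img_sel <- intersect(sel, std$features)
  missing <- setdiff(img_sel, colnames(m$values))
  if (length(missing))
    stop_apv("apv_schema_error", "matrix lacks selected features: %s",
             paste(utils::head(missing, 5), collapse = ", "))
  z <- standardize_apply(subset_cols_like(m$values, std$features), std)
  Z <- z[, img_sel, drop = FALSE]
  score_sel <- setdiff(sel, std$features)
  if (length(score_sel)) {
    if (is.null(m$scores) ||
        length(setdiff(score_sel, colnames(m$scores))))
      stop_apv("apv_schema_error", "matrix lacks selected clinical scores")
    zs <- standardize_apply(
      subset_cols_like(m$scores, model$score_standardization$features),
      model$score_standardization)
    Z <- cbind(Z, zs[, score_sel, drop = FALSE])
  }
  w <- model$weights[colnames(Z)]
  lp <- as.numeric(model$intercept + Z %*% w)
  stats::setNames(model$orientation * lp, m$subject_ids)
}

# reorder/validate columns against a reference feature-name vector
subset_cols_like <- function(values, features) {
  missing <- setdiff(features, colnames(values))
  if (length(missing))
    stop_apv("apv_schema_error", "missing %d expected columns (e.g. %s)",
             length(missing), missing[1])
  values[, features, drop = FALSE]
}

#' Fit the two-stage ApV cascade
#'
#' Stage 1 separates subjects without AD-related pathology (`nADrp`) from
#' those with it (`MCI_AD` + `AD`); stage 2 separates prodromal (`MCI_AD`)
#' from established (`AD`) disease, trained on the true stage-2 labels. At
#' deployment stage-1 positives are routed to stage 2.
#'
#' @param m training `apv_feature_matrix` with groups in
#'   `{nADrp, MCI_AD, AD}`.
#' @param include_scores fit the ApV_s variants (clinical scores as
#'   candidates).
#' @param region_set label recorded in the model (extraction is upstream).
#' @param catalogue_hash catalogue fingerprint recorded in the model.
#' @param ... passed to [fit_stage()] (family, folds, seed, ...).
#' @return list of class `apv_cascade_model` with `stage1`, `stage2`.
#' @export
fit_cascade <- function(m, include_scores = FALSE, region_set = "ALL115",
                        catalogue_hash = NA_character_, ...) {
  bad <- setdiff(unique(m$groups), c("nADrp", "MCI_AD", "AD"))
  if (length(bad))
    stop_apv("apv_label_error",
             "cascade groups must be nADrp/MCI_AD/AD (got %s); see collapse_supergroups()",
             paste(bad, collapse = ", "))
  s_suffix <- if (include_scores) "s" else ""
  stage1 <- fit_stage(m, contrast = list(negative = "nADrp",
                                         positive = c("MCI_AD", "AD")),
                      include_scores = include_scores,
                      tag = paste0("ApV1", s_suffix), ...)
  stage2 <- fit_stage(m, contrast = list(negative = "MCI_AD",
                                         positive = "AD"),
                      include_scores = include_scores,
                      tag = paste0("ApV2", s_suffix), ...)
  structure(list(stage1 = stage1, stage2 = stage2,
                 region_set = region_set, catalogue_hash = catalogue_hash,
                 include_scores = include_scores),
            class = "apv_cascade_model")
}

#' Cascade triage prediction
#'
#' Stage-1 score below its threshold labels the subject `nADrp` (the
#' stage-2 score is still reported, flagged unused); otherwise the stage-2
#' score below its threshold labels `MCI_AD`, else `AD`.
#'
#' @param cascade an `apv_cascade_model`.
#' @param m an `apv_feature_matrix` of subjects to classify.
#' @return data.frame `subject_id`, `apv1`, `apv2`, `stage2_used`, `label`.
#' @export
cascade_predict <- function(cascade, m) {
  s1 <- predict_stage(cascade$stage1, m)
  s2 <- predict_stage(cascade$stage2, m)
  pos1 <- s1 >= cascade$stage1$threshold
  pos2 <- s2 >= cascade$stage2$threshold
  label <- ifelse(!pos1, "nADrp", ifelse(!pos2, "MCI_AD", "AD"))
  data.frame(subject_id = m$subject_ids, apv1 = as.numeric(s1),
             apv2 = as.numeric(s2), stage2_used = pos1, label = label,
             stringsAsFactors = FALSE)
}

#' Collapse raw diagnostic groups into the cascade vocabulary
#'
#' @param groups raw labels (e.g. CN, PD, FTD, MCI_AD, AD).
#' @param nadrp labels mapped to `nADrp` (default CN/PD/FTD/nADrp).
#' @return character vector over `{nADrp, MCI_AD, AD}`.
#' @export
collapse_supergroups <- function(groups,
                                 nadrp = c("CN", "PD", "FTD", "nADrp")) {
  out <- ifelse(groups %in% nadrp, "nADrp", as.character(groups))
  bad <- setdiff(unique(out), c("nADrp", "MCI_AD", "AD"))
  if (length(bad))
    stop_apv("apv_label_error", "unmappable group labels: %s",
             paste(bad, collapse = ", "))
  out
}
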
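std_to_list <- function(p) {
  if (is.null(p)) return(NULL)
  list(features = p$features, mean = unname(p$mean), sd = unname(p$sd),
       flagged = unname(p$flagged))
}

std_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  feats <- unlist(x$features)
  structure(list(mean = stats::setNames(unlist(x$mean), feats),
                 sd = stats::setNames(unlist(x$sd), feats),
                 flagged = stats::setNames(as.logical(unlist(x$flagged)),
                                           feats),
                 features = feats),
            class = "apv_standardization")
}

stage_to_list <- function(s) {
  list(tag = s$tag,
       weights = as.list(s$weights),
       intercept = s$intercept,
       orientation = s$orientation,
       selected = s$selected,
       lambda_min = s$lambda_min,
       threshold = s$threshold,
       standardization = std_to_list(s$standardization),
       score_standardization = std_to_list(s$score_standardization),
       kept_features = s$screening$feature[s$screening$kept],
       contrast = s$contrast,
       include_scores = s$include_scores,
       family = s$family, folds = s$folds, seed = s$seed,
       train_auc = s$train_auc)
}

stage_from_list <- function(x) {
  structure(list(tag = x$tag,
                 weights = unlist(x$weights),
                 intercept = x$intercept,
                 orientation = x$orientation,
                 selected = unlist(x$selected),
                 lambda_min = x$lambda_min,
                 threshold = x$threshold,
                 standardization = std_from_list(x$standardization),
                 score_standardization =
                   std_from_list(x$score_standardization),
                 screening = data.frame(
                   feature = unlist(x$kept_features) %||% character(0),
                   kept = TRUE, stringsAsFactors = FALSE),
                 contrast = lapply(x$contrast, unlist),
                 include_scores = isTRUE(x$include_scores),
                 family = x$family, folds = x$folds, seed = x$seed,
                 train_auc = x$train_auc),
            class = "apv_stage_model")
}

#' Serialize / restore a cascade model as JSON
#'
#' Persists everything prediction needs: per-stage weights, intercepts,
#' orientations, thresholds, chosen lambdas, standardization parameters and
#' the catalogue hash, so a reloaded model refuses feature tables built
#' under a different catalogue only by its own checks upstream.
#'
#' @param model an `apv_cascade_model`.
#' @param path JSON path.
#' @return `path` invisibly; `read_cascade_model` returns the model.
#' @export
write_cascade_model <- function(model, path) {
  jsonlite::write_json(
    list(stage1 = stage_to_list(model$stage1),
         stage2 = stage_to_list(model$stage2),
         region_set = model$region_set,
         catalogue_hash = model$catalogue_hash,
         include_scores = model$include_scores),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_cascade_model
#' @export
read_cascade_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(list(stage1 = stage_from_list(x$stage1),
                 stage2 = stage_from_list(x$stage2),
                 region_set = x$region_set,
                 catalogue_hash = x$catalogue_hash,
                 include_scores = isTRUE(x$include_scores)),
            class = "apv_cascade_model")
}

#' Run configuration for the pipeline
#'
#' @param region_set `"ALL115"`, `"WM45"` or `"CTX70"`.
#' @param cat feature catalogue.
#' @param regions region table.
#' @param test screening test.
#' @param fdr_level FDR level.
#' @param family,folds LASSO settings.
#' @param seed master seed (folds, split).
#' @param include_scores fit ApV_s variants.
#' @param split_fraction training fraction.
#' @param target_spacing isotropic resampling target (mm).
#' @param out_dir artefact directory.
#' @return list of class `apv_run_config`.
#' @export
run_config <- function(region_set = "ALL115", cat = default_catalogue(),
                       regions = default_region_table(),
                       test = "mann_whitney", fdr_level = 0.05,
                       family = "binomial", folds = 10L, seed = 1L,
                       include_scores = FALSE, split_fraction = 0.7,
                       target_spacing = 1.0, out_dir = ".") {
  if (split_fraction <= 0 || split_fraction >= 1)
    stop_apv("apv_validation_error", "split_fraction must lie in (0, 1)")
  structure(list(region_set = region_set, cat = cat, regions = regions,
                 test = test, fdr_level = fdr_level, family = family,
                 folds = folds, seed = seed,
                 include_scores = include_scores,
                 split_fraction = split_fraction,
                 target_spacing = target_spacing, out_dir = out_dir),
            class = "apv_run_config")
}

#' Batch feature extraction from a subject manifest
#'
#' Reads each subject's volume and label map, resamples to the isotropic
#' target when needed, extracts the catalogue features, and writes one CSV
#' row per subject (first column `subject_id`). Per-subject failures are
#' logged and skipped; the run continues.
#'
#' @param config an [run_config()].
#' @param manifest data.frame with columns `subject_id`, `volume`,
#'   `labelmap` (file paths).
#' @param out_csv output CSV path (default `features.csv` under the config's
#'   `out_dir`).
#' @return list with `table` (path), `n_ok`, `failures` (named character
#'   vector of error messages).
#' @export
run_extract <- function(config, manifest,
                        out_csv = file.path(config$out_dir, "features.csv")) {
  need <- c("subject_id", "volume", "labelmap")
  if (!nrow(manifest) || !all(need %in% names(manifest)))
    stop_apv("apv_usage_error",
             "manifest needs >= 1 row and columns %s",
             paste(need, collapse = ", "))
  rows <- list(); failures <- character(0)
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    res <- tryCatch({
      vol <- read_volume(manifest$volume[i])
      map <- read_labelmap(manifest$labelmap[i], config$regions)
      iso <- resample_isotropic(vol, map, config$target_spacing)
      extract_subject_features(iso$volume, iso$labelmap, config$regions,
                               config$cat, config$region_set)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[sid] <- conditionMessage(res)
      message(sprintf("extraction failed for %s: %s", sid,
                      conditionMessage(res)))
    } else rows[[sid]] <- res
  }
  if (length(rows)) {
    mat <- do.call(rbind, rows)
    df <- data.frame(subject_id = names(rows), mat, check.names = FALSE,
                     stringsAsFactors = FALSE)
    dir.create(dirname(out_csv), recursive = TRUE, showWarnings = FALSE)
    write.csv(df, out_csv, row.names = FALSE)
  }
  list(table = if (length(rows)) out_csv else NULL,
       n_ok = length(rows), failures = failures)
}

#' Read a feature CSV back into a matrix
#' @param path CSV written by [run_extract()].
#' @return numeric matrix with subject-id rownames.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$subject_id
  mat
}

#' Train and evaluate the cascade on a feature table
#'
#' Stratified 70/30 (configurable) split by the config seed; fits the
#' cascade on the training split; writes the model JSON, four report CSVs
#' (per stage, train and validation) plus a cascade confusion CSV and a
#' machine-readable run manifest.
#'
#' @param config an [run_config()].
#' @param features numeric matrix (subjects x features) or path to a
#'   feature CSV.
#' @param groups named character vector or data.frame
#'   (`subject_id`, `group`) covering the table's subjects (raw labels are
#'   collapsed with [collapse_supergroups()]).
#' @param scores optional data.frame keyed by `subject_id` with clinical
#'   score columns.
#' @return list with `model`, `reports` (stage x split), `confusion`
#'   (validation cascade table), `paths`.
#' @export
run_train_eval <- function(config, features, groups, scores = NULL) {
  if (is.character(features)) features <- read_feature_table(features)
  if (is.data.frame(groups)) {
    g <- stats::setNames(as.character(groups$group), groups$subject_id)
  } else g <- groups
  if (!all(rownames(features) %in% names(g)))
    stop_apv("apv_validation_error", "labels must cover all table subjects")
  g <- collapse_supergroups(g[rownames(features)])
  sc <- NULL
  if (!is.null(scores)) {
    sc <- scores[match(rownames(features), scores$subject_id),
                 setdiff(names(scores), "subject_id"), drop = FALSE]
  }
  fm <- feature_matrix(features, g, sc)

  split <- stratified_split(fm$groups, config$split_fraction, config$seed)
  train <- subset_fm(fm, split$train)
  test <- subset_fm(fm, split$test)

  model <- fit_cascade(train, include_scores = config$include_scores,
                       region_set = config$region_set,
                       catalogue_hash = catalogue_hash(config$cat),
                       family = config$family, folds = config$folds,
                       seed = config$seed, test = config$test,
                       fdr_level = config$fdr_level)

  eval_stage <- function(stage, fm_eval) {
    y <- fm_eval$groups %in% stage$contrast$positive
    keep <- fm_eval$groups %in% unlist(stage$contrast)
    s <- predict_stage(stage, subset_fm(fm_eval, keep))
    roc <- roc_auc(s, y[keep])
    diagnostic_report(confusion_at_threshold(s, y[keep], stage$threshold),
                      auc = roc$auc, threshold = stage$threshold)
  }
  reports <- list(stage1_train = eval_stage(model$stage1, train),
                  stage1_validation = eval_stage(model$stage1, test),
                  stage2_train = eval_stage(model$stage2, train),
                  stage2_validation = eval_stage(model$stage2, test))
  pred <- cascade_predict(model, test)
  confusion <- table(truth = test$groups, predicted = pred$label)

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(model = file.path(config$out_dir, "cascade_model.json"),
                manifest = file.path(config$out_dir, "run_manifest.json"),
                predictions = file.path(config$out_dir, "predictions.csv"))
  write_cascade_model(model, paths$model)
  for (nm in names(reports)) {
    p <- file.path(config$out_dir, paste0("report_", nm, ".csv"))
    write.csv(report_table(reports[nm]), p, row.names = FALSE)
    paths[[nm]] <- p
  }
  write.csv(pred, paths$predictions, row.names = FALSE)
  jsonlite::write_json(
    list(seed = config$seed, region_set = config$region_set,
         split_fraction = config$split_fraction,
         include_scores = config$include_scores,
         catalogue_hash = catalogue_hash(config$cat),
         input_hash = fnv1a_hash(list(dim(features),
                                      colnames(features)[1],
                                      sum(features, na.rm = TRUE))),
         n_train = length(split$train), n_test = length(split$test)),
    paths$manifest, auto_unbox = TRUE, digits = NA)
  list(model = model, reports = reports, confusion = confusion,
       predictions = pred, paths = paths, split = split)
}

#' Write a phantom cohort to disk (NIfTI pairs + cohort and truth CSVs)
#'
#' @param cohort an `apv_cohort`.
#' @param dir output directory.
#' @return data.frame manifest (`subject_id`, `volume`, `labelmap`,
#'   `group`), invisibly; also written as `cohort.csv`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$subjects, function(s) {
    vp <- file.path(dir, paste0(s$id, "_T1w.nii.gz"))
    lp <- file.path(dir, paste0(s$id, "_labels.nii.gz"))
    write_volume(s$volume, vp)
    write_volume(s$labelmap, lp)
    data.frame(subject_id = s$id, volume = vp, labelmap = lp,
               group = s$group, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "cohort.csv"), row.names = FALSE)
  if (!is.null(cohort$truth) && nrow(cohort$truth))
    write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(manifest)
}
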
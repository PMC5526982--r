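#' Load a delimited feature table
#'
#' Reads a CSV/TSV table with a header row, one row per sample, a
#' designated label column and an optional subject column; all remaining
#' columns must be numeric features. Rows with missing or non-finite
#' feature values are rejected with an itemized error naming each offending
#' row and column.
#'
#' @param path file path (delimiter inferred from the extension: `.tsv` /
#'   `.txt` tab, otherwise comma).
#' @param label_col name of the label column.
#' @param subject_col optional name of the subject-identifier column.
#' @return list with `features` (numeric matrix, original column order),
#'   `labels` (factor), `subjects` (character or `NULL`).
#' @export
load_table <- function(path, label_col = "label", subject_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("empty table: ", path, call. = FALSE)
  if (!label_col %in% names(df))
    stop("label column '", label_col, "' not found", call. = FALSE)
  if (!is.null(subject_col) && !subject_col %in% names(df))
    stop("subject column '", subject_col, "' not found", call. = FALSE)
  feat_cols <- setdiff(names(df), c(label_col, subject_col))
  if (!length(feat_cols)) stop("no feature columns", call. = FALSE)
  non_num <- feat_cols[!vapply(df[feat_cols], is.numeric, logical(1))]
  if (length(non_num))
    stop("non-numeric feature column(s): ", paste(non_num, collapse = ", "),
         call. = FALSE)
  X <- as.matrix(df[feat_cols])
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite feature values at ",
         paste(sprintf("row %d, column '%s'", bad[, 1],
                       feat_cols[bad[, 2]]), collapse = "; "),
         call. = FALSE)
  list(features = X, labels = as.factor(df[[label_col]]),
       subjects = if (is.null(subject_col)) NULL
                  else as.character(df[[subject_col]]))
}

#' Write a feature table (with labels and subjects) as delimited text
#'
#' Inverse of [load_table()]; the written file round-trips losslessly up to
#' numeric printing precision (15 significant digits).
#'
#' @param x a `cka_synth` or a list with `features`, `labels`, `subjects`.
#' @param path output path (`.tsv`/`.txt` for tab, else comma).
#' @export
write_feature_table <- function(x, path) {
  df <- as.data.frame(x$features)
  df$label <- as.character(x$labels)
  if (!is.null(x$subjects)) df$subject <- x$subjects
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param classifiers character subset of `c("knn", "svm", "nn")`.
#' @param knn_grid,svm_grid hyperparameter grids (defaults: the neighbour
#'   counts 1, 3, 5, 7, 9 and soft-margin constants 0.1-1000 by decades).
#' @param nn_grid hidden-layer widths to search; `NULL` selects a log-spaced
#'   grid between C and P - 1 at run time.
#' @param nn_layers hidden layers in the NN (1 or 2).
#' @param nn_epochs fine-tuning epochs.
#' @param variants which variants to run: `"baseline"`, `"cka"` or both.
#' @param test_frac held-out subject fraction.
#' @param cv_folds subject-grouped folds for the grid search.
#' @param fit_cfg [fit_config()] for metric fits / pretraining.
#' @param n_boot bootstrap resamples for the final report.
#' @param seed global seed, fanned out to every stage.
#' @return list of class `cka_pipeline_config`.
#' @export
pipeline_config <- function(classifiers = c("knn", "svm"),
                            knn_grid = c(1, 3, 5, 7, 9),
                            svm_grid = c(0.1, 1, 10, 100, 1000),
                            nn_grid = NULL, nn_layers = 1L, nn_epochs = 150L,
                            variants = c("baseline", "cka"),
                            test_frac = 0.3, cv_folds = 5L,
                            fit_cfg = fit_config(), n_boot = 1000L,
                            seed = 1L) {
  classifiers <- match.arg(classifiers, c("knn", "svm", "nn"),
                           several.ok = TRUE)
  variants <- match.arg(variants, c("baseline", "cka"), several.ok = TRUE)
  structure(list(classifiers = classifiers, knn_grid = knn_grid,
                 svm_grid = svm_grid, nn_grid = nn_grid,
                 nn_layers = as.integer(nn_layers),
                 nn_epochs = as.integer(nn_epochs), variants = variants,
                 test_frac = test_frac, cv_folds = as.integer(cv_folds),
                 fit_cfg = fit_cfg, n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "cka_pipeline_config")
}

#' Run the full train/evaluate pipeline on a cohort
#'
#' Executes the complete experimental protocol on one feature table:
#' subject-grouped 70/30 split, hyperparameter grid search by
#' subject-grouped cross-validation on the training side, final fit and
#' test-set scoring with bootstrap confidence intervals — for the baseline
#' and the CKA-enhanced variant of every requested classifier.
#'
#' @param data a `cka_synth` or a list with `features`, `labels`,
#'   `subjects`.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, models, predictions and
#'   the report table are written there as portable text files.
#' @return list of class `cka_pipeline_result`: `reports` (named list of
#'   [evaluate_predictions()] outputs), `selected` (chosen hyperparameters),
#'   `table` (the formatted [report_table()]), `split` (test indicator),
#'   `seed`.
#' @export
run_pipeline <- function(data, config = pipeline_config(), out_dir = NULL) {
  X <- .as_matrix(data$features)
  labels <- as.factor(data$labels)
  subjects <- if (is.null(data$subjects)) paste0("s", seq_len(nrow(X)))
              else as.character(data$subjects)
  test <- subject_split(subjects, labels, config$test_frac, seed = config$seed)
  stopifnot(!any(subjects[test] %in% subjects[!test]))
  Xtr <- X[!test, , drop = FALSE]; ytr <- droplevels(labels[!test])
  Xte <- X[test, , drop = FALSE];  yte <- droplevels(labels[test])
  str <- subjects[!test]
  folds <- make_subject_folds(str, ytr, k = config$cv_folds,
                              seed = config$seed + 1L)
  reports <- list()
  selected <- list()
  for (fam in config$classifiers) {
    grid <- switch(fam, knn = config$knn_grid, svm = config$svm_grid,
                   nn = {
                     if (!is.null(config$nn_grid)) config$nn_grid
                     else unique(round(exp(seq(log(nlevels(ytr)),
                                               log(ncol(X) - 1),
                                               length.out = 4))))
                   })
    for (variant in config$variants) {
      use_metric <- variant == "cka"
      gs <- grid_search(fam, grid, Xtr, ytr, str, folds,
                        use_metric = use_metric, fit_cfg = config$fit_cfg,
                        nn_layers = config$nn_layers,
                        nn_epochs = config$nn_epochs)
      scores <- NULL
      if (fam == "nn") {
        sizes <- rep(as.integer(gs$best), config$nn_layers)
        stack <- if (use_metric) pretrain_network(Xtr, ytr, sizes, config$fit_cfg)
                 else random_network(Xtr, ytr, sizes, seed = config$fit_cfg$seed)
        stack <- nn_finetune(Xtr, ytr, stack, epochs = config$nn_epochs)
        pred <- predict(stack, Xte)
        scores <- nn_predict(stack, Xte)
        final_model <- stack
      } else {
        model <- if (use_metric) fit_metric(Xtr, ytr, config$fit_cfg) else NULL
        pred <- switch(fam,
          knn = knn_classify(Xtr, ytr, Xte, k = gs$best, model = model),
          svm = svm_classify(Xtr, ytr, Xte, C = gs$best, model = model))
        final_model <- model
      }
      tag <- paste0(if (use_metric) "cka_" else "baseline_", fam)
      reports[[tag]] <- evaluate_predictions(yte, pred, scores = scores,
                                             B = config$n_boot,
                                             seed = config$seed + 2L)
      selected[[tag]] <- gs$best
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(data.frame(subject = subjects[test],
                                    true = as.character(yte),
                                    predicted = as.character(pred)),
                         file.path(out_dir, paste0(tag, "_predictions.csv")),
                         row.names = FALSE)
        if (!is.null(final_model) && use_metric)
          write_cka_model(final_model,
                          file.path(out_dir, paste0(tag, "_model.json")))
        utils::write.csv(gs$cv_table,
                         file.path(out_dir, paste0(tag, "_cv_table.csv")),
                         row.names = FALSE)
      }
    }
  }
  tab <- report_table(reports)
  if (!is.null(out_dir))
    utils::write.csv(cbind(configuration = rownames(tab), tab),
                     file.path(out_dir, "report_table.csv"), row.names = FALSE)
  structure(list(reports = reports, selected = selected, table = tab,
                 split = test, seed = config$seed),
            class = "cka_pipeline_result")
}

#' @export
print.cka_pipeline_result <- function(x, ...) {
  cat("Pipeline report (bootstrap mean, 95% CI; percent):\n")
  print(x$table)
  invisible(x)
}
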
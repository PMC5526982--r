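#' Accuracy and per-class true-positive fractions
#'
#' Computes the overall accuracy `a = (sum_c t_c) / N` and, for every true
#' class c, the true-positive fraction `tau_c = t_c / N_c` (the
#' within-class recall). In a two-class setting the pathological class's
#' tau is the sensitivity and the control class's tau the specificity.
#' `std_tau`, the standard deviation of the per-class fractions, summarizes
#' how balanced the classifier is across classes. Accuracy always equals
#' the class-size-weighted mean of the tau values.
#'
#' @param true,pred equal-length label vectors; every true class must be
#'   non-empty.
#' @return list with `accuracy`, `tpf` (named per-class vector), `std_tau`
#'   (as a percentage), `n` and per-class counts `n_class`.
#' @export
score <- function(true, pred) {
  true <- as.factor(true)
  pred <- factor(as.character(pred), levels = union(levels(true),
                                                    unique(as.character(pred))))
  if (length(true) != length(pred))
    stop("'true' and 'pred' must have equal length", call. = FALSE)
  lev <- levels(droplevels(true))
  if (!length(lev)) stop("no true labels supplied", call. = FALSE)
  n_class <- table(factor(as.character(true), levels = lev))
  if (any(n_class == 0)) stop("every true class must be non-empty", call. = FALSE)
  correct <- as.character(true) == as.character(pred)
  tpf <- vapply(lev, function(cl) mean(correct[as.character(true) == cl]),
                numeric(1))
  list(accuracy = mean(correct), tpf = tpf,
       std_tau = 100 * stats::sd(tpf), n = length(true),
       n_class = as.integer(n_class))
}

.measure_value <- function(true, pred, measure, class = NULL) {
  s <- score(true, pred)
  switch(measure,
         accuracy = s$accuracy,
         tpf = unname(s$tpf[class]),
         std_tau = s$std_tau,
         stop("unknown measure '", measure, "'", call. = FALSE))
}

#' Bootstrap mean and 95% percentile confidence interval of a test-set
#' performance measure
#'
#' Resamples the test indices with replacement `B` times, recomputes the
#' measure on every resample, and reports the replicate mean with the
#' 2.5/97.5 percentile interval. A resample that lacks a class required by
#' the measure is redrawn (the count of redraws is returned).
#'
#' @param true,pred test-set labels and predictions.
#' @param measure `"accuracy"`, `"tpf"` (needs `class`) or `"std_tau"`.
#' @param class class identifier for `measure = "tpf"`.
#' @param B number of bootstrap resamples (the default 1000 matches
#'   common practice for test-set CIs).
#' @param seed integer seed; fixed seed gives bit-reproducible output.
#' @return list with `mean`, `low`, `high`, `point` (the plain point
#'   estimate), `replicates` (length-B vector, for significance
#'   comparisons), `redraws`.
#' @export
bootstrap_ci <- function(true, pred, measure = "accuracy", class = NULL,
                         B = 1000L, seed = 1L) {
  if (B < 1) stop("'B' must be >= 1", call. = FALSE)
  true <- as.factor(true)
  pred <- factor(as.character(pred), levels = levels(true))
  n <- length(true)
  need <- if (measure == "tpf") class else levels(droplevels(true))
  set.seed(seed)
  reps <- numeric(B)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (all(need %in% as.character(true[idx]))) break
      redraws <- redraws + 1L
      if (redraws > 1000L * B)
        stop("cannot draw resamples containing every required class",
             call. = FALSE)
    }
    reps[b] <- .measure_value(true[idx], pred[idx], measure, class)
  }
  q <- unname(stats::quantile(reps, c(0.025, 0.975), type = 7))
  list(mean = mean(reps), low = q[1], high = q[2],
       point = .measure_value(true, pred, measure, class),
       replicates = reps, redraws = redraws)
}

#' Significance of an improvement between two replicate sets
#'
#' Welch two-sample t-test comparing bootstrap replicate vectors of a
#' baseline classifier and its metric-enhanced version, one-sided in the
#' direction "enhanced exceeds baseline", judged at the 1% level.
#'
#' @param baseline,enhanced numeric replicate vectors (length >= 2).
#' @param alpha significance level (default 0.01).
#' @return list with `statistic`, `p_value`, `significant`.
#' @export
compare_significance <- function(baseline, enhanced, alpha = 0.01) {
  if (length(baseline) < 2 || length(enhanced) < 2)
    stop("both replicate vectors need length >= 2", call. = FALSE)
  if (stats::sd(baseline) == 0 && stats::sd(enhanced) == 0) {
    # degenerate: no variability; equal means are uninformative
    p <- if (mean(enhanced) > mean(baseline)) 0 else 1
    return(list(statistic = NA_real_, p_value = p,
                significant = p < alpha))
  }
  tt <- stats::t.test(enhanced, baseline, alternative = "greater",
                      var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       significant = tt$p.value < alpha)
}

#' One-vs-rest per-class AUC
#'
#' Rank-based (Mann-Whitney) area under the ROC curve for each class
#' against the rest, using that class's score column; ties are handled
#' mid-rank. The direction is fixed so that scores ranking the class above
#' the rest give AUC > 0.5 (null data gives about 0.5, never inflated).
#'
#' @param true length-N label vector.
#' @param scores N x C numeric score matrix with one column per class
#'   (column names matching the class levels, or columns in level order).
#' @return list with `auc` (named per-class vector) and `mean_auc`.
#' @export
per_class_auc <- function(true, scores) {
  true <- as.factor(true)
  scores <- .as_matrix(scores, "scores")
  lev <- levels(droplevels(true))
  if (ncol(scores) != length(lev))
    stop("'scores' must have one column per class", call. = FALSE)
  if (is.null(colnames(scores))) colnames(scores) <- lev
  if (!all(lev %in% colnames(scores)))
    stop("score columns do not match the class levels", call. = FALSE)
  aucs <- vapply(lev, function(cl) {
    resp <- factor(ifelse(as.character(true) == cl, "pos", "neg"),
                   levels = c("neg", "pos"))
    if (length(unique(resp)) < 2)
      stop("class '", cl, "' is missing from 'true'", call. = FALSE)
    as.numeric(pROC::auc(pROC::roc(resp, scores[, cl], levels = c("neg", "pos"),
                                   direction = "<", quiet = TRUE)))
  }, numeric(1))
  list(auc = aucs, mean_auc = mean(aucs))
}

#' Format evaluation reports as a performance table
#'
#' Renders one row per configuration in the style
#' `60.1 (56.9-62.7)` — the bootstrap mean with its 95% CI, all on the
#' percent scale with one decimal — for the accuracy and every per-class
#' true-positive fraction, plus `std_tau`.
#'
#' @param reports named list of evaluation reports as produced by
#'   [evaluate_predictions()].
#' @return data.frame with character columns, one row per report, in the
#'   order given.
#' @export
report_table <- function(reports) {
  fmt <- function(m, lo, hi)
    sprintf("%.1f (%.1f-%.1f)", 100 * m, 100 * lo, 100 * hi)
  classes <- names(reports[[1]]$tpf_ci)
  rows <- lapply(reports, function(r) {
    row <- c(fmt(r$accuracy_ci$mean, r$accuracy_ci$low, r$accuracy_ci$high),
             vapply(classes, function(cl)
               fmt(r$tpf_ci[[cl]]$mean, r$tpf_ci[[cl]]$low,
                   r$tpf_ci[[cl]]$high), character(1)),
             sprintf("%.1f", r$std_tau))
    stats::setNames(as.list(row),
                    c("a (CI)", paste0("tau_", classes, " (CI)"), "std_tau (%)"))
  })
  out <- do.call(rbind, lapply(rows, as.data.frame, check.names = FALSE))
  rownames(out) <- names(reports)
  out
}

#' Full evaluation of test-set predictions
#'
#' Bundles [score()], per-measure [bootstrap_ci()] and (when scores are
#' given) [per_class_auc()] into one report, the unit consumed by
#' [report_table()].
#'
#' @param true,pred test labels and predictions.
#' @param scores optional N x C score matrix for AUCs.
#' @param B bootstrap resamples.
#' @param seed integer seed.
#' @return list of class `cka_eval`: `accuracy`, `tpf`, `std_tau`,
#'   `accuracy_ci`, `tpf_ci` (per class), optional `auc`/`mean_auc`,
#'   `n_resamples`, `seed`.
#' @export
evaluate_predictions <- function(true, pred, scores = NULL, B = 1000L,
                                 seed = 1L) {
  s <- score(true, pred)
  acc_ci <- bootstrap_ci(true, pred, "accuracy", B = B, seed = seed)
  lev <- names(s$tpf)
  tpf_ci <- lapply(stats::setNames(lev, lev), function(cl)
    bootstrap_ci(true, pred, "tpf", class = cl, B = B, seed = seed))
  out <- list(accuracy = s$accuracy, tpf = s$tpf, std_tau = s$std_tau,
              accuracy_ci = acc_ci[c("mean", "low", "high")],
              tpf_ci = lapply(tpf_ci, `[`, c("mean", "low", "high")),
              accuracy_replicates = acc_ci$replicates,
              n_resamples = B, seed = seed)
  if (!is.null(scores)) {
    a <- per_class_auc(true, scores)
    out$auc <- a$auc
    out$mean_auc <- a$mean_auc
  }
  class(out) <- "cka_eval"
  out
}

#' @export
print.cka_eval <- function(x, ...) {
  cat(sprintf("accuracy %.1f%% (95%% CI %.1f-%.1f), std_tau %.1f%%\n",
              100 * x$accuracy_ci$mean, 100 * x$accuracy_ci$low,
              100 * x$accuracy_ci$high, x$std_tau))
  for (cl in names(x$tpf))
    cat(sprintf("  tau_%s %.1f%% (%.1f-%.1f)\n", cl, 100 * x$tpf_ci[[cl]]$mean,
                100 * x$tpf_ci[[cl]]$low, 100 * x$tpf_ci[[cl]]$high))
  if (!is.null(x$auc))
    cat(sprintf("  mean AUC %.3f (%s)\n", x$mean_auc,
                paste(sprintf("%s %.3f", names(x$auc), x$auc), collapse = ", ")))
  invisible(x)
}
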
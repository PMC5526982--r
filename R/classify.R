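#' k-nearest-neighbour classification in the (learned) metric space
#'
#' Majority vote among the `k` nearest training samples under Euclidean
#' distance, optionally after projecting both sets with a learned metric.
#' Vote ties are broken deterministically: the tied class with the smallest
#' summed neighbour distance wins, then the smallest class index.
#'
#' @param train_x,train_y training features (N x P) and class labels.
#' @param test_x test features (M x P).
#' @param k odd positive neighbour count, `k <= nrow(train_x)`.
#' @param model optional `cka_metric`; when given, both sets are projected
#'   with [metric_transform()] first.
#' @return factor of M predicted labels with the training class levels.
#' @export
knn_classify <- function(train_x, train_y, test_x, k = 1L, model = NULL) {
  train_x <- .as_matrix(train_x, "train_x")
  test_x <- .as_matrix(test_x, "test_x")
  train_y <- as.factor(train_y)
  if (length(train_y) != nrow(train_x))
    stop("'train_y' length must equal nrow(train_x)", call. = FALSE)
  if (k < 1 || k > nrow(train_x))
    stop("'k' must be in [1, nrow(train_x)]", call. = FALSE)
  if (!is.null(model)) {
    train_x <- metric_transform(model, train_x)
    test_x <- metric_transform(model, test_x)
  }
  sq_tr <- rowSums(train_x^2)
  sq_te <- rowSums(test_x^2)
  D2 <- outer(sq_te, sq_tr, "+") - 2 * tcrossprod(test_x, train_x)
  D2[D2 < 0] <- 0
  lev <- levels(train_y)
  pred <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    ord <- order(D2[i, ], seq_len(ncol(D2)))[seq_len(k)]
    votes <- table(train_y[ord])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1L) {
      sums <- vapply(top, function(cl)
        sum(sqrt(D2[i, ord[train_y[ord] == cl]])), numeric(1))
      top <- top[order(sums, match(top, lev))][1L]
    }
    pred[i] <- top
  }
  factor(pred, levels = lev)
}

#' Gaussian-kernel SVM in the (learned) metric space
#'
#' Soft-margin support vector machine on the Gaussian kernel of the
#' (optionally metric-projected) features, trained by kernlab's SMO-type
#' solver with one-vs-one reduction for more than two classes. The
#' bandwidth defaults to the model's fitted `sigma` (or the median
#' heuristic on the training features when no model is given).
#'
#' @inheritParams knn_classify
#' @param C positive soft-margin regularization constant.
#' @param sigma Gaussian bandwidth; `NULL` uses `model$sigma` or the median
#'   heuristic.
#' @param precomputed compute the kernel matrix explicitly and pass it to
#'   the solver (`TRUE`), or let kernlab evaluate the same radial kernel on
#'   the projected features (`FALSE`, default). Both routes give the same
#'   predictions; the flag exists for testing that identity.
#' @return factor of predicted labels for `test_x`.
#' @export
svm_classify <- function(train_x, train_y, test_x, C = 10, model = NULL,
                         sigma = NULL, precomputed = FALSE) {
  train_x <- .as_matrix(train_x, "train_x")
  test_x <- .as_matrix(test_x, "test_x")
  train_y <- as.factor(train_y)
  if (C <= 0) stop("'C' must be positive", call. = FALSE)
  if (!is.null(model)) {
    train_x <- metric_transform(model, train_x)
    test_x <- metric_transform(model, test_x)
    if (is.null(sigma)) sigma <- model$sigma
  }
  if (is.null(sigma)) sigma <- tune_bandwidth(train_x)
  if (precomputed) {
    Ktr <- gaussian_kernel(train_x, sigma = sigma)
    fit <- kernlab::ksvm(kernlab::as.kernelMatrix(Ktr), train_y,
                         type = "C-svc", C = C)
    sv <- kernlab::SVindex(fit)
    all_x <- rbind(train_x, test_x)
    Kfull <- gaussian_kernel(all_x, sigma = sigma)
    Kte <- Kfull[nrow(train_x) + seq_len(nrow(test_x)), sv, drop = FALSE]
    pred <- kernlab::predict(fit, kernlab::as.kernelMatrix(Kte))
  } else {
    fit <- kernlab::ksvm(train_x, train_y, type = "C-svc", C = C,
                         kernel = "rbfdot",
                         kpar = list(sigma = 1 / (2 * sigma^2)),
                         scaled = FALSE)
    pred <- kernlab::predict(fit, test_x)
  }
  factor(as.character(pred), levels = levels(train_y))
}

#' Fine-tune a network by backpropagation with cross-entropy loss
#'
#' Trains all weights and offsets of a `cka_network` (pretrained or random)
#' by full-batch gradient descent with momentum on the multinomial
#' cross-entropy, with the saturating sigmoid in hidden layers and a
#' softmax output.
#'
#' @param X,labels training features and classes.
#' @param stack a `cka_network` ([pretrain_network()] or
#'   [random_network()]).
#' @param epochs number of full-batch epochs.
#' @param learning_rate gradient step size.
#' @param momentum momentum coefficient in \[0, 1).
#' @return the updated `cka_network` with an added `loss_history` (mean
#'   cross-entropy per epoch, element 1 = loss before any update).
#' @export
nn_finetune <- function(X, labels, stack, epochs = 200L, learning_rate = 0.5,
                        momentum = 0.9) {
  stopifnot(inherits(stack, "cka_network"))
  if (!identical(stack$activation, "sigmoid"))
    stop("nn_finetune expects a sigmoid-activated network", call. = FALSE)
  X <- .as_matrix(X)
  labels <- factor(as.character(labels), levels = stack$levels)
  if (anyNA(labels))
    stop("labels contain classes unknown to the network", call. = FALSE)
  N <- nrow(X)
  C <- stack$sizes[length(stack$sizes)]
  Yh <- matrix(0, N, C)
  Yh[cbind(seq_len(N), as.integer(labels))] <- 1
  M <- length(stack$layers)
  vel <- lapply(stack$layers, function(l)
    list(W = matrix(0, nrow(l$W), ncol(l$W)), b = rep(0, length(l$b))))
  loss_history <- numeric(0)
  for (ep in seq_len(epochs)) {
    fwd <- .network_forward(stack, X)
    P <- fwd$probs
    loss <- -mean(log(pmax(P[cbind(seq_len(N), as.integer(labels))], 1e-300)))
    if (!is.finite(loss))
      stop("cross-entropy loss became non-finite; lower the learning rate",
           call. = FALSE)
    loss_history <- c(loss_history, loss)
    delta <- (P - Yh) / N
    grads <- vector("list", M)
    for (m in M:1) {
      grads[[m]] <- list(W = crossprod(fwd$hidden[[m]], delta),
                         b = colSums(delta))
      if (m > 1L) {
        delta <- tcrossprod(delta, stack$layers[[m]]$W)
        Hm <- fwd$hidden[[m]]
        delta <- delta * (2 * Hm * (1 - Hm))
      }
    }
    for (m in seq_len(M)) {
      vel[[m]]$W <- momentum * vel[[m]]$W - learning_rate * grads[[m]]$W
      vel[[m]]$b <- momentum * vel[[m]]$b - learning_rate * grads[[m]]$b
      stack$layers[[m]]$W <- stack$layers[[m]]$W + vel[[m]]$W
      stack$layers[[m]]$b <- stack$layers[[m]]$b + vel[[m]]$b
    }
  }
  fwd <- .network_forward(stack, X)
  loss_history <- c(loss_history,
                    -mean(log(pmax(fwd$probs[cbind(seq_len(N),
                                                   as.integer(labels))],
                                   1e-300))))
  stack$loss_history <- loss_history
  stack
}

#' Subject-grouped train/test split
#'
#' Assigns roughly `test_frac` of the *subjects* (not samples) to the test
#' set, stratified by class so every class appears on both sides; all scans
#' of one subject land on the same side.
#'
#' @param subjects vector of subject identifiers, one per sample.
#' @param labels class labels, one per sample (a subject's class is taken
#'   from its first sample).
#' @param test_frac fraction of subjects held out.
#' @param seed integer seed.
#' @return logical vector, `TRUE` for test samples.
#' @export
subject_split <- function(subjects, labels, test_frac = 0.3, seed = 1L) {
  subjects <- as.character(subjects)
  labels <- as.factor(labels)
  set.seed(seed)
  subj_class <- tapply(as.character(labels), subjects, function(x) x[1])
  test_subj <- character(0)
  for (cl in unique(subj_class)) {
    s <- names(subj_class)[subj_class == cl]
    n_test <- max(1L, round(test_frac * length(s)))
    test_subj <- c(test_subj, sample(s, n_test))
  }
  subjects %in% test_subj
}

#' Subject-grouped cross-validation folds
#'
#' Partitions subjects into `k` folds, stratified by class, so that all
#' samples of a subject share a fold.
#'
#' @inheritParams subject_split
#' @param k number of folds.
#' @return integer vector of fold ids (1..k), one per sample.
#' @export
make_subject_folds <- function(subjects, labels, k = 5L, seed = 1L) {
  subjects <- as.character(subjects)
  labels <- as.factor(labels)
  set.seed(seed)
  subj_class <- tapply(as.character(labels), subjects, function(x) x[1])
  fold_of <- integer(0)
  nm <- character(0)
  for (cl in unique(subj_class)) {
    s <- sample(names(subj_class)[subj_class == cl])
    fold_of <- c(fold_of, rep_len(seq_len(k), length(s)))
    nm <- c(nm, s)
  }
  names(fold_of) <- nm
  unname(fold_of[subjects])
}

.check_fold_grouping <- function(subjects, folds) {
  tab <- tapply(folds, as.character(subjects), function(f) length(unique(f)))
  bad <- names(tab)[tab > 1]
  if (length(bad))
    stop("subject(s) ", paste(bad, collapse = ", "),
         " appear in more than one fold", call. = FALSE)
  invisible(TRUE)
}

#' Hyperparameter grid search with subject-grouped cross-validation
#'
#' Scores every grid point by mean cross-validated accuracy over
#' subject-grouped folds and returns the winner, breaking ties toward the
#' simpler model (the smaller parameter value). When `use_metric = TRUE` a
#' CKA metric is fitted on each fold's training portion before
#' classification, so the metric never sees validation subjects.
#'
#' @param family `"knn"` (grid over `k`), `"svm"` (grid over `C`) or
#'   `"nn"` (grid over the hidden-layer width).
#' @param grid numeric vector of candidate hyperparameter values.
#' @param X,labels,subjects training data with subject identifiers.
#' @param folds integer fold assignment per sample (see
#'   [make_subject_folds()]); every fold must contain every class.
#' @param use_metric fit a CKA metric (or, for `"nn"`, CKA-pretrain) per
#'   fold before classifying.
#' @param fit_cfg [fit_config()] used for per-fold metric fits.
#' @param nn_layers number of hidden layers for `family = "nn"`.
#' @param nn_epochs fine-tuning epochs for `family = "nn"`.
#' @return list with `best` (selected value), `cv_table` (data.frame of
#'   value, mean accuracy, per-fold accuracies).
#' @export
grid_search <- function(family = c("knn", "svm", "nn"), grid, X, labels,
                        subjects, folds, use_metric = FALSE,
                        fit_cfg = fit_config(), nn_layers = 1L,
                        nn_epochs = 150L) {
  family <- match.arg(family)
  if (!length(grid)) stop("'grid' must be non-empty", call. = FALSE)
  X <- .as_matrix(X)
  labels <- as.factor(labels)
  .check_fold_grouping(subjects, folds)
  kf <- sort(unique(folds))
  for (f in kf)
    if (nlevels(droplevels(labels[folds == f])) < nlevels(droplevels(labels)))
      stop("fold ", f, " does not contain every class", call. = FALSE)
  acc <- matrix(NA_real_, length(grid), length(kf))
  for (fi in seq_along(kf)) {
    tr <- folds != kf[fi]
    model <- NULL
    stack0 <- NULL
    if (use_metric && family != "nn")
      model <- fit_metric(X[tr, , drop = FALSE], labels[tr], fit_cfg)
    for (gi in seq_along(grid)) {
      pred <- switch(family,
        knn = knn_classify(X[tr, , drop = FALSE], labels[tr],
                           X[!tr, , drop = FALSE], k = grid[gi],
                           model = model),
        svm = svm_classify(X[tr, , drop = FALSE], labels[tr],
                           X[!tr, , drop = FALSE], C = grid[gi],
                           model = model),
        nn = {
          sizes <- rep(as.integer(grid[gi]), nn_layers)
          stack <- if (use_metric)
            pretrain_network(X[tr, , drop = FALSE], labels[tr], sizes, fit_cfg)
          else
            random_network(X[tr, , drop = FALSE], labels[tr], sizes,
                           seed = fit_cfg$seed)
          stack <- nn_finetune(X[tr, , drop = FALSE], labels[tr], stack,
                               epochs = nn_epochs)
          predict(stack, X[!tr, , drop = FALSE])
        })
      acc[gi, fi] <- mean(pred == labels[!tr])
    }
  }
  mean_acc <- rowMeans(acc)
  best_i <- order(-mean_acc, grid)[1L]  # ties -> simpler (smaller) value
  cv_table <- data.frame(value = grid, mean_accuracy = mean_acc)
  cv_table <- cbind(cv_table,
                    stats::setNames(as.data.frame(acc),
                                    paste0("fold", kf)))
  list(best = grid[best_i], cv_table = cv_table)
}
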
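test_that("knn matches the exhaustive oracle and handles ties deterministically", {
  # a test point equal to a training point takes that point's label at k = 1
  dat <- two_blob_data(n_per = 10, seed = 1)
  expect_equal(as.character(knn_classify(dat$X, dat$y, dat$X[3, , drop = FALSE],
                                         k = 1)),
               as.character(dat$y[3]))

  set.seed(101)
  for (k in c(1, 3, 5)) {
    tr <- matrix(rnorm(30 * 4), 30, 4)
    y <- factor(sample(c("a", "b", "c"), 30, replace = TRUE))
    te <- matrix(rnorm(8 * 4), 8, 4)
    expect_equal(knn_classify(tr, y, te, k = k), oracle_knn(tr, y, te, k))
  }

  # agreement with class::knn where no vote ties arise (k = 1)
  tr <- matrix(rnorm(40 * 3), 40, 3)
  y <- factor(sample(c("a", "b"), 40, replace = TRUE))
  te <- matrix(rnorm(10 * 3), 10, 3)
  expect_equal(as.character(knn_classify(tr, y, te, k = 1)),
               as.character(class::knn(tr, te, y, k = 1)))

  expect_error(knn_classify(tr, y, te, k = 99), "k")
})

test_that("a metric that suppresses noise gives perfect knn on separated blobs", {
  d <- make_fixture("scale-confounded")
  test <- subject_split(d$subjects, d$labels, 0.3, seed = 3)
  m <- suppressWarnings(fit_metric(d$features[!test, ], d$labels[!test],
                                   fit_config(max_iters = 200, seed = 1)))
  pred <- knn_classify(d$features[!test, ], d$labels[!test],
                       d$features[test, ], k = 1, model = m)
  expect_equal(mean(pred == d$labels[test]), 1)
})

test_that("svm separates a wide-margin toy and is invariant to the kernel route", {
  dat <- two_blob_data(n_per = 12, gap = 8, seed = 7)
  pred_tr <- svm_classify(dat$X, dat$y, dat$X, C = 10)
  expect_equal(mean(pred_tr == dat$y), 1)

  # precomputed kernel and projected-feature routes agree
  d <- make_fixture("tiny3class")
  m <- suppressWarnings(fit_metric(d$features, d$labels,
                                   fit_config(max_iters = 30, seed = 1)))
  te <- matrix(seq_len(18) * 0.3, 3, 6)
  p1 <- svm_classify(d$features, d$labels, te, C = 10, model = m,
                     precomputed = FALSE)
  p2 <- svm_classify(d$features, d$labels, te, C = 10, model = m,
                     precomputed = TRUE)
  expect_equal(p1, p2)

  # classifying transformed features with the plain metric gives the same
  # result as classifying raw features with the learned metric
  Ytr <- metric_transform(m, d$features)
  Yte <- metric_transform(m, te)
  p3 <- svm_classify(Ytr, d$labels, Yte, C = 10, sigma = m$sigma)
  expect_equal(p1, p3)
  expect_error(svm_classify(dat$X, dat$y, dat$X, C = -1), "positive")
})

test_that("softmax backprop gradient matches finite differences", {
  set.seed(111)
  X <- matrix(rnorm(6 * 4), 6, 4)
  y <- factor(c("a", "b", "c", "a", "b", "c"))
  st <- random_network(X, y, sizes = 3, seed = 2)
  # loss as a function of one hidden weight and one output weight
  loss_of <- function(stack) {
    P <- nn_predict(stack, X)
    -mean(log(P[cbind(1:6, as.integer(y))]))
  }
  for (layer in 1:2) {
    G_fd <- fd_grad(function(w) {
      s <- st; s$layers[[layer]]$W <- w; loss_of(s)
    }, st$layers[[layer]]$W, h = 1e-6)
    # one epoch at zero momentum and tiny rate exposes the analytic gradient
    upd <- nn_finetune(X, y, st, epochs = 1, learning_rate = 1e-4,
                       momentum = 0)
    G_an <- (st$layers[[layer]]$W - upd$layers[[layer]]$W) / 1e-4
    expect_lt(max(abs(G_an - G_fd) / (abs(G_fd) + 1e-6)), 1e-3)
  }
})

test_that("fine-tuning decreases the loss and keeps softmax normalized", {
  d <- make_fixture("tiny3class")
  st <- suppressWarnings(pretrain_network(d$features, d$labels, sizes = 4,
                                          fit_config(max_iters = 30, seed = 1)))
  ft <- nn_finetune(d$features, d$labels, st, epochs = 120,
                    learning_rate = 0.3)
  expect_lt(rev(ft$loss_history)[1], ft$loss_history[1])
  P <- nn_predict(ft, d$features)
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-12)
  expect_gt(mean(predict(ft, d$features) == d$labels), 0.9)
})

test_that("subject grouping is never violated by splits or folds", {
  d <- make_fixture("tiny3class")
  test <- subject_split(d$subjects, d$labels, 0.3, seed = 2)
  expect_true(length(intersect(d$subjects[test], d$subjects[!test])) == 0)
  folds <- make_subject_folds(d$subjects, d$labels, k = 3, seed = 2)
  expect_true(all(tapply(folds, d$subjects,
                         function(f) length(unique(f))) == 1))
  # duplicated subject across folds is rejected
  bad <- folds
  bad[which(d$subjects == d$subjects[1])[1]] <- (bad[1] %% 3) + 1
  expect_error(grid_search("knn", 1, d$features, d$labels, d$subjects, bad),
               "more than one fold")
})

test_that("grid search returns single-point grids and prefers simpler ties", {
  d <- make_fixture("tiny3class")
  folds <- make_subject_folds(d$subjects, d$labels, k = 3, seed = 1)
  gs <- grid_search("knn", 3, d$features, d$labels, d$subjects, folds)
  expect_equal(gs$best, 3)
  expect_equal(nrow(gs$cv_table), 1)
  expect_true(all(gs$cv_table$mean_accuracy >= 0 &
                    gs$cv_table$mean_accuracy <= 1))
  # identical accuracies across the grid resolve to the smallest value
  d0 <- make_fixture("scale-confounded")
  folds0 <- make_subject_folds(d0$subjects, d0$labels, k = 3, seed = 1)
  gs0 <- grid_search("knn", c(5, 1, 3), d0$features, d0$labels, d0$subjects,
                     folds0)
  ma <- gs0$cv_table$mean_accuracy
  if (max(ma) - min(ma) < 1e-12) expect_equal(gs0$best, 1)
  expect_identical(gs0$cv_table,
                   grid_search("knn", c(5, 1, 3), d0$features, d0$labels,
                               d0$subjects, folds0)$cv_table)
})

test_that("label-noise overfitting pushes grid search away from k = 1", {
  # inject 30% label noise into well-separated blobs; k = 1 memorizes the
  # noise (expected CV accuracy 1 - 2p(1-p) = 0.58) while a large k votes
  # it away (expected 1 - p = 0.7)
  set.seed(121)
  dat <- two_blob_data(n_per = 100, gap = 8, seed = 9)
  y <- dat$y
  flip <- sample(length(y), 60)
  y[flip] <- ifelse(y[flip] == "a", "b", "a")
  subjects <- paste0("s", seq_along(y))
  folds <- make_subject_folds(subjects, y, k = 5, seed = 3)
  gs <- grid_search("knn", c(1, 3, 5, 7, 9), dat$X, y, subjects, folds)
  expect_gt(gs$best, 1)
})
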
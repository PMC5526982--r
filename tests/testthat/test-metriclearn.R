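test_that("pca_init recovers dominant variance directions deterministically", {
  set.seed(71)
  # variance concentrated on axis 1
  X <- cbind(rnorm(60, sd = 10), rnorm(60, sd = 0.1))
  W <- pca_init(X, 1)
  expect_equal(abs(W[1, 1]), 1, tolerance = 1e-3)
  # sign convention: largest-magnitude element positive
  expect_gt(W[which.max(abs(W[, 1])), 1], 0)

  # d = P on full-rank data gives an orthonormal basis
  X <- matrix(rnorm(50 * 4), 50, 4)
  W <- pca_init(X, 4)
  expect_equal(crossprod(W), diag(4), tolerance = 1e-10)

  # matches a brute-force eigendecomposition of the covariance
  X <- matrix(rnorm(50 * 6), 50, 6)
  W3 <- pca_init(X, 3)
  ev <- eigen(stats::cov(X), symmetric = TRUE)
  v_oracle <- ev$values[1:3]
  v_pca <- diag(crossprod(W3, stats::cov(X) %*% W3))
  expect_equal(v_pca, v_oracle, tolerance = 1e-8)

  expect_error(pca_init(X, 0), "'d'")
  expect_error(pca_init(X, 7), "'d'")
})

test_that("bandwidth tuning sits on the scale of projected distances", {
  # two points at projected distance 2 -> median heuristic gives 2
  X <- matrix(c(0, 2), ncol = 1)
  expect_equal(tune_bandwidth(X), 2)

  set.seed(81)
  X <- matrix(rnorm(20 * 3), 20, 3)
  s <- tune_bandwidth(X)
  # duplicating every sample leaves the positive-distance multiset's median
  # unchanged
  expect_equal(tune_bandwidth(rbind(X, X)), s, tolerance = 1e-12)
  # homogeneity: scaling the data scales sigma
  expect_equal(tune_bandwidth(3 * X), 3 * s, tolerance = 1e-12)
  expect_error(tune_bandwidth(matrix(1, 5, 2)), "identical")
  expect_gt(tune_bandwidth(X, method = "maxvar"), 0)
})

test_that("fit_metric decreases the cost monotonically and improves on PCA", {
  d <- make_fixture("tiny3class")
  m <- fit_metric(d$features, d$labels, fit_config(max_iters = 80, seed = 1))
  expect_true(all(diff(m$fit_history$cost) <= 1e-12))
  expect_gte(m$rho, m$fit_history$rho[1])
  expect_true(all(is.finite(m$W)))
  expect_gt(m$sigma, 0)
})

test_that("fit_metric is deterministic given the seed", {
  d <- make_fixture("tiny3class")
  cfg <- fit_config(max_iters = 25, seed = 9)
  m1 <- suppressWarnings(fit_metric(d$features, d$labels, cfg))
  m2 <- suppressWarnings(fit_metric(d$features, d$labels, cfg))
  expect_identical(m1$fit_history, m2$fit_history)
  expect_identical(m1$W, m2$W)
})

test_that("restarting at a converged solution changes nothing", {
  d <- make_fixture("tiny3class")
  m <- fit_metric(d$features, d$labels,
                  fit_config(max_iters = 2000, tolerance = 1e-12, seed = 1))
  # at the optimum the gradient is (numerically) zero
  Xs <- sweep(sweep(d$features, 2, m$center), 2, m$scale, "/")
  Kl_c <- center_kernel(label_kernel(d$labels))
  g <- cka_cost_grad(m$W, Xs, Kl_c, m$sigma)$grad
  expect_lt(sqrt(sum(g^2)), 1e-4)
  cost0 <- cka_cost_grad(m$W, Xs, Kl_c, m$sigma)$cost
  refit <- ckametric:::.fit_projection(Xs, Kl_c, m$W, m$sigma,
                                       fit_config(max_iters = 50, seed = 1))
  expect_lte(abs(refit$cost - cost0), 1e-7 * max(1, abs(cost0)))
  expect_lte(nrow(refit$history), 2)
})

test_that("the learned metric recovers the discriminative feature", {
  d <- make_fixture("scale-confounded")
  m <- suppressWarnings(fit_metric(d$features, d$labels,
                                   fit_config(max_iters = 400,
                                              tolerance = 1e-9, seed = 1)))
  rn <- sqrt(rowSums(m$W^2))
  expect_gt(rn[1], 5 * max(rn[-1]))
  # unstandardized PCA would have picked the large-scale noise instead
  W_raw <- pca_init(d$features, 1)
  expect_lt(abs(W_raw[1, 1]), 0.1)
})

test_that("alignment never falls below its PCA initialization across seeds", {
  ok <- sapply(1:10, function(s) {
    d <- make_fixture("tiny3class", seed = 100 + s)
    m <- suppressWarnings(fit_metric(d$features, d$labels,
                                     fit_config(max_iters = 60, seed = 1)))
    m$rho >= m$fit_history$rho[1] - 1e-12
  })
  expect_true(all(ok))
})

test_that("transform reproduces generalized Euclidean distances", {
  d <- make_fixture("tiny3class")
  m <- suppressWarnings(fit_metric(d$features, d$labels,
                                   fit_config(max_iters = 20, seed = 1)))
  Y <- metric_transform(m, d$features)
  expect_equal(dim(Y), c(nrow(d$features), m$d))
  # Euclidean distance in Y equals the W-metric distance in standardized X
  Xs <- sweep(sweep(d$features, 2, m$center), 2, m$scale, "/")
  M <- tcrossprod(m$W)
  i <- 3; j <- 17
  dxy <- sqrt(sum((Y[i, ] - Y[j, ])^2))
  dM <- sqrt(drop((Xs[i, ] - Xs[j, ]) %*% M %*% (Xs[i, ] - Xs[j, ])))
  expect_equal(dxy, dM, tolerance = 1e-10)
  # kernel consistency: plain Gaussian on Y equals projected kernel on Xs
  expect_equal(gaussian_kernel(Y, sigma = m$sigma),
               gaussian_kernel(Xs, m$W, sigma = m$sigma), tolerance = 1e-12)
  expect_equal(predict(m, d$features), Y)
  expect_error(metric_transform(m, d$features[, 1:3]), "columns")
})

test_that("minibatch stochastic gradient also improves alignment", {
  d <- make_fixture("tiny3class")
  cfg <- fit_config(max_iters = 30, batch_size = 10, learning_rate = 0.5,
                    seed = 4)
  m <- suppressWarnings(fit_metric(d$features, d$labels, cfg))
  expect_gt(m$rho, m$fit_history$rho[1])
})

test_that("model serialization round-trips bit-exactly", {
  d <- make_fixture("tiny3class")
  m <- suppressWarnings(fit_metric(d$features, d$labels,
                                   fit_config(max_iters = 25, seed = 2)))
  f <- withr::local_tempfile(fileext = ".json")
  write_cka_model(m, f)
  m2 <- read_cka_model(f)
  expect_identical(unclass(m)[sort(names(unclass(m)))],
                   unclass(m2)[sort(names(unclass(m2)))])
  st <- suppressWarnings(pretrain_network(d$features, d$labels, sizes = 4,
                                          fit_config(max_iters = 15, seed = 3)))
  f2 <- withr::local_tempfile(fileext = ".json")
  write_cka_model(st, f2)
  st2 <- read_cka_model(f2)
  expect_identical(st$layers, st2$layers)
  expect_identical(st$sigmas, st2$sigmas)
  expect_identical(st$alignments, st2$alignments)
})
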
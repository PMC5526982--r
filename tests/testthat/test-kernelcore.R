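test_that("projected Gaussian kernel matches its definition", {
  # hand value: two scalar points at distance 1, identity projection
  X <- matrix(c(0, 1), ncol = 1)
  K <- gaussian_kernel(X, W = matrix(1), sigma = 1)
  expect_equal(K[1, 2], exp(-1 / 2), tolerance = 1e-14)
  expect_equal(diag(K), c(1, 1))

  set.seed(11)
  X <- matrix(rnorm(8 * 5), 8, 5)
  W <- matrix(rnorm(5 * 3), 5, 3)
  K <- gaussian_kernel(X, W, sigma = 1.7)
  expect_equal(K, t(K))
  expect_true(all(K > 0 & K <= 1))
  expect_equal(K, oracle_gaussian(X %*% W, 1.7), tolerance = 1e-12)

  # identical rows give entry 1
  X2 <- rbind(X, X[1, ])
  expect_equal(gaussian_kernel(X2, W, sigma = 1)[1, 9], 1)

  # depends on W only through W W^T: right-multiplying by a rotation
  th <- 0.7
  Q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  W2 <- matrix(rnorm(5 * 2), 5, 2)
  expect_equal(gaussian_kernel(X, W2, 1.3), gaussian_kernel(X, W2 %*% Q, 1.3),
               tolerance = 1e-12)

  expect_error(gaussian_kernel(X, W, sigma = 0), "positive")
  expect_error(gaussian_kernel(X, matrix(1, 3, 2), sigma = 1), "rows")
})

test_that("label kernel is the class-indicator kernel and rejects one class", {
  expect_equal(label_kernel(c("a", "a", "b")),
               matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3, 3))
  expect_equal(label_kernel(1:4), diag(4))
  expect_error(label_kernel(rep("a", 5)), "single class")

  # centered 2v2 delta kernel has entries +-1/2, squared norm 4
  Kc <- center_kernel(label_kernel(c("a", "a", "b", "b")))
  expect_equal(sum(Kc^2), 4)
  expect_equal(sort(unique(round(as.vector(Kc), 12))), c(-0.5, 0.5))
})

test_that("kernel centering matches the elementwise rule and is idempotent", {
  expect_equal(center_kernel(matrix(1, 3, 3)), matrix(0, 3, 3))
  expect_equal(center_kernel(diag(2)),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2))

  set.seed(21)
  for (rep in 1:5) {
    A <- matrix(rnorm(25), 5, 5)
    K <- A + t(A)
    Kc <- center_kernel(K)
    expect_equal(Kc, oracle_center(K), tolerance = 1e-12)
    expect_equal(rowSums(Kc), rep(0, 5), tolerance = 1e-12)
    expect_equal(colSums(Kc), rep(0, 5), tolerance = 1e-12)
    expect_equal(center_kernel(Kc), Kc, tolerance = 1e-12)
  }
  expect_error(center_kernel(matrix(1, 2, 3)), "square")
})

test_that("cka matches the brute-force estimator and stays in [0, 1]", {
  # self-alignment of any non-constant kernel is exactly 1
  set.seed(31)
  A <- matrix(rnorm(36), 6, 6)
  K <- tcrossprod(A)
  a <- cka(K, K)
  expect_equal(a$rho, 1, tolerance = 1e-12)
  expect_equal(a$cost, 0, tolerance = 1e-10)

  # orthogonal centered kernels give rho 0 (derived: the two 4x4 delta
  # kernels on crossing label splits are Frobenius-orthogonal after
  # centering)
  K1 <- label_kernel(c("a", "a", "b", "b"))
  K2 <- label_kernel(c("a", "b", "a", "b"))
  expect_equal(cka(K2, K1)$rho, oracle_cka(K2, K1), tolerance = 1e-12)
  expect_equal(cka(K2, K1)$rho, 0, tolerance = 1e-12)

  # random kernels against the elementwise oracle; symmetry in arguments
  for (n in c(5, 9, 14)) {
    A <- matrix(rnorm(n * n), n, n); Kx <- tcrossprod(A) / n
    B <- matrix(rnorm(n * n), n, n); Kl <- tcrossprod(B) / n
    r <- cka(Kx, Kl)$rho
    expect_equal(r, oracle_cka(Kx, Kl), tolerance = 1e-10)
    expect_equal(r, cka(Kl, Kx)$rho, tolerance = 1e-12)
    expect_gte(r, 0); expect_lte(r, 1)
    # invariance to positive rescaling and to adding a constant kernel
    expect_equal(cka(3.7 * Kx, Kl)$rho, r, tolerance = 1e-10)
    expect_equal(cka(Kx + 2.5, Kl)$rho, r, tolerance = 1e-9)
  }
  expect_error(cka(matrix(1, 3, 3), label_kernel(c(1, 1, 2))), "degenerate")
})

test_that("trace route and centered-Frobenius route agree", {
  # tr(Kx H Kl H) equals <H Kx H, H Kl H>_F for symmetric kernels
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    A <- matrix(rnorm(n * n), n, n); Kx <- A + t(A)
    B <- matrix(rnorm(n * n), n, n); Kl <- B + t(B)
    H <- diag(n) - 1 / n
    lhs <- sum(diag(Kx %*% H %*% Kl %*% H))
    rhs <- sum(center_kernel(Kx) * center_kernel(Kl))
    expect_equal(lhs, rhs, tolerance = 1e-10 * max(1, abs(lhs)))
  }
})

test_that("analytic gradient of the alignment cost matches finite differences", {
  set.seed(51)
  for (act in c("identity", "sigmoid")) {
    for (rep in 1:5) {
      X <- matrix(rnorm(10 * 6), 10, 6)
      lab <- sample(rep(c("a", "b"), 5))
      Kl_c <- center_kernel(label_kernel(lab))
      W <- matrix(rnorm(6 * 2), 6, 2) * 0.7
      sigma <- 1.5
      res <- cka_cost_grad(W, X, Kl_c, sigma, activation = act)
      G <- fd_grad(function(w)
        cka_cost_grad(w, X, Kl_c, sigma, activation = act)$cost, W)
      expect_lt(max(abs(res$grad - G) / (abs(G) + 1e-8)), 1e-4)
    }
  }
})

test_that("gradient is orthogonal to the rotation symmetry direction", {
  # cost is invariant under W -> W Q, so <grad, W A> = 0 for antisymmetric A
  set.seed(61)
  X <- matrix(rnorm(12 * 5), 12, 5)
  Kl_c <- center_kernel(label_kernel(rep(c("a", "b", "c"), 4)))
  W <- matrix(rnorm(5 * 3), 5, 3)
  g <- cka_cost_grad(W, X, Kl_c, sigma = 2)$grad
  A <- matrix(c(0, 1, -0.5, -1, 0, 2, 0.5, -2, 0), 3, 3)  # antisymmetric
  expect_equal(sum(g * (W %*% A)), 0, tolerance = 1e-8)
})

test_that("degenerate bandwidths raise the re-tuning error", {
  X <- matrix(rnorm(16), 8, 2)
  Kl_c <- center_kernel(label_kernel(rep(c("a", "b"), 4)))
  expect_error(cka_cost_grad(diag(2), X, Kl_c, sigma = 1e8), "bandwidth")
})
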
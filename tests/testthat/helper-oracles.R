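# Independent brute-force oracles used to pin the fast implementations.
# These deliberately use elementwise loops / naive formulas, never the
# package's vectorized code paths.

# Elementwise double-centering: k - row mean - column mean + grand mean.
oracle_center <- function(K) {
  n <- nrow(K)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    out[i, j] <- K[i, j] - mean(K[i, ]) - mean(K[, j]) + mean(K)
  out
}

# CKA from the definition: center both kernels elementwise, then take the
# normalized Frobenius inner product.
oracle_cka <- function(Kx, Kl) {
  cx <- oracle_center(Kx)
  cl <- oracle_center(Kl)
  sum(cx * cl) / sqrt(sum(cx * cx) * sum(cl * cl))
}

# Pairwise-loop Gaussian kernel.
oracle_gaussian <- function(Y, sigma) {
  n <- nrow(Y)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- exp(-sum((Y[i, ] - Y[j, ])^2) / (2 * sigma^2))
  K
}

# Central finite differences of a scalar function of a matrix argument.
fd_grad <- function(fun, W, h = 1e-5) {
  G <- matrix(0, nrow(W), ncol(W))
  for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W))) {
    Wp <- W; Wp[i, j] <- W[i, j] + h
    Wm <- W; Wm[i, j] <- W[i, j] - h
    G[i, j] <- (fun(Wp) - fun(Wm)) / (2 * h)
  }
  G
}

# Exhaustive k-nn: all-pairs distances, majority vote, ties by smallest
# summed distance then smallest class index.
oracle_knn <- function(train_x, train_y, test_x, k) {
  train_y <- as.factor(train_y)
  lev <- levels(train_y)
  pred <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    d <- apply(train_x, 1, function(r) sqrt(sum((r - test_x[i, ])^2)))
    nb <- order(d, seq_along(d))[seq_len(k)]
    counts <- table(train_y[nb])
    cand <- names(counts)[counts == max(counts)]
    if (length(cand) > 1) {
      dsum <- sapply(cand, function(cl) sum(d[nb][train_y[nb] == cl]))
      cand <- cand[order(dsum, match(cand, lev))]
    }
    pred[i] <- cand[1]
  }
  factor(pred, levels = lev)
}

# Pair-counting one-vs-rest AUC with mid-rank tie handling.
oracle_auc <- function(is_pos, s) {
  pos <- s[is_pos]
  neg <- s[!is_pos]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Welch two-sample t statistic from the closed form.
oracle_welch_t <- function(a, b) {
  (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
}

# Small deterministic dataset builders for classifier tests.
two_blob_data <- function(n_per = 15, gap = 6, p_noise = 0, seed = 42) {
  set.seed(seed)
  x1 <- cbind(rnorm(n_per) - gap / 2, rnorm(n_per))
  x2 <- cbind(rnorm(n_per) + gap / 2, rnorm(n_per))
  X <- rbind(x1, x2)
  if (p_noise > 0)
    X <- cbind(X, matrix(rnorm(2 * n_per * p_noise), 2 * n_per, p_noise))
  list(X = X, y = factor(rep(c("a", "b"), each = n_per)))
}
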
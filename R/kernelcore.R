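# Numerical floor applied to the alignment before taking the log, so the
# cost stays finite during early optimization steps.
.RHO_FLOOR <- 1e-12

.as_matrix <- function(X, arg = "X") {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X))
    stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
  if (!all(is.finite(X)))
    stop(sprintf("'%s' contains non-finite values", arg), call. = FALSE)
  X
}

#' Gaussian kernel on linearly projected features
#'
#' Computes the N x N Gaussian kernel whose distances are measured in the
#' space `Y = X W`, i.e. the generalized Euclidean (Mahalanobis-type) metric
#' `(x - x') W W^T (x - x')^T` induced by the projection `W`:
#' `K[n, n'] = exp(-(x_n - x_n') W W^T (x_n - x_n')^T / (2 sigma^2))`.
#'
#' @param X numeric N x P matrix of features (rows are samples).
#' @param W numeric P x d projection matrix, or `NULL` for the identity
#'   (plain Euclidean kernel on `X`).
#' @param sigma positive kernel bandwidth, in the units of projected
#'   distances.
#' @return N x N symmetric numeric matrix with unit diagonal and entries in
#'   (0, 1].
#' @examples
#' X <- matrix(c(0, 1), ncol = 1)
#' gaussian_kernel(X, sigma = 1)[1, 2]  # exp(-1/2)
#' @export
gaussian_kernel <- function(X, W = NULL, sigma) {
  X <- .as_matrix(X)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("'sigma' must be a single positive number", call. = FALSE)
  if (!is.null(W)) {
    W <- .as_matrix(W, "W")
    if (nrow(W) != ncol(X))
      stop(sprintf("'W' has %d rows but 'X' has %d columns",
                   nrow(W), ncol(X)), call. = FALSE)
    Y <- X %*% W
  } else {
    Y <- X
  }
  D2 <- .pairwise_sqdist(Y)
  K <- exp(-D2 / (2 * sigma^2))
  diag(K) <- 1
  K
}

# Squared Euclidean distances between rows, clipped at 0 against round-off.
.pairwise_sqdist <- function(Y) {
  sq <- rowSums(Y * Y)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(Y)
  D2[D2 < 0] <- 0
  D2
}

#' Class-indicator (delta) label kernel
#'
#' Builds the label kernel `K_L[n, n'] = 1` when samples n and n' share a
#' class and 0 otherwise. This is the standard choice turning the centered
#' alignment into an HSIC-style class-separability score.
#'
#' @param labels vector (factor, character or integer) of class identifiers,
#'   with at least two distinct classes.
#' @return N x N symmetric 0/1 matrix with unit diagonal.
#' @export
label_kernel <- function(labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2L)
    stop("labels contain a single class; the centered label kernel would be zero",
         call. = FALSE)
  if (anyNA(labels)) stop("labels contain missing values", call. = FALSE)
  K <- outer(labels, labels, "==")
  mode(K) <- "double"
  K
}

#' Double-center a kernel matrix
#'
#' Subtracts row means, column means and adds back the grand mean,
#' equivalently `H K H` with `H = I - 11^T / N`. Centering a centered kernel
#' returns it unchanged; row and column sums of the result are zero.
#'
#' @param K square symmetric numeric matrix.
#' @return centered matrix of the same dimension.
#' @export
center_kernel <- function(K) {
  K <- .as_matrix(K, "K")
  if (nrow(K) != ncol(K)) stop("'K' must be square", call. = FALSE)
  rm <- rowMeans(K)
  cm <- colMeans(K)
  K - outer(rm, rep(1, ncol(K))) - outer(rep(1, nrow(K)), cm) + mean(K)
}

#' Empirical centered kernel alignment
#'
#' The normalized Frobenius inner product between the double-centered
#' versions of two kernel matrices,
#' `rho = <Kx_c, Kl_c>_F / sqrt(<Kx_c, Kx_c>_F <Kl_c, Kl_c>_F)`,
#' a dependence measure in \[0, 1\]. The associated cost is `-log(rho)`.
#'
#' @param Kx,Kl N x N kernel matrices (uncentered; they are centered
#'   internally). Pass `centered = TRUE` if both are already centered.
#' @param centered logical; skip the internal centering step.
#' @return object of class `cka_alignment`: a list with elements `rho` and
#'   `cost`.
#' @export
cka <- function(Kx, Kl, centered = FALSE) {
  Kx <- .as_matrix(Kx, "Kx")
  Kl <- .as_matrix(Kl, "Kl")
  if (!all(dim(Kx) == dim(Kl)))
    stop("'Kx' and 'Kl' must have identical dimensions", call. = FALSE)
  if (!centered) {
    Kx <- center_kernel(Kx)
    Kl <- center_kernel(Kl)
  }
  nx <- sum(Kx * Kx)
  nl <- sum(Kl * Kl)
  if (nx <= 0 || nl <= 0)
    stop("degenerate kernel: a centered kernel is identically zero ",
         "(constant kernel or single class)", call. = FALSE)
  rho <- sum(Kx * Kl) / sqrt(nx * nl)
  rho <- min(max(rho, 0), 1)
  structure(list(rho = rho, cost = -log(max(rho, .RHO_FLOOR))),
            class = "cka_alignment")
}

#' @export
print.cka_alignment <- function(x, ...) {
  cat(sprintf("Centered kernel alignment: rho = %.6f (cost -log rho = %.6f)\n",
              x$rho, x$cost))
  invisible(x)
}

# Shared core of the CKA cost/gradient for one projection layer.
# H_prev: N x Q input representation; W: Q x d; Kl_c: centered label kernel.
# activation "identity" gives the linear metric-learning objective; "sigmoid"
# applies theta(z) = (tanh(z) + 1) / 2 before the kernel, for layer-wise
# pretraining. Returns cost (-log rho up to the label-kernel constant),
# gradient wrt W, and the alignment rho itself.
.cka_objective <- function(W, H_prev, Kl_c, sigma,
                           activation = c("identity", "sigmoid"),
                           want_grad = TRUE) {
  activation <- match.arg(activation)
  Z <- H_prev %*% W
  H <- if (activation == "sigmoid") (tanh(Z) + 1) / 2 else Z
  K <- exp(-.pairwise_sqdist(H) / (2 * sigma^2))
  diag(K) <- 1
  Kc <- center_kernel(K)
  A <- sum(Kc * Kl_c)
  B <- sum(Kc * Kc)
  if (B <= .Machine$double.eps * nrow(K)^2)
    stop("degenerate kernel: centered Gaussian kernel is numerically zero; ",
         "re-tune the bandwidth", call. = FALSE)
  nl <- sqrt(sum(Kl_c * Kl_c))
  rho <- min(max(A / (sqrt(B) * nl), 0), 1)
  Apos <- max(A, .RHO_FLOOR * sqrt(B) * nl)
  cost <- -log(Apos) + 0.5 * log(B)
  if (!want_grad)
    return(list(cost = cost, rho = rho))
  S <- (-Kl_c / Apos + Kc / B) * K
  L <- diag(rowSums(S)) - S
  G_H <- (-2 / sigma^2) * (L %*% H)
  if (activation == "sigmoid") G_H <- G_H * (2 * H * (1 - H))
  list(cost = cost, grad = crossprod(H_prev, G_H), rho = rho)
}

#' CKA cost and analytic gradient with respect to the projection
#'
#' Evaluates the `-log rho` objective for the Gaussian kernel on `X W`
#' against a centered label kernel, together with its gradient in `W`
#' obtained by the chain rule through the kernel. The constant term
#' `0.5 * log <Kl_c, Kl_c>_F`, which does not depend on `W`, is dropped from
#' the reported cost.
#'
#' @param W numeric P x d projection.
#' @param X numeric N x P feature matrix.
#' @param Kl_c centered N x N label kernel (see [center_kernel()] and
#'   [label_kernel()]).
#' @param sigma positive Gaussian bandwidth.
#' @param activation `"identity"` for the linear metric; `"sigmoid"` applies
#'   the saturating unit `(tanh(z) + 1) / 2` before the kernel, as used in
#'   layer-wise pretraining.
#' @return list with elements `cost`, `grad` (P x d matrix) and `rho`.
#' @export
cka_cost_grad <- function(W, X, Kl_c, sigma, activation = "identity") {
  W <- .as_matrix(W, "W")
  X <- .as_matrix(X)
  Kl_c <- .as_matrix(Kl_c, "Kl_c")
  if (nrow(W) != ncol(X))
    stop(sprintf("'W' has %d rows but 'X' has %d columns", nrow(W), ncol(X)),
         call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a single positive number", call. = FALSE)
  if (sum(Kl_c * Kl_c) <= 0)
    stop("centered label kernel is identically zero", call. = FALSE)
  .cka_objective(W, X, Kl_c, sigma, activation = activation)
}
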
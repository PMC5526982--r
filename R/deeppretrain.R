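#' Saturating sigmoid activation
#'
#' The hidden-unit transfer function `theta(z) = (tanh(z) + 1) / 2`, which
#' maps into (0, 1).
#'
#' @param z numeric vector or matrix.
#' @return values in (0, 1), same shape as `z`.
#' @export
sigmoid_sat <- function(z) (tanh(z) + 1) / 2

#' Forward map of one network layer
#'
#' Computes `theta(b + H W)` (or the plain affine map when
#' `saturate = FALSE`) for a batch of row-vector inputs.
#'
#' @param H numeric N x Q input representation.
#' @param W numeric Q x Q' weight matrix.
#' @param b length-Q' offset vector (recycled scalar allowed).
#' @param saturate apply the saturating sigmoid.
#' @return N x Q' matrix; entries in (0, 1) when saturated.
#' @export
layer_forward <- function(H, W, b = 0, saturate = TRUE) {
  H <- .as_matrix(H, "H")
  W <- .as_matrix(W, "W")
  if (ncol(H) != nrow(W))
    stop(sprintf("'H' has %d columns but 'W' has %d rows", ncol(H), nrow(W)),
         call. = FALSE)
  if (!length(b) %in% c(1L, ncol(W)))
    stop("'b' must be scalar or match ncol(W)", call. = FALSE)
  Z <- sweep(H %*% W, 2, rep_len(b, ncol(W)), "+")
  if (saturate) sigmoid_sat(Z) else Z
}

#' Gaussian kernel among layer representations
#'
#' The Gaussian kernel on the Euclidean distances between the rows of a
#' layer's representation matrix; identical to
#' `gaussian_kernel(H, W = NULL, sigma)`.
#'
#' @inheritParams gaussian_kernel
#' @param H numeric N x Q layer representation.
#' @return N x N kernel with unit diagonal.
#' @export
layer_kernel <- function(H, sigma) gaussian_kernel(H, W = NULL, sigma = sigma)

#' Layer-wise CKA pretraining of a feed-forward network
#'
#' Sequentially fits each hidden layer's weights `W^m` so that the Gaussian
#' kernel among the layer's (saturated) representations aligns maximally
#' with the class-label kernel, giving discriminative initial weights for
#' subsequent fine-tuning by backpropagation ([nn_finetune()]). Offsets are
#' held at zero during pretraining and become trainable only in
#' fine-tuning. Each layer's projection is initialized from the principal
#' components of the previous layer's output and its bandwidth tuned on
#' that layer's scale; once a layer is fitted it is frozen. The output
#' (softmax) layer is initialized at random.
#'
#' @param X numeric N x P feature matrix.
#' @param labels class identifiers (C >= 2 classes).
#' @param sizes integer vector of hidden-layer widths (one entry per hidden
#'   layer); the full size chain is `c(P, sizes, C)`.
#' @param config a [fit_config()]; `d` is ignored (sizes rule the shapes).
#' @param saturate apply the saturating sigmoid in hidden layers. With
#'   `saturate = FALSE` and a single hidden layer the procedure reduces to
#'   the linear metric fit of [fit_metric()].
#' @return object of class `cka_network`: `layers` (list of `(W, b)`,
#'   output layer last), `sizes`, `activation`, per-layer `sigmas` and
#'   `alignments` (rho at each pretrained layer, element 1 being the
#'   raw-input kernel alignment), `pretrain_history`, standardization
#'   `center`/`scale`, `seed`.
#' @export
pretrain_network <- function(X, labels, sizes, config = fit_config(),
                             saturate = TRUE) {
  X <- .as_matrix(X)
  labels <- as.factor(labels)
  if (length(labels) != nrow(X))
    stop("'labels' length must equal nrow(X)", call. = FALSE)
  C <- nlevels(droplevels(labels))
  if (C < 2L) stop("at least two classes are required", call. = FALSE)
  sizes <- as.integer(sizes)
  if (length(sizes) < 1L || any(sizes < 1L))
    stop("'sizes' must list at least one positive hidden-layer width",
         call. = FALSE)
  chain <- c(ncol(X), sizes, C)
  set.seed(config$seed)
  ctr <- unname(colMeans(X))
  scl <- unname(apply(X, 2, stats::sd))
  scl[scl == 0] <- 1
  H <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Kl_c <- center_kernel(label_kernel(labels))
  act <- if (saturate) "sigmoid" else "identity"

  sigma0 <- tune_bandwidth(H, method = config$bandwidth_strategy)
  alignments <- cka(center_kernel(layer_kernel(H, sigma0)), Kl_c,
                    centered = TRUE)$rho
  sigmas <- numeric(0)
  layers <- list()
  histories <- list()
  for (m in seq_along(sizes)) {
    W0 <- pca_init(H, min(sizes[m], ncol(H), nrow(H) - 1L))
    if (ncol(W0) < sizes[m]) {
      # widen with small random columns when the width exceeds the rank
      extra <- matrix(stats::rnorm(nrow(W0) * (sizes[m] - ncol(W0)), sd = 0.01),
                      nrow(W0))
      W0 <- cbind(W0, extra)
    }
    sigma_m <- tryCatch(
      tune_bandwidth(if (saturate) sigmoid_sat(H %*% W0) else H %*% W0),
      error = function(e) 1)
    fit <- .fit_projection_best(H, Kl_c, W0, sigma_m, config, activation = act)
    layers[[m]] <- list(W = fit$W, b = rep(0, sizes[m]))
    histories[[m]] <- fit$history
    sigmas <- c(sigmas, fit$sigma)
    H <- if (saturate) sigmoid_sat(H %*% fit$W) else H %*% fit$W
    alignments <- c(alignments, fit$rho)
  }
  # random softmax output layer, scaled by fan-in
  q_in <- chain[length(chain) - 1L]
  layers[[length(sizes) + 1L]] <-
    list(W = matrix(stats::rnorm(q_in * C, sd = 1 / sqrt(q_in)), q_in, C),
         b = rep(0, C))
  structure(list(layers = layers, sizes = chain,
                 activation = if (saturate) "sigmoid" else "identity",
                 sigmas = sigmas, alignments = alignments,
                 pretrain_history = histories,
                 center = ctr, scale = scl, seed = config$seed,
                 levels = levels(droplevels(labels))),
            class = "cka_network")
}

#' @export
print.cka_network <- function(x, ...) {
  cat(sprintf("CKA-pretrained network: sizes %s, activation %s\n",
              paste(x$sizes, collapse = " -> "), x$activation))
  if (length(x$alignments))
    cat("  layer alignments (input, then per hidden layer): ",
        paste(sprintf("%.4f", x$alignments), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Forward pass through the whole stack; returns hidden representations and
# softmax output probabilities.
.network_forward <- function(stack, X) {
  Hs <- list(sweep(sweep(X, 2, stack$center), 2, stack$scale, "/"))
  M <- length(stack$layers)
  for (m in seq_len(M - 1L)) {
    Hs[[m + 1L]] <- layer_forward(Hs[[m]], stack$layers[[m]]$W,
                                  stack$layers[[m]]$b,
                                  saturate = stack$activation == "sigmoid")
  }
  Z <- sweep(Hs[[M]] %*% stack$layers[[M]]$W, 2, stack$layers[[M]]$b, "+")
  Z <- Z - apply(Z, 1, max)
  P <- exp(Z)
  P <- P / rowSums(P)
  list(hidden = Hs, probs = P)
}

#' Class probabilities from a (pretrained or fine-tuned) network
#'
#' @param stack a `cka_network`.
#' @param X feature matrix with the training columns.
#' @return N x C matrix of softmax probabilities (rows sum to 1); column
#'   names are the class levels.
#' @export
nn_predict <- function(stack, X) {
  stopifnot(inherits(stack, "cka_network"))
  X <- .as_matrix(X)
  P <- .network_forward(stack, X)$probs
  colnames(P) <- stack$levels
  P
}

#' @export
predict.cka_network <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  P <- nn_predict(object, newdata)
  if (type == "prob") return(P)
  factor(object$levels[max.col(P, ties.method = "first")],
         levels = object$levels)
}

#' Randomly initialized network of the same architecture
#'
#' Builds a `cka_network` with the given size chain and small random
#' weights (scaled by the inverse square root of fan-in), for use as the
#' random-initialization baseline against CKA pretraining.
#'
#' @param X,labels training features and classes (used for shapes and the
#'   stored standardization).
#' @param sizes hidden-layer widths, as in [pretrain_network()].
#' @param seed integer seed.
#' @return a `cka_network` with `alignments` empty.
#' @export
random_network <- function(X, labels, sizes, seed = 1L) {
  X <- .as_matrix(X)
  labels <- as.factor(labels)
  C <- nlevels(droplevels(labels))
  chain <- c(ncol(X), as.integer(sizes), C)
  set.seed(seed)
  ctr <- unname(colMeans(X))
  scl <- unname(apply(X, 2, stats::sd))
  scl[scl == 0] <- 1
  layers <- lapply(seq_len(length(chain) - 1L), function(m)
    list(W = matrix(stats::rnorm(chain[m] * chain[m + 1L],
                                 sd = 1 / sqrt(chain[m])),
                    chain[m], chain[m + 1L]),
         b = rep(0, chain[m + 1L])))
  structure(list(layers = layers, sizes = chain, activation = "sigmoid",
                 sigmas = numeric(0), alignments = numeric(0),
                 pretrain_history = list(), center = ctr, scale = scl,
                 seed = as.integer(seed), levels = levels(droplevels(labels))),
            class = "cka_network")
}
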
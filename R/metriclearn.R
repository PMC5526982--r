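#' Principal-component initialization of a projection
#'
#' Returns the top-`d` principal directions of `X` as a P x d orthonormal
#' matrix, used as the starting point of the alignment optimization. The
#' sign of each column is fixed so that its largest-magnitude element is
#' positive, making the result deterministic.
#'
#' @param X numeric N x P matrix. Features are expected to be on comparable
#'   scales (the metric fitter z-scores before calling this).
#' @param d number of components, `1 <= d <= min(P, N - 1)`.
#' @return P x d matrix with orthonormal columns.
#' @export
pca_init <- function(X, d) {
  X <- .as_matrix(X)
  dmax <- min(ncol(X), nrow(X) - 1L)
  if (!is.numeric(d) || length(d) != 1L || d < 1 || d > dmax)
    stop(sprintf("'d' must be an integer in [1, %d]", dmax), call. = FALSE)
  d <- as.integer(d)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  W <- pc$rotation[, seq_len(d), drop = FALSE]
  for (j in seq_len(d)) {
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  dimnames(W) <- NULL
  W
}

#' Tune the Gaussian bandwidth for a projected space
#'
#' Default strategy is the median heuristic: the median of the positive
#' pairwise Euclidean distances among the projected points, which puts the
#' kernel's observation window on the scale of typical inter-point
#' distances. The `"maxvar"` alternative scans a log-spaced grid around the
#' median and picks the bandwidth maximizing the empirical variance of the
#' off-diagonal kernel entries (the most informative kernel in the sense of
#' being farthest from the constant and identity extremes).
#'
#' @param X numeric N x P feature matrix.
#' @param W optional P x d projection (`NULL` = identity).
#' @param method `"median"` or `"maxvar"`.
#' @return a positive bandwidth on the scale of projected distances.
#' @export
tune_bandwidth <- function(X, W = NULL, method = c("median", "maxvar")) {
  method <- match.arg(method)
  X <- .as_matrix(X)
  Y <- if (is.null(W)) X else X %*% .as_matrix(W, "W")
  dists <- stats::dist(Y)
  pos <- dists[dists > 0]
  if (length(pos) == 0L)
    stop("all projected points are identical; cannot tune a bandwidth",
         call. = FALSE)
  med <- stats::median(pos)
  if (method == "median") return(med)
  grid <- med * 2^seq(-3, 3, length.out = 25)
  v <- vapply(grid, function(s) stats::var(exp(-as.vector(dists)^2 / (2 * s^2))),
              numeric(1))
  grid[which.max(v)]
}

#' Configuration for the alignment optimizer
#'
#' @param d target projection dimension; `NULL` selects
#'   `min(P, 3 * C, N - 1)` at fit time (alignment with a C-class label
#'   kernel needs only low rank, extra dimensions ease optimization).
#' @param max_iters maximum full-batch iterations (or epochs when
#'   `batch_size` is set).
#' @param learning_rate initial step size for gradient descent; the
#'   backtracking line search adapts it per iteration.
#' @param batch_size `NULL` for full-batch descent with backtracking (the
#'   default, which guarantees a non-increasing cost); an integer enables
#'   minibatch stochastic gradient with the cost recorded full-batch once
#'   per epoch.
#' @param tolerance relative cost-change convergence threshold.
#' @param seed integer seed controlling all randomness of the fit.
#' @param bandwidth_strategy `"median"` or `"maxvar"` (see
#'   [tune_bandwidth()]).
#' @param retune_every re-tune the bandwidth every this many iterations
#'   (0 = tune once at initialization only).
#' @param n_restarts number of optimizer starts per projection: the first
#'   start is the principal-component initialization, further starts are
#'   seeded random directions, and the solution with the best alignment is
#'   kept. The objective is nonconvex (saturating layers especially can
#'   trap gradient descent), so multi-start fitting is the standard remedy;
#'   1 keeps the purely deterministic PCA-start behaviour.
#' @return list of class `cka_fit_config`.
#' @export
fit_config <- function(d = NULL, max_iters = 200L, learning_rate = 1,
                       batch_size = NULL, tolerance = 1e-7, seed = 1L,
                       bandwidth_strategy = c("median", "maxvar"),
                       retune_every = 0L, n_restarts = 1L) {
  bandwidth_strategy <- match.arg(bandwidth_strategy)
  stopifnot(is.null(d) || (length(d) == 1L && d >= 1),
            max_iters >= 1, learning_rate > 0, tolerance > 0,
            is.null(batch_size) || (length(batch_size) == 1L && batch_size >= 1),
            retune_every >= 0, n_restarts >= 1)
  structure(list(d = if (is.null(d)) NULL else as.integer(d),
                 max_iters = as.integer(max_iters),
                 learning_rate = learning_rate,
                 batch_size = if (is.null(batch_size)) NULL else as.integer(batch_size),
                 tolerance = tolerance,
                 seed = as.integer(seed),
                 bandwidth_strategy = bandwidth_strategy,
                 retune_every = as.integer(retune_every),
                 n_restarts = as.integer(n_restarts)),
            class = "cka_fit_config")
}

# Full-batch gradient descent with Armijo backtracking on the CKA cost for
# one projection layer. Returns W, the (iteration, cost, rho) history and a
# convergence flag. Used by both fit_metric and pretrain_network so that the
# single-layer linear network reduces exactly to the linear metric fit.
.fit_projection <- function(H_prev, Kl_c, W0, sigma, config,
                            activation = "identity") {
  W <- W0
  obj <- .cka_objective(W, H_prev, Kl_c, sigma, activation)
  history <- data.frame(iteration = 0L, cost = obj$cost, rho = obj$rho)
  step <- config$learning_rate
  converged <- FALSE
  if (is.null(config$batch_size)) {
    for (it in seq_len(config$max_iters)) {
      g <- obj$grad
      gnorm2 <- sum(g * g)
      if (gnorm2 <= 1e-18) { converged <- TRUE; break }
      accepted <- FALSE
      for (bt in 1:40) {
        W_try <- W - step * g
        obj_try <- tryCatch(
          .cka_objective(W_try, H_prev, Kl_c, sigma, activation),
          error = function(e) NULL)
        if (!is.null(obj_try) &&
            obj_try$cost <= obj$cost - 1e-4 * step * gnorm2) {
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted) { converged <- TRUE; break }
      rel <- abs(obj$cost - obj_try$cost) / max(abs(obj$cost), 1e-12)
      W <- W_try
      obj <- obj_try
      history <- rbind(history,
                       data.frame(iteration = it, cost = obj$cost, rho = obj$rho))
      step <- min(step * 2, config$learning_rate * 64)
      if (rel < config$tolerance) { converged <- TRUE; break }
    }
  } else {
    n <- nrow(H_prev)
    b <- min(config$batch_size, n)
    for (epoch in seq_len(config$max_iters)) {
      idx <- sample.int(n)
      starts <- seq(1, n, by = b)
      for (s in starts) {
        rows <- idx[s:min(s + b - 1, n)]
        if (length(rows) < 4L) next
        Klb <- center_kernel(Kl_c[rows, rows, drop = FALSE])
        if (sum(Klb * Klb) <= 0) next
        gb <- .cka_objective(W, H_prev[rows, , drop = FALSE], Klb, sigma,
                             activation)$grad
        W <- W - (config$learning_rate / (1 + 0.1 * epoch)) * gb
      }
      obj <- .cka_objective(W, H_prev, Kl_c, sigma, activation)
      history <- rbind(history,
                       data.frame(iteration = epoch, cost = obj$cost, rho = obj$rho))
      nh <- nrow(history)
      if (nh > 1 && abs(history$cost[nh - 1] - history$cost[nh]) /
            max(abs(history$cost[nh - 1]), 1e-12) < config$tolerance) {
        converged <- TRUE
        break
      }
    }
  }
  list(W = W, history = history, converged = converged, rho = obj$rho,
       cost = obj$cost)
}

# Multi-start wrapper around .fit_projection: the first start is the given
# (PCA) initialization, further starts are random directions with their own
# tuned bandwidth; the start reaching the best alignment wins. Alignment
# (not cost) is compared because cost terms depend on the bandwidth.
.fit_projection_best <- function(H_prev, Kl_c, W0, sigma0, config,
                                 activation = "identity") {
  best <- .fit_projection(H_prev, Kl_c, W0, sigma0, config, activation)
  best$sigma <- sigma0
  if (config$n_restarts > 1L) {
    for (r in 2:config$n_restarts) {
      Wr <- matrix(stats::rnorm(length(W0), sd = 1 / sqrt(nrow(W0))),
                   nrow(W0), ncol(W0))
      Hr <- if (activation == "sigmoid") sigmoid_sat(H_prev %*% Wr)
            else H_prev %*% Wr
      sr <- tryCatch(tune_bandwidth(Hr, method = config$bandwidth_strategy),
                     error = function(e) sigma0)
      fit <- tryCatch(.fit_projection(H_prev, Kl_c, Wr, sr, config, activation),
                      error = function(e) NULL)
      if (!is.null(fit) && fit$rho > best$rho) {
        best <- fit
        best$sigma <- sr
      }
    }
  }
  best
}

#' Fit a supervised metric by centered kernel alignment
#'
#' Learns a linear projection `W` (and Gaussian bandwidth `sigma`) that
#' maximizes the centered kernel alignment between the Gaussian kernel on
#' `X W` and the class-label kernel, by minimizing `-log rho`. Features are
#' z-scored internally (the stored center/scale are re-applied by
#' [metric_transform()]); the projection is initialized from the principal
#' components of the standardized data and optimized by full-batch gradient
#' descent with a backtracking line search (or minibatch stochastic gradient
#' when `config$batch_size` is set).
#'
#' @param X numeric N x P feature matrix (or data.frame of numerics).
#' @param labels class identifiers, at least two classes, each non-empty.
#' @param config a [fit_config()].
#' @return object of class `cka_metric`: list with `W` (P x d), `sigma`,
#'   `d`, `center`, `scale`, `fit_history` (data.frame of iteration, cost,
#'   rho), `rho`, `converged`, `seed`.
#' @export
fit_metric <- function(X, labels, config = fit_config()) {
  X <- .as_matrix(X)
  labels <- as.factor(labels)
  if (length(labels) != nrow(X))
    stop("'labels' length must equal nrow(X)", call. = FALSE)
  C <- nlevels(droplevels(labels))
  if (C < 2L) stop("at least two classes are required", call. = FALSE)
  if (nrow(X) < C + 1L) stop("need at least C + 1 samples", call. = FALSE)
  set.seed(config$seed)
  ctr <- unname(colMeans(X))
  scl <- unname(apply(X, 2, stats::sd))
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  d <- if (is.null(config$d)) min(ncol(X), 3L * C, nrow(X) - 1L) else config$d
  W0 <- pca_init(Xs, d)
  sigma <- tune_bandwidth(Xs, W0, method = config$bandwidth_strategy)
  Kl_c <- center_kernel(label_kernel(labels))
  if (config$retune_every > 0 && is.null(config$batch_size)) {
    # optimize in rounds, re-tuning sigma between rounds
    W <- W0
    history <- NULL
    remaining <- config$max_iters
    offset <- 0L
    converged <- FALSE
    while (remaining > 0L) {
      cfg <- config
      cfg$max_iters <- min(config$retune_every, remaining)
      fit <- .fit_projection(Xs, Kl_c, W, sigma, cfg)
      h <- fit$history
      h$iteration <- h$iteration + offset
      history <- if (is.null(history)) h else rbind(history, h[-1, ])
      offset <- max(history$iteration)
      W <- fit$W
      remaining <- remaining - cfg$max_iters
      converged <- fit$converged
      if (converged && nrow(fit$history) <= cfg$max_iters) break
      sigma <- tune_bandwidth(Xs, W, method = config$bandwidth_strategy)
    }
    fit <- list(W = W, history = history, converged = converged)
    obj <- .cka_objective(W, Xs, Kl_c, sigma, want_grad = FALSE)
    fit$rho <- obj$rho
  } else {
    fit <- .fit_projection_best(Xs, Kl_c, W0, sigma, config)
    sigma <- fit$sigma
  }
  if (!fit$converged)
    warning("fit_metric did not converge within max_iters; ",
            "model carries converged = FALSE", call. = FALSE)
  structure(list(W = fit$W, sigma = sigma, d = d, center = ctr, scale = scl,
                 fit_history = fit$history, rho = fit$rho,
                 converged = fit$converged, seed = config$seed,
                 levels = levels(droplevels(labels))),
            class = "cka_metric")
}

#' @export
print.cka_metric <- function(x, ...) {
  cat(sprintf(
    "CKA metric: P = %d -> d = %d, sigma = %.4g, final rho = %.4f (%s)\n",
    nrow(x$W), ncol(x$W), x$sigma, x$rho,
    if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Apply a learned metric to features
#'
#' Standardizes `X` with the center/scale stored in the model and projects
#' with the learned `W`, so that plain Euclidean distances in the result
#' equal the learned generalized Euclidean distances in the original space.
#'
#' @param model a fitted [fit_metric()] model.
#' @param X numeric matrix with the same columns as the training features.
#' @return N x d projected matrix.
#' @export
metric_transform <- function(model, X) {
  stopifnot(inherits(model, "cka_metric"))
  X <- .as_matrix(X)
  if (ncol(X) != nrow(model$W))
    stop(sprintf("'X' has %d columns but the model expects %d",
                 ncol(X), nrow(model$W)), call. = FALSE)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  Xs %*% model$W
}

#' @export
predict.cka_metric <- function(object, newdata, ...) {
  metric_transform(object, newdata)
}

#' Write / read a fitted model as portable JSON
#'
#' Serializes a `cka_metric` or `cka_network` (see [pretrain_network()]) to
#' a JSON text container with full double precision, so a read-back
#' round-trip reproduces the model bit-exactly.
#'
#' @param model a `cka_metric` or `cka_network`.
#' @param path file path to write to / read from.
#' @return `read_cka_model` returns the restored model; `write_cka_model`
#'   returns `path` invisibly.
#' @export
write_cka_model <- function(model, path) {
  # doubles are encoded as %.17g strings: decimal JSON numbers do not
  # round-trip the last bit, 17 significant digits do
  num <- function(x) sprintf("%.17g", as.numeric(x))
  mat <- function(m) {  # column-major values + optional row names
    out <- list(nrow = nrow(m), values = num(m))
    if (!is.null(rownames(m))) out$rownames <- as.list(rownames(m))
    out
  }
  if (inherits(model, "cka_metric")) {
    payload <- list(type = "cka_metric",
                    W = mat(model$W), sigma = num(model$sigma),
                    d = model$d, center = num(model$center),
                    scale = num(model$scale), rho = num(model$rho),
                    converged = model$converged, seed = model$seed,
                    levels = as.list(model$levels),
                    fit_history = list(
                      iteration = model$fit_history$iteration,
                      cost = num(model$fit_history$cost),
                      rho = num(model$fit_history$rho)))
  } else if (inherits(model, "cka_network")) {
    payload <- list(type = "cka_network",
                    sizes = model$sizes, activation = model$activation,
                    layers = lapply(model$layers, function(l)
                      list(W = mat(l$W), b = num(l$b))),
                    sigmas = num(model$sigmas),
                    alignments = num(model$alignments),
                    center = num(model$center), scale = num(model$scale),
                    seed = model$seed, levels = as.list(model$levels))
  } else stop("unsupported model class", call. = FALSE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cka_model
#' @export
read_cka_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  chr <- function(x) as.character(unlist(x))
  mat <- function(m) {
    out <- matrix(num(m$values), nrow = as.integer(m$nrow))
    if (!is.null(m$rownames)) rownames(out) <- chr(m$rownames)
    out
  }
  if (identical(p$type, "cka_metric")) {
    structure(list(W = mat(p$W), sigma = num(p$sigma), d = as.integer(p$d),
                   center = num(p$center), scale = num(p$scale),
                   fit_history = data.frame(
                     iteration = as.integer(unlist(p$fit_history$iteration)),
                     cost = num(p$fit_history$cost),
                     rho = num(p$fit_history$rho)),
                   rho = num(p$rho), converged = isTRUE(p$converged),
                   seed = as.integer(p$seed),
                   levels = chr(p$levels)),
              class = "cka_metric")
  } else if (identical(p$type, "cka_network")) {
    layers <- lapply(p$layers, function(l) list(W = mat(l$W), b = num(l$b)))
    structure(list(layers = layers, activation = chr(p$activation),
                   sizes = as.integer(unlist(p$sizes)), sigmas = num(p$sigmas),
                   alignments = num(p$alignments),
                   center = num(p$center), scale = num(p$scale),
                   seed = as.integer(p$seed),
                   levels = chr(p$levels)),
              class = "cka_network")
  } else stop("unrecognized model file", call. = FALSE)
}
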
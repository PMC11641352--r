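#' t-SNE embedding configuration
#'
#' Hyperparameters for the three-dimensional t-SNE stage. Defaults follow
#' the widely used published settings: perplexity 30 (capped at `(n-1)/3`
#' at run time), 1000 gradient iterations at learning rate 200, and an
#' early-exaggeration factor of 12 for the first 250 iterations. A seed is
#' mandatory so embeddings are reproducible.
#'
#' @param perplexity positive real; effective neighbourhood size.
#' @param iterations number of gradient-descent iterations.
#' @param learning_rate gradient step size.
#' @param early_exaggeration multiplier applied to the input affinities
#'   during the first `exaggeration_iters` iterations.
#' @param exaggeration_iters length of the early-exaggeration phase.
#' @param seed integer RNG seed (required).
#' @param metric `"jaccard_distance"` (1 - Tanimoto on fingerprints,
#'   default) or `"euclidean_on_bits"`.
#' @return A list of class `tgv_tsne_config`.
#' @export
tsne_config <- function(perplexity = 30, iterations = 1000, learning_rate = 200,
                        early_exaggeration = 12, exaggeration_iters = 250,
                        seed, metric = c("jaccard_distance", "euclidean_on_bits")) {
  if (missing(seed)) stopf("tsne_config() requires an explicit seed")
  metric <- match.arg(metric)
  stopifnot(perplexity > 0, iterations >= 1, learning_rate > 0,
            early_exaggeration > 0, exaggeration_iters >= 0)
  structure(
    list(perplexity = perplexity, iterations = as.integer(iterations),
         learning_rate = learning_rate, early_exaggeration = early_exaggeration,
         exaggeration_iters = as.integer(exaggeration_iters),
         seed = as.integer(seed), metric = metric),
    class = "tgv_tsne_config"
  )
}

#' Embed fingerprints into three dimensions with t-SNE
#'
#' Projects a compound library into 3-D chemical space. Per-point Gaussian
#' bandwidths are calibrated by bisection so each conditional distribution's
#' entropy matches `log(perplexity)`; affinities are symmetrized; the
#' low-dimensional kernel is Student-t with one degree of freedom; the KL
#' divergence is minimized by momentum gradient descent with an
#' early-exaggeration phase. The result is deterministic given the input
#' and the config (including its seed).
#'
#' @param x a binary fingerprint matrix (rows = molecules), a precomputed
#'   symmetric distance matrix, or a [similarity_matrix()] result (detected
#'   by its unit diagonal and converted to `1 - similarity`).
#' @param config a [tsne_config()].
#' @return An object of class `tgv_embedding`: list with `ids`, `coords`
#'   (n x 3 matrix) and `config`.
#' @export
tsne_embed <- function(x, config) {
  stopifnot(inherits(config, "tgv_tsne_config"))
  D <- embedding_distances(x, config$metric)
  n <- nrow(D)
  if (n < 4L) stopf("tsne_embed() needs at least 4 points, got %d", n)

  # duplicate molecules give zero off-diagonal distances; jitter so the
  # bandwidth bisection cannot divide by zero
  off <- D == 0 & !diag(TRUE, n)
  if (any(off)) D[off] <- D[off] + 1e-10

  perp <- min(config$perplexity, (n - 1) / 3)
  P <- cond_to_joint(conditional_affinities(D, perp))

  Y <- with_seed(config$seed, matrix(stats::rnorm(n * 3L, sd = 1e-4), nrow = n))
  Y <- tsne_descend(P, Y, config)
  if (!all(is.finite(Y))) stopf("t-SNE diverged to non-finite coordinates")
  rownames(Y) <- rownames(D)
  colnames(Y) <- c("x", "y", "z")
  structure(list(ids = rownames(D), coords = Y, config = config),
            class = "tgv_embedding")
}

#' @export
print.tgv_embedding <- function(x, ...) {
  cat(sprintf("<tgv_embedding: %d molecules in 3-D (%s, perplexity %.3g, seed %d)>\n",
              nrow(x$coords), x$config$metric, x$config$perplexity, x$config$seed))
  invisible(x)
}

#' @noRd
embedding_distances <- function(x, metric) {
  stopifnot(is.matrix(x))
  if (nrow(x) == ncol(x) && isTRUE(all.equal(unname(diag(x)), rep(1, nrow(x)))) &&
      max(x) <= 1 && min(x) >= 0 && isTRUE(all.equal(x, t(x)))) {
    # similarity matrix
    D <- 1 - x
    diag(D) <- 0
    return(D)
  }
  if (nrow(x) == ncol(x) && all(abs(diag(x)) < 1e-12) && isTRUE(all.equal(x, t(x)))) {
    return(x) # already a distance matrix
  }
  if (metric == "jaccard_distance") {
    D <- 1 - similarity_matrix(x)
    diag(D) <- 0
    D
  } else {
    as.matrix(stats::dist(x))
  }
}

# Bisection bandwidth calibration: find per-point precisions beta so the
# entropy of p_{j|i} equals log(perplexity).
#' @noRd
conditional_affinities <- function(D, perplexity, tol = 1e-5, max_iter = 50L) {
  n <- nrow(D)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  D2 <- D^2
  for (i in seq_len(n)) {
    beta <- 1; beta_min <- -Inf; beta_max <- Inf
    d <- D2[i, -i]
    for (iter in seq_len(max_iter)) {
      p <- exp(-d * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 0 } else {
        H <- log(sp) + beta * sum(d * p) / sp
        p <- p / sp
      }
      diff <- H - target
      if (abs(diff) < tol) break
      if (diff > 0) { # entropy too high -> narrow the kernel
        beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else {
        beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P
}

#' @noRd
cond_to_joint <- function(P) {
  n <- nrow(P)
  J <- (P + t(P)) / (2 * n)
  pmax(J, .Machine$double.eps)
}

# Momentum gradient descent on the KL divergence with adaptive gains.
#' @noRd
tsne_descend <- function(P, Y, config) {
  n <- nrow(Y)
  dY <- matrix(0, n, 3L)
  gains <- matrix(1, n, 3L)
  Pex <- P * config$early_exaggeration
  for (iter in seq_len(config$iterations)) {
    Pit <- if (iter <= config$exaggeration_iters) Pex else P
    momentum <- if (iter <= config$exaggeration_iters) 0.5 else 0.8

    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), .Machine$double.eps)

    L <- (Pit - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y

    gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    dY <- momentum * dY - config$learning_rate * gains * grad
    Y <- Y + dY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
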
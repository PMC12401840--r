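#' Baseline graph-pooling methods
#'
#' Alternative pooling operators sharing the [hierarchicalPool()] output
#' contract, for controlled comparisons against hierarchical-clustering
#' pooling.
#'
#' * `"topk"` scores nodes with a linear projection of their features
#'   (`weights`, or a seeded random draw standing in for a learned scorer),
#'   keeps the `C` top-scoring nodes in original node order, and takes the
#'   induced subgraph. Rows of `S_hard` for dropped nodes are all zero, so
#'   the S-matrix product identities still hold.
#' * `"kmeans"` clusters node feature rows into `C` groups (`stats::kmeans`,
#'   seeded) and pools exactly as the hierarchical method does.
#'
#' @param name `"topk"` or `"kmeans"`.
#' @param X node feature matrix (N x D).
#' @param A adjacency (N x N).
#' @param C number of supernodes (`C <= N`).
#' @param tau soft-assignment temperature.
#' @param weights optional length-D scoring vector for `"topk"`.
#' @param seed seed for the random scorer / k-means initialization.
#' @return a `"PoolingResult"` (see [hierarchicalPool()]); for `"topk"`,
#'   `labels` is `NA` for dropped nodes.
#' @export
poolBaseline <- function(name = c("topk", "kmeans"), X, A, C, tau = 1.0,
                         weights = NULL, seed = 1L) {
  name <- match.arg(name)
  n <- nrow(X)
  if (C > n) stop("C must not exceed the number of nodes")
  if (name == "topk") {
    if (is.null(weights))
      weights <- .with_seed(seed, rnorm(ncol(X)))
    score <- drop(X %*% weights)
    keep <- sort(order(-score)[seq_len(C)])  # induced subgraph, node order
    S <- matrix(0, n, C)
    S[cbind(keep, seq_len(C))] <- 1
    labels <- rep(NA_integer_, n)
    labels[keep] <- seq_len(C)
    .finish_pool(X, A, S, labels, tau)
  } else {
    km <- .with_seed(seed, kmeans(X, centers = C, nstart = 5L))
    labels <- .canonical_labels(km$cluster)
    S <- matrix(0, n, C)
    S[cbind(seq_len(n), labels)] <- 1
    .finish_pool(X, A, S, labels, tau)
  }
}
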
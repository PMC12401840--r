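#' @title Graph-network building blocks
#' @description
#' The individual stages of the multimodal hierarchical graph classifier:
#' clinically guided node attention, prior-fused dynamic edge learning,
#' symmetric-normalized graph convolution, hierarchical-clustering pooling on
#' a blended topology/feature distance, the classification head, and the
#' three loss terms (cross-entropy, link reconstruction, assignment entropy).
#' These R functions define the reference semantics; the training loop runs
#' an equivalent compiled implementation.
#' @name model_ops
NULL

leakyRelu <- function(x, slope = 0.01) {
  x * ifelse(x > 0, 1, slope)
}

softmaxRows <- function(m) {
  m <- as.matrix(m)
  e <- exp(m - apply(m, 1, max))
  e / rowSums(e)
}

.check_finite <- function(x, what) {
  if (any(!is.finite(x))) stop(what, " contains non-finite values")
}

#' Clinically guided node attention
#'
#' Embeds the clinical vector with a LeakyReLU linear layer,
#' `F_t = LReLU(X_t W_t + b_t)`, forms a single query from it and keys/values
#' from the node features, and scores every brain region against the clinical
#' context: `A_node = softmax(Q K' / sqrt(D_k))`, a probability vector over
#' regions. Node features are rescaled per region as
#' `X_i = N * A_node[i] * V_i`, which leaves features unchanged under uniform
#' attention (`N * 1/N = 1`) and amplifies clinically salient regions
#' otherwise.
#'
#' @param clinical clinical covariate vector (length D_t).
#' @param X node feature matrix N x D_h (already projected to hidden width).
#' @param params list with `W_t` (D_t x D_h), `b_t`, `W_Q` (D_h x D_k),
#'   `W_K` (D_h x D_k), `W_V` (D_h x D_h).
#' @param slope LeakyReLU negative slope.
#' @return list with `X` (enhanced N x D_h features), `A_node` (length-N
#'   attention vector summing to 1) and `F_t` (clinical embedding).
#' @export
nodeEnhance <- function(clinical, X, params, slope = 0.01) {
  .check_finite(clinical, "clinical"); .check_finite(X, "X")
  ft <- leakyRelu(drop(clinical %*% params$W_t) + params$b_t, slope)
  dk <- ncol(params$W_Q)
  q <- drop(ft %*% params$W_Q)                       # 1 x D_k
  K <- X %*% params$W_K                              # N x D_k
  V <- X %*% params$W_V                              # N x D_h
  s <- drop(K %*% q) / sqrt(dk)
  a <- drop(softmaxRows(matrix(s, nrow = 1)))
  list(X = V * (nrow(X) * a), A_node = a, F_t = ft)
}

#' Fuse the structural-disconnection and anatomical edge priors
#'
#' `A_prior = SD + A_s`: the anatomical topology carries weight 1 on adjacent
#' region pairs and the individualized damage fractions add up to 1 more on
#' disconnected pairs. With `useDamage = FALSE` the prior is the anatomy
#' alone.
#'
#' @param SD structural-disconnection matrix (N x N, symmetric, zero diag).
#' @param A_s binary anatomical adjacency (same shape).
#' @param useDamage include the damage term?
#' @return symmetric N x N prior matrix.
#' @export
fuseEdgePrior <- function(SD, A_s, useDamage = TRUE) {
  if (!identical(dim(SD), dim(A_s)))
    stop("SD and A_s must have identical dimensions")
  if (useDamage) SD + A_s else A_s
}

#' Multi-head self-attention over node features
#'
#' Per head `h`, `A^h = softmax_rows(Q^h K^h' / sqrt(D_k))`; the learned
#' adjacency is the head average, so every row sums to 1.
#'
#' @param X node features (N x D_h).
#' @param W_Q,W_K projection matrices of shape D_h x (H * D_k); head `h`
#'   uses the h-th block of D_k columns.
#' @param H number of heads.
#' @return row-stochastic N x N learned adjacency.
#' @export
edgeAttention <- function(X, W_Q, W_K, H) {
  if (ncol(W_Q) %% H != 0L) stop("H must divide the projection width")
  dk <- ncol(W_Q) %/% H
  n <- nrow(X)
  A <- matrix(0, n, n)
  for (h in seq_len(H)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    Qh <- X %*% W_Q[, cols, drop = FALSE]
    Kh <- X %*% W_K[, cols, drop = FALSE]
    A <- A + softmaxRows(tcrossprod(Qh, Kh) / sqrt(dk))
  }
  A / H
}

#' Refine an adjacency with learned attention
#'
#' Hadamard product of the learned attention with the previous layer's edge
#' matrix, symmetrized by averaging with its transpose (the downstream graph
#' convolution assumes a symmetric adjacency). Layer 1 uses the fused prior;
#' layer 2 uses the pooled adjacency from the first pooling stage.
#'
#' @param A_learn row-stochastic learned adjacency.
#' @param A_prev prior/previous-layer edge matrix (same shape).
#' @return symmetric refined adjacency.
#' @export
refineAdjacency <- function(A_learn, A_prev) {
  if (!identical(dim(A_learn), dim(A_prev)))
    stop("A_learn and A_prev must have identical dimensions")
  raw <- A_learn * A_prev
  (raw + t(raw)) / 2
}

#' Symmetric-normalized graph convolution
#'
#' Adds self-loops (`A* = A + I`, guaranteeing positive degrees), normalizes
#' by `D^{-1/2} A* D^{-1/2}` and applies a linear map followed by LeakyReLU.
#'
#' @param X node features (N x D).
#' @param A symmetric non-negative adjacency (N x N).
#' @param W weight matrix (D x D_out).
#' @param slope LeakyReLU negative slope.
#' @return N x D_out activated features.
#' @export
gcnLayer <- function(X, A, W, slope = 0.01) {
  astar <- A + diag(nrow(A))
  dm <- 1 / sqrt(rowSums(astar))
  M <- astar * outer(dm, dm)
  leakyRelu(M %*% X %*% W, slope)
}

.scale01_offdiag <- function(M) {
  n <- nrow(M)
  if (n < 2L) return(M * 0)
  off <- M[row(M) != col(M)]
  lo <- min(off); hi <- max(off)
  if (hi == lo) {
    M[] <- 0
  } else {
    M <- (M - lo) / (hi - lo)
  }
  diag(M) <- 0
  M
}

#' Blended topology/feature distance matrix
#'
#' `D_path` is the shortest-path hop count on the binarized graph (an edge
#' wherever the adjacency is positive off the diagonal); unreachable pairs
#' are set to the largest finite hop count plus one. `D_features` is the
#' squared Euclidean distance between node feature rows. Each matrix is
#' min-max scaled to [0, 1] over its off-diagonal entries (the two scales are
#' otherwise incommensurate) and blended as
#' `alpha * D_path + (1 - alpha) * D_features`.
#'
#' @param X node features (N x D).
#' @param A adjacency defining the topology (N x N).
#' @param alpha blend weight of the path distance, in [0, 1].
#' @param pathDist optional precomputed raw hop-count matrix.
#' @return list with `D_combined`, `D_path`, `D_features` (all N x N; the
#'   path/feature components are returned on their raw scales).
#' @export
combinedDistance <- function(X, A, alpha = 0.5, pathDist = NULL) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  n <- nrow(A)
  if (n == 1L)
    return(list(D_combined = matrix(0, 1, 1), D_path = matrix(0, 1, 1),
                D_features = matrix(0, 1, 1)))
  if (is.null(pathDist)) {
    B <- (A > 0) * 1
    diag(B) <- 0
    g <- igraph::graph_from_adjacency_matrix(B, mode = "undirected")
    dp <- igraph::distances(g)
    if (any(is.infinite(dp))) {
      mx <- max(dp[is.finite(dp)])
      dp[is.infinite(dp)] <- mx + 1
    }
  } else {
    dp <- pathDist
  }
  dimnames(dp) <- NULL
  df <- as.matrix(dist(X))^2
  dimnames(df) <- NULL
  dcomb <- alpha * .scale01_offdiag(dp) + (1 - alpha) * .scale01_offdiag(df)
  list(D_combined = dcomb, D_path = dp, D_features = df)
}

# Canonical relabeling: clusters ordered by their smallest member index.
.canonical_labels <- function(labels) {
  first <- tapply(seq_along(labels), labels, min)
  ord <- order(first)
  relab <- integer(length(ord))
  relab[as.integer(names(first))[ord]] <- seq_along(ord)
  relab[labels]
}

#' Average-linkage hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering with average (UPGMA) linkage and deterministic
#' lowest-index tie-breaking, returning the merge history in the same
#' encoding as `stats::hclust` (negative entries are leaves).
#'
#' @param D symmetric distance matrix.
#' @return list with `merge` ((N-1) x 2 integer matrix) and `height`.
#' @export
averageLinkage <- function(D) {
  res <- hc_average_cpp(as.matrix(D), 1L)
  list(merge = res$merge, height = drop(res$height))
}

#' Hierarchical-clustering graph pooling
#'
#' Clusters nodes by average linkage on the blended distance
#' ([combinedDistance()]), cuts the dendrogram into `C` clusters (labels are
#' canonicalized so cluster 1 contains the smallest node index), and pools:
#' `X_pooled = S_hard' X`, `A_pooled = S_hard' A S_hard` with the diagonal
#' zeroed. The soft assignment used by the pooling losses is
#' `S_soft[i, c] = softmax_c(-||X_i - centroid_c||^2 / tau)` with centroids
#' from the hard clusters; it equals a differentiable relaxation of the hard
#' assignment at temperature `tau`.
#'
#' @inheritParams combinedDistance
#' @param C number of clusters, `1 <= C <= N`.
#' @param tau soft-assignment temperature (> 0).
#' @return a `"PoolingResult"`: list with `Z` (merge + height), `labels`,
#'   `S_hard` (N x C one-hot), `S_soft` (N x C row-stochastic), `X_pooled`
#'   (C x D), `A_pooled` (C x C, zero diagonal) and `D_combined`.
#' @export
hierarchicalPool <- function(X, A, C, alpha = 0.5, tau = 1.0,
                             pathDist = NULL) {
  n <- nrow(X)
  if (C > n) stop("C must not exceed the number of nodes")
  if (C < 1L) stop("C must be >= 1")
  dl <- combinedDistance(X, A, alpha = alpha, pathDist = pathDist)
  res <- hc_average_cpp(dl$D_combined, as.integer(C))
  labels <- .canonical_labels(drop(res$labels))
  S <- matrix(0, n, C)
  S[cbind(seq_len(n), labels)] <- 1
  .finish_pool(X, A, S, labels, tau,
               Z = list(merge = res$merge, height = drop(res$height)),
               D_combined = dl$D_combined)
}

# Shared pooling tail used by hierarchicalPool() and poolBaseline().
.finish_pool <- function(X, A, S, labels, tau, Z = NULL, D_combined = NULL) {
  nc <- colSums(S)
  Xp <- crossprod(S, X)
  centroids <- Xp / pmax(nc, 1)
  d2 <- outer(rowSums(X^2), rowSums(centroids^2), "+") -
    2 * tcrossprod(X, centroids)
  Ssoft <- softmaxRows(-d2 / tau)
  Ap <- crossprod(S, A) %*% S
  diag(Ap) <- 0
  structure(list(
    Z = Z, labels = labels, S_hard = S, S_soft = Ssoft,
    X_pooled = Xp, A_pooled = Ap, D_combined = D_combined
  ), class = "PoolingResult")
}

#' @export
print.PoolingResult <- function(x, ...) {
  cat(sprintf("PoolingResult: %d nodes -> %d supernodes\n",
              nrow(x$S_hard), ncol(x$S_hard)))
  invisible(x)
}

#' Cross-entropy classification loss
#'
#' `L_cls = -(1/M) * sum_m sum_n y_mn log p_mn` with the log argument clipped
#' at 1e-12.
#'
#' @param p M x 2 matrix of class probabilities (rows on the simplex).
#' @param y binary label vector (0 = non-PSCI, 1 = PSCI).
#' @return non-negative scalar.
#' @export
classificationLoss <- function(p, y) {
  p <- as.matrix(p)
  if (is.null(dim(p)) || ncol(p) != 2L) stop("p must be an M x 2 matrix")
  m <- nrow(p)
  -sum(log(pmax(p[cbind(seq_len(m), as.integer(y) + 1L)], 1e-12))) / m
}

#' Link-reconstruction pooling loss
#'
#' `L_link = ||A - S S'||_F^2`, optionally normalized by the squared number
#' of pre-pooling nodes so layers of different sizes contribute on comparable
#' scales.
#'
#' @param A pre-pooling adjacency of the layer.
#' @param S soft assignment matrix of that layer.
#' @param normalize divide by `nrow(A)^2`?
#' @return non-negative scalar.
#' @export
linkLoss <- function(A, S, normalize = TRUE) {
  if (nrow(A) != nrow(S)) stop("A and S must agree on the node dimension")
  v <- sum((A - tcrossprod(S))^2)
  if (normalize) v / nrow(A)^2 else v
}

#' Assignment-entropy pooling loss
#'
#' `L_entropy = -sum_ic S[i,c] log S[i,c]` with `0 log 0 = 0`, optionally
#' normalized by the number of nodes; zero exactly for one-hot assignments,
#' `log(C)` per node for uniform ones.
#'
#' @param S row-stochastic assignment matrix.
#' @param normalize divide by `nrow(S)`?
#' @return non-negative scalar.
#' @export
entropyLoss <- function(S, normalize = TRUE) {
  if (any(S < 0)) stop("S must be non-negative")
  pos <- S > 0
  v <- -sum(S[pos] * log(S[pos]))
  if (normalize) v / nrow(S) else v
}

#' Graph-level classification head
#'
#' Global average pooling over the final supernodes, parallel linear maps of
#' the pooled embedding and the clinical embedding, concatenation, dropout
#' (training only) and a softmax output layer.
#'
#' @param X_final final pooled feature matrix (C x D_h).
#' @param F_t clinical embedding (length D_h).
#' @param head list with `W_ct`, `b_ct`, `W_cg`, `b_cg`, `W_out` (2 D_h x 2),
#'   `b_out`.
#' @param dropout_p dropout probability applied to the concatenated vector.
#' @param training apply dropout? Evaluation passes are deterministic.
#' @return list with `prob` (length-2 probability vector) and `g_f`.
#' @export
classifyGraph <- function(X_final, F_t, head, dropout_p = 0,
                          training = FALSE) {
  g <- colMeans(X_final)
  u <- drop(F_t %*% head$W_ct) + head$b_ct
  v <- drop(g %*% head$W_cg) + head$b_cg
  gf <- c(u, v)
  if (training && dropout_p > 0) {
    mask <- rbinom(length(gf), 1L, 1 - dropout_p) / (1 - dropout_p)
    gf <- gf * mask
  }
  logits <- drop(gf %*% head$W_out) + head$b_out
  e <- exp(logits - max(logits))
  list(prob = e / sum(e), g_f = gf)
}
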
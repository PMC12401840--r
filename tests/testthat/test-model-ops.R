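test_that("node attention reduces to identity under constant keys", {
  set.seed(1)
  n <- 6; dh <- 4
  X <- matrix(rep(rnorm(dh), each = n), n, dh)  # identical rows
  prm <- list(W_t = matrix(rnorm(3 * dh), 3), b_t = rnorm(dh),
              W_Q = matrix(rnorm(dh * 2), dh), W_K = matrix(rnorm(dh * 2), dh),
              W_V = diag(dh))
  ne <- nodeEnhance(rnorm(3), X, prm)
  expect_equal(ne$A_node, rep(1 / n, n))
  expect_equal(ne$X, X %*% prm$W_V)  # X-tilde = V when attention is uniform
})

test_that("node attention matches a hand-evaluated scalar softmax", {
  # D_t = D_h = D_k = 1, N = 2: everything is scalar arithmetic
  prm <- list(W_t = matrix(0.5), b_t = 0.1, W_Q = matrix(0.3),
              W_K = matrix(0.7), W_V = matrix(1.0))
  X <- matrix(c(1, -1), 2, 1)
  ne <- nodeEnhance(2, X, prm)
  ft <- 2 * 0.5 + 0.1                   # positive -> LeakyReLU identity
  q <- ft * 0.3
  s <- q * c(0.7, -0.7) / sqrt(1)
  a <- exp(s) / sum(exp(s))
  expect_equal(ne$F_t, ft)
  expect_equal(ne$A_node, a)
  expect_equal(ne$X, matrix(2 * a * c(1, -1), 2, 1))
  expect_equal(sum(ne$A_node), 1)
})

test_that("edge prior fusion is additive with a damage switch", {
  SD <- matrix(c(0, 0.4, 0.4, 0), 2)
  As <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(fuseEdgePrior(SD * 0, As), As)
  expect_equal(fuseEdgePrior(SD, As * 0), SD)
  expect_equal(fuseEdgePrior(SD, As)[1, 2], 1.4)
  expect_equal(fuseEdgePrior(SD, As, useDamage = FALSE), As)
  expect_error(fuseEdgePrior(SD, diag(3)), "dimensions")
})

test_that("edge attention averages row-stochastic heads", {
  set.seed(2)
  n <- 7; dh <- 6
  X <- matrix(rnorm(n * dh), n, dh)
  Wq <- matrix(rnorm(dh * dh), dh); Wk <- matrix(rnorm(dh * dh), dh)
  # H = 1 equals a directly computed row softmax
  A1 <- edgeAttention(X, Wq[, 1:3], Wk[, 1:3], H = 1L)
  S <- (X %*% Wq[, 1:3]) %*% t(X %*% Wk[, 1:3]) / sqrt(3)
  manual <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(A1, manual)
  # identical node features -> uniform attention
  Xc <- matrix(rep(rnorm(dh), each = n), n, dh)
  expect_equal(edgeAttention(Xc, Wq, Wk, H = 2L),
               matrix(1 / n, n, n))
  # rows sum to 1 for any head count
  for (H in c(1L, 2L, 3L)) {
    A <- edgeAttention(X, Wq, Wk, H = H)
    expect_equal(rowSums(A), rep(1, n), tolerance = 1e-12)
  }
})

test_that("adjacency refinement is a symmetrized Hadamard product", {
  set.seed(3)
  A_learn <- matrix(runif(9), 3); A_prev <- matrix(runif(9), 3)
  expect_equal(refineAdjacency(A_learn, matrix(1, 3, 3)),
               (A_learn + t(A_learn)) / 2)
  expect_equal(refineAdjacency(A_learn, matrix(0, 3, 3)), matrix(0, 3, 3))
  Al <- matrix(0, 3, 3); Al[1, 2] <- 0.2; Al[2, 1] <- 0.4
  Ap <- matrix(0, 3, 3); Ap[1, 2] <- 0.5; Ap[2, 1] <- 0.5
  expect_equal(refineAdjacency(Al, Ap)[1, 2], 0.15)
})

test_that("graph convolution handles self-loops and block structure", {
  # single node: degree-1 self loop, output = LeakyReLU(X)
  X <- matrix(c(2, -3), 1)
  expect_equal(gcnLayer(X, matrix(0, 1, 1), diag(2)),
               matrix(c(2, -0.03), 1))
  # disconnected nodes only see themselves
  X2 <- matrix(rnorm(4), 2)
  A0 <- matrix(0, 2, 2)
  out <- gcnLayer(X2, A0, diag(2))
  X2b <- X2; X2b[2, ] <- X2b[2, ] + 10
  expect_equal(gcnLayer(X2b, A0, diag(2))[1, ], out[1, ])
  # 3-node path, one-hot features: matches the hand-built normalization
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1; A[2, 3] <- A[3, 2] <- 1
  deg <- c(2, 3, 2)
  M <- (A + diag(3)) / sqrt(outer(deg, deg))
  expect_equal(gcnLayer(diag(3), A, diag(3)), M)  # entries >= 0, LReLU no-op
})

test_that("combined distance blends scaled hops with feature distances", {
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1; A[2, 3] <- A[3, 2] <- 1
  X <- matrix(rnorm(6), 3)
  cd <- combinedDistance(X, A, alpha = 0.5)
  expect_equal(cd$D_path[1, 3], 2)
  # identical rows: D_features = 0, so the blend is alpha * scaled hops
  Xc <- matrix(1, 3, 2)
  cd2 <- combinedDistance(Xc, A, alpha = 0.7)
  expect_equal(cd2$D_features, matrix(0, 3, 3))
  sp <- cd2$D_path; off <- sp[row(sp) != col(sp)]
  sps <- (sp - min(off)) / (max(off) - min(off)); diag(sps) <- 0
  expect_equal(cd2$D_combined, 0.7 * sps)
  expect_equal(combinedDistance(matrix(1, 1, 2), matrix(0, 1, 1))$D_combined,
               matrix(0, 1, 1))
})

test_that("shortest-path hops match a Floyd-Warshall oracle", {
  set.seed(4)
  for (n in c(5, 17, 50)) {
    A <- random_sym_adj(n, density = 0.08)  # sparse enough to disconnect
    cd <- combinedDistance(matrix(rnorm(n * 3), n), A)
    expect_equal(cd$D_path, floyd_warshall_hops(A), ignore_attr = TRUE)
    expect_equal(psciNet:::bfs_hops_cpp(A), floyd_warshall_hops(A),
                 ignore_attr = TRUE)
  }
})

test_that("hierarchical pooling satisfies its definitional contracts", {
  set.seed(5)
  # C = N with distinct rows: identity assignment (canonical labels)
  n <- 8
  X <- matrix(rnorm(n * 3), n)
  A <- random_sym_adj(n, 0.5)
  pr <- hierarchicalPool(X, A, C = n)
  expect_equal(pr$S_hard, diag(n))
  expect_equal(pr$X_pooled, X)

  # two well-separated blobs, alpha = 0 (features only), C = 2
  blob <- rep(1:2, each = 5)
  Xb <- matrix(rnorm(10 * 4, sd = 0.2), 10) + 10 * (blob - 1)
  prb <- hierarchicalPool(Xb, random_sym_adj(10, 0.4), C = 2, alpha = 0)
  expect_true(same_partition(prb$labels, blob))

  # S-matrix product oracle on random graphs
  for (i in 1:5) {
    n <- sample(5:20, 1); C <- sample(2:min(6, n), 1)
    X <- matrix(rnorm(n * 4), n)
    A <- random_sym_adj(n)
    pr <- hierarchicalPool(X, A, C = C)
    expect_equal(pr$X_pooled, t(pr$S_hard) %*% X)
    Ap <- t(pr$S_hard) %*% A %*% pr$S_hard; diag(Ap) <- 0
    expect_equal(pr$A_pooled, Ap)
    expect_equal(rowSums(pr$S_hard), rep(1, n))
    expect_equal(rowSums(pr$S_soft), rep(1, n), tolerance = 1e-9)
  }
  expect_error(hierarchicalPool(X, A, C = 100), "exceed")
})

test_that("average linkage agrees with the stats::hclust oracle", {
  set.seed(6)
  for (i in 1:5) {
    n <- sample(8:40, 1)
    D <- as.matrix(dist(matrix(rnorm(n * 4), n)))
    al <- averageLinkage(D)
    hc <- hclust(as.dist(D), method = "average")
    expect_equal(al$height, hc$height, tolerance = 1e-9)
    for (C in c(2L, 4L)) {
      lab <- psciNet:::hc_average_cpp(D, C)$labels
      expect_true(same_partition(drop(lab), cutree(hc, k = C)))
    }
  }
})

test_that("loss terms match closed forms and direct summation", {
  # classification
  expect_equal(classificationLoss(rbind(c(1, 0), c(0, 1)), c(0, 1)), 0)
  expect_equal(classificationLoss(matrix(c(0.5, 0.5), 1), 1), log(2))
  p <- rbind(c(0.9, 0.1), c(0.3, 0.7), c(0.6, 0.4))
  y <- c(0, 1, 1)
  expect_equal(classificationLoss(p, y),
               -(log(0.9) + log(0.7) + log(0.4)) / 3)

  # link loss
  S <- matrix(0, 6, 2); S[cbind(1:6, rep(1:2, each = 3))] <- 1
  expect_equal(linkLoss(S %*% t(S), S), 0)
  expect_equal(linkLoss(matrix(0, 6, 6), S, normalize = FALSE), 3^2 + 3^2)
  set.seed(7)
  A5 <- matrix(runif(25), 5); S5 <- matrix(runif(15), 5)
  brute <- 0
  R <- A5 - S5 %*% t(S5)
  for (i in 1:5) for (j in 1:5) brute <- brute + R[i, j]^2
  expect_equal(linkLoss(A5, S5, normalize = FALSE), brute)
  expect_equal(linkLoss(A5, S5), brute / 25)

  # entropy loss
  expect_equal(entropyLoss(S), 0)
  U <- matrix(1 / 4, 6, 4)
  expect_equal(entropyLoss(U, normalize = FALSE), 6 * log(4))
  expect_equal(entropyLoss(U), log(4))
  Sr <- matrix(runif(12), 4); Sr <- Sr / rowSums(Sr)
  brute <- 0
  for (i in 1:4) for (j in 1:3) brute <- brute - Sr[i, j] * log(Sr[i, j])
  expect_equal(entropyLoss(Sr, normalize = FALSE), brute)
  expect_error(entropyLoss(-Sr), "non-negative")
})

test_that("classification head is a deterministic softmax at evaluation", {
  set.seed(8)
  dh <- 5
  head <- list(W_ct = matrix(rnorm(dh * dh), dh), b_ct = rnorm(dh),
               W_cg = matrix(rnorm(dh * dh), dh), b_cg = rnorm(dh),
               W_out = matrix(rnorm(2 * dh * 2), 2 * dh), b_out = rnorm(2))
  Xf <- matrix(rnorm(3 * dh), 3)
  ft <- rnorm(dh)
  out <- classifyGraph(Xf, ft, head)
  expect_equal(sum(out$prob), 1)
  expect_equal(out$prob, classifyGraph(Xf, ft, head)$prob)  # determinism
  head0 <- head; head0$W_out[] <- 0; head0$b_out[] <- 0
  expect_equal(classifyGraph(Xf, ft, head0)$prob, c(0.5, 0.5))
})
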
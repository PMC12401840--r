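# Small fixtures and independent brute-force oracles shared across tests.

tiny_sim <- function(n = 10L, N = 12L, D = 6L, seed = 3L, ...) {
  simulationConfig(n_subjects = n, n_psci = max(2L, round(n * 0.3)),
                   n_regions = N, D_node = D, n_hubs = 3L,
                   n_effect_features = 2L, seed = seed, ...)
}

tiny_cohort <- function(...) makeCohort(tiny_sim(...))

tiny_config <- function(seed = 7L, ...) {
  args <- utils::modifyList(
    list(D_h = 8L, H = 2L, C = 4L, lr = 1e-3, epochs = 3L, seed = seed),
    list(...))
  do.call(mdhcConfig, args)
}

random_sym_adj <- function(n, density = 0.3) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  on <- sample(up, max(1L, round(density * length(up))))
  A[on] <- runif(length(on))
  A <- A + t(A)
  diag(A) <- 0
  A
}

cpp_forward <- function(graph, params, config, useDamage = config$use_damage) {
  ap <- fuseEdgePrior(graph@damage, graph@anatAdj, useDamage = useDamage)
  psciNet:::mdhc_forward_cpp(graph@nodeFeatures, ap,
                             as.numeric(graph@clinical), graph@label,
                             unclass(params), unclass(config))
}

# ---- independent oracles (explicit loops, no package internals) ----

floyd_warshall_hops <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && A[i, j] > 0) D[i, j] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  if (any(is.infinite(D))) {
    mx <- max(D[is.finite(D)])
    D[is.infinite(D)] <- mx + 1
  }
  D
}

auc_concordant_pairs <- function(y, p) {
  pos <- which(y == 1L); neg <- which(y == 0L)
  tot <- 0
  for (i in pos) for (j in neg) {
    if (p[i] > p[j]) tot <- tot + 1
    else if (p[i] == p[j]) tot <- tot + 0.5
  }
  tot / (length(pos) * length(neg))
}

# brute-force greedy mRMR with the same discretization contract (5
# equal-frequency bins), recomputing every mutual information from a
# contingency table built by direct counting
oracle_discretize <- function(x, bins = 5L) {
  u <- unique(x)
  if (length(u) <= bins) return(match(x, sort(u)))
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                        names = FALSE, type = 7))
  if (length(br) < 2L) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

oracle_mi <- function(a, b) {
  va <- sort(unique(a)); vb <- sort(unique(b))
  n <- length(a)
  mi <- 0
  for (x in va) for (y in vb) {
    nxy <- sum(a == x & b == y)
    if (nxy > 0) {
      pxy <- nxy / n
      mi <- mi + pxy * log(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
    }
  }
  mi
}

oracle_mrmr <- function(features, target, k, bins = 5L) {
  f <- ncol(features)
  disc <- sapply(seq_len(f), function(j) oracle_discretize(features[, j],
                                                           bins))
  y <- as.integer(factor(target))
  selected <- integer(0)
  remaining <- seq_len(f)
  for (step in seq_len(min(k, f))) {
    best <- -Inf; pick <- NA_integer_
    for (j in remaining) {
      rel <- oracle_mi(disc[, j], y)
      red <- if (length(selected))
        mean(sapply(selected, function(s) oracle_mi(disc[, j], disc[, s])))
      else 0
      sc <- rel - red
      if (sc > best) { best <- sc; pick <- j }
    }
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
  }
  selected
}

# are two label vectors the same partition up to relabeling?
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}
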
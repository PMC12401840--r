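test_that("Spearman filter drops rank-duplicated features, keeps the rest", {
  set.seed(1)
  x <- rnorm(40)
  tab <- cbind(x, 2 * x + 5, rnorm(40), rep(1, 40))  # f2 duplicates f1's ranks
  expect_equal(spearmanFilter(tab, 0.95), c(1L, 3L, 4L))

  # mutually independent features at threshold 0.95: all kept (and the
  # premise |rho| < 0.95 verified directly)
  set.seed(2)
  tab2 <- matrix(rnorm(200 * 10), 200, 10)
  rho <- cor(tab2, method = "spearman"); diag(rho) <- 0
  expect_lt(max(abs(rho)), 0.95)
  expect_equal(spearmanFilter(tab2, 0.95), 1:10)

  # threshold 1.0 with no duplicated rank patterns keeps everything
  expect_equal(spearmanFilter(tab2, 1.0), 1:10)

  # idempotence: filtering the kept set changes nothing
  set.seed(3)
  tab3 <- matrix(rnorm(50 * 8), 50, 8)
  tab3[, 4] <- tab3[, 2]^3          # monotone copy -> dropped
  kept <- spearmanFilter(tab3, 0.95)
  expect_false(4L %in% kept)
  expect_equal(spearmanFilter(tab3[, kept, drop = FALSE], 0.95),
               seq_along(kept))

  # constant features have correlations defined as 0, so they survive
  expect_true(4L %in% spearmanFilter(cbind(x, x + 1, rnorm(40), 7), 0.5))
})

test_that("mRMR picks a target copy first and honours k", {
  set.seed(4)
  y <- rep(c(0L, 1L), each = 20)
  feats <- cbind(rnorm(40), rnorm(40), as.numeric(y) + 0, rnorm(40))
  expect_equal(mrmrSelect(feats, y, k = 1)[1], 3L)
  expect_setequal(mrmrSelect(feats, y, k = 10), 1:4)
  expect_error(mrmrSelect(feats, y, k = 0), "k")
  expect_error(mrmrSelect(feats, rep(0L, 40), k = 1), "classes")
})

test_that("mRMR agrees with the exhaustive greedy MI oracle", {
  for (i in 1:6) {
    set.seed(100 + i)
    ns <- sample(20:60, 1)
    nf <- sample(4:12, 1)
    y <- rbinom(ns, 1, 0.5)
    while (length(unique(y)) < 2) y <- rbinom(ns, 1, 0.5)
    feats <- matrix(rnorm(ns * nf), ns, nf)
    feats[, 1] <- feats[, 1] + y          # make one feature informative
    k <- sample(2:4, 1)
    expect_equal(mrmrSelect(feats, y, k = k), oracle_mrmr(feats, y, k))
  }
})

test_that("frequency aggregation ranks by count with index tie-breaks", {
  # a feature selected by every region ranks first
  per_region <- lapply(1:8, function(r) c(42L, sample(1:40, 5)))
  agg <- frequencyAggregate(per_region, topFraction = 0.5, kSelect = 6)
  expect_equal(agg$features[1], 42L)
  expect_length(agg$features, 3L)  # round(0.5 * 6)

  # reference shape: 100-feature budget, top 30% -> exactly 30 features
  set.seed(5)
  pr <- lapply(1:20, function(r) sample(1:500, 100))
  expect_length(frequencyAggregate(pr, topFraction = 0.30)$features, 30L)

  # equal counts break toward the lower feature index
  tie <- list(c(7L, 3L), c(7L, 3L), c(9L, 5L))
  expect_equal(frequencyAggregate(tie, topFraction = 1, kSelect = 2)$features,
               c(3L, 7L))

  # invariant to region relabeling
  expect_equal(frequencyAggregate(rev(pr), topFraction = 0.3)$features,
               frequencyAggregate(pr, topFraction = 0.3)$features)

  expect_length(frequencyAggregate(list(), 0.3)$features, 0L)
})

test_that("node feature assembly concatenates modalities per region", {
  set.seed(6)
  n_subj <- 5; n_reg <- 4
  mods <- c("DWI", "MRA", "T1W", "T2W")
  tables <- lapply(mods, function(m)
    lapply(1:n_reg, function(r) matrix(rnorm(n_subj * 10), n_subj, 10)))
  names(tables) <- mods
  sel <- setNames(lapply(mods, function(m) sample(1:10, 3)), mods)
  nf <- assembleNodeFeatures(tables, sel)
  expect_length(nf, n_subj)
  expect_equal(dim(nf[[1]]), c(n_reg, 12L))
  # region r, modality block m holds exactly that region-table's values
  expect_equal(nf[[2]][3, 4:6], unname(tables$MRA[[3]][2, sel$MRA]))

  # single modality of 30 features -> width 30
  one <- list(DWI = tables$DWI)
  nf1 <- assembleNodeFeatures(one, list(DWI = 1:10))
  expect_equal(ncol(nf1[[1]]), 10L)

  # permuting region order permutes rows identically
  perm <- c(3, 1, 4, 2)
  tables_p <- lapply(tables, function(tt) tt[perm])
  nf_p <- assembleNodeFeatures(tables_p, sel)
  expect_equal(nf_p[[1]], nf[[1]][perm, ])

  # missing region table for one modality is an error
  broken <- tables; broken$T2W <- broken$T2W[1:3]
  expect_error(assembleNodeFeatures(broken, sel), "missing")
})

test_that("full selection pipeline returns per-modality lists and features", {
  set.seed(7)
  n_subj <- 30; n_reg <- 5; n_feat <- 20
  y <- rbinom(n_subj, 1, 0.4)
  tables <- list(DWI = lapply(1:n_reg, function(r) {
    m <- matrix(rnorm(n_subj * n_feat), n_subj, n_feat)
    m[, 2] <- m[, 1] + 1e-9 * rnorm(n_subj)  # redundant pair
    m[, 5] <- m[, 5] + y                     # informative
    m
  }))
  res <- selectNodeFeatures(tables, y, k = 10, topFraction = 0.3)
  expect_length(res$selected$DWI, 3L)   # round(0.3 * 10)
  expect_true(5L %in% res$selected$DWI)
  expect_false(2L %in% res$selected$DWI)  # dropped by the Spearman filter
  expect_equal(ncol(res$nodeFeatures[[1]]), 3L)
  expect_equal(nrow(res$nodeFeatures[[1]]), n_reg)
})
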
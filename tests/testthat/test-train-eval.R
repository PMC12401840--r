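test_that("MoCA labeling follows the education-specific cutoffs", {
  expect_equal(mocaLabel(13, "illiterate"), "PSCI")
  expect_equal(mocaLabel(14, "illiterate"), "non-PSCI")
  expect_equal(mocaLabel(19, "primary"), "PSCI")
  expect_equal(mocaLabel(20, "primary"), "non-PSCI")
  expect_equal(mocaLabel(24, "junior_high_plus"), "PSCI")
  expect_equal(mocaLabel(25, "junior_high_plus"), "non-PSCI")
  expect_error(mocaLabel(10, "college"), "education")
  expect_error(mocaLabel(31, "primary"), "moca")
})

test_that("stratified folds balance both classes and the totals", {
  labels <- rep(c(1L, 0L), c(44L, 108L))
  folds <- stratifiedKFold(labels, 5L, seed = 2L)
  expect_setequal(unlist(folds), seq_along(labels))        # exhaustive
  expect_equal(sum(lengths(folds)), 152L)                  # disjoint
  pos <- vapply(folds, function(f) sum(labels[f] == 1L), integer(1))
  neg <- vapply(folds, function(f) sum(labels[f] == 0L), integer(1))
  expect_true(all(pos %in% 8:9))
  expect_true(all(neg %in% 21:22))
  expect_setequal(lengths(folds), c(31L, 31L, 30L, 30L, 30L))
  # determinism and the degenerate single fold
  expect_identical(folds, stratifiedKFold(labels, 5L, seed = 2L))
  expect_equal(stratifiedKFold(labels, 1L)[[1]], seq_along(labels))
  expect_error(stratifiedKFold(c(1, 0, 0, 0), 2L), "fewer")
})

test_that("metrics follow their confusion-matrix definitions", {
  m <- classificationMetrics(c(1, 1, 1, 1), c(0.9, 0.8, 0.9, 0.95))
  expect_equal(m$acc, 1); expect_equal(m$sen, 1)
  expect_true(is.na(m$auc))  # single class

  # TP=3 FN=1 TN=5 FP=1
  y <- c(rep(1, 4), rep(0, 6))
  p <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.2, 0.3, 0.1, 0.4, 0.6)
  m <- classificationMetrics(y, p)
  expect_equal(m$acc, 0.8)
  expect_equal(m$sen, 0.75)
  expect_equal(m$spe, 5 / 6)

  # constant-probability model: accuracy equals the majority-class fraction
  expect_equal(classificationMetrics(y, rep(0.3, 10))$acc, 0.6)

  # rank AUC equals brute-force concordant-pair counting, with ties
  set.seed(3)
  for (i in 1:4) {
    n <- sample(20:200, 1)
    yy <- rbinom(n, 1, 0.4)
    while (length(unique(yy)) < 2) yy <- rbinom(n, 1, 0.4)
    pp <- round(runif(n), 1)  # coarse grid forces ties
    expect_equal(classificationMetrics(yy, pp)$auc,
                 auc_concordant_pairs(yy, pp))
  }

  # null AUC concentrates near 0.5
  set.seed(4)
  y2 <- rbinom(2000, 1, 0.3)
  expect_lt(abs(classificationMetrics(y2, runif(2000))$auc - 0.5), 0.03)
})

test_that("zero learning rate freezes parameters and the loss", {
  set.seed(5)
  coh <- tiny_cohort(n = 8, N = 10, D = 5, seed = 21)
  cfg <- tiny_config(seed = 22, lr = 0, epochs = 4L, dropout_p = 0)
  fit <- trainFold(coh@graphs[1:6], coh@graphs[7:8], cfg)
  init <- mdhcInitParams(5, 8, cfg)
  expect_equal(fit$params$W_in, init$W_in)
  expect_equal(fit$params$W_out, init$W_out)
  expect_equal(max(fit$train_loss) - min(fit$train_loss), 0)
})

test_that("training reduces the loss on a separable synthetic fold", {
  coh <- makeCohort(simulationConfig(
    n_subjects = 24, n_psci = 10, n_regions = 16, D_node = 8, n_hubs = 4,
    n_effect_features = 3, effect_size = 2, seed = 23))
  cfg <- mdhcConfig(D_h = 16L, H = 2L, C = 4L, lr = 1e-3, epochs = 30L,
                    seed = 24)
  fit <- trainFold(coh@graphs[1:18], coh@graphs[19:24], cfg)
  expect_lt(fit$train_loss[30], fit$train_loss[1])
})

test_that("training is bit-reproducible under a fixed seed", {
  coh <- tiny_cohort(n = 10, N = 10, D = 5, seed = 25)
  cfg <- tiny_config(seed = 26, epochs = 3L)
  f1 <- trainFold(coh@graphs[1:7], coh@graphs[8:10], cfg)
  f2 <- trainFold(coh@graphs[1:7], coh@graphs[8:10], cfg)
  expect_identical(f1$metrics, f2$metrics)
  expect_identical(f1$params$W_in, f2$params$W_in)
  expect_identical(f1$train_loss, f2$train_loss)
})

test_that("cross-validation aggregates fold metrics", {
  coh <- tiny_cohort(n = 15, N = 8, D = 4, seed = 27)
  cfg <- tiny_config(seed = 28, epochs = 2L)
  rep <- crossValidate(coh, cfg, k = 3L)
  expect_s3_class(rep, "CVReport")
  expect_equal(nrow(rep$per_fold), 3L)
  expect_equal(unname(rep$mean["acc"]), mean(rep$per_fold$acc))
  expect_equal(unname(rep$sd["auc"]), sd(rep$per_fold$auc))
  expect_true(all(rep$per_fold$acc >= 0 & rep$per_fold$acc <= 1))
})

test_that("ablation rows share folds and reject unknown flags", {
  coh <- tiny_cohort(n = 14, N = 8, D = 4, seed = 29)
  cfg <- tiny_config(seed = 30, epochs = 2L)
  # the node/edge/damage ablation design is expressible as config rows
  variants <- list(
    full = character(0),
    no_node = "use_node_attention",
    no_edge = "use_edge_attention",
    no_damage = "use_damage",
    static_edges = c("use_edge_attention", "use_damage")
  )
  reps <- runAblation(coh, cfg, variants, k = 2L)
  expect_named(reps, names(variants))
  for (v in names(variants)[-1])
    expect_identical(reps[[v]]$folds, reps$full$folds)
  cmp <- attr(reps, "comparison")
  expect_equal(nrow(cmp), 5L)
  expect_error(runAblation(coh, cfg, list(x = "use_flux_capacitor")),
               "unknown")
  single <- runAblation(coh, cfg, list(base = character(0)), k = 2L)
  expect_length(single, 1L)
})
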
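test_that("R operation composition and the compiled forward agree", {
  set.seed(1)
  flag_sets <- list(
    list(),
    list(use_node_attention = FALSE),
    list(use_edge_attention = FALSE),
    list(use_damage = FALSE),
    list(use_clustering = FALSE),
    list(use_link_loss = FALSE, use_entropy_loss = FALSE)
  )
  for (i in seq_along(flag_sets)) {
    cfg <- do.call(tiny_config, c(list(seed = 20 + i), flag_sets[[i]]))
    coh <- tiny_cohort(n = 3, N = 14, D = 6, seed = 30 + i)
    g <- coh[[1]]
    params <- mdhcInitParams(6, 8, cfg)
    fr <- mdhcForward(g, params, cfg)
    fc <- cpp_forward(g, params, cfg)
    expect_equal(fr$prob, drop(fc$prob), tolerance = 1e-8)
    expect_equal(fr$losses$L_cls, fc$L_cls, tolerance = 1e-8)
    expect_equal(fr$losses$L_link, fc$L_link, tolerance = 1e-8)
    expect_equal(fr$losses$L_entropy, fc$L_entropy, tolerance = 1e-8)
    if (cfg$use_clustering)
      expect_equal(fr$diagnostics$layers[[1]]$labels,
                   as.integer(fc$labels1))
  }
})

test_that("loss bundle is exactly additive and softmaxes are stochastic", {
  set.seed(2)
  cfg <- tiny_config(seed = 5)
  coh <- tiny_cohort(n = 3, N = 12, D = 6, seed = 6)
  g <- coh[[1]]
  params <- mdhcInitParams(6, 8, cfg)
  f <- mdhcForward(g, params, cfg)
  expect_identical(f$losses$L_total,
                   f$losses$L_cls + f$losses$L_link + f$losses$L_entropy)
  expect_equal(sum(f$prob), 1, tolerance = 1e-9)
  expect_equal(sum(f$diagnostics$A_node), 1, tolerance = 1e-9)
  for (lay in f$diagnostics$layers) {
    expect_equal(rowSums(lay$A_learn), rep(1, nrow(lay$A_learn)),
                 tolerance = 1e-9)
    if (!is.null(lay$S_soft))
      expect_equal(rowSums(lay$S_soft), rep(1, nrow(lay$S_soft)),
                   tolerance = 1e-9)
  }
})

test_that("disabling clustering yields identity assignments", {
  cfg <- tiny_config(seed = 3, use_clustering = FALSE)
  coh <- tiny_cohort(n = 2, N = 9, D = 5, seed = 4)
  f <- mdhcForward(coh[[1]], mdhcInitParams(5, 8, cfg), cfg)
  expect_equal(f$diagnostics$layers[[1]]$S_hard, diag(9))
  expect_equal(f$diagnostics$layers[[1]]$labels, 1:9)
  expect_identical(f$losses$L_link, 0)
  expect_identical(f$losses$L_entropy, 0)
})

test_that("the forward pass is permutation-equivariant", {
  set.seed(7)
  cfg <- tiny_config(seed = 11)
  coh <- tiny_cohort(n = 2, N = 16, D = 6, seed = 12)
  g <- coh[[1]]
  params <- mdhcInitParams(6, 8, cfg)
  f0 <- mdhcForward(g, params, cfg)
  perm <- sample(16)
  gp <- BrainGraph(g@nodeFeatures[perm, ], g@anatAdj[perm, perm],
                   g@damage[perm, perm], g@clinical, g@label, "perm")
  fp <- mdhcForward(gp, params, cfg)
  expect_equal(fp$prob, f0$prob, tolerance = 1e-5)
  # cluster assignments agree up to relabeling
  expect_true(same_partition(fp$diagnostics$layers[[1]]$labels,
                             f0$diagnostics$layers[[1]]$labels[perm]))
})

test_that("analytic gradients match finite differences", {
  set.seed(8)
  cfg <- tiny_config(seed = 13)
  coh <- tiny_cohort(n = 2, N = 10, D = 5, seed = 14)
  g <- coh[[1]]
  params <- unclass(mdhcInitParams(5, 8, cfg))
  ap <- fuseEdgePrior(g@damage, g@anatAdj)
  clin <- as.numeric(g@clinical)
  gr <- psciNet:::mdhc_grad_cpp(g@nodeFeatures, ap, clin, g@label, params,
                                unclass(cfg))
  eps <- 1e-6
  loss_at <- function(p) psciNet:::mdhc_forward_cpp(
    g@nodeFeatures, ap, clin, g@label, p, unclass(cfg))$L_total
  for (nm in c("W_in", "W_t", "Wq_node", "Wk1", "Wg1", "Wq2", "W_ct",
               "W_out", "b_in")) {
    idx <- sample(length(params[[nm]]), 1)
    p2 <- params; p2[[nm]][idx] <- p2[[nm]][idx] + eps
    lp <- loss_at(p2)
    p2[[nm]][idx] <- p2[[nm]][idx] - 2 * eps
    lm <- loss_at(p2)
    fd <- (lp - lm) / (2 * eps)
    expect_equal(gr[[nm]][idx], fd, tolerance = 1e-4,
                 label = paste("gradient of", nm))
  }
})

test_that("parameters round-trip through the JSON container", {
  cfg <- tiny_config(seed = 17)
  p <- mdhcInitParams(5, 8, cfg)
  f <- tempfile(fileext = ".json")
  mdhcSaveParams(p, f)
  back <- mdhcLoadParams(f)
  expect_identical(names(back), names(unclass(p)))
  expect_equal(back$W_in, p$W_in, tolerance = 1e-15)
  expect_equal(back$b_out, p$b_out, tolerance = 1e-15)
  # a loaded parameter set drives the forward pass identically
  coh <- tiny_cohort(n = 2, N = 8, D = 5, seed = 18)
  expect_equal(mdhcForward(coh[[1]], back, cfg)$prob,
               mdhcForward(coh[[1]], p, cfg)$prob)
})

test_that("every trainable parameter receives gradient signal", {
  set.seed(9)
  cfg <- tiny_config(seed = 15)
  coh <- tiny_cohort(n = 2, N = 10, D = 5, seed = 16)
  g <- coh[[1]]
  params <- unclass(mdhcInitParams(5, 8, cfg))
  ap <- fuseEdgePrior(g@damage, g@anatAdj)
  gr <- psciNet:::mdhc_grad_cpp(g@nodeFeatures, ap,
                                as.numeric(g@clinical), g@label, params,
                                unclass(cfg))
  for (nm in setdiff(names(gr), "loss"))
    expect_gt(max(abs(gr[[nm]])), 0, label = paste("gradient norm of", nm))
})
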
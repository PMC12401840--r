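#' Initialize model parameters
#'
#' Draws all weight matrices from scaled normal distributions
#' (Glorot-style, sd = sqrt(2 / (fan_in + fan_out))) with zero biases,
#' deterministically from `config$seed`.
#'
#' @param D_node input node-feature width.
#' @param D_t clinical vector length.
#' @param config an [mdhcConfig()].
#' @return named list of parameter matrices/vectors (class `"mdhcParams"`).
#' @export
mdhcInitParams <- function(D_node, D_t, config) {
  dh <- config$D_h; dk <- config$D_k; H <- config$H
  rng <- local({
    set.seed(config$seed)
    function(nr, nc) matrix(rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
  })
  p <- list(
    W_in = rng(D_node, dh), b_in = numeric(dh),
    W_t = rng(D_t, dh), b_t = numeric(dh),
    Wq_node = rng(dh, dk), Wk_node = rng(dh, dk), Wv_node = rng(dh, dh),
    Wq1 = rng(dh, dk * H), Wk1 = rng(dh, dk * H), Wg1 = rng(dh, dh),
    Wq2 = rng(dh, dk * H), Wk2 = rng(dh, dk * H), Wg2 = rng(dh, dh),
    W_ct = rng(dh, dh), b_ct = numeric(dh),
    W_cg = rng(dh, dh), b_cg = numeric(dh),
    W_out = rng(2L * dh, 2L), b_out = numeric(2L)
  )
  class(p) <- "mdhcParams"
  p
}

#' Save / load model parameters
#'
#' Parameters are stored in a single JSON container (full double precision),
#' diffable and language-neutral.
#'
#' @param params an `mdhcParams` list (e.g. from [mdhcInitParams()] or
#'   [trainFold()]).
#' @param path file path.
#' @return `path` invisibly; `mdhcLoadParams()` returns the parameter list.
#' @export
mdhcSaveParams <- function(params, path) {
  obj <- lapply(unclass(params), function(w) {
    if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
    else list(dim = NULL, data = as.numeric(w))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname mdhcSaveParams
#' @export
mdhcLoadParams <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- lapply(obj, function(e) {
    if (!is.null(e$dim) && length(e$dim)) {
      matrix(e$data, e$dim[1], e$dim[2])
    } else {
      as.numeric(e$data)
    }
  })
  class(p) <- "mdhcParams"
  p
}

.loss_bundle <- function(L_cls, L_link, L_entropy) {
  structure(list(L_cls = L_cls, L_link = L_link, L_entropy = L_entropy,
                 L_total = L_cls + L_link + L_entropy),
            class = "LossBundle")
}

#' @export
print.LossBundle <- function(x, ...) {
  cat(sprintf("LossBundle: cls %.4f + link %.4f + entropy %.4f = %.4f\n",
              x$L_cls, x$L_link, x$L_entropy, x$L_total))
  invisible(x)
}

#' Full forward pass of the hierarchical graph classifier
#'
#' Pipeline: input linear map (D_node to D_h), clinically guided node
#' attention, dynamic edge refinement over the fused damage/anatomy prior,
#' graph convolution, hierarchical pooling N to C, a second (fresh-parameter)
#' edge refinement and convolution on the pooled graph, pooling C to C/2,
#' and the classification head. The loss bundle sums the cross-entropy with
#' the per-layer link and entropy pooling losses; ablation flags in `config`
#' bypass the corresponding stage (node attention off passes features
#' through, edge attention off keeps the prior, clustering off uses identity
#' pooling with zero pooling losses).
#'
#' @param graph a [BrainGraph-class] (its label drives the loss term).
#' @param params an [mdhcInitParams()] parameter list.
#' @param config an [mdhcConfig()].
#' @param training apply dropout before the output layer?
#' @return list with `prob` (length-2, non-PSCI/PSCI), `losses` (a
#'   `LossBundle` with `L_total = L_cls + L_link + L_entropy` exactly), and
#'   `diagnostics` (node attention, clinical embedding, and per-layer learned
#'   adjacency, cluster labels, hard/soft assignments and dendrogram).
#' @export
mdhcForward <- function(graph, params, config, training = FALSE) {
  stopifnot(is(graph, "BrainGraph"))
  slope <- config$leaky_slope
  n <- nrow(graph@nodeFeatures)
  X0 <- graph@nodeFeatures %*% params$W_in +
    matrix(params$b_in, n, config$D_h, byrow = TRUE)

  if (config$use_node_attention) {
    ne <- nodeEnhance(graph@clinical, X0,
                      list(W_t = params$W_t, b_t = params$b_t,
                           W_Q = params$Wq_node, W_K = params$Wk_node,
                           W_V = params$Wv_node), slope = slope)
    X1 <- ne$X; a_node <- ne$A_node; ft <- ne$F_t
  } else {
    X1 <- X0
    a_node <- rep(1 / n, n)
    ft <- leakyRelu(drop(graph@clinical %*% params$W_t) + params$b_t, slope)
  }

  a_prior <- fuseEdgePrior(graph@damage, graph@anatAdj,
                           useDamage = config$use_damage)

  run_layer <- function(X, A_prev, Wq, Wk, Wg, C_target) {
    A_learn <- NULL
    if (config$use_edge_attention) {
      A_learn <- edgeAttention(X, Wq, Wk, config$H)
      A_ref <- refineAdjacency(A_learn, A_prev)
    } else {
      A_ref <- A_prev
    }
    Xg <- gcnLayer(X, A_ref, Wg, slope = slope)
    if (config$use_clustering) {
      pool <- hierarchicalPool(Xg, A_ref, C_target, alpha = config$alpha,
                               tau = config$tau)
      l_link <- linkLoss(A_ref, pool$S_soft)
      l_ent <- entropyLoss(pool$S_soft)
    } else {
      nn <- nrow(Xg)
      pool <- structure(list(
        Z = NULL, labels = seq_len(nn), S_hard = diag(nn), S_soft = NULL,
        X_pooled = Xg, A_pooled = A_ref, D_combined = NULL),
        class = "PoolingResult")
      l_link <- 0; l_ent <- 0
    }
    list(A_learn = A_learn, A_ref = A_ref, pool = pool,
         l_link = l_link, l_ent = l_ent)
  }

  c1 <- if (config$use_clustering) min(config$C, n) else n
  lay1 <- run_layer(X1, a_prior, params$Wq1, params$Wk1, params$Wg1, c1)
  c2 <- if (config$use_clustering) max(1L, c1 %/% 2L) else c1
  lay2 <- run_layer(lay1$pool$X_pooled, lay1$pool$A_pooled,
                    params$Wq2, params$Wk2, params$Wg2, c2)

  head <- params[c("W_ct", "b_ct", "W_cg", "b_cg", "W_out", "b_out")]
  cls <- classifyGraph(lay2$pool$X_pooled, ft, head,
                       dropout_p = config$dropout_p, training = training)

  l_cls <- classificationLoss(matrix(cls$prob, nrow = 1), graph@label)
  l_link <- if (config$use_link_loss) lay1$l_link + lay2$l_link else 0
  l_ent <- if (config$use_entropy_loss) lay1$l_ent + lay2$l_ent else 0

  list(
    prob = cls$prob,
    losses = .loss_bundle(l_cls, l_link, l_ent),
    diagnostics = list(
      A_node = a_node, F_t = ft,
      layers = list(
        list(A_learn = lay1$A_learn, A_refined = lay1$A_ref,
             labels = lay1$pool$labels, S_hard = lay1$pool$S_hard,
             S_soft = lay1$pool$S_soft, Z = lay1$pool$Z,
             X_pooled = lay1$pool$X_pooled, A_pooled = lay1$pool$A_pooled),
        list(A_learn = lay2$A_learn, A_refined = lay2$A_ref,
             labels = lay2$pool$labels, S_hard = lay2$pool$S_hard,
             S_soft = lay2$pool$S_soft, Z = lay2$pool$Z,
             X_pooled = lay2$pool$X_pooled, A_pooled = lay2$pool$A_pooled)
      )
    )
  )
}
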
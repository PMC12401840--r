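#' Model and training configuration
#'
#' Assembles and validates the hyper-parameters of the hierarchical
#' graph-network classifier. Defaults follow the reference configuration:
#' hidden width `D_h = 64`, `H = 4` attention heads (key width
#' `D_k = D_h / H`), first-layer cluster count `C = 16` with the second layer
#' fixed at `C / 2`, distance mixing weight `alpha = 0.5`, dropout 0.5 before
#' the output layer, Adam with learning rate `1e-5` for 500 epochs and a step
#' scheduler (step 20). The scheduler decay `gamma` is configurable
#' (default 0.9).
#'
#' Ablation flags switch individual components off: `use_node_attention`
#' (clinically guided node attention), `use_edge_attention` (learned dynamic
#' edges), `use_damage` (structural-disconnection prior), `use_clustering`
#' (hierarchical pooling; off = identity pooling), `use_link_loss` and
#' `use_entropy_loss` (the two pooling regularizers).
#'
#' @param D_h hidden dimension (positive integer, divisible by `H`).
#' @param H number of attention heads.
#' @param C first-layer cluster count (even, `<= N`); layer 2 uses `C / 2`.
#' @param alpha weight of the shortest-path distance in the combined distance
#'   (`1 - alpha` weights the feature distance); in [0, 1].
#' @param tau temperature of the soft cluster-assignment softmax (> 0).
#' @param dropout_p dropout probability before the output layer.
#' @param lr,epochs,scheduler_step,scheduler_gamma Adam optimizer settings.
#' @param leaky_slope negative slope of the LeakyReLU activations.
#' @param augment_sd standard deviation of additive Gaussian noise applied to
#'   node features during training (0 disables augmentation).
#' @param seed integer seed for parameter initialization and training-time
#'   randomness.
#' @param use_node_attention,use_edge_attention,use_damage,use_clustering,use_link_loss,use_entropy_loss
#'   logical ablation flags (all `TRUE` by default).
#' @param track_best_epoch when `TRUE`, validation metrics are reported for
#'   the epoch with the lowest validation loss instead of the final epoch.
#' @return A classed list (`"mdhcConfig"`).
#' @export
mdhcConfig <- function(D_h = 64L, H = 4L, C = 16L, alpha = 0.5, tau = 1.0,
                       dropout_p = 0.5, lr = 1e-5, epochs = 500L,
                       scheduler_step = 20L, scheduler_gamma = 0.9,
                       leaky_slope = 0.01, augment_sd = 0, seed = 1L,
                       use_node_attention = TRUE, use_edge_attention = TRUE,
                       use_damage = TRUE, use_clustering = TRUE,
                       use_link_loss = TRUE, use_entropy_loss = TRUE,
                       track_best_epoch = FALSE) {
  D_h <- as.integer(D_h); H <- as.integer(H); C <- as.integer(C)
  stopifnot(D_h > 0L, H > 0L)
  if (D_h %% H != 0L)
    stop("H must divide D_h (per-head key width D_k = D_h / H)")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (tau <= 0) stop("tau must be positive")
  if (use_clustering && C %% 2L != 0L)
    stop("C must be even (second pooling layer uses C / 2 clusters)")
  if (dropout_p < 0 || dropout_p >= 1) stop("dropout_p must lie in [0, 1)")
  cfg <- list(
    D_h = D_h, H = H, D_k = D_h %/% H, C = C, alpha = alpha, tau = tau,
    dropout_p = dropout_p, lr = lr, epochs = as.integer(epochs),
    scheduler_step = as.integer(scheduler_step),
    scheduler_gamma = scheduler_gamma, leaky_slope = leaky_slope,
    augment_sd = augment_sd, seed = as.integer(seed),
    use_node_attention = isTRUE(use_node_attention),
    use_edge_attention = isTRUE(use_edge_attention),
    use_damage = isTRUE(use_damage),
    use_clustering = isTRUE(use_clustering),
    use_link_loss = isTRUE(use_link_loss),
    use_entropy_loss = isTRUE(use_entropy_loss),
    track_best_epoch = isTRUE(track_best_epoch)
  )
  class(cfg) <- "mdhcConfig"
  cfg
}

#' @export
print.mdhcConfig <- function(x, ...) {
  cat(sprintf(
    "mdhcConfig: D_h=%d H=%d C=%d alpha=%.2f tau=%.2f lr=%g epochs=%d\n",
    x$D_h, x$H, x$C, x$alpha, x$tau, x$lr, x$epochs))
  flags <- c("use_node_attention", "use_edge_attention", "use_damage",
             "use_clustering", "use_link_loss", "use_entropy_loss")
  on <- vapply(flags, function(f) isTRUE(x[[f]]), logical(1))
  cat("  flags on: ", paste(flags[on], collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Flag names accepted by runAblation()
.mdhc_flags <- c("use_node_attention", "use_edge_attention", "use_damage",
                 "use_clustering", "use_link_loss", "use_entropy_loss")
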
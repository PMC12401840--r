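#' Export interpretability tables from a forward pass
#'
#' Turns the diagnostics of [mdhcForward()] into per-subject tables: node
#' importance (the clinical-attention weight per region), per-layer edge
#' strength (column means of the learned adjacency, i.e. how strongly each
#' node is attended to by the rest of the graph), cluster membership per
#' layer, cluster importance (the summed importance of member nodes), and a
#' cluster-to-anatomy mapping naming each cluster after its
#' highest-importance member region.
#'
#' @param forward result of [mdhcForward()].
#' @param regionNames character vector of parcel names (length N).
#' @param dir optional directory; when given, each table is written as a TSV
#'   (`node_importance.tsv`, `edge_strength_layer<k>.tsv`,
#'   `clusters_layer<k>.tsv`, `cluster_importance_layer1.tsv`).
#' @return list of data.frames (invisibly writes TSVs when `dir` is set).
#' @export
exportInterpretability <- function(forward, regionNames, dir = NULL) {
  d <- forward$diagnostics
  n <- length(d$A_node)
  if (length(regionNames) != n)
    stop("regionNames must have one entry per region")
  out <- list()
  out$node_importance <- data.frame(
    region = regionNames, importance = d$A_node)

  for (k in seq_along(d$layers)) {
    lay <- d$layers[[k]]
    if (!is.null(lay$A_learn)) {
      node_ids <- if (k == 1L) regionNames
                  else sprintf("cluster_%02d", seq_len(nrow(lay$A_learn)))
      out[[sprintf("edge_strength_layer%d", k)]] <- data.frame(
        node = node_ids, mean_incoming_attention = colMeans(lay$A_learn))
    }
  }

  lab1 <- d$layers[[1]]$labels
  out$clusters_layer1 <- data.frame(
    region = regionNames, cluster = lab1)
  imp <- tapply(d$A_node, lab1, sum)
  anchor <- vapply(sort(unique(lab1)), function(cl) {
    members <- which(lab1 == cl)
    members[which.max(d$A_node[members])]
  }, integer(1))
  out$cluster_importance_layer1 <- data.frame(
    cluster = sort(unique(lab1)),
    importance = as.numeric(imp),
    anchor_region = regionNames[anchor])

  lab2 <- d$layers[[2]]$labels
  if (!is.null(lab2))
    out$clusters_layer2 <- data.frame(
      cluster_layer1 = seq_along(lab2), cluster_layer2 = lab2)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out))
      write.table(out[[nm]], file.path(dir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
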
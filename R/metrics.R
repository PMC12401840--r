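# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Education-specific MoCA cutoffs for PSCI
#'
#' PSCI is diagnosed at MoCA <= 13 for illiterate patients, <= 19 with
#' primary education, and <= 24 with junior high school education or higher
#' (Chinese-revised VICCCS protocol, 3-month follow-up).
#' @export
psciMocaCutoffs <- c(illiterate = 13L, primary = 19L, junior_high_plus = 24L)

#' Label PSCI from a MoCA score and education level
#'
#' @param moca integer MoCA score(s) in [0, 30].
#' @param education education level(s): `"illiterate"`, `"primary"` or
#'   `"junior_high_plus"` (recycled against `moca`).
#' @return character vector of `"PSCI"` / `"non-PSCI"`.
#' @export
mocaLabel <- function(moca, education) {
  if (any(moca < 0 | moca > 30)) stop("moca must lie in [0, 30]")
  bad <- setdiff(unique(education), names(psciMocaCutoffs))
  if (length(bad))
    stop("unknown education level: ", paste(bad, collapse = ", "))
  unname(ifelse(moca <= psciMocaCutoffs[education], "PSCI", "non-PSCI"))
}

#' Stratified k-fold split
#'
#' Shuffles each class independently (deterministically from `seed`) and
#' deals subjects round-robin across folds, continuing the fold counter from
#' one class to the next so that both the per-class counts and the total fold
#' sizes differ by at most 1 from proportionality.
#'
#' @param labels binary label vector.
#' @param k number of folds (every class must have >= k members).
#' @param seed integer seed.
#' @return list of `k` disjoint validation index vectors covering all
#'   indices.
#' @export
stratifiedKFold <- function(labels, k, seed = 1L) {
  k <- as.integer(k)
  classes <- sort(unique(labels))
  for (cl in classes)
    if (sum(labels == cl) < k)
      stop("class ", cl, " has fewer than k = ", k, " members")
  folds <- vector("list", k)
  .with_seed(seed, {
    offset <- 0L
    for (cl in classes) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fid <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[fid == f])
      offset <- (offset + length(idx)) %% k
    }
  })
  lapply(folds, sort)
}

#' Binary classification metrics: ACC, AUC, SEN, SPE
#'
#' Confusion-matrix metrics at threshold 0.5 on the PSCI probability
#' (PSCI = positive class; predicted positive when `y_prob >= 0.5`), plus
#' the rank-statistic AUC (Mann-Whitney with average ranks, so ties count
#' 0.5). AUC is `NA` when only one class is present.
#'
#' @param y_true binary label vector (1 = PSCI).
#' @param y_prob predicted PSCI probabilities.
#' @return named list with `acc`, `auc`, `sen`, `spe`.
#' @export
classificationMetrics <- function(y_true, y_prob) {
  y_true <- as.integer(y_true)
  pred <- as.integer(y_prob >= 0.5)
  tp <- sum(pred == 1L & y_true == 1L)
  tn <- sum(pred == 0L & y_true == 0L)
  fp <- sum(pred == 1L & y_true == 0L)
  fn <- sum(pred == 0L & y_true == 1L)
  n1 <- sum(y_true == 1L); n0 <- sum(y_true == 0L)
  auc <- if (n1 == 0L || n0 == 0L) NA_real_ else {
    r <- rank(y_prob)
    (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(
    acc = (tp + tn) / length(y_true),
    auc = auc,
    sen = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    spe = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}
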
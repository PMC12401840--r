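#' @import methods
#' @importFrom stats rnorm runif rbinom rbeta sd cor quantile kmeans dist
#' @importFrom utils write.table read.table combn
#' @useDynLib psciNet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Canonical order of the clinical covariate vector
#'
#' Fixed variable order used by every clinical vector in the package:
#' age (years), sex (0 = male, 1 = female), cerebral microbleed (0/1),
#' perivascular-space grade 2-4 (0/1), periventricular hyperintensity score,
#' deep white-matter hyperintensity score, total small-vessel-disease burden
#' score, and NIHSS. Binary variables are coded 0/1; the remainder are
#' continuous scores.
#'
#' @export
psciClinicalVariables <- c(
  "age", "sex", "microbleed", "pvs_grade_2_4",
  "periventricular_hyperintensity", "deep_hyperintensity",
  "total_burden", "nihss"
)

#' Indices of the continuous clinical variables
#'
#' Positions within [psciClinicalVariables] that hold continuous scores
#' (candidates for z-scoring with training-fold statistics).
#' @export
psciContinuousClinical <- c(1L, 5L, 6L, 7L, 8L)

.check_symmetric <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) && max(abs(m - t(m))) <= tol
}

#' BrainGraph: one subject's multimodal brain-network sample
#'
#' Holds the per-region node feature matrix (N regions x D_node radiomic-derived
#' features), the binary anatomical adjacency, the structural-disconnection
#' (damage) matrix with entries in [0, 1], the clinical covariate vector in the
#' order of [psciClinicalVariables], and the binary outcome label
#' (0 = non-PSCI, 1 = PSCI). MoCA score and education level are optional and
#' only needed when labels are derived with [mocaLabel()].
#'
#' @slot nodeFeatures numeric matrix, N x D_node, no missing values.
#' @slot anatAdj binary symmetric N x N matrix with zero diagonal.
#' @slot damage symmetric N x N matrix, entries in [0, 1], zero diagonal.
#' @slot clinical named numeric vector of clinical covariates.
#' @slot label integer, 0 (non-PSCI) or 1 (PSCI).
#' @slot subjectId character scalar.
#' @slot mocaScore integer 0-30, or NA when unavailable.
#' @slot educationLevel one of "illiterate", "primary", "junior_high_plus",
#'   or NA.
#' @export
setClass("BrainGraph",
  representation(
    nodeFeatures = "matrix",
    anatAdj = "matrix",
    damage = "matrix",
    clinical = "numeric",
    label = "integer",
    subjectId = "character",
    mocaScore = "integer",
    educationLevel = "character"
  ),
  prototype(mocaScore = NA_integer_, educationLevel = NA_character_)
)

setValidity("BrainGraph", function(object) {
  msgs <- character()
  n <- nrow(object@nodeFeatures)
  A <- object@anatAdj
  SD <- object@damage
  if (anyNA(object@nodeFeatures) || any(!is.finite(object@nodeFeatures)))
    msgs <- c(msgs, "nodeFeatures contains missing or non-finite values")
  if (!identical(dim(A), c(n, n)))
    msgs <- c(msgs, sprintf("anatAdj must be %d x %d", n, n))
  if (!identical(dim(SD), c(n, n)))
    msgs <- c(msgs, sprintf("damage must be %d x %d", n, n))
  if (identical(dim(A), c(n, n))) {
    if (!all(A %in% c(0, 1))) msgs <- c(msgs, "anatAdj entries must be 0/1")
    if (!.check_symmetric(A)) msgs <- c(msgs, "anatAdj must be symmetric")
    if (any(diag(A) != 0)) msgs <- c(msgs, "anatAdj must have zero diagonal")
  }
  if (identical(dim(SD), c(n, n))) {
    if (!.check_symmetric(SD)) msgs <- c(msgs, "damage must be symmetric")
    if (any(SD < 0) || any(SD > 1))
      msgs <- c(msgs, "damage entries must lie in [0, 1]")
    if (any(diag(SD) != 0)) msgs <- c(msgs, "damage must have zero diagonal")
  }
  if (!object@label %in% c(0L, 1L)) msgs <- c(msgs, "label must be 0 or 1")
  if (!is.na(object@mocaScore) &&
      (object@mocaScore < 0L || object@mocaScore > 30L))
    msgs <- c(msgs, "mocaScore must lie in [0, 30]")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a BrainGraph
#'
#' @param nodeFeatures N x D_node numeric matrix of per-region features.
#' @param anatAdj N x N binary symmetric anatomical adjacency, zero diagonal.
#' @param damage N x N symmetric structural-disconnection matrix in [0, 1].
#' @param clinical numeric vector of clinical covariates
#'   (order of [psciClinicalVariables]).
#' @param label 0 (non-PSCI) or 1 (PSCI).
#' @param subjectId character identifier.
#' @param mocaScore optional MoCA score (integer 0-30).
#' @param educationLevel optional education level
#'   ("illiterate", "primary", "junior_high_plus").
#' @return A validated [BrainGraph-class] object.
#' @export
BrainGraph <- function(nodeFeatures, anatAdj, damage, clinical, label,
                       subjectId = "subject", mocaScore = NA_integer_,
                       educationLevel = NA_character_) {
  clinical <- as.numeric(clinical)
  if (is.null(names(clinical)) && length(clinical) == length(psciClinicalVariables))
    names(clinical) <- psciClinicalVariables
  new("BrainGraph",
    nodeFeatures = as.matrix(nodeFeatures),
    anatAdj = as.matrix(anatAdj),
    damage = as.matrix(damage),
    clinical = clinical,
    label = as.integer(label),
    subjectId = as.character(subjectId),
    mocaScore = as.integer(mocaScore),
    educationLevel = as.character(educationLevel)
  )
}

#' BrainCohort: a collection of BrainGraph subjects sharing one parcellation
#'
#' @slot graphs list of [BrainGraph-class] objects.
#' @slot regionNames character vector of N parcel labels shared by all graphs.
#' @export
setClass("BrainCohort",
  representation(graphs = "list", regionNames = "character")
)

setValidity("BrainCohort", function(object) {
  if (!all(vapply(object@graphs, is, logical(1), "BrainGraph")))
    return("all elements of graphs must be BrainGraph objects")
  if (length(object@graphs)) {
    n <- vapply(object@graphs, function(g) nrow(g@nodeFeatures), integer(1))
    d <- vapply(object@graphs, function(g) ncol(g@nodeFeatures), integer(1))
    dt <- vapply(object@graphs, function(g) length(g@clinical), integer(1))
    if (length(unique(n)) != 1L || length(unique(d)) != 1L ||
        length(unique(dt)) != 1L)
      return("all graphs must share N, D_node and clinical dimension")
    if (length(object@regionNames) != n[1])
      return("regionNames length must equal the number of regions")
  }
  TRUE
})

#' Construct a BrainCohort
#'
#' @param graphs list of [BrainGraph-class] objects sharing dimensions.
#' @param regionNames character vector of parcel labels (length N).
#' @return A validated [BrainCohort-class] object.
#' @export
BrainCohort <- function(graphs, regionNames = NULL) {
  if (is.null(regionNames)) {
    n <- if (length(graphs)) nrow(graphs[[1]]@nodeFeatures) else 0L
    regionNames <- sprintf("region_%03d", seq_len(n))
  }
  new("BrainCohort", graphs = graphs, regionNames = as.character(regionNames))
}

setMethod("show", "BrainGraph", function(object) {
  cat(sprintf(
    "BrainGraph '%s': %d regions x %d node features, label = %s%s\n",
    object@subjectId, nrow(object@nodeFeatures), ncol(object@nodeFeatures),
    if (object@label == 1L) "PSCI" else "non-PSCI",
    if (!is.na(object@mocaScore))
      sprintf(" (MoCA %d, %s)", object@mocaScore, object@educationLevel)
    else ""
  ))
})

setMethod("show", "BrainCohort", function(object) {
  labs <- subjectLabels(object)
  cat(sprintf(
    "BrainCohort: %d subjects (%d PSCI / %d non-PSCI), %d regions\n",
    length(object@graphs), sum(labs == 1L), sum(labs == 0L),
    length(object@regionNames)
  ))
})

#' @describeIn BrainCohort number of subjects
#' @param x a BrainCohort
#' @export
setMethod("length", "BrainCohort", function(x) length(x@graphs))

#' @describeIn BrainCohort extract one subject's BrainGraph
#' @param i subject index
#' @export
setMethod("[[", "BrainCohort", function(x, i) x@graphs[[i]])
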
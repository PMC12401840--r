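#' Save a cohort to a directory of delimited text files
#'
#' Writes four tab-delimited files per subject (`<id>_features.tsv`,
#' `<id>_anat.tsv`, `<id>_damage.tsv`, `<id>_clinical.tsv`) plus a JSON
#' `manifest.json` recording subject ids, labels, region names and the
#' clinical variable order. N x N matrices carry a header row of region
#' names. Round-trips through [loadCohort()] bit-exactly for integer fields
#' and to better than 1e-12 relative error for reals.
#'
#' @param cohort a [BrainCohort-class].
#' @param path directory to create/write into.
#' @return `path`, invisibly.
#' @export
saveCohort <- function(cohort, path) {
  stopifnot(is(cohort, "BrainCohort"))
  validObject(cohort)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  rn <- cohort@regionNames
  wm <- function(m, file, col_names) {
    df <- as.data.frame(m)
    colnames(df) <- col_names
    write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                file = file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  subjects <- lapply(cohort@graphs, function(g) {
    id <- g@subjectId
    wm(g@nodeFeatures, file.path(path, paste0(id, "_features.tsv")),
       sprintf("f%03d", seq_len(ncol(g@nodeFeatures)) - 1L))
    wm(g@anatAdj, file.path(path, paste0(id, "_anat.tsv")), rn)
    wm(g@damage, file.path(path, paste0(id, "_damage.tsv")), rn)
    cl <- data.frame(variable = names(g@clinical),
                     value = format(unname(g@clinical), digits = 17,
                                    trim = TRUE, scientific = TRUE))
    write.table(cl, file.path(path, paste0(id, "_clinical.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    s <- list(id = id, label = g@label)
    if (!is.na(g@mocaScore)) s$moca_score <- g@mocaScore
    if (!is.na(g@educationLevel)) s$education_level <- g@educationLevel
    s
  })
  manifest <- list(
    format = "psciNet-cohort/1",
    n_regions = length(rn),
    region_names = rn,
    clinical_variables = psciClinicalVariables,
    damage_scale = "fraction [0,1] of normative streamlines disconnected",
    index_base = 0L,
    subjects = subjects
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.read_matrix_tsv <- function(file, header = TRUE) {
  m <- as.matrix(read.table(file, sep = "\t", header = header,
                            check.names = FALSE))
  storage.mode(m) <- "double"
  dimnames(m) <- NULL
  m
}

#' Load a cohort written by [saveCohort()]
#'
#' Re-reads the manifest and per-subject tables, then re-validates every
#' subject: asymmetric or out-of-range damage matrices (or tampered
#' adjacency) are rejected with an error naming the offending subject.
#'
#' @param path directory produced by [saveCohort()].
#' @return A [BrainCohort-class].
#' @export
loadCohort <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("missing manifest.json in ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$format, "psciNet-cohort/1"))
    stop("unrecognized cohort format in manifest")
  rn <- as.character(manifest$region_names)
  subs <- manifest$subjects
  if (is.null(subs) || (is.data.frame(subs) && nrow(subs) == 0L) ||
      (is.list(subs) && length(subs) == 0L))
    return(BrainCohort(list(), regionNames = rn))
  if (is.data.frame(subs)) subs <- split(subs, seq_len(nrow(subs)))
  field <- function(s, nm, default) {
    v <- s[[nm]]
    if (is.null(v) || (is.data.frame(v) && ncol(v) == 0L) || is.na(v))
      default
    else v
  }
  graphs <- lapply(subs, function(s) {
    id <- s$id
    files <- file.path(path, paste0(id, c("_features.tsv", "_anat.tsv",
                                          "_damage.tsv", "_clinical.tsv")))
    missing <- files[!file.exists(files)]
    if (length(missing))
      stop("manifest lists subject '", id, "' but file is missing: ",
           basename(missing[1]))
    cl <- read.table(files[4], sep = "\t", header = TRUE)
    clinical <- as.numeric(cl$value)
    names(clinical) <- cl$variable
    g <- tryCatch(
      BrainGraph(
        nodeFeatures = .read_matrix_tsv(files[1]),
        anatAdj = .read_matrix_tsv(files[2]),
        damage = .read_matrix_tsv(files[3]),
        clinical = clinical,
        label = s$label,
        subjectId = id,
        mocaScore = field(s, "moca_score", NA_integer_),
        educationLevel = field(s, "education_level", NA_character_)
      ),
      error = function(e) stop("subject '", id, "': ", conditionMessage(e),
                               call. = FALSE)
    )
    g
  })
  BrainCohort(unname(graphs), regionNames = rn)
}
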
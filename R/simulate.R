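#' @title Synthetic cohort generator
#' @description
#' Generates cohorts with the statistical structure the classifier assumes:
#' group-specific clinical covariate distributions (the published baseline
#' characteristics of a 152-subject lacunar-stroke cohort, 44 PSCI / 108
#' non-PSCI), lesion-localized structural disconnection (stronger around a
#' random lesion center in the PSCI group), and group-dependent node-feature
#' shifts at fixed hub regions. The generator exercises the full pipeline;
#' it makes no attempt at realistic neuroanatomy or radiomic covariance.
#' @name synthetic_data
NULL

#' Group-wise clinical distribution parameters
#'
#' Continuous variables as `c(mean, sd)`, binary variables as the event
#' proportion, per outcome group. Values are the baseline characteristics of
#' the reference cohort: age 64.05 +/- 10.49 vs 68.43 +/- 9.58 years, female
#' 36.1% vs 40.9%, microbleed 20.4% vs 31.8%, PVS grade 2-4 45.4% vs 63.6%,
#' periventricular hyperintensity 1.13 +/- 1.11 vs 2.11 +/- 0.95, deep
#' hyperintensity 0.67 +/- 0.84 vs 1.57 +/- 1.00, total burden 1.68 +/- 1.08
#' vs 2.50 +/- 1.05, NIHSS 2.33 +/- 2.43 vs 3.77 +/- 3.06
#' (non-PSCI vs PSCI).
#'
#' @return nested list `list(non_psci = ..., psci = ...)`.
#' @export
clinicalParamsTable <- function() {
  list(
    non_psci = list(
      age = c(64.05, 10.49), female = 0.361, microbleed = 0.204,
      pvs_grade_2_4 = 0.454,
      periventricular_hyperintensity = c(1.13, 1.11),
      deep_hyperintensity = c(0.67, 0.84),
      total_burden = c(1.68, 1.08), nihss = c(2.33, 2.43)
    ),
    psci = list(
      age = c(68.43, 9.58), female = 0.409, microbleed = 0.318,
      pvs_grade_2_4 = 0.636,
      periventricular_hyperintensity = c(2.11, 0.95),
      deep_hyperintensity = c(1.57, 1.00),
      total_burden = c(2.50, 1.05), nihss = c(3.77, 3.06)
    )
  )
}

#' Clinical parameters with no group differences
#'
#' Both groups draw from the non-PSCI distributions; used for null cohorts
#' where no covariate may carry outcome signal.
#' @return nested list like [clinicalParamsTable()].
#' @export
pooledClinicalParams <- function() {
  p <- clinicalParamsTable()
  list(non_psci = p$non_psci, psci = p$non_psci)
}

#' Simulation configuration
#'
#' Defaults reproduce the reference cohort structure: 152 subjects with 44
#' PSCI, 100 regions, 120 node features. The planted signal has two
#' channels: `effect_size` is added to a fixed subset of features at fixed
#' hub regions for PSCI subjects, and `damage_intensity` sets the mean
#' disconnection fraction (Beta-distributed) on region pairs within 2 hops
#' of each subject's lesion center, higher in the PSCI group.
#'
#' @param n_subjects,n_psci cohort size and number of PSCI subjects.
#' @param n_regions,D_node graph dimensions.
#' @param effect_size feature shift at hub regions for PSCI subjects.
#' @param damage_intensity named vector `c(non_psci=, psci=)` of mean
#'   disconnection fractions (each in (0, 1)).
#' @param damage_concentration Beta concentration of damage draws.
#' @param n_hubs,n_effect_features size of the hub-region and feature
#'   subsets carrying the planted shift.
#' @param chord_density target edge density of the anatomical graph.
#' @param clinical_params nested list as from [clinicalParamsTable()].
#' @param moca also generate MoCA scores and education levels such that
#'   [mocaLabel()] reproduces the group?
#' @param moca_margin,moca_noise mean and SD of the (rounded) margin between
#'   the MoCA score and the education-specific cutoff; with `moca_noise = 0`
#'   the labeling rule reproduces group membership exactly, larger values
#'   let scores cross the cutoff.
#' @param seed integer seed; generation is deterministic given the config.
#' @return classed list `"simulationConfig"`.
#' @export
simulationConfig <- function(n_subjects = 152L, n_psci = 44L,
                             n_regions = 100L, D_node = 120L,
                             effect_size = 2.0,
                             damage_intensity = c(non_psci = 0.1,
                                                  psci = 0.3),
                             damage_concentration = 10,
                             n_hubs = 10L, n_effect_features = 12L,
                             chord_density = 0.1,
                             clinical_params = clinicalParamsTable(),
                             moca = FALSE, moca_margin = 3,
                             moca_noise = 1.5, seed = 1L) {
  if (n_psci > n_subjects) stop("n_psci must not exceed n_subjects")
  if (effect_size < 0) stop("effect_size must be >= 0")
  stopifnot(all(damage_intensity > 0), all(damage_intensity < 1))
  if (n_hubs > n_regions) stop("n_hubs must not exceed n_regions")
  if (n_effect_features > D_node)
    stop("n_effect_features must not exceed D_node")
  structure(list(
    n_subjects = as.integer(n_subjects), n_psci = as.integer(n_psci),
    n_regions = as.integer(n_regions), D_node = as.integer(D_node),
    effect_size = effect_size, damage_intensity = damage_intensity,
    damage_concentration = damage_concentration,
    n_hubs = as.integer(n_hubs),
    n_effect_features = as.integer(n_effect_features),
    chord_density = chord_density, clinical_params = clinical_params,
    moca = isTRUE(moca), moca_margin = moca_margin,
    moca_noise = moca_noise, seed = as.integer(seed)
  ), class = "simulationConfig")
}

#' Null-cohort configuration
#'
#' No planted signal anywhere: zero feature effect, equal damage intensity
#' in both groups, and pooled clinical distributions. Cross-validated AUC on
#' such a cohort should hover around 0.5 (anything systematically higher
#' would indicate information leakage in the pipeline).
#'
#' @param seed integer seed.
#' @param ... overrides forwarded to [simulationConfig()].
#' @return a `"simulationConfig"`.
#' @export
nullSimulationConfig <- function(seed = 1L, ...) {
  simulationConfig(effect_size = 0,
                   damage_intensity = c(non_psci = 0.1, psci = 0.1),
                   clinical_params = pooledClinicalParams(),
                   seed = seed, ...)
}

#' Synthetic anatomical adjacency
#'
#' A connected ring over the N regions plus random chords up to the target
#' density, symmetric binary with zero diagonal, deterministic per seed.
#'
#' @param N number of regions (>= 2).
#' @param seed integer seed.
#' @param density target edge density (fraction of all pairs).
#' @return list with `A` (N x N binary) and `region_names`.
#' @export
makeAnatomy <- function(N, seed = 1L, density = 0.1) {
  if (N < 2L) stop("N must be >= 2")
  .with_seed(seed, {
    A <- matrix(0, N, N)
    ring <- cbind(seq_len(N), c(seq_len(N)[-1], 1L))
    A[ring] <- 1; A[ring[, 2:1]] <- 1
    target <- round(density * N * (N - 1) / 2)
    extra <- target - N
    if (extra > 0 && N > 3L) {
      pairs <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
      pick <- pairs[sample.int(nrow(pairs), min(extra, nrow(pairs))), ,
                    drop = FALSE]
      A[pick] <- 1; A[pick[, 2:1]] <- 1
    }
    diag(A) <- 0
    list(A = A, region_names = sprintf("region_%03d", seq_len(N)))
  })
}

#' Draw clinical covariate vectors for one group
#'
#' Continuous variables are normal with the group's parameters; age is
#' rejection-truncated at 18 years (more than 4 sd below either group mean,
#' so the printed moments are preserved to far below Monte-Carlo error).
#' Score variables are left untruncated so their sample moments converge to
#' the published means and SDs; rare slightly negative scores are accepted
#' as a synthetic-covariate simplification. Binary variables are Bernoulli
#' with the printed proportions. Uses the current RNG stream.
#'
#' @param group `"psci"` or `"non_psci"`.
#' @param clinical_params nested list as from [clinicalParamsTable()].
#' @param n number of draws.
#' @return n x 8 matrix, columns in [psciClinicalVariables] order.
#' @export
makeClinical <- function(group = c("non_psci", "psci"),
                         clinical_params = clinicalParamsTable(), n = 1L) {
  group <- match.arg(group)
  p <- clinical_params[[group]]
  age <- rnorm(n, p$age[1], p$age[2])
  while (any(bad <- age < 18))
    age[bad] <- rnorm(sum(bad), p$age[1], p$age[2])
  out <- cbind(
    age = age,
    sex = rbinom(n, 1L, p$female),
    microbleed = rbinom(n, 1L, p$microbleed),
    pvs_grade_2_4 = rbinom(n, 1L, p$pvs_grade_2_4),
    periventricular_hyperintensity =
      rnorm(n, p$periventricular_hyperintensity[1],
            p$periventricular_hyperintensity[2]),
    deep_hyperintensity =
      rnorm(n, p$deep_hyperintensity[1], p$deep_hyperintensity[2]),
    total_burden = rnorm(n, p$total_burden[1], p$total_burden[2]),
    nihss = rnorm(n, p$nihss[1], p$nihss[2])
  )
  colnames(out) <- psciClinicalVariables
  out
}

# hop distances from every node on the binary anatomy (used to localize
# damage around the lesion center)
.anatomy_hops <- function(A) bfs_hops_cpp(A)

#' Generate one synthetic subject
#'
#' Picks a lesion center region; damage is Beta-distributed with the group's
#' mean intensity on region pairs lying within 2 hops of the center (zero
#' elsewhere); node features are standard normal with `effect_size` added at
#' the hub-region/feature subset for PSCI subjects; the clinical vector
#' comes from [makeClinical()]. Uses the current RNG stream.
#'
#' @param group `"psci"` or `"non_psci"`.
#' @param anatomy result of [makeAnatomy()].
#' @param config a [simulationConfig()].
#' @param hubs,effect_features fixed index subsets carrying the feature
#'   shift (chosen once per cohort).
#' @param hops optional precomputed hop-distance matrix of the anatomy.
#' @param subjectId subject identifier.
#' @return a [BrainGraph-class].
#' @export
makeSubject <- function(group, anatomy, config, hubs, effect_features,
                        hops = NULL, subjectId = "subject") {
  N <- config$n_regions
  A <- anatomy$A
  if (is.null(hops)) hops <- .anatomy_hops(A)
  center <- sample.int(N, 1L)
  near <- which(hops[center, ] <= 2)
  mu <- config$damage_intensity[[if (group == "psci") "psci" else "non_psci"]]
  kappa <- config$damage_concentration
  damage <- matrix(0, N, N)
  if (length(near) >= 2L) {
    pairs <- t(combn(near, 2L))
    vals <- rbeta(nrow(pairs), mu * kappa, (1 - mu) * kappa)
    damage[pairs] <- vals
    damage[pairs[, 2:1, drop = FALSE]] <- vals
  }
  X <- matrix(rnorm(N * config$D_node), N, config$D_node)
  if (group == "psci" && config$effect_size > 0)
    X[hubs, effect_features] <- X[hubs, effect_features] + config$effect_size
  clin <- drop(makeClinical(group, config$clinical_params, n = 1L))
  moca <- NA_integer_; edu <- NA_character_
  if (config$moca) {
    edu <- sample(names(psciMocaCutoffs), 1L, prob = c(0.1, 0.3, 0.6))
    cutoff <- psciMocaCutoffs[[edu]]
    offset <- round(rnorm(1L, config$moca_margin, config$moca_noise))
    moca <- if (group == "psci") cutoff + 1L - as.integer(offset)
            else cutoff + as.integer(offset)
    moca <- max(0L, min(30L, moca))
  }
  BrainGraph(X, A, damage, clin,
             label = as.integer(group == "psci"), subjectId = subjectId,
             mocaScore = moca, educationLevel = edu)
}

#' Generate a full synthetic cohort
#'
#' `n_psci` PSCI and `n_subjects - n_psci` non-PSCI subjects in shuffled
#' order, all sharing one anatomy and one fixed hub/feature subset;
#' deterministic given `config$seed`.
#'
#' @param config a [simulationConfig()].
#' @return a [BrainCohort-class].
#' @export
makeCohort <- function(config = simulationConfig()) {
  anatomy <- makeAnatomy(config$n_regions, seed = config$seed,
                         density = config$chord_density)
  hops <- .anatomy_hops(anatomy$A)
  .with_seed(config$seed + 1000003L, {
    hubs <- sample.int(config$n_regions, config$n_hubs)
    effect_features <- sample.int(config$D_node, config$n_effect_features)
    groups <- sample(c(rep("psci", config$n_psci),
                       rep("non_psci", config$n_subjects - config$n_psci)))
    graphs <- lapply(seq_along(groups), function(i) {
      makeSubject(groups[i], anatomy, config, hubs, effect_features,
                  hops = hops, subjectId = sprintf("sub_%03d", i))
    })
    BrainCohort(graphs, regionNames = anatomy$region_names)
  })
}

#' Small tractogram fixture with exact ground truth
#'
#' Builds a labeled grid volume with `nParcels` compact box parcels spaced
#' along the x axis, straight x-parallel streamlines between random parcel
#' pairs at integer (y, z) rows, and an axis-aligned box lesion. Because all
#' geometry is axis-aligned on integer coordinates, whether each streamline
#' crosses the lesion is decided exactly by integer interval arithmetic,
#' giving analytically known normative/disrupted counts and damage
#' fractions, independent of the resampling-based detector.
#'
#' @param nParcels number of parcels (>= 2).
#' @param nStreamlines number of streamlines.
#' @param lesionSpec `NULL` for no lesion, or a list with integer voxel
#'   ranges `x = c(lo, hi)`, `y = c(lo, hi)`, `z = c(lo, hi)` (0-based).
#' @param seed integer seed.
#' @return list (class `"TractogramFixture"`) with `streamlines`, `atlas`
#'   and `lesionMask` (arrays with identity affine), `nParcels`, and `truth`
#'   (exact `normative`, `disrupted` and `damage` matrices).
#' @export
makeTractogramFixture <- function(nParcels = 4L, nStreamlines = 12L,
                                  lesionSpec = NULL, seed = 1L) {
  if (nParcels < 2L) stop("need at least 2 parcels")
  nx <- 4L * nParcels + 2L; ny <- 12L; nz <- 12L
  atlas <- array(0L, dim = c(nx, ny, nz))
  centers_x <- integer(nParcels)
  for (p in seq_len(nParcels)) {
    xs <- (4L * p - 2L):(4L * p - 1L)
    atlas[xs + 1L, 3:(ny - 2), 3:(nz - 2)] <- p
    centers_x[p] <- 4L * p - 2L
  }
  lesion <- array(0L, dim = c(nx, ny, nz))
  if (!is.null(lesionSpec)) {
    lesion[(lesionSpec$x[1]:lesionSpec$x[2]) + 1L,
           (lesionSpec$y[1]:lesionSpec$y[2]) + 1L,
           (lesionSpec$z[1]:lesionSpec$z[2]) + 1L] <- 1L
  }
  .with_seed(seed, {
    normative <- matrix(0L, nParcels, nParcels)
    disrupted <- matrix(0L, nParcels, nParcels)
    streamlines <- vector("list", nStreamlines)
    for (s in seq_len(nStreamlines)) {
      pr <- sort(sample.int(nParcels, 2L))
      yz <- sample(3:(ny - 3), 2L, replace = TRUE)
      streamlines[[s]] <- rbind(c(centers_x[pr[1]], yz[1], yz[2]),
                                c(centers_x[pr[2]], yz[1], yz[2]))
      normative[pr[1], pr[2]] <- normative[pr[1], pr[2]] + 1L
      hit <- FALSE
      if (!is.null(lesionSpec)) {
        # exact integer interval test: the x-parallel line at (y, z) crosses
        # the lesion box iff its x span meets the lesion's and (y, z) lie in
        # the lesion's y/z ranges
        hit <- yz[1] >= lesionSpec$y[1] && yz[1] <= lesionSpec$y[2] &&
               yz[2] >= lesionSpec$z[1] && yz[2] <= lesionSpec$z[2] &&
               centers_x[pr[2]] >= lesionSpec$x[1] &&
               centers_x[pr[1]] <= lesionSpec$x[2]
      }
      if (hit) disrupted[pr[1], pr[2]] <- disrupted[pr[1], pr[2]] + 1L
    }
    normative <- normative + t(normative)
    disrupted <- disrupted + t(disrupted)
    damage <- matrix(0, nParcels, nParcels)
    pos <- normative > 0L
    damage[pos] <- disrupted[pos] / normative[pos]
    attr(atlas, "affine") <- diag(4)
    attr(lesion, "affine") <- diag(4)
    structure(list(
      streamlines = streamlines, atlas = atlas, lesionMask = lesion,
      nParcels = nParcels, affine = diag(4),
      truth = list(normative = normative, disrupted = disrupted,
                   damage = damage)
    ), class = "TractogramFixture")
  })
}
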
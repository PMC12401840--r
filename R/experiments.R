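#' @title Reference synthetic experiments
#' @description
#' Pre-packaged experiment runners used by the test suite and the acceptance
#' script: signal recovery on a strong-effect cohort, a null-cohort leakage
#' check, the damage-prior ablation, and a Monte-Carlo check of the clinical
#' generator's moments. All experiments use the desk-scale model
#' configuration ([mdhcScaledConfig()]) and 30-region cohorts of 152
#' subjects (44 PSCI / 108 non-PSCI), sizes chosen so the full set
#' reproduces on a single CPU in minutes.
#' @name experiments
NULL

.experiment_regions <- 30L

#' Strong-effect cohort configuration
#'
#' Feature shift 2.0 at the hub regions plus a 3x damage-intensity ratio
#' (0.3 vs 0.1) between groups, on top of the group-specific clinical
#' distributions.
#'
#' @param seed integer seed.
#' @param n_regions number of regions (default 30, the experiment scale).
#' @return a `"simulationConfig"`.
#' @export
strongEffectConfig <- function(seed = 1L, n_regions = .experiment_regions) {
  simulationConfig(n_regions = n_regions, effect_size = 2.0,
                   damage_intensity = c(non_psci = 0.1, psci = 0.3),
                   seed = seed)
}

#' Damage-only cohort configuration
#'
#' The planted signal lives exclusively in the structural-disconnection
#' matrices (3x intensity ratio); node features carry no group shift and the
#' clinical distributions are pooled.
#'
#' @inheritParams strongEffectConfig
#' @return a `"simulationConfig"`.
#' @export
damageOnlyConfig <- function(seed = 1L, n_regions = .experiment_regions) {
  simulationConfig(n_regions = n_regions, effect_size = 0,
                   damage_intensity = c(non_psci = 0.1, psci = 0.3),
                   clinical_params = pooledClinicalParams(),
                   seed = seed)
}

.cv_over_seeds <- function(make_cfg, base_seed, n_seeds, model_cfg_fn,
                           k = 5L) {
  per_seed <- lapply(seq_len(n_seeds) - 1L, function(s) {
    seed <- base_seed + s
    cohort <- makeCohort(make_cfg(seed))
    crossValidate(cohort, model_cfg_fn(seed), k = k)
  })
  means <- do.call(rbind, lapply(per_seed, function(r) r$mean))
  list(reports = per_seed, mean = colMeans(means))
}

#' Signal-recovery and null-leakage experiment
#'
#' Cross-validates the full model on strong-effect cohorts and on null
#' cohorts (no planted signal anywhere, pooled clinical distributions),
#' averaging metrics over `n_seeds` generator/model seeds. Strong cohorts
#' should be recovered nearly perfectly; null AUC should hover around 0.5.
#'
#' @param seed base seed (seeds used are `seed`, `seed + 1`, ...).
#' @param n_seeds number of replicate seeds (default 3).
#' @param n_regions cohort regions (default 30).
#' @param k folds.
#' @return list with `strong` and `null`, each carrying per-seed `reports`
#'   and the seed-averaged `mean` metrics.
#' @export
signalRecoveryExperiment <- function(seed = 1L, n_seeds = 3L,
                                     n_regions = .experiment_regions,
                                     k = 5L) {
  mk_model <- function(s) mdhcScaledConfig(seed = s)
  list(
    strong = .cv_over_seeds(
      function(s) strongEffectConfig(s, n_regions), seed, n_seeds,
      mk_model, k),
    null = .cv_over_seeds(
      function(s) nullSimulationConfig(seed = s, n_regions = n_regions),
      seed, n_seeds, mk_model, k)
  )
}

#' Damage-prior ablation experiment
#'
#' On damage-only cohorts ([damageOnlyConfig()]), cross-validates the full
#' model and the `use_damage = FALSE` ablation on identical folds and seeds,
#' and reports the seed-averaged AUC drop when the structural-disconnection
#' prior is removed. Since the only group signal is in the damage matrices,
#' disabling the prior should cost discriminative power.
#'
#' @inheritParams signalRecoveryExperiment
#' @return list with `with_damage`, `without_damage` (seed-averaged metric
#'   vectors) and `auc_drop`.
#' @export
damageAblationExperiment <- function(seed = 1L, n_seeds = 3L,
                                     n_regions = .experiment_regions,
                                     k = 5L) {
  on <- .cv_over_seeds(function(s) damageOnlyConfig(s, n_regions), seed,
                       n_seeds, function(s) mdhcScaledConfig(seed = s), k)
  off <- .cv_over_seeds(function(s) damageOnlyConfig(s, n_regions), seed,
                        n_seeds,
                        function(s) mdhcScaledConfig(seed = s,
                                                     use_damage = FALSE), k)
  list(with_damage = on$mean, without_damage = off$mean,
       auc_drop = unname(on$mean["auc"] - off$mean["auc"]))
}

#' Monte-Carlo fidelity check of the clinical generator
#'
#' Draws `n` clinical vectors per group and compares sample moments against
#' the configured parameters: z-scores for continuous means
#' (`(xbar - mu) / (sd / sqrt(n))`) and proportions
#' (`(phat - p) / sqrt(p (1 - p) / n)`).
#'
#' @param n draws per group (default 10000).
#' @param seed integer seed.
#' @return data.frame with group, variable, target, estimate and z; the
#'   maximum |z| is attached as attribute `"max_abs_z"`.
#' @export
clinicalMomentCheck <- function(n = 10000L, seed = 1L) {
  params <- clinicalParamsTable()
  rows <- list()
  .with_seed(seed, {
    for (grp in c("non_psci", "psci")) {
      draws <- makeClinical(grp, params, n = n)
      p <- params[[grp]]
      cont <- list(age = p$age,
                   periventricular_hyperintensity =
                     p$periventricular_hyperintensity,
                   deep_hyperintensity = p$deep_hyperintensity,
                   total_burden = p$total_burden, nihss = p$nihss)
      for (v in names(cont)) {
        xb <- mean(draws[, v])
        rows[[length(rows) + 1L]] <- data.frame(
          group = grp, variable = v, target = cont[[v]][1], estimate = xb,
          z = (xb - cont[[v]][1]) / (cont[[v]][2] / sqrt(n)))
      }
      bin <- c(sex = p$female, microbleed = p$microbleed,
               pvs_grade_2_4 = p$pvs_grade_2_4)
      for (v in names(bin)) {
        ph <- mean(draws[, v])
        rows[[length(rows) + 1L]] <- data.frame(
          group = grp, variable = v, target = bin[[v]], estimate = ph,
          z = (ph - bin[[v]]) / sqrt(bin[[v]] * (1 - bin[[v]]) / n))
      }
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "max_abs_z") <- max(abs(out$z))
  out
}
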
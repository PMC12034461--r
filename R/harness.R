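# Parameter-recovery harnesses: simulate replicate cohorts and push them
# through the full analysis pipeline. Used by the validation suite and the
# reproduction script alike.

#' Detection-pipeline recovery over replicate simulated cohorts
#'
#' Simulates `nCohorts` cohorts of `spec@nAnimalsPerGroup` animals at one
#' timepoint/group, runs the full default detection pipeline
#' (dF/F, transient raster, circular-shuffle threshold, network events) on
#' every recording, and returns the per-animal network metrics.
#'
#' @param spec A [CohortSpec-class].
#' @param nCohorts replicate cohorts; default 20.
#' @param timepoint,group forwarded to [simulateRecording()].
#' @param seed base seed; every recording derives its own sub-seed.
#' @param nShuffles,alpha,floor shuffle-null settings (defaults 1000, 0.01,
#'   0.1).
#' @return data.frame with one row per animal per cohort: `cohort`,
#'   `animal`, `theta`, `n_events`, `event_frequency`,
#'   `mean_event_duration`, `network_activation`, plus `true_rate` (ground
#'   truth events per minute).
#' @examples
#' \donttest{
#' m <- simulateCohortMetrics(specShamBaseline(nAnimalsPerGroup = 2L),
#'                            nCohorts = 1, seed = 1)
#' }
#' @export
simulateCohortMetrics <- function(spec, nCohorts = 20L,
                                  timepoint = "baseline",
                                  group = spec@groupLabels[1L], seed = 1L,
                                  nShuffles = 1000L, alpha = 0.01,
                                  floor = 0.1) {
  rows <- list()
  idx <- 0L
  for (co in seq_len(nCohorts)) {
    for (a in seq_len(spec@nAnimalsPerGroup)) {
      idx <- idx + 1L
      sim <- simulateRecording(spec, timepoint = timepoint, group = group,
                               animalId = sprintf("c%02d_a%02d", co, a),
                               seed = derive_seed(seed, idx))
      dff <- computeDFF(sim$recording)
      raster <- detectTransients(dff)
      theta <- shuffleThreshold(raster, nShuffles = nShuffles,
                                alpha = alpha, floor = floor,
                                seed = derive_seed(seed, idx + 500000L))
      ev <- detectNetworkEvents(raster, theta)
      rows[[idx]] <- cbind(
        data.frame(cohort = co, animal = a, theta = theta,
                   true_rate = nrow(trueEventIntervals(sim$truth)) /
                     durationMinutes(sim$recording)),
        networkMetrics(ev))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Clustered-Cox hazard-ratio recovery over replicate cohorts
#'
#' Simulates `nReplicates` survival cohorts from the spec and fits the
#' cluster-robust Cox model to each; reports the per-replicate hazard-ratio
#' estimate, robust confidence interval, and whether the interval covers
#' the configured hazard ratio.
#'
#' @param spec A [CohortSpec-class].
#' @param nReplicates replicate cohorts; default 100.
#' @param seed base seed.
#' @param viaQuench simulate intensity tracks and call quench (full
#'   pipeline) rather than using the simulated survival table directly.
#' @return data.frame with `replicate`, `hr`, `log_hr`, `robust_se`,
#'   `ci_lo`, `ci_hi`, `z`, `covered`.
#' @examples
#' h <- hazardRecoveryHarness(specInVitroOGD(), nReplicates = 3, seed = 1)
#' mean(h$hr)
#' @export
hazardRecoveryHarness <- function(spec, nReplicates = 100L, seed = 1L,
                                  viaQuench = FALSE) {
  rows <- lapply(seq_len(nReplicates), function(r) {
    cohort <- simulateSurvivalCohort(spec, seed = derive_seed(seed, r))
    tab <- if (viaQuench) {
      tracks <- simulateIntensityTracks(cohort, spec,
                                        seed = derive_seed(seed, r + 700000L))
      quenchSurvivalTable(tracks)
    } else {
      cohort$table
    }
    fit <- coxClustered(tab)
    ci <- confint95(fit)
    data.frame(replicate = r, hr = hazardRatio(fit),
               log_hr = logHazardRatio(fit), robust_se = robustSe(fit),
               ci_lo = ci[1L], ci_hi = ci[2L], z = fit@z,
               covered = ci[1L] <= spec@hazardRatio &
                 spec@hazardRatio <= ci[2L])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
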
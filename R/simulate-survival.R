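# Forward simulation of pup-clustered neuronal survival and the longitudinal
# soma-intensity tracks that the quench caller consumes.

#' Simulate a pup-clustered neuronal survival cohort
#'
#' Each animal receives a lognormal frailty on the hazard scale (shared by
#' all of its neurons); each neuron's death day is drawn from the
#' piecewise-constant daily baseline hazard multiplied by the group hazard
#' ratio and the animal frailty, with administrative censoring at
#' `censorDay`. Death and censoring are resolved on integer days, so tied
#' event times are expected and the Cox stage must handle them.
#'
#' @param spec A [CohortSpec-class]; uses `nAnimalsPerGroup`, `neuronsRange`,
#'   `hazardSchedule`, `hazardRatio`, `frailtySd`, `censorDay`, `groupLabels`.
#' @param seed integer seed (default `spec@seed`).
#' @return A list with `table` (the survival table: `neuron_id`,
#'   `cluster_id`, `group`, `time`, `event`) and `truth`
#'   ([GroundTruthLog-class] with true death days, Inf when censored alive).
#' @examples
#' cohort <- simulateSurvivalCohort(specInVitroOGD(), seed = 1)
#' head(cohort$table)
#' @export
simulateSurvivalCohort <- function(spec, seed = spec@seed) {
  validObject(spec)
  if (spec@hazardRatio <= 0) nq_stop("invalid spec: hazardRatio must be > 0")
  maybe_with_seed(seed, {
    rows <- list()
    death <- numeric(); cl <- character(); ids <- character()
    for (g in 1:2) {
      label <- spec@groupLabels[g]
      hrMult <- if (g == 2L) spec@hazardRatio else 1
      for (a in seq_len(spec@nAnimalsPerGroup)) {
        animal <- sprintf("%s_p%02d", label, a)
        frailty <- exp(rnorm(1, 0, spec@frailtySd))
        nN <- spec@neuronsRange[1L] +
          sample.int(spec@neuronsRange[2L] - spec@neuronsRange[1L] + 1L,
                     1L) - 1L
        cum <- cumsum(spec@hazardSchedule * hrMult * frailty)
        E <- rexp(nN)
        day <- vapply(E, function(e) {
          d <- which(cum >= e)
          if (length(d)) d[1L] else NA_integer_
        }, integer(1L))
        nid <- sprintf("%s_n%03d", animal, seq_len(nN))
        time <- ifelse(is.na(day), spec@censorDay, day)
        event <- as.integer(!is.na(day))
        rows[[length(rows) + 1L]] <- data.frame(
          neuron_id = nid, cluster_id = animal, group = label,
          time = as.numeric(time), event = event,
          stringsAsFactors = FALSE)
        death <- c(death, setNames(ifelse(is.na(day), Inf, day), nid))
        cl <- c(cl, setNames(rep(animal, nN), nid))
        ids <- c(ids, nid)
      }
    }
    tab <- do.call(rbind, rows)
    tab$group <- factor(tab$group, levels = spec@groupLabels)
    truth <- new("GroundTruthLog",
                 deathDay = death, clusterId = cl,
                 spikeFrames = setNames(vector("list", 0L), character()))
    list(table = tab, truth = truth)
  })
}

#' Simulate longitudinal soma-intensity tracks
#'
#' Alive neurons emit intensity near the bright level with multiplicative
#' day-to-day lognormal noise and occasional dim-but-above-background days;
#' from the true death day onward the intensity sits at the residual
#' background level. Observation days are 0..censorDay.
#'
#' @param survival result of [simulateSurvivalCohort()] (list with `table`
#'   and `truth`) or a survival table plus `truth=`.
#' @param spec the [CohortSpec-class] used to generate the cohort.
#' @param seed integer seed (default `spec@seed`).
#' @param truth optional [GroundTruthLog-class] when `survival` is a bare
#'   table.
#' @return A tidy data.frame: `neuron_id`, `cluster_id`, `group`, `day`,
#'   `intensity`, `background_level`.
#' @examples
#' cohort <- simulateSurvivalCohort(specInVitroOGD(), seed = 1)
#' tracks <- simulateIntensityTracks(cohort, specInVitroOGD(), seed = 2)
#' @export
simulateIntensityTracks <- function(survival, spec, seed = spec@seed,
                                    truth = NULL) {
  validObject(spec)
  if (is.list(survival) && !is.data.frame(survival) &&
      !is.null(survival$table)) {
    truth <- survival$truth
    tab <- survival$table
  } else {
    tab <- survival
  }
  if (is.null(truth)) nq_stop("a GroundTruthLog with true death days is required")
  maybe_with_seed(seed, {
    days <- 0:spec@censorDay
    nD <- length(days)
    out <- vector("list", nrow(tab))
    dd <- trueDeathDay(truth)
    for (i in seq_len(nrow(tab))) {
      nid <- tab$neuron_id[i]
      death <- dd[[nid]]
      alive <- days < death
      base <- ifelse(alive, spec@brightLevel, spec@backgroundLevel)
      noise <- exp(rnorm(nD, 0,
                         ifelse(alive, spec@intensitySdlog, spec@bgSdlog)))
      dim_day <- alive & (runif(nD) < spec@dimDayProb)
      intensity <- base * noise * ifelse(dim_day, spec@dimDayFactor, 1)
      out[[i]] <- data.frame(
        neuron_id = nid, cluster_id = tab$cluster_id[i],
        group = tab$group[i], day = days,
        intensity = intensity, background_level = spec@backgroundLevel,
        stringsAsFactors = FALSE)
    }
    tracks <- do.call(rbind, out)
    tracks$group <- factor(as.character(tracks$group),
                           levels = spec@groupLabels)
    rownames(tracks) <- NULL
    tracks
  })
}

#' Simulate a participation table with a known fate effect
#'
#' Small generator used to validate the mixed-effects stage by parameter
#' recovery: per-neuron network participation is a group mean plus an
#' animal-level random intercept, a fate shift for neurons destined to die,
#' and residual noise, truncated to [0, 1].
#'
#' @param nAnimalsPerGroup animals per group.
#' @param neuronsRange neurons per animal (inclusive range).
#' @param mu baseline mean participation.
#' @param fateEffect additive shift for dying neurons.
#' @param groupEffect additive shift for the injured group.
#' @param animalSd SD of the animal random intercept.
#' @param residSd residual SD.
#' @param fateProb probability a neuron is destined to die.
#' @param groupLabels two group labels.
#' @param seed integer seed.
#' @return A data.frame: `neuron_id`, `animal_id`, `group`, `timepoint`,
#'   `fate`, `participation`.
#' @examples
#' head(simulateParticipationTable(seed = 1))
#' @export
simulateParticipationTable <- function(nAnimalsPerGroup = 8L,
                                       neuronsRange = c(18L, 85L),
                                       mu = 0.52, fateEffect = 0,
                                       groupEffect = 0, animalSd = 0.05,
                                       residSd = 0.1, fateProb = 0.3,
                                       groupLabels = c("sham", "HI"),
                                       seed = NULL) {
  maybe_with_seed(seed, {
    rows <- list()
    for (g in 1:2) {
      for (a in seq_len(nAnimalsPerGroup)) {
        animal <- sprintf("%s_p%02d", groupLabels[g], a)
        re <- rnorm(1, 0, animalSd)
        nN <- neuronsRange[1L] +
          sample.int(neuronsRange[2L] - neuronsRange[1L] + 1L, 1L) - 1L
        died <- runif(nN) < fateProb
        part <- mu + re + fateEffect * died + groupEffect * (g == 2L) +
          rnorm(nN, 0, residSd)
        rows[[length(rows) + 1L]] <- data.frame(
          neuron_id = sprintf("%s_n%03d", animal, seq_len(nN)),
          animal_id = animal, group = groupLabels[g],
          timepoint = "baseline",
          fate = ifelse(died, "died", "survived"),
          participation = pmin(1, pmax(0, part)),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    out$group <- factor(out$group, levels = groupLabels)
    out$fate <- factor(out$fate, levels = c("survived", "died"))
    rownames(out) <- NULL
    out
  })
}
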
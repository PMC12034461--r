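test_that("a spec with no signal sources yields a flat recording", {
  spec <- CohortSpec(eventRate = 0, backgroundRate = 0, noiseSd = 0,
                     neuronsRange = c(5L, 5L), nFrames = 100L)
  sim <- simulateRecording(spec, seed = 1)
  expect_equal(unname(assay(sim$recording)),
               matrix(spec@baselineFluor, 5, 100))
  expect_equal(nrow(trueEventIntervals(sim$truth)), 0L)
  expect_true(all(lengths(trueSpikeFrames(sim$truth)) == 0))
})

test_that("participation probability one makes every neuron a participant", {
  spec <- CohortSpec(participationMean = 1, neuronsRange = c(8L, 8L))
  sim <- simulateRecording(spec, seed = 2)
  n_ev <- nrow(trueEventIntervals(sim$truth))
  expect_gt(n_ev, 5)
  for (pp in trueParticipants(sim$truth))
    expect_setequal(pp, neuronIds(sim$recording))
})

test_that("identical spec and seed reproduce the simulation exactly", {
  spec <- specShamBaseline()
  a <- simulateRecording(spec, seed = 77)
  b <- simulateRecording(spec, seed = 77)
  expect_identical(assay(a$recording), assay(b$recording))
  expect_identical(trueEventIntervals(a$truth), trueEventIntervals(b$truth))
  expect_identical(trueSpikeFrames(a$truth), trueSpikeFrames(b$truth))
  c <- simulateRecording(spec, seed = 78)
  expect_false(identical(assay(a$recording), assay(c$recording)))
  s1 <- simulateSurvivalCohort(spec, seed = 5)
  s2 <- simulateSurvivalCohort(spec, seed = 5)
  expect_identical(s1$table, s2$table)
})

test_that("true event rate is conserved across many recordings", {
  spec <- CohortSpec(neuronsRange = c(5L, 5L))
  rates <- vapply(1:50, function(i) {
    sim <- simulateRecording(spec, seed = 4000 + i)
    nrow(trueEventIntervals(sim$truth)) / durationMinutes(sim$recording)
  }, numeric(1))
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - spec@eventRate), 3 * se)
})

test_that("an infeasible event rate is rejected as an invalid spec", {
  spec <- CohortSpec(eventRate = 12, eventDurationMean = 4.3)
  expect_error(simulateRecording(spec, seed = 1), "minimum gap")
  expect_error(simulateRecording(CohortSpec(timepointSchedule =
    default_sched <- data.frame(timepoint = "baseline", rate = 1,
                                duration = 1, participation = 1)),
    timepoint = "1h", seed = 1), "not in the schedule")
})

test_that("the injured group is suppressed at 1 h and recovered at 24 h", {
  spec <- specShamBaseline(neuronsRange = c(5L, 5L))
  n_base <- n_1h <- n_24h <- numeric(20)
  for (i in 1:20) {
    n_base[i] <- nrow(trueEventIntervals(
      simulateRecording(spec, "baseline", "HI", seed = 500 + i)$truth))
    n_1h[i] <- nrow(trueEventIntervals(
      simulateRecording(spec, "1h", "HI", seed = 600 + i)$truth))
    n_24h[i] <- nrow(trueEventIntervals(
      simulateRecording(spec, "24h", "HI", seed = 700 + i)$truth))
  }
  expect_lt(mean(n_1h), 0.6 * mean(n_base))
  # full recovery by 24 h: same configuration as baseline within noise
  se <- sqrt(sd(n_base)^2 + sd(n_24h)^2) / sqrt(20)
  expect_lt(abs(mean(n_24h) - mean(n_base)), 3 * se)
  # the control group is never suppressed
  sham_1h <- nrow(trueEventIntervals(
    simulateRecording(spec, "1h", "sham", seed = 800)$truth))
  expect_gt(sham_1h, 0.5 * mean(n_base))
})

test_that("zero hazard censors every neuron at the censoring day", {
  spec <- CohortSpec(hazardSchedule = rep(0, 11), frailtySd = 0)
  cohort <- simulateSurvivalCohort(spec, seed = 9)
  expect_true(all(cohort$table$event == 0))
  expect_true(all(cohort$table$time == spec@censorDay))
  expect_true(all(is.infinite(trueDeathDay(cohort$truth))))
})

test_that("unit hazard ratio makes the group death-day laws exchangeable", {
  spec <- CohortSpec(hazardRatio = 1, frailtySd = 0,
                     nAnimalsPerGroup = 4L, neuronsRange = c(400L, 400L))
  cohort <- simulateSurvivalCohort(spec, seed = 10)
  tab <- cohort$table
  d1 <- tab$time[tab$group == "sham" & tab$event == 1]
  d2 <- tab$time[tab$group == "HI" & tab$event == 1]
  ks <- suppressWarnings(ks.test(d1, d2))
  expect_gt(ks$p.value, 0.01)
})

test_that("raising the hazard ratio lowers treated-group survival time", {
  base <- CohortSpec(frailtySd = 0, nAnimalsPerGroup = 4L,
                     neuronsRange = c(500L, 500L))
  lo <- simulateSurvivalCohort(CohortSpec(hazardRatio = 1, frailtySd = 0,
    nAnimalsPerGroup = 4L, neuronsRange = c(500L, 500L)), seed = 11)
  hi <- simulateSurvivalCohort(CohortSpec(hazardRatio = 4, frailtySd = 0,
    nAnimalsPerGroup = 4L, neuronsRange = c(500L, 500L)), seed = 11)
  mt <- function(ch) mean(ch$table$time[ch$table$group == "HI"])
  expect_lt(mt(hi), mt(lo))
})

test_that("intensity tracks follow the true death day by construction", {
  spec <- specInVivoHI(nAnimalsPerGroup = 2L, neuronsRange = c(30L, 30L))
  cohort <- simulateSurvivalCohort(spec, seed = 12)
  tracks <- simulateIntensityTracks(cohort, spec, seed = 13)
  thresh <- spec@backgroundLevel * 1.5
  dd <- trueDeathDay(cohort$truth)
  dead <- names(dd)[is.finite(dd)]
  expect_gt(length(dead), 5)
  for (id in dead) {
    tr <- tracks[tracks$neuron_id == id, ]
    expect_true(all(tr$intensity[tr$day >= dd[id]] <= thresh))
  }
  # a censored neuron stays above background on every observed day
  alive <- names(dd)[is.infinite(dd)][1:10]
  for (id in alive) {
    tr <- tracks[tracks$neuron_id == id, ]
    expect_true(all(tr$intensity > thresh))
  }
})

test_that("invalid specs are rejected by the validity method", {
  expect_error(CohortSpec(participationMean = 0), "participationMean")
  expect_error(CohortSpec(participationMean = 1.2), "participationMean")
  expect_error(CohortSpec(eventDurationMean = -1), "eventDurationMean")
  expect_error(CohortSpec(hazardRatio = -2), "hazardRatio")
  expect_error(CohortSpec(nFrames = 0), "nFrames")
  expect_error(CohortSpec(frameRate = 0), "frameRate")
  expect_error(CohortSpec(hazardSchedule = rep(0.01, 3)), "hazardSchedule")
  # default injury schedule: multipliers at 24 h and later are exactly 1
  sched <- CohortSpec()@timepointSchedule
  late <- sched$timepoint %in% c("24h", "d2", "d4", "d11")
  expect_true(all(sched$rate[late] == 1 & sched$duration[late] == 1 &
                    sched$participation[late] == 1))
})

test_that("participation-table generator injects the requested effects", {
  tab <- simulateParticipationTable(nAnimalsPerGroup = 6L,
                                    neuronsRange = c(40L, 60L),
                                    fateEffect = -0.2, seed = 14)
  m_died <- mean(tab$participation[tab$fate == "died"])
  m_surv <- mean(tab$participation[tab$fate == "survived"])
  expect_lt(m_died, m_surv - 0.1)
  expect_true(all(tab$participation >= 0 & tab$participation <= 1))
})
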
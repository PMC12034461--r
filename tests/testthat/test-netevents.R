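test_that("co-active fraction is simple per-frame arithmetic", {
  m <- matrix(0L, 4, 6)
  m[1:2, 3] <- 1L
  r <- make_raster(m)
  expect_equal(coactiveFraction(r), c(0, 0, 0.5, 0, 0, 0))
  expect_equal(coactiveFraction(make_raster(matrix(0L, 3, 5))), rep(0, 5))
})

test_that("a full-population run is one event with the exact duration", {
  m <- matrix(0L, 4, 30)
  m[, 11:15] <- 1L              # frames 10..14 (0-based), half-open [10, 15)
  ev <- detectNetworkEvents(make_raster(m, 1.1), theta = 0.2)
  expect_equal(nEvents(ev), 1L)
  tab <- eventTable(ev)
  expect_equal(tab$onset, 10L)
  expect_equal(tab$offset, 15L)
  expect_equal(tab$duration, 5 / 1.1)
  expect_equal(tab$peakFraction, 1)
  expect_setequal(tab$participants[[1]], paste0("n", 1:4))
})

test_that("runs are merged across small gaps, then short runs dropped", {
  m <- matrix(0L, 2, 40)
  m[, c(5:8, 10:13)] <- 1L      # two runs separated by one silent frame
  m[, 30] <- 1L                 # an isolated 1-frame run
  ev <- detectNetworkEvents(make_raster(m), theta = 0.5, minFrames = 2,
                            mergeGap = 1)
  expect_equal(nEvents(ev), 1L)
  expect_equal(eventTable(ev)$onset, 4L)
  expect_equal(eventTable(ev)$offset, 13L)
  # without merging the isolated frame is still dropped and both runs kept
  ev0 <- detectNetworkEvents(make_raster(m), theta = 0.5, minFrames = 2,
                             mergeGap = 0)
  expect_equal(nEvents(ev0), 2L)
})

test_that("degenerate inputs are rejected or empty as specified", {
  m <- matrix(0L, 3, 20)
  expect_equal(nEvents(detectNetworkEvents(make_raster(m), theta = 0.2)), 0L)
  expect_error(detectNetworkEvents(make_raster(m), theta = 1.2), "theta")
  expect_error(detectNetworkEvents(make_raster(m), theta = 0), "theta")
  expect_error(coactiveFraction(make_raster(matrix(0L, 0, 5))), "zero")
  # zero events: frequency 0, duration/activation missing
  met <- networkMetrics(detectNetworkEvents(make_raster(m), theta = 0.2))
  expect_equal(met$event_frequency, 0)
  expect_true(is.na(met$mean_event_duration))
  expect_true(is.na(met$network_activation))
})

test_that("network activation matches a brute-force raster recomputation", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      m <- matrix(rbinom(12 * 80, 1, 0.2), 12, 80)
      m[, 21:28] <- 1L
      r <- make_raster(m)
      ev <- detectNetworkEvents(r, theta = 0.6, minFrames = 2)
      met <- networkMetrics(ev)
      # brute force: per event, count neurons with any active frame inside
      tab <- eventTable(ev)
      fracs <- vapply(seq_len(nrow(tab)), function(e) {
        cols <- (tab$onset[e] + 1):tab$offset[e]
        sum(rowSums(m[, cols, drop = FALSE]) > 0) / nrow(m)
      }, numeric(1))
      expect_equal(met$network_activation, mean(fracs), tolerance = 1e-15)
      expect_equal(met$event_frequency,
                   nrow(tab) / (80 / 1.1 / 60), tolerance = 1e-12)
    }
  })
})

test_that("participation counts events containing the neuron", {
  m <- matrix(0L, 3, 40)
  m[, 5:8] <- 1L                 # event 1: everyone
  m[1:2, 20:23] <- 1L            # event 2: neurons 1-2
  ev <- detectNetworkEvents(make_raster(m), theta = 0.5)
  expect_equal(nEvents(ev), 2L)
  p <- neuronalParticipation(ev)
  expect_equal(unname(p), c(1, 1, 0.5))
  expect_equal(neuronalParticipation(ev, "n3"), 0.5)
  expect_error(neuronalParticipation(ev, "nope"), "unknown neuron")
  # zero events -> missing participation for every neuron
  p0 <- neuronalParticipation(
    detectNetworkEvents(make_raster(matrix(0L, 3, 20)), theta = 0.5))
  expect_true(all(is.na(p0)))
})

test_that("shuffle threshold is seeded, bounded, and above the mean fraction", {
  withr::with_seed(32, {
    m <- matrix(rbinom(30 * 200, 1, 0.1), 30, 200)
    r <- make_raster(m)
    t1 <- shuffleThreshold(r, nShuffles = 300, seed = 99)
    t2 <- shuffleThreshold(r, nShuffles = 300, seed = 99)
    expect_identical(t1, t2)
    expect_lt(t1, 1)
    expect_gt(t1, mean(colMeans(m)))
    expect_warning(shuffleThreshold(r, nShuffles = 50, seed = 1), "below 100")
  })
  # all-zero raster: threshold collapses to the floor and detection is empty
  z <- make_raster(matrix(0L, 4, 50))
  tz <- shuffleThreshold(z, nShuffles = 100, seed = 1, floor = 0.1)
  expect_equal(tz, 0.1)
  expect_equal(nEvents(detectNetworkEvents(z, tz)), 0L)
})

test_that("detector on the ground-truth raster reproduces the true event log", {
  spec <- specShamBaseline()
  sim <- simulateRecording(spec, nNeurons = 30, seed = 33)
  iv <- trueEventIntervals(sim$truth)
  r <- truth_raster(sim$truth, neuronIds(sim$recording),
                    nFrames(sim$recording))
  ev <- detectNetworkEvents(r, theta = 0.1, minFrames = 1, mergeGap = 0)
  keep <- lengths(trueParticipants(sim$truth)) > 0
  expect_equal(eventTable(ev)$onset, unname(iv[keep, 1]))
  expect_equal(eventTable(ev)$offset, unname(iv[keep, 2]))
  for (e in which(keep)) {
    expect_setequal(
      eventTable(ev)$participants[[sum(keep[seq_len(e)])]],
      trueParticipants(sim$truth)[[e]])
  }
  # time-mean of the co-active fraction equals the oracle computed directly
  # from the truth log
  oracle_mean <- sum(vapply(seq_len(nrow(iv)), function(e)
    (iv[e, 2] - iv[e, 1]) * length(trueParticipants(sim$truth)[[e]]),
    numeric(1))) / (30 * nFrames(sim$recording))
  expect_equal(mean(coactiveFraction(r)), oracle_mean, tolerance = 1e-12)
})

test_that("long-run participation estimates the configured probability", {
  # near-degenerate participation distribution concentrated at 0.7
  spec <- CohortSpec(participationMean = 0.7,
                     participationDispersion = 1e6,
                     neuronsRange = c(25L, 25L))
  sim <- simulateRecording(spec, seed = 34)
  r <- truth_raster(sim$truth, neuronIds(sim$recording),
                    nFrames(sim$recording))
  ev <- detectNetworkEvents(r, theta = 0.1, minFrames = 1, mergeGap = 0)
  p <- neuronalParticipation(ev)
  n_ev <- nEvents(ev)
  se <- sqrt(0.7 * 0.3 / (n_ev * 25))
  expect_lt(abs(mean(p) - 0.7), 4 * se)
})

test_that("every participant has at least one active frame inside its event", {
  sim <- simulateRecording(specShamBaseline(), nNeurons = 25, seed = 35)
  raster <- detectTransients(computeDFF(sim$recording))
  ev <- detectNetworkEvents(raster, shuffleThreshold(raster, seed = 36))
  tab <- eventTable(ev)
  act <- assay(raster)
  for (e in seq_len(nrow(tab))) {
    cols <- (tab$onset[e] + 1):tab$offset[e]
    for (id in tab$participants[[e]])
      expect_true(any(act[id, cols] == 1))
  }
  # events sorted and disjoint
  if (nrow(tab) > 1) {
    expect_true(all(diff(tab$onset) > 0))
    expect_true(all(tab$onset[-1] >= tab$offset[-nrow(tab)]))
  }
})
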
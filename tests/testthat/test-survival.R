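test_that("quench calling follows the persistence rule", {
  bg <- 10
  # bright on all days -> censored at the last day
  expect_equal(callQuench(0:10, rep(100, 11), bg),
               list(time = 10, event = 0L))
  # at background from day 6 onward -> quenched on day 6
  expect_equal(callQuench(0:10, c(rep(100, 6), rep(10, 5)), bg),
               list(time = 6, event = 1L))
  # a transient dip on day 3 that recovers on day 4 -> censored
  x <- rep(100, 11); x[4] <- 10
  expect_equal(callQuench(0:10, x, bg), list(time = 10, event = 0L))
  # dim-but-above-threshold days never trigger quench (threshold 15)
  expect_equal(callQuench(0:10, rep(20, 11), bg),
               list(time = 10, event = 0L))
  # finite persistence window: low on days 3-4, recovered at 5; a 1-day
  # persistence window calls the quench at day 3 regardless
  y <- rep(100, 11); y[4:5] <- 10
  expect_equal(callQuench(0:10, y, bg, persistence = 1),
               list(time = 3, event = 1L))
  expect_equal(callQuench(0:10, y, bg), list(time = 10, event = 0L))
})

test_that("quench guards reject malformed tracks", {
  expect_error(callQuench(1:5, rep(100, 5), 10), "day-0")
  expect_error(callQuench(0, 100, 10), "at least 2")
  expect_error(callQuench(c(0, 2, 1), rep(100, 3), 10), "increasing")
  expect_error(callQuench(0:2, c(100, -1, 100), 10), ">= 0")
})

test_that("Kaplan-Meier reproduces the hand product-limit example", {
  tab <- data.frame(time = c(2, 5, 9, 9), event = c(1, 1, 0, 0))
  km <- kaplanMeier(tab)
  expect_equal(km$survival[km$time == 0], 1)
  expect_equal(km$survival[km$time == 2], 3 / 4)     # 4 at risk, 1 death
  expect_equal(km$survival[km$time == 5], 1 / 2)     # 3 at risk, 1 death
  expect_true(all(diff(km$survival) <= 1e-12))
  # no events -> S identically 1
  km1 <- kaplanMeier(data.frame(time = c(3, 7), event = c(0, 0)))
  expect_true(all(km1$survival == 1))
})

test_that("Kaplan-Meier matches the brute-force oracle on random tables", {
  for (s in 1:50) {
    tab <- random_survival_table(n = 5 + (s %% 20), seed = 4100 + s)
    km <- kaplanMeier(tab[, c("time", "event")])
    or <- oracle_km(tab$time, tab$event)
    for (i in seq_len(nrow(or))) {
      got <- km$survival[km$time == or$time[i]]
      expect_equal(got, or$surv[i], tolerance = 1e-12)
    }
  }
})

test_that("Kaplan-Meier is invariant to within-day record order", {
  tab <- random_survival_table(40, seed = 4200)
  perm <- withr::with_seed(1, sample(nrow(tab)))
  expect_equal(kaplanMeier(tab[, c("time", "event")]),
               kaplanMeier(tab[perm, c("time", "event")]))
})

test_that("clustered Cox matches an independent Efron partial-likelihood oracle", {
  # hand-built 8-row table with ties in both groups
  tab <- data.frame(
    neuron_id = paste0("n", 1:8),
    cluster_id = rep(c("c1", "c2"), 4),
    group = factor(rep(c("a", "b"), each = 4), levels = c("a", "b")),
    time = c(2, 4, 4, 9, 1, 2, 2, 5),
    event = c(1, 1, 0, 0, 1, 1, 1, 0))
  fit <- coxClustered(tab)
  x <- as.integer(tab$group) - 1
  beta_or <- oracle_efron_mle(tab$time, tab$event, x)
  expect_equal(logHazardRatio(fit), beta_or, tolerance = 1e-6)
  # Breslow flag is honoured (different tie handling, different estimate)
  fitb <- coxClustered(tab, ties = "breslow")
  expect_false(isTRUE(all.equal(logHazardRatio(fit),
                                logHazardRatio(fitb), tolerance = 1e-8)))
  # CoxFit internal consistency
  expect_equal(hazardRatio(fit), exp(logHazardRatio(fit)))
  expect_equal(confint95(fit),
               exp(logHazardRatio(fit) +
                     c(-1, 1) * fit@critValue * robustSe(fit)))
  expect_equal(fit@critValue, qt(0.975, fit@nClusters - 1))
  expect_equal(fit@z, logHazardRatio(fit) / robustSe(fit))
  # without the finite-cluster correction the quantile is 1.96
  raw <- coxClustered(tab, clusterCorrection = FALSE)
  expect_equal(raw@critValue, qnorm(0.975))
  expect_equal(robustSe(fit) / robustSe(raw),
               sqrt(fit@nClusters / (fit@nClusters - 1)))
})

test_that("Cox oracle agreement holds across random small tables", {
  for (s in 1:10) {
    tab <- random_survival_table(30, seed = 4300 + s)
    if (length(unique(tab$group[tab$event == 1])) < 2) next
    fit <- coxClustered(tab)
    beta_or <- oracle_efron_mle(tab$time, tab$event,
                                as.integer(tab$group) - 1)
    expect_lt(abs(logHazardRatio(fit) - beta_or), 1e-6)
  }
})

test_that("identical group laws at large n give HR near 1 and small z", {
  withr::with_seed(4400, {
    n <- 600
    tab <- data.frame(
      cluster_id = sample(paste0("c", 1:12), 2 * n, replace = TRUE),
      group = factor(rep(c("a", "b"), each = n)),
      time = sample(1:11, 2 * n, replace = TRUE),
      event = rbinom(2 * n, 1, 0.4))
    fit <- coxClustered(tab)
    expect_lt(abs(logHazardRatio(fit)), 0.15)
    expect_lt(abs(fit@z), 2.5)
  })
})

test_that("Cox estimate is invariant to rescaling all times", {
  tab <- random_survival_table(50, seed = 4500)
  f1 <- coxClustered(tab)
  tab2 <- tab; tab2$time <- tab2$time * 2.5
  f2 <- coxClustered(tab2)
  expect_equal(logHazardRatio(f1), logHazardRatio(f2), tolerance = 1e-12)
  expect_equal(robustSe(f1), robustSe(f2), tolerance = 1e-12)
})

test_that("singleton clusters reduce to the unclustered robust sandwich", {
  tab <- random_survival_table(60, seed = 4600)
  tab$cluster_id <- paste0("u", seq_len(nrow(tab)))   # one neuron per cluster
  fit <- coxClustered(tab, clusterCorrection = FALSE)
  ref <- survival::coxph(
    survival::Surv(time, event) ~ grp, robust = TRUE, ties = "efron",
    data = data.frame(time = tab$time, event = tab$event,
                      grp = as.integer(tab$group) - 1))
  expect_equal(robustSe(fit), sqrt(ref$var[1, 1]), tolerance = 1e-12)
  # and with ample data the robust SE approaches the model-based SE
  big <- random_survival_table(4000, seed = 4700)
  big$cluster_id <- paste0("u", seq_len(nrow(big)))
  fb <- coxClustered(big, clusterCorrection = FALSE)
  expect_lt(abs(fb@robustSe / fb@modelSe - 1), 0.1)
})

test_that("degenerate survival tables are rejected with diagnostics", {
  tab <- random_survival_table(20, seed = 4800)
  tab$event <- ifelse(tab$group == "b", tab$event, 0L)
  expect_error(coxClustered(tab), "monotone likelihood")
  one <- random_survival_table(20, seed = 4900)
  one$cluster_id <- "c1"
  expect_error(coxClustered(one), "2 clusters")
  three <- random_survival_table(20, seed = 4950)
  three$group <- as.character(three$group)
  three$group[1:3] <- "c"
  expect_error(coxClustered(three), "two groups")
})

test_that("quench caller recovers true death days on synthetic tracks", {
  spec <- specInVivoHI(nAnimalsPerGroup = 3L)
  cohort <- simulateSurvivalCohort(spec, seed = 20)
  tracks <- simulateIntensityTracks(cohort, spec, seed = 21)
  st <- quenchSurvivalTable(tracks)
  dd <- trueDeathDay(cohort$truth)[st$neuron_id]
  true_time <- ifelse(is.infinite(dd), spec@censorDay, dd)
  true_event <- as.integer(is.finite(dd))
  expect_gte(mean(st$time == true_time & st$event == true_event), 0.95)
  # group levels flow through from the tracks (injured group second)
  expect_identical(levels(st$group), c("sham", "HI"))
})
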
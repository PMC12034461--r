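test_that("zero-clustering data downgrade to the ordinary linear model", {
  tab <- simulateParticipationTable(nAnimalsPerGroup = 4L,
                                    neuronsRange = c(30L, 30L),
                                    animalSd = 0, residSd = 0.08, seed = 51)
  # forced fixed-only path equals lm() exactly
  forced <- fitParticipationLme(tab, fixed = "fate", forceFixedOnly = TRUE)
  ref <- lm(participation ~ fate, data = tab)
  expect_equal(unname(forced$coefficients), unname(coef(ref)),
               tolerance = 1e-8)
  expect_identical(forced$method, "lm")
})

test_that("a null fate effect tests as null in a seeded balanced design", {
  tab <- simulateParticipationTable(nAnimalsPerGroup = 8L,
                                    neuronsRange = c(40L, 40L),
                                    fateEffect = 0, animalSd = 0.05,
                                    residSd = 0.1, seed = 52)
  fit <- fitParticipationLme(tab, fixed = "fate")
  row <- fit$tests[fit$tests$effect == "fate", ]
  expect_lt(row$F, 4)
  expect_gt(row$p, 0.05)
  # an injected effect is detected with the same machinery
  tab2 <- simulateParticipationTable(nAnimalsPerGroup = 8L,
                                     neuronsRange = c(40L, 40L),
                                     fateEffect = -0.15, animalSd = 0.05,
                                     residSd = 0.1, seed = 52)
  fit2 <- fitParticipationLme(tab2, fixed = "fate")
  expect_lt(fit2$tests$p[fit2$tests$effect == "fate"], 0.001)
  expect_lt(fit2$coefficients[["fatedied"]], -0.1)
})

test_that("fixed effects are invariant to row order", {
  tab <- simulateParticipationTable(nAnimalsPerGroup = 5L,
                                    neuronsRange = c(20L, 30L),
                                    fateEffect = -0.1, seed = 53)
  perm <- withr::with_seed(2, sample(nrow(tab)))
  f1 <- fitParticipationLme(tab, fixed = c("fate", "group"))
  f2 <- fitParticipationLme(tab[perm, ], fixed = c("fate", "group"))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$tests$F, f2$tests$F, tolerance = 1e-8)
})

test_that("participation outside [0, 1] and tiny designs are rejected", {
  tab <- simulateParticipationTable(nAnimalsPerGroup = 3L, seed = 54,
                                    neuronsRange = c(5L, 8L))
  bad <- tab; bad$participation[1] <- 1.4
  expect_error(fitParticipationLme(bad, fixed = "fate"), "\\[0, 1\\]")
  one_animal <- tab[tab$animal_id == tab$animal_id[1], ]
  expect_error(fitParticipationLme(one_animal, fixed = "fate"),
               "2 animals")
  # records with missing participation (no events that day) are dropped
  tab$participation[1:4] <- NA
  fit <- fitParticipationLme(tab, fixed = "fate")
  expect_true(is.finite(fit$tests$F[1]))
})

test_that("a perfectly collinear toy input recovers the slope exactly", {
  # participation = death_day / 20, no noise, no clustering structure
  dd <- rep(c(2, 5, 8, 11), 3)
  rec <- data.frame(participation = dd / 20, death_day = dd,
                    animal_id = rep(c("a", "b", "c"), each = 4))
  # zero-residual input: lm's perfect-fit warning is the expected regime
  out <- suppressWarnings(baselineVsDeathdayRegression(rec))
  expect_equal(out$slope, 20, tolerance = 1e-8)
})

test_that("death-day regression refuses underpowered inputs", {
  rec <- data.frame(participation = c(0.5, 0.6), death_day = c(3, 7),
                    animal_id = c("a", "b"))
  expect_error(baselineVsDeathdayRegression(rec), "refusing")
  empty <- data.frame(participation = numeric(), death_day = numeric(),
                      animal_id = character())
  expect_error(baselineVsDeathdayRegression(empty), "refusing")
})

test_that("death days independent of participation give a null slope", {
  withr::with_seed(55, {
    rec <- data.frame(
      participation = runif(120, 0.2, 0.8),
      death_day = sample(1:11, 120, replace = TRUE),
      animal_id = rep(sprintf("p%02d", 1:8), 15))
    out <- baselineVsDeathdayRegression(rec)
    expect_true(out$ci95[1] <= 0 && 0 <= out$ci95[2])
    expect_gt(out$p, 0.05)
  })
})
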
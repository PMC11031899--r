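test_that("benefitScore sums intercept, main effects and interactions", {
  zero <- effectSpec(5)
  expect_identical(benefitScore(numeric(6), c(1, 3), zero), 0)

  spec <- effectSpec(5, beta0 = 1, betaVariant = c(0.5, 0, 0, 0, 0))
  expect_identical(benefitScore(numeric(6), 1L, spec), 1.5)

  inter <- effectSpec(5, gammaPairs = cbind(1, 2, 2.0))
  expect_identical(benefitScore(numeric(6), c(1L, 2L), inter), 2.0)
  expect_identical(benefitScore(numeric(6), 1L, inter), 0)      # pair incomplete
  expect_identical(benefitScore(numeric(6), c(2L, 1L, 1L), inter), 2.0)  # set

  clin <- effectSpec(5, betaClinical = c(male = 0.25))
  expect_identical(benefitScore(c(0, 1, 0, 0, 0, 0), integer(0), clin), 0.25)

  expect_error(benefitScore(numeric(6), 7L, spec), "unknown variant index: 7")
})

test_that("variant profiles follow configured prevalences", {
  cfgNone <- cohortConfig(nPatients = 1, variantPrevalences = 0, seed = 1)
  cfgAll <- cohortConfig(nPatients = 1, variantPrevalences = 1, seed = 1)
  set.seed(1)
  expect_identical(sampleVariantProfile(cfgNone), integer(0))
  expect_identical(sampleVariantProfile(cfgAll), 1:102)

  cfg <- cohortConfig(nPatients = 1, variantPrevalences = 0.1, seed = 1)
  set.seed(42)
  sizes <- replicate(10000, length(sampleVariantProfile(cfg)))
  # binomial oracle: mean 10.2, se of the mean = sqrt(102*.1*.9/10000)
  se <- sqrt(102 * 0.1 * 0.9 / 10000)
  expect_lt(abs(mean(sizes) - 10.2), 3 * se)
})

test_that("survival sampler is calibrated and respects the score", {
  cfg <- cohortConfig(nPatients = 1, seed = 1)
  set.seed(7)
  s0 <- sampleSurvival(rep(0, 10000), 0, cfg)
  expect_lt(abs(median(s0$pfs_months) - 2.70), 0.3)
  expect_true(all(s0$pfs_event == 1L), info = "no censoring, all events")
  expect_true(all(s0$os_event == 1L))
  expect_true(all(s0$os_months >= s0$pfs_months))

  set.seed(8)
  s1 <- sampleSurvival(rep(log(2), 10000), 0, cfg)
  expect_lt(abs(median(s1$pfs_months) - 5.40), 0.45)

  expect_error(cohortConfig(nPatients = 1, basePFSMedian = -1),
               "medians must be positive")
})

test_that("generateCohort is deterministic and hits configured prevalences", {
  cfg <- cohortConfig(nPatients = 0, seed = 3)
  expect_identical(ncol(generateCohort(cfg)), 0L)

  cfg <- cohortConfig(nPatients = 40, censoringRate = 0.2, seed = 5)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  fa <- tempfile(fileext = ".csv"); fb <- tempfile(fileext = ".csv")
  writePatientCSV(a, fa); writePatientCSV(b, fb)
  expect_identical(readLines(fa), readLines(fb))

  big <- generateCohort(cohortConfig(nPatients = 10000, seed = 11))
  pMale <- mean(colData(big)$sex == "male")
  target <- 189 / 288
  expect_lt(abs(pMale - target),
            3 * sqrt(target * (1 - target) / 10000))
})

test_that("os >= pfs whenever both events are observed, with censoring", {
  co <- generateCohort(cohortConfig(nPatients = 500, censoringRate = 0.3,
                                    seed = 9))
  both <- pfsEvent(co) == 1L & osEvent(co) == 1L
  expect_true(any(both) && any(!both))
  expect_true(all(osMonths(co)[both] >= pfsMonths(co)[both]))
})

test_that("raising a variant main effect lengthens carriers' PFS", {
  prev <- rep(0.2, 102)
  base <- cohortConfig(nPatients = 10000, variantPrevalences = prev,
                       seed = 21)
  boosted <- cohortConfig(nPatients = 10000, variantPrevalences = prev,
                          effect = effectSpec(102, betaVariant =
                                                c(0.5, rep(0, 101))),
                          seed = 21)
  a <- generateCohort(base); b <- generateCohort(boosted)
  carrier <- assay(a, "occurrence")[1, ] == 1L
  expect_identical(carrier, assay(b, "occurrence")[1, ] == 1L)
  expect_gt(mean(pfsMonths(b)[carrier]), mean(pfsMonths(a)[carrier]))
  # non-carriers untouched by construction (same seed, same draws)
  expect_equal(pfsMonths(b)[!carrier], pfsMonths(a)[!carrier])
})

test_that("effect spec validation catches out-of-panel interactions", {
  expect_error(effectSpec(5, gammaPairs = cbind(1, 9, 1)),
               "outside the panel")
  expect_error(cohortConfig(nPatients = 1, variantPrevalences = 1.4),
               "lie in")
})
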
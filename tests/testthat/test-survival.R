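test_that("product-limit estimate matches hand computation and conventions", {
  cv <- kmEstimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_identical(cv@time, c(1, 2, 3, 4))
  expect_equal(cv@surv, c(3 / 4, 1 / 2, 1 / 4, 0), tolerance = 1e-15)
  expect_identical(cv@nRisk, c(4, 3, 2, 1))

  allCens <- kmEstimate(c(2, 5, 9), c(0, 0, 0))
  expect_identical(length(allCens@time), 0L)
  expect_identical(kmMedian(allCens), NA_real_)

  # censoring at an event time keeps the censored subject at risk there
  tied <- kmEstimate(c(2, 2, 3), c(1, 0, 1))
  expect_equal(tied@surv, c(2 / 3, 0), tolerance = 1e-15)

  expect_error(kmEstimate(numeric(0), numeric(0)), "empty")
})

test_that("KM equals one minus the empirical CDF without censoring", {
  set.seed(40)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    times <- round(rexp(n, 0.3) + 0.01, 2)
    cv <- kmEstimate(times, rep(1, n))
    for (j in seq_along(cv@time))
      expect_equal(cv@surv[j], survFracBrute(times, cv@time[j]),
                   tolerance = 1e-12)
  }
})

test_that("KM agrees with the survival package under censoring", {
  skip_if_not_installed("survival")
  set.seed(41)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    times <- round(rexp(n, 0.2), 1) + 0.1  # rounding creates ties
    events <- sample(0:1, n, replace = TRUE)
    if (sum(events) == 0) events[1] <- 1
    cv <- kmEstimate(times, events)
    sf <- survival::survfit(survival::Surv(times, events) ~ 1)
    ref <- summary(sf, times = cv@time)
    expect_equal(cv@surv, ref$surv, tolerance = 1e-12)
    expect_equal(cv@nRisk, ref$n.risk, tolerance = 0)
  }
})

test_that("km median follows the first crossing and scales with time", {
  cv <- kmEstimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_identical(kmMedian(cv), 2)
  cv10 <- kmEstimate(10 * c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_identical(kmMedian(cv10), 20)
})

test_that("log-rank test matches hand computation and is symmetric", {
  same <- logrankTest(c(1, 2, 3), c(1, 1, 0), c(1, 2, 3), c(1, 1, 0))
  expect_true(same$defined)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p.value, 1, tolerance = 1e-12)

  # groups {1,2} vs {3,4}, all events: O - E = 7/6, V = 17/36 by hand
  lr <- logrankTest(c(1, 2), c(1, 1), c(3, 4), c(1, 1))
  expect_equal(lr$statistic, (7 / 6)^2 / (17 / 36), tolerance = 1e-12)
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-12)

  swap <- logrankTest(c(3, 4), c(1, 1), c(1, 2), c(1, 1))
  expect_equal(swap$statistic, lr$statistic, tolerance = 1e-12)
  expect_equal(swap$p.value, lr$p.value, tolerance = 1e-12)

  expect_error(logrankTest(1, 0, 2, 0), "no events")
})

test_that("log-rank agrees with survdiff on random censored instances", {
  skip_if_not_installed("survival")
  set.seed(42)
  for (i in 1:25) {
    nA <- sample(4:40, 1); nB <- sample(4:40, 1)
    tA <- round(rexp(nA, 0.2) + 0.01, 1)
    tB <- round(rexp(nB, 0.3) + 0.01, 1)
    eA <- sample(0:1, nA, replace = TRUE, prob = c(0.25, 0.75))
    eB <- sample(0:1, nB, replace = TRUE, prob = c(0.25, 0.75))
    if (sum(eA) + sum(eB) == 0) eA[1] <- 1
    mine <- logrankTest(tA, eA, tB, eB)
    sd <- survival::survdiff(
      survival::Surv(c(tA, tB), c(eA, eB)) ~ rep(1:2, c(nA, nB)))
    expect_equal(mine$statistic, sd$chisq, tolerance = 1e-9)
  }
})

test_that("predicted-strata comparison separates a planted signal", {
  # noiseless construction: carriers of VS have long PFS, others short
  cd <- data.frame(pfs_months = rep(c(10, 1), each = 10) + seq(0, 1.9, 0.1),
                   pfs_event = 1L, os_months = 20)
  vl <- stats::setNames(
    as.list(rep(c("VS", "VR"), each = 10)), sprintf("T%04d", 1:20))
  co <- makeCohort(cd = cd, variants = vl,
                   panel = data.frame(variant_id = c("VS", "VR"),
                                      gene = c("G1", "G2")))
  fs <- buildFeatureSet(co)
  m <- fitClassifier(modelSpec("logistic_regression", seed = 1), fs, 1:20)
  sc <- comparePredictedGroups(m, fs, co, 1:20, "pfs")
  expect_true(sc@testDefined)
  expect_gt(sc@medians[["predicted_sensitive"]],
            sc@medians[["predicted_resistant"]])
  expect_lt(sc@pValue, 0.01)

  # threshold 0 predicts everyone sensitive: flagged, no test
  degenerate <- comparePredictedGroups(m, fs, co, 1:20, "pfs", threshold = 0)
  expect_false(degenerate@testDefined)
  expect_identical(unname(degenerate@nPerGroup), c(20L, 0L))
})
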
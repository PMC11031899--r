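test_that("auroc equals the pair-counting statistic", {
  expect_identical(auroc(c(3, 2, 1, 0), c(1, 1, 0, 0)), 1)
  expect_identical(auroc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 1)), 2 / 3,
               tolerance = 1e-12)
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("auroc invariances hold on random instances", {
  set.seed(100)
  for (i in 1:25) {
    n <- sample(4:25, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(rnorm(n), 2)  # rounding forces occasional ties
    a <- auroc(s, y)
    expect_equal(a, auroc(exp(2 * s) + 5, y), tolerance = 1e-12)
    sTF <- s + seq_len(n) * 1e-9  # break ties
    expect_equal(auroc(sTF, y) + auroc(-sTF, y), 1, tolerance = 1e-12)
  }
})

test_that("roc curve has correct endpoints, monotonicity and area", {
  rc <- rocCurve(c(1, 0), c(1, 0))
  expect_identical(rc$fpr, c(0, 0, 1))
  expect_identical(rc$tpr, c(0, 1, 1))

  trapz <- function(rc) sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) +
                                            utils::tail(rc$tpr, -1)) / 2)
  set.seed(200)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), 1)
    rc <- rocCurve(s, y)
    expect_true(all(diff(rc$fpr) >= 0) && all(diff(rc$tpr) >= 0))
    expect_identical(c(rc$fpr[1], rc$tpr[1]), c(0, 0))
    expect_identical(c(rc$fpr[nrow(rc)], rc$tpr[nrow(rc)]), c(1, 1))
    expect_equal(trapz(rc), auroc(s, y), tolerance = 1e-12)
  }
})

test_that("bootstrap CI is seed-stable and brackets the point estimate", {
  s <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  y <- c(1, 1, 1, 0, 0, 0)
  ci <- bootstrapAurocCI(s, y, nBoot = 200, seed = 1)
  expect_identical(unname(ci), c(1, 1))  # perfect separation, any resample

  set.seed(300)
  for (i in 1:10) {
    sc <- rnorm(40)
    yy <- rep(c(1, 0), each = 20)
    ci <- bootstrapAurocCI(sc, yy, nBoot = 400, seed = i)
    expect_identical(bootstrapAurocCI(sc, yy, nBoot = 400, seed = i), ci)
    a <- auroc(sc, yy)
    expect_lte(ci["lower"], a + 1e-12)
    expect_gte(ci["upper"], a - 1e-12)
  }
})

test_that("threshold metrics recompute from confusion counts", {
  m <- thresholdMetrics(c(0.9, 0.4, 0.6, 0.2), c(1, 0, 1, 0))
  expect_identical(c(m$sensitivity, m$specificity, m$accuracy, m$f1),
                   c(1, 1, 1, 1))

  m2 <- thresholdMetrics(c(0.6, 0.4, 0.6, 0.4), c(1, 1, 0, 0))
  expect_identical(c(m2$tp, m2$fn, m2$fp, m2$tn), c(1L, 1L, 1L, 1L))
  expect_identical(c(m2$sensitivity, m2$specificity, m2$accuracy, m2$f1),
                   c(0.5, 0.5, 0.5, 0.5))

  m3 <- thresholdMetrics(runif(20), rep(c(1, 0), 10), threshold = 0)
  expect_identical(m3$sensitivity, 1)
})
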
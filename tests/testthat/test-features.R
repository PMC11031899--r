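test_that("PFS-threshold labels follow the decision rules", {
  expect_identical(as.character(assignLabel(2.0, 1)), "resistant")
  expect_identical(as.character(assignLabel(6.5, 1)), "sensitive")
  expect_identical(as.character(assignLabel(7.0, 0)), "sensitive")
  expect_identical(as.character(assignLabel(2.0, 0)), "excluded")
  expect_identical(as.character(assignLabel(4.0, 1)), "excluded")
  # boundaries are strict: exactly 3 or 6 months is indeterminate
  expect_identical(as.character(assignLabel(c(3, 6), c(1, 1))),
                   c("excluded", "excluded"))
  expect_error(assignLabel(-1, 1), "non-negative")
  expect_error(assignLabel(5, 1, tResistant = 7, tSensitive = 6),
               "thresholds")
})

test_that("labels are monotone in PFS for observed events", {
  grid <- seq(0, 10, by = 0.25)
  lab <- assignLabel(grid, rep(1, length(grid)))
  rank <- c(resistant = 1, excluded = 2, sensitive = 3)[as.character(lab)]
  expect_true(all(diff(rank) >= 0))
})

test_that("clinical features use the fixed binary encoding", {
  co <- makeCohort(cd = data.frame(
    age_years = c(37L, 70L), sex = c("male", "female"),
    histology = c("intestinal", "diffuse"),
    prior_trastuzumab = c(0L, 1L),
    first_line_duration = c("ge6", "mid")))
  m <- buildClinicalFeatures(co)
  expect_identical(colnames(m),
                   c("young_onset", "male", "intestinal_histology",
                     "prior_trastuzumab", "duration_lt3", "duration_ge6"))
  expect_identical(unname(m[1, ]), c(1L, 1L, 1L, 0L, 0L, 1L))
  expect_identical(unname(m[2, ]), c(0L, 0L, 0L, 1L, 0L, 0L))

  mixed <- makeCohort(cd = data.frame(histology = "mixed"))
  expect_identical(unname(buildClinicalFeatures(mixed)[1, "intestinal_histology"]),
                   0L)
  bad <- makeCohort(cd = data.frame(histology = "serous"))
  expect_error(buildClinicalFeatures(bad), "histology")
})

test_that("variant vocabulary is observed-only, unique and ordered", {
  expect_identical(length(buildVariantVocabulary(makeCohort(n = 2))@ids), 0L)

  co <- makeCohort(n = 3, variants = list(T0001 = c("V2", "V1"),
                                          T0002 = "V1"),
                   panel = data.frame(variant_id = c("V1", "V2", "V9"),
                                      gene = c("GB", "GA", "GC")))
  v <- buildVariantVocabulary(co)
  expect_identical(v@ids, c("V2", "V1"))  # gene GA before GB; V9 unobserved
  expect_identical(variantIndex(v, c("V1", "V2")), c(2L, 1L))
  expect_error(variantIndex(v, "V9"), "unknown variant")

  full <- smallCohort(4000, seed = 2)
  expect_identical(length(buildVariantVocabulary(full)@ids), 102L)
})

test_that("variant matrix round-trips sets and flags out-of-vocabulary", {
  co <- makeCohort(n = 3, variants = list(T0001 = c("V1", "V3"), T0003 = "V2"),
                   panel = data.frame(variant_id = paste0("V", 1:3),
                                      gene = paste0("G", 1:3)))
  vocab <- buildVariantVocabulary(co)
  m <- buildVariantMatrix(co, vocab)
  expect_identical(unname(rowSums(m)), c(2, 0, 1))
  sets <- variantSets(co)
  rebuilt <- lapply(seq_len(nrow(m)), function(i) colnames(m)[m[i, ] == 1])
  expect_identical(unname(lapply(rebuilt, sort)),
                   unname(lapply(sets, sort)))

  small <- variantVocabulary("V1", "G1")
  expect_error(buildVariantMatrix(co, small), "V2")
  dropped <- buildVariantMatrix(co, small, unknownVariants = "drop")
  expect_identical(dim(dropped), c(3L, 1L))
})

test_that("stratified split reproduces the 230/58 design and is stable", {
  labels <- rep(c("sensitive", "resistant"), c(116, 172))
  sp <- stratifiedSplit(labels, 0.2, seed = 1)
  expect_identical(length(sp$train), 230L)
  expect_identical(length(sp$validation), 58L)
  expect_identical(sort(c(sp$train, sp$validation)), 1:288)

  sp2 <- stratifiedSplit(labels, 0.2, seed = 1)
  expect_identical(sp, sp2)
  sp3 <- stratifiedSplit(labels, 0.2, seed = 99)
  expect_identical(lengths(sp3), lengths(sp))
  expect_false(identical(sp3$validation, sp$validation))

  tiny <- stratifiedSplit(rep(c(1, 0), each = 5), 0.2, seed = 3)
  valLab <- rep(c(1, 0), each = 5)[tiny$validation]
  expect_identical(sort(valLab), c(0, 1))

  expect_error(stratifiedSplit(rep("a", 10)), "two classes")
  expect_error(stratifiedSplit(labels, 1.2), "must lie in")
})

test_that("split class proportions stay within 1/val_n for all small inputs", {
  for (n in 2:12) for (pos in 1:(n - 1)) {
    labels <- rep(c(1, 0), c(pos, n - pos))
    sp <- stratifiedSplit(labels, 0.2, seed = 17)
    valN <- length(sp$validation)
    valPos <- sum(labels[sp$validation] == 1)
    expect_lte(abs(valPos / valN - pos / n), 1 / valN + 1e-12)
  }
})

test_that("baseline table counts, percentages and tests are coherent", {
  one <- makeCohort(cd = data.frame(sex = "male"))
  tab <- summarizeCohort(one)
  male <- tab[tab$characteristic == "sex" & tab$level == "male", ]
  expect_identical(male$count_group1, 1L)
  expect_identical(male$pct_group1, 100)

  co <- smallCohort(150, seed = 4)
  t2 <- summarizeCohort(co[, 1:100], co[, 101:150],
                        subsetNames = c("a", "b"))
  # percentages recompute exactly from counts at one-decimal rounding
  expect_identical(t2$pct_a, pctOf(t2$count_a, 100))
  expect_identical(t2$pct_b, pctOf(t2$count_b, 50))
  # subgroup counts sum to the subset size within each characteristic
  sums <- tapply(t2$count_a, t2$characteristic, sum)
  expect_true(all(sums == 100))
  expect_true(all(stats::na.omit(t2$p_value) >= 0 &
                  stats::na.omit(t2$p_value) <= 1))
})

test_that("balance test matches the closed form and reference code", {
  perfect <- categoricalBalanceTest(rbind(c(10, 10), c(10, 10)))
  expect_identical(perfect$statistic, 0)
  expect_identical(perfect$p.value, 1)

  t1 <- categoricalBalanceTest(rbind(c(20, 10), c(10, 20)))
  expect_equal(t1$statistic, 20 / 3, tolerance = 1e-12)
  # closed form n(ad-bc)^2 / (r1 r2 c1 c2)
  expect_equal(t1$statistic, 60 * (20 * 20 - 10 * 10)^2 /
                 (30 * 30 * 30 * 30), tolerance = 1e-12)
  expect_identical(categoricalBalanceTest(rbind(c(10, 20), c(20, 10)))$statistic,
                   t1$statistic)

  ref <- suppressWarnings(stats::chisq.test(rbind(c(18, 12, 9), c(7, 14, 21)),
                                            correct = FALSE))
  mine <- categoricalBalanceTest(rbind(c(18, 12, 9), c(7, 14, 21)))
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-12)
  expect_identical(mine$df, 2L)

  sparse <- categoricalBalanceTest(rbind(c(2, 8), c(9, 1)))
  expect_identical(sparse$method, "fisher")
  expect_equal(sparse$p.value,
               stats::fisher.test(rbind(c(2, 8), c(9, 1)))$p.value,
               tolerance = 1e-12)

  expect_error(categoricalBalanceTest(rbind(c(0, 0), c(1, 2))),
               "degenerate margin")
})
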
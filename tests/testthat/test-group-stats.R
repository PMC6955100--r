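test_that("group summaries report mean and SEM with the n-1 denominator", {
  s <- summarizeGroup(c(1, 2, 3), "A")
  expect_equal(s$mean, 2)
  expect_equal(s$sem, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(round(s$sem, 4), 0.5774)

  s <- summarizeGroup(c(5, 5, 5, 5))
  expect_equal(s$mean, 5)
  expect_equal(s$sem, 0)

  expect_error(summarizeGroup(3), "sample-size")

  set.seed(14)
  for (i in 1:10) {
    x <- rnorm(sample(5:50, 1), sd = 4)
    s <- summarizeGroup(x)
    # independent two-pass computation
    m <- sum(x) / length(x)
    expect_equal(s$mean, m)
    expect_equal(s$sem,
                 sqrt(sum((x - m)^2) / (length(x) - 1)) / sqrt(length(x)))
  }
})

test_that("the pooled t-test matches hand-computed statistics", {
  r <- twoSampleT(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)

  # pooled variance 1, SE = sqrt(2/3), diff -1
  r <- twoSampleT(c(1, 2, 3), c(2, 3, 4), variant = "student")
  expect_equal(r$t, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(r$t, 4), -1.2247)
  expect_equal(r$df, 4)
  expect_false(r$significant)
})

test_that("student and welch coincide for equal n and equal variance", {
  x <- c(1.2, 3.4, 2.2, 4.8)
  y <- x + 2  # identical spread
  s <- twoSampleT(x, y, "student")
  w <- twoSampleT(x, y, "welch")
  expect_equal(s$t, w$t)
  expect_equal(s$df, w$df)
  expect_equal(s$p, w$p)
})

test_that("swapping groups flips t and preserves p", {
  set.seed(5)
  x <- rnorm(12, 10); y <- rnorm(15, 11)
  ab <- twoSampleT(x, y)
  ba <- twoSampleT(y, x)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
})

test_that("zero-variance samples follow the documented limiting convention", {
  r <- twoSampleT(c(2, 2, 2), c(2, 2, 2))
  expect_equal(r$t, 0); expect_equal(r$p, 1)
  r <- twoSampleT(c(2, 2, 2), c(3, 3, 3))
  expect_true(is.infinite(r$t) && r$t < 0)
  expect_equal(r$p, 0)
  expect_true(r$significant)
})

test_that("the t-test holds its nominal size under a simulated null", {
  set.seed(2024)
  reps <- 1000
  rej <- vapply(seq_len(reps), function(i) {
    twoSampleT(rnorm(10), rnorm(10))$p < 0.05
  }, TRUE)
  rate <- mean(rej)
  # binomial 99% bounds around 0.05 at 1000 replicates
  expect_gte(rate, 0.033)
  expect_lte(rate, 0.069)
})

test_that("metric comparisons run per neuron and flag planted contrasts", {
  p <- growthParams()
  a <- generateCohort(cohortSpec("AD06", 20, p), seed = 7)
  bSame <- generateCohort(cohortSpec("AD12", 20, p), seed = 7)
  cm <- compareMetric(a, bSame, "length")
  expect_equal(cm$p, 1)           # identical trees, relabelled
  expect_equal(cm$mean_a, cm$mean_b)
  expect_identical(cm$group_a, "AD06")
  expect_identical(cm$n_a, 20L)

  cmV <- compareMetric(a, bSame, "spatial_volume", volumeMode = "cube")
  expect_identical(cmV$metric, "spatial_volume[cube]")

  expect_error(compareMetric(a[1], bSame[1], "length"), "sample-size")
})

test_that("per-shell and range-wise Sholl comparisons behave on identical cohorts", {
  p <- growthParams()
  a <- lapply(generateCohort(cohortSpec("AD06", 10, p), seed = 3),
              shollProfile)
  b <- lapply(generateCohort(cohortSpec("AD12", 10, p), seed = 3),
              shollProfile)
  sh <- suppressMessages(compareSholl(a, b, mode = "per_shell"))
  expect_true(all(sh$p == 1))
  expect_false(any(sh$significant))
  expect_true(all(grepl("^sholl_shell@", sh$metric)))

  rg <- suppressMessages(compareSholl(a, b, mode = "range",
                                      ranges = list(c(30, 90))))
  expect_equal(nrow(rg), 1L)
  expect_identical(rg$metric, "sholl_range@30-90")
  expect_equal(rg$p, 1)

  expect_warning(suppressMessages(
    compareSholl(a, b, mode = "range", ranges = list(c(45, 80)))),
    "snapped outward")
})

test_that("holm correction only ever reduces the significant set", {
  p <- growthParams()
  a <- lapply(generateCohort(cohortSpec("AD06", 15, p), seed = 21),
              shollProfile)
  b <- lapply(generateCohort(cohortSpec("AD12", 15, p,
                                        branchProbEffect = 1.2),
                             seed = 22), shollProfile)
  plain <- suppressMessages(compareSholl(a, b, mode = "per_shell"))
  holm <- suppressMessages(compareSholl(a, b, mode = "per_shell",
                                        correction = "holm"))
  expect_true(all(holm$p_adjusted >= holm$p))
  expect_lte(sum(holm$significant), sum(plain$significant))
})
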
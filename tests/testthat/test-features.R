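test_that("trial segmentation uses half-open 66-sample windows", {
  n <- 400
  rec <- randomRecording(n = n, seed = 20)
  sched <- eventSchedule(100, "high")
  trl <- segmentTrials(rec, sched)
  expect_length(trl, 1L)
  expect_equal(dim(trl[[1]]@hbo2), c(14L, 66L))
  # onset 100 s at 2 Hz -> 0-based samples [196, 262)
  expect_identical(trl[[1]]@hbo2[1, ], hbo2(rec)[1, 197:262])
  expect_equal(trl[[1]]@load, "high")

  expect_error(eventSchedule(0.5, "low"), "baseline")  # no 2 s baseline
  expect_error(segmentTrials(rec, eventSchedule(190, "low")),
               "trial 1.*outside")

  # back-to-back trials: segments disjoint iff onsets >= 33 s apart
  s2 <- eventSchedule(c(50, 83), c("low", "high"))
  t2 <- segmentTrials(rec, s2)
  # [-2,31) around 50 -> [96,162); around 83 -> [162,228): disjoint
  expect_identical(t2[[2]]@hbo2[1, 1], hbo2(rec)[1, 163])
})

test_that("window statistics match brute-force moment computation", {
  v <- c(0, 0, 0, 0, 0, 0, 0, 0, 0, 10)
  trial <- makeTrial(c(numeric(24), v), channel = 3)  # window [10,15) s
  f <- windowFeatures(trial, 10, 5, 3)
  expect_equal(f[["skew_hbo2"]], skewOracle(v))
  expect_equal(f[["kurt_hbo2"]], kurtOracle(v))
  expect_equal(f[["mean_hbo2"]], mean(v))
  expect_equal(f[["amp_hbo2"]], mean(v) - 0)

  # symmetric values -> zero skewness
  sym <- rep(c(-1, 0, 1, 0, -1, 1), length.out = 10)
  trial <- makeTrial(c(numeric(24), sym), channel = 1)
  expect_equal(windowFeatures(trial, 10, 5, 1)[["skew_hbo2"]], 0)

  # random window against direct moments, both species
  set.seed(21)
  m <- matrix(rnorm(14 * 66), 14)
  trial <- new("FnirsTrial", hbo2 = m, hhb = matrix(rnorm(14 * 66), 14),
               load = "high", index = 1L, onset = 50, fs = 2)
  f <- windowFeatures(trial, 12, 10, 7)
  idx <- 29:48  # [12, 22) s -> 0-based 28..47
  expect_equal(f[["mean_hbo2"]], mean(m[7, idx]))
  expect_equal(f[["amp_hbo2"]], mean(m[7, idx]) - mean(m[7, 1:4]))
  expect_equal(f[["skew_hbo2"]], skewOracle(m[7, idx]))
  expect_equal(f[["kurt_hbo2"]], kurtOracle(m[7, idx]))
  expect_equal(f[["kurt_hhb"]], kurtOracle(trial@hhb[7, idx]))
})

test_that("degenerate zero-variance windows yield zero shape statistics", {
  trial <- makeTrial(base = 2.5)   # constant everywhere
  expect_warning(f <- windowFeatures(trial, 10, 5, 2), "zero-variance")
  expect_equal(f[["mean_hbo2"]], 2.5)
  expect_equal(f[["amp_hbo2"]], 0)
  expect_equal(f[["kurt_hbo2"]], 0)
  expect_equal(f[["skew_hbo2"]], 0)
})

test_that("feature vector has the canonical length and ordering", {
  set.seed(22)
  trial <- new("FnirsTrial", hbo2 = matrix(rnorm(14 * 66), 14),
               hhb = matrix(rnorm(14 * 66), 14), load = "low",
               index = 1L, onset = 50, fs = 2)
  fv <- trialFeatures(trial)
  expect_length(fv, 2352L)
  expect_equal(names(fv)[1], "ch01_off10_len05_mean_hbo2")
  expect_equal(names(fv)[7], "ch01_off10_len05_skew_hbo2")
  expect_equal(names(fv)[8], "ch01_off10_len05_skew_hhb")
  # channel ascending, offset ascending, length ascending
  expect_equal(names(fv)[169], "ch02_off10_len05_mean_hbo2")
  expect_equal(names(fv)[9], "ch01_off10_len10_mean_hbo2")
  expect_equal(names(fv)[25], "ch01_off11_len05_mean_hbo2")

  # single channel -> 168 predictors
  one <- new("FnirsTrial", hbo2 = matrix(rnorm(66), 1),
             hhb = matrix(rnorm(66), 1), load = "low", index = 1L,
             onset = 50, fs = 2)
  expect_length(trialFeatures(one), 168L)

  # agreement with per-window extraction and determinism
  g <- windowGrid()
  w <- 11  # arbitrary grid row
  expect_equal(unname(fv[(5 - 1) * 168 + (w - 1) * 8 + 1:8]),
               unname(windowFeatures(trial, g$offset_s[w], g$length_s[w], 5)))
  expect_identical(fv, trialFeatures(trial))

  # feature-count conservation for other montages
  m9 <- new("FnirsTrial", hbo2 = matrix(rnorm(9 * 66), 9),
            hhb = matrix(rnorm(9 * 66), 9), load = "low", index = 1L,
            onset = 50, fs = 2)
  expect_length(trialFeatures(m9), 9 * 21 * 8)
})

test_that("constant shifts move means but not shape or amplitude features", {
  set.seed(23)
  base <- matrix(rnorm(14 * 66), 14)
  t1 <- new("FnirsTrial", hbo2 = base, hhb = base, load = "low",
            index = 1L, onset = 50, fs = 2)
  t2 <- new("FnirsTrial", hbo2 = base + 7, hhb = base + 7, load = "low",
            index = 1L, onset = 50, fs = 2)
  f1 <- trialFeatures(t1); f2 <- trialFeatures(t2)
  isMean <- grepl("_mean_", names(f1))
  expect_equal(f2[isMean], f1[isMean] + 7)
  expect_equal(f2[!isMean], f1[!isMean], tolerance = 1e-8)
})

test_that("peak response equals exhaustive max-minus-baseline", {
  # flat trial -> 0; single spike of 3 above zero baseline -> 3
  expect_equal(unname(peakResponse(makeTrial(base = 1))[1]), 0)
  spike <- numeric(66); spike[30] <- 3
  expect_equal(unname(peakResponse(makeTrial(spike, channel = 2),
                                   channel = 2)), 3)
  set.seed(24)
  m <- matrix(rnorm(14 * 66), 14)
  trial <- new("FnirsTrial", hbo2 = m, hhb = -m, load = "low", index = 1L,
               onset = 50, fs = 2)
  pr <- peakResponse(trial)
  for (ch in c(1, 6, 14)) {
    best <- -Inf
    for (j in 5:65) best <- max(best, m[ch, j])  # [0, 30] s inclusive
    expect_equal(pr[ch], best - mean(m[ch, 1:4]))
  }
})

test_that("feature matrices export with self-describing columns", {
  rec <- randomRecording(n = 300, seed = 25)
  sched <- eventSchedule(c(40, 80), c("low", "high"))
  fm <- featureMatrix(segmentTrials(rec, sched))
  expect_equal(dim(fm$X), c(2L, 2352L))
  expect_equal(fm$y, c("low", "high"))
  f <- withr::local_tempfile(fileext = ".csv")
  writeFeatures(fm, f)
  hdr <- strsplit(readLines(f, n = 1), ",")[[1]]
  expect_equal(hdr[1:3], c("trial", "load", "ch01_off10_len05_mean_hbo2"))
  expect_length(hdr, 2354L)
})
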
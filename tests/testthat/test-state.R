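test_that("channel averaging matches direct summation", {
  rec <- randomRecording(n = 30, seed = 6)
  avg <- averageActiveChannels(rec, "hbo2")
  # brute-force mean
  m <- hbo2(rec)
  ref <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) ref[j] <- sum(m[, j]) / nrow(m)
  expect_equal(avg, ref)

  # identical channels average to themselves; +v/-v cancels
  s <- rnorm(30)
  recSame <- fnirsRecording(matrix(rep(s, each = 16), 16, byrow = FALSE),
                            matrix(0, 16, 30))
  expect_equal(averageActiveChannels(recSame), s, ignore_attr = TRUE)
  two <- fnirsRecording(rbind(s, -s), matrix(0, 2, 30),
                        montage = channelMontage(1:2, integer(0)))
  expect_equal(averageActiveChannels(two), rep(0, 30), ignore_attr = TRUE)

  both <- averageActiveChannels(rec, "both")
  expect_equal(both, (colMeans(hbo2(rec)) + colMeans(hhb(rec))) / 2)
})

test_that("crossover detection follows the strict sign-change rule", {
  zero <- rep(0, 5)
  expect_equal(states(detectCrossovers(c(-1, -1, 1, 1, -1), zero)),
               c(FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(states(detectCrossovers(rep(-2, 10), zero[1] + numeric(10))),
               rep(FALSE, 10))
  # exact ties never trigger: flat zero difference stays not-on-task
  expect_equal(states(detectCrossovers(numeric(10), numeric(10))),
               rep(FALSE, 10))
  # touching zero from above without going negative is not an offset
  d <- c(-1, 1, 0, 2, -1)
  expect_equal(states(detectCrossovers(d, numeric(5))),
               c(FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_error(detectCrossovers(1:3, 1:4), "equal length")
})

test_that("state transitions alternate for random difference series", {
  set.seed(8)
  for (i in 1:20) {
    d <- rnorm(200)
    s <- states(detectCrossovers(d, numeric(200)))
    tr <- diff(s)
    runs <- tr[tr != 0]
    # alternating: consecutive transitions always have opposite sign
    if (length(runs) > 1) expect_true(all(diff(runs) != 0))
  }
})

test_that("chronogram scoring reproduces the brute-force confusion matrix", {
  est <- chronogram(rep(TRUE, 100), fs = 2)
  truth <- chronogram(rep(c(TRUE, FALSE), each = 50), fs = 2)
  sc <- scoreChronogram(est, truth, warmup_s = 0)
  expect_equal(sc$accuracy, 0.5)
  expect_equal(sc$sensitivity, 1.0)
  expect_equal(sc$specificity, 0.0)

  self <- scoreChronogram(truth, truth, warmup_s = 0)
  expect_equal(self$accuracy, 1.0)
  expect_equal(self$sensitivity, 1.0)
  expect_equal(self$specificity, 1.0)

  set.seed(9)
  e <- sample(c(TRUE, FALSE), 1000, TRUE)
  t <- sample(c(TRUE, FALSE), 1000, TRUE)
  sc <- scoreChronogram(chronogram(e, 2), chronogram(t, 2), warmup_s = 0)
  ref <- confusionOracle(e, t)
  expect_equal(sc$accuracy, ref$accuracy)
  expect_equal(sc$sensitivity, ref$sensitivity)
  expect_equal(sc$specificity, ref$specificity)
  expect_equal(sum(sc$labels == "Correct") / 1000, ref$accuracy)

  # sensitivity/specificity invariant under sample reordering
  p <- sample(1000)
  sc2 <- scoreChronogram(chronogram(e[p], 2), chronogram(t[p], 2),
                         warmup_s = 0)
  expect_equal(sc2$sensitivity, sc$sensitivity)
  expect_equal(sc2$specificity, sc$specificity)
})

test_that("warm-up exclusion drops the first samples from the tallies", {
  e <- c(rep(TRUE, 36), rep(FALSE, 64))     # wrong during warm-up
  t <- rep(FALSE, 100)
  sc <- scoreChronogram(chronogram(e, 2), chronogram(t, 2))  # 18 s = 36
  expect_equal(sc$n_scored, 64L)
  expect_equal(sc$accuracy, 1.0)
  sc0 <- scoreChronogram(chronogram(e, 2), chronogram(t, 2), warmup_s = 0)
  expect_equal(sc0$accuracy, 0.64)
})

test_that("shuffled truth drives accuracy to the base-rate bound", {
  set.seed(12)
  e <- rep(c(TRUE, FALSE), c(300, 700))
  accs <- replicate(50, {
    t <- sample(e)   # truth with same base rate, random alignment
    scoreChronogram(chronogram(e, 2), chronogram(t, 2), warmup_s = 0)$accuracy
  })
  # expected accuracy = p^2 + (1-p)^2 = 0.58 at p = 0.3
  expect_lt(abs(mean(accs) - 0.58), 0.03)
})

test_that("latency analysis matches exact, shifted, and jittered truths", {
  sched <- eventSchedule(seq(20, 20 + 39 * 45, by = 45),
                         rep(c("low", "high"), 20))
  onsets <- trials(sched)$onset_s
  n <- 4000
  mk <- function(shift) {
    st <- logical(n)
    for (o in onsets) {
      a <- round((o + shift) * 2); b <- round((o + shift + 11) * 2)
      st[(a + 1):b] <- TRUE
    }
    chronogram(st, fs = 2)
  }
  lat0 <- latencyAnalysis(mk(0), sched)
  expect_equal(lat0$onset_latency_s, rep(0, 40))
  expect_equal(lat0$offset_latency_s, rep(0, 40))
  expect_equal(lat0$unmatched_onsets, 0L)

  lat2 <- latencyAnalysis(mk(2), sched)
  expect_equal(mean(lat2$onset_latency_s), 2.0)
  expect_equal(mean(lat2$offset_latency_s), 2.0)

  # jittered transitions vs exhaustive nearest-match search
  set.seed(13)
  jit <- runif(40, -6, 6)
  st <- logical(n)
  for (i in seq_along(onsets)) {
    a <- round((onsets[i] + jit[i]) * 2)
    b <- round((onsets[i] + jit[i] + 11) * 2)
    st[(a + 1):b] <- TRUE
  }
  est <- chronogram(st, fs = 2)
  lat <- latencyAnalysis(est, sched)
  # oracle: enumerate all on-transitions, exhaustive nearest within window
  s <- states(est)
  ups <- (which(diff(s) == 1) + 1 - 1) / 2
  for (i in seq_along(onsets)) {
    cand <- ups[ups >= onsets[i] - 10 & ups <= onsets[i] + 15]
    best <- cand[which.min(abs(cand - onsets[i]))]
    expect_equal(lat$onset_latency_s[i], best - onsets[i])
  }
  # per-load breakdown covers all matched trials
  expect_equal(lat$matched + lat$unmatched_onsets, 40L)
  expect_error(latencyAnalysis(chronogram(logical(10), 2), sched),
               "beyond the recording")
})
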
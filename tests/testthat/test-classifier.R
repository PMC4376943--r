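sepData <- function(n = 20, p = 10, gap = 3, seed = 30) {
  set.seed(seed)
  y <- rep(c("low", "high"), n / 2)
  X <- matrix(rnorm(n * p, 0, 0.5), n, p)
  X[, 1] <- X[, 1] + ifelse(y == "high", gap, -gap)
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = y)
}

test_that("C selection finds perfect CV accuracy on separable clusters", {
  d <- sepData()
  sel <- selectC(d$X, d$y, plan = cvPlan(seed = 1))
  expect_equal(max(sel$cvTable$cv_accuracy), 1.0)
  expect_true(sel$C %in% sel$cvTable$C)
  # ties break toward the smallest C
  expect_equal(sel$C, min(sel$cvTable$C[sel$cvTable$cv_accuracy == 1.0]))
  # one-value grid short-circuits
  expect_equal(selectC(d$X, d$y, grid = 0.5)$C, 0.5)
  expect_error(selectC(d$X, rep("low", 20)), "both classes")
})

test_that("pure-noise features give chance-level CV accuracy", {
  set.seed(31)
  accs <- replicate(40, {
    X <- matrix(rnorm(20 * 30), 20, 30)
    y <- sample(rep(c("low", "high"), 10))
    sel <- selectC(X, y, grid = c(0.01, 1), plan = cvPlan(repeats = 2,
                                                          seed = sample.int(1e6, 1)))
    mean(sel$cvTable$cv_accuracy)
  })
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})

test_that("training on a separable 1-D feature puts the boundary near zero", {
  y <- rep(c("low", "high"), 10)
  X <- matrix(ifelse(y == "high", 1, -1) + rnorm(20, 0, 0.01), ncol = 1)
  colnames(X) <- "f1"
  m <- trainWorkloadModel(X, y, C = 10)
  preds <- apply(X, 1, function(r) classifyTrial(m, r))
  expect_equal(unname(preds), y)               # training accuracy 1
  # boundary near 0 on the original scale
  expect_equal(classifyTrial(m, 0.9), "high")
  expect_equal(classifyTrial(m, -0.9), "low")

  # zero-variance feature columns are tolerated via unit scale
  X2 <- cbind(X, constant = 5)
  m2 <- trainWorkloadModel(X2, y, C = 10)
  expect_equal(unname(apply(X2, 1, function(r) classifyTrial(m2, r))), y)
})

test_that("duplicating training rows leaves separable decisions unchanged", {
  d <- sepData(n = 12, p = 4, gap = 4)
  m1 <- trainWorkloadModel(d$X, d$y, C = 1)
  mDup <- trainWorkloadModel(rbind(d$X, d$X), c(d$y, d$y), C = 1)
  test <- sepData(n = 20, p = 4, gap = 4, seed = 99)
  p1 <- apply(test$X, 1, function(r) classifyTrial(m1, r))
  p2 <- apply(test$X, 1, function(r) classifyTrial(mDup, r))
  expect_equal(p1, p2)
  expect_equal(unname(p1), test$y)
})

test_that("classification matches the explicit dot-product rule and e1071", {
  d <- sepData(n = 20, p = 6, gap = 1, seed = 33)   # not cleanly separable
  m <- trainWorkloadModel(d$X, d$y, C = 1)
  test <- sepData(n = 30, p = 6, gap = 1, seed = 34)
  ours <- apply(test$X, 1, function(r) classifyTrial(m, r))
  # dot-product oracle on the scaled features
  for (i in 1:30) {
    z <- (test$X[i, ] - m@center) / m@scale
    d_i <- sum(m@weights * z) + m@bias
    expect_equal(unname(ours[i]), if (d_i >= 0) "high" else "low")
  }
  # independent route: e1071's own predict on the same scaled data
  Xs <- scale(d$X, m@center, m@scale)
  fit <- e1071::svm(x = Xs, y = factor(d$y, levels = c("high", "low")),
                    kernel = "linear", cost = 1, scale = FALSE)
  ref <- as.character(predict(fit, scale(test$X, m@center, m@scale)))
  expect_equal(unname(ours), ref)

  # frozen model: identical answer on repeated classification
  expect_identical(classifyTrial(m, test$X[1, ]), classifyTrial(m, test$X[1, ]))
  expect_error(classifyTrial(m, numeric(3)), "does not match")
})

test_that("a zero decision value classifies as high", {
  m <- new(Class = "WorkloadModel", weights = c(1, 0), bias = 0,
           C = 1, center = c(0, 0), scale = c(1, 1),
           featureNames = c("a", "b"), positiveClass = "high",
           cvTable = data.frame(C = numeric(0), cv_accuracy = numeric(0)))
  expect_equal(classifyTrial(m, c(0, 5)), "high")
  expect_equal(classifyTrial(m, c(-1e-9, 0)), "low")
})

test_that("evaluation reproduces a hand-tallied confusion matrix", {
  d <- sepData(n = 20, p = 4)
  m <- trainWorkloadModel(d$X, d$y, C = 1)
  ev <- evaluateModel(m, d$X, d$y)
  expect_equal(ev$accuracy, 1.0)
  expect_equal(ev$sensitivity, 1.0)
  expect_equal(ev$specificity, 1.0)

  set.seed(35)
  yt <- sample(c("low", "high"), 30, TRUE)
  Xt <- matrix(rnorm(30 * 4), 30, 4)
  ev <- evaluateModel(m, Xt, yt)
  pred <- apply(Xt, 1, function(r) classifyTrial(m, r))
  tp <- sum(pred == "high" & yt == "high")
  tn <- sum(pred == "low" & yt == "low")
  expect_equal(ev$accuracy, mean(pred == yt))
  expect_equal(ev$sensitivity, tp / sum(yt == "high"))
  expect_equal(ev$specificity, tn / sum(yt == "low"))

  # degenerate all-high prediction on balanced truth
  mAll <- new(Class = "WorkloadModel", weights = 0, bias = 1, C = 1,
              center = 0, scale = 1, featureNames = "a",
              positiveClass = "high",
              cvTable = data.frame(C = numeric(0), cv_accuracy = numeric(0)))
  ev <- evaluateModel(mAll, matrix(rnorm(20), 20, 1),
                      rep(c("low", "high"), 10))
  expect_equal(ev$accuracy, 0.5)
  expect_equal(ev$sensitivity, 1.0)
  expect_equal(ev$specificity, 0.0)
})

test_that("stratified folds preserve class balance within one", {
  set.seed(36)
  y <- rep(c("low", "high"), 10)
  plan <- cvPlan()
  sel <- selectC(matrix(rnorm(20 * 5), 20, 5), y, grid = c(0.1, 1),
                 plan = plan)
  # directly check the fold builder
  for (r in 1:5) {
    fold <- fnirsbci:::stratifiedFolds(y, 5)
    for (k in 1:5) {
      expect_lte(abs(sum(y[fold == k] == "high") -
                     sum(y[fold == k] == "low")), 1L)
    }
  }
})

test_that("model JSON serialization round trips", {
  d <- sepData(n = 20, p = 5)
  m <- trainWorkloadModel(d$X, d$y, C = 0.1)
  f <- withr::local_tempfile(fileext = ".json")
  writeModel(m, f)
  m2 <- readModel(f)
  expect_equal(m2@weights, m@weights)
  expect_equal(m2@bias, m@bias)
  expect_equal(m2@C, m@C)
  expect_equal(m2@center, m@center)
  expect_equal(m2@scale, m@scale)
  expect_equal(m2@featureNames, m@featureNames)
  test <- sepData(n = 10, p = 5, seed = 40)
  expect_equal(apply(test$X, 1, function(r) classifyTrial(m, r)),
               apply(test$X, 1, function(r) classifyTrial(m2, r)))
})

test_that("shuffled training labels give chance-level test accuracy", {
  set.seed(37)
  accs <- replicate(20, {
    d <- sepData(n = 20, p = 10, gap = 0, seed = sample.int(1e6, 1))
    yShuf <- sample(d$y)
    m <- trainWorkloadModel(d$X, yShuf, C = 1)
    test <- sepData(n = 20, p = 10, gap = 0, seed = sample.int(1e6, 1))
    evaluateModel(m, test$X, test$y)$accuracy
  })
  expect_gt(mean(accs), 0.35)
  expect_lt(mean(accs), 0.65)
})
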
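#' Cross-validation plan
#'
#' Stratified k-fold cross-validation repeated several times, the scheme
#' used to tune the SVM regularization value on the 20 labeled
#' data-gathering trials (5-fold, 10 repeats = 50 fold-fits). Folds are
#' stratified so each preserves the class balance to within one trial;
#' fold assignment is deterministic given the seed.
#'
#' @param folds number of folds (default 5).
#' @param repeats number of repetitions (default 10).
#' @param seed RNG seed for the fold shuffles (default 0).
#' @return named list of class `"CvPlan"`.
#' @export
cvPlan <- function(folds = 5L, repeats = 10L, seed = 0L) {
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed)), class = "CvPlan")
}

# stratified fold ids for one repeat: within each class, shuffle and deal
# round-robin so every fold's class balance is within +/-1.
stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

scaleConstants <- function(X) {
  n <- nrow(X)
  ctr <- colMeans(X)
  v <- (colSums(X^2) - n * ctr^2) / (n - 1)
  scl <- sqrt(pmax(v, 0))
  scl[!is.finite(scl) | scl <= 0] <- 1   # zero-variance columns: unit scale
  list(center = ctr, scale = scl)
}

fitLinearSvm <- function(Xs, y, C) {
  yf <- factor(y, levels = c("high", "low"))
  fit <- e1071::svm(x = Xs, y = yf, kernel = "linear", cost = C,
                    scale = FALSE)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # orient the rule so positive decision values mean "high": e1071 names
  # the decision column after its internal label order.
  dv <- attr(stats::predict(fit, Xs[1L, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  if (identical(colnames(dv), "low/high")) {
    w <- -w; b <- -b
  }
  list(weights = w, bias = b)
}

#' Select the SVM regularization value by repeated cross-validation
#'
#' For each candidate C, runs stratified repeated cross-validation (by
#' default 5-fold, 10 repeats on the 20 phase-D trials) and averages the
#' held-out accuracy over all fold-fits; the C with the highest mean
#' accuracy is selected, ties going to the smallest C (strongest
#' regularization). Features are z-scored inside each training fold.
#'
#' @param X feature matrix, trials x features.
#' @param y load labels (`"low"`/`"high"`); both classes must be present.
#' @param grid candidate C values (default the seven decades
#'   \eqn{10^{-5} \ldots 10}).
#' @param plan a [cvPlan()].
#' @return list with `C` (selected value) and `cvTable` (data.frame of
#'   `C`, `cv_accuracy`).
#' @export
selectC <- function(X, y, grid = 10^(-5:1), plan = cvPlan()) {
  if (length(unique(y)) < 2L) stop("both classes must be present in y")
  if (length(grid) == 1L) {
    return(list(C = grid,
                cvTable = data.frame(C = grid, cv_accuracy = NA_real_)))
  }
  acc <- withSeed(plan$seed, {
    folds <- lapply(seq_len(plan$repeats), function(r) {
      stratifiedFolds(y, plan$folds)
    })
    # z-score each training fold once, then sweep the C grid on it
    splits <- list()
    for (fold in folds) {
      for (k in seq_len(plan$folds)) {
        te <- fold == k
        if (!any(te) || length(unique(y[!te])) < 2L) next
        sc <- scaleConstants(X[!te, , drop = FALSE])
        splits[[length(splits) + 1L]] <- list(
          Xtr = scale(X[!te, , drop = FALSE], sc$center, sc$scale),
          Xte = scale(X[te, , drop = FALSE], sc$center, sc$scale),
          ytr = y[!te], yte = y[te]
        )
      }
    }
    vapply(grid, function(C) {
      hits <- 0L; total <- 0L
      for (s in splits) {
        m <- fitLinearSvm(s$Xtr, s$ytr, C)
        d <- as.numeric(s$Xte %*% m$weights + m$bias)
        pred <- ifelse(d >= 0, "high", "low")
        hits <- hits + sum(pred == s$yte)
        total <- total + length(s$yte)
      }
      hits / total
    }, numeric(1L))
  })
  best <- which(acc == max(acc))[1L]   # grid ascending: ties -> smallest C
  list(C = grid[best], cvTable = data.frame(C = grid, cv_accuracy = acc))
}

#' Train a per-subject workload classifier
#'
#' Fits a linear support-vector machine on the labeled training trials.
#' Features are z-scored with training-set statistics (zero-variance
#' features get unit scale); when `C` is `NULL` it is first selected with
#' [selectC()]. The returned model is frozen: classification applies a
#' fixed linear rule with no further training.
#'
#' @param X feature matrix, trials x features (named columns).
#' @param y load labels (`"low"`/`"high"`).
#' @param C regularization value, or `NULL` to tune by cross-validation.
#' @param grid candidate C values when tuning.
#' @param plan a [cvPlan()] used when tuning.
#' @return a \linkS4class{WorkloadModel}.
#' @export
trainWorkloadModel <- function(X, y, C = NULL, grid = 10^(-5:1),
                               plan = cvPlan()) {
  if (length(unique(y)) < 2L) stop("both classes must be present in y")
  cvTable <- data.frame(C = numeric(0), cv_accuracy = numeric(0))
  if (is.null(C)) {
    sel <- selectC(X, y, grid, plan)
    C <- sel$C
    cvTable <- sel$cvTable
  }
  sc <- scaleConstants(X)
  Xs <- scale(X, sc$center, sc$scale)
  fit <- fitLinearSvm(Xs, y, C)
  new(Class = "WorkloadModel",
      weights = fit$weights, bias = fit$bias, C = C,
      center = as.numeric(sc$center), scale = as.numeric(sc$scale),
      featureNames = if (is.null(colnames(X))) character(0) else colnames(X),
      positiveClass = "high", cvTable = cvTable)
}

#' Classify one trial's feature vector
#'
#' Applies the frozen linear rule: the feature vector is z-scored with the
#' model's training constants and the sign of
#' \eqn{w \cdot x_{scaled} + b} decides the class. A decision value of
#' exactly 0 classifies as `"high"` (the positive class).
#'
#' @param model a \linkS4class{WorkloadModel}.
#' @param fv numeric feature vector matching the model's feature length.
#' @return `"low"` or `"high"`.
#' @export
classifyTrial <- function(model, fv) {
  if (length(fv) != length(model@weights)) {
    stop(sprintf("feature vector length %d does not match model length %d",
                 length(fv), length(model@weights)))
  }
  z <- (as.numeric(fv) - model@center) / model@scale
  d <- sum(model@weights * z) + model@bias
  if (d >= 0) "high" else "low"
}

#' Evaluate a model on labeled test trials
#'
#' @param model a \linkS4class{WorkloadModel}.
#' @param X_test feature matrix, trials x features.
#' @param y_test true load labels.
#' @return list: `accuracy`, `sensitivity` (recall of `"high"`),
#'   `specificity` (recall of `"low"`), `predictions`, `truth`.
#' @export
evaluateModel <- function(model, X_test, y_test) {
  if (nrow(X_test) == 0L) stop("test set is empty")
  pred <- apply(X_test, 1L, function(r) classifyTrial(model, r))
  tp <- sum(pred == "high" & y_test == "high")
  tn <- sum(pred == "low" & y_test == "low")
  nhigh <- sum(y_test == "high"); nlow <- sum(y_test == "low")
  list(
    accuracy = mean(pred == y_test),
    sensitivity = if (nhigh > 0) tp / nhigh else NA_real_,
    specificity = if (nlow > 0) tn / nlow else NA_real_,
    predictions = unname(pred), truth = unname(y_test)
  )
}

#' Serialize and restore a workload model
#'
#' Models are stored as a documented JSON object: `weights`, `bias`, `C`,
#' `center`, `scale`, `feature_names`, `positive_class`, and the
#' cross-validation table.
#'
#' @param model a \linkS4class{WorkloadModel}.
#' @param path JSON file path.
#' @return `writeModel()`: `path`, invisibly. `readModel()`: the restored
#'   \linkS4class{WorkloadModel}.
#' @export
writeModel <- function(model, path) {
  jsonlite::write_json(list(
    weights = model@weights, bias = model@bias, C = model@C,
    center = model@center, scale = model@scale,
    feature_names = model@featureNames,
    positive_class = model@positiveClass,
    cv_table = model@cvTable
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cv <- as.data.frame(j$cv_table)
  if (!nrow(cv)) cv <- data.frame(C = numeric(0), cv_accuracy = numeric(0))
  new(Class = "WorkloadModel",
      weights = as.numeric(j$weights), bias = as.numeric(j$bias),
      C = as.numeric(j$C), center = as.numeric(j$center),
      scale = as.numeric(j$scale),
      featureNames = as.character(j$feature_names %||% character(0)),
      positiveClass = j$positive_class, cvTable = cv)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
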
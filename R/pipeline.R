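#' Data-availability gap of the feature grid
#'
#' Time between the end of a trial's response window and the moment the
#' last sample needed by the feature grid becomes available. With the
#' default grid (largest offset 16 s + largest length 15 s = 31 s after
#' onset) and the default timing (11 s message + 18 s response = 29 s),
#' the full trial feature vector is available 2 s after the response
#' window closes — the on-line availability constraint of the classifier.
#'
#' @param grid a [windowGrid()].
#' @param message_dur_s,response_dur_s trial timing, seconds.
#' @return gap in seconds (positive = features lag the response window).
#' @examples
#' featureAvailabilityGap()  # 2
#' @export
featureAvailabilityGap <- function(grid = windowGrid(),
                                   message_dur_s = 11,
                                   response_dur_s = 18) {
  lastNeeded <- max(grid$offset_s + grid$length_s)
  lastNeeded - (message_dur_s + response_dur_s)
}

#' Run the full three-phase experiment on one session
#'
#' Orchestrates the complete inference pipeline on a recorded (or
#' simulated) session: stream-equivalent MACD filtering of every channel;
#' continuous crossover state estimation over the whole session, scored
#' against the ground-truth chronogram with onset/offset latency analysis;
#' then the three classifier phases — D: the first `nTrain` trials
#' (balanced by protocol) provide labeled features; L: regularization
#' selection by repeated stratified cross-validation and a final SVM fit;
#' T: the remaining trials are classified one at a time with the frozen
#' model (each trial's features are computable 2 s after its response
#' window under the default timing) and only then evaluated against their
#' labels.
#'
#' @param recording an unfiltered \linkS4class{FnirsRecording}.
#' @param schedule the session's \linkS4class{EventSchedule}.
#' @param truth optional ground-truth \linkS4class{Chronogram}; derived
#'   from the schedule when `NULL`.
#' @param nTrain number of phase-D trials (default 20; must be balanced).
#' @param species series used for state estimation (default `"hbo2"`).
#' @param cfg a [macdConfig()].
#' @param grid a [windowGrid()].
#' @param cGrid candidate SVM regularization values.
#' @param plan a [cvPlan()] for regularization selection.
#' @param warmup_s filter warm-up excluded from chronogram scoring,
#'   seconds.
#' @param seed seed echoed into the report (fold shuffles use
#'   `plan$seed`).
#' @return list of class `"SessionReport"`: `state_score`, `latency`,
#'   `selected_C`, `cv_table`, `wm` (phase-T accuracy/sensitivity/
#'   specificity, predictions, truth), `availability_gap_s`, `n_trials`,
#'   `seed`, `config`.
#' @export
runExperiment <- function(recording, schedule, truth = NULL,
                          nTrain = 20L, species = "hbo2",
                          cfg = macdConfig(), grid = windowGrid(),
                          cGrid = 10^(-5:1), plan = cvPlan(),
                          warmup_s = 18, seed = plan$seed) {
  tr <- trials(schedule)
  if (nrow(tr) < nTrain + 1L) {
    stop("schedule must contain more trials than the training phase")
  }
  # startup self-check: the feature grid must fit the segmented trial span
  gap <- featureAvailabilityGap(grid, tr$message_dur_s[1L],
                                tr$response_dur_s[1L])
  stopifnot(max(grid$offset_s + grid$length_s) <= 31)

  filt <- macdFilterRecording(recording, cfg)
  avg <- averageActiveChannels(filt, species)
  sig <- signalLine(avg, cfg)
  est <- detectCrossovers(avg, sig, fs = samplingRate(recording),
                          t0 = startTime(recording))
  if (is.null(truth)) {
    truth <- truthChronogram(schedule, length(states(est)),
                             fs = samplingRate(recording),
                             t0 = startTime(recording))
  }
  score <- scoreChronogram(est, truth, warmup_s = warmup_s)
  lat <- latencyAnalysis(est, schedule)

  fm <- featureMatrix(segmentTrials(filt, schedule), grid)
  dIdx <- seq_len(nTrain)
  yD <- fm$y[dIdx]
  if (sum(yD == "high") != sum(yD == "low")) {
    stop("phase-D trials must be load-balanced")
  }
  model <- trainWorkloadModel(fm$X[dIdx, , drop = FALSE], yD,
                              grid = cGrid, plan = plan)
  tIdx <- setdiff(seq_along(fm$y), dIdx)
  preds <- vapply(tIdx, function(i) classifyTrial(model, fm$X[i, ]),
                  character(1L))
  wm <- evaluateModel(model, fm$X[tIdx, , drop = FALSE], fm$y[tIdx])
  stopifnot(identical(unname(wm$predictions), unname(preds)))  # frozen model

  structure(list(
    state_score = score[c("accuracy", "sensitivity", "specificity",
                          "n_scored")],
    latency = lat[c("onset_latency_s", "offset_latency_s", "matched",
                    "unmatched_onsets")],
    latency_summary = lat$summary,
    selected_C = model@C,
    cv_table = model@cvTable,
    wm = wm,
    availability_gap_s = gap,
    n_trials = nrow(tr),
    seed = seed,
    config = list(nTrain = nTrain, species = species,
                  nShort = cfg$nShort, nLong = cfg$nLong,
                  nSignal = cfg$nSignal, warmup_s = warmup_s,
                  c_grid = cGrid, folds = plan$folds,
                  repeats = plan$repeats)
  ), class = "SessionReport")
}

#' @export
print.SessionReport <- function(x, ...) {
  cat("SessionReport (", x$n_trials, "trials, seed", x$seed, ")\n")
  cat(sprintf("  state estimation: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              100 * x$state_score$accuracy, 100 * x$state_score$sensitivity,
              100 * x$state_score$specificity))
  onl <- x$latency$onset_latency_s
  cat(sprintf("  onset latency: mean %+.2f s (%d matched, %d unmatched)\n",
              mean(onl, na.rm = TRUE), x$latency$matched,
              x$latency$unmatched_onsets))
  cat(sprintf("  workload classifier: C = %g, phase-T accuracy %.1f%% (sens %.1f%%, spec %.1f%%)\n",
              x$selected_C, 100 * x$wm$accuracy, 100 * x$wm$sensitivity,
              100 * x$wm$specificity))
  invisible(x)
}

#' Serialize a session report to JSON
#'
#' @param report a `"SessionReport"` (or the summary of
#'   [multiSubjectStudy()]).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path) {
  jsonlite::write_json(unclass(report), path, digits = NA,
                       auto_unbox = TRUE, dataframe = "columns",
                       na = "null")
  invisible(path)
}

#' Simulate and analyze a cohort of synthetic subjects
#'
#' Runs [simulateSession()] + [runExperiment()] for `n` independent
#' synthetic subjects (seeds `baseSeed + 1 .. baseSeed + n`) and tabulates
#' the per-subject metrics with a mean/SD summary, mirroring a cohort
#' analysis of per-participant classification accuracy.
#'
#' @param n number of subjects.
#' @param baseSeed base RNG seed; subject i uses `baseSeed + i`.
#' @param config a [simulationConfig()] used as a template; its seed is
#'   replaced per subject.
#' @param ... passed to [runExperiment()].
#' @return list with `per_subject` (data.frame: subject, seed, wm_accuracy,
#'   wm_sensitivity, wm_specificity, state_accuracy, state_sensitivity,
#'   state_specificity, selected_C, mean_onset_latency_s) and `summary`
#'   (data.frame of mean and SD per metric).
#' @export
multiSubjectStudy <- function(n, baseSeed = 0L,
                              config = simulationConfig(), ...) {
  stopifnot(n >= 1L)
  rows <- lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- baseSeed + i
    ses <- simulateSession(cfg)
    rep <- runExperiment(ses$recording, ses$schedule, truth = ses$truth,
                         plan = cvPlan(seed = baseSeed + i), ...)
    data.frame(
      subject = i, seed = cfg$seed,
      wm_accuracy = rep$wm$accuracy,
      wm_sensitivity = rep$wm$sensitivity,
      wm_specificity = rep$wm$specificity,
      state_accuracy = rep$state_score$accuracy,
      state_sensitivity = rep$state_score$sensitivity,
      state_specificity = rep$state_score$specificity,
      selected_C = rep$selected_C,
      mean_onset_latency_s = mean(rep$latency$onset_latency_s, na.rm = TRUE)
    )
  })
  per <- do.call(rbind, rows)
  mets <- setdiff(names(per), c("subject", "seed"))
  summ <- data.frame(
    metric = mets,
    mean = vapply(per[mets], mean, numeric(1L)),
    sd = vapply(per[mets], stats::sd, numeric(1L)),
    row.names = NULL
  )
  list(per_subject = per, summary = summ)
}
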
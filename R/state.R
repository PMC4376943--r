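#' Average MACD-filtered data over active channels
#'
#' The crossover state estimator operates on a single series obtained by
#' averaging the MACD-filtered data over the active channels. By default
#' only \eqn{\Delta[HbO_2]} is used (the species carrying the strongest
#' task effect); averaging over \eqn{\Delta[hHb]} or over both species is
#' available.
#'
#' @param rec a (MACD-filtered) \linkS4class{FnirsRecording}.
#' @param species `"hbo2"` (default), `"hhb"`, or `"both"`.
#' @return numeric series: per-sample arithmetic mean across active
#'   channels (and across species when `"both"`).
#' @export
averageActiveChannels <- function(rec, species = c("hbo2", "hhb", "both")) {
  species <- match.arg(species)
  if (nrow(rec) == 0L) stop("no active channels to average")
  switch(species,
    hbo2 = colMeans(hbo2(rec)),
    hhb = colMeans(hhb(rec)),
    both = colMeans(rbind(hbo2(rec), hhb(rec)))
  )
}

#' Estimate the on-task/not-on-task state from MACD crossovers
#'
#' Produces a state chronogram from the channel-averaged MACD series and
#' its signal line. A rise onset is declared when the MACD line crosses the
#' signal line from below — at sample \eqn{n \ge 1},
#' \eqn{d_{n-1} \le 0} and \eqn{d_n > 0} with \eqn{d = MACD - Signal} —
#' switching the state to on-task; a crossing from above
#' (\eqn{d_{n-1} \ge 0}, \eqn{d_n < 0}) switches to not-on-task. The state
#' holds between crossings; the initial state is not-on-task. Exact ties
#' (\eqn{d = 0}) never trigger a transition, so a flat degenerate signal
#' yields a deterministic all-not-on-task chronogram.
#'
#' @param macdAvg channel-averaged MACD series.
#' @param signal its signal line (same length).
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample, seconds.
#' @return a \linkS4class{Chronogram}.
#' @examples
#' d <- c(-1, -1, 1, 1, -1)
#' cg <- detectCrossovers(d, rep(0, 5))
#' states(cg)  # FALSE FALSE TRUE TRUE FALSE
#' @export
detectCrossovers <- function(macdAvg, signal, fs = 2.0, t0 = 0) {
  if (length(macdAvg) != length(signal)) {
    stop("macd and signal series must have equal length")
  }
  d <- macdAvg - signal
  n <- length(d)
  st <- logical(n)
  if (n >= 2L) {
    dp <- d[-n]; dn <- d[-1L]
    up <- dp <= 0 & dn > 0
    down <- dp >= 0 & dn < 0
    ev <- which(up | down)           # event at sample ev+1 (1-based)
    cur <- FALSE
    prev <- 1L
    for (e in ev) {
      st[prev:e] <- cur
      cur <- up[e]
      prev <- e + 1L
    }
    st[prev:n] <- cur
  }
  chronogram(st, fs = fs, t0 = t0)
}

#' Ground-truth chronogram from an event schedule
#'
#' The subject is considered on-task during message reception, i.e. during
#' \eqn{[onset, onset + message\_dur)} of each trial, and not-on-task
#' elsewhere (including response windows).
#'
#' @param schedule an \linkS4class{EventSchedule}.
#' @param nSamples chronogram length in samples.
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample, seconds.
#' @return a \linkS4class{Chronogram}.
#' @export
truthChronogram <- function(schedule, nSamples, fs = 2.0, t0 = 0) {
  st <- logical(nSamples)
  tr <- trials(schedule)
  for (i in seq_len(nrow(tr))) {
    a <- round((tr$onset_s[i] - t0) * fs)
    b <- round((tr$onset_s[i] + tr$message_dur_s[i] - t0) * fs)
    a <- max(a, 0L); b <- min(b, nSamples)
    if (b > a) st[(a + 1L):b] <- TRUE
  }
  chronogram(st, fs = fs, t0 = t0)
}

#' Score an estimated chronogram against ground truth
#'
#' Compares the estimate to the actual state at every sample. A sample is
#' labeled `Correct` when the states agree, `FalsePositive` when estimated
#' on-task but actually not-on-task, and `FalseNegative` when estimated
#' not-on-task but actually on-task. Accuracy is the fraction of correct
#' samples; sensitivity is the recall of the on-task state and specificity
#' the recall of the not-on-task state. Samples inside the filter warm-up
#' period are excluded from the tallies (but still labeled); the default
#' warm-up is `(nLong + nSignal)/fs` = 18 s at the default windows, and can
#' be set to 0 to score every sample.
#'
#' @param est,truth \linkS4class{Chronogram}s of equal length and rate.
#' @param warmup_s seconds to exclude from the start (default 18).
#' @return list of class `"StateScore"` with elements `accuracy`,
#'   `sensitivity`, `specificity`, `labels` (per-sample character), and
#'   `n_scored`.
#' @export
scoreChronogram <- function(est, truth, warmup_s = 18) {
  if (length(states(est)) != length(states(truth))) {
    stop("chronograms must have equal length")
  }
  if (samplingRate(est) != samplingRate(truth)) {
    stop("chronograms must have equal sampling rate")
  }
  e <- states(est); tr <- states(truth)
  labels <- ifelse(e == tr, "Correct",
                   ifelse(e & !tr, "FalsePositive", "FalseNegative"))
  skip <- round(warmup_s * samplingRate(est))
  keep <- seq_along(e) > skip
  e2 <- e[keep]; t2 <- tr[keep]
  tp <- sum(e2 & t2); tn <- sum(!e2 & !t2)
  fp <- sum(e2 & !t2); fn <- sum(!e2 & t2)
  structure(list(
    accuracy = (tp + tn) / length(e2),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    labels = labels,
    n_scored = length(e2)
  ), class = "StateScore")
}

#' @export
print.StateScore <- function(x, ...) {
  cat(sprintf(
    "StateScore over %d samples: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
    x$n_scored, 100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity
  ))
  invisible(x)
}

transitionTimes <- function(cg) {
  s <- states(cg)
  n <- length(s)
  if (n < 2L) return(list(on = numeric(0), off = numeric(0)))
  idx <- which(s[-1L] != s[-n]) + 1L   # sample where the new state starts
  tt <- startTime(cg) + (idx - 1L) / samplingRate(cg)
  list(on = tt[s[idx]], off = tt[!s[idx]])
}

#' Onset and offset latency of the state estimate
#'
#' For each trial, the estimated onset is the on-task transition nearest to
#' the true message onset within a pairing window (default
#' \eqn{[-10, +15]} s around the onset); its latency is the signed
#' difference estimated minus true (negative = the estimate precedes the
#' stimulus). The estimated offset is the first off-transition after the
#' matched onset, compared to the message offset. Trials with no on-task
#' transition inside the window are counted as unmatched.
#'
#' @param est estimated \linkS4class{Chronogram}.
#' @param schedule the \linkS4class{EventSchedule} ground truth.
#' @param window_s numeric length-2: pairing window around each onset,
#'   seconds (default `c(-10, 15)`).
#' @return list of class `"LatencyReport"`: `onset_latency_s` and
#'   `offset_latency_s` (per trial, `NA` when unmatched), `load`,
#'   `matched`, `unmatched_onsets`, and a `summary` data.frame of
#'   mean/SE/n overall and per load.
#' @export
latencyAnalysis <- function(est, schedule, window_s = c(-10, 15)) {
  tr <- trials(schedule)
  span_end <- startTime(est) + length(states(est)) / samplingRate(est)
  if (nrow(tr) && max(tr$onset_s + tr$message_dur_s) > span_end) {
    stop("schedule extends beyond the recording span")
  }
  tt <- transitionTimes(est)
  n <- nrow(tr)
  onL <- offL <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    o <- tr$onset_s[i]
    cand <- tt$on[tt$on >= o + window_s[1L] & tt$on <= o + window_s[2L]]
    if (length(cand)) {
      onMatch <- cand[which.min(abs(cand - o))]
      onL[i] <- onMatch - o
      offs <- tt$off[tt$off > onMatch]
      if (length(offs)) {
        offL[i] <- offs[1L] - (o + tr$message_dur_s[i])
      }
    }
  }
  sumrow <- function(v, lab) {
    v <- v[is.finite(v)]
    data.frame(group = lab, mean_s = mean(v),
               se_s = stats::sd(v) / sqrt(length(v)), n = length(v))
  }
  summ <- rbind(
    cbind(metric = "onset", rbind(
      sumrow(onL, "all"), sumrow(onL[tr$load == "low"], "low"),
      sumrow(onL[tr$load == "high"], "high")
    )),
    cbind(metric = "offset", rbind(
      sumrow(offL, "all"), sumrow(offL[tr$load == "low"], "low"),
      sumrow(offL[tr$load == "high"], "high")
    ))
  )
  structure(list(
    onset_latency_s = onL, offset_latency_s = offL, load = tr$load,
    matched = sum(is.finite(onL)), unmatched_onsets = sum(!is.finite(onL)),
    summary = summ
  ), class = "LatencyReport")
}

#' @export
print.LatencyReport <- function(x, ...) {
  cat(sprintf("LatencyReport: %d matched, %d unmatched trials\n",
              x$matched, x$unmatched_onsets))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Full crossover state estimation on a recording
#'
#' Convenience wrapper: MACD-filter the recording, average the chosen
#' species over active channels, compute the signal line, and detect
#' crossovers.
#'
#' @param rec an unfiltered \linkS4class{FnirsRecording}.
#' @param species series to average: `"hbo2"` (default), `"hhb"`, `"both"`.
#' @param cfg a [macdConfig()].
#' @return a \linkS4class{Chronogram}.
#' @export
estimateState <- function(rec, species = "hbo2", cfg = macdConfig()) {
  filt <- macdFilterRecording(rec, cfg)
  avg <- averageActiveChannels(filt, species)
  sig <- signalLine(avg, cfg)
  detectCrossovers(avg, sig, fs = samplingRate(rec), t0 = startTime(rec))
}
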
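#' The sliding-window grid
#'
#' The single-trial feature grid combines seven window offsets (10–16 s
#' after trial onset, 1 s apart) with three window lengths (5, 10, 15 s):
#' 21 windows per channel. Each window is \eqn{[offset, offset + length)}
#' seconds relative to the message onset, placing the grid over the
#' hemodynamic response that follows the ~11 s message.
#'
#' @param offsets_s window offsets in seconds.
#' @param lengths_s window lengths in seconds.
#' @return data.frame with columns `offset_s`, `length_s`, ordered offset
#'   ascending then length ascending.
#' @export
windowGrid <- function(offsets_s = 10:16, lengths_s = c(5, 10, 15)) {
  g <- expand.grid(length_s = lengths_s, offset_s = offsets_s)
  data.frame(offset_s = g$offset_s, length_s = g$length_s)
}

trialSpan <- c(-2, 31)  # seconds around onset; 66 samples at 2 Hz
baselineSamples <- function(fs) round(2 * fs)

#' Segment a filtered recording into trials
#'
#' Cuts the MACD-filtered session into per-trial blocks spanning
#' \eqn{[-2, +31)} s around each message onset (66 samples per channel per
#' species at 2 Hz). Sample indices are `round(t * fs)` with half-open
#' windows, exact at 2 Hz for integer and half-integer onset times. The
#' first 2 s form the pre-trial baseline.
#'
#' @param rec a MACD-filtered \linkS4class{FnirsRecording}.
#' @param schedule the \linkS4class{EventSchedule}.
#' @return list of \linkS4class{FnirsTrial} objects, one per trial.
#' @export
segmentTrials <- function(rec, schedule) {
  tr <- trials(schedule)
  fs <- samplingRate(rec)
  t0 <- startTime(rec)
  h <- hbo2(rec); d <- hhb(rec)
  n <- ncol(h)
  lapply(seq_len(nrow(tr)), function(i) {
    a <- round((tr$onset_s[i] + trialSpan[1L] - t0) * fs)  # 0-based start
    b <- round((tr$onset_s[i] + trialSpan[2L] - t0) * fs)  # 0-based end (excl)
    if (a < 0L || b > n) {
      stop(sprintf(
        "trial %d at onset %.1f s: span [%.1f, %.1f) s outside the recording",
        i, tr$onset_s[i], tr$onset_s[i] + trialSpan[1L],
        tr$onset_s[i] + trialSpan[2L]
      ))
    }
    idx <- (a + 1L):b
    new("FnirsTrial",
        hbo2 = h[, idx, drop = FALSE], hhb = d[, idx, drop = FALSE],
        load = tr$load[i], index = i, onset = tr$onset_s[i], fs = fs)
  })
}

# biased (population) moment statistics; zero-variance windows yield 0
# for the shape statistics so degenerate flat channels stay classifiable.
momentStats <- function(v) {
  m <- mean(v)
  c2 <- mean((v - m)^2)
  if (c2 <= 0) {
    return(c(skew = 0, kurt = 0, degenerate = 1))
  }
  c(skew = mean((v - m)^3) / c2^1.5,
    kurt = mean((v - m)^4) / c2^2 - 3,
    degenerate = 0)
}

#' Features of one sliding window on one channel
#'
#' For each species (\eqn{\Delta[HbO_2]}, \eqn{\Delta[hHb]}) the window
#' yields four statistics: the window mean; the baseline-referenced mean
#' amplitude \eqn{\bar{A}} (window mean minus the 2 s pre-onset baseline
#' mean); excess kurtosis; and skewness. Shape statistics use biased
#' (population) moment estimators, \eqn{m_3/m_2^{3/2}} and
#' \eqn{m_4/m_2^2 - 3}. A window with zero variance returns 0 for both
#' shape statistics, with a warning.
#'
#' @param trial a \linkS4class{FnirsTrial}.
#' @param offset_s,length_s the window, seconds relative to onset; the
#'   window must lie within \eqn{[0, 31)} s.
#' @param channel row index of the channel within the trial matrices.
#' @return named numeric of length 8:
#'   `mean_hbo2, mean_hhb, amp_hbo2, amp_hhb, kurt_hbo2, kurt_hhb,
#'   skew_hbo2, skew_hhb`.
#' @export
windowFeatures <- function(trial, offset_s, length_s, channel) {
  fs <- trial@fs
  if (offset_s < 0 || offset_s + length_s > trialSpan[2L]) {
    stop("window must lie within [0, 31) s after onset")
  }
  a <- round((offset_s - trialSpan[1L]) * fs)        # 0-based within trial
  b <- round((offset_s + length_s - trialSpan[1L]) * fs)
  idx <- (a + 1L):b
  nb <- baselineSamples(fs)
  out <- numeric(8)
  names(out) <- c("mean_hbo2", "mean_hhb", "amp_hbo2", "amp_hhb",
                  "kurt_hbo2", "kurt_hhb", "skew_hbo2", "skew_hhb")
  degen <- FALSE
  for (sp in c("hbo2", "hhb")) {
    m <- slot(trial, sp)
    v <- m[channel, idx]
    base <- mean(m[channel, seq_len(nb)])
    ms <- momentStats(v)
    degen <- degen || ms[["degenerate"]] > 0
    out[paste0("mean_", sp)] <- mean(v)
    out[paste0("amp_", sp)] <- mean(v) - base
    out[paste0("kurt_", sp)] <- ms[["kurt"]]
    out[paste0("skew_", sp)] <- ms[["skew"]]
  }
  if (degen) {
    warning(sprintf(
      "zero-variance window (offset %g s, length %g s, channel %d): shape statistics set to 0",
      offset_s, length_s, channel
    ), call. = FALSE)
  }
  out
}

#' Feature names in canonical order
#'
#' @param channels channel ids (montage order).
#' @param grid a [windowGrid()].
#' @return character vector, `ch<id>_off<o>_len<l>_<feature>`, ordered
#'   channel ascending, then offset ascending, then length ascending, then
#'   the 8 features.
#' @export
featureNames <- function(channels, grid = windowGrid()) {
  feats <- c("mean_hbo2", "mean_hhb", "amp_hbo2", "amp_hhb",
             "kurt_hbo2", "kurt_hhb", "skew_hbo2", "skew_hhb")
  unlist(lapply(channels, function(ch) {
    unlist(lapply(seq_len(nrow(grid)), function(w) {
      sprintf("ch%02d_off%02d_len%02d_%s",
              ch, grid$offset_s[w], grid$length_s[w], feats)
    }))
  }), use.names = FALSE)
}

#' The full single-trial predictor vector
#'
#' Concatenates the 8 window statistics over the 21-window grid and all
#' active channels, in the fixed order channel, then offset, then length,
#' then feature. With the default 14-channel montage this yields
#' \eqn{14 \times 21 \times 8 = 2352} predictors per trial (168 per
#' channel). The mapping is deterministic: identical trials give
#' bit-identical vectors.
#'
#' @param trial a \linkS4class{FnirsTrial}.
#' @param grid a [windowGrid()].
#' @param channels channel ids used for naming (defaults to the active
#'   channels of the 16-channel montage when the trial has 14 rows, else
#'   sequential ids).
#' @return named numeric vector of length `nrow(trial) * nrow(grid) * 8`.
#' @export
trialFeatures <- function(trial, grid = windowGrid(), channels = NULL) {
  nch <- nrow(trial@hbo2)
  if (is.null(channels)) {
    channels <- if (nch == 14L) activeChannels(channelMontage()) else seq_len(nch)
  }
  fs <- trial@fs
  nw <- nrow(grid)
  if (any(grid$offset_s < 0) ||
      any(grid$offset_s + grid$length_s > trialSpan[2L])) {
    stop("window must lie within [0, 31) s after onset")
  }
  idxList <- lapply(seq_len(nw), function(w) {
    a <- round((grid$offset_s[w] - trialSpan[1L]) * fs)
    b <- round((grid$offset_s[w] + grid$length_s[w] - trialSpan[1L]) * fs)
    (a + 1L):b
  })
  nb <- baselineSamples(fs)
  vals <- numeric(nch * nw * 8L)
  nDegen <- 0L
  pos <- 0L
  for (ch in seq_len(nch)) {
    vh <- trial@hbo2[ch, ]; vd <- trial@hhb[ch, ]
    bh <- mean(vh[seq_len(nb)]); bd <- mean(vd[seq_len(nb)])
    for (w in seq_len(nw)) {
      wh <- vh[idxList[[w]]]; wd <- vd[idxList[[w]]]
      sh <- momentStats(wh); sd_ <- momentStats(wd)
      nDegen <- nDegen + sh[["degenerate"]] + sd_[["degenerate"]]
      mh <- mean(wh); md <- mean(wd)
      vals[pos + 1L:8L] <- c(mh, md, mh - bh, md - bd,
                             sh[["kurt"]], sd_[["kurt"]],
                             sh[["skew"]], sd_[["skew"]])
      pos <- pos + 8L
    }
  }
  if (nDegen > 0L) {
    warning(sprintf(
      "%d zero-variance window(s): shape statistics set to 0", nDegen
    ), call. = FALSE)
  }
  names(vals) <- featureNames(channels, grid)
  vals
}

#' Feature matrix for a list of trials
#'
#' @param trialList list of \linkS4class{FnirsTrial} (from
#'   [segmentTrials()]).
#' @param grid a [windowGrid()].
#' @return list with `X` (trials x features matrix, named columns) and `y`
#'   (character load labels).
#' @export
featureMatrix <- function(trialList, grid = windowGrid()) {
  X <- t(vapply(trialList, trialFeatures,
                numeric(nrow(trialList[[1L]]@hbo2) * nrow(grid) * 8L),
                grid = grid))
  list(X = X, y = vapply(trialList, function(tr) tr@load, character(1L)))
}

#' Peak hemodynamic response of a trial
#'
#' The peak value within 30 s post-onset minus the 2 s pre-onset baseline
#' average, computed on MACD-filtered data. This is the summary used to
#' quantify load effects per channel.
#'
#' @param trial a \linkS4class{FnirsTrial}.
#' @param species `"hbo2"` or `"hhb"`.
#' @param channel row index of the channel (default: all channels,
#'   returning a vector).
#' @return numeric: peak response per requested channel.
#' @export
peakResponse <- function(trial, species = c("hbo2", "hhb"), channel = NULL) {
  species <- match.arg(species)
  m <- slot(trial, species)
  fs <- trial@fs
  nb <- baselineSamples(fs)
  a <- round((0 - trialSpan[1L]) * fs)              # onset sample, 0-based
  b <- round((30 - trialSpan[1L]) * fs) + 1L        # include t = 30 s sample
  b <- min(b, ncol(m))
  idx <- (a + 1L):b
  rows <- if (is.null(channel)) seq_len(nrow(m)) else channel
  vapply(rows, function(ch) {
    max(m[ch, idx]) - mean(m[ch, seq_len(nb)])
  }, numeric(1L))
}

#' Export a feature matrix as CSV
#'
#' @param fm a [featureMatrix()] result.
#' @param path file path.
#' @return `path`, invisibly. Columns: `trial`, `load`, then the ordered
#'   feature columns.
#' @export
writeFeatures <- function(fm, path) {
  df <- data.frame(trial = seq_len(nrow(fm$X)), load = fm$y,
                   fm$X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
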
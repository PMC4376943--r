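#' MACD filter configuration
#'
#' Window lengths, in samples at the device rate, of the MACD band-pass
#' filter and its signal line. The defaults — a 12-sample (6 s) short-term
#' EMA, a 26-sample (13 s) long-term EMA, and a 10-sample (5 s) signal-line
#' EMA at 2 Hz — give a pass band that removes slow drifts (< 0.02 Hz) and
#' fast physiological components (> 0.33 Hz) from the hemodynamic signal.
#' Sample counts are authoritative; the seconds labels are derived.
#'
#' @param nShort short-term EMA window, samples (default 12).
#' @param nLong long-term EMA window, samples (default 26); must exceed
#'   `nShort`.
#' @param nSignal signal-line EMA window, samples (default 10).
#' @param fs sampling rate in Hz (default 2).
#' @return named list of class `"MacdConfig"`.
#' @export
macdConfig <- function(nShort = 12L, nLong = 26L, nSignal = 10L, fs = 2.0) {
  nShort <- as.integer(nShort); nLong <- as.integer(nLong)
  nSignal <- as.integer(nSignal)
  if (nShort < 1L || nLong < 1L || nSignal < 1L) stop("window lengths must be >= 1")
  if (nShort >= nLong) stop("nShort must be < nLong")
  structure(list(nShort = nShort, nLong = nLong, nSignal = nSignal, fs = fs),
            class = "MacdConfig")
}

#' Streaming exponential moving average
#'
#' The EMA is the first-order recursion
#' \deqn{y_n = \frac{2}{N+1} x_n + \frac{N-1}{N+1} y_{n-1}}
#' with smoothing coefficient \eqn{\alpha = 2/(N+1)}. The filter is
#' warm-started: the first sample is passed through unchanged
#' (\eqn{y_0 = x_0}), so a constant input produces a constant output from
#' the very first sample and no startup transient is injected.
#'
#' `emaState()` creates the streaming state; `emaUpdate()` consumes one
#' sample and returns the updated state together with the output sample;
#' `emaFilter()` runs the same recursion over a whole series (bit-identical
#' to repeated `emaUpdate()` calls).
#'
#' @param N window length in samples (N >= 1; N = 1 is the identity filter).
#' @return `emaState()`: list with elements `N`, `alpha`, `y_prev`,
#'   `initialized`.
#' @examples
#' st <- emaState(12)
#' out <- emaUpdate(st, 1)   # warm start: y = x
#' out$y
#' emaFilter(c(1, 0, 0, 0), 12)  # impulse response (11/13)^n
#' @export
emaState <- function(N) {
  N <- as.integer(N)
  if (N < 1L) stop("N must be >= 1")
  list(N = N, alpha = 2 / (N + 1), y_prev = NA_real_, initialized = FALSE)
}

#' @rdname emaState
#' @param state an `emaState()` list.
#' @param x one finite sample value.
#' @return `emaUpdate()`: list with the updated `state` and the output
#'   sample `y`.
#' @export
emaUpdate <- function(state, x) {
  if (length(x) != 1L || !is.finite(x)) stop("non-finite input sample")
  if (!state$initialized) {
    state$y_prev <- x
    state$initialized <- TRUE
  } else {
    state$y_prev <- state$alpha * x + (1 - state$alpha) * state$y_prev
  }
  list(state = state, y = state$y_prev)
}

#' @rdname emaState
#' @param x,series numeric series.
#' @return `emaFilter()`: filtered series, same length as the input.
#' @export
emaFilter <- function(series, N) {
  if (length(series) == 0L) return(numeric(0))
  if (any(!is.finite(series))) stop("non-finite input sample")
  N <- as.integer(N)
  if (N < 1L) stop("N must be >= 1")
  if (N == 1L || length(series) == 1L) return(as.numeric(series))
  alpha <- 2 / (N + 1)
  # recursive y[n] = alpha*x[n] + (1-alpha)*y[n-1], warm start y[1] = x[1];
  # stats::filter applies the same double-precision update order as
  # emaUpdate, so batch and stream outputs are bit-identical.
  y <- stats::filter(alpha * series[-1L], 1 - alpha,
                     method = "recursive", init = series[1L])
  c(series[1L], as.numeric(y))
}

#' MACD band-pass filtering and the signal line
#'
#' The MACD (moving average convergence divergence) of a series is the
#' difference between a short-term and a long-term EMA,
#' \deqn{MACD_{N_s,N_l}(x) = EMA_{N_s}(x) - EMA_{N_l}(x),}
#' a low-order band-pass filter with quasi-linear phase in its pass band,
#' suited to real-time use. With the default windows at 2 Hz the pass band
#' spans roughly 0.02–0.33 Hz, which brackets task-evoked hemodynamic
#' responses while rejecting baseline drift and respiration/cardiac
#' components. The signal line is a further EMA of the MACD,
#' \deqn{Signal(x) = EMA_{10}(MACD(x)).}
#'
#' @param series numeric series (one channel, one species).
#' @param cfg a [macdConfig()].
#' @return filtered series, same length as input.
#' @examples
#' x <- sin(2 * pi * 0.1 * seq(0, 60, by = 0.5))
#' m <- macd(x)
#' s <- signalLine(m)
#' @export
macd <- function(series, cfg = macdConfig()) {
  emaFilter(series, cfg$nShort) - emaFilter(series, cfg$nLong)
}

#' @rdname macd
#' @param macdSeries a MACD-filtered series.
#' @export
signalLine <- function(macdSeries, cfg = macdConfig()) {
  emaFilter(macdSeries, cfg$nSignal)
}

#' Streaming MACD state
#'
#' `macdState()` creates a streaming MACD filter; `macdUpdate()` consumes
#' one sample; `streamFilter()` consumes a list of sample blocks (chunks)
#' and returns the concatenated filtered output, bit-identical to batch
#' [macd()] on the concatenated input regardless of chunk boundaries —
#' the property that makes the filter usable on a live acquisition stream.
#'
#' @param cfg a [macdConfig()].
#' @return `macdState()`: list with the two EMA states.
#' @examples
#' x <- rnorm(100)
#' chunks <- split(x, rep(1:10, each = 10))
#' identical(streamFilter(chunks), macd(x))
#' @export
macdState <- function(cfg = macdConfig()) {
  list(short = emaState(cfg$nShort), long = emaState(cfg$nLong), cfg = cfg)
}

#' @rdname macdState
#' @param state a `macdState()` list.
#' @param x one sample value.
#' @export
macdUpdate <- function(state, x) {
  s <- emaUpdate(state$short, x)
  l <- emaUpdate(state$long, x)
  state$short <- s$state
  state$long <- l$state
  list(state = state, y = s$y - l$y)
}

#' @rdname macdState
#' @param chunks list of numeric vectors whose concatenation is the input
#'   series; empty chunks are allowed and have no effect.
#' @param cfg a [macdConfig()].
#' @return `streamFilter()`: the MACD-filtered concatenated series.
#' @export
streamFilter <- function(chunks, cfg = macdConfig()) {
  state <- macdState(cfg)
  out <- vector("list", length(chunks))
  for (i in seq_along(chunks)) {
    chunk <- chunks[[i]]
    y <- numeric(length(chunk))
    for (j in seq_along(chunk)) {
      u <- macdUpdate(state, chunk[j])
      state <- u$state
      y[j] <- u$y
    }
    out[[i]] <- y
  }
  unlist(out, use.names = FALSE)
}

#' Apply MACD filtering to every channel of a recording
#'
#' Filters \eqn{\Delta[HbO_2]} and \eqn{\Delta[hHb]} independently on each
#' active channel, as done on-line during acquisition.
#'
#' @param rec a \linkS4class{FnirsRecording}.
#' @param cfg a [macdConfig()].
#' @return a \linkS4class{FnirsRecording} of MACD-filtered series.
#' @export
macdFilterRecording <- function(rec, cfg = macdConfig()) {
  f <- function(m) t(apply(m, 1L, macd, cfg = cfg))
  fnirsRecording(f(hbo2(rec)), f(hhb(rec)),
                 montage = rec@montage, fs = samplingRate(rec),
                 t0 = startTime(rec))
}

#' Numerical frequency response of the MACD filter
#'
#' Computes the magnitude response by FFT of a truncated impulse response,
#' used to verify the band-pass shape (pass band inside 0.02–0.33 Hz at
#' 2 Hz sampling with the default windows).
#'
#' @param cfg a [macdConfig()].
#' @param nImpulse length of the impulse response to evaluate (samples).
#' @return data.frame with columns `freq_hz` and `gain` (one-sided).
#' @export
macdFrequencyResponse <- function(cfg = macdConfig(), nImpulse = 8192L) {
  # warm start makes the filter affine in the first sample; the impulse
  # response of the underlying linear recursion is macd(delta) with the
  # delta placed after a long run of zeros (steady state reached).
  lead <- 64L
  x <- c(numeric(lead), 1, numeric(nImpulse - lead - 1L))
  h <- macd(x, cfg)[-seq_len(lead)]
  gain <- Mod(stats::fft(c(h, numeric(length(h)))))
  n <- length(gain)
  k <- seq_len(n %/% 2L)
  data.frame(freq_hz = (k - 1L) * cfg$fs / n, gain = gain[k])
}
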
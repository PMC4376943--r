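#' Synthetic session configuration
#'
#' Parameters of the synthetic fNIRS session generator. The generator
#' reproduces the study protocol — 40 trials (11 s spoken message + 18 s
#' response window), two working-memory load levels with a balanced first
#' half and no more than two equal loads in a row — and overlays
#' load-dependent canonical hemodynamic responses and physiological noise
#' on a 16-channel montage. All physiological constants are explicit,
#' overridable defaults: they place task-evoked energy inside the MACD
#' pass band and confounds outside or at its edges, and make no claim of
#' reproducing any particular subject.
#'
#' @param seed RNG seed; the session is bit-reproducible given the seed.
#' @param n_trials number of trials (even; default 40).
#' @param message_dur_s,response_dur_s message and response-window
#'   durations, seconds (defaults 11 and 18).
#' @param iti_s inter-trial interval range after the response window,
#'   seconds, drawn uniformly (default `c(10, 20)`).
#' @param first_onset_s onset of the first message, seconds (default 20).
#' @param hrf_peak_s,hrf_undershoot_s,hrf_ratio canonical double-gamma
#'   hemodynamic response: peak at ~6 s, undershoot at ~16 s, undershoot
#'   ratio 1/6.
#' @param amp_low,amp_high \eqn{\Delta[HbO_2]} response amplitude scale at
#'   the focus channel, \eqn{\mu}mol/L (defaults 0.5 and 1.0).
#' @param focus_channel channel of maximal response (default 15, over the
#'   right dorsolateral prefrontal cortex).
#' @param profile_scale_ch spatial decay constant of the response over
#'   channel distance (default 4 channels).
#' @param hhb_ratio,hhb_lag_s the \eqn{\Delta[hHb]} response is this
#'   (negative) multiple of the \eqn{\Delta[HbO_2]} response, delayed by
#'   this lag (defaults -1/3 and 1 s).
#' @param drift_slope slow linear drift amplitude, \eqn{\mu}mol/L per
#'   second, random sign per channel (default 0.001).
#' @param mayer_amp,mayer_freq Mayer-wave sine: 0.3 \eqn{\mu}mol/L at
#'   0.1 Hz.
#' @param resp_amp,resp_freq respiration sine: 0.2 \eqn{\mu}mol/L at
#'   0.25 Hz.
#' @param white_sd white measurement noise SD, \eqn{\mu}mol/L (default
#'   0.1).
#' @param fs sampling rate, Hz (default 2).
#' @return named list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(seed = 0L, n_trials = 40L,
                             message_dur_s = 11, response_dur_s = 18,
                             iti_s = c(10, 20), first_onset_s = 20,
                             hrf_peak_s = 6, hrf_undershoot_s = 16,
                             hrf_ratio = 1 / 6,
                             amp_low = 0.5, amp_high = 1.0,
                             focus_channel = 15L, profile_scale_ch = 4,
                             hhb_ratio = -1 / 3, hhb_lag_s = 1.0,
                             drift_slope = 0.001,
                             mayer_amp = 0.3, mayer_freq = 0.1,
                             resp_amp = 0.2, resp_freq = 0.25,
                             white_sd = 0.1, fs = 2.0) {
  if (n_trials %% 2L != 0L) stop("n_trials must be even")
  if (amp_low < 0 || amp_high < 0) stop("amplitudes must be >= 0")
  if (hhb_ratio > 0) stop("hhb_ratio must be <= 0")
  structure(as.list(environment()), class = "SimulationConfig")
}

validTrialOrder <- function(labels, halfTol = 0L) {
  n <- length(labels)
  nh <- sum(labels == "high")
  if (nh != n %/% 2L) return(FALSE)
  half <- n %/% 2L
  fh <- sum(labels[seq_len(half)] == "high")
  if (abs(fh - half / 2) > 0.5) return(FALSE)
  r <- rle(labels)
  all(r$lengths <= 2L)
}

#' Generate a constrained trial-load order
#'
#' Draws a load sequence satisfying the protocol constraints: equal counts
#' of the two loads overall, a balanced first half (exactly half each at
#' n = 40; to within one trial when the half is odd), and never more than
#' two equal loads in succession. Sampling is by rejection from balanced
#' random permutations, i.e. uniform over the valid set, and deterministic
#' per seed.
#'
#' @param n number of trials (even; default 40).
#' @param seed RNG seed.
#' @return character vector of `"low"`/`"high"`.
#' @export
generateTrialOrder <- function(n = 40L, seed = 0L) {
  n <- as.integer(n)
  if (n %% 2L != 0L) stop("n must be even")
  withSeed(seed, generateTrialOrderLocal(n))
}

#' Canonical double-gamma hemodynamic response kernel
#'
#' The canonical hemodynamic response function modeled as a difference of
#' two gamma densities: a positive lobe peaking near `peak_s` (~6 s) and a
#' later undershoot near `undershoot_s` (~16 s) scaled by `ratio` (1/6).
#' The kernel is zero at t = 0, normalized to a maximum of 1, and decays
#' to zero at large t.
#'
#' @param t time grid in seconds (t >= 0).
#' @param peak_s time-to-peak of the positive lobe (must be positive).
#' @param undershoot_s time-to-trough of the undershoot.
#' @param ratio undershoot amplitude relative to the peak lobe.
#' @return numeric kernel values on `t`.
#' @export
canonicalHrf <- function(t, peak_s = 6, undershoot_s = 16, ratio = 1 / 6) {
  if (peak_s <= 0) stop("peak time must be positive")
  # gamma density with rate 1 peaks at shape - 1
  h <- stats::dgamma(t, shape = peak_s + 1, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot_s + 1, rate = 1)
  h / max(h)
}

#' Simulate a complete synthetic fNIRS session
#'
#' Builds the trial schedule (first onset, then message + response + a
#' uniform inter-trial interval), a per-trial neural boxcar of the message
#' duration scaled by the load amplitude and a spatial profile decaying
#' exponentially with channel distance from the focus channel, convolves
#' it with the canonical double-gamma kernel (continuous-convolution
#' scaling, i.e. discrete convolution times \eqn{1/f_s}) to produce
#' \eqn{\Delta[HbO_2]}; \eqn{\Delta[hHb]} is a delayed, negatively scaled
#' copy. Physiological noise — slow linear drift, Mayer-wave and
#' respiration sines with random per-channel phase, and white noise — is
#' added per channel. All 16 montage channels are synthesized; the
#' excluded channels are masked by the returned recording.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `recording` (a \linkS4class{FnirsRecording}),
#'   `schedule` (an \linkS4class{EventSchedule}), and `truth` (the
#'   ground-truth \linkS4class{Chronogram}; on-task = message reception).
#' @examples
#' ses <- simulateSession(simulationConfig(seed = 1))
#' ses$recording
#' @export
simulateSession <- function(cfg = simulationConfig()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  withSeed(cfg$seed, {
    fs <- cfg$fs
    loads <- generateTrialOrderLocal(cfg$n_trials)
    iti <- stats::runif(cfg$n_trials, cfg$iti_s[1L], cfg$iti_s[2L])
    onsets <- numeric(cfg$n_trials)
    onsets[1L] <- cfg$first_onset_s
    stride <- cfg$message_dur_s + cfg$response_dur_s
    for (i in seq_len(cfg$n_trials - 1L)) {
      onsets[i + 1L] <- onsets[i] + stride + iti[i]
    }
    # round onsets to the sample grid so segmentation is exact
    onsets <- round(onsets * fs) / fs
    schedule <- eventSchedule(onsets, loads, cfg$message_dur_s,
                              cfg$response_dur_s)
    dur <- onsets[cfg$n_trials] + stride + 35   # tail for the last windows
    n <- round(dur * fs)
    tt <- (seq_len(n) - 1L) / fs

    # neural boxcar (load-amplitude scaled) and hemodynamic convolution
    box <- numeric(n)
    for (i in seq_len(cfg$n_trials)) {
      a <- round(onsets[i] * fs) + 1L
      b <- min(round((onsets[i] + cfg$message_dur_s) * fs), n)
      amp <- if (loads[i] == "high") cfg$amp_high else cfg$amp_low
      box[a:b] <- amp
    }
    kern <- canonicalHrf(seq(0, 32, by = 1 / fs),
                         cfg$hrf_peak_s, cfg$hrf_undershoot_s, cfg$hrf_ratio)
    resp <- convolveResponse(box, kern, fs)
    lag <- round(cfg$hhb_lag_s * fs)
    respHhb <- c(numeric(lag), resp)[seq_len(n)] * cfg$hhb_ratio

    nch <- 16L
    profile <- exp(-abs(seq_len(nch) - cfg$focus_channel) /
                     cfg$profile_scale_ch)
    hbo2 <- matrix(0, nch, n)
    hhb <- matrix(0, nch, n)
    for (ch in seq_len(nch)) {
      drift <- stats::runif(1, -1, 1) * cfg$drift_slope * tt
      ph1 <- stats::runif(1, 0, 2 * pi)
      ph2 <- stats::runif(1, 0, 2 * pi)
      mayer <- cfg$mayer_amp * sin(2 * pi * cfg$mayer_freq * tt + ph1)
      respir <- cfg$resp_amp * sin(2 * pi * cfg$resp_freq * tt + ph2)
      wn1 <- stats::rnorm(n, 0, cfg$white_sd)
      wn2 <- stats::rnorm(n, 0, cfg$white_sd)
      noise1 <- drift + mayer + respir + wn1
      noise2 <- 0.5 * (drift + mayer + respir) + wn2
      hbo2[ch, ] <- profile[ch] * resp + noise1
      hhb[ch, ] <- profile[ch] * respHhb + noise2
    }
    rec <- fnirsRecording(hbo2, hhb, montage = channelMontage(), fs = fs)
    truth <- truthChronogram(schedule, n, fs = fs)
    list(recording = rec, schedule = schedule, truth = truth)
  })
}

# trial order draw using the ambient RNG stream (already seeded by caller);
# rejection sampling from balanced permutations gives a uniform draw over
# the valid set.
generateTrialOrderLocal <- function(n) {
  base <- rep(c("low", "high"), each = n %/% 2L)
  repeat {
    labels <- sample(base)
    if (validTrialOrder(labels)) return(labels)
  }
}

# discrete convolution scaled by the sample period, approximating the
# continuous convolution of the boxcar with the kernel.
convolveResponse <- function(box, kern, fs) {
  full <- stats::convolve(box, rev(kern), type = "open")
  full[seq_along(box)] / fs
}
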
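#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
NULL

#' Channel montage of the 16-channel prefrontal fNIRS sensor
#'
#' Describes the probe layout of a continuous-wave prefrontal fNIRS device:
#' an ordered set of channel identifiers, the subset excluded from analysis,
#' and optional anatomical labels. On the default 16-channel montage,
#' channels 8 and 10 sit above the nasal sinus and are systematically
#' removed, leaving 14 active channels; channel 15 overlays the right
#' dorsolateral prefrontal cortex.
#'
#' @slot channelIds integer vector of channel identifiers, ordered as laid
#'   out on the probe (default \code{1:16}).
#' @slot excluded integer vector of excluded channel identifiers, a subset of
#'   \code{channelIds} (default \code{c(8L, 10L)}).
#' @slot labels optional character vector of per-channel anatomical labels,
#'   parallel to \code{channelIds}.
#'
#' @seealso [channelMontage()], [activeChannels()]
#' @export
setClass("ChannelMontage",
  representation(
    channelIds = "integer",
    excluded = "integer",
    labels = "character"
  )
)

setValidity("ChannelMontage", function(object) {
  msg <- character()
  if (length(object@channelIds) == 0L) {
    msg <- c(msg, "montage must contain at least one channel")
  }
  if (anyDuplicated(object@channelIds)) {
    msg <- c(msg, "channel ids must be unique")
  }
  if (!all(object@excluded %in% object@channelIds)) {
    msg <- c(msg, "excluded channels must be a subset of channel ids")
  }
  if (length(object@labels) > 0L &&
      length(object@labels) != length(object@channelIds)) {
    msg <- c(msg, "labels must be empty or one per channel")
  }
  if (length(object@channelIds) == length(object@excluded)) {
    msg <- c(msg, "at least one channel must remain active")
  }
  if (length(msg)) msg else TRUE
})

#' Multichannel fNIRS concentration recording
#'
#' Container for a session of per-channel oxygenated (\eqn{\Delta[HbO_2]})
#' and deoxygenated (\eqn{\Delta[hHb]}) hemoglobin concentration changes in
#' \eqn{\mu}mol/L, sampled at a fixed rate (2 Hz on the fNIR100 device).
#' Extends \linkS4class{SummarizedExperiment}: rows are active channels,
#' columns are samples, and the two species live in the \code{"hbo2"} and
#' \code{"hhb"} assays. Sample \eqn{i} (0-based) covers the time interval
#' \eqn{[i/f_s, (i+1)/f_s)} seconds from session start.
#'
#' @slot montage the \linkS4class{ChannelMontage}; excluded channels are not
#'   stored in the assays.
#' @slot fs sampling rate in Hz.
#' @slot t0 session start time in seconds (time of the first sample).
#'
#' @seealso [fnirsRecording()], [readRecording()], [macdFilterRecording()]
#' @export
setClass("FnirsRecording",
  contains = "SummarizedExperiment",
  representation(
    montage = "ChannelMontage",
    fs = "numeric",
    t0 = "numeric"
  )
)

setValidity("FnirsRecording", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("hbo2", "hhb") %in% an)) {
    msg <- c(msg, "assays 'hbo2' and 'hhb' are required")
  }
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0) {
    msg <- c(msg, "fs must be a single positive number")
  }
  if (length(object@t0) != 1L || !is.finite(object@t0)) {
    msg <- c(msg, "t0 must be a single finite number")
  }
  if (all(c("hbo2", "hhb") %in% an)) {
    if (anyNA(SummarizedExperiment::assay(object, "hbo2")) ||
        anyNA(SummarizedExperiment::assay(object, "hhb"))) {
      msg <- c(msg, "recordings must not contain NA samples")
    }
  }
  act <- setdiff(object@montage@channelIds, object@montage@excluded)
  if (nrow(object) != length(act)) {
    msg <- c(msg, sprintf(
      "recording has %d channel rows but montage has %d active channels",
      nrow(object), length(act)
    ))
  }
  if (length(msg)) msg else TRUE
})

#' Trial event schedule
#'
#' Ground-truth timing of an air-traffic-control instruction session: one row
#' per trial with the message onset (seconds from session start), message and
#' response-window durations, and the working-memory load label. The default
#' protocol is 40 trials of an 11 s spoken message followed by an 18 s
#' response window, with load \code{"low"} or \code{"high"}.
#'
#' @slot trials data.frame with columns \code{onset_s},
#'   \code{message_dur_s}, \code{response_dur_s}, \code{load}.
#'
#' @seealso [eventSchedule()], [readEvents()], [truthChronogram()]
#' @export
setClass("EventSchedule", representation(trials = "data.frame"))

setValidity("EventSchedule", function(object) {
  tr <- object@trials
  need <- c("onset_s", "message_dur_s", "response_dur_s", "load")
  if (!all(need %in% names(tr))) {
    return(paste("trials must have columns", paste(need, collapse = ", ")))
  }
  msg <- character()
  if (!all(tr$load %in% c("low", "high"))) {
    msg <- c(msg, "unknown load label (must be 'low' or 'high')")
  }
  if (nrow(tr) > 0L) {
    if (any(!is.finite(tr$onset_s)) || any(tr$onset_s < 2)) {
      msg <- c(msg, "trial onsets must be finite and >= 2 s (baseline required)")
    }
    if (any(tr$message_dur_s <= 0) || any(tr$response_dur_s <= 0)) {
      msg <- c(msg, "durations must be positive")
    }
    if (nrow(tr) > 1L) {
      if (any(diff(tr$onset_s) <= 0)) {
        msg <- c(msg, "trial onsets must be strictly increasing")
      }
      ends <- tr$onset_s + tr$message_dur_s + tr$response_dur_s
      if (any(tr$onset_s[-1L] < ends[-nrow(tr)])) {
        msg <- c(msg, "trial windows must not overlap")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Per-sample binary state time course (chronogram)
#'
#' A chronogram is the per-sample boolean time course of a binary mental
#' state: \code{TRUE} = on-task (receiving an instruction), \code{FALSE} =
#' not-on-task. Chronograms are produced both as ground truth from an
#' [EventSchedule-class] and as real-time estimates from MACD/signal-line
#' crossovers.
#'
#' @slot states logical vector, one element per sample.
#' @slot fs sampling rate in Hz.
#' @slot t0 time of the first sample in seconds.
#'
#' @seealso [detectCrossovers()], [truthChronogram()], [scoreChronogram()]
#' @export
setClass("Chronogram",
  representation(states = "logical", fs = "numeric", t0 = "numeric")
)

setValidity("Chronogram", function(object) {
  msg <- character()
  if (anyNA(object@states)) msg <- c(msg, "states must not contain NA")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0) {
    msg <- c(msg, "fs must be a single positive number")
  }
  if (length(object@t0) != 1L || !is.finite(object@t0)) {
    msg <- c(msg, "t0 must be a single finite number")
  }
  if (length(msg)) msg else TRUE
})

#' One segmented trial of MACD-filtered fNIRS data
#'
#' Per-channel \eqn{\Delta[HbO_2]} and \eqn{\Delta[hHb]} samples spanning
#' \eqn{[-2, +31)} s around one trial onset (66 samples per channel per
#' species at 2 Hz). The first 4 samples (2 s) form the pre-trial baseline
#' used to reference amplitude features and the peak response.
#'
#' @slot hbo2 numeric matrix, channels x samples.
#' @slot hhb numeric matrix, channels x samples.
#' @slot load \code{"low"} or \code{"high"}.
#' @slot index trial number within the session (1-based).
#' @slot onset trial onset in seconds from session start.
#' @slot fs sampling rate in Hz.
#'
#' @seealso [segmentTrials()], [trialFeatures()], [peakResponse()]
#' @export
setClass("FnirsTrial",
  representation(
    hbo2 = "matrix", hhb = "matrix",
    load = "character", index = "integer",
    onset = "numeric", fs = "numeric"
  )
)

setValidity("FnirsTrial", function(object) {
  msg <- character()
  if (!identical(dim(object@hbo2), dim(object@hhb))) {
    msg <- c(msg, "hbo2 and hhb must have identical dimensions")
  }
  if (!object@load %in% c("low", "high")) {
    msg <- c(msg, "load must be 'low' or 'high'")
  }
  if (length(msg)) msg else TRUE
})

#' Per-subject linear working-memory load classifier
#'
#' A frozen linear decision rule trained on one subject's labeled trials:
#' z-scored features (training-set center/scale), a weight per feature, a
#' bias, and the selected regularization value C. The positive class is
#' \code{"high"} working-memory load; a decision value of exactly 0
#' classifies as \code{"high"}.
#'
#' @slot weights numeric, one weight per feature (on the z-scored scale).
#' @slot bias scalar intercept.
#' @slot C the selected SVM regularization value.
#' @slot center,scale per-feature training-set standardization constants
#'   (scale is 1 where the training variance is 0).
#' @slot featureNames feature names in model order.
#' @slot positiveClass the label mapped to positive decision values
#'   (\code{"high"}).
#' @slot cvTable data.frame of mean cross-validation accuracy per candidate
#'   C (empty when C was fixed by the caller).
#'
#' @seealso [trainWorkloadModel()], [classifyTrial()], [writeModel()]
#' @export
setClass("WorkloadModel",
  representation(
    weights = "numeric", bias = "numeric", C = "numeric",
    center = "numeric", scale = "numeric",
    featureNames = "character", positiveClass = "character",
    cvTable = "data.frame"
  )
)

setValidity("WorkloadModel", function(object) {
  msg <- character()
  p <- length(object@weights)
  if (length(object@center) != p || length(object@scale) != p) {
    msg <- c(msg, "center/scale must match weight length")
  }
  if (any(object@scale <= 0)) msg <- c(msg, "scale entries must be positive")
  if (length(object@bias) != 1L || !is.finite(object@bias)) {
    msg <- c(msg, "bias must be a single finite number")
  }
  if (!identical(object@positiveClass, "high")) {
    msg <- c(msg, "positive class must be 'high'")
  }
  if (length(msg)) msg else TRUE
})
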
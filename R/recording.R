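#' Construct a channel montage
#'
#' @param channelIds integer channel identifiers in probe order.
#' @param excluded integer identifiers of channels removed from analysis.
#'   The default removes channels 8 and 10, which sit above the nasal sinus
#'   on the 16-channel prefrontal montage and are prone to acquisition
#'   artifacts.
#' @param labels optional character vector of anatomical labels, one per
#'   channel (e.g. channel 15 = right dorsolateral prefrontal cortex).
#'
#' @return A \linkS4class{ChannelMontage}.
#' @examples
#' m <- channelMontage()
#' activeChannels(m)  # 14 channels: 1:16 without 8 and 10
#' @export
channelMontage <- function(channelIds = 1:16, excluded = c(8L, 10L),
                           labels = character()) {
  new("ChannelMontage",
    channelIds = as.integer(channelIds),
    excluded = as.integer(excluded),
    labels = as.character(labels)
  )
}

#' @rdname channelMontage
#' @param x a \linkS4class{ChannelMontage} or \linkS4class{FnirsRecording}.
#' @return `activeChannels()`: the retained channel ids, in montage order.
#' @export
setMethod("activeChannels", "ChannelMontage", function(x) {
  x@channelIds[!x@channelIds %in% x@excluded]
})

#' @rdname channelMontage
#' @export
setMethod("activeChannels", "FnirsRecording", function(x) {
  activeChannels(x@montage)
})

setMethod("show", "ChannelMontage", function(object) {
  cat("ChannelMontage with", length(object@channelIds), "channels,",
      length(activeChannels(object)), "active\n")
  if (length(object@excluded)) {
    cat("  excluded:", paste(object@excluded, collapse = ", "), "\n")
  }
})

#' Construct an fNIRS concentration recording
#'
#' Builds a \linkS4class{FnirsRecording} from per-channel concentration
#' matrices. Rows correspond to the montage's active channels in montage
#' order; excluded channels (if present in the input, identified by row
#' order over the full montage) are dropped.
#'
#' @param hbo2,hhb numeric matrices of concentration changes in
#'   \eqn{\mu}mol/L, channels x samples. Either one row per active channel,
#'   or one row per montage channel (in which case excluded channels are
#'   masked out).
#' @param montage a \linkS4class{ChannelMontage}.
#' @param fs sampling rate in Hz (2.0 for the fNIR100 device).
#' @param t0 time of the first sample, seconds.
#'
#' @return A \linkS4class{FnirsRecording}.
#' @examples
#' m <- channelMontage()
#' x <- matrix(0, nrow = 16, ncol = 10)
#' rec <- fnirsRecording(x, x, montage = m)
#' nrow(rec)  # 14 active channels
#' @export
fnirsRecording <- function(hbo2, hhb, montage = channelMontage(),
                           fs = 2.0, t0 = 0) {
  hbo2 <- as.matrix(hbo2)
  hhb <- as.matrix(hhb)
  if (!identical(dim(hbo2), dim(hhb))) {
    stop("hbo2 and hhb must have identical dimensions")
  }
  act <- activeChannels(montage)
  if (nrow(hbo2) == length(montage@channelIds) &&
      length(montage@excluded) > 0L &&
      nrow(hbo2) != length(act)) {
    keep <- !montage@channelIds %in% montage@excluded
    hbo2 <- hbo2[keep, , drop = FALSE]
    hhb <- hhb[keep, , drop = FALSE]
  }
  if (nrow(hbo2) != length(act)) {
    stop(sprintf(
      "expected %d (active) or %d (full montage) channel rows, got %d",
      length(act), length(montage@channelIds), nrow(hbo2)
    ))
  }
  rownames(hbo2) <- rownames(hhb) <- sprintf("ch%02d", act)
  se <- SummarizedExperiment(
    assays = list(hbo2 = hbo2, hhb = hhb),
    rowData = S4Vectors::DataFrame(channel = act)
  )
  new("FnirsRecording", se, montage = montage, fs = fs, t0 = t0)
}

#' Recording accessors
#'
#' @param x a \linkS4class{FnirsRecording} or \linkS4class{Chronogram}.
#' @return `samplingRate()`: sampling rate in Hz. `startTime()`: time of the
#'   first sample in seconds.
#' @name samplingRate
#' @examples
#' rec <- fnirsRecording(matrix(0, 16, 4), matrix(0, 16, 4))
#' samplingRate(rec)
#' timePoints(rec)
NULL

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "FnirsRecording", function(x) x@fs)

#' @rdname samplingRate
#' @export
setMethod("startTime", "FnirsRecording", function(x) x@t0)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "Chronogram", function(x) x@fs)

#' @rdname samplingRate
#' @export
setMethod("startTime", "Chronogram", function(x) x@t0)

#' Concentration assays
#'
#' @param x a \linkS4class{FnirsRecording}.
#' @return numeric matrix (active channels x samples) of
#'   \eqn{\Delta[HbO_2]} (`hbo2`) or \eqn{\Delta[hHb]} (`hhb`) in
#'   \eqn{\mu}mol/L.
#' @name hbo2
NULL

#' @rdname hbo2
#' @export
setMethod("hbo2", "FnirsRecording", function(x) assay(x, "hbo2"))

#' @rdname hbo2
#' @export
setMethod("hhb", "FnirsRecording", function(x) assay(x, "hhb"))

#' @rdname samplingRate
#' @export
timePoints <- function(x) {
  n <- if (is(x, "Chronogram")) length(x@states) else ncol(x)
  startTime(x) + (seq_len(n) - 1L) / samplingRate(x)
}

setMethod("show", "FnirsRecording", function(object) {
  cat("FnirsRecording:", nrow(object), "active channels x",
      ncol(object), "samples @", object@fs, "Hz ",
      sprintf("(%.1f s)\n", ncol(object) / object@fs))
  cat("  excluded channels:",
      paste(object@montage@excluded, collapse = ", "), "\n")
})

#' Construct an event schedule
#'
#' @param onset_s numeric vector of trial onsets, seconds from session
#'   start; must be strictly increasing and at least 2 s (a 2 s pre-trial
#'   baseline must exist).
#' @param load character vector of load labels, \code{"low"} or
#'   \code{"high"}.
#' @param message_dur_s spoken-message duration per trial, seconds
#'   (default 11).
#' @param response_dur_s response-window duration per trial, seconds
#'   (default 18).
#'
#' @return An \linkS4class{EventSchedule}.
#' @examples
#' sched <- eventSchedule(c(20, 70), c("low", "high"))
#' trials(sched)
#' @export
eventSchedule <- function(onset_s, load, message_dur_s = 11,
                          response_dur_s = 18) {
  n <- length(onset_s)
  new("EventSchedule", trials = data.frame(
    onset_s = as.numeric(onset_s),
    message_dur_s = rep_len(as.numeric(message_dur_s), n),
    response_dur_s = rep_len(as.numeric(response_dur_s), n),
    load = as.character(load)
  ))
}

#' @rdname eventSchedule
#' @param x an \linkS4class{EventSchedule}.
#' @return `trials()`: the trial table as a data.frame.
#' @export
setMethod("trials", "EventSchedule", function(x) x@trials)

setMethod("show", "EventSchedule", function(object) {
  tr <- object@trials
  cat("EventSchedule with", nrow(tr), "trials (",
      sum(tr$load == "low"), "low /", sum(tr$load == "high"), "high )\n")
  if (nrow(tr)) {
    cat(sprintf("  onsets %.1f .. %.1f s\n",
                tr$onset_s[1L], tr$onset_s[nrow(tr)]))
  }
})

#' Chronogram construction and accessors
#'
#' @param states logical vector, \code{TRUE} = on-task.
#' @param fs sampling rate in Hz.
#' @param t0 time of the first sample, seconds.
#' @param x a \linkS4class{Chronogram}.
#' @return `chronogram()`: a \linkS4class{Chronogram}. `states()`: the
#'   logical state vector.
#' @name Chronogram-utils
#' @examples
#' cg <- chronogram(c(FALSE, TRUE, TRUE), fs = 2)
#' states(cg)
NULL

#' @rdname Chronogram-utils
#' @export
chronogram <- function(states, fs = 2.0, t0 = 0) {
  new("Chronogram", states = as.logical(states), fs = fs, t0 = t0)
}

#' @rdname Chronogram-utils
#' @export
setMethod("states", "Chronogram", function(x) x@states)

setMethod("show", "Chronogram", function(object) {
  n <- length(object@states)
  cat("Chronogram:", n, "samples @", object@fs, "Hz,",
      sprintf("%.1f%% on-task\n", 100 * mean(object@states)))
})

setMethod("show", "FnirsTrial", function(object) {
  cat(sprintf("FnirsTrial #%d (%s load): %d channels x %d samples, onset %.1f s\n",
              object@index, object@load, nrow(object@hbo2),
              ncol(object@hbo2), object@onset))
})

setMethod("show", "WorkloadModel", function(object) {
  cat("WorkloadModel:", length(object@weights), "features, C =",
      format(object@C), "\n")
  cat("  positive class:", object@positiveClass, "\n")
  if (nrow(object@cvTable)) {
    cat(sprintf("  best mean CV accuracy: %.3f\n",
                max(object@cvTable$cv_accuracy)))
  }
})

# shared RNG helper: run expr with a locally seeded RNG, restoring the
# caller's RNG state afterwards so package functions never perturb it.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}
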
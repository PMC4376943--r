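#' @rdname samplingRate
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname samplingRate
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))

#' @rdname hbo2
#' @export
setGeneric("hbo2", function(x) standardGeneric("hbo2"))

#' @rdname hbo2
#' @export
setGeneric("hhb", function(x) standardGeneric("hhb"))

#' @rdname channelMontage
#' @export
setGeneric("activeChannels", function(x) standardGeneric("activeChannels"))

#' @rdname Chronogram-utils
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' @rdname eventSchedule
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))
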
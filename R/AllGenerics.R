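# Generics for the package's S4 classes (collated first).

#' @rdname frameRate
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' @rdname frameRate
#' @export
setGeneric("neuronIds", function(x) standardGeneric("neuronIds"))

#' @rdname frameRate
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname frameRate
#' @export
setGeneric("durationMinutes", function(x) standardGeneric("durationMinutes"))

#' @rdname frameRate
#' @export
setGeneric("recordingSession", function(x) standardGeneric("recordingSession"))

#' @rdname frameRate
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname frameRate
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))
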
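#' Population calcium recording
#'
#' A neuron x frame fluorescence matrix with acquisition metadata, stored as
#' a [SummarizedExperiment::SummarizedExperiment] whose single assay holds
#' raw fluorescence (`"fluor"`) or \eqn{\Delta F/F} (`"dff"`). Rows are
#' neurons (unique ids as rownames); columns are frames. Metadata carries the
#' frame rate (Hz), the session descriptor (`animal_id`, `group`,
#' `timepoint`) and the signal kind.
#'
#' @seealso [computeDFF()], [detectTransients()], [simulateRecording()]
#' @export
setClass("PopulationRecording", contains = "SummarizedExperiment")

setValidity("PopulationRecording", function(object) {
  fr <- metadata(object)$frame_rate
  if (is.null(fr) || !is.numeric(fr) || length(fr) != 1L || fr <= 0)
    return("metadata(.)$frame_rate must be a positive scalar (Hz)")
  m <- assay(object)
  if (!all(is.finite(m))) return("fluorescence matrix must be finite")
  ids <- rownames(object)
  if (is.null(ids) || anyDuplicated(ids))
    return("neuron ids (rownames) must be present and unique")
  TRUE
})

#' Construct a PopulationRecording
#'
#' @param mat numeric neuron x frame matrix.
#' @param frameRate sampling rate in Hz.
#' @param neuronIds character ids, defaults to existing rownames or `n1..nK`.
#' @param session list with `animal_id`, `group`, `timepoint` (free-form).
#' @param signal `"raw"` fluorescence or `"dff"`.
#' @return A [PopulationRecording-class].
#' @examples
#' rec <- PopulationRecording(matrix(100, 3, 10), frameRate = 1.1)
#' frameRate(rec)
#' @export
PopulationRecording <- function(mat, frameRate, neuronIds = NULL,
                                session = list(), signal = c("raw", "dff")) {
  signal <- match.arg(signal)
  mat <- as.matrix(mat)
  if (is.null(neuronIds))
    neuronIds <- rownames(mat)
  if (is.null(neuronIds))
    neuronIds <- paste0("n", seq_len(nrow(mat)))
  rownames(mat) <- as.character(neuronIds)
  colnames(mat) <- NULL
  se <- SummarizedExperiment(
    assays = setNames(list(mat), if (signal == "raw") "fluor" else "dff"),
    metadata = list(frame_rate = frameRate, session = session,
                    signal = signal))
  new("PopulationRecording", se)
}

#' Binary neuron x frame activity raster
#'
#' Output of [detectTransients()]: a `SummarizedExperiment` whose `"active"`
#' assay is 0/1, with the per-neuron robust noise scale and threshold in
#' `rowData` and the detection parameters in `metadata`.
#'
#' @export
setClass("ActivityRaster", contains = "SummarizedExperiment")

setValidity("ActivityRaster", function(object) {
  m <- assay(object)
  if (!all(m %in% c(0, 1))) return("raster entries must be 0/1")
  fr <- metadata(object)$frame_rate
  if (is.null(fr) || fr <= 0) return("frame_rate metadata required")
  TRUE
})


#' Accessors for recordings, rasters and event sets
#'
#' `frameRate()` returns the sampling rate in Hz, `neuronIds()` the stable
#' neuron identifiers, `nFrames()` the number of frames,
#' `durationMinutes()` the recording duration `nFrames / frameRate / 60`, and
#' `recordingSession()` the session descriptor list.
#'
#' @param x A [PopulationRecording-class], [ActivityRaster-class] or
#'   [NetworkEventSet-class].
#' @return Scalar or vector as described.
#' @examples
#' rec <- PopulationRecording(matrix(100, 2, 5), frameRate = 1.1)
#' durationMinutes(rec)
#' @name frameRate
NULL

setMethod("frameRate", "SummarizedExperiment",
          function(x) metadata(x)$frame_rate)


setMethod("neuronIds", "SummarizedExperiment", function(x) rownames(x))


setMethod("nFrames", "SummarizedExperiment", function(x) ncol(x))


setMethod("durationMinutes", "SummarizedExperiment",
          function(x) ncol(x) / metadata(x)$frame_rate / 60)


setMethod("recordingSession", "SummarizedExperiment",
          function(x) metadata(x)$session)

setMethod("show", "PopulationRecording", function(object) {
  s <- metadata(object)$session
  cat(sprintf(
    "PopulationRecording (%s): %d neurons x %d frames @ %.2f Hz (%.2f min)\n",
    metadata(object)$signal, nrow(object), ncol(object),
    frameRate(object), durationMinutes(object)))
  if (length(s))
    cat("  session:", paste(names(s), unlist(s), sep = "=", collapse = ", "),
        "\n")
})

setMethod("show", "ActivityRaster", function(object) {
  cat(sprintf(
    "ActivityRaster: %d neurons x %d frames, %.1f%% active frames\n",
    nrow(object), ncol(object), 100 * mean(assay(object))))
  p <- metadata(object)$params
  if (!is.null(p))
    cat(sprintf("  threshold: k=%g, minFrames=%d%s\n", p$k, p$minFrames,
                if (isTRUE(p$floor_used)) " (absolute floor fallback)" else ""))
})
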
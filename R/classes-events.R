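#' A set of detected synchronous network events
#'
#' Events are maximal intervals during which the fraction of co-active
#' neurons stays at or above the synchrony threshold. Frames are 0-based and
#' intervals half-open `[onset, offset)`; `duration = (offset - onset) /`
#' frame rate. Each event carries its participant set (neurons active during
#' at least one frame of the event) and peak co-active fraction.
#'
#' @slot events A [S4Vectors::DataFrame] with columns `onset`, `offset`,
#'   `duration`, `peakFraction` and a list-column `participants`.
#' @slot frameRate numeric, Hz.
#' @slot nFrames integer, frames in the source recording.
#' @slot neuronIds character, neurons of the source recording.
#' @slot theta numeric, synchrony threshold used.
#' @slot params list, detection parameters (minFrames, mergeGap, null settings).
#' @seealso [detectNetworkEvents()], [networkMetrics()]
#' @export
setClass("NetworkEventSet",
  representation(
    events = "DataFrame",
    frameRate = "numeric",
    nFrames = "integer",
    neuronIds = "character",
    theta = "numeric",
    params = "list"
  )
)

setValidity("NetworkEventSet", function(object) {
  ev <- object@events
  req <- c("onset", "offset", "duration", "peakFraction", "participants")
  if (!all(req %in% colnames(ev)))
    return(paste("events must have columns", paste(req, collapse = ", ")))
  if (nrow(ev) > 0L) {
    if (any(ev$offset <= ev$onset)) return("offset must exceed onset")
    if (nrow(ev) > 1L && any(ev$onset[-1L] < ev$offset[-nrow(ev)]))
      return("events must be sorted and disjoint")
    if (!all(unlist(ev$participants) %in% object@neuronIds))
      return("participants must be neurons of the recording")
    if (any(abs(ev$duration - (ev$offset - ev$onset) / object@frameRate) >
              1e-9))
      return("duration must equal (offset - onset) / frameRate")
  }
  TRUE
})


#' @rdname frameRate
#' @export
setMethod("nEvents", "NetworkEventSet", function(x) nrow(x@events))

setMethod("frameRate", "NetworkEventSet", function(x) x@frameRate)
setMethod("nFrames", "NetworkEventSet", function(x) x@nFrames)
setMethod("neuronIds", "NetworkEventSet", function(x) x@neuronIds)


#' @describeIn NetworkEventSet-class events as a base data.frame with
#'   `participants` as a list-column.
#' @param x A `NetworkEventSet`.
#' @export
setMethod("eventTable", "NetworkEventSet", function(x) {
  df <- as.data.frame(x@events[, c("onset", "offset", "duration",
                                   "peakFraction")])
  df$participants <- as.list(x@events$participants)
  df
})

setMethod("show", "NetworkEventSet", function(object) {
  cat(sprintf(
    "NetworkEventSet: %d events over %d frames @ %.2f Hz (theta = %.3f)\n",
    nrow(object@events), object@nFrames, object@frameRate, object@theta))
  if (nrow(object@events) > 0L)
    cat(sprintf("  mean duration %.2f s, mean participants %.1f of %d neurons\n",
                mean(object@events$duration),
                mean(lengths(object@events$participants)),
                length(object@neuronIds)))
})

#' Cluster-robust Cox proportional-hazards fit
#'
#' Result of [coxClustered()]: a single binary group covariate fitted by
#' maximum partial likelihood (Efron tie handling) with a cluster-robust
#' sandwich variance over grouped score residuals (by default carrying the
#' finite-cluster G/(G-1) correction). `hr = exp(logHr)`,
#' `z = logHr / robustSe`, `ci95 = exp(logHr +/- critValue * robustSe)`
#' with `critValue` the 97.5% t(G-1) quantile under the default correction
#' (1.96 otherwise).
#'
#' @slot logHr,hr,robustSe,modelSe,z,p,critValue numeric scalars.
#' @slot ci95 numeric length-2, 95% confidence interval on the HR scale.
#' @slot nClusters,nEvents,n integer counts.
#' @slot groups character, reference and treated group labels.
#' @export
setClass("CoxFit",
  representation(
    logHr = "numeric", hr = "numeric", robustSe = "numeric",
    modelSe = "numeric", ci95 = "numeric", z = "numeric", p = "numeric",
    critValue = "numeric",
    nClusters = "integer", nEvents = "integer", n = "integer",
    groups = "character"
  )
)

setValidity("CoxFit", function(object) {
  if (abs(object@hr - exp(object@logHr)) > 1e-8 * max(1, object@hr))
    return("hr must equal exp(logHr)")
  if (length(object@ci95) != 2L) return("ci95 must have length 2")
  TRUE
})

#' @describeIn CoxFit-class hazard ratio (treated vs reference).
#' @param fit A `CoxFit`.
#' @export
hazardRatio <- function(fit) fit@hr

#' @describeIn CoxFit-class log hazard ratio.
#' @export
logHazardRatio <- function(fit) fit@logHr

#' @describeIn CoxFit-class cluster-robust standard error of the log HR.
#' @export
robustSe <- function(fit) fit@robustSe

#' @describeIn CoxFit-class 95% CI on the hazard-ratio scale.
#' @export
confint95 <- function(fit) fit@ci95

setMethod("show", "CoxFit", function(object) {
  cat(sprintf(
    "Clustered Cox fit (%s vs %s): HR %.3f (95%% CI %.2f-%.2f)\n",
    object@groups[2L], object@groups[1L], object@hr, object@ci95[1L],
    object@ci95[2L]))
  cat(sprintf("  robust SE %.3f, z = %.2f, p = %.3g; %d events, %d clusters\n",
              object@robustSe, object@z, object@p, object@nEvents,
              object@nClusters))
})
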
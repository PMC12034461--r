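# Synchronous network-event detection and population metrics.

#' Fraction of co-active neurons per frame
#'
#' @param raster An [ActivityRaster-class].
#' @return Numeric vector of length `nFrames(raster)`: active neurons
#'   divided by total neurons at each frame.
#' @examples
#' r <- detectTransients(PopulationRecording(
#'   matrix(rnorm(100, 0, 0.05), 2), frameRate = 1.1, signal = "dff"))
#' coactiveFraction(r)[1:5]
#' @export
coactiveFraction <- function(raster) {
  stopifnot(is(raster, "ActivityRaster"))
  if (nrow(raster) == 0L) nq_stop("raster has zero neurons")
  colMeans(assay(raster))
}

#' Data-driven synchrony threshold from a circular-shuffle null
#'
#' Each neuron's active-frame train is independently circularly shifted by a
#' random offset, destroying cross-neuron synchrony while preserving every
#' neuron's activity statistics; the threshold is the `1 - alpha` quantile
#' of the pooled shuffled co-active-fraction distribution, with an absolute
#' floor. Seeded and reproducible.
#'
#' @param raster An [ActivityRaster-class].
#' @param nShuffles number of shuffles; values below 100 trigger a warning.
#' @param alpha upper tail probability; default 0.01 (99th percentile).
#' @param floor absolute lower bound on the returned threshold; default 0.1.
#' @param seed integer seed.
#' @return Scalar threshold theta in [0, 1].
#' @examples
#' r <- detectTransients(PopulationRecording(
#'   matrix(rnorm(500, 0, 0.05), 5), frameRate = 1.1, signal = "dff"))
#' shuffleThreshold(r, nShuffles = 100, seed = 1)
#' @export
shuffleThreshold <- function(raster, nShuffles = 1000L, alpha = 0.01,
                             floor = 0.1, seed = NULL) {
  stopifnot(is(raster, "ActivityRaster"))
  nShuffles <- assert_count(nShuffles, "nShuffles")
  if (nShuffles < 100L)
    nq_warn("nShuffles = %d is below 100; the null quantile will be unstable",
            nShuffles)
  assert_scalar_num(alpha, "alpha", 0, 1, strict_lower = TRUE)
  m <- assay(raster)
  nN <- nrow(m); nF <- ncol(m)
  if (nN == 0L) nq_stop("raster has zero neurons")
  frames <- lapply(seq_len(nN), function(i) which(m[i, ] == 1L) - 1L)
  maybe_with_seed(seed, {
    off <- matrix(sample.int(nF, nN * nShuffles, replace = TRUE) - 1L,
                  nN, nShuffles)
    counts <- shuffle_counts_cpp(frames, nF, off)
    theta <- quantile(as.vector(counts) / nN, 1 - alpha, names = FALSE,
                      type = 7)
    max(theta, floor)
  })
}

#' Detect synchronous network events
#'
#' Maximal runs of frames whose co-active fraction is at least `theta`;
#' runs separated by at most `mergeGap` frames are merged, then runs
#' shorter than `minFrames` are dropped. Onsets/offsets are 0-based,
#' half-open. An event's participants are the neurons active during at
#' least one of its frames.
#'
#' @param raster An [ActivityRaster-class].
#' @param theta synchrony threshold in (0, 1]; typically from
#'   [shuffleThreshold()].
#' @param minFrames minimum event length in frames; default 2.
#' @param mergeGap maximum separating gap (frames) merged; default 1.
#' @return A [NetworkEventSet-class].
#' @examples
#' m <- matrix(0L, 4, 30); m[, 11:15] <- 1L
#' r <- new("ActivityRaster", SummarizedExperiment::SummarizedExperiment(
#'   assays = list(active = m), metadata = list(frame_rate = 1.1)))
#' detectNetworkEvents(r, theta = 0.2)
#' @export
detectNetworkEvents <- function(raster, theta, minFrames = 2L,
                                mergeGap = 1L) {
  stopifnot(is(raster, "ActivityRaster"))
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta > 1)
    nq_stop("theta must be in (0, 1]")
  minFrames <- assert_count(minFrames, "minFrames")
  mergeGap <- assert_count(mergeGap, "mergeGap", min = 0L)
  frac <- coactiveFraction(raster)
  fr <- frameRate(raster)
  runs <- logical_runs(frac >= theta)
  if (nrow(runs) > 0L) {
    runs <- merge_runs(runs, mergeGap)
    runs <- runs[runs[, 2L] - runs[, 1L] >= minFrames, , drop = FALSE]
  }
  m <- assay(raster)
  ids <- rownames(m)
  n <- nrow(runs)
  participants <- vector("list", n)
  peak <- numeric(n)
  for (e in seq_len(n)) {
    idx <- (runs[e, 1L] + 1L):runs[e, 2L]
    participants[[e]] <- ids[rowSums(m[, idx, drop = FALSE]) > 0]
    peak[e] <- max(frac[idx])
  }
  ev <- DataFrame(
    onset = as.integer(runs[, 1L]), offset = as.integer(runs[, 2L]),
    duration = (runs[, 2L] - runs[, 1L]) / fr,
    peakFraction = peak)
  ev$participants <- participants
  new("NetworkEventSet",
      events = ev, frameRate = fr, nFrames = ncol(m),
      neuronIds = ids, theta = theta,
      params = list(minFrames = minFrames, mergeGap = mergeGap))
}

#' Per-animal network activity metrics
#'
#' Event frequency is `n_events / (n_frames / frame_rate / 60)` (events per
#' minute); mean event duration is in seconds; network activation is the
#' average proportion of co-active cells per network event (mean over events
#' of participants / total neurons). With zero events the frequency is 0 and
#' duration/activation are reported as missing, not zero.
#'
#' @param events A [NetworkEventSet-class].
#' @return A one-row data.frame: `n_events`, `event_frequency`,
#'   `mean_event_duration`, `network_activation`.
#' @examples
#' m <- matrix(0L, 4, 30); m[, 11:15] <- 1L
#' r <- new("ActivityRaster", SummarizedExperiment::SummarizedExperiment(
#'   assays = list(active = m), metadata = list(frame_rate = 1.1)))
#' networkMetrics(detectNetworkEvents(r, theta = 0.2))
#' @export
networkMetrics <- function(events) {
  stopifnot(is(events, "NetworkEventSet"))
  minutes <- events@nFrames / events@frameRate / 60
  n <- nEvents(events)
  if (n == 0L) {
    return(data.frame(n_events = 0L, event_frequency = 0,
                      mean_event_duration = NA_real_,
                      network_activation = NA_real_))
  }
  nN <- length(events@neuronIds)
  data.frame(
    n_events = n,
    event_frequency = n / minutes,
    mean_event_duration = mean(events@events$duration),
    network_activation = mean(lengths(events@events$participants) / nN))
}

#' Neuronal network participation
#'
#' The fraction of a recording's network events in which each neuron was
#' active. With zero events the participation is missing for every neuron
#' at that timepoint (such neurons are excluded listwise from the
#' mixed-effects stage).
#'
#' @param events A [NetworkEventSet-class].
#' @param neuron optional single neuron id; default all neurons.
#' @return Named numeric vector of participation fractions in [0, 1] (or a
#'   single value when `neuron` is given).
#' @examples
#' m <- matrix(0L, 4, 30); m[, 11:15] <- 1L; m[1, 21:25] <- 1L; m[2, 21:25] <- 1L
#' r <- new("ActivityRaster", SummarizedExperiment::SummarizedExperiment(
#'   assays = list(active = m), metadata = list(frame_rate = 1.1)))
#' neuronalParticipation(detectNetworkEvents(r, theta = 0.2))
#' @export
neuronalParticipation <- function(events, neuron = NULL) {
  stopifnot(is(events, "NetworkEventSet"))
  ids <- events@neuronIds
  n <- nEvents(events)
  if (n == 0L) {
    out <- setNames(rep(NA_real_, length(ids)), ids)
  } else {
    counts <- table(factor(unlist(events@events$participants),
                           levels = ids))
    out <- setNames(as.numeric(counts) / n, ids)
  }
  if (!is.null(neuron)) {
    if (!neuron %in% ids) nq_stop("unknown neuron id '%s'", neuron)
    return(out[[neuron]])
  }
  out
}
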
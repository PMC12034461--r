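# Fluorescence normalisation and per-neuron activity rasterisation.

# rolling percentile with edge-clipped windows; window is the full width in
# frames, centred on each frame
rolling_percentile <- function(x, window, prob) {
  rolling_percentile_cpp(as.numeric(x), as.integer(window), prob)
}

#' Convert raw fluorescence to \eqn{\Delta F/F}
#'
#' Per neuron, the baseline F0 is a rolling percentile of the raw trace
#' (window clipped at the recording edges) and the output is
#' \eqn{(F - F_0)/F_0}. Deterministic; invariant to multiplying a raw trace
#' by a positive constant. Neurons whose trace is all zero (no signal, F0 of
#' zero) are excluded with a warning rather than propagating NaNs; their ids
#' are recorded in `metadata(.)$excluded_neurons`.
#'
#' @param rec A raw-fluorescence [PopulationRecording-class].
#' @param baselinePercentile percentile (0-100) used for F0; default 20.
#' @param baselineWindowSec rolling window width in seconds; default 60.
#' @return A [PopulationRecording-class] with signal `"dff"`; the baseline
#'   parameters are stored in `metadata(.)$dff_params`.
#' @examples
#' rec <- PopulationRecording(matrix(c(10, 10, 20, 10), 1), frameRate = 1.1)
#' assay(computeDFF(rec))
#' @export
computeDFF <- function(rec, baselinePercentile = 20, baselineWindowSec = 60) {
  stopifnot(is(rec, "PopulationRecording"))
  if (identical(metadata(rec)$signal, "dff"))
    nq_stop("recording is already dF/F")
  assert_scalar_num(baselinePercentile, "baselinePercentile", 0, 100)
  assert_scalar_num(baselineWindowSec, "baselineWindowSec", 0,
                    strict_lower = TRUE)
  m <- assay(rec)
  fr <- frameRate(rec)
  window <- max(1L, as.integer(round(baselineWindowSec * fr)))
  zero <- apply(m, 1L, function(x) all(x == 0))
  if (any(zero)) {
    nq_warn("excluding %d all-zero neuron(s): %s", sum(zero),
            paste(rownames(m)[zero], collapse = ", "))
    m <- m[!zero, , drop = FALSE]
  }
  if (nrow(m) == 0L) nq_stop("no usable neurons after exclusion")
  prob <- baselinePercentile / 100
  dff <- t(apply(m, 1L, function(x) {
    f0 <- rolling_percentile(x, window, prob)
    if (any(f0 <= 0))
      nq_stop("non-positive baseline F0; raw intensities must be positive over the baseline fraction")
    (x - f0) / f0
  }))
  out <- PopulationRecording(dff, frameRate = fr,
                             neuronIds = rownames(m),
                             session = recordingSession(rec),
                             signal = "dff")
  metadata(out)$dff_params <- list(baseline_percentile = baselinePercentile,
                                   baseline_window_sec = baselineWindowSec,
                                   baseline_window_frames = window)
  metadata(out)$excluded_neurons <- rownames(assay(rec))[zero]
  out
}

#' Detect calcium transients and build the activity raster
#'
#' Per neuron, the noise scale \eqn{\sigma} is estimated robustly as the
#' median absolute deviation scaled to a Gaussian SD; frames whose
#' \eqn{\Delta F/F} is strictly greater than \eqn{k\sigma}, in runs of at
#' least `minFrames` consecutive frames, are marked active. Neurons whose
#' estimated \eqn{\sigma} is zero (noiseless synthetic input) fall back to
#' an absolute \eqn{\Delta F/F} floor, with a message.
#'
#' Raising `k` can never add active frames (raster monotone in `k`).
#'
#' @param dff A dF/F [PopulationRecording-class] from [computeDFF()].
#' @param k threshold in robust-noise units; default 3.
#' @param minFrames minimum run length in frames; default 2 (about 1.8 s at
#'   1.1 Hz).
#' @param floorDff absolute dF/F threshold used when \eqn{\sigma = 0}.
#' @return An [ActivityRaster-class]; per-neuron `sigma` and `threshold` are
#'   in `rowData`, parameters in `metadata(.)$params`.
#' @examples
#' rec <- PopulationRecording(matrix(rnorm(200, 0, 0.05), 2),
#'                            frameRate = 1.1, signal = "dff")
#' detectTransients(rec)
#' @export
detectTransients <- function(dff, k = 3, minFrames = 2L, floorDff = 0.05) {
  stopifnot(is(dff, "PopulationRecording"))
  if (!identical(metadata(dff)$signal, "dff"))
    nq_stop("input must be dF/F (run computeDFF first)")
  assert_scalar_num(k, "k", 0, strict_lower = TRUE)
  minFrames <- assert_count(minFrames, "minFrames")
  m <- assay(dff)
  sigma <- apply(m, 1L, mad)   # MAD scaled to Gaussian sigma
  floor_used <- sigma == 0
  if (any(floor_used))
    message(sprintf(
      "detectTransients: sigma = 0 for %d neuron(s); absolute floor %.3g used",
      sum(floor_used), floorDff))
  threshold <- ifelse(floor_used, floorDff, k * sigma)
  act <- matrix(0L, nrow(m), ncol(m), dimnames = list(rownames(m), NULL))
  for (i in seq_len(nrow(m))) {
    above <- m[i, ] > threshold[i]     # strict: ties are inactive
    runs <- logical_runs(above)
    runs <- runs[runs[, 2L] - runs[, 1L] >= minFrames, , drop = FALSE]
    for (r in seq_len(nrow(runs)))
      act[i, (runs[r, 1L] + 1L):runs[r, 2L]] <- 1L
  }
  se <- SummarizedExperiment(
    assays = list(active = act),
    rowData = DataFrame(sigma = sigma, threshold = threshold,
                        floor_used = floor_used),
    metadata = list(frame_rate = frameRate(dff),
                    session = recordingSession(dff),
                    params = list(k = k, minFrames = minFrames,
                                  floorDff = floorDff,
                                  floor_used = any(floor_used))))
  new("ActivityRaster", se)
}
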
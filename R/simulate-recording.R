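# Forward simulation of population calcium recordings.
#
# The generator draws a stationary alternating-renewal process of network
# events (gamma durations, exponential-plus-refractory gaps), assigns
# participants by per-neuron Bernoulli draws, places spikes, convolves with
# a double-exponential indicator kernel and adds Gaussian noise on top of a
# constant baseline fluorescence.

# discrete indicator kernel sampled at frame midpoints, normalised so a
# single spike of amplitude a peaks near a in dF/F units
indicator_kernel <- function(rise, decay, frameRate, tol = 0.01,
                             maxLen = 200L) {
  dt <- 1 / frameRate
  kfun <- function(t) (1 - exp(-t / rise)) * exp(-t / decay)
  tpeak <- rise * log(1 + decay / rise)
  kmax <- kfun(tpeak)
  j <- 0:(maxLen - 1L)
  h <- kfun((j + 0.5) * dt) / kmax
  keep <- seq_len(max(which(h >= tol)))
  h[keep]
}

# Predict the effective per-frame detection threshold the default analysis
# applies to the true dF/F signal. Two systematic effects are modelled (see
# vignette): the MAD noise estimate is inflated by the signal duty cycle,
# and the rolling-percentile baseline sits below the true baseline by the
# corresponding noise quantile, shifting computed dF/F up. Both follow from
# the mixture distribution of signal and noise frames and are solved
# numerically; `duty` is the predicted fraction of elevated frames.
effective_threshold <- function(noiseSd, duty, k_detect = 3,
                                baselinePercentile = 20, floorDff = 0.05) {
  if (noiseSd <= 0) return(floorDff)
  q <- min(max(duty, 0), 0.4)
  # median of the (1-q) noise + q high-signal mixture, in sigma units
  m <- qnorm(0.5 / (1 - q))
  # MAD: signal frames all lie far above, so they only displace quantiles
  f <- function(u) (1 - q) * (pnorm(m + u) - pnorm(m - u)) - 0.5
  u <- stats::uniroot(f, c(1e-6, 10))$root
  sigma_hat <- 1.4826 * u * noiseSd
  # rolling baseline percentile of the same mixture (noise quantile shift)
  offset <- -qnorm(min(baselinePercentile / 100 / (1 - q), 0.499)) * noiseSd
  max(k_detect * sigma_hat - offset, 0.5 * noiseSd)
}

# noiseless dF/F footprint (frames above threshold) of a burst driving
# `W` consecutive frames at the mean spike amplitude
burst_footprint <- function(W, h, amplitude, theta_eff, maxLen = 400L) {
  drive <- c(rep(amplitude, W), rep(0, length(h) + 20L))
  resp <- numeric(length(drive))
  for (j in seq_along(h)) {
    idx <- seq_len(length(drive) - j + 1L)
    resp[idx + j - 1L] <- resp[idx + j - 1L] + h[j] * drive[idx]
  }
  sum(resp > theta_eff)
}

# lookup of the driving-window length needed so the observable footprint
# matches each target event length (frames); the configured duration refers
# to the co-activity footprint, so the forward model inverts the indicator
# dynamics (see vignette)
driving_window_table <- function(spec, k_detect = 3, baselinePercentile = 20,
                                 floorDff = 0.05, maxFrames = 200L) {
  h <- indicator_kernel(spec@kernelRise, spec@kernelDecay, spec@frameRate)
  # two-pass fixed point: duty cycle needs the footprint, which needs the
  # threshold, which needs the duty cycle
  fp_s <- spec@eventDurationMean
  duty <- 0
  for (pass in 1:2) {
    duty <- (spec@eventRate * spec@participationMean * fp_s +
               spec@backgroundRate * max(fp_s / 2, 1)) / 60
    theta_eff <- effective_threshold(spec@noiseSd, duty, k_detect,
                                     baselinePercentile, floorDff)
    fp1 <- burst_footprint(1L, h, spec@spikeAmplitude, theta_eff)
    fp_s <- max(spec@eventDurationMean, fp1 / spec@frameRate)
  }
  # smallest driving window whose footprint reaches each target length
  maxW <- max(2L, as.integer(ceiling(maxFrames)))
  fp <- vapply(seq_len(maxW), burst_footprint, integer(1L), h = h,
               amplitude = spec@spikeAmplitude, theta_eff = theta_eff)
  fp <- cummax(fp)
  W_for <- function(L) {
    w <- which(fp >= L)
    if (length(w)) w[1L] else maxW
  }
  list(W_for_length = vapply(seq_len(maxFrames), W_for, integer(1L)),
       theta_eff = theta_eff, footprint = fp)
}

# timepoint multipliers for a given group; the control group is always 1
schedule_multipliers <- function(spec, timepoint, group) {
  sched <- spec@timepointSchedule
  row <- match(timepoint, sched$timepoint)
  if (is.na(row))
    nq_stop("timepoint '%s' is not in the schedule (%s)", timepoint,
            paste(sched$timepoint, collapse = ", "))
  if (identical(group, spec@groupLabels[2L])) {
    list(rate = sched$rate[row], duration = sched$duration[row],
         participation = sched$participation[row])
  } else {
    list(rate = 1, duration = 1, participation = 1)
  }
}

# stationary alternating-renewal event times over [0, T) seconds;
# gap = minGap + Exp(expMean), duration ~ gamma(shape, mean durMean)
draw_event_times <- function(T, rate_s, durMean, shape, minGap) {
  if (rate_s <= 0) return(matrix(numeric(), ncol = 2L))
  cycle <- 1 / rate_s
  gapMean <- cycle - durMean
  if (gapMean <= minGap)
    nq_stop(paste("event rate %.3g/s with mean duration %.3g s leaves no",
                  "room for the %.3g s minimum gap"),
            rate_s, durMean, minGap)
  expMean <- gapMean - minGap
  scale <- durMean / shape
  t0 <- numeric(); t1 <- numeric()
  # stationary initial condition: start inside an event with the duty-cycle
  # probability, using length-biased residual durations
  if (runif(1) < durMean / cycle) {
    Dlb <- rgamma(1, shape + 1, scale = scale)
    start <- 0; end <- runif(1) * Dlb
  } else {
    # equilibrium residual of the gap distribution: uniform over the
    # refractory part, memoryless over the exponential tail
    r <- if (runif(1) < minGap / gapMean) runif(1) * minGap
         else minGap + rexp(1, 1 / expMean)
    start <- r; end <- r + rgamma(1, shape, scale = scale)
  }
  while (start < T) {
    t0 <- c(t0, start); t1 <- c(t1, end)
    start <- end + minGap + rexp(1, 1 / expMean)
    end <- start + rgamma(1, shape, scale = scale)
  }
  cbind(t0, t1)
}

#' Simulate one population calcium recording with ground truth
#'
#' Draws synchronous network events as a stationary renewal process at the
#' (timepoint- and group-adjusted) configured rate, gamma-distributed event
#' durations, and per-neuron participation probabilities from a beta
#' distribution. Participating neurons fire a burst spanning the event;
#' asynchronous background transients are added per neuron; spikes are
#' convolved with a double-exponential GCaMP kernel and Gaussian noise is
#' added to a constant baseline fluorescence.
#'
#' The configured event duration refers to the observable co-activity
#' footprint: the spike-driving window is shortened by the predicted
#' indicator decay-to-threshold time so that the detected duration estimates
#' the configured one (see the methods vignette).
#'
#' @param spec A [CohortSpec-class].
#' @param timepoint label present in the spec's timepoint schedule.
#' @param group group label; multipliers apply to the injured group only.
#' @param animalId identifier stored in the session metadata.
#' @param nNeurons optional neuron count; default drawn from the spec range.
#' @param seed integer seed (default `spec@seed`); identical (spec, seed)
#'   reproduce the output exactly.
#' @return A list with elements `recording` ([PopulationRecording-class],
#'   raw fluorescence) and `truth` ([GroundTruthLog-class]).
#' @examples
#' sim <- simulateRecording(CohortSpec(nFrames = 120L), seed = 7)
#' sim$recording
#' @export
simulateRecording <- function(spec, timepoint = "baseline",
                              group = spec@groupLabels[1L],
                              animalId = "a1", nNeurons = NULL,
                              seed = spec@seed) {
  validObject(spec)
  if (spec@nFrames < 1L || spec@frameRate <= 0)
    nq_stop("invalid spec: non-positive frame count or rate")
  mult <- schedule_multipliers(spec, timepoint, group)
  maybe_with_seed(seed, {
    nNeurons <- if (is.null(nNeurons)) {
      spec@neuronsRange[1L] +
        sample.int(spec@neuronsRange[2L] - spec@neuronsRange[1L] + 1L, 1L) - 1L
    } else as.integer(nNeurons)
    fr <- spec@frameRate
    nF <- spec@nFrames
    T_s <- nF / fr
    ids <- paste0("n", seq_len(nNeurons))

    rate_s <- spec@eventRate * mult$rate / 60
    durMean <- spec@eventDurationMean * mult$duration
    times <- draw_event_times(T_s, rate_s, durMean,
                              spec@eventDurationShape, spec@minEventGap)

    # frame-quantised, clipped, non-overlapping half-open intervals
    iv <- matrix(integer(), ncol = 2L,
                 dimnames = list(NULL, c("onset", "offset")))
    if (nrow(times) > 0L) {
      onset <- pmax(0L, as.integer(round(times[, 1L] * fr)))
      len <- pmax(1L, as.integer(round((times[, 2L] - times[, 1L]) * fr)))
      offset <- onset + len
      keep <- onset < nF
      onset <- onset[keep]; offset <- pmin(offset[keep], nF)
      if (length(onset)) {
        for (i in seq_along(onset)[-1L]) {
          if (onset[i] < offset[i - 1L]) onset[i] <- offset[i - 1L]
        }
        ok <- offset > onset
        iv <- cbind(onset = onset[ok], offset = offset[ok])
      }
    }

    # per-neuron participation probabilities
    mu <- min(1, spec@participationMean * mult$participation)
    p <- if (mu >= 1) rep(1, nNeurons) else {
      phi <- spec@participationDispersion
      rbeta(nNeurons, mu * phi, (1 - mu) * phi)
    }

    nEv <- nrow(iv)
    participants <- vector("list", nEv)
    wtab <- driving_window_table(spec)
    spikes <- vector("list", nNeurons)  # 0-based frames
    amps <- vector("list", nNeurons)
    meanlog <- log(spec@spikeAmplitude) - spec@amplitudeSdlog^2 / 2
    for (e in seq_len(nEv)) {
      member <- runif(nNeurons) < p
      participants[[e]] <- ids[member]
      len <- iv[e, 2L] - iv[e, 1L]
      W <- min(wtab$W_for_length[min(len, length(wtab$W_for_length))], len)
      drive <- iv[e, 1L] + seq_len(W) - 1L
      for (i in which(member)) {
        spikes[[i]] <- c(spikes[[i]], drive)
      }
    }
    # background transients
    if (spec@backgroundRate > 0) {
      nbg <- rpois(nNeurons, spec@backgroundRate * T_s / 60)
      for (i in seq_len(nNeurons)) {
        if (nbg[i] > 0L)
          spikes[[i]] <- c(spikes[[i]], sample.int(nF, nbg[i],
                                                   replace = TRUE) - 1L)
      }
    }
    for (i in seq_len(nNeurons)) {
      if (length(spikes[[i]])) {
        spikes[[i]] <- sort(spikes[[i]])
        amps[[i]] <- if (spec@amplitudeSdlog > 0)
          rlnorm(length(spikes[[i]]), meanlog, spec@amplitudeSdlog)
        else rep(spec@spikeAmplitude, length(spikes[[i]]))
      } else {
        spikes[[i]] <- integer()
        amps[[i]] <- numeric()
      }
    }

    # spike train -> dF/F by discrete convolution
    S <- matrix(0, nNeurons, nF)
    for (i in seq_len(nNeurons)) {
      if (length(spikes[[i]])) {
        idx <- spikes[[i]] + 1L
        tr <- numeric(nF)
        agg <- tapply(amps[[i]], idx, sum)
        tr[as.integer(names(agg))] <- agg
        S[i, ] <- tr
      }
    }
    h <- indicator_kernel(spec@kernelRise, spec@kernelDecay, fr)
    D <- matrix(0, nNeurons, nF)
    for (j in seq_along(h)) {
      lag <- j - 1L
      if (lag < nF)
        D[, (lag + 1L):nF] <- D[, (lag + 1L):nF] +
          h[j] * S[, 1:(nF - lag), drop = FALSE]
    }
    noise <- if (spec@noiseSd > 0)
      matrix(rnorm(nNeurons * nF, 0, spec@noiseSd), nNeurons, nF)
    else 0
    fluor <- spec@baselineFluor * (1 + D + noise)

    rec <- PopulationRecording(
      fluor, frameRate = fr, neuronIds = ids,
      session = list(animal_id = animalId, group = group,
                     timepoint = timepoint),
      signal = "raw")
    truth <- new("GroundTruthLog",
                 eventIntervals = iv,
                 participants = participants,
                 spikeFrames = setNames(spikes, ids),
                 deathDay = setNames(rep(Inf, nNeurons), ids),
                 clusterId = setNames(rep(animalId, nNeurons), ids))
    list(recording = rec, truth = truth)
  })
}
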
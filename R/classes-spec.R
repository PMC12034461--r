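#' Cohort specification for the forward simulator
#'
#' A `CohortSpec` collects every parameter of the synthetic two-photon cohort
#' generator: the calcium-recording forward model (network-event process,
#' per-neuron participation, indicator kernel, noise), the injury schedule of
#' per-timepoint multipliers, and the survival model (piecewise-constant
#' daily hazard, group hazard ratio, animal-level frailty, censoring).
#'
#' Defaults reproduce the in vivo sham baseline condition: 1.1 Hz, 500-frame
#' recordings of 18-85 neurons per animal; synchronous network events at
#' 3.9 events/min with gamma-distributed durations (mean 4.3 s, SD about
#' 1.6 s); mean per-neuron participation probability 0.52; 11-day follow-up
#' with a late-rising daily hazard (days 7-11 exceed days 0-6).
#'
#' @slot nAnimalsPerGroup integer, animals (pups or slices) per group.
#' @slot neuronsRange integer length-2, inclusive range of neurons per animal.
#' @slot frameRate numeric, imaging rate in Hz.
#' @slot nFrames integer, frames per recording.
#' @slot eventRate numeric, network events per minute.
#' @slot eventDurationMean numeric, mean event duration in seconds (duration
#'   of the observable co-activity footprint).
#' @slot eventDurationShape numeric, gamma shape of the duration distribution
#'   (SD = mean / sqrt(shape)).
#' @slot participationMean numeric in (0, 1], mean per-neuron probability of
#'   joining an event.
#' @slot participationDispersion numeric > 0, beta concentration; larger
#'   values give less neuron-to-neuron spread.
#' @slot backgroundRate numeric, asynchronous background calcium transients
#'   per minute per neuron.
#' @slot noiseSd numeric, additive Gaussian noise SD in dF/F units.
#' @slot spikeAmplitude numeric, mean single-spike dF/F amplitude.
#' @slot amplitudeSdlog numeric, lognormal sdlog of per-spike amplitude.
#' @slot kernelRise,kernelDecay numeric, indicator kernel time constants (s).
#' @slot minEventGap numeric, minimum quiescent separation between network
#'   events (s).
#' @slot baselineFluor numeric, baseline raw fluorescence level (a.u.).
#' @slot timepointSchedule data.frame with columns `timepoint`, `rate`,
#'   `duration`, `participation`: multipliers applied to the injured group at
#'   each timepoint (the control group always uses multiplier 1).
#' @slot hazardSchedule numeric vector of per-day baseline hazards for days
#'   1..censorDay.
#' @slot hazardRatio numeric > 0, injured-vs-control hazard ratio.
#' @slot frailtySd numeric >= 0, SD of the animal-level log-hazard frailty.
#' @slot censorDay integer, administrative censoring day.
#' @slot groupLabels character length-2, control and injured group labels.
#' @slot brightLevel,backgroundLevel numeric, soma intensity of live neurons
#'   and residual background after quenching (a.u.).
#' @slot intensitySdlog numeric, day-to-day lognormal sdlog of live intensity.
#' @slot dimDayProb,dimDayFactor numeric, probability and multiplier of
#'   occasional dim-but-alive days.
#' @slot bgSdlog numeric, lognormal sdlog of the post-quench background.
#' @slot seed integer, default seed used when an operation is not given one.
#'
#' @seealso [CohortSpec()], [specInVivoHI()], [specInVitroOGD()]
#' @export
setClass("CohortSpec",
  representation(
    nAnimalsPerGroup = "integer",
    neuronsRange = "integer",
    frameRate = "numeric",
    nFrames = "integer",
    eventRate = "numeric",
    eventDurationMean = "numeric",
    eventDurationShape = "numeric",
    participationMean = "numeric",
    participationDispersion = "numeric",
    backgroundRate = "numeric",
    noiseSd = "numeric",
    spikeAmplitude = "numeric",
    amplitudeSdlog = "numeric",
    kernelRise = "numeric",
    kernelDecay = "numeric",
    minEventGap = "numeric",
    baselineFluor = "numeric",
    timepointSchedule = "data.frame",
    hazardSchedule = "numeric",
    hazardRatio = "numeric",
    frailtySd = "numeric",
    censorDay = "integer",
    groupLabels = "character",
    brightLevel = "numeric",
    backgroundLevel = "numeric",
    intensitySdlog = "numeric",
    dimDayProb = "numeric",
    dimDayFactor = "numeric",
    bgSdlog = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  chk <- function(cond, m) if (!isTRUE(cond)) msg <<- c(msg, m)
  chk(object@nAnimalsPerGroup >= 1L, "nAnimalsPerGroup must be >= 1")
  chk(length(object@neuronsRange) == 2L &&
        all(object@neuronsRange >= 1L) &&
        object@neuronsRange[1L] <= object@neuronsRange[2L],
      "neuronsRange must be an increasing pair of positive integers")
  chk(object@frameRate > 0, "frameRate must be > 0")
  chk(object@nFrames >= 1L, "nFrames must be >= 1")
  chk(object@eventRate >= 0, "eventRate must be >= 0")
  chk(object@eventDurationMean > 0, "eventDurationMean must be > 0")
  chk(object@eventDurationShape > 0, "eventDurationShape must be > 0")
  chk(object@participationMean > 0 && object@participationMean <= 1,
      "participationMean must be in (0, 1]")
  chk(object@participationDispersion > 0,
      "participationDispersion must be > 0")
  chk(object@backgroundRate >= 0, "backgroundRate must be >= 0")
  chk(object@noiseSd >= 0, "noiseSd must be >= 0")
  chk(object@spikeAmplitude > 0, "spikeAmplitude must be > 0")
  chk(object@kernelRise > 0 && object@kernelDecay > 0,
      "kernel time constants must be > 0")
  chk(object@minEventGap >= 0, "minEventGap must be >= 0")
  chk(all(c("timepoint", "rate", "duration", "participation") %in%
            names(object@timepointSchedule)),
      "timepointSchedule needs columns timepoint, rate, duration, participation")
  chk(!anyDuplicated(object@timepointSchedule$timepoint),
      "timepointSchedule timepoints must be unique")
  chk(all(unlist(object@timepointSchedule[, c("rate", "duration",
                                              "participation")]) > 0),
      "timepoint multipliers must be > 0")
  chk(object@censorDay >= 1L, "censorDay must be >= 1")
  chk(length(object@hazardSchedule) == object@censorDay,
      "hazardSchedule must have one entry per day 1..censorDay")
  chk(all(object@hazardSchedule >= 0), "hazards must be >= 0")
  chk(object@hazardRatio > 0, "hazardRatio must be > 0")
  chk(object@frailtySd >= 0, "frailtySd must be >= 0")
  chk(length(object@groupLabels) == 2L &&
        !anyDuplicated(object@groupLabels),
      "groupLabels must be two distinct labels")
  chk(object@brightLevel > object@backgroundLevel &&
        object@backgroundLevel > 0,
      "brightLevel must exceed backgroundLevel > 0")
  chk(object@dimDayProb >= 0 && object@dimDayProb < 1,
      "dimDayProb must be in [0, 1)")
  chk(object@dimDayFactor > 0, "dimDayFactor must be > 0")
  if (length(msg)) msg else TRUE
})

default_timepoint_schedule <- function() {
  data.frame(
    timepoint = c("baseline", "1h", "24h", "d2", "d4", "d11"),
    rate = c(1, 0.35, 1, 1, 1, 1),
    duration = c(1, 0.65, 1, 1, 1, 1),
    participation = c(1, 0.55, 1, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Construct a cohort specification
#'
#' With no arguments this returns the in vivo sham/HI default configuration
#' (see [specInVivoHI()]); any parameter can be overridden by name.
#'
#' @param nAnimalsPerGroup animals per group.
#' @param neuronsRange inclusive range of neurons per animal.
#' @param frameRate imaging rate (Hz).
#' @param nFrames frames per recording.
#' @param eventRate network events per minute.
#' @param eventDurationMean mean event duration (s).
#' @param eventDurationShape gamma shape of durations.
#' @param participationMean mean per-neuron participation probability.
#' @param participationDispersion beta concentration of participation.
#' @param backgroundRate background transients per minute per neuron.
#' @param noiseSd additive dF/F noise SD.
#' @param spikeAmplitude mean single-spike dF/F amplitude.
#' @param amplitudeSdlog lognormal sdlog of spike amplitudes.
#' @param kernelRise,kernelDecay indicator kernel time constants (s).
#' @param minEventGap minimum inter-event gap (s).
#' @param baselineFluor baseline raw fluorescence (a.u.).
#' @param timepointSchedule data.frame of injured-group multipliers.
#' @param hazardSchedule per-day baseline hazards, days 1..censorDay.
#' @param hazardRatio injured-vs-control hazard ratio.
#' @param frailtySd SD of animal-level log-hazard frailty.
#' @param censorDay administrative censoring day.
#' @param groupLabels control and injured group labels.
#' @param brightLevel,backgroundLevel live and quenched soma intensity (a.u.).
#' @param intensitySdlog day-to-day lognormal sdlog of live intensity.
#' @param dimDayProb,dimDayFactor probability/multiplier of dim-but-alive days.
#' @param bgSdlog lognormal sdlog of post-quench background intensity.
#' @param seed default seed for simulator calls.
#' @return A validated [CohortSpec-class] object.
#' @examples
#' spec <- CohortSpec(nAnimalsPerGroup = 2L, neuronsRange = c(10L, 12L))
#' @export
CohortSpec <- function(nAnimalsPerGroup = 13L,
                       neuronsRange = c(18L, 85L),
                       frameRate = 1.1,
                       nFrames = 500L,
                       eventRate = 3.9,
                       eventDurationMean = 4.3,
                       eventDurationShape = 7.2,
                       participationMean = 0.52,
                       participationDispersion = 10,
                       backgroundRate = 0.5,
                       noiseSd = 0.05,
                       spikeAmplitude = 0.8,
                       amplitudeSdlog = 0.2,
                       kernelRise = 0.18,
                       kernelDecay = 1.5,
                       minEventGap = 3,
                       baselineFluor = 100,
                       timepointSchedule = default_timepoint_schedule(),
                       hazardSchedule = c(rep(0.005, 6), rep(0.02, 5)),
                       hazardRatio = 3.232,
                       frailtySd = 0.25,
                       censorDay = 11L,
                       groupLabels = c("sham", "HI"),
                       brightLevel = 100,
                       backgroundLevel = 10,
                       intensitySdlog = 0.25,
                       dimDayProb = 0.05,
                       dimDayFactor = 0.3,
                       bgSdlog = 0.15,
                       seed = 1L) {
  new("CohortSpec",
      nAnimalsPerGroup = assert_count(nAnimalsPerGroup, "nAnimalsPerGroup"),
      neuronsRange = as.integer(neuronsRange),
      frameRate = frameRate,
      nFrames = assert_count(nFrames, "nFrames"),
      eventRate = eventRate,
      eventDurationMean = eventDurationMean,
      eventDurationShape = eventDurationShape,
      participationMean = participationMean,
      participationDispersion = participationDispersion,
      backgroundRate = backgroundRate,
      noiseSd = noiseSd,
      spikeAmplitude = spikeAmplitude,
      amplitudeSdlog = amplitudeSdlog,
      kernelRise = kernelRise,
      kernelDecay = kernelDecay,
      minEventGap = minEventGap,
      baselineFluor = baselineFluor,
      timepointSchedule = timepointSchedule,
      hazardSchedule = hazardSchedule,
      hazardRatio = hazardRatio,
      frailtySd = frailtySd,
      censorDay = assert_count(censorDay, "censorDay"),
      groupLabels = groupLabels,
      brightLevel = brightLevel,
      backgroundLevel = backgroundLevel,
      intensitySdlog = intensitySdlog,
      dimDayProb = dimDayProb,
      dimDayFactor = dimDayFactor,
      bgSdlog = bgSdlog,
      seed = as.integer(seed))
}

#' Preset cohort configurations
#'
#' `specInVivoHI()` is the in vivo sham/HI configuration: 8 pups per group,
#' 18-85 neurons per pup, hazard ratio 3.232 (the companion figure legend
#' prints 3.242; the text value is the default), censoring at day 11.
#' `specShamBaseline()` is the 13-animal calcium-imaging cohort used for the
#' baseline network-metric recovery checks. `specInVitroOGD()` is the slice
#' configuration: 6 slices per group, 26-56 neurons per slice, hazard ratio
#' 2.88, censoring at day 10.
#'
#' @param ... overrides forwarded to [CohortSpec()].
#' @return A [CohortSpec-class].
#' @examples
#' specInVitroOGD(nAnimalsPerGroup = 3L)
#' @export
specInVivoHI <- function(...) {
  args <- modifyList(list(nAnimalsPerGroup = 8L), list(...))
  do.call(CohortSpec, args)
}

#' @rdname specInVivoHI
#' @export
specShamBaseline <- function(...) {
  args <- modifyList(list(nAnimalsPerGroup = 13L), list(...))
  do.call(CohortSpec, args)
}

#' @rdname specInVivoHI
#' @export
specInVitroOGD <- function(...) {
  args <- modifyList(
    list(nAnimalsPerGroup = 6L,
         neuronsRange = c(26L, 56L),
         hazardRatio = 2.88,
         censorDay = 10L,
         hazardSchedule = c(rep(0.006, 6), rep(0.024, 4)),
         groupLabels = c("control", "OGD")),
    list(...))
  do.call(CohortSpec, args)
}

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:",
      sprintf("%d animals/group, %d-%d neurons/animal",
              object@nAnimalsPerGroup, object@neuronsRange[1L],
              object@neuronsRange[2L]), "\n")
  cat(sprintf("  recording: %.2f Hz x %d frames (%.2f min)\n",
              object@frameRate, object@nFrames,
              object@nFrames / object@frameRate / 60))
  cat(sprintf("  events: %.2f /min, duration %.2f s (shape %.1f), participation %.2f\n",
              object@eventRate, object@eventDurationMean,
              object@eventDurationShape, object@participationMean))
  cat(sprintf("  survival: HR %.3f, frailty sd %.2f, censor day %d, groups %s vs %s\n",
              object@hazardRatio, object@frailtySd, object@censorDay,
              object@groupLabels[1L], object@groupLabels[2L]))
})

#' Ground-truth log of a simulated recording or cohort
#'
#' Retains everything the simulator knows that the analysis pipeline must
#' recover: true network-event frame intervals (half-open, 0-based), the
#' participant set of each event, per-neuron spike frames, true death days
#' (Inf when the neuron never dies) and animal/cluster assignments.
#'
#' @slot eventIntervals integer matrix with columns `onset`, `offset`.
#' @slot participants list of character vectors, one per event.
#' @slot spikeFrames named list of integer vectors, one per neuron.
#' @slot deathDay named numeric vector, Inf when censored alive.
#' @slot clusterId named character vector, animal id per neuron.
#' @export
setClass("GroundTruthLog",
  representation(
    eventIntervals = "matrix",
    participants = "list",
    spikeFrames = "list",
    deathDay = "numeric",
    clusterId = "character"
  ),
  prototype(
    eventIntervals = matrix(integer(), ncol = 2L,
                            dimnames = list(NULL, c("onset", "offset"))),
    participants = list(),
    spikeFrames = list(),
    deathDay = numeric(),
    clusterId = character()
  )
)

setValidity("GroundTruthLog", function(object) {
  iv <- object@eventIntervals
  if (ncol(iv) != 2L) return("eventIntervals must have 2 columns")
  if (nrow(iv) > 0L) {
    if (any(iv[, 2L] <= iv[, 1L])) return("event intervals must be non-empty")
    if (is.unsorted(iv[, 1L], strictly = TRUE) && nrow(iv) > 1L)
      return("event intervals must be sorted")
    if (nrow(iv) > 1L && any(iv[-1L, 1L] < iv[-nrow(iv), 2L]))
      return("event intervals must be non-overlapping")
  }
  if (length(object@participants) != nrow(iv))
    return("one participant set per event required")
  TRUE
})

setMethod("show", "GroundTruthLog", function(object) {
  cat(sprintf("GroundTruthLog: %d events, %d neurons tracked\n",
              nrow(object@eventIntervals),
              max(length(object@spikeFrames), length(object@deathDay))))
})

#' @describeIn GroundTruthLog-class true event intervals (frames, half-open).
#' @param truth A `GroundTruthLog`.
#' @export
trueEventIntervals <- function(truth) truth@eventIntervals

#' @describeIn GroundTruthLog-class participant ids per true event.
#' @export
trueParticipants <- function(truth) truth@participants

#' @describeIn GroundTruthLog-class true death day per neuron (Inf = never).
#' @export
trueDeathDay <- function(truth) truth@deathDay

#' @describeIn GroundTruthLog-class true spike frames per neuron.
#' @export
trueSpikeFrames <- function(truth) truth@spikeFrames
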
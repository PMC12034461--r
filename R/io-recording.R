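# Recording readers/writers: delimited matrix or multi-frame TIFF, each with
# a JSON sidecar carrying {frame_rate_hz, timepoint, animal_id, group}.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(rec, path, extra = list()) {
  s <- recordingSession(rec)
  meta <- c(list(frame_rate_hz = frameRate(rec),
                 signal = metadata(rec)$signal,
                 neuron_ids = neuronIds(rec),
                 timepoint = s$timepoint, animal_id = s$animal_id,
                 group = s$group),
            extra)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1L))],
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    nq_stop("sidecar metadata file '%s' not found", sp)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Write and read population recordings
#'
#' `writeRecording()` stores a recording either as a tab-delimited matrix
#' (rows = neurons with a `neuron_id` first column, columns = frames) or as
#' a multi-frame 32-bit float TIFF (one page per frame, one pixel row per
#' neuron, intensities scaled into [0, 1] by a factor recorded in the
#' sidecar). Both formats carry a JSON sidecar `<path>.json` with
#' `frame_rate_hz`, neuron ids and the session descriptor.
#' `readRecording()` reverses either encoding; a missing frame rate is an
#' error, and non-finite cells are an error naming the offending positions.
#'
#' @param rec A [PopulationRecording-class].
#' @param path file path (sidecar written next to it).
#' @param format `"matrix"` (delimited) or `"tiff"`.
#' @return `readRecording()` returns a [PopulationRecording-class];
#'   `writeRecording()` returns `path` invisibly.
#' @examples
#' rec <- PopulationRecording(matrix(100 + rnorm(50), 5), frameRate = 1.1)
#' p <- tempfile(fileext = ".tsv")
#' writeRecording(rec, p)
#' readRecording(p)
#' @export
writeRecording <- function(rec, path, format = c("matrix", "tiff")) {
  format <- match.arg(format)
  stopifnot(is(rec, "PopulationRecording"))
  m <- assay(rec)
  if (format == "matrix") {
    df <- data.frame(neuron_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df) <- c("neuron_id", paste0("f", seq_len(ncol(m)) - 1L))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    write_sidecar(rec, path)
  } else {
    scale <- max(abs(m), 1e-12)
    pages <- lapply(seq_len(ncol(m)),
                    function(j) matrix(m[, j] / scale, ncol = 1L))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                    compression = "none")
    write_sidecar(rec, path, extra = list(intensity_scale = scale))
  }
  invisible(path)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path, format = c("matrix", "tiff")) {
  format <- match.arg(format)
  if (!file.exists(path)) nq_stop("file '%s' not found", path)
  meta <- read_sidecar(path)
  if (is.null(meta$frame_rate_hz))
    nq_stop("sidecar of '%s' is missing the required frame_rate_hz", path)
  if (format == "matrix") {
    df <- tryCatch(
      read.delim(path, check.names = FALSE, colClasses = NA),
      error = function(e) nq_stop("failed to parse '%s': %s", path,
                                  conditionMessage(e)))
    if (!"neuron_id" %in% names(df))
      nq_stop("delimited recording must have a neuron_id first column")
    ids <- as.character(df$neuron_id)
    m <- as.matrix(df[, setdiff(names(df), "neuron_id"), drop = FALSE])
    if (!is.numeric(m))
      nq_stop("non-numeric fluorescence values in '%s'", path)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    m <- vapply(pages, function(p) as.numeric(p), numeric(nrow(pages[[1L]])))
    if (!is.matrix(m)) m <- matrix(m, nrow = 1L)
    scale <- meta$intensity_scale
    if (is.null(scale)) scale <- 1
    m <- m * scale
    ids <- meta$neuron_ids
    if (is.null(ids)) ids <- paste0("n", seq_len(nrow(m)))
  }
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    nq_stop("non-finite values at %s in '%s'",
            paste(sprintf("[neuron %d, frame %d]", bad[, 1L], bad[, 2L]),
                  collapse = ", "), path)
  signal <- if (identical(meta$signal, "dff")) "dff" else "raw"
  PopulationRecording(
    m, frameRate = meta$frame_rate_hz, neuronIds = ids,
    session = list(animal_id = meta$animal_id, group = meta$group,
                   timepoint = meta$timepoint),
    signal = signal)
}

#' Write/read tidy tables and ground-truth logs
#'
#' Survival tables, neuron tracks, metric tables and participation records
#' are interchanged as plain CSV with their documented column names;
#' ground-truth logs are serialized as JSON.
#'
#' @param x data.frame (for `writeTidyCsv`) or [GroundTruthLog-class] (for
#'   `writeGroundTruth`).
#' @param path file path.
#' @return Readers return the parsed object; writers return `path`
#'   invisibly.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' writeTidyCsv(data.frame(a = 1:2), p)
#' readTidyCsv(p)
#' @export
writeTidyCsv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTidyCsv
#' @export
readTidyCsv <- function(path) {
  if (!file.exists(path)) nq_stop("file '%s' not found", path)
  read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname writeTidyCsv
#' @export
writeGroundTruth <- function(x, path) {
  stopifnot(is(x, "GroundTruthLog"))
  obj <- list(
    event_intervals = unname(apply(x@eventIntervals, 1L, as.list,
                                   simplify = FALSE)),
    participants = x@participants,
    spike_frames = x@spikeFrames,
    death_day = lapply(as.list(x@deathDay),
                       function(d) if (is.infinite(d)) "Inf" else d),
    cluster_id = as.list(x@clusterId))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeTidyCsv
#' @export
readGroundTruth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  iv <- if (length(obj$event_intervals)) {
    do.call(rbind, lapply(obj$event_intervals,
                          function(e) c(onset = e[[1L]], offset = e[[2L]])))
  } else {
    matrix(integer(), ncol = 2L, dimnames = list(NULL, c("onset", "offset")))
  }
  dd <- vapply(obj$death_day,
               function(d) if (identical(d, "Inf")) Inf else as.numeric(d),
               numeric(1L))
  new("GroundTruthLog",
      eventIntervals = iv,
      participants = lapply(obj$participants, function(p)
        as.character(unlist(p))),
      spikeFrames = lapply(obj$spike_frames, function(s)
        as.integer(unlist(s))),
      deathDay = dd,
      clusterId = vapply(obj$cluster_id, as.character, character(1L)))
}
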
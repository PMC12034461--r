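# Run configuration and the staged end-to-end pipeline.

CONFIG_SCHEMA_VERSION <- "1.0"

default_run_config <- function() {
  list(
    schema_version = CONFIG_SCHEMA_VERSION,
    seed = 1L,
    out_dir = NULL,
    simulate = list(
      preset = "invivo",            # invivo | invitro | sham_baseline
      n_animals_per_group = NULL,   # NULL = preset default
      timepoints = "baseline",
      overrides = list()            # forwarded to CohortSpec()
    ),
    signal = list(baseline_percentile = 20, baseline_window_sec = 60,
                  k = 3, min_frames = 2L),
    events = list(n_shuffles = 1000L, alpha = 0.01, floor = 0.1,
                  theta = NULL,      # fixed theta overrides the shuffle null
                  min_frames = 2L, merge_gap = 1L),
    quench = list(k_bg = 1.5, persistence = Inf),
    survival = list(ties = "efron"),
    lme = list(fixed = c("fate", "group"), df_method = "Satterthwaite")
  )
}

check_known_keys <- function(cfg, ref, prefix = "") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown))
    nq_stop("unknown config key(s): %s",
            paste0(prefix, unknown, collapse = ", "))
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) && is.list(cfg[[k]]) &&
        k != "overrides")
      check_known_keys(cfg[[k]], ref[[k]], paste0(prefix, k, "."))
  }
}

#' Validate and resolve a pipeline run configuration
#'
#' Unknown keys are rejected; omitted keys take their documented defaults.
#' Stage-parameter sanity checks (e.g. a synchrony threshold outside
#' (0, 1]) fail here, before any computation.
#'
#' @param config named list of overrides, or a path to a JSON config file.
#' @return The fully resolved configuration list.
#' @examples
#' cfg <- resolveRunConfig(list(seed = 7))
#' cfg$seed
#' @export
resolveRunConfig <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  ref <- default_run_config()
  check_known_keys(config, ref)
  cfg <- modifyList(ref, config)
  if (identical(cfg$quench$persistence, "Inf"))
    cfg$quench$persistence <- Inf   # JSON has no Inf literal
  if (!is.null(cfg$events$theta) &&
      (cfg$events$theta <= 0 || cfg$events$theta > 1))
    nq_stop("config events.theta must be in (0, 1]")
  if (cfg$signal$baseline_percentile < 0 ||
      cfg$signal$baseline_percentile > 100)
    nq_stop("config signal.baseline_percentile must be in [0, 100]")
  if (cfg$quench$k_bg <= 0) nq_stop("config quench.k_bg must be > 0")
  if (!cfg$simulate$preset %in% c("invivo", "invitro", "sham_baseline"))
    nq_stop("config simulate.preset must be invivo, invitro or sham_baseline")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

config_spec <- function(cfg) {
  maker <- switch(cfg$simulate$preset,
                  invivo = specInVivoHI,
                  invitro = specInVitroOGD,
                  sham_baseline = specShamBaseline)
  args <- cfg$simulate$overrides
  if (!is.null(cfg$simulate$n_animals_per_group))
    args$nAnimalsPerGroup <- as.integer(cfg$simulate$n_animals_per_group)
  do.call(maker, args)
}

# dff -> raster -> events -> metrics/participation for one recording
analyze_recording <- function(rec, cfg, seed) {
  dff <- computeDFF(rec,
                    baselinePercentile = cfg$signal$baseline_percentile,
                    baselineWindowSec = cfg$signal$baseline_window_sec)
  raster <- detectTransients(dff, k = cfg$signal$k,
                             minFrames = cfg$signal$min_frames)
  theta <- if (!is.null(cfg$events$theta)) cfg$events$theta else
    shuffleThreshold(raster, nShuffles = cfg$events$n_shuffles,
                     alpha = cfg$events$alpha, floor = cfg$events$floor,
                     seed = seed)
  events <- detectNetworkEvents(raster, theta,
                                minFrames = cfg$events$min_frames,
                                mergeGap = cfg$events$merge_gap)
  list(dff = dff, raster = raster, theta = theta, events = events,
       metrics = networkMetrics(events),
       participation = neuronalParticipation(events))
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort from the configured preset (recordings per animal and
#' timepoint, survival cohort, intensity tracks), then runs dF/F,
#' rasterisation, network-event detection, per-animal metrics, per-neuron
#' participation, quench calling, Kaplan-Meier, the clustered Cox model and
#' the participation mixed model. When `out_dir` is set, tidy CSV tables,
#' JSON fit reports and the resolved configuration are written there; a
#' rerun with the same configuration and seed reproduces the files
#' byte-for-byte.
#'
#' @param config overrides list or JSON path; see [resolveRunConfig()].
#' @return A result bundle list: `config`, `metrics`, `participation`,
#'   `survival_table`, `km`, `cox`, `lme`, `theta`.
#' @examples
#' \donttest{
#' res <- runPipeline(list(simulate = list(preset = "invitro",
#'   n_animals_per_group = 2, overrides = list(neuronsRange = c(8L, 10L),
#'   nFrames = 200L))))
#' }
#' @export
runPipeline <- function(config = list()) {
  cfg <- resolveRunConfig(config)
  spec <- config_spec(cfg)
  seed0 <- cfg$seed

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      nq_stop("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # --- calcium recordings per animal/group/timepoint ---------------------
  metrics_rows <- list(); part_rows <- list(); thetas <- list()
  idx <- 0L
  for (tp in cfg$simulate$timepoints) {
    for (g in spec@groupLabels) {
      for (a in seq_len(spec@nAnimalsPerGroup)) {
        idx <- idx + 1L
        animal <- sprintf("%s_p%02d", g, a)
        sim <- stage("simulate", simulateRecording(
          spec, timepoint = tp, group = g, animalId = animal,
          seed = derive_seed(seed0, idx)))
        an <- stage("events", analyze_recording(
          sim$recording, cfg, seed = derive_seed(seed0, idx + 100000L)))
        metrics_rows[[idx]] <- cbind(
          data.frame(animal_id = animal, group = g, timepoint = tp,
                     theta = an$theta, stringsAsFactors = FALSE),
          an$metrics)
        part_rows[[idx]] <- data.frame(
          neuron_id = paste(animal, names(an$participation), sep = "_"),
          animal_id = animal, group = g, timepoint = tp,
          participation = unname(an$participation),
          stringsAsFactors = FALSE)
      }
    }
  }
  metrics <- do.call(rbind, metrics_rows)
  participation <- do.call(rbind, part_rows)

  # --- survival arm ------------------------------------------------------
  cohort <- stage("survival-sim", simulateSurvivalCohort(
    spec, seed = derive_seed(seed0, 900001L)))
  tracks <- stage("tracks", simulateIntensityTracks(
    cohort, spec, seed = derive_seed(seed0, 900002L)))
  surv_tab <- stage("quench", quenchSurvivalTable(
    tracks, kBg = cfg$quench$k_bg, persistence = cfg$quench$persistence))
  surv_tab$group <- factor(surv_tab$group, levels = spec@groupLabels)
  km <- stage("km", kaplanMeier(surv_tab))
  cox <- stage("cox", coxClustered(surv_tab, ties = cfg$survival$ties))

  # --- participation mixed model ----------------------------------------
  # the recording and survival arms simulate neurons independently, so fate
  # is linked at the animal level: each recorded neuron draws its fate from
  # its own animal's simulated death rate
  lme_input <- participation
  rate_by_animal <- tapply(surv_tab$event, surv_tab$cluster_id, mean)
  pos <- match(lme_input$animal_id, names(rate_by_animal))
  pr <- ifelse(is.na(pos), mean(surv_tab$event), rate_by_animal[pos])
  lme_input$fate <- maybe_with_seed(derive_seed(seed0, 900003L),
    ifelse(runif(nrow(lme_input)) < pr, "died", "survived"))
  lme_input$fate <- factor(lme_input$fate, levels = c("survived", "died"))
  lme <- stage("lme", fitParticipationLme(
    lme_input, fixed = cfg$lme$fixed, dfMethod = cfg$lme$df_method))

  res <- list(config = cfg, metrics = metrics, participation = lme_input,
              survival_table = surv_tab, km = km, cox = cox, lme = lme)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(cfg$out_dir, f)
    writeTidyCsv(metrics, out("network_metrics.csv"))
    writeTidyCsv(lme_input, out("participation.csv"))
    writeTidyCsv(surv_tab, out("survival_table.csv"))
    writeTidyCsv(km, out("kaplan_meier.csv"))
    jsonlite::write_json(
      list(log_hr = cox@logHr, hr = cox@hr, robust_se = cox@robustSe,
           ci95 = cox@ci95, z = cox@z, p = cox@p,
           n_clusters = cox@nClusters, n_events = cox@nEvents),
      out("cox_fit.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(method = lme$method, df_method = lme$df_method,
           tests = lme$tests, coefficients = as.list(lme$coefficients)),
      out("lme_fit.json"), auto_unbox = TRUE, digits = NA)
    cfgw <- cfg
    cfgw$quench$persistence <-
      if (is.infinite(cfg$quench$persistence)) "Inf"
      else cfg$quench$persistence
    jsonlite::write_json(cfgw, out("resolved_config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(res)
}
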
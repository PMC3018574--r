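# Config-driven study runner: cohort -> forward -> operators -> metrics ->
# group statistics, with deterministic seed fan-out and TSV/JSON outputs.

.configKeys <- c("n_mag", "n_grad", "n_sources", "n_subjects",
                 "conductor_radius", "helmet_radius", "scalp_margin",
                 "fold_depth", "fold_frequency", "jitter_scale",
                 "gradiometer_baseline", "n_trials", "baseline_duration",
                 "sampling_rate", "brain_noise_fraction", "sensor_noise_sd",
                 "snr", "n_averages", "methods", "modes", "metrics",
                 "output_dir", "master_seed", "max_sources")

#' Default study configuration
#'
#' The defaults mirror the simulated study conditions: a 306-channel array
#' (102 magnetometers, 204 planar gradiometers), ~10,000 cortical sources,
#' 17 subjects, noise covariances from 146 concatenated 200 ms baselines,
#' SNR = 3 regularization and 100 averages for dSPM. \code{max_sources}
#' caps the dense resolution-matrix size; scale \code{n_sources} down (or
#' raise the cap explicitly) for desk-sized runs.
#'
#' @return named list of configuration values.
#' @export
defaultStudyConfig <- function() {
  list(n_mag = 102L, n_grad = 204L, n_sources = 10000L, n_subjects = 17L,
       conductor_radius = 0.09, helmet_radius = 0.12, scalp_margin = 0.01,
       fold_depth = 0.03, fold_frequency = 6, jitter_scale = 0.002,
       gradiometer_baseline = 0.0168, n_trials = 146L,
       baseline_duration = 0.2, sampling_rate = 250, brain_noise_fraction = 0.5,
       sensor_noise_sd = 1, snr = 3, n_averages = 100L,
       methods = c("MNE", "dSPM", "sLORETA"), modes = c("PSF", "CTF"),
       metrics = c("dle", "sd", "oa"), output_dir = "study_out",
       master_seed = 1L, max_sources = 4000L)
}

#' Read a study configuration file
#'
#' Flat key-value YAML; unknown keys are an error (misspelled keys must
#' never silently fall back to defaults). Given keys override the defaults
#' from \code{\link{defaultStudyConfig}}.
#'
#' @param path YAML file.
#' @return full configuration list.
#' @export
readStudyConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), .configKeys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- defaultStudyConfig()
  cfg[names(user)] <- user
  cfg
}

.validateConfig <- function(cfg) {
  unknown <- setdiff(names(cfg), .configKeys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  missing <- setdiff(.configKeys, names(cfg))
  if (length(missing))
    stop("missing config key(s): ", paste(missing, collapse = ", "))
  if (cfg$n_sources > cfg$max_sources)
    stop(sprintf(paste0("n_sources = %d exceeds max_sources = %d (dense ",
                        "resolution matrices); raise max_sources explicitly ",
                        "to override"), cfg$n_sources, cfg$max_sources))
  if (!all(cfg$methods %in% c("MNE", "dSPM", "sLORETA")))
    stop("config key 'methods': must be a subset of MNE, dSPM, sLORETA")
  if (!all(cfg$modes %in% c("PSF", "CTF")))
    stop("config key 'modes': must be a subset of PSF, CTF")
  if (!all(cfg$metrics %in% c("dle", "sd", "oa")))
    stop("config key 'metrics': must be a subset of dle, sd, oa")
  invisible(cfg)
}

#' Run the full resolution study
#'
#' Generates the synthetic cohort, builds per-subject leadfields, noise
#' covariances and MNE/dSPM/sLORETA operators, computes metric maps for
#' the requested modes, and (when at least two methods and two subjects
#' are present) between-method difference maps, across-subject SDs and
#' paired t-test maps. Writes per-subject metric TSVs, per-contrast group
#' TSVs, a machine-readable \code{summary.json} (maximum sLORETA PSF DLE,
#' maximum CTF-mode inter-method deviation, MNE symmetry residual) and a
#' \code{run_log.txt} recording all seeds and the per-subject lambda.
#' Outputs are a pure function of the configuration (including
#' \code{master_seed}); partial outputs are removed if the run fails.
#'
#' @param config configuration list (see \code{\link{defaultStudyConfig}}).
#' @return invisibly, a list with the summary, output file paths, template
#'   geometry and the per-subject metric maps.
#' @export
runStudy <- function(config = defaultStudyConfig()) {
  cfg <- .validateConfig(config)
  outdir <- cfg$output_dir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  ok <- FALSE
  on.exit(if (!ok && length(written)) unlink(written))

  log <- c(sprintf("master_seed\t%d", cfg$master_seed),
           sprintf("sensor_seed\t%d", .childSeed(cfg$master_seed, 0L, 1L)),
           sprintf("source_seed\t%d", .childSeed(cfg$master_seed, 0L, 2L)))

  cohort <- makeCohort(cfg$n_subjects, cfg, jitterScale = cfg$jitter_scale,
                       seed = cfg$master_seed)
  tmplSrc <- cohort$template$sources

  maps <- list()     # maps[[method]][[mode]] = list over subjects
  for (m in cfg$methods) maps[[m]] <- setNames(
    rep(list(vector("list", cfg$n_subjects)), length(cfg$modes)), cfg$modes)
  maxSlorDle <- -Inf
  symResid <- -Inf

  for (k in seq_len(cfg$n_subjects)) {
    sub <- cohort$subjects[[k]]
    lf <- buildLeadfield(sub$sensors, sub$sources)
    noiseSeed <- .childSeed(cfg$master_seed, k, 4L)
    nc <- simulateNoiseCovariance(sub$sensors, lf, cfg$n_trials,
                                  cfg$baseline_duration, cfg$sampling_rate,
                                  cfg$brain_noise_fraction, seed = noiseSeed,
                                  sensorNoiseSD = cfg$sensor_noise_sd,
                                  nAverages = cfg$n_averages)
    lam <- regularizationLambda(lf, nc, cfg$snr)
    mne <- suppressMessages(mneOperator(lf, nc, lambda = lam, snr = cfg$snr))
    ops <- list()
    if ("MNE" %in% cfg$methods) ops$MNE <- mne
    if ("dSPM" %in% cfg$methods)
      ops$dSPM <- applyNormalization(mne, dspmWeights(mne, nc), "dSPM")
    if ("sLORETA" %in% cfg$methods)
      ops$sLORETA <- applyNormalization(mne, sloretaWeights(mne, lf), "sLORETA")

    rmne <- resolutionMatrix(mne, lf)
    Rm <- getMatrix(rmne)
    symResid <- max(symResid, max(abs(Rm - t(Rm))) / max(abs(Rm)))

    subMaps <- list()
    for (m in cfg$methods) {
      # dSPM/sLORETA resolution rows are weight-scaled MNE rows
      Rmat <- if (m == "MNE") rmne else
        new("ResolutionMatrix", matrix = normWeights(ops[[m]]) * Rm,
            method = m, sourceRef = rmne@sourceRef)
      for (md in cfg$modes) {
        mm <- metricMaps(Rmat, md, sub$sources, subjectId = sub$id)
        maps[[m]][[md]][[k]] <- mm
        subMaps <- c(subMaps, mm)
        if (m == "sLORETA" && md == "PSF")
          maxSlorDle <- max(maxSlorDle, max(mm@dle))
      }
    }
    f <- file.path(outdir, sprintf("metric_maps_%s.tsv", sub$id))
    writeMetricMaps(subMaps, tmplSrc, f)
    written <- c(written, f)
    log <- c(log, sprintf("subject\t%s\tgeom_seed\t%d\tnoise_seed\t%d\tlambda\t%s",
                          sub$id, .childSeed(cfg$master_seed, k, 3L), noiseSeed,
                          .fmt17(lam)))
  }

  # group contrasts
  groupFiles <- character()
  ctfDev <- 0
  if (length(cfg$methods) >= 2 && cfg$n_subjects >= 2) {
    pairs <- combn(cfg$methods, 2, simplify = FALSE)
    for (pr in pairs) for (met in cfg$metrics) for (md in cfg$modes) {
      gr <- suppressMessages(
        pairedTTestMap(maps[[pr[1]]][[md]], maps[[pr[2]]][[md]], met, mode = md))
      f <- file.path(outdir, sprintf("group_%s_vs_%s_%s_%s.tsv",
                                     pr[1], pr[2], met, md))
      writeGroupResult(gr, tmplSrc, f)
      written <- c(written, f); groupFiles <- c(groupFiles, f)
      if (md == "CTF" && met %in% c("dle", "sd"))
        ctfDev <- max(ctfDev, max(abs(gr@meanMap)))
    }
  }

  summary <- list(
    n_subjects = cfg$n_subjects, n_sources = cfg$n_sources,
    max_sloreta_psf_dle_cm =
      if (is.finite(maxSlorDle)) maxSlorDle else NA_real_,
    max_ctf_intermethod_deviation = ctfDev,
    mne_symmetry_residual = symResid)
  sf <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, sf, auto_unbox = TRUE, digits = NA)
  lf <- file.path(outdir, "run_log.txt")
  writeLines(log, lf)
  written <- c(written, sf, lf)
  ok <- TRUE
  invisible(list(summary = summary, files = written, template = cohort$template,
                 maps = maps))
}

#' Plot a per-source map as a 3-D scatter projection
#'
#' Quick-look rendering of a metric or sensitivity map: sources plotted in
#' two axis-aligned projections, colored by value.
#'
#' @param sourceSpace the \code{SourceSpace}.
#' @param values numeric vector, one per source.
#' @param main plot title.
#' @return invisibly, NULL.
#' @export
plotSourceMap <- function(sourceSpace, values, main = "") {
  stopifnot(is(sourceSpace, "SourceSpace"))
  pos <- sourcePositions(sourceSpace)
  pal <- grDevices::hcl.colors(64, "viridis")
  idx <- cut(values, 64, labels = FALSE, include.lowest = TRUE)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  plot(pos[, 1], pos[, 3], col = pal[idx], pch = 16, cex = 0.6,
       xlab = "x (m)", ylab = "z (m)", main = main, asp = 1)
  plot(pos[, 2], pos[, 3], col = pal[idx], pch = 16, cex = 0.6,
       xlab = "y (m)", ylab = "z (m)", main = "side view", asp = 1)
  invisible(NULL)
}
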
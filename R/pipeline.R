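# Configuration and end-to-end pipeline composing all stages, plus a thin
# command-line wrapper in inst/scripts/run_pipeline.R.

#' Build and validate a pipeline configuration
#'
#' Collects every stage parameter, validates ranges, and returns a named
#' list that is serialized into every output bundle for provenance. The
#' pipeline either simulates its input (\code{simulate} holds
#' \code{\link{longitudinalParams}} arguments) or reads per-session raster
#' TSV files (\code{inputPaths}).
#'
#' @param simulate NULL, or a named list passed to
#'   \code{\link{longitudinalParams}} / \code{\link{sessionParams}}
#'   (entries \code{nNeurons}, \code{nFrames}, \code{nSessions},
#'   \code{nStableEnsembles}, \code{nTransientPerSession},
#'   \code{ensembleSize}, \code{eventsPerEnsemble},
#'   \code{participationProb}, \code{targetActivity},
#'   \code{commonNeuronFraction}, \code{coreRetention}).
#' @param inputPaths character vector of raster TSV paths (ignored when
#'   \code{simulate} is given).
#' @param detector \code{"connectivity"} or \code{"coactivity_peaks"}.
#' @param nSurrogates,alpha,minCoactive,similarityThreshold,minCluster,kMax,vectorSelection,matchThreshold,psnrThresholdDb
#'   stage parameters (defaults: 1000 surrogates, alpha 0.05, 3 coactive,
#'   2/3 similarity, 1/3 matching, 18 dB).
#' @param shuffleControl rerun the stability comparison on shuffled
#'   rasters.
#' @param seed root seed.
#' @param outDir output directory for \code{\link{runPipeline}}.
#' @return validated configuration list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(simulate = NULL, inputPaths = character(0),
                           detector = c("connectivity", "coactivity_peaks"),
                           nSurrogates = 1000, alpha = 0.05,
                           minCoactive = 3, similarityThreshold = 2 / 3,
                           minCluster = 2, kMax = 10, vectorSelection = TRUE,
                           matchThreshold = 1 / 3, psnrThresholdDb = 18,
                           shuffleControl = FALSE, seed = 1L,
                           outDir = ".") {
  detector <- match.arg(detector)
  bad <- character(0)
  check <- function(expr, key) if (!isTRUE(expr)) bad <<- c(bad, key)
  check(is.numeric(nSurrogates) && nSurrogates >= 100, "nSurrogates")
  check(is.numeric(alpha) && alpha > 0 && alpha < 1, "alpha")
  check(is.numeric(minCoactive) && minCoactive >= 1, "minCoactive")
  check(is.numeric(similarityThreshold) && similarityThreshold > 0 &&
          similarityThreshold < 1, "similarityThreshold")
  check(is.numeric(matchThreshold) && matchThreshold >= 0 &&
          matchThreshold <= 1, "matchThreshold")
  check(is.numeric(kMax) && kMax >= 2, "kMax")
  check(is.numeric(psnrThresholdDb), "psnrThresholdDb")
  check(is.logical(vectorSelection), "vectorSelection")
  check(is.logical(shuffleControl), "shuffleControl")
  check(is.numeric(seed) && seed == round(seed), "seed")
  if (is.null(simulate) && length(inputPaths) < 2L)
    bad <- c(bad, "simulate/inputPaths")
  if (length(bad))
    stop("invalid pipeline configuration, offending keys: ",
         paste(bad, collapse = ", "))
  structure(list(simulate = simulate, inputPaths = inputPaths,
                 detector = detector, nSurrogates = as.integer(nSurrogates),
                 alpha = alpha, minCoactive = as.integer(minCoactive),
                 similarityThreshold = similarityThreshold,
                 minCluster = minCluster, kMax = kMax,
                 vectorSelection = vectorSelection,
                 matchThreshold = matchThreshold,
                 psnrThresholdDb = psnrThresholdDb,
                 shuffleControl = shuffleControl,
                 seed = as.integer(seed), outDir = outDir),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   \code{\link{pipelineConfig}}.
#' @param ... overrides applied on top of the file.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  do.call(pipelineConfig, raw)
}

#' Run the full detection and stability pipeline
#'
#' Simulates (or reads) the session rasters, runs the stability analysis
#' (per-session ensemble detection, demixing, cross-session matching,
#' optional shuffle control) and writes a report bundle into
#' \code{config$outDir}: \code{report.json} (counts, matches, measures and
#' the full configuration), \code{ensembles.csv} and \code{neurons.csv},
#' plus the rasters and ground truth when simulating. Byte-identical
#' outputs for identical configuration and seed.
#'
#' @param config a \code{pipelineConfig} (or path to one in YAML).
#' @param verbose log stage progress to stderr.
#' @return invisibly, the \linkS4class{StabilityReport}.
#' @export
runPipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  if (!inherits(config, "pipelineConfig"))
    stop("config must be a pipelineConfig or a YAML path")
  say <- function(...) if (verbose) message(sprintf(...))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (!is.null(config$simulate)) {
    simArgs <- config$simulate
    sessionKeys <- intersect(names(simArgs),
                             names(formals(sessionParams)))
    longKeys <- intersect(names(simArgs),
                          setdiff(names(formals(longitudinalParams)),
                                  "session"))
    sp <- do.call(sessionParams, simArgs[sessionKeys])
    lp <- do.call(longitudinalParams,
                  c(list(session = sp), simArgs[longKeys]))
    say("simulate: %d sessions, %d neurons, %d frames, seed %d",
        lp@nSessions, sp@nNeurons, sp@nFrames, config$seed)
    sim <- generateLongitudinal(lp, seed = config$seed)
    sessions <- sim$rasters
    truth <- sim$truth
    for (i in seq_along(sessions))
      writeRaster(sessions[[i]],
                  file.path(config$outDir, sprintf("raster_s%d.tsv", i)))
    jsonlite::write_json(
      list(members = lapply(truth@members, lapply, as.integer),
           stableFlags = truth@stableFlags,
           commonNeurons = lapply(truth@commonNeurons, as.integer)),
      file.path(config$outDir, "ground_truth.json"))
  } else {
    say("reading %d raster files", length(config$inputPaths))
    sessions <- lapply(config$inputPaths, readRaster)
  }

  say("stability analysis: detector=%s, %d surrogates, alpha=%g",
      config$detector, config$nSurrogates, config$alpha)
  report <- stabilityAnalysis(
    sessions, nSurrogates = config$nSurrogates, alpha = config$alpha,
    seed = config$seed, minCoactive = config$minCoactive,
    similarityThreshold = config$similarityThreshold,
    minCluster = config$minCluster, kMax = config$kMax,
    vectorSelection = config$vectorSelection,
    matchThreshold = config$matchThreshold,
    shuffleControl = config$shuffleControl,
    detector = config$detector)

  ensTable <- NULL
  neuronTable <- NULL
  for (cmp in report@comparisons) {
    m <- cmp$measures
    if (!is.null(m)) {
      m$sessionPair <- paste(cmp$sessionPair, collapse = "v")
      stableFlag <- logical(nrow(m))
      for (r in seq_len(nrow(m)))
        stableFlag[r] <- if (m$session[r] == cmp$sessionPair[1L])
          isTRUE(cmp$matches$stable[m$ensemble[r]])
        else m$ensemble[r] %in% cmp$matches$idSecond[cmp$matches$stable]
      m$stable <- stableFlag
      jacc <- rep(NA_real_, nrow(m))
      first <- m$session == cmp$sessionPair[1L]
      jacc[first] <- cmp$matches$jaccard[m$ensemble[first]]
      m$jaccard <- jacc
      ensTable <- rbind(ensTable, m)
    }
    for (fate in cmp$fate) {
      neuronTable <- rbind(neuronTable, data.frame(
        sessionPair = paste(cmp$sessionPair, collapse = "v"),
        ensemble = fate$idFirst,
        neuronId = c(fate$stable, fate$lost, fate$new),
        fate = rep(c("stable", "lost", "new"),
                   c(length(fate$stable), length(fate$lost),
                     length(fate$new)))))
    }
  }
  if (!is.null(ensTable))
    utils::write.csv(ensTable, file.path(config$outDir, "ensembles.csv"),
                     row.names = FALSE)
  if (!is.null(neuronTable))
    utils::write.csv(neuronTable, file.path(config$outDir, "neurons.csv"),
                     row.names = FALSE)

  summary <- list(
    config = unclass(config),
    comparisons = lapply(report@comparisons, function(cmp) {
      out <- list(sessionPair = cmp$sessionPair,
                  nStable = cmp$nStable, nTransient = cmp$nTransient,
                  nCommonNeurons = length(cmp$commonNeurons),
                  matches = cmp$matches)
      if (!is.null(cmp$shuffle))
        out$shuffle <- list(nStable = cmp$shuffle$nStable,
                            nTransient = cmp$shuffle$nTransient)
      out
    }))
  jsonlite::write_json(summary, file.path(config$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  say("report written to %s", file.path(config$outDir, "report.json"))
  invisible(report)
}
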
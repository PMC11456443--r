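#' Write / read a session as JSON
#'
#' Text serialization of a [ColumnSession-class]: neuron and trial tables,
#' per-trial spike times, config, and (optionally) the LFP block. Spike
#' times keep 8 significant digits; LFP samples are rounded harder since
#' only their smooth stimulus-locked average is consumed downstream.
#'
#' @param session A `ColumnSession`.
#' @param path Output file.
#' @param includeLfp Write the LFP block?
#' @param lfpDigits Significant digits for LFP samples.
#' @return `path`, invisibly.
#' @export
writeSessionJson <- function(session, path, includeLfp = TRUE,
                             lfpDigits = 4) {
  obj <- list(
    neurons = session@neurons,
    trials = session@trials,
    spikes = lapply(session@spikes, function(tr)
      lapply(tr, function(s) round(s, 8))),
    config = session@config
  )
  if (includeLfp && length(session@lfp)) {
    lf <- session@lfp
    lf$data <- signif(lf$data, lfpDigits)
    obj$lfp <- lf
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname writeSessionJson
#' @export
readSessionJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  spikes <- lapply(obj$spikes, function(tr)
    lapply(tr, function(s) as.numeric(unlist(s))))
  lfp <- list()
  if (!is.null(obj$lfp))
    lfp <- list(data = matrix(unlist(obj$lfp$data),
                              nrow = length(obj$lfp$channelDepths)),
                channelDepths = as.numeric(obj$lfp$channelDepths),
                fs = obj$lfp$fs,
                t0 = if (is.null(obj$lfp$t0)) 0 else obj$lfp$t0)
  methods::new("ColumnSession",
               neurons = as.data.frame(obj$neurons),
               spikes = spikes,
               trials = as.data.frame(obj$trials),
               lfp = lfp,
               config = obj$config)
}

#' Validate a session container
#'
#' Schema and domain checks before any computation: direction labels must
#' be multiples of 10 in \[0, 350\], depths finite, spike lists aligned
#' with the trial table, onsets increasing, LFP channels ordered by depth.
#'
#' @param session A [ColumnSession-class].
#' @return Character vector of violations; empty when valid.
#' @export
validateSession <- function(session) {
  v <- character()
  tr <- session@trials
  ns <- session@neurons
  bad <- tr$direction %% 10 != 0 | tr$direction < 0 | tr$direction > 350
  if (any(bad))
    v <- c(v, paste0("trials$direction: domain violation in trial(s) ",
                     paste(utils::head(tr$trial[bad], 5), collapse = ",")))
  if (any(!is.finite(ns$depth)))
    v <- c(v, "neurons$depth: non-finite depth")
  if (length(session@spikes) != nrow(ns))
    v <- c(v, "spikes: one entry per neuron required")
  nt <- vapply(session@spikes, length, integer(1))
  if (length(nt) && any(nt != nrow(tr)))
    v <- c(v, "spikes: per-neuron trial count does not match trial table")
  if (nrow(tr) > 1 && any(diff(tr$onset) <= 0))
    v <- c(v, "trials$onset: onsets must be increasing")
  if (any(tr$sf <= 0)) v <- c(v, "trials$sf: nonpositive spatial frequency")
  if (length(session@lfp)) {
    d <- session@lfp$channelDepths
    if (is.unsorted(d)) v <- c(v, "lfp$channelDepths: not ordered by depth")
  }
  v
}

#' Pipeline run configuration
#'
#' Aggregates the analysis parameters; defaults equal the protocol values
#' (50 ms latency, 1 s stimulus, 10-neuron subpopulations, 10 outer /
#' 6 inner folds, 11-value C grid, up to 200 NDC combinations, 60%
#' sensitivity threshold). All defaults are overridable.
#'
#' @param session A [sessionConfig()] (simulated input) or a path to a
#'   session JSON.
#' @param k,stride Subpopulation size and step.
#' @param families Classifier families.
#' @param folds,innerFolds Outer / inner CV folds.
#' @param cGrid Regularization grid.
#' @param pairs Orientation-pair subset (`NULL` = all).
#' @param ndcReps Max neuron combinations per NDC size.
#' @param ndcMaxN Largest NDC subpopulation size.
#' @param sensThreshold Sensitivity accuracy threshold.
#' @param latency Response latency (s).
#' @param window Decoding window (s after onset).
#' @param seed Master seed.
#' @return list of class `RunConfig`.
#' @export
runConfig <- function(session = sessionConfig(), k = 10L, stride = 1L,
                      families = classifierFamilies(), folds = 10L,
                      innerFolds = 6L, cGrid = 10^(-6:4), pairs = NULL,
                      ndcReps = 200L, ndcMaxN = 10L, sensThreshold = 0.6,
                      latency = 0.05, window = c(0.05, 1.05), seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "RunConfig"
  cfg
}

.pipelineStages <- c("simulate", "layers", "tuning", "decode", "ndc",
                     "sensitivity", "report")

#' Run the laminar decoding pipeline
#'
#' Executes simulate -> layers -> tuning -> decode -> ndc -> sensitivity ->
#' report, writing each stage's artifact (CSV/JSON) under `outDir`. Stages
#' are idempotent: when a stage artifact exists and the manifest's config
#' hash matches, it is reused instead of recomputed, so the pipeline can be
#' resumed or run stage-by-stage. A manifest records the config, its hash
#' and the completed stages.
#'
#' @param config A [runConfig()].
#' @param outDir Output directory (created if needed).
#' @param stages Stages to run (prerequisites are loaded from disk).
#' @param overwrite Recompute even when a matching artifact exists.
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(config = runConfig(), outDir,
                        stages = .pipelineStages, overwrite = FALSE,
                        quiet = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  stages <- match.arg(stages, .pipelineStages, several.ok = TRUE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)
  hash <- rlang::hash(config)
  manPath <- file.path(outDir, "manifest.json")
  man <- if (file.exists(manPath))
    jsonlite::read_json(manPath, simplifyVector = TRUE) else
      list(configHash = hash, stages = character())
  if (!identical(man$configHash, hash)) {
    if (length(man$stages) && !overwrite)
      stop("outDir holds artifacts from a different config; ",
           "use overwrite = TRUE or a fresh directory")
    man <- list(configHash = hash, stages = character())
  }
  fresh <- function(stage, file) {
    overwrite || !(stage %in% man$stages) || !file.exists(file.path(outDir, file))
  }
  mark <- function(stage) {
    man$stages <<- union(man$stages, stage)
    jsonlite::write_json(list(configHash = hash, stages = man$stages,
                              config = unclass(config)),
                         manPath, auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  res <- list()

  sessPath <- file.path(outDir, "session.json")
  needSession <- any(stages %in% .pipelineStages[1:5])
  if (needSession) {
    if ("simulate" %in% stages && fresh("simulate", "session.json")) {
      say("simulate: generating synthetic session")
      if (inherits(config$session, "SessionConfig")) {
        res$session <- simulateSession(config$session)
      } else {
        res$session <- readSessionJson(config$session)
      }
      viol <- validateSession(res$session)
      if (length(viol))
        stop("session validation failed:\n  ", paste(viol, collapse = "\n  "))
      writeSessionJson(res$session, sessPath)
      mark("simulate")
    } else {
      if (!file.exists(sessPath))
        stop("missing upstream artifact 'session.json' (run stage 'simulate')")
      say("simulate: reusing cached session")
      res$session <- readSessionJson(sessPath)
    }
  }

  modelPath <- file.path(outDir, "laminar_model.json")
  if (any(stages %in% .pipelineStages[2:6])) {
    if ("layers" %in% stages && fresh("layers", "laminar_model.json")) {
      say("layers: CSD and laminar model")
      lam <- estimateLaminarModel(res$session)
      res$model <- lam$model
      jsonlite::write_json(list(boundary46 = lam$model@boundary46,
                                boundaries = as.list(lam$model@boundaries),
                                top23 = lam$model@top23,
                                thicknesses = as.list(lam$model@thicknesses)),
                           modelPath, auto_unbox = TRUE, digits = NA)
      csdDf <- data.frame(depth = rep(lam$csd$depths, ncol(lam$csd$values)),
                          lag = rep(lam$csd$lags, each = nrow(lam$csd$values)),
                          csd = as.vector(lam$csd$values))
      utils::write.csv(csdDf, file.path(outDir, "csd.csv"), row.names = FALSE)
      mark("layers")
    } else {
      if (!file.exists(modelPath))
        stop("missing upstream artifact 'laminar_model.json' (run stage 'layers')")
      say("layers: reusing cached laminar model")
      mj <- jsonlite::read_json(modelPath, simplifyVector = TRUE)
      res$model <- buildLaminarModel(mj$boundary46, unlist(mj$thicknesses))
    }
  }

  metricsPath <- file.path(outDir, "metrics.csv")
  if (any(stages %in% .pipelineStages[3:7])) {
    if ("tuning" %in% stages && fresh("tuning", "metrics.csv")) {
      say("tuning: single-neuron metrics")
      res$metrics <- neuronMetrics(res$session, res$model,
                                   latency = config$latency)
      utils::write.csv(res$metrics, metricsPath, row.names = FALSE)
      mark("tuning")
    } else {
      if (!file.exists(metricsPath))
        stop("missing upstream artifact 'metrics.csv' (run stage 'tuning')")
      say("tuning: reusing cached metrics")
      res$metrics <- utils::read.csv(metricsPath, stringsAsFactors = FALSE)
    }
  }

  decodePath <- file.path(outDir, "decode.csv")
  if (any(stages %in% c("decode", "sensitivity", "report"))) {
    if ("decode" %in% stages && fresh("decode", "decode.csv")) {
      say("decode: pairwise subpopulation decoding")
      dec <- decodeSession(res$session, res$model, metrics = res$metrics,
                           k = config$k, stride = config$stride,
                           families = config$families, pairs = config$pairs,
                           folds = config$folds,
                           innerFolds = config$innerFolds,
                           cGrid = config$cGrid, seed = config$seed,
                           window = config$window)
      res$decode <- dec$results
      utils::write.csv(dec$results, decodePath, row.names = FALSE)
      mark("decode")
    } else if (file.exists(decodePath)) {
      say("decode: reusing cached results")
      res$decode <- utils::read.csv(decodePath, stringsAsFactors = FALSE)
    } else if (any(c("sensitivity", "report") %in% stages)) {
      stop("missing upstream artifact 'decode.csv' (run stage 'decode')")
    }
  }

  if ("ndc" %in% stages) {
    say("ndc: neuron-dropping curves")
    resp <- which(res$metrics$responsive)
    sfOpt <- .majority(res$metrics$optimalSf[resp])
    eyeOpt <- .majority(res$metrics$optimalEye[resp])
    pop <- buildResponseMatrix(res$session, window = config$window,
                               sf = sfOpt, eye = eyeOpt, neurons = resp)
    keptResp <- if (length(pop@excluded)) resp[-pop@excluded] else resp
    comps <- assignNeuronLayer(res$metrics$depth[keptResp], res$model)
    ndc <- neuronDroppingCurve(pop, comps,
                               nGrid = seq_len(config$ndcMaxN),
                               reps = config$ndcReps, pairs = config$pairs,
                               folds = config$folds, seed = config$seed)
    res$ndc <- ndc
    utils::write.csv(ndc, file.path(outDir, "ndc.csv"), row.names = FALSE)
    mark("ndc")
  }

  if ("sensitivity" %in% stages) {
    say("sensitivity: threshold orientation differences")
    fam <- if ("lda" %in% res$decode$family) "lda" else res$decode$family[1]
    dd <- res$decode[res$decode$family == fam, , drop = FALSE]
    sens <- do.call(rbind, lapply(split(dd, dd$subpop), function(s) {
      out <- decodingSensitivity(s, threshold = config$sensThreshold)
      out$subpop <- s$subpop[1]
      out$compartment <- s$compartment[1]
      out
    }))
    res$sensitivity <- sens
    utils::write.csv(sens, file.path(outDir, "sensitivity.csv"),
                     row.names = FALSE)
    mark("sensitivity")
  }

  if ("report" %in% stages) {
    say("report: compartment statistics")
    rep <- laminarStatsReport(res$metrics, res$decode)
    res$report <- rep
    jsonlite::write_json(
      list(kurtosisConvention = "Pearson (non-excess; Gaussian = 3)",
           omnibus = lapply(rep$omnibus, function(x) if (is.null(x)) NULL else
             list(statistic = x$statistic, df = x$df, p = x$p)),
           pairwise4C = lapply(rep$pairwise4C, function(x)
             if (is.null(x)) NULL else list(statistic = x$statistic, p = x$p)),
           ffAccuracy = rep$ffAccuracy),
      file.path(outDir, "stats.json"), auto_unbox = TRUE, digits = NA,
      force = TRUE)
    mark("report")
  }

  invisible(res)
}
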
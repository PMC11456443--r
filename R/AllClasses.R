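#' @import methods
NULL

#' Laminar compartment labels
#'
#' The four laminar compartments used throughout the package, ordered from
#' the pial surface downward, plus the sentinel `"out"` for depths outside
#' gray matter.
#'
#' @return Character vector of compartment labels.
#' @export
compartmentLabels <- function() c("2/3", "4A/B", "4C", "5/6")

#' ColumnSession: a single columnar recording session
#'
#' Container for one (real or simulated) penetration: per-neuron spike times
#' for every trial, the trial table (drift direction, spatial frequency, eye,
#' onset), and an optional multi-channel LFP block with channel depths.
#'
#' Depths are in micrometers below the pia and increase downward. Spike times
#' are absolute (seconds on the session clock); each trial presents a
#' stimulus for `duration` seconds followed by an `isi`-second blank.
#'
#' @slot neurons data.frame with at least `id` and `depth` (um); simulated
#'   sessions carry the generating parameters as extra columns.
#' @slot spikes list of length `nrow(neurons)`; element `n` is a list of
#'   length `nrow(trials)` of numeric spike-time vectors (possibly empty).
#' @slot trials data.frame with `trial`, `direction` (deg), `sf` (cyc/deg),
#'   `eye`, `onset` (s), `duration` (s), `isi` (s).
#' @slot lfp list with `data` (channels x samples matrix, uV),
#'   `channelDepths` (um), `fs` (Hz), `t0` (s); may be empty.
#' @slot config list; the `sessionConfig()` used to simulate, if any.
#'
#' @export
setClass("ColumnSession",
  slots = c(
    neurons = "data.frame",
    spikes  = "list",
    trials  = "data.frame",
    lfp     = "list",
    config  = "list"
  )
)

setValidity("ColumnSession", function(object) {
  msg <- character()
  ns <- object@neurons
  tr <- object@trials
  if (!all(c("id", "depth") %in% names(ns)))
    msg <- c(msg, "neurons must have columns 'id' and 'depth'")
  need <- c("trial", "direction", "sf", "eye", "onset", "duration", "isi")
  if (!all(need %in% names(tr)))
    msg <- c(msg, paste("trials must have columns:", paste(need, collapse = ", ")))
  if (length(object@spikes) != nrow(ns))
    msg <- c(msg, "spikes must have one element per neuron")
  if (length(object@spikes) && nrow(tr)) {
    nt <- vapply(object@spikes, length, integer(1))
    if (!all(nt == nrow(tr)))
      msg <- c(msg, "every neuron needs a spike-time list for every trial")
    lo <- min(tr$onset)
    hi <- max(tr$onset + tr$duration + tr$isi)
    rng <- range(unlist(object@spikes), na.rm = TRUE)
    if (is.finite(rng[1]) && (rng[1] < lo - 1e-9 || rng[2] > hi + 1e-9))
      msg <- c(msg, "spike times fall outside the trial epochs")
  }
  if (length(object@lfp)) {
    if (!all(c("data", "channelDepths", "fs") %in% names(object@lfp)))
      msg <- c(msg, "lfp must have 'data', 'channelDepths' and 'fs'")
    else if (nrow(object@lfp$data) != length(object@lfp$channelDepths))
      msg <- c(msg, "lfp rows must match channelDepths")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ColumnSession-class Number of neurons in the session.
#' @param session,object A `ColumnSession`.
#' @export
nNeurons <- function(session) nrow(session@neurons)

#' @describeIn ColumnSession-class Number of trials in the session.
#' @export
nTrials <- function(session) nrow(session@trials)

#' @describeIn ColumnSession-class Neuron depths (um below pia).
#' @export
neuronDepths <- function(session) session@neurons$depth

#' @describeIn ColumnSession-class The trial table.
#' @export
trialInfo <- function(session) session@trials

#' @describeIn ColumnSession-class The neuron table.
#' @export
neuronInfo <- function(session) session@neurons

#' @describeIn ColumnSession-class The LFP block (list), or empty list.
#' @export
lfpBlock <- function(session) session@lfp

#' Spike times for one neuron
#'
#' @param session A `ColumnSession`.
#' @param neuron Neuron index (row in `neuronInfo(session)`).
#' @param trial Optional trial index; if `NULL`, the full per-trial list.
#' @return Numeric vector of spike times (s), or list of vectors.
#' @export
spikeTimes <- function(session, neuron, trial = NULL) {
  st <- session@spikes[[neuron]]
  if (is.null(trial)) st else st[[trial]]
}

setMethod("show", "ColumnSession", function(object) {
  cat("ColumnSession with", nrow(object@neurons), "neurons,",
      nrow(object@trials), "trials\n")
  if (nrow(object@trials)) {
    cat("  directions:", length(unique(object@trials$direction)),
        " sf:", paste(sort(unique(object@trials$sf)), collapse = "/"),
        " eye:", paste(unique(object@trials$eye), collapse = "/"), "\n")
  }
  if (nrow(object@neurons))
    cat("  depth range:", paste(round(range(object@neurons$depth)), collapse = "-"),
        "um\n")
  if (length(object@lfp))
    cat("  LFP:", nrow(object@lfp$data), "channels x",
        ncol(object@lfp$data), "samples @", object@lfp$fs, "Hz\n")
})

#' LaminarModel: compartment boundaries along the probe
#'
#' Boundary depths of the four laminar compartments, anchored on the lower
#' boundary of the major current sink (the 4C/5-6 border) and offset by the
#' configured compartment thicknesses. Compartments are half-open depth
#' intervals `[upper, lower)`.
#'
#' @slot boundary46 numeric; depth (um) of the 4C/5-6 border (sink lower
#'   boundary).
#' @slot boundaries named numeric; depths of the borders
#'   `2/3|4A/B`, `4A/B|4C`, `4C|5/6`, `5/6|WM`.
#' @slot top23 numeric; upper limit of compartment 2/3 (um).
#' @slot thicknesses named numeric; compartment thicknesses (um).
#'
#' @export
setClass("LaminarModel",
  slots = c(
    boundary46 = "numeric",
    boundaries = "numeric",
    top23 = "numeric",
    thicknesses = "numeric"
  )
)

setValidity("LaminarModel", function(object) {
  b <- c(object@top23, object@boundaries)
  if (length(object@boundaries) != 4L)
    return("need the four boundaries 2/3|4A/B, 4A/B|4C, 4C|5/6, 5/6|WM")
  if (any(diff(b) <= 0))
    return("boundaries must be strictly increasing with depth")
  if (any(object@thicknesses <= 0))
    return("thicknesses must be positive")
  TRUE
})

setMethod("show", "LaminarModel", function(object) {
  cat("LaminarModel (um below pia)\n")
  lab <- compartmentLabels()
  lo <- c(object@top23, object@boundaries[1:3])
  hi <- object@boundaries
  for (i in seq_along(lab))
    cat(sprintf("  %-5s [%7.1f, %7.1f)\n", lab[i], lo[i], hi[i]))
})

#' @describeIn LaminarModel-class Boundary depths incl. the 2/3 upper limit.
#' @param model A `LaminarModel`.
#' @export
modelBoundaries <- function(model) c("top" = model@top23, model@boundaries)

#' PopulationResponse: trials x neurons response matrix for decoding
#'
#' Spike counts in the decoding window, normalized per neuron by the
#' session-wide maximum, together with orientation labels (direction mod
#' 180) and neuron depths.
#'
#' @slot X numeric matrix, trials x neurons, each column scaled to max 1.
#' @slot counts integer-valued matrix of raw window counts (same shape).
#' @slot y numeric; orientation label (deg in 0,10,...,170) per trial.
#' @slot depths numeric; depth (um) per neuron (column).
#' @slot trials data.frame; the trial rows that went into `X`.
#' @slot excluded integer; indices (in the original session) of neurons
#'   dropped for an all-zero decoding window.
#'
#' @export
setClass("PopulationResponse",
  slots = c(
    X = "matrix",
    counts = "matrix",
    y = "numeric",
    depths = "numeric",
    trials = "data.frame",
    excluded = "integer"
  )
)

setValidity("PopulationResponse", function(object) {
  if (nrow(object@X) != length(object@y))
    return("rows of X must align with orientation labels")
  if (ncol(object@X) != length(object@depths))
    return("columns of X must align with neuron depths")
  cmax <- suppressWarnings(apply(object@X, 2, max))
  if (ncol(object@X) && any(abs(cmax - 1) > 1e-8))
    return("each neuron column must be normalized to maximum 1")
  TRUE
})

setMethod("show", "PopulationResponse", function(object) {
  cat("PopulationResponse:", nrow(object@X), "trials x", ncol(object@X),
      "neurons;", length(unique(object@y)), "orientations\n")
})
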
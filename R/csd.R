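#' Average neighboring LFP channels into groups of four
#'
#' Each 4 adjacent channels (ordered by depth) are averaged into one group;
#' the group depth is the mean of its members' depths. Trailing channels
#' that do not fill a group are dropped.
#'
#' @param lfp LFP block: list with `data` (channels x samples),
#'   `channelDepths`, `fs`, and optionally `t0`.
#' @param groupSize Channels per group.
#' @return An LFP block with `floor(n/groupSize)` grouped channels.
#' @export
groupAverageLfp <- function(lfp, groupSize = 4L) {
  d <- lfp$channelDepths
  if (length(d) < 2 * groupSize)
    stop("need at least ", 2 * groupSize, " channels")
  if (is.unsorted(d, strictly = FALSE))
    stop("channels must be ordered by depth")
  nG <- floor(length(d) / groupSize)
  idx <- rep(seq_len(nG), each = groupSize)
  keep <- seq_len(nG * groupSize)
  dat <- rowsum(lfp$data[keep, , drop = FALSE], idx) / groupSize
  list(data = unname(dat),
       channelDepths = as.vector(tapply(d[keep], idx, mean)),
       fs = lfp$fs, t0 = if (is.null(lfp$t0)) 0 else lfp$t0)
}

#' Stimulus-triggered average of an LFP block
#'
#' Realigns the recording to each stimulus onset and averages across
#' onsets, yielding an event-related potential matrix.
#'
#' @param lfp LFP block (typically grouped; see [groupAverageLfp()]).
#' @param onsets Stimulus onset times (s).
#' @param window Length-2 start/end of the epoch relative to onset (s).
#' @return list with `erp` (channels x lags), `lags` (s), `channelDepths`.
#' @export
stimulusTriggeredAverage <- function(lfp, onsets, window = c(-0.05, 0.25)) {
  if (!length(onsets)) stop("need at least one onset")
  fs <- lfp$fs
  t0 <- if (is.null(lfp$t0)) 0 else lfp$t0
  lagIdx <- seq(round(window[1] * fs), round(window[2] * fs))
  nS <- ncol(lfp$data)
  acc <- matrix(0, nrow(lfp$data), length(lagIdx))
  for (on in onsets) {
    i0 <- round((on - t0) * fs) + 1
    cols <- i0 + lagIdx
    if (cols[1] < 1 || cols[length(cols)] > nS)
      stop("onset at ", on, " s falls outside the recording")
    acc <- acc + lfp$data[, cols, drop = FALSE]
  }
  list(erp = acc / length(onsets), lags = lagIdx / fs,
       channelDepths = lfp$channelDepths)
}

#' Current source density by the five-point formula
#'
#' Second spatial derivative of the potential along the probe, estimated
#' with the spacing-2 stencil spanning five contacts:
#' `CSD_i = -(phi_{i-2} - 2 phi_i + phi_{i+2}) / (2h)^2`. With this sign
#' convention a local minimum of the potential in depth (a sink) yields
#' negative CSD. The two outermost bins on each edge are undefined and
#' dropped; conductivity is set to 1 (arbitrary units).
#'
#' @param erp Stimulus-triggered average: list with `erp` (depth bins x
#'   lags), `lags`, `channelDepths` — or a plain matrix plus `depths`.
#' @param depths Depth (um) per row when `erp` is a matrix.
#' @return list of class `CsdProfile`: `values` (interior bins x lags),
#'   `depths`, `lags`, `spacing` (um).
#' @export
computeCsd <- function(erp, depths = NULL) {
  if (is.list(erp) && !is.null(erp$erp)) {
    phi <- erp$erp; depths <- erp$channelDepths
    lags <- erp$lags
  } else {
    phi <- as.matrix(erp)
    lags <- seq_len(ncol(phi))
  }
  nD <- nrow(phi)
  if (nD < 5) stop("need at least 5 depth groups")
  h <- stats::median(diff(depths))
  i <- 3:(nD - 2)
  vals <- -(phi[i - 2, , drop = FALSE] - 2 * phi[i, , drop = FALSE] +
              phi[i + 2, , drop = FALSE]) / (2 * h)^2
  if (any(!is.finite(vals))) stop("non-finite CSD values")
  structure(list(values = vals, depths = depths[i], lags = lags, spacing = h),
            class = "CsdProfile")
}

#' Smooth a CSD profile across depth
#'
#' Gaussian smoothing along the depth axis only (`sigma` in um). The kernel
#' is renormalized at the edges so a constant field is preserved; away from
#' the edges column sums are conserved.
#'
#' @param csd A `CsdProfile` from [computeCsd()].
#' @param sigma Gaussian SD (um).
#' @return The smoothed `CsdProfile`.
#' @export
smoothCsd <- function(csd, sigma = 120) {
  stopifnot(sigma > 0)
  d <- csd$depths
  W <- exp(-outer(d, d, "-")^2 / (2 * sigma^2))
  W <- W / rowSums(W)
  csd$values <- W %*% csd$values
  csd$sigma <- sigma
  csd
}

#' Locate the lower boundary of the major current sink
#'
#' Averages the (smoothed) CSD over an early response window, finds the
#' largest-magnitude sink (most negative bin), and returns the depth of the
#' sink-to-source zero crossing immediately below it, by linear
#' interpolation between bins. Ties or plateaus resolve toward the
#' shallower depth. If no bin is more negative than `zThreshold` times a
#' robust spread estimate, the profile is declared sink-free.
#'
#' @param csd A smoothed `CsdProfile`.
#' @param responseWindow Early response window (s after onset) over which
#'   the CSD is averaged for sink identification.
#' @param zThreshold Sink detection threshold (robust z units).
#' @param adjustGroups Manual boundary adjustment in units of one depth
#'   bin (group pitch); integer in -1..1 by convention.
#' @return Boundary depth (um), or `NA` with attribute `reason = "no sink"`.
#' @export
locateSinkBoundary <- function(csd, responseWindow = c(0.03, 0.1),
                               zThreshold = 2, adjustGroups = 0) {
  sel <- csd$lags >= responseWindow[1] & csd$lags <= responseWindow[2]
  if (!any(sel)) sel <- rep(TRUE, length(csd$lags))
  p <- rowMeans(csd$values[, sel, drop = FALSE])
  # noise scale from pre-stimulus lags when available, else the profile MAD
  base <- csd$lags < responseWindow[1] - 0.01
  spread <- if (sum(base) >= 2) {
    stats::sd(as.vector(csd$values[, base, drop = FALSE]))
  } else {
    stats::mad(p)
  }
  noSink <- structure(NA_real_, reason = "no sink")
  if (!any(p < 0)) return(noSink)
  sinkIdx <- which.min(p)
  # spread 0 (noise-free recording): any negative deflection is a sink
  if (spread > 0 && p[sinkIdx] > -zThreshold * spread) return(noSink)
  below <- seq(sinkIdx, length(p))
  cross <- which(p[below] < 0 & c(p[below][-1], NA) >= 0)
  if (!length(cross)) return(noSink)
  i <- below[cross[1]]
  d <- csd$depths
  if (p[i + 1] == 0) {
    # plateau at zero: take the shallowest zero bin
    j <- i + 1
    while (j > 1 && p[j - 1] == 0) j <- j - 1
    b <- d[j]
  } else {
    b <- d[i] + (0 - p[i]) / (p[i + 1] - p[i]) * (d[i + 1] - d[i])
  }
  b + adjustGroups * csd$spacing
}

#' Build a laminar model from the sink boundary and thickness offsets
#'
#' Anchors the 4C/5-6 border at `boundary46` and offsets the remaining
#' boundaries by the compartment thicknesses: the 4A/B|4C border lies one
#' 4C thickness above, the 2/3|4A/B border one 4A/B thickness above that,
#' and the 5/6|WM border one 5/6 thickness below.
#'
#' @param boundary46 Depth (um) of the 4C/5-6 border.
#' @param thicknesses Compartment thicknesses (um) for 2/3, 4A/B, 4C, 5/6.
#' @return A [LaminarModel-class].
#' @export
buildLaminarModel <- function(boundary46,
                              thicknesses = c(650, 311, 281, 489)) {
  stopifnot(length(thicknesses) == 4L)
  if (any(thicknesses <= 0)) stop("thickness offsets must be positive")
  if (is.na(boundary46)) stop("boundary46 is NA (no sink detected?)")
  th <- stats::setNames(as.numeric(thicknesses), compartmentLabels())
  b_4ab_4c <- boundary46 - th["4C"]
  b_23_4ab <- b_4ab_4c - th["4A/B"]
  b_56_wm <- boundary46 + th["5/6"]
  methods::new("LaminarModel",
               boundary46 = as.numeric(boundary46),
               boundaries = stats::setNames(
                 as.numeric(c(b_23_4ab, b_4ab_4c, boundary46, b_56_wm)),
                 c("2/3|4A/B", "4A/B|4C", "4C|5/6", "5/6|WM")),
               top23 = as.numeric(b_23_4ab - th["2/3"]),
               thicknesses = th)
}

#' Assign a depth to a laminar compartment
#'
#' Half-open interval membership `[upper, lower)`: a depth exactly on a
#' boundary belongs to the deeper compartment. Depths above compartment 2/3
#' or at/below the 5/6|WM border are `"out"`.
#'
#' @param depth Depth(s) in um below pia.
#' @param model A [LaminarModel-class].
#' @return Character vector of compartment labels (or `"out"`).
#' @export
assignNeuronLayer <- function(depth, model) {
  edges <- c(model@top23, model@boundaries)
  lab <- compartmentLabels()
  idx <- findInterval(depth, edges, left.open = FALSE, rightmost.closed = FALSE)
  out <- rep("out", length(depth))
  inside <- idx >= 1 & idx <= 4
  out[inside] <- lab[idx[inside]]
  out[is.na(depth)] <- NA_character_
  out
}

#' Estimate a laminar model from a session's LFP
#'
#' Convenience wrapper: group-average the LFP, stimulus-trigger, compute
#' and smooth the CSD, locate the sink lower boundary and offset the
#' compartment thicknesses.
#'
#' @param session A [ColumnSession-class] with an LFP block.
#' @param thicknesses Compartment thicknesses (um).
#' @param sigma CSD smoothing SD (um).
#' @param responseWindow Sink-identification window (s after onset).
#' @param ... Passed to [locateSinkBoundary()].
#' @return list with `model` ([LaminarModel-class]), `csd` (smoothed
#'   `CsdProfile`), `boundary46`.
#' @export
estimateLaminarModel <- function(session,
                                 thicknesses = session@config$thicknesses,
                                 sigma = 120,
                                 responseWindow = c(0.03, 0.1), ...) {
  if (!length(session@lfp)) stop("session has no LFP block")
  if (is.null(thicknesses)) thicknesses <- c(650, 311, 281, 489)
  lfp <- session@lfp
  tr <- trialInfo(session)
  tEnd <- (if (is.null(lfp$t0)) 0 else lfp$t0) + ncol(lfp$data) / lfp$fs
  ons <- tr$onset[tr$onset + 0.3 < tEnd & tr$onset > 0.04]
  g <- groupAverageLfp(lfp)
  sta <- stimulusTriggeredAverage(g, ons, window = c(-0.04, 0.2))
  csd <- smoothCsd(computeCsd(sta), sigma = sigma)
  b46 <- locateSinkBoundary(csd, responseWindow = responseWindow, ...)
  list(model = buildLaminarModel(b46, thicknesses), csd = csd,
       boundary46 = b46)
}
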
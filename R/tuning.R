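#' Visual-responsiveness gate
#'
#' A neuron passes the gate when its stimulus-period rates differ from the
#' inter-stimulus rates (two-tailed t-test, p < 0.01) and its best-condition
#' rate reaches at least 3 spikes/s.
#'
#' @param stimRates Per-trial stimulus-period firing rates (spikes/s).
#' @param isiRates Per-trial inter-stimulus rates (spikes/s).
#' @param maxRate The neuron's best-condition mean rate (spikes/s).
#' @param alpha Significance level.
#' @param minRate Minimum best-condition rate (spikes/s).
#' @return logical flag.
#' @export
responsivenessGate <- function(stimRates, isiRates, maxRate,
                               alpha = 0.01, minRate = 3) {
  if (length(stimRates) < 2 || length(isiRates) < 2)
    stop("need at least 2 trials in each period")
  if (maxRate < minRate) return(FALSE)
  if (stats::var(stimRates) == 0 && stats::var(isiRates) == 0)
    return(mean(stimRates) != mean(isiRates))
  p <- stats::t.test(stimRates, isiRates, alternative = "two.sided")$p.value
  is.finite(p) && p < alpha
}

#' Per-condition mean responses of one neuron
#'
#' Mean firing rate over the stimulus presentation period, offset by the
#' response latency, for every (direction x sf x eye) condition.
#'
#' @param session A [ColumnSession-class].
#' @param neuron Neuron index.
#' @param latency Response latency offset (s).
#' @param window Response window relative to onset (s); default latency to
#'   stimulus offset + latency.
#' @return data.frame with `direction`, `sf`, `eye`, `meanRate`, `nTrials`.
#' @export
conditionResponses <- function(session, neuron, latency = 0.05,
                               window = NULL) {
  tr <- trialInfo(session)
  if (is.null(window)) window <- c(latency, tr$duration[1] + latency)
  st <- session@spikes[[neuron]]
  counts <- vapply(seq_len(nrow(tr)), function(t) {
    s <- st[[t]] - tr$onset[t]
    sum(s >= window[1] & s < window[2])
  }, numeric(1))
  rate <- counts / diff(window)
  agg <- stats::aggregate(rate,
                          by = list(direction = tr$direction, sf = tr$sf,
                                    eye = tr$eye),
                          FUN = mean)
  n <- stats::aggregate(rate,
                        by = list(direction = tr$direction, sf = tr$sf,
                                  eye = tr$eye),
                        FUN = length)
  agg$nTrials <- n$x
  names(agg)[names(agg) == "x"] <- "meanRate"
  agg[order(agg$eye, agg$sf, agg$direction), , drop = FALSE]
}

#' Select the optimal eye and spatial-frequency condition
#'
#' Returns the (eye, sf) pair maximizing the neuron's maximum direction
#' response. Ties resolve to the lower spatial frequency, then the first
#' eye label.
#'
#' @param responses data.frame from [conditionResponses()].
#' @return list with `eye`, `sf`, `maxRate`.
#' @export
selectOptimalCondition <- function(responses) {
  if (!nrow(responses)) stop("no conditions")
  peak <- stats::aggregate(responses$meanRate,
                           by = list(eye = responses$eye, sf = responses$sf),
                           FUN = max)
  peak <- peak[order(peak$sf, match(peak$eye, unique(responses$eye))), ]
  best <- peak[which.max(peak$x), ]  # which.max: first max -> lower sf, first eye
  list(eye = as.character(best$eye), sf = best$sf, maxRate = best$x)
}

#' Direction index
#'
#' `(pref - opp) / (pref + opp)`: response at the preferred orientation and
#' drift direction contrasted with the same orientation drifting the
#' opposite way.
#'
#' @param respPref,respOpp Nonnegative mean rates.
#' @return Direction index in \[-1, 1\], or `NA` when both rates are 0.
#' @export
directionIndex <- function(respPref, respOpp) {
  stopifnot(respPref >= 0, respOpp >= 0)
  s <- respPref + respOpp
  if (s == 0) return(NA_real_)
  (respPref - respOpp) / s
}

#' Orientation index
#'
#' `(pref - orth) / (pref + orth)`: preferred-orientation response
#' contrasted with the orthogonal (90 deg away) orientation.
#'
#' @param respPref,respOrth Nonnegative mean rates.
#' @return Orientation index in \[-1, 1\], or `NA` when both rates are 0.
#' @export
orientationIndex <- function(respPref, respOrth) {
  stopifnot(respPref >= 0, respOrth >= 0)
  s <- respPref + respOrth
  if (s == 0) return(NA_real_)
  (respPref - respOrth) / s
}

#' Modulation ratio F1/F0
#'
#' F0 is the mean rate over the response window; F1 is the amplitude of the
#' first harmonic at the grating temporal frequency, computed as twice the
#' magnitude of the discrete Fourier coefficient of the pooled spike train
#' divided by the total observation time. Spike times must be relative to
#' stimulus onset; trials are pooled phase-locked to onset.
#'
#' @param spikeTrains list of per-trial spike-time vectors (s, onset
#'   relative).
#' @param temporalFreq Grating temporal frequency (Hz).
#' @param window Response window (s).
#' @return F1/F0 (>= 0), or `NA` when no spikes fall in the window.
#' @export
modulationRatio <- function(spikeTrains, temporalFreq, window = c(0, 1)) {
  stopifnot(temporalFreq > 0)
  tt <- unlist(spikeTrains, use.names = FALSE)
  tt <- tt[tt >= window[1] & tt < window[2]]
  Ttot <- diff(window) * length(spikeTrains)
  if (!length(tt) || Ttot <= 0) return(NA_real_)
  f0 <- length(tt) / Ttot
  f1 <- 2 * Mod(sum(exp(-2i * pi * temporalFreq * tt))) / Ttot
  f1 / f0
}

#' Smooth an orientation tuning curve with a Hanning window
#'
#' Circular convolution (period 180 deg) of an 18-point orientation curve
#' with a raised-cosine kernel whose half width at half height is 20 deg
#' (full support 80 deg, nine taps at 10 deg spacing with zero endpoints),
#' normalized to unit sum.
#'
#' @param curve Numeric vector of 18 responses at orientations
#'   0, 10, ..., 170 deg.
#' @return Smoothed curve (same length).
#' @export
smoothTuning <- function(curve) {
  n <- length(curve)
  stopifnot(n == 18L)
  taps <- -4:4
  k <- 0.5 * (1 + cos(pi * taps / 4))
  k <- k / sum(k)
  idx <- outer(seq_len(n), taps, function(i, j) ((i - 1 + j) %% n) + 1L)
  as.vector(matrix(curve[idx], n)[, ] %*% k)
}

#' Fit a von Mises orientation tuning function
#'
#' Nonlinear least squares fit of
#' `y = a0 + a1 * exp(a2 * (cos(2x - 2*a3) - 1))` (x, a3 in degrees) to an
#' 18-point orientation curve, with a multi-start over a grid of preferred
#' angles to avoid local minima. The preferred angle is reported mod 180.
#'
#' @param curve 18 responses at orientations 0, 10, ..., 170 deg
#'   (typically smoothed; see [smoothTuning()]).
#' @param orientations Orientation grid (deg).
#' @return list of class `VonMisesFit`: `a0`, `a1`, `a2`, `a3`, `rSquared`,
#'   `converged`, `fitted`.
#' @export
fitVonMises <- function(curve, orientations = seq(0, 170, by = 10)) {
  stopifnot(length(curve) == length(orientations), all(curve >= -1e-9))
  vm <- function(x, a0, a1, a2, a3)
    a0 + a1 * exp(a2 * (cos(2 * (x - a3) * pi / 180) - 1))
  ssTot <- sum((curve - mean(curve))^2)
  if (ssTot < 1e-12) {
    # flat curve: degenerate but well-defined
    fit <- list(a0 = mean(curve), a1 = 0, a2 = 0,
                a3 = orientations[which.max(curve)], rSquared = 0,
                converged = TRUE, fitted = rep(mean(curve), length(curve)))
    class(fit) <- "VonMisesFit"
    return(fit)
  }
  best <- NULL
  df <- data.frame(x = orientations, y = curve)
  amp0 <- max(curve) - min(curve)
  for (a3start in seq(0, 160, by = 20)) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a0 + a1 * exp(a2 * (cos(2 * (x - a3) * pi / 180) - 1)),
        data = df,
        start = list(a0 = max(min(curve), 1e-3), a1 = max(amp0, 1e-3),
                     a2 = 2, a3 = a3start),
        lower = c(0, 0, 1e-4, -360), upper = c(Inf, Inf, 500, 720),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(f)) next
    rss <- sum(stats::residuals(f)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(rss = rss, coef = stats::coef(f))
  }
  if (is.null(best)) {
    fit <- list(a0 = NA_real_, a1 = NA_real_, a2 = NA_real_, a3 = NA_real_,
                rSquared = NA_real_, converged = FALSE, fitted = rep(NA_real_,
                                                                     length(curve)))
    class(fit) <- "VonMisesFit"
    return(fit)
  }
  co <- best$coef
  fit <- list(a0 = unname(co["a0"]), a1 = unname(co["a1"]),
              a2 = unname(co["a2"]), a3 = unname(co["a3"]) %% 180,
              rSquared = 1 - best$rss / ssTot, converged = TRUE)
  fit$fitted <- vm(orientations, fit$a0, fit$a1, fit$a2, fit$a3)
  class(fit) <- "VonMisesFit"
  fit
}

#' Orientation tuning bandwidth from a von Mises fit
#'
#' Locates the fitted-curve peak and the two flanking orientations where
#' the fitted response first drops to `criterion` times the peak; the
#' bandwidth is half their angular separation. If the curve never drops
#' below the criterion, the sentinel 180 deg is returned. The closed form
#' is `0.5 * acos(1 + log(q) / a2)` (deg) with
#' `q = (criterion * peak - a0) / a1`.
#'
#' @param fit A `VonMisesFit`.
#' @param criterion Drop criterion as a fraction of the peak; `1/sqrt(2)`
#'   (default) or `1/2`.
#' @return Bandwidth in degrees, in (0, 180\].
#' @export
tuningBandwidth <- function(fit, criterion = 1 / sqrt(2)) {
  stopifnot(inherits(fit, "VonMisesFit"), criterion > 0, criterion < 1)
  if (!isTRUE(fit$converged) || is.na(fit$a1)) return(NA_real_)
  peak <- fit$a0 + fit$a1
  if (fit$a1 <= 1e-12 || peak <= 0) return(180)
  trough <- fit$a0 + fit$a1 * exp(-2 * fit$a2)
  target <- criterion * peak
  if (trough >= target) return(180)   # never drops below the criterion
  q <- (target - fit$a0) / fit$a1
  if (q <= 0) return(180)             # baseline alone exceeds criterion: cannot drop
  arg <- 1 + log(q) / fit$a2
  if (arg < -1) return(90)
  0.5 * acos(arg) * 180 / pi
}

#' Fano factor of windowed spike counts
#'
#' For each stimulus condition, spikes are counted in non-overlapping
#' 100 ms windows tiling the stimulus period; the per-window Fano factor is
#' the across-trial variance over mean of the counts (sample variance,
#' n - 1 denominator). Ratios are averaged over windows and then over
#' conditions; windows with zero mean count are excluded.
#'
#' @param spikeTrains list of per-trial spike-time vectors (s, onset
#'   relative).
#' @param conditions Condition label per trial.
#' @param period Stimulus period tiled by the windows (s).
#' @param windowSize Counting window (s).
#' @return Fano factor (>= 0), or `NA` when every window has zero mean.
#' @export
fanoFactor <- function(spikeTrains, conditions,
                       period = c(0, 1), windowSize = 0.1) {
  stopifnot(length(spikeTrains) == length(conditions))
  edges <- seq(period[1], period[2], by = windowSize)
  nW <- length(edges) - 1L
  counts <- t(vapply(spikeTrains, function(s) {
    s <- s[s >= period[1] & s < period[2]]
    tabulate(findInterval(s, edges, rightmost.closed = TRUE), nbins = nW)
  }, numeric(nW)))
  perCond <- vapply(split(seq_along(conditions), conditions), function(tr) {
    if (length(tr) < 2) return(NA_real_)
    cm <- counts[tr, , drop = FALSE]
    mu <- colMeans(cm)
    v <- apply(cm, 2, stats::var)
    ok <- mu > 0
    if (!any(ok)) return(NA_real_)
    mean(v[ok] / mu[ok])
  }, numeric(1))
  if (all(is.na(perCond))) return(NA_real_)
  mean(perCond, na.rm = TRUE)
}

#' Single-neuron metrics table for a session
#'
#' Computes, for every neuron: the responsiveness gate, optimal eye and
#' spatial frequency, maximum rate, F1/F0 modulation ratio, direction and
#' orientation indices, von Mises fit (R-squared, preferred orientation),
#' tuning bandwidth and Fano factor — all at the neuron's optimal
#' condition. The orientation curve is formed by averaging responses at
#' directions theta and theta + 180 before Hanning smoothing and fitting.
#'
#' @param session A [ColumnSession-class].
#' @param model Optional [LaminarModel-class]; adds a `compartment` column.
#' @param latency Response latency offset (s).
#' @param bandwidthCriterion Drop criterion for [tuningBandwidth()].
#' @return data.frame, one row per neuron.
#' @export
neuronMetrics <- function(session, model = NULL, latency = 0.05,
                          bandwidthCriterion = 1 / sqrt(2)) {
  tr <- trialInfo(session)
  dur <- tr$duration[1]
  drift <- session@config$driftSpeed
  if (is.null(drift)) drift <- 2
  out <- vector("list", nNeurons(session))
  for (n in seq_len(nNeurons(session))) {
    resp <- conditionResponses(session, n, latency = latency)
    opt <- selectOptimalCondition(resp)
    sel <- resp$eye == opt$eye & resp$sf == opt$sf
    dirCurve <- resp$meanRate[sel][order(resp$direction[sel])]
    dirs <- sort(resp$direction[sel])
    # orientation curve: average opposite drift directions
    oriCurve <- (dirCurve[seq_len(18)] + dirCurve[19:36]) / 2
    sm <- smoothTuning(oriCurve)
    prefDirIdx <- which.max(dirCurve)  # ties -> smaller angle
    prefDir <- dirs[prefDirIdx]
    oppDir <- (prefDir + 180) %% 360
    orthDir <- (prefDir + 90) %% 360
    rAt <- function(d) dirCurve[match(d, dirs)]
    di <- directionIndex(rAt(prefDir), rAt(oppDir))
    oi <- orientationIndex(rAt(prefDir),
                           (rAt(orthDir) + rAt((prefDir + 270) %% 360)) / 2)
    fit <- fitVonMises(sm)
    bw <- tuningBandwidth(fit, criterion = bandwidthCriterion)
    # responsiveness: rates at the optimal condition vs blank rates
    optTrials <- which(tr$sf == opt$sf & tr$eye == opt$eye)
    stimRates <- vapply(optTrials, function(t) {
      s <- session@spikes[[n]][[t]] - tr$onset[t]
      sum(s >= latency & s < dur + latency) / dur
    }, numeric(1))
    isiRates <- vapply(optTrials, function(t) {
      s <- session@spikes[[n]][[t]] - tr$onset[t]
      sum(s >= dur + latency & s < dur + tr$isi[t]) / (tr$isi[t] - latency)
    }, numeric(1))
    responsive <- responsivenessGate(stimRates, isiRates, opt$maxRate)
    prefTrials <- which(tr$direction == prefDir & tr$sf == opt$sf &
                          tr$eye == opt$eye)
    trains <- lapply(prefTrials, function(t)
      session@spikes[[n]][[t]] - tr$onset[t])
    f1f0 <- modulationRatio(trains, temporalFreq = drift * opt$sf,
                            window = c(0, dur))
    allTrains <- lapply(optTrials, function(t)
      session@spikes[[n]][[t]] - tr$onset[t])
    ff <- fanoFactor(allTrains, conditions = tr$direction[optTrials],
                     period = c(0, dur))
    out[[n]] <- data.frame(
      id = session@neurons$id[n], depth = session@neurons$depth[n],
      responsive = responsive, optimalEye = opt$eye, optimalSf = opt$sf,
      maxRate = opt$maxRate, modulationRatio = f1f0, di = di, oi = oi,
      prefOrientation = fit$a3, rSquared = fit$rSquared, bandwidth = bw,
      fano = ff, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (!is.null(model)) res$compartment <- assignNeuronLayer(res$depth, model)
  res
}
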
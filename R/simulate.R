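#' Configuration for a synthetic columnar session
#'
#' Bundles every knob of the synthetic-session generator. Defaults encode the
#' study conditions the pipeline targets: 36 drift directions in 10 deg steps,
#' 1 s stimulus with 0.25 s blank, spatial frequencies {0.5, 1, 2, 4} cyc/deg,
#' compartment thicknesses 650/311/281/489 um (layers 2/3, 4A/B, 4C, 5/6) and
#' per-compartment Fano-factor targets 1.87/1.62/1.28/1.94.
#'
#' @param nNeurons Total neuron count, split evenly across the four
#'   compartments.
#' @param thicknesses Compartment thicknesses (um) for 2/3, 4A/B, 4C, 5/6.
#' @param columnar If `TRUE`, all neurons share a preferred orientation
#'   (single orientation column); if `FALSE`, preference drifts with depth.
#' @param repsPerDirection Stimulus repetitions per condition (>= 2; the
#'   protocol uses 5 or 10).
#' @param sfSet Spatial frequencies tested (cyc/deg).
#' @param eyes Eye-condition labels.
#' @param seed Integer seed; all generator randomness derives from it.
#' @param prefOrientation Column preferred orientation (deg in \[0, 180)).
#' @param orientationJitterSd Circular jitter (deg) of per-neuron preferred
#'   orientation around the column preference.
#' @param driftRange For non-columnar sessions, total monotonic drift (deg)
#'   of preferred orientation across the probe.
#' @param fanoTargets Per-compartment Fano-factor targets.
#' @param baselineRate,amplitude Mean untuned and tuned response components
#'   (spikes/s); per-neuron values are log-normally jittered around these.
#' @param concentration Mean von Mises concentration (dimensionless); 2.2
#'   yields a median orientation index near 0.7 and bandwidth near 16 deg.
#' @param directionBias Mean direction bias in \[0, 1\] (equals the direction
#'   index); given per compartment.
#' @param modRatioTargets Mean F1/F0 targets per compartment (4C
#'   simple-cell dominated).
#' @param noiseCorr Within-compartment pairwise spike-count correlation
#'   imposed via a trial-reordering copula (0 disables).
#' @param heterogeneity Scale factor on all neuron-to-neuron parameter
#'   jitters (1 = default realism; 0 = identical neurons within a
#'   compartment up to preferred-direction assignment). Set low for clean
#'   compartment-contrast experiments where only the planted per-compartment
#'   differences should matter.
#' @param spontRate Spontaneous rate (spikes/s) during the inter-stimulus
#'   blank.
#' @param driftSpeed Grating drift speed (deg/s); the temporal frequency of
#'   response modulation is `driftSpeed * sf`.
#' @param duration,isi Stimulus-on and blank durations (s).
#' @param sfBandwidthOct Spatial-frequency tuning width (octaves).
#' @param lfp Generate an LFP block?
#' @param lfpEpochs Number of leading trials covered by the LFP recording.
#' @param lfpNoiseSd LFP additive noise SD (uV).
#' @param lfpAmplitude Peak LFP amplitude (uV).
#' @param channelPitch Probe contact spacing (um).
#' @param fs LFP sampling rate (Hz).
#' @param depthMargin Extra depth (um) below the last compartment covered by
#'   the probe.
#' @param depthPlacement `"random"` (uniform within compartments; realistic)
#'   or `"even"` (regular spacing within compartments; makes subpopulation
#'   composition deterministic for controlled contrasts).
#' @return A list of class `SessionConfig`.
#' @export
sessionConfig <- function(nNeurons = 120,
                          thicknesses = c(650, 311, 281, 489),
                          columnar = TRUE,
                          repsPerDirection = 10,
                          sfSet = c(0.5, 1, 2, 4),
                          eyes = "right",
                          seed = 1L,
                          prefOrientation = 90,
                          orientationJitterSd = 4,
                          driftRange = 120,
                          fanoTargets = c(1.87, 1.62, 1.28, 1.94),
                          baselineRate = 8.6,
                          amplitude = 28,
                          concentration = 3,
                          directionBias = c(0.45, 0.45, 0.25, 0.45),
                          modRatioTargets = c(0.5, 0.6, 1.1, 0.5),
                          noiseCorr = 0,
                          heterogeneity = 1,
                          spontRate = 3,
                          driftSpeed = 2,
                          duration = 1,
                          isi = 0.25,
                          sfBandwidthOct = 1.5,
                          lfp = TRUE,
                          lfpEpochs = 20,
                          lfpNoiseSd = 5,
                          lfpAmplitude = 100,
                          channelPitch = 20,
                          fs = 2500,
                          depthMargin = 200,
                          depthPlacement = c("random", "even")) {
  cfg <- as.list(environment())
  cfg$depthPlacement <- match.arg(depthPlacement)
  stopifnot(length(cfg$thicknesses) == 4L)
  if (any(cfg$thicknesses <= 0)) stop("compartment thicknesses must be positive")
  if (cfg$repsPerDirection < 2) stop("repsPerDirection must be at least 2")
  if (cfg$noiseCorr < 0 || cfg$noiseCorr > 0.5)
    stop("noiseCorr must lie in [0, 0.5]")
  if (any(cfg$fanoTargets <= 0)) stop("fanoTargets must be positive")
  names(cfg$thicknesses) <- names(cfg$fanoTargets) <- compartmentLabels()
  class(cfg) <- "SessionConfig"
  cfg
}

#' Build the pseudorandom stimulus schedule
#'
#' Full factorial of 36 drift directions (0-350 deg, 10 deg steps) x spatial
#' frequency x eye, each condition repeated exactly `repsPerDirection` times,
#' in a pseudorandom order. Onsets tile the session with
#' `duration + isi`-second epochs, starting after one blank.
#'
#' @param cfg A `SessionConfig`.
#' @param seed Seed for the pseudorandom ordering; `NULL` continues the
#'   current RNG stream (used internally by [simulateSession()]).
#' @return data.frame with `trial`, `direction`, `sf`, `eye`, `onset`,
#'   `duration`, `isi`.
#' @export
buildStimulusSchedule <- function(cfg, seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(direction = seq(0, 350, by = 10),
                      sf = cfg$sfSet, eye = cfg$eyes,
                      stringsAsFactors = FALSE)
  full <- grid[rep(seq_len(nrow(grid)), each = cfg$repsPerDirection), ]
  ord <- sample.int(nrow(full))
  full <- full[ord, , drop = FALSE]
  n <- nrow(full)
  data.frame(trial = seq_len(n),
             direction = full$direction,
             sf = full$sf,
             eye = full$eye,
             onset = cfg$isi + (seq_len(n) - 1) * (cfg$duration + cfg$isi),
             duration = cfg$duration,
             isi = cfg$isi,
             row.names = NULL)
}

#' Sample spike counts with a target Fano factor
#'
#' Draws counts whose variance/mean ratio converges to `fano`. For
#' `fano > 1` a gamma-Poisson (negative binomial) mixture is used with
#' dispersion solved from the target at the given mean
#' (`var = mu + mu^2/size = fano * mu`); `fano = 1` is Poisson; `fano < 1`
#' is realized by binomial thinning of a regular process
#' (`count ~ Binomial(round(mu/(1-fano)), 1-fano)`, giving FF `= fano`).
#'
#' @param mean Expected count(s); recycled against `n`.
#' @param fano Target Fano factor (> 0).
#' @param n Number of draws.
#' @return Integer-valued numeric vector of counts.
#' @export
sampleTrialCounts <- function(mean, fano = 1, n = length(mean)) {
  if (any(mean < 0)) stop("mean count must be nonnegative")
  if (fano <= 0) stop("fano must be positive")
  mu <- rep_len(mean, n)
  out <- numeric(n)
  pos <- mu > 0
  if (!any(pos)) return(out)
  if (abs(fano - 1) < 1e-12) {
    out[pos] <- stats::rpois(sum(pos), mu[pos])
  } else if (fano > 1) {
    out[pos] <- stats::rnbinom(sum(pos), mu = mu[pos],
                               size = mu[pos] / (fano - 1))
  } else {
    p <- 1 - fano
    out[pos] <- stats::rbinom(sum(pos), round(mu[pos] / p), p)
  }
  out
}

# Temporal modulation profile of the firing intensity over one stimulus
# second. modRatio is the target F1/F0: <= 1 uses 1 + m*cos, > 1 a
# rectified 1 + m'*cos with m' solved so the Fourier ratio matches
# (saturating at pi/2, the rectified-cosine limit).
.modulationProfile <- function(modRatio, temporalFreq, tGrid) {
  if (modRatio < 1e-9 || temporalFreq <= 0) return(rep(1, length(tGrid)))
  co <- cos(2 * pi * temporalFreq * tGrid)
  if (modRatio <= 1) return(1 + modRatio * co)
  ratioOf <- function(mp) {
    x <- seq(0, 2 * pi, length.out = 2048L)
    r <- pmax(0, 1 + mp * cos(x))
    2 * mean(r * cos(x)) / mean(r)
  }
  capRatio <- ratioOf(1e6)
  if (modRatio >= capRatio) {
    mp <- 1e6
  } else {
    mp <- stats::uniroot(function(lmp) ratioOf(exp(lmp)) - modRatio,
                         lower = log(1 + 1e-6), upper = log(1e6),
                         tol = 1e-8)$root
    mp <- exp(mp)
  }
  pmax(0, 1 + mp * co)
}

# Inverse-CDF sampler from a tabulated nonnegative intensity on tGrid.
.sampleFromProfile <- function(n, rho, tGrid) {
  if (n == 0L) return(numeric(0))
  if (all(rho <= 0)) rho <- rep(1, length(rho))
  cdf <- cumsum(rho) / sum(rho)
  # prepend zero so interpolation covers the full first bin
  stats::approx(c(0, cdf), c(tGrid[1], tGrid), xout = stats::runif(n),
                ties = "ordered")$y
}

#' Render spike times within a stimulus epoch
#'
#' Distributes `count` spikes over the stimulus window according to a
#' sinusoidal intensity at the grating temporal frequency, so that the
#' measured F1/F0 approximates `modRatio`. `modRatio = 0` gives an
#' (unmodulated) uniform placement; values above 1 use a rectified
#' sinusoidal intensity (ratio saturates at pi/2).
#'
#' @param count Number of spikes (>= 0).
#' @param modRatio Target F1/F0.
#' @param temporalFreq Modulation frequency (Hz); drift speed x spatial
#'   frequency for a drifting grating.
#' @param window Length-2 start/end of the epoch (s, stimulus-onset
#'   relative).
#' @return Sorted numeric vector of `count` spike times within `window`.
#' @export
renderSpikeTimes <- function(count, modRatio = 0, temporalFreq = 2,
                             window = c(0, 1)) {
  stopifnot(count >= 0, length(window) == 2L)
  if (count == 0L) return(numeric(0))
  tGrid <- seq(window[1], window[2], length.out = 1024L)
  rho <- .modulationProfile(modRatio, temporalFreq, tGrid)
  sort(.sampleFromProfile(count, rho, tGrid))
}

# Per-neuron, per-condition trial-reordering permutation that imposes an
# equicorrelated Gaussian-copula structure on count ranks. Returns an
# index matrix (trials x neurons) into the original trial rows.
.correlationPermutation <- function(counts, rTarget, conditions) {
  n <- nrow(counts); p <- ncol(counts)
  idx <- matrix(seq_len(n), n, p)
  if (rTarget <= 0 || p < 2L) return(idx)
  for (g in split(seq_len(n), conditions)) {
    m <- length(g)
    if (m < 2L) next
    shared <- stats::rnorm(m)
    lat <- sqrt(rTarget) * shared +
      sqrt(1 - rTarget) * matrix(stats::rnorm(m * p), m, p)
    for (j in seq_len(p)) {
      ordCounts <- order(counts[g, j], stats::runif(m))
      latRank <- rank(lat[, j], ties.method = "first")
      idx[g, j] <- g[ordCounts][latRank]
    }
  }
  idx
}

#' Impose within-group noise correlations by trial reordering
#'
#' Reorders each neuron's trials within every stimulus condition so that
#' count ranks follow an equicorrelated Gaussian copula, yielding an average
#' pairwise spike-count correlation close to `rTarget` while leaving every
#' neuron's marginal count distribution (hence mean and Fano factor) exactly
#' unchanged. Independent trial shuffling removes the imposed structure.
#'
#' @param counts Trials x neurons count matrix.
#' @param rTarget Target mean pairwise correlation in \[0, 0.5\].
#' @param conditions Stimulus-condition label per trial (correlations are a
#'   within-condition, i.e. noise, property); a single condition if `NULL`.
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return The reordered count matrix.
#' @export
imposeNoiseCorrelations <- function(counts, rTarget, conditions = NULL,
                                    seed = NULL) {
  counts <- as.matrix(counts)
  if (rTarget < 0 || rTarget > 0.5) stop("rTarget must lie in [0, 0.5]")
  if (ncol(counts) < 2L || rTarget == 0) return(counts)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(conditions)) conditions <- rep(1L, nrow(counts))
  idx <- .correlationPermutation(counts, rTarget, conditions)
  out <- counts
  for (j in seq_len(ncol(counts))) out[, j] <- counts[idx[, j], j]
  out
}

#' Synthesize a stimulus-locked laminar LFP block
#'
#' Forward model of a current dipole: a current sink spanning
#' `sinkRange` with its return source mirrored immediately below, so the
#' sink-to-source reversal sits exactly at `sinkRange[2]` (the 4C/5-6
#' border). The depth profile of the potential is obtained by twice
#' integrating the target current-source density, and every stimulus onset
#' triggers a smooth response transient peaking ~70 ms after onset.
#'
#' @param channelDepths Contact depths (um), ordered increasing.
#' @param sinkRange Length-2 upper/lower depth (um) of the sink.
#' @param onsets Stimulus onset times (s).
#' @param fs Sampling rate (Hz).
#' @param duration Total recording duration (s); defaults to cover the last
#'   onset plus 0.5 s.
#' @param amplitude Peak potential amplitude (uV); 0 gives a flat (no-sink)
#'   recording.
#' @param noiseSd Additive white-noise SD (uV).
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return list with `data` (channels x samples), `channelDepths`, `fs`,
#'   `t0 = 0`.
#' @export
synthesizeLfp <- function(channelDepths, sinkRange, onsets, fs = 2500,
                          duration = NULL, amplitude = 100, noiseSd = 0,
                          seed = NULL) {
  stopifnot(length(sinkRange) == 2L, sinkRange[1] < sinkRange[2])
  if (!is.null(seed)) set.seed(seed)
  if (is.null(duration)) duration <- max(onsets) + 0.5
  if (sinkRange[1] < min(channelDepths) || sinkRange[2] > max(channelDepths))
    stop("sink range must lie within the channel depth range")
  nT <- round(duration * fs)
  tt <- (seq_len(nT) - 1) / fs
  # target CSD: negative (sink) Gaussian bump over sinkRange, positive
  # source mirrored about the lower sink boundary -> zero crossing there
  ctr <- mean(sinkRange)
  sdz <- diff(sinkRange) / 4
  srcCtr <- 2 * sinkRange[2] - ctr
  D <- -exp(-(channelDepths - ctr)^2 / (2 * sdz^2)) +
    exp(-(channelDepths - srcCtr)^2 / (2 * sdz^2))
  h <- diff(channelDepths)
  h <- if (length(h)) stats::median(h) else 1
  phiP <- -cumsum(D) * h                    # phi'' = -D
  phi <- cumsum(phiP) * h
  phi <- phi - mean(phi)
  if (max(abs(phi)) > 0 && amplitude > 0) {
    phi <- phi / max(abs(phi)) * amplitude
  } else {
    phi <- phi * 0
  }
  s <- numeric(nT)
  for (on in onsets) {
    i0 <- floor((on + 0.03) * fs) + 1
    i1 <- min(nT, floor((on + 0.11) * fs))
    if (i0 > nT || i1 < i0) next
    seg <- seq(i0, i1)
    s[seg] <- s[seg] + sin(pi * (seg - i0) / (i1 - i0))^2
  }
  dat <- outer(phi, s)
  if (noiseSd > 0)
    dat <- dat + matrix(stats::rnorm(length(dat), sd = noiseSd), nrow(dat))
  list(data = dat, channelDepths = channelDepths, fs = fs, t0 = 0)
}

# True compartment boundaries implied by a config (depth 0 at top of 2/3).
.trueBoundaries <- function(cfg) cumsum(cfg$thicknesses)

#' Simulate a full columnar recording session
#'
#' Generates a [ColumnSession-class] with the statistical structure the
#' pipeline assumes: neurons evenly split across four laminar compartments,
#' von Mises direction tuning (shared preferred orientation when
#' `columnar = TRUE`, depth-drifting otherwise), spike counts drawn per
#' 100 ms window from a gamma-Poisson model hitting the per-compartment
#' Fano-factor targets, sinusoidal temporal modulation realizing the F1/F0
#' targets, optional within-compartment noise correlations, spontaneous
#' activity in the blanks, and a stimulus-locked LFP whose current sink
#' ends at the true 4C/5-6 border.
#'
#' @param cfg A [sessionConfig()].
#' @return A `ColumnSession`; the neuron table carries the generating
#'   parameters (`compartmentTrue`, `prefOrientation`, `fanoTarget`, ...).
#' @export
simulateSession <- function(cfg) {
  stopifnot(inherits(cfg, "SessionConfig"))
  set.seed(cfg$seed)
  trials <- buildStimulusSchedule(cfg, seed = NULL)
  nTr <- nrow(trials)
  bnd <- .trueBoundaries(cfg)
  tops <- c(0, bnd[-4])
  labs <- compartmentLabels()

  # neurons: even split, uniform depth within compartment, sorted by depth
  nPer <- diff(round(seq(0, cfg$nNeurons, length.out = 5)))
  depth <- unlist(lapply(1:4, function(i) {
    if (identical(cfg$depthPlacement, "even")) {
      tops[i] + (seq_len(nPer[i]) - 0.5) / nPer[i] * (bnd[i] - tops[i])
    } else {
      stats::runif(nPer[i], tops[i], bnd[i])
    }
  }))
  comp <- rep(labs, nPer)
  o <- order(depth)
  depth <- depth[o]; comp <- comp[o]
  N <- length(depth)
  span <- range(depth)
  het <- cfg$heterogeneity
  oriSd <- cfg$orientationJitterSd * het
  prefOr <- if (cfg$columnar) {
    (cfg$prefOrientation + stats::rnorm(N, 0, oriSd)) %% 180
  } else {
    (cfg$prefOrientation + cfg$driftRange * (depth - span[1]) /
       max(1, diff(span)) + stats::rnorm(N, 0, oriSd)) %% 180
  }
  prefDir <- (prefOr + 180 * stats::rbinom(N, 1, 0.5)) %% 360
  ci <- match(comp, labs)
  neurons <- data.frame(
    id = seq_len(N),
    depth = depth,
    compartmentTrue = comp,
    prefOrientation = prefOr,
    prefDirection = prefDir,
    baseline = cfg$baselineRate * stats::rlnorm(N, 0, 0.1 * het),
    amplitude = cfg$amplitude * stats::rlnorm(N, 0, 0.1 * het),
    concentration = cfg$concentration * stats::rlnorm(N, 0, 0.1 * het),
    directionBias = pmin(1, pmax(0, stats::rnorm(N, cfg$directionBias[ci],
                                                 0.05 * het))),
    modRatioTarget = pmax(0, stats::rnorm(N, cfg$modRatioTargets[ci],
                                          0.15 * het)),
    fanoTarget = cfg$fanoTargets[ci] * stats::rlnorm(N, 0, 0.03 * het),
    optimalSf = sample(cfg$sfSet, N, replace = TRUE,
                       prob = .sfPreferenceWeights(cfg$sfSet)),
    stringsAsFactors = FALSE
  )

  # per-trial mean rates and 100 ms window counts for every neuron
  nWin <- max(1L, round(cfg$duration / 0.1))
  tGrid <- seq(0, cfg$duration, length.out = 1024L)
  winId <- pmin(nWin, 1L + floor(tGrid / cfg$duration * nWin))
  countsList <- vector("list", N)
  profList <- vector("list", N)
  for (n in seq_len(N)) {
    nn <- neurons[n, ]
    dOr <- (trials$direction - nn$prefOrientation) * pi / 180
    dDir <- (trials$direction - nn$prefDirection) * pi / 180
    sfFac <- exp(-(log2(trials$sf / nn$optimalSf))^2 /
                   (2 * cfg$sfBandwidthOct^2))
    rate <- (nn$baseline + nn$amplitude *
               exp(nn$concentration * (cos(2 * dOr) - 1))) *
      (1 + nn$directionBias * cos(dDir)) * sfFac
    mu <- rate * cfg$duration
    # window fractions depend on sf (temporal frequency); profile per sf
    profs <- lapply(sort(unique(trials$sf)), function(s)
      .modulationProfile(nn$modRatioTarget, cfg$driftSpeed * s, tGrid))
    names(profs) <- as.character(sort(unique(trials$sf)))
    wf <- vapply(profs, function(r)
      tapply(r, winId, sum) / sum(r), numeric(nWin))
    muW <- t(wf[, as.character(trials$sf), drop = FALSE]) * mu  # trials x win
    cw <- matrix(sampleTrialCounts(as.vector(muW), nn$fanoTarget,
                                   length(muW)), nTr, nWin)
    countsList[[n]] <- cw
    profList[[n]] <- profs
  }

  if (cfg$noiseCorr > 0) {
    condId <- interaction(trials$direction, trials$sf, trials$eye, drop = TRUE)
    for (lab in labs) {
      grp <- which(neurons$compartmentTrue == lab)
      if (length(grp) < 2L) next
      tot <- vapply(countsList[grp], rowSums, numeric(nTr))
      idx <- .correlationPermutation(tot, cfg$noiseCorr, condId)
      for (k in seq_along(grp))
        countsList[[grp[k]]] <- countsList[[grp[k]]][idx[, k], , drop = FALSE]
    }
  }

  # render spike times: vectorized per (neuron, sf, window)
  spikes <- vector("list", N)
  winEdges <- seq(0, cfg$duration, length.out = nWin + 1L)
  for (n in seq_len(N)) {
    cw <- countsList[[n]]
    perTrial <- vector("list", nTr)
    for (s in names(profList[[n]])) {
      rows <- which(abs(trials$sf - as.numeric(s)) < 1e-12)
      rho <- profList[[n]][[s]]
      for (w in seq_len(nWin)) {
        sel <- winId == w
        cnt <- cw[rows, w]
        tot <- sum(cnt)
        if (tot == 0) next
        ts <- .sampleFromProfile(tot, rho[sel], tGrid[sel])
        tr <- rep(rows, cnt)
        sp <- split(ts, factor(tr, levels = rows))
        nz <- which(cnt > 0)
        for (k in nz)
          perTrial[[rows[k]]] <- c(perTrial[[rows[k]]], sp[[as.character(rows[k])]])
      }
    }
    spont <- stats::rpois(nTr, cfg$spontRate * cfg$isi)
    for (t in seq_len(nTr)) {
      st <- perTrial[[t]]
      if (is.null(st)) st <- numeric(0)
      if (spont[t] > 0)
        st <- c(st, cfg$duration + stats::runif(spont[t]) * cfg$isi)
      spikes[[n]][[t]] <- sort(st) + trials$onset[t]
    }
    if (nTr == 0) spikes[[n]] <- list()
  }

  lfp <- list()
  if (isTRUE(cfg$lfp)) {
    chan <- seq(0, bnd[4] + cfg$depthMargin, by = cfg$channelPitch)
    eps <- min(cfg$lfpEpochs, nTr)
    ons <- trials$onset[seq_len(eps)]
    lfp <- synthesizeLfp(chan, sinkRange = c(bnd[2], bnd[3]), onsets = ons,
                         fs = cfg$fs,
                         duration = max(ons) + cfg$duration + cfg$isi,
                         amplitude = cfg$lfpAmplitude,
                         noiseSd = cfg$lfpNoiseSd, seed = NULL)
  }

  methods::new("ColumnSession", neurons = neurons, spikes = spikes,
               trials = trials, lfp = lfp, config = unclass(cfg))
}

# Mild preference for mid spatial frequencies so a dominant optimal SF
# exists at the subpopulation level.
.sfPreferenceWeights <- function(sfSet) {
  if (length(sfSet) == 1L) return(1)
  w <- exp(-(log2(sfSet) - log2(stats::median(sfSet)))^2 / 2)
  w / sum(w)
}
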
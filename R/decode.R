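#' All pairwise orientation problems
#'
#' Enumerates unordered pairs of the tested orientations; 18 orientations
#' give 153 pairs. The pair's orientation difference is circular with
#' period 180 deg.
#'
#' @param orientations Orientation grid (deg).
#' @return data.frame with `ori1`, `ori2`, `dtheta`.
#' @export
orientationPairs <- function(orientations = seq(0, 170, by = 10)) {
  cmb <- utils::combn(sort(orientations), 2)
  d <- abs(cmb[2, ] - cmb[1, ])
  data.frame(ori1 = cmb[1, ], ori2 = cmb[2, ],
             dtheta = pmin(d, 180 - d))
}

#' Build the decoding response matrix
#'
#' Spike counts per trial in the decoding window (default 50-1050 ms after
#' onset, accounting for response latency), normalized per neuron by the
#' maximum over the selected trials. Orientation labels are direction mod
#' 180. Neurons whose window counts are all zero are excluded (recorded in
#' the `excluded` slot).
#'
#' @param session A [ColumnSession-class].
#' @param window Decoding window relative to onset (s).
#' @param sf,eye Optional condition restriction (e.g. the subpopulation's
#'   optimal spatial frequency); `NULL` keeps all trials.
#' @param neurons Optional neuron indices (default all).
#' @return A [PopulationResponse-class].
#' @export
buildResponseMatrix <- function(session, window = c(0.05, 1.05),
                                sf = NULL, eye = NULL, neurons = NULL) {
  tr <- trialInfo(session)
  if (window[2] > tr$duration[1] + tr$isi[1] + 1e-9 || window[1] < -1e-9)
    stop("decoding window must lie within the trial epoch")
  keep <- rep(TRUE, nrow(tr))
  if (!is.null(sf)) keep <- keep & tr$sf %in% sf
  if (!is.null(eye)) keep <- keep & tr$eye %in% eye
  tr <- tr[keep, , drop = FALSE]
  if (!nrow(tr)) stop("no trials match the requested condition")
  if (is.null(neurons)) neurons <- seq_len(nNeurons(session))
  counts <- vapply(neurons, function(n) {
    st <- session@spikes[[n]]
    vapply(seq_len(nrow(tr)), function(i) {
      s <- st[[tr$trial[i]]] - tr$onset[i]
      sum(s >= window[1] & s < window[2])
    }, numeric(1))
  }, numeric(nrow(tr)))
  counts <- matrix(counts, nrow(tr))
  cmax <- apply(counts, 2, max)
  dead <- which(cmax == 0)
  if (length(dead)) {
    message(length(dead), " neuron(s) excluded for all-zero decoding window")
    counts <- counts[, -dead, drop = FALSE]
    neurons <- neurons[-dead]
    cmax <- cmax[-dead]
  }
  X <- sweep(counts, 2, pmax(cmax, 1), "/")
  methods::new("PopulationResponse",
               X = X, counts = counts,
               y = tr$direction %% 180,
               depths = neuronDepths(session)[neurons],
               trials = tr, excluded = as.integer(dead))
}

#' Build depth-adjacent neuronal subpopulations
#'
#' Sliding window of `k` depth-adjacent neurons (default stride 1,
#' maximally overlapping). The subpopulation's center depth is the mean
#' depth of the two middle neurons (k even) or the middle neuron (k odd);
#' the compartment label, when a model is given, follows from the center
#' depth.
#'
#' @param depths Neuron depths (um), in the column order of the response
#'   matrix.
#' @param k Neurons per subpopulation.
#' @param stride Step between consecutive window starts.
#' @param model Optional [LaminarModel-class].
#' @return list with `info` (data.frame: `subpop`, `centerDepth`,
#'   `compartment`) and `members` (list of index vectors).
#' @export
buildSubpopulations <- function(depths, k = 10L, stride = 1L, model = NULL) {
  n <- length(depths)
  if (n < k) {
    warning("fewer than ", k, " neurons; no subpopulations")
    return(list(info = data.frame(subpop = integer(), centerDepth = numeric(),
                                  compartment = character()),
                members = list()))
  }
  ord <- order(depths)
  starts <- seq(1L, n - k + 1L, by = stride)
  members <- lapply(starts, function(s) ord[s:(s + k - 1L)])
  centers <- vapply(members, function(m) {
    d <- sort(depths[m])
    if (k %% 2 == 0) mean(d[k / 2 + c(0, 1)]) else d[(k + 1) / 2]
  }, numeric(1))
  comp <- if (is.null(model)) rep(NA_character_, length(starts)) else
    assignNeuronLayer(centers, model)
  list(info = data.frame(subpop = seq_along(starts), centerDepth = centers,
                         compartment = comp, stringsAsFactors = FALSE),
       members = members)
}

#' Independently shuffle training trials within classes
#'
#' For each class label, permutes each neuron's (column's) trial values
#' independently, preserving every neuron's per-class marginal distribution
#' while destroying cross-neuron correlations. Applied to training folds
#' only; test folds stay unshuffled.
#'
#' @param X Trials x neurons matrix (training fold).
#' @param y Class label per row.
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return The shuffled matrix.
#' @export
shuffleTrainingTrials <- function(X, y, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < 2) next
    for (j in seq_len(ncol(X)))
      X[idx, j] <- X[sample(idx), j]
  }
  X
}

# Core binary CV loop on a prepared X/y pair.
.cvAccuracy <- function(X, yb, family, folds = 10L, innerFolds = 6L,
                        cGrid = 10^(-6:4), shuffle = FALSE) {
  minClass <- min(table(yb))
  k <- folds
  if (minClass < k) {
    k <- max(2L, minClass)
    warning("class with fewer trials than folds; using ", k, " folds")
  }
  fid <- stratifiedFolds(yb, k)
  ok <- 0L
  for (f in seq_len(k)) {
    te <- fid == f
    Xtr <- X[!te, , drop = FALSE]; ytr <- yb[!te]
    if (shuffle) Xtr <- shuffleTrainingTrials(Xtr, ytr)
    pred <- .familyFitPredict(family, Xtr, ytr, X[te, , drop = FALSE],
                              cGrid, innerFolds)
    ok <- ok + sum(pred == yb[te])
  }
  ok / length(yb)
}

#' Pairwise orientation decoding for one subpopulation
#'
#' For every orientation pair, runs stratified outer cross-validation
#' (default 10-fold); logistic regression and the RBF SVM select their
#' regularization parameter C on an 11-value log grid by 6-fold inner
#' validation on each training fold; LDA uses Ledoit-Wolf covariance
#' shrinkage; Gaussian NB and random forest run at defaults. Accuracy is
#' the fraction of correct held-out classifications.
#'
#' @param pop A [PopulationResponse-class].
#' @param families Classifier families (subset of [classifierFamilies()]).
#' @param pairs data.frame from [orientationPairs()] (default all pairs
#'   present in the data).
#' @param neurons Column indices of the subpopulation (default all).
#' @param folds,innerFolds Outer and inner fold counts.
#' @param cGrid Regularization grid for LogR and SVM.
#' @param shuffle Shuffle training trials within classes
#'   ([shuffleTrainingTrials()])?
#' @param seed Base seed; fold assignment is re-seeded per pair.
#' @return data.frame: `family`, `ori1`, `ori2`, `dtheta`, `accuracy`,
#'   `nTrials`.
#' @export
pairwiseDecode <- function(pop, families = classifierFamilies(),
                           pairs = NULL, neurons = NULL,
                           folds = 10L, innerFolds = 6L,
                           cGrid = 10^(-6:4), shuffle = FALSE, seed = 1L) {
  stopifnot(all(families %in% classifierFamilies()))
  y <- pop@y
  if (length(unique(y)) < 2) stop("need at least two orientation classes")
  if (is.null(pairs)) pairs <- orientationPairs(unique(y))
  if (is.null(neurons)) neurons <- seq_len(ncol(pop@X))
  out <- vector("list", nrow(pairs) * length(families))
  r <- 0L
  for (p in seq_len(nrow(pairs))) {
    sel <- y == pairs$ori1[p] | y == pairs$ori2[p]
    Xp <- pop@X[sel, neurons, drop = FALSE]
    yb <- as.integer(y[sel] == pairs$ori2[p])
    for (fam in families) {
      set.seed((seed + 7919L * p + match(fam, classifierFamilies())) %%
                 .Machine$integer.max)
      acc <- .cvAccuracy(Xp, yb, fam, folds, innerFolds, cGrid, shuffle)
      r <- r + 1L
      out[[r]] <- data.frame(family = fam, ori1 = pairs$ori1[p],
                             ori2 = pairs$ori2[p], dtheta = pairs$dtheta[p],
                             accuracy = acc, nTrials = length(yb),
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out[seq_len(r)])
}

#' Decode every depth-adjacent subpopulation of a session
#'
#' Orchestrates the laminar decoding comparison: filters to responsive
#' neurons, forms sliding `k`-neuron subpopulations, restricts each
#' subpopulation to its optimal spatial-frequency/eye trials (majority of
#' member neurons' optima), and runs [pairwiseDecode()] per subpopulation
#' and classifier family.
#'
#' @param session A [ColumnSession-class].
#' @param model A [LaminarModel-class] for compartment labels.
#' @param metrics Optional precomputed [neuronMetrics()] table.
#' @param k,stride Subpopulation size and step ([buildSubpopulations()]).
#' @param families,pairs,folds,innerFolds,cGrid,shuffle,seed Passed to
#'   [pairwiseDecode()].
#' @param window Decoding window (s after onset).
#' @return list with `results` (tidy data.frame incl. `subpop`,
#'   `centerDepth`, `compartment`), `subpops`, `metrics`.
#' @export
decodeSession <- function(session, model, metrics = NULL, k = 10L,
                          stride = 1L, families = classifierFamilies(),
                          pairs = NULL, folds = 10L, innerFolds = 6L,
                          cGrid = 10^(-6:4), shuffle = FALSE, seed = 1L,
                          window = c(0.05, 1.05)) {
  if (is.null(metrics)) metrics <- neuronMetrics(session, model)
  resp <- which(metrics$responsive)
  if (length(resp) < k) stop("fewer than k responsive neurons")
  sub <- buildSubpopulations(metrics$depth[resp], k = k, stride = stride,
                             model = model)
  popCache <- list()
  res <- vector("list", nrow(sub$info))
  for (s in seq_len(nrow(sub$info))) {
    mem <- resp[sub$members[[s]]]
    sfOpt <- .majority(metrics$optimalSf[mem])
    eyeOpt <- .majority(metrics$optimalEye[mem])
    key <- paste(sfOpt, eyeOpt)
    if (is.null(popCache[[key]]))
      popCache[[key]] <- buildResponseMatrix(session, window = window,
                                             sf = sfOpt, eye = eyeOpt,
                                             neurons = resp)
    pop <- popCache[[key]]
    cols <- match(mem, setdiff(resp, resp[pop@excluded]))
    cols <- cols[!is.na(cols)]
    d <- pairwiseDecode(pop, families = families, pairs = pairs,
                        neurons = cols, folds = folds,
                        innerFolds = innerFolds, cGrid = cGrid,
                        shuffle = shuffle, seed = seed + 1000L * s)
    d$subpop <- sub$info$subpop[s]
    d$centerDepth <- sub$info$centerDepth[s]
    d$compartment <- sub$info$compartment[s]
    d$optimalSf <- sfOpt
    res[[s]] <- d
  }
  list(results = do.call(rbind, res), subpops = sub, metrics = metrics)
}

.majority <- function(x) {
  tb <- sort(table(x), decreasing = TRUE)
  v <- names(tb)[1]
  if (is.numeric(x)) as.numeric(v) else v
}

#' Single-neuron decoding
#'
#' Runs the pairwise decoding suite with `k = 1` subpopulations: each
#' responsive neuron is its own decoder.
#'
#' @inheritParams decodeSession
#' @return As [decodeSession()].
#' @export
singleNeuronDecode <- function(session, model, metrics = NULL,
                               families = c("lda", "nb"), pairs = NULL,
                               folds = 10L, innerFolds = 6L,
                               cGrid = 10^(-6:4), seed = 1L,
                               window = c(0.05, 1.05)) {
  decodeSession(session, model, metrics = metrics, k = 1L, stride = 1L,
                families = families, pairs = pairs, folds = folds,
                innerFolds = innerFolds, cGrid = cGrid, seed = seed,
                window = window)
}

#' Neuron-dropping curves per compartment
#'
#' For each compartment and each subpopulation size `n`, samples up to
#' `reps` distinct neuron combinations (all of them when fewer exist) and
#' records the LDA decoding accuracy averaged over orientation pairs.
#'
#' @param pop A [PopulationResponse-class].
#' @param compartments Compartment label per neuron (column of `pop@X`).
#' @param nGrid Subpopulation sizes; default `1:min(10, compartment size)`.
#' @param reps Maximum combinations per size.
#' @param pairs Orientation pairs (default all present).
#' @param folds Outer CV folds.
#' @param seed Base seed.
#' @return data.frame: `compartment`, `n`, `combo`, `accuracy`.
#' @export
neuronDroppingCurve <- function(pop, compartments, nGrid = NULL,
                                reps = 200L, pairs = NULL, folds = 10L,
                                seed = 1L) {
  stopifnot(length(compartments) == ncol(pop@X))
  out <- list()
  for (comp in unique(compartments)) {
    idx <- which(compartments == comp)
    m <- length(idx)
    sizes <- if (is.null(nGrid)) seq_len(min(10L, m)) else nGrid[nGrid <= m]
    for (n in sizes) {
      set.seed((seed + 131L * n + match(comp, unique(compartments))) %%
                 .Machine$integer.max)
      combos <- .sampleCombinations(m, n, reps)
      for (ci in seq_along(combos)) {
        nm <- idx[combos[[ci]]]
        d <- pairwiseDecode(pop, families = "lda", pairs = pairs,
                            neurons = nm, folds = folds,
                            seed = seed + 17L * ci + n)
        out[[length(out) + 1L]] <- data.frame(
          compartment = comp, n = n, combo = ci,
          accuracy = mean(d$accuracy), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

# Up to `reps` distinct size-n subsets of 1:m (all when few enough).
.sampleCombinations <- function(m, n, reps) {
  total <- choose(m, n)
  if (total <= reps) {
    cmb <- utils::combn(m, n)
    return(lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  seen <- new.env(hash = TRUE)
  out <- list()
  guard <- 0L
  while (length(out) < reps && guard < 50L * reps) {
    guard <- guard + 1L
    s <- sort(sample.int(m, n))
    key <- paste(s, collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      out[[length(out) + 1L]] <- s
    }
  }
  out
}

#' Threshold crossing of an accuracy-vs-delta-theta curve
#'
#' Linear interpolation of the first crossing of `threshold` along
#' increasing orientation difference. If performance already meets the
#' threshold at the smallest tested difference, the minimum difference is
#' clamped there; if the threshold is never reached, it is floored at the
#' largest difference (90 deg).
#'
#' @param dtheta Orientation differences (deg), increasing.
#' @param accuracy Decoder accuracy at each difference.
#' @param threshold Performance threshold (default 0.60).
#' @param clampLow,floorHigh Edge conventions (see above); both default on.
#' @return list with `dthetaMin` (deg) and `sensitivity` (1/deg).
#' @export
sensitivityFromCurve <- function(dtheta, accuracy, threshold = 0.6,
                                 clampLow = TRUE, floorHigh = TRUE) {
  stopifnot(length(dtheta) == length(accuracy), length(dtheta) >= 1)
  o <- order(dtheta)
  dtheta <- dtheta[o]; accuracy <- accuracy[o]
  if (accuracy[1] >= threshold) {
    dmin <- if (clampLow) dtheta[1] else NA_real_
  } else if (all(accuracy < threshold)) {
    dmin <- if (floorHigh) max(dtheta) else NA_real_
  } else {
    i <- which(accuracy >= threshold)[1]
    dmin <- dtheta[i - 1] + (threshold - accuracy[i - 1]) /
      (accuracy[i] - accuracy[i - 1]) * (dtheta[i] - dtheta[i - 1])
  }
  list(dthetaMin = dmin,
       sensitivity = if (is.na(dmin)) NA_real_ else 1 / dmin)
}

#' Decoding sensitivity per reference orientation
#'
#' For each reference orientation, decoder accuracy on pairs involving the
#' reference is expressed as a function of the circular orientation
#' difference (10-90 deg); the minimum difference reaching 60% accuracy is
#' interpolated and inverted into a sensitivity (1/deg).
#'
#' @param pairAcc data.frame with `ori1`, `ori2`, `accuracy` covering the
#'   needed differences (e.g. one family/subpopulation slice of
#'   [pairwiseDecode()] output).
#' @param threshold Accuracy threshold.
#' @param clampLow,floorHigh Edge conventions ([sensitivityFromCurve()]).
#' @return data.frame: `reference`, `dthetaMin`, `sensitivity`.
#' @export
decodingSensitivity <- function(pairAcc, threshold = 0.6, clampLow = TRUE,
                                floorHigh = TRUE) {
  refs <- sort(unique(c(pairAcc$ori1, pairAcc$ori2)))
  grid <- seq(10, 90, by = 10)
  out <- lapply(refs, function(r) {
    sel <- pairAcc$ori1 == r | pairAcc$ori2 == r
    pa <- pairAcc[sel, , drop = FALSE]
    d <- abs(pa$ori1 - pa$ori2)
    d <- pmin(d, 180 - d)
    acc <- vapply(grid, function(g) mean(pa$accuracy[d == g]), numeric(1))
    keep <- !is.nan(acc)
    if (!any(keep)) stop("no pairs on the delta-theta grid for reference ", r)
    s <- sensitivityFromCurve(grid[keep], acc[keep], threshold,
                              clampLow, floorHigh)
    data.frame(reference = r, dthetaMin = s$dthetaMin,
               sensitivity = s$sensitivity)
  })
  do.call(rbind, out)
}
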
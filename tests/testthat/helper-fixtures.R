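# Shared synthetic fixtures, built once per test run.

# Small columnar session: 24 neurons, 5 reps, one SF -- used by the CSD,
# tuning and decoding unit tests.
smallSession <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sessionConfig(nNeurons = 24, repsPerDirection = 5, sfSet = 1,
                           seed = 42, lfpEpochs = 8)
      cache <<- simulateSession(cfg)
    }
    cache
  }
})

# Medium session with 10 repetitions (40 trials per orientation pair).
mediumSession <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sessionConfig(nNeurons = 12, repsPerDirection = 10, sfSet = 1,
                           seed = 7, lfp = FALSE)
      cache <<- simulateSession(cfg)
    }
    cache
  }
})

# Laminar model at the true generator boundaries (no CSD estimation).
trueModel <- function(session) {
  th <- session@config$thicknesses
  buildLaminarModel(sum(th[1:3]), th)
}

# Hand-built two-neuron session for container-level edge cases.
tinySession <- function(silentNeuron = FALSE) {
  trials <- data.frame(trial = 1:4, direction = c(0, 90, 0, 90), sf = 1,
                       eye = "right", onset = c(0.25, 1.5, 2.75, 4),
                       duration = 1, isi = 0.25)
  sp1 <- lapply(trials$onset, function(on) on + c(0.1, 0.3, 0.7))
  sp2 <- if (silentNeuron) lapply(1:4, function(i) numeric(0)) else
    lapply(trials$onset, function(on) on + c(0.2, 0.6))
  methods::new("ColumnSession",
               neurons = data.frame(id = 1:2, depth = c(300, 1000)),
               spikes = list(sp1, sp2), trials = trials,
               lfp = list(), config = list())
}

# Spike trains with given per-window counts (uniform placement), for
# Fano-factor estimator checks: counts is trials x windows.
trainsFromWindowCounts <- function(counts, windowSize = 0.1) {
  lapply(seq_len(nrow(counts)), function(t) {
    unlist(lapply(seq_len(ncol(counts)), function(w) {
      n <- counts[t, w]
      if (n == 0) numeric(0) else (w - 1) * windowSize +
        sort(stats::runif(n)) * windowSize
    }))
  })
}
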
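fakeLfp <- function(values, depths, fs = 100) {
  list(data = matrix(values, length(depths), 5), channelDepths = depths,
       fs = fs, t0 = 0)
}

test_that("channel grouping averages four neighbors", {
  d <- seq(0, by = 20, length.out = 384)
  g <- groupAverageLfp(fakeLfp(7, d))
  expect_equal(length(g$channelDepths), 96)
  expect_true(all(g$data == 7))
  expect_equal(g$channelDepths[1], mean(d[1:4]))
  # linear-in-depth potential stays linear after grouping
  lin <- fakeLfp(rep(2 * d + 1, 5), d)
  gl <- groupAverageLfp(lin)
  expect_equal(as.vector(gl$data[, 1]), 2 * gl$channelDepths + 1)
  expect_error(groupAverageLfp(fakeLfp(1, rev(d))), "ordered")
  expect_error(groupAverageLfp(fakeLfp(1, d[1:6])), "at least")
})

test_that("stimulus-triggered average behaves like a mean over epochs", {
  fs <- 100
  nCh <- 8
  tpl <- sin(seq(0, 2 * pi, length.out = 21))
  dat <- matrix(0, nCh, 400)
  ons <- c(0.5, 1.5, 2.5)
  for (on in ons) dat[, round(on * fs) + 1 + 0:20] <-
    dat[, round(on * fs) + 1 + 0:20] + rep(tpl, each = nCh)
  lfp <- list(data = dat, channelDepths = seq_len(nCh) * 20, fs = fs, t0 = 0)
  # identical epochs: average equals a single epoch; single onset: identity
  sta <- stimulusTriggeredAverage(lfp, ons, window = c(0, 0.2))
  sta1 <- stimulusTriggeredAverage(lfp, ons[1], window = c(0, 0.2))
  expect_equal(sta$erp, sta1$erp)
  expect_equal(sta$erp[1, ], tpl, tolerance = 1e-12)
  expect_error(stimulusTriggeredAverage(lfp, 10, window = c(0, 0.2)),
               "outside")
  # averaging zero-mean noise shrinks ~ 1/sqrt(N)
  set.seed(2)
  noisy <- list(data = matrix(rnorm(2 * 50000), 2), channelDepths = c(20, 40),
                fs = 1000, t0 = 0)
  onsN <- seq(0.05, 49.9, length.out = 2000)
  sN <- stimulusTriggeredAverage(noisy, onsN, window = c(0, 0.01))
  ratio <- sd(sN$erp) / 1
  expect_equal(ratio * sqrt(2000), 1, tolerance = 0.35)
})

test_that("five-point CSD stencil is exact on polynomials and linear", {
  z <- 0:20; h <- 80
  lin <- computeCsd(matrix(3 * z * h + 5, ncol = 1), depths = z * h)
  expect_true(all(abs(lin$values) < 1e-9))
  # phi = z^2 in units of h: stencil gives -(2 (2h)^2 h^2/h^2)/(2h)^2 = -2
  quad <- computeCsd(matrix((z * h)^2, ncol = 1), depths = z * h)
  expect_true(all(abs(quad$values + 2) < 1e-9))
  # two interior bins lost at each edge
  expect_equal(length(quad$depths), length(z) - 4)
  # sign convention: potential minimum in depth -> negative CSD (sink)
  par <- computeCsd(matrix((z - 10)^2, ncol = 1), depths = z * h)
  expect_lt(par$values[which(par$depths == 10 * h), 1], 0)
  expect_error(computeCsd(matrix(1:4, ncol = 1), depths = 1:4 * 80), "at least 5")
})

test_that("CSD is linear in the potential", {
  set.seed(6)
  z <- seq(0, 1600, by = 80)
  p1 <- matrix(rnorm(length(z) * 3), length(z))
  p2 <- matrix(rnorm(length(z) * 3), length(z))
  a <- 2.5; b <- -1.2
  lhs <- computeCsd(a * p1 + b * p2, depths = z)$values
  rhs <- a * computeCsd(p1, depths = z)$values +
    b * computeCsd(p2, depths = z)$values
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("spatial smoothing preserves mass and resolves bimodality", {
  z <- seq(0, 4000, by = 80)
  mkCsd <- function(v) structure(list(values = matrix(v, ncol = 1),
                                      depths = z, lags = 0, spacing = 80),
                                 class = "CsdProfile")
  # constant field unchanged
  cs <- smoothCsd(mkCsd(rep(3, length(z))))
  expect_equal(as.vector(cs$values), rep(3, length(z)), tolerance = 1e-12)
  # impulse response: Gaussian with sd 120 um, peak at the same bin
  mid <- which(z == 2000)
  imp <- rep(0, length(z)); imp[mid] <- 1
  si <- as.vector(smoothCsd(mkCsd(imp))$values)
  expect_equal(which.max(si), mid)
  expect_equal(si[mid + 1] / si[mid], exp(-80^2 / (2 * 120^2)),
               tolerance = 1e-6)
  expect_equal(si[mid + 2] / si[mid], exp(-160^2 / (2 * 120^2)),
               tolerance = 1e-6)
  # mass conserved away from edges
  expect_equal(sum(si), 1, tolerance = 0.01)
  # two deltas 400 um apart remain bimodal
  two <- rep(0, length(z)); two[mid] <- 1; two[mid + 5] <- 1
  st <- as.vector(smoothCsd(mkCsd(two))$values)
  localMax <- which(diff(sign(diff(st))) == -2) + 1
  expect_equal(length(localMax), 2)
  expect_error(smoothCsd(mkCsd(imp), sigma = 0), "sigma > 0")
})

test_that("sink boundary detection handles edge cases and scaling", {
  z <- seq(0, 2000, by = 80)
  mk <- function(v) structure(list(values = matrix(v, ncol = 1), depths = z,
                                   lags = 0.05, spacing = 80),
                              class = "CsdProfile")
  # all-positive CSD: no sink
  r <- locateSinkBoundary(mk(abs(rnorm(length(z))) + 1))
  expect_true(is.na(r))
  expect_equal(attr(r, "reason"), "no sink")
  # dipole profile with known zero crossing; invariant to scaling
  prof <- -exp(-(z - 900)^2 / (2 * 150^2)) + exp(-(z - 1500)^2 / (2 * 150^2))
  b1 <- locateSinkBoundary(mk(prof))
  b2 <- locateSinkBoundary(mk(17 * prof))
  expect_equal(b1, b2)
  expect_equal(b1, 1200, tolerance = 0.05)  # antisymmetric about 1200
  # manual adjustment moves by one group pitch
  expect_equal(locateSinkBoundary(mk(prof), adjustGroups = 1), b1 + 80)
})

test_that("laminar model offsets thicknesses from the sink boundary", {
  m <- buildLaminarModel(1200, c(650, 311, 281, 489))
  expect_equal(unname(m@boundaries), c(608, 919, 1200, 1689))
  expect_equal(m@top23, 608 - 650)
  expect_error(buildLaminarModel(1200, c(0, 311, 281, 489)), "positive")
  expect_error(buildLaminarModel(NA, c(650, 311, 281, 489)), "NA")
  # translation equivariance
  m2 <- buildLaminarModel(1200 + 55, c(650, 311, 281, 489))
  expect_equal(unname(m2@boundaries), c(608, 919, 1200, 1689) + 55)
})

test_that("layer assignment follows the half-open interval convention", {
  m <- buildLaminarModel(1200, c(650, 311, 281, 489))
  expect_equal(assignNeuronLayer(1000, m), "4C")        # 919 <= 1000 < 1200
  expect_equal(assignNeuronLayer(919, m), "4C")         # boundary -> deeper
  expect_equal(assignNeuronLayer(1200, m), "5/6")
  expect_equal(assignNeuronLayer(2000, m), "out")
  expect_equal(assignNeuronLayer(608 - 650 - 1, m), "out")
  expect_equal(assignNeuronLayer(c(700, 650), m), c("4A/B", "4A/B"))
})

test_that("noiseless synthetic sessions recover their generating layers", {
  cfg <- sessionConfig(nNeurons = 40, repsPerDirection = 5, sfSet = 1,
                       seed = 19, lfpNoiseSd = 0, lfpEpochs = 6)
  s <- simulateSession(cfg)
  lam <- estimateLaminarModel(s)
  truth <- cumsum(cfg$thicknesses)[3]
  expect_lt(abs(lam$boundary46 - truth), 80)
  est <- assignNeuronLayer(neuronDepths(s), lam$model)
  tru <- neuronInfo(s)$compartmentTrue
  expect_gte(mean(est == tru), 0.95)
  # any error lies within one group pitch of a true boundary
  wrong <- which(est != tru)
  if (length(wrong)) {
    db <- vapply(neuronDepths(s)[wrong], function(d)
      min(abs(d - cumsum(cfg$thicknesses))), numeric(1))
    expect_true(all(db <= 80))
  }
})
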
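test_that("responsiveness gate combines significance and rate threshold", {
  set.seed(1)
  expect_false(responsivenessGate(rep(5, 10), rep(5, 10), maxRate = 20))
  stim <- rnorm(50, 20, 1); isi <- rnorm(50, 2, 1)
  expect_true(responsivenessGate(stim, isi, maxRate = 25))
  # significant difference but rate below 3 spikes/s fails the gate
  expect_false(responsivenessGate(stim / 10, isi / 10, maxRate = 2))
  # degenerate zero-variance input with equal means
  expect_false(responsivenessGate(rep(4, 5), rep(4, 5), maxRate = 10))
  expect_error(responsivenessGate(1, 1:3, 10), "2 trials")
})

test_that("optimal condition maximizes the peak response with tie rules", {
  resp <- expand.grid(direction = seq(0, 350, 10), sf = c(0.5, 1, 2, 4),
                      eye = "right", stringsAsFactors = FALSE)
  resp$meanRate <- 1
  resp$meanRate[resp$sf == 2 & resp$direction == 90] <- 30
  opt <- selectOptimalCondition(resp)
  expect_equal(opt$sf, 2)
  expect_equal(opt$maxRate, 30)
  # exact tie across sf resolves to the lower sf
  resp$meanRate <- 1
  resp$meanRate[resp$direction == 90] <- 10
  expect_equal(selectOptimalCondition(resp)$sf, 0.5)
  one <- resp[resp$sf == 1, ]
  expect_equal(selectOptimalCondition(one)$sf, 1)
})

test_that("direction and orientation indices follow the rate contrasts", {
  expect_equal(directionIndex(10, 0), 1)
  expect_equal(directionIndex(10, 10), 0)
  expect_equal(directionIndex(15, 5), 0.5)
  expect_equal(orientationIndex(10, 0), 1)
  expect_equal(orientationIndex(10, 10), 0)
  expect_equal(orientationIndex(12, 4), 0.5)
  expect_true(is.na(directionIndex(0, 0)))
  # bounded and antisymmetric for arbitrary nonnegative rates
  set.seed(2)
  for (i in 1:50) {
    a <- runif(1, 0, 50); b <- runif(1, 0, 50)
    if (a + b == 0) next
    di <- directionIndex(a, b)
    expect_true(di >= -1 && di <= 1)
    expect_equal(directionIndex(b, a), -di)
  }
})

test_that("modulation ratio is undefined without spikes", {
  expect_true(is.na(modulationRatio(list(numeric(0), numeric(0)), 2)))
})

test_that("Hanning smoothing has the stated kernel and is mass-preserving", {
  expect_equal(smoothTuning(rep(4, 18)), rep(4, 18))
  imp <- c(1, rep(0, 17))
  k <- smoothTuning(imp)
  expect_equal(which.max(k), 1)
  expect_equal(sum(k), 1)
  # raised cosine: value at +-20 deg (2 bins) is half the center value
  expect_equal(k[3] / k[1], 0.5)
  expect_equal(k[17] / k[1], 0.5)
  # support is 80 deg: zero beyond +-4 bins
  expect_equal(k[6:14], rep(0, 9))
  expect_error(smoothTuning(rep(1, 10)))
})

test_that("von Mises fits recover planted parameters on noiseless curves", {
  x <- seq(0, 170, by = 10)
  truth <- list(a0 = 3, a1 = 22, a2 = 2.6, a3 = 57)
  y <- truth$a0 + truth$a1 *
    exp(truth$a2 * (cos(2 * (x - truth$a3) * pi / 180) - 1))
  f <- fitVonMises(y)
  expect_true(f$converged)
  expect_gt(f$rSquared, 0.999)
  expect_lt(abs(f$a3 - truth$a3), 1)
  expect_equal(f$a0, truth$a0, tolerance = 0.01)
  expect_equal(f$a1, truth$a1, tolerance = 0.01)
  expect_equal(f$a2, truth$a2, tolerance = 0.01)
  # flat curve: degenerate fit handled without error
  ff <- fitVonMises(rep(5, 18))
  expect_true(ff$converged)
  expect_equal(ff$a1, 0)
  expect_equal(ff$rSquared, 0)
  expect_equal(tuningBandwidth(ff), 180)
})

test_that("bandwidth matches the closed form and its conventions", {
  mkFit <- function(a0, a1, a2) structure(
    list(a0 = a0, a1 = a1, a2 = a2, a3 = 90, converged = TRUE),
    class = "VonMisesFit")
  # frozen from an independent numeric root-find of
  # a1*exp(a2*(cos(2*d)-1)) = a1/sqrt(2) at a2 = 2
  expect_equal(tuningBandwidth(mkFit(0, 10, 2)), 17.11871, tolerance = 1e-5)
  # amplitude scaling leaves bandwidth unchanged (a0 = 0)
  expect_equal(tuningBandwidth(mkFit(0, 20, 2)), tuningBandwidth(mkFit(0, 10, 2)))
  # high baseline: curve never drops below criterion -> 180 sentinel
  expect_equal(tuningBandwidth(mkFit(100, 1, 2)), 180)
  # shallow tuning: trough above criterion -> 180 sentinel
  expect_equal(tuningBandwidth(mkFit(0, 10, 0.1)), 180)
  # monotone decreasing in concentration at a0 = 0
  bw <- vapply(c(0.5, 1, 2, 4, 8), function(a2)
    tuningBandwidth(mkFit(0, 10, a2)), numeric(1))
  expect_true(all(diff(bw) < 0))
  # the 1/2 criterion is broader than 1/sqrt(2)
  expect_gt(tuningBandwidth(mkFit(0, 10, 2), criterion = 0.5),
            tuningBandwidth(mkFit(0, 10, 2)))
})

test_that("Fano factor estimator matches its generating process", {
  # identical counts on every trial -> zero variance -> 0
  cw <- matrix(3, 20, 10)
  expect_equal(fanoFactor(trainsFromWindowCounts(cw), rep(1, 20)), 0)
  set.seed(5)
  # Poisson generator: FF near 1 at 1000 trials
  cp <- matrix(rpois(1000 * 10, 2), 1000, 10)
  expect_equal(fanoFactor(trainsFromWindowCounts(cp), rep(1, 1000)), 1,
               tolerance = 0.05)
  # gamma-Poisson at target 1.9
  cg <- matrix(sampleTrialCounts(rep(2, 1000 * 10), 1.9, 1e4), 1000, 10)
  expect_equal(fanoFactor(trainsFromWindowCounts(cg), rep(1, 1000)) / 1.9, 1,
               tolerance = 0.1 / 1.9)
  # unbiased at Poisson: mean over 100 simulated neurons within 2 SE of 1
  est <- vapply(1:100, function(i) {
    cc <- matrix(rpois(50 * 10, 2), 50, 10)
    fanoFactor(trainsFromWindowCounts(cc), rep(1, 50))
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 1), 2 * se + 0.02)
  # all-empty trains are flagged undefined
  expect_true(is.na(fanoFactor(list(numeric(0), numeric(0)), c(1, 1))))
})

test_that("session-level metrics match the generator's planted structure", {
  s <- smallSession()
  m <- neuronMetrics(s, trueModel(s))
  ni <- neuronInfo(s)
  expect_true(all(m$responsive))
  # preferred orientations recovered
  dOri <- abs(m$prefOrientation - ni$prefOrientation)
  expect_lt(max(pmin(dOri, 180 - dOri)), 10)
  expect_gt(median(m$rSquared), 0.9)
  # orientation index calibrated near the 0.7 median
  expect_equal(median(m$oi), 0.7, tolerance = 0.1)
  # direction index tracks the planted direction bias
  expect_gt(cor(m$di, ni$directionBias), 0.6)
  # Fano estimates track the per-compartment targets (small-trial bias
  # tolerated; ordering must hold)
  expect_gt(cor(m$fano, ni$fanoTarget), 0.5)
  # compartment column present and in-range
  expect_true(all(m$compartment %in% c(compartmentLabels(), "out")))
  # measured bandwidth reflects smoothing-broadened tuning
  expect_true(all(m$bandwidth > 10 & m$bandwidth <= 180))
})
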
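# Minimal PopulationResponse straight from matrices.
mkPop <- function(X, y, depths = seq_len(ncol(X)) * 100) {
  X <- as.matrix(X)
  methods::new("PopulationResponse", X = sweep(X, 2, apply(X, 2, max), "/"),
               counts = X, y = y, depths = depths,
               trials = data.frame(trial = seq_len(nrow(X))),
               excluded = integer(0))
}

test_that("the stimulus protocol yields 153 orientation pairs", {
  pr <- orientationPairs()
  expect_equal(nrow(pr), 153)
  expect_setequal(unique(c(pr$ori1, pr$ori2)), seq(0, 170, 10))
  expect_true(all(pr$dtheta >= 10 & pr$dtheta <= 90))
  # 18 pairs at each difference below 90, 9 at 90
  expect_equal(unname(table(pr$dtheta)["90"]), 9)
  expect_equal(unname(table(pr$dtheta)["30"]), 18)
})

test_that("response matrix bookkeeping matches the protocol", {
  s <- mediumSession()  # 10 reps, one sf/eye
  pop <- buildResponseMatrix(s)
  expect_equal(nrow(pop@X), 360)
  expect_equal(sort(unique(pop@y)), seq(0, 170, 10))
  # 40 trials per orientation pair
  pr <- orientationPairs()
  nPair <- vapply(seq_len(nrow(pr)), function(i)
    sum(pop@y %in% c(pr$ori1[i], pr$ori2[i])), numeric(1))
  expect_true(all(nPair == 40))
  # per-neuron max normalization
  expect_true(all(abs(apply(pop@X, 2, max) - 1) < 1e-12))
  expect_error(buildResponseMatrix(s, window = c(0.05, 2)), "within the trial")
})

test_that("all-zero neurons are excluded with a message", {
  s <- tinySession(silentNeuron = TRUE)
  expect_message(pop <- buildResponseMatrix(s, window = c(0, 1)), "excluded")
  expect_equal(ncol(pop@X), 1)
  expect_equal(pop@excluded, 2L)
  # all counts equal -> normalized column of ones
  expect_true(all(pop@X[, 1] == 1))
})

test_that("subpopulation construction slides over depth", {
  d <- seq(100, 3000, length.out = 30)
  sub <- buildSubpopulations(d, k = 10)
  expect_equal(nrow(sub$info), 21)  # N - k + 1
  expect_length(sub$members[[1]], 10)
  # center depth: mean of the two middle members (k even)
  m1 <- sort(d[sub$members[[1]]])
  expect_equal(sub$info$centerDepth[1], mean(m1[5:6]))
  # k = 1: every neuron its own subpopulation
  s1 <- buildSubpopulations(d, k = 1)
  expect_equal(nrow(s1$info), 30)
  expect_equal(s1$info$centerDepth, sort(d))
  # all at the same depth: one compartment for all subpopulations
  m <- buildLaminarModel(1200, c(650, 311, 281, 489))
  sSame <- buildSubpopulations(rep(1000, 15), k = 10, model = m)
  expect_true(all(sSame$info$compartment == "4C"))
  expect_warning(buildSubpopulations(d[1:5], k = 10), "fewer")
})

test_that("training-trial shuffling preserves marginals, kills correlations", {
  set.seed(13)
  # single trial per class: unchanged
  X1 <- matrix(rnorm(6), 2, 3)
  expect_identical(shuffleTrainingTrials(X1, c(0, 1)), X1)
  # planted correlations destroyed, class means exactly preserved
  cnt <- imposeNoiseCorrelations(matrix(rpois(1000 * 12, 15), 1000, 12),
                                 0.3, seed = 2)
  y <- rep(c(0, 1), each = 500)
  sh <- shuffleTrainingTrials(cnt, y, seed = 3)
  for (cl in 0:1)
    expect_equal(colMeans(sh[y == cl, ]), colMeans(cnt[y == cl, ]))
  r0 <- cor(cnt[y == 0, ]); r1 <- cor(sh[y == 0, ])
  expect_gt(mean(r0[upper.tri(r0)]), 0.2)
  expect_lt(abs(mean(r1[upper.tri(r1)])), 0.02)
})

test_that("decoders are calibrated at chance and solve separable problems", {
  set.seed(23)
  # separable Gaussian classes: all five families reach 100%
  Xs <- rbind(matrix(rnorm(20 * 10, 0), 20), matrix(rnorm(20 * 10, 4), 20))
  ys <- rep(c(0, 40), each = 20)
  pop <- mkPop(Xs - min(Xs), ys)
  d <- pairwiseDecode(pop, families = classifierFamilies(), seed = 5)
  expect_equal(d$accuracy, rep(1, 5))
  # permuted labels: chance for the two closed-form families (fast check;
  # the full five-family calibration runs in the acceptance suite)
  Xr <- matrix(runif(100 * 6), 100)
  yr <- sample(rep(c(0, 10), each = 50))
  dr <- pairwiseDecode(mkPop(Xr, yr), families = c("lda", "nb"), seed = 6)
  expect_true(all(abs(dr$accuracy - 0.5) <= 3 * sqrt(0.25 / 100)))
})

test_that("fold reduction warns when classes are smaller than the folds", {
  set.seed(3)
  X <- matrix(runif(12 * 4), 12)
  y <- rep(c(0, 90), each = 6)
  expect_warning(d <- pairwiseDecode(mkPop(X, y), families = "lda",
                                     folds = 10, seed = 1), "folds")
  expect_equal(nrow(d), 1)
  expect_error(pairwiseDecode(mkPop(X, rep(0, 12)), families = "lda"),
               "two orientation classes")
})

test_that("LDA predictions equal the closed-form discriminant", {
  # isotropic within-class scatter: shrinkage toward a scaled identity
  # cannot rotate the discriminant direction
  base <- rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  X0 <- base; X1 <- sweep(base, 2, c(3, 1), "+")
  Xtr <- rbind(X0, X1); ytr <- rep(0:1, each = 5)
  set.seed(9)
  Xte <- matrix(runif(40, -1, 4), 20, 2)
  pred <- laminarDecoding:::.fitPredictLda(Xtr, ytr, Xte)
  # closed form: w = Sigma^-1 (mu1 - mu0), threshold at the midpoint
  mu0 <- colMeans(X0); mu1 <- colMeans(X1)
  Xc <- rbind(sweep(X0, 2, mu0), sweep(X1, 2, mu1))
  Sigma <- crossprod(Xc) / nrow(Xc)
  w <- solve(Sigma, mu1 - mu0)
  oracle <- as.integer(Xte %*% w - 0.5 * sum((mu1 + mu0) * w) > 0)
  expect_equal(pred, oracle)
})

test_that("Gaussian NB matches a brute-force posterior evaluation", {
  set.seed(10)
  X <- rbind(matrix(rnorm(30, 0, 1), 15, 2), matrix(rnorm(30, 2, 1.5), 15, 2))
  y <- rep(0:1, each = 15)
  m <- gaussianNbFit(X, y)
  Xte <- matrix(runif(40, -1, 3), 20, 2)
  pred <- gaussianNbPredict(m, Xte)
  oracle <- apply(Xte, 1, function(x) {
    post <- vapply(1:2, function(k)
      m$priors[k] * prod(dnorm(x, m$mu[, k], sqrt(m$sigma2[, k]))),
      numeric(1))
    m$classes[which.max(post)]
  })
  expect_equal(pred, oracle)
  # independent cross-check against e1071 on well-separated points
  nb2 <- e1071::naiveBayes(data.frame(a = X[, 1], b = X[, 2]), factor(y))
  XteFar <- rbind(c(-0.5, -0.5), c(2.5, 2.5), c(0, 0), c(2, 2))
  p2 <- as.integer(as.character(
    predict(nb2, data.frame(a = XteFar[, 1], b = XteFar[, 2]))))
  expect_equal(as.integer(gaussianNbPredict(m, XteFar)), p2)
  # symmetric classes, x at the midpoint: tie resolves to class 0
  ms <- gaussianNbFit(rbind(matrix(c(0, 0, 1, 1), 2), matrix(c(2, 2, 3, 3), 2)),
                      c(0, 0, 1, 1))
  expect_equal(gaussianNbPredict(ms, matrix(c(1, 2), 1)), 0)
  # uninformative features with unequal priors: majority class wins
  mu <- gaussianNbFit(matrix(rnorm(40), 20, 2), rep(c(0, 1), c(15, 5)))
  predU <- gaussianNbPredict(mu, matrix(rnorm(20), 10, 2))
  expect_true(mean(predU == 0) >= 0.8)
})

test_that("single-neuron decoding is weaker than 10-neuron populations", {
  s <- mediumSession()
  model <- trueModel(s)
  met <- neuronMetrics(s, model)
  prs <- orientationPairs()
  prs <- prs[prs$dtheta %in% c(20, 90) & prs$ori1 %% 40 == 0, ]
  dPop <- decodeSession(s, model, metrics = met, k = 10, stride = 2,
                        families = "lda", pairs = prs, seed = 2)
  dOne <- singleNeuronDecode(s, model, metrics = met, families = "lda",
                             pairs = prs, seed = 2)
  expect_gte(mean(dPop$results$accuracy), mean(dOne$results$accuracy))
  # a well-tuned neuron beats chance on large-difference pairs
  best <- dOne$results[dOne$results$dtheta == 90, ]
  expect_gt(max(best$accuracy), 0.8)
})

test_that("neuron-dropping curves enumerate combinations correctly", {
  set.seed(4)
  X <- matrix(rpois(80 * 5, 10), 80)
  y <- rep(c(0, 90), 40)
  X[y == 90, ] <- X[y == 90, ] + rep(c(8, 6, 4, 2, 0), each = sum(y == 90))
  pop <- mkPop(X, y)
  ndc <- neuronDroppingCurve(pop, compartments = rep("4C", 5),
                             nGrid = c(2, 5), reps = 200, folds = 5)
  # C(5,2) = 10 < 200: all combinations; n = population size: exactly one
  expect_equal(sum(ndc$n == 2), 10)
  expect_equal(sum(ndc$n == 5), 1)
  # mean accuracy non-decreasing in n (within a small CI allowance)
  expect_gte(mean(ndc$accuracy[ndc$n == 5]),
             mean(ndc$accuracy[ndc$n == 2]) - 0.05)
  # capped sampling of distinct combinations
  combos <- laminarDecoding:::.sampleCombinations(10, 3, 20)
  expect_equal(length(combos), 20)
  expect_equal(length(unique(vapply(combos, paste, collapse = ",",
                                    character(1)))), 20)
})

test_that("sensitivity interpolation follows the stated conventions", {
  s <- sensitivityFromCurve(c(10, 20), c(0.5, 0.7))
  expect_equal(s$dthetaMin, 15)
  expect_equal(s$sensitivity, 1 / 15)
  # threshold already met at 10 deg: clamp
  expect_equal(sensitivityFromCurve(seq(10, 90, 10), rep(1, 9))$dthetaMin, 10)
  # never reached: floor at 90
  expect_equal(sensitivityFromCurve(seq(10, 90, 10), rep(0.5, 9))$dthetaMin, 90)
  # conventions can be disabled
  expect_true(is.na(sensitivityFromCurve(c(10, 20), c(0.9, 1),
                                         clampLow = FALSE)$dthetaMin))
  expect_true(is.na(sensitivityFromCurve(c(10, 20), c(0.4, 0.5),
                                         floorHigh = FALSE)$dthetaMin))
  # grid assembly from pair accuracies: accuracy rising in dtheta
  pr <- orientationPairs()
  pr$accuracy <- 0.5 + 0.4 * pr$dtheta / 90
  sens <- decodingSensitivity(pr)
  expect_equal(nrow(sens), 18)
  # 0.6 reached where 0.5 + 0.4 d/90 = 0.6 -> d = 22.5
  expect_equal(sens$dthetaMin, rep(22.5, 18))
  expect_equal(sens$sensitivity, rep(1 / 22.5, 18))
})
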
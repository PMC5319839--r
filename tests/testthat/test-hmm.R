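# HMM click decoder.

test_that("the PCA front end recovers a known 4-D subspace", {
  set.seed(61)
  d <- 12L
  Q <- qr.Q(qr(matrix(rnorm(d * 4L), d, 4L)))
  scores <- matrix(rnorm(3000L * 4L), 3000L) %*% diag(c(8, 6, 4, 2))
  x <- scores %*% t(Q) + matrix(rnorm(3000L * d, 0, 1e-4), 3000L)
  pca <- fitClickPca(x)
  # principal angles between the true and recovered subspaces
  sv <- svd(crossprod(Q, pca$rotation))$d
  expect_true(all(acos(pmin(sv, 1)) < 1e-3))
  expect_identical(ncol(pca$rotation), 4L)
  # duplicated dataset: identical projection (determinism + sign rule)
  expect_identical(pca$rotation, fitClickPca(x)$rotation)
  # rank < 4 errors
  flat <- matrix(rnorm(200L), 100L, 2L)[, c(1, 2, 1, 2, 1)]
  expect_error(fitClickPca(flat), "rank")
})

test_that("isotropic data retains about 4/d of the variance", {
  set.seed(62)
  d <- 20L
  x <- matrix(rnorm(8000L * d), 8000L)
  pca <- fitClickPca(x)
  proj <- projectFeatures(pca, t(x))
  frac <- sum(apply(proj, 2L, var)) / sum(apply(x, 2L, var))
  # top sample eigenvalues are slightly inflated at finite n
  expect_equal(frac, 4 / d, tolerance = 0.1)
})

test_that("well-separated states are classified near the Bayes rate", {
  tr <- twoStateStream(3000L, sep = 8, seed = 63L)
  te <- twoStateStream(2000L, sep = 8, seed = 64L)
  pca <- list(center = rep(0, 4L), rotation = diag(4L),
              featureIndex = 1:4)
  hmm <- fitHmm(tr$z, tr$s, pca)
  post <- hmmFilter(hmm, te$z)
  acc <- mean((post[, "pClick"] > 0.5) == te$s)
  expect_gte(acc, 0.99)
  # Bayes oracle with the true parameters does no better than ~this
  bayes <- mean((te$z[, 1L] > 4) == te$s)
  expect_gte(acc, bayes - 0.01)
})

test_that("transition estimates match label bigram frequencies", {
  tr <- twoStateStream(20000L, pClickState = 0.1, seed = 65L)
  pca <- list(center = rep(0, 4L), rotation = diag(4L), featureIndex = 1:4)
  hmm <- fitHmm(tr$z, tr$s, pca)
  # i.i.d. labels with P(click) = 0.1: every row is ~ (0.9, 0.1)
  expect_lt(max(abs(unname(hmm@transition[, 2L]) - 0.1)), 0.025)
  expect_equal(rowSums(hmm@transition), c(1, 1), tolerance = 1e-12)
  expect_error(fitHmm(tr$z[1:30, ], c(rep(FALSE, 29L), TRUE), pca),
               "at least 10")
})

test_that("the forward step reproduces hand-computed posteriors", {
  # symmetric transition and flat prior: posterior proportional to the
  # emission likelihoods; construct a 1:4 likelihood ratio
  d <- 2
  pca <- list(center = rep(0, 4L), rotation = diag(4L), featureIndex = 1:4)
  hmm <- new("ClickHMM", center = rep(0, 4L), rotation = diag(4L),
             featureIndex = 1:4,
             stateMeans = rbind(move = c(0, 0, 0, 0),
                                click = c(d, 0, 0, 0)),
             stateCovs = list(move = diag(4L), click = diag(4L)),
             transition = matrix(c(0.9, 0.1, 0.1, 0.9), 2L),
             clickThreshold = NA_real_,
             consecutiveBinsRequired = 2L)
  z1 <- log(4) / d + d / 2       # density ratio click/move = 4
  post <- hmmStep(hmm, c(z1, 0, 0, 0), c(0.5, 0.5))
  expect_equal(post, c(0.2, 0.8), tolerance = 1e-9)
  # equal likelihoods: posterior equals the transition-propagated prior
  prev <- c(0.3, 0.7)
  postEq <- hmmStep(hmm, c(d / 2, 0, 0, 0), prev)
  expect_equal(postEq,
               as.numeric(crossprod(hmm@transition, prev)) /
                 sum(crossprod(hmm@transition, prev)),
               tolerance = 1e-9)
})

test_that("streaming recursion equals the batch forward oracle", {
  for (seed in c(66L, 67L, 68L)) {
    tr <- twoStateStream(100L, sep = 4, seed = seed, selfTrans = 0.95)
    pca <- list(center = rep(0, 4L), rotation = diag(4L), featureIndex = 1:4)
    hmm <- fitHmm(tr$z, tr$s, pca)
    stream <- hmmFilter(hmm, tr$z)
    batch <- forwardOracle(hmm@stateMeans, hmm@stateCovs,
                           hmm@transition, tr$z)
    expect_lt(max(abs(stream - batch)), 1e-10)
    expect_true(all(abs(rowSums(stream) - 1) < 1e-9))
  }
})

test_that("the recursion stays normalized and finite for extreme bins", {
  pca <- list(center = rep(0, 4L), rotation = diag(4L), featureIndex = 1:4)
  tr <- twoStateStream(500L, seed = 69L)
  hmm <- fitHmm(tr$z, tr$s, pca)
  far <- c(40, 0, 0, 0)   # likelihoods near 1e-300
  post <- hmmStep(hmm, far, c(0.5, 0.5))
  expect_true(all(is.finite(post)))
  expect_equal(sum(post), 1, tolerance = 1e-9)
})

test_that("identical emissions leave the posterior at the prior chain", {
  set.seed(70)
  z <- matrix(rnorm(400L * 4L), 400L)
  s <- rep(c(FALSE, TRUE), 200L)
  pca <- list(center = rep(0, 4L), rotation = diag(4L), featureIndex = 1:4)
  hmm <- fitHmm(z, s, pca)
  hmm@stateMeans[2L, ] <- hmm@stateMeans[1L, ]
  hmm@stateCovs[[2L]] <- hmm@stateCovs[[1L]]
  post <- hmmFilter(hmm, z)
  # threshold calibration still succeeds on the (transient) stream
  expect_silent(th <- calibrateClickThreshold(post[, "pClick"]))
  expect_true(is.finite(th))
})

test_that("threshold calibration is the 93rd interpolated quantile", {
  grid <- seq(0, 1, by = 0.01)
  expect_equal(calibrateClickThreshold(grid), 0.93)
  expect_equal(calibrateClickThreshold(grid * 0.5), 0.465)
  expect_error(calibrateClickThreshold(rep(0.4, 200L)), "degenerate")
  expect_error(calibrateClickThreshold(grid[1:50]), "100")
  # definitional check on a fitted synthetic stream: ~7% above
  tr <- twoStateStream(4000L, sep = 4, seed = 71L, selfTrans = 0.95)
  pca <- list(center = rep(0, 4L), rotation = diag(4L), featureIndex = 1:4)
  hmm <- fitHmm(tr$z, tr$s, pca)
  p <- hmmFilter(hmm, tr$z)[, "pClick"]
  th <- calibrateClickThreshold(p)
  expect_equal(mean(p > th), 0.07, tolerance = 0.01)
})

test_that("the consecutive-bin click rule matches the automaton oracle", {
  hi <- 0.99; lo <- 0.1; th <- 0.9
  expect_identical(detectClicks(rep(c(hi, lo), 5L), th), integer(0))
  expect_identical(detectClicks(c(lo, hi, hi, lo), th), 3L)
  expect_identical(detectClicks(rep(hi, 6L), th), c(2L, 4L, 6L))
  # property: agreement with the independent counter oracle
  set.seed(72)
  for (i in 1:25) {
    p <- runif(60L)
    expect_identical(detectClicks(p, 0.7),
                     clickRuleOracle(p > 0.7))
  }
})

test_that("click epochs are detected promptly with few false clicks", {
  # emission separation 4 sd, self-transition 0.95; closed-loop
  # semantics: a click ends the click epoch (the selection is made).
  # The threshold is calibrated on a retraining-like stream in which
  # click epochs occupy ~10% of bins (5-bin holds every 50 bins).
  pca <- list(center = rep(0, 4L), rotation = diag(4L), featureIndex = 1:4)
  set.seed(73)
  calLabels <- rep(rep(c(FALSE, TRUE), 60L), times = rep(c(45L, 5L), 60L))
  calZ <- matrix(rnorm(length(calLabels) * 4L), ncol = 4L)
  calZ[calLabels, 1L] <- calZ[calLabels, 1L] + 4
  hmm <- fitHmm(calZ, calLabels, pca)
  hmm@transition <- matrix(c(0.95, 0.05, 0.05, 0.95), 2L)
  p <- hmmFilter(hmm, calZ)[, "pClick"]
  hmm@clickThreshold <- calibrateClickThreshold(p)
  set.seed(74)
  nEpochs <- 60L
  moveBins <- 134L   # ~2 s
  clickMax <- 10L    # 150 ms window
  hits <- 0L; falseClicks <- 0L; moveTime <- 0
  prev <- c(0.5, 0.5)
  counter <- 0L
  for (e in seq_len(nEpochs)) {
    for (t in seq_len(moveBins)) {
      z <- rnorm(4L); prev <- hmmStep(hmm, z, prev)
      if (prev[2L] > hmm@clickThreshold) {
        counter <- counter + 1L
        if (counter >= 2L) { falseClicks <- falseClicks + 1L; counter <- 0L }
      } else counter <- 0L
    }
    moveTime <- moveTime + moveBins * 0.015
    clicked <- 0L
    for (t in seq_len(clickMax)) {
      z <- rnorm(4L); z[1L] <- z[1L] + 4
      prev <- hmmStep(hmm, z, prev)
      if (prev[2L] > hmm@clickThreshold) {
        counter <- counter + 1L
        if (counter >= 2L) { clicked <- clicked + 1L; counter <- 0L; break }
      } else counter <- 0L
    }
    if (clicked == 1L) hits <- hits + 1L
  }
  expect_gte(hits / nEpochs, 0.95)
  expect_lt(falseClicks / moveTime, 0.05)
})
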
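# Velocity Kalman decoder and feature selection.

test_that("feature selection finds tuned channels and drops noise", {
  pd <- runif(20L, 0, 2 * pi)
  depth <- c(rep(1.5, 10L), rep(0, 10L))
  p <- makeParticipant(nChannels = 20L, preferredDirection = pd,
                       modulationDepth = depth, baselineRate = 5,
                       seed = 30L)
  bf <- randomIntentStream(p, 2000L, seed = 31L)
  sel <- selectFeatures(bf, family = "spike")
  tuned <- which(featureFamily(bf) == "spike")[1:10]
  expect_true(all(sel %in% tuned))
  expect_gte(length(intersect(sel, tuned)), 8L)
})

test_that("zero-variance features are excluded with a warning", {
  p <- makeParticipant(nChannels = 10L, modulationDepth = 2,
                       baselineRate = 5, seed = 32L)
  bf <- randomIntentStream(p, 500L, seed = 33L)
  m <- featureMatrix(bf)
  m[3L, ] <- 0   # dead spike channel
  SummarizedExperiment::assay(bf, "features") <- m
  expect_warning(sel <- selectFeatures(bf, family = "spike"),
                 "zero-variance")
  expect_false(3L %in% sel)
})

test_that("noise-free linear features are decoded almost exactly", {
  # build an exactly linear-Gaussian stream on the hfp rows
  set.seed(34)
  nBins <- 600L; nCh <- 6L
  vx <- runif(nBins, -1, 1); vy <- runif(nBins, -1, 1)
  Hx <- runif(nCh, -2, 2); Hy <- runif(nCh, -2, 2)
  lin <- outer(Hx, vx) + outer(Hy, vy) + 10   # noise-free, positive
  bf <- binnedFeatures(matrix(0L, nCh, nBins), lin,
                       intent = data.frame(vx = vx, vy = vy,
                                           click = FALSE))
  rows <- which(featureFamily(bf) == "hfp")
  dec <- fitKalman(bf, rows)
  v <- decodeStream(dec, bf)
  # after filter convergence the exact model class is recovered
  idx <- 20:nBins
  rmsErr <- sqrt(mean((v[1L, idx] - vx[idx])^2 + (v[2L, idx] - vy[idx])^2))
  expect_lt(rmsErr / sqrt(mean(vx^2 + vy^2)), 0.01)
  # determinism
  dec2 <- fitKalman(bf, rows)
  expect_identical(dec@H, dec2@H)
  expect_identical(dec@K, dec2@K)
})

test_that("Poisson streams are decoded with small heading error", {
  p <- makeParticipant(nChannels = 40L, modulationDepth = 2,
                       baselineRate = 5, seed = 35L)
  bf <- randomIntentStream(p, 3000L, seed = 36L)
  sel <- selectFeatures(bf, family = "spike")
  dec <- fitKalman(bf, sel)
  v <- decodeStream(dec, bf)
  il <- intentLabels(bf)
  errs <- vapply(seq_len(ncol(v)), function(t)
    bcisim:::angleBetween(v[, t], c(il$vx[t], il$vy[t])), numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 20)
})

test_that("fitted observation directions recover the tuning map", {
  p <- makeParticipant(nChannels = 40L, modulationDepth = 2,
                       baselineRate = 5, seed = 37L)
  bf <- randomIntentStream(p, 3000L, seed = 38L)
  sel <- selectFeatures(bf, family = "spike")
  dec <- fitKalman(bf, sel)
  chan <- SummarizedExperiment::rowData(bf)$channel[sel]
  fitted <- atan2(dec@H[, 2L], dec@H[, 1L])
  errs <- angDiffDeg(fitted, preferredDirections(p)[chan])
  expect_gte(mean(errs <= 15), 0.8)
})

test_that("rank-deficient observation fits are rejected", {
  bf <- binnedFeatures(matrix(0L, 3L, 200L),
                       matrix(2, 3L, 200L),
                       intent = data.frame(vx = rep(0, 200L),
                                           vy = rep(0, 200L),
                                           click = FALSE))
  expect_error(fitKalman(bf, 4:6), "rank-deficient")
})

test_that("intention relabelling rotates speed toward the target", {
  out <- refitRelabel(cursor = matrix(c(0, 0)),
                      decoded = matrix(c(3, 4)),
                      target = matrix(c(100, 0)),
                      overTarget = FALSE)
  expect_equal(out[, 1L], c(5, 0))
  # over-target rule wins, even with nonzero decoded speed
  expect_equal(refitRelabel(matrix(c(1, 1)), matrix(c(3, 4)),
                            matrix(c(1, 1)), TRUE)[, 1L], c(0, 0))
  expect_equal(refitRelabel(matrix(c(1, 1)), matrix(c(3, 4)),
                            matrix(c(1, 1)), FALSE)[, 1L], c(0, 0))
  # magnitude preserved over random cases
  set.seed(39)
  for (i in 1:20) {
    cur <- matrix(rnorm(2)); dec <- matrix(rnorm(2)); tg <- matrix(rnorm(2))
    out <- refitRelabel(cur, dec, tg, FALSE)
    expect_equal(sqrt(sum(out^2)), sqrt(sum(dec^2)), tolerance = 1e-12)
    d <- tg - cur
    expect_gt(sum(out * d), 0)
  }
})

test_that("decode dynamics: decay, fixed point, zero-mean noise", {
  set.seed(40)
  nBins <- 500L; nCh <- 8L
  vx <- runif(nBins, -1, 1); vy <- runif(nBins, -1, 1)
  Hx <- runif(nCh, -2, 2); Hy <- runif(nCh, -2, 2)
  Z <- outer(Hx, vx) + outer(Hy, vy) + 10 +
    matrix(rnorm(nCh * nBins, 0, 0.5), nCh)
  bf <- binnedFeatures(matrix(0L, nCh, nBins), pmax(Z, 0),
                       intent = data.frame(vx = vx, vy = vy, click = FALSE))
  rows <- which(featureFamily(bf) == "hfp")
  dec <- fitKalman(bf, rows)
  # zero innovation: velocity decays along the kinematic model
  st <- c(2, -1, 1)
  zPred <- as.numeric(dec@H %*% (dec@A %*% st))
  st2 <- decodeStep(dec, zPred, st)
  expect_equal(st2[1:2], dec@decay * st[1:2], tolerance = 1e-9)
  # constant features for v*: decoded velocity converges near v*
  vStar <- c(0.5, -0.3)
  zStar <- as.numeric(dec@H %*% c(vStar, 1))
  st <- c(0, 0, 1)
  for (i in 1:300) st <- decodeStep(dec, zStar, st)
  expect_lt(sqrt(sum((st[1:2] - vStar)^2)) / sqrt(sum(vStar^2)), 0.1)
  # white-noise features: time-averaged decoded velocity ~ 0
  set.seed(41)
  st <- c(0, 0, 1); acc <- c(0, 0)
  for (t in 1:4000) {
    st <- decodeStep(dec, rnorm(nCh, 0, 1), st)
    acc <- acc + st[1:2]
  }
  expect_lt(max(abs(acc / 4000)), 0.05)
  expect_error(decodeStep(dec, c(NA, rep(0, nCh - 1L))), "non-finite")
})

test_that("position integration is a clamped 1-ms Euler scheme", {
  b <- c(0, 0, 10, 10)
  pos <- c(5, 5)
  for (i in 1:15) pos <- integratePosition(pos, c(100, 0), 0.001, b)
  expect_equal(pos, c(6.5, 5))
  expect_equal(integratePosition(c(10, 5), c(50, 0), 0.001, b), c(10, 5))
  # summation oracle when unclamped
  set.seed(42)
  vs <- matrix(rnorm(2000L), 2L)
  pos <- c(0, 0)
  for (t in seq_len(ncol(vs)))
    pos <- integratePosition(pos, vs[, t], 0.001, c(-1e6, -1e6, 1e6, 1e6))
  expect_equal(pos, rowSums(vs) * 0.001, tolerance = 1e-9)
})
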
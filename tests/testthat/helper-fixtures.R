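# Shared fixtures, built once per test run. All are generated in code
# under fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

# Random-intent calibration stream: intents drawn on the unit disk,
# features from a participant with known tuning.
randomIntentStream <- function(p, nBins, seed = 42L) {
  set.seed(seed)
  r <- sqrt(runif(nBins)); th <- runif(nBins, 0, 2 * pi)
  vx <- r * cos(th); vy <- r * sin(th)
  enc <- bcisim:::encodeBins(p, rbind(vx, vy), rep(FALSE, nBins))
  binnedFeatures(enc$counts, enc$hfPower,
                 intent = data.frame(vx = vx, vy = vy, click = FALSE))
}

# One calibrated spike-click session shared across tests.
sharedCalibration <- function() {
  if (is.null(.fixtures$cal)) {
    p <- makeParticipant(seed = 2L)
    cfg <- sessionConfig("spike-click", participant = p, seed = 3L)
    .fixtures$p <- p
    .fixtures$cfg <- cfg
    .fixtures$cal <- calibrateSession(cfg)
  }
  list(p = .fixtures$p, cfg = .fixtures$cfg, cal = .fixtures$cal)
}

# 4-D Gaussians separated along the first axis by `sep` standard
# deviations, used across several tests.
twoStateStream <- function(n, pClickState = 0.2, sep = 8, seed = 60L,
                           selfTrans = NULL) {
  set.seed(seed)
  if (is.null(selfTrans)) {
    s <- runif(n) < pClickState
  } else {
    s <- logical(n); s[1L] <- FALSE
    for (t in 2:n)
      s[t] <- if (s[t - 1L]) runif(1) < selfTrans else runif(1) > selfTrans
  }
  z <- matrix(rnorm(n * 4L), n, 4L)
  z[s, 1L] <- z[s, 1L] + sep
  list(z = z, s = s)
}

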
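# Synthetic participants and feature-stream generation.
#
# The generative model is the inverse of what the decoders assume:
# cosine-tuned linear rates on counts (rate = baseline + drift +
# depth * cos-gain + click shift), Poisson noise rectified at zero,
# and an HF-LFP power feature coupled to the same drive.

#' Create a synthetic participant
#'
#' @param nChannels number of channels (>= 2); 96 matches one recording
#'   array, 192 two arrays
#' @param preferredDirection optional per-channel preferred direction in
#'   radians; drawn uniformly on the circle when NULL
#' @param modulationDepth per-channel (or scalar) tuning depth,
#'   counts/bin per unit speed
#' @param baselineRate per-channel (or scalar) baseline counts per bin;
#'   default drawn uniformly on [2, 8]
#' @param clickShift per-channel additive mean shift in the click state;
#'   by default a random \code{clickFraction} of channels get a shift of
#'   magnitude \code{clickShiftSize} with random sign
#' @param clickFraction,clickShiftSize defaults for the click signature
#' @param lfpGain per-channel (or scalar) gain of the HF-LFP feature
#' @param driftSigma,driftTheta Ornstein-Uhlenbeck baseline drift:
#'   per-bin innovation s.d. (counts/bin) and mean-reversion rate;
#'   driftSigma = 0 disables drift
#' @param noiseModel "poisson" (default) or "gaussian"
#' @param seed integer seed; identical seed + parameters give
#'   bit-identical participants and generated streams
#' @return a \linkS4class{SyntheticParticipant}
#' @export
makeParticipant <- function(nChannels = 96L, preferredDirection = NULL,
                            modulationDepth = 2, baselineRate = NULL,
                            clickShift = NULL, clickFraction = 0.3,
                            clickShiftSize = 2, lfpGain = 1,
                            driftSigma = 0, driftTheta = 0.005,
                            noiseModel = c("poisson", "gaussian"),
                            seed = 1L) {
  noiseModel <- match.arg(noiseModel)
  nChannels <- as.integer(nChannels)
  if (is.na(nChannels) || nChannels < 2L)
    stop("configuration error: nChannels must be >= 2")
  if (!all(is.finite(modulationDepth)))
    stop("configuration error: modulationDepth must be finite")
  if (!is.null(baselineRate) && any(baselineRate < 0))
    stop("configuration error: baselineRate must be >= 0")
  rs <- childSeed(seed, 0L)
  withr_seed <- function(expr) { # local, deterministic draws
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(rs); expr
  }
  out <- withr_seed({
    pd <- preferredDirection %||% runif(nChannels, 0, 2 * pi)
    bl <- baselineRate %||% runif(nChannels, 2, 8)
    cs <- clickShift
    if (is.null(cs)) {
      cs <- numeric(nChannels)
      k <- max(1L, round(clickFraction * nChannels))
      idx <- sample.int(nChannels, k)
      cs[idx] <- clickShiftSize * sample(c(-1, 1), k, replace = TRUE)
    }
    list(pd = pd, bl = rep_len(bl, nChannels), cs = rep_len(cs, nChannels))
  })
  new("SyntheticParticipant",
      nChannels = nChannels,
      preferredDirection = rep_len(out$pd, nChannels),
      modulationDepth = rep_len(as.numeric(modulationDepth), nChannels),
      baselineRate = out$bl,
      clickShift = out$cs,
      lfpGain = rep_len(as.numeric(lfpGain), nChannels),
      driftSigma = as.numeric(driftSigma),
      driftTheta = as.numeric(driftTheta),
      noiseModel = noiseModel,
      seed = as.integer(seed))
}

#' Read a participant definition from a YAML key/value config file
#'
#' @param path YAML file whose keys match the arguments of
#'   \code{\link{makeParticipant}}
#' @return a \linkS4class{SyntheticParticipant}
#' @export
readParticipantConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(makeParticipant, cfg)
}

# Expected (pre-noise) drive per channel for one bin.
channelDrive <- function(p, v, click, drift = 0) {
  cosGain <- cos(p@preferredDirection) * v[1] + sin(p@preferredDirection) * v[2]
  p@baselineRate + drift + p@modulationDepth * cosGain +
    p@clickShift * as.numeric(click)
}

#' Encode one 15-ms bin of neural features
#'
#' Expected count per channel is baseline + drift + depth * (cosine
#' tuning gain) + click shift while click intent is on; the expectation
#' is rectified at zero before Poisson noise. The HF-LFP feature is the
#' same drive scaled by \code{lfpGain}, with noise, rectified at zero.
#'
#' @param p a \linkS4class{SyntheticParticipant}
#' @param v intended velocity, 2-vector (workspace units/s)
#' @param click logical click intent
#' @param drift per-channel baseline offsets (default 0)
#' @return list with numeric vectors \code{counts} and \code{hfPower}
#' @export
encodeBin <- function(p, v, click = FALSE, drift = 0) {
  drive <- channelDrive(p, v, click, drift)
  mu <- pmax(drive, 0)
  counts <- switch(p@noiseModel,
    # the 1-ms presence detector yields at most one event per window,
    # so counts saturate at binWidth / 1 ms = 15
    poisson  = pmin(rpois(p@nChannels, mu), 15L),
    gaussian = round(pmin(pmax(
      mu + rnorm(p@nChannels, 0, sqrt(pmax(mu, 1e-8))), 0), 15)))
  hfMu <- pmax(p@lfpGain * drive, 0)
  hf <- pmax(hfMu + rnorm(p@nChannels, 0, sqrt(hfMu + 0.5)), 0)
  list(counts = counts, hfPower = hf)
}

# Vectorised encoder: V is 2 x T, click length T, drift n x T (or 0).
# Returns list(counts = n x T, hfPower = n x T). Uses the current RNG
# state; callers seed it.
encodeBins <- function(p, V, click, drift = NULL) {
  n <- p@nChannels; TT <- ncol(V)
  cosv <- cos(p@preferredDirection); sinv <- sin(p@preferredDirection)
  drive <- outer(cosv, V[1, ]) + outer(sinv, V[2, ])
  drive <- p@baselineRate + p@modulationDepth * drive
  if (!is.null(drift)) drive <- drive + drift
  if (any(click))
    drive[, click] <- drive[, click] + p@clickShift
  mu <- pmax(drive, 0)
  counts <- switch(p@noiseModel,
    poisson  = matrix(pmin(rpois(n * TT, mu), 15L), n, TT),
    gaussian = matrix(round(pmin(pmax(
      mu + rnorm(n * TT, 0, sqrt(pmax(mu, 1e-8))), 0), 15)), n, TT))
  hfMu <- pmax(p@lfpGain * drive, 0)
  hf <- pmax(hfMu + matrix(rnorm(n * TT, 0, sqrt(hfMu + 0.5)), n, TT), 0)
  list(counts = counts, hfPower = hf)
}

# One step of the OU drift state (per-channel vector), per-bin cadence.
driftStep <- function(p, state) {
  state * (1 - p@driftTheta) + rnorm(p@nChannels, 0, p@driftSigma)
}

# Full OU drift path, n x T (zero matrix when driftSigma == 0).
driftPath <- function(p, nBins, init = NULL) {
  n <- p@nChannels
  out <- matrix(0, n, nBins)
  state <- init %||% numeric(n)
  if (p@driftSigma == 0 && all(state == 0)) return(out)
  for (t in seq_len(nBins)) {
    state <- driftStep(p, state)
    out[, t] <- state
  }
  out
}

#' Assemble a BinnedFeatures container
#'
#' @param counts channels x bins matrix of threshold-crossing counts
#' @param hfPower channels x bins matrix of HF-LFP band power
#' @param timestamps bin start times, s
#' @param intent optional data.frame with vx, vy, click per bin
#' @param binWidth bin width, s
#' @return a \linkS4class{BinnedFeatures} with 2 * channels feature rows
#' @export
binnedFeatures <- function(counts, hfPower, timestamps = NULL,
                           intent = NULL, binWidth = 0.015) {
  stopifnot(all(dim(counts) == dim(hfPower)))
  n <- nrow(counts); TT <- ncol(counts)
  timestamps <- timestamps %||% (seq_len(TT) - 1L) * binWidth
  x <- rbind(counts, hfPower)
  rownames(x) <- c(paste0("spike.ch", seq_len(n)), paste0("hfp.ch", seq_len(n)))
  rd <- S4Vectors::DataFrame(
    channel = rep(seq_len(n), 2L),
    family = rep(c("spike", "hfp"), each = n),
    baseline = rep(0, 2L * n))
  cd <- S4Vectors::DataFrame(timestamp = timestamps)
  if (!is.null(intent)) {
    cd$intentVx <- intent$vx
    cd$intentVy <- intent$vy
    cd$clickIntent <- intent$click
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = x), rowData = rd, colData = cd,
    metadata = list(binWidth = binWidth, crossingResolution = 0.001))
  new("BinnedFeatures", se)
}

#' Pre-programmed center-out-and-back calibration trajectory
#'
#' Builds the open-loop cursor path used for decoder calibration: the
#' cursor moves from the center to each of \code{nTargets} radial
#' targets and back, holding on the target between the two legs. Click
#' intent (emulating an attempted hand squeeze) is on during holds when
#' \code{clickOnHold} is TRUE.
#'
#' @param nTargets number of radial targets (default 8)
#' @param radius target ring radius, workspace units
#' @param legDuration duration of each movement leg, s
#' @param holdDuration hold on the target between legs, s
#' @param nRepeats number of passes over all targets
#' @param binWidth bin width, s
#' @param clickOnHold mark click intent during target holds
#' @return data.frame with t, x, y, vx, vy, click, targetX, targetY
#' @export
centerOutTrajectory <- function(nTargets = 8L, radius = 0.35,
                                legDuration = 0.6, holdDuration = 0.45,
                                nRepeats = 3L, binWidth = 0.015,
                                clickOnHold = TRUE) {
  stopifnot(nTargets >= 1L, legDuration > 0)
  ang <- 2 * pi * (seq_len(nTargets) - 1L) / nTargets
  legBins <- max(1L, round(legDuration / binWidth))
  holdBins <- max(0L, round(holdDuration / binWidth))
  speed <- radius / legDuration
  rows <- list()
  for (r in seq_len(nRepeats)) for (k in seq_len(nTargets)) {
    tx <- radius * cos(ang[k]); ty <- radius * sin(ang[k])
    u <- c(cos(ang[k]), sin(ang[k]))
    frac <- (seq_len(legBins) - 0.5) / legBins
    out <- data.frame(
      x = frac * tx, y = frac * ty,
      vx = speed * u[1], vy = speed * u[2],
      click = FALSE, targetX = tx, targetY = ty)
    hold <- if (holdBins > 0L) data.frame(
      x = tx, y = ty, vx = 0, vy = 0,
      click = clickOnHold, targetX = tx, targetY = ty)[rep(1L, holdBins), ]
      else NULL
    back <- data.frame(
      x = (1 - frac) * tx, y = (1 - frac) * ty,
      vx = -speed * u[1], vy = -speed * u[2],
      click = FALSE, targetX = 0, targetY = 0)
    rest <- if (holdBins > 0L) data.frame(
      x = 0, y = 0, vx = 0, vy = 0, click = FALSE,
      targetX = 0, targetY = 0)[rep(1L, holdBins), ] else NULL
    rows[[length(rows) + 1L]] <- rbind(out, hold, back, rest)
  }
  tr <- do.call(rbind, rows)
  tr$t <- (seq_len(nrow(tr)) - 1L) * binWidth
  rownames(tr) <- NULL
  tr[, c("t", "x", "y", "vx", "vy", "click", "targetX", "targetY")]
}

#' Simulate an open-loop calibration block
#'
#' The cursor follows the pre-programmed trajectory while the simulated
#' participant "attempts" the matching movement: the intent stream
#' mirrors the programmed velocity (click intent during programmed
#' selection epochs), and features are generated from the participant's
#' tuning model.
#'
#' @param p a \linkS4class{SyntheticParticipant}
#' @param trajectory data.frame from \code{\link{centerOutTrajectory}}
#' @param seed optional seed (defaults to the participant seed)
#' @param driftInit optional initial per-channel drift state
#' @return a \linkS4class{BinnedFeatures} with intent labels
#' @export
simulateOpenLoopBlock <- function(p, trajectory = centerOutTrajectory(),
                                  seed = NULL, driftInit = NULL) {
  if (is.null(trajectory) || nrow(trajectory) == 0L)
    stop("empty trajectory")
  set.seed(childSeed(seed %||% p@seed, 1L))
  V <- rbind(trajectory$vx, trajectory$vy)
  click <- trajectory$click
  dp <- driftPath(p, ncol(V), driftInit)
  enc <- encodeBins(p, V, click, dp)
  binnedFeatures(enc$counts, enc$hfPower, timestamps = trajectory$t,
                 intent = data.frame(vx = trajectory$vx, vy = trajectory$vy,
                                     click = click))
}

#' Write / read a BinnedFeatures stream as CSV
#'
#' Plain-text interchange for small fixtures. Columns: bin_index,
#' timestamp_s, one column per feature row (named family.chN), then
#' intent columns when present.
#'
#' @param x a \linkS4class{BinnedFeatures}
#' @param path CSV file path
#' @export
writeFeaturesCsv <- function(x, path) {
  m <- t(featureMatrix(x))
  df <- data.frame(bin_index = seq_len(nrow(m)), timestamp_s = binTimes(x))
  df <- cbind(df, as.data.frame(m))
  il <- intentLabels(x)
  if (!is.null(il)) {
    df$intent_vx <- il$vx; df$intent_vy <- il$vy; df$click_intent <- il$click
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeaturesCsv
#' @param binWidth bin width, s, of the stored stream
#' @export
readFeaturesCsv <- function(path, binWidth = 0.015) {
  df <- utils::read.csv(path, check.names = FALSE)
  featCols <- grep("^(spike|hfp)\\.ch", colnames(df), value = TRUE)
  sp <- grep("^spike\\.", featCols, value = TRUE)
  hf <- grep("^hfp\\.", featCols, value = TRUE)
  counts <- t(as.matrix(df[, sp, drop = FALSE]))
  hfp <- t(as.matrix(df[, hf, drop = FALSE]))
  intent <- if ("intent_vx" %in% colnames(df))
    data.frame(vx = df$intent_vx, vy = df$intent_vy,
               click = as.logical(df$click_intent)) else NULL
  binnedFeatures(counts, hfp, timestamps = df$timestamp_s,
                 intent = intent, binWidth = binWidth)
}
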
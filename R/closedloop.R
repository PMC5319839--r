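# Closed-loop orchestration: the neural controller (simulated user ->
# synthetic encoder -> decoders -> cursor), calibration, recalibration
# with error attenuation, bias re-estimation, and full sessions.

# Simulate a rest period (user relaxes: zero intent, no click) and
# return the per-feature baseline estimate plus the drift state.
restBaseline <- function(p, duration = 30, driftInit = NULL, seed = 1L,
                         minDuration = 30) {
  set.seed(childSeed(seed, 8L))
  nBins <- round(duration / 0.015)
  dp <- driftPath(p, nBins, driftInit)
  enc <- encodeBins(p, matrix(0, 2L, nBins), rep(FALSE, nBins), dp)
  bf <- binnedFeatures(enc$counts, enc$hfPower)
  list(baseline = estimateBaseline(bf, minDuration = minDuration),
       drift = dp[, nBins])
}

#' Build the neural closed-loop controller
#'
#' Returns a per-tick controller closure suitable for
#' \code{\link{runGridBlock}} / \code{\link{runCopyTypingBlock}}: each
#' 15-ms tick it runs the simulated user policy, encodes one bin of
#' synthetic features (with persistent baseline drift), decodes
#' velocity with the Kalman decoder, applies bias correction and
#' optional error attenuation, integrates position at 1 ms (15 steps
#' per bin), and runs the HMM click rule.
#'
#' @param participant a \linkS4class{SyntheticParticipant}
#' @param decoder a \linkS4class{KalmanDecoder}
#' @param hmm a calibrated \linkS4class{ClickHMM}, or NULL
#' @param policy a \linkS4class{SimulatedUserPolicy}
#' @param layout the block's \linkS4class{TaskLayout}
#' @param bias a \linkS4class{BiasState}, or NULL to disable correction
#' @param baseline per-feature baseline vector (length = feature rows)
#'   subtracted before Kalman decoding; defaults to the decoder's
#'   stored calibration baseline
#' @param errorAttenuation NULL, or a factor in [0, 1] scaling the
#'   velocity component perpendicular to the cursor-to-target direction
#'   (assistive; used in recalibration blocks)
#' @param driftInit initial per-channel drift state
#' @param collectLog keep per-bin logs (features, cursor, decoded
#'   velocity, target, over-target) for recalibration
#' @return controller function(ctx) -> list(position, click), with
#'   attribute "env" exposing drift/bias/log state after the run
#' @export
makeNeuralController <- function(participant, decoder, hmm = NULL,
                                 policy = userPolicy(), layout,
                                 bias = NULL, baseline = NULL,
                                 errorAttenuation = NULL,
                                 driftInit = NULL, collectLog = FALSE) {
  env <- new.env(parent = emptyenv())
  env$drift <- driftInit %||% numeric(participant@nChannels)
  env$bias <- bias
  env$userState <- newUserState()
  env$kalmanState <- c(0, 0, 1)
  env$hmmProbs <- c(0.5, 0.5)
  env$clickCounter <- 0L
  env$log <- if (collectLog) list() else NULL
  kbase <- (baseline %||% rep(NA_real_, 1L))
  useFullBaseline <- !is.null(baseline)
  controller <- function(ctx) {
    overCued <- identical(hitTest(layout, ctx$cursor), ctx$cued)
    us <- simulatedUserStep(policy, env$userState, ctx$cursor,
                            ctx$cuedCenter, overCued, time = ctx$time)
    env$userState <- us$state
    env$drift <- driftStep(participant, env$drift)
    enc <- encodeBin(participant, us$v, us$click, env$drift)
    feats <- c(enc$counts, enc$hfPower)
    z <- feats[decoder@selectedFeatures] -
      (if (useFullBaseline) kbase[decoder@selectedFeatures]
       else decoder@baseline)
    env$kalmanState <- decodeStep(decoder, z, env$kalmanState)
    v <- env$kalmanState[1:2]
    if (!is.null(env$bias)) {
      env$bias <- updateBiasBin(env$bias, v)
      v <- correctVelocity(env$bias, v)
    }
    if (!is.null(errorAttenuation)) {
      u <- unitVec(ctx$cuedCenter - ctx$cursor)
      if (any(u != 0)) {
        vPar <- sum(v * u) * u
        v <- vPar + errorAttenuation * (v - vPar)
      }
    }
    pos <- integrateBin(ctx$cursor, v, layout@bounds)
    click <- FALSE
    if (!is.null(hmm) && !is.na(hmm@clickThreshold)) {
      zp <- as.numeric(crossprod(hmm@rotation,
                                 feats[hmm@featureIndex] - hmm@center))
      env$hmmProbs <- hmmStep(hmm, zp, env$hmmProbs)
      if (env$hmmProbs[2L] > hmm@clickThreshold) {
        env$clickCounter <- env$clickCounter + 1L
        if (env$clickCounter >= hmm@consecutiveBinsRequired) {
          click <- TRUE
          env$clickCounter <- 0L
        }
      } else env$clickCounter <- 0L
    }
    if (collectLog)
      env$log[[length(env$log) + 1L]] <-
        list(feats = feats, cursor = ctx$cursor, decoded = v,
             target = ctx$cuedCenter, over = overCued,
             clickIntent = us$click)
    list(position = pos, click = click)
  }
  attr(controller, "env") <- env
  controller
}

# Closed-loop center-out target acquisition used for recalibration and
# bias-update blocks. Returns per-bin logs and summary statistics.
runAcquisitionBlock <- function(participant, decoder, hmm, policy,
                                bias, baseline, duration = 120,
                                errorAttenuation = NULL, seed = 1L,
                                driftInit = NULL,
                                bounds = c(0, 0, 1, 1),
                                radius = 0.35, targetRadius = 0.09,
                                holdRequired = 0.5, trialTimeout = 6) {
  set.seed(childSeed(seed, 9L))
  center <- c(mean(bounds[c(1, 3)]), mean(bounds[c(2, 4)]))
  ang <- 2 * pi * (0:7) / 8
  ring <- cbind(center[1] + radius * cos(ang),
                center[2] + radius * sin(ang))
  drift <- driftInit %||% numeric(participant@nChannels)
  userState <- newUserState()
  kstate <- c(0, 0, 1)
  cursor <- center
  nBins <- round(duration / 0.015)
  nf <- 2L * participant@nChannels
  featLog <- matrix(0, nf, nBins)
  cursorLog <- matrix(0, 2L, nBins)
  decodedLog <- matrix(0, 2L, nBins)
  targetLog <- matrix(0, 2L, nBins)
  overLog <- logical(nBins)
  clickLog <- logical(nBins)
  trialIdx <- 0L; onRing <- TRUE
  target <- ring[1L, ]
  hold <- 0; trialTime <- 0
  kbase <- baseline
  if (is.null(kbase)) {           # fall back to the stored calibration
    kbase <- rep(0, nf)           # baseline of the decoder
    kbase[decoder@selectedFeatures] <- decoder@baseline
  }
  for (t in seq_len(nBins)) {
    tNow <- t * 0.015
    over <- sqrt(sum((cursor - target)^2)) < targetRadius
    us <- simulatedUserStep(policy, userState, cursor, target, over,
                            time = tNow)
    userState <- us$state
    drift <- driftStep(participant, drift)
    enc <- encodeBin(participant, us$v, us$click, drift)
    feats <- c(enc$counts, enc$hfPower)
    z <- feats[decoder@selectedFeatures] - kbase[decoder@selectedFeatures]
    kstate <- decodeStep(decoder, z, kstate)
    v <- kstate[1:2]
    if (!is.null(bias)) {
      bias <- updateBiasBin(bias, v)
      v <- correctVelocity(bias, v)
    }
    if (!is.null(errorAttenuation)) {
      u <- unitVec(target - cursor)
      if (any(u != 0)) {
        vPar <- sum(v * u) * u
        v <- vPar + errorAttenuation * (v - vPar)
      }
    }
    featLog[, t] <- feats
    cursorLog[, t] <- cursor
    decodedLog[, t] <- v
    targetLog[, t] <- target
    overLog[t] <- over
    clickLog[t] <- us$click
    cursor <- integrateBin(cursor, v, bounds)
    hold <- if (over) hold + 0.015 else 0
    trialTime <- trialTime + 0.015
    if (hold >= holdRequired || trialTime > trialTimeout) {
      trialTime <- 0; hold <- 0
      if (onRing) { target <- center } else {
        trialIdx <- (trialIdx + 1L) %% 8L
        target <- ring[trialIdx + 1L, ]
      }
      onRing <- !onRing
    }
  }
  list(features = featLog, cursor = cursorLog, decoded = decodedLog,
       target = targetLog, over = overLog, clickIntent = clickLog,
       drift = drift, bias = bias,
       speeds = vecNorm(decodedLog))
}

# Median closed-loop heading error (deg) between decoded velocity and
# the cursor-to-target direction, over bins away from the target.
medianHeadingError <- function(acq) {
  idx <- which(!acq$over)
  errs <- vapply(idx, function(t)
    angleBetween(acq$decoded[, t], acq$target[, t] - acq$cursor[, t]),
    numeric(1))
  stats::median(errs, na.rm = TRUE)
}

#' Session configuration profiles
#'
#' Shipped decoder/protocol recipes mirroring the three study roles:
#' \describe{
#'   \item{"hybrid-click"}{spike + HF-LFP continuous decoding, HF-LFP
#'     click HMM, 1-s reset dwell, no bias correction, no recentering,
#'     decoders recalibrated each blockset, error attenuation on.}
#'   \item{"spike-click"}{spike-only continuous decoding and click HMM,
#'     1-s reset dwell, bias estimation on, no recentering, bias-update-
#'     only blocksets, no error attenuation.}
#'   \item{"dwell-bias"}{spike-only continuous decoding, no click
#'     decoder, 1.5-s cumulative dwell, bias estimation on, cursor
#'     recentering with a 500-ms lockout, bias-update-only blocksets,
#'     error attenuation on.}
#' }
#'
#' @param profile one of the names above
#' @param participant optional \linkS4class{SyntheticParticipant}
#' @param policy optional \linkS4class{SimulatedUserPolicy}
#' @param nBlocksets number of blocksets
#' @param blockDuration evaluation-block duration, s
#' @param gridN grid side (6 or 9)
#' @param sentence copy-typing sentence (same sentence in both keyboard
#'   blocks of a blockset)
#' @param seed session seed
#' @return a \linkS4class{SessionConfig}
#' @export
sessionConfig <- function(profile = c("spike-click", "hybrid-click",
                                      "dwell-bias"),
                          participant = NULL, policy = NULL,
                          nBlocksets = 1L, blockDuration = 120,
                          gridN = 6L,
                          sentence = "the quick brown fox jumps over the lazy dog",
                          seed = 1L) {
  profile <- match.arg(profile)
  participant <- participant %||% makeParticipant(seed = seed)
  base <- switch(profile,
    "hybrid-click" = list(cont = "both", click = "hfp",
                          dwellMode = "click_or_dwell", dwell = 1.0,
                          bias = FALSE, recenter = FALSE, recal = TRUE,
                          atten = 0.5, clickEnabled = TRUE,
                          keyboards = c("opti2", "qwerty")),
    "spike-click" = list(cont = "spike", click = "spike",
                         dwellMode = "click_or_dwell", dwell = 1.0,
                         bias = TRUE, recenter = FALSE, recal = FALSE,
                         atten = 1, clickEnabled = TRUE,
                         keyboards = c("opti2", "qwerty")),
    "dwell-bias" = list(cont = "spike", click = NA_character_,
                        dwellMode = "dwell_cumulative", dwell = 1.5,
                        bias = TRUE, recenter = TRUE, recal = FALSE,
                        atten = 0.5, clickEnabled = FALSE,
                        keyboards = c("opti2", "abcdef")))
  policy <- policy %||% userPolicy(clickEnabled = base$clickEnabled)
  new("SessionConfig",
      participant = participant, policy = policy,
      continuousFamily = base$cont, clickFamily = base$click,
      dwellMode = base$dwellMode, dwellRequired = base$dwell,
      useBias = base$bias, useRecenter = base$recenter,
      recalibrateEachBlockset = base$recal,
      errorAttenuation = base$atten,
      gridN = as.integer(gridN), keyboards = base$keyboards,
      sentence = sentence, nBlocksets = as.integer(nBlocksets),
      blockDuration = blockDuration, seed = as.integer(seed))
}

#' Calibrate a session's decoders
#'
#' Runs the calibration protocol on the synthetic participant: a 30-s
#' rest period for baselines, an open-loop center-out-and-back block
#' (pre-programmed cursor, attempted matching movements, attempted
#' squeezes during holds), feature selection by tuning significance,
#' Kalman and HMM fitting, a closed-loop recalibration block with
#' error attenuation where configured, intention-based refitting, and
#' unsupervised click-threshold calibration. Errors out when the
#' resulting cursor is not controllable (median closed-loop heading
#' error above 60 degrees).
#'
#' @param config a \linkS4class{SessionConfig}
#' @param openLoopRepeats passes over the 8 calibration targets
#' @param recalDuration closed-loop recalibration duration, s
#' @return list with decoder, hmm, baseline, bias, drift state, the
#'   speed gate, and the closed-loop median heading error
#' @export
calibrateSession <- function(config, openLoopRepeats = 6L,
                             recalDuration = 90) {
  p <- config@participant
  rest <- restBaseline(p, 30, seed = config@seed)
  traj <- centerOutTrajectory(nRepeats = openLoopRepeats,
                              clickOnHold = !is.na(config@clickFamily))
  ol <- simulateOpenLoopBlock(p, traj, seed = childSeed(config@seed, 10L),
                              driftInit = rest$drift)
  feats <- selectFeatures(ol, family = config@continuousFamily,
                          maxFeatures = 40L)
  decoder <- fitKalman(ol, feats, baseline = rest$baseline[feats])
  hmm <- NULL
  if (!is.na(config@clickFamily)) {
    pca <- fitClickPca(ol, family = config@clickFamily)
    proj <- projectFeatures(pca, ol)
    hmm <- fitHmm(proj, intentLabels(ol)$click, pca)
  }
  acq <- runAcquisitionBlock(
    p, decoder, hmm, config@policy, bias = NULL,
    baseline = expandBaseline(rest$baseline, decoder), duration = recalDuration,
    errorAttenuation = if (config@errorAttenuation < 1)
      config@errorAttenuation else NULL,
    seed = childSeed(config@seed, 11L), driftInit = rest$drift)
  he <- medianHeadingError(acq)
  if (!is.finite(he) || he > 60)
    stop(sprintf(
      "calibration failure: closed-loop median heading error %.1f deg", he))
  relabeled <- refitRelabel(acq$cursor, acq$decoded, acq$target, acq$over)
  recalBf <- binnedFeatures(
    acq$features[seq_len(p@nChannels), , drop = FALSE],
    acq$features[p@nChannels + seq_len(p@nChannels), , drop = FALSE],
    intent = data.frame(vx = relabeled[1L, ], vy = relabeled[2L, ],
                        click = acq$clickIntent))
  decoder <- fitKalman(recalBf, feats, baseline = rest$baseline[feats])
  if (!is.null(hmm)) {
    pca2 <- fitClickPca(recalBf, family = config@clickFamily)
    proj2 <- projectFeatures(pca2, recalBf)
    hmm <- fitHmm(proj2, acq$clickIntent, pca2)
    hmm <- setClickThreshold(hmm, recalBf)
  }
  gate <- estimateSpeedGate(acq$speeds)
  bias <- if (config@useBias)
    biasState(speedThreshold = gate) else NULL
  list(decoder = decoder, hmm = hmm, baseline = rest$baseline,
       bias = bias, drift = acq$drift, speedGate = gate,
       headingError = he)
}

# The controllers index baselines by feature row; rest baselines are
# already full-length, so this is a passthrough kept for clarity.
expandBaseline <- function(baseline, decoder) baseline

#' Run a full simulated session
#'
#' Executes the blockset protocol: each blockset re-estimates baselines
#' from a 30-s rest, then either recalibrates the decoders or runs a
#' bias-update acquisition block, then runs the three evaluation blocks
#' (grid + two copy-typing blocks, order randomized with the
#' copy-typing blocks adjacent, the same sentence in both).
#'
#' @param config a \linkS4class{SessionConfig}
#' @param calibration optional result of \code{\link{calibrateSession}}
#' @return list with \code{blocks} (one row per evaluation block),
#'   \code{summary} (mean and s.d. of bitrate / ccpm per task), and
#'   \code{events} (per-block selection logs)
#' @export
runSession <- function(config, calibration = NULL) {
  calibration <- calibration %||% calibrateSession(config)
  p <- config@participant
  decoder <- calibration$decoder
  hmm <- calibration$hmm
  bias <- calibration$bias
  drift <- calibration$drift
  rule <- selectionRule(
    mode = if (!is.na(config@clickFamily)) "click_or_dwell"
           else config@dwellMode,
    dwellRequired = config@dwellRequired,
    recenter = config@useRecenter)
  gridLayout <- makeGridLayout(config@gridN)
  kb <- lapply(config@keyboards, makeKeyboardLayout)
  names(kb) <- config@keyboards
  blocks <- list(); eventsLog <- list()
  for (b in seq_len(config@nBlocksets)) {
    bseed <- childSeed(config@seed, 100L + b)
    rest <- restBaseline(p, 30, driftInit = drift, seed = bseed)
    drift <- rest$drift
    baseline <- rest$baseline
    if (config@recalibrateEachBlockset && b > 1L) {
      acq <- runAcquisitionBlock(p, decoder, hmm, config@policy,
                                 bias = NULL, baseline = baseline,
                                 duration = 60,
                                 errorAttenuation =
                                   if (config@errorAttenuation < 1)
                                     config@errorAttenuation else NULL,
                                 seed = childSeed(bseed, 1L),
                                 driftInit = drift)
      drift <- acq$drift
      relabeled <- refitRelabel(acq$cursor, acq$decoded, acq$target,
                                acq$over)
      recalBf <- binnedFeatures(
        acq$features[seq_len(p@nChannels), , drop = FALSE],
        acq$features[p@nChannels + seq_len(p@nChannels), , drop = FALSE],
        intent = data.frame(vx = relabeled[1L, ], vy = relabeled[2L, ],
                            click = acq$clickIntent))
      decoder <- fitKalman(recalBf, decoder@selectedFeatures,
                           baseline = baseline[decoder@selectedFeatures])
      if (!is.null(hmm)) {
        pca2 <- fitClickPca(recalBf, family = config@clickFamily)
        proj2 <- projectFeatures(pca2, recalBf)
        hmm <- fitHmm(proj2, acq$clickIntent, pca2)
        hmm <- setClickThreshold(hmm, recalBf)
      }
    } else if (!config@recalibrateEachBlockset) {
      acq <- runAcquisitionBlock(p, decoder, hmm, config@policy,
                                 bias = bias, baseline = baseline,
                                 duration = 60,
                                 seed = childSeed(bseed, 1L),
                                 driftInit = drift)
      drift <- acq$drift
      bias <- acq$bias                       # only updated bias estimates
    }
    order <- sampleBlocksetOrder(c("grid", config@keyboards),
                                 seed = childSeed(bseed, 2L))
    for (task in order) {
      layout <- if (task == "grid") gridLayout else kb[[task]]
      ctrl <- makeNeuralController(p, decoder, hmm, config@policy,
                                   layout, bias = bias,
                                   baseline = baseline,
                                   driftInit = drift)
      blk <- if (task == "grid")
        runGridBlock(layout, rule, ctrl, duration = config@blockDuration,
                     seed = childSeed(bseed, 3L))
      else
        runCopyTypingBlock(layout, rule, ctrl, config@sentence,
                           duration = config@blockDuration,
                           seed = childSeed(bseed, 4L))
      env <- attr(ctrl, "env")
      drift <- env$drift
      if (!is.null(bias)) bias <- env$bias
      row <- blk$result
      row$blockset <- b
      row$task <- task
      blocks[[length(blocks) + 1L]] <- row
      eventsLog[[paste0("bs", b, "_", task)]] <- blk$events
    }
  }
  blocks <- do.call(rbind, blocks)
  agg <- lapply(split(blocks, blocks$task), function(d)
    data.frame(task = d$task[1L], nBlocks = nrow(d),
               meanBitrate = mean(d$bitrate), sdBitrate = stats::sd(d$bitrate),
               meanCcpm = mean(d$ccpm), sdCcpm = stats::sd(d$ccpm)))
  list(blocks = blocks, summary = do.call(rbind, agg), events = eventsLog,
       calibration = calibration)
}

#' Validate a session's block structure
#'
#' Checks the protocol invariants over a \code{runSession} result:
#' three evaluation blocks per blockset, the copy-typing blocks
#' adjacent within each blockset, and block durations within the cap.
#'
#' @param session result of \code{\link{runSession}}
#' @param config the \linkS4class{SessionConfig} used
#' @return TRUE (invisibly) or an error describing the violation
#' @export
validateSessionLog <- function(session, config) {
  blocks <- session$blocks
  for (b in unique(blocks$blockset)) {
    d <- blocks[blocks$blockset == b, ]
    if (nrow(d) != 3L) stop("blockset ", b, " must have 3 evaluation blocks")
    kbPos <- which(d$task %in% config@keyboards)
    if (length(kbPos) != 2L || diff(kbPos) != 1L)
      stop("copy-typing blocks must be adjacent in blockset ", b)
    if (any(d$t > config@blockDuration + 1e-9))
      stop("block duration exceeds the cap in blockset ", b)
  }
  invisible(TRUE)
}
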
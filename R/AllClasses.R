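#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' SyntheticParticipant: generative model of one simulated iBCI user
#'
#' Encodes the tuning map and noise structure of a simulated participant:
#' per-channel cosine tuning to intended cursor velocity, Poisson (or
#' Gaussian) count noise, an additive click-state mean shift on a channel
#' subset, a high-frequency LFP power feature co-modulated with the same
#' drive, and a mean-reverting (Ornstein-Uhlenbeck) random walk on the
#' per-channel baselines that emulates slow nonstationarity in baseline
#' firing rates.
#'
#' @slot nChannels number of recording channels (>= 2)
#' @slot preferredDirection per-channel preferred direction, radians
#' @slot modulationDepth per-channel depth, counts/bin per unit speed
#' @slot baselineRate per-channel baseline, counts per 15-ms bin (>= 0)
#' @slot clickShift per-channel additive mean shift (counts/bin) applied
#'   while the simulated user intends a click
#' @slot lfpGain per-channel gain mapping the shared drive to the HF-LFP
#'   power feature
#' @slot driftSigma,driftTheta innovation s.d. and mean-reversion rate
#'   (per bin) of the baseline drift process; driftSigma = 0 gives a
#'   stationary participant
#' @slot noiseModel "poisson" or "gaussian"
#' @slot seed integer seed from which all generated streams derive
#' @export
setClass("SyntheticParticipant",
  slots = c(
    nChannels          = "integer",
    preferredDirection = "numeric",
    modulationDepth    = "numeric",
    baselineRate       = "numeric",
    clickShift         = "numeric",
    lfpGain            = "numeric",
    driftSigma         = "numeric",
    driftTheta         = "numeric",
    noiseModel         = "character",
    seed               = "integer"
  )
)

setValidity("SyntheticParticipant", function(object) {
  n <- object@nChannels
  msg <- character()
  if (n < 2L) msg <- c(msg, "nChannels must be >= 2")
  for (s in c("preferredDirection", "modulationDepth", "baselineRate",
              "clickShift", "lfpGain")) {
    v <- slot(object, s)
    if (length(v) != n) msg <- c(msg, paste0(s, " must have length nChannels"))
    if (!all(is.finite(v))) msg <- c(msg, paste0(s, " must be finite"))
  }
  if (any(object@baselineRate < 0))
    msg <- c(msg, "baselineRate must be >= 0 on every channel")
  if (!object@noiseModel %in% c("poisson", "gaussian"))
    msg <- c(msg, "noiseModel must be 'poisson' or 'gaussian'")
  if (object@driftSigma < 0 || object@driftTheta < 0 || object@driftTheta > 1)
    msg <- c(msg, "driftSigma must be >= 0 and driftTheta in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' BinnedFeatures: 15-ms binned neural feature streams
#'
#' A \linkS4class{SummarizedExperiment} whose rows are neural features
#' (threshold-crossing counts and HF-LFP band power, one row per channel
#' and family) and whose columns are 15-ms bins. \code{rowData} carries
#' \code{channel}, \code{family} ("spike" or "hfp") and the per-feature
#' \code{baseline} currently subtracted downstream; \code{colData}
#' carries bin timestamps and, when known, the intended velocity and
#' click-intent labels used for decoder calibration.
#'
#' @export
setClass("BinnedFeatures", contains = "SummarizedExperiment")

setValidity("BinnedFeatures", function(object) {
  msg <- character()
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("channel", "family", "baseline") %in% colnames(rd)))
    return("rowData must contain channel, family, baseline")
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  x <- SummarizedExperiment::assay(object, "features")
  bw <- object@metadata$binWidth
  if (is.null(bw)) return("metadata$binWidth is required")
  sp <- rd$family == "spike"
  if (any(sp)) {
    xs <- x[sp, , drop = FALSE]
    if (any(xs < 0) || any(xs != round(xs)))
      msg <- c(msg, "spike crossings must be non-negative integers")
    maxPerBin <- round(bw / (object@metadata$crossingResolution %||% 0.001))
    if (any(xs > maxPerBin))
      msg <- c(msg, sprintf("crossings must be <= %d per bin", maxPerBin))
  }
  if (any(!sp) && any(x[!sp, , drop = FALSE] < 0))
    msg <- c(msg, "hfPower must be >= 0")
  if (!"timestamp" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain timestamp")
  if (length(msg)) msg else TRUE
})

#' SignalConfig: parameters of the broadband signal chain
#'
#' @slot sampleRate samples/s (the chain is specified at 30000)
#' @slot spikeThreshold fixed per-array threshold in uV (negative), or NA
#'   to derive thresholds as \code{rmsMultiplier} times each channel RMS
#' @slot rmsMultiplier unitless multiplier (e.g. -4.5) for RMS thresholds
#' @slot hfBand HF-LFP band edges in Hz (default 150-450)
#' @slot binWidth feature bin width, s (default 0.015)
#' @slot crossingResolution threshold-detector window, s (default 0.001)
#' @slot iirCutoff,iirOrder,firOrder spike-band high-pass realization:
#'   causal Butterworth IIR followed by a linear-phase FIR trim
#' @export
setClass("SignalConfig",
  slots = c(
    sampleRate         = "numeric",
    spikeThreshold     = "numeric",
    rmsMultiplier      = "numeric",
    hfBand             = "numeric",
    binWidth           = "numeric",
    crossingResolution = "numeric",
    iirCutoff          = "numeric",
    iirOrder           = "integer",
    firOrder           = "integer"
  )
)

setValidity("SignalConfig", function(object) {
  msg <- character()
  ratio <- object@binWidth / object@crossingResolution
  if (abs(ratio - round(ratio)) > 1e-9)
    msg <- c(msg, "binWidth must be an integer multiple of crossingResolution")
  ny <- object@sampleRate / 2
  if (!(object@hfBand[1] < object@hfBand[2] && object@hfBand[2] < ny))
    msg <- c(msg, "hfBand must satisfy low < high < Nyquist")
  if (length(msg)) msg else TRUE
})

#' KalmanDecoder: fitted velocity Kalman filter
#'
#' Linear-Gaussian velocity decoder over the state (vx, vy, 1): the
#' observation model maps state to the selected neural features, the
#' kinematic model is an AR(1) velocity decay, and decoding runs one
#' predict/update per 15-ms bin using the converged (steady-state)
#' Kalman gain. Position is not part of the observation update; it is
#' integrated from decoded velocity at 1-ms resolution.
#'
#' @slot A,W 3x3 state-transition matrix and process noise
#' @slot H,Q observation matrix (features x 3) and observation noise
#' @slot K steady-state Kalman gain (3 x features)
#' @slot selectedFeatures indices (rows of a BinnedFeatures) consumed
#' @slot baseline per-selected-feature offset subtracted before decoding
#' @slot binWidth decoding bin width, s
#' @slot decay per-bin velocity decay of the kinematic model
#' @export
setClass("KalmanDecoder",
  slots = c(
    A = "matrix", W = "matrix", H = "matrix", Q = "matrix", K = "matrix",
    selectedFeatures = "integer", baseline = "numeric",
    binWidth = "numeric", decay = "numeric"
  )
)

setValidity("KalmanDecoder", function(object) {
  msg <- character()
  if (length(object@selectedFeatures) < 1L)
    msg <- c(msg, "selectedFeatures must be non-empty")
  if (nrow(object@H) != length(object@selectedFeatures))
    msg <- c(msg, "H must have one row per selected feature")
  ev <- eigen(object@Q, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) msg <- c(msg, "Q must be symmetric positive definite")
  if (!all(is.finite(object@K))) msg <- c(msg, "steady-state gain must be finite")
  if (length(msg)) msg else TRUE
})

#' BiasState: online velocity-bias estimate
#'
#' Tracks the slowly drifting velocity offset B subtracted from decoded
#' velocity. B relaxes toward the observed velocity with a
#' magnitude-weighted rate (time constant tau = 30 s at a 1-ms update
#' step by default) and is only updated while decoded speed exceeds a
#' gate (roughly the 10-20% quantile of typical speeds).
#'
#' @export
setClass("BiasState",
  slots = c(B = "numeric", tau = "numeric", dt = "numeric",
            speedThreshold = "numeric")
)

setValidity("BiasState", function(object) {
  msg <- character()
  if (length(object@B) != 2L || !all(is.finite(object@B)))
    msg <- c(msg, "B must be a finite 2-vector")
  if (object@tau <= 0) msg <- c(msg, "tau must be > 0")
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (length(msg)) msg else TRUE
})

#' ClickHMM: two-state (move/click) hidden Markov classifier
#'
#' PCA front end retaining the top four eigenvalue-ranked components,
#' multivariate-Gaussian emission model per state, a 2x2 transition
#' matrix, and the unsupervised click threshold (93rd quantile of
#' calibration click-state posteriors). A click is generated after two
#' consecutive 15-ms bins above threshold.
#'
#' @export
setClass("ClickHMM",
  slots = c(
    center = "numeric", rotation = "matrix",
    featureIndex = "integer",
    stateMeans = "matrix", stateCovs = "list",
    transition = "matrix",
    clickThreshold = "numeric",
    consecutiveBinsRequired = "integer"
  )
)

setValidity("ClickHMM", function(object) {
  msg <- character()
  if (ncol(object@rotation) != 4L)
    msg <- c(msg, "projection must retain exactly the top 4 PCs")
  if (any(abs(rowSums(object@transition) - 1) > 1e-12))
    msg <- c(msg, "transition rows must sum to 1")
  for (S in object@stateCovs) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) msg <- c(msg, "state covariances must be SPD")
  }
  th <- object@clickThreshold
  if (!is.na(th) && (th <= 0 || th >= 1))
    msg <- c(msg, "clickThreshold must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' TaskLayout: geometry and labels of selectable targets
#'
#' @slot targets data.frame with columns id, label, x0, y0, x1, y1
#'   (axis-aligned rectangles, half-open on their upper edges)
#' @slot bounds workspace bounds c(xmin, ymin, xmax, ymax)
#' @slot layoutKind one of "grid6", "grid9", "grid", "opti2", "qwerty",
#'   "abcdef"
#' @export
setClass("TaskLayout",
  slots = c(targets = "data.frame", bounds = "numeric",
            layoutKind = "character")
)

setValidity("TaskLayout", function(object) {
  tg <- object@targets
  msg <- character()
  need <- c("id", "label", "x0", "y0", "x1", "y1")
  if (!all(need %in% colnames(tg)))
    return("targets must have columns id, label, x0, y0, x1, y1")
  b <- object@bounds
  eps <- 1e-9
  if (any(tg$x0 < b[1] - eps | tg$y0 < b[2] - eps |
          tg$x1 > b[3] + eps | tg$y1 > b[4] + eps))
    msg <- c(msg, "every target must lie within bounds")
  if (nrow(tg) > 1L) {
    for (i in seq_len(nrow(tg) - 1L)) {
      j <- (i + 1L):nrow(tg)
      overlap <- tg$x0[j] < tg$x1[i] - eps & tg$x1[j] > tg$x0[i] + eps &
                 tg$y0[j] < tg$y1[i] - eps & tg$y1[j] > tg$y0[i] + eps
      if (any(overlap)) { msg <- c(msg, "target interiors must be disjoint"); break }
    }
  }
  if (length(msg)) msg else TRUE
})

#' SelectionRule: how targets are selected
#'
#' @slot mode "dwell_reset" (hold timer zeroed on target exit),
#'   "dwell_cumulative" (per-target timers persist across exits), or
#'   "click_or_dwell" (HMM click in addition to reset-dwell)
#' @slot dwellRequired required hold, s (1.0 or 1.5 in shipped profiles)
#' @slot recenter recenter the cursor after every selection
#' @slot recenterLockout selection-disabled window after recentering, s
#' @export
setClass("SelectionRule",
  slots = c(mode = "character", dwellRequired = "numeric",
            recenter = "logical", recenterLockout = "numeric")
)

setValidity("SelectionRule", function(object) {
  msg <- character()
  if (!object@mode %in% c("dwell_reset", "dwell_cumulative", "click_or_dwell"))
    msg <- c(msg, "unknown selection mode")
  if (object@dwellRequired <= 0) msg <- c(msg, "dwellRequired must be > 0")
  if (object@recenterLockout < 0) msg <- c(msg, "recenterLockout must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SimulatedUserPolicy: feedback controller standing in for the user
#'
#' A saturating proportional controller: intended velocity points from
#' the cursor toward the cued target with speed gain * distance (capped),
#' with angular motor noise and a reaction delay; click intent turns on
#' after the cursor has hovered over the cued target for clickLatency.
#'
#' @export
setClass("SimulatedUserPolicy",
  slots = c(reactionDelay = "numeric", gain = "numeric",
            maxSpeed = "numeric", clickLatency = "numeric",
            motorNoiseSd = "numeric", clickEnabled = "logical")
)

setValidity("SimulatedUserPolicy", function(object) {
  msg <- character()
  if (object@gain < 0 || object@maxSpeed <= 0)
    msg <- c(msg, "gain must be >= 0 and maxSpeed > 0")
  if (object@reactionDelay < 0 || object@clickLatency < 0 ||
      object@motorNoiseSd < 0)
    msg <- c(msg, "delays and noise must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SessionConfig: one simulated participant-session recipe
#'
#' Captures the per-participant decoder and protocol configuration: the
#' feature family feeding each decoder, dwell rule, whether bias
#' correction and cursor recentering are active, whether each blockset
#' recalibrates the decoders or only refreshes the bias estimate, the
#' error-attenuation factor used in closed-loop recalibration, and the
#' task list and durations.
#'
#' @export
setClass("SessionConfig",
  slots = c(
    participant       = "SyntheticParticipant",
    policy            = "SimulatedUserPolicy",
    continuousFamily  = "character",
    clickFamily       = "character",   # NA_character_ = no click decoder
    dwellMode         = "character",
    dwellRequired     = "numeric",
    useBias           = "logical",
    useRecenter       = "logical",
    recalibrateEachBlockset = "logical",
    errorAttenuation  = "numeric",
    gridN             = "integer",
    keyboards         = "character",
    sentence          = "character",
    nBlocksets        = "integer",
    blockDuration     = "numeric",
    seed              = "integer"
  )
)

setValidity("SessionConfig", function(object) {
  msg <- character()
  if (!object@dwellRequired %in% c(1.0, 1.5))
    msg <- c(msg, "shipped profiles use a dwell time of 1.0 or 1.5 s")
  if (length(object@recalibrateEachBlockset) != 1L)
    msg <- c(msg, "exactly one of recalibrate vs bias-update-only per blockset")
  if (!object@continuousFamily %in% c("spike", "hfp", "both"))
    msg <- c(msg, "continuousFamily must be spike, hfp or both")
  if (!is.na(object@clickFamily) &&
      !object@clickFamily %in% c("spike", "hfp", "both"))
    msg <- c(msg, "clickFamily must be spike, hfp, both or NA")
  if (object@errorAttenuation < 0 || object@errorAttenuation > 1)
    msg <- c(msg, "errorAttenuation must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
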
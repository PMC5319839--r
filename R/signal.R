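# Broadband signal chain: CAR -> {spike band -> 1-ms threshold
# detection -> 15-ms counts} and {150-450 Hz band power per bin}.

#' Build a signal-chain configuration
#'
#' @param sampleRate samples/s (30000)
#' @param spikeThreshold fixed threshold, uV (negative), or NA to use
#'   \code{rmsMultiplier} x per-channel RMS
#' @param rmsMultiplier e.g. -4.5
#' @param hfBand HF-LFP band, Hz
#' @param binWidth bin width, s
#' @param crossingResolution detector window, s
#' @param iirCutoff,iirOrder,firOrder spike-band high-pass realization
#' @return a \linkS4class{SignalConfig}
#' @export
signalConfig <- function(sampleRate = 30000, spikeThreshold = NA_real_,
                         rmsMultiplier = -4.5, hfBand = c(150, 450),
                         binWidth = 0.015, crossingResolution = 0.001,
                         iirCutoff = 250, iirOrder = 4L, firOrder = 256L) {
  new("SignalConfig", sampleRate = sampleRate,
      spikeThreshold = as.numeric(spikeThreshold),
      rmsMultiplier = rmsMultiplier, hfBand = hfBand, binWidth = binWidth,
      crossingResolution = crossingResolution, iirCutoff = iirCutoff,
      iirOrder = as.integer(iirOrder), firOrder = as.integer(firOrder))
}

#' Common average reference
#'
#' Subtracts the cross-channel mean from every channel at each sample,
#' removing noise common to all recorded channels.
#'
#' @param segment channels x samples voltage matrix
#' @return referenced matrix whose column means are 0
#' @export
commonAverageReference <- function(segment) {
  if (!is.matrix(segment) || nrow(segment) < 2L)
    stop("CAR requires at least 2 channels")
  sweep(segment, 2L, colMeans(segment), "-")
}

#' Spike-band high-pass filter
#'
#' Cascaded causal Butterworth IIR and linear-phase FIR high-pass. The
#' FIR group delay (firOrder/2 samples) is compensated so detected
#' event times line up with the input.
#'
#' @param segment channels x samples matrix (already referenced)
#' @param config a \linkS4class{SignalConfig}
#' @return filtered matrix, same dimensions
#' @export
spikeBandFilter <- function(segment, config = signalConfig()) {
  if (is.vector(segment)) segment <- matrix(segment, 1L)
  nSamp <- ncol(segment)
  if (nSamp <= 2L * config@firOrder)
    stop("segment shorter than filter warm-up")
  ny <- config@sampleRate / 2
  bi <- signal::butter(config@iirOrder, config@iirCutoff / ny, type = "high")
  bf <- signal::fir1(config@firOrder, config@iirCutoff / ny, type = "high")
  half <- config@firOrder / 2
  out <- segment
  for (ch in seq_len(nrow(segment))) {
    x <- signal::filter(bi, segment[ch, ])
    x <- signal::filter(bf, c(as.numeric(x), numeric(half)))
    out[ch, ] <- x[(half + 1L):(half + nSamp)]   # remove FIR group delay
  }
  out
}

#' Per-channel RMS thresholds
#'
#' threshold_ch = multiplier x RMS_ch, the per-array convention for
#' setting spike detection thresholds.
#'
#' @param segment channels x samples matrix (spike-band filtered)
#' @param multiplier negative unitless multiplier (default -4.5)
#' @param fs samples/s, used to enforce the 1-s minimum segment length
#' @return named numeric vector of thresholds (uV); NA with a warning
#'   for zero-variance channels
#' @export
computeRmsThreshold <- function(segment, multiplier = -4.5, fs = 30000) {
  if (is.vector(segment)) segment <- matrix(segment, 1L)
  if (ncol(segment) < fs)
    stop("RMS threshold estimation requires at least 1 s of data")
  rms <- sqrt(rowMeans(segment^2))
  th <- multiplier * rms
  bad <- rms < .Machine$double.eps
  if (any(bad)) {
    warning(sum(bad), " zero-variance channel(s): threshold undefined")
    th[bad] <- NA_real_
  }
  th
}

#' Threshold-crossing presence detector
#'
#' Applies a 1-ms presence detector: each window reports 1 if any
#' sample within it falls below the (negative) threshold, else 0 -- at
#' most one putative spike per window.
#'
#' @param segment channels x samples filtered voltage
#' @param threshold per-channel (or scalar) negative threshold, uV
#' @param fs samples/s
#' @param windowSec detector window, s (default 0.001)
#' @return channels x windows 0/1 matrix
#' @export
detectThresholdCrossings <- function(segment, threshold, fs = 30000,
                                     windowSec = 0.001) {
  if (is.vector(segment)) segment <- matrix(segment, 1L)
  if (any(threshold >= 0, na.rm = TRUE))
    stop("configuration error: spike thresholds must be negative")
  n <- nrow(segment)
  threshold <- rep_len(threshold, n)
  spw <- round(fs * windowSec)
  nWin <- floor(ncol(segment) / spw)
  out <- matrix(0L, n, nWin)
  for (ch in seq_len(n)) {
    if (is.na(threshold[ch])) next
    below <- segment[ch, seq_len(nWin * spw)] < threshold[ch]
    out[ch, ] <- as.integer(colSums(matrix(below, spw, nWin)) > 0L)
  }
  out
}

#' HF-LFP band power per bin
#'
#' Band-passes the referenced signal to \code{config@hfBand} (causal
#' Butterworth) and reports the mean squared value per 15-ms bin.
#'
#' @param segment channels x samples referenced voltage
#' @param config a \linkS4class{SignalConfig}
#' @return channels x bins non-negative power matrix
#' @export
hfLfpPower <- function(segment, config = signalConfig()) {
  if (is.vector(segment)) segment <- matrix(segment, 1L)
  ny <- config@sampleRate / 2
  if (config@hfBand[2] >= ny)
    stop("configuration error: hfBand upper edge must be below Nyquist")
  spb <- round(config@sampleRate * config@binWidth)
  nBins <- floor(ncol(segment) / spb)
  if (nBins < 1L) stop("segment shorter than one bin")
  bp <- signal::butter(2, config@hfBand / ny, type = "pass")
  out <- matrix(0, nrow(segment), nBins)
  for (ch in seq_len(nrow(segment))) {
    x <- as.numeric(signal::filter(bp, segment[ch, ]))
    x2 <- x[seq_len(nBins * spb)]^2
    out[ch, ] <- colMeans(matrix(x2, spb, nBins))
  }
  out
}

#' Extract binned features from broadband voltage
#'
#' Runs the full chain: CAR, spike-band filter, per-channel thresholds
#' (fixed or RMS-derived), 1-ms presence detection summed into 15-ms
#' crossing counts, and HF-LFP band power per bin.
#'
#' @param segment channels x samples raw voltage (uV)
#' @param config a \linkS4class{SignalConfig}
#' @return a \linkS4class{BinnedFeatures}
#' @export
extractFeatures <- function(segment, config = signalConfig()) {
  ref <- commonAverageReference(segment)
  sb <- spikeBandFilter(ref, config)
  th <- if (!is.na(config@spikeThreshold))
    rep(config@spikeThreshold, nrow(segment))
  else computeRmsThreshold(sb, config@rmsMultiplier, config@sampleRate)
  win <- detectThresholdCrossings(sb, th, config@sampleRate,
                                  config@crossingResolution)
  winPerBin <- round(config@binWidth / config@crossingResolution)
  nBins <- floor(ncol(win) / winPerBin)
  counts <- matrix(0L, nrow(segment), nBins)
  for (b in seq_len(nBins)) {
    idx <- ((b - 1L) * winPerBin + 1L):(b * winPerBin)
    counts[, b] <- as.integer(rowSums(win[, idx, drop = FALSE]))
  }
  hp <- hfLfpPower(ref, config)[, seq_len(nBins), drop = FALSE]
  binnedFeatures(counts, hp, binWidth = config@binWidth)
}

#' Estimate per-feature baselines from a rest period
#'
#' Baseline rates are re-estimated de novo prior to each block from a
#' rest period (30 s by default) in which the user simply relaxes; the
#' per-feature means are stored into the stream's baseline field for
#' downstream mean-subtraction.
#'
#' @param features a \linkS4class{BinnedFeatures} recorded at rest
#' @param minDuration minimum rest duration, s; shorter periods proceed
#'   with a warning
#' @return named numeric vector of per-feature baselines
#' @export
estimateBaseline <- function(features, minDuration = 30) {
  bw <- features@metadata$binWidth
  dur <- ncol(features) * bw
  if (dur < minDuration)
    warning(sprintf("rest period (%.1f s) shorter than %.0f s; baseline flagged",
                    dur, minDuration))
  rowMeans(featureMatrix(features))
}
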
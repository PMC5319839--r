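# Synthetic broadband voltage: an optional fixture path used to
# exercise the signal chain (CAR, spike-band filtering, threshold
# detection, HF-LFP power). Not a biophysical simulation.

# Biphasic extracellular spike template at 30 kHz, negative peak = -1.
spikeTemplate <- function() {
  c(0, -0.25, -0.7, -1, -0.8, -0.4, 0.05, 0.3, 0.38, 0.3, 0.2, 0.12,
    0.06, 0.02, 0)
}

#' Synthesize broadband voltage from per-bin spike counts
#'
#' Places spike-shaped transients so that each spike's sub-threshold
#' lobe falls inside a single 1-ms detector window (the presence
#' detector reports at most one event per window, so counts above the
#' number of windows per bin are truncated), then adds white noise and
#' an optional common-mode component shared by all channels.
#'
#' @param counts channels x bins matrix of target spike counts per
#'   15-ms bin
#' @param fs sampling rate; the chain is specified at 30000 samples/s
#' @param binWidth bin width, s
#' @param spikeAmplitude negative peak amplitude, uV
#' @param noiseRms white-noise RMS, uV (0 = noise-free)
#' @param commonModeAmp,commonModeFreq amplitude (uV) and frequency (Hz)
#'   of a sinusoid added identically to every channel
#' @param seed RNG seed for noise and within-bin spike placement
#' @return channels x samples matrix with attribute "spikeWindows", a
#'   list of 1-ms window indices per channel
#' @export
synthesizeBroadband <- function(counts, fs = 30000, binWidth = 0.015,
                                spikeAmplitude = -120, noiseRms = 0,
                                commonModeAmp = 0, commonModeFreq = 60,
                                seed = 1L) {
  if (fs != 30000)
    stop("configuration error: the signal chain is specified at 30000 samples/s")
  set.seed(childSeed(seed, 2L))
  n <- nrow(counts); nBins <- ncol(counts)
  winPerBin <- round(binWidth * 1000)          # 1-ms windows per bin
  sampPerWin <- round(fs / 1000)
  nSamp <- nBins * winPerBin * sampPerWin
  tmpl <- spikeTemplate() * abs(spikeAmplitude)
  seg <- if (noiseRms > 0)
    matrix(rnorm(n * nSamp, 0, noiseRms), n, nSamp) else matrix(0, n, nSamp)
  spikeWindows <- vector("list", n)
  for (ch in seq_len(n)) {
    wins <- integer(0)
    for (b in seq_len(nBins)) {
      k <- min(counts[ch, b], winPerBin)
      if (k < 1) next
      w <- sample.int(winPerBin, k)           # distinct windows in bin
      wins <- c(wins, (b - 1L) * winPerBin + w)
    }
    wins <- sort(wins)
    for (w in wins) {
      s0 <- (w - 1L) * sampPerWin + 3L        # keep lobe inside window
      idx <- s0 + seq_along(tmpl) - 1L
      ok <- idx <= nSamp
      seg[ch, idx[ok]] <- seg[ch, idx[ok]] + tmpl[ok]
    }
    spikeWindows[[ch]] <- wins
  }
  if (commonModeAmp != 0) {
    cm <- commonModeAmp * sin(2 * pi * commonModeFreq *
                              (seq_len(nSamp) - 1L) / fs)
    seg <- sweep(seg, 2L, cm, "+")
  }
  attr(seg, "spikeWindows") <- spikeWindows
  attr(seg, "fs") <- fs
  seg
}

#' Simulate broadband voltage for a synthetic participant
#'
#' Draws per-bin spike counts from the participant's tuning model given
#' an intent stream, then synthesizes voltage with
#' \code{\link{synthesizeBroadband}}.
#'
#' @param p a \linkS4class{SyntheticParticipant}
#' @param intent data.frame with vx, vy, click per 15-ms bin
#' @param fs sampling rate (must be 30000)
#' @param ... passed to \code{\link{synthesizeBroadband}}
#' @param seed RNG seed
#' @return channels x samples voltage matrix (uV)
#' @export
simulateBroadband <- function(p, intent, fs = 30000, seed = NULL, ...) {
  if (fs != 30000)
    stop("configuration error: the signal chain is specified at 30000 samples/s")
  nBins <- nrow(intent)
  if (nBins * 0.015 < 0.1)
    stop("broadband segments must cover at least 100 ms")
  seed <- seed %||% p@seed
  set.seed(childSeed(seed, 3L))
  enc <- encodeBins(p, rbind(intent$vx, intent$vy), intent$click)
  synthesizeBroadband(enc$counts, fs = fs, seed = childSeed(seed, 4L), ...)
}
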
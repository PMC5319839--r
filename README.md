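# bcisim

Closed-loop simulation of a point-and-click intracortical
brain-computer interface (iBCI).

## What this package is for

Point-and-click iBCIs decode movement intent from multielectrode
recordings in motor cortex and turn it into continuous cursor control
plus a discrete "click" for selection. Evaluating such a system — the
signal chain, the decoders, the online nonstationarity corrections, and
the communication tasks used to measure throughput — normally requires
a human participant and recording hardware. `bcisim` re-creates the
entire decoding stack as a tested, seeded simulation so that every
stage can be exercised, measured, and regression-tested on synthetic
neural data:

- **Synthetic participants** (`makeParticipant`): cosine-tuned
  Poisson spiking per channel, a high-frequency LFP (HF-LFP) power
  feature co-modulated with the same drive, an additive click-state
  signature on a channel subset, and a mean-reverting
  (Ornstein–Uhlenbeck) drift on baseline rates — the nonstationarity
  that motivates online bias correction and per-block baseline
  re-estimation.
- **Signal chain** (`extractFeatures` and friends): common average
  referencing, cascaded IIR + linear-phase FIR spike-band high-pass,
  1-ms threshold-crossing presence detection (fixed per-array
  thresholds or −4.5 × RMS), 150–450 Hz band power, 15-ms binning, and
  30-s rest-period baseline estimation.
- **Continuous decoder** (`selectFeatures`, `fitKalman`,
  `decodeStream`, `refitRelabel`, `updateBias`): a velocity Kalman
  filter over the state (v_x, v_y, 1) with features chosen by tuning
  significance, intention-based relabelling for closed-loop
  recalibration (decoded speed kept, direction rotated toward the
  target, zero over the target), 15-ms decoding with 1-ms position
  integration, and an online velocity-bias corrector

      B_x(t) = B_x(t−1) + (V_x − B_x)·|V_x − B_x|·Δt/τ,

  with Δt = 1 ms, τ = 30 s, gated on decoded speed.
- **Click decoder** (`fitClickPca`, `fitHmm`, `hmmFilter`,
  `detectClicks`): a two-state (move/click) hidden Markov model over
  the top four principal components with Gaussian emissions,

      p(s_k, t) = p(s_k | z_t) · Σ_i p(s_k | s_i) · p(s_i, t−1),

  an unsupervised click threshold at the 93rd quantile of calibration
  click-state posteriors, and a click on the second of two consecutive
  above-threshold 15-ms bins.
- **Tasks and protocol** (`makeGridLayout`, `makeKeyboardLayout`,
  `runGridBlock`, `runCopyTypingBlock`, `runSession`): 6×6 / 9×9 grid
  and OPTI-II-style / QWERTY / ABCDEF keyboards, dwell (reset or
  cumulative) and click selection, optional cursor recentering with a
  500-ms lockout, and the blockset protocol (a recalibration or
  bias-update block followed by three randomized two-minute evaluation
  blocks with the copy-typing blocks adjacent).
- **Metrics** (`achievedBitrate`, `correctCharsPerMin`,
  `wordsPerMin`, `clickAccuracySummary`): achieved bitrate

      B = log2(N − 1) · max(S − 2E, 0) / t,

  with N targets, S selections, E errors, and elapsed time t (floored
  at zero; timeouts count toward t but not S or E), and correct
  characters per minute C = max(S − 2D, 0)/t with D delete-key
  selections.

## Worked example

```r
library(bcisim)

p   <- makeParticipant(seed = 2)                       # 96 channels
cfg <- sessionConfig("spike-click", participant = p, seed = 3)
cal <- calibrateSession(cfg)     # open-loop + closed-loop calibration
cal$headingError
#> [1] 9.322767

lay  <- makeGridLayout(6)
rule <- selectionRule("click_or_dwell", dwellRequired = 1.0)
ctrl <- makeNeuralController(p, cal$decoder, cal$hmm, cfg@policy, lay,
                             bias = cal$bias, baseline = cal$baseline,
                             driftInit = cal$drift)
blk <- runGridBlock(lay, rule, ctrl, duration = 120, seed = 9)
blk$result
#>   task  N  S E D   t  bitrate ccpm
#> 1 grid 36 96 0 0 120 4.103426   48
```

The calibrated simulated participant completed 96 correct selections
(no errors) in the two-minute 6×6 grid block, an achieved bitrate of
`log2(35)·96/120 ≈ 4.1` bits/s. A full session (`runSession(cfg)`)
adds the blockset structure and the two copy-typing blocks and returns
per-block results plus mean ± s.d. summaries per task.

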
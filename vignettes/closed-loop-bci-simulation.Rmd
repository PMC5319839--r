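---
title: "Simulating a point-and-click intracortical BCI in closed loop"
author: "bcisim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a point-and-click intracortical BCI in closed loop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcisim)
```

# The system being simulated

A point-and-click intracortical BCI translates multielectrode
recordings from motor cortex into two control signals: a continuous
2-D cursor velocity, decoded by a Kalman filter over binned neural
features, and a discrete selection ("click"), decoded by a two-state
hidden Markov model. Around those decoders sits a measurement
protocol: selectable workspaces (grids and keyboards), dwell- or
click-based selection, and throughput metrics (achieved bitrate,
correct characters per minute). `bcisim` implements the whole loop
against a generative model of a participant, so that each stage has a
ground truth to be tested against.

This vignette records the model assumptions, the tunable parameters
and their defaults, the numerical choices, and what the synthetic data
can and cannot tell you about real recordings.

# The synthetic participant

`makeParticipant()` draws a tuning map over `nChannels` channels:

* **Cosine tuning on counts.** The expected threshold-crossing count
  in a 15-ms bin is `baseline + drift + depth·(cos(pref)·vx +
  sin(pref)·vy) + clickShift·[click]`, rectified at zero, with Poisson
  noise (a Gaussian variant is available for idealized streams). A
  log-free linear cosine model is the simplest encoder consistent with
  the decoders' linear-Gaussian assumptions; real neurons are not this
  clean, and no claim is made that they are. Counts saturate at 15 per
  bin because the downstream 1-ms presence detector cannot report more
  than one event per window.
* **HF-LFP power feature.** The 150–450 Hz band-power feature is
  generated directly at the binned level as `lfpGain · drive` plus
  noise, rectified at zero — it is deliberately co-modulated with the
  spiking drive, mirroring the empirical observation that high-
  frequency LFP power tracks multiunit activity. Raw broadband
  synthesis (`simulateBroadband`) exists only as a fixture path for
  testing the signal chain.
* **Click signature.** A random ~30% subset of channels gains an
  additive mean shift (magnitude 2 counts/bin, random sign) while the
  user intends a click. This gives the HMM's Gaussian emission model a
  learnable, overlapping-but-separable state.
* **Baseline drift.** Per-channel baselines follow a discrete
  Ornstein–Uhlenbeck process (`driftSigma`, `driftTheta` per bin).
  Mean reversion keeps excursions bounded while still producing the
  slow baseline drift that motivates per-block baseline re-estimation
  and the online bias corrector. No quantitative drift magnitude is
  prescribed by the source protocol, so the defaults
  (`driftSigma = 0`, i.e. stationary unless asked for) are exposed in
  the generator configuration and chosen per experiment; tests that
  exercise drift use `driftSigma ≈ 0.01–0.08` counts/bin, which moves
  baselines by a noticeable fraction of a count over minutes.
* **Default rates.** Baselines are drawn uniformly on [2, 8] counts
  per 15-ms bin and the default modulation depth is 2 counts/bin per
  unit speed — multiunit-scale threshold-crossing rates with strong
  but not noiseless tuning; feature selection and Kalman fitting are
  tested down to depth 0.5.

Everything is seeded: identical parameters and seed give bit-identical
streams, which the test suite relies on.

# Signal chain

`extractFeatures()` runs: common average reference (the cross-channel
mean subtracted at every sample), a spike-band high-pass, a 1-ms
threshold detector, 15-ms binning, and band power.

Numerical choices worth recording:

* **Filter realization.** The spike-band high-pass is a causal
  4th-order Butterworth at 250 Hz followed by a 256-tap linear-phase
  FIR high-pass at the same cutoff; the FIR group delay (128 samples)
  is compensated so detected event times line up with the input. The
  original real-time chain is only described as "cascaded IIR and FIR
  high-pass" without orders or cutoffs, so these are declared package
  choices, configurable in `signalConfig()`, not inferences of the
  original values.
* **Presence semantics.** A 1-ms window reports at most one event
  (any sample below threshold), so bin counts are bounded by 15; the
  sum of 1-ms detections over a bin equals the bin's count exactly
  (tested).
* **Thresholds.** Either fixed per-array values (e.g. −50 µV) or
  −4.5 × per-channel RMS. Zero-variance channels get `NA` thresholds
  and a warning rather than a silent zero.
* **HF-LFP path.** Band power is computed on the CAR-referenced (not
  spike-band-filtered) signal with a 2nd-order Butterworth band-pass,
  as mean squared value per bin.
* **Bin alignment.** Bins are half-open `[t, t + 15 ms)`, aligned to
  stream start, making conservation accounting unambiguous.
* **Baselines.** `estimateBaseline()` averages a rest period (30 s by
  default); shorter periods proceed with a warning. Per-block
  re-estimation is what keeps the Kalman observation model honest
  under drift.

# Continuous decoder

The Kalman filter state is `(vx, vy, 1)`. Position is deliberately not
part of the observation update — decoded velocity is integrated into
position at 1 ms (15 integrations per 15-ms decode), which is the only
reading consistent with a velocity filter driving a cursor. The
kinematic model is an AR(1) velocity decay, default 0.96 per bin
(configurable; a free parameter of this implementation). Process noise
comes from the intent-velocity innovations, the observation model from
least squares of baseline-subtracted features on `(vx, vy, 1)`, and
observation noise from the residual covariance (with a 1e-6 diagonal
ridge). Decoding uses the converged steady-state gain, obtained by
Riccati iteration at fit time — the standard online form.

**Feature selection** ranks features by tuning significance (F-test
p-value of the regression of each feature on velocity), with a
Bonferroni-corrected eligibility threshold so untuned channels cannot
enter by multiplicity, then adds features in significance order and
keeps the smallest set whose cross-validated decoding R² is within
1e-3 of the maximum. The tolerance is a tie-break definition: it makes
"maximizing accuracy while minimizing features" concrete and
deterministic.

**Recalibration** (`refitRelabel`) keeps each bin's decoded speed and
rotates its direction to point from cursor to target; bins with the
cursor over the target get zero intent — the over-target rule wins
even when the cursor sits exactly on the target center. Closed-loop
recalibration blocks can apply **error attenuation**: the velocity
component perpendicular to the cursor→target direction is scaled by a
factor γ (default 0.5) so a shaky initial decoder can still reach all
targets. The exact attenuation used clinically is not printed
anywhere; γ is a free assistive parameter here.

**Bias correction** implements the magnitude-weighted relaxation
`B ← B + (V − B)·|V − B|·Δt/τ` per axis at Δt = 1 ms on the most
recent 15-ms velocity (held between decodes), τ = 30 s, updated only
while decoded speed exceeds a gate set at the 15% quantile of speeds
from the preceding calibration block (the protocol says "roughly the
10–20% quantile"; 15% is the midpoint). Whether the original gate used
instantaneous or smoothed speed is unstated; this implementation uses
the instantaneous 15-ms decoded speed, exposed via the `BiasState`
configuration. `V = B` is a fixed point; convergence to a constant
injected bias follows the scalar ODE `db/dt = (V − b)²/τ` and reaches
within 0.5 units/s of a 5 units/s step in 60 s (tested against the
closed form).

# Click decoder

Features (one family per profile: HF-LFP only, or spike only — a
configuration switch, both paths tested) are centered and projected
onto exactly the top four eigenvalue-ranked principal components, with
a deterministic sign convention (largest-magnitude loading positive).
Emissions are per-state multivariate Gaussians fit from labelled
calibration bins; the transition matrix comes from label bigram
frequencies with a +1 pseudocount (supervised, rather than
Baum–Welch: calibration blocks are labelled, and the supervised fit is
deterministic). The forward recursion is computed with log-domain
emission likelihoods and per-bin renormalization, and matches an
independent batch forward algorithm to 1e-10.

The click threshold is unsupervised: the 93rd quantile (linear
interpolation between order statistics — the quantile definition must
be pinned for reproducibility) of the per-bin click-state posterior
over the retraining block, so 7% of calibration bins exceed it by
construction. Both calibration and runtime compare the *normalized*
posterior to the threshold — using the same scale on both sides is
what makes the quantile meaningful. A click fires on the second of two
consecutive above-threshold bins, and the consecutive counter resets
after each click, so a sustained high posterior cannot machine-gun
clicks: a fresh pair of bins is required. Re-arm behaviour after a
click is not specified by the two-consecutive-bins phrase alone; the
reset is this package's choice and is tested explicitly
(`[hi]×6 → clicks at bins 2, 4, 6`).

# Tasks, selection and protocol

Grids tile the workspace into n×n equal half-open cells (6×6 and 9×9
standard, other sizes flagged); every interior point maps to exactly
one cell. Keyboards are data files (`inst/extdata/layout_*.csv`):
QWERTY and ABCDEF share identical key geometry with labels permuted
alphabetically; the OPTI-II-style layout is a *reconstruction* of the
published optimized arrangement (high-frequency letters clustered
around multiple space keys) — the original key coordinates are not
printed in the protocol this package follows, so the file documents a
layout with the property that motivates it: lower mean English-digraph
travel than QWERTY (tested against a packaged digraph table).

Selection: reset dwell (timer zeroed on exit), cumulative dwell
(per-target timers persist across exits; all timers zeroed after any
selection), or click-or-dwell. A selection fires on the tick where the
accumulated hold *exceeds* the requirement, counted in 15-ms ticks —
so a 1.0-s dwell needs 67 ticks and a 1.5-s dwell 101; defining the
comparison this way resolves the boundary case of an exact multiple
deterministically. Cursor recentering (optional, per profile) teleports
the cursor to the workspace center after *every* selection, correct or
not, and disables selection for 500 ms — implemented as 33 full locked
bins, so the 34th bin may select.

Grid blocks cue a uniformly random target per trial for a fixed 120 s;
timed-out trials (default limit 10 s, a package choice — the protocol
references timeouts without printing the limit) log a missing
selection, count toward elapsed time, and never toward S or E. Whether
a timed-out trial re-prompts the same target is also unstated; the
default cues a new one (configurable). Copy-typing blocks cue the next
needed character given the committed (net-of-backspace) transcript,
cue backspace after an incorrect selection, and end at sentence
completion or the 120-s cap. The simulated typist's
target-the-next-character policy mirrors the delete accounting of the
ccpm metric; human strategy was free-form. The shipped default
sentence is the standard pangram; sentence lists are configurable, and
each blockset uses the same sentence for both keyboard blocks.
Blockset order is randomized over exactly the four permutations that
keep the two copy-typing blocks adjacent.

# The simulated user

`userPolicy()` is a saturating proportional feedback controller with a
reaction delay: intent points from cursor to cued target at speed
`gain × distance` (default gain 4 /s), capped at `maxSpeed` (default
1.2 workspace units/s), with angular motor noise (s.d. 0.15 rad), a
200-ms reaction delay to target changes, and click intent after 300 ms
of hovering over the cued target. It is the minimal policy that closes
the loop; none of its parameters describe any human, and all live in
the session configuration.

# Sessions and profiles

`sessionConfig()` ships three profiles mirroring the three decoder/
protocol roles of the study design: hybrid features with a recalibrated
HF-LFP click HMM and 1-s reset dwell; spike-only features with a click
HMM, bias estimation, and bias-update-only blocksets; and a no-click
profile with 1.5-s cumulative dwell, bias estimation, recentering, and
bias-update-only blocksets. `calibrateSession()` runs the 30-s rest,
an open-loop center-out-and-back block (~100 s at the default six
passes over eight targets), decoder fitting, a closed-loop
recalibration block (90 s) with error attenuation where configured,
intention-based refitting, and click-threshold calibration. A
controllability gate — median closed-loop heading error below 60° —
stands in for the qualitative "controllable cursor" go/no-go of the
original protocol; 60° is a declared proxy, not a quoted rule.
`runSession()` then executes the blockset loop, re-estimating
baselines from a fresh 30-s rest before each blockset and either
recalibrating decoders or running a bias-update acquisition block.

Problem sizes in the shipped tests are chosen to keep the full suite
in the minutes range on a single CPU: evaluation blocks of 45–120 s,
calibration streams of 2,000–11,000 bins, ten seeds per condition in
the SNR-monotonicity check. All are ordinary function arguments and
scale up trivially.

# What passing tests do and do not show

The synthetic generator matches the decoders' model class closely (by
design), so end-to-end performance here is an upper bound on what the
same pipeline would do on real recordings: no spike-sorting ambiguity,
no artifacts, no non-cosine tuning, no behavioural nonstationarity
beyond the OU drift, no display latency (the 120-Hz frame path of the
real system is deliberately not simulated — the loop runs at the exact
1-ms/15-ms cadence). What the suite does establish: each stage
implements its stated contract (verified against independent oracles
and closed forms), the closed loop is stable and seeded-reproducible,
performance responds monotonically to SNR, the bias corrector earns
its keep under injected bias, and the evaluation metrics reproduce
their defining arithmetic exactly.

# Known limitations

* No biophysical realism: no waveforms, array geometry, or LFP
  spectra; the broadband synthesizer exists to exercise the signal
  chain, not to model tissue.
* The simulated user is a proportional controller; human learning,
  fatigue, and strategy are out of scope.
* Adaptive/self-calibrating decoders and multi-class direct-selection
  decoders are out of scope.
* The OPTI-II key coordinates are a documented reconstruction, not a
  verbatim copy of the published figure.
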
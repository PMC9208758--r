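---
title: "Models and methods behind mufeedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mufeedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mufeedback)
```

# The problem

In motor-unit (MU) biofeedback experiments, two motor units of one muscle are
decomposed from surface EMG in real time and their discharge rates drive a
cursor in a 2D plane. Targets along the axes and the diagonal ask the subject
to activate one unit without the other, or both together — a task whose
difficulty is governed by the common synaptic drive to the motoneuron pool
and by recruitment/de-recruitment hysteresis. `mufeedback` re-implements the
computational machinery of such an experiment — the task engine, its metrics,
threshold estimation and decomposition validation — and couples it to a
synthetic motoneuron pool so every stage can be exercised and tested without
human data.

# The motoneuron-pool model

Each unit is parameterised by a recruitment threshold `theta_on` (%MVC), a
de-recruitment threshold `theta_off` (%MVC), a rate at recruitment `r_min`
(pps), a rate gain (pps per %MVC), a saturation rate `r_sat` (pps), and an
inter-spike-interval coefficient of variation `isi_cov`. While active, the
instantaneous rate at drive level $d$ is

$$ r(d) = \min\{r_{sat},\; \max\{r_{min},\; r_{min} + g\,(d - \theta_{on})\}\}. $$

This is the minimal model that reproduces orderly recruitment (Henneman's
size principle: thresholds sorted ascending, common drive), rate modulation
with force, and rate saturation. Spikes are drawn as a renewal process: the
mean interval is $1/r$ at the current drive, perturbed by a Gaussian factor
$\max(0.2,\, 1 + c_v z)$ — the truncation at 20% of the mean keeps intervals
positive and bounds the instantaneous rate without changing the mean
materially at the CoV values used (≤ 0.3).

**Hysteresis.** De-recruitment thresholds are drawn once per unit as
`theta_off = theta_on + N(-1.11, 2.44²)` %MVC, floored at 0.01 %MVC. The
flooring is a clip, not a redraw: clipped values remain below `theta_on`, so
the fraction of units with reversed hysteresis stays exactly
$\Phi(1.11/2.44) \approx 0.675$, in line with the roughly two-thirds
prevalence the defaults emulate. The clip does bias the *mean* offset towards
zero for low-threshold units (a draw of −4 %MVC cannot be realised below a
1 %MVC threshold); the realised mean offset in a default pool is therefore
closer to −0.9 than to −1.11 %MVC. This static per-unit offset deliberately
abstracts the biophysics (persistent inward currents, neuromodulation) into
a single reversal-capable number; there is no history-dependent excitability.

**Activation state machine.** A unit recruits when the drive reaches
`theta_on`. It de-recruits when the drive is below `theta_off` *and* below
its running maximum since recruitment, and once de-recruited it re-arms only
after the drive falls below `theta_on`. For `theta_off <= theta_on` — the
reversed-hysteresis case the task exploits — this is exactly the plain
two-threshold machine. The two refinements only matter when
`theta_off > theta_on`: without them a unit would either de-recruit the
instant it was recruited (the drive having not yet risen past `theta_off`)
or chatter on and off inside the band `[theta_on, theta_off)` on a declining
drive. A consequence worth stating: the control-theoretic impossibility
property — "whenever the higher-threshold unit fires, the lower-threshold
one does too, provided the lower unit's de-recruitment threshold is not
above the higher unit's" — is guaranteed by the machine whenever the lower
unit's `theta_off` does not exceed its own `theta_on`; with positive
hysteresis on the lower unit *and* a drive that dips between the two
recruitment thresholds before rising again, the re-arm rule can leave the
lower unit silent where the literal two-threshold reading would have
(chaotically) re-recruited it. The property tests and acceptance suite
therefore probe the regime the constraint is about: lower-unit
`theta_off <= theta_on`.

**Force and EMG.** The measured force is the drive plus zero-mean noise
low-pass filtered below 5 Hz and rescaled to a target SD — no twitch
convolution, because every analysis reads force only through 100 ms window
averages, which a twitch model would not change materially. Global EMG
channels are zero-mean white carriers amplitude-modulated by the summed
active-pool discharge rate plus sensor noise: enough structure for the
envelope analyses (rectify, zero-phase 4th-order Butterworth at 10 Hz) to
behave monotonically in pool activity, and deliberately *not* a
mixing-matrix simulation capable of testing blind-source separation, which
is out of scope.

# The task engine

The engine consumes acquisition buffers of 256 samples at 2048 Hz (125 ms).
Per-buffer rates (spike count / 125 ms; boundary spikes belong to the later
buffer) are averaged over the preceding 8 buffers (1 s), normalised by the
unit's reference rate at 10 %MVC, multiplied by a per-unit gain, and
smoothed with a trailing 6-buffer (750 ms) moving average. Both windows
include the current buffer; that choice makes the stated totals (1 s,
750 ms) exact and gives the cascade an impulse-response support of exactly
$8 + 6 - 1 = 13$ buffers (1625 ms), verified empirically in the tests.

**Warm-up.** At stream start the windows are truncated (mean over the
buffers available), so a constant input maps to a constant cursor rather
than an artificial dip. The 13-buffer step response consequently applies to
a step *after* silence, which is how trials actually begin: the rest rule
requires both units silent for 2 s before target onset. The idealised
trajectories used for the performance bound are simulated with zero-padded
(from-rest) windows for the same reason.

**Geometry.** Targets TI = (1, 0), TII = (1, 1), TIII = (0, 1), radius 0.1
in normalised-rate units. Each target's angle region is an unbounded wedge
with apex at the origin and half-angle $\arcsin(r/\lVert c\rVert)$ (sides
tangent to the target's circumcircle), cropped by the origin-centred circle
of radius 0.4; the far side of the displayed triangle is not modelled, as
nothing in the analyses depends on it. All regions are closed (boundary
counts inside); the target disc is tested first and counts as inside the
wedge for angle-hit bookkeeping; the origin belongs to neither region. The
normalised space is unbounded upward — no clamping.

**Trial rules.** A target hit is granted at the 7th consecutive in-target
buffer (875 ms — one buffer longer than the moving average) and ends the
trial; an angle hit at the 7th consecutive in-wedge buffer, with the trial
continuing; a trial times out after 20 s (160 buffers). A single trial can
contain both hit types. Hit detection is checked against an exhaustive
7-buffer window scan in the property tests.

# Trial metrics

The per-trial performance is
$\sum_{n=1}^{N} (d(n)/d_{max})^2 + (\varphi(n)/\varphi_{max})^2$ with
$d_{max} = \lVert TI - TIII \rVert$ and $\varphi_{max} = 90°$ for TI/TIII,
$d_{max} = \lVert TII \rVert$ and $\varphi_{max} = 45°$ for TII, and
$\varphi(\mathbf{0}) := \varphi_{max}$. The typeset source formula is
ambiguous about a per-buffer square root; the sum-of-squares reading is the
default and a root-sum-square variant is available (`variant = "rss"`).
$\varphi$ is the absolute angle — no sign convention is imposed. Raw values
are normalised to $[0,1]$ between the origin-hold worst case
($160\,[(\lVert c\rVert/d_{max})^2 + 1]$: 240.0 for TI/TIII, 320.0 for TII)
and the performance of an idealised from-rest trajectory fed with constant
rates matching the target's required activation; values are clipped, since
a real trajectory that overshoots away from the target can transiently
exceed the origin-hold bound.

Nearest misses and unintended hits reuse the 875 ms hold window: the former
is the 7-buffer window mean closest to the target centre (earliest window on
ties), the latter counts maximal in-region excursions of at least 7 buffers,
re-entries counted separately (so per-trial unintended rates can exceed
100%). Direct movements are classified by strict silence — zero discharges
of the other unit between target onset and the qualifying hit — while the
three-stage characteristic forces use the softer "active means trailing 1 s
rate above 5 pps" criterion; both thresholds are arguments.

Under the minimal rate model, a simulated three-stage TIII hit typically
occurs while the drive still sits at the stage-2 level: with the rate floored
at `r_min` below threshold, stages 2 and 3 are indistinguishable in MU2's
rate, so the cursor reaches TIII as soon as MU1's smoothed rate has decayed.
The stage-force analysis therefore recovers `f1` near the stage-1 level and
`f2`/`f3` near the stage-2 level; the strictly three-tiered force profile of
human subjects would additionally require rate modulation below the
recruitment threshold, which the model deliberately omits.

# Threshold estimation

Onset is operationalised as the first spike that begins a run of at least
two spikes with ISI ≤ 200 ms — an instantaneous-rate reading of "discharging
at 5 pps or above" that is robust to isolated spurious discharges. Offset is
the last spike before at least 1.5 s of silence, taking the final activation
episode when several exist; the gap to the end of the analysis horizon
counts as silence. Forces at both events are closed, centred 100 ms window
means. Ranking is by ascending recruitment force with ties broken by earlier
onset, then unit id. On noiseless 1 %MVC/s ramps the estimators recover the
generator's thresholds to within 0.2 %MVC (the residual error is one
inter-spike interval of drive movement, at most `slope / r_min`); this
bound is enforced for 200 random units in the acceptance suite. Pair
selection splits the ranked pool into first/last-recruited halves (odd unit
to the first half) and picks adjacent-rank pairs with probability weighted
towards the smallest recruitment-force difference, then forms condition III
from the low pair's MU1 and the high pair's MU2.

# Two-source validation

Discharge matching is greedy and chronological with a 1 ms tolerance,
one-to-one, preferring the closer of the two next candidates. On trains
whose ISIs exceed twice the tolerance — true of any physiological discharge
pattern — each spike of one train has at most one candidate in the other,
so the greedy count equals the optimal bipartite matching count; the
property suite verifies this against a dynamic-programming oracle on 200
random corrupted trains. The rate of agreement uses the standard two-source
denominator `common + A-only + B-only`; the source text prints only
"percentage of discharges identified by both methods", so the convention is
isolated in `rate_of_agreement()` should a different denominator ever be
needed. Under the corruption model (independent deletions `p_miss`,
Gaussian jitter, uniform insertions at rate `p_extra`), the expected RoA is
$(1-p_{miss})/(1+p_{extra})$ when the jitter SD is well below the
tolerance; the acceptance suite checks the measured value within one
percentage point at 3000 discharges. Spike-triggered averages default to a
±25 ms window (not specified in the source; configurable), skip and count
edge-clipped triggers, and cross-source unit pairing correlates
channel-concatenated, mean-removed waveforms with a 0.9 acceptance
threshold resolved greedily by descending correlation.

# Numerical choices and degenerate inputs

* Window and region comparisons are closed, with 1e-9–1e-12 guards against
  floating-point boundary misses; buffer assignment uses
  `floor(t / 0.125 + 1e-9)`, sending boundary spikes to the later buffer.
* Fewer than two spikes → onset `NA` with a warning; a silent plateau →
  reference rate 0 with a warning (the unit is unusable as a feedback
  source); constant performances → learning correlation 0 with a warning;
  all-equal paired samples → Wilcoxon p = 1 by convention.
* All randomness flows through per-call seeds that save and restore the
  caller's RNG state, so every generator, session and corruption is
  reproducible and composable.
* Zero-phase (forward-backward) Butterworth filtering is used offline so
  100 ms window reads are not displaced by group delay; a causal online
  implementation would shift envelopes by the filter delay.

# Problem sizes

The test and acceptance suites run entirely on synthetic data generated at
test time: pools of 2–11 units (10 000 for distributional checks), ramps of
30–33 s sampled at 64–256 Hz for simulation (the engine's buffer clock is
always 125 ms), 200 random closed-loop TIII trials for the impossibility
suite, 50 four-unit pools for threshold recovery, 3000-discharge trains for
the rate-of-agreement check, and 200-case property sweeps for each
brute-force oracle. These sizes were chosen as the smallest at which the
Monte-Carlo bounds in use (3σ) are comfortably discriminating.

# Limitations

* No biophysical membrane or PIC model: hysteresis is a static draw, and
  the activity-dependence of real de-recruitment is not represented.
* The EMG model supports envelope analyses only; it cannot exercise a
  decomposition algorithm, which is upstream of this package.
* The generator emulates summary statistics of the emulated preparation
  (pool size, threshold range, hysteresis spread, ramp protocol); passing
  tests demonstrate the correctness of the pipeline's rules and estimators
  under those conditions, not behavioural claims about human subjects —
  learning effects in particular arise from humans and are reported here
  only as descriptive statistics of whatever sessions are fed in.
* The ramp-failure criterion ("subject failed to follow the ramp") is a
  configurable RMS bound in the session tools; the emulated protocol gives
  no operational definition.
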
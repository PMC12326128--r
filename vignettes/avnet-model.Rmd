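---
title: "The avnet model: architecture, calibration and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The avnet model: architecture, calibration and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Audiovisual perception depends jointly on where and when the auditory and
visual components of an event occur. Two well-documented behavioral
signatures probe the two axes: the *ventriloquist effect* (a sound is
mislocalized toward a concurrent, spatially discrepant visual stimulus) and
the *modality switch effect* (responses to a stimulus are slower when the
previous stimulus was of the other modality, for interstimulus intervals of
the order of a second). A third signature, the *redundant signals effect*,
ties them together: bimodal stimuli are detected faster than either
unisensory component, beyond what an independent race between the two
channels (Raab's model) predicts.

`avnet` implements a biologically inspired firing-rate network in which all
three phenomena emerge from one synaptic architecture, and exposes the
experiment battery needed to measure them: reaction-time (RT) tasks with
repeat/switch sequences, spatial localization with disparate audiovisual
pairs, race-model analytics, connection-strength sensitivity sweeps, and
prediction grids that cross interstimulus interval (ISI) with spatial
disparity.

## Architecture

Every area is a topographic sheet of `n_units = 180` units at 1° spacing
covering azimuths −90°…+89° (0° at unit 91). Each unit has first-order
membrane dynamics and a logistic input–output function,

$$\tau \,\dot y_j = -y_j + F(u_j), \qquad
  F(u) = \frac{1}{1 + e^{-s (u - \theta)}},$$

with saturation normalized to 1, central abscissa $\theta = 25$, slope
$s = 0.3$ and $\tau = 3$ ms everywhere except the premotor readout (below).
The four layers are:

1. **Input areas A and V.** Each unit receives (i) the external stimulus — a
   spatial Gaussian of spread $\sigma_a$ or $\sigma_v$ centred at the
   stimulus azimuth, gated on for the stimulus duration and low-pass
   filtered with $\tau_a = 15$ ms (audition) or $\tau_v = 25$ ms (vision),
   so that auditory responses lead visual ones; (ii) a Mexican-hat lateral
   drive (excitation SD 3°, strength 5; inhibition SD 120°, strength 4)
   which carves a winner bubble out of the broad input; (iii) an excitatory
   cross-modal drive from the other input area, Gaussian (SDs 7°/5°),
   delayed by 16 ms and filtered with $\tau_c = 3$ ms; and (iv) a slow
   inhibitory drive from the opposite modality's interneurons (Gaussian, SD
   15°, time constant $\tau_{in} = 180$ ms).
2. **Competitive interneurons Ia and Iv.** Driven by their own input area
   (Gaussian, SD 5°) and coupled one-to-one by reciprocal inhibition of
   strength 10 — a winner-takes-all pair. The winner projects the slow
   feedback inhibition onto the *opposite* input area; this carried-over
   inhibition is the switch cost mechanism.
3. **Multisensory area M.** Receives delayed (50 ms), filtered (15 ms)
   Gaussian feedforward drive from both input areas plus its own weak
   Mexican hat.
4. **Premotor readout PM.** One-to-one delayed (50 ms) drive from M; a
   simulated RT is the first time any premotor unit crosses 30% of
   saturation. Responses faster than 100 ms are flagged anticipatory.

The visual pathway is structurally stronger: the three weights carrying
visual information are the auditory ones divided by the asymmetry ratio
`av_ratio` (default 0.4 < 1), i.e. `wmv0 = wma0/av_ratio`,
`wav0 = wva0/av_ratio`, `wiv0 = wia0/av_ratio`. This, together with
$\sigma_v \ll \sigma_a$, is what makes vision capture audition and not the
reverse.

Perceived positions are read out as the activity barycentre of an input
area, evaluated at the offset of the (auditory) stimulus — by then the
cross-modal interaction has shaped the bubble, and the readout instant does
not depend on downstream stages.

## Slow memory states: the reconstruction choices

Two mechanisms in this model family operate on time scales much longer than
any single time constant above, and their exact equations live in material
that is not part of this implementation's sources. `avnet` realizes both
with asymmetric first-order states (fast rise, slow decay), which we
consider the simplest dynamics consistent with the described behavior:

* **WTA latch** (`tau_iex = 15` ms rise, `tau_iex_decay = 1900` ms decay on
  the interneuron excitatory drive): after a stimulus ends, the winning
  interneuron population keeps firing until its decaying drive falls below
  the sigmoid threshold, roughly 1–1.5 s later. The 180-ms feedback
  inhibition therefore stays charged through ISI ≈ 1000 ms and then
  releases, which is exactly the observed ISI profile of the switch cost:
  maximal near 1 s, essentially gone by 3 s.
* **Cross-modal trace** (`tau_c = 3` ms rise, `tau_c_decay = 100` ms
  decay): the excitatory cross-modal drive outlives its source bubble by
  ~100 ms. This yields the temporal window of integration: a trailing
  stimulus that is spatially congruent with the leading one is detected
  faster for onset asynchronies up to ~200 ms, and the residual visual
  attraction makes the auditory bias decay smoothly as the audiovisual
  asynchrony grows from 200 to 800 ms.

Both constants are calibration values of this package; if the reference
equations become available these states are the first thing to revisit.

## Parameters: fixed, derived and calibrated

Fixed by the model family (connection effectiveness/SD table): all `w*0`,
`w*_sd`, `l*` Mexican-hat values, `wta0 = 10`, `wpmm0 = 1`, the delays
(16/50/50 ms) and time constants ($\tau$, $\tau_a$, $\tau_v$, $\tau_{in}$,
$\tau_c$, feedforward 15 ms).

Calibrated here (each `av_params` field, with its role):

* `sigma_v = 4`, `sigma_a = 30` (degrees): visual input is sharp, auditory
  broad. The auditory spread controls how strongly the external input
  anchors the auditory bubble against visual attraction; 30° places the
  mean auditory bias near 70% at 5° disparity and near 35% at 20°.
* `i0_a = 60`, `i0_v = 50`: nominal input effectiveness, high in the
  sigmoid's saturated region so that the input areas reach 90% of their
  steady response within ~20 ms (A) and ~30 ms (V).
* `jitter_frac = 0.1`: per-stimulus uniform effectiveness jitter
  (±10% of nominal), the single noise source emulating within-subject
  variability. It is chosen so that even the weakest switch trials under
  full cross-sensory inhibition still produce a response.
* Per-component gains `g_*` (the $G_i^r$ family): scale each input
  component of each area. `g_m_a/g_m_v` put unisensory multisensory-area
  drive slightly below saturation (so bimodal input measurably speeds the
  response), `g_pm` gives the premotor stage enough margin that weakened
  responses are slowed rather than lost, `g_inh_a/g_inh_v` set the switch
  cost (≈6–14 ms at 1 s ISI), and `g_cross_a/g_cross_v` set the strength of
  the spatial capture and the cross-modal influence latency (< 40 ms).
* `tau_pm = 60` ms: the premotor stage integrates its drive slowly,
  standing in for the neural accumulation to a motor command; it sets the
  overall RT scale (~150–190 ms from stimulus onset, of which 100 ms are
  transmission delays) and converts graded multisensory-area differences
  into RT differences.

`av_params()` validates every record: positivity of time constants and
spreads, the stability guard on the integration step, and the three
pathway-asymmetry relations — a hand-built record that violates a relation
is rejected with the offending field named, never silently corrected.

## What the stimulus generator emulates — and what it does not

`make_rt_sequence()` reproduces the randomized A/V/AV detection protocol:
equiprobable modalities (the empirical mix is not documented; equiprobable
is the neutral choice), onset-to-onset ISIs uniform on 1000–3000 ms,
central fixation, 60-ms stimuli (brief flashes/beeps typical of speeded
detection; the reference duration is not documented), and independent
effectiveness jitter per stimulus component. `make_av_pair()` builds the
localization trials: V fixed at 0°, A displaced by ±5°…±20°, synchronous or
with the visual stimulus leading (the leading modality for the asynchronous
prediction grids is not documented; visual-leading matches the
ventriloquism-with-asynchrony literature and is the default, with
`order = "a_leads"` available).

The generator does *not* emulate: eccentricity-dependent reliability,
auditory spectral content, elevation, sensory noise beyond the scalar
effectiveness jitter, or inter-subject variability. Passing tests therefore
show that the *mechanisms* produce the qualitative and quantitative target
patterns under idealized stimulation — not that the model fits any
individual observer's data.

## Numerical choices

* **Integrator**: explicit Euler on all states, the standard choice for
  this model family; transport delays are exact ring-buffer lookups of
  presynaptic outputs. The integration step `dt_ms = 0.5` (guard:
  `dt <= tau_unit/3`) keeps the full experiment battery tractable; the
  test suite verifies that an isolated unit matches the closed-form
  exponential step response within 1% at `dt = 0.1`, that the compiled
  integrator tracks an independent adaptive ODE solver (`deSolve::lsoda`)
  on the coupled system, and that halving the step changes reaction times
  by less than 1 ms.
* **RT detection**: threshold crossings are linearly interpolated between
  samples, so RT resolution is finer than the integration step. When the
  premotor trace is still above threshold at a probe onset (overlapping
  responses at short ISIs), the detector waits for it to fall below before
  accepting a new upward crossing.
* **Barycentre readout**: plain activity-weighted mean over the full area;
  the quiescent floor ($F(0) \approx 5\times10^{-4}$) biases it toward 0°
  by well under a degree and is left uncorrected.
* **Degenerate inputs**: zero-activity barycentres are reported as
  no-percept (`NA`); trials whose premotor trace never crosses threshold
  within the 1000-ms response window are recorded as no-response and
  excluded from mean RTs; anticipatory responses (< 100 ms) are flagged
  and excluded from CDFs.
* **Seeding**: every experiment takes one seed; repetition $k$ uses a
  derived counter seed, so any single repetition can be reproduced in
  isolation and re-running a command with the same seed is byte-identical.
* **Problem sizes**: the shipped experiment defaults follow the reference
  protocols (100 repetitions per localization configuration, 250 for the
  asynchronous bias grid, ≥50 per switch-grid cell); the test suite runs
  reduced repetition counts chosen so that each asserted effect is several
  standard errors wide.

## Design decisions where the sources were open

* **Distance convention**: plain `|Δazimuth|` in degrees, no wraparound —
  all protocols live within ±20° of fixation, so edge effects are
  negligible.
* **Sigmoid placement**: $\tau \dot y = -y + F(u)$ (output-filtered), the
  convention of this model family.
* **Mexican-hat self-connection**: the distance-0 term is retained; the
  kernel formula is defined for all pairs and no exclusion rule is
  documented.
* **Feedback inhibition entry point**: inside the net-input sum,
  pre-sigmoid, alongside the other components.
* **Table-1 "dim = 100"**: interpreted as unused (saturation is normalized
  to 1 and the area size is 180); exposed nowhere.
* **Sensitivity sweep values**: the printed cross-modal sweep
  {0.08, 0.012, 0.016} is inconsistent with the baseline effectiveness
  0.12; `run_sensitivity()` defaults to the plausible reading
  {0.08, 0.12, 0.16} and provides the literal values behind
  `literal_grid = TRUE`.
* **Late ISI grid**: the switch-RT prediction grid's second window is read
  as 1000→3000 ms in 250-ms steps.
* **Between-trial state**: never reset within a sequence (the switch
  mechanism *is* the carried-over state); fully reset between independent
  repetitions.

## Known limitations

* The two slow-memory decay constants are reconstructions (see above); the
  quantitative ISI profiles between 300 and 1000 ms depend on them.
* Switch costs are of the order of 10 ms — the carried-over inhibition
  regime that keeps every trial responsive is narrow, because each
  processing stage is sigmoidal and saturating. The *patterns* (positive
  unisensory cost, near-zero audiovisual cost, peak near 1 s, gone by 3 s)
  are robust; absolute cost magnitudes are not calibrated to any empirical
  data set.
* For audiovisual asynchronies beyond ~400 ms the latched cross-sensory
  inhibition (spatially centred on the leading stimulus) *repels* the
  trailing auditory bubble, so the asynchronous localization bias crosses
  zero and becomes negative — an inhibition-of-return-like prediction of
  this reconstruction. The decrease of the bias with asynchrony is robust;
  its sign and magnitude at long asynchronies are not constrained by the
  sources and should be treated with caution.
* No feedback from the multisensory area to the input areas, no plasticity,
  no spiking dynamics, no Bayesian causal-inference layer: the model is
  deliberately a fixed-weight rate network.
* Reliability is azimuth-independent; results should not be extrapolated
  beyond ~±20°.

## Reproducing the headline numbers

```{r}
library(avnet)
p <- av_params()

vent <- run_ventriloquism(disparities = c(5, 20), n_reps = 100,
                          params = p, seed = 1)
vent$summary        # mean bias ~70% at 5 deg, ~35% at 20 deg

grid <- run_sw_grid(isis = c(0, 100, 200, 300), disparities = c(0, 20),
                    n_reps = 50, params = p, seed = 2)
grid$summary        # congruent pairs faster up to 200 ms, not at 300 ms
```

`scripts/acceptance.R` packages exactly these two computations (see the
README for how to run it).
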
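---
title: "Models and methods behind dawave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dawave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(dawave)
```

`dawave` simulates a dual-pathway dopaminergic spiking network that learns
associations between a color cue (conditioned stimulus, CS) and a preferred
direction of touch (unconditioned stimulus, US) on a 9-by-8 trackball
surface. This vignette documents the models, the parameters that matter,
the numerical choices, and the design decisions taken where the published
description leaves the implementation open.

## Neuron and synapse model

Every neuron follows the two-variable quadratic (Izhikevich) model

$$\dot v = 0.04 v^2 + 5v + 140 - u + I,\qquad \dot u = a(bv - u),$$

with a spike emitted when $v \ge 30$ mV followed by the reset
$v \leftarrow c$, $u \leftarrow u + d$. Two presets are used: regular
spiking (RS, $a=0.02, b=0.2, c=-65, d=8$) for excitatory cells and fast
spiking (FS, $a=0.1, b=0.2, c=-65, d=2$) for inhibitory cells. Input
currents come from four conductance channels,

$$I = g_{\mathrm{AMPA}}(0-v)
    + g_{\mathrm{NMDA}}\frac{\left(\frac{-80-v}{60}\right)^2}
        {1+\left(\frac{-80-v}{60}\right)^2}(0-v)
    + g_{\mathrm{GABA_A}}(-70-v) + g_{\mathrm{GABA_B}}(-90-v),$$

with decay constants 5, 100, 6 and 150 ms. A presynaptic spike arriving on
a synapse of weight $w$ (after its axonal delay) increments the target
conductances by $w$, split between the fast and slow receptor of its class
by a per-projection fraction.

### Integration

The grid step is 1 ms. The membrane potential is advanced with two 0.5-ms
half-steps per grid step and the recovery variable once per step. In the
compiled engine the conductance currents — which are linear in $v$ and can
make the membrane equation stiff when total conductance is large — are
integrated semi-implicitly (the $-vG$ term is taken at the new time level).
With an explicit update, strong shunting inhibition makes the membrane
oscillate numerically around the GABA$_A$ reversal and fire spuriously;
the semi-implicit form is unconditionally damping for the synaptic terms
and agrees with the explicit form to $O(h^2 g^2)$ when conductances are
small. The R-level `step_membrane()` keeps the plain explicit form, which
is adequate for the small op-level states it documents and tests.
Non-finite membrane state aborts the run with the offending neuron index;
weights are clipped to their bounds after every plasticity update.

Neurons sitting at the common resting point $(-70, -14)$ with negligible
conductance are skipped by the engine until an input wakes them; this is a
pure optimization and does not change trajectories, because that state is
an exact fixed point of the update.

## Plasticity

Four rules operate on tagged projections:

* **E-STDP** (PFC lateral excitatory): $\Delta w = A^+ e^{-\Delta t/\tau^+}$
  for pre-before-post and $-A^- e^{\Delta t/\tau^-}$ otherwise, with
  $A^\pm = 0.1/0.07$ and $\tau^\pm = 20/40$ ms. Pairing is
  nearest-neighbour: a spike pairs only with the partner's most recent
  spike, using the *arrival* time (delay included) on the presynaptic side.
  Exact coincidence ($\Delta t = 0$) contributes nothing.
* **I-STDP** (PFC inhibitory-to-excitatory): a piecewise Mexican hat on
  $|\Delta t|$ — $+B^+$ within $(0, \lambda]$, $-B^-$ within
  $(\lambda, \gamma]$, zero outside, with $B^\pm = 0.1/0.06$ and
  $\lambda/\gamma = 4/20$ ms. Updates fire on both the pre and the post
  event, so a close pair yields two increments.
* **DA-STDP** (PFC→STR and EXP→INT): pairings accumulate the E-STDP kernel
  in a per-synapse eligibility trace $c$ with $\tau_c = 1$ s; weights move
  by $\dot w = c\,d$ where $d$ is the dopamine concentration of the
  target's pool.
* **DA-PSF**: the AMPA and NMDA conductances of D1-bearing groups (STR and
  INT) are multiplied by $0.9 + 0.1\,d$ at current-computation time; the
  stored conductances are untouched.

Each dopamine pool decays toward zero with $\tau_d = 50$ ms, is reflected
at the 1 µM baseline, gains 0.04 µM per afferent dopaminergic spike, and is
capped at 20 µM. The printed equation decays $d$ toward zero while the text
fixes a 1 µM baseline; the reflecting floor honors both. Because
$d_\infty = 0.04 \cdot r \cdot \tau_d$ for a sustained dopaminergic rate
$r$ (spikes/ms), the pool only leaves baseline when the 100-cell DA
population bursts well above its ~3 Hz spontaneous rate; mid-insular drive
onto DA is sized so that genuine hedonic-touch bursts push $d$ to roughly
10–15 µM.

The engine integrates DA-STDP weights densely (per millisecond) over the
set of synapses with non-negligible traces; a brute-force R integrator is
used as the cross-check in the test suite at $10^{-6}$ relative tolerance.

## Architecture

The decremental pathway is AG → PFC → STR ⊣ DA; the incremental pathways
are AG → EXP → INT → DA for the cue and TH / TH:S1:S2 → pIC → mIC → DA for
touch. DA projects dopamine to the STR and INT pools. Group sizes follow
the published counts where stated (AG 4×16, PFC 512×4 excitatory + 512 FS
per color channel, 9×8 thalamic and insular channels per direction, 100 DA
cells); unreported sizes are package defaults (STR 512 FS, EXP 4×16 RS,
INT 256 RS, mIC 64 RS, pIC inhibitory pool 25%). All four PFC color
channels of a given geometry share one realized lateral wiring (drawn from
a dedicated RNG stream), so lateral weights developed on a standalone
sheet can be installed into every channel of a full network; this is a
desk-scale economy that trades channel-to-channel wiring variability for a
fourfold reduction in development cost.

Topographic projections connect with probability
$\exp(-d^2/2\sigma^2)$ of grid distance $d$ (hard cutoff at $3\sigma$),
with radii EFPR 2 (feed-forward), ELPR 3 (lateral excitatory), ILPR 5
(lateral inhibitory). Background spontaneous activity is a per-neuron
Poisson process of conductance kicks (weight 0.13 — one spike per kick
from rest) at cortical rates of 0.01–1 Hz depending on the group.

## The PFC traveling wave

A CS volley enters the left edge of its 512-column sheet; activity must
reach columns 508–511 inside a 1950–2050 ms window, so that a neuron's
x-position encodes time since cue onset. Waves propagate as a thick band:
recurrent excitation sustains the band, spike-frequency adaptation
extinguishes its trailing edge, and near-synchronous lateral delays make
the hop rate — and hence the traversal time — stable across trials.

Three choices matter here:

* **Delays.** Lateral excitatory delays are drawn uniformly per synapse
  (default 7.1–9.5 ms, rounded to the grid) and are not scaled with
  distance; distance-scaled delays desynchronize the arrivals of one
  band's spikes at the next and no propagating regime exists. The delay
  range is the package's calibration for a ~2-s traversal at ELPR 3: with
  15–20 ms delays the stable band regime tops out near 0.13 columns/ms
  (a ~4-s traversal), which cannot reach the rightmost columns inside the
  expected window.
* **Weight corridors.** The E-STDP kernel is depression-dominant
  ($A^-\tau^- > A^+\tau^+$), and unconstrained development first drives
  the sheet into reverberation and then crashes all weights to the floor.
  The published remedy — weight bounds "tuned to prevent run-away
  dynamics" — is implemented as tight corridors: lateral excitatory
  weights live in [0.052, 0.068] (initial 0.052, at which an undeveloped
  probe dies mid-sheet), inhibitory in [0.035, 0.045]. Development under
  E/I-STDP then potentiates left-to-right synapses toward the ceiling,
  holds backward synapses at the floor, and yields a reliable, correctly
  timed wave.
* **Development noise.** Development (2000 s, left-edge volleys every
  4 s) runs at a near-zero background rate (0.001 Hz) so that only
  stimulus-launched waves shape the weights; noise-spawned wavelets travel
  in both directions and would erase the forward selectivity. The probe
  noise level (0.01 Hz at height 4 in the reference experiments) is the
  experiment's own variable and is restored after development.

Ghost waves arise when two background spikes land close enough in space
and time to re-ignite the developed sheet; their rate grows with the noise
rate and the sheet height, while single stray spikes are subthreshold for
ignition and are also excluded from ghost scoring (an episode needs at
least 2 edge-column spikes within 50 ms).

## The tactile pathway and dopamine bursts

A synthetic sweep drives the fast pathway (one spike per touch event,
somatotopic, no delay) and the slow pathway (per-trackball tonic trains,
40 Hz for 300 ms, delayed 700 ms). Three implementation choices were
forced by the desk-scale geometry:

* **Refractory tonic windows.** A trackball's first touch opens one tonic
  window; repeats inside the window do not extend it. Additive per-event
  trains make horizontal sweeps (~305 events) systematically ~1.5× stronger
  than vertical ones (~207 events) at equal synaptic weight, which would
  invert the intended weight-controlled preference; with refractory
  windows the slow drive scales with the touched area, which is nearly
  direction-balanced.
* **Dense-random slow fan-out.** The slow projection connects each TH cell
  to a random 30% of its channel's pIC cells. A literally full fan-out
  gives every pIC neuron an identical input process, so any fluctuation is
  a whole-channel volley whose rate barely depends on the 0.03/0.04 weight
  being probed; sparse sampling decorrelates the drives while remaining
  spatially unstructured ("poor spatial resolution").
* **Pure-GABA$_A$ insular inhibition.** With a GABA$_B$ component, strong
  feedback volleys hyperpolarize pIC below −70 mV, reset the recovery
  variable low, and trigger synchronized rebound bursts that lock the
  channel into oscillation. GABA$_A$ (reversal −70 mV) cannot rebound.

The burst chain is: tonic drive primes pIC near rheobase in proportion to
the channel weight; event coincidences seed local recruitment which the
lateral excitation amplifies; the mid-insular population integrates pIC
spikes through NMDA-dominant synapses and bursts; mIC drives both DA
(strongly, so that the dopamine pools actually leave baseline) and the pIC
inhibitory pool (shunting feedback that makes the response one-shot). A
dopamine burst is detected as a run of sliding 50-ms population bins
exceeding baseline mean + 3 SD, with two floors: a Poisson floor
calibrated so a pure-baseline trial produces a false burst in under 1% of
trials, and a population floor (2.5 spikes per dopaminergic cell per bin)
so that a burst must engage a substantial fraction of the population
rather than merely exceed baseline noise. Runs closer than 200 ms merge,
and a trial is classified none / single / multiple.

When the tactile route is run as a standalone subnetwork (the
burst-probability experiments), it lacks the tonic striatal inhibition
that tempers dopaminergic excitability in the full circuit; the mIC→DA
weight therefore carries a separate calibration for that configuration
(0.19 standalone versus 0.30 in the full network), chosen so the
dopaminergic operating point matches across the two settings.

## Conditioning, extinction, behaviors

A 6-s trial presents the CS at 1100 ms: a 20-ms, 100-Hz packet on the
color's AG channel (which launches the PFC wave through a 200-ms axonal
path) plus a sustained 40-Hz experience drive on the color's EXP cells for
the 2-s display period. If a US sweep is attached it is placed uniformly
inside the 2-s US window (trial-by-trial interval jitter); touch events
past the window are dropped and never delivered. Behaviors follow the
stated thresholds: CR when INT exceeds 50 spikes in any 50-ms window, UR
when mIC exceeds 30, and a low tone when the longest DA-free interval in
the expected-reward window exceeds 400 ms (strict inequality); one event
per kind per trial.

The conditioned response is a sharp population event: the synchronized CS
volley through EXP fires the whole INT pool once the EXP→INT weights
exceed a threshold. Below that threshold sits the *unsupervised
equilibrium* of DA-STDP at baseline dopamine — the balance between volley
LTP and the depression generated by the sustained experience drive
arriving after INT has fallen silent. Reward pushes the weights above the
CR threshold (eligibility from CS pairings is still alive when the US
burst lifts $d$ ten-fold); omission lets them relax back below it, which
is the extinction mechanism. The same logic runs the decremental side:
during the reward burst DA-PSF lets the traveling wave fire striatal
cells, so the PFC columns active around reward time potentiate onto STR;
after learning that striatal volley suppresses DA at the expected reward
time, producing the omission dip that triggers the low tone.

Network wiring is drawn from a dedicated stream of the configured
`rng_seed`: the realized network is part of the model specification, and
experiment seeds vary inputs and background noise, not the anatomy. A
conditioning session engages a single color channel, so the desk-scale
runs build only that channel (idle channels carry nothing but sparse
background spikes and do not interact with the engaged pathway).

Trials are simulated from a resting state (weights and pools carry over;
membrane state and eligibility traces do not) — the 2.9-s stabilization
period makes carry-over negligible, and DA-STDP remains enabled throughout
the trial including stabilization.

## What the generator emulates — and what it does not

The sweep generator matches the printed per-direction-class statistics
(duration, speed, event count, direction-noise level) with truncated
Gaussians, places events monotonically along the swept path inside a 4–7
trackball footprint, and reassigns the noise fraction of events uniformly
to the other directions. It does not model pressure, temperature, hand
curvature, repeated strokes within one trial, or any correlation between
speed and event rate beyond what the joint means imply; speed is carried
as metadata only, since the physical trackball pitch is unknown. Passing
tests therefore show that the *circuit* behaves as described under
statistically faithful input, not that the generator reproduces every
property of human sweeps.

The 9×8 grid convention is columns × rows with origin top-left; the
printed maximum coordinate (8, 6) is inconsistent with a 9-by-8 matrix and
the matrix statement wins.

## Problem sizes and run lengths

The reference experiments use: 2000 s of wave development and 200 probe
trials per height; at least 100 synthetic sweeps per direction and weight
configuration for burst probabilities; conditioning sessions of 60–120
trials (yellow ↔ downward) and extinction sessions of 100–200 CS-only
trials over 3 seeds. The full network at default sizes has ~12,000 neurons
and ~470,000 synapses; a 6-s trial takes on the order of a second on one
CPU because quiescent neurons are skipped.

## Known limitations

* The traversal speed is calibrated through the lateral delay range rather
  than emerging from the printed 15–20 ms delays (see above).
* The burst-probability curve is flatter than published: with only ~25
  effective trackballs contributing per sweep, Poisson variability in the
  slow-pathway drive smears the weight–response relation, and the
  operating point trades the single-burst rate at weight 0.04 (~40–50%
  rather than >50%) and the preferred-direction rate (~40–60% rather than
  >70%) against keeping multiple-burst and non-preferred rates low.
* The conditioned response does not fully extinguish: with the weight
  change proportional to eligibility times a dopamine concentration
  floored at its 1 µM baseline, and a depression-dominant kernel, the
  cue-pathway weight self-pins near the response threshold (above it, the
  cue-evoked dopamine burst amplifies the post-volley depression; below
  it, no volley means no further change), so late-extinction response
  probability settles near 0.6–0.8 rather than zero. The omission dip and
  its low tone, which do not depend on this equilibrium, behave as
  described.
* The unconditioned response does not decay over conditioning; nothing in
  the implemented rule set couples dopamine prediction back onto the
  mIC threshold.
* Channel wiring is shared across PFC color channels (declared above), so
  cross-channel wiring variability is not represented.
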
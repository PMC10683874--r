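---
title: "Models and methods behind mapbmi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mapbmi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mapbmi)
```

`mapbmi` simulates and analyzes a hippocampal map-based brain–machine
interface end to end. This vignette documents the generative models, the
decoder, the closed-loop machinery and the statistics, together with every
numerical choice a user may want to question. Nothing here reports an
empirical number that the test suite or `scripts/acceptance.R` does not
itself compute.

## The arena and the place-cell model

The environment is a square arena with the origin at the lower-left
corner. The defaults — 100-cm side, 5-cm spatial bins, 10-cm goal
radius — are design choices on the scale of typical rodent VR arenas; all
three are configurable in `arena_spec()`. Spatial bins are indexed
row-major with x varying fastest, a convention shared by the rate maps,
the Bayesian decoder and its tie-breaking rule.

Each simulated unit has isotropic 2-D Gaussian tuning

$$ r_i(x) = b_i + a_i \exp\left(-\frac{\lVert x - c_i \rVert^2}{2\sigma_i^2}\right), $$

with centers $c_i$ uniform over the arena, widths $\sigma_i \in [8, 15]$
cm, in-field amplitudes $a_i \in [10, 20]$ Hz and baselines
$b_i \in [0.1, 0.5]$ Hz. The Gaussian-plus-baseline form is the simplest
standard place-field model; it deliberately omits phase precession,
multi-field cells, and experience-dependent dynamics. Spikes are
inhomogeneous Poisson at a 10-ms base bin, with the rate held constant
within each 100-ms behavioural tick. The base bin is fine enough for
population-burst detection while the decoder consumes 100-ms rebinnings;
rebinning conserves per-unit counts exactly.

## The Running task

The behavioural generator emulates goal-directed foraging: a goal is
placed uniformly at random (inset by the goal radius so the reward region
lies fully inside the walls) at least 30 cm from the current position;
the agent turns toward it with a first-order heading relaxation (gain 0.5
per tick, Gaussian heading noise of 10° SD) and advances at a truncated
Gaussian speed (15 ± 5 cm/s). After each goal the agent consumes reward
while essentially immobile for 8–16 s (treadmill jitter below 0.4 cm/s).

The pauses matter twice. First, they supply immobility epochs (≥ 8 s at
≤ 1 cm/s) for the still-theta spectral analysis and for burst detection.
Second, they put *stationary* decoder windows into the training set —
windows whose multi-scale features all agree on one location — which is
what lets a decoder trained only on natural behaviour decode the
stationary rPV probe inputs used in the robustness benchmark. With 120
trials the session lasts roughly 35–40 minutes, matching the regime in
which the decoder is meant to operate.

## Rate maps (rPVs)

`compute_rpv_map()` divides per-bin spike counts by per-bin occupancy on
the 100-ms grid. Bins occupied less than 0.5 s are masked and stay masked
through every downstream statistic. Smoothing is applied to the
rate *ratio* after masking, by mask-aware normalized Gaussian convolution
(σ = 5 cm): masked bins contribute neither numerator nor weight. We chose
ratio-smoothing over the smooth-counts/smooth-occupancy alternative
because it keeps the unsmoothed map exactly count-conserving
(`rates_raw × occupancy` sums to the spike totals), which the tests
assert as an identity.

## The decoder

Every 100 ms the decoder sees the spike counts of the most recent
`window_s` seconds (5 s by default; 1.5 s is the conventional faster
setting). Rather than flattening the raw units × bins window, the window
is summarized as per-unit mean rates over nested trailing sub-windows of
0.5, 1.5 and `window_s` seconds. The short scale carries the
position-specific signal (a flat 5-s average smears ~75 cm of path at
running speed); the long scales average Poisson noise and stabilize the
estimate when activity is stationary. The regressor is a multilayer
perceptron — two ReLU hidden layers of 192 units, linear output, MSE
loss — trained with Adam (learning rate 10⁻³, batch 128, 100 epochs,
weight decay 10⁻⁴) in compiled code with its own seeded RNG, so training
is bit-reproducible. Targets are scaled to the unit square and
predictions are clipped to the arena.

Training windows are split into contiguous blocks — the leading 80% for
training, the trailing 20% for validation — because a random split of
heavily overlapping windows would leak temporal structure. Training
windows are subsampled every 0.5 s (consecutive 100-ms windows are nearly
identical) and expanded with three augmented copies each. The
augmentation recipe is: unit dropout with probability 0.4, multiplicative
per-unit rate jitter `max(0, 1 + e)`, `e ~ N(0, 0.5)`, and a circular
time shift of up to 2 bins (a no-op on window-mean features, retained for
the window-level API). Augmentation strength was chosen as the training
recipe of the reference implementation; it is strong enough that the
regressor tolerates half the population dropping out, which is the point
of the design. Each component is independently switchable for ablation.

The Bayesian baseline is the standard memoryless Poisson decoder over
spatial bins,
$P(x \mid n) \propto P(x)\,\prod_i f_i(x)^{n_i}\, e^{-\tau \sum_i f_i(x)}$,
computed in log space with a uniform prior over unmasked bins, a 0.01-Hz
rate floor (to avoid `log 0`), and ties broken at the lowest row-major
bin index. The test suite checks it against an independent brute-force
evaluation on random small instances.

The robustness benchmark probes both decoders with windows whose expected
counts equal a bin's rPV, corrupted by unit dropout (probability = noise
level) and multiplicative jitter (SD = noise level). The corruption model
is declared, not inferred: it matches the augmentation family so that
"robustness" has one operational meaning across training and evaluation.

## The intention agent and the closed loop

During the BMI tasks the package replaces the animal with an *intention
agent* emitting Poisson activity at

$$ r_i = \phi\, g\, \mathrm{rPV}_i(x^\*) + (1 - \phi)\,\bar r_i + \eta, $$

where $x^\*$ is the intended location, $\phi$ the fidelity, $g$ a rate
gain, $\bar r_i$ the unit's session mean rate and $\eta$ a noise floor.
Fidelity 1 reproduces the map representation of the intended place;
fidelity 0 is spatially uninformative activity at unchanged mean rates.
This convex blend is the simplest one-knob family that sweeps
continuously from chance to ideal volitional control; it does not model
how a real subject learns or strategizes.

Both tasks run as strict 0.1-s loops: the agent emits spikes, the decoder
sees only spikes up to the current tick, the decoded point is smoothed by
a causal trailing mean (3 s in Jumper, 2 s in Jedi; the window expands
from the first sample, so output exists immediately), and the task rule
updates the world. One full decoder window of warm-up emission precedes
the first trial. In Jumper the avatar teleports to the smoothed decode
(a rate-limited movement rule is available; the teleport rule is the
default reading of the avatar being moved to the decoded location), a
trial ends on entering the goal region or at 62 s, and the next goal is
placed at least 30 cm away. In Jedi the agent is fixed at the center,
holds the goal's representation, and the object tracks the smoothed
decode; reward flows at 0.01 mL/s while the object touches the goal
(the flow rate is a declared modelling choice — only the 0.5-mL cap and
3-min limit are fixed by the task definition), and each new goal jumps at
least 40 cm. Body rotation is simulated as relaxation toward the goal
bearing plus noise, solely so the >12°/s exclusion rule has data to act
on.

## Statistics

**Shuffle nulls.** The unit-identity null permutes whole spike trains
across unit IDs, re-decodes, and replays the Jumper kinematics offline
against the original goal sequence, censored at the timeout. The
goal-location null preserves the BMI trajectories and redraws goals under
each task's placement constraints (without the minimum-distance
constraint the null would be artificially easy); for Jumper the
continuous trajectory is replayed against random goal sequences, for Jedi
the per-trial mean decoded distance is recomputed. Empirical p-values use
the add-one rule and can never be zero; because shuffle distributions in
this design sit far from the observed statistic, a normal-approximation
p-value is reported alongside, labelled as such — that is how
astronomically small p-values arise from a few hundred shuffles.

**Angles and distances.** The angle-to-goal histogram uses signed angles
in 15° bins with a 0.5-cm minimum step per 0.1-s tick to suppress jitter.
The Jedi performance metric is the time-average decoded distance to goal
over samples with body rotation at or below 12°/s.

**PV–rPV correlations.** At 0.5-s steps the PV over each integration
window (0.5–5 s) is Pearson-correlated across units with the rPV of the
location attributed to that moment, and with rPVs of random unmasked
bins as baseline; bootstrap CIs are taken over time points. Units with
zero spatial rate variance are excluded from the correlations; time
points with constant PVs are dropped. On hold-goal data the matched
correlation increases with the integration window because the underlying
rate vector is stationary and longer averages only remove Poisson noise.

**PBEs.** Population bursts are detected on the summed 10-ms trace after
Gaussian smoothing (σ = 10 ms) and z-scoring: peaks at z ≥ 3 extended to
z = 0, durations 50–500 ms, event-mean speed ≤ 5 cm/s. These are standard
field conventions; every threshold is a parameter. Excision replaces
in-event counts with each unit's session-mean count per bin by default
(keeping re-decoded windows inside the decoder's training range) with
zeroing as the alternative; re-decoded samples are flagged when their
window overlaps an event, and unflagged samples are bit-identical to the
plain decode.

**Spectra.** The PSD is Welch's method with 4-s Hann windows and 50%
overlap (0.25-Hz resolution), z-scoring the trace first, and it is
segment-aware: windows are placed only inside analysis segments, so no
estimate mixes samples across a gap. Peak prominence is judged against a
power-law background fitted in log-log space within the band, so a sloped
broadband spectrum is not mistaken for a peak. The spectrogram is a
Morlet continuous wavelet transform (width 7) on a log-spaced 2–50 Hz
grid. Movement epochs for the movement-theta PSD are segmented on
1-s-smoothed speed so brief dips below the 5-cm/s threshold do not chop
runs below the Welch window; immobility epochs use the strict raw
criterion (≥ 8 s at ≤ 1 cm/s).

## Determinism and problem sizes

Every stage takes an integer seed, and `run_experiment()` derives each
stage's seed from the master seed and the stage name by a fixed integer
hash below 2³¹, so one integer reproduces the whole experiment, including
the compiled network training. The default experiment uses 90 units and
120 Running trials (≈ 35–40 min of behaviour), 20 Jumper trials, 8 Jedi
trials and 200 shuffles per null; the test suite exercises the same code
paths at these sizes and, for the byte-identity determinism check, at a
reduced size (30 units, 20 trials, 40 shuffles) chosen so the property is
verified on the full pipeline without dominating the suite's runtime.

## What passing tests do and do not show

The generator realizes the assumptions the analyses test for: Gaussian
place fields, Poisson spiking, an agent that truly emits rPV-like
activity. Passing the pipeline's checks therefore validates the
*machinery* — decoding, closed-loop bookkeeping, nulls, spectral
estimates — under those assumptions. It does not show that real
hippocampal data satisfies them: real recordings add non-Poisson
variability, theta-coupled dynamics, unit-sorting noise, multi-field and
non-place cells, and behavioural strategies richer than any fidelity
knob. Conclusions about biology require the deposited in-vivo recordings;
this package's claim is that, given data of the assumed structure, every
statistic it reports is computed correctly and reproducibly.

## Known limitations

* The LFP is phenomenological (frequency-switched sinusoid plus 1/f
  noise); there is no spike–LFP coupling, so cross-domain analyses are
  out of scope.
* The intention agent has fixed competence within a run; learning across
  sessions is not modelled.
* The MLP is a reference implementation chosen for desk-scale accuracy
  and reproducibility, not a claim about the original network
  architecture; `decoder_config()$model` is the hyperparameter surface.
* Serialization of rasters and LFP uses plain-text CSV writers.
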
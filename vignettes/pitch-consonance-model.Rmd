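---
title: "A mesoscopic model of cortical pitch and consonance processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mesoscopic model of cortical pitch and consonance processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pitchcortex)
```

## The scientific problem

Pitch is the perceptual correlate of waveform periodicity. When a periodic
sound starts after an energy-matched noise, magnetoencephalography records a
pitch onset response (POR) in anterolateral Heschl's gyrus whose peak
latency grows with the period of the sound; for two simultaneous tones (a
dyad), the POR arrives earlier for consonant intervals (simple frequency
ratios) than for dissonant ones. `pitchcortex` implements a mesoscopic
model of this processing chain: it proposes that the POR marks the moment
at which a winner-take-all cortical network commits to a pitch decision,
and that consonant dyads are decided faster because their components share
lower harmonics.

The pipeline has four stages, mirrored by the package modules:

1. **Stimuli** (`generate_irn()`, `generate_dyad_irn()`,
   `make_noise_pitch_sequence()`): iterated rippled noise (IRN) and IRN
   dyads synthesized by a delay-and-add comb filter,
   `s(t) = sum_n g^n [s0(t - n T0) + s0(t - n T1)]`, band-pass filtered,
   preceded by an energy-balanced noise segment and cross-faded so that
   only periodicity — not energy — changes at the transition.
2. **Auditory nerve** (`auditory_nerve_probability()`): 40 gammatone
   channels (125 Hz-10 kHz), rectification, power-law compression,
   loss of phase locking, normalisation into firing probabilities.
3. **Periodicity detection** (`compute_sacf()`, `regularize()`): a summary
   autocorrelation function (SACF) — one leaky integrator per candidate
   period on a 250-lag grid from 0.5 to 30 ms — followed by divisive
   normalisation.
4. **Cortex** (`simulate_cortex()`): two networks of 250 columns, each an
   excitatory/inhibitory ensemble pair with AMPA, NMDA and GABA synaptic
   gating. The *decoder* receives the regularised SACF; harmonic
   connectivity lets the inhibitory ensemble tuned to period T fire only
   when the excitatory ensembles at T, 2T and 3T are jointly active, after
   which it silences the excitatory ensembles at the lower harmonics
   {2T, 3T, ...} — leaving the fundamental as the winner. The *sustainer*
   locks the decision in through top-down NMDA drive.

The equivalent dipole moment — the model's proxy for the measured field —
is the column-summed decoder excitatory rate shifted by a fixed subcortical
delay (50 ms single tones, 75 ms dyads); the POR latency is the windowed
maximum of this trace after pitch onset (`extract_por_latency()`), and the
decoded pitch is the dominant peak of the time-averaged decoder inhibitory
profile (`decode_pitch()`).

## Mean-field dynamics

Each ensemble follows `tau_pop dH/dt = -H + phi(I)` with the standard
current-to-rate transfer `phi(I) = (aI - b) / (1 - exp(-d(aI - b)))`
(`transfer()`); the singular point `aI = b` is evaluated by series
expansion (limit `1/d`). The population time constant is adaptive,
`tau_pop = tau0 * Delta_T * phi'(I) / H` (`effective_tau()`), using the
exact analytic derivative of the transfer function (verified against
central finite differences to 1e-6 relative error). Because this
expression diverges as `H -> 0`, `tau_pop` is clamped to [1, 100] ms; the
upper clamp acts as the effective activation time constant of silent
populations and the lower clamp keeps the 1 ms Euler step stable.
Synaptic gating follows `dS/dt = -S/tau + H` (AMPA, GABA) and
`dS/dt = -S/tau + gamma (1 - S) H` (NMDA), with per-variable white noise
`sigma * sqrt(dt) * z` in the Euler update. All constants — transfer
parameters, conductivities, time constants, baseline drives, `gamma`,
`sigma` — are the reference values in `cortical_params()`; simulations
integrate with forward Euler at 1 ms, which agrees with a 0.1 ms
integration to within 5% RMS of the rate trajectories (tested).

Two readings of the reference parameterisation were ambiguous and had to
be fixed by us:

* the additional sustainer drive (0.24 nA) is applied to **both**
  sustainer populations; with this choice the input-free sustainer rests
  with inhibitory ensembles firing (~80 Hz) and excitatory ensembles
  silent, which is the intended resting state;
* the top-down gating that drives the decoder inhibitory ensembles is the
  sustainer excitatory NMDA gating of the same column.

## Harmonic connectivity

`build_connectivity()` builds the four 250 x 250 matrices. `C_ee` is the
identity; `C_ii = 0.9 I + 0.1` mixes specific and unspecific inhibition.
In `C_ei`, the inhibitory ensemble at period T listens to the excitatory
ensembles at {T, 2T, 3T}; in `C_ie` it projects onto the excitatory
ensembles at {2T, 3T, ...} up to the grid edge. Because exact multiples of
a grid lag rarely coincide with grid points, each harmonic target
contributes a narrow Gaussian profile (sd 1.5 grid steps, narrower than a
semitone at the experiments' 6.25 ms lower note, so dyad components stay
separable). Each profile has **peak weight 1**: k active harmonics then
deliver about k unit-weight inputs, which with the reference
conductivities puts the two-input drive just below and the three-input
drive decisively above the inhibitory activation threshold. (Normalising
each row to total weight 1 instead would cap the three-harmonic drive at
about 0.07 nA, an order of magnitude short of threshold, so no decision
could ever fire; we therefore deviate from per-row normalisation.)
`harmonics_to_activate()` verifies the resulting activation rule by
controlled current injection: with a representative 0.3 nA drive into k
harmonic excitatory columns, the base inhibitory ensemble reaches
decision-scale rates (>= 50 Hz; committed decisions run 80-150 Hz) only
from k = 3.

## Front-end choices

The biophysical periphery that inspired this architecture is replaced by a
documented phenomenological chain — gammatone filterbank, half-wave
rectification, power-law compression (exponent 0.3), 3 kHz low-pass for
the loss of phase locking, decimation to 10 kHz, normalisation by the 99th
percentile with a spontaneous-rate floor. Channels are aligned by the
gammatone envelope group delay so that cross-channel summation in the SACF
does not smear onsets. The front end is deterministic and approximately
level-invariant (tested at +/- 10 dB); it is selected by name
(`periphery: simple`) and can be swapped for any stage with the same
contract.

The SACF integrators use `tau_n = max(1.5 ms, 0.25 * lag_n)`. These two
constants were calibrated once against the detector-activation property
that the lag-T channel first reaches half of its steady response about
`1.25 T` after an abrupt noise-to-IRN transition, for T in {2, 8} ms, and
frozen. The calibration is a compromise: at T = 8 ms the measured ratio is
~1.1, at T = 5 ms ~1.4; at T = 2 ms fixed front-end delays (gammatone
rise, marker rounding) dominate the 2.5 ms target, and the ratio is not
meaningful there. Measurements use an abrupt (fade = 0) transition because
the 10 ms cross-fade envelope otherwise adds its own delay to the
estimate.

Regularisation (`regularize()`) is divisive normalisation across the lag
axis, `r_n = A_n / (k + mean A)`, with two documented refinements: the
divisive pool averages only over causally live detectors (lag shorter than
the elapsed record), preventing a large spurious transient at record
onset; and the subtracted baseline is either a flat `theta` (default) or,
optionally, the per-lag precursor-window average. The contrast is clipped
at a saturation `sat` and affinely rescaled; single tones and dyads use
separate rescale factors. The constants (`k`, `theta`, `sat`, rescales)
are calibration constants of the model: they were chosen once so that a
single IRN drives its excitatory columns to tens of Hz — the regime in
which three, but not two, harmonic inputs activate an inhibitory ensemble
— and are stored in `sacf_params()`.

## Observables

Latency is reported from pitch onset and *includes* the subcortical delay,
so model numbers are directly comparable with measured POR latencies. The
dipole trace is smoothed with a 25 ms moving average before peak picking —
the counterpart of reading evoked-field latencies from 1-20 Hz filtered
source waveforms — and runs whose windowed maximum does not clear a
prominence floor (10% of the trace's dynamic range) are flagged "no
decision" and excluded from averages with a logged count. The decoded
pitch must additionally reach an absolute 10 Hz floor on the inhibitory
profile, so residual single-harmonic leakage does not count as a pitch,
and must dominate its subharmonic templates (the inhibitory ensembles at
P/2 and P/3, which receive the candidate's series as their own harmonics,
are silenced by a real winner-take-all decision but stay comparably
active under an undecided ridge).
A full-pipeline run is only assigned a latency when the network actually
committed to some pitch (the decoder inhibitory profile shows a decoded
peak); a run that never commits has no decision whose time the dipole
maximum could measure, and is flagged "no decision" as well.
The analysis window is 0-350 ms after pitch onset.

## What the synthetic stimuli do and do not capture

All experiments run on synthesized stimuli under the study conditions:
750 ms noise precursor, 750 ms pitch segment, 10 ms ramps and cross-fade,
80 dB SPL, 48 kHz; single-IRN experiments use 16 iterations and a
0.8-3.2 kHz band, dyads use 8 iterations, a 125-2000 Hz band and a 160 Hz
lower note (T0 = 6.25 ms) with just-intonation ratios. Fresh source noise
is drawn per run (the precursor question — frozen vs fresh noise — is
resolved as fresh per seed), so run-to-run latency variability reflects
stimulus noise, which dominates the small synaptic noise (sigma =
0.0007 nA). The generator does not model binaural presentation, transducer
calibration, middle-ear filtering or adaptation; passing tests show that
the decision mechanism behaves as described under these idealised
conditions, not that the front end reproduces auditory-nerve physiology.

## Numerical choices and degenerate inputs

* Euler step 1 ms (cortex); SACF integrated at the 10 kHz internal rate
  with the exact exponential update and resampled to 1 ms.
* The baseline state is obtained by damped fixed-point iteration and a
  settling period before stimulus onset.
* Gating is clamped to be non-negative (NMDA <= 1) after every step; rates
  are clamped non-negative.
* All-zero SACF input regularises to exactly zero (no division blow-up);
  a flat lag profile maps to the baseline value 0.
* Ties in peak picking break to the earliest sample; decode peaks are
  local maxima with a plateau rule at the grid edges.
* Buffers too short for a comb delay, fades longer than a segment, silent
  waveforms passed to the level calibrator, and out-of-range config keys
  all raise errors naming the offending parameter.

## Problem sizes used by the test-suite and acceptance script

Unit tests run the pipeline on shortened sequences (0.4 s noise + 0.5 s
pitch). The acceptance computations use the full study conditions with the
run counts stated alongside each experiment: 5 seeded runs per period for
the decoding-range sweep, 10 runs per delay for the latency trend, and 10
runs per interval for the six-dyad consonance comparison; the full N = 60
reproduction profile is available through `run_dyad_experiment(n_runs =
60)` but is not exercised by the default suite.

## Known limitations

* The periphery is phenomenological; absolute latencies are therefore
  calibration-dependent, and quantitative agreement is claimed only for
  printed structural numbers (dyad table, detector activation ratio,
  harmonic activation count, decoding range) and for orderings/trends
  (latency vs period, consonant vs dissonant).
* The model predicts no effect of the number of IRN iterations on latency,
  consistent with the reference account, but pitch-salience effects below
  about 4 iterations are outside the calibrated regime.
* Periods above half the 30 ms grid edge cannot be decoded by
  construction; extending the grid would extend the range.
* Dissonant dyads whose upper-note harmonic series is weakly represented
  in the front end may fail to decode the upper note even when latency
  behaviour is as expected.
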
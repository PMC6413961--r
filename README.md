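# pitchcortex

`pitchcortex` simulates how early auditory cortex extracts the pitch of a
sound and why consonant two-tone combinations (dyads) are processed faster
than dissonant ones. It is aimed at auditory and computational
neuroscientists who want a runnable, parameter-explicit model of the
pitch onset response (POR) — the pitch-selective component of the auditory
evoked field whose peak latency scales with the period of the sound and
with the consonance of a dyad.

## The model in brief

A stimulus waveform is turned into auditory-nerve firing probabilities
`p_m(t)` on a 40-channel cochlear bank, from which an array of periodicity
detectors computes a summary autocorrelation (SACF): one leaky integrator
per candidate period `δt_n` on a 250-lag grid (0.5–30 ms),

    τ_n dA_n/dt = −A_n + Σ_m p_m(t) · p_m(t − δt_n).

The regularised SACF drives a *decoder* network of 250 cortical columns
(each an excitatory/inhibitory mean-field ensemble pair with AMPA, NMDA
and GABA synaptic gating, rates `τ_pop dH/dt = −H + φ(I)` with
`φ(I) = (aI−b)/(1−e^{−d(aI−b)})`). Harmonic connectivity makes the
inhibitory ensemble tuned to period `T` fire only when the excitatory
ensembles at `T`, `2T` and `3T` are jointly active; it then silences the
lower-harmonic columns, leaving the fundamental as the winner, and a
second *sustainer* network locks the decision in via top-down NMDA drive.
The equivalent dipole moment is the column-summed decoder excitatory rate,
`m(t) = Σ_n H_n^e(t)`, shifted by a fixed subcortical delay; the POR
latency is its windowed maximum after pitch onset. Consonant dyads share
lower harmonics, so their periodicity detectors collaborate and the
network commits earlier — the model's account of the consonance effect.

## Worked example

Synthesize a noise-preceded IRN tone (16 comb iterations, 8 ms delay,
0.8–3.2 kHz band, 80 dB SPL) and run the full pipeline:

```r
library(pitchcortex)

spec <- stimulus_spec(kind = "irn", delay_T0 = 8e-3, iterations = 16,
                      band_low = 800, band_high = 3200, duration = 0.75,
                      seed = 42)
irn  <- generate_irn(spec)
wave <- make_noise_pitch_sequence(0.75, irn, band_low = 800,
                                  band_high = 3200, level = 80,
                                  noise_seed = 7)
run <- run_pitch_model(wave, model_config(), mode = "single", seed = 1)
run
#> <pitch_sim> mode = single, seed = 1
#> POR latency: 195.0 ms after pitch onset
#> decoded pitch: 125.6 Hz (T = 7.96 ms)
```

The decoded period sits on the lag grid within one grid step (0.118 ms) of
the true 8 ms comb delay, and the latency is reported from pitch onset
including the 50 ms subcortical delay. `autoplot(run)` shows the dipole
trace with the extracted latency; `plot_sacf(run$sacf)` shows the
periodicity-detector activity.

Batch experiments return tibbles and follow the broom conventions:

```r
ex <- run_dyad_experiment(intervals = c("P1", "P5", "TT", "m7", "m2"),
                          n_runs = 10, seed = 1)
glance(ex)               # per-interval mean ± SE latency
tidy(ex)                 # one row per seeded run
compare_consonance(ex, consonant = c("P1", "P5"),
                   dissonant = c("m2", "TT", "m7"))
autoplot(ex)
```

A thin command-line interface wraps the same functions
(`inst/cli/pitchcortex.R`, subcommands `synth`, `simulate`, `experiment`,
`replay`) driven by a YAML configuration (`load_config()`), and
`run_pipeline()` writes WAV stimuli with JSON sidecars, CSV trajectories,
summary JSON, figures and a replayable manifest.

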
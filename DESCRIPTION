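Package: pitchcortex
Title: Mesoscopic Modelling of Cortical Pitch and Consonance Processing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the cortical processing of pitch and consonance with a
    mean-field model of period-tuned cortical columns. Provides synthesis of
    iterated rippled noise (IRN) tones and dyads, pure tones, harmonic
    complexes and click trains; a phenomenological auditory-nerve front end;
    summary-autocorrelation (SACF) periodicity detection over a 250-lag grid;
    a two-network (decoder/sustainer) cortical model with AMPA, NMDA and
    GABA synaptic gating; and observables including the equivalent dipole
    moment, decoded pitch and the predicted latency of the pitch onset
    response (POR). Batch experiment runners reproduce latency predictions
    for single IRN tones and for consonant versus dissonant dyads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite,
    tibble,
    dplyr,
    generics,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
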
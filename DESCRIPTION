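Package: gridtheta
Title: Spatial, Theta-Rhythmic and Speed Coding Analysis for Open-Field
    Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for tetrode recordings from freely foraging
    animals in an open-field arena with alternating light and dark epochs.
    Computes occupancy-normalized spatial firing rate maps, grid scores
    (rotation-correlation power spectrum with elliptical eccentricity
    correction), border scores, head-direction tuning, spatial information,
    spike-triggered rate maps and grid spacing; fits a maximum-likelihood
    parametric model of spike-time lag densities to quantify theta-rhythmic
    firing frequency and magnitude; derives running speed (Kalman filter),
    instantaneous firing rate, and LFP theta phase, frequency, and amplitude
    (Butterworth band-pass plus Hilbert transform); fits linear-nonlinear
    Poisson conjunctive tuning models with forward covariate selection;
    and quantifies condition contrasts (epoch-wise rate modulation, theta
    frequency versus running speed regressions, 10-second time courses).
    Includes a synthetic-session generator (foraging trajectories, grid,
    border, head-direction, speed and theta-rhythmic Poisson units, and a
    speed-coupled theta LFP) so every stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
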
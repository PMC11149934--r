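# opmbeta

Source-space analysis of beta-band dynamics in wearable OPM-MEG
(optically pumped magnetometer magnetoencephalography) recordings of
somatosensory paradigms, with a synthetic developmental cohort generator
for end-to-end validation by parameter recovery.

The package is aimed at electrophysiology researchers who want a tested,
self-contained implementation of the modern beta-dynamics analysis chain:

- **Preprocessing** — automated bad-channel detection (power-spectrum
  z-scores), zero-phase notch (Q = 30) and 1–150 Hz Butterworth band-pass
  filtering, homogeneous field correction (projection out of the
  channels × 3 orientation subspace — the dominant interference mode of
  wearable magnetometer arrays), half-open-window epoching, and single-pass
  3 SD trial rejection.
- **Source localization** — analytic current-dipole forward model in a
  conducting sphere (Sarvas), LCMV beamforming with Tikhonov-regularized
  covariance (`C + 0.05 λ_max I`), unit-gain weights
  `w = C⁻¹Lη / (η'L'C⁻¹Lη)`, and pseudo-T beta-modulation images
  `T = (P_a − P_c)/(P_a + P_c)` contrasting stimulus (0.3–0.8 s) and rest
  (2.5–3 s) windows on 4 mm whole-head and 1 mm refined grids.
- **Oscillation metrics** — Hilbert-envelope time–frequency spectrograms,
  the beta modulation index
  `βmod = (βPost − βStim)/βBaseline` over the 0.3–0.8 / 1.0–1.5 / 2.5–3.0 s
  windows of the 13–30 Hz envelope, and the evoked M50.
- **Connectivity** — 78-region beamformer time courses, pairwise
  orthogonalization (zero-lag leakage removal), amplitude envelope
  correlation (AEC) connectomes, global connectivity and node degree.
- **Burst detection** — three-state time-delay-embedded HMM (zero-mean
  Gaussian states over a ±70 ms lag space at 100 Hz) on the 1–48 Hz
  virtual electrode, 2/3 posterior binarization, task-modulated burst-state
  selection, burst probability modulation
  `ΔP = mean P[1.0,1.5) − mean P[0.3,0.8)`, multitaper state spectra and
  burst amplitude.
- **Group statistics** — Pearson fits of every metric against age,
  within-group (child/adult) z-transforms for cross-metric association,
  per-region degree-vs-age slopes and per-frequency burst-PSD age
  correlations.

The synthetic cohort plants the corresponding ground truth — age-dependent
burst probability modulation and spectral tilt (low frequencies down, high
frequencies up, alpha and burst amplitude invariant), an evoked M50, and
region networks whose envelope coupling rises faster with age frontally
than occipitally — so every claim the pipeline makes is testable against
known parameters. See the methods vignette
(`vignettes/opmbeta-methods.Rmd`) for the models, defaults and design
decisions.

## Worked example

```r
library(opmbeta)

cfg <- pipelineConfig(seed = 1,
                      cohort = list(nSubjects = 12, nTrialsPerFinger = 12))
out <- runPipeline(cfg, progress = TRUE)
#> subject 1/12: betamod=-0.012 deltaP=0.002 locErr=8.4 mm
#> ...
#> subject 12/12: betamod=0.495 deltaP=0.332 locErr=5.9 mm

out$fits$betamodAge
#>        slope   intercept         r        r2           p  n
#> 1 0.01459428 -0.05380925 0.7079558 0.5012014 0.009989605 12

cor(out$table$deltaP, out$groundTruth$depth)
#> [1] 0.8352465

out$groupDegreeSlopes
#>    frontal  occipital      other
#> 0.12270795 0.05936648 0.08630424
```

Each subject row reports the beta modulation index, M50, burst probability
modulation, burst amplitude, global connectivity and the localized peak;
the fits list gives the age trends (here: beta modulation rising with age,
r² = 0.50 on 12 subjects) and the recovery summary compares estimates with
the planted ground truth (burst probability modulation correlates 0.84
with the planted depth). Frontal node-degree slopes exceed occipital ones,
as planted. A command-line wrapper is provided in
`inst/scripts/run_pipeline.R`.

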
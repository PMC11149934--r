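---
title: "Beta-band bursts, connectivity and neurodevelopment: methods and design of opmbeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-band bursts, connectivity and neurodevelopment: methods and design of opmbeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`opmbeta` implements a complete source-space analysis chain for wearable
OPM-MEG recordings of a passive somatosensory task — preprocessing, LCMV
beamforming with an analytic spherical forward model, Hilbert-envelope beta
metrics, orthogonalized amplitude-envelope-correlation (AEC) connectomes, a
three-state time-delay-embedded hidden Markov model (TDE-HMM) for
pan-spectral burst detection, and cohort-level trend estimation — together
with a synthetic cohort generator that plants age-dependent effects so that
every stage can be validated by parameter recovery without any external
data. This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic validation does and does not
demonstrate about real data.

# The synthetic world

## Paradigm and sensors

The simulated task alternates tactile stimulation of two fingers: 0.5 s of
stimulation followed by 3.0 s of rest, 42 trials per finger by default, so
the default paradigm spans 84 x 3.5 s = 294 s. Sensors are triaxial
magnetometers placed quasi-uniformly (Fibonacci lattice, optionally
randomly rotated per subject) on a sphere 15 mm outside an 80 mm spherical
head model; 64 sensors give the full 192-channel array. Each sensor
carries one radial and two tangential orthonormal channels.

## Burst model

The sensorimotor source is a train of transient, pan-spectral bursts over a
weak white noise floor (floor SD 0.1 in source units against a burst RMS
of 1). Burst onsets follow an inhomogeneous Poisson process whose rate
drops by the modulation depth `d` inside the 0-0.8 s post-onset window;
durations are lognormal (mean 0.2 s, sdlog 0.5) and are truncated at the
next onset so bursts never overlap. Truncation — rather than dead-time
insertion — keeps the onset statistics exactly Poisson, so window-rate
recovery checks are exact at the cost of a slightly reduced realized mean
duration.

Defaults of 2 bursts/s and 0.2 s mean duration give a burst-state
occupancy near 0.35, in the range reported by the beta-burst literature
(burst rates of 2-3/s, lifetimes of 100-400 ms, occupancies of 0.3-0.5).
This choice is also a matter of statistical power: with 84 trials and 0.5 s
analysis windows, the sampling error of a window-occupancy difference is
roughly `sqrt(2 * occ * (1 - occ) * tau / (W * nTrials))`. At occupancy
0.12 (a rate of 0.8/s with 150 ms bursts) that error is ~0.025 against a
planted signal spread of ~0.02 — parameter recovery could then never reach
the correlations this package validates against, regardless of
implementation quality. At occupancy ~0.35 the planted spread exceeds the
sampling error about two-fold.

Each burst waveform is coloured noise shaped in the frequency domain,
Tukey-windowed (taper fraction 0.5), and RMS-normalized — bursts are
characterised only by probability, amplitude and spectrum, so no specific
biophysical waveform is assumed. The spectral shape over 1-48 Hz is
`S(f; tau) = max(1 + tau * g(f), 0.05)` where `g` is a log-frequency
sigmoid constructed (once, by root-finding on its pivot) so that both
`g(9 Hz) = 0` and `mean(g) = 0` over the band. The tilt parameter `tau`
therefore moves power from low to high frequencies as it increases while
leaving two quantities invariant by construction: the 9 Hz (alpha anchor)
density and the total burst power — matching a world in which low
frequencies fall and high frequencies rise with age while alpha and
broadband burst amplitude do not change. A fixed-amplitude windowed 9 Hz
component is added on top as the explicit alpha peak. A phase-locked
Gaussian bump (peak 50 ms after onset, sigma 10 ms) provides the evoked
deflection read out as the M50.

## Connectivity model

78 region centroids sit on an inner sphere (radius 50 mm) with deterministic
anterior/posterior tags (frontal / occipital / other). Each region emits a
narrowband beta carrier (15-28 Hz, slowly drifting phase) whose positive
slow envelope mixes a group-shared process with an independent process as
`sqrt(rho) * shared + sqrt(1 - rho) * own`, planting the pairwise envelope
correlation `rho` exactly. Envelope processes live in the 0.2-2 Hz band —
the dominant fluctuation scale of beta amplitude envelopes. Per-subject
`rho` values are derived from the planted node-degree targets (frontal
0.26 + 0.27/year, occipital 2.92 + 0.10/year, intermediate elsewhere)
divided by the number of within-group partners. Region amplitude defaults
to 0.25 source units so that the sensorimotor source remains the locally
dominant beta source, as in task data.

## Interference and artifacts

Sensor data are the forward-projected sources plus: white noise (scaled so
that the mean channel RMS of the sensorimotor source alone divided by the
noise SD equals the configured SNR, default 1); mains interference at
50/100/150 Hz with random per-channel amplitudes; a homogeneous-field
drift — a 3-parameter slowly varying field vector seen identically by all
sensors and projected onto each channel orientation, which is exactly the
subspace homogeneous field correction removes; and planted artifacts (one
flat channel, one channel at 10x noise, and two high-variance trials for
the default paradigm — one for short paradigms, because two >= 5 sigma
outliers among fewer than ~40 trials inflate a 3-SD threshold past both).

## Age trends

Per-subject parameters are linear in age with Gaussian spread: modulation
depth `d = 0.05 + 0.03 * age` (SD 0.08, clipped to [0, 1]), spectral tilt
`tau = -0.9 + 0.05 * age` (SD 0.08, clipped to +-0.9), the degree targets
above (SD 0.3), and age-invariant burst amplitude (1.0) and M50 amplitude
(0.5). The depth trend spans most of [0, 1] over ages 2-34 so that the
planted between-subject spread comfortably exceeds the estimation noise
derived above.

# The analysis chain

## Preprocessing

Bad channels: zero-variance channels are flagged "flat"; channels whose
mean log-PSD (Welch, 1-150 Hz or up to 0.48 fs) exceeds the across-channel
mean by more than 3 SD are "noisy" — an automated, reproducible stand-in
for visual spectrum inspection. Filtering is zero phase: the squared
magnitude response of a Butterworth order-4 band-pass (1-150 Hz, upper edge
clipped to 0.45 fs with a warning when the sampling rate is too low) and
band-stop notches (Q = 30) at 50 Hz and two harmonics is applied in the
frequency domain with reflection padding — for long series this equals
forward-backward IIR filtering while processing 192 channels in a few
FFTs. Homogeneous field correction projects out the column space of the
channels x 3 orientation matrix; it is an exact idempotent projector.
Epochs use the half-open convention [start, end): the default [-0.5, 3.0) s
window has exactly 1050 samples at 300 Hz. Trial rejection is a single
pass: per-trial variance pooled over kept channels, strict `>` at
mean + 3 SD (sample SD), matching a one-shot "exceeding 3 SD" criterion;
iterating would change rejected counts.

## Forward model and beamformer

The forward model is the closed-form field of a current dipole in a
homogeneous conducting sphere. It replaces a realistic single-shell mesh
deliberately: it is exact, fast, and — because simulation and inversion
share it — forward-model mismatch is excluded from what the recovery tests
probe. Radial dipoles are silent in a sphere, so lead fields are restricted
to the two tangential columns per voxel; voxels at the origin are flagged
non-localizable.

Data covariance is estimated over all kept-trial samples (band-limited
where the stage requires it) and Tikhonov-regularized with 5% of its
largest eigenvalue. LCMV weights per voxel use the orientation minimizing
`eta' (L' C^-1 L) eta` — the closed-form 2 x 2 minimum eigenvector, which
maximizes beamformer output power — normalized to unit gain
(`w' L eta = 1`). The pseudo-T image contrasts beta-band source power
between the active (0.3-0.8 s) and control (2.5-3.0 s) windows as
`T = (Pa - Pc) / (Pa + Pc)`: bounded, noise-model-free, monotone in the
contrast.

Peak selection deserves care. The exported `pseudoTMap()` defaults to the
largest |T| over the whole grid. The cohort pipeline instead localizes the
peak of beta desynchronization (signed minimum) inside an anatomical
sensorimotor prior, and takes the final coordinate from a 1 mm grid over
that prior region constrained to a cortical-depth band (+-6 mm around the
canonical source radius). The reason is a property of ratio images:
coherent background activity (the 78-region network) depresses |T| near
the background shell and inflates it radially outward, biasing the
unconstrained extremum ~1 cm outward regardless of background amplitude.
Anatomical source spaces prevent exactly this in empirical pipelines; the
canonical sensorimotor coordinate plays the role of an atlas coordinate,
fixed for the synthetic world, never per-subject truth. The virtual
electrode is the broadband-covariance LCMV projection of the continuous
cleaned recording at that peak; projecting the continuous data (rather
than concatenated epochs) avoids band-pass transients at trial seams, and
kept-trial onsets travel with the VE for epoching.

## Envelope metrics

The Hilbert envelope is the magnitude of the FFT-based analytic signal of
the band-passed series (long series are reflection-padded to composite FFT
lengths; the Hilbert kernel decays as 1/t, so interior values are
unaffected). The TFS uses 4 Hz-wide bands centred every 1 Hz from 3 to
46 Hz (configurable); each band's trial-averaged envelope is expressed as
fractional change from its 2.5-3.0 s baseline mean, which is therefore zero
by construction. Note the sampling floor of an envelope TFS: per
(band, time) values have SE = CV_Rayleigh / sqrt(nTrials) = 0.058 at 80
trials, so stationarity checks are made on the grand-mean TFS (measured
|mean| of ~0.01 on stationary input), not on per-sample maxima.

The beta modulation index is `(betaPost - betaStim) / betaBaseline` from
the trial-averaged 13-30 Hz envelope over the stimulus (0.3-0.8 s),
post-stimulus (1.0-1.5 s) and baseline (2.5-3.0 s) windows — the window-
mean formulation; a peak-difference variant of the underlying trace is
available to callers via the returned envelope. The index is invariant to
global VE rescaling. The M50 is the signed value of the trial-averaged
4-40 Hz VE at the sample nearest 50 ms (no peak search by default; a
peak-in-window option exists). The 4-40 Hz band attenuates a sigma = 10 ms
Gaussian bump by ~20%; tests therefore compare against the same filter
applied to the template rather than the raw amplitude.

## Connectivity

Region time courses are LCMV projections at the 78 centroids from a shared
beta-band covariance. AEC applies pairwise orthogonalization
(`y - x <x,y>/<x,x>`, removing the zero-lag leakage component) before
correlating Hilbert envelopes, computed in both directions and averaged —
the regression is asymmetric and the reported connectome is symmetric.
The analytic signal is linear, so the corrected envelope is
`|A_y - c A_x|`, which the compiled kernel exploits to avoid per-pair
FFTs. A zero-variance corrected envelope (a pure leaked copy) has an
undefined correlation; the convention is 0 with a warning, keeping cohort
matrices complete. The correlation sums sample the envelope series at
75 Hz or more — several times the envelope bandwidth, so the estimate
equals the full-resolution one, while the orthogonalization coefficients
always use the full signals; no lossy envelope smoothing is applied.
Global connectivity is the mean off-diagonal entry; node degree the
off-diagonal column sum.

## Burst detection

The VE is band-passed 1-48 Hz at the recording rate (the band-pass doubles
as the anti-alias filter), decimated to 100 Hz, standardized, and embedded
with 7 lags each side (15 dimensions, +-70 ms) — no PCA reduction, the
embedded space is small enough. The HMM has zero-mean Gaussian states
distinguished purely by lag-space covariance, i.e. by spectral signature.
Baum-Welch EM (scaled forward-backward in compiled code) runs to a relative
log-likelihood change below 1e-6 or 500 iterations, best of `nRestarts`
random initializations (function default 5; the cohort validation runs
use a single restart, which is reliably sufficient on the strongly bimodal
synthetic VE).
Covariance collapse triggers diagonal loading. The log-likelihood trace is
non-decreasing within every restart and is asserted in tests.

Posteriors are binarized strictly above 2/3 (a posterior of exactly 2/3 is
"off"; at most one state can exceed 2/3). The burst state is the state
whose window occupancy modulates most between the post-stimulus and
stimulus windows — restricted to burst-like states whose mean visit
envelope exceeds the overall mean envelope. The restriction matters in the
synthetic world: with three states on a two-regime signal the homogeneous
quiescent floor collapses into a single state carrying the full
complementary (sign-flipped) occupancy modulation, while the burst class
splits; a burst is by definition a high-amplitude transient, so the
amplitude filter implements the definition rather than a heuristic. Ties
break to the lowest index; a winning modulation below 0.02 raises a "weak
modulation" warning. Burst probability P(t) is the across-trial fraction
of burst-state samples; its modulation is deltaP = mean P over [1.0, 1.5)
minus mean P over [0.3, 0.8), signed. State spectra are multitaper PSDs
(2 s windows, time-bandwidth 4, 7 Slepian tapers, 50% overlap) with
windows weighted by within-window posterior occupancy; states occupied
under 1 s are flagged undefined. Burst amplitude is the mean 1-48 Hz
analytic-signal magnitude over burst-on samples. No minimum burst duration
is imposed.

## Group statistics

Metric-age relations use Pearson correlation / least-squares lines with
two-sided t-distributed p-values (n - 2 df), sample (n - 1) SDs
throughout, and uncorrected p-values for the per-frequency PSD sweep
(p < 0.01 flags; a Benjamini-Hochberg option is exposed). The cross-metric
association between beta modulation and burst probability modulation is
computed after z-transforming each within the child (< 18 y) and adult
groups, removing the shared age trend.

# Validation design, problem sizes, and what passing shows

The cohort validation runs the full sensor-level chain on 30 subjects with
21 trials per finger (147 s at 300 Hz per subject) — enough trials for the
burst-occupancy estimates to resolve the planted spread (the full 84-trial
paradigm roughly halves the estimation error again but doubles runtime;
the simulation rate of 300 Hz rather than 1200 Hz likewise only affects
cost, as all analysis bands sit far below either Nyquist). On that cohort
the package verifies that estimated beta modulation and burst probability
modulation track the planted modulation depth, that the two associate
after within-group z-transforms, and that the localization error stays
within the fine-grid prior region. The test-suite cohort disables the
region network (whose claims are validated separately below); the
acceptance script analyzes the full default cohort including the network
and additionally reports its global-connectivity age trend and degree
slopes. The beta-modulation estimator's depth recovery (r > 0.8) is
measured on source-level cohorts at the full 84-trial paradigm, 3 seeds,
where a decomposition shows the burst-process realization ceiling is
r ~ 0.91 and the sensor-level chain at SNR 1 attenuates recovery to
r ~ 0.73 through beamformer output noise — the sensor-level value is
asserted above 0.6 and reported as its own quantity. The depth-grid
monotonicity check couples the grid with common random numbers (shared
candidate bursts and per-onset waveform seeds), so the planted ordering is
structural and the check isolates the estimator.

Three effects are validated on focused source-level cohorts instead, where
the quantity under test is isolated from beamformer gain jitter: the
monotonicity of deltaP over a planted depth grid; the spectral-tilt signs
(negative 3 Hz and positive 37 Hz PSD-age correlations with an unflagged
9 Hz anchor, 10 cohorts of 30 at 80 s per subject); and the amplitude-invariance null (no
significant amplitude-age slope at alpha = 0.01 in >= 9/10 cohorts). At
the sensor level, state-spectrum estimates mix in beamformer output noise
across their 2 s windows, which attenuates the per-frequency tilt
correlations without changing their meaning; the full-pipeline spectra are
still computed and reported. Degree-slope ordering (frontal > occipital)
is likewise validated over 10 source-level cohorts of 16 subjects at 15 s
per subject, where AEC estimation noise — not beamformer leakage — is the
binding constraint.

Passing these tests shows that the implementation recovers what the
generator plants under the generator's assumptions. The synthetic world
deliberately omits: ocular/cardiac artifacts (removed by ICA in empirical
pipelines, out of scope here), head movement, realistic cortical geometry
and forward-model mismatch (simulation and inversion share the sphere),
1/f background at the sensors, and any difference between the two fingers'
cortical representations. Conclusions about real recordings require the
usual empirical caveats; what the package guarantees is the internal
correctness of each stage and of their composition.

# Degenerate inputs and numerical conventions

Tie-breaks and edge cases are fixed as follows: half-open sample windows
everywhere; strict inequalities at the trial-rejection (3 SD) and
binarization (2/3) thresholds; burst-state ties to the lowest index;
AEC of a zero-variance envelope is 0 with a warning; voxels at the sphere
origin are non-localizable; a covariance with fewer than 5 samples per
channel warns; all-flagged channels abort the pipeline; epochs extending
past the recording are dropped with a log entry. All randomness flows from
explicit integer seeds, with per-subject and per-restart seeds derived
deterministically from the master seed; identical configurations produce
byte-identical CSV outputs.

# Worked example

```{r example}
library(opmbeta)

cfg <- pipelineConfig(seed = 1,
                      cohort = list(nSubjects = 12, nTrialsPerFinger = 12),
                      outDir = "opmbeta-demo")
out <- runPipeline(cfg, progress = TRUE)

out$fits$betamodAge       # beta modulation increases with age
out$fits$connectivityAge  # global connectivity increases with age
out$fits$betamodDeltaP    # beta modulation tracks burst probability modulation
out$groupDegreeSlopes     # frontal > occipital degree slopes
```
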
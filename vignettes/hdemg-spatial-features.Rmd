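---
title: "Methods: spatial features of HDEMG activation maps"
author: "gridEMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial features of HDEMG activation maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridEMG)
```

# The measurement model

A high-density grid of surface electrodes (default 8 rows x 4 columns,
8 mm interelectrode distance, one corner electrode absent, so 31 monopolar
channels) samples the electrical activity over one muscle at 1000 Hz. The
package's analysis unit is a *trial*: a multichannel recording, a
synchronized hand-force trace in newtons, and the participant's MVC
calibration trials. The pipeline assumes

* all channels share one clock and one sampling rate;
* the recording bandwidth of interest is 10–500 Hz (the acquisition chain
  is taken to have low-passed at 500 Hz and high-passed at 10 Hz already;
  the software band-pass enforces the same band after any re-import);
* electrode columns run parallel to the muscle fibers, so
  single-differential channels are differences of *consecutive rows within
  a column*;
* channel order is fixed and column-major with names `r<row>c<col>`
  (0-based, row 0 at the top of the grid as placed); every on-disk file
  carries this convention in its JSON sidecar.

# Pipeline stages and their parameters

## Band-pass filter

`bandpassRecording()` applies a 4th-order digital Butterworth band-pass
*zero-phase* — i.e. with the squared magnitude response $|H(\omega)|^2$ and
no phase shift — so EMG events are not delayed relative to the force clock.
The filter is designed with `signal::butter()`; the forward–backward pass
is carried out in the frequency domain (multiplying the FFT of each channel
by $|H(\omega)|^2$), which is the circular-boundary equivalent of
time-domain `filtfilt` and vectorizes across all 31 channels in one
operation. A unit test pins agreement with `signal::filtfilt()` on interior
samples to <2% relative RMS error; boundary samples can differ, which is
immaterial here because analysis windows are interior by construction. At
1000 Hz the nominal 500 Hz upper edge coincides with Nyquist and is clamped
to 499 Hz (0.998 x Nyquist).

* `low = 10` Hz, `high = 500` Hz — the recording bandwidth.

## Initiation window

`detectInitiation()` defines the push-initiation window as the 0.5 s
interval **starting at the first sample whose force strictly exceeds
20 N**. The phrase "0.5 s after the force surpassed 20 N" admits a second
reading — a window *beginning* 0.5 s after the crossing — and that variant
is available as `offsetS = 0.5` (CLI flag `--window-offset`); the default
reading is the one that captures the initiation phase itself. Parameters:

* `thresholdN = 20` N — the force threshold;
* `windowS = 0.5` s — the analysis window length;
* `minHoldS = 0` s — optional debounce: minimum time the force must stay
  above threshold before a crossing counts. Zero by default (synthetic
  traces are clean); imported force data with spikes can set e.g. 0.05 s.

A trace that never exceeds the threshold raises a `gridEMG_no_initiation`
error; a crossing closer than the window length to the end of the trace
raises `gridEMG_truncated_window`. The study layer converts both into
*failed trial records* rather than dropping trials, so group Ns stay
auditable.

## MVC reference

`computeMVC()` reduces the three 5 s maximal contractions to one reference
value per channel: the maximum across trials of the RMS over a sliding
window (`windowS = 0.5` s, matching the analysis window). The sliding-max
is the conventional MVC amplitude reduction; a whole-trial RMS would be
biased low by on/off ramps. Normalization is **per channel** by default —
maps are per-channel objects, and per-channel normalization cancels
electrode-specific gain — but whether a per-channel or a single grid-level
scalar reference is preferable is genuinely open; a grid-scalar variant can
be obtained by building an `MVCReference` whose channels share
`max(mapValues(ref), na.rm = TRUE)`.

## Activation maps and features

`buildActivationMap()` computes $HM_{ij} = \mathrm{RMS}(sEMG_{ij})$ over
the half-open window. Features:

* **Intensity** $I = \log_{10}\left(\frac{1}{N}\sum HM_{ij}\right)$, on the
  **raw** (un-normalized) map by default: log-amplitude is meant to
  compress the nonlinear EMG-amplitude/force relation, and normalizing
  first would change its meaning to log-%MVC. Both are possible; the
  pipeline default keeps intensity raw and mean RMS normalized.
* **Differential intensity** forms every single-differential signal along
  the fiber direction (up to 7 pairs x 4 columns = 28 on a full grid; 27
  on the default grid because the missing corner breaks one pair), takes
  each pair's RMS over the window, and returns
  $DI = \log_{10}(\overline{\mathrm{RMS}})$ — the *log of the mean*,
  mirroring the structure of $I$. The alternative aggregation (mean of
  per-pair logs) is `aggregate = "mean-of-logs"`. If every differential is
  identically zero (perfect common mode) the value is floored at
  `log10(.Machine$double.eps)` and flagged `floored_di` instead of
  returning $-\infty$.
* **Mean RMS**: the arithmetic mean of the valid channels of the
  MVC-normalized map, a fraction of MVC (reported x100 as %MVC).
* **Modified entropy** $E = -\sum_i p_i^2 \log_2 p_i^2$ with
  $p_i^2 = HM_i^2 / \sum_j HM_j^2$, in bits, with $0\log 0 \equiv 0$.
  $E \in [0, \log_2 N]$: maximal for a uniform map, 0 when one channel
  carries all power. **$N$ is always the map's valid-channel count, never a
  hard-coded 32, 31 or 28.** Reported entropy ceilings in the HDEMG
  literature vary because different montages are used: a full 32-electrode
  grid gives $\log_2 32 = 5$, the default 31-electrode monopolar grid
  $\log_2 31 \approx 4.95$, and the 28 single-differential channels of a
  full grid $\log_2 28 \approx 4.8$. The package computes entropy on
  whatever map it is given and exposes `nChannels()` so the ceiling in use
  is always explicit.
* **CoV** $= 100\,\mathrm{SD}/\mathrm{mean}$ over valid channels, in
  percent (the magnitudes reported for trunk muscles — tens of percent —
  are only consistent with a percentage scale). The SD is the **sample**
  SD ($N-1$), the common default in human-movement work; population SD via
  `sdType = "population"`. CoV requires at least two valid channels and a
  positive mean.

Degenerate inputs (all-zero maps, zero mean) raise classed errors rather
than returning sentinels such as 0 or $-\infty$, because a silent value
would corrupt group summaries downstream.

# The synthetic study generator

## Source model

Each trial is a sum of *territory* sources: a territory is an isotropic
Gaussian amplitude profile on the grid (center, spread in electrode units,
gain), driving one band-limited Gaussian noise process shared across
channels; territories are mutually independent, and each channel adds
independent band-limited noise of RMS `noiseSd`. Channel RMS therefore
follows $\mathrm{RMS}(e)^2 = \sum_t w_t(e)^2 + \sigma_\text{noise}^2$ with
$w_t(e) = g_t \exp(-d^2/2s_t^2)$. This reproduces exactly the quantity the
spatial features measure — the RMS surface — without modelling motor-unit
action-potential trains, which would add realism the features cannot see.

Band-limiting uses the same zero-phase Butterworth as the pipeline; 0.25 s
of extra signal is generated at each end and discarded so stated durations
carry no filter edge transients. Each territory source is rescaled to unit
RMS after trimming, so the generated per-channel RMS matches the analytic
target up to the noise cross-terms (the generator test pins 5%).

The `clustering` dial maps **linearly** onto the derived territory spread:

$$s(c) = (1 - c)\,25 + c\,0.8 \quad \text{electrode units},$$

exported as `clusteringToSpread()` so tests can invert it. At $c = 0$ the
territory is far wider than the grid (weights uniform to ~1%); at $c = 1$
it is a sub-electrode cluster (essentially one active channel). Increasing
$c$ strictly decreases map entropy and increases CoV; the test suite
verifies this ordering end to end (Spearman $|\rho| \ge 0.9$ over 20 seeds
at clustering levels 0, 0.5, 0.75, 0.9, 1).

## Study-level structure

`generateStudy()` emulates the full design: each participant completes 18
recording trials (3 bilateral muscle pairs x 6 handle designs), each trial
bundling both sides' recordings, one force trace, and the participant's
per-muscle/side MVC sets (three 5 s maximal contractions). Defaults:

| parameter | default | rationale |
|---|---|---|
| trial duration | 3 s | accommodates a 1 s pre-push baseline, the 20 N crossing at `onsetTime = 1` s and >0.5 s of post-crossing data |
| force plateau | 100 N | a moderate cart push; any value >20 N triggers detection |
| force rise rate | 200 N/s | crosses 20 N exactly at the configured onset |
| `noiseSd` | 0.05 | ~5% of the unit task amplitude — clean laboratory EMG |
| `mvcAmplitude` | 10 | puts task activity near 10% MVC, the right order for submaximal pushing |
| participant gain factors | lognormal, sd 0.10 / 0.15 | electrode/skin gain and behavioral activation level |
| trial-to-trial activation | lognormal, sd 0.15 | natural repetition variability |

The per-design **effect table** is the simulated ground truth. Its default
emulates the qualitative pattern the pipeline is designed to resolve:
pushing at hip height with a horizontal handle (HH) yields the lowest mean
activation (gain 0.60 vs 1.0–1.15) and the most homogeneous maps
(clustering 0.25 vs 0.45–0.65, i.e. highest entropy, lowest CoV), with the
shoulder-height semi-pronated/vertical designs most clustered. An identity
table makes all designs exchangeable. Every bundle is seeded from
(study seed, participant, trial index), so any single trial is reproducible
without regenerating the study.

## What the generator does and does not emulate

It emulates: grid geometry with the missing electrode, band limits,
spatially structured RMS with a controllable clustering dial, additive
noise, force traces with a known 20 N crossing, MVC calibration, design
effects, and participant/trial variability.

It deliberately does **not** emulate: motor-unit action potentials,
conduction velocity or fiber anatomy; motion artifacts and ECG
interference; electrode–skin impedance variation. The last point means
simulated maps are *more spatially homogeneous* than real trunk-muscle
recordings — synthetic CoV values sit well below the tens of percent seen
in vivo unless `clustering` is pushed high. Passing tests therefore
demonstrate that the pipeline recovers spatial structure and design effects
it is fed, not that it has been validated against physiological variation;
amplitude units are arbitrary, and no calibration of the intensity scale to
any particular hardware is attempted.

# Validation problem sizes

The test suite exercises the pipeline at sizes chosen to make every
property decidable in minutes on one CPU: spatial-feature oracles on maps
of up to 31 channels (brute-force agreement at $10^{-12}$ relative
tolerance on maps of up to 8 channels); heterogeneity ordering over 20
seeds x 5 clustering levels of 1 s trials; and design-effect recovery over
100 replicate single-participant studies at the default effect size, where
the HH design must have the lowest summarized mean RMS in at least 95 of
100 replicates. Single-participant replicates are the smallest study for
which the per-design summary is defined over all six groups (six records
per design: 3 muscles x 2 sides).

# Known limitations

* The frequency-domain zero-phase filter assumes approximately stationary,
  zero-mean signals; signals with large steps at the record boundary would
  leak circularly (not the case for band-limited EMG, and analysis windows
  are interior).
* `readStudy()` groups files by sidecar metadata; hand-assembled
  directories must carry complete sidecars.
* The study layer computes descriptive group summaries only. Inferential
  statistics (mixed-model ANOVA, post-hoc corrections, normality checks)
  are intentionally out of scope: `summarizeStudy()`'s input table — one
  row per trial and side with participant, sex, muscle, side, design and
  the five features — is the tidy substrate any external stats package can
  consume.
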
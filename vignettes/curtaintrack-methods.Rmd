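---
title: "Models and methods behind curtaintrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind curtaintrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curtaintrack)
```

# Scope

curtaintrack analyzes single-molecule DNA-curtain experiments in which
motor proteins (helicase/nuclease resection machines such as BLM-TOP3A-RMI1/2
with DNA2, together with MRN and RPA) are imaged while translocating on
48.5 kb DNA molecules stretched by buffer flow. Because raw curtain movies
are rarely deposited, the package pairs the analysis pipeline with a
synthetic-imaging simulator that produces ground-truthed movies, so that
every stage — localization, drift correction, tracking, calibration,
kinetics, cohort statistics — can be validated against known truth.

# The acquisition and image model

Movies are shuttered time-lapse acquisitions: 0.2 s exposures every 2 s,
i.e. 1800 frames per hour. One or two spectral channels image quantum-dot
(QD) labeled proteins on an EMCCD camera. The simulator's image model is:

* **Emitters.** Each emitting molecule contributes an *integrated* symmetric
  2D Gaussian: the PSF integral over each pixel, so the summed signal equals
  the photon amplitude exactly (QDs are unresolved point sources). The
  default sigma is 1.1 px.
* **Noise.** Poisson shot noise on signal + background, plus additive
  Gaussian read noise. EM-register excess noise is folded into the
  amplitude/background scale rather than modeled explicitly; this
  underestimates the true variance by up to a factor of ~2 at low signal,
  which matters for absolute photometry but not for the geometric
  quantities (positions, velocities) the pipeline measures.
* **Blinking.** QD blinking is a two-state Markov telegraph process sampled
  at frame boundaries. Sub-frame blinking is not modeled: the exposure
  (0.2 s) is much shorter than the frame interval (2 s), so within-exposure
  state changes are second-order.
* **Drift.** A global per-frame (dx, dy) offset applied to all emitters,
  exactly what a moving stage does.
* **Flow stop.** During a flow-stop window, the tether relaxes; bound
  molecules are remapped toward the anchor by a fixed compression factor
  (default: 80% of the anchor distance is removed). Real polymer recoil
  dynamics are richer, but only the binary recoils / does-not-recoil
  contrast is consumed downstream, so a fixed factor suffices.

## Geometry, units, defaults

Pixel coordinates are 0-based with pixel centers at integers; x runs along
columns, y along rows. DNA coordinates are base pairs from the tethered
(anchor) end. Time is seconds from the frame-0 midpoint. The camera pixel
size, QD photon budget, and DNA extension in pixels are not published for
this assay; the package declares defaults rather than inferring them:
0.27 um/px, ~2000 photons/frame, and a 48,502 bp tether spanning 100 px
(485 bp/px). With subpixel localization noise of a few hundredths of a
pixel this calibration naturally reproduces the assay's ~500 bp practical
resolution, which is the role these defaults have to play.

# The motor model

Each simulated molecule follows a piecewise path: constant signed velocity,
interrupted by pauses (zero velocity) whose initiations are Poisson
(`pause_rate`) and durations exponential (`pause_duration_mean`), with
optional deterministic pause schedules for fixtures. Dissociation is
exponential (`dissociation_rate`) and/or occurs after a fixed run length
(`stop_after_bp`), which is how a drawn ground-truth processivity is
encoded. Diffusive jitter is added as Brownian increments
(SD `velocity_noise_sd * sqrt(dt)`) while moving. Random draws follow a
documented order (dissociation, then alternating segment/pause durations,
then per-frame blinking, then jitter) so independent event-queue oracles
can replay a seed.

The reference cohort emulates the published resection kinetics: velocity
drawn from N(18, 11) bp/s and processivity from N(18, 6) kb, truncated at
small positive floors (2 bp/s, 2 kb) to keep molecules physical. The
truncation slightly raises the realized means; recovery tests therefore
always compare against the *drawn* values, not the nominal ones.

# Localization and drift

Spot candidates are local maxima at least `min_snr` robust noise SDs above
the frame median; the noise SD is the median absolute deviation, which is
insensitive to the sparse bright spots themselves. Each candidate is
refined by nonlinear least squares of an integrated 2D Gaussian (amplitude,
subpixel center, shared isotropic sigma, constant background) over a 9x9 px
window. The production solver is a compiled Levenberg-Marquardt loop; an
independent `stats::optim()` route is retained and cross-checked in the
tests, along with a brute-force SSE grid-search oracle. Non-convergence is
recorded in the output (`converged = FALSE`), not silently dropped, so
downstream filters remain auditable.

Drift is measured from a designated stationary fiducial (explicit ROI,
mirroring the manual pick used in practice): its position minus its frame-0
position, linearly interpolated across blink gaps, smoothed by a short
running mean, and re-zeroed at frame 0. Subtracting this series from all
detections removes stage motion to within the fiducial's own localization
precision.

# Tracking and calibration

Frame-to-frame linking is greedy nearest neighbor with a per-frame-step
cap (default 3 px, generous against the ~0.07 px/frame of a fast resection
motor) and dark-gap bridging up to 10 frames (20 s of blinking). Curtain
molecules sit on parallel, well-separated tethers, so global assignment
optimization would add cost without changing the result; the tests bound
the greedy linker's identity-swap rate against ground truth instead.

Calibration projects (x, y) onto the tether axis and scales by bp/px; the
anchor maps to 0 bp. Two filters then partition molecules:

* **Flow-stop filter.** Retained iff the molecule's axial position during
  the stop window moves toward the anchor by at least a threshold (default
  2000 bp) relative to adjacent flowing frames. The recoil jump breaks
  trajectory linking by design, so the filter can also consume raw
  stop-window detections, matched to trajectories by tether row.
* **Movement filter.** Translocating iff maximum displacement from start
  reaches 1 kb, *inclusive* at the boundary. Sub-kb movers approach the
  assay resolution and are excluded from kinetics but kept as initiation
  denominators.

# Kinetics

**Velocity** is the OLS slope of position vs time over the motile span
(take-off to maximum excursion), one line per molecule, pauses included —
with an `exclude_pauses` diagnostic mode, since the convention is not
settled. The sign convention reports movement away from the start as
positive. **Processivity** is the maximum excursion from the starting
position in kb (net displacement; resection motors are unidirectional).
Total path length is available as a diagnostic but over-counts localization
noise.

**Pause detection.** A pause is >= 30 s with no net movement beyond the
~500 bp resolution. A literal dwell rule ("displacement < 500 bp over a
30 s window") cannot work at typical resection speeds: a 10 bp/s mover
covers only 300 bp in 30 s, so the rule would flag every frame of an
honestly moving molecule. The detector therefore classifies frames by a
sliding OLS local velocity (window = 30 s) against an *adaptive* threshold,
45% of the molecule's own motile-span speed; flagged runs separated by
sub-resolution gaps (< half a window) are merged; and a run becomes a pause
only if it lasts >= 30 s, its net displacement (noise-robust 3-frame
endpoints) stays under 500 bp, and that displacement is clearly below what
continued translocation would have produced (< 0.5 x speed x duration —
without this, slow noisy movers chain spurious flags into false pauses
while still advancing). Window centers must fit inside the motile span, so
stalls within ~15 s of either end are not detectable; Monte Carlo tests
put sensitivity for injected 60 s stalls at ~97% with a false-positive
rate under 5% across the reference velocity distribution.

**Survival.** Bound lifetimes form a Kaplan-Meier curve (right-censored
molecules — still bound at the movie end — contribute at-risk time), and
S(t) = exp(-k t) is fitted by least squares of log S on t through the
origin over points with S > 0. This is the closed form
k = -sum(t log S) / sum(t^2) and reduces to the two-point log-linear
solution for two uncensored lifetimes. Direct nonlinear LS on S(t) and the
censoring-aware exponential MLE (events / total time) are selectable
alternatives; all three agree within a few percent on clean exponential
data.

# Cohort statistics

Fractions (initiation, pause, dissociation, colocalization) carry bootstrap
SDs: molecules are resampled with replacement (default 1000 resamples,
seed recorded in the output). Two-channel colocalization requires a partner
within 1000 bp (twice the spatial resolution; the threshold is not
published, so it is a declared, exposed default) for at least 5 consecutive
simultaneous frames, and is directional — both directions should be
reported. Group comparisons use the two-sided Welch t test by default — when an
analysis reports only a generic Student's t test, Welch is the safer
reconstruction under unequal variances, and the pooled-variance test is
available — with the conventional star bins (ns > 0.05 down to
**** < 0.0001) and no multiple-testing correction (flagged in output
metadata).
GC analysis tiles the substrate into windows, and pause-position
association compares GC at pauses against matched random non-pause
positions with the same t machinery.

# What a green test establishes — and what it does not

The simulator reproduces the acquisition cadence, shot/read noise,
blinking, drift, recoil, and piecewise-linear motor kinetics. It does not
reproduce: EM-register excess noise, PSF aberrations or astigmatism,
overlapping molecules on one tether, tether wobble transverse to flow, or
sequence-dependent motor behavior. Recovery of simulated cohorts therefore
validates the *pipeline arithmetic* (localization accuracy, linking
fidelity, estimator bias) — it cannot validate the biological model
itself, and headline velocities/processivities of the real complexes are
not reproducible without the raw movies. Count-derived percentages and
fold changes, by contrast, are exact arithmetic on published molecule
counts and are reproduced exactly.

# Numerical choices and edge cases

* PSF fits clamp the center inside the window, sigma to [0.3, window/2],
  and amplitude to be non-negative; flat windows are an error, not a fit.
* Degenerate zero-variance group comparisons short-circuit to t = 0, p = 1
  (equal means) rather than dividing by zero.
* The movement filter boundary is inclusive at exactly 1 kb (tested).
* Pause durations are quantized to the frame interval; a one-frame
  boundary correction compensates the half-window lag of the sliding
  slope at pause edges.
* All simulation entry points take explicit seeds, restore the caller's
  RNG state, and derive stage-specific sub-seeds, so whole-pipeline runs
  are bit-reproducible (manifests record config, seeds and file hashes).

# Known limitations

Greedy linking can in principle swap identities if two molecules on the
same tether cross; the simulator places one molecule per tether, and real
curtain analyses handle crossings manually. The pause detector's adaptive
threshold makes pauses undefined for molecules whose overall speed is
statistically indistinguishable from zero (near the 2 bp/s floor) — such
molecules barely pass the 1 kb movement filter only in very long movies.
Survival fitting by least squares on S(t) weights late, low-S points
heavily relative to the MLE; it is kept as the default because it is the
fitting convention this assay family reports.
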
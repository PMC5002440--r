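---
title: "Methods: validating dense extracellular probes with paired juxtacellular recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating dense extracellular probes with paired juxtacellular recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairedval)
```

## The problem

A juxtacellular (loose-patch) pipette sealed against a single neuron records
that cell's spikes at millivolt scale and unambiguous identity. A silicon
polytrode a few tens of micrometres away records the same spikes
extracellularly at microvolt scale, mixed with background units and noise.
Recording both simultaneously turns the juxtacellular train into ground truth
for everything the extracellular side claims to measure: where a cell's
extracellular action potential (EAP) lands on the array, how its amplitude
decays with distance, and whether a detection algorithm finds its spikes.

`pairedval` implements the computations this paradigm needs, end to end:

1. **Co-registration** of the two micromanipulators carrying pipette and
   probe (`tilt_to_reference()`, `fit_affine_correction()`), so the
   pipette-tip-to-probe distance is known to ~10 µm.
2. **Ground-truth analysis**: juxtacellular spike detection
   (`detect_juxta_spikes()`), the juxtacellular-triggered average
   (`compute_jta()`), the peak-to-peak footprint over the shank
   (`p2p_footprint()`, `interpolate_footprint()`), amplitude–distance
   summaries (`amplitude_distance_curve()`) and back-propagation velocity
   (`propagation_velocity()`).
3. **Detection evaluation**: dual-threshold flood-fill event extraction
   (`detect_floodfill()`) scored against the juxtacellular train with PETHs
   (`compute_peth()`) and hit/miss matching (`match_events()`).
4. **A synthetic paired-recording generator** (`generate_pair()`,
   `generate_calibration_scene()`) with known ground truth, so every stage is
   testable without any recorded dataset.

## Manipulator geometry and the affine correction

The reference manipulator (pipette) defines the common frame; the probe
manipulator is a rigid three-axis actuator tilted \(\theta = 48.2^\circ\)
from the horizontal about the Y axis. Its native readings \((x, y, z)\)
rotate into the reference frame as

\[
x' = \cos\theta\, z + \sin\theta\, x,\qquad
y' = y,\qquad
z' = -\sin\theta\, z + \cos\theta\, x .
\]

This matrix is symmetric and orthogonal (an involution, determinant −1), so
it is its own inverse — a convenient property used throughout the tests. The
package stores \(\theta\) as +48.2° and documents that negating \(\theta\)
transposes the rotation; one convention everywhere.

Mechanical alignment leaves residual axis misalignment of tens of
micrometres over a 5-mm working volume. The software correction models it
affinely,

\[
\mathbf{p}_\mathrm{ref} \approx A\,\mathbf{p}_\mathrm{tilt} + \mathbf{b},
\]

fitted by ordinary least squares on paired calibration observations of the
same physical point (a microscope crosshair). Design choices, made once:

* **A translation offset is included.** Zeroing errors behave exactly like
  offsets and a bare linear map cannot absorb them.
* **The fit acts on tilt-transformed coordinates**, not raw axis counts: the
  deterministic rotation is applied first and the affine map removes only
  what is left.
* **Plain least squares, no robust loss.** n is small (~15) and the
  measurement errors are near-Gaussian; residual mean and SD are reported
  with the fit.
* **At least 4 non-coplanar points** are required; rank deficiency raises a
  named error rather than a silent pseudo-inverse.

Calibration positions are a seeded subsample of a 5,000 µm cube in 1,000-µm
steps (`calibration_grid()`), since the point list of any particular session
is not a reproducible quantity; the subsample is drawn until the affine
design has rank 4, which for 15 points essentially always succeeds on the
first draw.

## Filtering

All analyses run on zero-phase band-passed data: third-order Butterworth
applied forward–backward. Bands: 100–14,250 Hz for waveform analysis (the
upper edge is 95% of Nyquist at 30 kHz), 500–14,250 Hz for detection, and
100–5,000 Hz as the alternative for recordings with high-frequency noise.

Numerical choices worth knowing:

* Filter design is delegated to `signal::butter()`; the forward–backward
  pass itself is implemented with **odd-reflection padding** whose length is
  3× the filter length or **fifteen time constants of the slowest pole**,
  whichever is longer. The 100-Hz corner at 30 kHz has a pole radius of
  0.9896 — a ~96-sample time constant — so the conventional 3×-filter-length
  pad leaves percent-scale transients.
* Even with generous padding, a reflect-padded junction transient decays into
  the data with that same time constant; treat the first and last ~5 time
  constants (~500 samples at 30 kHz for the analysis band) of a filtered
  trace as edge-contaminated. Filtering is therefore always applied to whole
  recordings, never to extracted windows.
* Band edges at or above 95% of Nyquist are allowed (they are the reference
  configuration) but the design is checked for finite coefficients and a
  message is emitted.

Noise is quantified per channel as the plain standard deviation
(`estimate_noise_sd()`), because the detection thresholds are defined
against it; a MAD-based robust variant exists behind a flag for
spike-contaminated traces, off by default.

## Juxtacellular ground truth and the JTA

Juxtacellular spikes are the peaks of well-isolated threshold crossings.
"Well isolated" is operationalised as: no second crossing extremum within
±1 ms (both offenders are rejected). The alignment point is the maximum for
positive-first spikes — the typical capacitively coupled cell-attached
waveform — and the minimum for the rare negative-first pairs; polarity is
per-pair metadata, defaulting from a documented list of known
negative-first pair ids.

The JTA is the per-channel mean of ±2 ms extracellular windows centred on
each juxtacellular peak. Events whose window would clip a recording edge are
**excluded and counted**, not zero-padded: exclusion keeps the estimator an
unweighted mean with standard \(\sigma/\sqrt{n}\) convergence, which the
test-suite verifies at n ∈ {10, 100, 400}. The footprint is the per-channel
peak-to-peak amplitude within ±1 ms of the alignment time.

Footprint interpolation over the shank is piecewise-linear on a Delaunay
triangulation, evaluated on a 1-µm grid (configurable). No triangulation
package is part of the package's dependency set, so a small Bowyer–Watson
triangulator is implemented internally; exactly co-circular site layouts
(regular grids) are disambiguated with a deterministic sub-nanometre
perturbation while values remain attached to the true coordinates, keeping
the interpolant exact at sites and linear-precise to ~1e-9 of the field.

Back-propagation velocity between two chosen sites is the inter-site
distance divided by the delay between negative peaks. Peak times are argmin
within the ±1-ms core **refined by 3-point parabolic interpolation**: at
30 kHz a sample is 33 µs, which would otherwise dominate delays of a few
hundred µs. The operation takes explicit site arguments; it does not guess
which sites to compare.

## Flood-fill detection and its evaluation

Detection follows the two-threshold flood-fill scheme: per-channel
deflections beyond 2σ form a weak mask; connected components of that mask —
over temporal sample adjacency and the probe adjacency graph (sites within
30 µm by default, covering nearest neighbours of both supported probes) —
survive only if they contain at least one sample beyond 4.5σ; each
component becomes one event at its largest deflection. Components are
tracked as per-channel *runs* merged with a union–find over adjacent
channels, which the tests verify against a brute-force breadth-first
labelling on small instances. Events with peaks closer than 0.5 ms on
overlapping channel sets are merged. Polarity is negative-only by default
(extracellular somatic spikes deflect negative first); a both-polarities
flag exists.

Evaluation against the juxtacellular train uses 1-ms PETH bins aligned so
one bin is centred at 0 ms, and greedy nearest-neighbour matching within
±0.5 ms (the zero bin's half-width). Greedy matching is deliberately simple;
the suite checks it against an independent re-implementation and bounds it
by the optimal assignment. `hits + misses` always equals the reference
count.

## The synthetic generator

The generator emulates the statistics of the recorded pairs so that every
pipeline stage has computable ground truth:

* **Amplitude–distance decay**: \(A(d) = A_0 e^{-d/\lambda}\) anchored at
  A(50 µm) = 38 µV and A(150 µm) = 5 µV, giving λ ≈ 49.3 µm and
  A₀ ≈ 104.8 µV. The exponential form is a modelling choice (two anchor
  points determine it uniquely and it respects the observation that large
  amplitudes occur only below ~50 µm); tests treat λ as the generator's
  truth, not an empirical claim.
* **Spike trains**: Poisson with a 1-ms absolute refractory period; the
  juxtacellular target fires at ~1 Hz in the default scenes.
* **Waveforms**: Gaussian-lobe templates, peak-to-peak normalised,
  positive-before-negative for the juxtacellular trace (~4 mV p2p),
  negative-before-positive for EAPs, with per-site delays
  \((z_\mathrm{site} - z_\mathrm{soma})/v\) evaluated in continuous time so
  sub-sample propagation (default 0.55 m/s) is represented exactly.
* **Noise**: white Gaussian, 6 µV SD extracellular, 0.05 mV juxtacellular.
  Real recordings have correlated and 1/f components that this does not
  model — passing tests demonstrate correctness of the computations, not
  performance on real tissue.
* **Cross-talk**: an optional common-mode copy of the juxtacellular waveform
  on all channels, constrained below the 5-µV artifact floor that the
  amplitude–distance analysis uses for exclusion.
* **Background units**: placed uniformly in a 200-µm slab in front of the
  probe at 0.5–5 Hz, with counts consistent with cortical densities of
  40,000–60,000 neurons/mm³.
* **Reproducibility**: all randomness flows from one seed through named
  substreams (placement, per-neuron spikes, noise), so identical configs are
  bit-identical and components can be regenerated in isolation.

For calibration scenes, the misalignment generator composes per-axis
rotations of 0.25–0.75° (random sign), ±1% per-axis scale errors and
offsets up to 50 µm. These magnitudes are calibrated so the raw
pre-correction distance error over the 5-mm grid concentrates around the
~75 µm scale observed for mechanically aligned manipulators; with 15 points
and 3 µm per-axis measurement noise the post-fit residual lands near 4 µm,
comfortably inside the ~10.5 µm benchmark.

One measurement subtlety the generator exposes: the max-over-channels
peak-to-peak of an averaged window never falls below the JTA noise level, so
amplitude–distance cohorts show an additive floor of
\(\mathcal{O}(\sigma/\sqrt{n})\) µV at large distances. The suite therefore
recovers λ by fitting \(A e^{-d/\lambda} + c\) with an explicit floor term;
a log-linear fit without it overestimates λ by tens of percent. The same
floor is why distinguishing a ~3 µV cross-talk artifact from 6 µV noise
takes hundreds of averaged events — as it does in real recordings.

## Problem sizes

Scenes used by the test-suite are sized for a single CPU: 4–12 channel
probes, 4–150 s at 30 kHz, with the long scenes reserved for the cross-talk
analyses that genuinely need hundreds of averaged events. The calibration
Monte-Carlo uses 100 seeded replicates of 15-point scenes. All fixtures are
generated in code at run time.

## Electrode sensitivity volume

`expected_neurons_per_site()` implements the closed-form estimate
\(\mathrm{count} = \rho \cdot \tfrac{2}{3}\pi r^3\): neurons within the
half-spherical volume of radius *r* in front of an electrode site, for
density ρ. With ρ = 40,000–60,000 /mm³ and r = 50 µm this gives ≈10.5–15.7
neurons per site — the argument that extracellular electrodes sense a much
smaller volume than often assumed. Half-sphere, not sphere, because tissue
lies on one side of the shank; the unrounded value is always reported
alongside the rounded one.

## File formats

* **Raw binary** (`read_raw()` / `write_raw()`): 16-bit signed little-endian
  integers, channel-interleaved in sample-major order, no header; microvolt
  conversion via a configurable scale (default 0.195 µV/bit, the step of the
  common acquisition chip family — a default, not a constant).
* **Probe geometry CSV**: `site_id, x_um, z_um, area_um2` plus `# name` /
  `# adjacency_radius_um` comment headers. The 32-channel poly3 coordinates
  are a documented package convention (12-site centre column at 25-µm pitch,
  flanks at ±20 µm offset half a pitch) satisfying the probe's printed
  dimensions: 275-µm axial span, 22–25 µm nearest-neighbour pitch, 177 µm²
  sites. Axial coordinate increases with depth, 0 at the top-most site.
* **Calibration CSV**: `pair_index, ref_{x,y,z}_um, mov_{x,y,z}_um,
  theta_deg`; corrections serialise as flat JSON (row-major 3×3 + offset +
  residual stats).
* **Pair metadata CSV**: `pair_id, distance_um, depth_um, juxta_threshold`
  (+ optional `distance_err_um` [default 10.5], `polarity`, `notes`;
  unknown columns fold into `notes`). Per-pair juxtacellular thresholds are
  always explicit inputs, never guessed.

## Known limitations

* The synthetic EAP model is phenomenological (template × exponential decay),
  not biophysical; no compartmental currents, tissue filtering, or electrode
  impedance effects.
* White noise only; detection performance on correlated noise will differ.
* The flood-fill variant is this package's own documented one; it does not
  byte-match any particular historical implementation's alignment or
  deduplication internals.
* Spike sorting (clustering) is out of scope: the pipeline stops at
  detection and its evaluation.
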
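---
title: "Simulating ground-truth extracellular recordings with SpikeForge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating ground-truth extracellular recordings with SpikeForge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpikeForge)
```

# Why simulate extracellular recordings?

Spike sorting — the unsupervised assignment of extracellular spikes to the
neurons that fired them — can only be evaluated against ground truth, and
ground truth is exactly what experimental recordings lack. Paired
juxtacellular/extracellular recordings provide it for one or two cells at a
time; hybrid recordings for a handful of injected units. Simulation is the
only approach that provides exact spike times, waveforms and positions for
*every* unit at once, and, just as importantly, lets the experimenter dial
individual difficulties — bursting, spike collisions, electrode drift,
noise structure — up and down independently while everything else stays
fixed.

SpikeForge is built for that use case: a *testbench*, not just a benchmark.
Its two-phase design separates the expensive part (building a library of
extracellular action potential templates around a probe) from the cheap
part (assembling recordings from that library), so that one library
supports arbitrarily many recordings. Four independent seeds — spike
trains, template selection, noise, convolution — make every recording
exactly reproducible and allow controlled one-factor-at-a-time
experiments: the same spiking activity under four noise levels, the same
units at three drift velocities, and so on.

# Phase 1: the template library

## The forward model

Each neurite segment is treated as a line of uniform current density in an
infinite homogeneous medium of conductivity $\sigma$ (0.3 S/m, the
standard value for cortical tissue). For a segment of length $\Delta s$
carrying current $I(t)$, the potential at an electrode is the line-source
kernel

$$
\phi(t) \;=\; \frac{I(t)}{4 \pi \sigma \Delta s}\,
\ln \frac{\Delta s - x + \sqrt{(\Delta s - x)^2 + r^2}}
         {-x + \sqrt{x^2 + r^2}},
$$

with $x$ the longitudinal and $r$ the perpendicular coordinate of the
electrode in the segment's frame. The kernel is linear in the current, so
an entire cell is a weight matrix (channels × segments) applied to the
current matrix (segments × time). In the far field the log term tends to
$\Delta s / r$ and the kernel converges to the point source
$I / (4\pi\sigma r)$; the test suite checks 1% agreement at 100 segment
lengths. Because cells are placed randomly, a dendrite may pass
arbitrarily close to — or through — an electrode; the perpendicular
distance is clamped at 1 µm to keep the kernel finite. Electrodes are
ideal points: probe-surface effects (method of images) and finite-contact
averaging are out of scope.

## The synthetic cell bank

The library is driven by a bank of 13 parametric "ball-and-stick+" cell
models (10 excitatory, 3 inhibitory): a 20 µm somatic segment, an apical
trunk of five 40 µm segments, and two basal dendrites, with per-model size
jitter drawn deterministically from the bank seed. These models are not
meant to be biophysically detailed; they are designed to preserve exactly
the properties the forward model cares about:

* **Charge conservation.** The somatic segment carries the action
  potential current — a difference of exponentials (depolarization
  $\tau_1 = 0.1$ ms; repolarization $\tau_2 = 0.5$ ms excitatory /
  0.25 ms inhibitory) normalized so its trough equals the model's peak
  current, followed by a shallow rectangular after-hyperpolarization that
  makes the somatic waveform integrate to zero. The negated somatic
  current is distributed over the dendritic segments in proportion to
  membrane area, so the total membrane current is zero at every instant —
  the column sums of every current matrix vanish to rounding.
* **Cell-type asymmetry.** Inhibitory models have narrower spikes
  (trough width 0.3 ms vs 0.6 ms) and, during recording generation,
  higher default firing rates (15 Hz vs 5 Hz).
* **Realistic amplitude scale.** Somatic peak currents are drawn from
  5–10 nA per model — the scale of somatic action currents in large
  cortical cells. This puts template amplitudes in the tens of µV within
  a few tens of µm of the probe, so that the default 30 µV acceptance
  threshold admits somas throughout a realistic volume rather than only
  cells pressed against the probe plane. The after-hyperpolarization
  rectangle is six trough-widths long, which keeps its height near 20% of
  the trough: extracellular spikes stay negative-dominant, matching the
  amplitude definition used everywhere in the package
  (amplitude = $|\min|$ over time, maximum over channels).

What the bank does **not** emulate: detailed morphologies, active
dendrites, ion-channel kinetics, morphology-dependent burst waveform
changes, or probe-conductor effects. Tests passing on this bank show the
*pipeline* is correct (geometry, conservation, decay, selection,
modulation, bookkeeping), not that the waveforms are faithful
reproductions of any particular cell type.

## Placement, acceptance, drift

Each model is repeatedly placed uniformly inside a box (off-plane distance
10–80 µm; in-plane within the probe's bounding box padded by 30 µm) with a
random rotation (full azimuth about the vertical, tilts limited to ±15°),
until the requested number of templates passes the minimum-amplitude test;
generation fails loudly after 1000 × n attempts. A 13-model bank with
`n_per_model = 30` therefore yields 390 templates.

Drifting templates additionally draw a linear trajectory: direction within
±30° of the probe's vertical axis, length uniform in 20–60 µm, end point
re-sampled until inside the placement bounds. The template is recomputed
at each of the (default 30) equally spaced steps with the rotation held
fixed; acceptance is decided at the initial position.

# Phase 2: recording assembly

## Spike trains and synchrony

Trains are homogeneous renewal processes (gamma with shape 2 by default;
Poisson available) with a 2 ms dead time enforced by deletion. Synchrony
between spatially overlapping pairs — pairs where one template's amplitude
on the other's best channel reaches 90% of its own maximum — is
controlled by `sync_rate`:

* unset: trains untouched;
* 0: the later spike of every colliding pair (|Δt| ≤ 1 ms) is deleted,
  re-scanning to a fixed point;
* $s > 0$: collisions are *injected* until the colliding fraction of the
  lower-rate unit's spikes reaches $s$. The colliding events are created
  by **moving** randomly chosen non-colliding spikes of the second unit
  to within half a window of spikes of the first (respecting
  refractoriness), not by inserting new spikes: inserting would inflate
  the unit's firing rate, whereas moving attains the target synchrony
  with no side effect on rates. Using the lower-rate unit's spike count
  as the denominator makes $s = 1$ attainable.

The 1 ms collision window is of the order of a spike trough width; it is a
convention, not a measured constant.

## Bursting modulation

Without bursting, each spike's modulation value is drawn from
$\mathcal{N}(1, 0.05^2)$ — a few percent of physiological amplitude
variability. With bursting, spikes are grouped into burst events:
consecutive inter-spike intervals below 50 ms extend the event, which
closes at 10 spikes or 100 ms (all configurable). Within an event the
$i$-th spike is depressed by

$$
\max\!\left(m_\text{floor},\;
\exp\!\left[-\beta\, n_i \max\!\left(0, 1 - \overline{\text{ISI}}_i /
\text{ISI}_\text{sat}\right)\right]\right),
$$

with $n_i$ the number of prior spikes in the event,
$\overline{\text{ISI}}_i$ the event's mean ISI so far, $\beta = 0.2$,
$\text{ISI}_\text{sat} = 50$ ms and $m_\text{floor} = 0.1$. The exact
functional form is a design choice; its three defining properties —
decreasing in the within-burst spike count, weakening with longer
within-burst intervals, resetting at event boundaries — are what the
tests pin down.

When shape modulation is enabled, the waveform is also stretched about its
trough by the factor $k = 1 + \text{shape\_stretch} \cdot \max(0, 1-m)$,
tying stretch to the same modulation value: deeper depression, wider
spike. Stretching is implemented as cubic-spline resampling of the time
axis; the sample count and the trough index are preserved and edge values
held. Sub-sample jitter uses the same spline machinery: templates are
upsampled 10×, shifted by a random integer number of fine steps, and
decimated; the first jitter version is always the unshifted template.

## Drift playback

Slow drift moves the cell along its trajectory at a constant velocity
(default 5 µm/min), reflecting at both ends; the active drift step is the
nearest trajectory step to the travelled position. Fast drift jumps every
20 s (default) to a step whose max-channel amplitude differs from the
current one by 5–20 µV; if no step qualifies, the step closest to that
band is taken — the band prevents a jump from teleporting the neuron
implausibly far. `slow+fast` adds the fast jump offsets to the slow
baseline index, clipped to the valid range; offsets are defined relative
to the trajectory start (one of two defensible readings of the combined
mode — the choice is recorded here and implemented consistently).

## Convolution and assembly

For every spike the engine picks a jitter version (uniformly), the active
drift step, and the modulation value, then adds the scaled (and possibly
stretched) template into the recording with its trough on the spike
sample; copies at the recording edge are truncated rather than dropped so
ground-truth spike counts are preserved. All per-spike random choices are
drawn *before* the chunked convolution loop, which makes the chunked
result identical — bit for bit — to the unchunked one regardless of chunk
size.

The bundle records, per unit: the spike train, the jittered templates,
soma locations and rotations, signed per-channel voltage peaks (signed
trough values, preserving polarity), and a clean spike trace — the
unmodulated convolution of the train with the max-channel template — plus
timestamps and the complete parameter/seed record.

## Noise models

Four families, all scaled to a per-channel standard deviation equal to
`level`:

1. **Uncorrelated Gaussian** — flat spectrum, diagonal channel covariance.
2. **Distance-correlated Gaussian** — multivariate normal with
   $C_{ij} = \text{level}^2 \exp(-d_{ij}/\lambda)$, $\lambda = 30$ µm; the
   exponential kernel is the simplest monotone choice that is positive
   semi-definite for any geometry. Sampling goes through the Cholesky
   factor, with a one-shot $10^{-9}$ diagonal jitter fallback.
3. **Coloured variants** — either Gaussian model passed through a
   second-order resonant low-pass biquad (centre 300 Hz, Q = 1), mixed
   with a 0.3 fraction of the unfiltered input, then rescaled. One filter
   for all channels, so the spatial correlation structure is untouched.
4. **Far neurons** — biological noise: many (default 300) cells whose
   templates are kept only if their amplitude stays *below* 10 µV,
   convolved with independent 5 Hz Poisson trains, plus a Gaussian floor
   at 0.3 × level, then rescaled. Its amplitude distribution is skewed
   negative — the signature that distinguishes biological from Gaussian
   noise in real recordings.

Optional filtering is zero-phase (forward–backward) Butterworth, order 3,
high-pass or band-pass (default 300–6000 Hz).

# Numerical and interface choices

* **Amplitude definition**: per-channel $|\min|$ over time; max channel by
  argmax with ties to the lowest index. Used identically for acceptance,
  selection rules, overlap classification, drift amplitudes and voltage
  peaks.
* **Overlap threshold comparison** is inclusive (≥), so identical
  templates are classified as overlapping at threshold 1.
* **Seeds** are plain integers; each public generator either takes a seed
  or documents that it uses the current RNG state. `defaultCellBank()`
  restores the caller's RNG state after building the bank, so it can be
  constructed lazily inside other seeded generators without perturbing
  their streams.
* **HDF5 storage** keeps every numeric array as 64-bit floats. Storing
  recordings as 32-bit floats would halve file sizes, but it would break
  the save/load bit-exactness guarantee the ground-truth containers are
  meant to provide; exactness won.
* **Selection** is randomized-greedy with restarts, bounded at 10 000
  candidate draws; failure names the binding constraint (amplitude
  window, distance, or overlap count).
* **Degenerate inputs**: zero-rate trains are valid and empty; zero noise
  level short-circuits to zeros; `n_jitters = 1` means "no jitter";
  single-channel probes reduce the correlated noise model to the
  uncorrelated one.

# Scale of the shipped test suite

The test-suite and acceptance computations run at desk scale, chosen as
the smallest sizes at which each statistical check has comfortable power:
libraries of 2–30 templates per model on a tetrode, recordings of 1–50 s,
spike-train statistics over 120–300 s, noise statistics over 2–3 × 10⁵
samples, 10⁴ modulation draws, 50 far neurons. All fixtures are generated
in code; nothing is shipped pre-computed.

# Known limitations

* Waveform realism is limited by the parametric cell bank (see above).
* The homogeneous-medium line-source model ignores the probe itself;
  dense MEAs in particular amplify recorded potentials in ways only a
  finite-element model captures.
* Bursting modulation is phenomenological; morphology-dependent burst
  dynamics require full compartmental simulation.
* Firing is stationary; no rate drifts, no network correlations beyond
  pairwise synchrony control.
* Fast-drift jumps are instantaneous; real re-adjustments have finite
  settling dynamics.
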
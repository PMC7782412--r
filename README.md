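# SpikeForge

Ground-truth extracellular recording simulation for spike-sorting
development and validation, in R.

## The problem

Spike sorting — recovering single-neuron spike trains from extracellular
voltage traces — is unsupervised: real recordings come with no ground
truth, so sorter accuracy cannot be measured on them directly. SpikeForge
synthesizes multi-electrode-array recordings *together with* the exact
spike times, waveforms and positions of every unit, and gives independent
control over the phenomena that make sorting hard: bursting amplitude and
shape modulation, spatio-temporal spike collisions, slow and fast
electrode drift, and four structurally different noise models.

The simulation is split into two phases:

1. **Template generation.** A bank of 13 parametric cortical cell models
   (10 excitatory, 3 inhibitory) is repeatedly placed and rotated around
   a probe geometry. Each segment of a cell is a line source in a
   homogeneous medium: a segment of length Δs carrying current *I*
   contributes

   φ = I / (4πσΔs) · ln[ (Δs − x + √((Δs−x)² + r²)) / (−x + √(x² + r²)) ]

   at an electrode with longitudinal/perpendicular coordinates (x, r),
   with σ = 0.3 S/m. Per-segment currents conserve charge exactly (the
   dendrites return the somatic action current), and templates whose
   amplitude falls below a threshold (default 30 µV) are rejected. The
   result is a reusable template library, optionally with templates
   recomputed along linear drift trajectories.

2. **Recording generation.** Templates selected by rules (cell-type
   counts, minimum inter-soma distance, amplitude window, required number
   of spatially overlapping pairs at the 90% relative-amplitude rule) are
   convolved with stochastic spike trains. Each spike is scaled by a
   modulation value — 𝒩(1, 0.05²) at baseline, depressed within burst
   events — optionally stretched in shape, jittered by sub-sample shifts,
   and placed at its drift position. Additive noise (uncorrelated or
   distance-correlated Gaussian, coloured variants, or "far neurons"
   biological background) and optional zero-phase Butterworth filtering
   complete the recording. Four independent seeds (spike trains, template
   selection, noise, convolution) make every output exactly reproducible.

Both phases write self-describing HDF5 containers that carry the full
parameter and seed record alongside the data.

## Worked example

A tetrode recording with 4 excitatory and 2 inhibitory units, 30 s at
32 kHz, 10 µV uncorrelated noise:

```r
library(SpikeForge)

probe <- buildProbe("tetrode")
lib <- generateTemplates(defaultCellBank(seed = 0), probe,
                         n_per_model = 30, seed = 0)
lib
#> TemplateLibrary: 390 templates, 4 channels, 225 points
#>   cell types: excitatory (300), inhibitory (90)
#>   probe: tetrode
#>   seed: 0

rec <- assembleRecording(
  lib,
  rules      = selectionRules(n_exc = 4, n_inh = 2),
  noise      = noiseSpec("uncorrelated", level = 10),
  rec_params = recordingParams(duration = 30, st_seed = 0, temp_seed = 1,
                               noise_seed = 2, conv_seed = 3))
rec
#> RecordingBundle: 4 channels x 960000 samples (30 s at 32 kHz)
#>   6 ground-truth units (excitatory, excitatory, excitatory, excitatory, inhibitory, inhibitory)
#>   seeds: st 0, temp 1, noise 2, conv 3

spikeTrains(rec)
#> SpikeTrainSet: 6 units on [0, 30] s
#>   spike counts: 161, 147, 151, 143, 436, 433
#>   cell types:   excitatory, excitatory, excitatory, excitatory, inhibitory, inhibitory
```

The library holds 30 accepted templates per cell model (13 × 30 = 390),
each 225 samples (2 ms before to 5 ms after the trough at 32 kHz). In the
recording, the two inhibitory units fire at roughly three times the
excitatory rate (their default rates are 15 Hz vs 5 Hz), and
`voltagePeaks(rec)` gives each unit's signed trough amplitude on every
electrode, e.g. unit 4 peaks at −86.2 µV on channel 1:

```r
round(voltagePeaks(rec), 1)
#>       [,1]  [,2]  [,3]  [,4]
#> [1,] -18.1 -10.5 -31.5 -14.2
#> [2,] -40.8  -6.2 -49.7  -3.9
#> [3,] -19.0 -37.6 -13.8 -19.9
#> [4,] -86.2 -44.9 -30.7 -23.1
#> [5,] -18.4 -30.6 -22.7 -41.1
#> [6,] -12.8 -15.4 -22.2 -38.4
```

`saveRecording(rec, "rec.h5")` / `loadRecording("rec.h5")` round-trip the
bundle bit-exactly. The same workflow is available from a shell through
the CLI wrapper in `inst/cli/`:

```sh
spikeforge available-probes
spikeforge gen-templates  -prb tetrode -n 30 --seed 0 --out templates.h5
spikeforge gen-recordings -t templates.h5 -ne 4 -ni 2 -d 30 \
    --st-seed 0 --temp-seed 1 --noise-seed 2 --conv-seed 3 --out rec.h5
```

Two runs with identical flags and seeds produce byte-identical files.

## Learning more

The methods vignette
(`vignettes/simulating-extracellular-recordings.Rmd`) documents the
forward model, the synthetic cell bank and its deliberate simplifications,
the bursting, synchrony, drift and noise models, all tunable parameters
with units and defaults, and the package's numerical choices and known
limitations.
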
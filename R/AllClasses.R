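#' @import methods
NULL

#' Probe: a named multi-electrode geometry
#'
#' A `Probe` holds the 3D positions (micrometres) of the recording sites of a
#' multi-electrode array, together with the pair of coordinate axes spanning
#' the electrode plane. Built-in probes are constructed with
#' [buildProbe()]; custom designs are loaded from YAML files with
#' [loadProbeFile()].
#'
#' @slot name identifier of the probe design.
#' @slot positions numeric matrix (n_channels x 3), electrode positions in um.
#' @slot planeAxes integer pair: indices (1-based) of the coordinate axes
#'   spanning the electrode plane. The remaining axis is the distance from
#'   the probe plane.
#' @slot description free-text description.
#'
#' @seealso [buildProbe()], [listAvailableProbes()], [pairwiseDistances()]
#' @export
setClass("Probe",
  representation(
    name = "character",
    positions = "matrix",
    planeAxes = "integer",
    description = "character"
  )
)

setValidity("Probe", function(object) {
  p <- object@positions
  if (!is.numeric(p) || ncol(p) != 3L) {
    return("positions must be a numeric matrix with 3 columns")
  }
  if (nrow(p) < 1L) return("probe must have at least one electrode")
  if (anyNA(p)) return("positions contain missing values")
  if (length(object@planeAxes) != 2L ||
      !all(object@planeAxes %in% 1:3) ||
      object@planeAxes[1] == object@planeAxes[2]) {
    return("planeAxes must be two distinct axis indices in 1:3")
  }
  if (nrow(p) > 1L) {
    d <- stats::dist(p)
    if (min(d) <= 0) return("duplicate electrode positions (min pairwise distance must be > 0)")
  }
  TRUE
})

#' SyntheticCellModel: a parametric neuron used for template generation
#'
#' A segmented "ball-and-stick+" morphology (somatic segment, apical trunk,
#' basal dendrites) together with the parameters of its action-potential
#' current waveform. These models stand in for detailed compartmental
#' simulations: they preserve the properties that matter for the forward
#' model -- a spatially extended, charge-conserving current source
#' distribution with cell-type-dependent spike width.
#'
#' @slot modelId identifier string.
#' @slot cellType `"excitatory"` or `"inhibitory"`.
#' @slot segments numeric matrix (n_segments x 7): columns are start x/y/z,
#'   end x/y/z (um, local coordinates with the soma centre at the origin)
#'   and radius (um).
#' @slot somaIndex row index of the somatic segment.
#' @slot apParams named list: `peak_amp` (nA, trough current of the somatic
#'   action potential), `tau_dep` (ms, depolarization time constant),
#'   `tau_rep` (ms, repolarization time constant), `trough_width` (ms,
#'   width of the after-hyperpolarization lobe; narrow for inhibitory cells).
#'
#' @export
setClass("SyntheticCellModel",
  representation(
    modelId = "character",
    cellType = "character",
    segments = "matrix",
    somaIndex = "integer",
    apParams = "list"
  )
)

setValidity("SyntheticCellModel", function(object) {
  s <- object@segments
  if (!is.numeric(s) || ncol(s) != 7L) {
    return("segments must be a numeric matrix with 7 columns (start xyz, end xyz, radius)")
  }
  if (nrow(s) < 2L) return("a cell model needs at least 2 segments")
  len <- sqrt(rowSums((s[, 4:6, drop = FALSE] - s[, 1:3, drop = FALSE])^2))
  if (any(len <= 0)) return("all segment lengths must be > 0")
  if (any(s[, 7] <= 0)) return("all segment radii must be > 0")
  if (!object@cellType %in% c("excitatory", "inhibitory")) {
    return("cellType must be 'excitatory' or 'inhibitory'")
  }
  if (object@somaIndex < 1L || object@somaIndex > nrow(s)) {
    return("somaIndex out of range")
  }
  need <- c("peak_amp", "tau_dep", "tau_rep", "trough_width")
  if (!all(need %in% names(object@apParams))) {
    return(paste("apParams must contain:", paste(need, collapse = ", ")))
  }
  TRUE
})

#' TemplateLibrary: a bank of extracellular action potential templates
#'
#' Result of the template-generation phase. For non-drifting libraries
#' `templates` has shape (n_templates, n_channels, n_points) and `locations`
#' (n_templates, 3); for drifting libraries the arrays carry an extra drift
#' step axis: (n_templates, n_drift_steps, n_channels, n_points) and
#' (n_templates, n_drift_steps, 3). All waveform values are in microvolts,
#' locations in micrometres, rotations in radians.
#'
#' @slot templates numeric array of templates (uV).
#' @slot locations numeric array of soma locations (um).
#' @slot rotations numeric matrix (n_templates x 3) of applied rotations (rad).
#' @slot celltypes character vector of cell-type labels.
#' @slot info list of generation parameters, including the probe and the seed.
#'
#' @seealso [generateTemplates()], [saveTemplateLibrary()]
#' @export
setClass("TemplateLibrary",
  representation(
    templates = "array",
    locations = "array",
    rotations = "matrix",
    celltypes = "character",
    info = "list"
  )
)

setValidity("TemplateLibrary", function(object) {
  dt <- dim(object@templates)
  drifting <- isTRUE(object@info$drifting)
  if (drifting && length(dt) != 4L) {
    return("drifting templates must have 4 dimensions (templates, steps, channels, points)")
  }
  if (!drifting && length(dt) != 3L) {
    return("templates must have 3 dimensions (templates, channels, points)")
  }
  n <- dt[1]
  dl <- dim(object@locations)
  if (drifting) {
    if (length(dl) != 3L || dl[1] != n || dl[2] != dt[2] || dl[3] != 3L) {
      return("drifting locations must have shape (n_templates, n_drift_steps, 3)")
    }
  } else if (length(dl) != 2L || dl[1] != n || dl[2] != 3L) {
    return("locations must have shape (n_templates, 3)")
  }
  if (nrow(object@rotations) != n || ncol(object@rotations) != 3L) {
    return("rotations must have shape (n_templates, 3)")
  }
  if (length(object@celltypes) != n) {
    return("celltypes length must equal the number of templates")
  }
  TRUE
})

#' SpikeTrainSet: per-unit spike times with cell types and rates
#'
#' Spike times are in seconds, sorted, and confined to `[tStart, tStop]`.
#'
#' @slot trains list of numeric vectors of sorted spike times (s).
#' @slot tStart,tStop recording window (s).
#' @slot celltypes character vector of per-unit cell-type labels.
#' @slot rates numeric vector of nominal firing rates (Hz).
#' @slot seed integer seed used for generation.
#'
#' @seealso [generateSpikeTrainSet()], [applySynchrony()]
#' @export
setClass("SpikeTrainSet",
  representation(
    trains = "list",
    tStart = "numeric",
    tStop = "numeric",
    celltypes = "character",
    rates = "numeric",
    seed = "integer"
  )
)

setValidity("SpikeTrainSet", function(object) {
  if (object@tStop <= object@tStart) return("tStop must be > tStart")
  n <- length(object@trains)
  if (length(object@celltypes) != n || length(object@rates) != n) {
    return("celltypes and rates must have one entry per train")
  }
  for (i in seq_len(n)) {
    tr <- object@trains[[i]]
    if (length(tr) > 0) {
      if (is.unsorted(tr, strictly = TRUE)) {
        return(sprintf("train %d is not strictly increasing", i))
      }
      if (tr[1] < object@tStart || tr[length(tr)] > object@tStop) {
        return(sprintf("train %d has spikes outside [tStart, tStop]", i))
      }
    }
  }
  TRUE
})

#' RecordingBundle: a simulated recording with full ground truth
#'
#' Result of the recording-generation phase: the voltage traces plus
#' everything needed to evaluate a spike sorter against ground truth --
#' the spike trains, the selected (jittered) templates, their locations,
#' rotations and cell types, per-channel voltage peaks, clean per-unit spike
#' traces, timestamps, and the full parameter/seed record.
#'
#' @slot recordings numeric matrix (n_electrodes x n_samples), uV.
#' @slot spiketrains a [SpikeTrainSet-class].
#' @slot templates numeric array (n_neurons, n_jitters, n_electrodes,
#'   n_points), with an extra drift-step axis inserted after the neuron axis
#'   for drifting recordings.
#' @slot templatesCelltypes character vector (n_neurons).
#' @slot templatesLocations numeric array of soma locations.
#' @slot templatesRotations numeric matrix (n_neurons x 3).
#' @slot channelPositions numeric matrix (n_electrodes x 3), um.
#' @slot timestamps numeric vector (n_samples), seconds.
#' @slot voltagePeaks numeric matrix (n_neurons x n_electrodes): signed
#'   trough value of each unit's template on each electrode (uV).
#' @slot spikeTraces numeric matrix (n_neurons x n_samples): clean
#'   convolution of each unit's train with its max-channel template.
#' @slot info list with every generation parameter and all four seeds.
#'
#' @seealso [assembleRecording()], [saveRecording()]
#' @export
setClass("RecordingBundle",
  representation(
    recordings = "matrix",
    spiketrains = "SpikeTrainSet",
    templates = "array",
    templatesCelltypes = "character",
    templatesLocations = "array",
    templatesRotations = "matrix",
    channelPositions = "matrix",
    timestamps = "numeric",
    voltagePeaks = "matrix",
    spikeTraces = "matrix",
    info = "list"
  )
)

setValidity("RecordingBundle", function(object) {
  nch <- nrow(object@recordings)
  ns <- ncol(object@recordings)
  if (length(object@timestamps) != ns) {
    return("timestamps length must equal n_samples")
  }
  nu <- length(object@spiketrains@trains)
  if (length(object@templatesCelltypes) != nu) {
    return("templatesCelltypes must have one entry per neuron")
  }
  if (nrow(object@voltagePeaks) != nu || ncol(object@voltagePeaks) != nch) {
    return("voltagePeaks must have shape (n_neurons, n_electrodes)")
  }
  if (nrow(object@spikeTraces) != nu || ncol(object@spikeTraces) != ns) {
    return("spikeTraces must have shape (n_neurons, n_samples)")
  }
  if (nrow(object@channelPositions) != nch) {
    return("channelPositions must have one row per electrode")
  }
  TRUE
})
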
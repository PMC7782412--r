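#' Forward-model parameters
#'
#' Parameters of the extracellular forward model used during template
#' generation.
#'
#' @param sigma extracellular conductivity (S/m). Homogeneous, isotropic
#'   medium; 0.3 S/m is the standard value for cortical tissue.
#' @param fs sampling rate (Hz) of the generated templates.
#' @param cut_out numeric pair (ms): window kept around the template trough,
#'   `(pre, post)`.
#' @param min_amplitude minimum accepted template amplitude (uV): templates
#'   whose largest per-channel trough is shallower are rejected and the cell
#'   is re-placed. Set to 0 to accept everything (required for the
#'   far-neurons noise model, which needs sub-threshold templates).
#' @param position_bounds either `NULL` (derived from the probe: off-plane
#'   axis in `[10, 80]` um, plane axes within the probe bounding box padded
#'   by 30 um) or a 3x2 matrix of per-axis `(lo, hi)` bounds in um.
#' @param rotation_mode one of `"none"`, `"z-only"` (azimuthal rotation about
#'   the probe's vertical axis only) or `"3d"` (azimuthal rotation plus tilts
#'   of at most `tilt_limit`).
#' @param tilt_limit maximum tilt away from the vertical (radians) in
#'   `"3d"` mode.
#' @return named list of class `"ForwardModelParams"`.
#' @export
forwardModelParams <- function(sigma = 0.3, fs = 32000,
                               cut_out = c(2, 5), min_amplitude = 30,
                               position_bounds = NULL,
                               rotation_mode = c("3d", "z-only", "none"),
                               tilt_limit = 15 * pi / 180) {
  rotation_mode <- match.arg(rotation_mode)
  if (sigma <= 0) stop("sigma must be > 0")
  if (fs <= 0) stop("fs must be > 0")
  if (length(cut_out) != 2L || any(cut_out <= 0)) {
    stop("cut_out must be two positive durations (ms)")
  }
  if (min_amplitude < 0) stop("min_amplitude must be >= 0")
  structure(list(sigma = sigma, fs = fs, cut_out = cut_out,
                 min_amplitude = min_amplitude,
                 position_bounds = position_bounds,
                 rotation_mode = rotation_mode, tilt_limit = tilt_limit),
            class = "ForwardModelParams")
}

#' Template-selection rules
#'
#' Rules applied when drawing the units of a recording from a template
#' library: cell-type composition, a minimum inter-somatic distance, an
#' amplitude window, and a required number of spatially overlapping pairs.
#'
#' @param n_exc,n_inh number of excitatory / inhibitory units.
#' @param min_dist minimum pairwise soma distance (um).
#' @param min_amp,max_amp accepted template amplitude window (uV).
#' @param n_overlapping_pairs minimum number of selected unit pairs that must
#'   be spatially overlapping (see [isSpatiallyOverlapping()]); 0 disables
#'   the constraint.
#' @param overlap_threshold relative-amplitude threshold of the spatial
#'   overlap classifier (fraction of a template's own maximum amplitude).
#' @return named list of class `"SelectionRules"`.
#' @export
selectionRules <- function(n_exc = 4, n_inh = 2, min_dist = 25,
                           min_amp = 0, max_amp = Inf,
                           n_overlapping_pairs = 0,
                           overlap_threshold = 0.9) {
  if (n_exc < 0 || n_inh < 0 || n_exc + n_inh < 1) {
    stop("need at least one unit (n_exc + n_inh >= 1)")
  }
  if (min_dist < 0) stop("min_dist must be >= 0")
  if (overlap_threshold <= 0 || overlap_threshold > 1) {
    stop("overlap_threshold must be in (0, 1]")
  }
  structure(list(n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
                 min_dist = min_dist, min_amp = min_amp, max_amp = max_amp,
                 n_overlapping_pairs = as.integer(n_overlapping_pairs),
                 overlap_threshold = overlap_threshold),
            class = "SelectionRules")
}

#' Waveform modulation parameters
#'
#' Controls the per-spike modulation applied during the convolution:
#' amplitude scaling (always, when mode is not `"none"`), optional shape
#' stretching, and bursting. Without bursting each spike's modulation value
#' is drawn from Normal(1, `mod_sd`^2). With bursting, spikes are grouped
#' into burst events (consecutive inter-spike intervals below
#' `burst_isi_threshold`; an event is closed when it reaches
#' `max_spikes_per_burst` spikes or spans `max_burst_duration`) and the
#' value decays with the number of prior spikes in the event, more steeply
#' for shorter within-burst intervals.
#'
#' @param mode `"none"`, `"amplitude"` or `"amplitude+shape"`.
#' @param mod_sd standard deviation of the baseline modulation values.
#' @param bursting logical: enable burst-dependent amplitude depression.
#' @param max_spikes_per_burst maximum spikes per burst event.
#' @param max_burst_duration maximum span of a burst event (ms).
#' @param burst_isi_threshold ISI (ms) below which consecutive spikes belong
#'   to the same burst event.
#' @param shape_stretch overall amount of shape stretching (unitless;
#'   the per-spike stretch also depends on the modulation value).
#' @param depression_beta decay rate of within-burst amplitude depression.
#' @param isi_sat ISI saturation (ms): burst depression vanishes as the mean
#'   within-burst ISI approaches this value.
#' @param mod_floor lower bound on the burst depression factor, in (0, 1].
#' @return named list of class `"ModulationParams"`.
#' @export
modulationParams <- function(mode = c("amplitude", "amplitude+shape", "none"),
                             mod_sd = 0.05, bursting = FALSE,
                             max_spikes_per_burst = 10,
                             max_burst_duration = 100,
                             burst_isi_threshold = 50,
                             shape_stretch = 30,
                             depression_beta = 0.2, isi_sat = 50,
                             mod_floor = 0.1) {
  mode <- match.arg(mode)
  if (mod_sd < 0) stop("mod_sd must be >= 0")
  if (mod_floor <= 0 || mod_floor > 1) stop("mod_floor must be in (0, 1]")
  if (shape_stretch < 0) stop("shape_stretch must be >= 0")
  structure(list(mode = mode, mod_sd = mod_sd, bursting = bursting,
                 max_spikes_per_burst = as.integer(max_spikes_per_burst),
                 max_burst_duration = max_burst_duration,
                 burst_isi_threshold = burst_isi_threshold,
                 shape_stretch = shape_stretch,
                 depression_beta = depression_beta, isi_sat = isi_sat,
                 mod_floor = mod_floor),
            class = "ModulationParams")
}

#' Drift playback parameters
#'
#' Controls how drifting templates are played back over time. In `"slow"`
#' mode the cell moves along its drift trajectory at a constant velocity,
#' reversing direction at either end. In `"fast"` mode the position jumps
#' abruptly with a fixed period to a drift step whose max-channel amplitude
#' differs from the current one by an amount within `fast_amp_limits`.
#' `"slow+fast"` combines both.
#'
#' @param mode `"slow"`, `"fast"` or `"slow+fast"`.
#' @param velocity slow-drift velocity (um/min).
#' @param fast_period interval between fast drift events (s).
#' @param fast_amp_limits numeric pair (uV): admissible amplitude change of
#'   a fast jump on the current maximum channel.
#' @param enabled logical: drift on/off.
#' @return named list of class `"DriftParams"`.
#' @export
driftParams <- function(mode = c("slow", "fast", "slow+fast"),
                        velocity = 5, fast_period = 20,
                        fast_amp_limits = c(5, 20), enabled = TRUE) {
  mode <- match.arg(mode)
  if (velocity < 0) stop("velocity must be >= 0")
  if (fast_period <= 0) stop("fast_period must be > 0")
  if (length(fast_amp_limits) != 2L || diff(fast_amp_limits) <= 0) {
    stop("fast_amp_limits must be an increasing pair")
  }
  structure(list(mode = mode, velocity = velocity, fast_period = fast_period,
                 fast_amp_limits = fast_amp_limits, enabled = enabled),
            class = "DriftParams")
}

#' Recording parameters
#'
#' Global parameters of the recording-generation phase, including the four
#' random seeds that control, separately, the spike-train generation
#' (`st_seed`), the template selection (`temp_seed`), the noise generation
#' (`noise_seed`), and the convolution process (`conv_seed`). Keeping the
#' streams separate means e.g. two recordings differing only in `noise_seed`
#' share exactly the same underlying spiking activity.
#'
#' @param fs sampling rate (Hz).
#' @param duration recording duration (s).
#' @param n_jitters number of sub-sample-shifted versions of each template
#'   used during convolution.
#' @param upsample_factor temporal upsampling factor used to compute the
#'   jittered versions.
#' @param chunk_duration duration (s) of the chunks the convolution is
#'   computed in; results are identical to an unchunked computation.
#' @param filter `"none"`, `"highpass"` or `"bandpass"`.
#' @param filter_cutoffs cutoff(s) in Hz (one for highpass, two for
#'   bandpass).
#' @param filter_order Butterworth filter order.
#' @param st_seed,temp_seed,noise_seed,conv_seed integer seeds.
#' @return named list of class `"RecordingParams"`.
#' @export
recordingParams <- function(fs = 32000, duration = 10, n_jitters = 10,
                            upsample_factor = 10, chunk_duration = 20,
                            filter = c("none", "highpass", "bandpass"),
                            filter_cutoffs = c(300, 6000), filter_order = 3,
                            st_seed = 0, temp_seed = 1,
                            noise_seed = 2, conv_seed = 3) {
  filter <- match.arg(filter)
  if (fs <= 0) stop("fs must be > 0")
  if (duration <= 0) stop("duration must be > 0")
  if (n_jitters < 1) stop("n_jitters must be >= 1")
  if (chunk_duration <= 0) stop("chunk_duration must be > 0")
  structure(list(fs = fs, duration = duration,
                 n_jitters = as.integer(n_jitters),
                 upsample_factor = as.integer(upsample_factor),
                 chunk_duration = chunk_duration,
                 filter = filter, filter_cutoffs = filter_cutoffs,
                 filter_order = as.integer(filter_order),
                 seeds = list(st_seed = as.integer(st_seed),
                              temp_seed = as.integer(temp_seed),
                              noise_seed = as.integer(noise_seed),
                              conv_seed = as.integer(conv_seed))),
            class = "RecordingParams")
}

#' Synchrony-control parameters
#'
#' @param sync_rate target fraction of the lower-rate unit's spikes that are
#'   spatio-temporal collisions, in `[0, 1]`, or `NULL` to leave the spike
#'   trains untouched. 0 removes all collisions.
#' @param collision_window total collision window (s): two spikes collide
#'   when their times differ by at most `collision_window / 2`... see
#'   Details.
#' @details A pair of spikes of two units is a collision when the absolute
#'   time difference is at most `collision_window`. Injected collisions are
#'   placed within `collision_window / 2` of an existing spike of the other
#'   unit.
#' @return named list of class `"SynchronyParams"`.
#' @export
synchronyParams <- function(sync_rate = NULL, collision_window = 0.001) {
  if (collision_window <= 0) stop("collision_window must be > 0")
  if (!is.null(sync_rate) && (sync_rate < 0 || sync_rate > 1)) {
    stop("sync_rate must be in [0, 1]")
  }
  structure(list(sync_rate = sync_rate, collision_window = collision_window),
            class = "SynchronyParams")
}

#' Spike-train generation parameters
#'
#' Inhibitory cells default to a higher firing rate and excitatory cells to
#' a lower one; both trains are renewal processes with a dead time.
#'
#' @param rate_exc,rate_inh nominal firing rates (Hz).
#' @param process `"gamma"` or `"poisson"`.
#' @param gamma_shape shape parameter of the gamma renewal process.
#' @param refractory absolute refractory period (s); spikes violating it are
#'   deleted.
#' @return named list of class `"SpikeTrainParams"`.
#' @export
spikeTrainParams <- function(rate_exc = 5, rate_inh = 15,
                             process = c("gamma", "poisson"),
                             gamma_shape = 2, refractory = 0.002) {
  process <- match.arg(process)
  if (rate_exc < 0 || rate_inh < 0) stop("rates must be >= 0")
  if (refractory < 0) stop("refractory must be >= 0")
  structure(list(rate_exc = rate_exc, rate_inh = rate_inh, process = process,
                 gamma_shape = gamma_shape, refractory = refractory),
            class = "SpikeTrainParams")
}

#' Noise specification
#'
#' Selects one of the five additive-noise models and its parameters. All
#' models are scaled so that the per-channel sample standard deviation
#' matches `level`.
#'
#' @param model noise model: `"uncorrelated"` (white Gaussian, diagonal
#'   channel covariance), `"distance-correlated"` (multivariate Gaussian
#'   with covariance decaying with inter-electrode distance),
#'   `"colored-uncorrelated"` / `"colored-distance-correlated"` (the same
#'   two with the spectrum shaped by a second-order IIR resonance), or
#'   `"far-neurons"` (background built from many sub-threshold neuron
#'   templates convolved with Poisson spike trains, plus a Gaussian floor).
#' @param level target per-channel standard deviation (uV).
#' @param half_distance_lambda decay length (um) of the exponential
#'   channel-covariance kernel exp(-d / lambda).
#' @param color_peak,color_q centre frequency (Hz) and quality factor of the
#'   colouring resonance.
#' @param color_floor fraction of unfiltered white noise mixed back in after
#'   colouring.
#' @param far_n number of far (sub-threshold) neurons.
#' @param far_amp_threshold maximum accepted amplitude (uV) of a far
#'   neuron's template.
#' @param far_rate firing rate (Hz) of the far neurons.
#' @param far_floor_fraction sd of the added Gaussian floor as a fraction of
#'   `level`.
#' @return named list of class `"NoiseSpec"`.
#' @export
noiseSpec <- function(model = c("uncorrelated", "distance-correlated",
                                "colored-uncorrelated",
                                "colored-distance-correlated", "far-neurons"),
                      level = 10, half_distance_lambda = 30,
                      color_peak = 300, color_q = 1, color_floor = 0.3,
                      far_n = 300, far_amp_threshold = 10, far_rate = 5,
                      far_floor_fraction = 0.3) {
  model <- match.arg(model)
  if (level < 0) stop("level must be >= 0")
  if (far_n < 1) stop("far_n must be >= 1")
  if (far_amp_threshold <= 0 || half_distance_lambda <= 0) {
    stop("thresholds must be > 0")
  }
  structure(list(model = model, level = level,
                 half_distance_lambda = half_distance_lambda,
                 color_peak = color_peak, color_q = color_q,
                 color_floor = color_floor,
                 far_n = as.integer(far_n),
                 far_amp_threshold = far_amp_threshold,
                 far_rate = far_rate,
                 far_floor_fraction = far_floor_fraction),
            class = "NoiseSpec")
}
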
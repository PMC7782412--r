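# Template-library generation: randomized placement with amplitude-based
# rejection sampling, and drifting trajectories.

#' Linear drift trajectory
#'
#' Positions of a drifting soma along the straight line from `initial` to
#' `final`, with `n_steps` equally spaced steps (first row = initial, last
#' row = final).
#'
#' @param initial,final 3D positions (um).
#' @param n_steps number of drift steps (>= 2); 30 by default.
#' @return numeric matrix (n_steps x 3), um.
#' @examples
#' makeDriftTrajectory(c(0, 0, 0), c(0, 0, 29), 30)[1:3, ]
#' @export
makeDriftTrajectory <- function(initial, final, n_steps = 30) {
  if (n_steps < 2) stop("n_steps must be >= 2")
  f <- seq(0, 1, length.out = n_steps)
  out <- outer(f, as.numeric(final) - as.numeric(initial)) +
    matrix(as.numeric(initial), n_steps, 3, byrow = TRUE)
  out
}

# per-channel amplitude = |trough depth|; shared definition used by
# template acceptance, selection rules and the overlap classifier
.channelAmplitudes <- function(template) {
  apply(template, 1, function(v) abs(min(v)))
}

.maxAmplitude <- function(template) max(.channelAmplitudes(template))

# sample a drift direction within an angular tolerance cone around the
# probe's vertical (+z) axis, and a drift distance
.sampleDriftTarget <- function(initial, bounds, angTol = 30 * pi / 180,
                               distRange = c(20, 60), maxTries = 100) {
  for (i in seq_len(maxTries)) {
    theta <- stats::runif(1, 0, angTol)
    phiAz <- stats::runif(1, 0, 2 * pi)
    dir <- c(sin(theta) * cos(phiAz), sin(theta) * sin(phiAz), cos(theta))
    dist <- stats::runif(1, distRange[1], distRange[2])
    final <- initial + dir * dist
    if (all(final >= bounds[, 1] & final <= bounds[, 2])) return(final)
  }
  NULL
}

#' Generate a template library
#'
#' The core of the template-generation phase. For every cell model in the
#' bank, the cell is repeatedly placed at random positions and rotations
#' around the probe and its extracellular action potential computed with
#' the line-source model, until `n_per_model` templates whose maximum
#' amplitude reaches `params$min_amplitude` have been accepted (rejection
#' sampling; an error is raised after `1000 * n_per_model` failed attempts
#' per model). The library therefore holds `n_per_model * length(bank)`
#' templates.
#'
#' With `drifting = TRUE`, each accepted template is computed at all
#' `n_drift_steps` positions of a linear drift trajectory (direction within
#' `drift_ang_tol` of the probe's vertical axis, length uniform in
#' `drift_dist_range`), with the rotation held fixed; acceptance is based
#' on the initial position.
#'
#' @param bank list of [SyntheticCellModel-class], e.g. [defaultCellBank()].
#' @param probe a [Probe-class].
#' @param n_per_model accepted templates per cell model.
#' @param params a [forwardModelParams()] list.
#' @param drifting logical: generate drifting templates.
#' @param n_drift_steps number of drift steps (default 30).
#' @param drift_ang_tol angular tolerance (rad) of the drift direction
#'   around the probe's vertical axis.
#' @param drift_dist_range min/max drift distance (um).
#' @param seed integer seed; the library is bit-reproducible per seed.
#' @return a [TemplateLibrary-class]; `simInfo()` records all parameters
#'   and the seed.
#' @examples
#' lib <- generateTemplates(defaultCellBank(0)[1:2], buildProbe("tetrode"),
#'                          n_per_model = 2, seed = 1)
#' dim(templates(lib))
#' @export
generateTemplates <- function(bank, probe, n_per_model = 30,
                              params = forwardModelParams(),
                              drifting = FALSE, n_drift_steps = 30,
                              drift_ang_tol = 30 * pi / 180,
                              drift_dist_range = c(20, 60),
                              seed = NULL) {
  if (n_per_model < 1) stop("n_per_model must be >= 1")
  force(bank); force(probe); force(params)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  seed <- as.integer(seed)
  set.seed(seed)
  bounds <- params$position_bounds
  if (is.null(bounds)) bounds <- .defaultPositionBounds(probe)
  bounds <- as.matrix(bounds)
  paramsEff <- params
  paramsEff$position_bounds <- bounds

  dt <- 1000 / params$fs
  # generous margin: the global trough may fall as late as the
  # after-hyperpolarization on dendrite-proximal channels
  simDur <- sum(params$cut_out) + 10
  simOnset <- params$cut_out[1] + 1
  nCh <- nChannels(probe)
  nPts <- round(params$cut_out[1] / 1000 * params$fs) +
    round(params$cut_out[2] / 1000 * params$fs) + 1

  nTot <- n_per_model * length(bank)
  if (drifting) {
    tpl <- array(0, c(nTot, n_drift_steps, nCh, nPts))
    loc <- array(0, c(nTot, n_drift_steps, 3))
  } else {
    tpl <- array(0, c(nTot, nCh, nPts))
    loc <- array(0, c(nTot, 3))
  }
  rot <- matrix(0, nTot, 3)
  ct <- character(nTot)

  k <- 0L
  for (m in seq_along(bank)) {
    model <- bank[[m]]
    currents <- simulateTransmembraneCurrents(model, dt, simDur, simOnset)
    accepted <- 0L
    attempts <- 0L
    maxAttempts <- 1000L * n_per_model
    while (accepted < n_per_model) {
      attempts <- attempts + 1L
      if (attempts > maxAttempts) {
        stop(sprintf(
          "could not accept %d templates for model '%s' within %d attempts; min_amplitude = %g uV may be too strict",
          n_per_model, model@modelId, maxAttempts, params$min_amplitude))
      }
      pl <- placeCell(model, probe, paramsEff)
      eap <- computeEAP(pl$segments, currents, probe, params)
      if (params$min_amplitude > 0 && .maxAmplitude(eap) < params$min_amplitude) next
      if (drifting) {
        final <- .sampleDriftTarget(pl$location, bounds, drift_ang_tol,
                                    drift_dist_range)
        if (is.null(final)) next
        traj <- makeDriftTrajectory(pl$location, final, n_drift_steps)
        accepted <- accepted + 1L
        k <- k + 1L
        R <- .rotationMatrix(pl$rotation)
        base <- bank[[m]]@segments
        for (s in seq_len(n_drift_steps)) {
          segs <- base
          segs[, 1:3] <- sweep(base[, 1:3, drop = FALSE] %*% t(R), 2, traj[s, ], `+`)
          segs[, 4:6] <- sweep(base[, 4:6, drop = FALSE] %*% t(R), 2, traj[s, ], `+`)
          tpl[k, s, , ] <- computeEAP(segs, currents, probe, params)
          loc[k, s, ] <- traj[s, ]
        }
        rot[k, ] <- pl$rotation
        ct[k] <- model@cellType
      } else {
        accepted <- accepted + 1L
        k <- k + 1L
        tpl[k, , ] <- eap
        loc[k, ] <- pl$location
        rot[k, ] <- pl$rotation
        ct[k] <- model@cellType
      }
    }
  }

  info <- list(
    probe = probe@name, seed = seed, n_per_model = n_per_model,
    n_models = length(bank), drifting = drifting,
    n_drift_steps = if (drifting) n_drift_steps else NULL,
    drift_ang_tol = if (drifting) drift_ang_tol else NULL,
    drift_dist_range = if (drifting) drift_dist_range else NULL,
    fs = params$fs, sigma = params$sigma, cut_out = params$cut_out,
    min_amplitude = params$min_amplitude,
    rotation_mode = params$rotation_mode,
    position_bounds = bounds,
    channel_positions = probe@positions
  )
  info <- info[!vapply(info, is.null, logical(1))]
  new("TemplateLibrary", templates = tpl, locations = loc, rotations = rot,
      celltypes = ct, info = info)
}
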
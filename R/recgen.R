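# Recording synthesis: template selection, modulated convolution, drift
# playback, assembly with noise, filtering, ground-truth bookkeeping.

#' Per-channel template amplitudes
#'
#' Amplitude of a template on each channel, defined as the absolute trough
#' depth `|min over time|` (extracellular somatic spikes are
#' negative-dominant), and the index of the channel with the largest
#' amplitude (ties resolved to the lowest index).
#'
#' @param template numeric matrix (n_channels x n_points).
#' @return list with `amplitudes` (numeric vector, uV) and `max_channel`
#'   (integer).
#' @export
templateAmplitudes <- function(template) {
  amps <- .channelAmplitudes(template)
  list(amplitudes = amps, max_channel = which.max(amps))
}

#' Spatial-overlap classifier for a template pair
#'
#' Two templates are spatially overlapping when, on the channel where one
#' of them is largest, the other has an amplitude greater than `threshold`
#' times its own maximum amplitude (by default 90%), in either direction.
#'
#' @param tA,tB numeric matrices (n_channels x n_points) of equal shape.
#' @param threshold fraction in (0, 1].
#' @return logical.
#' @export
isSpatiallyOverlapping <- function(tA, tB, threshold = 0.9) {
  stopifnot(all(dim(tA) == dim(tB)))
  aA <- templateAmplitudes(tA)
  aB <- templateAmplitudes(tB)
  (aB$amplitudes[aA$max_channel] >= threshold * max(aB$amplitudes)) ||
    (aA$amplitudes[aB$max_channel] >= threshold * max(aA$amplitudes))
}

# step-1 template of entry i (drifting libraries play back from step 1)
.libTemplate <- function(lib, i) {
  if (isTRUE(lib@info$drifting)) {
    t0 <- lib@templates[i, 1, , ]
  } else {
    t0 <- lib@templates[i, , ]
  }
  matrix(t0, nrow = dim(lib@templates)[length(dim(lib@templates)) - 1])
}

.libLocation <- function(lib, i) {
  if (isTRUE(lib@info$drifting)) lib@locations[i, 1, ] else lib@locations[i, ]
}

#' Select templates for a recording
#'
#' Randomly draws `n_exc` excitatory and `n_inh` inhibitory templates from
#' a library subject to the selection rules: amplitudes within
#' `[min_amp, max_amp]`, pairwise soma distance at least `min_dist`, and at
#' least `n_overlapping_pairs` selected pairs spatially overlapping.
#' Selection is randomized-greedy with restarts (bounded at 10000 draws);
#' deterministic per `temp_seed`.
#'
#' @param library a [TemplateLibrary-class].
#' @param rules a [selectionRules()] list.
#' @param temp_seed integer seed of the template-selection stream.
#' @return integer vector of selected library indices (excitatory first).
#' @export
selectTemplates <- function(library, rules = selectionRules(), temp_seed = 1) {
  set.seed(as.integer(temp_seed))
  amps <- vapply(seq_len(dim(library@templates)[1]),
                 function(i) .maxAmplitude(.libTemplate(library, i)),
                 numeric(1))
  okAmp <- amps >= rules$min_amp & amps <= rules$max_amp
  candE <- which(library@celltypes == "excitatory" & okAmp)
  candI <- which(library@celltypes == "inhibitory" & okAmp)
  if (length(candE) < rules$n_exc || length(candI) < rules$n_inh) {
    stop(sprintf(
      "library has too few candidates within the amplitude window [%g, %g] (excitatory %d/%d, inhibitory %d/%d)",
      rules$min_amp, rules$max_amp, length(candE), rules$n_exc,
      length(candI), rules$n_inh))
  }
  locs <- t(vapply(seq_len(dim(library@templates)[1]),
                   function(i) .libLocation(library, i), numeric(3)))
  nWanted <- rules$n_exc + rules$n_inh
  maxDraws <- 10000L
  draws <- 0L
  lastFail <- "distance"
  while (draws < maxDraws) {
    sel <- integer(0)
    pool <- c(sample(candE), sample(candI))
    wantTypes <- c(rep("excitatory", rules$n_exc), rep("inhibitory", rules$n_inh))
    ok <- TRUE
    for (w in seq_len(nWanted)) {
      found <- FALSE
      for (cand in pool) {
        draws <- draws + 1L
        if (library@celltypes[cand] != wantTypes[w] || cand %in% sel) next
        if (length(sel) > 0) {
          d <- sqrt(colSums((t(locs[sel, , drop = FALSE]) - locs[cand, ])^2))
          if (any(d < rules$min_dist)) next
        }
        sel <- c(sel, cand)
        found <- TRUE
        break
      }
      if (!found) { ok <- FALSE; lastFail <- "distance"; break }
    }
    if (!ok) {
      if (draws >= maxDraws) break
      next
    }
    if (rules$n_overlapping_pairs > 0) {
      nOv <- 0L
      for (a in seq_len(nWanted - 1)) {
        for (b in (a + 1):nWanted) {
          if (isSpatiallyOverlapping(.libTemplate(library, sel[a]),
                                     .libTemplate(library, sel[b]),
                                     rules$overlap_threshold)) {
            nOv <- nOv + 1L
          }
        }
      }
      if (nOv < rules$n_overlapping_pairs) {
        lastFail <- "spatial overlap"
        next
      }
    }
    return(sel)
  }
  stop(sprintf(
    "template selection failed after %d draws; the binding constraint appears to be the %s requirement (min_dist = %g um, n_overlapping_pairs = %d)",
    maxDraws, lastFail, rules$min_dist, rules$n_overlapping_pairs))
}

#' Modulated convolution of one unit
#'
#' Places one (optionally stretched) copy of the unit's template at every
#' spike, aligned so that the trough lands on the spike sample, scaled by
#' the per-spike modulation value. For each spike a jitter version is
#' chosen uniformly, and for drifting units the active drift step is taken
#' from `drift_steps`. Copies extending beyond the recording edge are
#' truncated, not dropped. Uses the current RNG state for jitter choice.
#'
#' @param times spike times (s) within `[0, duration)`.
#' @param jittered numeric array: (n_jitters x n_channels x n_points), or
#'   (n_drift_steps x n_jitters x n_channels x n_points) for drifting
#'   units.
#' @param mod_values per-spike modulation values (length of `times`).
#' @param fs sampling rate (Hz).
#' @param n_samples total number of samples of the recording.
#' @param trough_idx sample index of the template trough (1-based).
#' @param drift_steps optional integer vector: active drift step per spike.
#' @param mod_params a [modulationParams()] list (for shape stretching).
#' @param jitter_pick optional integer vector: jitter version per spike
#'   (drawn uniformly from the current RNG state when `NULL`).
#' @return numeric matrix (n_channels x n_samples).
#' @export
convolveUnit <- function(times, jittered, mod_values, fs, n_samples,
                         trough_idx, drift_steps = NULL,
                         mod_params = modulationParams(),
                         jitter_pick = NULL) {
  drifting <- length(dim(jittered)) == 4L
  nJit <- if (drifting) dim(jittered)[2] else dim(jittered)[1]
  nCh <- if (drifting) dim(jittered)[3] else dim(jittered)[2]
  nPts <- if (drifting) dim(jittered)[4] else dim(jittered)[3]
  out <- matrix(0, nCh, n_samples)
  if (length(times) == 0) return(out)
  stopifnot(length(mod_values) == length(times))
  jitPick <- if (!is.null(jitter_pick)) jitter_pick
             else if (nJit > 1) sample.int(nJit, length(times), replace = TRUE)
             else rep(1L, length(times))
  doStretch <- mod_params$mode == "amplitude+shape"
  for (k in seq_along(times)) {
    s <- round(times[k] * fs) + 1L
    tplM <- if (drifting) {
      matrix(jittered[drift_steps[k], jitPick[k], , ], nCh, nPts)
    } else {
      matrix(jittered[jitPick[k], , ], nCh, nPts)
    }
    m <- mod_values[k]
    if (doStretch && m < 1) {
      tplM <- stretchTemplate(tplM, m, mod_params$shape_stretch)
    }
    if (mod_params$mode != "none") tplM <- m * tplM
    lo <- s - trough_idx + 1L
    hi <- lo + nPts - 1L
    tLo <- max(1L, lo); tHi <- min(n_samples, hi)
    if (tLo > tHi) next
    out[, tLo:tHi] <- out[, tLo:tHi] +
      tplM[, (tLo - lo + 1L):(tHi - lo + 1L), drop = FALSE]
  }
  out
}

#' Zero-phase filter a recording
#'
#' Forward-backward (zero-phase) Butterworth filtering of every channel.
#'
#' @param rec numeric matrix (n_channels x n_samples).
#' @param mode `"highpass"` or `"bandpass"`.
#' @param cutoffs cutoff frequency(ies) in Hz: one for highpass, two for
#'   bandpass (default 300-6000 Hz).
#' @param order filter order (default 3).
#' @param fs sampling rate (Hz).
#' @return filtered matrix, same shape.
#' @export
filterRecording <- function(rec, mode = c("bandpass", "highpass"),
                            cutoffs = c(300, 6000), order = 3, fs = 32000) {
  mode <- match.arg(mode)
  if (any(cutoffs >= fs / 2) || any(cutoffs <= 0)) {
    stop("filter cutoffs must be in (0, fs/2)")
  }
  if (mode == "highpass") {
    flt <- signal::butter(order, cutoffs[1] / (fs / 2), type = "high")
  } else {
    if (length(cutoffs) != 2L || diff(cutoffs) <= 0) {
      stop("bandpass needs two increasing cutoffs")
    }
    flt <- signal::butter(order, cutoffs / (fs / 2), type = "pass")
  }
  out <- rec
  for (ch in seq_len(nrow(rec))) {
    out[ch, ] <- signal::filtfilt(flt, rec[ch, ])
  }
  out
}

#' Assemble a ground-truth recording
#'
#' The full recording-generation phase: selects templates from the library
#' (`temp_seed`), simulates spike trains and applies synchrony control
#' (`st_seed`), computes jittered template versions and per-spike
#' modulation values and runs the modulated convolution (`conv_seed`),
#' adds noise (`noise_seed`), and optionally filters. The convolution is
#' computed in chunks of `rec_params$chunk_duration`; chunking does not
#' change the result. All parameters and the four seeds are recorded in
#' the bundle's `info`.
#'
#' @param library a [TemplateLibrary-class].
#' @param rules a [selectionRules()] list.
#' @param st_params a [spikeTrainParams()] list.
#' @param sync_params a [synchronyParams()] list.
#' @param mod_params a [modulationParams()] list.
#' @param drift a [driftParams()] list (used when the library is drifting
#'   and `drift$enabled`).
#' @param noise a [noiseSpec()] list; `level = 0` gives a noise-free
#'   recording.
#' @param rec_params a [recordingParams()] list.
#' @return a [RecordingBundle-class].
#' @examples
#' \donttest{
#' lib <- generateTemplates(defaultCellBank(0), buildProbe("tetrode"),
#'                          n_per_model = 2, seed = 1)
#' rec <- assembleRecording(lib, selectionRules(2, 1),
#'                          rec_params = recordingParams(duration = 2))
#' }
#' @export
assembleRecording <- function(library,
                              rules = selectionRules(),
                              st_params = spikeTrainParams(),
                              sync_params = synchronyParams(),
                              mod_params = modulationParams(),
                              drift = driftParams(),
                              noise = noiseSpec(),
                              rec_params = recordingParams()) {
  seeds <- rec_params$seeds
  fs <- rec_params$fs
  duration <- rec_params$duration
  nSamples <- round(duration * fs)
  nCh <- dim(library@templates)[length(dim(library@templates)) - 1]
  drifting <- isTRUE(library@info$drifting) && isTRUE(drift$enabled)

  # --- template selection (temp_seed stream) -------------------------------
  sel <- selectTemplates(library, rules, seeds$temp_seed)
  nU <- length(sel)

  # --- spike trains (st_seed stream) ---------------------------------------
  sts <- generateSpikeTrainSet(rules$n_exc, rules$n_inh, duration,
                               st_params, seeds$st_seed)
  # synchrony control acts on the spatially overlapping selected pairs
  ovPairs <- NULL
  if (!is.null(sync_params$sync_rate) && nU > 1) {
    prs <- utils::combn(nU, 2)
    keep <- apply(prs, 2, function(p) {
      isSpatiallyOverlapping(.libTemplate(library, sel[p[1]]),
                             .libTemplate(library, sel[p[2]]),
                             rules$overlap_threshold)
    })
    if (any(keep)) {
      ovPairs <- t(prs[, keep, drop = FALSE])
      sts <- applySynchrony(sts, ovPairs, sync_params, st_params$refractory)
    }
  }

  # --- jittered templates, modulation, convolution (conv_seed stream) ------
  set.seed(seeds$conv_seed)
  troughIdx <- round(library@info$cut_out[1] / 1000 * library@info$fs) + 1L
  nPts <- dim(library@templates)[length(dim(library@templates))]
  nJit <- rec_params$n_jitters
  nSteps <- if (isTRUE(library@info$drifting)) dim(library@templates)[2] else 1L

  if (isTRUE(library@info$drifting)) {
    tplArr <- array(0, c(nU, nSteps, nJit, nCh, nPts))
  } else {
    tplArr <- array(0, c(nU, nJit, nCh, nPts))
  }
  jitList <- vector("list", nU)
  for (u in seq_len(nU)) {
    if (isTRUE(library@info$drifting)) {
      ja <- array(0, c(nSteps, nJit, nCh, nPts))
      for (s in seq_len(nSteps)) {
        ja[s, , , ] <- jitterTemplates(
          matrix(library@templates[sel[u], s, , ], nCh, nPts),
          nJit, rec_params$upsample_factor)
      }
      tplArr[u, , , , ] <- ja
    } else {
      ja <- jitterTemplates(.libTemplate(library, sel[u]), nJit,
                            rec_params$upsample_factor)
      tplArr[u, , , ] <- ja
    }
    jitList[[u]] <- ja
  }

  modList <- lapply(seq_len(nU), function(u) {
    computeModulationValues(sts@trains[[u]], mod_params)
  })

  # per-spike jitter choices are drawn up front so that the result cannot
  # depend on how the convolution is chunked
  jitPickList <- lapply(seq_len(nU), function(u) {
    n <- length(sts@trains[[u]])
    if (nJit > 1) sample.int(nJit, n, replace = TRUE) else rep(1L, n)
  })

  driftList <- vector("list", nU)
  trajSpans <- numeric(nU)
  if (drifting) {
    for (u in seq_len(nU)) {
      trajLoc <- library@locations[sel[u], , ]
      span <- sum(sqrt(rowSums(diff(trajLoc)^2)))
      trajSpans[u] <- span
      trajAmps <- vapply(seq_len(nSteps), function(s) {
        .maxAmplitude(matrix(library@templates[sel[u], s, , ], nCh, nPts))
      }, numeric(1))
      driftList[[u]] <- driftStepAt(sts@trains[[u]], drift, nSteps,
                                    traj_amplitudes = trajAmps,
                                    span_um = span)
    }
  }

  # convolution, chunk by chunk: spikes are binned into chunks and each
  # chunk's contributions are written into the full output array, so the
  # result is identical to an unchunked computation by construction
  clean <- matrix(0, nCh, nSamples)
  chunkStarts <- seq(0, duration, by = rec_params$chunk_duration)
  chunkStarts <- chunkStarts[chunkStarts < duration]
  for (u in seq_len(nU)) {
    tr <- sts@trains[[u]]
    mv <- modList[[u]]
    dsAll <- driftList[[u]]
    for (cs in chunkStarts) {
      ce <- min(cs + rec_params$chunk_duration, duration)
      inChunk <- which(tr >= cs & tr < ce)
      if (length(inChunk) == 0) next
      clean <- clean + convolveUnit(
        tr[inChunk], jitList[[u]], mv[inChunk], fs, nSamples, troughIdx,
        drift_steps = if (drifting) dsAll[inChunk] else NULL,
        mod_params = mod_params,
        jitter_pick = jitPickList[[u]][inChunk])
    }
  }

  # clean per-unit spike traces on the max channel (unmodulated, unjittered)
  spikeTr <- matrix(0, nU, nSamples)
  peaks <- matrix(0, nU, nCh)
  for (u in seq_len(nU)) {
    tpl0 <- .libTemplate(library, sel[u])
    peaks[u, ] <- apply(tpl0, 1, min)          # signed trough values
    maxCh <- templateAmplitudes(tpl0)$max_channel
    wave <- tpl0[maxCh, ]
    for (tk in sts@trains[[u]]) {
      s <- round(tk * fs) + 1L
      lo <- s - troughIdx + 1L
      hi <- lo + nPts - 1L
      tLo <- max(1L, lo); tHi <- min(nSamples, hi)
      if (tLo > tHi) next
      spikeTr[u, tLo:tHi] <- spikeTr[u, tLo:tHi] +
        wave[(tLo - lo + 1L):(tHi - lo + 1L)]
    }
  }

  # --- noise (noise_seed stream) -------------------------------------------
  probe <- new("Probe", name = as.character(library@info$probe),
               positions = .probePositionsFromInfo(library),
               planeAxes = c(2L, 3L), description = "")
  noiseMat <- generateNoise(noise, probe, duration, fs, seeds$noise_seed)
  rec <- clean + noiseMat

  if (rec_params$filter != "none") {
    rec <- filterRecording(rec, rec_params$filter, rec_params$filter_cutoffs,
                           rec_params$filter_order, fs)
  }

  selLoc <- if (isTRUE(library@info$drifting)) {
    library@locations[sel, , , drop = FALSE]
  } else {
    library@locations[sel, , drop = FALSE]
  }

  info <- list(
    fs = fs, duration = duration, n_exc = rules$n_exc, n_inh = rules$n_inh,
    seeds = seeds, selected_indices = sel,
    drifting = drifting,
    probe = library@info$probe,
    cut_out = library@info$cut_out,
    n_jitters = nJit, upsample_factor = rec_params$upsample_factor,
    chunk_duration = rec_params$chunk_duration,
    filter = rec_params$filter,
    filter_cutoffs = rec_params$filter_cutoffs,
    filter_order = rec_params$filter_order,
    st_params = unclass(st_params),
    sync_params = unclass(sync_params),
    mod_params = unclass(mod_params),
    drift_params = unclass(drift),
    noise_spec = unclass(noise),
    overlapping_pairs = ovPairs,
    library_seed = library@info$seed
  )

  new("RecordingBundle",
      recordings = rec,
      spiketrains = sts,
      templates = tplArr,
      templatesCelltypes = library@celltypes[sel],
      templatesLocations = selLoc,
      templatesRotations = library@rotations[sel, , drop = FALSE],
      channelPositions = probe@positions,
      timestamps = seq(0, by = 1 / fs, length.out = nSamples),
      voltagePeaks = peaks,
      spikeTraces = spikeTr,
      info = info)
}

# the probe geometry is carried inside the library info so a recording can
# be assembled without re-building the probe by name
.probePositionsFromInfo <- function(library) {
  if (!is.null(library@info$channel_positions)) {
    return(as.matrix(library@info$channel_positions))
  }
  buildProbe(library@info$probe)@positions
}
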
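# Synthetic cell bank: parametric "ball-and-stick+" models standing in for
# detailed compartmental simulations. Each model is a soma segment, an
# apical trunk of 5 segments and 2 basal dendrites, plus the parameters of
# its somatic action-potential current waveform.

.makeCellModel <- function(modelId, cellType, sizeScale, peakAmp,
                           basalSpread) {
  # local coordinates: soma centre at the origin, apical trunk along +z
  somaHalf <- 10 * sizeScale
  segs <- rbind(
    c(0, 0, -somaHalf, 0, 0, somaHalf, 10 * sizeScale)  # soma
  )
  z <- somaHalf
  apicalLen <- 40 * sizeScale
  for (i in 1:5) {
    segs <- rbind(segs, c(0, 0, z, 0, 0, z + apicalLen, 2))
    z <- z + apicalLen
  }
  for (s in c(-1, 1)) {
    segs <- rbind(segs, c(0, 0, -somaHalf,
                          s * basalSpread, 0, -somaHalf - basalSpread, 1.5))
  }
  troughWidth <- if (cellType == "excitatory") 0.6 else 0.3
  tauRep <- if (cellType == "excitatory") 0.5 else 0.25
  new("SyntheticCellModel",
      modelId = modelId, cellType = cellType, segments = unname(segs),
      somaIndex = 1L,
      apParams = list(peak_amp = peakAmp, tau_dep = 0.1, tau_rep = tauRep,
                      trough_width = troughWidth))
}

#' Default synthetic cell bank
#'
#' Builds the bank of 13 layer-5-like cortical cell models shipped with the
#' package: 10 excitatory and 3 inhibitory. Morphological scale and somatic
#' peak current are drawn per model (deterministically for a given seed) to
#' give the library waveform diversity; inhibitory cells have narrower
#' spikes (smaller trough width and repolarization time constant) than
#' excitatory ones.
#'
#' @param seed integer seed; the bank is deterministic per seed.
#' @return list of 13 [SyntheticCellModel-class] objects.
#' @examples
#' bank <- defaultCellBank(seed = 0)
#' table(vapply(bank, function(m) m@cellType, character(1)))
#' @export
defaultCellBank <- function(seed = 0) {
  # uses its own stream without disturbing the caller's RNG state (the
  # bank is often constructed lazily inside other seeded generators)
  haveOld <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (haveOld) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (haveOld) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  types <- c(rep("excitatory", 10), rep("inhibitory", 3))
  lapply(seq_along(types), function(i) {
    .makeCellModel(
      modelId = sprintf("%s_L5_%02d", substr(types[i], 1, 3), i),
      cellType = types[i],
      sizeScale = stats::runif(1, 0.8, 1.2),
      peakAmp = stats::runif(1, 5, 10),   # nA; somatic action currents
      basalSpread = stats::runif(1, 25, 40)
    )
  })
}

.segmentLengths <- function(segments) {
  sqrt(rowSums((segments[, 4:6, drop = FALSE] - segments[, 1:3, drop = FALSE])^2))
}

.segmentAreas <- function(segments) {
  2 * pi * segments[, 7] * .segmentLengths(segments)
}

#' Simulate transmembrane currents of an action potential
#'
#' Computes the per-segment transmembrane current traces (nA) of one action
#' potential. The somatic segment carries the spike waveform: a difference
#' of exponentials (fast depolarization, slower repolarization), normalized
#' so its trough equals `-peak_amp`, followed by a rectangular
#' after-hyperpolarization lobe scaled so the somatic waveform sums to zero
#' over the simulated window. The negated somatic current is distributed
#' over the remaining segments in proportion to their lateral membrane
#' area, so the total membrane current is zero at every time point (charge
#' conservation).
#'
#' @param model a [SyntheticCellModel-class].
#' @param dt time step (ms).
#' @param duration simulated duration (ms).
#' @param onset time (ms) of spike onset within the window.
#' @return numeric matrix (n_segments x n_t) of currents in nA; the time
#'   axis is `seq(0, duration, by = dt)` and the soma row is
#'   `model@somaIndex`.
#' @export
simulateTransmembraneCurrents <- function(model, dt, duration = 10, onset = 3) {
  if (dt <= 0) stop("dt must be > 0")
  stopifnot(is(model, "SyntheticCellModel"))
  p <- model@apParams
  t <- seq(0, duration, by = dt)
  tt <- t - onset
  w <- ifelse(tt >= 0, -(exp(-tt / p$tau_rep) - exp(-tt / p$tau_dep)), 0)
  # normalize trough to -peak_amp
  w <- w / max(abs(w)) * p$peak_amp
  # shallow rectangular after-hyperpolarization: starts once the main lobe
  # has decayed, 6x the trough width (so its height stays well below the
  # trough and spikes remain negative-dominant extracellularly), height
  # chosen so that sum(w) == 0
  ahpStart <- onset + 6 * p$tau_rep
  ahpIdx <- which(t >= ahpStart & t < ahpStart + 6 * p$trough_width)
  if (length(ahpIdx) == 0) stop("duration too short for the after-hyperpolarization lobe")
  w[ahpIdx] <- w[ahpIdx] - sum(w) / length(ahpIdx)
  nSeg <- nrow(model@segments)
  areas <- .segmentAreas(model@segments)
  frac <- areas[-model@somaIndex] / sum(areas[-model@somaIndex])
  currents <- matrix(0, nSeg, length(t))
  currents[model@somaIndex, ] <- w
  currents[-model@somaIndex, ] <- outer(frac, -w)
  currents
}
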
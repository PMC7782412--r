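# Additive noise models: uncorrelated / distance-correlated Gaussian noise,
# their coloured variants, and a biological "far neurons" background.

#' Uncorrelated Gaussian noise
#'
#' Independent Normal(0, level^2) samples per channel and time point:
#' flat spectrum, diagonal channel covariance, symmetric amplitude
#' distribution.
#'
#' @param level target per-channel standard deviation (uV).
#' @param n_channels,n_samples output shape.
#' @param seed optional integer seed (`NULL` uses the current RNG state).
#' @return numeric matrix (n_channels x n_samples), uV.
#' @export
uncorrelatedGaussian <- function(level, n_channels, n_samples, seed = NULL) {
  if (level < 0) stop("level must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  matrix(stats::rnorm(n_channels * n_samples, 0, level), n_channels, n_samples)
}

# covariance factor for distance-correlated noise; jitters the diagonal
# once if the Cholesky factorization fails numerically
.covFactor <- function(positions, level, lambda) {
  D <- as.matrix(stats::dist(positions))
  C <- level^2 * exp(-D / lambda)
  L <- tryCatch(t(chol(C)), error = function(e) NULL)
  if (is.null(L)) {
    C <- C + diag(1e-9 * level^2, nrow(C))
    L <- t(chol(C))   # errors if still not positive definite
  }
  L
}

#' Distance-correlated Gaussian noise
#'
#' Zero-mean multivariate Gaussian noise with channel covariance
#' `C[i, j] = level^2 * exp(-d[i, j] / lambda)`, where `d` is the
#' inter-electrode distance: nearby channels see correlated noise, distant
#' ones nearly independent noise. Realized through the Cholesky factor of
#' `C`.
#'
#' @param level target per-channel standard deviation (uV).
#' @param positions electrode positions (n_channels x 3, um) or a
#'   [Probe-class].
#' @param lambda covariance decay length (um).
#' @param n_samples number of time points.
#' @param seed optional integer seed.
#' @return numeric matrix (n_channels x n_samples), uV.
#' @export
distanceCorrelatedGaussian <- function(level, positions, lambda = 30,
                                       n_samples, seed = NULL) {
  if (level < 0) stop("level must be >= 0")
  if (lambda <= 0) stop("lambda must be > 0")
  if (is(positions, "Probe")) positions <- positions@positions
  if (!is.null(seed)) set.seed(as.integer(seed))
  nCh <- nrow(positions)
  if (nCh == 1L) return(uncorrelatedGaussian(level, 1L, n_samples))
  L <- .covFactor(positions, level, lambda)
  Z <- matrix(stats::rnorm(nCh * n_samples), nCh, n_samples)
  L %*% Z
}

#' Colour a noise matrix with a second-order IIR resonance
#'
#' Shapes the spectrum of (white) Gaussian noise to resemble extracellular
#' noise, whose power is concentrated at spiking frequencies: each channel
#' is passed through a second-order resonant low-pass IIR filter (centre
#' frequency `peak`, quality factor `q`), a fraction `floor_fraction` of
#' the unfiltered input is mixed back in, and each channel is rescaled to
#' standard deviation `level`. The same filter is applied to every channel,
#' so inter-channel correlation structure of the input is preserved.
#'
#' @param white input noise matrix (n_channels x n_samples).
#' @param fs sampling rate (Hz).
#' @param peak resonance centre frequency (Hz), must be below `fs / 2`.
#' @param q quality factor of the resonance.
#' @param floor_fraction white-noise mixing fraction.
#' @param level target per-channel standard deviation (uV).
#' @return coloured noise matrix, same shape.
#' @export
colorNoise <- function(white, fs, peak = 300, q = 1, floor_fraction = 0.3,
                       level = 10) {
  if (peak >= fs / 2) stop("peak must be below the Nyquist frequency")
  # RBJ resonant low-pass biquad
  w0 <- 2 * pi * peak / fs
  alpha <- sin(w0) / (2 * q)
  b <- c((1 - cos(w0)) / 2, 1 - cos(w0), (1 - cos(w0)) / 2)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  out <- white
  for (ch in seq_len(nrow(white))) {
    x <- white[ch, ]
    y <- as.numeric(signal::filter(b, a, x))
    y <- y / stats::sd(y)
    mix <- y + floor_fraction * (x / stats::sd(x))
    out[ch, ] <- mix / stats::sd(mix) * level
  }
  out
}

#' Sub-threshold templates for the far-neurons noise model
#'
#' Generates the templates of `spec$far_n` distant ("far") neurons:
#' placement and rotation follow the ordinary template-generation
#' procedure with no minimum amplitude, and a template is accepted only if
#' its maximum amplitude is below `spec$far_amp_threshold` (the upper
#' bound keeps all contributors sub-threshold).
#'
#' @param probe a [Probe-class].
#' @param bank cell bank, e.g. [defaultCellBank()].
#' @param spec a [noiseSpec()] list with `model = "far-neurons"`.
#' @param fm a [forwardModelParams()] list (its `min_amplitude` is
#'   ignored).
#' @param seed optional integer seed.
#' @return numeric array (far_n x n_channels x n_points), uV.
#' @export
farNeuronTemplates <- function(probe, bank, spec = noiseSpec("far-neurons"),
                               fm = forwardModelParams(), seed = NULL) {
  force(probe); force(bank); force(spec); force(fm)
  if (!is.null(seed)) set.seed(as.integer(seed))
  dt <- 1000 / fm$fs
  simDur <- sum(fm$cut_out) + 10
  simOnset <- fm$cut_out[1] + 1
  bounds <- fm$position_bounds
  if (is.null(bounds)) bounds <- .defaultPositionBounds(probe)
  fmEff <- fm
  fmEff$position_bounds <- as.matrix(bounds)
  nCh <- nChannels(probe)
  nPts <- round(fm$cut_out[1] / 1000 * fm$fs) +
    round(fm$cut_out[2] / 1000 * fm$fs) + 1
  out <- array(0, c(spec$far_n, nCh, nPts))
  currentsCache <- lapply(bank, simulateTransmembraneCurrents, dt = dt,
                          duration = simDur, onset = simOnset)
  k <- 0L
  maxAttempts <- 1000L * spec$far_n
  attempts <- 0L
  while (k < spec$far_n) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts) {
      stop("could not generate enough sub-threshold far-neuron templates")
    }
    m <- sample.int(length(bank), 1)
    pl <- placeCell(bank[[m]], probe, fmEff)
    eap <- computeEAP(pl$segments, currentsCache[[m]], probe, fmEff)
    if (.maxAmplitude(eap) >= spec$far_amp_threshold) next
    k <- k + 1L
    out[k, , ] <- eap
  }
  out
}

#' Far-neurons noise
#'
#' Biological background noise built from the activity of many distant
#' neurons: each sub-threshold template (see [farNeuronTemplates()]) is
#' convolved with an independent homogeneous Poisson spike train, the
#' contributions are summed, a Gaussian noise floor with standard
#' deviation `far_floor_fraction * level` is added, and each channel is
#' rescaled to standard deviation `level`. Unlike the Gaussian models, the
#' amplitude distribution is skewed towards negative values by the
#' spikes' negative troughs.
#'
#' @param probe a [Probe-class].
#' @param bank cell bank, e.g. [defaultCellBank()].
#' @param spec a [noiseSpec()] list with `model = "far-neurons"`.
#' @param duration duration (s).
#' @param fs sampling rate (Hz).
#' @param seed optional integer seed.
#' @param fm a [forwardModelParams()] list for the far templates.
#' @param return_templates logical: also return the accepted templates.
#' @return numeric matrix (n_channels x n_samples), or, with
#'   `return_templates = TRUE`, a list with `noise` and `templates`.
#' @export
farNeuronsNoise <- function(probe, bank, spec = noiseSpec("far-neurons"),
                            duration, fs = 32000, seed = NULL,
                            fm = forwardModelParams(fs = fs),
                            return_templates = FALSE) {
  force(probe); force(bank); force(spec); force(fm)
  if (!is.null(seed)) set.seed(as.integer(seed))
  tpls <- farNeuronTemplates(probe, bank, spec, fm)
  nCh <- dim(tpls)[2]; nPts <- dim(tpls)[3]
  nSamples <- round(duration * fs)
  troughIdx <- round(fm$cut_out[1] / 1000 * fm$fs) + 1L
  acc <- matrix(0, nCh, nSamples)
  for (i in seq_len(spec$far_n)) {
    train <- generateSpikeTrain(spec$far_rate, 0, duration,
                                process = "poisson", refractory = 0.002)
    if (length(train) == 0) next
    acc <- acc + convolveUnit(train, array(tpls[i, , ], c(1, nCh, nPts)),
                              rep(1, length(train)), fs, nSamples, troughIdx,
                              mod_params = modulationParams("none"))
  }
  floorSd <- spec$far_floor_fraction * spec$level
  acc <- acc + matrix(stats::rnorm(nCh * nSamples, 0, floorSd), nCh, nSamples)
  for (ch in seq_len(nCh)) {
    s <- stats::sd(acc[ch, ])
    if (s > 0) acc[ch, ] <- acc[ch, ] / s * spec$level
  }
  if (return_templates) list(noise = acc, templates = tpls) else acc
}

#' Generate noise for a recording
#'
#' Dispatches on `spec$model` to the matching generator, at the recording's
#' shape. `level = 0` returns zeros.
#'
#' @param spec a [noiseSpec()] list.
#' @param probe a [Probe-class].
#' @param duration duration (s).
#' @param fs sampling rate (Hz).
#' @param seed integer seed of the noise stream.
#' @param bank cell bank for the far-neurons model.
#' @return numeric matrix (n_channels x n_samples), uV.
#' @export
generateNoise <- function(spec, probe, duration, fs, seed = NULL,
                          bank = NULL) {
  force(spec); force(probe)
  nCh <- nChannels(probe)
  nSamples <- round(duration * fs)
  if (spec$level == 0) return(matrix(0, nCh, nSamples))
  if (!is.null(seed)) set.seed(as.integer(seed))
  white <- switch(spec$model,
    "uncorrelated" = ,
    "colored-uncorrelated" = uncorrelatedGaussian(spec$level, nCh, nSamples),
    "distance-correlated" = ,
    "colored-distance-correlated" =
      distanceCorrelatedGaussian(spec$level, probe@positions,
                                 spec$half_distance_lambda, nSamples),
    "far-neurons" = {
      if (is.null(bank)) bank <- defaultCellBank(seed = 0)
      return(farNeuronsNoise(probe, bank, spec, duration, fs,
                             fm = forwardModelParams(fs = fs,
                                                     min_amplitude = 0)))
    })
  if (spec$model %in% c("colored-uncorrelated", "colored-distance-correlated")) {
    white <- colorNoise(white, fs, spec$color_peak, spec$color_q,
                        spec$color_floor, spec$level)
  }
  white
}
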
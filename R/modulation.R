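# Per-spike waveform modulation: baseline Gaussian variability, bursting
# amplitude depression, shape stretching, and sub-sample jittering.

#' Compute per-spike modulation values
#'
#' One value per spike. The baseline value is drawn from
#' Normal(1, `mod_sd`^2), adding physiological variability to the inserted
#' waveforms. With `bursting = TRUE`, spikes are grouped into burst events:
#' consecutive ISIs below `burst_isi_threshold` extend the current event,
#' which is closed when it reaches `max_spikes_per_burst` spikes or spans
#' `max_burst_duration`. Within an event the i-th spike's value is
#' depressed by
#' `max(mod_floor, exp(-depression_beta * n_i * max(0, 1 - meanISI_i / isi_sat)))`
#' where `n_i` counts prior spikes in the event and `meanISI_i` is the mean
#' ISI of the event so far: depression deepens with the number of
#' consecutive spikes, weakens for longer within-burst intervals, and
#' resets at event boundaries.
#'
#' @param times sorted spike times (s).
#' @param params a [modulationParams()] list.
#' @param seed optional integer seed (`NULL` uses the current RNG state).
#' @return numeric vector of modulation values, one per spike.
#' @examples
#' v <- computeModulationValues(seq(0, 0.29, by = 0.01),
#'        modulationParams(bursting = TRUE, mod_sd = 0,
#'                         max_spikes_per_burst = 5))
#' @export
computeModulationValues <- function(times, params = modulationParams(),
                                    seed = NULL) {
  if (is.unsorted(times)) stop("spike times must be sorted")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(times)
  q <- stats::rnorm(n, 1, params$mod_sd)
  if (!isTRUE(params$bursting) || n == 0) return(q)

  isiThr <- params$burst_isi_threshold / 1000   # ms -> s
  maxDur <- params$max_burst_duration / 1000
  isiSat <- params$isi_sat / 1000
  vals <- numeric(n)
  evStart <- 1L
  for (i in seq_len(n)) {
    newEvent <- i == 1L ||
      (times[i] - times[i - 1]) >= isiThr ||
      (i - evStart) >= params$max_spikes_per_burst ||
      (times[i] - times[evStart]) >= maxDur
    if (newEvent) evStart <- i
    nPrior <- i - evStart
    if (nPrior == 0) {
      vals[i] <- q[i]
    } else {
      meanIsi <- (times[i] - times[evStart]) / nPrior
      dep <- exp(-params$depression_beta * nPrior *
                   max(0, 1 - meanIsi / isiSat))
      vals[i] <- q[i] * max(params$mod_floor, dep)
    }
  }
  vals
}

#' Stretch a template's time axis
#'
#' Rescales the time axis about the trough by a factor
#' `k = 1 + shape_stretch * max(0, 1 - m)`: spikes with modulation values
#' below 1 (e.g. within a burst) become wider, and the lower the value the
#' wider the waveform. Resampling is done channel-wise by cubic spline
#' evaluation at the contracted time grid; the output has the same number
#' of samples (edge values held) and the trough sample index is unchanged.
#'
#' @param template numeric matrix (n_channels x n_points).
#' @param m modulation value (> 0).
#' @param shape_stretch overall stretch amount (>= 0).
#' @return stretched template, same shape.
#' @export
stretchTemplate <- function(template, m, shape_stretch = 30) {
  if (m <= 0) stop("modulation value must be > 0")
  k <- 1 + shape_stretch * max(0, 1 - m)
  if (k == 1) return(template)
  nPts <- ncol(template)
  troughIdx <- which(template == min(template), arr.ind = TRUE)[1, 2]
  query <- troughIdx + (seq_len(nPts) - troughIdx) / k
  query <- pmin(pmax(query, 1), nPts)
  out <- template
  for (ch in seq_len(nrow(template))) {
    out[ch, ] <- stats::spline(seq_len(nPts), template[ch, ],
                               xout = query, method = "natural")$y
  }
  out
}

#' Jittered versions of a template
#'
#' Produces `n_jitters` copies of the template shifted by random fractions
#' of a sample (computed by temporal upsampling, integer sub-sample shifts,
#' and decimation). The first version is the unshifted template. Jittering
#' reproduces the fact that real spikes are not locked to the sampling
#' grid. Uses the current RNG state.
#'
#' @param template numeric matrix (n_channels x n_points).
#' @param n_jitters number of versions (>= 1).
#' @param upsample_factor temporal upsampling factor.
#' @return numeric array (n_jitters x n_channels x n_points).
#' @export
jitterTemplates <- function(template, n_jitters = 10, upsample_factor = 10) {
  if (n_jitters < 1) stop("n_jitters must be >= 1")
  nCh <- nrow(template); nPts <- ncol(template)
  out <- array(0, c(n_jitters, nCh, nPts))
  out[1, , ] <- template
  if (n_jitters == 1) return(out)
  u <- as.integer(upsample_factor)
  # cubic-spline upsampling on a u-times finer grid; edges held
  fine <- seq(1, nPts, by = 1 / u)
  up <- t(vapply(seq_len(nCh), function(ch) {
    stats::spline(seq_len(nPts), template[ch, ], xout = fine,
                  method = "natural")$y
  }, numeric(length(fine))))
  shifts <- sample(setdiff(seq(-floor(u / 2), floor(u / 2)), 0),
                   n_jitters - 1, replace = TRUE)
  for (j in 2:n_jitters) {
    idx <- seq(1, by = u, length.out = nPts) + shifts[j - 1]
    idx <- pmin(pmax(idx, 1), ncol(up))
    out[j, , ] <- up[, idx, drop = FALSE]
  }
  out
}
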
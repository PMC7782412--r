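# Drift playback: mapping recording time onto drift-step indices.

# triangle wave: distance p folded into [0, span] with reflection
.reflect <- function(p, span) {
  if (span <= 0) return(rep(0, length(p)))
  m <- p %% (2 * span)
  ifelse(m > span, 2 * span - m, m)
}

#' Drift step index at a given time
#'
#' Maps recording times onto drift-step indices (1-based; step 1 is the
#' initial position):
#'
#' * `"slow"`: the cell travels along the trajectory at `velocity`
#'   (um/min), reflecting at both ends; the active step is the nearest
#'   trajectory step to the travelled position.
#' * `"fast"`: the step is piecewise constant and jumps every
#'   `fast_period` seconds to a step (chosen uniformly) whose max-channel
#'   amplitude differs from the current one by an amount within
#'   `fast_amp_limits`; if no step qualifies, the step whose amplitude
#'   difference is closest to the admissible band is taken.
#' * `"slow+fast"`: the fast jump offsets are added to the slow baseline
#'   index, clipped to the valid range.
#'
#' The fast-jump sequence is drawn from the current RNG state (or from
#' `seed`), so a fixed seed gives a reproducible drift path.
#'
#' @param t numeric vector of times (s), >= 0.
#' @param drift a [driftParams()] list.
#' @param n_drift_steps number of steps of the drifting template.
#' @param traj_amplitudes numeric vector (length `n_drift_steps`):
#'   max-channel amplitude of the template at each step (used by fast
#'   drift). May be `NULL` for pure slow drift.
#' @param span_um total trajectory length (um), used by slow drift.
#' @param seed optional integer seed for the fast-jump sequence.
#' @return integer vector of step indices in `1:n_drift_steps`.
#' @examples
#' driftStepAt(c(0, 60), driftParams("slow", velocity = 5), 30, span_um = 29)
#' @export
driftStepAt <- function(t, drift, n_drift_steps, traj_amplitudes = NULL,
                        span_um = NULL, seed = NULL) {
  if (any(t < 0)) stop("t must be >= 0")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- n_drift_steps
  stepOfSlow <- function(t) {
    if (is.null(span_um)) stop("span_um is required for slow drift")
    stepLen <- span_um / (n - 1)
    p <- drift$velocity / 60 * t             # um travelled
    pos <- .reflect(p, span_um)
    as.integer(round(pos / stepLen)) + 1L
  }
  fastOffsets <- function(maxT) {
    # jump times: fast_period, 2*fast_period, ... ; returns the step chosen
    # at each jump (absolute for "fast", relative offsets for "slow+fast")
    jumps <- seq(drift$fast_period, maxT, by = drift$fast_period)
    if (length(jumps) == 0) return(list(times = numeric(0), steps = integer(0)))
    if (is.null(traj_amplitudes)) stop("traj_amplitudes is required for fast drift")
    cur <- 1L
    steps <- integer(length(jumps))
    for (k in seq_along(jumps)) {
      dAmp <- abs(traj_amplitudes - traj_amplitudes[cur])
      ok <- which(dAmp >= drift$fast_amp_limits[1] &
                    dAmp <= drift$fast_amp_limits[2])
      ok <- setdiff(ok, cur)
      if (length(ok) > 0) {
        cur <- ok[sample.int(length(ok), 1)]
      } else {
        # nearest-difference fallback: step whose amplitude difference is
        # closest to the admissible band
        cand <- setdiff(seq_len(n), cur)
        distBand <- pmax(drift$fast_amp_limits[1] - dAmp[cand], 0) +
          pmax(dAmp[cand] - drift$fast_amp_limits[2], 0)
        cur <- cand[which.min(distBand)]
      }
      steps[k] <- cur
    }
    list(times = jumps, steps = steps)
  }
  if (drift$mode == "slow") {
    return(stepOfSlow(t))
  }
  jp <- fastOffsets(max(t))
  atJump <- findInterval(t, jp$times)          # 0 before the first jump
  if (drift$mode == "fast") {
    out <- ifelse(atJump == 0, 1L, jp$steps[pmax(atJump, 1L)])
    return(as.integer(out))
  }
  # slow+fast: fast jumps displace the slow baseline
  base <- stepOfSlow(t)
  offs <- c(0L, jp$steps - 1L)                 # offset relative to step 1
  out <- base + offs[atJump + 1L]
  as.integer(pmin(pmax(out, 1L), n))
}
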
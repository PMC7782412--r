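# Stochastic spike trains (renewal processes with a dead time) and
# spatio-temporal synchrony editing.

#' Generate one spike train
#'
#' Homogeneous renewal process (`"poisson"`: exponential inter-spike
#' intervals; `"gamma"`: gamma ISIs with the given shape and mean `1/rate`)
#' on `[t_start, t_stop]`. Spikes violating the refractory period are
#' deleted. Uses the current RNG state.
#'
#' @param rate firing rate (Hz); 0 gives an empty train.
#' @param t_start,t_stop window (s).
#' @param process `"poisson"` or `"gamma"`.
#' @param gamma_shape shape of the gamma renewal process.
#' @param refractory dead time (s).
#' @return sorted numeric vector of spike times (s).
#' @export
generateSpikeTrain <- function(rate, t_start = 0, t_stop, process = "poisson",
                               gamma_shape = 2, refractory = 0.002) {
  if (rate < 0) stop("rate must be >= 0")
  if (t_stop <= t_start) stop("t_stop must be > t_start")
  if (rate == 0) return(numeric(0))
  span <- t_stop - t_start
  # draw ISIs in blocks until the window is covered
  nGuess <- max(10, ceiling(rate * span * 1.5 + 4 * sqrt(rate * span)))
  drawIsi <- function(n) {
    if (process == "poisson") stats::rexp(n, rate)
    else stats::rgamma(n, shape = gamma_shape, rate = rate * gamma_shape)
  }
  isis <- drawIsi(nGuess)
  while (sum(isis) < span) isis <- c(isis, drawIsi(nGuess))
  times <- t_start + cumsum(isis)
  times <- times[times <= t_stop]
  .enforceRefractory(times, refractory)
}

# delete spikes closer than the refractory period to the previous kept one
.enforceRefractory <- function(times, refractory) {
  if (length(times) < 2 || refractory <= 0) return(times)
  keep <- logical(length(times))
  keep[1] <- TRUE
  last <- times[1]
  for (i in 2:length(times)) {
    if (times[i] - last >= refractory) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Generate a set of spike trains
#'
#' One train per unit: `n_exc` excitatory units at `rate_exc` and `n_inh`
#' inhibitory units at `rate_inh` (inhibitory cells fire faster by
#' default). Deterministic per seed.
#'
#' @param n_exc,n_inh unit counts (at least one unit in total).
#' @param duration recording duration (s).
#' @param params a [spikeTrainParams()] list.
#' @param seed integer seed.
#' @return a [SpikeTrainSet-class].
#' @examples
#' sts <- generateSpikeTrainSet(4, 2, duration = 10, seed = 0)
#' lengths(trains(sts))
#' @export
generateSpikeTrainSet <- function(n_exc, n_inh, duration,
                                  params = spikeTrainParams(), seed = 0) {
  if (n_exc + n_inh < 1) stop("need at least one unit")
  force(params)
  seed <- as.integer(seed)
  set.seed(seed)
  types <- c(rep("excitatory", n_exc), rep("inhibitory", n_inh))
  rates <- ifelse(types == "excitatory", params$rate_exc, params$rate_inh)
  tr <- lapply(rates, function(r) {
    generateSpikeTrain(r, 0, duration, params$process, params$gamma_shape,
                       params$refractory)
  })
  new("SpikeTrainSet", trains = tr, tStart = 0, tStop = duration,
      celltypes = types, rates = rates, seed = seed)
}

#' Find spatio-temporal collisions between two spike trains
#'
#' All index pairs `(i, j)` with `|a[i] - b[j]| <= window`. A spike may
#' participate in several pairs.
#'
#' @param a,b sorted spike-time vectors (s).
#' @param window collision window (s).
#' @return integer matrix with columns `i` (index into `a`) and `j`
#'   (index into `b`); zero rows when there are no collisions.
#' @export
findCollisions <- function(a, b, window = 0.001) {
  if (length(a) == 0 || length(b) == 0) {
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  }
  lo <- findInterval(a - window, b) + 1L        # first j with b[j] >= a[i] - window
  hi <- findInterval(a + window, b)             # last  j with b[j] <= a[i] + window
  n <- pmax(hi - lo + 1L, 0L)
  i <- rep.int(seq_along(a), n)
  j <- unlist(lapply(which(n > 0L), function(k) lo[k]:hi[k]), use.names = FALSE)
  out <- cbind(i = i, j = as.integer(j))
  out
}

# delete the later spike of every colliding pair, re-scan to fixpoint
.removeCollisions <- function(ta, tb, window) {
  repeat {
    cl <- findCollisions(ta, tb, window)
    if (nrow(cl) == 0) break
    dropA <- integer(0); dropB <- integer(0)
    for (r in seq_len(nrow(cl))) {
      i <- cl[r, 1]; j <- cl[r, 2]
      if (ta[i] >= tb[j]) dropA <- c(dropA, i) else dropB <- c(dropB, j)
    }
    if (length(dropA)) ta <- ta[-unique(dropA)]
    if (length(dropB)) tb <- tb[-unique(dropB)]
  }
  list(a = ta, b = tb)
}

# move non-colliding spikes of tb next to randomly chosen spikes of ta until
# the collision count reaches `target`; spikes are moved, not created, so
# per-unit spike counts are conserved
.injectCollisions <- function(ta, tb, window, target, refractory,
                              tStart, tStop, maxTries = 2000) {
  countCollisions <- function(a, b) nrow(findCollisions(a, b, window))
  tries <- 0
  while (countCollisions(ta, tb) < target && tries < maxTries) {
    tries <- tries + 1
    cl <- findCollisions(ta, tb, window)
    freeB <- setdiff(seq_along(tb), unique(cl[, 2]))
    if (length(freeB) == 0) break
    mv <- freeB[sample.int(length(freeB), 1)]
    anchor <- ta[sample.int(length(ta), 1)]
    cand <- anchor + stats::runif(1, -window / 2, window / 2)
    if (cand < tStart || cand > tStop) next
    nb <- sort(tb[-mv])
    pos <- findInterval(cand, nb)
    okBefore <- pos == 0 || cand - nb[pos] >= refractory
    okAfter <- pos == length(nb) || nb[pos + 1] - cand >= refractory
    if (!okBefore || !okAfter) next
    tb <- sort(c(nb, cand))
  }
  tb
}

#' Control the spatio-temporal synchrony of overlapping unit pairs
#'
#' For each pair of spatially overlapping units, adjusts the rate of
#' spatio-temporal collisions (spike pairs within the collision window):
#'
#' * `sync_rate = NULL` (unset): the spike trains are returned untouched.
#' * `sync_rate = 0`: collisions are removed — the later spike of every
#'   colliding pair is deleted, re-scanning until no collisions remain.
#' * `sync_rate = s > 0`: collisions are injected without removals until,
#'   for each pair, the fraction of colliding events relative to the spike
#'   count of the pair's lower-rate unit reaches `s`. Injection moves
#'   randomly chosen non-colliding spikes of the pair's second unit to
#'   within half a collision window of randomly chosen spikes of the first,
#'   respecting the refractory period, so per-unit spike counts are
#'   conserved.
#'
#' @param set a [SpikeTrainSet-class].
#' @param overlapping_pairs integer matrix (or 2-vector) of unit-index
#'   pairs considered spatially overlapping.
#' @param params a [synchronyParams()] list.
#' @param refractory refractory period (s) respected by injected spikes.
#' @param seed optional integer seed (`NULL` uses the current RNG state).
#' @return a [SpikeTrainSet-class] with edited trains.
#' @export
applySynchrony <- function(set, overlapping_pairs,
                           params = synchronyParams(), refractory = 0.002,
                           seed = NULL) {
  s <- params$sync_rate
  if (is.null(s)) return(set)
  if (s < 0 || s > 1) stop("sync_rate must be in [0, 1]")
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(dim(overlapping_pairs))) {
    overlapping_pairs <- matrix(overlapping_pairs, ncol = 2)
  }
  tr <- set@trains
  w <- params$collision_window
  for (r in seq_len(nrow(overlapping_pairs))) {
    u1 <- overlapping_pairs[r, 1]; u2 <- overlapping_pairs[r, 2]
    if (u1 < 1 || u2 < 1 || u1 > length(tr) || u2 > length(tr)) {
      stop("overlapping pair indexes a unit outside the set")
    }
    if (s == 0) {
      res <- .removeCollisions(tr[[u1]], tr[[u2]], w)
      tr[[u1]] <- res$a; tr[[u2]] <- res$b
    } else {
      nLow <- min(length(tr[[u1]]), length(tr[[u2]]))
      target <- round(s * nLow)
      tr[[u2]] <- .injectCollisions(tr[[u1]], tr[[u2]], w, target,
                                    refractory, set@tStart, set@tStop)
    }
  }
  methods::initialize(set, trains = tr)
}
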
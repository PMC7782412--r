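# Line-source forward model: each neurite segment is a uniform line of
# current in a homogeneous, isotropic conductive medium.

# geometry factor of the line-source kernel: potential in uV per nA of
# current, for one segment (start a, end b, um) at one point (um).
# Derivation: phi(p) = I / (4 pi sigma L) * integral_0^L ds / |p - a - u s|
#           = I / (4 pi sigma L) * ln( (L - x + sqrt((L-x)^2 + r^2)) /
#                                      (  - x + sqrt(x^2     + r^2)) )
# with x the longitudinal and r the perpendicular coordinate of p in the
# segment frame. r is clamped to >= 1 um to avoid the singularity when a
# dendrite passes arbitrarily close to an electrode.
.lineSourceWeight <- function(a, b, points, sigma, rClamp = 1) {
  d <- b - a
  L <- sqrt(sum(d^2))
  u <- d / L
  rel <- sweep(points, 2, a)
  x <- as.numeric(rel %*% u)
  perp2 <- pmax(rowSums(rel^2) - x^2, 0)
  r <- pmax(sqrt(perp2), rClamp)
  num <- (L - x) + sqrt((L - x)^2 + r^2)
  den <- (-x) + sqrt(x^2 + r^2)
  # 1e3 converts nA / (S/m * um) to uV
  1e3 / (4 * pi * sigma * L) * log(num / den)
}

#' Extracellular potential of a single line-source segment
#'
#' Evaluates the line-source kernel for one neurite segment carrying a
#' uniform current, at one observation point. The potential is linear in
#' the current; the perpendicular distance is clamped to a minimum of 1 um.
#'
#' @param segment numeric vector of length 6: start x/y/z, end x/y/z (um).
#' @param current numeric vector: current trace (nA).
#' @param point numeric vector of length 3: observation point (um).
#' @param sigma extracellular conductivity (S/m).
#' @return numeric vector: potential trace (uV), same length as `current`.
#' @examples
#' # far from the segment the kernel approaches the point-source 1/r law
#' lineSourcePotential(c(0, 0, -5, 0, 0, 5), 1, c(1000, 0, 0), 0.3)
#' @export
lineSourcePotential <- function(segment, current, point, sigma = 0.3) {
  w <- .lineSourceWeight(segment[1:3], segment[4:6],
                         matrix(point, nrow = 1), sigma)
  as.numeric(w) * current
}

.defaultPositionBounds <- function(probe, pad = 30, xRange = c(10, 80)) {
  pos <- probe@positions
  rbind(xRange,
        range(pos[, 2]) + c(-pad, pad),
        range(pos[, 3]) + c(-pad, pad))
}

.rotationMatrix <- function(angles) {
  # angles = (rx, ry, rz); applied as R = Rz %*% Ry %*% Rx
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

#' Randomly place and rotate a cell model near a probe
#'
#' Draws a soma location uniformly inside the position bounds and a random
#' rotation according to `rotation_mode` (`"none"`: identity; `"z-only"`:
#' azimuthal rotation about the vertical axis; `"3d"`: azimuthal rotation
#' plus tilts limited to `tilt_limit`), then applies the rigid transform to
#' the model's segments. Uses the current RNG state.
#'
#' @param model a [SyntheticCellModel-class].
#' @param probe a [Probe-class].
#' @param params a [forwardModelParams()] list.
#' @return list with `segments` (transformed matrix), `location` (soma
#'   centre, um) and `rotation` (3 angles, rad).
#' @export
placeCell <- function(model, probe, params = forwardModelParams()) {
  bounds <- params$position_bounds
  if (is.null(bounds)) bounds <- .defaultPositionBounds(probe)
  bounds <- as.matrix(bounds)
  if (any(bounds[, 2] < bounds[, 1])) stop("degenerate position bounds")
  loc <- stats::runif(3, bounds[, 1], bounds[, 2])
  rot <- switch(params$rotation_mode,
    "none" = c(0, 0, 0),
    "z-only" = c(0, 0, stats::runif(1, 0, 2 * pi)),
    "3d" = c(stats::runif(2, -params$tilt_limit, params$tilt_limit),
             stats::runif(1, 0, 2 * pi))
  )
  segs <- model@segments
  R <- .rotationMatrix(rot)
  start <- segs[, 1:3, drop = FALSE] %*% t(R)
  end <- segs[, 4:6, drop = FALSE] %*% t(R)
  segs[, 1:3] <- sweep(start, 2, loc, `+`)
  segs[, 4:6] <- sweep(end, 2, loc, `+`)
  list(segments = segs, location = loc, rotation = rot)
}

#' Compute an extracellular action potential on a probe
#'
#' Sums the line-source contributions of all segments at every electrode
#' and trims the result to the cut-out window around the global trough
#' (minimum over all channels).
#'
#' @param segments transformed segment matrix (n_segments x 7), um.
#' @param currents current matrix from [simulateTransmembraneCurrents()]
#'   (n_segments x n_t), nA.
#' @param probe a [Probe-class].
#' @param params a [forwardModelParams()] list; `cut_out` (ms) and `sigma`
#'   are used.
#' @return numeric matrix (n_channels x n_points), uV. The trough of the
#'   deepest channel sits at sample `round(cut_out[1] * fs / 1000) + 1`.
#' @export
computeEAP <- function(segments, currents, probe, params = forwardModelParams()) {
  stopifnot(nrow(segments) == nrow(currents))
  W <- vapply(seq_len(nrow(segments)), function(i) {
    .lineSourceWeight(segments[i, 1:3], segments[i, 4:6],
                      probe@positions, params$sigma)
  }, numeric(nrow(probe@positions)))
  W <- matrix(W, nrow = nrow(probe@positions))
  phi <- W %*% currents
  preN <- round(params$cut_out[1] / 1000 * params$fs)
  postN <- round(params$cut_out[2] / 1000 * params$fs)
  troughIdx <- which(phi == min(phi), arr.ind = TRUE)[1, 2]
  idx <- (troughIdx - preN):(troughIdx + postN)
  if (idx[1] < 1 || idx[length(idx)] > ncol(phi)) {
    stop("currents window too short for the requested cut_out")
  }
  phi[, idx, drop = FALSE]
}
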
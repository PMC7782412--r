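# Built-in probe registry.
#
# Coordinate convention used throughout the package: the electrode plane is
# spanned by axes 2 and 3 ("y", "z"); axis 1 ("x") is the distance from the
# probe plane, which sits at x = 0. z is the probe's vertical axis.

.probeRegistry <- function() {
  list(
    "tetrode" = function() {
      # four electrodes at the corners of a 25 um square
      yz <- rbind(c(-12.5, -12.5), c(-12.5, 12.5), c(12.5, -12.5), c(12.5, 12.5))
      list(positions = cbind(0, yz),
           description = "Tetrode: 4 electrodes at the corners of a 25 um square")
    },
    "Neuronexus-32" = function() {
      # 32 sites in 3 staggered columns, 25 um vertical pitch
      z1 <- seq(0, by = 25, length.out = 11)
      z2 <- seq(12.5, by = 25, length.out = 10)
      pos <- rbind(cbind(-18, z1), cbind(0, z2), cbind(18, z1))
      pos[, 2] <- pos[, 2] - mean(pos[, 2])
      list(positions = cbind(0, pos),
           description = "Linear silicon probe: 32 sites in 3 staggered columns, 25 um pitch")
    },
    "Neuropixels-128" = function() {
      # 4-column checkerboard, 128 sites, 25 um pitch
      cols <- c(-37.5, -12.5, 12.5, 37.5)
      pos <- do.call(rbind, lapply(seq_along(cols), function(i) {
        z <- seq(0, by = 25, length.out = 32) + if (i %% 2 == 0) 12.5 else 0
        cbind(cols[i], z)
      }))
      pos[, 2] <- pos[, 2] - mean(pos[, 2])
      list(positions = cbind(0, pos),
           description = "High-density probe: 128 sites in a 4-column checkerboard, 25 um pitch")
    },
    "SqMEA-10-15" = function() {
      # square 10x10 MEA with 15 um inter-electrode distance
      g <- seq(0, by = 15, length.out = 10)
      g <- g - mean(g)
      pos <- as.matrix(expand.grid(y = g, z = g))
      list(positions = cbind(0, pos),
           description = "Square MEA: 10x10 grid, 15 um pitch")
    }
  )
}

#' List built-in probe designs
#'
#' @return sorted, duplicate-free character vector of probe identifiers
#'   accepted by [buildProbe()].
#' @examples
#' listAvailableProbes()
#' @export
listAvailableProbes <- function() {
  sort(names(.probeRegistry()))
}

#' Build a built-in probe
#'
#' Constructs one of the registered probe geometries. Construction is
#' deterministic: two calls with the same name return identical positions.
#'
#' @param name a probe identifier from [listAvailableProbes()].
#' @return a [Probe-class].
#' @examples
#' buildProbe("tetrode")
#' @export
buildProbe <- function(name) {
  reg <- .probeRegistry()
  if (!name %in% names(reg)) {
    stop(sprintf("unknown probe '%s'; see listAvailableProbes()", name))
  }
  spec <- reg[[name]]()
  pos <- unname(as.matrix(spec$positions))
  dimnames(pos) <- NULL
  new("Probe", name = name, positions = pos, planeAxes = c(2L, 3L),
      description = spec$description)
}

#' Load a custom probe definition file
#'
#' Reads a probe from a small YAML dialect with keys `name` (string),
#' `positions` (list of `[x, y, z]` triplets in um) and an optional
#' `description`. The loaded probe must satisfy all `Probe` invariants
#' (distinct positions in particular).
#'
#' @param path path to the YAML file.
#' @return a [Probe-class].
#' @seealso [writeProbeFile()]
#' @export
loadProbeFile <- function(path) {
  if (!file.exists(path)) stop(sprintf("probe file not found: %s", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$name)) stop("probe file is missing required key 'name'")
  if (is.null(y$positions)) stop("probe file is missing required key 'positions'")
  pos <- tryCatch(do.call(rbind, lapply(y$positions, as.numeric)),
                  warning = function(w) stop("probe positions must be numeric"),
                  error = function(e) stop("probe positions must be numeric"))
  if (anyNA(pos)) stop("probe positions must be numeric")
  if (is.null(dim(pos)) || ncol(pos) != 3L) {
    stop("each probe position must be a 3-element [x, y, z] vector")
  }
  if (nrow(pos) > 1L && min(stats::dist(pos)) <= 0) {
    stop("probe file contains duplicated electrode positions")
  }
  new("Probe", name = as.character(y$name), positions = unname(pos),
      planeAxes = c(2L, 3L),
      description = if (is.null(y$description)) "" else as.character(y$description))
}

#' Write a probe definition file
#'
#' Writes a [Probe-class] to the YAML dialect read by [loadProbeFile()].
#' Round-trips exactly: loading a written file reproduces the positions
#' bit-for-bit.
#'
#' @param probe a [Probe-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProbeFile <- function(probe, path) {
  stopifnot(is(probe, "Probe"))
  y <- list(name = probe@name,
            positions = lapply(seq_len(nrow(probe@positions)),
                               function(i) as.numeric(probe@positions[i, ])),
            description = probe@description)
  # precision = 15 significant digits preserves doubles exactly enough for
  # the geometries in use (multiples of 0.5 um)
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}
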
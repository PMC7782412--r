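#' @rdname accessors
#' @export
setMethod("nChannels", "Probe", function(object) nrow(object@positions))

#' @rdname accessors
#' @export
setMethod("channelPositions", "Probe", function(object) object@positions)

#' @rdname accessors
#' @export
setMethod("probeName", "Probe", function(object) object@name)

#' @rdname accessors
#' @export
setMethod("pairwiseDistances", "Probe", function(object) {
  as.matrix(stats::dist(object@positions))
})

#' @rdname accessors
#' @export
setMethod("templates", "TemplateLibrary", function(object) object@templates)

#' @rdname accessors
#' @export
setMethod("locations", "TemplateLibrary", function(object) object@locations)

#' @rdname accessors
#' @export
setMethod("rotations", "TemplateLibrary", function(object) object@rotations)

#' @rdname accessors
#' @export
setMethod("celltypes", "TemplateLibrary", function(object) object@celltypes)

#' @rdname accessors
#' @export
setMethod("simInfo", "TemplateLibrary", function(object) object@info)

#' @rdname accessors
#' @export
setMethod("trains", "SpikeTrainSet", function(object) object@trains)

#' @rdname accessors
#' @export
setMethod("celltypes", "SpikeTrainSet", function(object) object@celltypes)

#' @rdname accessors
#' @export
setMethod("recordings", "RecordingBundle", function(object) object@recordings)

#' @rdname accessors
#' @export
setMethod("spikeTrains", "RecordingBundle", function(object) object@spiketrains)

#' @rdname accessors
#' @export
setMethod("templates", "RecordingBundle", function(object) object@templates)

#' @rdname accessors
#' @export
setMethod("celltypes", "RecordingBundle", function(object) object@templatesCelltypes)

#' @rdname accessors
#' @export
setMethod("locations", "RecordingBundle", function(object) object@templatesLocations)

#' @rdname accessors
#' @export
setMethod("rotations", "RecordingBundle", function(object) object@templatesRotations)

#' @rdname accessors
#' @export
setMethod("channelPositions", "RecordingBundle", function(object) object@channelPositions)

#' @rdname accessors
#' @export
setMethod("spikeTraces", "RecordingBundle", function(object) object@spikeTraces)

#' @rdname accessors
#' @export
setMethod("voltagePeaks", "RecordingBundle", function(object) object@voltagePeaks)

#' @rdname accessors
#' @export
setMethod("timestamps", "RecordingBundle", function(object) object@timestamps)

#' @rdname accessors
#' @export
setMethod("simInfo", "RecordingBundle", function(object) object@info)

setMethod("show", "Probe", function(object) {
  cat(sprintf("Probe '%s': %d channels\n", object@name, nrow(object@positions)))
  ext <- apply(object@positions, 2, range)
  cat(sprintf("  extent (um): x [%g, %g], y [%g, %g], z [%g, %g]\n",
              ext[1, 1], ext[2, 1], ext[1, 2], ext[2, 2], ext[1, 3], ext[2, 3]))
  if (nzchar(object@description)) cat(" ", object@description, "\n")
})

setMethod("show", "SyntheticCellModel", function(object) {
  cat(sprintf("SyntheticCellModel '%s' (%s): %d segments, trough width %g ms\n",
              object@modelId, object@cellType, nrow(object@segments),
              object@apParams$trough_width))
})

setMethod("show", "TemplateLibrary", function(object) {
  d <- dim(object@templates)
  if (isTRUE(object@info$drifting)) {
    cat(sprintf("TemplateLibrary: %d drifting templates (%d steps), %d channels, %d points\n",
                d[1], d[2], d[3], d[4]))
  } else {
    cat(sprintf("TemplateLibrary: %d templates, %d channels, %d points\n",
                d[1], d[2], d[3]))
  }
  tab <- table(object@celltypes)
  cat("  cell types:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  if (!is.null(object@info$probe)) cat("  probe:", object@info$probe, "\n")
  if (!is.null(object@info$seed)) cat("  seed:", object@info$seed, "\n")
})

setMethod("show", "SpikeTrainSet", function(object) {
  cat(sprintf("SpikeTrainSet: %d units on [%g, %g] s\n",
              length(object@trains), object@tStart, object@tStop))
  counts <- vapply(object@trains, length, integer(1))
  cat("  spike counts:", paste(counts, collapse = ", "), "\n")
  cat("  cell types:  ", paste(object@celltypes, collapse = ", "), "\n")
})

setMethod("show", "RecordingBundle", function(object) {
  cat(sprintf("RecordingBundle: %d channels x %d samples (%.3g s at %g kHz)\n",
              nrow(object@recordings), ncol(object@recordings),
              object@info$duration, object@info$fs / 1000))
  cat(sprintf("  %d ground-truth units (%s)\n",
              length(object@spiketrains@trains),
              paste(object@templatesCelltypes, collapse = ", ")))
  s <- object@info$seeds
  if (!is.null(s)) {
    cat(sprintf("  seeds: st %d, temp %d, noise %d, conv %d\n",
                s$st_seed, s$temp_seed, s$noise_seed, s$conv_seed))
  }
})
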
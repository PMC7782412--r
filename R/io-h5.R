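# Self-describing HDF5 persistence for template libraries and recording
# bundles. Dataset names are part of the container contract. All numeric
# arrays are stored as 64-bit floats so that save/load round-trips are
# bit-exact; the parameter record is embedded as a YAML string plus a
# schema-version attribute.

.SCHEMA_VERSION <- "1.0"

# keys whose values are matrices; converted to row-lists for YAML and
# rebuilt on load
.matrixInfoKeys <- c("position_bounds", "channel_positions",
                     "overlapping_pairs")

.infoToYaml <- function(info) {
  for (k in .matrixInfoKeys) {
    if (!is.null(info[[k]])) {
      m <- as.matrix(info[[k]])
      info[[k]] <- lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))
    }
  }
  yaml::as.yaml(info, precision = 15)
}

.infoFromYaml <- function(txt) {
  info <- yaml::yaml.load(txt)
  for (k in .matrixInfoKeys) {
    if (!is.null(info[[k]])) {
      info[[k]] <- do.call(rbind, lapply(info[[k]], as.numeric))
    }
  }
  info
}

.h5Open <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ls <- tryCatch(rhdf5::h5ls(path, recursive = TRUE),
                 error = function(e) {
                   stop(sprintf("'%s' is not a readable HDF5 file: %s",
                                path, conditionMessage(e)))
                 })
  ls
}

.checkSchema <- function(path, expectedKind) {
  att <- tryCatch(rhdf5::h5readAttributes(path, "/"),
                  error = function(e) list())
  ver <- att$schema_version
  kind <- att$container
  if (is.null(ver)) stop(sprintf("'%s' has no schema_version attribute", path))
  if (as.character(ver) != .SCHEMA_VERSION) {
    stop(sprintf("schema version mismatch in '%s': file %s, expected %s",
                 path, ver, .SCHEMA_VERSION))
  }
  if (!is.null(kind) && as.character(kind) != expectedKind) {
    stop(sprintf("'%s' is a %s container, expected %s", path, kind,
                 expectedKind))
  }
}

.requireDatasets <- function(path, ls, needed) {
  have <- paste0(ifelse(ls$group == "/", "/", paste0(ls$group, "/")), ls$name)
  for (d in needed) {
    if (!d %in% have) {
      stop(sprintf("'%s' is missing required dataset '%s'", path, d))
    }
  }
}

.writeRootAttrs <- function(path, kind) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(.SCHEMA_VERSION, fid, "schema_version")
  rhdf5::h5writeAttribute(kind, fid, "container")
}

#' Save / load a template library
#'
#' Writes a [TemplateLibrary-class] to an HDF5 file with datasets
#' `templates`, `locations`, `rotations`, `celltypes` and `info` (the
#' parameter record, including the generation seed, as a YAML string), plus
#' `schema_version` and `container` root attributes. `loadTemplateLibrary()`
#' restores the object; numeric arrays round-trip bit-exactly.
#'
#' @param lib a [TemplateLibrary-class].
#' @param path output `.h5` path (overwritten if it exists).
#' @return `saveTemplateLibrary()`: `path`, invisibly;
#'   `loadTemplateLibrary()`: a [TemplateLibrary-class].
#' @export
saveTemplateLibrary <- function(lib, path) {
  stopifnot(is(lib, "TemplateLibrary"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(lib@templates, path, "templates")
  rhdf5::h5write(lib@locations, path, "locations")
  rhdf5::h5write(lib@rotations, path, "rotations")
  rhdf5::h5write(lib@celltypes, path, "celltypes")
  rhdf5::h5write(.infoToYaml(lib@info), path, "info")
  .writeRootAttrs(path, "templates")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname saveTemplateLibrary
#' @export
loadTemplateLibrary <- function(path) {
  ls <- .h5Open(path)
  .checkSchema(path, "templates")
  .requireDatasets(path, ls, c("/templates", "/locations", "/rotations",
                               "/celltypes", "/info"))
  info <- .infoFromYaml(rhdf5::h5read(path, "info"))
  tpl <- rhdf5::h5read(path, "templates")
  loc <- rhdf5::h5read(path, "locations")
  out <- new("TemplateLibrary",
             templates = tpl,
             locations = loc,
             rotations = as.matrix(rhdf5::h5read(path, "rotations")),
             celltypes = as.character(rhdf5::h5read(path, "celltypes")),
             info = info)
  rhdf5::h5closeAll()
  out
}

#' Save / load a recording bundle
#'
#' Writes a [RecordingBundle-class] to an HDF5 file with datasets
#' `recordings`, `templates`, `templates_celltypes`, `templates_locations`,
#' `templates_rotations`, `channel_positions`, `timestamps`,
#' `voltage_peaks`, `spike_traces`, `info`, and a `spiketrains` group with
#' one sub-group per unit holding the spike `times` (seconds) and
#' `t_start` / `t_stop` / `celltype` / `rate` attributes. All four
#' generation seeds are inside `info`. Numeric arrays round-trip
#' bit-exactly.
#'
#' @param bundle a [RecordingBundle-class].
#' @param path output `.h5` path (overwritten if it exists).
#' @return `saveRecording()`: `path`, invisibly; `loadRecording()`: a
#'   [RecordingBundle-class].
#' @export
saveRecording <- function(bundle, path) {
  stopifnot(is(bundle, "RecordingBundle"))
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(bundle@recordings, path, "recordings")
  rhdf5::h5write(bundle@templates, path, "templates")
  rhdf5::h5write(bundle@templatesCelltypes, path, "templates_celltypes")
  rhdf5::h5write(bundle@templatesLocations, path, "templates_locations")
  rhdf5::h5write(bundle@templatesRotations, path, "templates_rotations")
  rhdf5::h5write(bundle@channelPositions, path, "channel_positions")
  rhdf5::h5write(bundle@timestamps, path, "timestamps")
  rhdf5::h5write(bundle@voltagePeaks, path, "voltage_peaks")
  rhdf5::h5write(bundle@spikeTraces, path, "spike_traces")
  rhdf5::h5write(.infoToYaml(bundle@info), path, "info")
  rhdf5::h5createGroup(path, "spiketrains")
  sts <- bundle@spiketrains
  fid <- rhdf5::H5Fopen(path)
  for (u in seq_along(sts@trains)) {
    g <- sprintf("spiketrains/unit_%03d", u - 1L)
    rhdf5::h5createGroup(fid, g)
    rhdf5::h5write(sts@trains[[u]], fid, paste0(g, "/times"))
    gid <- rhdf5::H5Gopen(fid, g)
    rhdf5::h5writeAttribute(sts@tStart, gid, "t_start")
    rhdf5::h5writeAttribute(sts@tStop, gid, "t_stop")
    rhdf5::h5writeAttribute(sts@celltypes[u], gid, "celltype")
    rhdf5::h5writeAttribute(sts@rates[u], gid, "rate")
    rhdf5::H5Gclose(gid)
  }
  gid <- rhdf5::H5Gopen(fid, "spiketrains")
  rhdf5::h5writeAttribute(sts@seed, gid, "seed")
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)
  .writeRootAttrs(path, "recordings")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname saveRecording
#' @export
loadRecording <- function(path) {
  ls <- .h5Open(path)
  .checkSchema(path, "recordings")
  .requireDatasets(path, ls, c(
    "/recordings", "/templates", "/templates_celltypes",
    "/templates_locations", "/templates_rotations", "/channel_positions",
    "/timestamps", "/voltage_peaks", "/spike_traces", "/info"))
  if (!"spiketrains" %in% ls$name[ls$group == "/"]) {
    stop(sprintf("'%s' is missing required group 'spiketrains'", path))
  }
  info <- .infoFromYaml(rhdf5::h5read(path, "info"))
  units <- sort(ls$name[ls$group == "/spiketrains"])
  tr <- vector("list", length(units))
  ctypes <- character(length(units))
  rates <- numeric(length(units))
  tStart <- 0; tStop <- 1; stSeed <- 0L
  for (u in seq_along(units)) {
    g <- paste0("spiketrains/", units[u])
    tr[[u]] <- as.numeric(rhdf5::h5read(path, paste0(g, "/times")))
    att <- rhdf5::h5readAttributes(path, g)
    tStart <- as.numeric(att$t_start)
    tStop <- as.numeric(att$t_stop)
    ctypes[u] <- as.character(att$celltype)
    rates[u] <- as.numeric(att$rate)
  }
  stAtt <- rhdf5::h5readAttributes(path, "spiketrains")
  if (!is.null(stAtt$seed)) stSeed <- as.integer(stAtt$seed)
  sts <- new("SpikeTrainSet", trains = tr, tStart = tStart, tStop = tStop,
             celltypes = ctypes, rates = rates, seed = stSeed)
  out <- new("RecordingBundle",
             recordings = as.matrix(rhdf5::h5read(path, "recordings")),
             spiketrains = sts,
             templates = rhdf5::h5read(path, "templates"),
             templatesCelltypes = as.character(
               rhdf5::h5read(path, "templates_celltypes")),
             templatesLocations = rhdf5::h5read(path, "templates_locations"),
             templatesRotations = as.matrix(
               rhdf5::h5read(path, "templates_rotations")),
             channelPositions = as.matrix(
               rhdf5::h5read(path, "channel_positions")),
             timestamps = as.numeric(rhdf5::h5read(path, "timestamps")),
             voltagePeaks = as.matrix(rhdf5::h5read(path, "voltage_peaks")),
             spikeTraces = as.matrix(rhdf5::h5read(path, "spike_traces")),
             info = info)
  rhdf5::h5closeAll()
  out
}
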
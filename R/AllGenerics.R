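#' Accessor generics
#'
#' Small accessor API for the package's S4 containers. Accessors are
#' preferred over direct slot access.
#'
#' @param object an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("channelPositions", function(object) standardGeneric("channelPositions"))

#' @rdname accessors
#' @export
setGeneric("probeName", function(object) standardGeneric("probeName"))

#' @rdname accessors
#' @export
setGeneric("templates", function(object) standardGeneric("templates"))

#' @rdname accessors
#' @export
setGeneric("locations", function(object) standardGeneric("locations"))

#' @rdname accessors
#' @export
setGeneric("rotations", function(object) standardGeneric("rotations"))

#' @rdname accessors
#' @export
setGeneric("celltypes", function(object) standardGeneric("celltypes"))

#' @rdname accessors
#' @export
setGeneric("simInfo", function(object) standardGeneric("simInfo"))

#' @rdname accessors
#' @export
setGeneric("trains", function(object) standardGeneric("trains"))

#' @rdname accessors
#' @export
setGeneric("recordings", function(object) standardGeneric("recordings"))

#' @rdname accessors
#' @export
setGeneric("spikeTrains", function(object) standardGeneric("spikeTrains"))

#' @rdname accessors
#' @export
setGeneric("spikeTraces", function(object) standardGeneric("spikeTraces"))

#' @rdname accessors
#' @export
setGeneric("voltagePeaks", function(object) standardGeneric("voltagePeaks"))

#' @rdname accessors
#' @export
setGeneric("timestamps", function(object) standardGeneric("timestamps"))

#' Pairwise electrode distances
#'
#' Euclidean distance matrix between all electrode pairs of a probe, in
#' micrometres. Symmetric with a zero diagonal. Used, among other things,
#' by the distance-correlated noise model, whose channel covariance decays
#' with inter-electrode distance.
#'
#' @param object a [Probe-class].
#' @return numeric matrix (n_channels x n_channels).
#' @examples
#' pairwiseDistances(buildProbe("tetrode"))
#' @export
setGeneric("pairwiseDistances", function(object) standardGeneric("pairwiseDistances"))
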
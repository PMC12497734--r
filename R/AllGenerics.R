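#' @name clustMEA-accessors
#' @title Accessors for clustMEA classes
#'
#' @description Slot accessors shared by the core classes. `electrodeId()`,
#' `clusterId()`, `positions()` and `samplingRate()` read the layout;
#' `spikeTimes()` returns the per-electrode train list, `nSpikes()` the spike
#' count per electrode, `duration()` the recording length in seconds,
#' `edges()` the edge table of a [ConnectivityGraph-class].
#'
#' @param x an object of one of the clustMEA classes.
#' @param ... unused.
#' @return the corresponding slot value (see Description).
NULL

#' @rdname clustMEA-accessors
#' @export
setGeneric("electrodeId", function(x) standardGeneric("electrodeId"))

#' @rdname clustMEA-accessors
#' @export
setGeneric("clusterId", function(x) standardGeneric("clusterId"))

#' @rdname clustMEA-accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname clustMEA-accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname clustMEA-accessors
#' @export
setGeneric("layout4", function(x) standardGeneric("layout4"))

#' @rdname clustMEA-accessors
#' @export
setGeneric("spikeTimes", function(x, ...) standardGeneric("spikeTimes"))

#' @rdname clustMEA-accessors
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))

#' @rdname clustMEA-accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname clustMEA-accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))
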
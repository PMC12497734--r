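#' @import methods
NULL

#' MEALayout: electrode geometry and cluster map of a multi-electrode array
#'
#' Describes a planar MEA: electrode identifiers, positions in micrometres
#' (origin at the array centre), the cluster each electrode records from, and
#' the acquisition sampling rate. For the four-quadrant arrays used with
#' cross-shaped culture masks, clusters are the four spatially separated
#' neuronal assemblies; see [defaultLayout4Q()].
#'
#' @slot electrodeId character vector of unique electrode identifiers.
#' @slot x,y numeric electrode coordinates in micrometres.
#' @slot clusterId integer cluster membership, values in `1:4` for the
#'   default four-quadrant layout (any set of positive labels is accepted as
#'   long as all clusters are non-empty).
#' @slot samplingRate acquisition sampling rate in Hz (default 10000).
#'
#' @seealso [defaultLayout4Q()], [readLayout()]
#' @export
setClass("MEALayout", representation(
    electrodeId = "character",
    x = "numeric",
    y = "numeric",
    clusterId = "integer",
    samplingRate = "numeric"
))

setValidity("MEALayout", function(object) {
    n <- length(object@electrodeId)
    msg <- character(0)
    if (length(object@x) != n || length(object@y) != n ||
        length(object@clusterId) != n)
        msg <- c(msg, "electrodeId, x, y and clusterId must have equal length")
    if (anyDuplicated(object@electrodeId))
        msg <- c(msg, "electrode ids must be unique")
    if (n > 0 && anyDuplicated(cbind(object@x, object@y)))
        msg <- c(msg, "electrode positions must be unique")
    if (n > 0 && (anyNA(object@clusterId) || any(object@clusterId < 1L)))
        msg <- c(msg, "cluster ids must be positive integers")
    if (n > 0 && any(tabulate(object@clusterId) == 0L))
        msg <- c(msg, "every cluster label up to max(clusterId) must be non-empty")
    if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
        object@samplingRate <= 0)
        msg <- c(msg, "samplingRate must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' SpikeTrainSet: per-electrode spike times with layout
#'
#' The central currency of the pipeline: one sorted vector of spike times in
#' seconds per electrode ("peak trains"), together with the [MEALayout-class]
#' and the recording duration. Trains are strictly increasing and confined to
#' `[0, duration]`.
#'
#' @slot layout a [MEALayout-class].
#' @slot spikes named list, one numeric vector of spike times (seconds) per
#'   electrode; names match `electrodeId(layout)` and keep its order.
#' @slot duration recording duration in seconds.
#'
#' @seealso [readSpikeTrains()], [simulateActivity()], [detectSpikesPTSD()]
#' @export
setClass("SpikeTrainSet", representation(
    layout = "MEALayout",
    spikes = "list",
    duration = "numeric"
))

setValidity("SpikeTrainSet", function(object) {
    msg <- character(0)
    ids <- object@layout@electrodeId
    if (!identical(names(object@spikes), ids))
        msg <- c(msg, "names(spikes) must equal the layout electrode ids (same order)")
    if (length(object@duration) != 1L || !is.finite(object@duration) ||
        object@duration <= 0)
        msg <- c(msg, "duration must be a single positive number")
    for (id in names(object@spikes)) {
        tr <- object@spikes[[id]]
        if (!is.numeric(tr)) {
            msg <- c(msg, sprintf("train '%s' is not numeric", id))
            next
        }
        if (length(tr) && (anyNA(tr) || any(tr < 0) || any(tr > object@duration)))
            msg <- c(msg, sprintf("train '%s' has times outside [0, duration]", id))
        if (length(tr) > 1L && any(diff(tr) <= 0))
            msg <- c(msg, sprintf("train '%s' is not strictly increasing", id))
    }
    if (length(msg)) msg else TRUE
})

#' VoltageRecording: raw extracellular voltage traces
#'
#' Uniformly sampled microvolt traces, one column per electrode, at the
#' layout's sampling rate. Input to the precision-time spike detector.
#'
#' @slot layout a [MEALayout-class].
#' @slot samples numeric matrix, `n_samples x n_electrodes`, microvolts;
#'   column names match the layout electrode ids.
#' @slot duration duration in seconds; `nrow(samples)` equals
#'   `duration * samplingRate(layout)` within one sample.
#'
#' @seealso [synthesizeVoltage()], [detectSpikesPTSD()]
#' @export
setClass("VoltageRecording", representation(
    layout = "MEALayout",
    samples = "matrix",
    duration = "numeric"
))

setValidity("VoltageRecording", function(object) {
    msg <- character(0)
    if (!identical(colnames(object@samples), object@layout@electrodeId))
        msg <- c(msg, "colnames(samples) must equal the layout electrode ids")
    if (length(object@duration) != 1L || object@duration <= 0)
        msg <- c(msg, "duration must be a single positive number")
    else {
        expected <- object@duration * object@layout@samplingRate
        if (abs(nrow(object@samples) - expected) > 1)
            msg <- c(msg, "nrow(samples) must equal duration * samplingRate within one sample")
    }
    if (length(msg)) msg else TRUE
})

#' ConnectivityGraph: directed functional connectivity between electrodes
#'
#' Directed weighted graph inferred by TSPE ([tspe()]): one row per ordered
#' electrode pair retained, with the signed TSPE weight (positive = putative
#' excitation, negative = putative inhibition), the best delay in ms, the
#' intra/inter-cluster label derived from the layout, and optionally the
#' coincidence index CI0 of the pair.
#'
#' @slot layout a [MEALayout-class].
#' @slot edges data.frame with columns `source`, `target`, `weight`,
#'   `delay_ms`, `label` ("intra" or "inter") and `ci0` (numeric in
#'   `[0,1]`, `NA` when not computed).
#' @slot filtered logical: have the spatial/physiological/weight filters been
#'   applied ([filterEdges()])?
#'
#' @seealso [tspe()], [filterEdges()], [variationVsBaseline()]
#' @export
setClass("ConnectivityGraph", representation(
    layout = "MEALayout",
    edges = "data.frame",
    filtered = "logical"
))

setValidity("ConnectivityGraph", function(object) {
    msg <- character(0)
    need <- c("source", "target", "weight", "delay_ms", "label", "ci0")
    if (!all(need %in% names(object@edges)))
        msg <- c(msg, paste("edges must have columns:", paste(need, collapse = ", ")))
    else {
        e <- object@edges
        ids <- object@layout@electrodeId
        if (nrow(e)) {
            if (any(e$source == e$target))
                msg <- c(msg, "self-edges are not allowed")
            if (!all(e$source %in% ids) || !all(e$target %in% ids))
                msg <- c(msg, "edge endpoints must be layout electrodes")
            if (!all(e$label %in% c("intra", "inter")))
                msg <- c(msg, "edge labels must be 'intra' or 'inter'")
            cl <- object@layout@clusterId
            names(cl) <- ids
            expect <- ifelse(cl[e$source] == cl[e$target], "intra", "inter")
            if (!all(e$label == expect))
                msg <- c(msg, "edge labels inconsistent with layout clusters")
            ok <- is.na(e$ci0) | (e$ci0 >= 0 & e$ci0 <= 1)
            if (!all(ok))
                msg <- c(msg, "ci0 must lie in [0, 1]")
        }
    }
    if (length(object@filtered) != 1L || is.na(object@filtered))
        msg <- c(msg, "filtered must be TRUE or FALSE")
    if (length(msg)) msg else TRUE
})

#' DoseResponseFit: Hill-equation fit of normalized firing vs concentration
#'
#' Result of [fitHill()]: the data, the fitted half-maximal inhibitory
#' concentration (IC50, molar), Hill coefficient, fixed or fitted asymptotes,
#' residual norm and a convergence flag. On a successful fit
#' `r(IC50) = (top + bottom) / 2`.
#'
#' @slot concentrations molar concentrations (sorted ascending).
#' @slot responses baseline-normalized responses (unitless, >= 0).
#' @slot ic50 fitted IC50 in molar.
#' @slot hillN fitted Hill coefficient.
#' @slot top,bottom upper/lower asymptotes of the fitted curve.
#' @slot residualNorm Euclidean norm of the residuals.
#' @slot converged logical: did the fit converge to an identifiable IC50?
#'
#' @seealso [fitHill()], [simulateDoseResponse()]
#' @export
setClass("DoseResponseFit", representation(
    concentrations = "numeric",
    responses = "numeric",
    ic50 = "numeric",
    hillN = "numeric",
    top = "numeric",
    bottom = "numeric",
    residualNorm = "numeric",
    converged = "logical"
))

setValidity("DoseResponseFit", function(object) {
    msg <- character(0)
    if (length(object@concentrations) != length(object@responses))
        msg <- c(msg, "concentrations and responses must have equal length")
    if (any(object@responses < 0))
        msg <- c(msg, "responses must be >= 0")
    if (isTRUE(object@converged)) {
        if (!length(object@ic50) || !is.finite(object@ic50) || object@ic50 <= 0)
            msg <- c(msg, "ic50 must be positive on a converged fit")
        if (!length(object@hillN) || !is.finite(object@hillN) || object@hillN <= 0)
            msg <- c(msg, "hillN must be positive on a converged fit")
    }
    if (length(msg)) msg else TRUE
})
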
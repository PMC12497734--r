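#' @rdname clustMEA-accessors
#' @export
setMethod("electrodeId", "MEALayout", function(x) x@electrodeId)

#' @rdname clustMEA-accessors
#' @export
setMethod("electrodeId", "SpikeTrainSet", function(x) x@layout@electrodeId)

#' @rdname clustMEA-accessors
#' @export
setMethod("electrodeId", "VoltageRecording", function(x) x@layout@electrodeId)

#' @rdname clustMEA-accessors
#' @export
setMethod("clusterId", "MEALayout", function(x) {
    stats::setNames(x@clusterId, x@electrodeId)
})

#' @rdname clustMEA-accessors
#' @export
setMethod("clusterId", "SpikeTrainSet", function(x) clusterId(x@layout))

#' @rdname clustMEA-accessors
#' @export
setMethod("positions", "MEALayout", function(x) {
    data.frame(electrode_id = x@electrodeId, x_um = x@x, y_um = x@y,
               cluster_id = x@clusterId, stringsAsFactors = FALSE)
})

#' @rdname clustMEA-accessors
#' @export
setMethod("samplingRate", "MEALayout", function(x) x@samplingRate)

#' @rdname clustMEA-accessors
#' @export
setMethod("samplingRate", "SpikeTrainSet", function(x) x@layout@samplingRate)

#' @rdname clustMEA-accessors
#' @export
setMethod("samplingRate", "VoltageRecording", function(x) x@layout@samplingRate)

#' @rdname clustMEA-accessors
#' @export
setMethod("layout4", "SpikeTrainSet", function(x) x@layout)

#' @rdname clustMEA-accessors
#' @export
setMethod("layout4", "VoltageRecording", function(x) x@layout)

#' @rdname clustMEA-accessors
#' @export
setMethod("layout4", "ConnectivityGraph", function(x) x@layout)

#' @rdname clustMEA-accessors
#' @export
setMethod("spikeTimes", "SpikeTrainSet", function(x, ...) x@spikes)

#' @rdname clustMEA-accessors
#' @export
setMethod("nSpikes", "SpikeTrainSet", function(x) {
    vapply(x@spikes, length, integer(1))
})

#' @rdname clustMEA-accessors
#' @export
setMethod("duration", "SpikeTrainSet", function(x) x@duration)

#' @rdname clustMEA-accessors
#' @export
setMethod("duration", "VoltageRecording", function(x) x@duration)

#' @rdname clustMEA-accessors
#' @export
setMethod("edges", "ConnectivityGraph", function(x) x@edges)

setMethod("show", "MEALayout", function(object) {
    cat(sprintf("MEALayout: %d electrodes, %d clusters, %g Hz\n",
                length(object@electrodeId), max(object@clusterId),
                object@samplingRate))
    tab <- table(object@clusterId)
    cat("  electrodes per cluster:",
        paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
})

setMethod("show", "SpikeTrainSet", function(object) {
    n <- nSpikes(object)
    cat(sprintf("SpikeTrainSet: %d electrodes, %.1f s, %d spikes total\n",
                length(n), object@duration, sum(n)))
    cat(sprintf("  mean firing rate: %.3f spikes/s per electrode\n",
                mean(n) / object@duration))
})

setMethod("show", "VoltageRecording", function(object) {
    cat(sprintf("VoltageRecording: %d electrodes, %.1f s at %g Hz (%d samples)\n",
                ncol(object@samples), object@duration,
                object@layout@samplingRate, nrow(object@samples)))
})

setMethod("show", "ConnectivityGraph", function(object) {
    e <- object@edges
    cat(sprintf("ConnectivityGraph: %d directed edges (%s)\n", nrow(e),
                if (object@filtered) "filtered" else "unfiltered"))
    if (nrow(e)) {
        cat(sprintf("  intra: %d, inter: %d; weight range [%.3g, %.3g]\n",
                    sum(e$label == "intra"), sum(e$label == "inter"),
                    min(e$weight), max(e$weight)))
    }
})

setMethod("show", "DoseResponseFit", function(object) {
    cat(sprintf("DoseResponseFit: %d concentrations\n",
                length(object@concentrations)))
    if (object@converged) {
        cat(sprintf("  IC50 = %.3g M, Hill n = %.3g (converged; residual norm %.3g)\n",
                    object@ic50, object@hillN, object@residualNorm))
    } else {
        cat("  fit did not converge to an identifiable IC50\n")
    }
})
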
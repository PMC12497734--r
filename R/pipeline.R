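#' Analyse one recording with a run configuration
#'
#' Runs burst detection, network-burst detection, activity metrics, and
#' activation-sequence statistics on a [SpikeTrainSet-class], using the
#' parameters in `config` (see [defaultRunConfig()]).
#'
#' @param sts a [SpikeTrainSet-class].
#' @param config a `RunConfig` list.
#' @param seed integer seed (Monte Carlo null).
#' @return list: `bursts`, `nbs`, `metrics`, `sequences`, `seq_stats`.
#' @export
analyzeRecording <- function(sts, config = defaultRunConfig(), seed = 1) {
    bursts <- detectBursts(sts, max_isi = config$bursts$max_isi_s,
                           min_spikes = config$bursts$min_spikes)
    nbs <- detectNetworkBursts(
        sts, bursts, min_fraction = config$network_bursts$min_fraction,
        merge_interval = config$network_bursts$merge_interval_s,
        fraction_base = config$network_bursts$fraction_base,
        active_threshold = config$activity$active_mfr_threshold)
    metrics <- computeActivityMetrics(
        sts, bursts, nbs,
        active_threshold = config$activity$active_mfr_threshold)
    sequences <- if (nrow(nbs))
        extractSequences(nbs, kernel_sd_ms = config$ifr$kernel_sd_ms,
                         bin_ms = config$ifr$bin_ms,
                         truncation_sd = config$ifr$kernel_truncation_sd)
    else list()
    seq_stats <- if (length(sequences) >= 2L)
        sequenceStats(sequences, n_iter = config$sequences$mc_iterations,
                      seed = seed,
                      full_only = !config$sequences$include_partial)
    else NULL
    list(bursts = bursts, nbs = nbs, metrics = metrics,
         sequences = sequences, seq_stats = seq_stats)
}

.cumulativeRunTable <- function(run_lengths, min_length = 2L) {
    rl <- run_lengths[run_lengths >= min_length]
    if (!length(rl))
        return(data.frame(run_length = integer(0), cum_freq = numeric(0)))
    lv <- sort(unique(rl))
    data.frame(run_length = lv,
               cum_freq = stats::ecdf(rl)(lv))
}

#' Compare experimental conditions against a baseline recording
#'
#' The condition-versus-baseline analysis flow: per condition (baseline,
#' treatment, optional washout) it computes activity metrics, activation-
#' sequence statistics with the Monte Carlo null, and filtered TSPE
#' connectivity with CI0; it then emits run-length cumulative-frequency
#' tables per condition, KS comparisons of condition run lengths against
#' baseline, per-electrode metric tables for box-plot style summaries, and
#' the connectivity [variationVsBaseline()] of each condition. Deterministic
#' given `config` and `seed`.
#'
#' @param baseline,condition [SpikeTrainSet-class] recordings on the same
#'   layout.
#' @param washout optional [SpikeTrainSet-class].
#' @param config a `RunConfig` list.
#' @param seed integer seed.
#' @param connectivity compute TSPE/CI0 stages (the slowest part); set
#'   `FALSE` to skip.
#' @return list with one entry per condition (`analysis`, `graph`) plus
#'   `run_length_cdf` (named list of tables), `ks_vs_baseline`,
#'   `metric_tables`, `variation` (named list of [variationVsBaseline()]
#'   tables), and `manifest`.
#' @export
runConditionComparison <- function(baseline, condition, washout = NULL,
                                   config = defaultRunConfig(), seed = 1,
                                   connectivity = TRUE) {
    sets <- list(baseline = baseline, condition = condition)
    if (!is.null(washout)) sets$washout <- washout
    ids0 <- electrodeId(baseline)
    for (nm in names(sets))
        if (!identical(electrodeId(sets[[nm]]), ids0))
            stop("layout mismatch between baseline and ", nm)
    cfg_c <- config$connectivity
    out <- list()
    for (nm in names(sets)) {
        an <- analyzeRecording(sets[[nm]], config, seed)
        g <- NULL
        if (connectivity) {
            g <- suppressWarnings(tspe(
                sets[[nm]], bin_ms = cfg_c$bin_ms,
                max_delay_ms = cfg_c$max_delay_ms,
                surrounding_bins = cfg_c$surrounding_bins,
                observed_bins = cfg_c$observed_bins,
                crossing_bins = cfg_c$crossing_bins,
                min_spikes_per_train = cfg_c$min_spikes_per_train))
            g <- filterEdges(g, speed_bounds_m_s = cfg_c$speed_bounds_m_s,
                             latency_bounds_ms = cfg_c$latency_bounds_ms)
            g <- addCoincidenceIndex(
                g, sets[[nm]],
                sync_halfwidth_ms = config$ci0$sync_halfwidth_ms,
                lag_halfwidth_ms = config$ci0$lag_halfwidth_ms,
                bin_ms = config$ci0$bin_ms)
        }
        out[[nm]] <- list(analysis = an, graph = g)
    }
    run_cdf <- lapply(out, function(o)
        .cumulativeRunTable(o$analysis$seq_stats$run_lengths))
    ks_vs_base <- lapply(names(sets)[-1], function(nm) {
        rb <- out$baseline$analysis$seq_stats$run_lengths
        rc <- out[[nm]]$analysis$seq_stats$run_lengths
        if (length(rb) && length(rc)) ksTwoSample(rc, rb) else NULL
    })
    names(ks_vs_base) <- names(sets)[-1]
    metric_tables <- lapply(out, function(o) o$analysis$metrics$per_electrode)
    variation <- if (connectivity)
        lapply(names(sets)[-1], function(nm)
            variationVsBaseline(out$baseline$graph, out[[nm]]$graph))
    else NULL
    if (!is.null(variation)) names(variation) <- names(sets)[-1]
    c(out, list(run_length_cdf = run_cdf, ks_vs_baseline = ks_vs_base,
                metric_tables = metric_tables, variation = variation,
                manifest = runManifest(config, seed,
                                       conditions = names(sets))))
}

#' Build a run manifest
#'
#' Records everything needed to reproduce a run: the full configuration
#' snapshot, the seed, the package version, input file digests (MD5) and a
#' timestamp. Re-running with an identical manifest reproduces every output
#' bit-exactly, because all stochastic stages derive their streams from the
#' recorded seed.
#'
#' @param config a `RunConfig` list.
#' @param seed integer seed.
#' @param inputs character vector of input file paths to digest (optional).
#' @param ... further fields to record.
#' @return list of class `RunManifest`.
#' @export
runManifest <- function(config, seed, inputs = character(0), ...) {
    digests <- if (length(inputs)) tools::md5sum(inputs) else NULL
    m <- list(package_version = as.character(utils::packageVersion("clustMEA")),
              seed = seed, config = unclass(config),
              input_digests = as.list(digests),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), ...)
    class(m) <- "RunManifest"
    m
}

#' Write a manifest (or any report list) as JSON
#'
#' @param x a list (e.g. `RunManifest`).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(x, path) {
    jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", force = TRUE)
    invisible(path)
}
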
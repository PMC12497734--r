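#' Default run configuration
#'
#' All tunable parameters of every pipeline stage, grouped by stage, with the
#' study's stated settings as defaults: spike detection at 8 x noise SD with a
#' 2 ms peak lifetime and 1 ms refractory period; bursts as strings of at
#' least 5 spikes with inter-spike intervals at most 100 ms; network bursts
#' requiring 20% of active electrodes within a 100 ms merge interval;
#' electrodes active when their mean firing rate exceeds 0.1 spikes/s; the
#' coincidence index integrating the cross-correlogram within +/-1 ms of a
#' +/-100 ms lag window; and 2 nM as the highlighted sub-IC50 test
#' concentration of the NMDA-receptor antagonist.
#'
#' @return nested named list of class `RunConfig`; sections
#'   `detection`, `bursts`, `network_bursts`, `activity`, `ifr`, `sequences`,
#'   `connectivity`, `ci0`, `dose_response`, `simulate`.
#' @seealso [readRunConfig()], [writeRunConfig()]
#' @export
#' @examples
#' cfg <- defaultRunConfig()
#' cfg$detection$threshold_factor
defaultRunConfig <- function() {
    cfg <- list(
        detection = list(
            threshold_factor = 8,        # multiple of noise SD (peak-to-peak)
            peak_lifetime_ms = 2,
            refractory_ms = 1,
            noise_estimator = "whole_trace"  # or "windowed"
        ),
        bursts = list(
            min_spikes = 5,
            max_isi_s = 0.1
        ),
        network_bursts = list(
            min_fraction = 0.20,
            merge_interval_s = 0.1,
            fraction_base = "active"     # or "all"
        ),
        activity = list(
            active_mfr_threshold = 0.1   # spikes/s, strict inequality
        ),
        ifr = list(
            kernel_sd_ms = 25,           # Gaussian kernel SD; +/-2 SD = 100 ms window
            kernel_truncation_sd = 2,
            bin_ms = 1
        ),
        sequences = list(
            include_partial = TRUE,
            mc_iterations = 1000
        ),
        connectivity = list(
            bin_ms = 1,
            max_delay_ms = 25,
            surrounding_bins = 3:8,      # TSPE running-average window sizes
            observed_bins = 2:3,         # TSPE edge window sizes
            crossing_bins = 0,
            min_spikes_per_train = 10,
            speed_bounds_m_s = c(0.02, 2),
            latency_bounds_ms = c(1, 25),
            surrogate_n = 100,
            surrogate_jitter_ms = 10,
            surrogate_quantile = 0.99
        ),
        ci0 = list(
            sync_halfwidth_ms = 1,
            lag_halfwidth_ms = 100,
            bin_ms = 0.5
        ),
        dose_response = list(
            concentrations_molar = c(1e-9, 3e-9, 1e-8, 3e-8, 1e-7, 3e-7,
                                     1e-6, 3e-6, 1e-5),
            test_concentration_molar = 2e-9,
            fixed_top = 1,
            fixed_bottom = 0
        ),
        simulate = list(
            duration_s = 600,            # one 10-min recording
            nb_rate_hz = 0.2,
            p_rep = 0.5,
            inter_cluster_lag_ms = 100,
            intra_cluster_lag_ms = 2,
            background_rate_hz = 0.2,
            burst_spikes_per_electrode = 8,
            min_separation_s = 1
        )
    )
    class(cfg) <- "RunConfig"
    cfg
}

#' Read / write a run configuration
#'
#' Configurations are stored as a YAML file with one section per stage;
#' values omitted from the file keep their defaults from
#' [defaultRunConfig()]. Unknown sections or keys are rejected, so typos fail
#' loudly.
#'
#' @param path file path.
#' @return `readRunConfig` returns a `RunConfig` list; `writeRunConfig`
#'   returns `path` invisibly.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- defaultRunConfig()
    for (sec in names(user)) {
        if (!sec %in% names(cfg))
            stop("unknown config section: ", sec)
        for (key in names(user[[sec]])) {
            if (!key %in% names(cfg[[sec]]))
                stop("unknown config key: ", sec, "$", key)
            cfg[[sec]][[key]] <- user[[sec]][[key]]
        }
    }
    cfg
}

#' @rdname readRunConfig
#' @param config a `RunConfig` list.
#' @export
writeRunConfig <- function(config, path) {
    stopifnot(inherits(config, "RunConfig"))
    yaml::write_yaml(unclass(config), path)
    invisible(path)
}
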
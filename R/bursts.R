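#' Burst detection on a single spike train (string method)
#'
#' Partitions a sorted spike train into maximal strings whose consecutive
#' inter-spike intervals are at most `max_isi` and keeps strings with at
#' least `min_spikes` spikes. Burst start/end are the first/last spike of
#' the string. Defaults: at least 5 spikes, at most 100 ms between
#' consecutive spikes.
#'
#' @param train sorted numeric spike times, seconds.
#' @param max_isi maximum intra-burst inter-spike interval, seconds.
#' @param min_spikes minimum spikes per burst.
#' @return data.frame with columns `start`, `end`, `n_spikes`, `first_idx`,
#'   `last_idx` (indices into `train`); zero rows if no burst.
#' @export
#' @examples
#' detectBurstsString(c(0, .05, .10, .15, .20))
detectBurstsString <- function(train, max_isi = 0.1, min_spikes = 5) {
    empty <- data.frame(start = numeric(0), end = numeric(0),
                        n_spikes = integer(0), first_idx = integer(0),
                        last_idx = integer(0))
    n <- length(train)
    if (n < min_spikes) return(empty)
    if (is.unsorted(train)) stop("train must be sorted")
    # tiny slack so ISIs of exactly max_isi stay inside a string despite
    # floating-point representation
    brk <- c(0L, which(diff(train) > max_isi + 1e-12), n)
    first <- brk[-length(brk)] + 1L
    last <- brk[-1]
    len <- last - first + 1L
    keep <- len >= min_spikes
    data.frame(start = train[first[keep]], end = train[last[keep]],
               n_spikes = len[keep], first_idx = first[keep],
               last_idx = last[keep])
}

#' Burst detection across all electrodes of a SpikeTrainSet
#'
#' @param sts a [SpikeTrainSet-class].
#' @inheritParams detectBurstsString
#' @return data.frame with `electrode_id` plus the [detectBurstsString()]
#'   columns, ordered by electrode then start time.
#' @export
detectBursts <- function(sts, max_isi = 0.1, min_spikes = 5) {
    out <- lapply(electrodeId(sts), function(id) {
        b <- detectBurstsString(spikeTimes(sts)[[id]], max_isi, min_spikes)
        if (nrow(b)) cbind(electrode_id = id, b, stringsAsFactors = FALSE)
        else NULL
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        out <- cbind(electrode_id = character(0),
                     detectBurstsString(numeric(0)))
    rownames(out) <- NULL
    out
}

#' Active electrodes of a recording
#'
#' An electrode is active when its mean firing rate strictly exceeds
#' `threshold` (default 0.1 spikes/s).
#'
#' @param sts a [SpikeTrainSet-class].
#' @param threshold spikes/s.
#' @return named logical vector per electrode.
#' @export
activeElectrodes <- function(sts, threshold = 0.1) {
    nSpikes(sts) / duration(sts) > threshold
}

#' Network-burst detection
#'
#' Electrode bursts that overlap or fall within `merge_interval` of each
#' other are merged into candidate population events; a candidate becomes a
#' network burst (NB) when it involves at least `min_fraction` of the
#' electrodes in the chosen base (active electrodes by default; all layout
#' electrodes with `fraction_base = "all"`). NB start/end are the min/max of
#' the merged burst bounds. Per-cluster spike subsets within the NB span are
#' attached.
#'
#' @param sts a [SpikeTrainSet-class].
#' @param bursts burst table from [detectBursts()] on the same `sts`.
#' @param min_fraction minimum participating fraction (default 0.20).
#' @param merge_interval merge gap, seconds (default 0.1).
#' @param fraction_base `"active"` (default) or `"all"`.
#' @param active_threshold MFR threshold for [activeElectrodes()].
#' @return data.frame with columns `start`, `end`, `n_electrodes`,
#'   `electrodes` (list column of ids) and `cluster_spikes` (list column:
#'   per-cluster spike-time lists within the NB span).
#' @export
detectNetworkBursts <- function(sts, bursts, min_fraction = 0.20,
                                merge_interval = 0.1,
                                fraction_base = c("active", "all"),
                                active_threshold = 0.1) {
    fraction_base <- match.arg(fraction_base)
    empty <- data.frame(start = numeric(0), end = numeric(0),
                        n_electrodes = integer(0))
    empty$electrodes <- list()
    empty$cluster_spikes <- list()
    act <- activeElectrodes(sts, active_threshold)
    n_base <- if (fraction_base == "active") sum(act) else length(act)
    if (n_base == 0L) {
        warning("no active electrodes; no network bursts")
        return(empty)
    }
    if (!nrow(bursts)) return(empty)
    b <- bursts[order(bursts$start), ]
    grp <- cumsum(c(1L, as.integer(b$start[-1] >
                                   cummax(b$end)[-nrow(b)] + merge_interval)))
    cl <- clusterId(sts)
    spikes <- spikeTimes(sts)
    rows <- lapply(split(seq_len(nrow(b)), grp), function(ix) {
        el <- unique(b$electrode_id[ix])
        if (length(el) < min_fraction * n_base) return(NULL)
        s0 <- min(b$start[ix]); s1 <- max(b$end[ix])
        by_cl <- lapply(sort(unique(cl)), function(q) {
            ids_q <- names(cl)[cl == q]
            unlist(lapply(spikes[ids_q],
                          function(tr) tr[tr >= s0 & tr <= s1]),
                   use.names = FALSE)
        })
        names(by_cl) <- paste0("cluster", sort(unique(cl)))
        out <- data.frame(start = s0, end = s1, n_electrodes = length(el))
        out$electrodes <- list(el)
        out$cluster_spikes <- list(by_cl)
        out
    })
    rows <- Filter(Negate(is.null), rows)
    if (!length(rows)) return(empty)
    out <- do.call(rbind, rows)
    out <- out[order(out$start), ]
    rownames(out) <- NULL
    out
}

#' Spiking and bursting activity metrics
#'
#' The four activity metrics: mean firing rate (MFR, spikes/s) per
#' electrode — also used to flag electrodes as active (MFR strictly above
#' 0.1 spikes/s); mean bursting rate (MBR, bursts/min) per electrode; burst
#' duration (BD, seconds) per burst; and inter-burst interval (IBI,
#' seconds) — the time elapsed between the end of one burst and the onset of
#' the next one on the same electrode.
#'
#' @param sts a [SpikeTrainSet-class].
#' @param bursts burst table from [detectBursts()].
#' @param nbs optional NB table from [detectNetworkBursts()]; when given,
#'   NB-level inter-event intervals are included.
#' @param active_threshold MFR threshold, spikes/s.
#' @return list with `per_electrode` (data.frame: `electrode_id`, `mfr`,
#'   `active`, `mbr`), `bd` (numeric vector of burst durations), `ibi`
#'   (numeric vector pooled over electrodes) and `nb_intervals` (onsets
#'   differences between consecutive NBs, or NULL).
#' @export
computeActivityMetrics <- function(sts, bursts, nbs = NULL,
                                   active_threshold = 0.1) {
    if (duration(sts) <= 0) stop("zero-duration recording")
    ids <- electrodeId(sts)
    mfr <- nSpikes(sts) / duration(sts)
    nb_per_el <- table(factor(bursts$electrode_id, levels = ids))
    mbr <- as.numeric(nb_per_el) / duration(sts) * 60
    ibi <- unlist(lapply(split(bursts, bursts$electrode_id), function(b) {
        if (nrow(b) < 2L) return(numeric(0))
        b <- b[order(b$start), ]
        b$start[-1] - b$end[-nrow(b)]
    }), use.names = FALSE)
    list(
        per_electrode = data.frame(
            electrode_id = ids, mfr = as.numeric(mfr),
            active = as.numeric(mfr) > active_threshold, mbr = mbr),
        bd = if (nrow(bursts)) bursts$end - bursts$start else numeric(0),
        ibi = if (is.null(ibi)) numeric(0) else ibi,
        nb_intervals = if (!is.null(nbs) && nrow(nbs) > 1L)
            diff(nbs$start) else NULL
    )
}
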
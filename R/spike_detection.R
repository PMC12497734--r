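#' Robust noise standard deviation of a voltage trace
#'
#' Spike-resistant estimate of the background noise SD: the median absolute
#' sample value divided by 0.6745 (the median absolute deviation of a
#' zero-mean Gaussian in SD units). Because spikes occupy a tiny fraction of
#' samples, the median is essentially unaffected by them, unlike the plain
#' SD which inflates.
#'
#' @param trace numeric samples, microvolts; at least 1000 samples.
#' @param windowed if `TRUE`, estimate per non-overlapping `window_s` chunk
#'   and return the median of the chunk estimates (for slowly drifting
#'   noise); default is the whole-trace estimate.
#' @param window_s chunk length in seconds for the windowed variant.
#' @param sampling_rate Hz, needed only for the windowed variant.
#' @return noise SD in the units of `trace`; 0 (with a warning) for a
#'   constant trace.
#' @export
estimateNoiseSD <- function(trace, windowed = FALSE, window_s = 1,
                            sampling_rate = 10000) {
    if (length(trace) < 1000) stop("trace must have at least 1000 samples")
    if (length(unique(trace)) == 1L) {
        warning("constant trace; returning noise SD 0")
        return(0)
    }
    if (windowed) {
        w <- max(1L, floor(window_s * sampling_rate))
        chunks <- split(trace, (seq_along(trace) - 1L) %/% w)
        return(stats::median(vapply(chunks, function(ch)
            stats::median(abs(ch)) / 0.6745, numeric(1))))
    }
    stats::median(abs(trace)) / 0.6745
}

#' Precision-time spike detection (differential threshold)
#'
#' Detects spikes on each electrode of a [VoltageRecording-class] by the
#' precision-time scheme: local extrema of the trace are located, and a
#' spike is declared whenever the peak-to-peak excursion between an extremum
#' and an opposite-sign extremum occurring within the `peak_lifetime_ms`
#' window exceeds `threshold_factor` times the electrode's noise SD
#' ([estimateNoiseSD()]). The spike timestamp is the time of the
#' larger-magnitude extremum of the pair (ties broken toward the earlier
#' sample). Detections closer than `refractory_ms` are collapsed, keeping
#' the larger-excursion one (earlier on ties).
#'
#' @param rec a [VoltageRecording-class].
#' @param threshold_factor multiple of the noise SD the peak-to-peak
#'   excursion must exceed (default 8).
#' @param peak_lifetime_ms maximum time between the two extrema of a spike,
#'   ms (default 2).
#' @param refractory_ms dead time after a detection, ms (default 1;
#'   `peak_lifetime_ms >= refractory_ms` required).
#' @param noise_windowed passed to [estimateNoiseSD()] as `windowed`.
#' @return a [SpikeTrainSet-class] of detected spike times.
#' @export
detectSpikesPTSD <- function(rec, threshold_factor = 8, peak_lifetime_ms = 2,
                             refractory_ms = 1, noise_windowed = FALSE) {
    stopifnot(threshold_factor > 0, peak_lifetime_ms > 0, refractory_ms > 0)
    if (peak_lifetime_ms < refractory_ms)
        stop("peak_lifetime_ms must be >= refractory_ms")
    rate <- samplingRate(rec)
    if (nrow(rec@samples) < peak_lifetime_ms / 1000 * rate)
        stop("trace shorter than the peak lifetime window")
    ids <- electrodeId(rec)
    spikes <- stats::setNames(vector("list", length(ids)), ids)
    for (id in ids) {
        spikes[[id]] <- .ptsdTrain(rec@samples[, id], rate, threshold_factor,
                                   peak_lifetime_ms / 1000,
                                   refractory_ms / 1000, noise_windowed)
    }
    SpikeTrainSet(layout4(rec), spikes, duration(rec))
}

.localExtrema <- function(x) {
    d <- diff(x)
    s <- sign(d)
    # carry the sign of the previous non-flat segment across plateaus
    nz <- s != 0
    if (!any(nz)) return(integer(0))
    s_f <- s
    s_f[!nz] <- NA
    s_f <- stats::approx(seq_along(s_f)[nz], s_f[nz], xout = seq_along(s_f),
                         method = "constant", rule = 2)$y
    which(diff(s_f) != 0) + 1L
}

.ptsdTrain <- function(trace, rate, thr_factor, lifetime_s, refractory_s,
                       noise_windowed) {
    sd0 <- suppressWarnings(estimateNoiseSD(trace, windowed = noise_windowed,
                                            sampling_rate = rate))
    # a zero noise estimate (noiseless/synthetic trace) degenerates to
    # detecting any positive excursion
    thr <- thr_factor * sd0
    ext_i <- .localExtrema(trace)
    if (length(ext_i) < 2L) return(numeric(0))
    ev <- trace[ext_i]
    n <- length(ext_i)
    max_lag_samples <- lifetime_s * rate
    # compare each extremum with the following ones inside the lifetime
    # window; consecutive extrema alternate polarity, so opposite-sign
    # partners are found at odd lags, but noise riding on a spike can insert
    # small wiggles — scanning all lags inside the window is robust to that
    best_exc <- numeric(n)
    best_j <- integer(n)
    lag <- 1L
    repeat {
        k <- seq_len(n - lag)
        in_win <- (ext_i[k + lag] - ext_i[k]) <= max_lag_samples
        if (!any(in_win)) break
        exc <- abs(ev[k + lag] - ev[k])
        exc[!in_win] <- 0
        upd <- which(exc > best_exc[k])
        best_exc[upd] <- exc[upd]
        best_j[upd] <- upd + lag
        lag <- lag + 1L
        if (lag >= n) break
    }
    hit <- which(best_exc > thr)
    if (!length(hit)) return(numeric(0))
    # timestamp = larger-magnitude extremum of the pair, earlier on ties
    t_idx <- vapply(hit, function(k) {
        j <- best_j[k]
        if (abs(ev[j]) > abs(ev[k])) ext_i[j] else ext_i[k]
    }, integer(1))
    ord <- order(ext_i[hit])
    times <- (t_idx - 1L) / rate
    exc_o <- best_exc[hit][ord]
    times <- times[ord]
    # refractory collapse: within a refractory of the previous kept spike,
    # keep the larger excursion (earlier on ties)
    keep_t <- numeric(0)
    keep_e <- numeric(0)
    for (m in seq_along(times)) {
        if (length(keep_t) && times[m] - keep_t[length(keep_t)] < refractory_s) {
            if (exc_o[m] > keep_e[length(keep_e)]) {
                keep_t[length(keep_t)] <- times[m]
                keep_e[length(keep_e)] <- exc_o[m]
            }
        } else {
            keep_t <- c(keep_t, times[m])
            keep_e <- c(keep_e, exc_o[m])
        }
    }
    unique(sort(keep_t))
}
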
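#' Simulate clustered network activity with known ground truth
#'
#' Generates a [SpikeTrainSet-class] emulating spontaneous activity of a
#' four-cluster culture: network-burst (NB) events arrive as a homogeneous
#' Poisson process (with a minimum separation enforced so consecutive NBs
#' remain resolvable); each NB activates the clusters in an ordered
#' activation sequence that repeats the previous NB's sequence with
#' probability `p_rep` (first-order Markov persistence) and is otherwise
#' drawn uniformly from `motif_repertoire`; within an NB every electrode of a
#' participating cluster emits a burst of `burst_spikes_per_electrode` spikes
#' (intra-burst inter-spike intervals well below 100 ms) centred on its
#' cluster's activation time, successive clusters being spaced by
#' `inter_cluster_lag_ms`; independent Poisson background spikes are
#' superimposed. All randomness derives from `seed`.
#'
#' Defaults (see [defaultRunConfig()] section `simulate`) represent one
#' 10-minute recording of a moderately active culture.
#'
#' @param layout an [MEALayout-class]; default [defaultLayout4Q()].
#' @param duration recording length, seconds.
#' @param nb_rate NB rate, events/s, before the minimum-separation thinning.
#' @param motif_repertoire list of integer vectors: cluster orderings the
#'   sequences are drawn from.
#' @param p_rep probability in `[0,1]` that an NB repeats the previous
#'   sequence.
#' @param intra_cluster_lag_ms spread (SD, ms) of electrode burst centres
#'   around their cluster activation time.
#' @param inter_cluster_lag_ms spacing, ms, between consecutive cluster
#'   activations within an NB.
#' @param background_rate background Poisson rate, spikes/s per electrode.
#' @param burst_spikes_per_electrode spikes per electrode per NB burst
#'   (>= 5 so bursts satisfy the string-method definition).
#' @param min_separation_s minimum separation between NB onsets, seconds.
#' @param seed integer seed.
#' @return list with elements `spikes` (a [SpikeTrainSet-class]) and `truth`
#'   (list: `nb_onsets`, `sequences` — list of integer vectors, `p_rep`,
#'   `background_rate`, `connections` — empty data.frame placeholder filled
#'   by [plantConnectivity()]).
#' @seealso [plantConnectivity()], [synthesizeVoltage()]
#' @export
#' @examples
#' sim <- simulateActivity(duration = 60, seed = 1)
#' sim$spikes
#' head(sim$truth$nb_onsets)
simulateActivity <- function(layout = defaultLayout4Q(),
                             duration = 600,
                             nb_rate = 0.2,
                             motif_repertoire = list(c(1, 2, 3, 4),
                                                     c(2, 1, 4, 3),
                                                     c(3, 4, 1, 2),
                                                     c(4, 3, 2, 1),
                                                     c(1, 3, 2, 4),
                                                     c(2, 4, 3, 1)),
                             p_rep = 0.5,
                             intra_cluster_lag_ms = 2,
                             inter_cluster_lag_ms = 100,
                             background_rate = 0.2,
                             burst_spikes_per_electrode = 8,
                             min_separation_s = 1,
                             seed = 1) {
    if (!length(motif_repertoire)) stop("motif repertoire must be non-empty")
    if (duration <= 0) stop("duration must be positive")
    if (nb_rate < 0 || background_rate < 0) stop("rates must be >= 0")
    if (p_rep < 0 || p_rep > 1) stop("p_rep must be in [0, 1]")
    if (nb_rate > 0 && nb_rate * min_separation_s >= 1)
        stop("infeasible packing: nb_rate * min_separation_s must be < 1")
    set.seed(.seedFor(seed, "simulate_activity"))

    cl <- clusterId(layout)
    ids <- electrodeId(layout)
    n_cl <- max(cl)
    seq_span <- (n_cl - 1) * inter_cluster_lag_ms / 1000 + 0.2
    # NB onsets: exponential gaps with the minimum separation enforced
    onsets <- numeric(0)
    if (nb_rate > 0) {
        t <- 0.1
        repeat {
            t <- t + stats::rexp(1, nb_rate)
            if (length(onsets) && t - onsets[length(onsets)] < min_separation_s)
                t <- onsets[length(onsets)] + min_separation_s
            if (t > duration - seq_span) break
            onsets <- c(onsets, t)
        }
    }

    sequences <- vector("list", length(onsets))
    if (length(onsets)) {
        sequences[[1]] <- motif_repertoire[[sample.int(length(motif_repertoire), 1)]]
        for (k in seq_along(onsets)[-1]) {
            sequences[[k]] <- if (stats::runif(1) < p_rep) sequences[[k - 1]]
                else motif_repertoire[[sample.int(length(motif_repertoire), 1)]]
        }
    }

    spikes <- stats::setNames(vector("list", length(ids)), ids)
    for (id in ids) spikes[[id]] <- numeric(0)

    nb_spk <- burst_spikes_per_electrode
    for (k in seq_along(onsets)) {
        sq <- sequences[[k]]
        for (pos in seq_along(sq)) {
            centre <- onsets[k] + (pos - 1) * inter_cluster_lag_ms / 1000
            for (id in ids[cl == sq[pos]]) {
                if (nb_spk <= 0) next
                jitter <- stats::rnorm(1, 0, intra_cluster_lag_ms / 1000)
                isis <- stats::runif(nb_spk - 1, 0.002, 0.006)
                st <- centre + jitter + c(0, cumsum(isis)) -
                    sum(isis) / 2
                spikes[[id]] <- c(spikes[[id]], st)
            }
        }
    }

    if (background_rate > 0) {
        for (id in ids) {
            n_bg <- stats::rpois(1, background_rate * duration)
            spikes[[id]] <- c(spikes[[id]], stats::runif(n_bg, 0, duration))
        }
    }

    spikes <- lapply(spikes, .canonicalTrain, duration = duration)
    sts <- SpikeTrainSet(layout, spikes, duration)
    truth <- list(nb_onsets = onsets, sequences = sequences, p_rep = p_rep,
                  background_rate = background_rate,
                  connections = .emptyConnections())
    list(spikes = sts, truth = truth)
}

# sort, clamp to [0, duration], deduplicate at 0.1 ms resolution
.canonicalTrain <- function(tr, duration) {
    tr <- tr[tr >= 0 & tr <= duration]
    tr <- sort(tr)
    if (length(tr) > 1L) {
        keep <- c(TRUE, diff(tr) >= 1e-4)
        tr <- tr[keep]
    }
    tr
}

.emptyConnections <- function() {
    data.frame(source = character(0), target = character(0),
               sign = integer(0), delay_ms = numeric(0),
               prob = numeric(0), stringsAsFactors = FALSE)
}

#' Plant directed connections into a spike-train set
#'
#' Benchmark substrate for connectivity estimation. For each excitatory
#' connection (`sign = +1`), every source spike triggers an inserted target
#' spike at `source time + delay_ms` with probability `prob`. For each
#' inhibitory connection (`sign = -1`), target spikes falling within a 5 ms
#' suppression window after a source spike are deleted with probability
#' `prob`. Output trains are re-sorted, clipped to the recording and
#' deduplicated at 0.1 ms resolution.
#'
#' @param sts a [SpikeTrainSet-class].
#' @param connections data.frame with columns `source`, `target` (electrode
#'   ids), `sign` (+1 excitatory / -1 inhibitory), `delay_ms` (> 0) and
#'   `prob` in `[0,1]`.
#' @param seed integer seed.
#' @return a new [SpikeTrainSet-class] with the connections expressed.
#' @export
plantConnectivity <- function(sts, connections, seed = 1) {
    ids <- electrodeId(sts)
    if (!all(connections$source %in% ids) || !all(connections$target %in% ids))
        stop("connection endpoints must be layout electrodes")
    if (any(connections$delay_ms <= 0)) stop("delays must be > 0")
    if (any(connections$prob < 0 | connections$prob > 1))
        stop("transfer probabilities must be in [0, 1]")
    set.seed(.seedFor(seed, "plant_connectivity"))
    spikes <- spikeTimes(sts)
    for (i in seq_len(nrow(connections))) {
        cn <- connections[i, ]
        src <- spikes[[cn$source]]
        if (!length(src)) next
        if (cn$sign > 0) {
            take <- stats::runif(length(src)) < cn$prob
            ins <- src[take] + cn$delay_ms / 1000
            spikes[[cn$target]] <- c(spikes[[cn$target]], ins)
        } else {
            tgt <- spikes[[cn$target]]
            if (!length(tgt)) next
            idx <- findInterval(tgt, src)
            hit <- idx >= 1L & (tgt - src[pmax(idx, 1L)]) <= 0.005 &
                (tgt - src[pmax(idx, 1L)]) > 0
            del <- hit & stats::runif(length(tgt)) < cn$prob
            spikes[[cn$target]] <- tgt[!del]
        }
    }
    spikes <- lapply(spikes, .canonicalTrain, duration = duration(sts))
    SpikeTrainSet(layout4(sts), spikes, duration(sts))
}

#' Default biphasic spike waveform template
#'
#' A 1 ms biphasic (negative-then-positive) waveform at the given sampling
#' rate, normalized to unit peak-to-peak amplitude: the classic extracellular
#' spike shape used to synthesize test voltage.
#'
#' @param sampling_rate Hz.
#' @return numeric vector of samples, peak-to-peak = 1.
#' @export
biphasicTemplate <- function(sampling_rate = 10000) {
    t <- seq(0, 0.001, by = 1 / sampling_rate)
    # dominant negative phase followed by a smaller repolarization lobe
    w <- -exp(-((t - 0.00025) / 0.0001)^2) +
        0.45 * exp(-((t - 0.0005) / 0.00012)^2)
    w / (max(w) - min(w))
}

#' Synthesize a voltage recording from spike times
#'
#' White Gaussian noise of SD `noise_sd` with the spike `template` added at
#' every spike time, scaled so the template peak-to-peak amplitude equals
#' `amplitude_sd_ratio * noise_sd` (if `noise_sd` is 0 the template is scaled
#' by `amplitude_sd_ratio` microvolts). Templates closer than the template
#' length overlap and are summed linearly, with a warning.
#'
#' @param sts a [SpikeTrainSet-class] giving the true spike times.
#' @param template waveform samples at the layout sampling rate; must be
#'   shorter than 2 ms.
#' @param amplitude_sd_ratio target peak-to-peak amplitude as a multiple of
#'   the noise SD.
#' @param noise_sd noise standard deviation, microvolts.
#' @param seed integer seed.
#' @return a [VoltageRecording-class].
#' @export
synthesizeVoltage <- function(sts, template = biphasicTemplate(samplingRate(sts)),
                              amplitude_sd_ratio = 10, noise_sd = 1,
                              seed = 1) {
    rate <- samplingRate(sts)
    if (length(template) >= 0.002 * rate + 1)
        stop("template must be shorter than 2 ms at the layout sampling rate")
    set.seed(.seedFor(seed, "synthesize_voltage"))
    n <- round(duration(sts) * rate)
    ids <- electrodeId(sts)
    p2p <- max(template) - min(template)
    amp <- amplitude_sd_ratio * if (noise_sd > 0) noise_sd else 1
    shape <- template / p2p * amp
    sam <- matrix(0, nrow = n, ncol = length(ids),
                  dimnames = list(NULL, ids))
    for (j in seq_along(ids)) {
        trace <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
        st <- spikeTimes(sts)[[ids[j]]]
        if (length(st)) {
            if (length(st) > 1L && any(diff(st) < length(template) / rate))
                warning("overlapping spike templates on electrode ", ids[j],
                        "; summed linearly")
            # template centred so its largest-magnitude extremum lands on the
            # spike time
            peak_off <- which.max(abs(shape)) - 1L
            for (tt in st) {
                i0 <- round(tt * rate) - peak_off + 1L
                idx <- i0:(i0 + length(shape) - 1L)
                ok <- idx >= 1L & idx <= n
                trace[idx[ok]] <- trace[idx[ok]] + shape[ok]
            }
        }
        sam[, j] <- trace
    }
    new("VoltageRecording", layout = layout4(sts), samples = sam,
        duration = n / rate)
}

#' Simulate normalized dose-response data
#'
#' Responses follow the Hill inhibition curve
#' `r(c) = 1 / (1 + (c / ic50)^hill_n)` with additive Gaussian noise,
#' clipped at 0. The default concentration ladder is the nine-step MK-801
#' protocol (1 nM to 10 uM in 1-3-10 steps).
#'
#' @param ic50 half-maximal inhibitory concentration, molar (> 0).
#' @param hill_n Hill coefficient (> 0).
#' @param concentrations molar concentrations.
#' @param noise_sd SD of additive Gaussian noise on the unitless response.
#' @param seed integer seed.
#' @return data.frame with columns `concentration`, `response`.
#' @export
simulateDoseResponse <- function(ic50, hill_n,
                                 concentrations =
                                     defaultRunConfig()$dose_response$concentrations_molar,
                                 noise_sd = 0, seed = 1) {
    if (ic50 <= 0 || hill_n <= 0) stop("ic50 and hill_n must be > 0")
    set.seed(.seedFor(seed, "simulate_dose_response"))
    r <- 1 / (1 + (concentrations / ic50)^hill_n)
    if (noise_sd > 0) r <- r + stats::rnorm(length(r), 0, noise_sd)
    data.frame(concentration = concentrations, response = pmax(r, 0))
}

# derive a stage-specific 31-bit seed from the user seed so stages using the
# same user seed draw independent streams
.seedFor <- function(seed, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
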
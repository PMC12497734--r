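#' Cross-correlogram of two spike trains
#'
#' Counts of time differences `t_j - t_i` (target minus source) falling into
#' uniform lag bins. Bin `k` covers `((k - 0.5) * bin, (k + 0.5) * bin]`
#' seconds, so bin centres sit on multiples of the bin width and lag 0 is a
#' bin centre.
#'
#' @param ti,tj sorted spike times, seconds (source, target).
#' @param bin bin width, seconds.
#' @param lag_min,lag_max lag range in bins (integers, inclusive).
#' @return integer vector of counts, one per bin `lag_min:lag_max`.
#' @keywords internal
.crossCounts <- function(ti, tj, bin, lag_min, lag_max) {
    counts <- integer(lag_max - lag_min + 1L)
    if (!length(ti) || !length(tj)) return(counts)
    lo_t <- (lag_min - 0.5) * bin
    hi_t <- (lag_max + 0.5) * bin
    i_lo <- findInterval(ti + lo_t, tj) + 1L
    i_hi <- findInterval(ti + hi_t, tj)
    n_per <- pmax(i_hi - i_lo + 1L, 0L)
    if (!sum(n_per)) return(counts)
    j_idx <- sequence(n_per) + rep(i_lo - 1L, n_per)
    d <- tj[j_idx] - rep(ti, n_per)
    k <- as.integer(ceiling(d / bin - 0.5))
    k <- k[k >= lag_min & k <= lag_max]
    tabulate(k - lag_min + 1L, length(counts))
}

.tspeFilterBank <- function(surrounding = 3:8, observed = 2:3, crossing = 0) {
    combos <- expand.grid(a = surrounding, b = observed, c = crossing)
    lapply(seq_len(nrow(combos)), function(i)
        list(a = combos$a[i], b = combos$b[i], c = combos$c[i]))
}

# SPE curve over candidate delays 1..max_delay (bins) from a normalized
# cross-correlogram ncc covering bins lag_min:lag_max
.speCurve <- function(ncc, lag_min, max_delay, bank) {
    at <- function(k) ncc[k - lag_min + 1L]
    d <- seq_len(max_delay)
    spe <- numeric(max_delay)
    for (f in bank) {
        obs <- rowMeans(vapply(0:(f$b - 1L), function(k) at(d + k),
                               numeric(length(d))))
        fl_lo <- rowMeans(vapply(seq_len(f$a), function(k)
            at(d - f$c - k), numeric(length(d))))
        fl_hi <- rowMeans(vapply(seq_len(f$a), function(k)
            at(d + f$b - 1L + f$c + k), numeric(length(d))))
        spe <- spe + (obs - (fl_lo + fl_hi) / 2)
    }
    spe
}

#' Total Spiking Probability Edges (TSPE) connectivity
#'
#' For every ordered electrode pair, the cross-correlogram of target-minus-
#' source spike-time differences is computed at `bin_ms` resolution over
#' candidate delays `1..max_delay_ms`, normalized by the source spike count
#' (an empirical spiking probability), and convolved with a bank of edge
#' filters (running-average flanks of `surrounding_bins` bins on each side,
#' an observation window of `observed_bins` bins, separated by
#' `crossing_bins` bins). The pair's weight is the signed extremum of the
#' summed filtered curve over delays; a positive weight marks putative
#' excitation (a correlogram peak at positive delay), a negative weight
#' putative inhibition (a trough). The delay at the extremum is recorded.
#'
#' Pairs in which either train has fewer than `min_spikes_per_train` spikes
#' are skipped with a warning (too few events for a stable correlogram).
#'
#' @param sts a [SpikeTrainSet-class] (>= 2 active electrodes; >= 60 s
#'   recommended).
#' @param bin_ms correlogram bin width, ms (default 1).
#' @param max_delay_ms maximum candidate delay, ms (default 25).
#' @param surrounding_bins,observed_bins,crossing_bins filter-bank window
#'   sizes in bins.
#' @param min_spikes_per_train minimum spikes per electrode (default 10).
#' @return an unfiltered [ConnectivityGraph-class] (CI0 column `NA`; attach
#'   with [addCoincidenceIndex()]).
#' @export
tspe <- function(sts, bin_ms = 1, max_delay_ms = 25, surrounding_bins = 3:8,
                 observed_bins = 2:3, crossing_bins = 0,
                 min_spikes_per_train = 10) {
    spikes <- spikeTimes(sts)
    ids <- electrodeId(sts)
    n_sp <- nSpikes(sts)
    usable <- ids[n_sp >= min_spikes_per_train]
    if (length(usable) < length(ids))
        warning(length(ids) - length(usable),
                " electrode(s) with < ", min_spikes_per_train,
                " spikes skipped")
    if (length(usable) < 2L)
        stop("need at least 2 electrodes with enough spikes")
    bank <- .tspeFilterBank(surrounding_bins, observed_bins, crossing_bins)
    bin <- bin_ms / 1000
    max_d <- as.integer(round(max_delay_ms / bin_ms))
    pad <- max(surrounding_bins) + max(crossing_bins) + max(observed_bins)
    lag_min <- 1L - max(crossing_bins) - max(surrounding_bins)
    lag_max <- max_d + pad
    cl <- clusterId(sts)
    res <- vector("list", length(usable) * (length(usable) - 1L))
    r <- 0L
    for (i in usable) {
        for (j in usable) {
            if (i == j) next
            cc <- .crossCounts(spikes[[i]], spikes[[j]], bin, lag_min, lag_max)
            ncc <- cc / length(spikes[[i]])
            spe <- .speCurve(ncc, lag_min, max_d, bank)
            k <- which.max(abs(spe))
            r <- r + 1L
            res[[r]] <- data.frame(
                source = i, target = j, weight = spe[k],
                delay_ms = k * bin_ms,
                label = if (cl[[i]] == cl[[j]]) "intra" else "inter",
                stringsAsFactors = FALSE)
        }
    }
    e <- do.call(rbind, res[seq_len(r)])
    e$ci0 <- NA_real_
    rownames(e) <- NULL
    new("ConnectivityGraph", layout = layout4(sts), edges = e,
        filtered = FALSE)
}

#' Surrogate-based significance threshold for TSPE weights
#'
#' Destroys fine spike timing while preserving rates: every spike is
#' independently jittered by a uniform offset in `+/- jitter_ms`, TSPE is
#' recomputed, and the pooled absolute weights across `n_surrogates`
#' surrogates form the null. The returned threshold is the `q` quantile of
#' that null; observed edges with `|weight|` below it are consistent with
#' chance coincidences.
#'
#' @param sts a [SpikeTrainSet-class].
#' @param n_surrogates number of jitter surrogates (default 100).
#' @param jitter_ms jitter half-width, ms (default 10).
#' @param q quantile of the pooled null (default 0.99).
#' @param seed integer seed.
#' @param ... passed to [tspe()].
#' @return numeric threshold, with attribute `null` (pooled |weights|).
#' @export
tspeSurrogateThreshold <- function(sts, n_surrogates = 100, jitter_ms = 10,
                                   q = 0.99, seed = 1, ...) {
    set.seed(.seedFor(seed, "tspe_surrogates"))
    pool <- vector("list", n_surrogates)
    for (s in seq_len(n_surrogates)) {
        jit <- lapply(spikeTimes(sts), function(tr)
            .canonicalTrain(tr + stats::runif(length(tr), -jitter_ms / 1000,
                                              jitter_ms / 1000),
                            duration(sts)))
        sur <- SpikeTrainSet(layout4(sts), jit, duration(sts))
        g <- suppressWarnings(tspe(sur, ...))
        pool[[s]] <- abs(edges(g)$weight)
    }
    pool <- unlist(pool)
    thr <- unname(stats::quantile(pool, q))
    attr(thr, "null") <- pool
    thr
}

#' Filter a connectivity graph by spatial, physiological and weight rules
#'
#' Three deterministic filters, each disabled by passing `NULL`:
#' \describe{
#'   \item{spatial}{the implied propagation speed (electrode distance /
#'     best delay) must lie within `speed_bounds_m_s`, excluding connections
#'     beyond plausible propagation distances;}
#'   \item{physiological}{the best delay must lie within
#'     `latency_bounds_ms`, removing edges inconsistent with synaptic
#'     timing;}
#'   \item{weight}{`|weight|` must reach `weight_threshold`, e.g. from
#'     [tspeSurrogateThreshold()].}
#' }
#' Output edges are a subset of the input; the operation is idempotent.
#'
#' @param g a [ConnectivityGraph-class].
#' @param speed_bounds_m_s numeric `c(min, max)` in m/s, or `NULL`.
#' @param latency_bounds_ms numeric `c(min, max)` in ms, or `NULL`.
#' @param weight_threshold scalar, or `NULL`.
#' @return a filtered [ConnectivityGraph-class].
#' @export
filterEdges <- function(g, speed_bounds_m_s = c(0.02, 2),
                        latency_bounds_ms = c(1, 25),
                        weight_threshold = NULL) {
    e <- edges(g)
    keep <- rep(TRUE, nrow(e))
    if (!is.null(speed_bounds_m_s) && nrow(e)) {
        dmat <- electrodeDistances(layout4(g))
        dist_m <- dmat[cbind(e$source, e$target)] * 1e-6
        speed <- dist_m / (e$delay_ms * 1e-3)
        keep <- keep & speed >= speed_bounds_m_s[1] &
            speed <= speed_bounds_m_s[2]
    }
    if (!is.null(latency_bounds_ms) && nrow(e))
        keep <- keep & e$delay_ms >= latency_bounds_ms[1] &
            e$delay_ms <= latency_bounds_ms[2]
    if (!is.null(weight_threshold) && nrow(e))
        keep <- keep & abs(e$weight) >= weight_threshold
    out <- e[keep, , drop = FALSE]
    rownames(out) <- NULL
    new("ConnectivityGraph", layout = layout4(g), edges = out,
        filtered = TRUE)
}

#' Coincidence index CI0 of two spike trains
#'
#' The fraction of cross-correlogram mass at near-zero lag: the integral of
#' the cross-correlation within `+/- sync_halfwidth_ms` divided by the total
#' integral across the `+/- lag_halfwidth_ms` window. Computed directly from
#' the spike-time differences, so it is exactly symmetric under exchange of
#' the trains. 1 means all co-occurrences are near-simultaneous (strong
#' functional coupling); an uncorrelated pair with a flat correlogram gives
#' approximately `sync_halfwidth / lag_halfwidth` (0.01 at the +/-1 ms /
#' +/-100 ms defaults). Defined as 0 when no differences fall in the lag
#' window.
#'
#' @param train_i,train_j non-empty sorted spike-time vectors, seconds.
#' @param sync_halfwidth_ms synchrony window half-width, ms (default 1).
#' @param lag_halfwidth_ms correlogram half-width, ms (default 100).
#' @param bin_ms correlogram bin, ms (default 0.5; CI0 itself is computed
#'   from exact differences, the bin only shapes the returned correlogram).
#' @return CI0 in `[0, 1]`, with attribute `correlogram` (data.frame
#'   `lag_ms`, `count`).
#' @export
coincidenceIndex <- function(train_i, train_j, sync_halfwidth_ms = 1,
                             lag_halfwidth_ms = 100, bin_ms = 0.5) {
    if (!length(train_i) || !length(train_j))
        stop("coincidence index requires two non-empty trains")
    lag <- lag_halfwidth_ms / 1000
    sync <- sync_halfwidth_ms / 1000
    i_lo <- findInterval(train_i - lag, train_j) + 1L
    i_hi <- findInterval(train_i + lag, train_j)
    n_per <- pmax(i_hi - i_lo + 1L, 0L)
    total <- sum(n_per)
    if (!total) {
        out <- 0
        attr(out, "correlogram") <- data.frame(lag_ms = numeric(0),
                                               count = integer(0))
        return(out)
    }
    j_idx <- sequence(n_per) + rep(i_lo - 1L, n_per)
    d <- train_j[j_idx] - rep(train_i, n_per)
    ci0 <- sum(abs(d) <= sync) / total
    nb <- as.integer(round(lag_halfwidth_ms / bin_ms))
    k <- pmax(pmin(as.integer(ceiling(d * 1000 / bin_ms - 0.5)), nb), -nb)
    cg <- data.frame(lag_ms = (-nb:nb) * bin_ms,
                     count = tabulate(k + nb + 1L, 2L * nb + 1L))
    attr(ci0, "correlogram") <- cg
    ci0
}

#' Attach CI0 values to a connectivity graph
#'
#' Computes [coincidenceIndex()] for every edge of `g` (undirected pair
#' value, so reciprocal edges get the same CI0).
#'
#' @param g a [ConnectivityGraph-class].
#' @param sts the [SpikeTrainSet-class] the graph was estimated from.
#' @param ... passed to [coincidenceIndex()].
#' @return `g` with the `ci0` edge column filled.
#' @export
addCoincidenceIndex <- function(g, sts, ...) {
    e <- edges(g)
    if (nrow(e)) {
        key <- ifelse(e$source < e$target, paste(e$source, e$target),
                      paste(e$target, e$source))
        spikes <- spikeTimes(sts)
        vals <- vapply(unique(key), function(k) {
            pr <- strsplit(k, " ")[[1]]
            as.numeric(coincidenceIndex(spikes[[pr[1]]], spikes[[pr[2]]], ...))
        }, numeric(1))
        e$ci0 <- unname(vals[key])
    }
    methods::initialize(g, edges = e)
}

#' Condition-versus-baseline variation of connectivity summaries
#'
#' Percent change, relative to baseline, of six summaries of the filtered
#' connectivity graph: inter- and intra-cluster edge counts, mean absolute
#' edge weight (inter/intra) and mean CI0 (inter/intra). Quantities whose
#' baseline value is 0 (or unavailable) are flagged undefined rather than
#' silently zeroed.
#'
#' @param g_base,g_cond [ConnectivityGraph-class] objects on the same layout.
#' @return data.frame with columns `quantity`, `baseline`, `condition`,
#'   `pct_change`, `defined`.
#' @export
variationVsBaseline <- function(g_base, g_cond) {
    if (!identical(electrodeId(layout4(g_base)), electrodeId(layout4(g_cond))))
        stop("graphs must share the same layout")
    summarise <- function(g) {
        e <- edges(g)
        per <- function(lbl) {
            sub <- e[e$label == lbl, , drop = FALSE]
            c(count = nrow(sub),
              mean_weight = if (nrow(sub)) mean(abs(sub$weight)) else NA_real_,
              mean_ci0 = if (nrow(sub) && any(!is.na(sub$ci0)))
                  mean(sub$ci0, na.rm = TRUE) else NA_real_)
        }
        c(inter = per("inter"), intra = per("intra"))
    }
    b <- summarise(g_base); cnd <- summarise(g_cond)
    qty <- c("inter.count", "intra.count", "inter.mean_weight",
             "intra.mean_weight", "inter.mean_ci0", "intra.mean_ci0")
    base_v <- b[qty]; cond_v <- cnd[qty]
    defined <- !is.na(base_v) & !is.na(cond_v) & base_v > 0
    pct <- ifelse(defined, 100 * (cond_v - base_v) / base_v, NA_real_)
    data.frame(quantity = qty, baseline = unname(base_v),
               condition = unname(cond_v), pct_change = unname(pct),
               defined = unname(defined), row.names = NULL)
}
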
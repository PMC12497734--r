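#' Instantaneous firing rate by Gaussian-kernel smoothing
#'
#' Spike counts on a uniform grid convolved with a unit-area Gaussian kernel
#' (SD `kernel_sd_ms`, truncated at `truncation_sd` SDs and renormalized to
#' unit mass) and scaled to spikes/s. With the defaults the kernel support
#' spans 100 ms (+/-2 SD of a 25 ms kernel). The operation is linear in the
#' input, and the time integral of the returned rate equals the spike count
#' falling on the grid (up to mass smoothed past the grid ends, which the
#' caller avoids by padding the window).
#'
#' @param spikes numeric spike times, seconds (any order; may be empty).
#' @param t_start,t_end window over which to evaluate the rate, seconds.
#' @param kernel_sd_ms Gaussian kernel SD, ms (> 0).
#' @param bin_ms grid resolution, ms; must be at most `kernel_sd_ms / 5`.
#' @param truncation_sd kernel truncation, in SDs.
#' @return data.frame with columns `time` (bin centres, s) and `rate`
#'   (spikes/s).
#' @export
computeIFR <- function(spikes, t_start, t_end, kernel_sd_ms = 25, bin_ms = 1,
                       truncation_sd = 2) {
    stopifnot(kernel_sd_ms > 0, t_end > t_start)
    if (bin_ms > kernel_sd_ms / 5)
        stop("bin_ms must be at most kernel_sd_ms / 5")
    bin <- bin_ms / 1000
    edges <- seq(t_start, t_end + bin, by = bin)
    centres <- edges[-length(edges)] + bin / 2
    counts <- if (length(spikes))
        tabulate(findInterval(spikes[spikes >= t_start & spikes < t_end],
                              edges), length(centres))
    else rep(0L, length(centres))
    half <- ceiling(truncation_sd * kernel_sd_ms / bin_ms)
    kx <- (-half:half) * bin
    kern <- exp(-0.5 * (kx / (kernel_sd_ms / 1000))^2)
    kern <- kern / sum(kern)
    sm <- stats::convolve(counts, rev(kern), type = "open")
    sm <- sm[(half + 1):(half + length(centres))]
    data.frame(time = centres, rate = pmax(sm, 0) / bin)
}

#' Cluster activation sequence of one network burst
#'
#' For each cluster with at least one spike inside the NB span, the IFR is
#' evaluated over the span padded by the kernel truncation, and clusters are
#' ordered by the time of their global IFR maximum. The first cluster is the
#' initiator. Ties are broken by the earlier peak sample, then by cluster
#' id. Silent clusters are excluded, yielding a partial sequence.
#'
#' @param nb one row of the [detectNetworkBursts()] table (data.frame with
#'   `start`, `end`, `cluster_spikes`).
#' @param kernel_sd_ms,bin_ms,truncation_sd passed to [computeIFR()].
#' @return integer vector of cluster ids in activation order, with
#'   attributes `peak_times` (numeric, seconds) and `initiator`.
#' @export
extractSequence <- function(nb, kernel_sd_ms = 25, bin_ms = 1,
                            truncation_sd = 2) {
    spk <- nb$cluster_spikes[[1]]
    pad <- truncation_sd * kernel_sd_ms / 1000
    t0 <- nb$start - pad
    t1 <- nb$end + pad
    present <- which(vapply(spk, function(s)
        sum(s >= nb$start & s <= nb$end) > 0, logical(1)))
    if (!length(present))
        stop("inconsistent network burst: all clusters silent")
    peak <- vapply(present, function(q) {
        ifr <- computeIFR(spk[[q]], t0, t1, kernel_sd_ms, bin_ms,
                          truncation_sd)
        ifr$time[which.max(ifr$rate)]   # which.max: earliest bin on ties
    }, numeric(1))
    ord <- order(peak, present)          # cluster id breaks remaining ties
    out <- as.integer(present[ord])
    attr(out, "peak_times") <- peak[ord]
    attr(out, "initiator") <- out[1]
    out
}

#' Activation sequences for all network bursts
#'
#' @param nbs table from [detectNetworkBursts()].
#' @param ... passed to [extractSequence()].
#' @return list of integer vectors (one per NB, in NB order).
#' @export
extractSequences <- function(nbs, ...) {
    lapply(seq_len(nrow(nbs)), function(i) extractSequence(nbs[i, ], ...))
}

.sequenceKey <- function(sq) paste(sq, collapse = "-")

#' Run lengths of identical consecutive activation sequences
#'
#' Given sequences ordered by NB time, returns the length of every maximal
#' run of consecutive identical sequences (equality = identical ordered
#' cluster tuple, including participation). A run of length >= 2 is a
#' "repeated" series; the count axis includes the first occurrence, so a
#' pair counts as 2.
#'
#' @param sequences list of integer vectors (or character keys), NB order.
#' @return integer vector of run lengths; sums to `length(sequences)`.
#' @export
#' @examples
#' runLengths(list(c(1,2), c(1,2), c(1,2), c(3,4), c(3,4), c(2,1)))
runLengths <- function(sequences) {
    if (!length(sequences)) return(integer(0))
    keys <- vapply(sequences, function(s)
        if (is.character(s)) s else .sequenceKey(s), character(1))
    rle(keys)$lengths
}

#' Shannon diversity and equitability of sequence types
#'
#' `H = -sum(p_i * log(p_i))` in nats over the observed types;
#' `J = H / log(N)` with `N` the number of observed types (J defined as 0
#' when a single type is observed). J ranges from 0 (one dominant type) to 1
#' (all observed types equally frequent).
#'
#' @param counts non-negative type counts, at least one positive; zero
#'   counts are dropped (unobserved types carry no mass).
#' @return list with elements `H` (nats) and `J` (unitless in `[0,1]`).
#' @export
#' @examples
#' shannonEquitability(c(2, 1, 1))
shannonEquitability <- function(counts) {
    if (any(counts < 0)) stop("counts must be >= 0")
    counts <- counts[counts > 0]
    if (!length(counts)) stop("at least one count must be positive")
    p <- counts / sum(counts)
    H <- -sum(p * log(p))
    J <- if (length(counts) == 1L) 0 else H / log(length(counts))
    list(H = H, J = J)
}

#' Type counts of a sequence list
#'
#' @param sequences list of integer vectors.
#' @return named integer vector of counts per sequence type.
#' @export
sequenceTypeCounts <- function(sequences) {
    keys <- vapply(sequences, .sequenceKey, character(1))
    table_ <- table(keys)
    stats::setNames(as.integer(table_), names(table_))
}

#' Monte Carlo permutation null for run lengths
#'
#' Each iteration uniformly permutes the observed sequence list — preserving
#' the multiset of sequence types exactly — and records the run lengths. The
#' pooled lengths across iterations form the null distribution of run
#' lengths under temporal exchangeability; comparing the observed run-length
#' distribution against it asks whether identical sequences recur in
#' consecutive network bursts more than chance ordering would produce.
#'
#' @param sequences list of >= 2 integer vectors (NB order).
#' @param n_iter iterations, >= 100 (default 1000).
#' @param seed integer seed (reproducible).
#' @return list: `pooled` (integer run lengths pooled across iterations),
#'   `per_iter` (data.frame: `mean_run`, `max_run`, `n_runs` per iteration),
#'   `n_iter`, `seed`.
#' @export
monteCarloNull <- function(sequences, n_iter = 1000, seed = 1) {
    if (length(sequences) < 2L) stop("need at least 2 sequences")
    if (n_iter < 100) stop("n_iter must be >= 100")
    set.seed(.seedFor(seed, "monte_carlo_null"))
    keys <- vapply(sequences, .sequenceKey, character(1))
    pooled <- vector("list", n_iter)
    mean_run <- numeric(n_iter); max_run <- numeric(n_iter)
    n_runs <- integer(n_iter)
    for (i in seq_len(n_iter)) {
        rl <- rle(sample(keys))$lengths
        pooled[[i]] <- rl
        mean_run[i] <- mean(rl); max_run[i] <- max(rl); n_runs[i] <- length(rl)
    }
    list(pooled = unlist(pooled),
         per_iter = data.frame(mean_run = mean_run, max_run = max_run,
                               n_runs = n_runs),
         n_iter = n_iter, seed = seed)
}

#' Two-sample Kolmogorov-Smirnov comparison of run-length distributions
#'
#' @param observed,reference non-empty numeric samples of run lengths.
#' @return list with `D` (KS statistic) and `p` (asymptotic two-sided p).
#' @export
compareRunDistributions <- function(observed, reference) {
    if (!length(observed) || !length(reference))
        stop("both samples must be non-empty")
    kt <- suppressWarnings(stats::ks.test(observed, reference,
                                          exact = FALSE))
    list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Full sequence statistics of a recording
#'
#' Convenience wrapper: type counts, run lengths, Shannon H and J, the Monte
#' Carlo null and the observed-vs-null KS comparison.
#'
#' @param sequences list of activation sequences in NB order.
#' @param n_iter,seed passed to [monteCarloNull()].
#' @param full_only if `TRUE`, restrict to full sequences (all clusters
#'   participating, i.e. maximal observed length) before analysis.
#' @return list: `counts`, `run_lengths`, `H`, `J`, `null`, `ks`.
#' @export
sequenceStats <- function(sequences, n_iter = 1000, seed = 1,
                          full_only = FALSE) {
    if (full_only) {
        lens <- vapply(sequences, length, integer(1))
        sequences <- sequences[lens == max(lens)]
    }
    counts <- sequenceTypeCounts(sequences)
    rl <- runLengths(sequences)
    he <- shannonEquitability(counts)
    nulld <- if (length(sequences) >= 2L)
        monteCarloNull(sequences, n_iter, seed) else NULL
    ks <- if (!is.null(nulld)) compareRunDistributions(rl, nulld$pooled)
          else NULL
    list(counts = counts, run_lengths = rl, H = he$H, J = he$J,
         null = nulld, ks = ks)
}
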
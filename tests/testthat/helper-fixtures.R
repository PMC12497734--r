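# shared fixture builders (everything generated in code, no stored data)

twoElectrodeLayout <- function(sampling_rate = 10000) {
    MEALayout(c("a", "b"), x = c(0, 500), y = c(0, 0),
              cluster_id = c(1, 2), sampling_rate = sampling_rate)
}

gridLayout <- function(n_side = 5, n_rows = 4, pitch = 200) {
    n <- n_side * n_rows
    MEALayout(sprintf("e%02d", seq_len(n)),
              x = rep(seq_len(n_side), n_rows) * pitch,
              y = rep(seq_len(n_rows), each = n_side) * pitch,
              cluster_id = rep(seq_len(4), each = n %/% 4))
}

poissonTrain <- function(rate, dur) {
    sort(stats::runif(stats::rpois(1, rate * dur), 0, dur))
}

# Wilcoxon rank-sum AUC of scores for a logical label vector
rankAUC <- function(score, label) {
    r <- rank(score)
    n1 <- sum(label); n0 <- sum(!label)
    (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# brute-force exact two-sided signed-rank p (independent of the package path)
bruteWilcoxonP <- function(a, b) {
    d <- a - b
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    w_obs <- min(sum(r[d > 0]), sum(r[d < 0]))
    total <- n * (n + 1) / 2
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    sums <- as.vector(signs %*% r)
    min(1, (sum(sums <= w_obs) + sum(sums >= total - w_obs)) / length(sums))
}
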
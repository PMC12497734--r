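test_that("IFR is zero for empty input, unit-mass and peaked for one spike", {
    z <- computeIFR(numeric(0), 0, 1)
    expect_true(all(z$rate == 0))
    one <- computeIFR(1.0, 0.8, 1.2)
    expect_lte(abs(one$time[which.max(one$rate)] - 1.0), 1e-3)
    integral <- sum(one$rate) * 1e-3
    expect_lt(abs(integral - 1), 0.02)
})

test_that("IFR is linear: disjoint trains add", {
    set.seed(41)
    a <- sort(stats::runif(20, 0, 0.4))
    b <- sort(stats::runif(20, 0.6, 1.0))
    f_a <- computeIFR(a, 0, 1)
    f_b <- computeIFR(b, 0, 1)
    f_ab <- computeIFR(sort(c(a, b)), 0, 1)
    expect_lt(max(abs(f_ab$rate - (f_a$rate + f_b$rate))), 1e-9)
})

test_that("IFR rejects too-coarse bins", {
    expect_error(computeIFR(0.5, 0, 1, kernel_sd_ms = 25, bin_ms = 10),
                 "bin_ms")
})

.toyNB <- function(cluster_times, width = 0.03, n = 6, start = NULL,
                   end = NULL) {
    # one NB whose clusters emit n-spike bursts centred at cluster_times
    spk <- lapply(cluster_times, function(tc) {
        if (is.na(tc)) return(numeric(0))
        seq(tc - width / 2, tc + width / 2, length.out = n)
    })
    names(spk) <- paste0("cluster", seq_along(spk))
    all_t <- unlist(spk)
    nb <- data.frame(start = if (is.null(start)) min(all_t) else start,
                     end = if (is.null(end)) max(all_t) else end)
    nb$cluster_spikes <- list(spk)
    nb
}

test_that("activation order follows IFR peak times; initiator is first", {
    nb <- .toyNB(c(1.020, 1.010, 1.040, 1.030))  # peaks: 2,1,4,3
    sq <- extractSequence(nb)
    expect_equal(as.integer(sq), c(2, 1, 4, 3))
    expect_equal(attr(sq, "initiator"), 2L)
})

test_that("identical peak bins break ties by cluster id; silent clusters drop", {
    nb <- .toyNB(c(1.0, 1.2, 1.0, NA))
    sq <- extractSequence(nb)
    expect_equal(as.integer(sq), c(1, 3, 2))     # 1 before 3 at equal peaks
    expect_length(sq, 3)                          # cluster 4 silent
    nb_silent <- .toyNB(c(NA, NA, NA, NA), start = 0, end = 1)
    expect_error(extractSequence(nb_silent), "silent")
})

test_that("run lengths enumerate maximal runs and sum to the NB count", {
    A <- c(1, 2, 3, 4); B <- c(2, 1, 4, 3); C <- c(3, 4, 1, 2)
    expect_equal(runLengths(list(A, A, A, B, B, C)), c(3L, 2L, 1L))
    expect_equal(runLengths(list(A, B, C, A, B, C)), rep(1L, 6))
    expect_equal(runLengths(list(A, A, A, A, A)), 5L)
    expect_equal(runLengths(list()), integer(0))
    # partial sequences are distinct types from full ones
    expect_equal(runLengths(list(c(1, 2, 3), A)), c(1L, 1L))
    set.seed(42)
    for (rep in 1:20) {
        n <- sample(2:30, 1)
        seqs <- lapply(sample(1:3, n, replace = TRUE), function(k)
            list(A, B, C)[[k]])
        expect_equal(sum(runLengths(seqs)), n)
    }
})

test_that("Shannon H and equitability match closed forms", {
    r1 <- shannonEquitability(4)
    expect_equal(r1$H, 0); expect_equal(r1$J, 0)
    r2 <- shannonEquitability(c(1, 1, 1, 1))
    expect_equal(r2$H, log(4)); expect_equal(r2$J, 1)
    r3 <- shannonEquitability(c(2, 1, 1))
    expect_equal(r3$H, 1.0397, tolerance = 1e-4)
    expect_equal(r3$J, 0.9464, tolerance = 1e-4)
    expect_error(shannonEquitability(c(0, 0)), "positive")
})

test_that("Monte Carlo null preserves the type multiset and is seeded", {
    A <- c(1, 2); B <- c(2, 1)
    seqs <- list(A, A, A, A)
    mc <- monteCarloNull(seqs, n_iter = 200, seed = 1)
    expect_true(all(mc$pooled == 4))              # permutation-invariant
    seqs2 <- list(A, B, A, B, A)
    m1 <- monteCarloNull(seqs2, n_iter = 500, seed = 7)
    m2 <- monteCarloNull(seqs2, n_iter = 500, seed = 7)
    expect_identical(m1$pooled, m2$pooled)
    expect_true(all(m1$per_iter$n_runs >= 1))
    expect_equal(unique(vapply(split(m1$pooled,
                                     rep(seq_len(500), m1$per_iter$n_runs)),
                               sum, numeric(1))), 5)
    expect_error(monteCarloNull(list(A), 200, 1), "at least 2")
    expect_error(monteCarloNull(seqs2, 50, 1), "100")
})

test_that("null run probability matches exhaustive enumeration on [A,A,B,B]", {
    # 6 equally likely distinct arrangements of the multiset {A,A,B,B}:
    # AABB ABAB ABBA BAAB BABA BBAA. A pair of equal neighbours (a run of
    # length 2) occurs in AABB, ABBA, BAAB, BBAA -> P = 4/6; each single
    # type is adjacent in 3 of 6 -> P = 1/2, which the 2/3 figure pools.
    A <- c(1, 2); B <- c(2, 1)
    mc <- monteCarloNull(list(A, A, B, B), n_iter = 10000, seed = 3)
    has_pair <- vapply(
        split(mc$pooled, rep(seq_len(10000), mc$per_iter$n_runs)),
        function(rl) any(rl >= 2), logical(1))
    p_hat <- mean(has_pair)
    expect_lt(abs(p_hat - 2 / 3), 3 * sqrt(2 / 9 / 10000))
})

test_that("observed vs reference KS behaves at the extremes", {
    same <- compareRunDistributions(c(1, 2, 3), c(1, 2, 3))
    expect_equal(same$D, 0)
    expect_equal(same$p, 1)
    disjoint <- compareRunDistributions(rep(1, 100), rep(2, 100))
    expect_equal(disjoint$D, 1)
})

test_that("equitability J decreases as persistence p_rep increases", {
    # seed-averaged: J reacts to persistence only via count overdispersion
    J <- vapply(c(0, 0.5, 0.9, 1), function(p) {
        mean(vapply(1:5, function(s) {
            sim <- simulateActivity(duration = 420, nb_rate = 0.7,
                                    background_rate = 0, p_rep = p,
                                    seed = 40 + s)
            sequenceStats(sim$truth$sequences, n_iter = 100, seed = 1)$J
        }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(J) < 0))
})

test_that("non-persistent generator data is indistinguishable from its MC null", {
    # p_rep = 0 sequences are exchangeable, so the observed run-length CDF
    # should rarely deviate from the permutation null (KS p > 0.01 in at
    # least 95% of seeded replicates)
    ok <- vapply(1:50, function(s) {
        sim <- simulateActivity(duration = 200, nb_rate = 0.6,
                                background_rate = 0, p_rep = 0,
                                seed = 500 + s)
        st <- sequenceStats(sim$truth$sequences, n_iter = 150, seed = s)
        st$ks$p > 0.01
    }, logical(1))
    expect_gte(mean(ok), 0.95)
})

test_that("analysis recovers >= 95% of true sequences on default-style data", {
    sim <- simulateActivity(duration = 300, background_rate = 0.5, seed = 45)
    an <- analyzeRecording(sim$spikes, seed = 1)
    truth <- sim$truth$sequences
    got <- an$sequences
    m <- min(length(got), length(truth))
    expect_gte(m / length(truth), 0.95)
    agree <- mean(mapply(function(a, b) identical(as.integer(a),
                                                  as.integer(b)),
                         got[seq_len(m)], truth[seq_len(m)]))
    expect_gte(agree, 0.95)
})
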
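test_that("string method matches hand-enumerated fixtures", {
    b <- detectBurstsString(c(0, .05, .10, .15, .20))
    expect_equal(nrow(b), 1)
    expect_equal(b$n_spikes, 5)
    expect_equal(b$end - b$start, 0.20)
    # gap of 0.101 s splits into strings of 4 and 2 -> no burst
    expect_equal(nrow(detectBurstsString(c(0, .05, .10, .15, .251, .30))), 0)
    b10 <- detectBurstsString(seq(0, by = 0.05, length.out = 10))
    expect_equal(b10$n_spikes, 10)
    expect_equal(nrow(detectBurstsString(numeric(0))), 0)
    # boundary: ISI exactly 0.1 stays inside the string
    expect_equal(nrow(detectBurstsString(seq(0, by = 0.1, length.out = 5))), 1)
})

test_that("burst spikes are a disjoint subset of the train", {
    set.seed(31)
    for (rep in 1:20) {
        train <- sort(stats::runif(stats::rpois(1, 300), 0, 20))
        train <- unique(train)
        b <- detectBurstsString(train)
        if (!nrow(b)) next
        idx <- unlist(mapply(seq, b$first_idx, b$last_idx,
                             SIMPLIFY = FALSE))
        expect_equal(anyDuplicated(idx), 0L)       # at most one burst each
        expect_true(all(train[idx] >= 0))
        for (i in seq_len(nrow(b)))                # intra-burst ISI bound
            expect_true(all(diff(train[b$first_idx[i]:b$last_idx[i]]) <=
                            0.1 + 1e-12))
    }
})

test_that("network-burst participation threshold uses active electrodes", {
    lay <- defaultLayout4Q()
    mk_burst <- function(t0) seq(t0, by = 0.02, length.out = 6)
    # all 60 electrodes active (background well above 0.1 spikes/s)
    bg <- lapply(stats::setNames(nm = electrodeId(lay)), function(id)
        seq(0.05, 99, by = 0.61) + stats::runif(1, 0, 1e-3))
    set.seed(32)
    # 15 simultaneous bursting electrodes = 25% >= 20% -> one NB
    ids15 <- electrodeId(lay)[1:15]
    sp <- bg
    for (id in ids15) sp[[id]] <- sort(c(sp[[id]], mk_burst(50)))
    sts <- SpikeTrainSet(lay, sp, 100)
    nbs <- detectNetworkBursts(sts, detectBursts(sts))
    expect_equal(nrow(nbs), 1)
    expect_gte(nbs$n_electrodes, 15)
    # 10 of 60 (16.7%) -> no NB
    sp <- bg
    for (id in electrodeId(lay)[1:10]) sp[[id]] <- sort(c(sp[[id]], mk_burst(50)))
    sts10 <- SpikeTrainSet(lay, sp, 100)
    expect_equal(nrow(detectNetworkBursts(sts10, detectBursts(sts10))), 0)
})

test_that("candidate events separated by 0.05 s merge into one NB", {
    lay <- defaultLayout4Q()
    sp <- list()
    ids <- electrodeId(lay)
    for (id in ids[1:15]) sp[[id]] <- seq(10, by = 0.02, length.out = 6)
    # second volley starting 0.05 s after the first ends
    for (id in ids[16:30]) sp[[id]] <- seq(10.15, by = 0.02, length.out = 6)
    sts <- SpikeTrainSet(lay, sp, 60)
    nbs <- detectNetworkBursts(sts, detectBursts(sts), fraction_base = "all")
    expect_equal(nrow(nbs), 1)
    expect_equal(nbs$n_electrodes, 30)
})

test_that("NB count is non-increasing in min_fraction", {
    sim <- simulateActivity(duration = 120, seed = 33)
    bursts <- detectBursts(sim$spikes)
    counts <- vapply(c(0.1, 0.2, 0.4), function(f)
        nrow(detectNetworkBursts(sim$spikes, bursts, min_fraction = f)),
        numeric(1))
    expect_true(all(diff(counts) <= 0))
})

test_that("detected NB count matches ground truth within 5% on default sim", {
    sim <- simulateActivity(duration = 300, seed = 34)
    nbs <- detectNetworkBursts(sim$spikes, detectBursts(sim$spikes))
    n_true <- length(sim$truth$nb_onsets)
    expect_lte(abs(nrow(nbs) - n_true), ceiling(0.05 * n_true))
})

test_that("activity metrics: MFR, strict active threshold, IBI", {
    lay <- twoElectrodeLayout()
    # 600 spikes in 600 s -> MFR exactly 1.0; b has MFR exactly 0.1 -> inactive
    sp <- list(a = seq(0.5, 599.5, length.out = 600),
               b = seq(1, 600, length.out = 60) - 0.5)
    sts <- SpikeTrainSet(lay, sp, 600)
    m <- computeActivityMetrics(sts, detectBursts(sts))
    expect_equal(m$per_electrode$mfr, c(1.0, 0.1))
    expect_identical(m$per_electrode$active, c(TRUE, FALSE))
    # bursts (0.0-1.0) and (3.0-3.5) -> IBI 2.0
    sp2 <- list(a = c(seq(0, 1, length.out = 11), seq(3, 3.5, length.out = 6)))
    sts2 <- SpikeTrainSet(twoElectrodeLayout(), sp2, 10)
    m2 <- computeActivityMetrics(sts2, detectBursts(sts2))
    expect_equal(m2$ibi, 2.0)
    expect_equal(m2$bd, c(1.0, 0.5))
    expect_equal(m2$per_electrode$mbr[1], 2 / 10 * 60)
})

test_that("NB cluster spike subsets never exceed the total spike count", {
    sim <- simulateActivity(duration = 120, seed = 35)
    nbs <- detectNetworkBursts(sim$spikes, detectBursts(sim$spikes))
    per_nb <- vapply(nbs$cluster_spikes, function(cs)
        sum(lengths(cs)), numeric(1))
    expect_lte(sum(per_nb), sum(nSpikes(sim$spikes)))
})
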
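test_that("independent Poisson pairs stay below the surrogate null threshold", {
    lay <- twoElectrodeLayout()
    set.seed(51)
    sts <- SpikeTrainSet(lay, list(a = poissonTrain(1, 600),
                                   b = poissonTrain(1, 600)), 600)
    g <- tspe(sts)
    thr <- tspeSurrogateThreshold(sts, n_surrogates = 100, seed = 52)
    expect_true(all(abs(edges(g)$weight) < thr))
})

test_that("planted excitatory link gives a positive, directed weight at its delay", {
    lay <- twoElectrodeLayout()
    set.seed(53)
    sts0 <- SpikeTrainSet(lay, list(a = poissonTrain(2, 600),
                                    b = poissonTrain(2, 600)), 600)
    cn <- data.frame(source = "a", target = "b", sign = 1, delay_ms = 5,
                     prob = 0.5)
    g <- tspe(plantConnectivity(sts0, cn, seed = 54))
    e <- edges(g)
    fwd <- e[e$source == "a" & e$target == "b", ]
    rev <- e[e$source == "b" & e$target == "a", ]
    expect_gt(fwd$weight, 0)
    expect_lte(abs(fwd$delay_ms - 5), 1)
    expect_gt(fwd$weight, rev$weight)
})

test_that("planted inhibitory link gives a negative weight in the true direction", {
    lay <- twoElectrodeLayout()
    set.seed(55)
    sts0 <- SpikeTrainSet(lay, list(a = poissonTrain(4, 600),
                                    b = poissonTrain(8, 600)), 600)
    cn <- data.frame(source = "a", target = "b", sign = -1, delay_ms = 3,
                     prob = 1)
    g <- tspe(plantConnectivity(sts0, cn, seed = 56))
    e <- edges(g)
    expect_lt(e$weight[e$source == "a" & e$target == "b"], 0)
})

test_that("ranking |weight| recovers 30 planted edges in a 20-electrode net", {
    set.seed(57)
    lay <- gridLayout()
    n <- length(electrodeId(lay))
    trains <- stats::setNames(lapply(seq_len(n), function(i)
        poissonTrain(2, 300)), electrodeId(lay))
    sts0 <- SpikeTrainSet(lay, trains, 300)
    pairs <- expand.grid(s = seq_len(n), t = seq_len(n))
    pairs <- pairs[pairs$s != pairs$t, ]
    pick <- pairs[sample(nrow(pairs), 30), ]
    cn <- data.frame(source = electrodeId(lay)[pick$s],
                     target = electrodeId(lay)[pick$t],
                     sign = 1, delay_ms = stats::runif(30, 3, 10), prob = 0.5)
    g <- tspe(plantConnectivity(sts0, cn, seed = 58))
    e <- edges(g)
    truth <- paste(e$source, e$target) %in% paste(cn$source, cn$target)
    expect_gte(rankAUC(abs(e$weight), truth), 0.9)
})

test_that("edge filters apply the stated rules and are idempotent", {
    lay <- twoElectrodeLayout()   # electrodes 500 um apart
    set.seed(59)
    sts <- SpikeTrainSet(lay, list(a = poissonTrain(3, 120),
                                   b = poissonTrain(3, 120)), 120)
    g <- tspe(sts)
    # all filters disabled -> identity
    g_id <- filterEdges(g, NULL, NULL, NULL)
    expect_equal(edges(g_id), edges(g))
    # latency filter: best delay below lat_min is removed
    e <- edges(g)
    e$delay_ms <- c(0.5, 10)
    g2 <- methods::initialize(g, edges = e)
    kept <- edges(filterEdges(g2, NULL, latency_bounds_ms = c(1, 25)))
    expect_equal(kept$delay_ms, 10)
    # spatial filter: 500 um at 10 ms -> 0.05 m/s inside [0.02, 2];
    # at 0.1 ms the implied speed 5 m/s is implausible
    e$delay_ms <- c(0.1, 10)
    g3 <- methods::initialize(g, edges = e)
    kept3 <- edges(filterEdges(g3, speed_bounds_m_s = c(0.02, 2),
                               latency_bounds_ms = NULL))
    expect_equal(kept3$delay_ms, 10)
    # subset + idempotence
    f1 <- filterEdges(g)
    f2 <- filterEdges(f1)
    expect_true(all(paste(edges(f1)$source, edges(f1)$target) %in%
                    paste(edges(g)$source, edges(g)$target)))
    expect_equal(edges(f2), edges(f1))
})

test_that("2000 um at 25 ms implies 0.08 m/s and survives default bounds", {
    lay <- MEALayout(c("a", "b"), x = c(0, 2000), y = c(0, 0),
                     cluster_id = c(1, 2))
    set.seed(60)
    sts <- SpikeTrainSet(lay, list(a = poissonTrain(3, 120),
                                   b = poissonTrain(3, 120)), 120)
    g <- tspe(sts)
    e <- edges(g)
    e$delay_ms <- 25
    g2 <- methods::initialize(g, edges = e)
    expect_equal(nrow(edges(filterEdges(g2))), nrow(e))
})

test_that("CI0 is 1 for identical sparse trains, ~0.01 for independent ones", {
    sparse <- seq(1, 59, by = 1)          # ISI 1 s >> 200 ms lag window
    expect_equal(as.numeric(coincidenceIndex(sparse, sparse)), 1)
    set.seed(61)
    a <- poissonTrain(5, 600); b <- poissonTrain(5, 600)
    ci <- as.numeric(coincidenceIndex(a, b))
    expect_lt(abs(ci - 0.01), 0.005)
    expect_error(coincidenceIndex(numeric(0), sparse), "non-empty")
})

test_that("CI0 is exactly symmetric under train exchange", {
    set.seed(62)
    for (rep in 1:5) {
        a <- poissonTrain(4, 60); b <- poissonTrain(4, 60)
        expect_lt(abs(as.numeric(coincidenceIndex(a, b)) -
                      as.numeric(coincidenceIndex(b, a))), 1e-9)
    }
})

test_that("variation vs baseline reports the six percent changes", {
    lay <- gridLayout()
    set.seed(63)
    trains <- stats::setNames(lapply(seq_along(electrodeId(lay)), function(i)
        poissonTrain(3, 60)), electrodeId(lay))
    sts <- SpikeTrainSet(lay, trains, 60)
    g <- addCoincidenceIndex(tspe(sts), sts)
    v0 <- variationVsBaseline(g, g)
    expect_true(all(v0$pct_change[v0$defined] == 0))
    # halve inter edges, double all weights
    e <- edges(g)
    inter_idx <- which(e$label == "inter")
    drop <- inter_idx[seq_len(floor(length(inter_idx) / 2))]
    e2 <- e[-drop, ]
    e2$weight <- e2$weight * 2
    g2 <- methods::initialize(g, edges = e2)
    v <- variationVsBaseline(g, g2)
    expect_equal(v$pct_change[v$quantity == "inter.count"],
                 100 * (length(inter_idx) - length(drop) -
                        length(inter_idx)) / length(inter_idx))
    expect_equal(v$pct_change[v$quantity == "intra.count"], 0)
    expect_equal(v$pct_change[v$quantity == "intra.mean_weight"], 100)
    # undefined baselines are flagged, not zeroed
    g_empty <- methods::initialize(g, edges = e[0, ])
    v_u <- variationVsBaseline(g_empty, g)
    expect_true(all(!v_u$defined))
    expect_true(all(is.na(v_u$pct_change)))
})

test_that("pairs with too few spikes are skipped with a warning", {
    lay <- twoElectrodeLayout()
    sts <- SpikeTrainSet(lay, list(a = seq(1, 50), b = c(1, 2)), 60)
    expect_warning(expect_error(tspe(sts), "at least 2"), "skipped")
})
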
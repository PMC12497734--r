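test_that("p_rep = 1 with a single motif forces every true sequence", {
    sim <- simulateActivity(duration = 120, p_rep = 1,
                            motif_repertoire = list(c(1, 2, 3, 4)), seed = 4)
    expect_gt(length(sim$truth$sequences), 5)
    for (sq in sim$truth$sequences)
        expect_equal(sq, c(1, 2, 3, 4))
})

test_that("true NB count is Poisson-consistent (120 +/- 33 at 0.2/s, 600 s)", {
    sim <- simulateActivity(duration = 600, nb_rate = 0.2, seed = 8)
    expect_gte(length(sim$truth$nb_onsets), 120 - 33)
    expect_lte(length(sim$truth$nb_onsets), 120 + 33)
    expect_true(all(diff(sim$truth$nb_onsets) >= 1 - 1e-12))
})

test_that("silent parameters produce an empty set; infeasible packing errors", {
    sim <- simulateActivity(duration = 60, nb_rate = 0,
                            background_rate = 0, seed = 1)
    expect_equal(sum(nSpikes(sim$spikes)), 0)
    expect_error(simulateActivity(nb_rate = 1.2, min_separation_s = 1),
                 "infeasible packing")
})

test_that("identical seeds reproduce bit-identical output, different seeds differ", {
    a <- simulateActivity(duration = 60, seed = 9)
    b <- simulateActivity(duration = 60, seed = 9)
    c <- simulateActivity(duration = 60, seed = 10)
    expect_identical(spikeTimes(a$spikes), spikeTimes(b$spikes))
    expect_identical(a$truth$sequences, b$truth$sequences)
    expect_false(identical(nSpikes(a$spikes), nSpikes(c$spikes)))
})

test_that("excitatory planting is deterministic at p = 1 and identity at p = 0", {
    lay <- twoElectrodeLayout()
    sts <- SpikeTrainSet(lay, list(a = c(1.0, 2.0)), duration = 10)
    cn <- data.frame(source = "a", target = "b", sign = 1, delay_ms = 5,
                     prob = 1)
    out <- plantConnectivity(sts, cn, seed = 1)
    expect_equal(spikeTimes(out)$b, c(1.005, 2.005))
    cn$prob <- 0
    out0 <- plantConnectivity(sts, cn, seed = 1)
    expect_identical(spikeTimes(out0), spikeTimes(sts))
})

test_that("transfer probability 0.5 inserts a binomially plausible count", {
    lay <- twoElectrodeLayout()
    set.seed(3)
    src <- sort(stats::runif(1000, 0, 1000))
    sts <- SpikeTrainSet(lay, list(a = src), duration = 1000)
    cn <- data.frame(source = "a", target = "b", sign = 1, delay_ms = 5,
                     prob = 0.5)
    out <- plantConnectivity(sts, cn, seed = 5)
    n_ins <- length(spikeTimes(out)$b)
    expect_gte(n_ins, 500 - 47)   # 3 sigma of Binomial(1000, .5)
    expect_lte(n_ins, 500 + 47)
})

test_that("inhibitory planting deletes target spikes only inside the window", {
    lay <- twoElectrodeLayout()
    sts <- SpikeTrainSet(lay, list(a = c(1.0), b = c(1.003, 1.050)),
                         duration = 10)
    cn <- data.frame(source = "a", target = "b", sign = -1, delay_ms = 5,
                     prob = 1)
    out <- plantConnectivity(sts, cn, seed = 1)
    expect_equal(spikeTimes(out)$b, 1.050)   # 1.003 in the 5 ms window
})

test_that("noiseless voltage equals the shifted scaled template", {
    lay <- twoElectrodeLayout()
    sts <- SpikeTrainSet(lay, list(a = 0.5), duration = 1)
    rec <- synthesizeVoltage(sts, amplitude_sd_ratio = 10, noise_sd = 0,
                             seed = 1)
    tr <- rec@samples[, "a"]
    expect_equal(max(tr) - min(tr), 10)   # p2p = ratio when noise_sd = 0
    peak_i <- which.max(abs(tr))
    expect_lt(abs((peak_i - 1) / 10000 - 0.5), 2e-4)
    expect_true(all(rec@samples[, "b"] == 0))
})

test_that("pure-noise synthesis has the requested SD within 5% over 60 s", {
    lay <- twoElectrodeLayout()
    sts <- SpikeTrainSet(lay, list(), duration = 60)
    rec <- synthesizeVoltage(sts, noise_sd = 2, seed = 2)
    expect_lt(abs(stats::sd(rec@samples[, "a"]) - 2) / 2, 0.05)
})

test_that("one noisy spike leaves the trace extremum within 0.2 ms", {
    lay <- twoElectrodeLayout()
    sts <- SpikeTrainSet(lay, list(a = 1.0), duration = 2)
    rec <- synthesizeVoltage(sts, amplitude_sd_ratio = 10, noise_sd = 1,
                             seed = 6)
    tr <- rec@samples[, "a"]
    expect_lt(abs((which.max(abs(tr)) - 1) / 10000 - 1.0), 2e-4)
})

test_that("overlapping templates warn and are summed linearly", {
    lay <- twoElectrodeLayout()
    sts <- SpikeTrainSet(lay, list(a = c(0.5, 0.5005)), duration = 1)
    expect_warning(synthesizeVoltage(sts, noise_sd = 0, seed = 1),
                   "overlapping")
})

test_that("dose-response simulation follows the Hill curve", {
    d <- simulateDoseResponse(ic50 = 1e-8, hill_n = 2,
                              concentrations = c(1e-9, 1e-8, 1e-7),
                              noise_sd = 0)
    expect_equal(d$response[2], 0.5)
    expect_gt(d$response[1], 0.98)   # c << ic50 -> response -> 1
    d9 <- simulateDoseResponse(ic50 = 2e-9, hill_n = 1, noise_sd = 0)
    expect_equal(nrow(d9), 9)
    expect_true(all(diff(d9$response) < 0))
})
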
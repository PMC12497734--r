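# clustMEA

Spike-train analysis of **clustered cortical networks on multi-electrode
arrays (MEAs)**: an R implementation of the complete pipeline used to study
how four spatially separated, mutually interconnected neuronal assemblies
("clusters", grown under a cross-shaped mask on a 60-electrode 4Q-MEA)
organise their spontaneous activity into repeated cluster **activation
sequences**, and how that organisation changes under pharmacological
manipulation (e.g. NMDA-receptor blockade) relative to a baseline recording.

It is written for electrophysiologists and neuroengineers working with
population recordings of cultured networks who need the full chain — from raw
voltage or deposited "peak trains" to condition-versus-baseline statistics —
as tested, scriptable building blocks rather than one-off analysis code.

## What it computes

- **Spike detection** from 10 kHz voltage traces with a precision-time
  differential threshold: a spike is a peak-to-peak excursion exceeding
  8 × the noise SD (robustly estimated as median(|V|)/0.6745) between
  opposite-polarity extrema within a 2 ms peak lifetime, with a 1 ms
  refractory period.
- **Burst detection** (string method: ≥ 5 spikes, inter-spike intervals
  ≤ 100 ms), **network bursts** (NBs: ≥ 20 % of active electrodes bursting
  within a 100 ms merge interval) and the four activity metrics MFR, MBR,
  BD, IBI (electrodes are *active* when MFR > 0.1 spikes/s).
- **Activation sequences**: each cluster's instantaneous firing rate (IFR;
  Gaussian kernel over a 100 ms window) is peaked within each NB, and the
  order of the IFR peaks — starting with the *initiator* cluster — is the
  NB's activation sequence. Sequence diversity is quantified by the Shannon
  index H = −Σ pᵢ ln pᵢ and the equitability J = H / ln N ∈ [0, 1];
  temporal persistence by the run lengths of identical consecutive
  sequences, compared against a seeded **Monte Carlo permutation null**
  (two-sample Kolmogorov–Smirnov test).
- **Functional connectivity** with the Total Spiking Probability Edges
  (TSPE) cross-correlogram filter bank, significance thresholds from
  spike-jitter surrogates, spatial (propagation-speed) and physiological
  (latency) edge filters, intra-/inter-cluster edge labels, and the
  coincidence index CI₀ — cross-correlogram mass within ±1 ms over the
  ±100 ms lag window — as a synchrony measure. Condition graphs are
  summarised as percent variation versus baseline (edge counts, weights,
  CI₀, split by intra/inter).
- **Dose–response**: firing normalized to baseline and fitted with the Hill
  equation r(c) = 1 / (1 + (c/IC₅₀)ⁿ) on the nine-step 1 nM – 10 µM ladder,
  with multi-start log-concentration least squares and an identifiability
  guard.
- **Statistics**: exact (full-enumeration) and normal-approximation
  Wilcoxon signed-rank tests for paired cultures, two-sample KS tests for
  cumulative run-length distributions, and Student's t-tests with
  Bonferroni correction.
- A **synthetic-data generator** with planted ground truth — NB times,
  motif repertoire with first-order Markov persistence p_rep, directed
  excitatory/inhibitory connections, optional voltage synthesis — so every
  stage is testable without recordings.

Spike-train sets round-trip through CSV and a restricted MATLAB v5 "peak
train" dialect (one cell array of sample ticks, as in deposited MEA
datasets).

## Worked example

```r
library(clustMEA)

lay <- defaultLayout4Q()                      # 60 electrodes, 4 clusters
sim <- simulateActivity(lay, duration = 300, p_rep = 0.8,
                        background_rate = 0.5, seed = 1)
sim$spikes
#> SpikeTrainSet: 60 electrodes, 300.0 s, 36734 spikes total
#>   mean firing rate: 2.041 spikes/s per electrode

an <- analyzeRecording(sim$spikes, seed = 1)
nrow(an$nbs)                                  # 58 network bursts
head(an$seq_stats$run_lengths)                # 24 2 2 8 8 14
an$seq_stats$H                                # 1.365 nats over 5 types
an$seq_stats$J                                # 0.848
an$seq_stats$ks                               # D = 0.741, p = 0.0028
```

With persistence `p_rep = 0.8` the same ordering recurs in long runs (a run
of 24 consecutive identical sequences here), so the observed run-length
distribution differs sharply from the permutation null (KS p ≈ 0.003):
exactly the signature of non-random, repeated activation sequences the
pipeline is built to detect. Equitability J = 0.85 < 1 reflects the uneven
use of the 5 observed sequence types.

```r
g <- filterEdges(tspe(sim$spikes))            # TSPE + spatial/latency filters
g <- addCoincidenceIndex(g, sim$spikes)
g
#> ConnectivityGraph: 3379 directed edges (filtered)
#>   intra: 814, inter: 2565; weight range [-0.241, 0.352]

d <- simulateDoseResponse(ic50 = 2e-9, hill_n = 1, noise_sd = 0.03, seed = 2)
fitHill(d$concentration, d$response)
#> DoseResponseFit: 9 concentrations
#>   IC50 = 1.87e-09 M, Hill n = 0.889 (converged; residual norm 0.0685)
```

A command-line wrapper over the same functions ships in
`inst/scripts/mea.R` (`simulate`, `bursts`, `sequences`, `connectivity`,
`doseresponse`, `compare`), writing CSV/JSON outputs plus a `manifest.json`
with the full configuration and seed; identical manifests reproduce outputs
bit-exactly.

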
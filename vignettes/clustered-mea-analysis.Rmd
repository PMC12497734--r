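---
title: "Methods: spike-train analysis of clustered MEA networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-train analysis of clustered MEA networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustMEA)
```

# The system and the analysis problem

Cortical neurons cultured on a 60-electrode multi-electrode array under a
cross-shaped mask grow into four spatially separated but mutually
interconnected assemblies ("clusters"). Such networks fire spontaneously:
single-electrode spikes organise into bursts, bursts into network bursts
(NBs) sweeping across clusters, and the *order* in which the clusters
activate within an NB — the activation sequence — tends to repeat across
consecutive NBs far more than chance ordering would produce. The pipeline in
this package quantifies that temporal organisation and how it changes
between experimental conditions (baseline, drug, washout): activity levels,
sequence diversity and persistence, directed functional connectivity within
and between clusters, pairwise synchrony, and pharmacological
dose–response.

Throughout, the electrode is the unit of analysis (no spike sorting into
single units), times are seconds as doubles, and sample indices appear only
at I/O boundaries.

# Detection chain

## Spike detection

`detectSpikesPTSD()` implements a precision-time differential threshold.
Local extrema of each trace are located; a spike is declared when the
peak-to-peak excursion between an extremum and an opposite-polarity
extremum within the *peak lifetime* window exceeds
`threshold_factor` × noise SD. Defaults: threshold factor 8, peak lifetime
2 ms, refractory period 1 ms. The noise SD is the spike-resistant estimate
median(|V|)/0.6745 over the whole trace (`estimateNoiseSD()`); a windowed
variant (median of per-second estimates) is available for drifting noise,
but the whole-trace estimate is the default because the detector's contract
is stationary noise. The spike timestamp is the larger-magnitude extremum
of the pair, with ties broken toward the earlier sample; detections closer
than the refractory period collapse to the larger-excursion one. A zero
noise estimate (noiseless synthetic traces) degenerates gracefully to
detecting any positive excursion.

## Bursts and network bursts

`detectBurstsString()` partitions each train into maximal strings with
inter-spike intervals ≤ 100 ms and keeps strings of ≥ 5 spikes. A 10⁻¹² s
slack on the ISI comparison keeps boundary intervals (exactly 100 ms)
inside a string despite floating-point representation.

`detectNetworkBursts()` merges electrode bursts that overlap or fall within
the 100 ms merge interval into candidate population events and promotes
candidates involving ≥ 20 % of *active* electrodes (MFR strictly
> 0.1 spikes/s). Whether the 20 % refers to active or to all electrodes is
an open design point; active electrodes are the default (consistent with
the activity definition and robust to dead electrodes), and
`fraction_base = "all"` switches the base. The self-adapting ISI-threshold
variant of the NB detector is deliberately not implemented: both
parameters are pinned (20 %, 100 ms), so the fixed-parameter rule *is* the
contract.

## Activity metrics

MFR (spikes/s), MBR (bursts/min), BD (s) and IBI (s; end of one burst to
the onset of the next on the same electrode) via
`computeActivityMetrics()`. NB-level inter-event intervals are exposed
separately (`nb_intervals`) rather than mixed into the electrode-level IBI.

# Activation sequences and their statistics

`computeIFR()` bins spikes at 1 ms and convolves with a unit-mass Gaussian
kernel. The kernel is parameterized by its SD (25 ms) and truncated at
±2 SD, so the support spans 100 ms: a plain-language "100 ms smoothing
window" most plausibly denotes the kernel's support, not its SD, and both
numbers are configurable (`kernel_sd_ms`, `kernel_truncation_sd`). The
truncated kernel is renormalized to unit mass, so the time-integral of the
IFR equals the spike count on the grid; the bin must be ≤ SD/5 so the peak
location is not quantization-limited.

`extractSequence()` evaluates each cluster's IFR over the NB span padded by
the kernel truncation and orders clusters by the time of the global IFR
maximum. Ties break toward the earlier peak bin, then the smaller cluster
id. Clusters without spikes in the NB are excluded, yielding a *partial*
sequence; partial sequences are distinct types from full ones (equality is
the full ordered tuple including participation), and `sequenceStats(...,
full_only = TRUE)` restricts the analysis to full sequences when desired.

Run lengths (`runLengths()`) count maximal series of identical consecutive
sequences, *including* the first occurrence (a pair counts as 2). All runs
(including singletons) enter the internal statistics; Fig-style cumulative
frequency tables are computed over runs of length ≥ 2 by
`runConditionComparison()`.

Shannon diversity uses natural logarithms over the *observed* sequence
types; equitability J = H/ln N with N the number of observed types (not
the 24 possible orderings — an unobservable type carries no probability
mass in the plug-in estimate), and J ≡ 0 for a single type.

## Monte Carlo null and its calibration

`monteCarloNull()` permutes the observed sequence list uniformly
(preserving the type multiset exactly), recomputes run lengths per
iteration (default 1000), and pools them; the observed run-length sample is
compared against the pooled null with a two-sample KS test
(`compareRunDistributions()`, asymptotic p). Two numerical caveats are
worth stating. First, run lengths are small-support integers, so the KS
p-value is discrete and conservative; the meaningful calibration property
for exchangeable (non-persistent) data is therefore one-sided — the
rejection rate at level α must not exceed α — and that is what the test
suite asserts (at α ∈ {0.01, 0.05, 0.1} over 200 seeded replicates).
Second, equitability J reacts to persistence only through the run-induced
overdispersion of the type counts (the marginal type distribution remains
uniform under the first-order Markov repetition mechanism), a ~0.01 effect
at a few hundred NBs; the monotone decline of J with persistence is
therefore asserted on seed-averaged estimates rather than a single draw.

# Functional connectivity

## TSPE

`tspe()` computes, for every ordered electrode pair, the cross-correlogram
of target-minus-source spike-time differences at 1 ms bins over candidate
delays 1–25 ms, normalizes by the source spike count (an empirical spiking
probability), and convolves with a bank of edge filters: running-average
flanks of a ∈ {3,…,8} bins on each side, observation window b ∈ {2, 3}
bins, crossing window c = 0 bins between them. The pair's weight is the
signed extremum of the summed filtered curve over delays — positive for a
correlogram peak (putative excitation), negative for a trough (putative
inhibition) — and the delay at the extremum is recorded. The filter window
sets are the algorithm's published defaults; the source study names the
algorithm without parameter values, so all of them are configurable and
recorded in run manifests. Pairs with fewer than 10 spikes on either
electrode are skipped (no stable correlogram).

Significance: the study gives no numeric weight cutoff, so
`tspeSurrogateThreshold()` builds a null by jittering every spike
uniformly in ±10 ms (destroying millisecond timing, preserving rates),
recomputing TSPE 100 times, and taking the 99th percentile of the pooled
absolute weights.

`filterEdges()` applies three deterministic rules, each disabled by `NULL`:
implied propagation speed (electrode distance / best delay) within
0.02–2 m/s, best delay within 1–25 ms, and |weight| above the surrogate
threshold. The speed and latency bounds are defaults chosen to bracket
unmyelinated-culture conduction and monosynaptic-to-oligosynaptic latencies;
the study states the two filters exist but not their values, so both
bounds are configurable and live in the manifest. Filtering is idempotent
and only ever removes edges.

## Coincidence index

`coincidenceIndex()` is the fraction of cross-correlogram mass within
±1 ms of the ±100 ms lag window. It is computed directly from the
spike-time differences (|Δ| ≤ 1 ms over |Δ| ≤ 100 ms), which makes it
exactly symmetric under exchange of the trains and independent of the bin
width (the bin only shapes the correlogram returned as an attribute). For
a flat correlogram the expectation is the window ratio 2/200 = 0.01; for
identical trains whose ISIs exceed the lag window it is exactly 1.
`variationVsBaseline()` reports percent change of six summaries (edge
count, mean |weight|, mean CI₀ — each split intra/inter); quantities with
zero or missing baseline are flagged undefined, never silently zeroed.
Mean |weight| is used because the weight's sign encodes putative direction
of effect, not magnitude of coupling.

# Dose–response

`fitHill()` fits r(c) = bottom + (top − bottom)/(1 + (c/IC₅₀)ⁿ) by
least squares on log₁₀-concentration, with asymptotes fixed at top = 1,
bottom = 0 (responses are baseline-normalized; full block is assumed at
saturation) unless `free_asymptotes = TRUE`. A multi-start over one IC₅₀
start per decade spanning the data protects against local minima across
the 4-decade default ladder (1 nM – 10 µM in 1–3–10 steps). The fit is
declared unidentifiable (`converged = FALSE`) when the response range is
below 0.2, when no start converges, or when the optimum pins the IC₅₀
more than a decade outside the sampled range — flat or non-monotone data
never yield a silent success. On any successful fit
r(IC₅₀) = (top + bottom)/2 holds analytically, and scaling all
concentrations by k scales the fitted IC₅₀ by k.

# Paired statistics

`wilcoxonSignedRank()` drops zero differences, midranks tied absolute
differences, and reports W = min(W⁺, W⁻). Exact mode (default for n ≤ 15)
enumerates all 2ⁿ sign assignments of the observed ranks, which remains
correct under ties; normal mode reports z with the tie-corrected variance
n(n+1)(2n+1)/24 − Σ(t³−t)/48 and the two-sided normal p. The two modes can
legitimately disagree at small n; both are reported rather than forcing
either convention. `ksTwoSample()` and `tTestBonferroni()` delegate to the
standard library tests (`ks.test`, `t.test` with pooled variance), adding
the α/m Bonferroni decision; pairing across conditions uses the culture as
the unit.

# The synthetic generator: what it does and does not emulate

`simulateActivity()` generates the study-condition phenomenology with
known ground truth:

- NB onsets: homogeneous Poisson (default 0.2 events/s over 600 s — one
  10-minute recording) with a 1 s minimum separation so consecutive NBs
  stay resolvable by the 100 ms merge rule;
- activation sequences: first-order Markov persistence — repeat the
  previous sequence with probability `p_rep` (default 0.5), otherwise draw
  uniformly from the motif repertoire. This is the simplest mechanism that
  generates heavy-tailed run-length structure;
- within an NB, every electrode of a participating cluster emits a burst
  (default 8 spikes, ISIs 2–6 ms) centred on its cluster's activation
  time; successive clusters are spaced by `inter_cluster_lag_ms`
  (default 100 ms). The lag default is pinned by two constraints: it must
  exceed ~3× the 25 ms IFR kernel SD so peak order is resolvable, and the
  gap between consecutive cluster bursts must stay below the 100 ms NB
  merge interval so one simulated event is detected as one NB;
- independent Poisson background spikes per electrode (default
  0.2 spikes/s, a quiet but active culture);
- `plantConnectivity()` expresses directed links: excitatory connections
  insert a target spike at source time + delay with the stated transfer
  probability; inhibitory connections delete target spikes within a 5 ms
  window after source spikes — a deletion model that gives TSPE a
  negative-delay signature without any membrane model. Trains are
  re-sorted and deduplicated at 0.1 ms;
- `synthesizeVoltage()` adds a biphasic template (dominant negative phase,
  1 ms) at each spike time over white Gaussian noise, scaled so
  peak-to-peak amplitude = `amplitude_sd_ratio` × noise SD.

It does **not** emulate: biophysical neuron or synapse dynamics, emergent
plasticity (ground truth is imposed), pacemaker mechanisms, rate
non-stationarity, electrode drift or artifacts, or correlated (non-white)
noise. Passing tests on this substrate therefore demonstrate that the
estimators recover *planted* structure under realistic event statistics —
not that they are robust to every pathology of real recordings.

All generator randomness derives from a single integer seed; per-stage
streams are decoupled so the same seed can drive independent stages.

# Degenerate inputs and numerical conventions

- Empty trains: IFR returns zeros; burst/NB detectors return empty tables;
  CI₀ on an empty train is an error (the ratio is undefined).
- An NB whose clusters are all silent is an inconsistency and errors.
- Constant voltage traces warn and return noise SD 0.
- Zero baseline quantities in variation summaries are flagged, not zeroed.
- All-zero difference vectors, zero pooled variances, and all-zero count
  vectors are errors in the statistics layer.
- Cross-correlogram bins are centred on multiples of the bin width (lag 0
  is a bin centre); CI₀ uses exact |Δ| comparisons, so no edge-assignment
  asymmetry can arise.
- The IFR convolution uses FFT (`stats::convolve`); additivity holds to
  ~10⁻¹².

# Problem sizes in the test suite

The suite runs desk-scale problems chosen to give each statistical
assertion clear margins: 60-electrode recordings of 120–600 s for
detection and pipeline checks, a 20-electrode 300 s network with 30
planted edges for connectivity ranking (AUC ≥ 0.9), 200 replicates for
null calibration, 10 000 Monte Carlo iterations against the exhaustive
4-element enumeration, and 20 seeded replicates for noisy IC₅₀ recovery.
`scripts/acceptance.R` re-runs the same computations end-to-end and writes
the resulting quantities as JSON.

# Known limitations

- The MAT reader supports one deposited dialect (uncompressed or
  zlib-compressed MAT v5, numeric and cell arrays); structurally different
  files fail loudly by design. HDF5 is not currently supported.
- TSPE weights are relative scores; absolute comparability across
  recordings relies on the surrogate threshold, not on the raw scale.
- The exact Wilcoxon mode is limited to n ≤ 20 (2ⁿ enumeration).
- Sequence equality is exact; near-miss motifs (one transposition) count
  as distinct types, by design.
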
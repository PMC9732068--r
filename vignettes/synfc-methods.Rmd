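---
title: "Inferring synaptic structure and weight dynamics from spiking functional connectivity"
author: "synfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring synaptic structure and weight dynamics from spiking functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Synapses in cortical circuits are directed, sparse, delayed and plastic.
Extracellular recordings give us spike trains, not synapses, so any claim
about which neurons are connected — and about how the strength of those
connections evolves — must be read out of the statistics of the spikes.
`synfc` packages the two halves of that programme:

1. a **ground-truth generator**: a recurrent network of Izhikevich neurons
   with heterogeneous conduction delays and spike timing-dependent
   plasticity (STDP), simulated at 1-ms resolution, for which every
   synapse, delay and per-second weight is known; and
2. an **inference layer**: directed, delay-resolved functional
   connectivity (FC) measures applied to the binary spike raster, used to
   recover synapse presence, sign, communication delay, and — through
   sliding windows — the temporal evolution of synaptic weights.

Because the generator's structure is known exactly, every inference can be
scored. The package is therefore both a simulator and a benchmark: the
inference layer also accepts imported spike-time tables, so the same
machinery can be pointed at real spike-sorted data.

## The simulated network

Each neuron follows the two-variable quadratic integrate-and-fire model

$$v' = 0.04 v^2 + 5 v + 140 - u + I_{\mathrm{syn}}, \qquad u' = a(bv - u),$$

with a spike emitted when $v$ reaches 30 mV, followed by the reset
$v \leftarrow c$, $u \leftarrow u + d$. Excitatory neurons use the
regular-spiking preset $(a,b,c,d) = (0.02, 0.2, -65, 8)$ and inhibitory
neurons the fast-spiking preset $(0.1, 0.2, -65, 2)$. Integration uses
two 0.5-ms Euler substeps for $v$ and one 1-ms step for $u$, the numerical
convention of the reference cortical network model this simulator follows.

The default network has 100 neurons, 80 excitatory. Every excitatory
neuron projects to 10 random targets of either type (800 excitatory
synapses), with integer conduction delays uniform on 1–20 ms and initial
weight 6 mV. Every inhibitory neuron projects to 10 random *excitatory*
targets (200 synapses) at a fixed 1-ms delay and constant weight −5 mV;
there are no inhibitory→inhibitory synapses, which is why inhibitory
neurons fire faster than excitatory ones (≈8.2 vs ≈5.1 Hz under the
defaults). External drive is +20 mV to one uniformly chosen neuron per
1-ms step. A presynaptic spike is delivered to each target after that
synapse's delay, via a ring buffer of pending arrivals.

### Plasticity

Excitatory weights evolve under an asymmetric Hebbian exponential rule
with the presynaptic timestamp taken at spike *arrival* (emission +
delay): an arrival $\Delta t$ ms before a postsynaptic spike contributes
$+A_+ e^{-\Delta t/\tau}$, an arrival after it contributes
$-A_- e^{-\Delta t/\tau}$, with $A_+ = 0.1$, $A_- = 0.12$,
$\tau = 20$ ms. Contributions accumulate in a per-synapse buffer
$\Delta w$; once per simulated second the weights are updated as
$w \leftarrow \mathrm{clip}(w + \Delta w + \lambda,\, 0,\, 10\ \mathrm{mV})$
and the buffer is carried over scaled by the memory factor
$\Delta w \leftarrow 0.9\,\Delta w$. The carry-over is what stretches
weight dynamics to the minute timescale; the package measures that
timescale as the lag at which the across-synapse mean autocorrelation of
the 1-s weight series first drops below 0.5 (linearly interpolated), which
lands near one minute under the defaults.

Two implementation choices deserve explanation because the printed rule
alone does not fix them:

- **Trace scheme.** The rule is implemented with exponential traces. A
  spike can either *add* to its neuron's trace (all-pairs interaction) or
  *reset* it to unit amplitude (nearest-spike interaction). The reference
  cortical-model code resets, and resetting reproduces the reference
  firing rates and the minute-scale weight autocorrelation noticeably
  better than accumulation, so `stdpTraces = "reset"` is the default and
  `"additive"` remains available.
- **Weight drift $\lambda$.** The reference implementation adds a small
  constant $\lambda = 0.01$ mV at every 1-s update, counteracting the
  depression bias $A_- > A_+$. With $\lambda = 0$ the weight population
  hugs the lower bound slightly more and decorrelates faster. The default
  is `weightDrift = 0.01`, configurable to 0.
- The kernel uses decaying exponentials $e^{-|\Delta t|/\tau}$; a growing
  exponential would be non-physical. Simultaneous arrival and spike
  ($\Delta t = 0$) is counted on both sides of the rule, as in the
  reference code.

Excitatory weights are clipped below at 0 so a synapse can never silently
change sign; inhibitory weights are fixed. Wiring, signs and delays never
change during a run — only excitatory weights do — and with
`stdp = FALSE` the whole weight trajectory is constant. Runs are pure
functions of `(network, seed)`.

## Functional connectivity measures

All measures are directed (sender $i$, receiver $j$) and evaluated at
candidate delays $\delta = 1 \ldots 50$ ms on binary 1-ms trains. Lagged
expectations run over the valid overlap $t = \delta + 1 \ldots T$ only; no
circular wrap-around, which would fabricate acausal coincidences.

- **XCorr** $= E[i_{t-\delta} j_t]/(\sigma_i \sigma_j)$: normalized
  cross-correlation *without* mean subtraction. It inherits the product of
  firing rates, so two independent but active neurons score well above
  zero — the rate-sensitivity defect that makes it overestimate
  connections among fast-firing inhibitory neurons.
- **XCov**: the Pearson correlation of the lagged pair (mean rates
  subtracted). Signed: positive for excitatory, negative for inhibitory
  coupling.
- **TE**: plug-in transfer entropy in bits, with a 1-bin sender past at
  $t-\delta$ conditioned on the 1-bin receiver past at $t-1$. Estimated
  with raw frequencies — no bias correction and no shuffling null, with
  $0 \log(\cdot) = 0$ for empty cells — so finite recordings carry a small
  positive bias.
- **HOTE**: the same conditional mutual information with $k$-bin sender
  and $l$-bin receiver past *words* ($k = l = 5$ ms by default), encoded
  as integers with the most recent bin in the least-significant bit.

The static FC value $f_{ij}$ is the profile value at the delay maximizing
its magnitude (absolute value for the signed measures, the signed value is
kept), and $\hat\delta_{ij}$ is that argmax delay, ties broken toward the
smallest delay. Pairs involving silent neurons are undefined and rank
last. The rank-overlap index of two measures,
$O_{ij} = \tfrac12(\mathrm{rank}_{M_1}(ij) + \mathrm{rank}_{M_2}(ij))$
with ascending magnitude ranks, is available for presence inference only —
averaging ranks of two delay profiles has no delay interpretation.

Presence is inferred by thresholding $|f|$ at a percentile of its
distribution over all $N(N-1)$ directed pairs (linear-interpolation
quantile, strict `>` comparison, so the 90th percentile on 100 neurons
retains exactly 990 pairs, and higher thresholds give nested networks).
Performance against ground truth is summarized by precision–recall curves
over percentiles 1–99 and their area (AUPR): trapezoidal over recall,
duplicate recalls keeping maximum precision, the curve anchored
horizontally at its extreme recall points. With these conventions a
perfect ranking scores 1 (up to the discreteness of the percentile grid)
and uninformative scores land at the positive-class prevalence, 0.1 for
the default network. Sign classification uses the $f_{ij} = 0$ boundary of
XCov; the information-theoretic measures are positively defined and are
rejected for this task. Delay recovery is scored on true positives at the
chosen threshold by Pearson correlation and mean absolute error.

## Dynamic functional connectivity vs weight dynamics

Windowed inference uses non-overlapping windows of width $T$ minutes
aligned to $t = 0$ (trailing remainder discarded). DFC is computed only
for pairs whose static FC magnitude is in the top 5th percentile,
restricted to putatively excitatory pairs — inhibitory weights are
constant, so there is nothing to track. Because TE and HOTE carry no sign,
two labelled restriction modes exist: `"sign"` (positive signed FC, with a
companion XCov result when the selecting measure is unsigned) and
`"truth"` (ground-truth excitatory synapses; evaluation mode). Both are
reported so audits can compare them.

Each window is evaluated either at the pair's statically inferred delay
(**delay-consistent**) or at the per-window magnitude-argmax over the full
sweep. The ground-truth comparison series (DSC) is the 1-s weight
trajectory averaged within the same windows. Per pair, the across-time
Pearson correlation between DFC and DSC is computed after subsampling both
series to the number of windows a 30-min window would give (6 for a
180-min recording) — narrower windows give more samples, and correlation
estimates from more samples are not comparable, so sample counts are
matched. Subsampling is evenly spaced by default (a seeded uniform-random
option exists and the choice is reported); evenly spaced indices preserve
the slow component of both series, which is the signal of interest.
False-positive pairs have no weight series: they are excluded from the
correlation distribution and counted. Delay consistency matters most for
narrow windows, where a per-window sweep overfits sampling noise in 50
profiles; at the package defaults the delay-consistent variant gains more
than 0.2 mean correlation below $T \approx 10$ min.

## What the generator does and does not emulate

The generator reproduces the study conditions: sparse random wiring with
the stated in/out-degrees, heterogeneous delays, STDP with the stated
amplitudes, cut-off and memory factor, and Poisson-like single-neuron
drive. It does **not** include global oscillations, correlated common
input, structural plasticity, delay plasticity, conductance-based
synapses, or heterogeneity in per-neuron excitability. Passing tests
therefore demonstrate correct recovery under sparse, stationary,
delay-stable conditions; on real recordings, common input and global
covariations can produce functional couplings with no synaptic
counterpart, and nothing in these benchmarks measures robustness to that.

## Numerical and scale choices

Problem sizes in the test-suite were chosen so the full suite runs in
minutes on one CPU: population firing rates are checked on three 10-min
runs; the weight-autocorrelation timescale on a 60-min trajectory;
structure recovery (AUPR ordering across measures, delay-error ordering)
on a 30-min segment; and the DFC–DSC relationship on a full 180-min
recording with XCov, the measure the full comparison singles out. The
compiled sweeps make this practical: the delay sweep shares one pass over
the sender's spikes per pair, and the TE/HOTE tabulation visits only
times where the sender word is non-zero, recovering the zero-word slice
of the joint table from receiver-only marginals.

Other conventions: percentile thresholds use R's default type-7 quantile;
`reduceProfiles` breaks delay ties toward the smallest delay so estimates
are deterministic; zero-variance windows or trains yield NA and are
excluded pairwise; word tables guard against memory blow-up for long
sweeps with large $k, l$. All randomness (wiring, external drive,
random subsampling) flows from user-supplied integer seeds through R's
RNG, so every output is reproducible bit for bit.

## Known limitations

- Single-repetition desk-scale runs show sampling scatter of a few
  percent in AUPR and precision; the pipeline's `runExperiment` reports
  mean ± SEM over independent repetitions (5 by default) for this reason.
- The plug-in TE estimators are biased upward at finite sample sizes;
  since inference uses within-measure rank comparisons, the bias mostly
  cancels, but absolute bit values should not be over-interpreted.
- XCov and TE systematically overestimate communication delays by a few
  ms (the postsynaptic response peaks after the arrival); HOTE's
  word-embedding largely removes this offset. Delay estimates are
  integers; sub-ms resolution is out of scope.
- The inference layer assumes at most one spike per neuron per 1-ms bin;
  imported spike times violating this are collapsed with a warning.
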
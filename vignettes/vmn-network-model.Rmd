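---
title: "Modelling spike patterning and emergent rhythms in the VMN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling spike patterning and emergent rhythms in the VMN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmnsim)
```

## The model

Neurons of the ventromedial nucleus of the hypothalamus (VMN) recorded *in
vivo* show a spectrum of spike-patterning phenotypes — from apparently random
spiking shaped only by a refractory period, through doublet and short-burst
firing, to regular and oscillatory cells with multimodal interspike-interval
(ISI) distributions. `vmnsim` implements a minimal model family intended to
explain this spectrum with two ingredients: heterogeneous intrinsic
post-spike excitability, and random mutual excitation.

### Single neuron

Each neuron is a modified leaky integrate-and-fire unit. The membrane
potential is assembled from components rather than integrated as a single
state:

$$V = V_{rest} + V_{syn} - HAP - AHP + DAP$$

`V_syn` integrates synaptic input $I = I_{ext} + I_{net}$ and leaks with
half-life $\lambda_{syn}$:

$$\frac{dV_{syn}}{dt} = -\frac{V_{syn}}{\tau_{syn}} + I, \qquad
  \tau_x = \lambda_x / \ln 2 .$$

External drive is a pair of independent Poisson streams: EPSPs of fixed
amplitude $e_h$ at rate $I_{re}$ and IPSPs of amplitude $i_h$ at rate
$I_{ratio} \cdot I_{re}$, so a single rate parameter controls the drive.
Three post-spike potentials are incremented by their $k$ amplitude at every
spike and decay with their own half-lives:

* **HAP** — large and brief (default 30 mV, 8 ms): produces the relative
  refractory period that dominates the ISI distribution.
* **AHP** — small and slow (0–5 mV, hundreds of ms): activity-dependent
  negative feedback; lowers the index of dispersion (IoD) at long
  binwidths.
* **DAP** — small, slow depolarisation: activity-dependent positive
  feedback; raises the IoD at long binwidths and, in a network, enables
  bistability.

Unlike the classic integrate-and-fire model there is **no post-spike
reset**: all three potentials accumulate across intervals, which is what
lets the slow AHP and DAP integrate activity over seconds. A spike is fired
when $V \ge V_{thresh}$ and at least the 2-ms absolute refractory period
has elapsed; the spike waveform itself is not modelled, and the spike's own
increments act from the next step.

A useful derived quantity is the *relative refractory period*: the time for
$V$ to return within 1 mV of rest after a spike with no input
(`relative_refractory_estimate()`); for an HAP-only cell it is
$\lambda_{HAP} \log_2 k_{HAP}$.

### Network

A population of such neurons is wired at random: each ordered pair is
connected independently with probability `esyn_1` (self-connections
excluded; the two directions of a pair are independent draws). Two-type
networks add a feed-forward projection from type 1 onto type 2 with
probability `esyn_12`. A presynaptic spike triggers, per connection, an
independent Bernoulli(`syntrans` = 0.5) transmission trial; a successful
trial delivers one EPSP of amplitude `synweight_1 * n_h` (default 3 mV)
after the connection's frozen delay
$\Delta = \Delta_{min} + \Delta_{range} U(0,1)$ (default 5–15 ms),
implemented with a per-neuron delay queue at the simulation step
resolution. Summation within a step is linear. Transmission failure and
delay dispersion are not decoration: without them the network
over-synchronises into all-or-none population spikes instead of the graded
oscillations of interest.

### Noisy drive

For slow drive fluctuations the external rate can be made an
Ornstein–Uhlenbeck variable (`ou_params()`), updated by Euler–Maruyama with
mean `mu_noise`, time constant `tau_noise` (seconds) and amplitude
`k_noise`, clamped at zero because it is a Poisson rate. The amplitude
convention is a genuinely open choice: we default to a *relative*
amplitude (`k_noise = amp * mu_noise`, in Hz per √s) with an absolute
option, and treat any behaviour that depends on the exact convention as
qualitative.

## Numerical choices

* **Integration.** Each step, state variables are decayed and the step's
  input added. Two decay factors are offered: the forward-Euler factor
  $1 - dt/\tau$ (default) and the exact factor $e^{-dt/\tau}$
  (`integration = "exact"`). The model's reference behaviours — in
  particular the bistable network, which sits deliberately at a knife-edge
  of its input range — are defined at $dt = 1$ ms under the Euler
  discretisation of the equations above, and the two factors differ enough
  (0.9076 vs 0.9118 for $\lambda_{syn} = 7.5$ ms) to move that network off
  its calibrated critical point: under the exact factor the slow state at
  100 Hz input escapes to the fast state. We therefore ship Euler as the
  default and keep the exact factor for analyses that need
  step-size-independent half-lives (it is what the decay-exactness test
  uses).
* **Update order.** Per step: read the delay queue, draw external input,
  decay state, add input to `V_syn`, threshold, then apply post-spike
  increments (so a spike's HAP acts from the next step). Adding input
  *before* the decay was evaluated and rejected: it weakens every PSP by
  the decay factor and detunes the bistable network's calibrated input
  range.
* **Determinism.** Every neuron owns two private RNG streams (external
  input, inbound transmission) seeded from `(seed, neuron, purpose)`, so a
  run is bit-reproducible from its seed, an unconnected network is
  bit-identical to the matching single-neuron runs, and disabling
  transmission does not perturb the input streams. The generators (64-bit
  Mersenne Twister, Knuth Poisson, Box–Muller) are implemented in the
  package's compiled code rather than delegated to platform-dependent
  library distributions.
* **Delays** are rounded to the nearest step when indexing the queue
  (minimum one step) and frozen per connection; per-event draws were
  reported equivalent for the original model and are not the default.
* **Initialisation.** `V_syn` starts at 0 and the post-spike potentials at
  their `k` values (a configuration switch starts them at 0); statistics
  discard the first 5 s by default (`pattern_summary(discard_ms = 5000)`).

## Spike-pattern statistics

`pattern_summary()` bundles the three fit-relevant statistics:

* **ISI histogram** in 5-ms bins (10-ms for display), optionally
  normalised to total 10000 so cells with different spike counts compare.
* **Hazard function**: bin count divided by the number of intervals
  surviving to the bin's left edge — the post-spike excitability profile.
  We compute the survivor count as "length ≥ left edge" so that hazard ×
  survivors reconstructs the histogram exactly from binned data (for
  continuous spike times this differs from a strict ">" reading only on a
  measure-zero set).
* **IoD range**: variance/mean of spike counts in bins of 0.5–10 s,
  tiling the recording window from its origin (trailing partial bin
  dropped). Poisson spiking gives 1 at every binwidth; regularity pushes
  it down; clustering pushes it up with strong binwidth dependence. It is
  the statistic that *sees* the slow AHP/DAP feedback.

Population tools (`population_rate()`, `postsynaptic_signal()`,
`oscillation_frequency()`, `segment_bistable_states()`,
`spike_triggered_average()`, `crosscorrelogram()`, `isi_modes()`) quantify
the network-level claims. `oscillation_frequency()` uses an averaged
periodogram (50-s segments, half overlap, mean removed) and flags a peak
below 4× the median band power as non-significant; the segment length is a
compromise fixing 0.02-Hz resolution for 500-s runs. Bistable-state
segmentation smooths the per-neuron population rate with a 10-s window and
thresholds at 3 spikes/s — the geometric midpoint of the two states it
separates (~0.85 and ~6 spikes/s) — merging intervals shorter than 10 s.
`isi_modes()` breaks ties by keeping the taller peak when two candidate
modes fall within the minimum separation.

## Genetic-algorithm fitting

`ga_run()` fits the single-neuron model to a target `pattern_summary` by
evolving parameter vectors inside fixed physiological ranges
(`fit_param_ranges()`): populations of 128 over 40 generations by default,
32 truncation-selected parents, uniform per-parameter crossover between two
distinct parents, mutation by uniform redraw (p = 0.05), and elitism (the
incumbent best survives unchanged, making the best-score trace
non-increasing). Each candidate is simulated for 1000 s with a seed derived
from (run seed, generation, index), so any evaluation can be reproduced
bit-for-bit.

The score is a weighted sum of mean absolute per-bin differences: ISI head
range (bins 0–50, i.e. 0–250 ms, weight 200), ISI tail range (bins 50–200,
weight 100), hazard (weight 100, bins with fewer than 20 surviving target
intervals masked as noise-dominated), and the seven IoD-range values
(weight 100). The mean-per-bin (rather than summed) distance keeps the
weights comparable across ranges of different widths. Head/tail bounds are
interpreted as 5-ms bin indices; both the distance and the interpretation
are package design choices, since only the weights and ranges of the
original fitting protocol are documented.

Because the score surface has a ridge along the $k_{HAP}$–$\lambda_{HAP}$
trade-off (a taller, faster HAP mimics a smaller, slower one over the ISI
head), single short GA runs can land on the ridge; the remedy is the
consensus protocol (`consensus_fit()`): repeat the GA with distinct seeds
and take per-parameter medians of the best runs. The reference protocol is
100 runs/best 10; the package defaults to a desk-scale 20/5, and the test
suite uses 4/2 with 64-candidate populations — enough for the recovery
tolerance it asserts. `mode_comparison()` repeats the fit with HAP-only,
HAP+AHP and HAP+DAP parameter sets; nesting guarantees the richer mode can
only help, and which component improves (the IoD range) identifies the
feedback sign of the underlying cell.

## What the synthetic generators do and do not emulate

`synthetic_train()` provides Poisson, regular, gamma-renewal, burst-epoch
and sinusoid-modulated (thinning-generated) trains whose ISI and IoD
structure is known in closed form; they anchor the analysis tests and the
GA recovery harness. They emulate *stationary* patterning regimes only.
Real VMN recordings add slow nonstationarity, state switches, spike-sorting
errors and finite recording windows; passing tests on these fixtures
therefore validates the statistics and the fitter's machinery, not the
model's adequacy for any particular recorded cell.

## Problem sizes

The package's own test and reproduction scale is: 500-s network runs (100–
200 neurons) for the emergent-behaviour checks, 2000-s single-neuron runs
for distributional checks, 200-neuron/200-s heterogeneous galleries, and
the reduced GA protocol above. Longer paper-scale runs (2000 s, 100-run
consensus) are available through the same functions by changing arguments.

## Known limitations

* The signal-generator network's oscillation onset is sensitive to the
  discretisation details discussed above: at 130-Hz input the package
  produces ~2.9 Hz where ~2.3 Hz has been described for this configuration;
  the two values bracket the same qualitative onset and converge at higher
  drive (6 Hz at 600-Hz input). We report the computed value rather than
  calibrating toward the description.
* A strong slow DAP on a fast-HAP cell is supercritical: cumulative
  positive feedback saturates the cell at the refractory-limited rate.
  This is a property of the cumulative no-reset formulation, and it is why
  DAP-carrying configurations pair the DAP with a slow HAP brake.
* No inhibitory synapses, plasticity, spatial structure, or conductance-
  based membrane dynamics; one neuron model per cell with per-neuron
  parameter heterogeneity only.
* Network-model fitting is deliberately manual/scripted (sweeps via the
  `exp_*` experiment drivers); the GA fits single neurons only.
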
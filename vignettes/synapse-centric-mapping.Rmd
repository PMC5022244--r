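---
title: "Synapse-centric mapping: models, cost constants, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synapse-centric mapping: models, cost constants, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synapsim)
```

# The problem

Cortical-scale spiking network models are synapse-dominated: a neuron
receives on the order of 8000 inputs, at connection densities of 20% or
below, and at a few Hz of presynaptic activity this amounts to roughly
24,000 synaptic events per neuron per second. On many-core neuromorphic
hardware of the SpiNNaker type, the conventional ("standard") mapping gives
each 200 MHz core a slice of neurons *plus all their afferent synapses*.
Synapses are processed event-wise: each presynaptic spike triggers the
fetch of one synaptic-matrix row, and each fetched row carries a fixed
overhead (interrupt servicing, DMA setup, loop setup) on top of the
per-synapse cost. When connectivity is sparse, rows are short, the fixed
cost dominates, and the only remedy — putting fewer neurons on the core —
makes the rows shorter still.

The synapse-centric mapping splits the synaptic matrix **row-wise** over
dedicated *synapse processors*, which accumulate their slice of each
neuron's input in ring buffers and publish the accumulated input once per
time step through shared memory buffers to dedicated *neuron processors*.
Row length then depends only on the postsynaptic slice width, not on how
many cores share the processing load. `synapsim` is a software simulator of
this architecture: it reproduces the mapping's cost models and partitioning
rules, and executes the partitioned network as communicating virtual cores
with the same dataflow.

# Cost models

All planning arithmetic lives in `cost_constants()`. The per-event and
per-neuron cycle counts are profiling figures for a 200 MHz core:

* standard mapping: 181 cycles per neuron update and 21 cycles per static
  synaptic event; with pair-based STDP, 187 cycles per neuron and
  `131 + 31 h` cycles per event, where `h` is the expected number of
  postsynaptic history entries replayed per row update (`h = 1` when pre-
  and postsynaptic rates are similar);
* synapse-centric: 15 cycles per static event and `107 + 30 h` per STDP
  event, the improvement coming from each processor handling a single
  synapse type.

The standard-mapping capacity is
`floor(clock / (per_neuron/dt + per_event * mu))` neurons per core
(`estimate_standard_neurons_per_core()`); the static value is capped at 256
neurons, the figure used in practice. A synapse processor's throughput is
`clock / (per_event + per_row/row_len)` events per second
(`synproc_capacity()`), which reduces to the peak figures `200e6/15 ≈
13.3e6` and `200e6/137 ≈ 1.46e6` when the per-row overhead is ignored.

Two constants are **not** profiling figures: the per-row overheads
`sc_static_per_row = 800` and `sc_stdp_per_row = 1500` cycles. The source
analysis does not print them; they are calibrated to the narrow admissible
intervals implied by the processor counts the row-aware model must yield on
the 10 Hz-source benchmark (static: 2 processors at 100% connectivity but 3
at 10%, which pins the constant to roughly (547, 964]; STDP: 9 at 100%, 10
at 20%, failure of 10 at 10%, pinning it to roughly (1319, 2638]). Both are
exposed as arguments of `cost_constants()` and should be re-profiled for
any real target platform.

One published formula for the standard static mapping is corrupted in the
source text; it is reconstructed here as `clock/(181/dt + 21 mu)` by
analogy with the printed STDP formula's structure. The reconstruction
reproduces every 1 ms quantity used by the package, but at `dt = 0.1` ms it
gives 86 neurons per core where 84 was reported; nothing in the package
depends on the 0.1 ms value, and it is left as a known discrepancy.

# The partitioner

`partition_synapse_centric()` splits each population's afferent synapses in
three stages:

1. **by synapse type** (receptor × plasticity rule), so each synapse
   processor holds a single ring buffer and a single rule — this is also
   what makes heterogeneous learning rules on one population trivial;
2. **postsynaptically**, into groups of at most 1024 neurons (static) or
   512 (STDP) — local-memory limits of the ring-buffer and postsynaptic
   history structures;
3. **presynaptically**, into the minimal processor count `k` whose cycle
   budget covers the estimated event and row-fetch load
   (`count_synapse_processors()`), planned from a presynaptic rate
   assumption (default 3 Hz, the cortical figure behind
   8000 × 3 Hz = 24 kHz) and `h` (default 1).

Neuron processors hold 1024 neurons by default. When the synapse processors
serving one 1024-neuron group number four or more, or a shared-buffer group
would exceed the 16 cores of a chip, the neuron processor is halved to 512
neurons — the rule behind the published example in which a 17-core buffer
group is cut to 9. The population's synapse-core total is
`ceiling(neuron_cores × k_group × nsize/1024)` with types summed *before*
rounding; rounding per type instead would add a spurious core on the
80,000-neuron benchmark. Per-type core labels are then apportioned by
largest remainder. Populations with background input get one current-input
processor per neuron core; Poisson source populations get spike-source
cores. `partition_standard()` implements the column-wise mapping for
comparison, and `audit_allocation()` converts recorded per-step event and
row counts back into cycles to check every core against its real-time
budget `clock × dt`.

On the two reference networks (80/20 excitatory/inhibitory random networks
at 2% of 10,000 neurons and 10% of 80,000), the partitioner yields 10+20=30
and 157+314=471 cores:

```{r partition}
partition_synapse_centric(make_vogels_abbott(10000, 0.02))$totals
partition_synapse_centric(make_vogels_abbott(80000, 0.1))$totals
```

# Deferred plasticity

Synapses are updated event-wise, so plasticity must be *deferred*: a
synapse's state is only reconciled when its row is fetched. Each row stores
the last presynaptic spike time, the presynaptic trace at that time, and
the last-update time; each postsynaptic neuron keeps a fixed-capacity
(default 10-entry) circular queue of (spike time, postsynaptic trace)
pairs. On a presynaptic spike at `t`, `process_row()` replays, for every
synapse, the history entries accumulated since the last update as
potentiation (pairing each with the stored presynaptic spike), applies
depression against the most recent postsynaptic entry, inserts the settled
weight into the ring buffer at the synapse's delay, and advances the
header. The kernel is all-pairs pair-based STDP with additive weight
dependence, hard-clipped to `[0, w_max]`; the shipped defaults
(`tau = 20` ms, `a_plus = 0.01`, `a_minus = 0.012`) are the conventional
values for that rule, not measurements.

With unbounded history the deferred algorithm is *exactly* — to the last
bit — equivalent to an online implementation that updates the weight at
every spike; the test suite verifies this on 1000 random spike-train pairs.
The finite queue can overflow when a presynaptic neuron stays silent while
its targets fire. The chosen capacity of 10 reflects the published analysis
of cortical rate-ratio distributions (a 10-entry buffer covers over 90% of
the ratio distribution). To protect the tail of that distribution, a
neuron that has been silent for `capacity × (1000/max_rate)` ms emits a
**flush event**: a non-spike event carrying its id with a flag bit set,
which forces its efferent rows to replay accumulated history without
applying a presynaptic update. The silence timer re-arms after each flush.

Two interpretation choices here were genuinely open. The source description
says each *postsynaptic* neuron tracks its interspike interval, yet the
emitted event must traverse the presynaptic side of the rows it flushes;
`synapsim` has every neuron monitor its own silence (each neuron is
presynaptic to its efferent rows), which delivers the intended guarantee.
Whether the timer re-arms after a flush is unstated; it re-arms here, since
otherwise a silent neuron would flush on every subsequent step.
Simultaneous pre- and postsynaptic spikes are ordered post-before-pre: a
history entry at exactly the update time is replayed before the
presynaptic update, and the zero-gap interaction contributes with no decay.

Queue overflow accounting distinguishes the module level from the engine.
`post_history()` counts every overwritten entry, which is the right measure
for an isolated queue. The engine counts an overwrite as *lost* only when
some row of the unit had not yet replayed the entry — once every row has
consumed an entry, overwriting it is the queue's normal wrap-around, not a
loss. With flushes enabled and all rates at or below `max_rate` (in the ISI
sense: no interspike interval shorter than `1/max_rate`), the engine
records zero lost entries; with flushes disabled and a fast postsynaptic
target, entries are lost and the final weight measurably diverges from the
online oracle. Lost entries are always counted and reported, never silent.

# Fixed-point accumulation and exact integration

Ring-buffer accumulators are saturating fixed-point integers (default 16
fraction bits, saturation at ±(2³¹−1)), stored as integer-valued doubles.
Integer addition is associative, so the drained input — and therefore the
whole simulation — is **bit-identical** under any partitioning of the same
network. This is the central correctness claim of the mapping: results must
not depend on how the network is laid out across cores. With
floating-point accumulators the claim could only hold to a tolerance;
here it is exact, and the suite asserts `identical()` rasters and weights
across the standard mapping and synapse-centric partitionings with 1, 2,
and 4 synapse processors per type.

Neuron dynamics use per-step closed-form exponential integration: each
receptor current decays by `exp(-dt/tau_syn)` and receives the drained
input, then the membrane relaxes toward `v_rest + R I` with factor
`exp(-dt/tau_m)`, treating the current as constant within the step. Under
constant input this reproduces the analytic charging curve to better than
1e-9 mV. Spikes are detected after integration; refractory neurons are
held at reset while their synaptic currents continue to evolve. Whether
the hardware implementation integrates exactly or by forward Euler is not
documented; exact integration is chosen for testability, and no claim of
numerical equivalence to any hardware binary is made.

Delays are integer multiples of `dt`, all modelled as dendritic and applied
through the ring buffer (following the restricted delay model in which the
axonal delay never exceeds the dendritic one); the minimum delay is one
step and the default ring depth is 16 steps. A spike emitted at step `t`
is processed by synapse units at step `t+1`, and a delay of `d` makes its
weight reach the target's input at step `t+d`, so the end-to-end latency
equals the projection delay.

# Randomness and reproducibility

Every stochastic element draws from a sub-stream keyed by the master seed
and a stable label (`stream_seed()`): connectivity rows by (seed,
projection, presynaptic id), source spike trains and background input by
population, initial voltages by population. Rows are always sampled
against the full postsynaptic population and sliced afterwards, so
postsynaptic slicing cannot change which pairs exist; source and
background realizations are pre-generated at engine build, so partitioning
cannot change the realized input. A counter-based generator keyed the same
way would be the natural choice in a lower-level language; per-stream
seeding of R's generator provides the identical guarantee (the simulation
is a pure function of spec and seed) without hand-rolling 64-bit integer
arithmetic in R. Within a step, events are processed in ascending key
order — a deliberate determinism trade against the arrival
nondeterminism of real routing fabric.

# The benchmark generators and what they do (not) show

`make_poisson_benchmark()` reproduces the throughput benchmark's geometry:
`ceiling(mu/(source_rate × connectivity))` independent 10 Hz sources so
each neuron's expected input rate is `mu` regardless of connectivity, with
optional STDP and an analytically calibrated DC drive (`dc_for_rate()`,
the closed-form inverse of the LIF ISI; the source's drive magnitudes for
10/20 Hz targets are unstated) for nonzero postsynaptic rates.

`make_vogels_abbott()` builds the classic 80/20 current-based LIF random
network. The source analysis uses it only for partitioning counts and
prints neither its neuron parameters nor its firing rates, so the fixture
adopts the cited benchmark literature's values (20 ms membrane, 5/10 ms
exc/inh synapses, threshold −50 mV, reset −60 mV, rest −49 mV — above
threshold, which is what makes the network self-sustaining — 5 ms
refractory; reference weights 1.62/−9 mV at the 4000-cell, 2% scale).
Weights are scaled inversely with expected in-degree so the mean drive is
preserved at 10,000 and 80,000 neurons; a 50 ms DC kick starts the
activity, and the suite checks only the qualitative property that activity
persists after the kick at a plausible population rate (1–100 Hz).

`make_modular_attractor()` builds the hypercolumn/minicolumn skeleton
(1000 excitatory cells in 10 minicolumns plus 250 inhibitory per
hypercolumn) with **two simultaneously trained plastic synapse types** on
the same population — a short symmetric-window AMPA-like rule and a long
asymmetric-window NMDA-like rule — plus static inhibition. The original
model's learning rule (BCPNN) is defined in cited work, not in the source
analysis, so the two rules here are STDP configurations chosen to exercise
the same architectural feature (heterogeneous rules, one population); the
fixture validates architecture, not the original model's numerics. After
training on a repeating minicolumn sequence
(`attractor_training_stimulus()`), the learned NMDA-like cross-minicolumn
weights are directionally asymmetric — forward transitions stronger than
backward — which is the property the suite asserts.

Passing these tests shows that the *mechanisms* (event-driven rows,
deferred plasticity, flushing, partitioning) behave exactly as specified
under controlled synthetic conditions. It does not validate biological
realism of any fixture, reproduce hardware throughput or memory-bandwidth
measurements (which depend on DMA contention and interconnect behavior
this simulator deliberately does not model), or calibrate the two per-row
overhead constants beyond the intervals stated above.

# Problem sizes used by the test suite

Simulation-backed checks are sized to run comfortably on one CPU: the
partition-invariance check uses a 2000-neuron mixed plastic/static network
for 200 ms under four partitionings; the oracle-equivalence check uses
1000 random train pairs of 10 s at up to 50 Hz; the flush check uses 10 s
of 1 Hz presynaptic against 100 Hz postsynaptic activity; the
self-sustained-activity check runs the full 10,000-neuron network for
500 ms; the attractor check trains one hypercolumn on a 6-element sequence
for two repetitions. The cost-model and partitioning checks are closed
form and run instantly at the published sizes (up to 80,000 neurons).

# Known limitations

* No placement onto physical chip/board topology, routing tables, DMA
  latency, packet loss, or router congestion: costs are *accounted*, not
  enacted, and "chip" exists only as the 16-core shared-buffer constraint.
* Current-based exponential synapses only; no conductance synapses,
  adaptive thresholds, or spike-frequency adaptation.
* Weight state is double precision except inside ring buffers; hardware
  16-bit weight quantization outside the accumulators is not modelled.
* The per-row overhead defaults are calibrated, not measured, and the
  0.1 ms standard-mapping capacities are outside the validated domain.
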
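---
title: "The construction model behind netconstr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The construction model behind netconstr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netconstr)
```

## What is being modeled

Parallel spiking-network simulators spend a distinct phase instantiating the
network in memory before any dynamics runs. netconstr models that phase as a
self-contained, testable kernel. The ingredients are:

* **Node distribution.** All nodes (neurons and devices) are enumerated by
  0-based global identifiers (gids) and assigned round-robin to
  `vp = M x T` virtual processes: `vp(gid) = gid mod VP`. Every result
  depends only on the VP count, never on the process/thread factorization
  `(M, T)` — a contract this package enforces by deriving one random stream
  per VP from `(master_seed, vp)` alone, and which the test suite checks by
  comparing builds and spike records across factorizations.
* **Adjacency storage.** Each VP stores every connection whose *target* it
  owns, keyed by source. A source with no local target costs only an unset
  presence bit in a sparse source table. Below `k_cutoff = 3` local
  connections of one synapse type, a connector is a fixed-size array that is
  reallocated on each growth step; from `k_cutoff` on it is a dynamic array
  whose capacity doubles when exceeded; sources with two or more synapse
  types hold one homogeneous sub-connector per type inside a heterogeneous
  wrapper.
* **Allocation accounting.** Every state transition of that hierarchy
  implies a fixed set of allocation/free events, and the store logs them in
  a per-VP ledger. The ledger models the *accounting*, not the host
  runtime's heap — which is exactly what makes the closed-form operation
  counts below testable in any language.
* **Wiring rules.** Fixed in-degree (each target draws `K` sources i.i.d.
  uniformly with replacement; multapses and autapses permitted) and
  all-to-all, each in two loop orders: a *target scan* that iterates all
  targets on every VP and skips non-local ones, and a *local scan* that
  iterates only the VP's own nodes and tests membership in the target set.
  Phase counters (outer iterations, skips, draws, connect calls, membership
  tests) act as the hardware-independent surrogate for phase timings.

## The closed-form predictions

For the balanced random network benchmark (`N` neurons, `epsilon = 0.8`
excitatory, in-degree `K`), excitatory sources project with two synapse
types (plastic to excitatory targets, static to inhibitory ones) while
inhibitory sources use a single type. Expected per-VP connector sizes are

    k_EE = epsilon K / VP,   k_EI = (1 - epsilon) K / VP,   k_I = K / VP.

Creating the connectors of `S` sources with eventual average size
`k >= k_cutoff` costs approximately

    n_alloc = (4 + ceil(log2(k / k_cutoff))) S
    n_free  = (3 + ceil(log2(k / k_cutoff))) S

per VP (`predicted_memory_ops_dense()`): one-element connector plus
source-table registration, the fixed-size growth step, the transition to a
dynamic connector, and one pair per capacity doubling. In the sparse,
highly distributed regime where almost every source has at most one local
connection, only the `N1c` singly connected sources cost anything:
`n_alloc = 2 N1c`, `n_free = N1c` (`predicted_memory_ops_sparse()`).

Per-VP source occupancy follows the Poisson limit of placing
`K_vp = floor(N K / VP)` uniform draws over `N` sources: with
`lambda = K_vp / N`, the expected counts of sources with 0, 1 and more than
one local connection are `N e^-lambda`, `N lambda e^-lambda` and the
remainder (`occupancy_expectation()`), with `occupancy_montecarlo()` as the
stochastic check that simulates single VPs directly.

```{r}
spec <- network_spec(25000, 2500)
expected_connector_sizes(spec, vp = 48)[c("k_EE_display", "k_EI_display", "k_I_display")]
```

## Numerical and design choices

Several conventions are not forced by the model and had to be fixed once:

* **Gids are 0-based, ranges half-open** (`[first, first + count)`), and
  assignment is `gid mod VP`. The fixed bijection to processes is
  `process = vp mod M`, `thread = vp div M`; only the vp identity matters.
* **Seed derivation.** Stream `vp` is splitmix64 seeded with
  `mix64(master_seed + golden_gamma * (vp + 1))`, where `mix64` is the
  standard 64-bit finalizer. Bounded draws use rejection sampling, so they
  are exactly uniform. No bit-compatibility with any simulator's native
  generators is attempted.
* **Loop-order equivalence requires an iteration convention.** Both loop
  orders visit a VP's local targets in ascending gid order; this is what
  makes the stream consumption — and therefore the networks, ledgers and
  event logs — identical edge for edge. Explicit target lists are sorted
  internally for the same reason. Streams advance only for local targets.
* **Dynamic capacity sequence.** Doubling starts at `k_cutoff`
  (capacities 3, 6, 12, 24, ...), which makes the number of doublings for a
  connector of size `k` exactly `ceil(log2(k / k_cutoff))` and the ledger
  replay equal to the closed form whenever a source's realized size is the
  integral mean. Below the cutoff the replay gives `2 + (k - 1)` allocations
  and `1 + (k - 1)` frees, outside the dense formula's domain.
* **Registration costs.** Source-table registration is charged once, on a
  source's first local connection (not on every connector replacement), and
  the heterogeneous conversion is charged the same one-allocation-one-free
  as registration. With these choices the full small-benchmark build lands
  about 1% above the closed-form 325,000 / 280,000 per VP — inside the 3%
  band the approximation is expected to hold, the residual coming from the
  randomness of realized connector sizes around their means.
* **Table conventions.** `N_vp` is reported as `round(N / VP)` and `K_vp`
  as `floor(N K / VP)`, which reproduce the printed per-VP neuron and
  synapse counts for both benchmark geometries; `lambda` is defined from
  `K_vp / N`. The occupancy expectations then match the printed class
  counts to about a part in 10^4; the exact convention behind the last
  digits of those printed values is unknowable from the text, and the
  Monte-Carlo tolerance (3 standard errors) absorbs it.
* **Display rounding** of connector sizes is half-up to one decimal.

## What the benchmark generator emulates — and what it does not

`build_benchmark()` is a first-class synthetic-world generator: excitatory
gids first, then inhibitory, then one drive device and one recorder, wired
E->E (plastic), E->I (static), I->all (static), drive all-to-all. Defaults
follow the stated benchmark where values exist (`epsilon = 0.8`, and the
two published geometries `N = 25,000, K = 2,500` on 48 VPs and
`N = 2 x 10^8, K = 11,250` on 1,835,008 VPs). Everything dynamical is *not*
printed in the source material and is chosen here once, conventionally:
leaky integrate-and-fire with `tau_m = 10` ms, `C_m = 250` pF, 20 mV
threshold, 2 ms refractoriness, exponential synaptic currents
(`tau_syn = 0.5` ms), `dt = 0.1` ms, delay 1.5 ms, excitatory weight
87.8 pA with inhibition ratio `g = 5`, and an aggregate Poisson drive of
12,000 spikes/s per neuron — set so the mean drive sits just above
threshold, the standard operating point for an active balanced network.
The plasticity stand-in is an additive all-pairs STDP rule
(`stdp_update()`), exposed but not applied during the demonstration loop.

Consequences for interpreting green tests: structural claims (in-degrees,
connector states, ledgers, censuses, loop-order and partition invariance)
are exercised exactly and at the published small-benchmark scale; dynamical
output is only a functional probe of the store (spikes flow through the
adjacency and respect delays) and says nothing quantitative about the
biology of the benchmark network. Real distributed execution, message
passing, wall-clock timings, resident-set sizes and actual allocator
implementations are all outside the model; the allocator module
(`contention_summary()`) counts guarded interactions of an abstract
serialized vs thread-local-pool allocator instead, with the refill size `R`
as a free parameter (CLI default 64 objects per pool exchange).

The one recorder is implicit: it observes all local neurons without stored
edges. Storing neuron-to-recorder connections would add a third synapse
type to every source on the recorder's VP and distort the very ledger the
accounting model predicts; device connectivity is therefore represented by
the drive's `N` all-to-all edges only, and recording happens in the
simulation loop directly.

## Scaling choices in the test suite

The acceptance suite builds the full small benchmark (62.5 million
connections, counts-only mode, ~6 s) and recovers the large benchmark's
occupancy classes by single-VP Monte Carlo (about 1.23 million draws per
replicate, 100 replicates, under a minute) rather than building
2.25 x 10^12 synapses, which no desk machine can hold. The large geometry's
iteration behaviour is exercised through `dryrun_build()` of a single
emulated rank, where the local scan needs only ~109 outer iterations per VP
against 2 x 10^8 under a target scan.

## Known limitations

* Connection parameters are homogeneous per request; no per-connection
  randomization of weights or delays.
* Only fixed in-degree and all-to-all rules; no fixed out-degree or
  pairwise-Bernoulli.
* The dynamics loop is plain R and meant for networks of tens to hundreds
  of neurons; the compiled path covers construction, where the scale is.
* Heterogeneous connectors beyond two synapse types follow the obvious
  extension (one new sub-connector allocation per additional type), which
  the accounting model never exercises.
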
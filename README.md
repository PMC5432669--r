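# netconstr

Parallel construction kernel for spiking neuronal networks, as an R package.

Before a spiking network can be simulated it must be instantiated in memory:
nodes enumerated and distributed over parallel workers, and for every neuron
a fixed number of randomly drawn incoming connections created and stored.
At scale this phase is dominated by data-structure growth and memory
allocation, not by neuroscience. netconstr models that construction phase
end to end — reproducibly, on one desk-scale machine — so its structural
and cost properties can be measured and checked against closed-form
predictions:

* **Topology**: 0-based gids assigned round-robin to `VP = M x T` virtual
  processes (`vp = gid mod VP`); populations registered en bloc so registry
  memory is independent of network size.
* **Per-VP random streams** (splitmix64) derived from `(master_seed, vp)`
  only, making every result invariant under repartitioning between
  processes and threads at fixed `VP`.
* **Connection store**: per-source connectors behind a sparse source table —
  fixed-size below `k_cutoff = 3` connections, capacity-doubling dynamic
  arrays above, heterogeneous wrappers for multiple synapse types — with a
  ledger of every modeled allocation/free.
* **Wiring rules**: fixed in-degree and all-to-all, each in two loop orders
  (scan all targets and skip non-local ones, or scan only local nodes and
  test membership), producing identical networks but very different
  iteration counts.
* **Predictions**: expected connector sizes `k_EE = epsilon K / VP`,
  `k_EI = (1 - epsilon) K / VP`, `k_I = K / VP`; per-VP allocation counts
  `n_alloc = (4 + ceil(log2(k / k_cutoff))) S`,
  `n_free = (3 + ceil(log2(k / k_cutoff))) S` in the dense regime and
  `(2 N1c, N1c)` in the sparse one; Poisson occupancy classes of the source
  population per VP, with a Monte-Carlo cross-check.
* **Benchmark builder** for the balanced random network (80% excitatory,
  fixed in-degree, plastic E-to-E synapses), a dryrun mode emulating one
  rank of a huge distributed layout, a minimal leaky integrate-and-fire
  loop over the constructed adjacency, an abstract allocator-contention
  model, and a CLI.

## Worked example

```r
library(netconstr)

# the published small benchmark: 25,000 neurons, in-degree 2,500, 48 VPs
spec <- network_spec(25000, 2500, epsilon = 0.8)
ks <- expected_connector_sizes(spec, vp = 48)
c(ks$k_EE_display, ks$k_EI_display, ks$k_I_display)
#> [1] 41.7 10.4 52.1
# -> an excitatory source ends with ~41.7 plastic and ~10.4 static
#    connections per VP, an inhibitory source with ~52.1

# predicted per-VP memory operations, summed over source groups
ee <- predicted_memory_ops_dense(20000, ks$k_EE)
ei <- predicted_memory_ops_dense(20000, ks$k_EI)
ii <- predicted_memory_ops_dense(5000, ks$k_I)
c(ee$n_alloc + ei$n_alloc + ii$n_alloc, ee$n_free + ei$n_free + ii$n_free)
#> [1] 325000 280000

# a scaled-down instrumented build: 1,000 neurons, in-degree 100, 4 VPs
b <- build_benchmark(hpc_benchmark_spec(1000, 100), parallel_layout(vp = 4),
                     seed = 1, retain_records = TRUE)
b$report$ledger
#>   vp n_alloc n_free
#> 1  0   11070   9272
#> 2  1   11031   9237
#> 3  2   11039   9241
#> 4  3   11061   9266
b$report$census          # every source has >1 local connection on every VP
#>   vp n0 n1 n_more
#> 1  0  0  0   1000
#> ...
n_connections(b$store)   # 1000 x 100 neuron edges + 1000 drive edges
#> [1] 101000

# how a thread-local pool allocator (64 objects per refill) would reduce
# globally guarded interactions relative to a serialized allocator
contention_summary(b$report$ledger, "serialized")$guarded_interactions
#> [1] 81217
contention_summary(b$report$ledger, "thread_local_pool", refill = 64)$guarded_interactions
#> [1] 1272

# spikes actually flow through the constructed store
sim <- simulate_benchmark(b, duration = 200)
nrow(sim$spikes)
#> [1] 7676
```

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "netconstr", package = "netconstr"))')
Rscript "$CLI" predict --N 25000 --K 2500 --epsilon 0.8 --vp 48 --out-dir out/
Rscript "$CLI" build --N 1000 --K 100 --vp 4 --seed 1 --loop-order local-scan --out-dir out/
Rscript "$CLI" simulate --N 40 --K 10 --vp 2 --duration-ms 100 --out-dir out/
Rscript "$CLI" contention --report out/report.json --refill-size 64 --out-dir out/
```

Outputs: `edges.tsv` (source/target/type/weight/delay), `spikes.gdf`
(`time_ms<TAB>gid`), `report.json`, `contention.json`. A `--config` file
(JSON or flat `key: value` lines) supplies defaults; flags override it.

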
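# shared test helpers: tiny deterministic builds and comparisons

# wire one fixed in-degree request into a fresh store, returning everything
# needed for comparisons
tiny_fid_build <- function(n_src, n_tgt, K, vp, seed,
                           loop_order = "target-scan",
                           tgt_first = 0, universe = NULL,
                           retain_events = FALSE) {
  layout <- parallel_layout(vp = vp)
  store <- connection_store(layout, retain_events = retain_events)
  suite <- vp_rng_suite(seed, layout)
  rq <- conn_request(gid_range(0, n_src), gid_range(tgt_first, n_tgt),
                     "fixed_in_degree", K = K)
  connect_fixed_in_degree(rq, store, suite, loop_order, universe = universe)
  list(store = store, layout = layout, edges = edge_list(store),
       ledger = ledger_totals(store), counters = phase_counters(store))
}

# per-source ledger totals of a single-source replay with k same-type
# connections (independent rule replay used as the Eq-style oracle)
replay_single_source <- function(k, k_cutoff = 3) {
  alloc <- 2; free <- 1; cap <- 1  # first connection
  if (k >= 2) {
    for (i in 2:k) {
      if (i < k_cutoff) { alloc <- alloc + 1; free <- free + 1; cap <- i }
      else if (i == k_cutoff) { alloc <- alloc + 1; free <- free + 1; cap <- k_cutoff }
      else if (i > cap) { cap <- cap * 2; alloc <- alloc + 1; free <- free + 1 }
    }
  }
  c(n_alloc = alloc, n_free = free)
}

expect_same_edges <- function(a, b) {
  expect_equal(nrow(a), nrow(b))
  expect_equal(a, b)
}
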
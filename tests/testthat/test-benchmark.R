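# shared small build: N = 1000, K = 100, 4 VPs, records retained
bb <- build_benchmark(hpc_benchmark_spec(1000, 100), parallel_layout(vp = 4),
                      seed = 31, retain_records = TRUE)

test_that("every neuron gets exactly n_E excitatory and n_I inhibitory inputs", {
  edges <- edge_list(bb$store)
  neuron_edges <- edges[edges$source < 1000, ]
  expect_equal(nrow(neuron_edges), 1000 * 100)
  deg_e <- in_degrees(bb$store, gid_range(0, 1000),
                      synapse_type = c("stdp_exc", "static_exc"))
  deg_i <- in_degrees(bb$store, gid_range(0, 1000), synapse_type = "static_inh")
  expect_equal(deg_e$in_degree, rep(80, 1000))
  expect_equal(deg_i$in_degree, rep(20, 1000))
  # sources drawn from the right populations
  expect_true(all(neuron_edges$source[neuron_edges$synapse_type != "static_inh"] < 800))
  expect_true(all(neuron_edges$source[neuron_edges$synapse_type == "static_inh"] >= 800))
  # E->E plastic targets are excitatory, E->I static targets inhibitory
  expect_true(all(neuron_edges$target[neuron_edges$synapse_type == "stdp_exc"] < 800))
  expect_true(all(neuron_edges$target[neuron_edges$synapse_type == "static_exc"] >= 800))
  # one drive edge per neuron
  expect_equal(sum(edges$source == bb$drive_gid), 1000)
  expect_equal(bb$report$total_connections, 1000 * 100 + 1000)
})

test_that("census and connector types in the dense regime", {
  cc <- bb$report$census
  expect_equal(cc$n0, rep(0, 4))
  expect_equal(cc$n1, rep(0, 4))
  expect_equal(cc$n_more, rep(1000, 4))
  # excitatory sources end heterogeneous (two types), inhibitory homogeneous
  for (v in 0:3) {
    expect_equal(connector_info(bb$store, v, 5)$kind, "heterogeneous")
    expect_equal(sort(connector_info(bb$store, v, 5)$types),
                 c("static_exc", "stdp_exc"))
    expect_equal(connector_info(bb$store, v, 900)$kind, "hom_dynamic")
  }
})

test_that("builds are reproducible and seed-sensitive", {
  again <- build_benchmark(hpc_benchmark_spec(1000, 100),
                           parallel_layout(vp = 4), seed = 31,
                           retain_records = TRUE)
  expect_same_edges(edge_list(bb$store), edge_list(again$store))
  expect_equal(bb$report$ledger, again$report$ledger)
  other <- build_benchmark(hpc_benchmark_spec(1000, 100),
                           parallel_layout(vp = 4), seed = 32,
                           retain_records = TRUE)
  expect_false(identical(edge_list(bb$store), edge_list(other$store)))
})

test_that("loop orders and (M,T) factorizations leave the network unchanged", {
  ref <- edge_list(bb$store)
  for (args in list(list(loop_order = "local-scan"),
                    list(layout = parallel_layout(processes = 4, threads = 1)),
                    list(layout = parallel_layout(processes = 2, threads = 2)))) {
    b2 <- build_benchmark(hpc_benchmark_spec(1000, 100),
                          layout = if (is.null(args$layout))
                            parallel_layout(vp = 4) else args$layout,
                          seed = 31,
                          loop_order = if (is.null(args$loop_order))
                            "target-scan" else args$loop_order,
                          retain_records = TRUE)
    expect_same_edges(edge_list(b2$store), ref)
  }
})

test_that("dryrun of each rank reproduces its share of the full build", {
  bench <- hpc_benchmark_spec(200, 20)
  full <- build_benchmark(bench, parallel_layout(processes = 3, threads = 2),
                          seed = 8, retain_records = TRUE,
                          loop_order = "local-scan")
  seen <- list()
  for (rank in 0:2) {
    dr <- dryrun_build(bench, processes = 3, threads = 2, rank = rank,
                       seed = 8, retain_records = TRUE)
    expect_equal(dr$store$vp_ids, rank_vps(rank, full$layout))
    expect_equal(ledger_totals(dr$store),
                 ledger_totals(full$store, vp = dr$store$vp_ids),
                 ignore_attr = TRUE)
    seen[[rank + 1]] <- edge_list(dr$store)
  }
  # union over ranks equals the full build
  all_edges <- do.call(rbind, seen)
  all_edges <- all_edges[order(all_edges$source), ]
  rownames(all_edges) <- NULL
  full_edges <- edge_list(full$store)
  expect_equal(nrow(all_edges), nrow(full_edges))
  o <- function(d) d[do.call(order, d), ]
  expect_equal(o(all_edges), o(full_edges), ignore_attr = TRUE)
  expect_error(dryrun_build(bench, 3, 2, rank = 3, seed = 8), "out of range")
})

test_that("dryrun handles the large-benchmark geometry on one vp", {
  # 1,835,008 emulated virtual processes; rank 0 of an M = VP, T = 1 layout
  # builds exactly vp 0: iteration work scales with local nodes, not N
  bench <- hpc_benchmark_spec(2e8, 11250)
  dr <- dryrun_build(bench, processes = 1835008, threads = 1, rank = 0,
                     seed = 1)
  ph <- dr$report$phases
  expect_equal(nrow(ph), 1)
  n_local <- ceiling((2e8 + 2) / 1835008)  # 109 local nodes on vp 0
  expect_equal(ph$outer_iterations, 4 * n_local)  # 3 in-degree + 1 device call
  expect_equal(ph$source_draws, 11250 * 109)
  # occupancy of this single vp is one draw from the predicted classes
  cc <- dr$report$census
  ex <- occupancy_expectation(bench$spec, 1835008)
  expect_lt(abs(cc$n1 - ex$n1) / ex$n1, 0.01)
  expect_lt(abs(cc$n0 - ex$n0) / ex$n0, 1e-4)
})

test_that("spec validation and report serialization", {
  expect_error(hpc_benchmark_spec(1001, 100), "non-integral")
  js <- report_json(bb$report)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$network$N, 1000)
  expect_equal(parsed$total_connections, 101000)
  expect_equal(length(parsed$phases$vp), 4)
})
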
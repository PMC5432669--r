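#' Balanced random network benchmark specification
#'
#' The benchmark network: `epsilon * N` excitatory and `(1 - epsilon) * N`
#' inhibitory integrate-and-fire neurons, each receiving `n_E` excitatory
#' and `n_I` inhibitory inputs chosen at random with replacement.
#' Excitatory-to-excitatory connections use a plastic synapse type and
#' excitatory-to-inhibitory a distinct static type, which forces every
#' excitatory source into a heterogeneous connector; all connections from
#' inhibitory sources use a single static inhibitory type. One external
#' drive device is connected all-to-all to all neurons; one spike
#' recorder observes all local neurons implicitly (recording contributes
#' no stored edges, so the ledger and census reflect neuron wiring plus
#' the single drive connector per VP).
#'
#' @param N,K,epsilon network parameters (see [network_spec()]).
#' @param w_exc excitatory weight (pA, amplitude of the synaptic current
#'   jump; default 87.8).
#' @param g inhibition-to-excitation weight ratio; `w_inh = -g * w_exc`
#'   (default 5).
#' @param drive_rate external drive rate per neuron in spikes/s
#'   (aggregate Poisson; default 12000, which puts the mean drive just
#'   above threshold so the default network is active).
#' @param drive_weight weight of drive events (default `w_exc`).
#' @param delay transmission delay in ms (default 1.5).
#' @param duration default simulation duration in ms.
#' @export
hpc_benchmark_spec <- function(N, K, epsilon = 0.8, w_exc = 87.8, g = 5,
                               drive_rate = 12000, drive_weight = w_exc,
                               delay = 1.5, duration = 1000) {
  spec <- network_spec(N, K, epsilon)
  if (spec$N * spec$epsilon != round(spec$N * spec$epsilon) ||
      spec$n_E != round(spec$n_E))
    stop("non-integral population split: epsilon * N and epsilon * K must be integers")
  structure(list(spec = spec,
                 synapse_map = c(EE = "stdp_exc", EI = "static_exc",
                                 I = "static_inh", drive = "drive"),
                 w_exc = w_exc, w_inh = -g * w_exc, g = g,
                 drive_rate = drive_rate, drive_weight = drive_weight,
                 delay = delay, duration = duration),
            class = "hpc_benchmark_spec")
}

#' @export
print.hpc_benchmark_spec <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  weights %g / %g pA, delay %g ms, drive %g /s\n",
              x$w_exc, x$w_inh, x$delay, x$drive_rate))
  invisible(x)
}

#' Build the benchmark network
#'
#' Creates the node populations (excitatory gids first, then inhibitory,
#' then the drive device and the recorder, all from one contiguous
#' enumeration), then wires, in order: excitatory sources to excitatory
#' targets (in-degree `n_E`, plastic type), excitatory sources to
#' inhibitory targets (in-degree `n_E`, static excitatory type),
#' inhibitory sources to all neurons (in-degree `n_I`, static inhibitory
#' type), and the drive device all-to-all to all neurons. Every neuron
#' ends with exactly `K = n_E + n_I` neuron inputs plus one drive input.
#'
#' @param bench an [hpc_benchmark_spec()].
#' @param layout a [parallel_layout()].
#' @param seed master seed for the per-VP streams.
#' @param loop_order `"target-scan"` or `"local-scan"` (both produce
#'   identical networks for the same seed).
#' @param vp_ids vps to build (default all); [dryrun_build()] passes one
#'   rank's share.
#' @param retain_records,retain_events see [connection_store()].
#' @return an object of class `benchmark_build`: fields `store`,
#'   `registry`, `suite`, `bench`, `layout`, `seed`, `loop_order`,
#'   `neurons`, `excitatory`, `inhibitory`, `drive_gid`, `recorder_gid`,
#'   and `report` (a [build_report()]).
#' @export
build_benchmark <- function(bench, layout, seed = 12345,
                            loop_order = c("target-scan", "local-scan"),
                            vp_ids = NULL, retain_records = FALSE,
                            retain_events = FALSE) {
  stopifnot(inherits(bench, "hpc_benchmark_spec"),
            inherits(layout, "parallel_layout"))
  loop_order <- match.arg(loop_order)
  sp <- bench$spec
  N_E <- sp$N * sp$epsilon
  N_I <- sp$N - N_E

  registry <- model_registry()
  exc <- create_nodes(registry, "iaf_neuron_exc", N_E)
  inh <- create_nodes(registry, "iaf_neuron_inh", N_I)
  drive <- create_nodes(registry, "poisson_drive", 1)
  recorder <- create_nodes(registry, "spike_recorder", 1)
  neurons <- gid_range(0, sp$N)
  universe <- gid_range(0, registry_size(registry))

  store <- connection_store(layout, vp_ids = vp_ids,
                            retain_records = retain_records,
                            retain_events = retain_events)
  suite <- vp_rng_suite(seed, layout)
  syn <- bench$synapse_map

  reqs <- list(
    conn_request(exc, exc, "fixed_in_degree", K = sp$n_E,
                 synapse_type = syn[["EE"]], weight = bench$w_exc,
                 delay = bench$delay),
    conn_request(exc, inh, "fixed_in_degree", K = sp$n_E,
                 synapse_type = syn[["EI"]], weight = bench$w_exc,
                 delay = bench$delay),
    conn_request(inh, neurons, "fixed_in_degree", K = sp$n_I,
                 synapse_type = syn[["I"]], weight = bench$w_inh,
                 delay = bench$delay))
  for (rq in reqs)
    connect_fixed_in_degree(rq, store, suite, loop_order, universe = universe)
  drive_req <- conn_request(gid_range(drive$first, 1), neurons, "all_to_all",
                            synapse_type = syn[["drive"]],
                            weight = bench$drive_weight, delay = bench$delay)
  connect_all_to_all(drive_req, store, loop_order, universe = universe)

  out <- structure(list(store = store, registry = registry, suite = suite,
                        bench = bench, layout = layout, seed = seed,
                        loop_order = loop_order, neurons = neurons,
                        excitatory = exc, inhibitory = inh,
                        drive_gid = drive$first,
                        recorder_gid = recorder$first),
                   class = "benchmark_build")
  out$report <- build_report(out)
  out
}

#' @export
print.benchmark_build <- function(x, ...) {
  print(x$bench)
  print(x$layout)
  cat("  loop order:", x$loop_order, " seed:", x$seed, "\n")
  cat("  connections:", format(n_connections(x$store), big.mark = ","), "\n")
  invisible(x)
}

#' Build report
#'
#' Per-VP phase counters and ledger totals, the source-occupancy census
#' over the `N` neuron sources, and the total connection count
#' (`N * K` neuron edges plus `N` drive edges when all VPs are built).
#'
#' @param build a `benchmark_build`.
#' @return an object of class `build_report` (a list; serialize with
#'   [report_json()]).
#' @export
build_report <- function(build) {
  stopifnot(inherits(build, "benchmark_build"))
  sp <- build$bench$spec
  structure(list(
    network = list(N = sp$N, K = sp$K, epsilon = sp$epsilon,
                   n_E = sp$n_E, n_I = sp$n_I),
    layout = list(processes = build$layout$M, threads = build$layout$T,
                  vp = build$layout$vp),
    seed = build$seed, loop_order = build$loop_order,
    phases = phase_counters(build$store),
    ledger = ledger_totals(build$store),
    census = occupancy_census(build$store, total_sources = sp$N),
    total_connections = n_connections(build$store)),
    class = "build_report")
}

#' Serialize a build report (or any report list) to JSON
#' @param report a report list.
#' @param path optional path; when given the JSON is written there.
#' @return the JSON string, invisibly when written to a file.
#' @export
report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), dataframe = "columns",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Dryrun build of a single rank
#'
#' Emulates one process (rank) of a distributed build: only the rank's
#' `T` virtual processes are instantiated and wired, which is valid
#' because construction involves no inter-process communication. Per-VP
#' results are identical to the corresponding VPs of a full build with
#' the same seed.
#'
#' @param bench an [hpc_benchmark_spec()].
#' @param processes,threads the emulated layout (M processes, T threads).
#' @param rank process index in `0..processes-1`.
#' @param seed master seed.
#' @param loop_order loop order; `local-scan` is the one that keeps the
#'   per-VP iteration count proportional to the local node count and is
#'   the only practical choice for very large emulated layouts.
#' @inheritParams build_benchmark
#' @export
dryrun_build <- function(bench, processes, threads, rank, seed = 12345,
                         loop_order = c("local-scan", "target-scan"),
                         retain_records = FALSE, retain_events = FALSE) {
  loop_order <- match.arg(loop_order)
  layout <- parallel_layout(processes = processes, threads = threads)
  build_benchmark(bench, layout, seed = seed, loop_order = loop_order,
                  vp_ids = rank_vps(rank, layout),
                  retain_records = retain_records,
                  retain_events = retain_events)
}

#' In-degree tally per target
#'
#' Counts stored records per target gid (requires retained records);
#' targets with no records are reported with in-degree 0.
#'
#' @param store a [connection_store()].
#' @param targets a [gid_range()] of targets to tally over.
#' @param synapse_type optional type filter.
#' @return data.frame with columns `target`, `in_degree`.
#' @export
in_degrees <- function(store, targets, synapse_type = NULL) {
  df <- edge_list(store)
  if (!is.null(synapse_type)) df <- df[df$synapse_type %in% synapse_type, ]
  tg <- seq(targets$first, targets$first + targets$count - 1)
  tab <- table(factor(df$target[df$target %in% tg], levels = tg))
  data.frame(target = tg, in_degree = as.numeric(tab))
}
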
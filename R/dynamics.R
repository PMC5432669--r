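#' Leaky integrate-and-fire parameters
#'
#' Conventional values for the stand-in dynamics: membrane time constant
#' 10 ms, capacitance 250 pF, threshold 20 mV above a resting potential
#' of 0 mV, reset to 0 mV, 2 ms refractory period, exponentially decaying
#' synaptic current with 0.5 ms time constant.
#'
#' @param tau_m membrane time constant (ms).
#' @param C_m membrane capacitance (pF).
#' @param V_th spike threshold (mV).
#' @param V_reset reset potential (mV).
#' @param E_L resting potential (mV).
#' @param t_ref absolute refractory period (ms).
#' @param tau_syn synaptic current time constant (ms).
#' @export
lif_params <- function(tau_m = 10, C_m = 250, V_th = 20, V_reset = 0,
                       E_L = 0, t_ref = 2, tau_syn = 0.5) {
  list(tau_m = tau_m, C_m = C_m, V_th = V_th, V_reset = V_reset, E_L = E_L,
       t_ref = t_ref, tau_syn = tau_syn)
}

#' Time-driven simulation over a constructed store
#'
#' Minimal leaky integrate-and-fire loop demonstrating that the
#' connection store supports state propagation. Per step (length `dt`):
#' the synaptic current decays by `exp(-dt / tau_syn)` and receives the
#' weights of spikes whose delay elapses this step plus Poisson drive
#' events drawn from each VP's stream (local neurons in ascending gid
#' order); non-refractory membranes relax toward
#' `E_L + R_m (I_syn + i_ext)` with `R_m = tau_m / C_m`; crossings of
#' `V_th` emit a spike timestamped at the end of the step, reset the
#' membrane and start the refractory countdown. Spikes are delivered
#' through the store's records after their (dt-divisible) delay. Weights
#' are never modified, so simulation leaves the construction ledger
#' untouched.
#'
#' The result is fully determined by (store, initial state, suite seed)
#' and depends on the layout only through the vp count.
#'
#' @param store a [connection_store()] with retained records.
#' @param neurons [gid_range()] of the simulated neurons.
#' @param suite a [vp_rng_suite()] (drive draws consume its streams).
#' @param duration simulated time (ms).
#' @param dt time step (ms, default 0.1).
#' @param params a [lif_params()] list.
#' @param i_ext constant external current (pA), scalar or per neuron.
#' @param drive_rate Poisson drive rate per neuron (spikes/s).
#' @param drive_weight weight added to `I_syn` per drive event (pA).
#' @param v_init initial membrane potentials (default `E_L`).
#' @return list with `spikes` (data.frame `time_ms`, `gid`, sorted by
#'   time then gid), `V`, `I_syn`.
#' @export
simulate_network <- function(store, neurons, suite, duration, dt = 0.1,
                             params = lif_params(), i_ext = 0,
                             drive_rate = 0, drive_weight = 0,
                             v_init = NULL) {
  stopifnot(inherits(store, "connection_store"), inherits(neurons, "gid_range"),
            inherits(suite, "vp_rng_suite"))
  N <- neurons$count
  if (neurons$first != 0) stop("neuron gids must start at 0")
  VP <- store$layout$vp
  vps <- store$vp_ids

  edges <- edge_list(store)
  edges <- edges[edges$source < N & edges$target < N, , drop = FALSE]
  delay_steps <- edges$delay / dt
  if (any(abs(delay_steps - round(delay_steps)) > 1e-9))
    stop("discretization error: all delays must be integer multiples of dt")
  edges$dstep <- as.integer(round(delay_steps))
  if (nrow(edges) > 0 && any(edges$dstep < 1))
    stop("delays must be >= dt")
  adj <- split(edges[c("target", "weight", "dstep")], edges$source)

  steps <- as.integer(round(duration / dt))
  ref_steps <- as.integer(round(params$t_ref / dt))
  P_m <- exp(-dt / params$tau_m)
  P_syn <- exp(-dt / params$tau_syn)
  R_m <- params$tau_m / params$C_m
  lambda <- drive_rate * dt / 1000

  V <- if (is.null(v_init)) rep(params$E_L, N) else rep(v_init, length.out = N)
  I_syn <- rep(0, N)
  ref <- integer(N)
  i_ext <- rep(i_ext, length.out = N)

  D <- max(c(1L, if (nrow(edges)) max(edges$dstep))) + 1L
  buf <- matrix(0, nrow = N, ncol = D)  # ring buffer of pending currents

  local_idx <- lapply(vps, function(v) {
    g <- local_gids(v, neurons, store$layout)
    as.integer(g) + 1L
  })

  sp_time <- numeric(0)
  sp_gid <- numeric(0)

  for (t in seq_len(steps) - 1L) {
    slot <- t %% D + 1L
    arriving <- buf[, slot]
    buf[, slot] <- 0
    if (lambda > 0) {
      for (i in seq_along(vps)) {
        li <- local_idx[[i]]
        if (length(li) == 0L) next
        n_ev <- draw_poisson(suite, vps[i], lambda, draws = length(li))
        arriving[li] <- arriving[li] + n_ev * drive_weight
      }
    }
    I_syn <- I_syn * P_syn + arriving
    active <- ref == 0L
    V[active] <- P_m * V[active] +
      (1 - P_m) * (params$E_L + R_m * (I_syn[active] + i_ext[active]))
    ref[!active] <- ref[!active] - 1L
    fired <- which(active & V >= params$V_th)
    if (length(fired)) {
      V[fired] <- params$V_reset
      ref[fired] <- ref_steps
      tm <- (t + 1L) * dt
      for (i in fired) {  # ascending gid order
        gid <- i - 1
        sp_time <- c(sp_time, tm)
        sp_gid <- c(sp_gid, gid)
        a <- adj[[as.character(gid)]]
        if (!is.null(a)) {
          slots <- (t + a$dstep) %% D + 1L
          for (j in seq_len(nrow(a)))
            buf[a$target[j] + 1L, slots[j]] <- buf[a$target[j] + 1L, slots[j]] +
              a$weight[j]
        }
      }
    }
  }
  spikes <- data.frame(time_ms = sp_time, gid = sp_gid)
  spikes <- spikes[order(spikes$time_ms, spikes$gid), , drop = FALSE]
  rownames(spikes) <- NULL
  list(spikes = spikes, V = V, I_syn = I_syn)
}

#' Simulate a built benchmark network
#'
#' Runs [simulate_network()] over a [build_benchmark()] result (which
#' must have been built with `retain_records = TRUE`), using the
#' benchmark's drive rate and weight. The drive device's stored edges
#' mark the connectivity; at run time the drive is realized as
#' independent per-neuron Poisson input from the per-VP streams.
#'
#' @param build a `benchmark_build`.
#' @param duration duration in ms (default: the spec's).
#' @param dt time step (ms).
#' @param params a [lif_params()] list.
#' @export
simulate_benchmark <- function(build, duration = NULL, dt = 0.1,
                               params = lif_params()) {
  stopifnot(inherits(build, "benchmark_build"))
  simulate_network(build$store, build$neurons, build$suite,
                   duration = if (is.null(duration)) build$bench$duration else duration,
                   dt = dt, params = params,
                   drive_rate = build$bench$drive_rate,
                   drive_weight = build$bench$drive_weight)
}

#' Write spikes in gdf style
#'
#' Plain text, one `time_ms<TAB>gid` per line, sorted by time then gid,
#' no header.
#'
#' @param spikes data.frame with `time_ms`, `gid`.
#' @param path file path.
#' @export
write_spikes <- function(spikes, path) {
  spikes <- spikes[order(spikes$time_ms, spikes$gid), , drop = FALSE]
  write.table(spikes, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Pair-based additive STDP update
#'
#' Applies the standard all-pairs additive rule to one weight: every
#' pre-before-post pair at lag `dt = t_post - t_pre > 0` potentiates by
#' `A_plus * exp(-dt / tau_plus)`, every post-before-pre pair depresses
#' by `A_minus * exp(dt / tau_minus)`; coincident pairs contribute
#' nothing. The result is clipped to `[w_min, w_max]`. A simplified,
#' configurable stand-in for the plastic synapse type of the benchmark.
#'
#' @param weight current weight.
#' @param pre_times,post_times spike times (ms).
#' @param A_plus,A_minus potentiation/depression amplitudes.
#' @param tau_plus,tau_minus trace time constants (ms).
#' @param w_min,w_max clipping bounds.
#' @return the updated weight.
#' @export
stdp_update <- function(weight, pre_times, post_times, A_plus = 0.01,
                        A_minus = 0.01, tau_plus = 20, tau_minus = 20,
                        w_min = 0, w_max = Inf) {
  if (length(pre_times) && length(post_times)) {
    lag <- outer(post_times, pre_times, "-")  # t_post - t_pre
    weight <- weight + sum(A_plus * exp(-lag[lag > 0] / tau_plus)) -
      sum(A_minus * exp(lag[lag < 0] / tau_minus))
  }
  min(max(weight, w_min), w_max)
}
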
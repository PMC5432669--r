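#' Balanced random network specification
#'
#' `N` neurons, a fraction `epsilon` of them excitatory, each neuron
#' receiving a fixed in-degree of `K` inputs split as `n_E = epsilon * K`
#' from excitatory and `n_I = (1 - epsilon) * K` from inhibitory sources.
#'
#' @param N total number of neurons.
#' @param K in-degree per neuron.
#' @param epsilon excitatory fraction, strictly between 0 and 1
#'   (default 0.8).
#' @export
network_spec <- function(N, K, epsilon = 0.8) {
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must be in (0, 1)")
  if (N < 1 || K < 0) stop("N must be >= 1 and K >= 0")
  n_E <- epsilon * K
  # counts like epsilon * K are exact when integral; snap away fp noise
  if (abs(n_E - round(n_E)) < 1e-6) n_E <- round(n_E)
  structure(list(N = as.numeric(N), K = as.numeric(K),
                 epsilon = as.numeric(epsilon),
                 n_E = n_E, n_I = K - n_E),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("network spec: N = %s, K = %s (n_E = %s, n_I = %s), epsilon = %g\n",
              format(x$N, big.mark = ","), format(x$K, big.mark = ","),
              format(x$n_E, big.mark = ","), format(x$n_I, big.mark = ","),
              x$epsilon))
  invisible(x)
}

# round half-up to `digits` decimals (display convention for connector sizes)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Expected connector sizes per virtual process
#'
#' An excitatory source neuron has on average `epsilon * K` outgoing
#' connections to excitatory and `(1 - epsilon) * K` to inhibitory
#' targets, spread over `vp` virtual processes; inhibitory sources keep
#' all `K` outgoing connections in one homogeneous connector. Expected
#' per-VP connector sizes are therefore
#' `k_EE = epsilon * K / vp`, `k_EI = (1 - epsilon) * K / vp`,
#' `k_I = K / vp` (so `k_EE + k_EI = k_I`).
#'
#' @param spec a [network_spec()].
#' @param vp number of virtual processes.
#' @return list with exact values `k_EE`, `k_EI`, `k_I` and their
#'   one-decimal half-up roundings `k_EE_display` etc.
#' @examples
#' expected_connector_sizes(network_spec(25000, 2500), vp = 48)
#' @export
expected_connector_sizes <- function(spec, vp) {
  stopifnot(inherits(spec, "network_spec"))
  if (vp < 1) stop("vp must be >= 1")
  k_EE <- spec$epsilon * spec$K / vp
  k_EI <- (1 - spec$epsilon) * spec$K / vp
  k_I <- spec$K / vp
  list(k_EE = k_EE, k_EI = k_EI, k_I = k_I,
       k_EE_display = round_half_up(k_EE), k_EI_display = round_half_up(k_EI),
       k_I_display = round_half_up(k_I))
}

#' Predicted memory operations, dense regime
#'
#' For `S` source neurons whose local connectors grow to an average size
#' `k >= k_cutoff`, building the connectors costs approximately
#' `n_alloc = (4 + ceil(log2(k / k_cutoff))) * S` allocations and
#' `n_free = (3 + ceil(log2(k / k_cutoff))) * S` frees per virtual
#' process: one-element connector plus source-table registration (or
#' heterogeneous conversion for a second synapse type), the fixed-size
#' growth step, the transition to a dynamic connector, and one
#' allocation/free pair per capacity doubling.
#'
#' @param S number of source neurons in the group.
#' @param k expected connector size (real-valued), must be `>= k_cutoff`.
#' @param k_cutoff connector-size cutoff (default 3).
#' @return list with `n_alloc`, `n_free`, `doublings`.
#' @export
predicted_memory_ops_dense <- function(S, k, k_cutoff = 3) {
  if (k < k_cutoff)
    stop("k < k_cutoff: fixed-size regime is outside the dense formula's domain")
  d <- ceiling(log2(k / k_cutoff))
  list(n_alloc = (4 + d) * S, n_free = (3 + d) * S, doublings = d)
}

#' Predicted memory operations, sparse regime
#'
#' When almost every source has at most one local connection (the large,
#' highly distributed regime), the only costs are the one-element
#' connector and the source-table registration of the `N1c` singly
#' connected sources: `n_alloc = 2 * N1c`, `n_free = N1c`.
#'
#' @param N1c number of sources with exactly one local connection.
#' @export
predicted_memory_ops_sparse <- function(N1c) {
  list(n_alloc = 2 * N1c, n_free = N1c)
}

#' Expected per-VP occupancy of the source population
#'
#' A virtual process owns about `N / vp` targets and draws
#' `K_vp = floor(N * K / vp)` incoming connections uniformly over the `N`
#' sources. In the Poisson limit of this binomial placement, with
#' `lambda = K_vp / N`, the expected numbers of sources with 0, 1 and >1
#' local connections are `N * exp(-lambda)`, `N * lambda * exp(-lambda)`
#' and the remainder.
#'
#' @param spec a [network_spec()].
#' @param vp number of virtual processes.
#' @return list with `N_vp` (= `round(N / vp)`), `K_vp`
#'   (= `floor(N * K / vp)`), `lambda`, and expected class counts `n0`,
#'   `n1`, `n_more` (summing to `N`).
#' @export
occupancy_expectation <- function(spec, vp) {
  stopifnot(inherits(spec, "network_spec"))
  if (vp < 1) stop("vp must be >= 1")
  N_vp <- round(spec$N / vp)
  K_vp <- floor(spec$N * spec$K / vp)
  lambda <- K_vp / spec$N
  n0 <- spec$N * exp(-lambda)
  n1 <- spec$N * lambda * exp(-lambda)
  list(N_vp = N_vp, K_vp = K_vp, lambda = lambda,
       n0 = n0, n1 = n1, n_more = spec$N - n0 - n1)
}

#' Monte-Carlo estimate of per-VP source occupancy
#'
#' Simulates a single virtual process: `floor(N * K / vp)` uniform source
#' draws over `[0, N)`, tallying sources hit 0 / 1 / >1 times. Each
#' replicate is one independent simulated VP; means and standard errors
#' are over replicates. The per-replicate tallies are whole-network
#' counts already (the classification is "local connections on this VP"
#' for every one of the `N` sources).
#'
#' @param spec a [network_spec()].
#' @param vp number of virtual processes (sets the per-VP draw count).
#' @param replicates number of simulated VPs.
#' @param seed master seed for the replicate streams.
#' @return list with `draws`, `replicates`, per-class `mean` and `se`
#'   (named n0/n1/n_more), and the raw per-replicate matrix `tallies`.
#' @export
occupancy_montecarlo <- function(spec, vp, replicates = 100, seed = 12345) {
  stopifnot(inherits(spec, "network_spec"))
  draws <- floor(spec$N * spec$K / vp)
  m <- cpp_occupancy_mc(spec$N, draws, as.integer(replicates),
                        as.numeric(seed))
  means <- colMeans(m)
  ses <- apply(m, 2, stats::sd) / sqrt(nrow(m))
  list(draws = draws, replicates = replicates, mean = means, se = ses,
       tallies = m)
}
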
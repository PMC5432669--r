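#' Connection request
#'
#' Population-level wiring specification: source and target gid sets (a
#' [gid_range()] or an explicit numeric vector), a rule, the in-degree
#' `K` for the fixed in-degree rule, and one synapse spec. Multapses and
#' autapses are permitted: sources are drawn with replacement, uniformly
#' over the source set, and no self-connection check is made.
#'
#' @param sources,targets gid sets.
#' @param rule `"fixed_in_degree"` or `"all_to_all"`.
#' @param K in-degree (number of sources drawn per target); required for
#'   `fixed_in_degree`.
#' @param synapse_type,weight,delay synapse spec applied to every created
#'   connection.
#' @export
conn_request <- function(sources, targets, rule = c("fixed_in_degree", "all_to_all"),
                         K = NULL, synapse_type = "static", weight = 1,
                         delay = 1.5) {
  rule <- match.arg(rule)
  if (rule == "fixed_in_degree") {
    if (is.null(K) || K < 0) stop("fixed_in_degree requires K >= 0")
    if (abs(K - round(K)) > 1e-6) stop("K must be an integer count")
    K <- round(K)
  }
  if (set_size(sources) < 1 || set_size(targets) < 1)
    stop("source and target sets must be non-empty")
  structure(list(sources = sources, targets = targets, rule = rule,
                 K = if (is.null(K)) NA_real_ else as.numeric(K),
                 synapse_type = synapse_type, weight = as.numeric(weight),
                 delay = as.numeric(delay)),
            class = "conn_request")
}

set_size <- function(set) {
  if (inherits(set, "gid_range")) set$count else length(set)
}

# destructure a gid set for the C++ loops; explicit target lists must be
# ascending so both loop orders visit local targets in the same order
set_args <- function(set, sort_list = FALSE) {
  if (inherits(set, "gid_range")) {
    list(first = set$first, count = set$count, list = numeric(0),
         is_range = TRUE)
  } else {
    v <- as.numeric(set)
    if (sort_list) v <- sort(v)
    list(first = 0, count = 0, list = v, is_range = FALSE)
  }
}

#' Membership test for gid sets
#'
#' Constant cost for contiguous ranges (two comparisons against the
#' half-open bounds), logarithmic for explicit lists.
#'
#' @param set a [gid_range()] or numeric vector.
#' @param gid gid (vectorized).
#' @return logical vector.
#' @export
membership <- function(set, gid) {
  if (inherits(set, "gid_range"))
    gid >= set$first & gid < set$first + set$count
  else
    gid %in% set
}

# span of a gid set (used to derive a default local-scan universe)
set_span <- function(set) {
  if (inherits(set, "gid_range")) c(set$first, set$count)
  else if (length(set) == 0L) c(0, 0)
  else c(min(set), max(set) - min(set) + 1)
}

#' Fixed in-degree wiring
#'
#' Gives every target exactly `K` new connections whose sources are drawn
#' i.i.d. uniformly (with replacement) from the source set, created on
#' the virtual process owning the target and consuming only that VP's
#' random stream.
#'
#' Two loop orders are available. `"target-scan"` iterates over all
#' targets on every VP and skips non-local ones, so per-VP outer
#' iterations equal the target-set size regardless of how many VPs
#' participate. `"local-scan"` iterates only over the VP's own nodes of
#' the iteration `universe` and tests membership in the target set, so
#' per-VP outer iterations shrink proportionally to `1/vp`. Both orders
#' visit local targets in ascending gid order and therefore consume the
#' per-VP streams identically: the resulting stores are identical edge
#' for edge.
#'
#' @param request a [conn_request()] with rule `fixed_in_degree`.
#' @param store a [connection_store()] (mutated in place).
#' @param suite a [vp_rng_suite()] (streams advanced in place).
#' @param loop_order `"target-scan"` or `"local-scan"`.
#' @param universe iteration universe for local-scan: a [gid_range()]
#'   covering at least the target set (default: the target set's span).
#' @return the phase-counter data.frame for the whole store, invisibly.
#' @export
connect_fixed_in_degree <- function(request, store, suite,
                                    loop_order = c("target-scan", "local-scan"),
                                    universe = NULL) {
  stopifnot(inherits(request, "conn_request"),
            inherits(store, "connection_store"),
            inherits(suite, "vp_rng_suite"))
  if (request$rule != "fixed_in_degree") stop("request rule is not fixed_in_degree")
  loop_order <- match.arg(loop_order)
  if (set_size(request$sources) < 1 && request$K > 0)
    stop("empty source set with K > 0")
  src <- set_args(request$sources)
  tgt <- set_args(request$targets, sort_list = TRUE)
  uni <- local_scan_universe(universe, request$targets)
  cpp_connect_fixed_indegree(store$ptr, suite$ptr,
                             src$first, src$count, src$list, src$is_range,
                             tgt$first, tgt$count, tgt$list, tgt$is_range,
                             uni[1], uni[2],
                             as.integer(request$K),
                             type_id(store, request$synapse_type),
                             request$weight, request$delay,
                             loop_order == "local-scan")
  invisible(phase_counters(store))
}

local_scan_universe <- function(universe, targets) {
  if (is.null(universe)) return(set_span(targets))
  stopifnot(inherits(universe, "gid_range"))
  sp <- set_span(targets)
  if (sp[1] < universe$first ||
      sp[1] + sp[2] > universe$first + universe$count)
    stop("local-scan universe does not cover the target set")
  c(universe$first, universe$count)
}

#' All-to-all wiring
#'
#' One connection from every source to every target, no randomness.
#' Both loop orders yield identical edge sets; sources are attached to
#' each local target in the order given.
#'
#' @inheritParams connect_fixed_in_degree
#' @param request a [conn_request()] with rule `all_to_all`.
#' @export
connect_all_to_all <- function(request, store,
                               loop_order = c("target-scan", "local-scan"),
                               universe = NULL) {
  stopifnot(inherits(request, "conn_request"),
            inherits(store, "connection_store"))
  if (request$rule != "all_to_all") stop("request rule is not all_to_all")
  loop_order <- match.arg(loop_order)
  src <- set_args(request$sources)
  tgt <- set_args(request$targets, sort_list = TRUE)
  uni <- local_scan_universe(universe, request$targets)
  cpp_connect_all_to_all(store$ptr,
                         src$first, src$count, src$list, src$is_range,
                         tgt$first, tgt$count, tgt$list, tgt$is_range,
                         uni[1], uni[2],
                         type_id(store, request$synapse_type),
                         request$weight, request$delay,
                         loop_order == "local-scan")
  invisible(phase_counters(store))
}
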
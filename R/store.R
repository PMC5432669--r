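#' Per-virtual-process connection store
#'
#' Each virtual process stores every connection whose target it owns, in a
#' hierarchy of per-source connectors behind a sparse source table. Four
#' cases arise for a source on a VP:
#'
#' 1. no local targets: only an unset presence bit (no connector);
#' 2. fewer than `k_cutoff` local targets of one synapse type: a
#'    homogeneous fixed-size connector (capacity equals size);
#' 3. `k_cutoff` or more local targets of one type: a homogeneous dynamic
#'    connector whose capacity starts at `k_cutoff` and doubles when
#'    exceeded (capacities `k_cutoff * 2^j`);
#' 4. targets of two or more synapse types: a heterogeneous connector of
#'    homogeneous sub-connectors, each obeying the rules above.
#'
#' An allocation ledger records every modeled allocation/free these state
#' transitions incur (the model's accounting, not the host heap): first
#' connection of a source costs one allocation for the one-element
#' connector plus one allocation and one free for source-table
#' registration; every fixed-size growth step, the transition to dynamic,
#' and every capacity doubling cost one allocation and one free; the first
#' connection of a second synapse type costs a heterogeneous conversion
#' (one allocation, one free) plus one allocation for the new one-element
#' sub-connector.
#'
#' @param layout a [parallel_layout()].
#' @param k_cutoff connector size at which storage switches from
#'   fixed-size to dynamic (default 3, must be >= 2).
#' @param vp_ids vps held by this store; default all `0..vp-1`. A dryrun
#'   of one rank passes [rank_vps()].
#' @param retain_records keep full connection records (target, type,
#'   weight, delay) for export and spike delivery. Disable for large
#'   count-only builds.
#' @param retain_events keep the ordered alloc/free event log per vp in
#'   addition to the totals.
#' @return an object of class `connection_store` (mutable; backed by an
#'   external pointer).
#' @export
connection_store <- function(layout, k_cutoff = 3, vp_ids = NULL,
                             retain_records = TRUE, retain_events = FALSE) {
  stopifnot(inherits(layout, "parallel_layout"))
  if (k_cutoff < 2) stop("k_cutoff must be >= 2")
  if (is.null(vp_ids)) vp_ids <- seq.int(0L, layout$vp - 1L)
  types <- new.env(parent = emptyenv())
  types$names <- character(0)
  structure(list(ptr = cpp_store_new(as.integer(vp_ids), layout$vp,
                                     as.numeric(k_cutoff),
                                     retain_records, retain_events),
                 layout = layout, k_cutoff = k_cutoff,
                 vp_ids = as.integer(sort(vp_ids)),
                 retain_records = retain_records,
                 retain_events = retain_events, types = types),
            class = "connection_store")
}

#' @export
print.connection_store <- function(x, ...) {
  cat("connection store:", length(x$vp_ids), "of", x$layout$vp,
      "virtual processes, k_cutoff =", x$k_cutoff, "\n")
  cat("  records:", format(cpp_store_n_records(x$ptr), big.mark = ","),
      if (x$retain_records) "(retained)" else "(counts only)", "\n")
  invisible(x)
}

# synapse type name -> stable integer id (order of first use)
type_id <- function(store, synapse_type) {
  i <- match(synapse_type, store$types$names)
  if (is.na(i)) {
    store$types$names <- c(store$types$names, synapse_type)
    i <- length(store$types$names)
  }
  i - 1L
}

type_name <- function(store, id) store$types$names[id + 1L]

#' Add one connection
#'
#' Advances the connector state machine of `source` on the VP owning
#' `target` and appends the implied ledger events. The target must be
#' local to one of the vps held by the store.
#'
#' @param store a [connection_store()].
#' @param source,target gids.
#' @param synapse_type synapse type name.
#' @param weight synaptic weight (model units).
#' @param delay transmission delay in ms, > 0.
#' @export
add_connection <- function(store, source, target, synapse_type = "static",
                           weight = 1, delay = 1.5) {
  stopifnot(inherits(store, "connection_store"))
  if (delay <= 0) stop("delay must be > 0")
  cpp_store_add(store$ptr, as.numeric(source), as.numeric(target),
                type_id(store, synapse_type), as.numeric(weight),
                as.numeric(delay))
  invisible(store)
}

#' Connection records of one source on one VP
#'
#' Records are returned in insertion order; an empty data frame when the
#' source's presence bit is unset. Requires `retain_records = TRUE`.
#'
#' @param store a [connection_store()].
#' @param vp vp index; default the single vp for single-vp stores, else
#'   required.
#' @param source source gid.
#' @param synapse_type optional type filter.
#' @export
targets_of <- function(store, source, vp = NULL, synapse_type = NULL) {
  stopifnot(inherits(store, "connection_store"))
  if (is.null(vp)) {
    if (length(store$vp_ids) != 1L) stop("vp required for multi-vp stores")
    vp <- store$vp_ids[1L]
  }
  tid <- if (is.null(synapse_type)) -1L else {
    i <- match(synapse_type, store$types$names)
    if (is.na(i)) return(empty_edges())
    i - 1L
  }
  r <- cpp_store_targets_of(store$ptr, as.integer(vp), as.numeric(source), tid)
  data.frame(target = as.numeric(r$target),
             synapse_type = type_name(store, as.integer(r$type)),
             weight = as.numeric(r$weight), delay = as.numeric(r$delay),
             stringsAsFactors = FALSE)
}

empty_edges <- function() {
  data.frame(source = numeric(0), target = numeric(0),
             synapse_type = character(0), weight = numeric(0),
             delay = numeric(0), stringsAsFactors = FALSE)
}

#' Source-occupancy census
#'
#' Counts sources in `[0, total_sources)` with 0, 1, or more than 1 local
#' connection on a VP (the Table-of-benchmark-properties classes). The
#' three counts sum to `total_sources`.
#'
#' @param store a [connection_store()].
#' @param total_sources size of the source enumeration to census over.
#' @param vp vp index, or `NULL` to return one row per held vp.
#' @return data.frame with columns `vp`, `n0`, `n1`, `n_more`.
#' @export
occupancy_census <- function(store, total_sources, vp = NULL) {
  stopifnot(inherits(store, "connection_store"))
  vps <- if (is.null(vp)) store$vp_ids else as.integer(vp)
  rows <- lapply(vps, function(v) {
    cc <- cpp_store_census(store$ptr, v, as.numeric(total_sources))
    data.frame(vp = v, n0 = cc[["n0"]], n1 = cc[["n1"]],
               n_more = cc[["n_more"]])
  })
  do.call(rbind, rows)
}

#' Allocation ledger totals per VP
#'
#' @param store a [connection_store()].
#' @param vp vp index, or `NULL` for all held vps.
#' @return data.frame with columns `vp`, `n_alloc`, `n_free`.
#' @export
ledger_totals <- function(store, vp = NULL) {
  stopifnot(inherits(store, "connection_store"))
  vps <- if (is.null(vp)) store$vp_ids else as.integer(vp)
  rows <- lapply(vps, function(v) {
    l <- cpp_store_ledger(store$ptr, v)
    data.frame(vp = v, n_alloc = l[["n_alloc"]], n_free = l[["n_free"]])
  })
  do.call(rbind, rows)
}

#' Ordered alloc/free event log of one VP
#'
#' Requires `retain_events = TRUE`. Events are `"alloc"`/`"free"` in the
#' order they were modeled.
#'
#' @param store a [connection_store()].
#' @param vp vp index.
#' @export
ledger_events <- function(store, vp) {
  stopifnot(inherits(store, "connection_store"))
  if (!store$retain_events) stop("store was built without retain_events")
  ev <- cpp_store_events(store$ptr, as.integer(vp))
  c("free", "alloc")[ev + 1L]
}

#' Connector state of one source on one VP
#'
#' @param store a [connection_store()].
#' @param vp vp index.
#' @param source source gid.
#' @return list with `kind` (one of `absent`, `hom_fixed`, `hom_dynamic`,
#'   `heterogeneous`), total size `K_old`, and per-type `types`, `counts`,
#'   `capacities`.
#' @export
connector_info <- function(store, vp, source) {
  stopifnot(inherits(store, "connection_store"))
  info <- cpp_store_connector(store$ptr, as.integer(vp), as.numeric(source))
  if (!is.null(info$types))
    info$types <- vapply(as.integer(info$types), function(i) type_name(store, i), "")
  info
}

#' Total stored connection records across held VPs
#' @param store a [connection_store()].
#' @export
n_connections <- function(store) cpp_store_n_records(store$ptr)

#' Phase counters accumulated by the wiring loops
#'
#' Operation counts mirroring the construction-phase decomposition:
#' outer loop iterations, non-local skips (target scan) or failed
#' membership tests (local scan), source draws, connect calls, and
#' membership tests, per held VP.
#'
#' @param store a [connection_store()].
#' @return data.frame, one row per held vp.
#' @export
phase_counters <- function(store) {
  stopifnot(inherits(store, "connection_store"))
  as.data.frame(cpp_store_counters(store$ptr))
}

#' Edge list of the full store
#'
#' One row per connection record, sorted by source gid and, within a
#' source, insertion order (vps in ascending order contribute their
#' records for a source consecutively; each target lives on exactly one
#' vp). Requires `retain_records = TRUE`.
#'
#' @param store a [connection_store()].
#' @return data.frame with columns `source`, `target`, `synapse_type`,
#'   `weight`, `delay`.
#' @export
edge_list <- function(store) {
  stopifnot(inherits(store, "connection_store"))
  parts <- lapply(store$vp_ids, function(v) {
    r <- cpp_store_edges(store$ptr, as.integer(v))
    data.frame(source = as.numeric(r$source), target = as.numeric(r$target),
               synapse_type = type_name(store, as.integer(r$type)),
               weight = as.numeric(r$weight), delay = as.numeric(r$delay),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  if (is.null(df) || nrow(df) == 0L) return(empty_edges())
  df <- df[order(df$source), , drop = FALSE]  # stable: keeps insertion order
  rownames(df) <- NULL
  df
}

#' Write / read an edge-list TSV
#'
#' Tab-separated with header `source target synapse_type weight delay`,
#' one row per record, in [edge_list()] order.
#'
#' @param x a `connection_store` or an edge-list data.frame.
#' @param path file path.
#' @export
write_edges <- function(x, path) {
  df <- if (inherits(x, "connection_store")) edge_list(x) else x
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
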
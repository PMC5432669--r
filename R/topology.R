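#' Parallel layout of processes, threads and virtual processes
#'
#' A simulation is distributed over `vp = processes x threads` virtual
#' processes (VPs). Any two of the three quantities determine the third;
#' if all three are given they must be consistent. Results of a build
#' depend only on `vp`, never on the factorization into processes and
#' threads (partition invariance).
#'
#' @param processes number of processes (M). Default 1 when only `threads`
#'   or `vp` is given.
#' @param threads number of threads per process (T).
#' @param vp total number of virtual processes.
#' @return an object of class `parallel_layout` with fields `M`, `T`, `vp`.
#' @examples
#' parallel_layout(processes = 2, threads = 3)
#' parallel_layout(vp = 48)
#' @export
parallel_layout <- function(processes = NULL, threads = NULL, vp = NULL) {
  n_given <- sum(!is.null(processes), !is.null(threads), !is.null(vp))
  if (n_given == 0L) stop("give at least one of processes, threads, vp")
  if (is.null(processes) && is.null(threads)) { processes <- 1L; threads <- vp }
  if (is.null(processes)) processes <- if (is.null(vp)) 1L else vp / threads
  if (is.null(threads))   threads   <- if (is.null(vp)) 1L else vp / processes
  if (is.null(vp)) vp <- processes * threads
  bad <- function(x) length(x) != 1L || !is.finite(x) || x < 1 || x != round(x)
  if (bad(processes) || bad(threads) || bad(vp))
    stop("invalid layout: processes, threads and vp must be positive integers")
  if (processes * threads != vp)
    stop("inconsistent layout: processes x threads (", processes * threads,
         ") != vp (", vp, ")")
  structure(list(M = as.integer(processes), T = as.integer(threads),
                 vp = as.integer(vp)),
            class = "parallel_layout")
}

#' @export
print.parallel_layout <- function(x, ...) {
  cat("parallel layout:", x$M, "process(es) x", x$T, "thread(s) =",
      x$vp, "virtual processes\n")
  invisible(x)
}

#' Round-robin assignment of gids to virtual processes
#'
#' Gids are 0-based and assigned as `gid mod vp`, so every block of `vp`
#' consecutive gids maps bijectively onto the virtual processes.
#'
#' @param gid non-negative gid (vectorized).
#' @param layout a [parallel_layout()].
#' @return integer vp index in `0..vp-1`.
#' @export
assign_vp <- function(gid, layout) {
  stopifnot(inherits(layout, "parallel_layout"))
  if (any(gid < 0)) stop("gids must be non-negative")
  gid %% layout$vp
}

#' Process and thread owning a virtual process
#'
#' The fixed bijection `vp -> (process, thread)` is `process = vp mod M`,
#' `thread = vp div M`. Only the vp identity matters for results; the
#' bijection is exposed for dryrun emulation of a single rank.
#'
#' @param vp vp index (vectorized).
#' @param layout a [parallel_layout()].
#' @return data.frame with columns `process`, `thread`.
#' @export
vp_coords <- function(vp, layout) {
  stopifnot(inherits(layout, "parallel_layout"))
  data.frame(process = vp %% layout$M, thread = vp %/% layout$M)
}

#' Virtual processes owned by one rank (process)
#' @param rank process index in `0..M-1`.
#' @param layout a [parallel_layout()].
#' @return ascending integer vector of vp indices.
#' @export
rank_vps <- function(rank, layout) {
  stopifnot(inherits(layout, "parallel_layout"))
  if (rank < 0 || rank >= layout$M) stop("rank out of range")
  seq.int(rank, layout$vp - 1L, by = layout$M)
}

#' Contiguous gid range
#'
#' Half-open convention: the range covers `[first, first + count)`.
#'
#' @param first first gid (0-based).
#' @param count number of gids, >= 1.
#' @param model_id optional model identifier.
#' @export
gid_range <- function(first, count, model_id = NA_character_) {
  if (count < 1) stop("empty population: count must be >= 1")
  structure(list(first = as.numeric(first), count = as.numeric(count),
                 model_id = model_id),
            class = "gid_range")
}

#' @export
print.gid_range <- function(x, ...) {
  cat(sprintf("gid range [%s, %s) model=%s\n",
              format(x$first, big.mark = ","),
              format(x$first + x$count, big.mark = ","), x$model_id))
  invisible(x)
}

#' Gids of a range local to one virtual process
#'
#' Returns, in ascending order (stride `vp`), exactly the gids of `range`
#' that `assign_vp()` maps to `vp`.
#'
#' @param vp vp index.
#' @param range a [gid_range()].
#' @param layout a [parallel_layout()].
#' @export
local_gids <- function(vp, range, layout) {
  stopifnot(inherits(range, "gid_range"), inherits(layout, "parallel_layout"))
  if (vp < 0 || vp >= layout$vp) stop("vp out of range")
  VP <- layout$vp
  off <- (vp - range$first %% VP) %% VP
  g0 <- range$first + off
  last <- range$first + range$count - 1
  if (g0 > last) return(numeric(0))
  seq(g0, last, by = VP)
}

#' Node registry with en-bloc registration
#'
#' The registry records one entry per `create_nodes()` call (a contiguous
#' gid range plus the model id), never one entry per node, so its memory
#' footprint is independent of the number of nodes created. This is the
#' en-bloc registration of non-local node metadata: every process can
#' answer "which model is gid g?" from the range table alone.
#'
#' @return an object of class `model_registry`.
#' @export
model_registry <- function() {
  e <- new.env(parent = emptyenv())
  e$first <- numeric(0)
  e$count <- numeric(0)
  e$model_id <- character(0)
  class(e) <- "model_registry"
  e
}

#' @export
print.model_registry <- function(x, ...) {
  cat("model registry:", length(x$first), "entries,",
      format(registry_size(x), big.mark = ","), "nodes\n")
  invisible(x)
}

#' Total nodes created so far
#' @param registry a [model_registry()].
#' @export
registry_size <- function(registry) sum(registry$count)

#' Create a population of nodes
#'
#' Appends one registry entry covering `count` new contiguous gids
#' starting right after the last created gid. No per-node object is
#' materialized here; local node state is instantiated lazily by the
#' consumer (e.g. the dynamics loop) for gids local to each VP.
#'
#' @param registry a [model_registry()].
#' @param model_id model identifier string.
#' @param count number of nodes, >= 1.
#' @return the [gid_range()] assigned to the new population.
#' @export
create_nodes <- function(registry, model_id, count) {
  stopifnot(inherits(registry, "model_registry"))
  if (count < 1) stop("empty population: count must be >= 1")
  first <- registry_size(registry)
  registry$first <- c(registry$first, first)
  registry$count <- c(registry$count, count)
  registry$model_id <- c(registry$model_id, model_id)
  gid_range(first, count, model_id)
}

#' Model of a gid
#' @param registry a [model_registry()].
#' @param gid gid (vectorized), must be < total created.
#' @return character vector of model ids.
#' @export
model_of <- function(registry, gid) {
  stopifnot(inherits(registry, "model_registry"))
  if (any(gid < 0) || any(gid >= registry_size(registry)))
    stop("gid outside created range")
  idx <- findInterval(gid, registry$first)
  registry$model_id[idx]
}
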
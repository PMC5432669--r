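#' Allocator contention model
#'
#' Abstracts the access regimes of a multi-threaded memory manager over
#' the per-VP ledger event counts. Under a `serialized` allocator every
#' allocation and free passes a global guard, so the number of guarded
#' interactions equals the total event count over all VPs. Under a
#' `thread_local_pool` allocator each VP satisfies requests from a
#' private region and only exchanges chunks of `refill` objects with the
#' shared pool, so a VP with `a` allocations and `f` frees causes
#' `ceil(a / refill) + ceil(f / refill)` guarded interactions.
#' `refill = 1` degenerates to the serialized count; the guarded count is
#' non-increasing in `refill`.
#'
#' @param ledger per-VP ledger totals: a data.frame with columns
#'   `n_alloc`, `n_free` (as from [ledger_totals()]).
#' @param regime `"serialized"` or `"thread_local_pool"`.
#' @param refill objects exchanged per guarded pool interaction
#'   (`thread_local_pool` only; >= 1).
#' @return list with `guarded_interactions`, `total_events`, and the
#'   per-VP event totals `per_vp_events`.
#' @examples
#' lg <- data.frame(n_alloc = c(10, 12), n_free = c(8, 9))
#' contention_summary(lg, "serialized")
#' contention_summary(lg, "thread_local_pool", refill = 64)
#' @export
contention_summary <- function(ledger, regime = c("serialized", "thread_local_pool"),
                               refill = 1) {
  regime <- match.arg(regime)
  stopifnot(all(c("n_alloc", "n_free") %in% names(ledger)))
  if (refill < 1) stop("refill must be >= 1")
  per_vp <- ledger$n_alloc + ledger$n_free
  guarded <- if (regime == "serialized") sum(per_vp)
  else sum(ceiling(ledger$n_alloc / refill) + ceiling(ledger$n_free / refill))
  list(regime = regime, refill = if (regime == "serialized") NA_real_ else refill,
       guarded_interactions = guarded, total_events = sum(per_vp),
       per_vp_events = per_vp)
}
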
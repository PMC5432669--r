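test_that("fixed in-degree gives every target exactly K connections", {
  b <- tiny_fid_build(n_src = 6, n_tgt = 6, K = 2, vp = 2, seed = 1)
  deg <- in_degrees(b$store, gid_range(0, 6))
  expect_equal(deg$in_degree, rep(2, 6))
  # every VP scans all targets under the target-scan order
  expect_equal(b$counters$outer_iterations, c(6, 6))
  expect_equal(b$counters$nonlocal_skips, c(3, 3))
  expect_equal(b$counters$source_draws, c(6, 6))       # K x local targets
  expect_equal(b$counters$connect_calls, b$counters$source_draws)
  expect_equal(b$counters$membership_tests, c(0, 0))
  # sources drawn from the source set only
  expect_true(all(b$edges$source %in% 0:5))
  expect_error(
    connect_fixed_in_degree(
      conn_request(c(4), gid_range(0, 2), "fixed_in_degree", K = 1),
      connection_store(parallel_layout(vp = 1)),
      vp_rng_suite(1, parallel_layout(vp = 1))),
    NA)  # singleton explicit source list is fine
})

test_that("the two loop orders produce identical stores", {
  for (seed in 1:5) {
    a <- tiny_fid_build(10, 8, 3, vp = 3, seed = seed, "target-scan",
                        retain_events = TRUE)
    b <- tiny_fid_build(10, 8, 3, vp = 3, seed = seed, "local-scan",
                        retain_events = TRUE)
    expect_same_edges(a$edges, b$edges)
    expect_equal(a$ledger, b$ledger)
    for (v in 0:2)
      expect_equal(ledger_events(a$store, v), ledger_events(b$store, v))
    # but the local-scan outer loop only visits local nodes
    expect_equal(b$counters$outer_iterations,
                 vapply(0:2, function(v)
                   length(local_gids(v, gid_range(0, 8),
                                     parallel_layout(vp = 3))), 0))
  }
})

test_that("explicit target lists work in both orders (sorted internally)", {
  l <- parallel_layout(vp = 2)
  mk <- function(order) {
    store <- connection_store(l)
    suite <- vp_rng_suite(4, l)
    rq <- conn_request(gid_range(0, 9), c(7, 2, 5, 3), "fixed_in_degree",
                       K = 2)
    connect_fixed_in_degree(rq, store, suite, order,
                            universe = gid_range(0, 9))
    edge_list(store)
  }
  a <- mk("target-scan"); b <- mk("local-scan")
  expect_same_edges(a, b)
  expect_equal(sort(unique(a$target)), c(2, 3, 5, 7))
})

test_that("membership obeys the half-open convention and matches brute force", {
  r <- gid_range(10, 10)  # [10, 20)
  expect_true(membership(r, 10)); expect_false(membership(r, 20))
  expect_equal(membership(r, c(9, 10, 19, 20)), c(FALSE, TRUE, TRUE, FALSE))
  set.seed(3)
  lst <- sort(sample(0:99, 30))
  probes <- 0:99
  expect_equal(membership(lst, probes),
               vapply(probes, function(g) any(lst == g), TRUE))  # linear scan
  expect_equal(membership(numeric(0), probes), rep(FALSE, 100))
})

test_that("all-to-all connects every pair once, identically in both orders", {
  fx <- make_fixture("all2all_3x4")
  expect_equal(nrow(fx$edges), 12)
  got <- fx$edges[order(fx$edges$source, fx$edges$target),
                  c("source", "target")]
  want <- expand.grid(target = 3:6, source = 0:2)[c("source", "target")]
  want <- want[order(want$source, want$target), ]
  expect_equal(got, want, ignore_attr = TRUE)
  l <- parallel_layout(vp = 3)
  mk <- function(order) {
    store <- connection_store(l)
    rq <- conn_request(gid_range(0, 3), gid_range(3, 4), "all_to_all")
    connect_all_to_all(rq, store, order, universe = gid_range(0, 7))
    edge_list(store)
  }
  expect_same_edges(mk("target-scan"), mk("local-scan"))
})

test_that("a single device source fans out to each VP's local neurons", {
  l <- parallel_layout(vp = 4)
  store <- connection_store(l)
  rq <- conn_request(gid_range(10, 1), gid_range(0, 10), "all_to_all")
  connect_all_to_all(rq, store)
  for (v in 0:3) {
    nloc <- length(local_gids(v, gid_range(0, 10), l))
    expect_equal(nrow(targets_of(store, 10, vp = v)), nloc)
  }
})

test_that("local-scan over the exact target set makes no failed tests", {
  b <- tiny_fid_build(5, 12, 1, vp = 3, seed = 9, "local-scan")
  expect_equal(b$counters$nonlocal_skips, c(0, 0, 0))
  expect_equal(b$counters$membership_tests, b$counters$outer_iterations)
})

test_that("iteration work: target-scan constant in vp, local-scan ~ 1/vp", {
  n_tgt <- 60
  for (vp in c(1, 2, 4, 6)) {
    a <- tiny_fid_build(10, n_tgt, 1, vp = vp, seed = 2, "target-scan")
    expect_equal(a$counters$outer_iterations, rep(n_tgt, vp))
    b <- tiny_fid_build(10, n_tgt, 1, vp = vp, seed = 2, "local-scan")
    expect_true(all(abs(b$counters$outer_iterations - n_tgt / vp) <= 1))
    expect_equal(sum(b$counters$outer_iterations), n_tgt)
  }
})

test_that("wiring validation", {
  expect_error(conn_request(gid_range(0, 3), gid_range(0, 3),
                            "fixed_in_degree"), "requires K")
  expect_error(conn_request(numeric(0), gid_range(0, 3), "all_to_all"),
               "non-empty")
  l <- parallel_layout(vp = 1)
  rq <- conn_request(gid_range(0, 3), gid_range(0, 3), "all_to_all")
  expect_error(connect_fixed_in_degree(rq, connection_store(l),
                                       vp_rng_suite(1, l)),
               "not fixed_in_degree")
  rq2 <- conn_request(gid_range(0, 3), gid_range(5, 4), "fixed_in_degree",
                      K = 1)
  expect_error(connect_fixed_in_degree(rq2, connection_store(l),
                                       vp_rng_suite(1, l), "local-scan",
                                       universe = gid_range(0, 6)),
               "universe")
})
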
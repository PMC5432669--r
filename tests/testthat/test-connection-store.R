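# One VP everywhere below unless stated; target gid chosen local to it.

new_store1 <- function(...) connection_store(parallel_layout(vp = 1), ...)

test_that("ledger accounting for a single source follows the modeled rules", {
  st <- new_store1(retain_events = TRUE)
  add_connection(st, 5, 0, "a")
  expect_equal(connector_info(st, 0, 5)$kind, "hom_fixed")
  expect_equal(unname(unlist(ledger_totals(st)[c("n_alloc", "n_free")])),
               c(2, 1))
  add_connection(st, 5, 0, "a"); add_connection(st, 5, 0, "a")
  info <- connector_info(st, 0, 5)
  expect_equal(info$kind, "hom_dynamic")
  expect_equal(info$counts, 3); expect_equal(info$capacities, 3)
  expect_equal(unname(unlist(ledger_totals(st)[c("n_alloc", "n_free")])),
               c(4, 3))
  # event log: alloc count never falls below free count at any prefix
  ev <- ledger_events(st, 0)
  bal <- cumsum(ifelse(ev == "alloc", 1, -1))
  expect_true(all(bal >= 0))
})

test_that("52 same-type connections cost 9 allocations and 8 frees", {
  st <- new_store1()
  for (i in 1:52) add_connection(st, 7, 0, "a")
  expect_equal(unname(unlist(ledger_totals(st)[c("n_alloc", "n_free")])),
               c(9, 8))
  expect_equal(connector_info(st, 0, 7)$capacities, 96)
})

test_that("per-source ledger equals the closed-form count for k >= k_cutoff", {
  # dual route: incremental store vs independent rule replay + formula
  for (k in c(3, 4, 5, 7, 13, 24, 25, 52, 60)) {
    st <- new_store1()
    for (i in seq_len(k)) add_connection(st, 0, 0, "t")
    got <- unname(unlist(ledger_totals(st)[c("n_alloc", "n_free")]))
    d <- ceiling(log2(k / 3))
    expect_equal(got, c(4 + d, 3 + d), info = paste("k =", k))
    expect_equal(got, unname(replay_single_source(k)))
  }
  # fixed-size end states below the cutoff
  for (k in 1:2) {
    st <- new_store1()
    for (i in seq_len(k)) add_connection(st, 0, 0, "t")
    expect_equal(unname(unlist(ledger_totals(st)[c("n_alloc", "n_free")])),
                 c(2 + (k - 1), 1 + (k - 1)))
  }
})

test_that("connector kind is a pure function of (count, distinct types)", {
  for (n1 in 1:10) for (n2 in 0:10) {
    st <- new_store1()
    for (i in seq_len(n1)) add_connection(st, 3, 0, "a")
    for (i in seq_len(n2)) add_connection(st, 3, 0, "b")
    info <- connector_info(st, 0, 3)
    expected <- if (n2 > 0) "heterogeneous"
    else if (n1 < 3) "hom_fixed" else "hom_dynamic"
    expect_equal(info$kind, expected, info = paste(n1, n2))
    expect_equal(info$K_old, n1 + n2)
    if (n2 > 0) {
      expect_equal(sort(info$types), c("a", "b"))
      expect_equal(info$counts, c(n1, n2))
      # each sub-connector obeys the homogeneous capacity rule
      for (cnt in info$counts) {
        cap <- info$capacities[match(cnt, info$counts)]
        if (cnt < 3) expect_equal(cap, cnt)
        else expect_true(cap %in% (3 * 2^(0:5)) && cap >= cnt)
      }
    }
  }
})

test_that("two one-type connections plus heterogeneous conversion costs add up", {
  st <- new_store1()
  add_connection(st, 1, 0, "a")
  add_connection(st, 1, 0, "b")
  info <- connector_info(st, 0, 1)
  expect_equal(info$kind, "heterogeneous")
  expect_equal(info$counts, c(1, 1))
  # 2a+1f (first) + conversion 1a+1f + new one-element 1a
  expect_equal(unname(unlist(ledger_totals(st)[c("n_alloc", "n_free")])),
               c(4, 2))
})

test_that("targets_of preserves insertion order and loses nothing", {
  st <- new_store1()
  expect_equal(nrow(targets_of(st, 42)), 0L)
  set.seed(1)
  log <- data.frame(source = sample(0:5, 40, TRUE), target = 0,
                    synapse_type = sample(c("a", "b"), 40, TRUE))
  log$weight <- round(runif(40), 3)
  for (i in seq_len(40))
    add_connection(st, log$source[i], 0, log$synapse_type[i],
                   weight = log$weight[i])
  # per-source recall matches the bookkeeping log, in order
  for (s in unique(log$source)) {
    want <- log[log$source == s, c("synapse_type", "weight")]
    got <- targets_of(st, s)[c("synapse_type", "weight")]
    expect_equal(got, want, ignore_attr = TRUE)
  }
  # type filter
  got_a <- targets_of(st, log$source[1], synapse_type = "a")
  expect_true(all(got_a$synapse_type == "a"))
  # concatenation over sources = everything inserted
  expect_equal(n_connections(st), 40)
})

test_that("occupancy census tallies local-connection classes exactly", {
  st <- new_store1()
  expect_equal(unname(unlist(occupancy_census(st, 100)[c("n0", "n1", "n_more")])),
               c(100, 0, 0))
  set.seed(2)
  sources <- sample(0:19, 60, TRUE)
  for (s in sources) add_connection(st, s, 0, "t")
  cc <- occupancy_census(st, 20)
  tab <- table(factor(sources, levels = 0:19))
  expect_equal(cc$n0, sum(tab == 0))
  expect_equal(cc$n1, sum(tab == 1))
  expect_equal(cc$n_more, sum(tab > 1))
  expect_equal(cc$n0 + cc$n1 + cc$n_more, 20)
})

test_that("store validates locality, delay and cutoff", {
  l4 <- parallel_layout(vp = 4)
  st <- connection_store(l4, vp_ids = c(0, 1))
  expect_error(add_connection(st, 0, 2, "t"), "locality violation")
  expect_silent(add_connection(st, 0, 1, "t"))
  expect_error(add_connection(st, 0, 0, "t", delay = 0), "delay")
  expect_error(connection_store(l4, k_cutoff = 1), "k_cutoff")
})

test_that("edge lists round-trip through the TSV format", {
  fx <- make_fixture("indeg2_ring")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edges(fx$store, path)
  back <- read_edges(path)
  expect_equal(back, fx$edges)
  expect_equal(names(back),
               c("source", "target", "synapse_type", "weight", "delay"))
  # identical per-vp census after the round trip
  for (v in 0:(fx$layout$vp - 1)) {
    tab <- table(factor(back$source[back$target %% fx$layout$vp == v],
                        levels = 0:5))
    cc <- occupancy_census(fx$store, 6, v)
    expect_equal(unname(unlist(cc[c("n0", "n1", "n_more")])),
                 unname(c(sum(tab == 0), sum(tab == 1), sum(tab > 1))))
  }
})
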
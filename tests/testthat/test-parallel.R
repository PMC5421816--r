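make_pool_records <- function(seed = 31, n = 40) {
  set.seed(seed)
  random_instance(n_reads = n)
}

test_that("a worker pool answers queries exactly like the serial engine", {
  recs <- make_pool_records()
  n <- nrow(recs)
  pool <- spawn_workers(recs, d_up = 0.15, workers = 2)
  on.exit(halt_workers(pool), add = TRUE)

  # serial master replica for reference answers
  sp <- sequence_space(recs$seq, recs$abundance)
  eng <- pbpclust:::.eng_new(sp$ptr, 0.15 / 2^(0:5), 0, 0.15, 40L,
                             as.integer(n))
  serial <- pbpclust:::.eng_query(eng, seq_len(n))

  one <- dispatch_updates(pool, 1L)
  expect_identical(nrow(one), 1L)
  expect_identical(one$nn, as.integer(serial[1, 2]))
  expect_identical(one$distance, serial[1, 3])

  all40 <- dispatch_updates(pool, seq_len(n))
  expect_identical(nrow(all40), n)
  expect_identical(all40$cluster, seq_len(n))  # answers in request order
  expect_equal(all40$distance, serial[, 3])

  expect_identical(nrow(dispatch_updates(pool, integer())), 0L)
})

test_that("broadcast keeps replicas consistent and guards double application", {
  recs <- make_pool_records(seed = 32)
  n <- nrow(recs)
  pool <- spawn_workers(recs, d_up = 0.15, workers = 2)
  on.exit(halt_workers(pool), add = TRUE)

  before <- dispatch_updates(pool, seq_len(n))
  pair <- c(before$cluster[which.min(before$distance)],
            before$nn[which.min(before$distance)])
  ev <- tibble::tibble(a = min(pair), b = max(pair),
                       merged = as.integer(n + 1))
  broadcast_apply(pool, ev)
  after <- dispatch_updates(pool, ev$merged)
  expect_identical(nrow(after), 1L)
  expect_false(after$nn %in% pair)
  # replicas already applied the event: applying it again must fail
  expect_error(broadcast_apply(pool, ev), "not in tree|already present")
  # no-op broadcast is fine
  broadcast_apply(pool, ev[0, ])
})

test_that("the merge-event list is invariant to the worker count", {
  for (seed in c(33, 34, 35)) {
    recs <- make_pool_records(seed = seed, n = 50)
    f1 <- hc_multipoint(recs, d_up = 0.15, workers = 1)
    f2 <- hc_multipoint(recs, d_up = 0.15, workers = 2)
    expect_identical(f1$events, f2$events)
  }
})

test_that("a halted pool refuses further work", {
  recs <- make_pool_records(seed = 36, n = 10)
  pool <- spawn_workers(recs, d_up = 0.15, workers = 2)
  halt_workers(pool)
  expect_error(dispatch_updates(pool, 1L))
  expect_false(pool$alive)
})
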
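test_that("the sequential reference engine handles base cases", {
  one <- data.frame(id = "a", seq = "ACGT")
  expect_identical(nrow(hc_oracle(one, d_up = 0.5)), 0L)

  two <- data.frame(id = c("a", "b"), seq = c("ACGT", "ACGT"))
  ev <- hc_oracle(two, d_up = 0.5)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$distance, 0)
  expect_identical(ev$merged, 3L)
})

test_that("sequential single linkage on 1-D points merges at 1, 2, 4", {
  ev <- hc_oracle(matrix(c(0, 1, 3, 7), 4, 1), d_up = 10, linkage = "single")
  expect_equal(ev$distance, c(1, 2, 4))
  expect_identical(ev$merged, c(5L, 6L, 7L))
})

test_that("mutual NN pairs are exactly the reciprocal pairs below d_up", {
  # brute-force table for 1-D points {0, 1, 3, 7}
  pts <- c(0, 1, 3, 7)
  nn <- tibble::tibble(
    cluster = 1:4,
    nn = vapply(1:4, function(i) {
      d <- abs(pts - pts[i]); d[i] <- Inf; which.min(d)
    }, integer(1)),
    distance = vapply(1:4, function(i) {
      d <- abs(pts - pts[i]); d[i] <- Inf; min(d)
    }, numeric(1)),
    state = "fresh")
  phi <- mutual_nn_pairs(nn, d_up = 10)
  expect_identical(nrow(phi), 1L)
  expect_identical(c(phi$a, phi$b), c(1L, 2L))

  expect_identical(nrow(mutual_nn_pairs(nn, d_up = 0.5)), 0L)

  # two well-separated twin pairs are both mergeable at once
  nn2 <- tibble::tibble(cluster = 1:4, nn = c(2L, 1L, 4L, 3L),
                        distance = c(1, 1, 1, 1), state = "fresh")
  phi2 <- mutual_nn_pairs(nn2, d_up = 10)
  expect_identical(nrow(phi2), 2L)

  nn2$state[2] <- "stale"
  expect_error(mutual_nn_pairs(nn2, 10), "stale")
})

test_that("tie-breaking turns equal-distance cycles into mergeable pairs", {
  cyc <- tibble::tibble(cluster = 1:3, nn = c(2L, 3L, 1L),
                        distance = c(1, 1, 1))
  fixed <- tie_break(cyc)
  expect_gte(nrow(mutual_nn_pairs(dplyr::mutate(fixed, state = "fresh"),
                                  d_up = 10)), 1L)

  # an existing mutual pair is never touched
  tab <- tibble::tibble(cluster = 1:3, nn = c(2L, 1L, 1L),
                        distance = c(1, 1, 2))
  expect_identical(tie_break(tab)[1:2, ], tab[1:2, ])

  # strictly decreasing chain: the rule may not fire downhill
  chain <- tibble::tibble(cluster = 1:3, nn = c(2L, 3L, 2L),
                          distance = c(3, 2, 2))
  fixed <- tie_break(chain)
  expect_identical(fixed$nn[2], 3L)  # D(2, NN(2)) = 2 < 3 = D(1, 2)
})

test_that("the delayed-update scheduler follows the safe-merge rule", {
  act <- schedule_next(tibble::tibble(a = 1L, b = 2L, distance = 0.02),
                       tibble::tibble(cluster = 3L, bound = 0.05),
                       d_up = 0.15, batch_size = 40)
  expect_identical(act$action, "merge")
  expect_identical(c(act$a, act$b), c(1L, 2L))

  stale <- tibble::tibble(cluster = 3:60, bound = seq(0.05, 0.1, length.out = 58))
  act <- schedule_next(tibble::tibble(a = 1L, b = 2L, distance = 0.06),
                       stale, d_up = 0.15, batch_size = 40)
  expect_identical(act$action, "update")
  expect_lte(length(act$ids), 40L)
  expect_identical(act$ids[1], 3L)  # smallest bound first

  act <- schedule_next(tibble::tibble(a = integer(), b = integer(),
                                      distance = numeric()),
                       tibble::tibble(cluster = integer(), bound = numeric()),
                       d_up = 0.15, batch_size = 40)
  expect_identical(act$action, "done")
})

test_that("merge rounds keep the registry consistent", {
  st <- hc_state(data.frame(seq = c("AAAA", "AAAA", "TTTT", "TTTT")),
                 d_up = 0.5)
  empty <- tibble::tibble(a = integer(), b = integer(), distance = numeric())
  expect_identical(nrow(merge_round(st, empty)), 0L)
  pairs <- mutual_nn_pairs(st$nn, d_up = 0.5)
  expect_identical(nrow(pairs), 2L)  # two identical twins
  ev <- merge_round(st, pairs)
  expect_identical(nrow(ev), 2L)
  expect_identical(length(st$active), 2L)
  expect_identical(ev$distance, c(0, 0))
})

test_that("flat partition cutting applies events strictly below threshold", {
  ev <- tibble::tibble(a = c(1L, 3L), b = c(2L, 4L), merged = c(4L, 5L),
                       distance = c(0.01, 0.08))
  p0 <- cut_partitions(ev[1, ], n = 3, thresholds = 0)
  expect_identical(p0$otu, 1:3)

  p <- cut_partitions(ev, n = 3, thresholds = 0.05)
  expect_identical(p$otu, c(1L, 1L, 3L))
  p2 <- cut_partitions(ev, n = 3, thresholds = 0.10)
  expect_identical(p2$otu, c(1L, 1L, 1L))
  expect_error(cut_partitions(ev, n = 3, thresholds = 0.2, d_up = 0.15),
               "exceeds d_up")
})

test_that("multi-point engine replicates the sequential reference", {
  set.seed(21)
  for (rep in 1:12) {
    recs <- random_instance(n_reads = sample(10:40, 1))
    fit <- hc_multipoint(recs, d_up = 0.15)
    ora <- hc_oracle(recs, d_up = 0.15)
    expect_equal(sort(fit$events$distance), sort(ora$distance),
                 tolerance = 1e-9)
    for (t in c(0.03, 0.05, 0.10))
      expect_identical(partition_at(fit$events, nrow(recs), t),
                       partition_at(ora, nrow(recs), t))
  }
})

test_that("d_up = 0 yields no merges (singleton partitions)", {
  recs <- random_instance(n_reads = 12)
  fit <- hc_multipoint(recs, d_up = 1e-12)
  expect_identical(nrow(fit$events), 0L)
})

test_that("identical inputs give identical merge-event lists", {
  set.seed(22)
  recs <- random_instance(n_reads = 30)
  f1 <- hc_multipoint(recs, d_up = 0.15)
  f2 <- hc_multipoint(recs, d_up = 0.15)
  expect_identical(f1$events, f2$events)
})

test_that("membership is conserved through every merge", {
  set.seed(23)
  recs <- random_instance(n_reads = 30)
  n <- nrow(recs)
  fit <- hc_multipoint(recs, d_up = 0.15)
  for (t in c(0.001, 0.05, 0.15)) {
    part <- cut_partitions(fit$events, n, t)
    expect_identical(sort(part$id), 1:n)  # every record in exactly one OTU
  }
})

test_that("merge heights are non-decreasing under exact average linkage", {
  set.seed(24)
  pts <- matrix(runif(60), 30, 2)
  ev <- hc_oracle(pts, d_up = 2, linkage = "average")
  expect_true(!is.unsorted(ev$distance))
  # under the representative provider, inversions are counted, not asserted
  recs <- random_instance(n_reads = 40)
  evr <- hc_oracle(recs, d_up = 0.15)
  inversions <- sum(diff(evr$distance) < -1e-9)
  expect_gte(inversions, 0)
})

test_that("round mode replicates the reference on reducible linkages", {
  set.seed(25)
  for (rep in 1:6) {
    pts <- matrix(runif(30), 15, 2)
    for (lk in c("single", "average")) {
      fit <- hc_multipoint(pts, d_up = 2, linkage = lk, slack = Inf,
                           mode = "round")
      ora <- hc_oracle(pts, d_up = 2, linkage = lk)
      for (t in c(0.1, 0.3, 0.6))
        expect_identical(partition_at(fit$events, 15, t),
                         partition_at(ora, 15, t))
    }
  }
})

test_that("stale lower bounds are sound under a reducible linkage", {
  # drive the engine manually on Euclidean average linkage (reducible, so
  # merging never brings a cluster closer to third parties) and check that
  # every re-search returns at least its scheduled lower bound
  set.seed(26)
  pts <- matrix(runif(160), 80, 2)
  sp <- point_space(pts, linkage = "average")
  eng <- pbpclust:::.eng_new(sp$ptr, 0.6 / 2^(0:5), 1e9, 0.6, 40L, 80L)
  ids <- pbpclust:::.eng_pending(eng)
  q <- pbpclust:::.eng_query(eng, ids)
  pbpclust:::.eng_set_nn(eng, as.integer(q[, 1]), as.integer(q[, 2]),
                         q[, 3], q[, 4])
  violations <- 0
  repeat {
    act <- pbpclust:::.eng_next(eng)
    if (act$action == 0L) break
    if (act$action == 1L) {
      pbpclust:::.eng_do_merge(eng, act$a, act$b)
    } else {
      q <- pbpclust:::.eng_query(eng, act$ids)
      new_d <- q[, 3]
      if (any(new_d < act$bounds - 1e-9)) violations <- violations + 1
      pbpclust:::.eng_set_nn(eng, as.integer(q[, 1]), as.integer(q[, 2]),
                             q[, 3], q[, 4])
    }
  }
  expect_identical(violations, 0)
})

test_that("tidy and glance summarize a fit", {
  recs <- random_instance(n_reads = 15)
  fit <- hc_multipoint(recs, d_up = 0.15)
  expect_identical(tidy(fit), fit$events)
  g <- glance(fit)
  expect_identical(nrow(g), 1L)
  expect_identical(g$n_clusters, fit$n - nrow(fit$events))
})
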
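test_that("alignment distance reproduces worked examples", {
  expect_identical(align_distance("ACGT", "ACGT"), 0)
  expect_identical(align_distance("ACGT", "ACGA"), 0.25)
  expect_identical(align_distance("ACGTACGT", "ACGACGT"), 0.125)
  # half-mass column against a single base: expected mismatch 1 - 0.5
  half <- new_cluster_rep(
    matrix(c(0.5, 0, 0, 0.5, 0), 5, 1,
           dimnames = list(c("A", "C", "G", "T", "gap"), NULL)), 1)
  expect_identical(align_distance(half, "A"), 0.5)
  expect_error(align_distance("", "A"), "empty|invalid|nchar")
})

test_that("alignment distance agrees with the full-matrix oracle exactly", {
  set.seed(101)
  seqs <- replicate(10, random_seq(sample(1:8, 1)))
  for (i in 1:9) {
    for (j in (i + 1):10) {
      expect_equal(align_distance(seqs[i], seqs[j]),
                   align_oracle(seqs[i], seqs[j]), tolerance = 1e-12)
    }
  }
  # longer pairs exercise the corridor escalation against the full matrix
  set.seed(102)
  for (k in 1:25) {
    a <- random_seq(sample(20:60, 1))
    b <- random_seq(sample(20:60, 1))
    expect_equal(align_distance(a, b), align_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("distance is symmetric, zero on identity, and within [0, 1]", {
  set.seed(7)
  for (k in 1:200) {
    a <- random_seq(sample(20:60, 1))
    b <- random_seq(sample(20:60, 1))
    dab <- align_distance(a, b)
    expect_identical(dab, align_distance(b, a))
    expect_gte(dab, 0)
    expect_lte(dab, 1)
    expect_identical(align_distance(a, a), 0)
  }
})

test_that("near-metric diagnostic: triangle violations are negligible", {
  set.seed(8)
  worst <- 0
  for (k in 1:200) {
    t <- random_seq(60)
    tri <- c(mutate_seq(t, 3), mutate_seq(t, 3), mutate_seq(t, 3))
    v <- align_distance(tri[1], tri[3]) - align_distance(tri[1], tri[2]) -
      align_distance(tri[2], tri[3])
    worst <- max(worst, v)
  }
  # documents the slack needed for exact tree search: effectively none
  expect_lt(worst, 1e-9)
})

test_that("merge_reps builds weight-averaged profiles", {
  m <- merge_reps(rep_from_sequence("AAAA"), rep_from_sequence("AAAA"))
  expect_identical(unname(m$profile["A", ]), rep(1, 4))
  expect_identical(m$weight, 2)

  m <- merge_reps(rep_from_sequence("AAAA"), rep_from_sequence("AAAT"))
  expect_identical(unname(m$profile[c("A", "T"), 4]), c(0.5, 0.5))
  expect_identical(unname(m$profile["A", 1:3]), rep(1, 3))

  m <- merge_reps(rep_from_sequence("AAAA", 3), rep_from_sequence("AAAT", 1))
  expect_identical(unname(m$profile[c("A", "T"), 4]), c(0.75, 0.25))
  expect_identical(m$weight, 4)

  # commutative up to the tie-broken alignment path
  m2 <- merge_reps(rep_from_sequence("AAAT", 1), rep_from_sequence("AAAA", 3))
  expect_equal(m$profile, m2$profile)

  # a gap contributes gap mass proportional to the absent profile's weight
  m3 <- merge_reps(rep_from_sequence("ACGTACGT"),
                   rep_from_sequence("ACGACGT"))
  expect_identical(sum(m3$profile["gap", ]), 0.5)
  expect_identical(ncol(m3$profile), 8L)
})

test_that("rep_from_sequence maps bases and ambiguity codes", {
  r <- rep_from_sequence("ACG", abundance = 2)
  expect_identical(ncol(r$profile), 3L)
  expect_identical(r$weight, 2)
  expect_identical(unname(diag(r$profile[1:3, ])), rep(1, 3))

  n <- rep_from_sequence("N")
  expect_identical(unname(n$profile[1:4, 1]), rep(0.25, 4))
  r2 <- rep_from_sequence("R")  # A or G
  expect_identical(unname(r2$profile[c(1, 3), 1]), c(0.5, 0.5))

  s <- random_seq(30)
  expect_identical(align_distance(rep_from_sequence(s),
                                  rep_from_sequence(s)), 0)
  expect_error(rep_from_sequence("ACGX"), "invalid")
})

test_that("profile columns must be stochastic", {
  bad <- matrix(c(0.5, 0, 0, 0, 0), 5, 1)
  expect_error(align_distance(new_cluster_rep(bad, 1), "A"), "sum to 1")
})
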
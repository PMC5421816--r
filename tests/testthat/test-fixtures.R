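test_that("the read simulator is deterministic and honours its spec", {
  spec <- synthetic_spec(n_templates = 3, template_length = 50,
                         reads_per_template = 8, sub_rate = 0.05,
                         indel_rate = 0.01, seed = 9)
  d1 <- make_dataset(spec)
  d2 <- make_dataset(spec)
  expect_identical(d1, d2)
  expect_identical(nrow(d1$reads), 24L)
  expect_identical(unique(d1$reads$template), 1:3)

  clean <- make_dataset(synthetic_spec(n_templates = 2, template_length = 40,
                                       reads_per_template = 5, sub_rate = 0,
                                       indel_rate = 0, seed = 1))
  expect_true(all(clean$reads$seq ==
                    clean$templates$seq[clean$reads$template]))

  expect_error(synthetic_spec(sub_rate = 0.7), "sub_rate")
  # unattainable separation fails loudly (the distance never exceeds 1)
  expect_error(make_dataset(synthetic_spec(n_templates = 2,
                                           template_length = 10,
                                           min_separation = 1.01, seed = 1)),
               "separation")
})

test_that("templates respect the minimum pairwise separation", {
  ds <- make_dataset(synthetic_spec(n_templates = 5, template_length = 80,
                                    reads_per_template = 1,
                                    min_separation = 0.3, seed = 10))
  tmpl <- ds$templates$seq
  for (i in 1:4)
    for (j in (i + 1):5)
      expect_gte(align_distance(tmpl[i], tmpl[j]), 0.3)
})

test_that("mean read-to-template distance matches the error model", {
  spec <- synthetic_spec(n_templates = 1, template_length = 80,
                         reads_per_template = 1000, sub_rate = 0.03,
                         indel_rate = 0.01, seed = 11)
  ds <- make_dataset(spec)
  d <- vapply(ds$reads$seq, align_distance, numeric(1),
              b = ds$templates$seq[1], USE.NAMES = FALSE)
  expected <- spec$sub_rate + 2 * spec$indel_rate
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - expected), 3 * se + 0.005)
})

test_that("NMI reproduces hand-computed values and degenerate cases", {
  expect_identical(nmi(c(1, 1, 2, 2), c("x", "x", "y", "y")), 1)
  expect_identical(nmi(c(1, 1, 2, 2), rep(1, 4)), 0)
  expect_identical(nmi(rep(1, 5), rep("a", 5)), 1)
  # I(U;V) = 0.3113 bits, H(U) = 1, H(V) = 0.8113: NMI = 0.3456
  expect_equal(nmi(c(1, 1, 2, 2), c(1, 2, 2, 2)), 0.34559, tolerance = 1e-4)
  expect_error(nmi(1:3, 1:4), "different item sets")
})

test_that("NMI is symmetric and invariant to label names", {
  set.seed(61)
  for (k in 1:25) {
    u <- sample(1:4, 30, replace = TRUE)
    v <- sample(1:3, 30, replace = TRUE)
    expect_equal(nmi(u, v), nmi(v, u), tolerance = 1e-12)
    relab <- c(10, 20, 30, 40)[u]
    expect_equal(nmi(u, v), nmi(relab, v), tolerance = 1e-12)
  }
})

test_that("peak NMI finds the right threshold on clean data", {
  set.seed(62)
  ds <- make_dataset(synthetic_spec(n_templates = 4, template_length = 100,
                                    min_separation = 0.3,
                                    reads_per_template = 12,
                                    sub_rate = 0.01, seed = 12))
  recs <- dereplicate(ds$reads[, c("id", "seq")])
  fit <- hc_multipoint(recs, d_up = 0.15)
  truth <- stats::setNames(ds$reads$template, ds$reads$id)
  pk <- peak_nmi(truth, fit, thresholds = c(0.03, 0.05, 0.10),
                 members = recs$members)
  expect_identical(pk$nmi, 1)
  expect_identical(nrow(pk$scores), 3L)

  single <- peak_nmi(truth, fit, thresholds = 0.10, members = recs$members)
  expect_identical(single$threshold, 0.10)
  expect_error(peak_nmi(truth, fit, thresholds = numeric(),
                        members = recs$members), "no thresholds")
})
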
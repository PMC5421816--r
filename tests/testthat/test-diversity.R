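test_that("chao1 follows the doubleton and bias-corrected branches", {
  expect_identical(chao1(c(1, 1, 2, 3)), 6)       # 4 + 2^2 / (2*1)
  expect_identical(chao1(c(2, 3, 10)), 3)          # no singletons
  expect_identical(chao1(c(1, 1, 1)), 6)           # F2 = 0: 3 + 3*2/2
  expect_gte(chao1(c(1, 5, 5)), 3)                 # never below S_obs
  expect_error(chao1(numeric()), "empty")
  expect_error(chao1(c(1, 0.5)), "positive integers")
})

test_that("ace handles the rare/abundant split and degenerate cases", {
  expect_identical(ace(c(1, 1, 2, 11)), 7)
  expect_identical(ace(c(11, 12, 13)), 3L)          # nothing rare
  expect_identical(ace(c(1, 1, 1)), chao1(c(1, 1, 1)))  # C = 0 fallback
  expect_gte(ace(c(1, 1, 2, 3, 20)), 5)
})

test_that("rarefaction matches the closed form with pinned endpoints", {
  expect_equal(rarefaction(c(2, 2), 2), 5 / 3, tolerance = 1e-12)
  v <- c(5, 3, 1, 1, 8)
  expect_identical(rarefaction(v, 0), 0)
  expect_identical(rarefaction(v, sum(v)), 5)
  curve <- rarefaction(v, 0:sum(v))
  expect_true(!is.unsorted(curve))
  expect_error(rarefaction(v, sum(v) + 1), "out of range")
})

test_that("rarefaction and ACE agree with vegan on random vectors", {
  set.seed(51)
  for (k in 1:10) {
    v <- sample(1:20, 12, replace = TRUE)
    n <- sample(sum(v), 1)
    expect_equal(rarefaction(v, n), suppressWarnings(as.numeric(vegan::rarefy(v, n))),
                 tolerance = 1e-9)
    expect_equal(ace(v), unname(vegan::estimateR(v)["S.ACE"]),
                 tolerance = 1e-6)
  }
})

test_that("rarefaction equals Monte-Carlo subsampling within 3 SE", {
  set.seed(52)
  v <- c(9, 5, 3, 2, 1, 1, 1)
  n <- 8
  pool <- rep(seq_along(v), v)
  draws <- replicate(4000, length(unique(sample(pool, n))))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(rarefaction(v, n) - mean(draws)), 3 * se)
})

test_that("estimators ignore the order of OTUs", {
  set.seed(53)
  v <- sample(1:12, 15, replace = TRUE)
  p <- sample(v)
  expect_identical(chao1(v), chao1(p))
  expect_identical(ace(v), ace(p))
  expect_identical(rarefaction(v, 7), rarefaction(p, 7))
})

test_that("diversity_table summarizes a pipeline result", {
  set.seed(54)
  ds <- make_dataset(synthetic_spec(n_templates = 3, template_length = 60,
                                    reads_per_template = 12,
                                    sub_rate = 0.02, seed = 6))
  suppressMessages(
    res <- otu_pipeline(ds$reads[, c("id", "seq")], d_up = 0.15,
                        thresholds = c(0.03, 0.10), filter = FALSE))
  tab <- diversity_table(res)
  expect_identical(nrow(tab), 2L)
  expect_true(all(tab$chao1 >= tab$s_obs))
  expect_true(all(tab$n_reads == nrow(ds$reads)))
})
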
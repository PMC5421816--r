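test_that("radius schedule halves from the top and ends at zero", {
  sp <- point_space(matrix(0, 1, 1))
  tr <- pbp_tree(sp, d_up = 0.15, levels = 4)
  expect_equal(tr$radii, c(0.15, 0.075, 0.0375, 0.01875, 0))
  tr1 <- pbp_tree(sp, d_up = 0.15, levels = 1)
  expect_equal(tr1$radii, c(0.15, 0))
  expect_error(pbp_tree(sp, d_up = -1), "d_up")
})

test_that("an empty tree reports no nearest neighbour", {
  sp <- point_space(matrix(c(0, 5), 2, 1))
  tr <- pbp_tree(sp, d_up = 4, levels = 2)
  got <- pbp_nearest(tr, 1)
  expect_identical(got$id, -1L)
  expect_identical(got$distance, Inf)
})

test_that("insertion follows the covering rule on a hand-traced 1-D case", {
  # points 0, 1, 5 with radii [4, 1, 0]
  sp <- point_space(matrix(c(0, 1, 5), 3, 1))
  tr <- pbp_tree(sp, radii = c(4, 1))
  pbp_insert(tr, 1, 1)  # first insertion creates a full path
  n1 <- pbpclust:::.tree_node_count(tr$ptr)
  expect_identical(n1, 4L)  # root + level-1 + level-2 + leaf
  pbp_insert(tr, 2, 2)  # |1-0| = 1 <= 4 and <= 1: reuses both levels
  expect_identical(pbpclust:::.tree_node_count(tr$ptr), 5L)
  pbp_insert(tr, 3, 3)  # |5-0| = 5 > 4: fresh path
  expect_identical(pbpclust:::.tree_node_count(tr$ptr), 8L)
  expect_true(pbp_audit(tr, check_order = TRUE)$ok)
})

test_that("deletion prunes childless ancestors and preserves the map", {
  sp <- point_space(matrix(c(0, 1), 2, 1))
  tr <- pbp_tree(sp, radii = c(4, 1))
  pbp_insert(tr, 1, 1)
  pbp_delete(tr, 1)
  expect_identical(pbp_size(tr), 0L)
  expect_identical(pbpclust:::.tree_node_count(tr$ptr), 1L)  # root only

  pbp_insert(tr, 1, 1)
  pbp_insert(tr, 2, 2)  # same level-2 parent (|1-0| <= 1)
  pbp_delete(tr, 1)
  expect_identical(pbp_size(tr), 1L)
  expect_true(pbp_audit(tr)$ok)
  expect_error(pbp_delete(tr, 99), "not in tree")
  expect_error(pbp_insert(tr, 2, 2), "already present")
})

test_that("random insert/delete churn keeps the audit invariants", {
  set.seed(11)
  pts <- matrix(runif(400), 200, 2)
  sp <- point_space(pts)
  tr <- pbp_tree(sp, d_up = 1.5, levels = 5)
  present <- integer()
  for (op in 1:600) {
    if (length(present) == 0 || (runif(1) < 0.6 && length(present) < 200)) {
      pool <- setdiff(1:200, present)
      id <- pool[sample.int(length(pool), 1)]
      pbp_insert(tr, id, id)
      present <- c(present, id)
    } else {
      id <- present[sample.int(length(present), 1)]
      pbp_delete(tr, id)
      present <- setdiff(present, id)
    }
  }
  expect_setequal(pbp_leaf_ids(tr), present)
  expect_true(pbp_audit(tr)$ok)
})

test_that("nearest matches a linear scan on Euclidean points", {
  # 1-D example with an exact tie resolved toward the smaller id
  sp <- point_space(matrix(c(0, 1, 3, 7), 4, 1))
  tr <- pbp_tree(sp, radii = c(8, 2))
  for (i in 1:4) pbp_insert(tr, i, i)
  got <- pbp_nearest(tr, space_add_point(sp, 2))
  expect_identical(got$id, 2L)  # coords 1 and 3 tie at distance 1
  expect_identical(got$distance, 1)

  set.seed(12)
  for (rep in 1:20) {
    pts <- matrix(runif(400), 200, 2)
    sp <- point_space(pts)
    tr <- pbp_tree(sp, d_up = 1.5, levels = 6)
    for (i in 1:200) pbp_insert(tr, i, i)
    for (q in sample(200, 10)) {
      got <- pbp_nearest(tr, q, exclude = q)
      want <- scan_nn(pts, q)
      expect_identical(got$id, as.integer(want$id))
      expect_equal(got$distance, want$distance, tolerance = 1e-12)
    }
  }
})

test_that("the evaluation counter counts real distance computations", {
  seqs <- replicate(20, random_seq(30))
  sp <- sequence_space(seqs)
  tr <- pbp_tree(sp, d_up = 0.8, levels = 4)
  expect_identical(distance_evals(sp), 0)
  for (i in 1:20) pbp_insert(tr, i, i)
  reset_distance_evals(sp)
  q <- space_add_sequence(sp, random_seq(30))
  pbp_nearest(tr, q)
  expect_gte(distance_evals(sp), 1)
  # slack = Inf disables pruning: exactly one evaluation per leaf item
  tr2 <- pbp_tree(sp, d_up = 0.8, levels = 4, slack = Inf)
  for (i in 1:20) pbp_insert(tr2, i, i)
  reset_distance_evals(sp)
  pbp_nearest(tr2, q)
  expect_identical(distance_evals(sp), 20)
})

test_that("mean search cost grows sublinearly on uniform 2-D points", {
  set.seed(13)
  sizes <- c(250, 1000, 4000)
  cost <- vapply(sizes, function(N) {
    pts <- matrix(runif(2 * N), N, 2)
    sp <- point_space(pts)
    tr <- pbp_tree(sp, d_up = 1.5, levels = 7)
    for (i in seq_len(N)) pbp_insert(tr, i, i)
    reset_distance_evals(sp)
    for (q in sample(N, 60)) pbp_nearest(tr, q, exclude = q)
    distance_evals(sp) / 60
  }, numeric(1))
  slope <- coef(lm(log(cost) ~ log(sizes)))[2]
  expect_lt(slope, 1)
})
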
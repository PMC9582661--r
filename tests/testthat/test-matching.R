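# Cross-trajectory group matching, disparity and kernels.

as_partition <- function(labels) {
  semirigid:::partition_renumber_identity(as.integer(labels))
}

test_that("symmetric difference loss", {
  expect_equal(symmetric_difference_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(symmetric_difference_loss(c(1, 2, 3), c(4, 5, 6, 7)), 7)
  expect_equal(symmetric_difference_loss(c(1, 2, 3), c(2, 3, 4)), 2)
})

test_that("loss matrix: self-match, shifted labels, random oracle", {
  withr::local_seed(61)
  p <- as_partition(sample(1:4, 20, replace = TRUE))
  L <- loss_matrix(p, p)
  expect_equal(diag(L), rep(0L, 4))
  # cyclic shift of labels moves the zeros off the diagonal
  shifted <- as_partition((unclass(p) %% 4) + 1)
  Ls <- loss_matrix(p, shifted)
  for (i in 1:4) expect_equal(Ls[i, (i %% 4) + 1], 0L)
  # random pair re-checked by direct set arithmetic
  q <- as_partition(sample(1:4, 20, replace = TRUE))
  Lpq <- loss_matrix(p, q)
  for (i in 1:4) for (j in 1:4) {
    a <- which(unclass(p) == i); b <- which(unclass(q) == j)
    expect_equal(Lpq[i, j], length(setdiff(a, b)) + length(setdiff(b, a)))
  }
  expect_error(loss_matrix(p, as_partition(rep(1:2, 10))),
               class = "srd_usage_error")
})

test_that("match_pairs: self and permuted self-matches", {
  withr::local_seed(62)
  p <- as_partition(sample(1:5, 30, replace = TRUE))
  m_self <- match_pairs(loss_matrix(p, p))
  expect_equal(m_self$assignment, 1:5)
  expect_equal(m_self$total_disparity, 0)

  perm <- sample(5)
  relabeled <- as_partition(perm[unclass(p)])
  m <- match_pairs(loss_matrix(p, relabeled))
  expect_equal(m$assignment, perm)
  expect_equal(m$total_disparity, 0)
  expect_identical(unclass(relabel_partition(relabeled, m)), unclass(p))
})

test_that("hungarian equals the factorial brute force on random matrices", {
  withr::local_seed(63)
  for (case in 1:40) {
    n <- sample(2:6, 1)
    L <- matrix(sample(0:30, n * n, replace = TRUE), n, n)
    m <- match_pairs(L)
    bf <- brute_force_lap(L)
    expect_equal(m$total_disparity, bf$cost)
    expect_equal(sum(L[cbind(seq_len(n), m$assignment)]), bf$cost)
    expect_equal(sort(m$assignment), 1:n) # bijection
  }
})

test_that("ties resolve to the lexicographically smallest permutation", {
  # all-equal costs: every permutation optimal -> identity wins
  L <- matrix(5, 4, 4)
  expect_equal(match_pairs(L)$assignment, 1:4)
  # two optima: (1->1, 2->2) and (1->2, 2->1) both cost 2
  L2 <- matrix(c(1, 1, 1, 1), 2, 2)
  expect_equal(match_pairs(L2)$assignment, 1:2)
})

test_that("matching cost is symmetric for symmetric-difference losses", {
  withr::local_seed(64)
  for (case in 1:10) {
    a <- as_partition(sample(1:4, 25, replace = TRUE))
    b <- as_partition(sample(1:4, 25, replace = TRUE))
    expect_equal(match_pairs(loss_matrix(a, b))$total_disparity,
                 match_pairs(loss_matrix(b, a))$total_disparity)
  }
})

test_that("disparity: bounds, identity characterisation, kernel identity", {
  withr::local_seed(65)
  n <- 30
  a <- as_partition(sample(1:3, n, replace = TRUE))
  expect_equal(disparity_multi(a, list(a, a)), 0L)

  # moving 5 atoms of a copy into other groups gives disparity 5
  bl <- unclass(a)
  idx <- which(bl == 1)[1:5]
  bl[idx] <- ifelse(seq_along(idx) %% 2 == 0, 2L, 3L)
  b <- as_partition(bl)
  expect_equal(disparity_multi(a, list(a, b)), 5L)

  for (case in 1:10) {
    parts <- lapply(1:3, function(i) as_partition(sample(1:3, n, replace = TRUE)))
    mp <- match_partitions(parts[[1]], parts[-1])
    ker <- stable_kernels(mp$partitions)
    expect_equal(disparity_multi(parts[[1]], parts[-1]),
                 n - sum(lengths(ker$kernels)))
    # pairwise disparity bound and zero-iff-relabeling
    m <- mp$matches[[1]]
    expect_lte(m$total_disparity, 2 * n)
    if (m$total_disparity == 0)
      expect_equal(adjusted_rand_index(unclass(parts[[1]]),
                                       unclass(parts[[2]])), 1)
  }
})

test_that("kernels: disjointness, membership, coverage monotonicity", {
  withr::local_seed(66)
  n <- 24
  p1 <- as_partition(sample(1:3, n, replace = TRUE))
  ker_id <- stable_kernels(list(p1, p1))
  expect_equal(ker_id$coverage, 1)
  expect_equal(lengths(ker_id$kernels), attr(p1, "sizes"))

  for (case in 1:8) {
    parts <- lapply(1:3, function(i) as_partition(sample(1:3, n, replace = TRUE)))
    mp <- match_partitions(parts[[1]], parts[-1])
    ker <- stable_kernels(mp$partitions)
    allk <- unlist(ker$kernels)
    expect_equal(length(allk), length(unique(allk))) # disjoint
    for (m in seq_along(ker$kernels)) {
      for (p in mp$partitions) {
        expect_true(all(unclass(p)[ker$kernels[[m]]] == m))
      }
    }
    # coverage non-increasing as more trajectories are intersected
    ker2 <- stable_kernels(mp$partitions[1:2])
    expect_lte(ker$coverage, ker2$coverage + 1e-12)
  }

  # a group disjoint across trajectories gives an empty kernel
  pa <- as_partition(c(1, 1, 2, 2))
  pb <- as_partition(c(2, 2, 1, 1))
  ker0 <- stable_kernels(list(pa, pb))
  expect_equal(lengths(ker0$kernels), c(0L, 0L))
})
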
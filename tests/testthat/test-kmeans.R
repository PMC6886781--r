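test_that("k-means++ seeding spreads centroids by squared distance", {
  pts <- matrix(c(0, 10), ncol = 1)
  for (s in 1:20) {
    set.seed(s)
    init <- kmeans_pp_init(pts, 2)
    # the second pick always lands on the other point: the first has weight 0
    expect_setequal(as.vector(init), c(0, 10))
  }

  set.seed(1)
  one <- kmeans_pp_init(matrix(c(3, 8, 1), ncol = 1), 1)
  expect_true(as.vector(one) %in% c(3, 8, 1))

  expect_error(kmeans_pp_init(matrix(1:2, ncol = 1), 3), "at least k")

  # D^2 weighting: with points {0, 1, 100} and the first centroid at 0, the
  # second is 100 with probability 10000/10001
  pts <- matrix(c(0, 1, 100), ncol = 1)
  n_second_100 <- 0L
  n_first_0 <- 0L
  for (s in 1:600) {
    set.seed(s)
    init <- kmeans_pp_init(pts, 2)
    if (init[1, 1] == 0) {
      n_first_0 <- n_first_0 + 1L
      if (init[2, 1] == 100) n_second_100 <- n_second_100 + 1L
    }
  }
  expect_gt(n_first_0, 100L)               # sanity: uniform first pick
  expect_gt(n_second_100 / n_first_0, 0.98)
})

test_that("Lloyd iterations find exact partitions on tiny instances", {
  pts <- matrix(c(0, 0, 10, 10), ncol = 1)
  m <- lloyd_iterate(pts, matrix(c(1, 9), ncol = 1))
  expect_equal(sort(as.vector(m$centroids)), c(0, 10))
  expect_equal(m$loss, 0)

  # brute force over the 3 bipartitions of {0, 2, 10} gives losses 2, 32, 200/3
  pts <- matrix(c(0, 2, 10), ncol = 1)
  bf <- brute_force_kmeans(pts, 2)
  expect_equal(bf$loss, 2)
  m <- lloyd_iterate(pts, matrix(c(0, 10), ncol = 1))
  expect_equal(m$loss, bf$loss)
  expect_equal(sort(as.vector(m$centroids)), c(1, 10))
})

test_that("Lloyd loss is non-increasing and recomputable from the model", {
  set.seed(7)
  for (case in 1:5) {
    pts <- matrix(rnorm(60 * 3), ncol = 3)
    init <- kmeans_pp_init(pts, 4)
    m <- lloyd_iterate(pts, init)
    expect_true(all(diff(m$loss_trace) <= 1e-9))
    expect_equal(m$loss,
                 sum((pts - m$centroids[m$assignment, ])^2),
                 tolerance = 1e-6)
  }
})

test_that("empty clusters are re-seeded to the farthest point, never crash", {
  pts <- matrix(c(0, 1, 2), ncol = 1)
  # the second centroid is so remote that it captures nothing in iteration 1
  m <- lloyd_iterate(pts, matrix(c(0.5, 100), ncol = 1), max_iter = 50)
  expect_equal(length(unique(m$assignment)), 2L)
  expect_true(m$converged)
})

test_that("replicated clustering returns the minimum-loss replicate", {
  set.seed(3)
  pts <- matrix(rnorm(80 * 2), ncol = 2)
  m <- cluster_replicated(pts, 3, num_replicates = 8, seed = 10)
  expect_equal(m$loss, min(m$replicate_losses))

  single <- cluster_replicated(pts, 3, num_replicates = 1, seed = 10)
  set.seed(11)                              # replicate r uses seed + r
  ref <- lloyd_iterate(pts, kmeans_pp_init(pts, 3))
  expect_equal(single$assignment, ref$assignment)
  expect_equal(single$loss, ref$loss)
})

test_that("replicated clustering attains the brute-force global optimum on toys", {
  set.seed(17)
  for (case in 1:3) {
    pts <- matrix(stats::runif(8 * 2, 0, 10), ncol = 2)
    bf <- brute_force_kmeans(pts, 3)
    m <- cluster_replicated(pts, 3, num_replicates = 50, seed = 100 + case)
    expect_equal(m$loss, bf$loss, tolerance = 1e-9)
  }
})

test_that("well-separated blobs are recovered and agree with stats::kmeans", {
  set.seed(23)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  pts <- centers[rep(1:4, each = 25), ] + matrix(rnorm(200, sd = 0.3), ncol = 2)
  m <- cluster_replicated(pts, 4, num_replicates = 10, seed = 9)
  expect_equal(sort(round(rowSums(m$centroids))), c(0, 10, 10, 20))
  truth <- rep(1:4, each = 25)
  expect_equal(length(unique(paste(truth, m$assignment))), 4L)

  # same fixed init: our Lloyd and the reference implementation must agree
  set.seed(9 + 1)
  init <- kmeans_pp_init(pts, 4)
  ours <- lloyd_iterate(pts, init)
  ref <- stats::kmeans(pts, centers = init, algorithm = "Lloyd", iter.max = 100)
  expect_equal(ours$assignment, as.integer(ref$cluster))
  expect_equal(ours$loss, ref$tot.withinss, tolerance = 1e-8)
})

test_that("identical seeds give bit-identical assignments", {
  set.seed(41)
  pts <- matrix(rnorm(500 * 3), ncol = 3)
  a <- cluster_replicated(pts, 4, num_replicates = 3, seed = 77)
  b <- cluster_replicated(pts, 4, num_replicates = 3, seed = 77)
  expect_identical(a$assignment, b$assignment)
  expect_identical(a$centroids, b$centroids)
})
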
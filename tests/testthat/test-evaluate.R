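test_that("cluster matching recovers identity and permutations", {
  truth <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
  m <- match_clusters(truth, truth)
  expect_equal(unname(m$mapping), sort(unique(as.vector(truth))))
  expect_equal(m$agreement, 64)

  perm <- c(2L, 0L, 3L, 1L)                       # relabel 0->2, 1->0, 2->3, 3->1
  pred <- array(perm[truth + 1L], dim(truth))
  m <- match_clusters(pred, truth)
  expect_equal(m$mapping[as.character(perm)],
               stats::setNames(0:3, as.character(perm)))
  expect_equal(m$agreement, 64)

  expect_error(match_clusters(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("matching equals brute-force permutation search on random toys", {
  set.seed(19)
  for (case in 1:10) {
    k <- sample(2:5, 1)
    pred <- matrix(sample(seq_len(k) - 1L, 16, replace = TRUE), 4, 4)
    truth <- matrix(sample(seq_len(k) - 1L, 16, replace = TRUE), 4, 4)
    if (length(unique(as.vector(pred))) != length(unique(as.vector(truth)))) next
    got <- match_clusters(pred, truth)
    bf <- brute_force_matching(pred, truth)
    expect_equal(got$agreement, bf$agreement)
  }
})

test_that("precision, recall and F1 follow their definitions and conventions", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(f1_for_cluster(a, a), c(precision = 1, recall = 1, f1 = 1))

  truth <- c(TRUE, TRUE, FALSE, FALSE)
  pred <- c(TRUE, TRUE, TRUE, TRUE)               # covers truth + equal false area
  got <- f1_for_cluster(pred, truth)
  expect_equal(unname(got), c(0.5, 1, 2 / 3))

  truth <- rep(c(TRUE, FALSE), c(8, 2))
  pred <- rep(TRUE, 10)                           # TP 8, FP 2, FN 0
  got <- f1_for_cluster(pred, truth)
  expect_equal(unname(got), c(0.8, 1, 2 * 0.8 / 1.8))

  none <- rep(FALSE, 4)
  expect_equal(f1_for_cluster(none, none), c(precision = 1, recall = 1, f1 = 1))
  expect_equal(unname(f1_for_cluster(none, !none)[["f1"]]), 0)
})

test_that("evaluation reports the smallest truth cluster and is relabel-invariant", {
  truth <- matrix(0L, 10, 10)
  truth[, 1:4] <- 1L
  truth[1:2, 10] <- 2L                            # smallest cluster: 2 px
  pred <- truth
  pred[1, 10] <- 0L                               # miss half of it
  ev <- evaluate_unmixing(pred, truth)
  expect_equal(ev$smallest_cluster_f1, 2 * 1 * 0.5 / 1.5)
  expect_equal(ev$per_cluster$f1[ev$per_cluster$truth_label == 1L], 1)

  # permuting prediction labels changes nothing after matching
  relab <- c(5L, 9L, 7L)[pred + 1L]
  ev2 <- evaluate_unmixing(array(relab, dim(pred)), truth)
  expect_equal(ev2$per_cluster$f1, ev$per_cluster$f1)
})

test_that("Mander's coefficients follow the raw-intensity definition", {
  # 4 pixels, channel A then B; clusters: 1 = A-only, 2 = B-only, 3 = coloc
  raw <- multichannel_image(array(c(10, 10, 10, 0,
                                    0, 6, 6, 12), c(4, 1, 2)))
  fit <- fake_fit(raw, c(1L, 3L, 3L, 2L))
  mm <- manders_coefficients(fit, channel_a = 1, channel_b = 2,
                             cluster_a = 1, cluster_b = 2, cluster_coloc = 3)
  expect_equal(unname(mm["M_A"]), 100 * 20 / 30, tolerance = 1e-12)
  expect_equal(unname(mm["M_B"]), 100 * 12 / 24, tolerance = 1e-12)
  expect_true(all(mm >= 0 & mm <= 100))

  # no colocalized pixels -> both coefficients 0
  fit0 <- fake_fit(raw, c(1L, 1L, 2L, 2L))
  mm0 <- manders_coefficients(fit0, 1, 2, 1, 2, 3L)
  expect_equal(unname(mm0), c(0, 0))

  # every A pixel colocalized -> M_A = 100
  fit1 <- fake_fit(raw, c(3L, 3L, 3L, 2L))
  mm1 <- manders_coefficients(fit1, 1, 2, 1, 2, 3L)
  expect_equal(unname(mm1["M_A"]), 100)

  # zero denominator flags an undefined result
  zraw <- multichannel_image(array(0, c(4, 1, 2)))
  expect_warning(expect_warning(   # both channels have zero denominators
    out <- manders_coefficients(fake_fit(zraw, c(1L, 2L, 3L, 3L)), 1, 2, 1, 2, 3),
    "undefined"), "undefined")
  expect_true(all(is.na(out)))
})

test_that("sweeps are seeded, tabulated and averaged correctly", {
  sw <- run_sweep("snr", values = c(20, 30), n_reps = 2,
                  base_config = small_config(n_fluorophores = 3),
                  seed = 5, replicates = 3)
  expect_equal(nrow(sw$results), 4L)
  expect_equal(sw$means$value, c(20, 30))
  for (v in c(20, 30)) {
    rows <- sw$results$smallest_cluster_f1[sw$results$value == v]
    expect_equal(mean(rows),
                 sw$means$mean_smallest_cluster_f1[sw$means$value == v])
  }
  # single-rep sweep: one row per value; reruns are identical
  sw1 <- run_sweep("cluster_size_ratio", values = 0.5, n_reps = 1,
                   base_config = small_config(n_fluorophores = 3),
                   seed = 5, replicates = 3)
  expect_equal(nrow(sw1$results), 1L)
  sw1b <- run_sweep("cluster_size_ratio", values = 0.5, n_reps = 1,
                    base_config = small_config(n_fluorophores = 3),
                    seed = 5, replicates = 3)
  expect_identical(sw1$results, sw1b$results)
})
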
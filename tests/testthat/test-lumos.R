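test_that("reconstruction is winner-take-all on the raw maximum intensity", {
  raw <- multichannel_image(array(c(5, 1, 0, 9, 2, 0), c(3, 1, 2)))
  # pixel raws: (5,9), (1,2), (0,0); clusters: 2 of 3, 1, 3
  out <- reconstruct_output(raw, c(2L, 1L, 3L))
  expect_equal(out$data[1, 1, ], c(0, 9, 0))
  expect_equal(out$data[2, 1, ], c(2, 0, 0))
  expect_equal(out$data[3, 1, ], c(0, 0, 0))
  # at most one nonzero channel per pixel
  expect_true(all(rowSums(matrix(out$data, ncol = 3) > 0) <= 1))
  expect_error(reconstruct_output(raw, c(1L, 2L)), "pixel count")
})

test_that("background is the cluster with lowest mean raw intensity", {
  raw <- multichannel_image(array(c(2, 80, 1.8, 80), c(2, 2, 1)))
  model <- structure(list(assignment = c(1L, 2L, 1L, 2L),
                          centroids = matrix(0, 2, 1)),
                     class = "cluster_model")
  expect_equal(identify_background(model, raw), 1L)

  tied <- multichannel_image(array(c(3, 3, 3, 3), c(2, 2, 1)))
  expect_equal(identify_background(model, tied), 1L)  # tie -> lowest index
})

test_that("spectral signatures are per-cluster channel means with row max 1", {
  raw <- multichannel_image(array(c(10, 4, 2, 0, 8, 4), c(3, 1, 2)))
  model <- structure(list(assignment = c(1L, 2L, 2L),
                          centroids = matrix(0, 2, 2)),
                     class = "cluster_model")
  sig <- spectral_signatures(raw, model)
  expect_equal(sig$matrix[1, ], c(1, 0))          # pixels all (10, 0)
  expect_equal(sig$matrix[2, ], c(0.5, 1))        # means (3, 6)
  expect_equal(sig$mean_intensity[2, ], c(3, 6))

  model$assignment <- c(1L, 1L, 1L)
  model$centroids <- matrix(0, 3, 2)
  # clusters 2 and 3 are both empty: one warning each
  expect_warning(expect_warning(spectral_signatures(raw, model), "empty"),
                 "empty")
})

test_that("a noise-free two-fluorophore scene is unmixed perfectly", {
  cfg <- small_config(n_fluorophores = 2, snr = 100, jitter_sd = 0,
                      blur_sd = 0, postfilter_window = 0)
  sim <- simulate_scene(cfg, seed = 5)
  # nothing to filter in the noise-free limit; the median prefilter would
  # only erode strip corners
  fit <- lumos(sim$image, n_fluorophores = 2, median_window = 0, seed = 5)
  ev <- evaluate_unmixing(fit, sim$scene$labels)
  expect_equal(ev$smallest_cluster_f1, 1.0)
  expect_true(all(ev$per_cluster$f1 == 1.0))
})

test_that("the fitted model obeys the k rule and output conventions", {
  cfg <- small_config()
  sim <- simulate_scene(cfg, seed = 2)
  fit <- lumos(sim$image, n_fluorophores = 4, seed = 2)
  expect_s3_class(fit, "lumos")
  expect_equal(fit$k, 5L)                        # fluorophores + background
  expect_equal(fit$roles[fit$background_index], "background")
  expect_equal(dim(fitted(fit)), c(128, 128, 5))
  expect_equal(dim(fitted(fit, remove_background = TRUE)), c(128, 128, 4))

  # reconstruction conservation: one nonzero channel = max raw channel
  un <- matrix(fitted(fit), ncol = 5)
  m <- matrix(sim$image$data, ncol = 4)
  pixmax <- do.call(pmax, as.data.frame(m))
  nz <- pixmax > 0
  expect_true(all(rowSums(un > 0) <= 1))
  expect_equal(apply(un, 1, max)[nz], pixmax[nz])

  # fluorophore clusters come in wavelength order of their peak channel
  pk <- apply(coef(fit)[seq_len(4), ], 1, which.max)
  expect_true(all(diff(pk) >= 0))

  # extra clusters extend k and roles
  fit5 <- lumos(sim$image, n_fluorophores = 4, extra_clusters = 1,
                seed = 2, extra_roles = "autofluorescence")
  expect_equal(fit5$k, 6L)
  expect_true("autofluorescence" %in% fit5$roles)
})

test_that("channel selection restricts the fit like the two-channel use case", {
  cfg <- small_config(n_fluorophores = 2)
  sim <- simulate_scene(cfg, seed = 3)
  fit <- lumos(sim$image, n_fluorophores = 2, channels = c(1, 2), seed = 3)
  expect_equal(n_channels(fit$raw), 2L)
  expect_equal(dim(fitted(fit))[3], 3L)          # two fluorophores + background
  expect_equal(ncol(coef(fit)), 2L)
})

test_that("identified background covers the true empty pixels at SNR 10", {
  cfg <- small_config()
  sim <- simulate_scene(cfg, seed = 7)
  fit <- lumos(sim$image, n_fluorophores = 4, seed = 7)
  truth_bg <- sim$scene$labels == 0
  pred_bg <- cluster_labels(fit) == 0
  expect_gt(sum(pred_bg & truth_bg) / sum(truth_bg), 0.95)
})

test_that("signature peak channels match the generating spectra", {
  cfg <- small_config(snr = 50, jitter_sd = 0)
  sim <- simulate_scene(cfg, seed = 11)
  fit <- lumos(sim$image, n_fluorophores = 4, seed = 11)
  ev <- evaluate_unmixing(fit, sim$scene$labels)
  sig_peak <- apply(coef(fit), 1, which.max)
  for (f in seq_len(4)) {
    pred_cluster <- ev$per_cluster$pred_label[ev$per_cluster$truth_label == f]
    ideal <- which.max(channel_response(sim$scene$spectra[[f]],
                                        cfg$bands))
    expect_equal(unname(sig_peak[pred_cluster]), unname(ideal))
  }
})

test_that("unmixing is deterministic for a fixed seed", {
  sim <- simulate_scene(small_config(), seed = 13)
  f1 <- lumos(sim$image, n_fluorophores = 4, seed = 99)
  f2 <- lumos(sim$image, n_fluorophores = 4, seed = 99)
  expect_identical(f1$model$assignment, f2$model$assignment)
  expect_identical(fitted(f1), fitted(f2))
})

test_that("too many clusters for the distinct feature vectors errors with guidance", {
  img <- multichannel_image(array(rep(c(0, 10), each = 8), c(4, 4, 1)))
  expect_error(lumos(img, n_fluorophores = 5, median_window = 0, seed = 1),
               "distinct")
})

test_that("predict and residuals are consistent with the fit", {
  sim <- simulate_scene(small_config(), seed = 17)
  fit <- lumos(sim$image, n_fluorophores = 4, seed = 17)
  relab <- predict(fit, sim$image)
  expect_equal(as.vector(relab), fit$model$assignment)
  r <- residuals(fit)
  expect_equal(dim(r), c(128, 128))
  expect_true(all(r >= 0))
})
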
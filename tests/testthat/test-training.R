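tiny_cohort <- function(n = 8, seed = 7, func_fraction = 1) {
  make_cohort(generative_config(n_lat = 16, n_lon = 32, n_subjects = n,
                                smoothness_scale = 4, blob_radius = 3,
                                n_blobs = 3, func_fraction = func_fraction,
                                seed = seed))
}

tiny_model <- function(grid, seed = 7, ...) {
  build_model(network_config(scale_divisor = 8, ...), grid, 1, 1,
              seed = seed)
}

test_that("the learning-rate schedule follows the printed values", {
  tc <- train_config()
  expect_equal(lr_at(list(epoch = 0), tc), 1e-3)
  expect_equal(lr_at(list(epoch = 250), tc), 5.5e-4)
  expect_equal(lr_at(list(epoch = 500), tc), 1e-4)
  # monotone non-increasing over the linear phase
  lrs <- vapply(0:500, function(e) lr_at(list(epoch = e), tc), numeric(1))
  expect_true(all(diff(lrs) <= 0))
  # past the linear phase the rate drops by 0.9 per plateau event
  expect_equal(lr_at(list(epoch = 600, plateau_events = 0), tc), 1e-4)
  expect_equal(lr_at(list(epoch = 600, plateau_events = 2), tc),
               1e-4 * 0.9^2)
  expect_error(lr_at(list(epoch = -1), tc))
  expect_error(train_config(lr_floor = 0))
  expect_error(train_config(lr_floor = 2e-3, lr_init = 1e-3))
})

test_that("augmentation is a no-op when disabled and has the configured noise level", {
  coh <- tiny_cohort()
  tc0 <- train_config(warp_aug_sigma = 0, noise_aug_geom = 0,
                      noise_aug_func = 0)
  b0 <- augment_batch(coh$subjects[1:2], tc0)
  expect_identical(b0[[1]]$geom$values, coh$subjects[[1]]$geom$values)
  expect_identical(b0[[2]]$func$values, coh$subjects[[2]]$func$values)
  # empirical sd of the additive geometric noise
  tc1 <- train_config(warp_aug_sigma = 0, noise_aug_geom = 1,
                      noise_aug_func = 6)
  set.seed(1)
  devg <- devf <- numeric(0)
  for (r in 1:120) {
    b <- augment_batch(coh$subjects[1], tc1)
    devg <- c(devg, b[[1]]$geom$values - coh$subjects[[1]]$geom$values)
    devf <- c(devf, b[[1]]$func$values - coh$subjects[[1]]$func$values)
  }
  expect_lt(abs(sd(devg) - 1), 0.02)
  expect_lt(abs(sd(devf) - 6), 6 * 0.02)
})

test_that("one subject's channels share the identical augmentation warp", {
  g <- make_grid(16, 32)
  # geometric and functional channels carry the same pattern; after a shared
  # warp (and no noise) they must remain identical
  m <- matrix(rnorm(16 * 32), 16)
  s <- list(geom = feature_map(g, m, "geometric"),
            func = feature_map(g, m, "functional"))
  tc <- train_config(warp_aug_sigma = 2, noise_aug_geom = 0,
                     noise_aug_func = 0)
  set.seed(3)
  b <- augment_batch(list(s), tc)
  expect_identical(b[[1]]$geom$values[, , 1], b[[1]]$func$values[, , 1])
  expect_false(identical(b[[1]]$geom$values[, , 1], m))
})

test_that("augmentation warps are distortion-corrected across latitude", {
  g <- make_grid(16, 32)
  tc <- train_config(warp_aug_sigma = 2)
  # reproduce the warp draw: the longitudinal displacement is divided by
  # sin(theta), so its row-wise spread grows toward the poles
  set.seed(5)
  draws <- replicate(200, {
    f <- spherereg:::gaussian_smooth_grid(matrix(rnorm(16 * 32), 16),
                                          tc$aug_smoothness)
    f2 <- spherereg:::gaussian_smooth_grid(matrix(rnorm(16 * 32), 16),
                                           tc$aug_smoothness)
    u2 <- f2 / sd(f2) * tc$warp_aug_sigma / sin(g$theta)
    c(sd(u2[1, ]), sd(u2[8, ]))
  })
  expect_gt(mean(draws[1, ]), mean(draws[2, ]))
})

test_that("a short training run is finite, logged, and reproducible", {
  coh <- tiny_cohort()
  m <- tiny_model(coh$grid)
  tc <- train_config(epochs = 2, batch_size = 8, seed = 7,
                     val_fraction = 0)
  fit <- train_model(m, coh, tc)
  expect_equal(nrow(fit$history), 2)
  expect_true(all(is.finite(fit$history$total)))
  expect_true(all(c("sim_geom_atlas", "sim_func_subject", "smooth_j",
                    "central_j", "lr") %in% names(fit$history)))
  # bit-identical replay from the same seed
  fit2 <- train_model(tiny_model(coh$grid), coh, tc)
  expect_identical(fit$history$total, fit2$history$total)
  expect_identical(fit$model$params$head_j$w, fit2$model$params$head_j$w)
  # cohort smaller than a batch is rejected
  expect_error(train_model(m, tiny_cohort(4),
                           train_config(batch_size = 8)), "smaller")
})

test_that("training reduces the loss on a small cohort", {
  coh <- tiny_cohort(n = 8, seed = 11)
  m <- tiny_model(coh$grid, seed = 11)
  tc <- train_config(epochs = 25, seed = 11, val_fraction = 0)
  fit <- train_model(m, coh, tc)
  expect_lt(fit$history$total[25], fit$history$total[1])
})

test_that("the reference 200-epoch run halves its objective", {
  ref <- reference_run()
  h <- ref$fit$history
  expect_true(all(is.finite(h$total)))
  expect_lt(h$total[200], 0.5 * h$total[1])
})

test_that("semi-supervision degrades gracefully without functional data", {
  # training on a cohort whose functional maps were removed equals training
  # on the same cohort generated without functional maps: identical losses
  coh_f <- tiny_cohort(n = 8, seed = 13, func_fraction = 1)
  stripped <- coh_f
  stripped$subjects <- lapply(stripped$subjects, function(s) {
    s$func <- NULL
    s
  })
  coh_n <- tiny_cohort(n = 8, seed = 13, func_fraction = 0)
  tc <- train_config(epochs = 3, seed = 5, val_fraction = 0)
  fit_a <- train_model(tiny_model(coh_f$grid, seed = 5), stripped, tc)
  fit_b <- train_model(tiny_model(coh_n$grid, seed = 5), coh_n, tc)
  expect_identical(fit_a$history$total, fit_b$history$total)
  expect_true(all(fit_a$history$sim_func_atlas == 0))
  expect_identical(fit_a$model$params$head_g$w, fit_b$model$params$head_g$w)
})

test_that("a frozen atlas receives no updates while the network still trains", {
  coh <- tiny_cohort(n = 8, seed = 17)
  m <- tiny_model(coh$grid, seed = 17)
  tc <- train_config(epochs = 2, seed = 17, atlas_frozen = TRUE,
                     val_fraction = 0)
  fit <- train_model(m, coh, tc)
  expect_identical(fit$model$atlas$geometric, m$atlas$geometric)
  expect_false(identical(fit$model$params$enc1$w, m$params$enc1$w))
  # the ablation harness: frozen true atlas vs learned-from-noise both run
  m_true <- tiny_model(coh$grid, seed = 17)
  st <- standardize(coh$atlas)
  m_true$atlas$geometric <- st$values[, , 1, drop = FALSE]
  m_true$atlas$functional <- st$values[, , 2, drop = FALSE]
  fit_true <- train_model(m_true, coh, tc)
  expect_equal(nrow(fit_true$history), nrow(fit$history))
  expect_true(all(is.finite(fit_true$history$total)))
})
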
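test_that("the true atlas has the constructed structure", {
  cfg <- generative_config(seed = 1)
  atlas <- make_true_atlas(cfg)
  expect_equal(dim(atlas$values), c(64, 128, 2))
  expect_equal(atlas$channel_roles, c("geometric", "functional"))
  # geometric channel has exactly zero median by construction
  expect_lt(abs(median(atlas$values[, , 1])), 1e-6)
  # functional blobs are nonnegative and t-statistic scaled
  expect_true(all(atlas$values[, , 2] >= 0))
  expect_gt(max(atlas$values[, , 2]), 0.9 * cfg$func_amplitude)
  # blob count equals the configuration, by connected-component labeling
  lab <- label_components(atlas$values[, , 2] > cfg$func_amplitude / 2)
  expect_equal(max(lab), cfg$n_blobs)
  # with zero offset, blob centers coincide with geometric ridge maxima
  cfg0 <- generative_config(func_offset = 0, seed = 1)
  at0 <- make_true_atlas(cfg0)
  centers <- attr(at0, "blob_centers")
  gvals <- at0$values[, , 1]
  for (b in seq_len(nrow(centers))) {
    i <- centers[b, 1]; j <- centers[b, 2]
    nb <- gvals[max(1, i - 1):min(64, i + 1),
                ((j + c(-1, 0, 1) - 1) %% 128) + 1]
    expect_equal(gvals[i, j], max(nb))
  }
  # offset shifts centers along longitude by func_offset cells
  cfg4 <- generative_config(func_offset = 4, seed = 1)
  c4 <- attr(make_true_atlas(cfg4), "blob_centers")
  expect_equal(((c4[, 2] - centers[, 2]) %% 128), rep(4, nrow(c4)))
})

test_that("the degenerate generative model reproduces the atlas exactly", {
  cfg <- generative_config(n_lat = 16, n_lon = 32, joint_amplitude = 0,
                           modality_amplitude = 0, sigma_noise = 0,
                           seed = 3)
  atlas <- make_true_atlas(cfg)
  s <- sample_subject(atlas, cfg, seed = 5)
  expect_equal(s$geom$values[, , 1], atlas$values[, , 1])
  expect_equal(s$func$values[, , 1], atlas$values[, , 2])
  expect_true(all(s$v_j$v == 0))
})

test_that("subject sampling is reproducible from its seed", {
  cfg <- generative_config(n_lat = 16, n_lon = 32, seed = 3)
  atlas <- make_true_atlas(cfg)
  s1 <- sample_subject(atlas, cfg, seed = 11)
  s2 <- sample_subject(atlas, cfg, seed = 11)
  expect_identical(s1$geom$values, s2$geom$values)
  expect_identical(s1$v_j$v, s2$v_j$v)
  s3 <- sample_subject(atlas, cfg, seed = 12)
  expect_false(identical(s1$geom$values, s3$geom$values))
  # cohorts replay bit-identically too
  c1 <- make_cohort(generative_config(n_lat = 16, n_lon = 32,
                                      n_subjects = 4, seed = 7))
  c2 <- make_cohort(generative_config(n_lat = 16, n_lon = 32,
                                      n_subjects = 4, seed = 7))
  expect_identical(c1$subjects[[4]]$geom$values,
                   c2$subjects[[4]]$geom$values)
})

test_that("two-stage noise yields the 2 sigma^2 marginal around the atlas", {
  # identity deformations, sigma = 1: Var(I_g - A) = 2 sigma^2
  cfg <- generative_config(n_lat = 4, n_lon = 8, joint_amplitude = 0,
                           modality_amplitude = 0, sigma_noise = 1,
                           seed = 2)
  atlas <- make_true_atlas(cfg)
  set.seed(99)
  n_draw <- 4000  # 4000 draws x 32 pixels = 1.28e5 realizations
  devs <- numeric(n_draw * 32)
  for (k in seq_len(n_draw)) {
    s <- sample_subject(atlas, cfg)
    devs[(k - 1) * 32 + 1:32] <- s$geom$values[, , 1] - atlas$values[, , 1]
  }
  expect_lt(abs(var(devs) / cfg$sigma_noise^2 - 2), 2 * 0.02)
})

test_that("cohorts honour the functional fraction and antithetic centering", {
  cfg <- generative_config(n_lat = 16, n_lon = 32, n_subjects = 10,
                           func_fraction = 0.5, seed = 13)
  coh <- make_cohort(cfg)
  nf <- sum(vapply(coh$subjects, function(s) !is.null(s$func), logical(1)))
  expect_equal(nf, 5L)
  # centered cohort: the mean joint velocity vanishes by construction
  vbar <- Reduce(`+`, lapply(coh$subjects, function(s) s$v_j$v)) / 10
  expect_lt(mean(sqrt(vbar[, , 1]^2 + vbar[, , 2]^2)), 1e-12)
  # the mean joint displacement is near zero at the reference resolution
  # (exp is nonlinear, so antithetic velocity pairs cancel only to second
  # order; 3-cell velocities on a 64-row grid leave a ~0.02-cell residual)
  cref <- make_cohort(generative_config(n_subjects = 10, seed = 13))
  ubar <- Reduce(`+`, lapply(cref$subjects, function(s)
    integrate_svf(s$v_j)$u)) / 10
  expect_lt(mean(sqrt(ubar[, , 1]^2 + ubar[, , 2]^2)), 0.05)
})

test_that("between-subject variability grows with the joint amplitude", {
  meanu <- function(amp) {
    coh <- make_cohort(generative_config(n_lat = 16, n_lon = 32,
                                         n_subjects = 8,
                                         joint_amplitude = amp,
                                         seed = 17))
    mean(vapply(coh$subjects, function(s) {
      u <- integrate_svf(s$v_j)$u
      mean(sqrt(u[, , 1]^2 + u[, , 2]^2))
    }, numeric(1)))
  }
  expect_gt(meanu(3), meanu(1))
})

test_that("inverse-warping a subject raises its correlation to the atlas", {
  cfg <- generative_config(seed = 23, sigma_noise = 0.25)
  coh <- make_cohort(cfg)
  w <- distortion_weights(coh$grid)
  at <- coh$atlas$values[, , 1]
  for (s in coh$subjects[1:4]) {
    before <- weighted_pearson_oracle(s$geom$values[, , 1], at, w$w)
    inv <- compose_deformation(invert_svf(s$v_g), invert_svf(s$v_j))
    after <- weighted_pearson_oracle(
      warp_feature_map(s$geom, inv)$values[, , 1], at, w$w)
    expect_gt(after, before)
  }
})

test_that("functional maps align better under their own inverse field than the geometric one", {
  # the within-subject geometry/function discrepancy (v_g vs v_f) is real:
  # undoing the functional observation with the geometric modality field
  # leaves residual misalignment
  cfg <- generative_config(seed = 29, sigma_noise = 0.1)
  coh <- make_cohort(cfg)
  w <- distortion_weights(coh$grid)
  atf <- coh$atlas$values[, , 2]
  diffs <- vapply(coh$subjects[1:4], function(s) {
    inv_f <- compose_deformation(invert_svf(s$v_f), invert_svf(s$v_j))
    inv_g <- compose_deformation(invert_svf(s$v_g), invert_svf(s$v_j))
    good <- weighted_pearson_oracle(
      warp_feature_map(s$func, inv_f)$values[, , 1], atf, w$w)
    wrong <- weighted_pearson_oracle(
      warp_feature_map(s$func, inv_g)$values[, , 1], atf, w$w)
    good - wrong
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
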
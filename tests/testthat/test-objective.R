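make_test_subject <- function(g, with_func = TRUE, seed = 1) {
  set.seed(seed)
  geom <- feature_map(g, matrix(rnorm(g$n_lat * g$n_lon), g$n_lat),
                      "geometric")
  func <- if (with_func) {
    feature_map(g, matrix(rnorm(g$n_lat * g$n_lon), g$n_lat), "functional")
  }
  list(geom = geom, func = func)
}

make_test_fields <- function(g, amplitude = 0.8, seed = 1) {
  set.seed(seed)
  list(v_j = smooth_velocity(g, amplitude, 3),
       v_g = smooth_velocity(g, amplitude / 3, 3),
       v_f = smooth_velocity(g, amplitude / 3, 3))
}

test_that("loss weights validate their invariants", {
  lw <- loss_weights()
  expect_equal(lw$lambda_j, 0.1)
  expect_equal(lw$lambda_g, 0.2)
  expect_equal(lw$w_func + lw$w_geom, 1)
  expect_error(loss_weights(w_func = 0.5, w_geom = 0.4), "must equal 1")
  expect_error(loss_weights(lambda_j = -1))
})

test_that("smoothness penalty matches the explicit summation oracle", {
  g <- make_grid(8, 16)
  w <- distortion_weights(g)
  # zero and constant (wrap-aware translation) fields are unpenalized
  expect_equal(smoothness_penalty(array(0, c(8, 16, 2)), 0.2, w), 0)
  expect_equal(smoothness_penalty(array(rep(c(2, 7), each = 8 * 16),
                                        c(8, 16, 2)), 0.2, w), 0)
  set.seed(21)
  for (rep in 1:3) {
    u <- array(rnorm(8 * 16 * 2), c(8, 16, 2))
    expect_lt(abs(smoothness_penalty(u, 0.37, w) -
                  smoothness_oracle(u, 0.37, w$w)), 1e-8)
  }
  # a mod-aware longitudinal ramp: wrap contributes exactly one seam jump
  u <- array(0, c(8, 16, 2))
  u[, , 1] <- 0.25 * (col(matrix(0, 8, 16)) - 1)
  expect_lt(abs(smoothness_penalty(u, 1, w) -
                smoothness_oracle(u, 1, w$w)), 1e-10)
})

test_that("centrality penalty matches the mean-then-norm oracle", {
  set.seed(31)
  us <- lapply(1:8, function(i) array(rnorm(8 * 16 * 2), c(8, 16, 2)))
  # antisymmetric batch cancels
  expect_equal(centrality_penalty(list(us[[1]], -us[[1]]), 0.5), 0)
  # single element: alpha * mean(u^2)
  expect_equal(centrality_penalty(us[1], 2), 2 * mean(us[[1]]^2))
  ubar <- Reduce(`+`, us) / 8
  expect_lt(abs(centrality_penalty(us, 0.01) - 0.01 * mean(ubar^2)), 1e-8)
  expect_error(centrality_penalty(list(), 1), "empty")
})

test_that("similarity loss is a distortion-weighted MSE over valid channels", {
  g <- make_grid(8, 16)
  w <- distortion_weights(g)
  m1 <- matrix(rnorm(8 * 16), 8)
  fm1 <- feature_map(g, m1, "geometric")
  expect_equal(similarity_loss(fm1, fm1, w), 0)
  # constant difference with unit weights gives d^2
  ones <- matrix(1, 8, 16)
  fm2 <- feature_map(g, m1 + 3, "geometric")
  expect_equal(similarity_loss(fm1, fm2, ones), 9)
  # random pair vs the loop oracle with sin(theta) weights
  set.seed(5)
  for (rep in 1:3) {
    a <- matrix(rnorm(8 * 16), 8)
    b <- matrix(rnorm(8 * 16), 8)
    expect_lt(abs(similarity_loss(feature_map(g, a, "geometric"),
                                  feature_map(g, b, "geometric"), w) -
                  wmse_oracle(a, b, w$w)), 1e-8)
  }
  # masked channels are excluded; all-masked input errors
  both <- feature_map(g, array(c(m1, m1 + 1), c(8, 16, 2)),
                      c("geometric", "functional"),
                      valid_mask = c(TRUE, FALSE))
  ref <- feature_map(g, array(c(m1, m1), c(8, 16, 2)),
                     c("geometric", "functional"))
  expect_equal(similarity_loss(both, ref, ones), 0)
  none <- feature_map(g, array(c(m1, m1), c(8, 16, 2)),
                      c("geometric", "functional"),
                      valid_mask = c(FALSE, FALSE))
  expect_error(similarity_loss(none, ref, w), "no valid channels")
})

test_that("total loss vanishes in the perfect-fit limit", {
  g <- make_grid(16, 32)
  atlas <- list(geometric = array(rnorm(16 * 32), c(16, 32, 1)),
                functional = array(rnorm(16 * 32), c(16, 32, 1)))
  id <- velocity_field(g, array(0, c(16, 32, 2)))
  subj <- list(geom = feature_map(g, atlas$geometric, "geometric"),
               func = feature_map(g, atlas$functional, "functional"))
  rep <- total_loss(list(subj), list(list(v_j = id, v_g = id, v_f = id)),
                    atlas, loss_weights(), distortion_weights(g))
  expect_equal(rep$total, 0)
  expect_equal(rep$sim_geom_atlas, 0)
  expect_equal(rep$sim_func_subject, 0)
  expect_equal(rep$n_func_observed, 1L)
})

test_that("total loss recombines exactly from its reported components", {
  g <- make_grid(16, 32)
  w <- distortion_weights(g)
  lw <- loss_weights(alpha_j = 0.05)
  atlas <- list(geometric = array(rnorm(16 * 32), c(16, 32, 1)),
                functional = array(rnorm(16 * 32), c(16, 32, 1)))
  subjects <- lapply(1:3, function(i) make_test_subject(g, i < 3, seed = i))
  fields <- lapply(1:3, function(i) make_test_fields(g, seed = 10 + i))
  rep <- total_loss(subjects, fields, atlas, lw, w)
  manual <- lw$w_geom * (rep$sim_geom_atlas + rep$sim_geom_subject) / 2 +
    lw$w_func * (rep$sim_func_atlas + rep$sim_func_subject) / 2 +
    rep$smooth_j + rep$smooth_g + rep$smooth_f +
    rep$central_j + rep$central_g + rep$central_f
  expect_lt(abs(rep$total - manual), 1e-6)
  expect_equal(rep$n_func_observed, 2L)
  # independent recomputation of a similarity component through the public
  # deformation API (dual route: graph vs composed-warp calls)
  phi1 <- compose_deformation(integrate_svf(fields[[1]]$v_j),
                              integrate_svf(fields[[1]]$v_g))
  pred1 <- warp_feature_map(
    feature_map(g, atlas$geometric, "geometric"), phi1)
  direct <- similarity_loss(subjects[[1]]$geom, pred1, w)
  reps1 <- total_loss(subjects[1], fields[1], atlas, lw, w)
  expect_lt(abs(reps1$sim_geom_subject - direct), 1e-10)
})

test_that("doubling lambda_j doubles smooth_j and nothing else", {
  g <- make_grid(16, 32)
  w <- distortion_weights(g)
  atlas <- list(geometric = array(rnorm(16 * 32), c(16, 32, 1)),
                functional = array(rnorm(16 * 32), c(16, 32, 1)))
  subjects <- lapply(1:2, function(i) make_test_subject(g, TRUE, seed = i))
  fields <- lapply(1:2, function(i) make_test_fields(g, seed = i))
  r1 <- total_loss(subjects, fields, atlas, loss_weights(lambda_j = 0.1), w)
  r2 <- total_loss(subjects, fields, atlas, loss_weights(lambda_j = 0.2), w)
  expect_equal(r2$smooth_j, 2 * r1$smooth_j)
  expect_equal(r2$sim_geom_atlas, r1$sim_geom_atlas)
  expect_equal(r2$sim_func_subject, r1$sim_func_subject)
  expect_equal(r2$smooth_g, r1$smooth_g)
})

test_that("functional terms are masked means over observed subjects", {
  g <- make_grid(16, 32)
  w <- distortion_weights(g)
  atlas <- list(geometric = array(rnorm(16 * 32), c(16, 32, 1)),
                functional = array(rnorm(16 * 32), c(16, 32, 1)))
  s1 <- make_test_subject(g, TRUE, seed = 1)
  s2 <- make_test_subject(g, TRUE, seed = 2)
  s3 <- make_test_subject(g, FALSE, seed = 3)
  f <- lapply(1:3, function(i) make_test_fields(g, seed = i))
  r12 <- total_loss(list(s1, s2), f[1:2], atlas, loss_weights(), w)
  r123 <- total_loss(list(s1, s2, s3), f, atlas, loss_weights(), w)
  # adding a subject without functional data never touches functional sums
  expect_equal(r123$sim_func_atlas, r12$sim_func_atlas)
  expect_equal(r123$sim_func_subject, r12$sim_func_subject)
  expect_equal(r123$n_func_observed, 2L)
  # with no functional subjects the objective is geometric-only
  r3 <- total_loss(list(s3), f[3], atlas, loss_weights(), w)
  expect_equal(r3$sim_func_atlas, 0)
  expect_equal(r3$sim_func_subject, 0)
  expect_equal(r3$n_func_observed, 0L)
})

test_that("the true atlas beats a random atlas on noisy identity-deformation data", {
  cfg <- generative_config(n_lat = 16, n_lon = 32, n_subjects = 4,
                           joint_amplitude = 0, modality_amplitude = 0,
                           sigma_noise = 0.3, seed = 42)
  coh <- make_cohort(cfg)
  g <- coh$grid
  id <- velocity_field(g, array(0, c(16, 32, 2)))
  fields <- lapply(coh$subjects, function(s) list(v_j = id, v_g = id,
                                                  v_f = id))
  subj <- lapply(coh$subjects, function(s)
    list(geom = s$geom, func = s$func))
  true_atlas <- list(
    geometric = coh$atlas$values[, , 1, drop = FALSE],
    functional = coh$atlas$values[, , 2, drop = FALSE])
  set.seed(9)
  rand_atlas <- list(
    geometric = array(rnorm(16 * 32), c(16, 32, 1)),
    functional = array(rnorm(16 * 32), c(16, 32, 1)))
  w <- distortion_weights(g)
  r_true <- total_loss(subj, fields, true_atlas, loss_weights(), w)
  r_rand <- total_loss(subj, fields, rand_atlas, loss_weights(), w)
  expect_lt(r_true$total, r_rand$total)
})
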
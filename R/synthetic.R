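#' Configuration of the synthetic cortex generator
#'
#' The simulator draws cohorts from the generative model the registration is
#' built on: a shared multi-channel atlas is warped by a large smooth joint
#' deformation per subject, then by small modality-specific deformations, with
#' additive Gaussian noise at both stages. The defaults define the reference
#' study conditions used throughout the tests.
#'
#' @param n_lat,n_lon grid dimensions (default 64 x 128).
#' @param n_subjects cohort size (default 20).
#' @param joint_amplitude maximum magnitude of the joint velocity, in grid
#'   cells (default 3.0; "large" between-subject variability).
#' @param modality_amplitude maximum magnitude of the geometric/functional
#'   velocities (default 0.8; must be below `joint_amplitude` — within-subject
#'   geometry-function discrepancies are small).
#' @param smoothness_scale Gaussian blur sd (cells) applied to sampled white
#'   noise velocities; matches the smoothness prior family.
#' @param sigma_noise per-stage additive noise sd (default 0.25, on the raw
#'   feature scale).
#' @param func_offset longitude displacement (cells) between functional blob
#'   centers and geometric ridge maxima (default 4); with a positive offset
#'   the optimal functional alignment genuinely differs from the geometric
#'   one.
#' @param n_blobs number of functional activation blobs (default 6).
#' @param geom_amplitude peak scale of the folding pattern (sulcal-depth-like,
#'   default 3).
#' @param func_amplitude peak of the functional blobs (t-statistic-like,
#'   default 10).
#' @param blob_radius Gaussian radius of functional blobs in cells
#'   (default 5).
#' @param func_fraction fraction of subjects carrying functional maps
#'   (default 1).
#' @param centered pair subjects with antithetic joint velocities `+v/-v` so
#'   the cohort-mean joint displacement is near zero (default TRUE).
#' @param seed integer seed.
#' @return an object of class `generative_config`.
#' @export
generative_config <- function(n_lat = 64L, n_lon = 128L, n_subjects = 20L,
                              joint_amplitude = 3.0,
                              modality_amplitude = 0.8,
                              smoothness_scale = 6,
                              sigma_noise = 0.25,
                              func_offset = 4L,
                              n_blobs = 6L,
                              geom_amplitude = 3,
                              func_amplitude = 10,
                              blob_radius = 5,
                              func_fraction = 1,
                              centered = TRUE,
                              seed = 1L) {
  stopifnot(joint_amplitude >= 0, modality_amplitude >= 0,
            sigma_noise >= 0, n_subjects >= 1)
  if (modality_amplitude > 0 && modality_amplitude >= joint_amplitude &&
      joint_amplitude > 0) {
    stop("modality_amplitude must be smaller than joint_amplitude",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "generative_config")
}

# Separable Gaussian blur with wrap in longitude and replicate in latitude.
gaussian_smooth_grid <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  H <- nrow(m); W <- ncol(m)
  # latitude (rows): replicate padding
  idx <- pmin(pmax(seq(1 - r, H + r), 1L), H)
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, H, W)
  for (t in seq_along(k)) out <- out + k[t] * mp[(t - 1) + seq_len(H), ,
                                                 drop = FALSE]
  # longitude (cols): wrap padding
  idx <- ((seq(1 - r, W + r) - 1L) %% W) + 1L
  mp <- out[, idx, drop = FALSE]
  out2 <- matrix(0, H, W)
  for (t in seq_along(k)) out2 <- out2 + k[t] * mp[, (t - 1) + seq_len(W),
                                                   drop = FALSE]
  out2
}

#' Draw a smooth random velocity field
#'
#' Gaussian white noise smoothed to `smoothness_scale` and rescaled so the
#' maximum velocity magnitude equals `amplitude` (zero amplitude gives the
#' zero field).
#'
#' @param grid a [make_grid()] object.
#' @param amplitude maximum magnitude in grid cells.
#' @param smoothness_scale Gaussian blur sd in cells.
#' @return a [velocity_field()].
#' @export
smooth_velocity <- function(grid, amplitude, smoothness_scale = 6) {
  v <- array(0, c(grid$n_lat, grid$n_lon, 2L))
  if (amplitude > 0) {
    for (c in 1:2) {
      v[, , c] <- gaussian_smooth_grid(
        matrix(rnorm(grid$n_lat * grid$n_lon), grid$n_lat),
        smoothness_scale)
    }
    mx <- max(sqrt(v[, , 1]^2 + v[, , 2]^2))
    if (mx > 0) v <- v * amplitude / mx
  } else {
    # keep RNG consumption identical across amplitude settings
    invisible(rnorm(2 * grid$n_lat * grid$n_lon))
  }
  velocity_field(grid, v)
}

#' Construct the ground-truth synthetic atlas
#'
#' The geometric channel is a banded sinusoidal folding pattern (curvature
#' like, exactly zero median); the functional channel is a sum of smooth
#' positive blobs (t-map like) whose centers sit at the strongest geometric
#' ridge maxima, shifted along longitude by `func_offset` cells.
#'
#' @param config a [generative_config()].
#' @return a [feature_map()] with one geometric and one functional channel,
#'   with attribute `"blob_centers"` (matrix of row/col centers).
#' @export
make_true_atlas <- function(config) {
  g <- make_grid(config$n_lat, config$n_lon)
  th <- matrix(g$theta, g$n_lat, g$n_lon)
  ph <- matrix(g$phi, g$n_lat, g$n_lon, byrow = TRUE)
  geom <- sin(4 * th) * cos(3 * ph) + 0.6 * sin(7 * th + 2 * ph)
  geom <- config$geom_amplitude * geom / max(abs(geom))
  geom <- geom - median(geom)
  # ridge maxima: local maxima over the 8-neighborhood (wrap in longitude),
  # greedily thinned to keep blobs separated
  mx <- local_maxima(geom)
  ord <- order(geom[mx], decreasing = TRUE)
  cand <- which(mx, arr.ind = TRUE)[ord, , drop = FALSE]
  centers <- matrix(0, 0, 2)
  min_sep <- 3.5 * config$blob_radius
  for (r in seq_len(nrow(cand))) {
    if (nrow(centers) >= config$n_blobs) break
    ok <- TRUE
    if (nrow(centers) > 0) {
      dlat <- centers[, 1] - cand[r, 1]
      dlon <- abs(centers[, 2] - cand[r, 2])
      dlon <- pmin(dlon, g$n_lon - dlon)
      if (any(sqrt(dlat^2 + dlon^2) < min_sep)) ok <- FALSE
    }
    if (ok) centers <- rbind(centers, cand[r, ])
  }
  centers[, 2] <- ((centers[, 2] - 1 + config$func_offset) %% g$n_lon) + 1
  func <- matrix(0, g$n_lat, g$n_lon)
  rows <- row(func); cols <- col(func)
  for (b in seq_len(nrow(centers))) {
    dlat <- rows - centers[b, 1]
    dlon <- abs(cols - centers[b, 2])
    dlon <- pmin(dlon, g$n_lon - dlon)
    func <- func + exp(-(dlat^2 + dlon^2) / (2 * config$blob_radius^2))
  }
  func <- config$func_amplitude * func
  fm <- feature_map(g, array(c(geom, func), c(g$n_lat, g$n_lon, 2L)),
                    c("geometric", "functional"))
  attr(fm, "blob_centers") <- centers
  fm
}

local_maxima <- function(m) {
  H <- nrow(m); W <- ncol(m)
  up <- m[pmax(seq_len(H) - 1, 1), ]
  dn <- m[pmin(seq_len(H) + 1, H), ]
  res <- m >= up & m >= dn
  for (dj in c(-1L, 1L)) {
    sh <- m[, ((seq_len(W) - 1 + dj) %% W) + 1]
    res <- res & m >= sh & m >= up[, ((seq_len(W) - 1 + dj) %% W) + 1] &
      m >= dn[, ((seq_len(W) - 1 + dj) %% W) + 1]
  }
  res
}

#' Simulate one subject from the generative model
#'
#' Draws the joint and modality velocities, forms the latent joint image
#' `I_j = exp(v_j) o A + noise`, then the observations
#' `I_g = exp(v_g) o I_j[geom] + noise` and
#' `I_f = exp(v_f) o I_j[func] + noise` (two-stage additive Gaussian noise,
#' so with identity deformations the marginal variance around the atlas is
#' `2 sigma^2`).
#'
#' @param atlas the true atlas [feature_map()] (one geometric + one
#'   functional channel).
#' @param config a [generative_config()].
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @param v_j optional pre-drawn joint [velocity_field()] (used for
#'   antithetic cohort centering).
#' @param with_func simulate the functional observation (default TRUE).
#' @return an object of class `synthetic_subject`: feature maps `geom` and
#'   `func` (or `NULL`), true velocities `v_j`, `v_g`, `v_f`, and the true
#'   composed atlas-to-subject deformations `phi_geom`, `phi_func`.
#' @export
sample_subject <- function(atlas, config, seed = NULL, v_j = NULL,
                           with_func = TRUE) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- atlas$grid
  if (is.null(v_j)) {
    v_j <- smooth_velocity(g, config$joint_amplitude,
                           config$smoothness_scale)
  }
  v_g <- smooth_velocity(g, config$modality_amplitude,
                         config$smoothness_scale)
  v_f <- smooth_velocity(g, config$modality_amplitude,
                         config$smoothness_scale)
  phi_j <- integrate_svf(v_j)
  phi_g <- integrate_svf(v_g)
  phi_f <- integrate_svf(v_f)
  ij <- warp_feature_map(atlas, phi_j)
  ij$values <- ij$values +
    array(rnorm(length(ij$values), sd = config$sigma_noise), dim(ij$values))
  gsel <- which(ij$channel_roles == "geometric")
  fsel <- which(ij$channel_roles == "functional")
  ig <- warp_img_fwd(ij$values[, , gsel, drop = FALSE], phi_g$u)
  ig <- ig + array(rnorm(length(ig), sd = config$sigma_noise), dim(ig))
  geom_fm <- feature_map(g, ig, rep("geometric", length(gsel)))
  func_fm <- NULL
  if (with_func && length(fsel) > 0) {
    iff <- warp_img_fwd(ij$values[, , fsel, drop = FALSE], phi_f$u)
    iff <- iff + array(rnorm(length(iff), sd = config$sigma_noise), dim(iff))
    func_fm <- feature_map(g, iff, rep("functional", length(fsel)))
  }
  structure(
    list(geom = geom_fm, func = func_fm,
         v_j = v_j, v_g = v_g, v_f = v_f,
         phi_geom = compose_deformation(phi_j, phi_g),
         phi_func = compose_deformation(phi_j, phi_f)),
    class = "synthetic_subject")
}

#' Simulate a cohort with known ground truth
#'
#' Generates `n_subjects` independent subjects plus the true atlas. With
#' `centered = TRUE` joint velocities are drawn in antithetic `+v/-v` pairs so
#' the cohort-mean joint displacement is close to zero (the unbiased-atlas
#' regime); `func_fraction` controls how many subjects carry functional maps
#' (the semi-supervised regime).
#'
#' @param config a [generative_config()].
#' @return an object of class `synthetic_cohort`: `subjects` (list of
#'   [sample_subject()] results), `atlas` (true [feature_map()]), `grid`, and
#'   the `config`.
#' @export
make_cohort <- function(config) {
  stopifnot(inherits(config, "generative_config"))
  set.seed(as.integer(config$seed))
  atlas <- make_true_atlas(config)
  g <- atlas$grid
  n <- config$n_subjects
  n_func <- round(config$func_fraction * n)
  # joint velocities and per-subject sub-seeds are drawn up front so that a
  # subject's data depend only on its own stream; the functional observation
  # is the last draw of that stream, which keeps the geometric data
  # bit-identical whether or not functional maps are generated
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  vjs <- vector("list", n)
  for (i in seq_len(n)) {
    if (config$centered && i %% 2 == 0) {
      vjs[[i]] <- velocity_field(g, -vjs[[i - 1]]$v)
    } else {
      vjs[[i]] <- smooth_velocity(g, config$joint_amplitude,
                                  config$smoothness_scale)
    }
  }
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    subjects[[i]] <- sample_subject(atlas, config, seed = sub_seeds[i],
                                    v_j = vjs[[i]],
                                    with_func = i <= n_func)
  }
  structure(list(subjects = subjects, atlas = atlas, grid = g,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  nf <- sum(vapply(x$subjects, function(s) !is.null(s$func), logical(1)))
  cat(sprintf("<synthetic_cohort %d subjects (%d with functional maps), %dx%d grid>\n",
              length(x$subjects), nf, x$grid$n_lat, x$grid$n_lon))
  invisible(x)
}
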
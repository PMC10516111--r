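#' Registration network configuration
#'
#' An encoder-decoder (U-Net style) network maps standardized geometric
#' features to three stationary velocity fields: a joint field capturing the
#' large between-subject deformation and two small modality-specific fields
#' for geometry and function. Defaults follow the full-scale architecture
#' (5-layer encoder with 128/256/384/512/640 filters, symmetric decoder, two
#' final convolutions with 64/32 filters, 3x3 kernels, 2x2 max pooling,
#' leaky-rectifier activations); `scale_divisor` shrinks every filter count
#' for desk-scale experiments.
#'
#' @param encoder_filters filter counts of the encoder levels.
#' @param final_filters filter counts of the two full-resolution convolutions
#'   after the decoder.
#' @param scale_divisor divide all filter counts by this factor (rounded up).
#' @param leaky_slope negative-side slope of the leaky rectifier.
#' @param velocity_scale multiplier applied to the raw head outputs
#'   (velocities in grid cells).
#' @param n_steps scaling-and-squaring depth for the integration layers.
#' @param tied_fields if `TRUE` the functional head is tied to the geometric
#'   head (`v_f = v_g`), the single-field ablation.
#' @param atlas_init_sd standard deviation of the Gaussian atlas
#'   initialization (default 1, the scale of standardized features).
#' @return an object of class `network_config`.
#' @export
network_config <- function(encoder_filters = c(128L, 256L, 384L, 512L, 640L),
                           final_filters = c(64L, 32L),
                           scale_divisor = 1,
                           leaky_slope = 0.2,
                           velocity_scale = 1,
                           n_steps = 7L,
                           tied_fields = FALSE,
                           atlas_init_sd = 1) {
  stopifnot(all(encoder_filters > 0), all(final_filters > 0),
            scale_divisor >= 1)
  structure(
    list(
      encoder_filters = as.integer(ceiling(encoder_filters / scale_divisor)),
      decoder_filters = as.integer(ceiling(
        rev(encoder_filters[-length(encoder_filters)]) / scale_divisor)),
      final_filters = as.integer(ceiling(final_filters / scale_divisor)),
      leaky_slope = leaky_slope,
      velocity_scale = velocity_scale,
      n_steps = as.integer(n_steps),
      tied_fields = isTRUE(tied_fields),
      atlas_init_sd = atlas_init_sd
    ),
    class = "network_config"
  )
}

conv_init <- function(cin, cout, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / (9 * cin))
  list(w = array(rnorm(9 * cin * cout, sd = sd), c(3, 3, cin, cout)),
       b = numeric(cout))
}

#' Build a registration model
#'
#' Instantiates network weights and the learnable atlas. The atlas is
#' initialized from seeded Gaussian noise and is part of the trainable
#' parameter set unless frozen; velocity heads are initialized with
#' near-zero weights so an untrained model predicts fields close to the
#' identity.
#'
#' @param config a [network_config()].
#' @param grid a [make_grid()] object; both dimensions must be divisible by
#'   `2^(encoder depth - 1)` for the pooling pyramid.
#' @param n_geom_channels,n_func_channels channel counts of the atlas (and of
#'   the training data).
#' @param seed integer seed for weight and atlas initialization.
#' @return an object of class `registration_model` with fields `config`,
#'   `grid`, `params` (named list of conv weights), and `atlas`
#'   (`geometric`, `functional`, `frozen`).
#' @export
build_model <- function(config, grid, n_geom_channels = 1L,
                        n_func_channels = 1L, seed = 1L) {
  stopifnot(inherits(config, "network_config"),
            inherits(grid, "sphere_grid"))
  depth <- length(config$encoder_filters)
  div <- 2^(depth - 1)
  if (grid$n_lat %% div != 0 || grid$n_lon %% div != 0) {
    stop(sprintf("grid dimensions must be divisible by %d for a depth-%d encoder",
                 div, depth), call. = FALSE)
  }
  set.seed(as.integer(seed))
  ef <- config$encoder_filters
  df <- config$decoder_filters
  ff <- config$final_filters
  params <- list()
  cin <- n_geom_channels
  for (l in seq_len(depth)) {
    params[[paste0("enc", l)]] <- conv_init(cin, ef[l])
    cin <- ef[l]
  }
  for (l in seq_len(depth - 1)) {
    skip <- ef[depth - l]
    params[[paste0("dec", l)]] <- conv_init(cin + skip, df[l])
    cin <- df[l]
  }
  for (l in seq_along(ff)) {
    params[[paste0("fin", l)]] <- conv_init(cin, ff[l])
    cin <- ff[l]
  }
  for (h in c("head_j", "head_g", "head_f")) {
    params[[h]] <- conv_init(cin, 2L, sd = 1e-5)
  }
  atlas <- list(
    geometric = array(rnorm(grid$n_lat * grid$n_lon * n_geom_channels,
                            sd = config$atlas_init_sd),
                      c(grid$n_lat, grid$n_lon, n_geom_channels)),
    functional = array(rnorm(grid$n_lat * grid$n_lon * n_func_channels,
                             sd = config$atlas_init_sd),
                       c(grid$n_lat, grid$n_lon, n_func_channels)),
    frozen = FALSE
  )
  structure(
    list(config = config, grid = grid, params = params, atlas = atlas,
         n_geom_channels = as.integer(n_geom_channels),
         n_func_channels = as.integer(n_func_channels),
         seed = as.integer(seed)),
    class = "registration_model"
  )
}

#' @export
print.registration_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$w) + length(p$b),
                   numeric(1)))
  cat(sprintf(
    "<registration_model %dx%d grid, %d conv parameters, atlas %d+%d channels%s>\n",
    x$grid$n_lat, x$grid$n_lon, np, x$n_geom_channels, x$n_func_channels,
    if (x$atlas$frozen) " (frozen)" else ""))
  invisible(x)
}

# Forward pass on an autodiff tape. `param_nodes` is a named list mirroring
# model$params where each entry has tape nodes $w and $b. Returns the three
# velocity head outputs as [H, W, 2, N] nodes.
network_forward <- function(tape, param_nodes, config, x_node) {
  depth <- length(config$encoder_filters)
  sl <- config$leaky_slope
  skips <- vector("list", depth)
  x <- x_node
  for (l in seq_len(depth)) {
    p <- param_nodes[[paste0("enc", l)]]
    x <- ad_conv2d(tape, x, p$w, p$b, slope = sl)
    skips[[l]] <- x
    if (l < depth) x <- ad_maxpool2(tape, x)
  }
  for (l in seq_len(depth - 1)) {
    p <- param_nodes[[paste0("dec", l)]]
    x <- ad_upsample2(tape, x)
    x <- ad_concat_channels(tape, x, skips[[depth - l]])
    x <- ad_conv2d(tape, x, p$w, p$b, slope = sl)
  }
  for (l in seq_along(config$final_filters)) {
    p <- param_nodes[[paste0("fin", l)]]
    x <- ad_conv2d(tape, x, p$w, p$b, slope = sl)
  }
  head <- function(name) {
    p <- param_nodes[[name]]
    out <- ad_conv2d(tape, x, p$w, p$b)
    if (config$velocity_scale != 1) {
      out <- ad_scale(tape, out, config$velocity_scale)
    }
    out
  }
  v_j <- head("head_j")
  v_g <- head("head_g")
  v_f <- if (config$tied_fields) v_g else head("head_f")
  list(v_j = v_j, v_g = v_g, v_f = v_f)
}

# Wrap model parameters (and atlas, unless excluded) as tape leaves.
make_param_nodes <- function(tape, model, include_atlas = TRUE) {
  pn <- lapply(model$params, function(p) {
    list(w = ad_leaf(tape, p$w), b = ad_leaf(tape, p$b))
  })
  if (include_atlas) {
    pn$atlas_geom <- ad_leaf(tape, model$atlas$geometric)
    pn$atlas_func <- ad_leaf(tape, model$atlas$functional)
  }
  pn
}

#' Predict deformation fields for a subject
#'
#' Runs the network on a subject's geometric features only — functional
#' channels must not be present, enforcing the semi-supervised contract that
#' inference needs geometry alone — and integrates the three predicted
#' velocity fields. Input features are expected to be standardized (see
#' [standardize()]).
#'
#' @param model a [build_model()] object (trained or not).
#' @param geom a [feature_map()] carrying only geometric channels.
#' @return a list with velocity fields `v_j`, `v_g`, `v_f`, their integrated
#'   deformations `phi_j`, `phi_g`, `phi_f`, and the composed atlas-to-subject
#'   maps `phi_geom` (apply `phi_j` then `phi_g`) and `phi_func`.
#' @export
predict_fields <- function(model, geom) {
  stopifnot(inherits(model, "registration_model"),
            inherits(geom, "feature_map"))
  stop_grid_mismatch(model$grid, geom$grid)
  if (any(geom$channel_roles != "geometric")) {
    stop("functional channels must not enter the network; pass geometric channels only",
         call. = FALSE)
  }
  if (dim(geom$values)[3] != model$n_geom_channels) {
    stop("geometric channel count does not match the model", call. = FALSE)
  }
  tape <- ad_tape()
  pn <- make_param_nodes(tape, model, include_atlas = FALSE)
  x <- ad_const(tape, array(geom$values,
                            c(dim(geom$values)[1:2],
                              dim(geom$values)[3], 1L)))
  heads <- network_forward(tape, pn, model$config, x)
  g <- model$grid
  take <- function(node) {
    velocity_field(g, array(node$value[, , , 1], c(g$n_lat, g$n_lon, 2L)))
  }
  v_j <- take(heads$v_j)
  v_g <- take(heads$v_g)
  v_f <- take(heads$v_f)
  ns <- model$config$n_steps
  phi_j <- integrate_svf(v_j, ns)
  phi_g <- integrate_svf(v_g, ns)
  phi_f <- integrate_svf(v_f, ns)
  list(
    v_j = v_j, v_g = v_g, v_f = v_f,
    phi_j = phi_j, phi_g = phi_g, phi_f = phi_f,
    phi_geom = compose_deformation(phi_j, phi_g),
    phi_func = compose_deformation(phi_j, phi_f)
  )
}

#' Map a subject into atlas space
#'
#' Warps subject feature maps to the atlas using the inverse of the predicted
#' composed deformations (`exp(-v_g) o exp(-v_j)` for geometric channels,
#' `exp(-v_f) o exp(-v_j)` for functional channels). Only geometric features
#' drive the prediction; functional maps, if supplied, are carried along.
#'
#' @param model a [build_model()] object.
#' @param geom standardized geometric [feature_map()].
#' @param func optional functional [feature_map()] to warp with the
#'   functional inverse field.
#' @return a list with `geom` (warped geometric map), `func` (warped
#'   functional map or `NULL`), and the predicted `fields`.
#' @export
register_to_atlas <- function(model, geom, func = NULL) {
  fields <- predict_fields(model, geom)
  ns <- model$config$n_steps
  inv_g <- compose_deformation(invert_svf(fields$v_g, ns),
                               invert_svf(fields$v_j, ns))
  out_geom <- warp_feature_map(geom, inv_g)
  out_func <- NULL
  if (!is.null(func)) {
    inv_f <- compose_deformation(invert_svf(fields$v_f, ns),
                                 invert_svf(fields$v_j, ns))
    out_func <- warp_feature_map(func, inv_f)
  }
  list(geom = out_geom, func = out_func, fields = fields)
}

#' Extract the learned atlas as a feature map
#'
#' @param model a [build_model()] object.
#' @return a [feature_map()] with the atlas geometric and functional channels.
#' @export
atlas_feature_map <- function(model) {
  vals <- array(c(model$atlas$geometric, model$atlas$functional),
                c(model$grid$n_lat, model$grid$n_lon,
                  model$n_geom_channels + model$n_func_channels))
  feature_map(model$grid, vals,
              c(rep("geometric", model$n_geom_channels),
                rep("functional", model$n_func_channels)))
}

#' Save / load a model checkpoint
#'
#' Checkpoints hold weights, atlas and configuration.
#'
#' @param model a [build_model()] object.
#' @param path file path.
#' @return `load_model` returns the model; `save_model` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "registration_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "registration_model"))
  m
}
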
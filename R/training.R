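#' Training configuration
#'
#' Hyperparameters of the semi-supervised training loop. Defaults follow the
#' published schedule: batches of 8, Adam starting at 1e-3 decreasing linearly
#' to 1e-4 over the first 500 epochs, then multiplied by 0.9 whenever the
#' validation loss fails to improve for 100 consecutive epochs; augmentation
#' adds a random smooth warp (metric displacement sd 4 cells, distortion
#' corrected) and Gaussian noise (sd 1 on geometric, sd 6 on functional
#' channels, raw feature scale).
#'
#' @param epochs number of training epochs.
#' @param batch_size mini-batch size (default 8).
#' @param lr_init,lr_floor initial and end-of-linear-phase learning rates.
#' @param linear_phase_epochs length of the linear decay phase (default 500).
#' @param plateau_factor,plateau_patience post-linear-phase decay factor and
#'   patience in epochs.
#' @param warp_aug_sigma metric displacement sd (cells) of augmentation warps;
#'   0 disables.
#' @param aug_smoothness Gaussian blur sd of augmentation warps (cells).
#' @param noise_aug_geom,noise_aug_func augmentation noise sd per role.
#' @param val_fraction held-out fraction for the validation loss (default
#'   0.2); validation subjects are never augmented.
#' @param val_every evaluate the validation loss every this many epochs
#'   (default 1; the plateau counter advances per evaluation).
#' @param atlas_frozen if `TRUE` the atlas receives no gradient updates (the
#'   fixed-atlas ablation).
#' @param atlas_lr_mult learning-rate multiplier for the atlas parameters,
#'   which live on the data scale rather than the conv-weight scale
#'   (default 10).
#' @param grad_clip global L2-norm bound on the concatenated gradient per
#'   step (default 1); 0 or `Inf` disables clipping.
#' @param seed master seed controlling the split, batching, augmentation.
#' @param n_steps integration depth used inside the loss.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 8L,
                         lr_init = 1e-3, lr_floor = 1e-4,
                         linear_phase_epochs = 500L,
                         plateau_factor = 0.9, plateau_patience = 100L,
                         warp_aug_sigma = 4, aug_smoothness = 8,
                         noise_aug_geom = 1, noise_aug_func = 6,
                         val_fraction = 0.2, val_every = 1L,
                         atlas_frozen = FALSE, atlas_lr_mult = 10,
                         grad_clip = 1, seed = 1L, n_steps = 7L) {
  stopifnot(lr_floor > 0, lr_floor <= lr_init, plateau_patience >= 1,
            batch_size >= 1, epochs >= 1, val_fraction >= 0,
            val_fraction < 1)
  structure(as.list(environment()), class = "train_config")
}

#' Learning rate at a training state
#'
#' During the first `linear_phase_epochs` epochs the rate decays linearly from
#' `lr_init` to `lr_floor`; afterwards it is multiplied by `plateau_factor`
#' each time `plateau_patience` consecutive epochs pass without a validation
#' improvement.
#'
#' @param state a list with `epoch` (0-based) and `plateau_events` (count of
#'   plateau reductions so far, default 0).
#' @param config a [train_config()].
#' @return the learning rate.
#' @export
lr_at <- function(state, config) {
  e <- state$epoch
  stopifnot(e >= 0)
  pe <- if (is.null(state$plateau_events)) 0L else state$plateau_events
  L <- config$linear_phase_epochs
  if (e <= L) {
    config$lr_init + (config$lr_floor - config$lr_init) * e / L
  } else {
    config$lr_floor * config$plateau_factor^pe
  }
}

#' Augment a batch of subjects
#'
#' Each subject is warped by a random smooth deformation and perturbed with
#' additive Gaussian noise. The warp is identical for all channels of a
#' subject (geometric and functional move together); its latitude component
#' has displacement sd `warp_aug_sigma` cells while the longitude component is
#' drawn with the same metric sd and divided by `sin(theta)`, so the
#' on-sphere displacement magnitude is uniform across latitudes (distortion
#' correction of the augmentation). Noise sds differ per channel role and are
#' applied on the raw feature scale, before standardization.
#'
#' @param batch list of subjects (each a list with `geom` and optional
#'   `func` [feature_map()]s).
#' @param config a [train_config()].
#' @return the augmented batch.
#' @export
augment_batch <- function(batch, config) {
  lapply(batch, function(s) {
    g <- s$geom$grid
    if (config$warp_aug_sigma > 0) {
      u <- array(0, c(g$n_lat, g$n_lon, 2L))
      for (c in 1:2) {
        f <- gaussian_smooth_grid(matrix(rnorm(g$n_lat * g$n_lon), g$n_lat),
                                  config$aug_smoothness)
        u[, , c] <- f / sd(f) * config$warp_aug_sigma
      }
      # metric correction: the same on-sphere displacement spans 1/sin(theta)
      # more cells near the poles; capped at an eighth of the circumference
      # so polar-row warps stay meaningful
      u[, , 2] <- u[, , 2] / sin(g$theta)
      cap <- g$n_lon / 8
      u[, , 2] <- pmin(pmax(u[, , 2], -cap), cap)
      phi <- deformation_field(g, u)
      s$geom <- warp_feature_map(s$geom, phi)
      if (!is.null(s$func)) s$func <- warp_feature_map(s$func, phi)
    }
    if (config$noise_aug_geom > 0) {
      s$geom$values <- s$geom$values +
        array(rnorm(length(s$geom$values), sd = config$noise_aug_geom),
              dim(s$geom$values))
    }
    if (!is.null(s$func) && config$noise_aug_func > 0) {
      s$func$values <- s$func$values +
        array(rnorm(length(s$func$values), sd = config$noise_aug_func),
              dim(s$func$values))
    }
    s
  })
}

# Standardize a subject's maps (per subject, per channel, geometric and
# functional handled identically but separately).
standardize_subject <- function(s) {
  s$geom <- standardize(s$geom)
  if (!is.null(s$func)) s$func <- standardize(s$func)
  s
}

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    st <- state[[k]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[k]] <- params[[k]] - lr[[k]] * mhat / (sqrt(vhat) + eps)
    state[[k]] <- st
  }
  list(params = params, state = state)
}

flatten_params <- function(model, include_atlas) {
  out <- list()
  for (nm in names(model$params)) {
    out[[paste0(nm, ".w")]] <- model$params[[nm]]$w
    out[[paste0(nm, ".b")]] <- model$params[[nm]]$b
  }
  if (include_atlas) {
    out[["atlas.geometric"]] <- model$atlas$geometric
    out[["atlas.functional"]] <- model$atlas$functional
  }
  out
}

unflatten_params <- function(model, flat) {
  for (nm in names(model$params)) {
    model$params[[nm]]$w <- flat[[paste0(nm, ".w")]]
    model$params[[nm]]$b <- flat[[paste0(nm, ".b")]]
  }
  if (!is.null(flat[["atlas.geometric"]])) {
    model$atlas$geometric <- flat[["atlas.geometric"]]
    model$atlas$functional <- flat[["atlas.functional"]]
  }
  model
}

# Build the per-batch loss graph from the network forward pass and return the
# graph together with the parameter leaves (for gradient extraction).
batch_loss_graph <- function(model, batch, weights, wmat, n_steps,
                             train_atlas) {
  tape <- ad_tape()
  pn <- make_param_nodes(tape, model, include_atlas = TRUE)
  H <- model$grid$n_lat
  W <- model$grid$n_lon
  n <- length(batch)
  x <- array(0, c(H, W, model$n_geom_channels, n))
  for (i in seq_len(n)) x[, , , i] <- batch[[i]]$geom$values
  heads <- network_forward(tape, pn, model$config, ad_const(tape, x))
  v_list <- lapply(seq_len(n), function(i) {
    list(v_j = ad_sample_field(tape, heads$v_j, i),
         v_g = ad_sample_field(tape, heads$v_g, i),
         v_f = ad_sample_field(tape, heads$v_f, i))
  })
  geom_t <- lapply(batch, function(s) s$geom$values)
  func_t <- lapply(batch, function(s) if (is.null(s$func)) NULL
                   else s$func$values)
  atlas_g <- if (train_atlas) pn$atlas_geom else
    ad_const(tape, model$atlas$geometric)
  atlas_f <- if (train_atlas) pn$atlas_func else
    ad_const(tape, model$atlas$functional)
  gr <- build_loss_graph(tape, v_list, geom_t, func_t, atlas_g, atlas_f,
                         weights, wmat, n_steps)
  list(tape = tape, graph = gr, pn = pn,
       atlas_g = atlas_g, atlas_f = atlas_f)
}

#' Train a registration model on a cohort
#'
#' Semi-supervised optimization of the network weights and (unless frozen)
#' the atlas with Adam against [total_loss()]: subjects lacking functional
#' maps contribute only geometric terms; augmentation runs on the raw maps
#' and standardization follows it; the validation loss (no augmentation)
#' drives the plateau schedule and the retained best checkpoint.
#'
#' @param model a [build_model()] object.
#' @param cohort a [make_cohort()] result, or a list of subjects (each with
#'   `geom` and optional `func` feature maps).
#' @param config a [train_config()].
#' @param weights a [loss_weights()] object.
#' @param verbose print a line every `verbose` epochs (0 = silent).
#' @return a list with `model` (best-validation checkpoint), `final_model`,
#'   and `history` (one row per epoch: learning rate, every loss component,
#'   validation total).
#' @export
train_model <- function(model, cohort, config = train_config(),
                        weights = loss_weights(), verbose = 0L) {
  stopifnot(inherits(model, "registration_model"),
            inherits(config, "train_config"))
  subjects <- if (inherits(cohort, "synthetic_cohort")) cohort$subjects
              else cohort
  if (length(subjects) < config$batch_size) {
    stop("cohort smaller than batch size", call. = FALSE)
  }
  set.seed(as.integer(config$seed))
  n <- length(subjects)
  n_val <- floor(config$val_fraction * n)
  perm <- sample(n)
  val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
  train_idx <- setdiff(perm, val_idx)
  val_std <- lapply(subjects[val_idx], standardize_subject)
  wmat <- distortion_weights(model$grid)$w
  train_atlas <- !config$atlas_frozen && !model$atlas$frozen
  flat <- flatten_params(model, include_atlas = train_atlas)
  astate <- adam_init(flat)
  t_step <- 0L
  best_val <- Inf
  best_flat <- NULL
  since_improve <- 0L
  plateau_events <- 0L
  hist <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    lr <- lr_at(list(epoch = epoch - 1L, plateau_events = plateau_events),
                config)
    lrs <- lapply(names(flat), function(k) {
      if (startsWith(k, "atlas.")) lr * config$atlas_lr_mult else lr
    })
    names(lrs) <- names(flat)
    ord <- sample(train_idx)
    nb <- ceiling(length(ord) / config$batch_size)
    comp_sum <- NULL
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1) * config$batch_size + 1):
                   min(b * config$batch_size, length(ord))]
      batch <- augment_batch(subjects[idx], config)
      batch <- lapply(batch, standardize_subject)
      model <- unflatten_params(model, flat)
      bl <- batch_loss_graph(model, batch, weights, wmat, config$n_steps,
                             train_atlas)
      if (!is.finite(ad_value(bl$graph$total))) {
        stop(sprintf("non-finite training loss at epoch %d", epoch),
             call. = FALSE)
      }
      gr <- ad_backward(bl$tape, bl$graph$total)
      grads <- list()
      for (nm in names(model$params)) {
        grads[[paste0(nm, ".w")]] <- gr[[bl$pn[[nm]]$w$id]]
        grads[[paste0(nm, ".b")]] <- gr[[bl$pn[[nm]]$b$id]]
      }
      if (train_atlas) {
        grads[["atlas.geometric"]] <- gr[[bl$pn$atlas_geom$id]]
        grads[["atlas.functional"]] <- gr[[bl$pn$atlas_func$id]]
      }
      if (config$grad_clip > 0 && is.finite(config$grad_clip)) {
        gnorm <- sqrt(sum(vapply(grads, function(g)
          if (is.null(g)) 0 else sum(g^2), numeric(1))))
        if (gnorm > config$grad_clip) {
          grads <- lapply(grads, function(g)
            if (is.null(g)) NULL else g * (config$grad_clip / gnorm))
        }
      }
      t_step <- t_step + 1L
      upd <- adam_step(flat, grads, astate, lrs, t_step)
      flat <- upd$params
      astate <- upd$state
      rep <- graph_to_report(bl$graph)
      comp <- unlist(rep[setdiff(names(rep), "n_func_observed")])
      comp_sum <- if (is.null(comp_sum)) comp else comp_sum + comp
    }
    comp_mean <- comp_sum / nb
    model <- unflatten_params(model, flat)
    val_total <- NA_real_
    if (length(val_std) > 0 &&
        (epoch %% config$val_every == 0 || epoch == config$epochs)) {
      vl <- batch_loss_graph(model, val_std, weights, wmat, config$n_steps,
                             train_atlas = FALSE)
      val_total <- ad_value(vl$graph$total)
      if (val_total < best_val - 1e-12) {
        best_val <- val_total
        best_flat <- flat
        since_improve <- 0L
      } else {
        since_improve <- since_improve + as.integer(config$val_every)
        if (epoch > config$linear_phase_epochs &&
            since_improve >= config$plateau_patience) {
          plateau_events <- plateau_events + 1L
          since_improve <- 0L
        }
      }
    }
    hist[[epoch]] <- c(epoch = epoch, lr = lr, comp_mean,
                       val_total = val_total)
    if (verbose > 0 && epoch %% verbose == 0) {
      message(sprintf("epoch %4d  lr %.2e  total %.5f  val %.5f",
                      epoch, lr, comp_mean[["total"]], val_total))
    }
  }
  history <- as.data.frame(do.call(rbind, hist))
  best_model <- unflatten_params(model, if (!is.null(best_flat)) best_flat
                                 else flat)
  list(model = best_model, final_model = model, history = history,
       best_val = best_val, config = config, weights = weights)
}
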
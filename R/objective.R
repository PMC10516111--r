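#' Loss weights for the registration objective
#'
#' The training objective is the negative log posterior of the generative
#' model: distortion-weighted mean-squared similarity terms (the Gaussian
#' likelihood with its variance absorbed into the modality weights), smoothness
#' priors on the three displacement fields, and a centrality prior on the
#' batch-mean joint displacement that keeps the learned atlas unbiased.
#'
#' @param lambda_j smoothness weight of the joint (large) deformation
#'   (default 0.1).
#' @param lambda_g,lambda_f smoothness weights of the modality-specific
#'   (small) deformations (default 0.2).
#' @param alpha_j centrality weight on the mean displacements (default 1).
#'   With a learnable atlas every field's cohort-mean displacement is a flat
#'   (gauge) direction of the likelihood; `alpha_j` must be large enough to
#'   damp those modes within the training budget. Sensitivity runs showed
#'   0.01 leaves ~1-cell residual global offsets at desk scale while 0.1-1
#'   remove them without affecting the similarity terms.
#' @param w_func,w_geom relative weights of the functional and geometric
#'   similarity terms; must sum to 1 (default 0.7 / 0.3).
#' @return an object of class `loss_weights`.
#' @export
loss_weights <- function(lambda_j = 0.1, lambda_g = 0.2, lambda_f = 0.2,
                         alpha_j = 1, w_func = 0.7, w_geom = 0.3) {
  stopifnot(lambda_j >= 0, lambda_g >= 0, lambda_f >= 0, alpha_j >= 0,
            w_func >= 0, w_geom >= 0)
  if (abs(w_func + w_geom - 1) > 1e-12) {
    stop("w_func + w_geom must equal 1", call. = FALSE)
  }
  structure(list(lambda_j = lambda_j, lambda_g = lambda_g,
                 lambda_f = lambda_f, alpha_j = alpha_j,
                 w_func = w_func, w_geom = w_geom),
            class = "loss_weights")
}

as_weight_matrix <- function(w) {
  if (inherits(w, "weight_map")) w$w else as.matrix(w)
}

#' Smoothness penalty of a displacement field
#'
#' `lam` times the distortion-weighted mean of squared forward-difference
#' gradients of both displacement components (differences wrap in longitude
#' and are one-sided at the latitude edges). Rigid translations along the
#' periodic longitude axis are unpenalized.
#'
#' @param u a [deformation_field()], [velocity_field()], or a raw
#'   `n_lat x n_lon x 2` displacement array.
#' @param lam nonnegative weight.
#' @param w a [distortion_weights()] map (or plain matrix).
#' @return a scalar penalty.
#' @export
smoothness_penalty <- function(u, lam, w) {
  uu <- if (inherits(u, "deformation_field")) u$u
        else if (inherits(u, "velocity_field")) u$v else u
  stopifnot(all(is.finite(uu)))
  lam * grad_penalty_fwd(uu, as_weight_matrix(w))$val
}

#' Centrality penalty on a batch of displacement fields
#'
#' `alpha` times the mean square of the across-batch average displacement
#' `u_bar = (1/n) sum_i u_i`. Penalizing the mean rather than each field
#' drives the learned atlas toward the deformation barycenter of the cohort.
#'
#' @param batch_displacements nonempty list of displacement arrays or
#'   [deformation_field()] objects.
#' @param alpha nonnegative weight.
#' @return a scalar penalty.
#' @export
centrality_penalty <- function(batch_displacements, alpha) {
  if (length(batch_displacements) == 0) {
    stop("empty batch", call. = FALSE)
  }
  us <- lapply(batch_displacements, function(u) {
    if (inherits(u, "deformation_field")) u$u
    else if (inherits(u, "velocity_field")) u$v else u
  })
  ubar <- Reduce(`+`, us) / length(us)
  alpha * mean(ubar^2)
}

#' Distortion-weighted similarity loss between two feature maps
#'
#' Weighted mean squared error over valid cells, averaged over channels; the
#' data-fidelity term implied by the Gaussian observation model.
#'
#' @param observed,model_image [feature_map()] objects on the same grid with
#'   matching channels.
#' @param w a [distortion_weights()] map.
#' @return a scalar loss.
#' @export
similarity_loss <- function(observed, model_image, w) {
  stopifnot(inherits(observed, "feature_map"),
            inherits(model_image, "feature_map"))
  stop_grid_mismatch(observed$grid, model_image$grid)
  wm <- as_weight_matrix(w)
  valid <- observed$valid_mask & model_image$valid_mask
  if (!any(valid)) stop("no valid channels to compare", call. = FALSE)
  tot <- 0
  for (c in which(valid)) {
    d2 <- (observed$values[, , c] - model_image$values[, , c])^2
    tot <- tot + sum(wm * d2) / sum(wm)
  }
  tot / sum(valid)
}

# ---------------------------------------------------------------------------
# Shared loss-graph builder: used verbatim by the numeric total_loss() API and
# by the training loop (where velocities come from the network heads).
#
# v_list:  per subject, list(v_j, v_g, v_f) as [H, W, 2] tape nodes
# geom_t:  per subject, [H, W, Cg] target array (standardized)
# func_t:  per subject, [H, W, Cf] target array or NULL (unobserved)
# ---------------------------------------------------------------------------
build_loss_graph <- function(tape, v_list, geom_t, func_t,
                             atlas_g, atlas_f, weights, wmat, n_steps) {
  n <- length(v_list)
  stopifnot(n >= 1)
  sgs <- sga <- vector("list", n)
  sfs <- sfa <- list()
  gp_j <- gp_g <- gp_f <- vector("list", n)
  uj_nodes <- ug_nodes <- uf_nodes <- vector("list", n)
  for (i in seq_len(n)) {
    v <- v_list[[i]]
    u_j <- ad_svf_exp(tape, v$v_j, n_steps)
    u_g <- ad_svf_exp(tape, v$v_g, n_steps)
    u_f <- ad_svf_exp(tape, v$v_f, n_steps)
    u_j_inv <- ad_svf_exp(tape, ad_scale(tape, v$v_j, -1), n_steps)
    u_g_inv <- ad_svf_exp(tape, ad_scale(tape, v$v_g, -1), n_steps)
    uj_nodes[[i]] <- u_j
    ug_nodes[[i]] <- u_g
    uf_nodes[[i]] <- u_f
    gp_j[[i]] <- ad_grad_penalty(tape, u_j, wmat)
    gp_g[[i]] <- ad_grad_penalty(tape, u_g, wmat)
    gp_f[[i]] <- ad_grad_penalty(tape, u_f, wmat)

    ig <- ad_const(tape, geom_t[[i]])
    comp_g <- ad_compose_disp(tape, u_j, u_g)
    inv_comp_g <- ad_compose_disp(tape, u_g_inv, u_j_inv)
    sgs[[i]] <- ad_weighted_mse(tape, ad_warp(tape, atlas_g, comp_g), ig, wmat)
    sga[[i]] <- ad_weighted_mse(tape, ad_warp(tape, ig, inv_comp_g),
                                atlas_g, wmat)

    if (!is.null(func_t[[i]])) {
      u_f_inv <- ad_svf_exp(tape, ad_scale(tape, v$v_f, -1), n_steps)
      iff <- ad_const(tape, func_t[[i]])
      comp_f <- ad_compose_disp(tape, u_j, u_f)
      inv_comp_f <- ad_compose_disp(tape, u_f_inv, u_j_inv)
      sfs[[length(sfs) + 1L]] <-
        ad_weighted_mse(tape, ad_warp(tape, atlas_f, comp_f), iff, wmat)
      sfa[[length(sfa) + 1L]] <-
        ad_weighted_mse(tape, ad_warp(tape, iff, inv_comp_f), atlas_f, wmat)
    }
  }
  nf <- length(sfs)
  mean_node <- function(nodes) {
    ad_lincomb(tape, nodes, rep(1 / length(nodes), length(nodes)))
  }
  sim_geom_subject <- mean_node(sgs)
  sim_geom_atlas <- mean_node(sga)
  sim_func_subject <- if (nf > 0) mean_node(sfs) else ad_const(tape, 0)
  sim_func_atlas <- if (nf > 0) mean_node(sfa) else ad_const(tape, 0)
  smooth_j <- ad_lincomb(tape, gp_j, rep(weights$lambda_j / n, n))
  smooth_g <- ad_lincomb(tape, gp_g, rep(weights$lambda_g / n, n))
  smooth_f <- ad_lincomb(tape, gp_f, rep(weights$lambda_f / n, n))
  # centrality on each field's batch-mean displacement: all three fields
  # carry a translational gauge freedom against the learnable atlas, so an
  # unbiased atlas requires every cohort-mean displacement to vanish
  cpen <- function(nodes) {
    ubar <- ad_lincomb_arrays(tape, nodes, rep(1 / n, n))
    ad_scale(tape, ad_mean_sq(tape, ubar), weights$alpha_j)
  }
  central_j <- cpen(uj_nodes)
  central_g <- cpen(ug_nodes)
  central_f <- cpen(uf_nodes)
  total <- ad_lincomb(
    tape,
    list(sim_geom_atlas, sim_geom_subject, sim_func_atlas, sim_func_subject,
         smooth_j, smooth_g, smooth_f, central_j, central_g, central_f),
    c(weights$w_geom / 2, weights$w_geom / 2,
      weights$w_func / 2, weights$w_func / 2, 1, 1, 1, 1, 1, 1))
  list(total = total,
       sim_geom_atlas = sim_geom_atlas, sim_geom_subject = sim_geom_subject,
       sim_func_atlas = sim_func_atlas, sim_func_subject = sim_func_subject,
       smooth_j = smooth_j, smooth_g = smooth_g, smooth_f = smooth_f,
       central_j = central_j, central_g = central_g, central_f = central_f,
       n_func_observed = nf)
}

graph_to_report <- function(gr) {
  structure(
    list(total = ad_value(gr$total),
         sim_geom_atlas = ad_value(gr$sim_geom_atlas),
         sim_geom_subject = ad_value(gr$sim_geom_subject),
         sim_func_atlas = ad_value(gr$sim_func_atlas),
         sim_func_subject = ad_value(gr$sim_func_subject),
         smooth_j = ad_value(gr$smooth_j),
         smooth_g = ad_value(gr$smooth_g),
         smooth_f = ad_value(gr$smooth_f),
         central_j = ad_value(gr$central_j),
         central_g = ad_value(gr$central_g),
         central_f = ad_value(gr$central_f),
         n_func_observed = gr$n_func_observed),
    class = "loss_report")
}

#' @export
print.loss_report <- function(x, ...) {
  cat(sprintf(
    paste0("<loss_report total=%.5g | geom %0.4g/%0.4g func %0.4g/%0.4g ",
           "(atlas/subject) | smooth %0.3g/%0.3g/%0.3g central %0.3g | ",
           "%d functional subjects>\n"),
    x$total, x$sim_geom_atlas, x$sim_geom_subject, x$sim_func_atlas,
    x$sim_func_subject, x$smooth_j, x$smooth_g, x$smooth_f, x$central_j,
    x$n_func_observed))
  invisible(x)
}

#' Full training objective for a batch of subjects
#'
#' Evaluates the complete negative-log-posterior loss:
#' `w_geom * (L_geom^atlas + L_geom^subject) / 2 +
#'  w_func * (L_func^atlas + L_func^subject) / 2 + smoothness + centrality`.
#' Subject-space terms warp the atlas by the composed forward fields (joint
#' then modality-specific) and compare with the subject; atlas-space terms
#' warp the subject by the inverse composed fields and compare with the atlas
#' — evaluating both spaces prevents atlas drift. Functional terms average
#' only over subjects with observed functional data; with none, they are 0.
#'
#' @param subjects list of subjects, each a list with `geom` (a
#'   [feature_map()]) and optionally `func` (a functional [feature_map()] or
#'   `NULL`).
#' @param fields list (one per subject) with velocity fields `v_j`, `v_g`,
#'   `v_f` (e.g. from [predict_fields()]).
#' @param atlas a [feature_map()] with geometric and functional channels, a
#'   [build_model()] object, or a list with `geometric` / `functional` arrays.
#' @param weights a [loss_weights()] object.
#' @param w a [distortion_weights()] map.
#' @param n_steps integration depth.
#' @return a `loss_report`: total plus every component and the count of
#'   subjects contributing functional terms.
#' @export
total_loss <- function(subjects, fields, atlas, weights = loss_weights(),
                       w = NULL, n_steps = 7L) {
  stopifnot(length(subjects) == length(fields), length(subjects) >= 1)
  g <- subjects[[1]]$geom$grid
  if (is.null(w)) w <- distortion_weights(g)
  wmat <- as_weight_matrix(w)
  at <- split_atlas(atlas)
  tape <- ad_tape()
  v_list <- lapply(fields, function(f) {
    list(v_j = ad_const(tape, f$v_j$v),
         v_g = ad_const(tape, f$v_g$v),
         v_f = ad_const(tape, f$v_f$v))
  })
  geom_t <- lapply(subjects, function(s) s$geom$values)
  func_t <- lapply(subjects, function(s) {
    if (is.null(s$func) || !any(s$func$valid_mask)) NULL else s$func$values
  })
  gr <- build_loss_graph(tape, v_list, geom_t, func_t,
                         ad_const(tape, at$geometric),
                         ad_const(tape, at$functional),
                         weights, wmat, n_steps)
  graph_to_report(gr)
}

split_atlas <- function(atlas) {
  if (inherits(atlas, "registration_model")) {
    return(list(geometric = atlas$atlas$geometric,
                functional = atlas$atlas$functional))
  }
  if (inherits(atlas, "feature_map")) {
    gsel <- atlas$channel_roles == "geometric"
    return(list(geometric = atlas$values[, , gsel, drop = FALSE],
                functional = atlas$values[, , !gsel, drop = FALSE]))
  }
  stopifnot(is.list(atlas), !is.null(atlas$geometric),
            !is.null(atlas$functional))
  atlas
}
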
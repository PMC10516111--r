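#' Per-subject correlation to the group mean map
#'
#' For each subject `k`, the Pearson correlation between the subject's map and
#' the across-subject mean map (subject `k` included, matching the
#' registration-accuracy metric `corr(I_k, 1/N sum_k I_k)`). Area-distortion
#' weights enter as frequency weights on every spatial moment. Subjects whose
#' weighted variance vanishes (constant maps, or a degenerate mean) yield
#' `NA` with a warning rather than a silent zero.
#'
#' @param images list of [feature_map()] objects (or plain matrices) on a
#'   common grid; at least two.
#' @param channel channel index to evaluate.
#' @param w optional [distortion_weights()]; defaults to the grid's weights.
#' @return named numeric vector of correlations, one per subject.
#' @export
corr_to_group_mean <- function(images, channel = 1L, w = NULL) {
  stopifnot(length(images) >= 2)
  mats <- lapply(images, function(im) {
    if (inherits(im, "feature_map")) im$values[, , channel] else as.matrix(im)
  })
  d <- dim(mats[[1]])
  if (is.null(w)) {
    if (inherits(images[[1]], "feature_map")) {
      w <- distortion_weights(images[[1]]$grid)
    } else {
      w <- matrix(1, d[1], d[2])
    }
  }
  wm <- as_weight_matrix(w)
  gmean <- Reduce(`+`, mats) / length(mats)
  out <- vapply(mats, function(m) weighted_pearson(m, gmean, wm), numeric(1))
  names(out) <- if (!is.null(names(images))) names(images)
                else paste0("subject", seq_along(images))
  if (anyNA(out)) {
    warning("undefined correlation for constant map(s); returned NA",
            call. = FALSE)
  }
  out
}

weighted_pearson <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  vx <- sum(w * (x - mx)^2) / sw
  vy <- sum(w * (y - my)^2) / sw
  if (vx <= 1e-24 || vy <= 1e-24) return(NA_real_)
  sum(w * (x - mx) * (y - my)) / sw / sqrt(vx * vy)
}

#' Per-subject correlation improvement
#'
#' `Delta_k = after_k - before_k` for aligned subject lists; the pairwise
#' improvement over the initial (rigid) alignment. Inputs must be named
#' consistently so that accidental reordering is caught.
#'
#' @param after,before numeric vectors of per-subject correlations with
#'   matching names and length.
#' @return named vector of differences.
#' @export
pairwise_improvement <- function(after, before) {
  if (length(after) != length(before)) {
    stop("subject lists differ in length", call. = FALSE)
  }
  if (!is.null(names(after)) && !is.null(names(before)) &&
      !identical(names(after), names(before))) {
    stop("subject order mismatch between 'after' and 'before'",
         call. = FALSE)
  }
  after - before
}

#' One-tailed Wilcoxon signed-rank test for paired improvements
#'
#' Tests whether paired samples `a` exceed `b` (alternative: a > b). The
#' exact signed-rank null distribution is used for n <= 25 without ties; a
#' normal approximation with tie correction and continuity correction
#' otherwise. Zero differences are dropped.
#'
#' @param deltas_a,deltas_b paired numeric vectors, length >= 5.
#' @return the one-tailed p-value.
#' @export
signed_rank_onetailed <- function(deltas_a, deltas_b) {
  stopifnot(length(deltas_a) == length(deltas_b))
  d <- deltas_a - deltas_b
  d <- d[d != 0]
  if (length(d) == 0) stop("all paired differences are zero", call. = FALSE)
  n <- length(d)
  if (n < 5) stop("need at least 5 non-zero paired differences",
                  call. = FALSE)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25 && !ties) {
    # P(W >= observed) under the exact null
    psignrank(W - 1, n, lower.tail = FALSE)
  } else {
    tab <- table(r)
    tiecorr <- sum(tab^3 - tab) / 48
    mu <- n * (n + 1) / 4
    sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tiecorr)
    pnorm((W - 0.5 - mu) / sig, lower.tail = FALSE)
  }
}

#' Endpoint error between recovered and true deformations
#'
#' Distortion-weighted mean Euclidean distance, in grid cells, between the
#' predicted and true composed maps `phi(x) = x + u(x)` at every grid point.
#' The longitude component is compared modulo the grid width (shortest way
#' around the sphere).
#'
#' @param predicted,true [deformation_field()] objects on the same grid.
#' @param w optional [distortion_weights()].
#' @return mean endpoint error (cells).
#' @export
deformation_recovery_error <- function(predicted, true, w = NULL) {
  stopifnot(inherits(predicted, "deformation_field"),
            inherits(true, "deformation_field"))
  stop_grid_mismatch(predicted$grid, true$grid)
  if (is.null(w)) w <- distortion_weights(predicted$grid)
  wm <- as_weight_matrix(w)
  W <- predicted$grid$n_lon
  dlat <- predicted$u[, , 1] - true$u[, , 1]
  dlon <- (predicted$u[, , 2] - true$u[, , 2] + W / 2) %% W - W / 2
  sum(wm * sqrt(dlat^2 + dlon^2)) / sum(wm)
}

#' Evaluate a trained model on a cohort
#'
#' Registers every subject to atlas space (geometry-only inference), then
#' reports per-subject correlations to the group mean before and after
#' registration (geometric and, where observed, functional channels), the
#' pairwise improvements, the mean negative-Jacobian percentage of the
#' composed forward fields and, when the cohort carries synthetic ground
#' truth, the deformation recovery errors.
#'
#' @param model a trained [build_model()] object.
#' @param cohort a [make_cohort()] result or list of subjects.
#' @return an `evaluation_report` list.
#' @export
evaluate_cohort <- function(model, cohort) {
  subjects <- if (inherits(cohort, "synthetic_cohort")) cohort$subjects
              else cohort
  n <- length(subjects)
  w <- distortion_weights(model$grid)
  before_g <- vector("list", n)
  after_g <- vector("list", n)
  before_f <- list()
  after_f <- list()
  negjac <- numeric(0)
  rec_g <- rec_f <- numeric(0)
  for (i in seq_len(n)) {
    s <- standardize_subject(subjects[[i]])
    reg <- register_to_atlas(model, s$geom, s$func)
    before_g[[i]] <- s$geom$values[, , 1]
    after_g[[i]] <- reg$geom$values[, , 1]
    if (!is.null(s$func)) {
      before_f[[length(before_f) + 1L]] <- s$func$values[, , 1]
      after_f[[length(after_f) + 1L]] <- reg$func$values[, , 1]
    }
    negjac <- c(negjac,
                negative_jacobian_fraction(reg$fields$phi_geom),
                negative_jacobian_fraction(reg$fields$phi_func))
    if (!is.null(subjects[[i]]$phi_geom)) {
      rec_g <- c(rec_g, deformation_recovery_error(reg$fields$phi_geom,
                                                   subjects[[i]]$phi_geom, w))
      rec_f <- c(rec_f, deformation_recovery_error(reg$fields$phi_func,
                                                   subjects[[i]]$phi_func, w))
    }
  }
  corr <- function(maps) if (length(maps) >= 2)
    corr_to_group_mean(maps, w = w) else NULL
  cb_g <- corr(before_g)
  ca_g <- corr(after_g)
  cb_f <- corr(before_f)
  ca_f <- corr(after_f)
  structure(list(
    corr_geom_before = cb_g, corr_geom_after = ca_g,
    corr_func_before = cb_f, corr_func_after = ca_f,
    improvement_geom = if (!is.null(ca_g)) pairwise_improvement(ca_g, cb_g),
    improvement_func = if (!is.null(ca_f)) pairwise_improvement(ca_f, cb_f),
    neg_jacobian_pct = mean(negjac),
    recovery_error_geom = if (length(rec_g)) mean(rec_g),
    recovery_error_func = if (length(rec_f)) mean(rec_f)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  if (!is.null(x$improvement_geom)) {
    cat(sprintf("  geometric correlation: %.3f -> %.3f (mean improvement %+.3f)\n",
                mean(x$corr_geom_before), mean(x$corr_geom_after),
                mean(x$improvement_geom)))
  }
  if (!is.null(x$improvement_func)) {
    cat(sprintf("  functional correlation: %.3f -> %.3f (mean improvement %+.3f)\n",
                mean(x$corr_func_before), mean(x$corr_func_after),
                mean(x$improvement_func)))
  }
  cat(sprintf("  negative Jacobians: %.4f%% of locations\n",
              x$neg_jacobian_pct))
  if (!is.null(x$recovery_error_geom)) {
    cat(sprintf("  recovery error (cells): geom %.3f, func %.3f\n",
                x$recovery_error_geom, x$recovery_error_func))
  }
  invisible(x)
}
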
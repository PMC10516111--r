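#' Stationary velocity field on the parameterized grid
#'
#' Velocities (and displacements) are expressed in grid-cell units: channel 1
#' moves along the latitude axis (rows), channel 2 along the periodic
#' longitude axis (columns).
#'
#' @param grid a [make_grid()] object.
#' @param v numeric array `n_lat x n_lon x 2`.
#' @return an object of class `velocity_field`.
#' @export
velocity_field <- function(grid, v) {
  stopifnot(inherits(grid, "sphere_grid"))
  d <- dim(v)
  if (length(d) != 3L || d[1] != grid$n_lat || d[2] != grid$n_lon ||
      d[3] != 2L) {
    stop("v must be n_lat x n_lon x 2", call. = FALSE)
  }
  if (!all(is.finite(v))) stop("non-finite velocity", call. = FALSE)
  structure(list(grid = grid, v = v), class = "velocity_field")
}

#' Dense deformation field phi = Id + u
#'
#' @param grid a [make_grid()] object.
#' @param u displacement array `n_lat x n_lon x 2` in grid cells.
#' @return an object of class `deformation_field`.
#' @export
deformation_field <- function(grid, u) {
  stopifnot(inherits(grid, "sphere_grid"))
  d <- dim(u)
  if (length(d) != 3L || d[1] != grid$n_lat || d[2] != grid$n_lon ||
      d[3] != 2L) {
    stop("u must be n_lat x n_lon x 2", call. = FALSE)
  }
  if (!all(is.finite(u))) stop("non-finite displacement", call. = FALSE)
  structure(list(grid = grid, u = u), class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf("<deformation_field %d x %d, mean |u| = %.4f cells>\n",
              x$grid$n_lat, x$grid$n_lon,
              mean(sqrt(x$u[, , 1]^2 + x$u[, , 2]^2))))
  invisible(x)
}

#' Exponentiate a stationary velocity field (scaling and squaring)
#'
#' Computes the flow `exp(v)` of a stationary velocity field as a dense
#' deformation: the velocity is scaled by `2^-n_steps` and the resulting
#' small deformation is self-composed `n_steps` times. For smooth fields this
#' yields a diffeomorphic (fold-free) map.
#'
#' @param v a [velocity_field()].
#' @param n_steps number of squaring steps (default 7).
#' @return a [deformation_field()].
#' @export
integrate_svf <- function(v, n_steps = 7L) {
  stopifnot(inherits(v, "velocity_field"))
  if (length(n_steps) != 1L || n_steps < 1L || n_steps != round(n_steps)) {
    stop("n_steps must be a positive integer", call. = FALSE)
  }
  u <- v$v / 2^n_steps
  for (s in seq_len(n_steps)) {
    u <- u + warp_img_fwd(u, u)
  }
  deformation_field(v$grid, u)
}

#' Inverse deformation of a stationary velocity field
#'
#' Returns `exp(-v)`, the group inverse of [integrate_svf()]; used to map
#' subject data into atlas space at inference time.
#'
#' @inheritParams integrate_svf
#' @return a [deformation_field()].
#' @export
invert_svf <- function(v, n_steps = 7L) {
  stopifnot(inherits(v, "velocity_field"))
  integrate_svf(velocity_field(v$grid, -v$v), n_steps)
}

#' Compose two deformation fields
#'
#' `compose_deformation(outer, inner)` returns the map
#' `x -> outer(inner(x))`; displacements are resampled with wrap-aware
#' bilinear interpolation (periodic longitude, clamped latitude).
#'
#' @param phi_outer,phi_inner [deformation_field()] objects on the same grid.
#' @return a [deformation_field()].
#' @export
compose_deformation <- function(phi_outer, phi_inner) {
  stopifnot(inherits(phi_outer, "deformation_field"),
            inherits(phi_inner, "deformation_field"))
  stop_grid_mismatch(phi_outer$grid, phi_inner$grid)
  u <- phi_inner$u + warp_img_fwd(phi_outer$u, phi_inner$u)
  deformation_field(phi_outer$grid, u)
}

#' Warp a feature map by a deformation field
#'
#' `warp_feature_map(fm, phi)(x) = fm(phi(x))` by bilinear interpolation with
#' longitude wrap and latitude clamp. Two successive warps, first by `phi_a`
#' then by `phi_b`, equal a single warp by
#' `compose_deformation(phi_a, phi_b)`. Channel roles and validity masks are
#' propagated.
#'
#' @param fm a [feature_map()].
#' @param phi a [deformation_field()] on the same grid.
#' @return a warped [feature_map()].
#' @export
warp_feature_map <- function(fm, phi) {
  stopifnot(inherits(fm, "feature_map"),
            inherits(phi, "deformation_field"))
  stop_grid_mismatch(fm$grid, phi$grid)
  vals <- fm$values
  for (c in seq_len(dim(vals)[3])) {
    if (!fm$valid_mask[c]) next
    vals[, , c] <- warp_img_fwd(fm$values[, , c, drop = FALSE], phi$u)
  }
  feature_map(fm$grid, vals, fm$channel_roles, fm$valid_mask)
}

#' Jacobian determinant map of a deformation
#'
#' Determinant of the 2x2 central-difference Jacobian of `x -> x + u(x)`
#' (one-sided differences at the latitude edges, wrapped in longitude). The
#' identity map has determinant 1 everywhere; non-positive values mark folds.
#'
#' @param phi a [deformation_field()].
#' @return an `n_lat x n_lon` matrix of determinants.
#' @export
jacobian_determinant <- function(phi) {
  stopifnot(inherits(phi, "deformation_field"))
  jacobian_det_cpp(phi$u)
}

#' Percentage of folded grid locations
#'
#' `100 * #\{det <= 0\} / (n_lat * n_lon)`, the standard regularity metric for
#' registration deformations.
#'
#' @param phi a [deformation_field()].
#' @return a percentage in `[0, 100]`.
#' @export
negative_jacobian_fraction <- function(phi) {
  d <- jacobian_determinant(phi)
  100 * mean(d <= 0)
}
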
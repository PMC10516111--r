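#' Cell-centered latitude-longitude grid on the unit sphere
#'
#' Builds the 2D parameterization domain used throughout the package. Rows are
#' latitude (elevation theta measured from the north pole), columns are
#' longitude (azimuth phi). Cells are centered so that no row sits exactly at a
#' pole: `theta_i = pi * (i + 0.5) / n_lat`, `phi_j = 2 * pi * j / n_lon`.
#' The longitude axis is periodic (column `n_lon` is adjacent to column 1).
#'
#' @param n_lat number of latitude rows (>= 4).
#' @param n_lon number of longitude columns (>= 4).
#' @return an object of class `sphere_grid` with fields `n_lat`, `n_lon`,
#'   `theta` (radians, strictly increasing inside (0, pi)) and `phi`
#'   (radians in `[0, 2*pi)`).
#' @export
#' @examples
#' g <- make_grid(64, 128)
#' range(g$theta)
make_grid <- function(n_lat, n_lon) {
  if (length(n_lat) != 1L || length(n_lon) != 1L ||
      !is.finite(n_lat) || !is.finite(n_lon) ||
      n_lat != round(n_lat) || n_lon != round(n_lon)) {
    stop("n_lat and n_lon must be single integers", call. = FALSE)
  }
  if (n_lat < 4 || n_lon < 4) {
    stop("grid too small: need n_lat >= 4 and n_lon >= 4", call. = FALSE)
  }
  n_lat <- as.integer(n_lat)
  n_lon <- as.integer(n_lon)
  structure(
    list(
      n_lat = n_lat,
      n_lon = n_lon,
      theta = pi * (seq_len(n_lat) - 0.5) / n_lat,
      phi = 2 * pi * (seq_len(n_lon) - 1) / n_lon
    ),
    class = "sphere_grid"
  )
}

#' @export
print.sphere_grid <- function(x, ...) {
  cat(sprintf("<sphere_grid %d x %d (lat x lon), cell-centered>\n",
              x$n_lat, x$n_lon))
  invisible(x)
}

same_grid <- function(a, b) {
  a$n_lat == b$n_lat && a$n_lon == b$n_lon
}

stop_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b)) stop("grid mismatch", call. = FALSE)
  invisible(NULL)
}

#' Area-distortion weights for a latitude-longitude grid
#'
#' The equiangular parameterization oversamples high latitudes; a cell at
#' elevation theta covers an area proportional to sin(theta). These weights,
#' `w(i, j) = sin(theta_i) / max_k sin(theta_k)`, correct that distortion and
#' multiply every spatial average in the losses and evaluation metrics.
#' Weights are constant along rows and the maximum entry is 1.
#'
#' @param grid a [make_grid()] object.
#' @return an object of class `weight_map` with fields `grid` and `w`
#'   (`n_lat` x `n_lon` matrix).
#' @export
distortion_weights <- function(grid) {
  stopifnot(inherits(grid, "sphere_grid"))
  s <- sin(grid$theta)
  w <- matrix(s / max(s), nrow = grid$n_lat, ncol = grid$n_lon)
  structure(list(grid = grid, w = w), class = "weight_map")
}

#' Multi-channel feature map on a spherical grid
#'
#' Container for per-cell values of geometric (sulcal depth, curvature) and/or
#' functional (task-contrast) channels. At least one geometric channel must be
#' present; functional channels are optional and may be flagged absent through
#' `valid_mask` (the semi-supervised setting).
#'
#' @param grid a [make_grid()] object.
#' @param values numeric array `n_lat x n_lon x n_channels` (a matrix is
#'   promoted to a single channel).
#' @param channel_roles character vector, one of `"geometric"` or
#'   `"functional"` per channel.
#' @param valid_mask optional logical vector, one flag per channel; `FALSE`
#'   marks a channel as unobserved.
#' @return an object of class `feature_map`.
#' @export
feature_map <- function(grid, values, channel_roles,
                        valid_mask = NULL) {
  stopifnot(inherits(grid, "sphere_grid"))
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  d <- dim(values)
  if (length(d) != 3L || d[1] != grid$n_lat || d[2] != grid$n_lon) {
    stop("values must be an n_lat x n_lon x channels array", call. = FALSE)
  }
  channel_roles <- match.arg(channel_roles, c("geometric", "functional"),
                             several.ok = TRUE)
  if (length(channel_roles) != d[3]) {
    stop("one channel role per channel required", call. = FALSE)
  }
  if (length(channel_roles) == 0) {
    stop("at least one channel is required", call. = FALSE)
  }
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, d[3])
  stopifnot(is.logical(valid_mask), length(valid_mask) == d[3])
  for (c in seq_len(d[3])) {
    if (valid_mask[c] && !all(is.finite(values[, , c]))) {
      stop("non-finite values in a valid channel", call. = FALSE)
    }
  }
  structure(
    list(grid = grid, values = values, channel_roles = channel_roles,
         valid_mask = valid_mask),
    class = "feature_map"
  )
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map %d x %d, channels: %s>\n",
              x$grid$n_lat, x$grid$n_lon,
              paste0(x$channel_roles,
                     ifelse(x$valid_mask, "", " (absent)"), collapse = ", ")))
  invisible(x)
}

#' Extract channels of a feature map by role
#'
#' @param fm a [feature_map()].
#' @param role `"geometric"` or `"functional"`.
#' @param drop_invalid drop channels whose `valid_mask` is `FALSE`.
#' @return a `feature_map` with the selected channels, or `NULL` if none.
#' @export
channels_by_role <- function(fm, role = c("geometric", "functional"),
                             drop_invalid = TRUE) {
  role <- match.arg(role)
  sel <- fm$channel_roles == role
  if (drop_invalid) sel <- sel & fm$valid_mask
  if (!any(sel)) return(NULL)
  feature_map(fm$grid, fm$values[, , sel, drop = FALSE],
              fm$channel_roles[sel], fm$valid_mask[sel])
}

#' Standardize a feature map per channel
#'
#' Each channel is independently centered at its median and scaled by its
#' standard deviation, the preprocessing applied identically but separately to
#' geometric and functional features before they enter the network or the
#' loss. A floor `eps` on the standard deviation guards constant channels,
#' which map to all zeros.
#'
#' @param fm a [feature_map()].
#' @param eps floor on the per-channel standard deviation.
#' @return a standardized `feature_map` (median 0, sd ~1 per channel).
#' @export
standardize <- function(fm, eps = 1e-6) {
  stopifnot(inherits(fm, "feature_map"))
  out <- fm$values
  for (c in seq_len(dim(out)[3])) {
    if (!fm$valid_mask[c]) next
    v <- out[, , c]
    out[, , c] <- (v - median(v)) / max(sd(v), eps)
  }
  feature_map(fm$grid, out, fm$channel_roles, fm$valid_mask)
}

#' Cartesian coordinates of grid cell centers
#'
#' @param grid a [make_grid()] object.
#' @return an `(n_lat * n_lon) x 3` matrix of unit vectors, cells in
#'   column-major (latitude-fastest) order.
#' @export
grid_cell_centers <- function(grid) {
  th <- rep(grid$theta, times = grid$n_lon)
  ph <- rep(grid$phi, each = grid$n_lat)
  cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

#' Parameterize scattered spherical vertex data onto the grid
#'
#' Converts per-vertex values living on a unit sphere (e.g. an inflated,
#' rigidly aligned cortical sphere) into a grid [feature_map()] by
#' inverse-great-circle-distance interpolation over the `k` nearest vertices
#' of each cell center. The longitude seam is handled by working in Cartesian
#' coordinates throughout.
#'
#' @param vertex_coords `V x 3` matrix of unit-sphere points (norms within
#'   1e-3 of 1).
#' @param vertex_values `V x C` matrix (or length-V vector) of per-vertex
#'   channel values.
#' @param grid a [make_grid()] object.
#' @param channel_roles roles for the resulting channels (default geometric).
#' @param k number of nearest vertices (default 3).
#' @return a [feature_map()] on `grid`.
#' @export
parameterize <- function(vertex_coords, vertex_values, grid,
                         channel_roles = NULL, k = 3L) {
  vertex_coords <- as.matrix(vertex_coords)
  if (nrow(vertex_coords) < 1L) stop("no vertices supplied", call. = FALSE)
  if (ncol(vertex_coords) != 3L) stop("vertex_coords must be V x 3",
                                      call. = FALSE)
  nrm <- sqrt(rowSums(vertex_coords^2))
  if (any(abs(nrm - 1) > 1e-3)) {
    stop("vertex coordinates must lie on the unit sphere (|norm - 1| <= 1e-3)",
         call. = FALSE)
  }
  if (is.null(dim(vertex_values))) vertex_values <- cbind(vertex_values)
  vertex_values <- as.matrix(vertex_values)
  if (nrow(vertex_values) != nrow(vertex_coords)) {
    stop("vertex count mismatch between coordinates and values",
         call. = FALSE)
  }
  if (is.null(channel_roles)) {
    channel_roles <- rep("geometric", ncol(vertex_values))
  }
  cells <- grid_cell_centers(grid)
  vals <- knn_idw_sphere(cells, vertex_coords, vertex_values,
                         as.integer(k))
  feature_map(grid, array(vals, c(grid$n_lat, grid$n_lon,
                                  ncol(vertex_values))),
              channel_roles)
}

#' Sample a feature map at arbitrary unit-sphere points
#'
#' Nearest-cell bilinear sampling in (theta, phi) with longitude wrap; used to
#' read a parameterized map back at vertex locations.
#'
#' @param fm a [feature_map()].
#' @param points `P x 3` matrix of unit vectors.
#' @return `P x C` matrix of sampled values.
#' @export
sample_at_points <- function(fm, points) {
  g <- fm$grid
  points <- as.matrix(points)
  th <- acos(pmin(pmax(points[, 3], -1), 1))
  ph <- atan2(points[, 2], points[, 1]) %% (2 * pi)
  # fractional cell-center coordinates of each point (0-based)
  i <- th / pi * g$n_lat - 0.5
  j <- ph / (2 * pi) * g$n_lon
  u <- array(0, c(length(th), 1, 2))
  u[, 1, 1] <- pmin(pmax(i, 0), g$n_lat - 1)
  u[, 1, 2] <- j
  # reuse the warp kernel on a degenerate 1-column "grid" of query offsets
  C <- dim(fm$values)[3]
  out <- matrix(0, length(th), C)
  for (c in seq_len(C)) {
    img <- array(fm$values[, , c], c(g$n_lat, g$n_lon, 1L))
    ii <- floor(u[, 1, 1]); fi <- u[, 1, 1] - ii
    jj <- floor(u[, 1, 2]) %% g$n_lon; fj <- u[, 1, 2] - floor(u[, 1, 2])
    i0 <- ii + 1; i1 <- pmin(ii + 2, g$n_lat)
    j0 <- jj + 1; j1 <- (jj + 1) %% g$n_lon + 1
    m <- img[, , 1]
    out[, c] <- (1 - fi) * ((1 - fj) * m[cbind(i0, j0)] +
                            fj * m[cbind(i0, j1)]) +
                fi * ((1 - fj) * m[cbind(i1, j0)] + fj * m[cbind(i1, j1)])
  }
  out
}
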
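# Independent oracles: deliberately naive scalar-loop implementations used to
# pin down expected values. They share no code with the package internals.

# Fine-step explicit Euler integration of a stationary velocity field.
# Velocities are bilinearly sampled (clamped latitude lookup, wrapped
# longitude); positions evolve freely.
euler_flow_oracle <- function(v, nsteps = 1024) {
  H <- v$grid$n_lat
  W <- v$grid$n_lon
  pos_i <- matrix(rep(0:(H - 1), W), H)
  pos_j <- matrix(rep(0:(W - 1), each = H), H)
  samp <- function(m, pi_, pj_) {
    pi_ <- pmin(pmax(pi_, 0), H - 1)
    pj_ <- pj_ %% W
    i0 <- floor(pi_); i1 <- pmin(i0 + 1, H - 1); fi <- pi_ - i0
    j0 <- floor(pj_) %% W; j1 <- (j0 + 1) %% W; fj <- pj_ - floor(pj_)
    val <- c(1 - fi) * (c(1 - fj) * m[cbind(c(i0 + 1), c(j0 + 1))] +
                        c(fj) * m[cbind(c(i0 + 1), c(j1 + 1))]) +
      c(fi) * (c(1 - fj) * m[cbind(c(i1 + 1), c(j0 + 1))] +
               c(fj) * m[cbind(c(i1 + 1), c(j1 + 1))])
    matrix(val, H, W)
  }
  ci <- pos_i
  cj <- pos_j
  h <- 1 / nsteps
  for (s in seq_len(nsteps)) {
    vi <- samp(v$v[, , 1], ci, cj)
    vj <- samp(v$v[, , 2], ci, cj)
    ci <- ci + h * vi
    cj <- cj + h * vj
  }
  list(ui = ci - pos_i, uj = cj - pos_j)
}

# Per-pixel scalar-loop bilinear warp of one channel.
warp_oracle <- function(m, u) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (j in 1:W) for (i in 1:H) {
    y <- (i - 1) + u[i, j, 1]
    y <- min(max(y, 0), H - 1)
    x <- ((j - 1) + u[i, j, 2]) %% W
    i0 <- floor(y); i1 <- min(i0 + 1, H - 1); fy <- y - i0
    j0 <- floor(x) %% W; j1 <- (j0 + 1) %% W; fx <- x - floor(x)
    out[i, j] <- (1 - fy) * ((1 - fx) * m[i0 + 1, j0 + 1] +
                             fx * m[i0 + 1, j1 + 1]) +
      fy * ((1 - fx) * m[i1 + 1, j0 + 1] + fx * m[i1 + 1, j1 + 1])
  }
  out
}

# Loop-based distortion-weighted forward-difference smoothness penalty.
smoothness_oracle <- function(u, lam, w) {
  H <- nrow(w); W <- ncol(w)
  num <- 0; den <- 0
  for (j in 1:W) {
    jn <- j %% W + 1
    for (i in 1:H) {
      s <- 0
      for (c in 1:2) s <- s + (u[i, jn, c] - u[i, j, c])^2
      num <- num + w[i, j] * s
      den <- den + w[i, j]
      if (i < H) {
        s <- 0
        for (c in 1:2) s <- s + (u[i + 1, j, c] - u[i, j, c])^2
        num <- num + w[i, j] * s
        den <- den + w[i, j]
      }
    }
  }
  lam * num / den
}

# Loop-based distortion-weighted MSE over one channel.
wmse_oracle <- function(a, b, w) {
  num <- 0; den <- 0
  for (j in 1:ncol(w)) for (i in 1:nrow(w)) {
    num <- num + w[i, j] * (a[i, j] - b[i, j])^2
    den <- den + w[i, j]
  }
  num / den
}

# Loop-based weighted Pearson correlation.
weighted_pearson_oracle <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  cov <- sum(w * (x - mx) * (y - my)) / sw
  cov / sqrt(sum(w * (x - mx)^2) / sw) / sqrt(sum(w * (y - my)^2) / sw)
}

# 4-neighbour connected components with longitude wrap (flood fill).
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (j0 in 1:W) for (i0 in 1:H) {
    if (!mask[i0, j0] || lab[i0, j0] > 0) next
    cur <- cur + 1L
    stack <- list(c(i0, j0))
    lab[i0, j0] <- cur
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- p[1]; j <- p[2]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]
        jj <- (j + d[2] - 1) %% W + 1
        if (ii >= 1 && ii <= H && mask[ii, jj] && lab[ii, jj] == 0L) {
          lab[ii, jj] <- cur
          stack[[length(stack) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  lab
}

# Icosahedron subdivided n times, projected to the unit sphere.
icosphere <- function(n_sub = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(n_sub)) {
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(sort(c(a, b)), collapse = "-")
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      m <- (v[a, ] + v[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      v <<- rbind(v, m)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc),
                  c(ab, bc, ca))
    }
    f <- nf
  }
  storage.mode(f) <- "integer"
  dimnames(v) <- NULL
  dimnames(f) <- NULL
  list(vertices = v, faces = f)
}

# Smooth random velocity with the latitude component tapered at the poles
# (no flow across the pole rows), rescaled to a maximum magnitude.
smooth_test_velocity <- function(grid, amplitude, scale = 4) {
  v <- smooth_velocity(grid, amplitude, scale)
  v$v[, , 1] <- v$v[, , 1] * sin(grid$theta)
  mx <- max(sqrt(v$v[, , 1]^2 + v$v[, , 2]^2))
  if (mx > 0) v$v <- v$v * amplitude / mx
  v
}

# Central finite-difference gradient of scalar f at selected indices of x.
fd_grad <- function(f, x, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}
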
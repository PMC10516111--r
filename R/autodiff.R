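# Minimal reverse-mode automatic differentiation tape.
#
# Nodes are environments holding a value, parent ids and a backward closure;
# the tape records creation order, and ad_backward() sweeps it in reverse.
# Only the operations the registration model needs are provided; each is
# gradient-checked against finite differences in the test suite.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  class(tp) <- "ad_tape"
  tp
}

ad_node <- function(tape, value, parents = list(), backfun = NULL) {
  # force arguments first: evaluating them may create nodes (nested calls),
  # and the id below must be allocated after those
  force(value)
  pids <- vapply(parents, function(p) p$id, integer(1))
  force(backfun)
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$n <- n
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$id <- n
  node$parents <- pids
  node$backfun <- backfun
  class(node) <- "ad_node"
  tape$nodes[[n]] <- node
  node
}

# Leaf that receives gradients (a trainable parameter).
ad_leaf <- function(tape, value) ad_node(tape, value)

# Constant input: also a leaf; its gradient is simply never used.
ad_const <- function(tape, value) ad_node(tape, value)

ad_value <- function(node) node$value

# Accumulate gradients into every node reachable from `root` (a scalar).
# Returns a list indexed by node id; entries are NULL where no gradient flows.
ad_backward <- function(tape, root) {
  grads <- vector("list", tape$n)
  grads[[root$id]] <- 1
  for (k in seq(root$id, 1L)) {
    node <- tape$nodes[[k]]
    g <- grads[[k]]
    if (is.null(g) || is.null(node$backfun)) next
    pg <- node$backfun(g)
    ps <- node$parents
    for (m in seq_along(ps)) {
      gm <- pg[[m]]
      if (is.null(gm)) next
      pid <- ps[m]
      grads[[pid]] <- if (is.null(grads[[pid]])) gm else grads[[pid]] + gm
    }
  }
  grads
}

# --- elementwise / shape ops -----------------------------------------------

ad_add <- function(tape, a, b) {
  ad_node(tape, a$value + b$value, list(a, b),
          function(g) list(g, g))
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, a$value - b$value, list(a, b),
          function(g) list(g, -g))
}

ad_scale <- function(tape, a, s) {
  ad_node(tape, a$value * s, list(a), function(g) list(g * s))
}

ad_lrelu <- function(tape, a, slope = 0.2) {
  v <- a$value
  ad_node(tape, lrelu_fwd(v, slope), list(a),
          function(g) list(lrelu_bwd(v, g, slope)))
}

ad_concat_channels <- function(tape, a, b) {
  da <- dim(a$value)
  db <- dim(b$value)
  v <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  v[, , seq_len(da[3]), ] <- a$value
  v[, , da[3] + seq_len(db[3]), ] <- b$value
  ad_node(tape, v, list(a, b), function(g) {
    list(g[, , seq_len(da[3]), , drop = FALSE],
         g[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

# Extract one sample's channel pair [H, W, 2] from a 4D head output.
ad_sample_field <- function(tape, x, sample) {
  d <- dim(x$value)
  v <- array(x$value[, , , sample], c(d[1], d[2], d[3]))
  ad_node(tape, v, list(x), function(g) {
    gx <- array(0, d)
    gx[, , , sample] <- g
    list(gx)
  })
}

# --- network layers ---------------------------------------------------------

# Convolution with optional fused leaky-rectifier (slope >= 0 enables it).
ad_conv2d <- function(tape, x, w, b, slope = -1) {
  node <- ad_node(tape, conv2d_sphere_fwd(x$value, w$value, b$value, slope),
                  list(x, w, b), function(g) {
                    r <- conv2d_sphere_bwd(x$value, w$value, g,
                                           node$value, slope)
                    list(r$gx, r$gw, r$gb)
                  })
  node
}

ad_maxpool2 <- function(tape, x) {
  f <- maxpool2_fwd(x$value)
  d <- dim(x$value)
  ad_node(tape, f$out, list(x),
          function(g) list(maxpool2_bwd(f$idx, g, d[1], d[2])))
}

ad_upsample2 <- function(tape, x) {
  ad_node(tape, upsample2_fwd(x$value), list(x),
          function(g) list(upsample2_bwd(g)))
}

# --- warping and flow integration ------------------------------------------

# img: [H, W, C] node; u: [H, W, 2] node. Gradients flow to both.
ad_warp <- function(tape, img, u) {
  ad_node(tape, warp_img_fwd(img$value, u$value), list(img, u),
          function(g) {
            r <- warp_img_bwd(img$value, u$value, g)
            list(r$gimg, r$gu)
          })
}

# Displacement of outer(inner(x)): u_inner + warp(u_outer, u_inner).
ad_compose_disp <- function(tape, u_outer, u_inner) {
  ad_add(tape, u_inner, ad_warp(tape, u_outer, u_inner))
}

# Scaling and squaring on the tape: u <- v / 2^n, then n self-compositions.
# Runs as a single fused kernel; intermediates are cached for the backward
# recursion.
ad_svf_exp <- function(tape, v, n_steps = 7L) {
  f <- svf_exp_fwd(v$value, as.integer(n_steps))
  ad_node(tape, f$u, list(v),
          function(g) list(svf_exp_bwd(f$steps, g, as.integer(n_steps),
                                       f$H, f$W)))
}

# --- loss terms -------------------------------------------------------------

# Distortion-weighted MSE between two [H, W, C] nodes: weighted spatial mean
# per channel, then averaged over channels.
ad_weighted_mse <- function(tape, a, b, wmat) {
  C <- dim(a$value)[3]
  wsum <- sum(wmat)
  diff <- a$value - b$value
  wfull <- array(wmat, dim(a$value))
  val <- sum(wfull * diff^2) / (wsum * C)
  ad_node(tape, val, list(a, b), function(g) {
    gd <- g * 2 * wfull * diff / (wsum * C)
    list(gd, -gd)
  })
}

# Distortion-weighted mean squared forward-difference gradient of a
# displacement node [H, W, 2]: longitude differences wrap, latitude
# differences stop at the last row; each base cell is weighted by wmat and the
# two displacement components are summed.
grad_penalty_fwd <- function(u, wmat) {
  H <- dim(u)[1]
  dlat <- u[-1, , , drop = FALSE] - u[-H, , , drop = FALSE]
  dlon <- u[, c(2:ncol(wmat), 1), , drop = FALSE] - u
  num <- sum(wmat[-H, ] * (dlat[, , 1]^2 + dlat[, , 2]^2)) +
    sum(wmat * (dlon[, , 1]^2 + dlon[, , 2]^2))
  den <- sum(wmat[-H, ]) + sum(wmat)
  list(val = num / den, dlat = dlat, dlon = dlon, den = den)
}

ad_grad_penalty <- function(tape, u, wmat) {
  f <- grad_penalty_fwd(u$value, wmat)
  H <- nrow(wmat)
  W <- ncol(wmat)
  ad_node(tape, f$val, list(u), function(g) {
    gu <- array(0, dim(u$value))
    for (c in 1:2) {
      glat <- 2 * wmat[-H, ] * f$dlat[, , c] * (g / f$den)
      gu[-H, , c] <- gu[-H, , c] - glat
      gu[-1, , c] <- gu[-1, , c] + glat
      glon <- 2 * wmat * f$dlon[, , c] * (g / f$den)
      gu[, , c] <- gu[, , c] - glon
      # dlon at column j involves u at column j+1 (wrapped)
      gu[, c(2:W, 1), c] <- gu[, c(2:W, 1), c] + glon
    }
    list(gu)
  })
}

# Plain (unweighted) mean of squares of a node; used for the centrality term.
ad_mean_sq <- function(tape, a) {
  n <- length(a$value)
  ad_node(tape, sum(a$value^2) / n, list(a),
          function(g) list(g * 2 * a$value / n))
}

# Scalar linear combination sum_i coefs[i] * nodes[[i]].
ad_lincomb <- function(tape, nodes, coefs) {
  val <- 0
  for (i in seq_along(nodes)) val <- val + coefs[i] * nodes[[i]]$value
  ad_node(tape, val, nodes,
          function(g) lapply(coefs, function(cf) g * cf))
}

# Mean of a list of equally-shaped nodes.
ad_list_mean <- function(tape, nodes) {
  ad_lincomb_arrays(tape, nodes, rep(1 / length(nodes), length(nodes)))
}

ad_lincomb_arrays <- function(tape, nodes, coefs) {
  val <- coefs[1] * nodes[[1]]$value
  if (length(nodes) > 1) {
    for (i in 2:length(nodes)) val <- val + coefs[i] * nodes[[i]]$value
  }
  ad_node(tape, val, nodes,
          function(g) lapply(coefs, function(cf) g * cf))
}
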
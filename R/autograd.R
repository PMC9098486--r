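#' @useDynLib meanet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif rbinom sd plogis
NULL

# ---------------------------------------------------------------------------
# Reverse-mode automatic differentiation on a linear tape.
#
# A node is an environment holding $value, $grad, $parents (list of nodes)
# and $backward, a function(grad) returning one gradient per parent.
# Activations are arrays dim c(H, W, C, N); vector-valued nodes (channel
# gates, squeeze vectors) hold matrices dim c(C, N).
# ---------------------------------------------------------------------------

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

ag_node <- function(tape, value, parents = list(), backward = NULL,
                    pname = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$backward <- backward
  nd$pname <- pname
  if (!is.null(tape)) {
    tape$n <- tape$n + 1L
    if (tape$n > length(tape$nodes))
      length(tape$nodes) <- 2L * length(tape$nodes)
    tape$nodes[[tape$n]] <- nd
    nd$id <- tape$n
  }
  nd
}

ag_leaf <- function(tape, value, pname = NULL)
  ag_node(tape, value, pname = pname)

ag_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' Run the backward pass of a recorded computation
#'
#' Seeds the root node's gradient with 1 and propagates adjoints through the
#' tape in reverse recording order.
#'
#' @param tape tape returned by the forward pass machinery.
#' @param root scalar-valued node (typically a loss) to differentiate.
#' @return invisibly, the tape; leaf nodes carry their accumulated `$grad`.
#' @keywords internal
ag_backward <- function(tape, root) {
  stopifnot(length(root$value) == 1L)
  root$grad <- 1
  for (i in seq.int(root$id, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd) || is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    for (j in seq_along(nd$parents)) {
      if (!is.null(gs[[j]])) ag_accum(nd$parents[[j]], gs[[j]])
    }
    if (i != root$id) nd$grad <- NULL   # free memory as we go
  }
  invisible(tape)
}

# --- primitive ops ---------------------------------------------------------

ag_conv2d <- function(tape, x, w, b, ph, pw) {
  y <- .cpp_conv2d_fw(x$value, w$value, b$value, ph, pw)
  xv <- x$value; wv <- w$value
  ag_node(tape, y, list(x, w, b), function(g) {
    bw <- .cpp_conv2d_bw(xv, wv, g, ph, pw)
    list(bw$gx, bw$gw, bw$gb)
  })
}

ag_relu <- function(tape, x) {
  mask <- x$value > 0
  ag_node(tape, x$value * mask, list(x), function(g) list(g * mask))
}

ag_sigmoid <- function(tape, x) {
  y <- plogis(x$value)
  ag_node(tape, y, list(x), function(g) list(g * y * (1 - y)))
}

ag_add <- function(tape, x, y) {
  ag_node(tape, x$value + y$value, list(x, y), function(g) list(g, g))
}

ag_maxpool2 <- function(tape, x) {
  fw <- .cpp_maxpool2_fw(x$value)
  xd <- dim(x$value)
  ag_node(tape, fw$y, list(x), function(g)
    list(.cpp_maxpool2_bw(fw$idx, g, xd)))
}

ag_up2 <- function(tape, x) {
  xd <- dim(x$value)
  ag_node(tape, .cpp_up2_fw(x$value), list(x), function(g)
    list(.cpp_up2_bw(g, xd)))
}

# channel concatenation along dim 3
ag_concat <- function(tape, x, y) {
  dx <- dim(x$value); dy <- dim(y$value)
  stopifnot(dx[1] == dy[1], dx[2] == dy[2], dx[4] == dy[4])
  v <- array(0, c(dx[1], dx[2], dx[3] + dy[3], dx[4]))
  v[, , seq_len(dx[3]), ] <- x$value
  v[, , dx[3] + seq_len(dy[3]), ] <- y$value
  ag_node(tape, v, list(x, y), function(g)
    list(g[, , seq_len(dx[3]), , drop = FALSE],
         g[, , dx[3] + seq_len(dy[3]), , drop = FALSE]))
}

# sum over the channel axis -> (H, W, 1, N)
ag_sum_channels <- function(tape, x) {
  d <- dim(x$value)
  v <- array(0, c(d[1], d[2], 1L, d[4]))
  for (n in seq_len(d[4]))
    v[, , 1L, n] <- rowSums(x$value[, , , n, drop = FALSE], dims = 2L)
  ag_node(tape, v, list(x), function(g) {
    gx <- array(0, d)
    for (n in seq_len(d[4]))
      gx[, , , n] <- array(g[, , 1L, n], c(d[1], d[2], d[3]))
    list(gx)
  })
}

# multiply a single-channel map (H, W, 1, N) into every channel of x
ag_broadcast_mul <- function(tape, a, x) {
  da <- dim(a$value); dx <- dim(x$value)
  stopifnot(da[1] == dx[1], da[2] == dx[2], da[3] == 1L, da[4] == dx[4])
  av <- a$value; xv <- x$value
  v <- array(0, dx)
  for (n in seq_len(dx[4]))
    v[, , , n] <- xv[, , , n, drop = FALSE] *
      as.vector(av[, , 1L, n])
  ag_node(tape, v, list(a, x), function(g) {
    ga <- array(0, da); gx <- array(0, dx)
    for (n in seq_len(dx[4])) {
      gx[, , , n] <- g[, , , n, drop = FALSE] * as.vector(av[, , 1L, n])
      ga[, , 1L, n] <- rowSums(g[, , , n, drop = FALSE] *
                                 xv[, , , n, drop = FALSE], dims = 2L)
    }
    list(ga, gx)
  })
}

# per-channel, per-sample scaling; s is a (C, N) matrix node
ag_scale_channels <- function(tape, x, s) {
  d <- dim(x$value)
  sv <- s$value; xv <- x$value
  v <- array(0, d)
  for (n in seq_len(d[4]))
    v[, , , n] <- sweep(xv[, , , n, drop = FALSE], 3L, sv[, n], "*")
  ag_node(tape, v, list(x, s), function(g) {
    gx <- array(0, d); gs <- matrix(0, d[3], d[4])
    for (n in seq_len(d[4])) {
      gx[, , , n] <- sweep(g[, , , n, drop = FALSE], 3L, sv[, n], "*")
      gs[, n] <- colSums(matrix(g[, , , n] * xv[, , , n], d[1] * d[2], d[3]))
    }
    list(gx, gs)
  })
}

# global average pooling -> (C, N) matrix node
ag_gap <- function(tape, x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  v <- apply(x$value, c(3, 4), mean)
  dim(v) <- c(d[3], d[4])
  ag_node(tape, v, list(x), function(g) {
    gx <- array(0, d)
    for (n in seq_len(d[4]))
      gx[, , , n] <- array(rep(g[, n] / hw, each = hw), c(d[1], d[2], d[3]))
    list(gx)
  })
}

# global max pooling over all spatial positions -> (C, N) matrix node
ag_gmp <- function(tape, x) {
  d <- dim(x$value)
  hw <- d[1] * d[2]
  xm <- matrix(x$value, hw, d[3] * d[4])
  which_best <- max.col(t(xm), ties.method = "first")
  v <- xm[cbind(which_best, seq_len(d[3] * d[4]))]
  dim(v) <- c(d[3], d[4])
  ag_node(tape, v, list(x), function(g) {
    gxm <- matrix(0, hw, d[3] * d[4])
    gxm[cbind(which_best, seq_len(d[3] * d[4]))] <- as.vector(g)
    list(array(gxm, d))
  })
}

# dense layer on (Cin, N) matrix nodes: y = W %*% z  (no bias, SE-style)
ag_dense <- function(tape, z, w) {
  zv <- z$value; wv <- w$value
  ag_node(tape, wv %*% zv, list(z, w), function(g)
    list(t(wv) %*% g, g %*% t(zv)))
}

# batch normalisation per channel over (H, W, N); conv -> ReLU -> BN order
# is handled by callers. `state` is an environment with $mean, $var updated
# in training mode (momentum 0.1); eval mode uses the running stats.
ag_batchnorm <- function(tape, x, gamma, beta, state, training,
                         eps = 1e-5, momentum = 0.1) {
  d <- dim(x$value)
  m <- d[1] * d[2] * d[4]
  if (training) {
    st <- .cpp_bn_stats(x$value)
    mu <- st$mean
    va <- st$var
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var  <- (1 - momentum) * state$var +
      momentum * va * m / max(1, m - 1)
  } else {
    mu <- state$mean
    va <- state$var
  }
  y <- .cpp_bn_fw(x$value, gamma$value, beta$value, mu, va, eps)
  xv <- x$value
  gv <- gamma$value
  ag_node(tape, y, list(x, gamma, beta), function(g) {
    bw <- .cpp_bn_bw(xv, g, gv, mu, va, eps, training)
    list(bw$gx, bw$ggamma, bw$gbeta)
  })
}
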
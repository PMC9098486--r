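# Independent, loop-based reference implementations used as oracles.
# They share no code with the package internals.

# stride-1 zero-padded 2-D convolution on (H, W, C) arrays
oracle_conv2d <- function(x, w, b) {
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; Cout <- dim(w)[4]
  ph <- (kh - 1) %/% 2; pw <- (kw - 1) %/% 2
  y <- array(0, c(H, W, Cout))
  for (co in seq_len(Cout)) for (i in seq_len(H)) for (j in seq_len(W)) {
    s <- b[co]
    for (ci in seq_len(Cin)) for (di in seq_len(kh)) for (dj in seq_len(kw)) {
      ii <- i + di - 1 - ph; jj <- j + dj - 1 - pw
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W)
        s <- s + x[ii, jj, ci] * w[di, dj, ci, co]
    }
    y[i, j, co] <- s
  }
  y
}

# evaluation-mode batch norm with fresh running stats (mean 0, var 1)
oracle_bn_eval <- function(x, gamma = 1, beta = 0, eps = 1e-5)
  gamma * x / sqrt(1 + eps) + beta

# conv -> ReLU -> eval-mode BN, the package's standard convolution unit
oracle_conv_unit <- function(x, w, b) oracle_bn_eval(pmax(oracle_conv2d(x, w, b), 0))

# factor-2 bilinear upsampling, half-pixel centres, clamped edges
oracle_up2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  pick <- function(v, n) min(max(v, 1), n)
  y <- array(0, c(2 * H, 2 * W, C))
  for (c in seq_len(C)) for (i in seq_len(2 * H)) for (j in seq_len(2 * W)) {
    si <- (i - 0.5) / 2 + 0.5; sj <- (j - 0.5) / 2 + 0.5
    i0 <- floor(si); j0 <- floor(sj)
    a <- si - i0; b <- sj - j0
    if (i0 < 1) { i0 <- 1; a <- 0 }
    if (i0 >= H) { i0 <- H; a <- 0 }
    if (j0 < 1) { j0 <- 1; b <- 0 }
    if (j0 >= W) { j0 <- W; b <- 0 }
    i1 <- pick(i0 + 1, H); j1 <- pick(j0 + 1, W)
    y[i, j, c] <- (1 - a) * (1 - b) * x[i0, j0, c] +
      a * (1 - b) * x[i1, j0, c] +
      (1 - a) * b * x[i0, j1, c] + a * b * x[i1, j1, c]
  }
  y
}

# Eq.-style attention aggregation: explicit triple loop over maps,
# channels and pixels
oracle_mag_aggregate <- function(A, X1) {
  H <- dim(X1)[1]; W <- dim(X1)[2]; C <- dim(X1)[3]; N <- dim(A)[3]
  U <- array(0, c(H, W, C))
  for (m in seq_len(N)) for (c in seq_len(C))
    for (i in seq_len(H)) for (j in seq_len(W))
      U[i, j, c] <- U[i, j, c] + A[i, j, m] * X1[i, j, c]
  U
}

# scalar-loop squeeze / excitation / scale
oracle_se <- function(U, W1, W2) {
  H <- dim(U)[1]; W <- dim(U)[2]; C <- dim(U)[3]
  z <- numeric(C)
  for (k in seq_len(C)) z[k] <- sum(U[, , k]) / (H * W)
  h <- pmax(as.vector(W2 %*% z), 0)
  s <- 1 / (1 + exp(-as.vector(W1 %*% h)))
  out <- array(0, dim(U))
  for (k in seq_len(C)) out[, , k] <- s[k] * U[, , k]
  list(scaled = out, z = z, s = s)
}

# confusion counts by pixel enumeration
oracle_confusion <- function(pred, gt) {
  tp <- fp <- tn <- fn <- 0L
  for (k in seq_along(pred)) {
    if (pred[k] == 1 && gt[k] == 1) tp <- tp + 1L
    else if (pred[k] == 1) fp <- fp + 1L
    else if (gt[k] == 1) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

# AUC by enumerating foreground/background pairs, ties worth one half
oracle_auc <- function(score, gt) {
  f <- score[gt == 1]; b <- score[gt == 0]
  if (length(f) == 0 || length(b) == 0) return(NA_real_)
  s <- 0
  for (x in f) for (y in b)
    s <- s + if (x > y) 1 else if (x == y) 0.5 else 0
  s / (length(f) * length(b))
}

# boundary F1 with exhaustive nearest-distance matching
oracle_bf <- function(pred, gt, theta) {
  bnd <- function(m) {
    pts <- NULL
    H <- nrow(m); W <- ncol(m)
    for (i in seq_len(H)) for (j in seq_len(W)) {
      if (m[i, j] != 1) next
      nb <- c(if (i > 1) m[i - 1, j] else 0, if (i < H) m[i + 1, j] else 0,
              if (j > 1) m[i, j - 1] else 0, if (j < W) m[i, j + 1] else 0)
      if (any(nb == 0)) pts <- rbind(pts, c(i, j))
    }
    pts
  }
  bp <- bnd(pred); bg <- bnd(gt)
  if (is.null(bp) && is.null(bg)) return(1)
  if (is.null(bp) || is.null(bg)) return(0)
  mind <- function(p, set) min(sqrt((set[, 1] - p[1])^2 + (set[, 2] - p[2])^2))
  prec <- mean(apply(bp, 1, function(p) mind(p, bg) <= theta))
  rec <- mean(apply(bg, 1, function(p) mind(p, bp) <= theta))
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

rand_feat <- function(H, W, C, sd = 1) array(rnorm(H * W * C, 0, sd), c(H, W, C))

tiny_net_config <- function(...)
  network_config(in_channels = 1L, stage_widths = c(4L, 8L, 12L, 16L),
                 attention_maps = 4L, se_reduction = 2L, ...)

blob_set <- function(n, size = 32L, seed0 = 100L)
  lapply(seq_len(n), function(k)
    generate_phantom(phantom_spec("blob", c(size, size), seed = seed0 + k)))
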
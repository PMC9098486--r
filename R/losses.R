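# Training objective: soft Dice loss on the edge head, binary cross-entropy
# on the segmentation head, mixed as total = alpha * dice + (1 - alpha) * bce.

#' Loss configuration
#'
#' @param alpha mixing weight of the Dice term in the joint loss, in
#'   `[0, 1]`; 0.3 by default, the value found to work best empirically.
#' @param smooth_eps small positive constant added to the Dice denominator.
#' @param clip_eps predictions are clipped to `[clip_eps, 1 - clip_eps]`
#'   before the cross-entropy logs.
#' @param supervision `"split"` (default): Dice supervises the edge head and
#'   BCE the segmentation head. `"joint_both"`: each head receives the full
#'   joint loss against its own target, and the two are averaged.
#' @return a `loss_config` list.
#' @export
loss_config <- function(alpha = 0.3, smooth_eps = 1e-6, clip_eps = 1e-7,
                        supervision = c("split", "joint_both")) {
  stopifnot(alpha >= 0, alpha <= 1, smooth_eps > 0, clip_eps > 0)
  structure(list(alpha = alpha, smooth_eps = smooth_eps,
                 clip_eps = clip_eps, supervision = match.arg(supervision)),
            class = "loss_config")
}

check_pg <- function(p, g) {
  if (length(p) == 0L) stop("empty prediction")
  if (length(p) != length(g))
    stop("prediction and ground truth shapes differ")
  if (any(p < 0 | p > 1)) stop("predictions must lie in [0, 1]")
  if (!all(g %in% c(0, 1))) stop("ground truth must be binary")
}

#' Soft Dice loss
#'
#' `1 - 2 * sum(p g) / (sum(p^2) + sum(g^2) + smooth_eps)`, computed over
#' all pixels of one image (or one image pair).
#'
#' @param p prediction array with values in `[0, 1]`.
#' @param g binary ground-truth array of the same shape.
#' @param smooth_eps denominator smoothing constant.
#' @return scalar loss in `[0, 1]` (up to smoothing).
#' @export
dice_loss <- function(p, g, smooth_eps = 1e-6) {
  check_pg(p, g)
  1 - 2 * sum(p * g) / (sum(p * p) + sum(g * g) + smooth_eps)
}

#' Binary cross-entropy loss
#'
#' Pixel mean of `-g log(p) - (1 - g) log(1 - p)` with `p` clipped to
#' `[clip_eps, 1 - clip_eps]`.
#'
#' @inheritParams dice_loss
#' @param clip_eps clipping constant for the logs.
#' @return non-negative scalar loss.
#' @export
bce_loss <- function(p, g, clip_eps = 1e-7) {
  check_pg(p, g)
  pc <- pmin(pmax(p, clip_eps), 1 - clip_eps)
  -mean(g * log(pc) + (1 - g) * log(1 - pc))
}

#' Joint segmentation / edge objective
#'
#' `total = alpha * L_Dice(edge_pred, edge_gt) +
#'  (1 - alpha) * L_BCE(seg_pred, seg_gt)`: the Dice term supervises the
#' edge module's early prediction, the cross-entropy term the final
#' segmentation. With `supervision = "joint_both"` each head instead gets
#' the full mixed loss against its own target and the heads are averaged.
#'
#' @param seg_pred,seg_gt final segmentation probability map and binary
#'   mask.
#' @param edge_pred,edge_gt edge probability map and binary edge label.
#' @param cfg a [loss_config()].
#' @return list with `total`, `dice_term` and `bce_term`.
#' @export
joint_loss <- function(seg_pred, seg_gt, edge_pred, edge_gt,
                       cfg = loss_config()) {
  a <- cfg$alpha
  if (cfg$supervision == "split") {
    d <- dice_loss(edge_pred, edge_gt, cfg$smooth_eps)
    b <- bce_loss(seg_pred, seg_gt, cfg$clip_eps)
    list(total = a * d + (1 - a) * b, dice_term = d, bce_term = b)
  } else {
    ds <- dice_loss(seg_pred, seg_gt, cfg$smooth_eps)
    bs <- bce_loss(seg_pred, seg_gt, cfg$clip_eps)
    de <- dice_loss(edge_pred, edge_gt, cfg$smooth_eps)
    be <- bce_loss(edge_pred, edge_gt, cfg$clip_eps)
    list(total = mean(c(a * ds + (1 - a) * bs, a * de + (1 - a) * be)),
         dice_term = mean(c(de, ds)), bce_term = mean(c(bs, be)))
  }
}

# --- tape-level losses (per-image Dice then mean over the batch) ------------

ag_dice_loss <- function(tape, p, g, smooth_eps = 1e-6) {
  pv <- p$value
  d <- dim(pv)
  N <- d[4]
  S <- D <- L <- numeric(N)
  for (n in seq_len(N)) {
    pn <- pv[, , , n]; gn <- g[, , , n]
    S[n] <- sum(pn * gn)
    D[n] <- sum(pn * pn) + sum(gn * gn) + smooth_eps
    L[n] <- 1 - 2 * S[n] / D[n]
  }
  ag_node(tape, mean(L), list(p), function(gr) {
    gp <- array(0, d)
    for (n in seq_len(N))
      gp[, , , n] <- gr / N *
        (-2 * g[, , , n] * D[n] + 4 * S[n] * pv[, , , n]) / D[n]^2
    list(gp)
  })
}

ag_bce_loss <- function(tape, p, g, clip_eps = 1e-7) {
  pv <- p$value
  pc <- pmin(pmax(pv, clip_eps), 1 - clip_eps)
  inside <- pv > clip_eps & pv < 1 - clip_eps
  n_px <- length(pv)
  val <- -mean(g * log(pc) + (1 - g) * log(1 - pc))
  ag_node(tape, val, list(p), function(gr) {
    gp <- gr / n_px * (pc - g) / (pc * (1 - pc))
    gp[!inside] <- 0
    list(gp)
  })
}

ag_joint_loss <- function(tape, out, seg_gt, edge_gt, cfg = loss_config()) {
  a <- cfg$alpha
  scal <- function(x, k) ag_node(tape, k * x$value, list(x),
                                 function(g) list(k * g))
  if (cfg$supervision == "split" || is.null(out$edge_prob)) {
    b <- ag_bce_loss(tape, out$seg_prob, seg_gt, cfg$clip_eps)
    if (is.null(out$edge_prob)) {
      # baseline without an edge module: Dice falls on the segmentation head
      d <- ag_dice_loss(tape, out$seg_prob, seg_gt, cfg$smooth_eps)
    } else {
      d <- ag_dice_loss(tape, out$edge_prob, edge_gt, cfg$smooth_eps)
    }
    total <- ag_add(tape, scal(d, a), scal(b, 1 - a))
  } else {
    ls <- ag_add(tape,
                 scal(ag_dice_loss(tape, out$seg_prob, seg_gt,
                                   cfg$smooth_eps), a),
                 scal(ag_bce_loss(tape, out$seg_prob, seg_gt,
                                  cfg$clip_eps), 1 - a))
    le <- ag_add(tape,
                 scal(ag_dice_loss(tape, out$edge_prob, edge_gt,
                                   cfg$smooth_eps), a),
                 scal(ag_bce_loss(tape, out$edge_prob, edge_gt,
                                  cfg$clip_eps), 1 - a))
    total <- scal(ag_add(tape, ls, le), 0.5)
    d <- ls; b <- le
  }
  list(total = total, dice_term = d$value, bce_term = b$value)
}
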
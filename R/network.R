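#' Network configuration
#'
#' Describes the edge-attention encoder-decoder architecture: four encoder
#' stages with asymmetric-convolution residual blocks, three cascaded
#' decoding blocks, and an edge module made of an edge feature extraction
#' (EFE) stack and a multilayer attention guidance (MAG) block with
#' squeeze-and-excitation channel gating.
#'
#' @param in_channels number of image channels (1 grayscale, 3 RGB).
#' @param stage_widths channel widths of encoder stages E1..E4.
#' @param attention_maps number of edge attention maps produced by EFE.
#' @param se_reduction reduction ratio of the squeeze-and-excitation
#'   bottleneck; the bottleneck width is `max(1, floor(C / se_reduction))`.
#' @param efe_stages which encoder stages feed the EFE module (subset of
#'   1:4); deeper stages are bilinearly upsampled back to E1 resolution.
#' @param use_efe,use_mag ablation switches for the two edge-module blocks.
#'   With both off the network is the plain baseline encoder-decoder.
#' @param fuse_mode how decoder output and edge features Y1 are combined
#'   before the final convolution: `"concat"` or `"add"`.
#' @param decoder_combine how the two decoding-block branches are combined:
#'   `"add"` (elementwise) or `"concat"` (followed by a 1x1 projection).
#' @return a `meanet_config` list.
#' @export
network_config <- function(in_channels = 1L,
                           stage_widths = c(64L, 128L, 256L, 512L),
                           attention_maps = 16L,
                           se_reduction = 16L,
                           efe_stages = c(1L, 2L),
                           use_efe = TRUE,
                           use_mag = TRUE,
                           fuse_mode = c("concat", "add"),
                           decoder_combine = c("add", "concat")) {
  stopifnot(length(stage_widths) == 4L, all(stage_widths >= 1L),
            attention_maps >= 1L, se_reduction >= 1L, in_channels >= 1L)
  efe_stages <- sort(unique(as.integer(efe_stages)))
  if (use_efe) {
    if (length(efe_stages) == 0L || any(!efe_stages %in% 1:4))
      stop("efe_stages must be a non-empty subset of stages 1..4")
  }
  cfg <- list(in_channels = as.integer(in_channels),
              stage_widths = as.integer(stage_widths),
              attention_maps = as.integer(attention_maps),
              se_reduction = as.integer(se_reduction),
              efe_stages = efe_stages,
              use_efe = isTRUE(use_efe),
              use_mag = isTRUE(use_mag),
              fuse_mode = match.arg(fuse_mode),
              decoder_combine = match.arg(decoder_combine))
  class(cfg) <- "meanet_config"
  cfg
}

has_edge_module <- function(cfg) cfg$use_efe || cfg$use_mag

se_bottleneck <- function(C, reduction) max(1L, C %/% reduction)

#' Create an edge-attention segmentation network
#'
#' Allocates and initialises all trainable parameters (Kaiming-uniform
#' convolution kernels, unit-gamma batch-norm) for the architecture
#' described by `cfg`. Construction is deterministic given `seed`.
#'
#' @param cfg a [network_config()].
#' @param seed integer seed for weight initialisation.
#' @return a `meanet_model` with elements `config`, `params` (named list of
#'   arrays) and `state` (batch-norm running statistics).
#' @export
new_meanet <- function(cfg = network_config(), seed = 42L) {
  stopifnot(inherits(cfg, "meanet_config"))
  sw <- cfg$stage_widths
  b <- new_builder()
  local_seed(seed, {
    add_enc_block(b, "enc1", cfg$in_channels, sw[1])
    add_enc_block(b, "enc2", sw[1], sw[2])
    add_enc_block(b, "enc3", sw[2], sw[3])
    add_enc_block(b, "enc4", sw[3], sw[4])
    if (has_edge_module(cfg)) {
      if (cfg$use_efe)
        for (s in cfg$efe_stages)
          add_conv(b, paste0("efe.s", s), 3L, 3L, sw[s], cfg$attention_maps)
      cu <- edge_feature_channels(cfg)
      if (cfg$use_mag) {
        cr <- se_bottleneck(cu, cfg$se_reduction)
        add_dense(b, "se.w2", cr, cu)   # reduction, applied first
        add_dense(b, "se.w1", cu, cr)   # expansion, applied second
      }
      add_conv(b, "edge.y1", 1L, 1L, cu, sw[1])
      add_conv(b, "edge.y2a", 1L, 1L, cu, cu)
      add_conv(b, "edge.y2", 1L, 1L, cu, 1L, bn = FALSE)
    }
    add_dec_block(b, "dec3", sw[3], sw[4], cfg$decoder_combine)
    add_dec_block(b, "dec2", sw[2], sw[3], cfg$decoder_combine)
    add_dec_block(b, "dec1", sw[1], sw[2], cfg$decoder_combine)
    cfin <- if (has_edge_module(cfg) && cfg$fuse_mode == "concat")
      2L * sw[1] else sw[1]
    add_conv(b, "final", 3L, 3L, cfin, 1L, bn = FALSE)
  })
  model <- list(config = cfg, params = b$params, state = b$state)
  class(model) <- "meanet_model"
  model
}

# channel count of the tensor entering the edge-module heads
edge_feature_channels <- function(cfg) {
  if (cfg$use_mag) cfg$stage_widths[1]            # U_total has X1's channels
  else cfg$attention_maps                          # heads read A directly
}

add_enc_block <- function(b, name, cin, cout) {
  if (cout < 1L) stop("encoding block '", name, "': out_channels must be >= 1")
  add_conv(b, paste0(name, ".c0"), 3L, 3L, cin, cout)
  add_conv(b, paste0(name, ".c1"), 3L, 1L, cout, cout)
  add_conv(b, paste0(name, ".c2"), 1L, 3L, cout, cout)
  add_conv(b, paste0(name, ".res"), 1L, 1L, cin, cout)
  invisible(b)
}

add_dec_block <- function(b, name, c_low, c_high, combine = "add") {
  add_conv(b, paste0(name, ".low"), 1L, 1L, c_low, c_low)
  add_conv(b, paste0(name, ".high"), 1L, 1L, c_high, c_low)
  add_dense(b, paste0(name, ".g1"), c_low, c_low)
  add_dense(b, paste0(name, ".g2"), c_low, c_low)
  if (combine == "concat")
    add_conv(b, paste0(name, ".proj"), 1L, 1L, 2L * c_low, c_low, bn = FALSE)
  invisible(b)
}

#' Total number of trainable parameters
#' @param model a `meanet_model`.
#' @return integer parameter count.
#' @export
meanet_nparams <- function(model) sum(vapply(model$params, length, 1L))

# --- tape-level block forwards ---------------------------------------------

fw_enc_block <- function(ctx, name, x) {
  m <- fw_conv(ctx, paste0(name, ".c0"), x)
  m <- fw_conv(ctx, paste0(name, ".c1"), m)
  m <- fw_conv(ctx, paste0(name, ".c2"), m)
  r <- fw_conv(ctx, paste0(name, ".res"), x)
  ag_add(ctx$tape, m, r)
}

fw_encode <- function(ctx, x) {
  d <- dim(x$value)
  if (d[1] %% 8L != 0L || d[2] %% 8L != 0L)
    stop("input spatial size ", d[1], " x ", d[2],
         " must be divisible by 8 (three 2x2 down-samplings)")
  E1 <- fw_enc_block(ctx, "enc1", x)
  E2 <- fw_enc_block(ctx, "enc2", ag_maxpool2(ctx$tape, E1))
  E3 <- fw_enc_block(ctx, "enc3", ag_maxpool2(ctx$tape, E2))
  E4 <- fw_enc_block(ctx, "enc4", ag_maxpool2(ctx$tape, E3))
  list(E1 = E1, E2 = E2, E3 = E3, E4 = E4)
}

# A = sum over configured stages of Conv3x3(Es) upsampled to E1 resolution
fw_efe <- function(ctx, stages) {
  cfg <- ctx$model$config
  A <- NULL
  for (s in cfg$efe_stages) {
    br <- fw_conv(ctx, paste0("efe.s", s), stages[[s]])
    if (s > 1L) for (k in seq_len(s - 1L)) br <- ag_up2(ctx$tape, br)
    A <- if (is.null(A)) br else ag_add(ctx$tape, A, br)
  }
  A
}

fw_se <- function(ctx, U) {
  z <- ag_gap(ctx$tape, U)
  h <- ag_relu(ctx$tape, ag_dense(ctx$tape, z, ctx_param(ctx, "se.w2.w")))
  s <- ag_sigmoid(ctx$tape, ag_dense(ctx$tape, h, ctx_param(ctx, "se.w1.w")))
  ag_scale_channels(ctx$tape, U, s)
}

fw_edge_module <- function(ctx, stages) {
  cfg <- ctx$model$config
  X1 <- stages$E1
  A <- if (cfg$use_efe) fw_efe(ctx, stages) else NULL
  if (cfg$use_mag) {
    U <- if (is.null(A)) X1
    else ag_broadcast_mul(ctx$tape, ag_sum_channels(ctx$tape, A), X1)
    Ut <- fw_se(ctx, U)
  } else {
    Ut <- A
  }
  Y1 <- fw_conv(ctx, "edge.y1", Ut)
  y2 <- fw_conv(ctx, "edge.y2a", Ut)
  edge_logits <- fw_conv(ctx, "edge.y2", y2, act = "plain")
  list(Y1 = Y1, edge_logits = edge_logits)
}

fw_dec_block <- function(ctx, name, low, high) {
  cfg <- ctx$model$config
  b1 <- fw_conv(ctx, paste0(name, ".low"), low)
  f <- fw_conv(ctx, paste0(name, ".high"), high)
  f <- ag_up2(ctx$tape, f)
  v <- ag_gmp(ctx$tape, f)
  v <- ag_relu(ctx$tape, ag_dense(ctx$tape, v,
                                  ctx_param(ctx, paste0(name, ".g1.w"))))
  w <- ag_sigmoid(ctx$tape, ag_dense(ctx$tape, v,
                                     ctx_param(ctx, paste0(name, ".g2.w"))))
  b2 <- ag_scale_channels(ctx$tape, f, w)
  if (cfg$decoder_combine == "concat")
    fw_conv(ctx, paste0(name, ".proj"), ag_concat(ctx$tape, b1, b2),
            act = "plain")
  else ag_add(ctx$tape, b1, b2)
}

# full forward pass on the tape; returns nodes
fw_meanet <- function(ctx, x) {
  cfg <- ctx$model$config
  stages <- fw_encode(ctx, x)
  edge <- if (has_edge_module(cfg)) fw_edge_module(ctx, stages) else NULL
  D3 <- fw_dec_block(ctx, "dec3", stages$E3, stages$E4)
  D2 <- fw_dec_block(ctx, "dec2", stages$E2, D3)
  D1 <- fw_dec_block(ctx, "dec1", stages$E1, D2)
  head_in <- if (is.null(edge)) D1
  else if (cfg$fuse_mode == "concat") ag_concat(ctx$tape, D1, edge$Y1)
  else ag_add(ctx$tape, D1, edge$Y1)
  seg_logits <- fw_conv(ctx, "final", head_in, act = "plain")
  list(seg_logits = seg_logits,
       seg_prob = ag_sigmoid(ctx$tape, seg_logits),
       edge_logits = edge$edge_logits,
       edge_prob = if (!is.null(edge))
         ag_sigmoid(ctx$tape, edge$edge_logits))
}

#' Run the network on one image or a batch
#'
#' Evaluation-mode forward pass (batch-norm uses running statistics).
#'
#' @param model a `meanet_model`.
#' @param image an `(H, W, C)` array, `(H, W, C, N)` array, or list of
#'   `(H, W, C)` arrays; `H` and `W` must be divisible by 8.
#' @return list with `seg_prob` and `edge_prob`, `(H, W, 1, N)` probability
#'   arrays at the input resolution (`edge_prob` is `NULL` for the plain
#'   baseline without an edge module).
#' @export
meanet_forward <- function(model, image) {
  stopifnot(inherits(model, "meanet_model"))
  ctx <- new_ctx(model, training = FALSE)
  x <- ag_leaf(ctx$tape, as_batch(image))
  out <- fw_meanet(ctx, x)
  list(seg_prob = out$seg_prob$value,
       edge_prob = if (!is.null(out$edge_prob)) out$edge_prob$value)
}

#' Encoder feature maps E1..E4
#'
#' @param model a `meanet_model`.
#' @param image input image as for [meanet_forward()].
#' @return list of four `(H, W, C, N)` arrays; spatial size halves at each
#'   stage (E1 full resolution, E4 at 1/8).
#' @export
encode <- function(model, image) {
  ctx <- new_ctx(model, training = FALSE)
  x <- ag_leaf(ctx$tape, as_batch(image))
  lapply(fw_encode(ctx, x), function(nd) nd$value)
}

# --- functional single-block surfaces (eval-mode, fresh or given weights) ---

mini_model <- function(build, seed) {
  b <- new_builder()
  local_seed(seed, build(b))
  m <- list(config = NULL, params = b$params, state = b$state)
  class(m) <- "meanet_model"
  m
}

run_mini <- function(model, inputs, fn) {
  ctx <- new_ctx(model, training = FALSE)
  nodes <- lapply(inputs, function(v) ag_leaf(ctx$tape, as_batch(v)))
  out <- fn(ctx, nodes)
  if (is.environment(out)) drop_batch(out$value)
  else lapply(out, function(nd) if (!is.null(nd)) drop_batch(nd$value))
}

drop_batch <- function(v) {
  d <- dim(v)
  if (length(d) == 4L && d[4] == 1L) array(v, d[1:3]) else v
}

#' Create / run one encoding block
#'
#' Main path 3x3 -> 3x1 -> 1x3 convolutions (each ReLU + batch-norm) plus a
#' 1x1 convolution residual path, summed. Spatial size is preserved.
#'
#' @param in_channels,out_channels block widths.
#' @param seed seed for weight initialisation.
#' @export
new_encoding_block <- function(in_channels, out_channels, seed = 1L) {
  if (length(out_channels) != 1L || out_channels < 1L)
    stop("out_channels must be a positive integer")
  m <- mini_model(function(b) add_enc_block(b, "enc", in_channels,
                                            out_channels), seed)
  m$in_channels <- in_channels
  m
}

#' @rdname new_encoding_block
#' @param x an `(H, W, C)` input array.
#' @param block a block from [new_encoding_block()], or an integer
#'   `out_channels` (a fresh block is then created with `seed`).
#' @return `(H, W, out_channels)` array.
#' @export
encoding_block_forward <- function(x, block, seed = 1L) {
  if (is.numeric(block))
    block <- new_encoding_block(dim(x)[3], as.integer(block), seed)
  run_mini(block, list(x), function(ctx, nd) fw_enc_block(ctx, "enc", nd[[1]]))
}

#' Create / run the edge feature extraction (EFE) stack
#'
#' Both inputs are mapped to `n_maps` channels by 3x3 convolutions
#' (ReLU + batch-norm); the half-resolution branch is bilinearly upsampled
#' by 2 and the branches are summed into the attention stack A.
#'
#' @param c1,c2 channel counts of the full- and half-resolution inputs.
#' @param n_maps number of attention maps (default 16).
#' @param seed seed for weight initialisation.
#' @export
new_efe <- function(c1, c2, n_maps = 16L, seed = 1L) {
  m <- mini_model(function(b) {
    add_conv(b, "efe.s1", 3L, 3L, c1, n_maps)
    add_conv(b, "efe.s2", 3L, 3L, c2, n_maps)
  }, seed)
  m$n_maps <- n_maps
  m
}

#' @rdname new_efe
#' @param X1 `(H, W, c1)` array (E1 features, full resolution).
#' @param X2 `(H/2, W/2, c2)` array (E2 features, half resolution).
#' @param efe module from [new_efe()]; created fresh when `NULL`.
#' @return `(H, W, n_maps)` attention stack.
#' @export
efe_forward <- function(X1, X2, efe = NULL, n_maps = 16L, seed = 1L) {
  d1 <- dim(X1); d2 <- dim(X2)
  if (d1[1] != 2L * d2[1] || d1[2] != 2L * d2[2])
    stop("X2 spatial size (", d2[1], " x ", d2[2],
         ") must be exactly half of X1's (", d1[1], " x ", d1[2], ")")
  if (is.null(efe)) efe <- new_efe(d1[3], d2[3], n_maps, seed)
  run_mini(efe, list(X1, X2), function(ctx, nd) {
    a1 <- fw_conv(ctx, "efe.s1", nd[[1]])
    a2 <- ag_up2(ctx$tape, fw_conv(ctx, "efe.s2", nd[[2]]))
    ag_add(ctx$tape, a1, a2)
  })
}

#' Attention-weighted aggregation of shallow features
#'
#' Each single-channel attention map is multiplied elementwise into every
#' channel of `X1`; the N products are summed, so the output keeps `X1`'s
#' channel count.
#'
#' @param A `(H, W, N)` attention stack.
#' @param X1 `(H, W, C)` feature array at the same resolution.
#' @return `(H, W, C)` aggregated features.
#' @export
mag_aggregate <- function(A, X1) {
  da <- dim(A); dx <- dim(X1)
  if (da[1] != dx[1] || da[2] != dx[2])
    stop("attention stack and features must share spatial size")
  asum <- rowSums(A, dims = 2L)
  out <- X1 * as.vector(asum)    # recycles the map across channels
  array(out, dx)
}

#' Squeeze-and-excitation channel gate
#'
#' Squeeze: global average pooling per channel (z). Excitation:
#' `s = sigmoid(W1 relu(W2 z))` with `W2` the reducing and `W1` the
#' expanding fully-connected weight. Scale: each channel of `U` is
#' multiplied by its gate `s_k` in `[0, 1]`.
#'
#' @param C channel count; `reduction` sets the bottleneck width
#'   `max(1, floor(C / reduction))`.
#' @param reduction bottleneck reduction ratio (default 16).
#' @param seed seed for weight initialisation.
#' @return `se_state()`: list with `W1` (`C x Cr`) and `W2` (`Cr x C`).
#' @export
se_state <- function(C, reduction = 16L, seed = 1L) {
  cr <- se_bottleneck(as.integer(C), as.integer(reduction))
  local_seed(seed, list(W1 = init_dense_w(C, cr), W2 = init_dense_w(cr, C)))
}

#' @rdname se_state
#' @param U `(H, W, C)` feature array.
#' @param state an [se_state()].
#' @return list with `scaled` (`(H, W, C)` rescaled features), `z` (squeeze
#'   vector) and `s` (gates in `[0, 1]`).
#' @export
se_forward <- function(U, state) {
  d <- dim(U)
  if (ncol(state$W2) != d[3])
    stop("SE weights expect ", ncol(state$W2), " channels, got ", d[3])
  z <- apply(U, 3L, mean)
  s <- plogis(as.vector(state$W1 %*% pmax(state$W2 %*% z, 0)))
  list(scaled = sweep(U, 3L, s, "*"), z = z, s = s)
}

#' Create / run the multilayer attention guidance (MAG) block
#'
#' Aggregates the attention stack into the shallow features
#' ([mag_aggregate()]), gates channels with squeeze-and-excitation, then
#' branches into 1x1 convolutions producing the decoder-bound edge features
#' Y1 and the one-channel edge logits Y2 for early supervision.
#'
#' @param c_in channel count of `X1`; `c_y1` output channels of Y1.
#' @param c_y1 channels of the decoder-bound edge features.
#' @param se_reduction squeeze-and-excitation reduction ratio.
#' @param seed seed for weight initialisation.
#' @export
new_mag <- function(c_in, c_y1 = c_in, se_reduction = 16L, seed = 1L) {
  cr <- se_bottleneck(c_in, se_reduction)
  mini_model(function(b) {
    add_dense(b, "se.w2", cr, c_in)
    add_dense(b, "se.w1", c_in, cr)
    add_conv(b, "edge.y1", 1L, 1L, c_in, c_y1)
    add_conv(b, "edge.y2a", 1L, 1L, c_in, c_in)
    add_conv(b, "edge.y2", 1L, 1L, c_in, 1L, bn = FALSE)
  }, seed)
}

#' @rdname new_mag
#' @param A `(H, W, N)` attention stack.
#' @param X1 `(H, W, C)` shallow features.
#' @param mag module from [new_mag()]; created fresh when `NULL`.
#' @return list with `Y1` (edge features) and `Y2` (one-channel edge
#'   logits), both at `X1`'s resolution.
#' @export
mag_forward <- function(A, X1, mag = NULL, se_reduction = 16L, seed = 1L) {
  if (is.null(mag)) mag <- new_mag(dim(X1)[3], dim(X1)[3], se_reduction, seed)
  run_mini(mag, list(A, X1), function(ctx, nd) {
    U <- ag_broadcast_mul(ctx$tape, ag_sum_channels(ctx$tape, nd[[1]]),
                          nd[[2]])
    Ut <- fw_se(ctx, U)
    Y1 <- fw_conv(ctx, "edge.y1", Ut)
    Y2 <- fw_conv(ctx, "edge.y2", fw_conv(ctx, "edge.y2a", Ut), act = "plain")
    list(Y1 = Y1, Y2 = Y2)
  })
}

#' Create / run one decoding block
#'
#' Branch 1: 1x1 convolution of the low-level features. Branch 2: 1x1
#' convolution of the high-level features, bilinear x2 upsampling, global
#' max pooling, and two 1x1 convolutions (ReLU then sigmoid) producing
#' per-channel weights in `[0, 1]` that rescale the upsampled features.
#' The branches are combined at the low-level resolution.
#'
#' @param c_low,c_high channel counts of the two inputs.
#' @param combine `"add"` or `"concat"` (with 1x1 projection).
#' @param seed seed for weight initialisation.
#' @export
new_decoding_block <- function(c_low, c_high, combine = "add", seed = 1L) {
  m <- mini_model(function(b) add_dec_block(b, "dec", c_low, c_high, combine),
                  seed)
  m$config <- list(decoder_combine = combine)
  m
}

#' @rdname new_decoding_block
#' @param low `(H, W, c_low)` array; `high` `(H/2, W/2, c_high)` array.
#' @param high high-level (half resolution) features.
#' @param block module from [new_decoding_block()]; created fresh if `NULL`.
#' @return `(H, W, c_low)` array.
#' @export
decoding_block_forward <- function(low, high, block = NULL, seed = 1L) {
  dl <- dim(low); dh <- dim(high)
  if (dl[1] != 2L * dh[1] || dl[2] != 2L * dh[2])
    stop("high-level features must be at half the low-level resolution")
  if (is.null(block))
    block <- new_decoding_block(dl[3], dh[3], seed = seed)
  run_mini(block, list(low, high), function(ctx, nd)
    fw_dec_block(ctx, "dec", nd[[1]], nd[[2]]))
}

# --- checkpoints ------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file holding the weights, the batch-norm
#' running statistics and the full network configuration. Loading verifies
#' the stored configuration and fails loudly on mismatch.
#'
#' @param model a `meanet_model`.
#' @param path file path.
#' @param extra optional named list stored alongside (e.g. history).
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  st <- lapply(model$state, function(e) list(mean = e$mean, var = e$var))
  obj <- c(list(format = "meanet-checkpoint-1", config = model$config,
                params = model$params, state = st), extra)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param config optional `meanet_config`; if supplied it must be identical
#'   to the stored one.
#' @return the restored `meanet_model` (attributes of the checkpoint other
#'   than weights are attached as `attr(model, "extra")`).
#' @export
load_checkpoint <- function(path, config = NULL) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "meanet-checkpoint-1"))
    stop("not a recognised checkpoint file: ", path)
  if (!is.null(config) && !identical(unclass(config), unclass(obj$config)))
    stop("checkpoint configuration does not match the requested one")
  state <- lapply(obj$state, function(s) {
    e <- new.env(parent = emptyenv()); e$mean <- s$mean; e$var <- s$var; e
  })
  model <- list(config = obj$config, params = obj$params, state = state)
  class(model) <- "meanet_model"
  attr(model, "extra") <- obj[setdiff(names(obj),
                                      c("format", "config", "params",
                                        "state"))]
  model
}
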
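# Training, evaluation and prediction: seeded splits, Adam optimisation of
# the joint Dice/BCE objective, best-by-validation-Dice checkpointing, and
# report generation.

#' Training configuration
#'
#' Defaults follow the study protocol: Adam with learning rate 2e-3 and
#' betas (0.5, 0.999), batch size 4, up to 300 epochs, 8:1:1
#' train/validation/test split or five-fold cross-validation, and
#' rotation/flip/translation/mirroring augmentation.
#'
#' @param learning_rate Adam step size.
#' @param adam_betas length-2 numeric, Adam (beta1, beta2).
#' @param batch_size images per optimisation step.
#' @param max_epochs maximum training epochs.
#' @param folds number of cross-validation folds.
#' @param split_ratio length-3 positive weights for train/val/test.
#' @param augment_ops augmentation families applied during training
#'   (subset of rotation, flip, translation, mirroring); `character(0)`
#'   disables augmentation.
#' @param global_seed master seed; splits, weight init, shuffling and
#'   augmentation all derive named sub-seeds from it.
#' @param lr_schedule `"constant"` (default) or `"cosine"` decay.
#' @param eval_every validate every this many epochs.
#' @param loss a [loss_config()].
#' @param network a [network_config()].
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 2e-3,
                         adam_betas = c(0.5, 0.999),
                         batch_size = 4L,
                         max_epochs = 300L,
                         folds = 5L,
                         split_ratio = c(8, 1, 1),
                         augment_ops = c("rotation", "flip", "translation",
                                         "mirroring"),
                         global_seed = 42L,
                         lr_schedule = c("constant", "cosine"),
                         eval_every = 1L,
                         loss = loss_config(),
                         network = network_config()) {
  stopifnot(batch_size >= 1L, folds >= 2L, length(split_ratio) == 3L,
            all(split_ratio > 0), max_epochs >= 1L, learning_rate > 0)
  structure(list(learning_rate = learning_rate, adam_betas = adam_betas,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 folds = as.integer(folds), split_ratio = split_ratio,
                 augment_ops = augment_ops,
                 global_seed = as.integer(global_seed),
                 lr_schedule = match.arg(lr_schedule),
                 eval_every = as.integer(eval_every),
                 loss = loss, network = network),
            class = "train_config")
}

sub_seed <- function(global_seed, what, k = 0L) {
  # small stable offsets keep every derived seed below 2^31
  off <- c(split = 1000L, init = 2000L, shuffle = 3000L, augment = 4000L,
           phantom = 5000L)[[what]]
  (as.integer(global_seed) + off + as.integer(k)) %% .Machine$integer.max
}

#' Seeded dataset splits
#'
#' Either a single ratio split (train/val/test, default 8:1:1) or a k-fold
#' partition where each fold serves once as the test set (the following
#' fold is the validation set, the rest train). Deterministic given
#' `cfg$global_seed`.
#'
#' @param ids character or integer sample identifiers.
#' @param cfg a [train_config()].
#' @param method `"ratio"` or `"kfold"`.
#' @return for `"ratio"`, a list with `train`, `val`, `test`; for
#'   `"kfold"`, a list of `cfg$folds` such lists. Both carry the seed and
#'   method and can be serialised as a manifest with
#'   [write_split_manifest()].
#' @export
make_splits <- function(ids, cfg = train_config(),
                        method = c("ratio", "kfold")) {
  method <- match.arg(method)
  ids <- as.character(ids)
  n <- length(ids)
  need <- if (method == "kfold") cfg$folds else 3L
  if (n < need) stop("need at least ", need, " samples, got ", n)
  perm <- local_seed(sub_seed(cfg$global_seed, "split"), sample(ids))
  out <- if (method == "ratio") {
    r <- cfg$split_ratio / sum(cfg$split_ratio)
    n_tr <- floor(n * r[1]); n_va <- floor(n * r[2])
    list(train = perm[seq_len(n_tr)],
         val = perm[n_tr + seq_len(n_va)],
         test = perm[seq.int(n_tr + n_va + 1L, n)])
  } else {
    fold_of <- rep(seq_len(cfg$folds), length.out = n)
    lapply(seq_len(cfg$folds), function(f) {
      va <- f %% cfg$folds + 1L
      list(test = perm[fold_of == f],
           val = perm[fold_of == va],
           train = perm[!fold_of %in% c(f, va)])
    })
  }
  structure(out, method = method, seed = cfg$global_seed, class = "fold_split")
}

#' @rdname make_splits
#' @param split a `fold_split`.
#' @param path JSON output path.
#' @export
write_split_manifest <- function(split, path) {
  jsonlite::write_json(list(method = attr(split, "method"),
                            seed = attr(split, "seed"),
                            splits = unclass(split)),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params)
  list(t = 0L,
       m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))))

adam_step <- function(params, grads, st, lr, betas, eps = 1e-8) {
  st$t <- st$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  c1 <- 1 - b1^st$t; c2 <- 1 - b2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
    st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(params = params, state = st)
}

# --- gradients / single step ------------------------------------------------

batch_targets <- function(samples) {
  H <- nrow(samples[[1]]$mask); W <- ncol(samples[[1]]$mask)
  n <- length(samples)
  seg <- array(0, c(H, W, 1L, n)); edg <- array(0, c(H, W, 1L, n))
  for (i in seq_len(n)) {
    seg[, , 1L, i] <- samples[[i]]$mask
    edg[, , 1L, i] <- samples[[i]]$edge
  }
  list(seg = seg, edge = edg,
       images = lapply(samples, function(s) s$image))
}

#' Loss and parameter gradients for one batch
#'
#' Runs a training-mode forward pass, evaluates the joint loss and returns
#' the gradient of every trainable parameter.
#'
#' @param model a `meanet_model`.
#' @param samples list of `segmentation_sample`s forming the batch.
#' @param loss_cfg a [loss_config()].
#' @param training batch-norm mode (batch statistics when `TRUE`).
#' @return list with `loss`, `dice_term`, `bce_term` and `grads` (named
#'   list parallel to `model$params`).
#' @export
meanet_gradients <- function(model, samples, loss_cfg = loss_config(),
                             training = TRUE) {
  tg <- batch_targets(samples)
  ctx <- new_ctx(model, training = training)
  x <- ag_leaf(ctx$tape, as_batch(tg$images))
  out <- fw_meanet(ctx, x)
  jl <- ag_joint_loss(ctx$tape, out, tg$seg, tg$edge, loss_cfg)
  ag_backward(ctx$tape, jl$total)
  list(loss = jl$total$value, dice_term = jl$dice_term,
       bce_term = jl$bce_term, grads = ctx_grads(ctx))
}

mean_dice_on <- function(model, samples, threshold = 0.5) {
  d <- vapply(samples, function(sm) {
    pr <- meanet_forward(model, sm$image)$seg_prob[, , 1L, 1L]
    ct <- confusion_counts((pr >= threshold) * 1, sm$mask)
    if (2 * ct$TP + ct$FP + ct$FN == 0) return(NA_real_)
    2 * ct$TP / (2 * ct$TP + ct$FP + ct$FN)
  }, 1)
  mean(d, na.rm = TRUE)
}

#' Train a network on a set of samples
#'
#' Epoch loop of forward pass, joint loss, backpropagation and an Adam
#' update, with seeded shuffling and optional joint augmentation.
#' Validation Dice is monitored every `cfg$eval_every` epochs and the best
#' checkpoint is retained when `checkpoint` is given.
#'
#' @param samples training samples (list of `segmentation_sample`).
#' @param cfg a [train_config()].
#' @param val_samples validation samples; when `NULL` the training set is
#'   monitored instead.
#' @param checkpoint optional path for the best-by-validation-Dice
#'   checkpoint.
#' @param max_steps optional cap on optimiser steps (overrides
#'   `max_epochs` when reached first).
#' @param stop_dice optional early-stop target: training stops once
#'   monitored Dice reaches this value.
#' @param model optional pre-built `meanet_model` to continue training.
#' @param verbose print one line per validation.
#' @return list with `model` (final weights), `best_model`, `history`
#'   (data.frame: epoch, step, lr, train_loss, dice_term, bce_term,
#'   val_dice), and `checkpoint` path (or `NULL`).
#' @export
train_meanet <- function(samples, cfg = train_config(), val_samples = NULL,
                         checkpoint = NULL, max_steps = NULL,
                         stop_dice = NULL, model = NULL, verbose = FALSE) {
  if (length(samples) == 0L) stop("no training samples")
  if (is.null(model))
    model <- new_meanet(cfg$network, seed = sub_seed(cfg$global_seed, "init"))
  monitor <- if (is.null(val_samples)) samples else val_samples
  ad <- adam_init(model$params)
  hist <- list()
  best_dice <- -Inf; best_model <- model
  step <- 0L
  n <- length(samples)
  done <- FALSE
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- local_seed(sub_seed(cfg$global_seed, "shuffle", epoch),
                      sample.int(n))
    losses <- dts <- bts <- c()
    for (b0 in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[seq.int(b0, min(b0 + cfg$batch_size - 1L, n))]
      batch <- lapply(seq_along(idx), function(j) {
        sm <- samples[[idx[j]]]
        if (length(cfg$augment_ops))
          augment_sample(sm, cfg$augment_ops,
                         seed = sub_seed(cfg$global_seed, "augment",
                                         epoch * 1009L + idx[j]))
        else sm
      })
      gr <- meanet_gradients(model, batch, cfg$loss, training = TRUE)
      if (!is.finite(gr$loss))
        stop("non-finite loss at epoch ", epoch, ", step ", step + 1L,
             " (batch ids: ",
             paste(vapply(batch, `[[`, "", "id"), collapse = ", "), ")")
      lr <- if (cfg$lr_schedule == "cosine")
        cfg$learning_rate * 0.5 *
          (1 + cos(pi * (epoch - 1) / cfg$max_epochs))
      else cfg$learning_rate
      upd <- adam_step(model$params, gr$grads, ad, lr, cfg$adam_betas)
      model$params <- upd$params; ad <- upd$state
      step <- step + 1L
      losses <- c(losses, gr$loss); dts <- c(dts, gr$dice_term)
      bts <- c(bts, gr$bce_term)
      if (!is.null(max_steps) && step >= max_steps) { done <- TRUE; break }
    }
    val_dice <- NA_real_
    if (epoch %% cfg$eval_every == 0L || done || epoch == cfg$max_epochs) {
      val_dice <- mean_dice_on(model, monitor)
      if (val_dice > best_dice) {
        best_dice <- val_dice
        best_model <- model
        if (!is.null(checkpoint))
          save_checkpoint(model, checkpoint,
                          extra = list(val_dice = val_dice, epoch = epoch,
                                       step = step))
      }
      if (verbose)
        message(sprintf("epoch %d step %d loss %.4f val_dice %.4f",
                        epoch, step, mean(losses), val_dice))
      if (!is.null(stop_dice) && val_dice >= stop_dice) done <- TRUE
    }
    hist[[length(hist) + 1L]] <-
      data.frame(epoch = epoch, step = step,
                 lr = if (cfg$lr_schedule == "cosine")
                   cfg$learning_rate * 0.5 *
                   (1 + cos(pi * (epoch - 1) / cfg$max_epochs))
                 else cfg$learning_rate,
                 train_loss = mean(losses), dice_term = mean(dts),
                 bce_term = mean(bts), val_dice = val_dice)
    if (done) break
  }
  list(model = model, best_model = best_model,
       history = do.call(rbind, hist),
       best_dice = best_dice,
       checkpoint = checkpoint)
}

#' Evaluate a trained model on a test set
#'
#' @param model a `meanet_model` or path to a checkpoint file.
#' @param samples list of `segmentation_sample`s.
#' @param threshold binarisation threshold.
#' @param bf_cfg a [boundary_match_config()].
#' @param csv,json optional report output paths.
#' @return a `metric_report` (see [evaluate_batch()]).
#' @export
evaluate_meanet <- function(model, samples, threshold = 0.5,
                            bf_cfg = boundary_match_config(),
                            csv = NULL, json = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  preds <- lapply(samples, function(sm) {
    pr <- meanet_forward(model, sm$image)$seg_prob[, , 1L, 1L]
    list(prob = pr, gt = sm$mask, id = sm$id)
  })
  rep <- evaluate_batch(preds, threshold = threshold, cfg = bf_cfg)
  write_report(rep, csv = csv, json = json)
  rep
}

#' Predict masks for images
#'
#' @param model a `meanet_model` or checkpoint path.
#' @param images list of `(H, W, C)` arrays, or paths to PNG files.
#' @param out_dir optional directory; per-image probability
#'   (`<id>_prob.png`, 8-bit), mask (`<id>_mask.png`, 0/255) and edge
#'   (`<id>_edge.png`) files are written there.
#' @param threshold binarisation threshold.
#' @return list per image with `prob`, `mask`, `edge_prob` and `id`;
#'   unreadable image files are skipped with a warning (error if all
#'   fail).
#' @export
predict_meanet <- function(model, images, out_dir = NULL, threshold = 0.5) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ids <- names(images) %||% rep(NA_character_, length(images))
  out <- list()
  for (i in seq_along(images)) {
    im <- images[[i]]
    id <- if (!is.na(ids[i]) && nzchar(ids[i])) ids[i] else
      if (is.character(im)) sub("\\.png$", "", basename(im)) else
        sprintf("img%03d", i)
    if (is.character(im)) {
      im <- tryCatch(read_image_png(im, model$config$in_channels),
                     error = function(e) {
                       warning("skipping unreadable image: ",
                               conditionMessage(e))
                       NULL
                     })
      if (is.null(im)) next
    }
    fw <- meanet_forward(model, im)
    prob <- fw$seg_prob[, , 1L, 1L]
    mask <- (prob >= threshold) * 1
    eprob <- if (!is.null(fw$edge_prob)) fw$edge_prob[, , 1L, 1L]
    if (!is.null(out_dir)) {
      png::writePNG(prob, file.path(out_dir, paste0(id, "_prob.png")))
      png::writePNG(mask, file.path(out_dir, paste0(id, "_mask.png")))
      if (!is.null(eprob))
        png::writePNG((eprob >= threshold) * 1,
                      file.path(out_dir, paste0(id, "_edge.png")))
    }
    out[[length(out) + 1L]] <- list(id = id, prob = prob, mask = mask,
                                    edge_prob = eprob)
  }
  if (length(out) == 0L) stop("no image could be read")
  out
}

# --- YAML configuration -----------------------------------------------------

#' Build a training configuration from a YAML file
#'
#' The file may contain `network:`, `loss:` and `train:` sections whose
#' keys mirror the [network_config()], [loss_config()] and
#' [train_config()] arguments.
#'
#' @param path YAML file path.
#' @return a `train_config`.
#' @export
config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  net <- do.call(network_config, y$network %||% list())
  los <- do.call(loss_config, y$loss %||% list())
  args <- y$train %||% list()
  args$network <- net
  args$loss <- los
  do.call(train_config, args)
}
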
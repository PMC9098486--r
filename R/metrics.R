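# Per-image evaluation suite: confusion-matrix metrics (accuracy,
# sensitivity, Dice), pixelwise ROC AUC, and the boundary F1 score (BF),
# each computed per image and aggregated as mean +/- standard deviation
# over the test images.

#' Pixel confusion counts
#'
#' @param pred_mask,gt_mask binary arrays/matrices of equal shape.
#' @return list with integer `TP`, `FP`, `TN`, `FN` summing to the pixel
#'   count.
#' @export
confusion_counts <- function(pred_mask, gt_mask) {
  if (length(pred_mask) != length(gt_mask))
    stop("prediction and ground truth shapes differ")
  if (!all(pred_mask %in% c(0, 1)) || !all(gt_mask %in% c(0, 1)))
    stop("confusion_counts expects binary masks; threshold first")
  p <- as.logical(pred_mask); g <- as.logical(gt_mask)
  list(TP = sum(p & g), FP = sum(p & !g), TN = sum(!p & !g),
       FN = sum(!p & g))
}

#' Confusion-matrix metrics averaged over images
#'
#' Accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)` and Dice
#' `2TP/(2TP+FP+FN)` are computed per image and then averaged over the N
#' test images. Images whose ground truth has no foreground leave
#' sensitivity and Dice undefined (0/0) and are dropped from those two
#' means with a warning.
#'
#' @param counts list of per-image confusion counts
#'   ([confusion_counts()]).
#' @return list with `accuracy`, `sensitivity`, `dice` (each the mean over
#'   images) and the per-image vectors in `per_image`.
#' @export
scalar_metrics <- function(counts) {
  if (length(counts) == 0L) stop("no images to evaluate")
  acc <- sen <- dic <- numeric(length(counts))
  for (i in seq_along(counts)) {
    ct <- counts[[i]]
    tot <- ct$TP + ct$TN + ct$FP + ct$FN
    acc[i] <- (ct$TP + ct$TN) / tot
    pos <- ct$TP + ct$FN
    sen[i] <- if (pos > 0) ct$TP / pos else NA_real_
    dic[i] <- if (2 * ct$TP + ct$FP + ct$FN > 0)
      2 * ct$TP / (2 * ct$TP + ct$FP + ct$FN) else NA_real_
  }
  if (anyNA(sen) || anyNA(dic))
    warning("images with empty ground-truth foreground excluded from ",
            "sensitivity/Dice means")
  list(accuracy = mean(acc), sensitivity = mean(sen, na.rm = TRUE),
       dice = mean(dic, na.rm = TRUE),
       per_image = list(accuracy = acc, sensitivity = sen, dice = dic))
}

#' Pixelwise ROC AUC
#'
#' The probability that a randomly drawn foreground pixel is scored above a
#' randomly drawn background pixel, with ties counted one half
#' (Mann-Whitney form via midranks).
#'
#' @param prob_map numeric score array.
#' @param gt_mask binary array of the same shape.
#' @return AUC in `[0, 1]`, or `NA` when the ground truth has one class.
#' @export
auc_score <- function(prob_map, gt_mask) {
  if (length(prob_map) != length(gt_mask))
    stop("score map and ground truth shapes differ")
  g <- as.logical(gt_mask)
  n1 <- sum(g); n0 <- sum(!g)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(as.vector(prob_map), ties.method = "average")
  (sum(r[g]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Boundary matching configuration
#'
#' @param tolerance matching distance in pixels; a boundary point counts as
#'   matched when some boundary point of the other mask lies within this
#'   Euclidean distance. The default, `NULL`, resolves per image to 0.75%
#'   of the image diagonal (the usual contour-matching convention).
#' @param connectivity 4 or 8; a mask pixel is a boundary pixel when at
#'   least one of its 4- (or 8-) neighbours is background.
#' @return a `boundary_match_config` list.
#' @export
boundary_match_config <- function(tolerance = NULL, connectivity = 4L) {
  if (!is.null(tolerance)) stopifnot(tolerance >= 0)
  stopifnot(connectivity %in% c(4L, 8L))
  structure(list(tolerance = tolerance,
                 connectivity = as.integer(connectivity)),
            class = "boundary_match_config")
}

# (row, col) coordinates of mask pixels with a background neighbour
boundary_points <- function(mask, connectivity = 4L) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- m
  shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8L)
    shifts <- c(shifts, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  has_bg <- matrix(FALSE, H, W)
  for (s in shifts)
    has_bg <- has_bg |
      pad[2:(H + 1L) + s[1], 2:(W + 1L) + s[2]] == 0
  which(m == 1 & has_bg, arr.ind = TRUE)
}

#' Boundary F1 score
#'
#' Boundary precision is the fraction of predicted-boundary points within
#' the tolerance of some ground-truth boundary point; boundary recall is
#' the symmetric fraction; BF is their harmonic mean. Two empty boundaries
#' agree perfectly (BF = 1); exactly one empty boundary scores 0.
#'
#' @param pred_mask,gt_mask binary arrays of equal shape.
#' @param cfg a [boundary_match_config()].
#' @return BF score in `[0, 1]`.
#' @export
bf_score <- function(pred_mask, gt_mask, cfg = boundary_match_config()) {
  pred_mask <- as_mask_matrix(pred_mask); gt_mask <- as_mask_matrix(gt_mask)
  if (!identical(dim(pred_mask), dim(gt_mask)))
    stop("masks must share shape")
  theta <- cfg$tolerance
  if (is.null(theta))
    theta <- 0.0075 * sqrt(sum(dim(gt_mask)^2))
  bp <- boundary_points(pred_mask, cfg$connectivity)
  bg <- boundary_points(gt_mask, cfg$connectivity)
  if (nrow(bp) == 0L && nrow(bg) == 0L) return(1)
  if (nrow(bp) == 0L || nrow(bg) == 0L) return(0)
  d2 <- outer(bp[, 1], bg[, 1], "-")^2 + outer(bp[, 2], bg[, 2], "-")^2
  prec <- mean(apply(d2, 1L, min) <= theta^2)
  rec <- mean(apply(d2, 2L, min) <= theta^2)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

as_mask_matrix <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("mask must be a matrix or array")
  if (length(d) > 2L) {
    if (prod(d[-(1:2)]) != 1L) stop("mask must be single-channel")
    x <- array(x, d[1:2])
  }
  as.matrix(x)
}

#' Evaluate a batch of predictions
#'
#' Binarises each probability map at `threshold`, computes the five
#' per-image metrics (accuracy, sensitivity, Dice, AUC, BF score) and
#' aggregates mean and standard deviation over the images.
#'
#' @param samples list of lists, each with `prob` (probability map), `gt`
#'   (binary mask) and optionally `id`.
#' @param threshold binarisation threshold in (0, 1).
#' @param cfg a [boundary_match_config()].
#' @return a `metric_report`: list with `per_image` (data.frame, one row
#'   per image) and `aggregate` (data.frame with mean and sd per metric).
#' @export
evaluate_batch <- function(samples, threshold = 0.5,
                           cfg = boundary_match_config()) {
  if (length(samples) == 0L) stop("empty sample list")
  stopifnot(threshold > 0, threshold < 1)
  rows <- lapply(seq_along(samples), function(i) {
    sm <- samples[[i]]
    prob <- as_mask_matrix(sm$prob)
    gt <- as_mask_matrix(sm$gt)
    pred <- (prob >= threshold) * 1
    ct <- confusion_counts(pred, gt)
    sc <- suppressWarnings(scalar_metrics(list(ct)))
    data.frame(id = if (!is.null(sm$id)) sm$id else paste0("img", i),
               accuracy = sc$accuracy,
               sensitivity = sc$per_image$sensitivity[1],
               dice = sc$per_image$dice[1],
               auc = auc_score(prob, gt),
               bf = bf_score(pred, gt, cfg),
               stringsAsFactors = FALSE)
  })
  per_image <- do.call(rbind, rows)
  metrics <- c("accuracy", "sensitivity", "dice", "auc", "bf")
  aggregate <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_image[[m]], na.rm = TRUE), 1),
    sd = vapply(metrics, function(m) {
      v <- per_image[[m]][!is.na(per_image[[m]])]
      if (length(v) > 1L) sd(v) else 0
    }, 1),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(per_image = per_image, aggregate = aggregate,
                 threshold = threshold), class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  cat("Segmentation metrics over", nrow(x$per_image), "images",
      sprintf("(threshold %.2f)\n", x$threshold))
  for (i in seq_len(nrow(x$aggregate)))
    cat(sprintf("  %-12s %s\n", x$aggregate$metric[i],
                format_pm(x$aggregate$mean[i], x$aggregate$sd[i], digits)))
  invisible(x)
}

format_pm <- function(m, s, digits = 4)
  sprintf("%.*f \u00b1 %.*f", digits, m, digits, s)

#' Write a metric report to CSV and JSON
#'
#' The CSV holds one row per image plus `mean`/`sd` aggregate rows; the
#' JSON mirrors the report structure.
#'
#' @param report a `metric_report` from [evaluate_batch()].
#' @param csv,json output paths (either may be `NULL` to skip).
#' @return invisibly, the report.
#' @export
write_report <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv)) {
    per <- report$per_image
    agg <- as.data.frame(c(list(id = c("mean", "sd")),
                           lapply(report$aggregate$metric, function(m) {
                             i <- match(m, report$aggregate$metric)
                             c(report$aggregate$mean[i],
                               report$aggregate$sd[i])
                           })))
    names(agg) <- names(per)
    utils::write.csv(rbind(per, agg), csv, row.names = FALSE)
  }
  if (!is.null(json))
    jsonlite::write_json(list(per_image = report$per_image,
                              aggregate = report$aggregate,
                              threshold = report$threshold),
                         json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(report)
}
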
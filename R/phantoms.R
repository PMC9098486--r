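# Seeded synthetic phantoms emulating three binary-segmentation regimes:
# one large compact object on a cluttered background (tongue-like), thin
# branching curvilinear trees (retinal-vessel-like), and paired smooth
# regions with interior holes (lung-CT-like). Foreground intensity is
# centred at 0.7 and background at 0.3 with additive Gaussian noise, so
# toy problems are learnable in minutes on a CPU.

#' Phantom specification
#'
#' @param kind `"blob"`, `"vessel"` or `"lung_pair"`.
#' @param size `(H, W)` in pixels, each divisible by 8 (the network's
#'   input precondition).
#' @param noise_sigma standard deviation of additive Gaussian image noise.
#' @param clutter_level amount of background clutter / interior structure
#'   in `[0, 1]`.
#' @param seed integer; generation is bitwise deterministic given the spec.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(kind = c("blob", "vessel", "lung_pair"),
                         size = c(64L, 64L), noise_sigma = 0.05,
                         clutter_level = 0.3, seed = 1L) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 8L) || any(size %% 8L != 0L))
    stop("size must be two integers, each >= 8 and divisible by 8")
  stopifnot(noise_sigma >= 0, clutter_level >= 0, clutter_level <= 1)
  structure(list(kind = kind, size = size, noise_sigma = noise_sigma,
                 clutter_level = clutter_level, seed = as.integer(seed)),
            class = "phantom_spec")
}

# radius profile r(theta) = r0 * (1 + sum_k a_k cos(k theta + phi_k))
fourier_blob_mask <- function(H, W, centre, r0, n_harm = 5L, amp = 0.12) {
  a <- runif(n_harm, 0, amp) / seq_len(n_harm)
  phi <- runif(n_harm, 0, 2 * pi)
  ii <- matrix(seq_len(H), H, W)
  jj <- matrix(seq_len(W), H, W, byrow = TRUE)
  dy <- ii - centre[1]; dx <- jj - centre[2]
  th <- atan2(dx, dy)
  r <- sqrt(dy^2 + dx^2)
  rmax <- r0 * (1 + Reduce(`+`, lapply(seq_len(n_harm), function(k)
    a[k] * cos(k * th + phi[k]))))
  (r <= rmax) * 1
}

disc_mask <- function(H, W, centre, radius) {
  ii <- matrix(seq_len(H), H, W)
  jj <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((ii - centre[1])^2 + (jj - centre[2])^2 <= radius^2) * 1
}

phantom_blob <- function(H, W, clutter) {
  centre <- c(H / 2 + runif(1, -0.06, 0.06) * H,
              W / 2 + runif(1, -0.06, 0.06) * W)
  mask <- fourier_blob_mask(H, W, centre, 0.30 * min(H, W))
  n_d <- round(6 * clutter)
  clut <- matrix(0, H, W)
  for (k in seq_len(n_d)) {
    c_k <- c(runif(1, 0.1, 0.9) * H, runif(1, 0.1, 0.9) * W)
    d <- disc_mask(H, W, c_k, runif(1, 0.03, 0.08) * min(H, W))
    clut <- clut + d * runif(1, -0.25, 0.25)
  }
  list(mask = mask, clutter = clut * (1 - mask))
}

phantom_vessel <- function(H, W, clutter) {
  mask <- matrix(0, H, W)
  stamp <- function(y, x, wdt) {
    r <- max(0, (wdt - 1) / 2)
    for (dy in -ceiling(r):ceiling(r)) for (dx in -ceiling(r):ceiling(r)) {
      if (dy * dy + dx * dx > r * r + 0.26) next
      yy <- round(y) + dy; xx <- round(x) + dx
      if (yy >= 1 && yy <= H && xx >= 1 && xx <= W) mask[yy, xx] <<- 1
    }
  }
  n_trunk <- 2L + rbinom(1L, 1L, 0.5)
  queue <- lapply(seq_len(n_trunk), function(k)
    list(y = runif(1, 0.05, 0.95) * H, x = 1, dir = runif(1, -0.5, 0.5),
         wdt = sample(2:3, 1), depth = 0L))
  max_seg <- 40L + round(20 * clutter)
  while (length(queue) > 0L) {
    br <- queue[[1L]]; queue <- queue[-1L]
    y <- br$y; x <- br$x; dir <- br$dir; wdt <- br$wdt
    for (s in seq_len(max_seg)) {
      stamp(y, x, wdt)
      dir <- dir + rnorm(1, 0, 0.18)
      dir <- max(min(dir, 1.2), -1.2)     # keep flowing left to right
      y <- y + sin(dir); x <- x + cos(dir)
      if (y < 1 || y > H || x < 1 || x > W) break
      if (br$depth < 2L && runif(1) < 0.04) {
        queue <- c(queue, list(list(y = y, x = x,
                                    dir = dir + sample(c(-1, 1), 1) *
                                      runif(1, 0.4, 0.8),
                                    wdt = max(1, wdt - 1),
                                    depth = br$depth + 1L)))
      }
    }
  }
  list(mask = mask, clutter = matrix(0, H, W))
}

phantom_lung_pair <- function(H, W, clutter) {
  centre_l <- c(H / 2 + runif(1, -0.04, 0.04) * H, 0.30 * W)
  r0 <- 0.21 * min(H, W)
  left <- fourier_blob_mask(H, W, centre_l, r0, amp = 0.08)
  # squash horizontally into a lung-ish ellipse, then mirror
  left <- left * (abs(matrix(seq_len(W), H, W, byrow = TRUE) -
                        centre_l[2]) <= 0.18 * W)
  right <- left[, W:1]
  mask <- pmax(left, right)
  n_h <- round(3 * clutter)
  for (k in seq_len(n_h)) {
    side <- if (runif(1) < 0.5) centre_l[2] else W + 1 - centre_l[2]
    hc <- c(centre_l[1] + runif(1, -0.08, 0.08) * H,
            side + runif(1, -0.05, 0.05) * W)
    mask <- mask * (1 - disc_mask(H, W, hc, runif(1, 0.02, 0.045) *
                                    min(H, W)))
  }
  list(mask = mask, clutter = matrix(0, H, W))
}

#' Generate a synthetic segmentation phantom
#'
#' Produces an image, its binary mask and a derived binary edge label
#' (width-1 morphological gradient of the mask), bitwise deterministic for
#' a given spec.
#'
#' @param spec a [phantom_spec()].
#' @return a `segmentation_sample`: list with `image` (`(H, W, 1)` array in
#'   `[0, 1]`), `mask` and `edge` (binary `H x W` matrices) and `id`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$size[1]; W <- spec$size[2]
  local_seed(spec$seed, {
    geo <- switch(spec$kind,
                  blob = phantom_blob(H, W, spec$clutter_level),
                  vessel = phantom_vessel(H, W, spec$clutter_level),
                  lung_pair = phantom_lung_pair(H, W, spec$clutter_level))
    img <- 0.3 + 0.4 * geo$mask + geo$clutter
    if (spec$noise_sigma > 0)
      img <- img + matrix(rnorm(H * W, 0, spec$noise_sigma), H, W)
    img <- pmin(pmax(img, 0), 1)
    sample_obj(array(img, c(H, W, 1L)), geo$mask,
               derive_edge_map(geo$mask),
               sprintf("%s-%06d", spec$kind, spec$seed))
  })
}

sample_obj <- function(image, mask, edge, id) {
  structure(list(image = image, mask = mask, edge = edge, id = id),
            class = "segmentation_sample")
}

#' Derive a binary edge label from a mask
#'
#' Morphological gradient: dilation minus erosion with a width-`width`
#' structuring element, i.e. the band of pixels within `width` of the mask
#' boundary. `side = "inner"` keeps only mask pixels of the band
#' (mask minus erosion); `"outer"` only background pixels.
#'
#' @param mask binary matrix.
#' @param width band half-width in pixels (>= 1).
#' @param side `"both"` (default, the full gradient), `"inner"` or
#'   `"outer"`.
#' @param connectivity 4 (diamond element) or 8 (box element).
#' @return binary matrix of the same size.
#' @export
derive_edge_map <- function(mask, width = 1L,
                            side = c("both", "inner", "outer"),
                            connectivity = 4L) {
  side <- match.arg(side)
  stopifnot(width >= 1L, connectivity %in% c(4L, 8L))
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  if (all(m == 0)) return(m)
  kern <- EBImage::makeBrush(2L * as.integer(width) + 1L,
                             if (connectivity == 4L) "diamond" else "box")
  dil <- EBImage::dilate(m, kern)
  ero <- EBImage::erode(m, kern)
  out <- switch(side, both = dil - ero, inner = m - ero, outer = dil - m)
  matrix(as.numeric(out > 0), nrow(m), ncol(m))
}

# --- augmentation -----------------------------------------------------------

# rotate counter-clockwise k quarter turns
rotate_ccw <- function(x, k) {
  k <- k %% 4L
  if (k == 0L) return(x)
  for (i in seq_len(k)) x <- t(x)[nrow(t(x)):1, , drop = FALSE]
  x
}

shift_int <- function(x, dy, dx, fill = 0) {
  H <- nrow(x); W <- ncol(x)
  out <- matrix(fill, H, W)
  ys <- seq_len(H) - dy; xs <- seq_len(W) - dx
  ok_y <- ys >= 1 & ys <= H; ok_x <- xs >= 1 & xs <= W
  out[which(ok_y), which(ok_x)] <- x[ys[ok_y], xs[ok_x], drop = FALSE]
  out
}

apply_geom <- function(x, tf, fill = 0) {
  x <- rotate_ccw(x, tf$rot)
  if (tf$flip) x <- x[, ncol(x):1, drop = FALSE]     # horizontal flip
  if (tf$mirror) x <- x[nrow(x):1, , drop = FALSE]   # vertical mirror
  if (tf$shift[1] != 0L || tf$shift[2] != 0L)
    x <- shift_int(x, tf$shift[1], tf$shift[2], fill)
  x
}

#' Jointly augment an image/mask/edge sample
#'
#' Samples one geometric transform from the requested op families and
#' applies it identically to image, mask and edge label. All transforms
#' are exact (quarter-turn rotations, axis flips, integer translations),
#' so masks stay binary without resampling. Translation pads the image
#' with the background intensity (0.3) and labels with 0.
#'
#' @param sample a `segmentation_sample`.
#' @param ops subset of `c("rotation", "flip", "translation",
#'   "mirroring")`.
#' @param seed integer seed for the sampled transform.
#' @param transform optional explicit transform (list with `rot`, `flip`,
#'   `mirror`, `shift`) overriding sampling; ops outside `ops` are forced
#'   to identity.
#' @return the augmented `segmentation_sample`; the applied transform is
#'   attached as `attr(, "transform")`.
#' @export
augment_sample <- function(sample,
                           ops = c("rotation", "flip", "translation",
                                   "mirroring"),
                           seed = 1L, transform = NULL) {
  known <- c("rotation", "flip", "translation", "mirroring")
  bad <- setdiff(ops, known)
  if (length(bad)) stop("unknown augmentation op(s): ",
                        paste(bad, collapse = ", "))
  H <- nrow(sample$mask); W <- ncol(sample$mask)
  if (is.null(transform)) {
    transform <- local_seed(seed, list(
      rot = if ("rotation" %in% ops && H == W) sample.int(4L, 1L) - 1L
      else 0L,
      flip = "flip" %in% ops && runif(1) < 0.5,
      mirror = "mirroring" %in% ops && runif(1) < 0.5,
      shift = if ("translation" %in% ops)
        c(sample.int(2L * (H %/% 10L) + 1L, 1L) - (H %/% 10L) - 1L,
          sample.int(2L * (W %/% 10L) + 1L, 1L) - (W %/% 10L) - 1L)
      else c(0L, 0L)))
  } else {
    transform <- list(rot = if ("rotation" %in% ops) transform$rot %||% 0L
                      else 0L,
                      flip = "flip" %in% ops && isTRUE(transform$flip),
                      mirror = "mirroring" %in% ops &&
                        isTRUE(transform$mirror),
                      shift = if ("translation" %in% ops)
                        as.integer(transform$shift %||% c(0L, 0L))
                      else c(0L, 0L))
  }
  img <- apply_geom(sample$image[, , 1L], transform, fill = 0.3)
  out <- sample_obj(array(img, c(dim(img), 1L)),
                    apply_geom(sample$mask, transform, 0),
                    apply_geom(sample$edge, transform, 0),
                    sample$id)
  attr(out, "transform") <- transform
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
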
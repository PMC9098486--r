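# Phantom generation, edge-label derivation, joint augmentation and
# dataset round-trips.

test_that("phantom generation is bitwise deterministic and well-formed", {
  sp <- phantom_spec("blob", c(32, 32), noise_sigma = 0.05,
                     clutter_level = 0.5, seed = 7)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a, b)
  expect_equal(dim(a$image), c(32L, 32L, 1L))
  expect_true(all(a$image >= 0 & a$image <= 1))
  expect_true(all(a$mask %in% c(0, 1)))
  expect_true(all(a$edge %in% c(0, 1)))
  expect_error(phantom_spec("blob", c(30, 32)), "divisible by 8")
})

test_that("noise-free clutter-free blob is two-valued with exact mask", {
  sp <- phantom_spec("blob", c(32, 32), noise_sigma = 0,
                     clutter_level = 0, seed = 3)
  sm <- generate_phantom(sp)
  vals <- sort(unique(as.vector(sm$image)))
  expect_equal(vals, c(0.3, 0.7))
  expect_equal((sm$image[, , 1] > 0.5) * 1, sm$mask)
})

test_that("vessel phantoms occupy a plausible foreground fraction", {
  fr <- vapply(1:40, function(s) {
    m <- generate_phantom(phantom_spec("vessel", c(64, 64), seed = s))$mask
    mean(m)
  }, 1)
  expect_true(all(fr > 0.01 & fr < 0.25))
})

test_that("lung-pair phantoms are mirrored regions, holes under clutter", {
  sm <- generate_phantom(phantom_spec("lung_pair", c(64, 64),
                                      clutter_level = 0, seed = 5))
  # two disjoint components, mirror-symmetric up to the random centre jitter
  left <- sm$mask[, 1:32]; right <- sm$mask[, 64:33]
  expect_gt(sum(left), 0); expect_gt(sum(right), 0)
  expect_equal(left, right)
  holey <- generate_phantom(phantom_spec("lung_pair", c(64, 64),
                                         clutter_level = 1, seed = 5))
  expect_lte(sum(holey$mask), sum(sm$mask))
})

test_that("edge maps follow the morphological gradient and its variants", {
  m <- matrix(0, 8, 8); m[3:6, 3:6] <- 1
  inner <- derive_edge_map(m, width = 1, side = "inner")
  expect_equal(sum(inner), 12)                       # 16 - 4 interior
  expect_equal(inner, m - (m == 1 & rbind(m[-1, ], 0) == 1 &
                             rbind(0, m[-8, ]) == 1 &
                             cbind(m[, -1], 0) == 1 &
                             cbind(0, m[, -8]) == 1) * 1)
  grad <- derive_edge_map(m, width = 1)
  expect_equal(sum(grad), 28)                        # 12 inner + 16 outer
  # gradient is symmetric under mask complement
  expect_equal(derive_edge_map(1 - m, width = 1), grad)
  expect_equal(derive_edge_map(matrix(0, 5, 5)), matrix(0, 5, 5))
  # the band never reaches pixels eroded by width + 1
  sp <- phantom_spec("blob", c(32, 32), seed = 11)
  msk <- generate_phantom(sp)$mask
  for (w in 1:2) {
    band <- derive_edge_map(msk, width = w)
    deep <- EBImage::erode(msk, EBImage::makeBrush(2 * (w + 1) + 1,
                                                   "diamond"))
    expect_equal(sum(band * deep), 0)
  }
})

test_that("augmentation applies one joint transform exactly", {
  sm <- generate_phantom(phantom_spec("blob", c(32, 32), seed = 13))
  # flips are involutions
  tf <- list(flip = TRUE)
  once <- augment_sample(sm, ops = "flip", transform = tf)
  twice <- augment_sample(once, ops = "flip", transform = tf)
  expect_equal(twice$image, sm$image)
  expect_equal(twice$mask, sm$mask)
  # identity transform
  id <- augment_sample(sm, transform = list(rot = 0L, flip = FALSE,
                                            mirror = FALSE,
                                            shift = c(0L, 0L)))
  expect_equal(id$mask, sm$mask)
  expect_equal(id$image, sm$image)
  expect_error(augment_sample(sm, ops = "shear"), "unknown")

  # sampled transforms keep image/mask/edge aligned and masks binary
  for (s in 1:5) {
    aug <- augment_sample(sm, seed = s)
    expect_true(all(aug$mask %in% c(0, 1)))
    tf <- attr(aug, "transform")
    moved <- meanet:::apply_geom(sm$mask, tf, 0)
    expect_equal(aug$mask, moved)   # mask transformed exactly like a map
    # rotations/flips preserve foreground count; translation may clip
    if (all(tf$shift == 0L))
      expect_equal(sum(aug$mask), sum(sm$mask))
  }
})

test_that("datasets round-trip through PNG plus manifest", {
  sms <- lapply(1:3, function(s)
    generate_phantom(phantom_spec("blob", c(16, 16), seed = s)))
  dir <- file.path(tempfile(), "ds")
  man <- write_dataset(sms, dir, splits = c("blob-000001" = "train",
                                            "blob-000002" = "val",
                                            "blob-000003" = "test"))
  expect_setequal(vapply(man$samples, `[[`, "", "id"),
                  vapply(sms, `[[`, "", "id"))
  back <- read_dataset(dir)
  for (i in 1:3) {
    expect_identical(back[[i]]$mask, sms[[i]]$mask)
    expect_identical(back[[i]]$edge, sms[[i]]$edge)
    expect_lt(max(abs(back[[i]]$image - sms[[i]]$image)), 1 / 255)
  }
  expect_length(read_dataset(dir, split = "val"), 1L)
  file.remove(file.path(dir, "masks", "blob-000002.png"))
  expect_error(read_dataset(dir), "blob-000002")
})

test_that("gray-level and RGBA mask PNGs normalise by the nonzero rule", {
  m <- matrix(0, 8, 8); m[2:5, 3:7] <- 1
  fgray <- tempfile(fileext = ".png")
  png::writePNG(m * 0.2, fgray)             # non-255 gray levels
  expect_equal(meanet:::read_mask_png(fgray), m)
  rgba <- array(0, c(8, 8, 4)); rgba[, , 1] <- m * 0.5; rgba[, , 4] <- 1
  frgba <- tempfile(fileext = ".png")
  png::writePNG(rgba, frgba)                # opaque alpha must be ignored
  expect_equal(meanet:::read_mask_png(frgba), m)
})
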
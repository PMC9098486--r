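# On-disk dataset layout: PNG images/masks/edges plus a JSON manifest.
# Masks and edges are written as 0/255 single-channel PNGs; on read, any
# nonzero pixel (after collapsing channels by max) maps to 1, which also
# normalises 16-bit and RGBA mask files.

#' Write a phantom dataset to disk
#'
#' @param samples list of `segmentation_sample`s.
#' @param directory output directory (created if missing).
#' @param splits optional named character vector mapping sample id to a
#'   split label, recorded in the manifest.
#' @return invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
write_dataset <- function(samples, directory, splits = NULL) {
  for (sub in c("images", "masks", "edges"))
    dir.create(file.path(directory, sub), recursive = TRUE,
               showWarnings = FALSE)
  entries <- lapply(samples, function(sm) {
    id <- sm$id
    img <- sm$image
    if (length(dim(img)) == 3L && dim(img)[3] == 1L)
      img <- img[, , 1L]
    png::writePNG(img, file.path(directory, "images",
                                 paste0(id, ".png")))
    png::writePNG(sm$mask, file.path(directory, "masks",
                                     paste0(id, ".png")))
    png::writePNG(sm$edge, file.path(directory, "edges",
                                     paste0(id, ".png")))
    list(id = id,
         split = if (!is.null(splits) && id %in% names(splits))
           unname(splits[id]) else "train",
         image = file.path("images", paste0(id, ".png")),
         mask = file.path("masks", paste0(id, ".png")),
         edge = file.path("edges", paste0(id, ".png")))
  })
  manifest <- list(format = "meanet-dataset-1", samples = entries)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

read_mask_png <- function(path) {
  px <- png::readPNG(path)   # 8- and 16-bit PNGs both arrive scaled to [0,1]
  if (length(dim(px)) == 3L) {
    nc <- dim(px)[3]
    keep <- if (nc %in% c(2L, 4L)) seq_len(nc - 1L) else seq_len(nc)
    px <- apply(px[, , keep, drop = FALSE], c(1, 2), max)  # drop alpha
  }
  matrix(as.numeric(px > 0), nrow(px), ncol(px))
}

read_image_png <- function(path, channels = NULL) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 1L))
  if (!is.null(channels) && dim(px)[3] != channels) {
    if (channels == 1L) px <- array(apply(px[, , 1:min(3, dim(px)[3]),
                                             drop = FALSE], c(1, 2), mean),
                                    c(dim(px)[1:2], 1L))
    else stop("image ", path, " has ", dim(px)[3], " channels, expected ",
              channels)
  }
  px
}

#' Read a dataset written by [write_dataset()]
#'
#' @param directory dataset directory containing `manifest.json`.
#' @param split optional split label filter.
#' @return list of `segmentation_sample`s; the manifest is attached as an
#'   attribute.
#' @export
read_dataset <- function(directory, split = NULL) {
  mpath <- file.path(directory, "manifest.json")
  if (!file.exists(mpath)) stop("no manifest.json under ", directory)
  manifest <- jsonlite::read_json(mpath)
  entries <- manifest$samples
  if (!is.null(split))
    entries <- Filter(function(e) identical(e$split, split), entries)
  samples <- lapply(entries, function(e) {
    paths <- file.path(directory, c(e$image, e$mask, e$edge))
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("sample '", e$id, "': missing file(s) ",
           paste(missing, collapse = ", "))
    mask <- read_mask_png(paths[2])
    edge <- read_mask_png(paths[3])
    sample_obj(read_image_png(paths[1]), mask, edge, e$id)
  })
  attr(samples, "manifest") <- manifest
  samples
}
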
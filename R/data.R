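# Fundus dataset handling.
#
# A sample record is one fundus case: RGB image, binary vessel mask (first
# expert annotation), binary FOV mask and an id, tagged train or test. The
# public datasets follow a 1:1 train/test split: DRIVE 565x584, 40 images;
# CHASE_DB1 999x960, 28; STARE 700x605, 20. Images are read from an
# `images/`, `1st_manual/`, `mask/` directory triple (the DRIVE layout; the
# synthetic writer emits the same structure), PNG or TIFF.

dataset_table <- list(
  DRIVE = list(resolution = c(584L, 565L), count = 40L),
  CHASE_DB1 = list(resolution = c(960L, 999L), count = 28L),
  STARE = list(resolution = c(605L, 700L), count = 20L),
  synthetic = list(resolution = NULL, count = NULL))

#' Describe a dataset on disk
#'
#' @param name One of `"DRIVE"`, `"STARE"`, `"CHASE_DB1"`, `"synthetic"`.
#'   The named public layouts carry expected resolution and image count
#'   (DRIVE 565x584/40, CHASE_DB1 999x960/28, STARE 700x605/20) which
#'   [load_dataset()] verifies; `"synthetic"` accepts any.
#' @param root Directory containing `images/`, `1st_manual/` and `mask/`.
#' @param split_rule `"half"` (default): the first half of the
#'   lexicographically ordered ids is the training split, the second half
#'   the test split (the 1:1 convention; for STARE, which ships no official
#'   split, this means the first 10 ids train). Or a character vector of
#'   training ids.
#' @return A `dataset_spec` object.
#' @export
dataset_spec <- function(name = c("synthetic", "DRIVE", "STARE", "CHASE_DB1"),
                         root, split_rule = "half") {
  name <- match.arg(name)
  structure(list(name = name, root = root,
                 resolution = dataset_table[[name]]$resolution,
                 count = dataset_table[[name]]$count,
                 split_rule = split_rule),
            class = "dataset_spec")
}

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop(sprintf("unsupported raster format '.%s' (PNG or TIFF expected): %s",
                             ext, path), call. = FALSE))
  if (length(dim(img)) == 3L && dim(img)[3] == 4L) img <- img[, , 1:3]  # drop alpha
  img
}

write_raster <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

#' Binarize a mask raster
#'
#' Values above 127 (8-bit encodings) or above 0.5 (unit-scaled encodings)
#' become 1, the rest 0.
#'
#' @param raster Single-channel numeric matrix/array.
#' @return Integer 0/1 matrix of the same extents.
#' @export
binarize_mask <- function(raster) {
  d <- dim(raster)
  if (!is.null(d) && length(d) == 3L) {
    if (d[3] != 1L) stop("mask must be single-channel", call. = FALSE)
    raster <- raster[, , 1]
  }
  thr <- if (max(raster) > 1) 127 else 0.5
  out <- (raster > thr) * 1L
  dim(out) <- dim(raster)
  out
}

list_ids <- function(dir) {
  fs <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE))
  stats::setNames(fs, tools::file_path_sans_ext(fs))
}

#' Load a fundus dataset from disk
#'
#' Reads every image/vessel-mask/FOV triple under `spec$root`
#' (`images/`, `1st_manual/`, `mask/`), binarizes the masks, orders records
#' lexicographically by id and assigns the 1:1 train/test split.
#'
#' @param spec A [dataset_spec()].
#' @return List of sample records, each with fields `id`, `image`
#'   (HxWx3 in \[0,1\]), `vessel_mask`, `fov_mask` (0/1 matrices) and
#'   `split` (`"train"` or `"test"`).
#' @export
load_dataset <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  root <- spec$root
  dirs <- file.path(root, c("images", "1st_manual", "mask"))
  if (!all(dir.exists(dirs)))
    stop(sprintf("layout error: %s must contain images/, 1st_manual/ and mask/", root),
         call. = FALSE)
  imgs <- list_ids(dirs[1])
  if (!is.null(spec$count) && length(imgs) != spec$count)
    stop(sprintf("layout error: %s expects %d images, found %d",
                 spec$name, spec$count, length(imgs)), call. = FALSE)
  manuals <- list_ids(dirs[2])
  fovs <- list_ids(dirs[3])
  ids <- names(imgs)
  train_ids <- if (identical(spec$split_rule, "half")) {
    ids[seq_len(length(ids) %/% 2L)]
  } else spec$split_rule
  records <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    if (!id %in% names(manuals) || !id %in% names(fovs))
      stop(sprintf("layout error: no annotation/FOV for id '%s'", id), call. = FALSE)
    img <- read_raster(file.path(dirs[1], imgs[[id]]))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    if (!is.null(spec$resolution) &&
        !identical(dim(img)[1:2], as.integer(spec$resolution)))
      stop(sprintf("layout error: %s expects %d x %d rasters, '%s' is %d x %d",
                   spec$name, spec$resolution[1], spec$resolution[2], id,
                   dim(img)[1], dim(img)[2]), call. = FALSE)
    records[[i]] <- list(
      id = id,
      image = img,
      vessel_mask = binarize_mask(read_raster(file.path(dirs[2], manuals[[id]]))),
      fov_mask = binarize_mask(read_raster(file.path(dirs[3], fovs[[id]]))),
      split = if (id %in% train_ids) "train" else "test")
  }
  records
}

#' Pad an image for the network
#'
#' Scales 8-bit input to \[0, 1\] and reflect-pads both spatial extents up to
#' the next multiple of `2^(depth - 1)` so the encoder's pooling chain
#' divides evenly; the amount of padding is recorded so predictions can be
#' cropped back with [crop_prediction()].
#'
#' @param image HxWx3 (or HxW) numeric raster, 8-bit or unit-scaled.
#' @param depth Number of network resolution levels.
#' @return List with `x` (padded `(H', W', C, 1)` array) and `pad`
#'   (`c(bottom, right)` padding applied).
#' @export
preprocess <- function(image, depth = 4L) {
  if (max(image) > 1) image <- image / 255
  d <- dim(image)
  if (is.null(d)) stop("image must be a matrix or array", call. = FALSE)
  if (length(d) == 2L) dim(image) <- c(d, 1L)
  f <- as.integer(2^(as.integer(depth) - 1L))
  H <- dim(image)[1]; W <- dim(image)[2]
  ph <- (f - H %% f) %% f
  pw <- (f - W %% f) %% f
  out <- image
  if (ph > 0) {
    refl <- out[H - seq_len(ph), , , drop = FALSE]  # mirror rows H-1, H-2, ...
    out <- abind_rows(out, refl)
  }
  if (pw > 0) {
    refl <- out[, W - seq_len(pw), , drop = FALSE]
    out <- abind_cols(out, refl)
  }
  dim(out) <- c(dim(out), 1L)
  list(x = out, pad = c(ph, pw))
}

abind_rows <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(db[1]), , ] <- b
  out
}

abind_cols <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2] + db[2], da[3]))
  out[, seq_len(da[2]), ] <- a
  out[, da[2] + seq_len(db[2]), ] <- b
  out
}

#' Crop a padded prediction back to the original extents
#'
#' @param pred Matrix or array whose first two extents include the padding.
#' @param pad `c(bottom, right)` padding as returned by [preprocess()].
#' @return The cropped prediction.
#' @export
crop_prediction <- function(pred, pad) {
  d <- dim(pred)
  H <- d[1] - pad[1]; W <- d[2] - pad[2]
  if (length(d) == 2L) pred[seq_len(H), seq_len(W)]
  else pred[seq_len(H), seq_len(W), , drop = TRUE]
}
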
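# Data preparation: random overlapping tiling, resizing, mask I/O,
# small-component denoising, dataset splitting, and the coarse-to-fine
# annotation bootstrap.  Tile coordinates are 0-based with half-open extents
# [top, top + size) throughout.

#' Read an RGB image (PNG or TIFF)
#'
#' Values are returned in [0, 1] as an (H, W, 3) array.  An alpha channel is
#' dropped with a warning; a grayscale image is replicated to three
#' channels.
#'
#' @param path Path to a .png, .tif or .tiff file.
#' @return An (H, W, 3) array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image: %s", path))
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format `%s` (%s)", ext, path))
  )
  if (is.matrix(img)) {
    img <- array(rep(img, 3), c(dim(img), 3))
  } else if (dim(img)[3] == 2) {
    img <- array(rep(img[, , 1], 3), c(dim(img)[1:2], 3))
  } else if (dim(img)[3] == 4) {
    warning(sprintf("dropping alpha channel of %s", path))
    img <- img[, , 1:3, drop = FALSE]
  }
  img
}

#' Read / write a binary mask PNG
#'
#' Masks are single-channel 8-bit PNGs with 255 = tubule foreground and 0 =
#' background.  On read, any intermediate grey value is thresholded at 128
#' with a warning; a multi-channel file uses its first channel.  A written
#' mask reads back identically.
#'
#' @param path PNG file path.
#' @param mask An (H, W) matrix with values in {0, 1}.
#' @return \code{read_mask} returns an (H, W) 0/1 matrix;
#'   \code{write_mask} returns \code{path} invisibly.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read mask: %s", path))
  m <- png::readPNG(path)
  if (!is.matrix(m)) m <- m[, , 1]
  v <- round(m * 255)
  if (!all(v %in% c(0, 255))) {
    warning(sprintf(
      "%s contains grey values; thresholding at 128", path))
  }
  (v >= 128) * 1
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary (values in {0, 1})")
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  png::writePNG(m, path)
  invisible(path)
}

#' Random overlapping tiles from a large image
#'
#' Draws \code{n_tiles} top-left corners uniformly at random (with
#' replacement) from the valid range and extracts pixel-aligned image and
#' mask tiles; with \code{mode = "grid"} a deterministic grid covering the
#' image with minimal overlap is used instead (for inference).  Coordinates
#' are 0-based with half-open extents.
#'
#' @param image An (H, W, 3) array.
#' @param mask An (H, W) binary matrix aligned with \code{image}.
#' @param n_tiles Number of random tiles (default 16).
#' @param size Tile side in pixels (default 512).
#' @param seed RNG seed; identical seeds give identical tile lists.
#' @param source_id Optional identifier stored in each tile's spec.
#' @param mode \code{"random"} (default) or \code{"grid"}.
#' @return A list of tiles, each \code{list(image, mask, spec)} with
#'   \code{spec = list(source_id, top, left, size)}.
#' @export
tile_image <- function(image, mask, n_tiles = 16L, size = 512L, seed = 1L,
                       source_id = NULL, mode = c("random", "grid")) {
  mode <- match.arg(mode)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (!identical(dim(mask), c(H, W))) {
    stop("mask dims must equal image dims")
  }
  size <- check_count(size, "size")
  if (H < size || W < size) {
    stop(sprintf("image (%d x %d) is smaller than the tile size %d",
                 H, W, size))
  }
  if (mode == "random") {
    n_tiles <- check_count(n_tiles, "n_tiles")
    corners <- with_seed(seed, cbind(
      top = sample.int(H - size + 1L, n_tiles, replace = TRUE) - 1L,
      left = sample.int(W - size + 1L, n_tiles, replace = TRUE) - 1L))
  } else {
    tops <- unique(c(seq(0L, H - size, by = size), H - size))
    lefts <- unique(c(seq(0L, W - size, by = size), W - size))
    corners <- cbind(top = rep(tops, times = length(lefts)),
                     left = rep(lefts, each = length(tops)))
  }
  lapply(seq_len(nrow(corners)), function(i) {
    top <- unname(corners[i, "top"]); left <- unname(corners[i, "left"])
    rows <- (top + 1L):(top + size)
    cols <- (left + 1L):(left + size)
    list(image = image[rows, cols, , drop = FALSE],
         mask = mask[rows, cols],
         spec = list(source_id = source_id, top = top, left = left,
                     size = size))
  })
}

#' Resize an image/mask pair
#'
#' The image is resized with bilinear interpolation, the mask with nearest
#' neighbour so it stays binary.
#'
#' @param image An (H, W, 3) array.
#' @param mask An (H, W) binary matrix, or NULL.
#' @param size Target side in pixels (output is size x size).
#' @return \code{list(image, mask)}.
#' @export
resize_pair <- function(image, mask, size) {
  size <- check_count(size, "size")
  img <- EBImage::resize(image, w = size, h = size, filter = "bilinear")
  img[img < 0] <- 0
  img[img > 1] <- 1
  msk <- if (is.null(mask)) NULL else {
    EBImage::resize(mask, w = size, h = size, filter = "none")
  }
  list(image = img, mask = msk)
}

#' Remove small connected components
#'
#' Deletes every 8-connected foreground component of area below
#' \code{min_area} pixels (the behaviour of MATLAB's \code{bwareaopen} with
#' its default connectivity); larger components pass through unchanged, so
#' the operation is idempotent.
#'
#' @param mask An (H, W) binary matrix.
#' @param min_area Minimum component area in pixels (>= 1).
#' @return A binary matrix of the same shape.
#' @export
remove_small_components <- function(mask, min_area) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary (values in {0, 1})")
  min_area <- check_count(min_area, "min_area")
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab <- nn_label8(m)
  if (max(lab) == 0) return(m * 0)
  areas <- tabulate(lab)
  out <- matrix(0, nrow(m), ncol(m))
  sel <- lab > 0
  out[sel] <- as.numeric(areas[lab[sel]] >= min_area)
  out
}

#' Split identifiers into train/validation/test
#'
#' Seeded shuffle, then partition: validation and test receive
#' \code{floor(frac * n)} identifiers each and training the remainder, so
#' the default fractions (0.8, 0.1, 0.1) on 10 ids give 8/1/1 and on 398 ids
#' give 320/39/39.  Splitting is done at source-image level (before tiling)
#' so tiles of one image never leak across splits.
#'
#' @param ids Character or integer vector of at least 3 identifiers.
#' @param fractions Train/validation/test fractions summing to 1.
#' @param seed RNG seed.
#' @return A list of class \code{dataset_split} with \code{train_ids},
#'   \code{val_ids}, \code{test_ids}, \code{fractions}.
#' @export
split_dataset <- function(ids, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(ids) < 3) stop("need at least 3 ids to split")
  if (anyDuplicated(ids)) stop("ids must be unique")
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8) {
    stop("`fractions` must be 3 numbers summing to 1")
  }
  n <- length(ids)
  shuffled <- with_seed(seed, sample(ids))
  n_val <- floor(fractions[2] * n)
  n_test <- floor(fractions[3] * n)
  n_train <- n - n_val - n_test
  structure(list(
    train_ids = shuffled[seq_len(n_train)],
    val_ids = shuffled[n_train + seq_len(n_val)],
    test_ids = shuffled[n_train + n_val + seq_len(n_test)],
    fractions = fractions
  ), class = "dataset_split")
}

#' Bootstrap coarse annotations from a trained model
#'
#' For each unlabeled image: predict a binary mask, denoise it with
#' \code{\link{remove_small_components}}, and write it next to a JSON
#' manifest recording which images were bootstrapped (for later manual
#' refinement).  Unreadable images are logged and skipped.  Images whose
#' dimensions are not divisible by 16 are resized (with a warning) to the
#' nearest valid size before prediction.
#'
#' @param model A trained \code{\link{dks_model}} or a checkpoint path.
#' @param image_paths Character vector of image files.
#' @param out_dir Output directory (created if missing).
#' @param min_area Minimum component area for denoising; no default — choose
#'   it for the data at hand.
#' @param threshold Binarisation threshold (default 0.5).
#' @return Invisibly, a data frame manifest (also written as
#'   \code{manifest.json} in \code{out_dir}).
#' @export
annotation_bootstrap <- function(model, image_paths, out_dir, min_area,
                                 threshold = 0.5) {
  if (is.character(model)) model <- load_checkpoint(model)
  stopifnot(inherits(model, "dks_model"))
  min_area <- check_count(min_area, "min_area")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(image_paths, function(p) {
    res <- tryCatch({
      img <- read_image(p)
      d <- dim(img)
      if (d[1] %% 16 != 0 || d[2] %% 16 != 0) {
        warning(sprintf("resizing %s to a divisible-by-16 size", p))
        side <- max(16L, 16L * round(max(d[1:2]) / 16))
        img <- resize_pair(img, NULL, side)$image
      }
      m <- predict_mask(model, img, threshold)
      m <- remove_small_components(m, min_area)
      out <- file.path(out_dir, paste0(
        tools::file_path_sans_ext(basename(p)), "_mask.png"))
      write_mask(m, out)
      list(image = p, mask = out, status = "ok", error = NA_character_)
    }, error = function(e) {
      list(image = p, mask = NA_character_, status = "skipped",
           error = conditionMessage(e))
    })
    res
  })
  manifest <- do.call(rbind, lapply(rows, as.data.frame))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
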
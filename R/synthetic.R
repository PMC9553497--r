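# Seeded generator of H&E-like tiles with exact ground-truth masks.
#
# Each tubule is a rotated ellipse: a near-white lumen surrounded by an
# epithelial ring in a darker eosin-purple, stippled with nuclei dots; the
# ground-truth mask labels ring + lumen (the whole tubule).  Distractor
# clefts — thin white slits mimicking tissue-shrinkage artifacts — are drawn
# only on background pixels and are deliberately excluded from the mask, so
# a segmenter must learn context (the epithelial ring), not just brightness.

#' Parameters of the synthetic tile generator
#'
#' Geometry is in pixels at the configured \code{image_size}; colors are RGB
#' means in [0, 1]; noise is multiplicative Gaussian speckle.  The defaults
#' describe a 128 px tile (the test/demonstration scale); for 512 px tiles
#' scale the geometric ranges accordingly.
#'
#' @param image_size Tile side in pixels, divisible by 16 (default 128).
#' @param tubule_count_range (min, max) number of tubules per tile.
#' @param semi_axis_range (min, max) of each lumen semi-axis in pixels.
#' @param ring_thickness_range (min, max) epithelial ring thickness.
#' @param background_color,epithelium_color,lumen_color,nuclei_color RGB
#'   triplets in [0, 1].
#' @param noise_sd Standard deviation of the multiplicative speckle.
#' @param nuclei_density Probability that a ring pixel carries a nucleus dot.
#' @param distractor_cleft_range (min, max) number of cleft distractors.
#' @param seed Default seed used by \code{\link{generate_sample}}.
#' @return A list of class \code{synthetic_params}.
#' @export
synthetic_params <- function(image_size = 128L,
                             tubule_count_range = c(2L, 6L),
                             semi_axis_range = c(10, 26),
                             ring_thickness_range = c(3, 6),
                             background_color = c(0.91, 0.75, 0.85),
                             epithelium_color = c(0.55, 0.38, 0.62),
                             lumen_color = c(0.97, 0.95, 0.97),
                             nuclei_color = c(0.30, 0.15, 0.42),
                             noise_sd = 0.05, nuclei_density = 0.06,
                             distractor_cleft_range = c(1L, 4L),
                             seed = 1L) {
  image_size <- check_count(image_size, "image_size", min = 16L)
  if (image_size %% 16 != 0) stop("`image_size` must be divisible by 16")
  rng_ok <- function(r) length(r) == 2 && r[1] <= r[2]
  if (!rng_ok(tubule_count_range) || !rng_ok(semi_axis_range) ||
      !rng_ok(ring_thickness_range) || !rng_ok(distractor_cleft_range)) {
    stop("all ranges must be (min, max) with min <= max")
  }
  structure(list(
    image_size = image_size,
    tubule_count_range = as.integer(tubule_count_range),
    semi_axis_range = semi_axis_range,
    ring_thickness_range = ring_thickness_range,
    background_color = background_color,
    epithelium_color = epithelium_color,
    lumen_color = lumen_color, nuclei_color = nuclei_color,
    noise_sd = noise_sd, nuclei_density = nuclei_density,
    distractor_cleft_range = as.integer(distractor_cleft_range),
    seed = check_count(seed, "seed", min = 0L)
  ), class = "synthetic_params")
}

# Logical raster of a rotated ellipse on an S x S pixel grid whose pixel
# (r, c) has centre coordinates (r, c), 1-based.
raster_ellipse <- function(size, center, a, b, angle = 0) {
  rr <- matrix(seq_len(size), size, size)
  cc <- matrix(seq_len(size), size, size, byrow = TRUE)
  dr <- rr - center[1]; dc <- cc - center[2]
  u <- dr * cos(angle) + dc * sin(angle)
  v <- -dr * sin(angle) + dc * cos(angle)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Rasterize a single tubule's mask
#'
#' The 0/1 mask of the outer ellipse (lumen semi-axes plus the ring
#' thickness), i.e. the whole tubule as labelled in the ground truth.
#'
#' @param size Image side in pixels.
#' @param center (row, col) centre, 1-based pixel coordinates.
#' @param semi_axes (a, b) lumen semi-axes in pixels.
#' @param ring_thickness Epithelial ring thickness in pixels.
#' @param angle Rotation in radians (0 = axis-aligned).
#' @return An (size, size) 0/1 matrix.
#' @export
rasterize_tubule <- function(size, center, semi_axes, ring_thickness,
                             angle = 0) {
  raster_ellipse(size, center, semi_axes[1] + ring_thickness,
                 semi_axes[2] + ring_thickness, angle) * 1
}

# Pixels within `halfwidth` of the segment p0 -> p1.
raster_slit <- function(size, p0, p1, halfwidth) {
  rr <- matrix(seq_len(size), size, size)
  cc <- matrix(seq_len(size), size, size, byrow = TRUE)
  d <- p1 - p0
  len2 <- max(sum(d * d), 1e-9)
  t <- ((rr - p0[1]) * d[1] + (cc - p0[2]) * d[2]) / len2
  t[t < 0] <- 0; t[t > 1] <- 1
  pr <- p0[1] + t * d[1]; pc <- p0[2] + t * d[2]
  (rr - pr)^2 + (cc - pc)^2 <= halfwidth^2
}

#' Generate one synthetic tile and its ground-truth mask
#'
#' Deterministic given (params, seed): the same pair is byte-identical on
#' regeneration.  The mask is exactly the union of the tubules' outer
#' ellipses; cleft distractors never contribute to it.
#'
#' @param params A \code{\link{synthetic_params}} object.
#' @param seed RNG seed (defaults to \code{params$seed}).
#' @return A list with \code{image} (H, W, 3 array in [0, 1], quantised to
#'   8 bits), \code{mask} (H, W 0/1 matrix), and \code{tubules} (data frame
#'   of the drawn geometry).
#' @export
generate_sample <- function(params = synthetic_params(), seed = params$seed) {
  stopifnot(inherits(params, "synthetic_params"))
  S <- params$image_size
  with_seed(seed, {
    n_tub <- sample(params$tubule_count_range[1]:params$tubule_count_range[2], 1)
    tubs <- vector("list", n_tub)
    i <- 0L
    while (i < n_tub) {
      a <- stats::runif(1, params$semi_axis_range[1], params$semi_axis_range[2])
      b <- stats::runif(1, params$semi_axis_range[1], params$semi_axis_range[2])
      ring <- stats::runif(1, params$ring_thickness_range[1],
                           params$ring_thickness_range[2])
      if (ring >= min(a, b)) next  # degenerate: ring swallows the lumen
      i <- i + 1L
      tubs[[i]] <- list(
        center = c(stats::runif(1, 1, S), stats::runif(1, 1, S)),
        a = a, b = b, ring = ring, angle = stats::runif(1, 0, pi))
    }

    img <- array(rep(params$background_color, each = S * S), c(S, S, 3))
    mask <- matrix(FALSE, S, S)
    for (tb in tubs) {
      outer <- raster_ellipse(S, tb$center, tb$a + tb$ring, tb$b + tb$ring,
                              tb$angle)
      inner <- raster_ellipse(S, tb$center, tb$a, tb$b, tb$angle)
      ringpx <- outer & !inner
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[ringpx] <- params$epithelium_color[ch]
        plane[inner] <- params$lumen_color[ch]
        img[, , ch] <- plane
      }
      idx <- which(ringpx)
      dots <- idx[stats::runif(length(idx)) < params$nuclei_density]
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[dots] <- params$nuclei_color[ch]
        img[, , ch] <- plane
      }
      mask <- mask | outer
    }

    n_cleft <- sample(params$distractor_cleft_range[1]:params$distractor_cleft_range[2], 1)
    if (n_cleft > 0) {
      for (j in seq_len(n_cleft)) {
        ctr <- c(stats::runif(1, 1, S), stats::runif(1, 1, S))
        ang <- stats::runif(1, 0, pi)
        len <- stats::runif(1, 0.12, 0.3) * S
        hw <- stats::runif(1, 0.8, 1.6)
        p0 <- ctr - len / 2 * c(cos(ang), sin(ang))
        p1 <- ctr + len / 2 * c(cos(ang), sin(ang))
        slit <- raster_slit(S, p0, p1, hw) & !mask
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[slit] <- params$lumen_color[ch]
          img[, , ch] <- plane
        }
      }
    }

    speckle <- 1 + params$noise_sd * stats::rnorm(S * S)
    img <- img * array(rep(speckle, 3), c(S, S, 3))
    img[img < 0] <- 0; img[img > 1] <- 1
    img <- round(img * 255) / 255

    geom <- if (n_tub > 0) {
      data.frame(
        row = vapply(tubs, function(t) t$center[1], numeric(1)),
        col = vapply(tubs, function(t) t$center[2], numeric(1)),
        a = vapply(tubs, `[[`, numeric(1), "a"),
        b = vapply(tubs, `[[`, numeric(1), "b"),
        ring = vapply(tubs, `[[`, numeric(1), "ring"),
        angle = vapply(tubs, `[[`, numeric(1), "angle"))
    } else {
      data.frame(row = numeric(0), col = numeric(0), a = numeric(0),
                 b = numeric(0), ring = numeric(0), angle = numeric(0))
    }
    list(image = img, mask = mask * 1, tubules = geom)
  })
}

#' Generate a dataset of synthetic tiles on disk
#'
#' Per-sample seeds are drawn deterministically from the master seed, so the
#' whole dataset is byte-identical on regeneration.  Images go to
#' \code{out_dir/images/}, masks to \code{out_dir/masks/}, and a JSON
#' manifest listing files, per-sample seeds and tubule counts to
#' \code{out_dir/manifest.json}.
#'
#' @param params A \code{\link{synthetic_params}} object.
#' @param n_samples Number of image/mask pairs.
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed.
#' @return Invisibly, the manifest data frame.
#' @export
generate_dataset <- function(params, n_samples, out_dir, seed = 1L) {
  stopifnot(inherits(params, "synthetic_params"))
  n_samples <- check_count(n_samples, "n_samples")
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create `%s`", out_dir))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_samples))
  rows <- lapply(seq_len(n_samples), function(i) {
    smp <- generate_sample(params, seeds[i])
    id <- sprintf("sample_%04d", i)
    ipath <- file.path(out_dir, "images", paste0(id, ".png"))
    mpath <- file.path(out_dir, "masks", paste0(id, ".png"))
    png::writePNG(smp$image, ipath)
    write_mask(smp$mask, mpath)
    data.frame(id = id, image = file.path("images", paste0(id, ".png")),
               mask = file.path("masks", paste0(id, ".png")),
               seed = seeds[i], n_tubules = nrow(smp$tubules))
  })
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Load an image/mask dataset directory
#'
#' Reads the manifest written by \code{\link{generate_dataset}} (or any
#' directory following the same layout) into an in-memory list of pairs.
#'
#' @param dir Dataset directory containing \code{manifest.json}.
#' @return A list of \code{list(image, mask, id)} pairs.
#' @export
load_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop(sprintf("no manifest.json under `%s`", dir))
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  lapply(seq_len(nrow(manifest)), function(i) {
    list(image = read_image(file.path(dir, manifest$image[i])),
         mask = read_mask(file.path(dir, manifest$mask[i])),
         id = manifest$id[i])
  })
}
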
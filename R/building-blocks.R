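# Shared layers: convolution units, squeeze-excitation gating, atrous
# spatial pyramid pooling, and the decoder block used by both branches.

scale_ch <- function(v, wm) pmax(1L, as.integer(round(v * wm)))

mk_conv <- function(store, name, k, cin, cout, bias = FALSE) {
  add_param(store, paste0(name, ".W"),
            init_he(c(k, k, cin, cout), k * k * cin))
  if (bias) add_param(store, paste0(name, ".b"), numeric(cout))
  invisible(cout)
}

mk_bn <- function(store, name, c) {
  add_param(store, paste0(name, ".gamma"), rep(1, c))
  add_param(store, paste0(name, ".beta"), numeric(c))
}

mk_fc <- function(store, name, din, dout, bias = TRUE) {
  add_param(store, paste0(name, ".W"),
            matrix(stats::rnorm(dout * din, sd = sqrt(2 / din)), dout, din))
  if (bias) add_param(store, paste0(name, ".b"), numeric(dout))
}

mk_bn1d <- function(store, name, d) {
  add_param(store, paste0(name, ".gamma"), rep(1, d))
  add_param(store, paste0(name, ".beta"), numeric(d))
}

# --- conv unit: two (conv k x k -> batch norm -> ReLU) stages --------------

mk_conv_unit <- function(store, prefix, cin, cout, kernel = 3L) {
  mk_conv(store, paste0(prefix, ".c1"), kernel, cin, cout)
  mk_bn(store, paste0(prefix, ".bn1"), cout)
  mk_conv(store, paste0(prefix, ".c2"), kernel, cout, cout)
  mk_bn(store, paste0(prefix, ".bn2"), cout)
  invisible(cout)
}

fwd_conv_unit <- function(tape, x, store, prefix, training,
                          need_dx = TRUE) {
  h <- op_conv(tape, x, store, paste0(prefix, ".c1"), need_dx = need_dx)
  h <- op_relu(tape, op_bn(tape, h, store, paste0(prefix, ".bn1"), training))
  h <- op_conv(tape, h, store, paste0(prefix, ".c2"))
  op_relu(tape, op_bn(tape, h, store, paste0(prefix, ".bn2"), training))
}

# --- squeeze and excitation ------------------------------------------------

mk_se <- function(store, prefix, c, reduction = 8L) {
  d <- max(c %/% reduction, 1L)
  mk_fc(store, paste0(prefix, ".fc1"), c, d)
  # start the squeeze units well inside the active side of the ReLU: with
  # very narrow bottlenecks (d of 1-2 at small width multipliers) a zero-bias
  # He init can leave every unit dead and silently freeze the gate
  store$params[[paste0(prefix, ".fc1.W")]] <-
    store$params[[paste0(prefix, ".fc1.W")]] * 0.25
  store$params[[paste0(prefix, ".fc1.b")]] <- rep(1, d)
  mk_fc(store, paste0(prefix, ".fc2"), d, c)
}

fwd_se <- function(tape, x, store, prefix) {
  z <- op_gap(tape, x)
  z <- op_relu(tape, op_fc(tape, z, store, paste0(prefix, ".fc1")))
  z <- op_sigmoid(tape, op_fc(tape, z, store, paste0(prefix, ".fc2")))
  op_channel_scale(tape, x, z)
}

# --- atrous spatial pyramid pooling ---------------------------------------

mk_aspp <- function(store, prefix, cin, cout, rates) {
  for (r in rates) {
    k <- if (r == 1) 1L else 3L
    mk_conv(store, paste0(prefix, ".r", r), k, cin, cout)
    mk_bn(store, paste0(prefix, ".r", r, ".bn"), cout)
  }
  mk_fc(store, paste0(prefix, ".pool"), cin, cout, bias = FALSE)
  mk_bn1d(store, paste0(prefix, ".pool.bn"), cout)
  mk_conv(store, paste0(prefix, ".proj"), 1L, cout * (length(rates) + 1L),
          cout)
  mk_bn(store, paste0(prefix, ".proj.bn"), cout)
  invisible(cout)
}

check_aspp_rates <- function(rates, H, W) {
  if (length(rates) < 1) stop("`rates` must be non-empty")
  if (any(rates < 1 | rates != round(rates))) {
    stop("all dilation rates must be integers >= 1")
  }
  # Zero padding makes a dilated kernel computable even when it exceeds the
  # feature size (DeepLab behaviour at small bottlenecks), so smaller-than-
  # kernel inputs are fine; only a padding amount beyond what the dense
  # padded buffer can reasonably represent is rejected.
  bad <- rates[rates > 4096]
  if (length(bad)) {
    stop(sprintf(
      "dilation rate %d exceeds representable padding for a %dx%d input",
      bad[1], H, W))
  }
}

fwd_aspp <- function(tape, x, store, prefix, rates, training) {
  d <- dim(x$v)
  check_aspp_rates(rates, d[1], d[2])
  branches <- lapply(rates, function(r) {
    h <- op_conv(tape, x, store, paste0(prefix, ".r", r), dilation = r)
    op_relu(tape, op_bn(tape, h, store, paste0(prefix, ".r", r, ".bn"),
                        training))
  })
  p <- op_gap(tape, x)
  p <- op_fc(tape, p, store, paste0(prefix, ".pool"))
  p <- op_relu(tape, op_bn1d(tape, p, store, paste0(prefix, ".pool.bn"),
                             training))
  p <- op_broadcast_hw(tape, p, d[1], d[2])
  h <- op_concat(tape, c(branches, list(p)))
  h <- op_conv(tape, h, store, paste0(prefix, ".proj"))
  h <- op_relu(tape, op_bn(tape, h, store, paste0(prefix, ".proj.bn"),
                           training))
  list(out = h, branches = branches, pooled = p)
}

# --- decoder block ---------------------------------------------------------

mk_decoder_block <- function(store, prefix, cin, skip_chs, cout,
                             se_reduction = 8L) {
  mk_conv_unit(store, paste0(prefix, ".cu"), cin + sum(skip_chs), cout)
  mk_se(store, paste0(prefix, ".se"), cout, se_reduction)
  invisible(cout)
}

fwd_decoder_block <- function(tape, x, skips, store, prefix, training) {
  d <- dim(x$v)
  for (s in skips) {
    ds <- dim(s$v)
    if (ds[1] != 2 * d[1] || ds[2] != 2 * d[2]) {
      stop(sprintf(
        "decoder skip at %dx%d does not match the expected %dx%d (2x the %dx%d input)",
        ds[1], ds[2], 2 * d[1], 2 * d[2], d[1], d[2]))
    }
  }
  up <- op_upsample2(tape, x)
  h <- op_concat(tape, c(list(up), skips))
  h <- fwd_conv_unit(tape, h, store, paste0(prefix, ".cu"), training)
  fwd_se(tape, h, store, paste0(prefix, ".se"))
}

# --- exported standalone surfaces -----------------------------------------

# Build a seeded store via `build`, then apply any user-supplied parameter
# overrides (named as documented per block).
standalone_store <- function(build, seed, params = NULL) {
  store <- new_store()
  with_seed(seed, build(store))
  if (!is.null(params)) {
    for (nm in names(params)) {
      if (!nm %in% store$order) {
        stop(sprintf("unknown parameter override `%s`", nm))
      }
      store$params[[nm]] <- params[[nm]]
    }
  }
  store
}

#' Convolution unit: two (conv -> batch norm -> ReLU) stages
#'
#' The building block used throughout both branches: two successive
#' convolutions of size \code{kernel} with same padding, each followed by
#' batch normalisation and a ReLU.  Spatial dimensions are preserved and the
#' output is non-negative.
#'
#' This standalone form initialises a fresh, seeded layer and applies it in
#' inference mode (running batch-norm statistics at their initial mean 0 /
#' variance 1); inside a model the unit shares the model's parameter store.
#'
#' @param x An (H, W, C) or (H, W, C, N) numeric array.
#' @param out_channels Number of output channels.
#' @param kernel Odd kernel size (default 3).
#' @param params Optional named list of parameter overrides; names are
#'   \code{cu.c1.W}, \code{cu.bn1.gamma}, \code{cu.bn1.beta}, \code{cu.c2.W},
#'   \code{cu.bn2.gamma}, \code{cu.bn2.beta}.
#' @param seed Seed for the random initialisation.
#' @return An (H, W, out_channels, N) array.
#' @export
conv_unit <- function(x, out_channels, kernel = 3L, params = NULL,
                      seed = 1L) {
  x <- as_feature_map(x)
  out_channels <- check_count(out_channels, "out_channels")
  kernel <- check_count(kernel, "kernel")
  if (kernel %% 2 == 0) stop("`kernel` must be odd")
  cin <- dim(x)[3]
  store <- standalone_store(function(s) {
    mk_conv_unit(s, "cu", cin, out_channels, kernel)
  }, seed, params)
  fwd_conv_unit(NULL, op_input(NULL, x), store, "cu", training = FALSE)$v
}

#' Squeeze-and-excitation block
#'
#' Gates each channel by a sigmoid weight learned from globally pooled
#' features: global average pool, a bottleneck fully connected layer of width
#' \code{max(C \%/\% reduction, 1)} with ReLU, an expansion layer back to C,
#' and a sigmoid.  Because every gate lies in (0, 1), the output is bounded
#' elementwise by the input in absolute value.
#'
#' @param x An (H, W, C) or (H, W, C, N) numeric array.
#' @param reduction Bottleneck reduction ratio (default 8).
#' @param params Optional overrides; names are \code{se.fc1.W},
#'   \code{se.fc1.b}, \code{se.fc2.W}, \code{se.fc2.b}.
#' @param seed Seed for the random initialisation.
#' @return An array of the same shape as \code{x}.
#' @export
se_block <- function(x, reduction = 8L, params = NULL, seed = 1L) {
  x <- as_feature_map(x)
  reduction <- check_count(reduction, "reduction")
  cin <- dim(x)[3]
  store <- standalone_store(function(s) {
    mk_se(s, "se", cin, reduction)
  }, seed, params)
  fwd_se(NULL, op_input(NULL, x), store, "se")$v
}

#' Atrous spatial pyramid pooling
#'
#' Parallel branches at the given dilation rates (a 1x1 convolution for rate
#' 1, dilated 3x3 convolutions otherwise), plus an image-level pooled branch,
#' concatenated and projected back to \code{out_channels} by a 1x1
#' convolution.  Each branch is conv -> batch norm -> ReLU.  Spatial
#' dimensions are preserved.
#'
#' @param x An (H, W, C) or (H, W, C, N) numeric array.
#' @param out_channels Channels of every branch and of the projected output.
#' @param rates Integer dilation rates, all >= 1 (default \code{c(1, 6, 12,
#'   18)}, the DeepLabV3+ convention).
#' @param params Optional overrides; names are \code{aspp.r<rate>.W},
#'   \code{aspp.r<rate>.bn.gamma/.beta}, \code{aspp.pool.W},
#'   \code{aspp.pool.bn.gamma/.beta}, \code{aspp.proj.W},
#'   \code{aspp.proj.bn.gamma/.beta}.
#' @param seed Seed for the random initialisation.
#' @param return_branches If TRUE, also return the individual branch outputs
#'   (used e.g. to inspect receptive fields).
#' @return An (H, W, out_channels, N) array, or a list with elements
#'   \code{out} and \code{branches} when \code{return_branches} is TRUE.
#' @export
aspp <- function(x, out_channels, rates = c(1L, 6L, 12L, 18L),
                 params = NULL, seed = 1L, return_branches = FALSE) {
  x <- as_feature_map(x)
  out_channels <- check_count(out_channels, "out_channels")
  check_aspp_rates(rates, dim(x)[1], dim(x)[2])
  cin <- dim(x)[3]
  store <- standalone_store(function(s) {
    mk_aspp(s, "aspp", cin, out_channels, rates)
  }, seed, params)
  r <- fwd_aspp(NULL, op_input(NULL, x), store, "aspp", rates,
                training = FALSE)
  if (return_branches) {
    list(out = r$out$v, branches = lapply(r$branches, `[[`, "v"))
  } else {
    r$out$v
  }
}

#' Decoder block
#'
#' One step of the decoding path: bilinear x2 upsampling, concatenation with
#' the matching-scale encoder skip(s), a \code{\link{conv_unit}}, and a
#' squeeze-and-excitation block.  Every skip must have exactly twice the
#' spatial dimensions of \code{x}; branch 1 passes one skip, branch 2 passes
#' two (one from each encoder).
#'
#' @param x An (H, W, C) or (H, W, C, N) numeric array.
#' @param skips A single array or a list of 1 or 2 arrays at (2H, 2W).
#' @param out_channels Output channels of the block.
#' @param se_reduction Reduction ratio of the squeeze-excitation block.
#' @param params Optional overrides; names are \code{dec.cu.*} and
#'   \code{dec.se.*} following \code{\link{conv_unit}} /
#'   \code{\link{se_block}}.
#' @param seed Seed for the random initialisation.
#' @return A (2H, 2W, out_channels, N) array.
#' @export
decoder_block <- function(x, skips, out_channels, se_reduction = 8L,
                          params = NULL, seed = 1L) {
  x <- as_feature_map(x)
  if (!is.list(skips)) skips <- list(skips)
  if (!length(skips) %in% 1:2) stop("`skips` must hold 1 or 2 feature maps")
  skips <- lapply(skips, as_feature_map, name = "skips")
  out_channels <- check_count(out_channels, "out_channels")
  cin <- dim(x)[3]
  skip_chs <- vapply(skips, function(s) dim(s)[3], numeric(1))
  store <- standalone_store(function(s) {
    mk_decoder_block(s, "dec", cin, skip_chs, out_channels, se_reduction)
  }, seed, params)
  fwd_decoder_block(NULL, op_input(NULL, x),
                    lapply(skips, function(s) op_input(NULL, s)),
                    store, "dec", training = FALSE)$v
}
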
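# The two feature extractors: a VGG19-style encoder (branch 1) and a
# dense-connectivity encoder (branch 2).  Both emit four skip taps at scales
# 1, 1/2, 1/4, 1/8 and a bottleneck at 1/16, which is exactly what four x2
# decoder blocks consume.

vgg_channel_plan <- function(width_multiplier) {
  list(channels = scale_ch(c(64L, 128L, 256L, 512L, 512L), width_multiplier),
       convs = c(2L, 2L, 4L, 4L, 4L))
}

check_div16 <- function(H, W) {
  if (H %% 16 != 0 || W %% 16 != 0) {
    stop(sprintf(
      "input spatial dims (%d x %d) must be divisible by 16 (four x2 downsamplings)",
      H, W))
  }
}

mk_vgg <- function(store, prefix, cin, width_multiplier) {
  plan <- vgg_channel_plan(width_multiplier)
  c_prev <- cin
  for (s in 1:5) {
    for (j in seq_len(plan$convs[s])) {
      nm <- sprintf("%s.s%d.c%d", prefix, s, j)
      mk_conv(store, nm, 3L, c_prev, plan$channels[s])
      mk_bn(store, paste0(nm, ".bn"), plan$channels[s])
      c_prev <- plan$channels[s]
    }
  }
  list(skips = plan$channels[1:4], bottleneck = plan$channels[5])
}

fwd_vgg <- function(tape, x, store, prefix, width_multiplier, training) {
  d <- dim(x$v)
  check_div16(d[1], d[2])
  plan <- vgg_channel_plan(width_multiplier)
  skips <- vector("list", 4L)
  h <- x
  for (s in 1:5) {
    for (j in seq_len(plan$convs[s])) {
      nm <- sprintf("%s.s%d.c%d", prefix, s, j)
      h <- op_conv(tape, h, store, nm, need_dx = !(s == 1L && j == 1L))
      h <- op_relu(tape, op_bn(tape, h, store, paste0(nm, ".bn"), training))
    }
    if (s < 5) {
      skips[[s]] <- h
      h <- op_maxpool(tape, h)
    }
  }
  list(bottleneck = h, skips = skips)
}

mk_dense_layer <- function(store, prefix, cin, growth) {
  mk_bn(store, paste0(prefix, ".bn1"), cin)
  mk_conv(store, paste0(prefix, ".c1"), 1L, cin, 4L * growth)
  mk_bn(store, paste0(prefix, ".bn2"), 4L * growth)
  mk_conv(store, paste0(prefix, ".c2"), 3L, 4L * growth, growth)
}

fwd_dense_layer <- function(tape, x, store, prefix, training) {
  h <- op_relu(tape, op_bn(tape, x, store, paste0(prefix, ".bn1"), training))
  h <- op_conv(tape, h, store, paste0(prefix, ".c1"))
  h <- op_relu(tape, op_bn(tape, h, store, paste0(prefix, ".bn2"), training))
  op_conv(tape, h, store, paste0(prefix, ".c2"))
}

mk_dense_block <- function(store, prefix, cin, num_layers, growth) {
  c_run <- cin
  for (l in seq_len(num_layers)) {
    mk_dense_layer(store, sprintf("%s.l%d", prefix, l), c_run, growth)
    c_run <- c_run + growth
  }
  invisible(c_run)
}

fwd_dense_block <- function(tape, x, store, prefix, num_layers, training) {
  h <- x
  for (l in seq_len(num_layers)) {
    new <- fwd_dense_layer(tape, h, store, sprintf("%s.l%d", prefix, l),
                           training)
    h <- op_concat(tape, list(h, new))
  }
  h
}

mk_transition <- function(store, prefix, cin, compression) {
  cout <- max(1L, as.integer(floor(compression * cin)))
  mk_bn(store, paste0(prefix, ".bn"), cin)
  mk_conv(store, paste0(prefix, ".c"), 1L, cin, cout)
  invisible(cout)
}

fwd_transition <- function(tape, x, store, prefix, training) {
  d <- dim(x$v)
  if (d[1] %% 2 != 0 || d[2] %% 2 != 0) {
    stop("transition requires even spatial dims")
  }
  h <- op_bn(tape, x, store, paste0(prefix, ".bn"), training)
  h <- op_conv(tape, h, store, paste0(prefix, ".c"))
  op_avgpool(tape, h)
}

# Stem width follows the DenseNet convention of twice the growth rate.
dense_channel_plan <- function(cin, block_lengths, growth_rate,
                               width_multiplier, compression) {
  g <- scale_ch(growth_rate, width_multiplier)
  stem <- scale_ch(2L * growth_rate, width_multiplier)
  taps <- integer(4)
  c_run <- stem
  trans_in <- integer(4)
  for (i in 1:4) {
    trans_in[i] <- c_run
    c_run <- max(1L, as.integer(floor(compression * c_run)))
    c_run <- c_run + block_lengths[i] * g
    taps[i] <- c_run
  }
  list(growth = g, stem = stem, skips = c(stem, taps[1:3]),
       bottleneck = taps[4], trans_in = trans_in)
}

mk_dense_enc <- function(store, prefix, cin, block_lengths, growth_rate,
                         width_multiplier, compression) {
  plan <- dense_channel_plan(cin, block_lengths, growth_rate,
                             width_multiplier, compression)
  mk_conv_unit(store, paste0(prefix, ".stem"), cin, plan$stem)
  c_run <- plan$stem
  for (i in 1:4) {
    c_run <- mk_transition(store, sprintf("%s.t%d", prefix, i), c_run,
                           compression)
    c_run <- mk_dense_block(store, sprintf("%s.db%d", prefix, i), c_run,
                            block_lengths[i], plan$growth)
  }
  plan
}

fwd_dense_enc <- function(tape, x, store, prefix, block_lengths, training) {
  d <- dim(x$v)
  check_div16(d[1], d[2])
  skips <- vector("list", 4L)
  h <- fwd_conv_unit(tape, x, store, paste0(prefix, ".stem"), training)
  skips[[1]] <- h
  for (i in 1:4) {
    h <- fwd_transition(tape, h, store, sprintf("%s.t%d", prefix, i),
                        training)
    h <- fwd_dense_block(tape, h, store, sprintf("%s.db%d", prefix, i),
                         block_lengths[i], training)
    if (i < 4) skips[[i + 1]] <- h
  }
  list(bottleneck = h, skips = skips)
}

# --- exported standalone surfaces -----------------------------------------

#' VGG19-style encoder
#'
#' Five stages of 3x3 convolutions (2, 2, 4, 4, 4 per stage) with channel
#' plan (64, 128, 256, 512, 512) scaled by \code{width_multiplier}, each
#' convolution followed by batch norm and ReLU, with 2x2 max pooling between
#' stages.  Skips are tapped from the outputs of stages 1-4 (before pooling);
#' the bottleneck is the stage-5 output at 1/16 scale.
#'
#' @param x An (H, W, C) or (H, W, C, N) array; H and W divisible by 16.
#' @param width_multiplier Positive real channel scaling; widths are
#'   \code{max(1, round(base * width_multiplier))}.
#' @param seed Seed for the random initialisation.
#' @return A list with \code{bottleneck} (1/16 scale) and \code{skips}
#'   (list of 4 arrays at scales 1, 1/2, 1/4, 1/8).
#' @export
vgg_encoder <- function(x, width_multiplier = 1, seed = 1L) {
  x <- as_feature_map(x)
  if (width_multiplier <= 0) stop("`width_multiplier` must be positive")
  check_div16(dim(x)[1], dim(x)[2])
  cin <- dim(x)[3]
  store <- standalone_store(function(s) {
    mk_vgg(s, "vgg", cin, width_multiplier)
  }, seed)
  r <- fwd_vgg(NULL, op_input(NULL, x), store, "vgg", width_multiplier,
               training = FALSE)
  list(bottleneck = r$bottleneck$v, skips = lapply(r$skips, `[[`, "v"))
}

#' Dense block
#'
#' \code{num_layers} layers, each norm -> ReLU -> 1x1 conv (4 * growth_rate
#' channels) -> norm -> ReLU -> 3x3 conv (growth_rate channels), with each
#' layer's output concatenated onto the running feature stack.  The input
#' channels survive verbatim as the leading slab of the output, and output
#' channels equal \code{input channels + num_layers * growth_rate}.
#'
#' @param x An (H, W, C) or (H, W, C, N) numeric array.
#' @param num_layers Number of densely connected layers (>= 1).
#' @param growth_rate Channels added per layer (>= 1).
#' @param params Optional overrides; names are \code{db.l<j>.bn1.*},
#'   \code{db.l<j>.c1.W}, \code{db.l<j>.bn2.*}, \code{db.l<j>.c2.W}.
#' @param seed Seed for the random initialisation.
#' @return An (H, W, C + num_layers * growth_rate, N) array.
#' @export
dense_block <- function(x, num_layers, growth_rate, params = NULL,
                        seed = 1L) {
  x <- as_feature_map(x)
  num_layers <- check_count(num_layers, "num_layers")
  growth_rate <- check_count(growth_rate, "growth_rate")
  cin <- dim(x)[3]
  store <- standalone_store(function(s) {
    mk_dense_block(s, "db", cin, num_layers, growth_rate)
  }, seed, params)
  fwd_dense_block(NULL, op_input(NULL, x), store, "db", num_layers,
                  training = FALSE)$v
}

#' Transition layer
#'
#' Downsampling between dense stages: batch norm, a 1x1 convolution to
#' \code{floor(compression * channels)} channels, then 2x2 average pooling.
#'
#' @param x An (H, W, C) or (H, W, C, N) array with even spatial dims.
#' @param compression Channel compression factor in (0, 1].
#' @param params Optional overrides; names are \code{tr.bn.gamma},
#'   \code{tr.bn.beta}, \code{tr.c.W}.
#' @param seed Seed for the random initialisation.
#' @return An (H/2, W/2, floor(compression * C), N) array.
#' @export
transition_layer <- function(x, compression = 0.5, params = NULL,
                             seed = 1L) {
  x <- as_feature_map(x)
  if (compression <= 0 || compression > 1) {
    stop("`compression` must lie in (0, 1]")
  }
  cin <- dim(x)[3]
  store <- standalone_store(function(s) {
    mk_transition(s, "tr", cin, compression)
  }, seed, params)
  fwd_transition(NULL, op_input(NULL, x), store, "tr", training = FALSE)$v
}

#' Dense-connectivity encoder
#'
#' The branch-2 feature extractor: a full-resolution \code{\link{conv_unit}}
#' stem (tapped as the scale-1 skip), then four stages of [transition,
#' dense block], tapping skips at scales 1/2, 1/4 and 1/8 and the bottleneck
#' at 1/16.  A standard DenseNet-121 stem (7x7 stride-2 conv + pool) cannot
#' provide a full-resolution skip, hence this custom arrangement that keeps
#' the dense-connectivity mechanism while matching the 4-stage decoder.
#'
#' @param x An (H, W, C) or (H, W, C, N) array; H and W divisible by 16.
#' @param block_lengths Integer vector of 4 dense-block lengths.
#' @param growth_rate Base growth rate, scaled by \code{width_multiplier}.
#' @param width_multiplier Positive real channel scaling.
#' @param compression Transition compression factor (default 0.5).
#' @param seed Seed for the random initialisation.
#' @return A list with \code{bottleneck} and \code{skips} as for
#'   \code{\link{vgg_encoder}}.
#' @export
dense_encoder <- function(x, block_lengths = c(4L, 6L, 8L, 10L),
                          growth_rate = 16L, width_multiplier = 1,
                          compression = 0.5, seed = 1L) {
  x <- as_feature_map(x)
  if (length(block_lengths) != 4) stop("`block_lengths` must have 4 entries")
  if (width_multiplier <= 0) stop("`width_multiplier` must be positive")
  check_div16(dim(x)[1], dim(x)[2])
  cin <- dim(x)[3]
  store <- standalone_store(function(s) {
    mk_dense_enc(s, "den", cin, block_lengths, growth_rate,
                 width_multiplier, compression)
  }, seed)
  r <- fwd_dense_enc(NULL, op_input(NULL, x), store, "den", block_lengths,
                     training = FALSE)
  list(bottleneck = r$bottleneck$v, skips = lapply(r$skips, `[[`, "v"))
}
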
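# Assembly of the full dual-branch network: branch 1 (VGG encoder -> ASPP ->
# 4 decoder blocks -> KSM -> 1x1 conv + sigmoid head), multiplicative gating
# of the input by branch-1's mask, branch 2 (dense encoder -> ASPP -> 4
# decoder blocks with skips from BOTH encoders -> KSM -> head).

#' Model configuration
#'
#' Collects every architectural hyperparameter.  Channel widths (VGG plan,
#' decoder widths, ASPP channels, growth rate, stem) are scaled by
#' \code{width_multiplier} as \code{max(1, round(base * multiplier))}.  The
#' KSM kernel sizes are fixed at (3, 5, 7).
#'
#' @param input_size Nominal input side in pixels, divisible by 16.  The
#'   network is fully convolutional, so any divisible-by-16 input runs; this
#'   value documents the intended tile size.
#' @param width_multiplier Positive real global channel scaling.
#' @param decoder_widths Four output widths for the decoder blocks
#'   (coarse to fine), before scaling.
#' @param aspp_rates Dilation rates of the ASPP branches.
#' @param aspp_channels ASPP branch/projection channels, before scaling.
#' @param ksm_reduction,ksm_min_width Bottleneck of the KSM attention.
#' @param se_reduction Squeeze-excitation reduction ratio.
#' @param dense_block_lengths Four dense-block lengths of the branch-2
#'   encoder.
#' @param growth_rate Dense-block growth rate, before scaling.
#' @param dense_compression Transition compression factor in (0, 1].
#' @param gating_mode \code{"soft"} multiplies the input by branch-1's
#'   continuous sigmoid output (differentiable; used during training
#'   regardless); \code{"hard"} thresholds the mask at 0.5 at inference.
#' @param seed Seed for the parameter initialisation.
#' @return An object of class \code{dks_model_config}.
#' @export
model_config <- function(input_size = 512L, width_multiplier = 1,
                         decoder_widths = c(256L, 128L, 64L, 32L),
                         aspp_rates = c(1L, 6L, 12L, 18L),
                         aspp_channels = 64L, ksm_reduction = 8L,
                         ksm_min_width = 32L, se_reduction = 8L,
                         dense_block_lengths = c(4L, 6L, 8L, 10L),
                         growth_rate = 16L, dense_compression = 0.5,
                         gating_mode = c("soft", "hard"), seed = 42L) {
  gating_mode <- match.arg(gating_mode)
  input_size <- check_count(input_size, "input_size", min = 16L)
  if (input_size %% 16 != 0) stop("`input_size` must be divisible by 16")
  if (width_multiplier <= 0) stop("`width_multiplier` must be positive")
  if (length(decoder_widths) != 4 || any(decoder_widths < 1)) {
    stop("`decoder_widths` must be 4 counts >= 1")
  }
  if (length(dense_block_lengths) != 4 || any(dense_block_lengths < 1)) {
    stop("`dense_block_lengths` must be 4 counts >= 1")
  }
  if (dense_compression <= 0 || dense_compression > 1) {
    stop("`dense_compression` must lie in (0, 1]")
  }
  structure(list(
    input_size = input_size, width_multiplier = width_multiplier,
    decoder_widths = as.integer(decoder_widths),
    aspp_rates = as.integer(aspp_rates),
    aspp_channels = check_count(aspp_channels, "aspp_channels"),
    ksm_kernels = c(3L, 5L, 7L),
    ksm_reduction = check_count(ksm_reduction, "ksm_reduction"),
    ksm_min_width = check_count(ksm_min_width, "ksm_min_width"),
    se_reduction = check_count(se_reduction, "se_reduction"),
    dense_block_lengths = as.integer(dense_block_lengths),
    growth_rate = check_count(growth_rate, "growth_rate"),
    dense_compression = dense_compression,
    gating_mode = gating_mode,
    seed = check_count(seed, "seed", min = 0L)
  ), class = "dks_model_config")
}

# Channel bookkeeping for the whole model, used by both the builder and the
# forward pass (and re-derived independently in the test suite).
dks_plan <- function(config) {
  wm <- config$width_multiplier
  vgg <- vgg_channel_plan(wm)
  dense <- dense_channel_plan(3L, config$dense_block_lengths,
                              config$growth_rate, wm,
                              config$dense_compression)
  list(
    vgg = vgg,
    dense = dense,
    aspp_ch = scale_ch(config$aspp_channels, wm),
    dec_w = scale_ch(config$decoder_widths, wm)
  )
}

build_dks <- function(store, config) {
  plan <- dks_plan(config)
  mk_vgg(store, "b1.enc", 3L, config$width_multiplier)
  mk_aspp(store, "b1.aspp", plan$vgg$channels[5], plan$aspp_ch,
          config$aspp_rates)
  c_run <- plan$aspp_ch
  for (i in 1:4) {
    c_run <- mk_decoder_block(store, sprintf("b1.dec%d", i), c_run,
                              plan$vgg$channels[5 - i], plan$dec_w[i],
                              config$se_reduction)
  }
  mk_ksm(store, "b1.ksm", plan$dec_w[4], config$ksm_reduction,
         config$ksm_min_width)
  mk_conv(store, "b1.head", 1L, plan$dec_w[4], 1L, bias = TRUE)

  mk_dense_enc(store, "b2.enc", 3L, config$dense_block_lengths,
               config$growth_rate, config$width_multiplier,
               config$dense_compression)
  mk_aspp(store, "b2.aspp", plan$dense$bottleneck, plan$aspp_ch,
          config$aspp_rates)
  enc2_skips <- plan$dense$skips  # scales 1, 1/2, 1/4, 1/8
  c_run <- plan$aspp_ch
  for (i in 1:4) {
    c_run <- mk_decoder_block(
      store, sprintf("b2.dec%d", i), c_run,
      c(plan$vgg$channels[5 - i], enc2_skips[5 - i]), plan$dec_w[i],
      config$se_reduction)
  }
  mk_ksm(store, "b2.ksm", plan$dec_w[4], config$ksm_reduction,
         config$ksm_min_width)
  mk_conv(store, "b2.head", 1L, plan$dec_w[4], 1L, bias = TRUE)
  invisible(plan)
}

#' Build the dual-branch segmentation model
#'
#' Instantiates every layer with He-initialised weights seeded from
#' \code{config$seed}, so identical configurations build bitwise-identical
#' models.
#'
#' @param config A \code{\link{model_config}}.
#' @return An object of class \code{dks_model} holding the configuration and
#'   the parameter store.
#' @export
dks_model <- function(config = model_config()) {
  if (!inherits(config, "dks_model_config")) {
    stop("`config` must come from model_config()")
  }
  store <- new_store()
  with_seed(config$seed, build_dks(store, config))
  structure(list(config = config, store = store), class = "dks_model")
}

# Forward graph shared by inference and training.  Returns nodes.
dks_graph <- function(model, x, tape, training) {
  cfg <- model$config
  store <- model$store
  enc1 <- fwd_vgg(tape, x, store, "b1.enc", cfg$width_multiplier, training)
  h <- fwd_aspp(tape, enc1$bottleneck, store, "b1.aspp", cfg$aspp_rates,
                training)$out
  for (i in 1:4) {
    h <- fwd_decoder_block(tape, h, list(enc1$skips[[5 - i]]), store,
                           sprintf("b1.dec%d", i), training)
  }
  h <- fwd_ksm(tape, h, store, "b1.ksm", training)
  mask1 <- op_sigmoid(tape, op_conv(tape, h, store, "b1.head"))

  gate <- mask1
  if (cfg$gating_mode == "hard" && !training) {
    gate <- op_input(tape, (mask1$v > 0.5) * 1)
  }
  gated <- op_gate(tape, x, gate)

  enc2 <- fwd_dense_enc(tape, gated, store, "b2.enc",
                        cfg$dense_block_lengths, training)
  h <- fwd_aspp(tape, enc2$bottleneck, store, "b2.aspp", cfg$aspp_rates,
                training)$out
  for (i in 1:4) {
    h <- fwd_decoder_block(
      tape, h, list(enc1$skips[[5 - i]], enc2$skips[[5 - i]]), store,
      sprintf("b2.dec%d", i), training)
  }
  h <- fwd_ksm(tape, h, store, "b2.ksm", training)
  mask2 <- op_sigmoid(tape, op_conv(tape, h, store, "b2.head"))
  list(mask1 = mask1, mask2 = mask2, gated = gated)
}

#' Forward pass
#'
#' Runs the full two-branch network on a batch of RGB images and returns the
#' two probability masks (branch 1's coarse mask and branch 2's refined
#' mask), both at the input's spatial resolution with values in [0, 1].
#'
#' @param model A \code{\link{dks_model}}.
#' @param x An (H, W, 3) or (H, W, 3, N) array with H, W divisible by 16 and
#'   finite values (images are expected in [0, 1]).
#' @param training Logical; use batch statistics (TRUE) or running
#'   statistics (FALSE) in the normalisation layers.
#' @return A list with \code{mask1_prob} and \code{mask2_prob}, each
#'   (H, W, 1, N).
#' @export
model_forward <- function(model, x, training = FALSE) {
  x <- as_feature_map(x)
  if (dim(x)[3] != 3) {
    stop(sprintf("expected 3 input channels, got %d", dim(x)[3]))
  }
  check_div16(dim(x)[1], dim(x)[2])
  nodes <- dks_graph(model, op_input(NULL, x), NULL, training)
  list(mask1_prob = nodes$mask1$v, mask2_prob = nodes$mask2$v)
}

#' Count trainable parameters
#'
#' Total number of trainable scalars (convolution and fully connected
#' weights and biases, batch-norm scale and shift).  Running batch-norm
#' statistics are not parameters.  The model is fully convolutional, so the
#' count does not depend on the input size.
#'
#' @param model A \code{\link{dks_model}}.
#' @return Integer-valued count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "dks_model"))
  sum(vapply(model$store$order,
             function(nm) length(model$store$params[[nm]]), numeric(1)))
}

#' Predict a binary mask
#'
#' Thresholds branch 2's probability map.  The comparison is strictly
#' greater, so probabilities exactly equal to the threshold map to
#' background.
#'
#' @param model A \code{\link{dks_model}}.
#' @param image An (H, W, 3) array (single image) or (H, W, 3, N) batch.
#' @param threshold Binarisation threshold in (0, 1), default 0.5.
#' @return An (H, W) matrix of 0/1 for a single image, else an
#'   (H, W, 1, N) array.
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie strictly in (0, 1)")
  }
  single <- length(dim(image)) == 3L || is.matrix(image)
  out <- model_forward(model, image)
  m <- (out$mask2_prob > threshold) * 1
  if (single) {
    d <- dim(m)
    m <- m[, , 1, 1]
    dim(m) <- d[1:2]
  }
  m
}

#' @export
predict.dks_model <- function(object, image, type = c("mask", "prob"),
                              threshold = 0.5, ...) {
  type <- match.arg(type)
  if (type == "mask") return(predict_mask(object, image, threshold))
  single <- length(dim(image)) == 3L || is.matrix(image)
  p <- model_forward(object, image)$mask2_prob
  if (single) {
    d <- dim(p)
    p <- p[, , 1, 1]
    dim(p) <- d[1:2]
  }
  p
}

#' @export
print.dks_model <- function(x, ...) {
  cfg <- x$config
  plan <- dks_plan(cfg)
  cat("Dual-branch kernel-selecting U-Net\n")
  cat(sprintf("  input: %dx%dx3 (any div-16 size runs)  width multiplier: %g\n",
              cfg$input_size, cfg$input_size, cfg$width_multiplier))
  cat(sprintf("  branch 1: VGG19-style encoder (%s)\n",
              paste(plan$vgg$channels, collapse = ", ")))
  cat(sprintf("  branch 2: dense encoder (stem %d, growth %d, blocks %s)\n",
              plan$dense$stem, plan$dense$growth,
              paste(cfg$dense_block_lengths, collapse = "-")))
  cat(sprintf("  ASPP rates (%s) @ %d ch; decoder widths (%s); KSM 3/5/7\n",
              paste(cfg$aspp_rates, collapse = ", "), plan$aspp_ch,
              paste(plan$dec_w, collapse = ", ")))
  cat(sprintf("  gating: %s;  parameters: %s\n", cfg$gating_mode,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' @export
summary.dks_model <- function(object, ...) {
  nms <- object$store$order
  group <- sub("^((b[12])\\.(enc|aspp|ksm|head|dec[1-4])).*", "\\1", nms)
  sizes <- vapply(nms, function(nm) length(object$store$params[[nm]]),
                  numeric(1))
  tab <- tapply(sizes, group, sum)
  print(object)
  cat("\nParameters by module:\n")
  for (g in names(tab)) cat(sprintf("  %-12s %12s\n", g,
                                    format(tab[[g]], big.mark = ",")))
  invisible(tab)
}

# --- checkpoints -----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Checkpoints are self-describing: they embed the full
#' \code{\link{model_config}}, every parameter array, and the batch-norm
#' running statistics, so \code{load_checkpoint} reconstructs a model whose
#' forward pass is bitwise identical.
#'
#' @param model A \code{\link{dks_model}}.
#' @param path File path (conventionally \code{.rds}).
#' @return \code{save_checkpoint} returns \code{path} invisibly;
#'   \code{load_checkpoint} returns a \code{dks_model}.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "dks_model"))
  obj <- list(
    format = "dksunet-checkpoint", format_version = 1L,
    config = model$config,
    params = as.list(model$store$params, all.names = TRUE),
    state = as.list(model$store$state, all.names = TRUE),
    order = model$store$order
  )
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "dksunet-checkpoint")) {
    stop(sprintf("`%s` is not a dksunet checkpoint", path))
  }
  store <- new_store()
  for (nm in names(obj$params)) store$params[[nm]] <- obj$params[[nm]]
  for (nm in names(obj$state)) store$state[[nm]] <- obj$state[[nm]]
  store$order <- obj$order
  structure(list(config = obj$config, store = store), class = "dks_model")
}
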
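# Training loop, evaluation and file-level prediction.

#' Training configuration
#'
#' Shipped defaults follow the reference protocol for 512 px tiles on GPU
#' hardware: Adam, learning rate 1e-5, batch size 4, 200 epochs, both heads
#' supervised with equal Dice-loss weights.  Desk-scale runs on small
#' synthetic tiles use far fewer epochs and a larger learning rate (see the
#' vignette's scaled-down profile).
#'
#' @param learning_rate Positive Adam step size (default 1e-5).
#' @param batch_size Minibatch size (default 4).
#' @param epochs Number of epochs (default 200).
#' @param loss_weights Weights (w1, w2) of the two heads' Dice losses;
#'   must sum to 1 (default 0.5/0.5).
#' @param seed Seed controlling shuffling (and thus the whole run, given a
#'   seeded model).
#' @param checkpoint_dir Optional directory for the best checkpoint and the
#'   history JSON.
#' @param early_stop_patience Stop after this many epochs without validation
#'   improvement; NULL (default) disables early stopping.
#' @param smooth Dice smoothing constant.
#' @param verbose Print one line per epoch.
#' @return A list of class \code{dks_train_config}.
#' @export
train_config <- function(learning_rate = 1e-5, batch_size = 4L,
                         epochs = 200L, loss_weights = c(0.5, 0.5),
                         seed = 1L, checkpoint_dir = NULL,
                         early_stop_patience = NULL, smooth = 1e-6,
                         verbose = TRUE) {
  if (learning_rate <= 0) stop("`learning_rate` must be positive")
  batch_size <- check_count(batch_size, "batch_size")
  epochs <- check_count(epochs, "epochs")
  if (length(loss_weights) != 2 || abs(sum(loss_weights) - 1) > 1e-8) {
    stop("`loss_weights` must be two weights summing to 1")
  }
  if (!is.null(early_stop_patience)) {
    early_stop_patience <- check_count(early_stop_patience,
                                       "early_stop_patience")
  }
  structure(list(
    learning_rate = learning_rate, batch_size = batch_size,
    epochs = epochs, loss_weights = loss_weights,
    seed = check_count(seed, "seed", min = 0L),
    checkpoint_dir = checkpoint_dir,
    early_stop_patience = early_stop_patience,
    smooth = smooth, verbose = isTRUE(verbose)
  ), class = "dks_train_config")
}

clone_model <- function(model) {
  store <- new_store()
  for (nm in ls(model$store$params, all.names = TRUE)) {
    store$params[[nm]] <- model$store$params[[nm]]
  }
  for (nm in ls(model$store$state, all.names = TRUE)) {
    store$state[[nm]] <- model$store$state[[nm]]
  }
  store$order <- model$store$order
  structure(list(config = model$config, store = store), class = "dks_model")
}

as_pairs <- function(data, what) {
  if (is.character(data) && length(data) == 1) return(load_dataset(data))
  if (!is.list(data) || length(data) == 0) {
    stop(sprintf("`%s` must be a dataset directory or a non-empty list of image/mask pairs", what))
  }
  data
}

batch_arrays <- function(pairs, idx) {
  d <- dim(pairs[[idx[1]]]$image)
  B <- length(idx)
  x <- array(0, c(d[1], d[2], 3, B))
  t <- array(0, c(d[1], d[2], 1, B))
  for (j in seq_along(idx)) {
    p <- pairs[[idx[j]]]
    if (!identical(dim(p$image)[1:2], dim(p$mask)[1:2]) ||
        !identical(dim(p$image)[1:2], d[1:2])) {
      stop(sprintf("image/mask shape mismatch in pair %d%s", idx[j],
                   if (!is.null(p$id)) sprintf(" (%s)", p$id) else ""))
    }
    x[, , , j] <- p$image
    t[, , 1, j] <- p$mask
  }
  list(x = x, t = t)
}

# One Adam step on a batch; returns the combined loss value.
train_step <- function(model, opt, x, t, w, smooth) {
  tape <- new_tape()
  nodes <- dks_graph(model, op_input(tape, x), tape, training = TRUE)
  l1 <- op_dice_loss(tape, nodes$mask1, t, smooth)
  l2 <- op_dice_loss(tape, nodes$mask2, t, smooth)
  loss <- op_wsum2(tape, l1, l2, w[1], w[2])
  tape_backward(tape, loss$id)
  adam_step(opt, model$store, tape$pgrads)
  loss$v
}

eval_pass <- function(model, pairs, batch_size, w, smooth, threshold = 0.5) {
  n <- length(pairs)
  dices <- numeric(n)
  losses <- numeric(0)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    ba <- batch_arrays(pairs, idx)
    out <- dks_graph(model, op_input(NULL, ba$x), NULL, training = FALSE)
    l <- w[1] * op_dice_loss(NULL, out$mask1, ba$t, smooth)$v +
      w[2] * op_dice_loss(NULL, out$mask2, ba$t, smooth)$v
    losses <- c(losses, l)
    for (j in seq_along(idx)) {
      pred <- (out$mask2$v[, , 1, j] > threshold) * 1
      tgt <- ba$t[, , 1, j]
      cc <- confusion_counts(pred, tgt)
      dices[idx[j]] <- compute_metrics(cc)$dice
    }
  }
  list(dice = mean(dices), loss = mean(losses), per_image = dices)
}

#' Train the model
#'
#' Minibatch Adam on the combined loss \code{w1 * dice_loss(mask1) + w2 *
#' dice_loss(mask2)} (both heads supervised).  After each epoch the
#' validation Dice of the binarised branch-2 mask is computed and the
#' best-by-validation parameters are retained.  The run is fully seeded:
#' data order comes from \code{config$seed}, initial weights from the model
#' config's seed, and there is no augmentation, so identical seeds reproduce
#' identical histories.
#'
#' The passed model is not modified; a trained copy is returned.
#'
#' @param model A \code{\link{dks_model}}.
#' @param train_data A \code{\link{generate_dataset}}-style directory or a
#'   list of \code{list(image, mask)} pairs.
#' @param val_data Like \code{train_data}, or NULL to select by training
#'   loss.
#' @param config A \code{\link{train_config}}.
#' @return An object of class \code{dks_fit}: list with \code{model} (best
#'   weights), \code{history} (data frame epoch/train_loss/val_loss/
#'   val_dice), and \code{train_config}.
#' @export
train_model <- function(model, train_data, val_data = NULL,
                        config = train_config()) {
  stopifnot(inherits(model, "dks_model"),
            inherits(config, "dks_train_config"))
  train_pairs <- as_pairs(train_data, "train_data")
  val_pairs <- if (!is.null(val_data)) as_pairs(val_data, "val_data")
  if (length(train_pairs) == 0) stop("empty training set")
  model <- clone_model(model)
  opt <- new_adam(lr = config$learning_rate)
  w <- config$loss_weights
  n <- length(train_pairs)
  hist_rows <- vector("list", config$epochs)
  best <- list(dice = -Inf, params = NULL, state = NULL)
  since_best <- 0L

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      order <- sample.int(n)
      batch_losses <- numeric(0)
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- order[start:min(start + config$batch_size - 1, n)]
        ba <- batch_arrays(train_pairs, idx)
        batch_losses <- c(batch_losses,
                          train_step(model, opt, ba$x, ba$t, w,
                                     config$smooth))
      }
      train_loss <- mean(batch_losses)
      val_dice <- NA_real_; val_loss <- NA_real_
      if (!is.null(val_pairs)) {
        ev <- eval_pass(model, val_pairs, config$batch_size, w,
                        config$smooth)
        val_dice <- ev$dice; val_loss <- ev$loss
      }
      hist_rows[[epoch]] <- data.frame(
        epoch = epoch, train_loss = train_loss, val_loss = val_loss,
        val_dice = val_dice)
      score <- if (is.na(val_dice)) -train_loss else val_dice
      if (score > best$dice) {
        best <- list(dice = score,
                     params = as.list(model$store$params, all.names = TRUE),
                     state = as.list(model$store$state, all.names = TRUE))
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
      if (config$verbose) {
        message(sprintf(
          "epoch %3d/%d  train loss %.4f%s", epoch, config$epochs,
          train_loss,
          if (is.na(val_dice)) "" else
            sprintf("  val loss %.4f  val Dice %.4f", val_loss, val_dice)))
      }
      if (!is.null(config$early_stop_patience) &&
          since_best >= config$early_stop_patience) break
    }
  })

  history <- do.call(rbind, hist_rows[!vapply(hist_rows, is.null,
                                              logical(1))])
  if (!is.null(best$params)) {
    for (nm in names(best$params)) model$store$params[[nm]] <- best$params[[nm]]
    for (nm in names(best$state)) model$store$state[[nm]] <- best$state[[nm]]
  }
  fit <- structure(list(model = model, history = history,
                        train_config = config), class = "dks_fit")
  if (!is.null(config$checkpoint_dir)) {
    dir.create(config$checkpoint_dir, recursive = TRUE,
               showWarnings = FALSE)
    save_checkpoint(model, file.path(config$checkpoint_dir, "best.rds"))
    jsonlite::write_json(history,
                         file.path(config$checkpoint_dir, "history.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  fit
}

#' @export
print.dks_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("Trained dual-branch model: %d epoch(s)\n", nrow(h)))
  cat(sprintf("  final train loss %.4f\n", h$train_loss[nrow(h)]))
  if (!all(is.na(h$val_dice))) {
    cat(sprintf("  best val Dice %.4f (epoch %d)\n",
                max(h$val_dice, na.rm = TRUE),
                h$epoch[which.max(h$val_dice)]))
  }
  invisible(x)
}

#' @export
plot.dks_fit <- function(x, ...) {
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = "Dice loss",
                 main = "Training history", ylim = c(0, max(h$train_loss)),
                 ...)
  if (!all(is.na(h$val_dice))) {
    graphics::lines(h$epoch, 1 - h$val_dice, type = "b", pch = 1, lty = 2)
    graphics::legend("topright",
                     legend = c("train loss", "1 - val Dice"),
                     lty = c(1, 2), pch = c(16, 1), bty = "n")
  }
  invisible(x)
}

#' Evaluate on a test set
#'
#' Computes per-image confusion counts and metrics, plus both aggregation
#' conventions (per-image mean and globally pooled).  When \code{json_path}
#' is given, a report with the columns Dice, mIou, Recall, Precision,
#' F1-Score (plus the 2-class IoU audit column) is written as JSON.
#'
#' @param model A \code{\link{dks_model}}, a \code{dks_fit}, or a
#'   checkpoint path.
#' @param test_data Dataset directory or list of pairs.
#' @param threshold Binarisation threshold (default 0.5).
#' @param json_path Optional output JSON path.
#' @param batch_size Forward-pass batch size (default 4).
#' @return A list of class \code{dks_eval} with \code{per_image} (data
#'   frame), \code{mean} and \code{pooled} (\code{metrics_report}s).
#' @export
evaluate_model <- function(model, test_data, threshold = 0.5,
                           json_path = NULL, batch_size = 4L) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (inherits(model, "dks_fit")) model <- model$model
  stopifnot(inherits(model, "dks_model"))
  pairs <- as_pairs(test_data, "test_data")
  n <- length(pairs)
  counts <- vector("list", n)
  reports <- vector("list", n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    ba <- batch_arrays(pairs, idx)
    out <- model_forward(model, ba$x)
    for (j in seq_along(idx)) {
      pred <- (out$mask2_prob[, , 1, j] > threshold) * 1
      counts[[idx[j]]] <- confusion_counts(pred, ba$t[, , 1, j])
      reports[[idx[j]]] <- compute_metrics(counts[[idx[j]]])
    }
  }
  agg <- aggregate_metrics(reports, counts)
  per_image <- data.frame(
    id = vapply(seq_len(n), function(i) {
      if (!is.null(pairs[[i]]$id)) pairs[[i]]$id else sprintf("img_%03d", i)
    }, character(1)),
    Dice = vapply(reports, `[[`, numeric(1), "dice"),
    mIou = vapply(reports, `[[`, numeric(1), "miou_paper"),
    Recall = vapply(reports, `[[`, numeric(1), "recall"),
    Precision = vapply(reports, `[[`, numeric(1), "precision"),
    `F1-Score` = vapply(reports, `[[`, numeric(1), "f1"),
    iou_mean2class = vapply(reports, `[[`, numeric(1), "iou_mean2class"),
    check.names = FALSE)
  res <- structure(list(per_image = per_image, mean = agg$mean,
                        pooled = agg$pooled, threshold = threshold),
                   class = "dks_eval")
  if (!is.null(json_path)) {
    fmt <- function(r) list(
      Dice = r$dice, mIou = r$miou_paper, Recall = r$recall,
      Precision = r$precision, `F1-Score` = r$f1,
      iou_mean2class = r$iou_mean2class)
    jsonlite::write_json(
      list(columns = c("Dice", "mIou", "Recall", "Precision", "F1-Score"),
           per_image = per_image, mean = fmt(agg$mean),
           pooled = fmt(agg$pooled)),
      json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

#' @export
print.dks_eval <- function(x, ...) {
  cat(sprintf("Evaluation over %d image(s), threshold %.2f\n",
              nrow(x$per_image), x$threshold))
  cat("  per-image mean: "); print(x$mean)
  cat("  pooled:         "); print(x$pooled)
  invisible(x)
}

#' Predict a mask for an image file
#'
#' Reads the image (resizing with a warning if its dimensions are not
#' divisible by 16), runs the model, and writes the binary mask as PNG
#' (optionally also the probability map).  Inference is deterministic: the
#' same checkpoint and input produce identical output bytes.
#'
#' @param model A \code{\link{dks_model}}, \code{dks_fit} or checkpoint
#'   path.
#' @param input_path Input image (PNG/TIFF).
#' @param out_path Output mask PNG.
#' @param threshold Binarisation threshold.
#' @param prob_path Optional output PNG for the probability map.
#' @return \code{out_path}, invisibly.
#' @export
predict_to_file <- function(model, input_path, out_path, threshold = 0.5,
                            prob_path = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  if (inherits(model, "dks_fit")) model <- model$model
  img <- read_image(input_path)
  d <- dim(img)
  if (d[1] %% 16 != 0 || d[2] %% 16 != 0) {
    warning(sprintf("resizing %s to a divisible-by-16 size", input_path))
    side <- max(16L, 16L * round(max(d[1:2]) / 16))
    img <- resize_pair(img, NULL, side)$image
  }
  prob <- model_forward(model, img)$mask2_prob
  m <- (prob[, , 1, 1] > threshold) * 1
  dim(m) <- dim(prob)[1:2]
  write_mask(m, out_path)
  if (!is.null(prob_path)) {
    p <- prob[, , 1, 1]
    dim(p) <- dim(prob)[1:2]
    png::writePNG(p, prob_path)
  }
  invisible(out_path)
}

#' Read a model + training configuration from YAML
#'
#' The file may hold top-level \code{model:} and \code{train:} sections
#' whose keys are the arguments of \code{\link{model_config}} and
#' \code{\link{train_config}}; missing keys take the documented defaults.
#'
#' @param path YAML file.
#' @return \code{list(model = model_config, train = train_config)}.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  model_args <- y$model
  if (!is.null(model_args)) {
    for (f in c("decoder_widths", "aspp_rates", "dense_block_lengths")) {
      if (!is.null(model_args[[f]])) {
        model_args[[f]] <- as.integer(unlist(model_args[[f]]))
      }
    }
  }
  train_args <- y$train
  if (!is.null(train_args$loss_weights)) {
    train_args$loss_weights <- as.numeric(unlist(train_args$loss_weights))
  }
  list(model = do.call(model_config, as.list(model_args)),
       train = do.call(train_config, as.list(train_args)))
}
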
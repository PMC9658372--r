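# Training protocol: SGD with momentum on species-level cross-entropy,
# step-decay learning rate (x0.1 every 7 epochs from 0.005), 50 epochs with
# a validation pass at the end of every epoch.

#' Training configuration
#'
#' Defaults follow the experimental protocol the package implements: an
#' initial learning rate of 0.005 reduced to 10% of its current value every
#' 7 epochs, 50 epochs in total, SGD with momentum 0.9 and batch size 32,
#' species-level cross-entropy loss, and a validation pass after each epoch.
#'
#' @param initial_lr Initial learning rate (default 0.005).
#' @param decay_factor Multiplicative decay (default 0.1).
#' @param decay_step Epochs between decays (default 7).
#' @param epochs Number of training epochs (default 50).
#' @param batch_size Minibatch size (default 32).
#' @param optimizer Only `"sgd"` is implemented.
#' @param momentum SGD momentum (default 0.9).
#' @param seed Seed controlling weight initialisation and shuffling.
#' @param omega Attention amplification used during training and prediction
#'   (default 1.2; 1 disables attention).
#' @param select_best Keep the weights of the epoch with the highest
#'   validation accuracy (ties broken toward the earlier epoch); otherwise
#'   keep the final weights and use validation purely as monitoring.
#' @return An object of class `amcnn_train_config`.
#' @export
train_config <- function(initial_lr = 0.005, decay_factor = 0.1,
                         decay_step = 7L, epochs = 50L, batch_size = 32L,
                         optimizer = "sgd", momentum = 0.9, seed = 0L,
                         omega = 1.2, select_best = TRUE) {
  if (decay_factor <= 0 || decay_factor > 1)
    stop("decay_factor must lie in (0, 1]")
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  optimizer <- match.arg(optimizer, "sgd")
  if (omega <= 0) stop("omega must be > 0")
  structure(list(initial_lr = initial_lr, decay_factor = decay_factor,
                 decay_step = as.integer(decay_step), epochs = epochs,
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 momentum = momentum, seed = as.integer(seed), omega = omega,
                 select_best = isTRUE(select_best)),
            class = "amcnn_train_config")
}

#' Learning rate at a given epoch
#'
#' Step decay: `initial_lr * decay_factor^(epoch %/% decay_step)` with
#' 0-based epochs, i.e. epochs 0..6 run at the initial rate and epoch 7 at
#' 10% of it under the defaults.
#'
#' @param config An [train_config()].
#' @param epoch 0-based epoch index (vectorised).
#' @return Learning rate(s).
#' @export
lr_at_epoch <- function(config, epoch) {
  stopifnot(inherits(config, "amcnn_train_config"))
  epoch <- as.integer(epoch)
  if (any(epoch < 0L)) stop("epoch must be >= 0")
  config$initial_lr * config$decay_factor^(epoch %/% config$decay_step)
}

# Load the image tensor + weight maps for a set of records.
prepare_part <- function(records, image_root, mask_provider, omega, side) {
  paths <- resolve_paths(records, image_root)
  list(x = load_image_tensor(paths, side = side),
       w = if (is.null(mask_provider)) NULL
           else weight_map_stack(records, mask_provider, omega),
       records = records)
}

part_accuracy <- function(model, part, labels, batch_size) {
  if (nrow(part$records) == 0L) return(NA_real_)
  probs <- predict_probs(model, part$x, part$w, batch_size)
  mean(max.col(probs, ties.method = "first") == labels)
}

#' Fit the attention-masked CNN to a labelled image manifest
#'
#' The single fitting entry point: trains the network on the `train` part
#' of the split with SGD + momentum under the step-decay schedule of
#' `config`, computing validation accuracy after every epoch, and returns a
#' classed fit object with `print`, `summary`, `plot` and `predict`
#' methods.  Masks for the attention layer are fetched per image from
#' `mask_provider` and mapped to weight maps with `config$omega` (pass
#' `mask_provider = NULL`, or omega = 1, to train the plain backbone).
#'
#' @param manifest An [build_manifest()] manifest.
#' @param split An [split_manifest()] assignment for it.
#' @param config A [train_config()].
#' @param spec An [amcnn_spec()]; by default one is derived from the
#'   manifest (species-level classes) and `config$omega`.
#' @param mask_provider A mask provider (see [mask_provider_oracle()]), or
#'   `NULL` for no attention weighting.
#' @param image_root Directory that record paths are relative to.
#' @param level Taxonomic level whose classes are the training target
#'   (default `"species"`; genus- or family-level models can be trained for
#'   per-level evaluation instead of roll-up).
#' @param verbose Print a line per epoch.
#' @return An object of class `amcnn_fit`: list with the trained `model`,
#'   per-epoch `history` (epoch, lr, train_loss, val_accuracy),
#'   `best_epoch`, `class_index`, `taxonomy`, the `config` echo and
#'   `wall_time` in seconds (informational).
#' @export
amcnn_fit <- function(manifest, split, config = train_config(), spec = NULL,
                      mask_provider = NULL, image_root = NULL,
                      level = c("species", "genus", "family"),
                      verbose = FALSE) {
  stopifnot(inherits(manifest, "amcnn_manifest"), inherits(split, "amcnn_split"),
            inherits(config, "amcnn_train_config"))
  level <- match.arg(level)
  t0 <- proc.time()[["elapsed"]]

  class_index <- manifest$class_index[[level]]
  if (is.null(spec))
    spec <- amcnn_spec(n_classes = length(class_index), omega = config$omega)
  omega <- config$omega

  tr_recs <- split_records(manifest, split, "train")
  if (nrow(tr_recs) == 0L) stop("empty train split")
  va_recs <- split_records(manifest, split, "val")

  lab_of <- function(recs) unname(class_index[recs[[level]]]) + 1L  # 1-based
  tr_y <- lab_of(tr_recs)
  va_y <- lab_of(va_recs)
  missing_cls <- setdiff(unique(c(va_recs[[level]],
                                  split_records(manifest, split, "test")[[level]])),
                         unique(tr_recs[[level]]))
  if (length(missing_cls))
    warning("classes absent from the train split: ",
            paste(missing_cls, collapse = ", "))

  use_masks <- !is.null(mask_provider) && omega != 1
  mp <- if (use_masks) mask_provider else NULL
  tr <- prepare_part(tr_recs, image_root, mp, omega, spec$input_side)
  va <- prepare_part(va_recs, image_root, mp, omega, spec$input_side)

  model <- amcnn_model(spec, seed = config$seed)
  vel <- NULL
  bbcache <- NULL
  n_tr <- nrow(tr_recs)
  history <- data.frame(epoch = seq_len(config$epochs), lr = NA_real_,
                        train_loss = NA_real_, val_accuracy = NA_real_)
  best <- list(acc = -Inf, epoch = NA_integer_, model = NULL)

  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      lr <- lr_at_epoch(config, ep - 1L)
      ord <- sample(n_tr)
      losses <- c()
      for (i0 in seq(1L, n_tr, by = config$batch_size)) {
        idx <- ord[i0:min(i0 + config$batch_size - 1L, n_tr)]
        lg <- loss_and_grads(model,
                             tr$x[, , , idx, drop = FALSE],
                             if (is.null(tr$w)) NULL else tr$w[, , idx, drop = FALSE],
                             tr_y[idx], reuse_cache = bbcache)
        bbcache <- lg$cache
        up <- sgd_update(model$layers, lg$grads, vel, lr, config$momentum)
        model$layers <- up$m
        vel <- up$v
        losses <- c(losses, lg$loss)
      }
      val_acc <- part_accuracy(model, va, va_y, config$batch_size)
      history$lr[ep] <- lr
      history$train_loss[ep] <- mean(losses)
      history$val_accuracy[ep] <- val_acc
      if (!is.na(val_acc) && val_acc > best$acc) {
        best$acc <- val_acc
        best$epoch <- ep
        if (config$select_best) best$model <- model
      }
      if (verbose)
        message(sprintf("epoch %d/%d lr=%.4g loss=%.4f val_acc=%s",
                        ep, config$epochs, lr, mean(losses),
                        ifelse(is.na(val_acc), "NA", sprintf("%.3f", val_acc))))
    }
  })

  final <- if (config$select_best && !is.null(best$model)) best$model else model
  structure(list(model = final, history = history,
                 best_epoch = if (is.na(best$epoch)) config$epochs else best$epoch,
                 class_index = class_index, level = level,
                 taxonomy = unique(manifest$records[, c("family", "genus", "species")]),
                 config = config, omega = omega, use_masks = use_masks,
                 wall_time = proc.time()[["elapsed"]] - t0),
            class = "amcnn_fit")
}

#' @export
print.amcnn_fit <- function(x, ...) {
  h <- x$history
  cat("Attention-masked CNN fit (", x$level, " level, ",
      length(x$class_index), " classes)\n", sep = "")
  cat("  omega = ", x$omega,
      if (x$use_masks) " (mask-weighted attention)" else " (no attention weighting)",
      "; ", nrow(h), " epochs\n", sep = "")
  best_acc <- suppressWarnings(max(h$val_accuracy, na.rm = TRUE))
  cat(sprintf("  final train loss %.4f; best val accuracy %s (epoch %d)\n",
              h$train_loss[nrow(h)],
              if (is.finite(best_acc)) sprintf("%.3f", best_acc) else "NA",
              x$best_epoch))
  invisible(x)
}

#' @export
summary.amcnn_fit <- function(object, ...) {
  print(object)
  cat("\nPer-epoch history:\n")
  print(object$history, row.names = FALSE)
  invisible(object$history)
}

#' @export
plot.amcnn_fit <- function(x, ...) {
  h <- x$history
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(h$epoch, h$train_loss, type = "b", xlab = "epoch",
       ylab = "training loss", main = "Loss", ...)
  plot(h$epoch, h$val_accuracy, type = "b", xlab = "epoch",
       ylab = "validation accuracy", ylim = c(0, 1), main = "Validation", ...)
  invisible(x)
}

#' Predict from a fitted model
#'
#' @param object An `amcnn_fit`.
#' @param newdata An image array `(side, side, 3[, N])`, a character vector
#'   of image paths, or a record data.frame with a `path` column.
#' @param type `"class"` (default; 0-based class indices with names),
#'   `"prob"` (N x K matrix) or `"topk"` (list of ranked data.frames).
#' @param mask_provider Optional mask provider for attention weighting at
#'   prediction time (used with the fitted omega).
#' @param k Number of ranked classes for `type = "topk"`.
#' @param image_root Directory that record paths are relative to.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.amcnn_fit <- function(object, newdata, type = c("class", "prob", "topk"),
                              mask_provider = NULL, k = 3L, image_root = NULL,
                              ...) {
  type <- match.arg(type)
  side <- object$model$spec$input_side
  recs <- NULL
  if (is.character(newdata))
    recs <- data.frame(path = newdata, stringsAsFactors = FALSE)
  else if (is.data.frame(newdata)) recs <- newdata
  if (!is.null(recs)) {
    x <- load_image_tensor(resolve_paths(recs, image_root), side = side)
  } else {
    x <- as_batch(newdata, side)
  }
  w <- NULL
  if (!is.null(mask_provider) && object$omega != 1) {
    if (is.null(recs))
      stop("mask providers need image records (paths), not raw arrays")
    w <- weight_map_stack(recs, mask_provider, object$omega)
  }
  probs <- predict_probs(object$model, x, w,
                         object$config$batch_size)
  labels <- names(object$class_index)
  colnames(probs) <- labels
  if (type == "prob") return(probs)
  if (type == "class") {
    i <- max.col(probs, ties.method = "first")
    return(stats::setNames(object$class_index[labels[i]], labels[i]))
  }
  lapply(seq_len(nrow(probs)), function(r) top_k(probs[r, ], k = k))
}

#' Sweep the attention amplification factor
#'
#' Trains and tests one model per omega value on an identical
#' manifest/split/config (same seed), reporting species-level test
#' accuracy.  One row per (omega, seed) combination; rows are sorted by
#' omega.  When `csv` is given the table is written with header
#' `omega,accuracy,seed`.
#'
#' @param values Positive omega values to sweep.
#' @param manifest,split,config,mask_provider,image_root As [amcnn_fit()].
#' @param seeds Integer seeds; each seed trains the whole grid once.
#' @param csv Optional output CSV path.
#' @param verbose Print one line per run.
#' @return data.frame with columns `omega`, `accuracy`, `seed`.
#' @export
omega_sweep <- function(values, manifest, split, config = train_config(),
                        mask_provider = mask_provider_oracle(), image_root = NULL,
                        seeds = config$seed, csv = NULL, verbose = FALSE) {
  if (length(values) == 0L || any(values <= 0))
    stop("omega values must be positive and non-empty")
  values <- sort(as.numeric(values))
  rows <- list()
  for (seed in seeds) {
    for (om in values) {
      cfg <- config
      cfg$seed <- as.integer(seed)
      cfg$omega <- om
      fit <- amcnn_fit(manifest, split, cfg, mask_provider = mask_provider,
                       image_root = image_root)
      preds <- predict_set(fit, manifest, split, part = "test",
                           mask_provider = mask_provider,
                           image_root = image_root)
      acc <- accuracy(preds)
      rows[[length(rows) + 1L]] <- data.frame(omega = om, accuracy = acc,
                                              seed = seed)
      if (verbose)
        message(sprintf("omega=%.2f seed=%d accuracy=%.3f", om, seed, acc))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$omega, out$seed), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}

#' Save and load model checkpoints
#'
#' A checkpoint is a single archive holding the weights, the architecture
#' spec, the class-index maps and a format-version field; a save/load
#' round trip reproduces inference scores bitwise.
#'
#' @param fit An `amcnn_fit`.
#' @param path Checkpoint file path (.rds).
#' @return `amcnn_load` returns the restored `amcnn_fit`.
#' @export
amcnn_save <- function(fit, path) {
  stopifnot(inherits(fit, "amcnn_fit"))
  obj <- unclass(fit)
  obj$format_version <- 1L
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname amcnn_save
#' @export
amcnn_load <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stop("unsupported checkpoint format version")
  obj$format_version <- NULL
  structure(obj, class = "amcnn_fit")
}
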
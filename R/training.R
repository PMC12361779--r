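# Cross-entropy training with the two published strategies: the baseline
# (SGD with momentum and an exponential "lambda" learning-rate decay) and
# the improved one (Adam with cosine-annealing decay, optionally warm-
# started by transfer learning from a larger source dataset).

#' Training configuration
#'
#' @param optimizer `"sgd"` or `"adam"`.
#' @param lr0 initial learning rate (default 0.001).
#' @param epochs number of epochs (default 100).
#' @param batch mini-batch size (default 16).
#' @param schedule `"lambda_decay"` (exponential), `"cosine"`, or `"none"`.
#' @param lambda_gamma per-epoch decay factor for the lambda schedule.
#' @param eta_min floor of the cosine schedule.
#' @param momentum SGD momentum.
#' @param seed RNG seed covering data order, dropout and augmentation.
#' @param freeze character vector of layer-id prefixes excluded from
#'   updates.
#' @param class_weights optional per-class loss weights (default uniform).
#' @param augment optional [augmentation_config()] applied online to
#'   training batches.
#' @param early_stop_acc optional validation-accuracy threshold at which
#'   training stops early.
#' @return a `train_config` list.
#' @export
train_config <- function(optimizer = c("sgd", "adam"), lr0 = 0.001,
                         epochs = 100L, batch = 16L,
                         schedule = c("lambda_decay", "cosine", "none"),
                         lambda_gamma = 0.97, eta_min = 0, momentum = 0.9,
                         seed = 42L, freeze = character(0),
                         class_weights = NULL, augment = NULL,
                         early_stop_acc = NULL) {
  optimizer <- match.arg(optimizer)
  schedule <- match.arg(schedule)
  stopifnot(lr0 > 0, epochs >= 1, batch >= 1)
  structure(list(optimizer = optimizer, lr0 = lr0, epochs = as.integer(epochs),
                 batch = as.integer(batch), schedule = schedule,
                 lambda_gamma = lambda_gamma, eta_min = eta_min,
                 momentum = momentum, seed = as.integer(seed),
                 freeze = freeze, class_weights = class_weights,
                 augment = augment, early_stop_acc = early_stop_acc),
            class = "train_config")
}

#' Learning-rate schedule
#'
#' Closed forms: cosine annealing
#' `eta_min + (lr0 - eta_min) * (1 + cos(pi * epoch/epochs)) / 2`,
#' exponential lambda decay `lr0 * lambda_gamma^epoch`, or constant.
#'
#' @param epoch 0-based epoch index, `0 <= epoch <= cfg$epochs`.
#' @param cfg a [train_config()].
#' @return learning rate.
#' @export
lr_schedule <- function(epoch, cfg) {
  if (epoch < 0 || epoch > cfg$epochs)
    stop("epoch must lie in [0, ", cfg$epochs, "]")
  switch(cfg$schedule,
    cosine = cfg$eta_min +
      (cfg$lr0 - cfg$eta_min) * (1 + cos(pi * epoch / cfg$epochs)) / 2,
    lambda_decay = cfg$lr0 * cfg$lambda_gamma^epoch,
    none = cfg$lr0)
}

softmax_ce <- function(logits, y, class_weights = NULL) {
  n <- nrow(logits)
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  p <- e / rowSums(e)
  iy <- cbind(seq_len(n), y + 1L)
  wts <- if (is.null(class_weights)) rep(1, n) else class_weights[y + 1L]
  loss <- -sum(wts * log(pmax(p[iy], 1e-300))) / sum(wts)
  d <- p
  d[iy] <- d[iy] - 1
  d <- d * (wts / sum(wts))
  list(loss = loss, grad = d)
}

frozen_layer <- function(id, freeze) {
  length(freeze) > 0 && any(startsWith(id, freeze))
}

opt_step <- function(leaves, cfg, lr, step) {
  for (lf in leaves) {
    if (!length(lf$w) || frozen_layer(lf$id, cfg$freeze)) next
    for (wn in names(lf$w)) {
      g <- lf$g[[wn]]
      if (is.null(g)) next
      if (cfg$optimizer == "sgd") {
        if (is.null(lf$.vel)) lf$.vel <- list()
        v <- lf$.vel[[wn]]
        if (is.null(v)) v <- g * 0
        v <- cfg$momentum * v + g
        lf$.vel[[wn]] <- v
        lf$w[[wn]] <- lf$w[[wn]] - lr * v
      } else {
        if (is.null(lf$.m)) { lf$.m <- list(); lf$.v <- list() }
        m <- lf$.m[[wn]]; v <- lf$.v[[wn]]
        if (is.null(m)) { m <- g * 0; v <- g * 0 }
        m <- 0.9 * m + 0.1 * g
        v <- 0.999 * v + 0.001 * g * g
        lf$.m[[wn]] <- m; lf$.v[[wn]] <- v
        mhat <- m / (1 - 0.9^step)
        vhat <- v / (1 - 0.999^step)
        lf$w[[wn]] <- lf$w[[wn]] - lr * mhat / (sqrt(vhat) + 1e-8)
      }
    }
  }
}

batch_input <- function(images, idx, augment = NULL,
                        mean = c(0.485, 0.456, 0.406),
                        sd = c(0.229, 0.224, 0.225)) {
  d <- dim(images)
  h <- d[2]; w <- d[3]
  sub <- images[idx, , , , drop = FALSE]
  if (!is.null(augment)) {
    for (i in seq_along(idx)) {
      img <- array(sub[i, , , ], d[2:4])
      sub[i, , , ] <- augment_image(img, augment)
    }
  }
  n <- length(idx)
  x <- matrix(aperm(sub, c(3, 2, 1, 4)), n * h * w, 3L)
  for (c in 1:3) x[, c] <- (x[, c] - mean[c]) / sd[c]
  fm_new(x, n, h, w)
}

eval_dataset <- function(model, ds, batch = 32L, class_weights = NULL) {
  n <- length(ds$labels)
  loss <- 0
  pred <- integer(n)
  done <- 0L
  while (done < n) {
    idx <- (done + 1L):min(done + batch, n)
    fmx <- batch_input(ds$images, idx)
    out <- layer_fwd(model, fmx, training = FALSE)
    sc <- softmax_ce(out$x, ds$labels[idx], class_weights)
    loss <- loss + sc$loss * length(idx)
    pred[idx] <- max.col(out$x) - 1L
    done <- done + length(idx)
  }
  list(loss = loss / n, acc = mean(pred == ds$labels), pred = pred)
}

#' Fit a model
#'
#' Minimizes mean cross-entropy with per-epoch validation and
#' best-by-validation-accuracy checkpointing. Fully seeded: data order,
#' dropout masks and augmentation draws derive from `cfg$seed`.
#'
#' @param model a built model (its label space must match the data).
#' @param train,val dataset tensors from [load_dataset_tensor()]:
#'   lists with `images` (N x H x W x 3 in `[0,1]`) and `labels` (0-based).
#' @param cfg a [train_config()].
#' @param checkpoint_dir optional directory receiving `best.rds` /
#'   `last.rds` checkpoints and an architecture manifest.
#' @param verbose print per-epoch progress.
#' @return a `train_log`: data.frame `log` (epoch, train_loss, val_loss,
#'   val_acc, lr), `best_epoch`, `best_val_acc`, `epochs_to_threshold`
#'   (NA when no `early_stop_acc` given or never reached), and checkpoint
#'   paths when written.
#' @export
fit <- function(model, train, val, cfg = train_config(),
                checkpoint_dir = NULL, verbose = FALSE) {
  ky <- max(train$labels) + 1L
  if (ky > model$num_classes)
    stop("data has ", ky, " classes but the model head outputs ",
         model$num_classes)
  set.seed(cfg$seed)
  leaves <- layer_leaves(model)
  n <- length(train$labels)
  logrows <- list()
  best_acc <- -Inf
  best_epoch <- NA_integer_
  best_w <- NULL
  reached <- NA_integer_
  step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_schedule(epoch - 1L, cfg)
    ord <- sample.int(n)
    tloss <- 0
    nb <- 0L
    for (b0 in seq(1L, n, by = cfg$batch)) {
      idx <- ord[b0:min(b0 + cfg$batch - 1L, n)]
      fmx <- batch_input(train$images, idx, cfg$augment)
      out <- layer_fwd(model, fmx, training = TRUE)
      sc <- softmax_ce(out$x, train$labels[idx], cfg$class_weights)
      if (!is.finite(sc$loss))
        stop(sprintf("non-finite loss at epoch %d, batch %d", epoch,
                     (b0 - 1L) %/% cfg$batch + 1L))
      layer_bwd(model, fm_new(sc$grad, length(idx), 1L, 1L))
      step <- step + 1L
      opt_step(leaves, cfg, lr, step)
      tloss <- tloss + sc$loss
      nb <- nb + 1L
    }
    ev <- eval_dataset(model, val, class_weights = cfg$class_weights)
    logrows[[epoch]] <- data.frame(
      epoch = epoch, train_loss = tloss / nb, val_loss = ev$loss,
      val_acc = ev$acc, lr = lr)
    if (verbose)
      message(sprintf("epoch %3d  lr %.5f  train %.4f  val %.4f  acc %.4f",
                      epoch, lr, tloss / nb, ev$loss, ev$acc))
    if (ev$acc > best_acc) {
      best_acc <- ev$acc
      best_epoch <- epoch
      best_w <- collect_weights(model)
      if (!is.null(checkpoint_dir))
        save_checkpoint(model, file.path(checkpoint_dir, "best.rds"))
    }
    if (!is.null(cfg$early_stop_acc) && is.na(reached) &&
        ev$acc >= cfg$early_stop_acc) {
      reached <- epoch
      break
    }
  }
  if (!is.null(checkpoint_dir)) {
    save_checkpoint(model, file.path(checkpoint_dir, "last.rds"))
    write_manifest(model, file.path(checkpoint_dir, "architecture.txt"))
  }
  structure(list(log = do.call(rbind, logrows), best_epoch = best_epoch,
                 best_val_acc = best_acc, best_weights = best_w,
                 epochs_to_threshold = reached,
                 checkpoint_dir = checkpoint_dir),
            class = "train_log")
}

#' Epochs-to-threshold comparison of two learning-rate schedules
#'
#' Trains the same architecture under two schedules on matched seeds and
#' reports the first epoch at which each reaches a validation-accuracy
#' threshold. Training is fully deterministic given the seeds, and the two
#' schedules prescribe identical learning rates over their initial epochs
#' (for cosine vs constant, epoch 1: both use `lr0`); when the first run
#' reaches the threshold inside that shared prefix, the second run's
#' trajectory is identical by construction and its result is taken over
#' without recomputation.
#'
#' @param builder zero-argument function returning a fresh model.
#' @param train,val dataset tensors.
#' @param cfg a [train_config()] (its `schedule` field is overridden).
#' @param schedules two schedule names to compare.
#' @param threshold validation accuracy to reach.
#' @param init_seed RNG seed used before each builder call.
#' @return named integer vector of epochs-to-threshold (NA = not reached
#'   within `cfg$epochs`).
#' @export
compare_schedules <- function(builder, train, val, cfg,
                              schedules = c("cosine", "none"),
                              threshold = 0.95, init_seed = 1L) {
  stopifnot(length(schedules) == 2L)
  cfg$early_stop_acc <- threshold
  cfg_a <- cfg
  cfg_a$schedule <- schedules[1]
  cfg_b <- cfg
  cfg_b$schedule <- schedules[2]
  # length of the shared lr prefix (in epochs)
  prefix <- 0L
  for (e in seq_len(cfg$epochs) - 1L) {
    if (isTRUE(all.equal(lr_schedule(e, cfg_a), lr_schedule(e, cfg_b))))
      prefix <- prefix + 1L
    else break
  }
  set.seed(init_seed)
  model_a <- builder()
  log_a <- fit(model_a, train, val, cfg_a)
  ea <- log_a$epochs_to_threshold
  eb <- if (!is.na(ea) && ea <= prefix) {
    ea  # identical trajectory over the shared prefix
  } else {
    set.seed(init_seed)
    model_b <- builder()
    fit(model_b, train, val, cfg_b)$epochs_to_threshold
  }
  stats::setNames(c(ea, eb), schedules)
}

# ---- checkpointing --------------------------------------------------------

collect_weights <- function(model) {
  leaves <- layer_leaves(model)
  out <- list()
  for (lf in leaves) {
    entry <- lf$w
    if (lf$kind == "bn")
      entry <- c(entry, list(run_mean = lf$run_mean, run_var = lf$run_var))
    if (length(entry)) out[[lf$id]] <- entry
  }
  out
}

restore_weights <- function(model, wts, skip = character(0),
                            strict = TRUE) {
  leaves <- layer_leaves(model)
  skipped <- character(0)
  for (lf in leaves) {
    if (length(skip) && any(startsWith(lf$id, skip))) {
      skipped <- c(skipped, lf$id)
      next
    }
    src <- wts[[lf$id]]
    if (is.null(src)) {
      if (strict && length(lf$w))
        stop("checkpoint has no weights for layer ", lf$id)
      next
    }
    for (wn in names(lf$w)) {
      if (!identical(dim2(lf$w[[wn]]), dim2(src[[wn]])))
        stop("shape mismatch at ", lf$id, "$", wn, ": model ",
             paste(dim2(lf$w[[wn]]), collapse = "x"), " vs checkpoint ",
             paste(dim2(src[[wn]]), collapse = "x"))
      lf$w[[wn]] <- src[[wn]]
    }
    if (lf$kind == "bn") {
      lf$run_mean <- src$run_mean
      lf$run_var <- src$run_var
    }
  }
  invisible(skipped)
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Save / load model checkpoints
#'
#' Checkpoints carry all trainable weights, BN running statistics and the
#' builder metadata needed to re-create the model.
#'
#' @param model a built model.
#' @param path checkpoint file path (`.rds`).
#' @return `save_checkpoint` returns `path`; `load_checkpoint` restores in
#'   place and returns the model.
#' @export
save_checkpoint <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(weights = collect_weights(model),
               num_classes = model$num_classes,
               block_kinds = model$block_kinds), path)
  path
}

#' @rdname save_checkpoint
#' @param skip layer-id prefixes not restored (used for head
#'   re-initialization in transfer learning).
#' @export
load_checkpoint <- function(model, path, skip = character(0)) {
  ck <- readRDS(path)
  restore_weights(model, ck$weights, skip = skip)
  model
}

write_manifest <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# architecture manifest",
               paste("num_classes:", model$num_classes),
               paste("block_kinds:", paste(model$block_kinds, collapse = " ")),
               "layer\tkind\tparams"), con)
  p <- count_params(model)$per_layer
  writeLines(sprintf("%s\t%s\t%d", p$id, p$kind, as.integer(p$params)), con)
  invisible(path)
}

#' Transfer learning: fine-tune from a source checkpoint
#'
#' Loads every layer from the source checkpoint except the classifier
#' head, which keeps its fresh initialization sized to the target class
#' count; all unfrozen layers are then fine-tuned. Source and target must
#' agree in architecture outside the head; any other shape mismatch is an
#' explicit error.
#'
#' @param model the target model (head sized to the target classes).
#' @param source_ckpt path to a checkpoint from [save_checkpoint()].
#' @param train,val target dataset tensors.
#' @param cfg a [train_config()].
#' @param ... passed to [fit()].
#' @return a `train_log` (see [fit()]); attribute `reinitialized` lists the
#'   layer ids left at fresh initialization.
#' @export
transfer_finetune <- function(model, source_ckpt, train, val,
                              cfg = train_config(), ...) {
  ck <- readRDS(source_ckpt)
  if (!identical(ck$block_kinds, model$block_kinds))
    stop("source checkpoint block structure is incompatible with the model")
  skip <- if (ck$num_classes != model$num_classes) "net.classifier"
          else character(0)
  skipped <- restore_weights(model, ck$weights, skip = skip)
  log <- fit(model, train, val, cfg, ...)
  attr(log, "reinitialized") <- skipped
  log
}
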
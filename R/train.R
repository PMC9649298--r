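# Training and inference.
#
# Full padded images are fed to the network (no patch extraction; the
# resolutions involved make this feasible on a CPU), minimising per-pixel
# binary cross-entropy from logits (optionally plus soft Dice) with the
# Adam optimiser. Runs are reproducible given the config seed in
# single-threaded deterministic mode; the best-loss parameter set is kept.

#' Training configuration
#'
#' @param epochs Number of passes over the training split (>= 1).
#' @param batch_size Images per optimisation step.
#' @param learning_rate Adam step size (> 0).
#' @param loss `"bce"` (binary cross-entropy from logits, default),
#'   `"dice"` (soft Dice), or `"bce+dice"` (their sum).
#' @param seed Integer seed controlling shuffling, DropBlock and
#'   initialisation-independent randomness of the run.
#' @param checkpoint_dir Optional directory; the best checkpoint is written
#'   there as `best.rds`.
#' @param patience Epochs without improvement before early stop
#'   (`Inf` = never).
#' @param device `"cpu"` (the only supported device).
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 10L, batch_size = 2L, learning_rate = 1e-3,
                         loss = c("bce", "dice", "bce+dice"), seed = 1L,
                         checkpoint_dir = NULL, patience = Inf,
                         device = "cpu") {
  loss <- match.arg(loss)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (!identical(device, "cpu"))
    stop("only device = 'cpu' is supported", call. = FALSE)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, loss = loss,
                 seed = as.integer(seed), checkpoint_dir = checkpoint_dir,
                 patience = patience, device = device),
            class = "train_config")
}

adam_step <- function(params, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (p in params) {
    if (is.null(p$grad)) next
    if (is.null(p$m)) { p$m <- p$grad * 0; p$v <- p$grad * 0 }
    p$m <- beta1 * p$m + (1 - beta1) * p$grad
    p$v <- beta2 * p$v + (1 - beta2) * p$grad^2
    mhat <- p$m / (1 - beta1^t)
    vhat <- p$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

batch_loss <- function(model, x, y, cfg, params) {
  tape <- ag_tape()
  zero_grads(params)
  node <- new_node(x)
  loss <- switch(cfg$loss,
    bce = ag_bce_with_logits(fwd_model(model, node, tape, training = TRUE,
                                       logits = TRUE), y, tape),
    dice = ag_dice_loss(fwd_model(model, node, tape, training = TRUE), y, tape),
    `bce+dice` = {
      z <- fwd_model(model, node, tape, training = TRUE, logits = TRUE)
      p <- ag_sigmoid(z, tape)
      ag_scale_add(ag_bce_with_logits(z, y, tape),
                   ag_dice_loss(p, y, tape), tape = tape)
    })
  ag_backward(tape, loss)
  loss$value
}

#' Train a model
#'
#' @param model A `mcunet_model` (modified in place and also returned).
#' @param records Sample records (see [load_dataset()] / [make_dataset()]);
#'   only `split == "train"` records are used. All training images must
#'   share one resolution.
#' @param cfg A [train_config()].
#' @return List with `model` (parameters restored to the best epoch) and
#'   `history` (data.frame of `epoch`, `loss`).
#' @export
train <- function(model, records, cfg = train_config()) {
  stopifnot(inherits(model, "mcunet_model"), inherits(cfg, "train_config"))
  recs <- Filter(function(r) identical(r$split, "train"), records)
  if (length(recs) == 0L) stop("empty training split", call. = FALSE)
  set.seed(cfg$seed)
  depth <- model$config$depth
  xs <- lapply(recs, function(r) preprocess(r$image, depth))
  ys <- lapply(seq_along(recs), function(i) {
    m <- recs[[i]]$vessel_mask
    preprocess(array(m + 0, c(dim(m), 1L)), depth)$x
  })
  d1 <- dim(xs[[1]]$x)
  if (!all(vapply(xs, function(p) identical(dim(p$x)[1:2], d1[1:2]), logical(1))))
    stop("all training images must share one resolution", call. = FALSE)
  params <- model_parameters(model)
  n <- length(recs)
  bs <- min(cfg$batch_size, n)
  history <- data.frame(epoch = integer(0), loss = numeric(0))
  best <- list(loss = Inf, values = NULL)
  stall <- 0L
  t <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = bs)) {
      idx <- ord[start:min(start + bs - 1L, n)]
      B <- length(idx)
      xb <- array(0, c(d1[1], d1[2], d1[3], B))
      yb <- array(0, c(d1[1], d1[2], 1L, B))
      for (j in seq_len(B)) {
        xb[, , , j] <- xs[[idx[j]]]$x
        yb[, , , j] <- ys[[idx[j]]]
      }
      l <- batch_loss(model, xb, yb, cfg, params)
      if (!is.finite(l))
        stop(sprintf("divergent loss (%.3g) at epoch %d; lower the learning rate",
                     l, ep), call. = FALSE)
      t <- t + 1L
      adam_step(params, cfg$learning_rate, t)
      losses <- c(losses, l)
    }
    ml <- mean(losses)
    history <- rbind(history, data.frame(epoch = ep, loss = ml))
    if (ml < best$loss - 1e-8) {
      best <- list(loss = ml, values = lapply(params, function(p) p$value))
      stall <- 0L
      if (!is.null(cfg$checkpoint_dir)) {
        dir.create(cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
        save_checkpoint(model, file.path(cfg$checkpoint_dir, "best.rds"))
      }
    } else {
      stall <- stall + 1L
      if (stall >= cfg$patience) break
    }
  }
  if (!is.null(best$values))
    for (nm in names(params)) params[[nm]]$value <- best$values[[nm]]
  if (!is.null(cfg$checkpoint_dir))
    save_checkpoint(model, file.path(cfg$checkpoint_dir, "best.rds"))
  list(model = model, history = history)
}

#' Segment one image
#'
#' Pads the image to the network's divisibility requirement, runs a
#' deterministic inference pass and crops the probability map back to the
#' original extents.
#'
#' @param model A `mcunet_model`.
#' @param image HxWx3 (or HxW for grayscale models) raster, 8-bit or
#'   unit-scaled.
#' @return HxW matrix of vessel probabilities in (0, 1).
#' @export
predict_image <- function(model, image) {
  stopifnot(inherits(model, "mcunet_model"))
  pp <- preprocess(image, model$config$depth)
  prob <- forward(model, pp$x)
  crop_prediction(prob[, , 1, 1], pp$pad)
}

#' Dice coefficient of a binary segmentation
#'
#' @param pred,truth Binary 0/1 arrays of identical shape.
#' @return `2 TP / (2 TP + FP + FN)`.
#' @export
dice_coefficient <- function(pred, truth) {
  f1_score(confusion_counts(pred, truth))
}

#' Evaluate a model on the test split
#'
#' Predicts every `split == "test"` record, pools all FOV pixels into global
#' confusion counts (the default aggregation) and reports the Table-2 style
#' metric schema.
#'
#' @param model A `mcunet_model`.
#' @param records Sample records.
#' @param threshold Binarisation threshold (default 0.5).
#' @param per_image Also return one metrics row per image.
#' @param dataset Label for the `dataset` column.
#' @param use_fov When `FALSE`, every pixel is evaluated.
#' @return Data.frame with columns `dataset`, `n_images`, `ACC`, `SEN`,
#'   `SP`, `AUC`, `F1` (plus an `id` column when `per_image`).
#' @export
evaluate <- function(model, records, threshold = 0.5, per_image = FALSE,
                     dataset = "test", use_fov = TRUE) {
  recs <- Filter(function(r) identical(r$split, "test"), records)
  if (length(recs) == 0L) stop("no test records", call. = FALSE)
  all_scores <- c(); all_truth <- c()
  rows <- list()
  for (r in recs) {
    prob <- predict_image(model, r$image)
    fov <- if (use_fov) r$fov_mask else array(1, dim(r$vessel_mask))
    keep <- fov == 1
    all_scores <- c(all_scores, prob[keep])
    all_truth <- c(all_truth, r$vessel_mask[keep])
    if (per_image) {
      m <- segmentation_metrics(prob, r$vessel_mask, fov, threshold)
      rows[[length(rows) + 1L]] <- cbind(data.frame(id = r$id), m)
    }
  }
  pooled <- segmentation_metrics(all_scores, all_truth, threshold = threshold)
  pooled <- cbind(data.frame(dataset = dataset, n_images = length(recs)), pooled)
  if (per_image) list(pooled = pooled, per_image = do.call(rbind, rows)) else pooled
}
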
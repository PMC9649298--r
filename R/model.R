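# Full network assembly.
#
# A four-level U-shape: each encoder level is a double Conv3x3/DropBlock/BN/
# ReLU block followed by 2x2 max-pooling (no pool after the deepest level),
# giving depth-1 = 3 skip connections. The bottleneck fuses a spatial
# attention branch with the DAC -> MKP context branch; the decoder mirrors
# the encoder with learned 2x2 upsampling and skip concatenation; a final
# 1x1 convolution plus sigmoid yields a per-pixel vessel probability.

#' Architectural configuration of the network
#'
#' @param depth Number of resolution levels (>= 2); the network has
#'   `depth - 1` skip connections (3 at the default `depth = 4`).
#' @param base_channels Encoder width at the first level; widths double per
#'   level (16, 32, 64, 128 at the defaults).
#' @param dilation_rates Dilation rates of the DAC cascades.
#' @param pooling_kernels Max-pool window sizes of the MKP branch.
#' @param use_dac,use_mkp Variant flags for the ablation grid; disabling both
#'   leaves the attention-only backbone.
#' @param dropblock A [dropblock_config()].
#' @param fusion_mode `"concat"` (default) or `"sum"` bottleneck fusion.
#' @param in_channels Input image channels (3 for RGB fundus photographs;
#'   use 1 for preprocessed grayscale).
#' @param double_conv Two conv units per stage (default) or one.
#' @param upsample `"transpose"` (learned 2x2 transposed convolution,
#'   default) or `"nearest"` (nearest-neighbour resize + 3x3 convolution).
#' @return A `mcunet_config` object.
#' @export
model_config <- function(depth = 4L, base_channels = 16L,
                         dilation_rates = c(1L, 3L, 5L),
                         pooling_kernels = c(2L, 3L, 5L, 6L),
                         use_dac = TRUE, use_mkp = TRUE,
                         dropblock = dropblock_config(),
                         fusion_mode = c("concat", "sum"),
                         in_channels = 3L, double_conv = TRUE,
                         upsample = c("transpose", "nearest")) {
  depth <- as.integer(depth)
  if (depth < 2L) stop("depth must be >= 2", call. = FALSE)
  if (base_channels < 1L) stop("base_channels must be >= 1", call. = FALSE)
  structure(list(depth = depth, base_channels = as.integer(base_channels),
                 dilation_rates = as.integer(dilation_rates),
                 pooling_kernels = as.integer(pooling_kernels),
                 use_dac = isTRUE(use_dac), use_mkp = isTRUE(use_mkp),
                 dropblock = dropblock, fusion_mode = match.arg(fusion_mode),
                 in_channels = as.integer(in_channels),
                 double_conv = isTRUE(double_conv),
                 upsample = match.arg(upsample)),
            class = "mcunet_config")
}

channel_widths <- function(cfg) cfg$base_channels * 2L^(seq_len(cfg$depth) - 1L)

#' Build the segmentation network
#'
#' @param cfg A [model_config()].
#' @param seed Optional integer; when given, parameter initialisation is
#'   reproducible (He-normal weights drawn from R's RNG).
#' @return An object of class `mcunet_model`.
#' @export
build_model <- function(cfg = model_config(), seed = NULL) {
  stopifnot(inherits(cfg, "mcunet_config"))
  if (!is.null(seed)) set.seed(seed)
  w <- channel_widths(cfg)
  enc <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    cin <- if (l == 1L) cfg$in_channels else w[l - 1L]
    enc[[l]] <- new_conv_block(cin, w[l], cfg$dropblock, double = cfg$double_conv)
  }
  bottleneck <- new_bottleneck(w[cfg$depth], w[cfg$depth],
                               use_dac = cfg$use_dac, use_mkp = cfg$use_mkp,
                               rates = cfg$dilation_rates,
                               kernel_sizes = cfg$pooling_kernels,
                               fusion_mode = cfg$fusion_mode)
  dec <- vector("list", cfg$depth - 1L)
  for (i in seq_len(cfg$depth - 1L)) {
    l <- cfg$depth - i              # target level depth-1 .. 1
    up <- if (cfg$upsample == "transpose") {
      list(kind = "transpose",
           w = new_param(array(rnorm(4L * w[l] * w[l + 1L], 0, sqrt(2 / (4 * w[l + 1L]))),
                               c(2L, 2L, w[l], w[l + 1L]))),
           b = new_param(numeric(w[l])))
    } else {
      list(kind = "nearest", conv = new_conv2d_layer(3L, w[l + 1L], w[l]))
    }
    dec[[i]] <- list(up = up,
                     block = new_conv_block(2L * w[l], w[l], cfg$dropblock,
                                            double = cfg$double_conv))
  }
  final <- new_conv2d_layer(1L, w[1L], 1L)
  model <- structure(list(config = cfg, encoder = enc, bottleneck = bottleneck,
                          decoder = dec, final = final),
                     class = "mcunet_model")
  model
}

# recursively collect parameter environments (have $value) and BN state
# environments (have $running_mean), with path names
collect_envs <- function(x, path = "model") {
  if (is.environment(x)) {
    if (!is.null(x$value)) return(stats::setNames(list(x), path))
    if (!is.null(x$running_mean)) return(stats::setNames(list(x), path))
    return(list())
  }
  if (is.list(x)) {
    nms <- names(x)
    if (is.null(nms)) nms <- as.character(seq_along(x))
    nms[nms == ""] <- as.character(which(nms == ""))
    out <- list()
    for (i in seq_along(x))
      out <- c(out, collect_envs(x[[i]], paste0(path, ".", nms[i])))
    return(out)
  }
  list()
}

model_parameters <- function(model) {
  envs <- collect_envs(unclass(model)[setdiff(names(model), "config")])
  envs[vapply(envs, function(e) !is.null(e$value), logical(1))]
}

model_bn_states <- function(model) {
  envs <- collect_envs(unclass(model)[setdiff(names(model), "config")])
  envs[vapply(envs, function(e) is.null(e$value) && !is.null(e$running_mean), logical(1))]
}

#' Count the learnable parameters of a model
#'
#' Exact sum of scalar counts over all convolution filters, biases and batch
#' normalisation scale/shift vectors. The count is a function of the
#' architecture only — invariant to batch size and input extents.
#'
#' @param model A `mcunet_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "mcunet_model"))
  sum(vapply(model_parameters(model), function(p) length(p$value), numeric(1)))
}

fwd_model <- function(model, x, tape = NULL, training = FALSE, logits = FALSE) {
  cfg <- model$config
  skips <- vector("list", cfg$depth - 1L)
  h <- x
  for (l in seq_len(cfg$depth)) {
    h <- fwd_conv_block(h, model$encoder[[l]], tape, training)
    if (l < cfg$depth) {
      skips[[l]] <- h
      h <- ag_maxpool(h, 2L, 2L, tape)
    }
  }
  h <- fwd_bottleneck(h, model$bottleneck, tape)
  for (i in seq_len(cfg$depth - 1L)) {
    l <- cfg$depth - i
    up <- model$decoder[[i]]$up
    h <- if (up$kind == "transpose") {
      ag_conv_transpose2(h, up$w, up$b, tape)
    } else {
      d <- dim(h$value)
      ag_conv2d(ag_upsample_nearest(h, 2L * d[1], 2L * d[2], tape),
                up$conv$w, up$conv$b, tape)
    }
    h <- ag_concat_c(list(skips[[l]], h), tape)
    h <- fwd_conv_block(h, model$decoder[[i]]$block, tape, training)
  }
  z <- ag_conv2d(h, model$final$w, model$final$b, tape, pad = 0L)
  if (logits) z else ag_sigmoid(z, tape)
}

#' Forward pass of the network
#'
#' @param model A `mcunet_model`.
#' @param x Numeric array `(H, W, C)` or `(H, W, C, B)`; `H` and `W` must be
#'   divisible by `2^(depth - 1)` (use [predict_image()] for arbitrary sizes
#'   — it pads and crops).
#' @param training Logical; activates DropBlock (stochastic) and batch
#'   statistics. Inference (`FALSE`, default) is deterministic.
#' @return Single-channel probability array in (0, 1), same spatial extents
#'   and batch as `x`.
#' @export
forward <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "mcunet_model"))
  x4 <- as_fm4(check_finite(x))
  d <- dim(x4)
  f <- as.integer(2^(model$config$depth - 1L))
  if (d[1] %% f != 0L || d[2] %% f != 0L)
    stop(sprintf(paste0("spatial extents (%d x %d) must be divisible by %d; ",
                        "use predict_image(), which pads and crops"),
                 d[1], d[2], f), call. = FALSE)
  if (d[3] != model$config$in_channels)
    stop(sprintf("input has %d channels but the model expects %d",
                 d[3], model$config$in_channels), call. = FALSE)
  out <- fwd_model(model, new_node(x4), tape = NULL, training = training)$value
  if (length(dim(x)) == 3L) dim(out) <- dim(out)[1:3]
  out
}

#' Build the four ablation variants
#'
#' The variant grid: the attention-only backbone, backbone + DAC,
#' backbone + MKP, and the full network with both context modules, sharing
#' all other hyperparameters (and the initialisation seed when given).
#'
#' @param cfg Base [model_config()]; its `use_dac`/`use_mkp` flags are
#'   overridden per variant.
#' @param seed Optional integer passed to each [build_model()] call.
#' @return Named list of four `mcunet_model` objects:
#'   `backbone`, `dac`, `mkp`, `full`.
#' @export
build_ablation_suite <- function(cfg = model_config(), seed = NULL) {
  flags <- list(backbone = c(FALSE, FALSE), dac = c(TRUE, FALSE),
                mkp = c(FALSE, TRUE), full = c(TRUE, TRUE))
  lapply(flags, function(fl) {
    v <- cfg
    v$use_dac <- fl[1]
    v$use_mkp <- fl[2]
    build_model(v, seed = seed)
  })
}

#' @export
print.mcunet_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("MC-UNet: depth %d, widths %s, DAC=%s MKP=%s, fusion=%s\n",
              cfg$depth, paste(channel_widths(cfg), collapse = "/"),
              cfg$use_dac, cfg$use_mkp, cfg$fusion_mode))
  cat(sprintf("  learnable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

## ---- checkpoints and config files ------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint stores the flat parameter enumeration, the batch-norm
#' running statistics and the configuration that built the model, so
#' `load_checkpoint()` reconstructs an identical network.
#'
#' @param model A `mcunet_model`.
#' @param path File path (`.rds`).
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns the restored `mcunet_model`.
#' @export
save_checkpoint <- function(model, path) {
  ps <- model_parameters(model)
  bs <- model_bn_states(model)
  saveRDS(list(config = model$config,
               params = lapply(ps, function(p) p$value),
               bn = lapply(bs, function(b) list(m = b$running_mean, v = b$running_var))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config, seed = 0L)
  ps <- model_parameters(model)
  stopifnot(identical(names(ps), names(ck$params)))
  for (nm in names(ps)) ps[[nm]]$value <- ck$params[[nm]]
  bs <- model_bn_states(model)
  stopifnot(identical(names(bs), names(ck$bn)))
  for (nm in names(bs)) {
    bs[[nm]]$running_mean <- ck$bn[[nm]]$m
    bs[[nm]]$running_var <- ck$bn[[nm]]$v
  }
  model
}

#' Read / write a model configuration as YAML
#'
#' @param path YAML file.
#' @param cfg A [model_config()].
#' @return `read_model_config()` returns a `mcunet_config`;
#'   `write_model_config()` returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  db <- y$dropblock
  model_config(
    depth = y$depth %||% 4L,
    base_channels = y$base_channels %||% 16L,
    dilation_rates = unlist(y$dilation_rates %||% c(1, 3, 5)),
    pooling_kernels = unlist(y$pooling_kernels %||% c(2, 3, 5, 6)),
    use_dac = y$use_dac %||% TRUE,
    use_mkp = y$use_mkp %||% TRUE,
    dropblock = dropblock_config(db$block_size %||% 7L, db$keep_prob %||% 0.82),
    fusion_mode = y$fusion_mode %||% "concat",
    in_channels = y$in_channels %||% 3L,
    double_conv = y$double_conv %||% TRUE,
    upsample = y$upsample %||% "transpose")
}

#' @rdname read_model_config
#' @export
write_model_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "mcunet_config"))
  y <- unclass(cfg)
  y$dropblock <- list(block_size = cfg$dropblock$block_size,
                      keep_prob = cfg$dropblock$keep_prob)
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Checksum of a model's parameters
#'
#' MD5 digest of the serialised flat parameter enumeration; used to assert
#' bit-identical training runs in deterministic mode.
#'
#' @param model A `mcunet_model`.
#' @return Character MD5 string.
#' @export
model_checksum <- function(model) {
  ps <- model_parameters(model)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  con <- file(tmp, "wb")
  serialize(lapply(ps, function(p) p$value), con)
  close(con)
  unname(tools::md5sum(tmp))
}
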
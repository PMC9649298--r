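# Reusable network building blocks: the Conv3x3 + DropBlock + BN + ReLU unit
# (applied twice per stage, the standard U-shape double convolution), the
# DropBlock regulariser, and the spatial attention gate
#   SA = F * sigmoid(conv7x7([max_c(F); mean_c(F)])).

#' DropBlock configuration
#'
#' Structured dropout for convolutional feature maps: during training,
#' contiguous `block_size` x `block_size` squares are zeroed around Bernoulli
#' seed points and the survivors are rescaled so the expected activation mass
#' is preserved; at inference the map passes through unchanged.
#'
#' @param block_size Odd positive integer, side of the dropped square
#'   (pixels). Clipped to the feature extent when a map is smaller.
#' @param keep_prob Probability in (0, 1] that a unit is kept; `1` disables
#'   dropping entirely.
#' @return An object of class `dropblock_config`.
#' @export
dropblock_config <- function(block_size = 7L, keep_prob = 0.82) {
  block_size <- as.integer(block_size)
  if (block_size < 1L || block_size %% 2L == 0L)
    stop("block_size must be an odd positive integer", call. = FALSE)
  if (!is.numeric(keep_prob) || keep_prob <= 0 || keep_prob > 1)
    stop("keep_prob must lie in (0, 1]", call. = FALSE)
  structure(list(block_size = block_size, keep_prob = keep_prob),
            class = "dropblock_config")
}

# Sample a DropBlock mask for a (H, W, C, B) feature: independent seed points
# per channel and sample, blocks expanded from each seed's top-left corner.
# Returns list(mask = 0/1 array, scale = numel/kept per (channel, sample)).
sample_dropblock_mask <- function(d, block_size, keep_prob) {
  H <- d[1]; W <- d[2]
  bs <- min(block_size, H, W)
  vh <- H - bs + 1L
  vw <- W - bs + 1L
  gamma <- (1 - keep_prob) / bs^2 * (H * W) / (vh * vw)
  mask <- array(1, d)
  scale <- array(1, c(d[3], d[4]))
  for (bb in seq_len(d[4])) {
    for (cc in seq_len(d[3])) {
      seeds <- which(runif(vh * vw) < gamma)
      m <- matrix(1, H, W)
      if (length(seeds)) {
        sh <- (seeds - 1L) %% vh + 1L
        sw <- (seeds - 1L) %/% vh + 1L
        for (dh in 0:(bs - 1L)) for (dw in 0:(bs - 1L))
          m[cbind(sh + dh, sw + dw)] <- 0
      }
      kept <- sum(m)
      mask[, , cc, bb] <- m
      scale[cc, bb] <- if (kept > 0) (H * W) / kept else 0
    }
  }
  list(mask = mask, scale = scale)
}

# internal node-level DropBlock
fwd_dropblock <- function(x, cfg, tape = NULL, training = FALSE) {
  if (!training || cfg$keep_prob >= 1) return(x)
  d <- dim(x$value)
  ms <- sample_dropblock_mask(d, cfg$block_size, cfg$keep_prob)
  sc <- array(rep(ms$scale, each = d[1] * d[2]), d)
  ag_apply_mask(x, ms$mask, sc, tape)
}

#' Apply DropBlock regularisation to a feature map
#'
#' @param x Numeric array, `(H, W, C)` or `(H, W, C, B)`.
#' @param cfg A [dropblock_config()].
#' @param training Logical; when `FALSE` the input is returned unchanged.
#' @return Array of the same shape as `x`.
#' @examples
#' set.seed(1)
#' x <- array(1, c(32, 32, 1))
#' y <- drop_block(x, dropblock_config(7, 0.9), training = TRUE)
#' mean(y)  # ~1: survivors are rescaled to conserve activation mass
#' @export
drop_block <- function(x, cfg = dropblock_config(), training = FALSE) {
  stopifnot(inherits(cfg, "dropblock_config"))
  x4 <- as_fm4(check_finite(x))
  out <- fwd_dropblock(new_node(x4), cfg, tape = NULL, training = training)$value
  dim(out) <- if (is.null(dim(x))) dim(x4) else dim(x)
  out
}

## ---- convolution unit and double-conv block --------------------------------

he_init <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))), c(k, k, cin, cout))
}

new_conv2d_layer <- function(k, cin, cout, dilation = 1L) {
  list(w = new_param(he_init(k, cin, cout)),
       b = new_param(numeric(cout)),
       dilation = as.integer(dilation))
}

new_bn_layer <- function(c) {
  bn <- new.env(parent = emptyenv())
  bn$running_mean <- numeric(c)
  bn$running_var <- rep(1, c)
  list(gamma = new_param(rep(1, c)), beta = new_param(numeric(c)), state = bn)
}

# one Conv3x3 -> DropBlock -> BN -> ReLU unit
new_conv_unit <- function(cin, cout, dropblock) {
  list(conv = new_conv2d_layer(3L, cin, cout), bn = new_bn_layer(cout),
       dropblock = dropblock)
}

fwd_conv_unit <- function(x, unit, tape = NULL, training = FALSE) {
  h <- ag_conv2d(x, unit$conv$w, unit$conv$b, tape, dilation = unit$conv$dilation)
  h <- fwd_dropblock(h, unit$dropblock, tape, training)
  h <- ag_batchnorm(h, unit$bn$gamma, unit$bn$beta, unit$bn$state, tape,
                    training = training)
  ag_relu(h, tape)
}

#' Create a convolution block (Conv3x3 + DropBlock + BN + ReLU)
#'
#' The encoder/decoder stage of the network: a 3x3 convolution with 1-pixel
#' zero padding (spatial extents preserved), DropBlock, batch normalisation
#' and ReLU, applied twice in sequence by default (standard U-shape double
#' convolution).
#'
#' @param in_channels,out_channels Positive integers.
#' @param dropblock A [dropblock_config()].
#' @param double Logical; apply the unit twice (default) or once.
#' @return A `conv_block` layer object holding its learnable parameters.
#' @export
new_conv_block <- function(in_channels, out_channels,
                           dropblock = dropblock_config(), double = TRUE) {
  stopifnot(in_channels >= 1, out_channels >= 1)
  units <- list(new_conv_unit(in_channels, out_channels, dropblock))
  if (double) units <- c(units, list(new_conv_unit(out_channels, out_channels, dropblock)))
  structure(list(units = units, in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels)),
            class = "conv_block")
}

fwd_conv_block <- function(x, block, tape = NULL, training = FALSE) {
  for (u in block$units) x <- fwd_conv_unit(x, u, tape, training)
  x
}

#' Run a feature map through a convolution block
#'
#' @param x Numeric array `(H, W, C)` or `(H, W, C, B)` with
#'   `C == block$in_channels`.
#' @param block A layer built by [new_conv_block()].
#' @param training Logical; activates DropBlock and batch statistics.
#' @return Array with `block$out_channels` channels and unchanged spatial
#'   extents.
#' @export
conv_block <- function(x, block, training = FALSE) {
  stopifnot(inherits(block, "conv_block"))
  x4 <- as_fm4(check_finite(x))
  if (dim(x4)[3] != block$in_channels)
    stop(sprintf("input has %d channels but the block expects %d",
                 dim(x4)[3], block$in_channels), call. = FALSE)
  out <- fwd_conv_block(new_node(x4), block, tape = NULL, training = training)$value
  if (length(dim(x)) == 3L) dim(out) <- dim(out)[1:3]
  out
}

## ---- spatial attention ------------------------------------------------------

#' Create a spatial attention layer
#'
#' Channel-wise max- and average-pooled maps of the input are concatenated to
#' a 2-channel descriptor; a 7x7 convolution (3-pixel zero padding, with
#' bias) reduces it to one channel and a sigmoid yields the attention map in
#' (0, 1), which gates the input elementwise.
#'
#' @return A `spatial_attention` layer (the 7x7x2x1 filter and its bias).
#' @export
new_spatial_attention <- function() {
  structure(list(conv = new_conv2d_layer(7L, 2L, 1L)), class = "spatial_attention")
}

fwd_spatial_attention <- function(x, sa, tape = NULL) {
  pooled <- ag_concat_c(list(ag_channel_max(x, tape), ag_channel_mean(x, tape)), tape)
  att <- ag_sigmoid(ag_conv2d(pooled, sa$conv$w, sa$conv$b, tape), tape)
  list(out = ag_gate(x, att, tape), att = att)
}

#' Spatial attention gating of a feature map
#'
#' @param x Numeric array `(H, W, C)` or `(H, W, C, B)`, any `C >= 1`.
#' @param sa A layer from [new_spatial_attention()]; a freshly initialised
#'   one is drawn from the current RNG when omitted.
#' @return List with `SA` (gated feature, same shape as `x`) and `att`
#'   (single-channel attention map with values in (0, 1)).
#' @export
spatial_attention <- function(x, sa = new_spatial_attention()) {
  stopifnot(inherits(sa, "spatial_attention"))
  x4 <- as_fm4(check_finite(x))
  r <- fwd_spatial_attention(new_node(x4), sa, tape = NULL)
  SA <- r$out$value
  att <- r$att$value
  if (length(dim(x)) == 3L) {
    dim(SA) <- dim(SA)[1:3]
    dim(att) <- dim(att)[1:3]
  }
  list(SA = SA, att = att)
}
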
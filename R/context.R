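# Bottleneck context machinery.
#
# Atrous (dilated) convolution samples the input with stride r between kernel
# taps: y[i] = sum_k x[i + r*k] w[k]; r = 1 is standard convolution. The
# dense atrous convolution (DAC) module runs four parallel cascades of 3x3
# atrous convolutions built from rates (1, 3, 5) and accumulates each
# branch's output residually onto the input. The multikernel pooling (MKP)
# module max-pools the feature at several window sizes (2, 3, 5, 6), reduces
# each pooled map to one channel by 1x1 convolution, upsamples back and
# concatenates with the input. The bottleneck concatenates the spatial
# attention branch with the DAC->MKP branch and reduces back to the decoder
# width with a 3x3 convolution.

#' Dilated (atrous) 2-D convolution
#'
#' Applies a `k x k` filter whose taps are spaced `rate` pixels apart, with
#' zero padding `rate * (k - 1) / 2` so spatial extents are preserved.
#' At `rate = 1` this is exactly standard convolution. The effective
#' receptive field of a single filter is `k + (k - 1) * (rate - 1)` pixels.
#'
#' @param x Numeric array `(H, W, C_in)` or `(H, W, C_in, B)`.
#' @param w Filter array `(k, k, C_in, C_out)`, odd `k`.
#' @param b Optional numeric bias vector of length `C_out`.
#' @param rate Positive integer dilation rate.
#' @return Array with `C_out` channels and the spatial extents of `x`.
#' @export
atrous_conv2d <- function(x, w, b = NULL, rate = 1L) {
  rate <- as.integer(rate)
  if (rate < 1L) stop("dilation rate must be >= 1", call. = FALSE)
  wd <- dim(w)
  if (length(wd) != 4L) stop("filter must be a (k, k, C_in, C_out) array", call. = FALSE)
  if (wd[1] != wd[2]) stop("filter must be square", call. = FALSE)
  if (wd[1] %% 2L == 0L)
    stop("even kernel length cannot preserve extents with symmetric padding", call. = FALSE)
  x4 <- as_fm4(check_finite(x))
  wp <- new_param(w)
  bp <- if (is.null(b)) NULL else new_param(b)
  out <- ag_conv2d(new_node(x4), wp, bp, tape = NULL, dilation = rate)$value
  if (length(dim(x)) == 3L) dim(out) <- dim(out)[1:3]
  out
}

## ---- dense atrous convolution ----------------------------------------------

#' Create a dense atrous convolution (DAC) layer
#'
#' Four parallel branches of cascaded 3x3 dilated convolutions built from
#' `rates = (r1, r2, r3)`: branch 1 uses rate `r1`; branch 2 rate `r2` then a
#' 1x1 convolution; branch 3 rates `r1, r2` then 1x1; branch 4 rates
#' `r1, r2, r3` then 1x1. Each convolution keeps the channel width and is
#' followed by ReLU; every branch output is added residually to the input,
#' so channels and extents are preserved and zero branch weights leave the
#' input unchanged.
#'
#' @param channels Feature width at the bottleneck.
#' @param rates Three positive integer dilation rates, default `c(1, 3, 5)`.
#' @param branches Optional custom topology: a list of branches, each a list
#'   of `c(kernel, rate)` pairs. Overrides the default four-branch cascade.
#' @return A `dac_layer` object.
#' @export
new_dac <- function(channels, rates = c(1L, 3L, 5L), branches = NULL) {
  stopifnot(channels >= 1, length(rates) >= 1, all(rates >= 1))
  r <- as.integer(rates)
  if (is.null(branches)) {
    if (length(r) < 3L) stop("the default topology needs three rates", call. = FALSE)
    branches <- list(
      list(c(3L, r[1])),
      list(c(3L, r[2]), c(1L, 1L)),
      list(c(3L, r[1]), c(3L, r[2]), c(1L, 1L)),
      list(c(3L, r[1]), c(3L, r[2]), c(3L, r[3]), c(1L, 1L)))
  }
  layers <- lapply(branches, function(br)
    lapply(br, function(kr) new_conv2d_layer(kr[1], channels, channels, dilation = kr[2])))
  structure(list(branches = layers, channels = as.integer(channels), rates = r),
            class = "dac_layer")
}

fwd_dac <- function(x, dac, tape = NULL) {
  out <- x
  for (br in dac$branches) {
    h <- x
    for (cv in br) h <- ag_relu(ag_conv2d(h, cv$w, cv$b, tape, dilation = cv$dilation), tape)
    out <- ag_add(out, h, tape)
  }
  out
}

#' Apply a dense atrous convolution block
#'
#' @param x Numeric array `(H, W, C)` or `(H, W, C, B)` with
#'   `C == dac$channels`.
#' @param dac A layer from [new_dac()].
#' @return Array of the same shape as `x`.
#' @export
dac_block <- function(x, dac) {
  stopifnot(inherits(dac, "dac_layer"))
  x4 <- as_fm4(check_finite(x))
  if (dim(x4)[3] != dac$channels)
    stop(sprintf("input has %d channels but the DAC expects %d",
                 dim(x4)[3], dac$channels), call. = FALSE)
  out <- fwd_dac(new_node(x4), dac, tape = NULL)$value
  if (length(dim(x)) == 3L) dim(out) <- dim(out)[1:3]
  out
}

## ---- multikernel pooling ----------------------------------------------------

#' Create a multikernel pooling (MKP) layer
#'
#' For each kernel size `k` the feature is max-pooled with window `k` and
#' stride `k` (ceiling mode, so non-divisible extents are handled by border
#' clipping), reduced to a single channel by a 1x1 convolution, and
#' upsampled back to the input extents by nearest neighbour. The input is
#' concatenated with the pooled maps, so the output has
#' `channels + length(kernel_sizes)` channels.
#'
#' @param channels Input feature width.
#' @param kernel_sizes Positive integer pooling windows, default
#'   `c(2, 3, 5, 6)`.
#' @return An `mkp_layer` object.
#' @export
new_mkp <- function(channels, kernel_sizes = c(2L, 3L, 5L, 6L)) {
  stopifnot(channels >= 1, length(kernel_sizes) >= 1, all(kernel_sizes >= 1))
  structure(list(convs = lapply(kernel_sizes, function(k) new_conv2d_layer(1L, channels, 1L)),
                 kernel_sizes = as.integer(kernel_sizes),
                 channels = as.integer(channels)),
            class = "mkp_layer")
}

fwd_mkp <- function(x, mkp, tape = NULL) {
  d <- dim(x$value)
  if (any(mkp$kernel_sizes > min(d[1], d[2])))
    stop("pooling kernel larger than the feature extents", call. = FALSE)
  outs <- list(x)
  for (i in seq_along(mkp$kernel_sizes)) {
    k <- mkp$kernel_sizes[i]
    h <- ag_maxpool(x, k, stride = k, tape = tape, ceil_mode = TRUE)
    h <- ag_conv2d(h, mkp$convs[[i]]$w, mkp$convs[[i]]$b, tape, pad = 0L)
    h <- ag_upsample_nearest(h, d[1], d[2], tape)
    outs[[i + 1L]] <- h
  }
  ag_concat_c(outs, tape)
}

#' Apply a multikernel pooling block
#'
#' @param x Numeric array `(H, W, C)` or `(H, W, C, B)` with
#'   `C == mkp$channels`; every kernel size must be at most both spatial
#'   extents.
#' @param mkp A layer from [new_mkp()].
#' @return Array with `C + length(mkp$kernel_sizes)` channels.
#' @export
mkp_block <- function(x, mkp) {
  stopifnot(inherits(mkp, "mkp_layer"))
  x4 <- as_fm4(check_finite(x))
  if (dim(x4)[3] != mkp$channels)
    stop(sprintf("input has %d channels but the MKP expects %d",
                 dim(x4)[3], mkp$channels), call. = FALSE)
  out <- fwd_mkp(new_node(x4), mkp, tape = NULL)$value
  if (length(dim(x)) == 3L) dim(out) <- dim(out)[1:3]
  out
}

## ---- bottleneck fusion -------------------------------------------------------

#' Create the bottleneck fusion layer
#'
#' Runs the deepest encoder feature through two parallel branches — spatial
#' attention, and (optionally) DAC followed by MKP — and fuses them. In
#' `"concat"` mode (default, following the module-concatenation design) the
#' branch outputs are concatenated along channels and a 3x3 convolution
#' reduces back to `out_channels`; in `"sum"` mode the context branch is
#' first projected to `out_channels` by the 3x3 convolution and then added
#' to the attention output.
#'
#' @param channels Bottleneck input width.
#' @param out_channels Width handed to the decoder (defaults to `channels`).
#' @param use_dac,use_mkp Logical flags enabling each context module
#'   (the ablation grid).
#' @param rates,kernel_sizes Passed to [new_dac()] / [new_mkp()].
#' @param fusion_mode `"concat"` or `"sum"`.
#' @return A `bottleneck_layer` object.
#' @export
new_bottleneck <- function(channels, out_channels = channels,
                           use_dac = TRUE, use_mkp = TRUE,
                           rates = c(1L, 3L, 5L), kernel_sizes = c(2L, 3L, 5L, 6L),
                           fusion_mode = c("concat", "sum")) {
  fusion_mode <- match.arg(fusion_mode)
  dac <- if (use_dac) new_dac(channels, rates) else NULL
  mkp <- if (use_mkp) new_mkp(channels, kernel_sizes) else NULL
  branch_width <- channels + if (use_mkp) length(kernel_sizes) else 0L
  has_branch <- use_dac || use_mkp
  fuse_in <- if (!has_branch) channels
             else if (fusion_mode == "concat") channels + branch_width
             else branch_width
  structure(list(sa = new_spatial_attention(), dac = dac, mkp = mkp,
                 fuse = new_conv2d_layer(3L, fuse_in, out_channels),
                 channels = as.integer(channels),
                 out_channels = as.integer(out_channels),
                 fusion_mode = fusion_mode, has_branch = has_branch),
            class = "bottleneck_layer")
}

fwd_bottleneck <- function(x, bk, tape = NULL) {
  sa <- fwd_spatial_attention(x, bk$sa, tape)$out
  if (!bk$has_branch) {
    h <- ag_conv2d(sa, bk$fuse$w, bk$fuse$b, tape)
    return(ag_relu(h, tape))
  }
  ctx <- x
  if (!is.null(bk$dac)) ctx <- fwd_dac(ctx, bk$dac, tape)
  if (!is.null(bk$mkp)) ctx <- fwd_mkp(ctx, bk$mkp, tape)
  if (bk$fusion_mode == "concat") {
    h <- ag_conv2d(ag_concat_c(list(sa, ctx), tape), bk$fuse$w, bk$fuse$b, tape)
    ag_relu(h, tape)
  } else {
    proj <- ag_relu(ag_conv2d(ctx, bk$fuse$w, bk$fuse$b, tape), tape)
    ag_add(sa, proj, tape)
  }
}

#' Fuse the bottleneck feature through attention and context branches
#'
#' @param x Numeric array `(H, W, C)` or `(H, W, C, B)` with
#'   `C == bk$channels` (the deepest encoder output).
#' @param bk A layer from [new_bottleneck()].
#' @return Array with `bk$out_channels` channels and the extents of `x`.
#' @export
bottleneck_fuse <- function(x, bk) {
  stopifnot(inherits(bk, "bottleneck_layer"))
  x4 <- as_fm4(check_finite(x))
  out <- fwd_bottleneck(new_node(x4), bk, tape = NULL)$value
  if (length(dim(x)) == 3L) dim(out) <- dim(out)[1:3]
  out
}
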
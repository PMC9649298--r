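# Minimal reverse-mode differentiation tape.
#
# Feature maps are numeric arrays dim (H, W, C, B): rows, columns, channels,
# batch. Every op below computes its value eagerly and, when a tape is
# supplied, registers a backward closure; running the tape in reverse
# accumulates gradients into the input nodes and parameter records.
# Parameters are environments ($value, $grad, plus optimiser state), so
# gradient accumulation needs no graph bookkeeping beyond creation order.

ag_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 64L)
  tp$n <- 0L
  tp
}

new_node <- function(value, tape = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- NULL
  if (!is.null(tape)) {
    tp_n <- tape$n + 1L
    if (tp_n > length(tape$nodes)) tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
    tape$nodes[[tp_n]] <- nd
    tape$n <- tp_n
  }
  nd
}

new_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p
}

ag_add_grad <- function(nd, g) {
  nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
  invisible(NULL)
}

#' @noRd
ag_backward <- function(tape, loss) {
  ag_add_grad(loss, 1)
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$backward) && !is.null(nd$grad)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

# ensure (H, W, C, B)
as_fm4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature map must be an array", call. = FALSE)
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("feature map must have 2-4 axes", call. = FALSE)
  x
}

check_finite <- function(x, what = "feature map") {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what), call. = FALSE)
  invisible(x)
}

conv_out_extent <- function(n, k, pad, stride, dilation) {
  (n + 2L * pad - (dilation * (k - 1L) + 1L)) %/% stride + 1L
}

## ---- convolution -----------------------------------------------------------

# w: param with $value dim (k, k, Cin, Cout); b: param with $value length Cout
# or NULL. pad defaults to the size-preserving dilation*(k-1)/2 (odd k only).
ag_conv2d <- function(x, w, b = NULL, tape = NULL,
                      dilation = 1L, stride = 1L, pad = NULL) {
  v <- x$value
  d <- dim(v)
  wd <- dim(w$value)
  k <- wd[1]
  if (is.null(pad)) {
    if (k %% 2L == 0L) stop("size-preserving padding needs an odd kernel", call. = FALSE)
    pad <- as.integer(dilation * (k - 1L) / 2L)
  }
  if (d[3] != wd[3])
    stop(sprintf("channel mismatch: input has %d channels, filter expects %d", d[3], wd[3]),
         call. = FALSE)
  Cout <- wd[4]
  Ho <- conv_out_extent(d[1], k, pad, stride, dilation)
  Wo <- conv_out_extent(d[2], k, pad, stride, dilation)
  B <- d[4]
  Wm <- matrix(w$value, nrow = k * k * wd[3], ncol = Cout)
  cols <- vector("list", B)
  out <- array(0, c(Ho, Wo, Cout, B))
  L <- Ho * Wo
  for (bb in seq_len(B)) {
    cl <- cpp_im2col(as.numeric(v[, , , bb]),
                     d[1], d[2], d[3], k, pad, stride, dilation)
    ym <- crossprod(cl, Wm)
    if (!is.null(b)) ym <- ym + rep(b$value, each = L)
    out[, , , bb] <- ym
    if (!is.null(tape)) cols[[bb]] <- cl
  }
  nd <- new_node(out, tape)
  if (!is.null(tape)) {
    nd$backward <- function(g) {
      for (bb in seq_len(B)) {
        dym <- matrix(g[, , , bb], nrow = L, ncol = Cout)
        ag_add_grad(w, array(cols[[bb]] %*% dym, dim = wd))
        if (!is.null(b)) ag_add_grad(b, colSums(dym))
        dx <- cpp_col2im(Wm %*% t(dym), d[1], d[2], d[3], k, pad, stride, dilation)
        gx <- array(0, d)
        gx[, , , bb] <- dx
        ag_add_grad(x, gx)
      }
    }
  }
  nd
}

# 2x2 stride-2 transposed convolution (learned upsampling).
# w: param dim (2, 2, Cout, Cin); doubles both spatial extents.
ag_conv_transpose2 <- function(x, w, b = NULL, tape = NULL) {
  v <- x$value
  d <- dim(v)
  wd <- dim(w$value)
  Cout <- wd[3]; Cin <- wd[4]
  stopifnot(d[3] == Cin)
  H2 <- 2L * d[1]; W2 <- 2L * d[2]; B <- d[4]; L <- d[1] * d[2]
  Wm <- matrix(w$value, nrow = 4L * Cout, ncol = Cin)
  out <- array(0, c(H2, W2, Cout, B))
  xmats <- vector("list", B)
  for (bb in seq_len(B)) {
    xm <- t(matrix(v[, , , bb], nrow = L, ncol = Cin))
    y <- cpp_col2im(Wm %*% xm, H2, W2, Cout, 2L, 0L, 2L, 1L)
    if (!is.null(b)) y <- y + rep(b$value, each = H2 * W2)
    out[, , , bb] <- y
    if (!is.null(tape)) xmats[[bb]] <- xm
  }
  nd <- new_node(out, tape)
  if (!is.null(tape)) {
    nd$backward <- function(g) {
      for (bb in seq_len(B)) {
        dcols <- cpp_im2col(g[, , , bb][seq_len(H2 * W2 * Cout)],
                            H2, W2, Cout, 2L, 0L, 2L, 1L)
        ag_add_grad(w, array(dcols %*% t(xmats[[bb]]), dim = wd))
        if (!is.null(b))
          ag_add_grad(b, colSums(matrix(g[, , , bb], nrow = H2 * W2, ncol = Cout)))
        dxm <- crossprod(Wm, dcols)
        gx <- array(0, d)
        gx[, , , bb] <- array(t(dxm), c(d[1], d[2], Cin))
        ag_add_grad(x, gx)
      }
    }
  }
  nd
}

## ---- batch normalisation ---------------------------------------------------

# Per-channel batch norm over (H, W, B); gamma/beta are params of length C,
# bn is an environment carrying running_mean / running_var for inference.
ag_batchnorm <- function(x, gamma, beta, bn, tape = NULL, training = FALSE,
                         momentum = 0.1, eps = 1e-5) {
  v <- x$value
  d <- dim(v)
  C <- d[3]
  N <- d[1] * d[2] * d[4]
  xm <- matrix(aperm(v, c(1, 2, 4, 3)), ncol = C)   # (H*W*B, C)
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    va <- colMeans(xc * xc)
    bn$running_mean <- (1 - momentum) * bn$running_mean + momentum * mu
    bn$running_var <- (1 - momentum) * bn$running_var + momentum * va
  } else {
    mu <- bn$running_mean
    va <- bn$running_var
    xc <- sweep(xm, 2L, mu)
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, invstd, `*`)
  ym <- sweep(sweep(xhat, 2L, gamma$value, `*`), 2L, beta$value, `+`)
  out <- aperm(array(ym, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
  nd <- new_node(out, tape)
  if (!is.null(tape)) {
    nd$backward <- function(g) {
      gm <- matrix(aperm(g, c(1, 2, 4, 3)), ncol = C)
      ag_add_grad(gamma, colSums(gm * xhat))
      ag_add_grad(beta, colSums(gm))
      dxhat <- sweep(gm, 2L, gamma$value, `*`)
      if (training) {
        s1 <- colSums(dxhat)
        s2 <- colSums(dxhat * xhat)
        dxm <- sweep(N * dxhat, 2L, s1) - sweep(xhat, 2L, s2, `*`)
        dxm <- sweep(dxm, 2L, invstd / N, `*`)
      } else {
        dxm <- sweep(dxhat, 2L, invstd, `*`)
      }
      ag_add_grad(x, aperm(array(dxm, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3)))
    }
  }
  nd
}

## ---- pointwise ops ---------------------------------------------------------

ag_relu <- function(x, tape = NULL) {
  mask <- x$value > 0
  nd <- new_node(x$value * mask, tape)
  if (!is.null(tape)) nd$backward <- function(g) ag_add_grad(x, g * mask)
  nd
}

ag_sigmoid <- function(x, tape = NULL) {
  s <- 1 / (1 + exp(-x$value))
  nd <- new_node(s, tape)
  if (!is.null(tape)) nd$backward <- function(g) ag_add_grad(x, g * s * (1 - s))
  nd
}

ag_add <- function(a, b, tape = NULL) {
  nd <- new_node(a$value + b$value, tape)
  if (!is.null(tape)) nd$backward <- function(g) { ag_add_grad(a, g); ag_add_grad(b, g) }
  nd
}

# elementwise product of a (H,W,C,B) feature with a single-channel (H,W,1,B)
# gate, broadcast over channels
ag_gate <- function(x, att, tape = NULL) {
  d <- dim(x$value)
  g1 <- att$value
  dim(g1) <- c(d[1], d[2], d[4])
  gate <- array(0, d)
  for (cc in seq_len(d[3])) gate[, , cc, ] <- g1
  out <- x$value * gate
  nd <- new_node(out, tape)
  if (!is.null(tape)) {
    nd$backward <- function(g) {
      ag_add_grad(x, g * gate)
      da <- g * x$value
      da1 <- apply(da, c(1, 2, 4), sum)
      dim(da1) <- c(d[1], d[2], 1, d[4])
      ag_add_grad(att, da1)
    }
  }
  nd
}

ag_concat_c <- function(xs, tape = NULL) {
  ds <- lapply(xs, function(x) dim(x$value))
  d1 <- ds[[1]]
  cs <- vapply(ds, `[`, integer(1), 3L)
  out <- array(0, c(d1[1], d1[2], sum(cs), d1[4]))
  off <- 0L
  for (i in seq_along(xs)) {
    out[, , off + seq_len(cs[i]), ] <- xs[[i]]$value
    off <- off + cs[i]
  }
  nd <- new_node(out, tape)
  if (!is.null(tape)) {
    nd$backward <- function(g) {
      off <- 0L
      for (i in seq_along(xs)) {
        ag_add_grad(xs[[i]], g[, , off + seq_len(cs[i]), , drop = FALSE])
        off <- off + cs[i]
      }
    }
  }
  nd
}

## ---- pooling and resampling ------------------------------------------------

ag_maxpool <- function(x, k, stride = k, tape = NULL, ceil_mode = FALSE) {
  v <- x$value
  d <- dim(v)
  B <- d[4]
  args <- vector("list", B)
  out <- NULL
  for (bb in seq_len(B)) {
    r <- cpp_maxpool(v[, , , bb][seq_len(d[1] * d[2] * d[3])],
                     d[1], d[2], d[3], as.integer(k), as.integer(stride), ceil_mode)
    if (is.null(out)) {
      dy <- dim(r$y)
      out <- array(0, c(dy[1], dy[2], dy[3], B))
    }
    out[, , , bb] <- r$y
    args[[bb]] <- r$argmax
  }
  nd <- new_node(out, tape)
  if (!is.null(tape)) {
    nd$backward <- function(g) {
      gx <- array(0, d)
      for (bb in seq_len(B)) {
        gx[, , , bb] <- cpp_maxpool_backward(
          g[, , , bb][seq_len(prod(dim(g)[1:3]))], args[[bb]], d[1], d[2], d[3])
      }
      ag_add_grad(x, gx)
    }
  }
  nd
}

# nearest-neighbour resize to (Ho, Wo); floor index mapping keeps the result
# piecewise constant over the source cells
ag_upsample_nearest <- function(x, Ho, Wo, tape = NULL) {
  v <- x$value
  d <- dim(v)
  ih <- floor(seq(0, Ho - 1) * d[1] / Ho) + 1L
  iw <- floor(seq(0, Wo - 1) * d[2] / Wo) + 1L
  out <- v[ih, iw, , , drop = FALSE]
  nd <- new_node(out, tape)
  if (!is.null(tape)) {
    nd$backward <- function(g) {
      CB <- d[3] * d[4]
      m <- matrix(g, nrow = Ho, ncol = Wo * CB)
      g1 <- rowsum(m, group = ih)                       # (h, Wo*CB)
      a <- array(g1, c(d[1], Wo, CB))
      m2 <- matrix(aperm(a, c(2, 1, 3)), nrow = Wo, ncol = d[1] * CB)
      g2 <- rowsum(m2, group = iw)                      # (w, h*CB)
      gx <- aperm(array(g2, c(d[2], d[1], CB)), c(2, 1, 3))
      dim(gx) <- d
      ag_add_grad(x, gx)
    }
  }
  nd
}

# channel-wise max and mean, returning (H, W, 1, B)
ag_channel_max <- function(x, tape = NULL) {
  v <- x$value
  d <- dim(v)
  out <- array(0, c(d[1], d[2], 1, d[4]))
  argc <- vector("list", d[4])
  for (bb in seq_len(d[4])) {
    m <- matrix(v[, , , bb], nrow = d[1] * d[2], ncol = d[3])
    j <- max.col(m, ties.method = "first")
    out[, , 1, bb] <- m[cbind(seq_len(nrow(m)), j)]
    argc[[bb]] <- j
  }
  nd <- new_node(out, tape)
  if (!is.null(tape)) {
    nd$backward <- function(g) {
      gx <- array(0, d)
      for (bb in seq_len(d[4])) {
        gm <- matrix(0, d[1] * d[2], d[3])
        gm[cbind(seq_len(nrow(gm)), argc[[bb]])] <- g[, , 1, bb]
        gx[, , , bb] <- gm
      }
      ag_add_grad(x, gx)
    }
  }
  nd
}

ag_channel_mean <- function(x, tape = NULL) {
  v <- x$value
  d <- dim(v)
  out <- array(0, c(d[1], d[2], 1, d[4]))
  for (bb in seq_len(d[4]))
    out[, , 1, bb] <- rowMeans(matrix(v[, , , bb], nrow = d[1] * d[2], ncol = d[3]))
  nd <- new_node(out, tape)
  if (!is.null(tape)) {
    nd$backward <- function(g) {
      gx <- array(0, d)
      for (bb in seq_len(d[4]))
        gx[, , , bb] <- matrix(g[, , 1, bb], d[1] * d[2], d[3]) / d[3]
      ag_add_grad(x, gx)
    }
  }
  nd
}

# apply a fixed DropBlock mask (already sampled) with survivor rescaling;
# gradients flow through surviving positions only
ag_apply_mask <- function(x, mask, scale, tape = NULL) {
  ms <- mask * scale
  nd <- new_node(x$value * ms, tape)
  if (!is.null(tape)) nd$backward <- function(g) ag_add_grad(x, g * ms)
  nd
}

## ---- losses ----------------------------------------------------------------

# numerically stable binary cross-entropy straight from logits;
# target is a plain array the same shape as z
ag_bce_with_logits <- function(z, target, tape = NULL) {
  zv <- z$value
  n <- length(zv)
  # log(1 + exp(-|z|)) + max(z, 0) - z*t
  val <- sum(pmax(zv, 0) - zv * target + log1p(exp(-abs(zv)))) / n
  nd <- new_node(val, tape)
  if (!is.null(tape)) {
    p <- 1 / (1 + exp(-zv))
    nd$backward <- function(g) ag_add_grad(z, g * (p - target) / n)
  }
  nd
}

# soft Dice loss on probabilities: 1 - (2*sum(p*t) + s)/(sum(p) + sum(t) + s)
ag_dice_loss <- function(p, target, tape = NULL, smooth = 1) {
  pv <- p$value
  inter <- sum(pv * target)
  denom <- sum(pv) + sum(target) + smooth
  val <- 1 - (2 * inter + smooth) / denom
  nd <- new_node(val, tape)
  if (!is.null(tape)) {
    nd$backward <- function(g) {
      dp <- -(2 * target * denom - (2 * inter + smooth)) / denom^2
      ag_add_grad(p, g * dp)
    }
  }
  nd
}

ag_scale_add <- function(a, b, wa = 1, wb = 1, tape = NULL) {
  nd <- new_node(wa * a$value + wb * b$value, tape)
  if (!is.null(tape)) nd$backward <- function(g) { ag_add_grad(a, wa * g); ag_add_grad(b, wb * g) }
  nd
}
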
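# Independent brute-force oracles used against the package implementations.

# Dilated cross-correlation with zero padding rate*(k-1)/2, explicit loops.
brute_atrous <- function(x, w, rate) {
  # x: (H, W, Cin); w: (k, k, Cin, Cout)
  d <- dim(x); wd <- dim(w)
  k <- wd[1]
  half <- (k - 1) / 2
  out <- array(0, c(d[1], d[2], wd[4]))
  for (co in seq_len(wd[4])) {
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      s <- 0
      for (ci in seq_len(wd[3])) for (a in seq_len(k)) for (b in seq_len(k)) {
        ii <- i + rate * (a - 1 - half)
        jj <- j + rate * (b - 1 - half)
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2])
          s <- s + x[ii, jj, ci] * w[a, b, ci, co]
      }
      out[i, j, co] <- s
    }
  }
  out
}

# Spatial attention by explicit loops: channel max/mean pools, 7x7 conv with
# 3-pixel zero padding, sigmoid, gate.
brute_spatial_attention <- function(x, w, b) {
  d <- dim(x)  # (H, W, C)
  pooled <- array(0, c(d[1], d[2], 2))
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    pooled[i, j, 1] <- max(x[i, j, ])
    pooled[i, j, 2] <- mean(x[i, j, ])
  }
  z <- brute_atrous(pooled, w, 1)[, , 1] + b
  att <- 1 / (1 + exp(-z))
  sa <- x
  for (cc in seq_len(d[3])) sa[, , cc] <- x[, , cc] * att
  list(SA = sa, att = att)
}

# AUC as the exhaustive pairwise ranking statistic.
pairwise_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Largest 4/8-connected component's bounding-box span (pixels).
largest_component_span <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  best <- 0
  idx_all <- which(mask == 1)
  H <- nrow(mask); W <- ncol(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    frontier <- start
    lab[start] <- cur
    comp <- start
    while (length(frontier)) {
      r <- (frontier - 1L) %% H + 1L
      c <- (frontier - 1L) %/% H + 1L
      nb <- c()
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
        nb <- c(nb, (cc[ok] - 1L) * H + rr[ok])
      }
      nb <- unique(nb[mask[nb] == 1 & lab[nb] == 0L])
      lab[nb] <- cur
      comp <- c(comp, nb)
      frontier <- nb
    }
    r <- (comp - 1L) %% H + 1L
    c <- (comp - 1L) %/% H + 1L
    best <- max(best, diff(range(r)) + 1L, diff(range(c)) + 1L)
  }
  best
}

# set every conv/transpose kernel to zero (biases too) in a layer structure
zero_params <- function(obj) {
  for (p in mcunet:::collect_envs(obj, "x"))
    if (!is.null(p$value)) p$value <- p$value * 0
  invisible(obj)
}

tiny_records <- function(n = 4, size = 64, seed = 11) {
  recs <- make_dataset(n, synthetic_config(size = c(size, size), n_trees = 2,
                                           width_root = 3, seed = seed))
  for (i in seq_along(recs)) recs[[i]]$split <- "train"
  recs
}
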
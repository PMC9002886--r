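# Compact CNN engine.
#
# Feature maps are numeric arrays of shape (H, W, N, C): time frames by
# joints by batch samples by channels. Putting the channel axis last makes
# im2col a pure reshape-and-gather, so every convolution (forward, weight
# gradient, input gradient) is a single BLAS GEMM. All shapes here are small
# (H <= a few hundred, C <= 128), so R-level bookkeeping around the GEMMs is
# not a bottleneck.

.im2col_cache <- new.env(parent = emptyenv())

# "same" padding arithmetic: output size ceil(H / stride), surplus split
# with the smaller half first.
pad_same <- function(h, k, stride) {
  ho <- ceiling(h / stride)
  pt <- max((ho - 1L) * stride + k - h, 0L)
  c(beg = pt %/% 2L, end = pt - pt %/% 2L, out = ho)
}

# (Ho*Wo) x (K*K) matrix of 1-based linear spatial indices into the padded
# (Hp, Wp) grid; kernel offsets enumerated column-major (a fastest), matching
# the memory order of a (K, K, Cin, Cout) weight array.
im2col_index <- function(hp, wp, ho, wo, k, stride) {
  key <- paste(hp, wp, ho, wo, k, stride, sep = "_")
  idx <- .im2col_cache[[key]]
  if (!is.null(idx)) return(idx)
  i0 <- (seq_len(ho) - 1L) * stride          # 0-based top row of each patch
  j0 <- (seq_len(wo) - 1L) * stride
  a <- rep(seq_len(k), times = k)            # row offset within kernel
  b <- rep(seq_len(k), each = k)             # col offset within kernel
  rows <- outer(rep(i0 + 1L, times = wo), a - 1L, `+`)          # (HoWo, KK)
  cols <- outer(rep(j0 + 1L, each = ho), b - 1L, `+`)
  idx <- rows + hp * (cols - 1L)
  storage.mode(idx) <- "integer"
  .im2col_cache[[key]] <- idx
  idx
}

conv_fwd <- function(x, w, stride) {
  d <- dim(x)
  h <- d[1L]; wd <- d[2L]; n <- d[3L]; cin <- d[4L]
  k <- dim(w)[1L]; cout <- dim(w)[4L]
  if (k == 1L) {
    # 1x1 convolution: a plain channel mix on (strided) positions
    ho <- ceiling(h / stride); wo <- ceiling(wd / stride)
    sub <- x[seq.int(1L, h, stride), seq.int(1L, wd, stride), , , drop = FALSE]
    dim(sub) <- c(ho * wo * n, cin)
    y <- sub %*% matrix(w, cin, cout)
    dim(y) <- c(ho, wo, n, cout)
    return(list(out = y,
                cache = list(xcol = sub, dims = d, k = 1L, stride = stride,
                             ho = ho, wo = wo)))
  }
  ph <- pad_same(h, k, stride); pw <- pad_same(wd, k, stride)
  ho <- ph[["out"]]; wo <- pw[["out"]]
  hp <- h + ph[["beg"]] + ph[["end"]]; wp <- wd + pw[["beg"]] + pw[["end"]]
  if (hp == h && wp == wd) {
    xp <- x
  } else {
    xp <- array(0, c(hp, wp, n, cin))
    xp[ph[["beg"]] + seq_len(h), pw[["beg"]] + seq_len(wd), , ] <- x
  }
  idx <- im2col_index(hp, wp, ho, wo, k, stride)
  kk <- k * k
  xcol <- im2col_gather(xp, idx, hp, wp, n, cin)
  wm <- w
  dim(wm) <- c(kk * cin, cout)
  y <- xcol %*% wm
  dim(y) <- c(ho, wo, n, cout)
  list(out = y,
       cache = list(xcol = xcol, dims = d, k = k, stride = stride,
                    hp = hp, wp = wp, ho = ho, wo = wo,
                    ph = ph, pw = pw, idx = idx))
}

conv_bwd <- function(dout, cache, w) {
  d <- cache$dims
  h <- d[1L]; wd <- d[2L]; n <- d[3L]; cin <- d[4L]
  k <- cache$k; kk <- k * k
  if (k == 1L) {
    cout <- dim(w)[4L]
    ho <- cache$ho; wo <- cache$wo
    dy <- dout
    dim(dy) <- c(ho * wo * n, cout)
    dw <- crossprod(cache$xcol, dy)
    dim(dw) <- dim(w)
    dsub <- tcrossprod(dy, matrix(w, cin, cout))
    dim(dsub) <- c(ho, wo, n, cin)
    if (cache$stride == 1L) return(list(dx = dsub, dw = dw))
    dx <- array(0, d)
    dx[seq.int(1L, h, cache$stride), seq.int(1L, wd, cache$stride), , ] <- dsub
    return(list(dx = dx, dw = dw))
  }
  cout <- dim(w)[4L]
  ho <- cache$ho; wo <- cache$wo
  dy <- dout
  dim(dy) <- c(ho * wo * n, cout)
  dw <- crossprod(cache$xcol, dy)
  dim(dw) <- dim(w)
  wm <- w
  dim(wm) <- c(kk * cin, cout)
  dxcol <- tcrossprod(dy, wm)                # (HoWo*N, KK*Cin)
  dm <- col2im_scatter(dxcol, cache$idx, cache$hp, cache$wp, n, cin)
  dim(dm) <- c(cache$hp, cache$wp, n, cin)
  dx <- dm[cache$ph[["beg"]] + seq_len(h), cache$pw[["beg"]] + seq_len(wd), , ,
           drop = FALSE]
  list(dx = dx, dw = dw)
}

# Batch normalization over (H, W, N) per channel, pooled across the
# equal-length sub-groups of a mixed batch (xs is a list of (H, W, N, C)
# arrays sharing C): one set of batch statistics covers the whole
# optimization step, exactly as if the groups were one batch. Biased batch
# variance; running statistics updated as
# running <- mom * running + (1 - mom) * batch.
bn_fwd <- function(xs, gamma, beta, rmean, rvar, training,
                   eps = 1e-3, momentum = 0.99) {
  dims <- lapply(xs, dim)
  cc <- dims[[1L]][4L]
  ms <- vapply(dims, function(d) prod(d[1:3]), numeric(1))
  mt <- sum(ms)
  xms <- lapply(seq_along(xs), function(g) {
    xm <- xs[[g]]
    dim(xm) <- c(ms[g], cc)
    xm
  })
  ones <- rep(1, cc)
  if (training) {
    mu <- Reduce(`+`, lapply(xms, colSums)) / mt
    ctrs <- lapply(xms, affine_cols, s = ones, b = -mu)
    v <- Reduce(`+`, lapply(ctrs, function(ct) colSums(ct * ct))) / mt
    rmean <- momentum * rmean + (1 - momentum) * mu
    rvar <- momentum * rvar + (1 - momentum) * v
  } else {
    mu <- rmean
    v <- rvar
    ctrs <- lapply(xms, affine_cols, s = ones, b = -mu)
  }
  istd <- 1 / sqrt(v + eps)
  ys <- lapply(seq_along(ctrs), function(g) {
    y <- affine_cols(ctrs[[g]], gamma * istd, beta)
    dim(y) <- dims[[g]]
    y
  })
  list(out = ys,
       cache = list(ctrs = ctrs, istd = istd, gamma = gamma, dims = dims,
                    ms = ms, training = training, mu = mu, v = v),
       rmean = rmean, rvar = rvar)
}

bn_bwd <- function(douts, cache) {
  ms <- cache$ms
  mt <- sum(ms)
  cc <- cache$dims[[1L]][4L]
  dys <- lapply(seq_along(douts), function(g) {
    dy <- douts[[g]]
    dim(dy) <- c(ms[g], cc)
    dy
  })
  dgamma <- Reduce(`+`, lapply(seq_along(dys), function(g) {
    colSums(dys[[g]] * cache$ctrs[[g]])
  })) * cache$istd
  dbeta <- Reduce(`+`, lapply(dys, colSums))
  gs <- cache$gamma * cache$istd
  zeros <- rep(0, cc)
  dxs <- lapply(seq_along(dys), function(g) {
    dx <- if (cache$training) {
      bn_bwd_core(dys[[g]], cache$ctrs[[g]], cache$istd, gs,
                  dbeta / mt, dgamma / mt)
    } else {
      affine_cols(dys[[g]], gs, zeros)
    }
    dim(dx) <- cache$dims[[g]]
    dx
  })
  list(dx = dxs, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

relu_bwd <- function(dout, mask) dout * mask

# Adaptive average-pool region boundaries: cell i of l covers input rows
# floor((i-1)*H/l)+1 .. floor(i*H/l) — an exact partition of the axis (every
# row in exactly one cell), so the level-1 cell always equals the global
# average.
adaptive_bounds <- function(h, l) {
  lo <- floor((seq_len(l) - 1L) * h / l) + 1L
  hi <- floor(seq_len(l) * h / l)
  cbind(lo, hi)
}

#' Pool a feature map to a fixed-length embedding
#'
#' Collapses the two spatial axes of a feature map so that inputs of any
#' spatial size produce an embedding of fixed length — the mechanism that
#' lets the network accept gait cycles of variable length without
#' resampling. Modes: `"gap"` (global average per channel, embedding length
#' = channels), `"gmp"` (global max per channel), `"spp"` (spatial pyramid:
#' adaptive average pooling over an `l x l` grid for each level `l`,
#' concatenated; length = channels * sum(levels^2), ordered level by level,
#' cells row-major within a level, channels blocked outermost).
#'
#' @param x Feature map array `(H, W, C)` for one sample, or `(H, W, N, C)`
#'   for a batch.
#' @param mode One of `"gap"`, `"gmp"`, `"spp"`.
#' @param levels Integer pyramid levels for `"spp"` (default `c(1, 2, 4)`).
#' @return A numeric vector (single sample) or an `N x D` matrix (batch).
#' @examples
#' m <- array(c(1, 3, 2, 4), c(2, 2, 1))  # [[1,2],[3,4]] in one channel
#' pool_features(m, "gap")  # 2.5
#' pool_features(m, "gmp")  # 4
#' @export
pool_features <- function(x, mode = c("gap", "gmp", "spp"), levels = c(1L, 2L, 4L)) {
  mode <- match.arg(mode)
  single <- length(dim(x)) == 3L
  if (single) {
    d <- dim(x)
    dim(x) <- c(d[1L], d[2L], 1L, d[3L])
  }
  out <- pool_fwd(x, mode, levels)$out
  if (single) drop(out) else out
}

pool_fwd <- function(x, mode, levels = c(1L, 2L, 4L)) {
  d <- dim(x)
  h <- d[1L]; w <- d[2L]; n <- d[3L]; cc <- d[4L]
  if (mode == "gap") {
    m <- x
    dim(m) <- c(h * w, n * cc)
    out <- matrix(colMeans(m), n, cc)
    return(list(out = out, cache = list(mode = mode, dims = d)))
  }
  if (mode == "gmp") {
    m <- x
    dim(m) <- c(h * w, n * cc)
    amax <- max.col(t(m), ties.method = "first")
    out <- matrix(m[cbind(amax, seq_len(n * cc))], n, cc)
    return(list(out = out, cache = list(mode = mode, dims = d, amax = amax)))
  }
  # spp
  if (h < max(levels) || w < max(levels)) {
    abort(sprintf(
      "Spatial size (%d x %d) is smaller than the largest pyramid level %d.",
      h, w, max(levels)))
  }
  pieces <- list()
  regions <- list()
  for (l in levels) {
    bh <- adaptive_bounds(h, l)
    bw <- adaptive_bounds(w, l)
    cells <- matrix(0, n * cc, l * l)
    cellreg <- vector("list", l * l)
    q <- 1L
    for (i in seq_len(l)) {        # row-major cell order: rows outer
      for (j in seq_len(l)) {
        sub <- x[bh[i, 1]:bh[i, 2], bw[j, 1]:bw[j, 2], , , drop = FALSE]
        sd <- dim(sub)
        dim(sub) <- c(sd[1L] * sd[2L], n * cc)
        cells[, q] <- colMeans(sub)
        cellreg[[q]] <- c(bh[i, 1], bh[i, 2], bw[j, 1], bw[j, 2])
        q <- q + 1L
      }
    }
    pieces[[as.character(l)]] <- cells     # (N*C, l^2), N fastest within C
    regions[[as.character(l)]] <- cellreg
  }
  # assemble per-level blocks: within a level, columns are cell + l^2*(c-1)
  blocks <- lapply(seq_along(levels), function(ii) {
    l <- levels[ii]
    cells <- pieces[[ii]]                  # rows ordered (n, c)
    arr <- array(cells, c(n, cc, l * l))
    arr <- aperm(arr, c(1L, 3L, 2L))       # (n, cell, c)
    matrix(arr, n, l * l * cc)
  })
  out <- do.call(cbind, blocks)
  list(out = out, cache = list(mode = mode, dims = d, levels = levels,
                               regions = regions))
}

pool_bwd <- function(dout, cache) {
  d <- cache$dims
  h <- d[1L]; w <- d[2L]; n <- d[3L]; cc <- d[4L]
  if (cache$mode == "gap") {
    dx <- array(rep(as.vector(dout) / (h * w), each = h * w), d)
    return(dx)
  }
  if (cache$mode == "gmp") {
    dm <- matrix(0, h * w, n * cc)
    dm[cbind(cache$amax, seq_len(n * cc))] <- as.vector(dout)
    dim(dm) <- d
    return(dm)
  }
  dx <- array(0, d)
  off <- 0L
  for (ii in seq_along(cache$levels)) {
    l <- cache$levels[ii]
    block <- dout[, off + seq_len(l * l * cc), drop = FALSE]
    arr <- array(block, c(n, l * l, cc))
    for (q in seq_len(l * l)) {
      rg <- cache$regions[[ii]][[q]]
      nr <- (rg[2] - rg[1] + 1L) * (rg[4] - rg[3] + 1L)
      g <- arr[, q, , drop = FALSE]                 # (n, 1, cc)
      add <- array(rep(as.vector(g) / nr, each = nr),
                   c(rg[2] - rg[1] + 1L, rg[4] - rg[3] + 1L, n, cc))
      dx[rg[1]:rg[2], rg[3]:rg[4], , ] <-
        dx[rg[1]:rg[2], rg[3]:rg[4], , , drop = FALSE] + add
    }
    off <- off + l * l * cc
  }
  dx
}

dense_fwd <- function(x, w, b) {
  list(out = x %*% w + rep(b, each = nrow(x)), cache = x)
}

dense_bwd <- function(dout, cache, w) {
  list(dx = tcrossprod(dout, w),
       dw = crossprod(cache, dout),
       db = colSums(dout))
}

softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean categorical cross-entropy and its gradient w.r.t. the logits
xent_loss <- function(probs, y_onehot) {
  n <- nrow(probs)
  p <- pmax(probs[y_onehot > 0], 1e-12)
  list(loss = -mean(log(p)), dlogits = (probs - y_onehot) / n)
}
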
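#' Residual-block and model configuration
#'
#' The network is a stem convolution (conv -> batch norm -> ReLU) followed by
#' exactly five residual stages, a pooling layer that collapses the variable
#' spatial extent to a fixed-length embedding, and a dense softmax head with
#' one unit per enrolled subject. A stage with stride 1 uses an identity skip
#' (conv-BN-ReLU-conv-BN, input added before the final ReLU; requires the
#' input channel count to equal `filters`). A stage with stride 2 halves both
#' spatial axes (ceiling division under "same" padding) and projects the
#' shortcut with a 1x1 convolution plus batch norm so the addition is
#' shape-compatible. `repeats > 1` stacks further identity blocks after the
#' first.
#'
#' The default configuration — stem 3x3x16; stages
#' (3x3,16,s1), (3x3,32,s2), (3x3,32,s1), (3x3,64,s2), (3x3,64,s1); global
#' average pooling — yields a 64-dimensional embedding and, with a 30-class
#' head, 171,886 trainable and 1,056 non-trainable parameters.
#'
#' @param kernel Square kernel size K.
#' @param filters Number of filters F.
#' @param stride 1 or 2.
#' @param repeats Number of stacked blocks in the stage (`>= 1`; blocks after
#'   the first are always stride-1 identity blocks).
#' @return `block_spec()` a `block_spec` list; `model_config()` a
#'   `gait_model_config`.
#' @export
block_spec <- function(kernel = 3L, filters, stride = 1L, repeats = 1L) {
  stopifnot(kernel >= 1, filters >= 1, stride %in% c(1L, 2L), repeats >= 1)
  structure(list(kernel = as.integer(kernel), filters = as.integer(filters),
                 stride = as.integer(stride), repeats = as.integer(repeats)),
            class = "block_spec")
}

#' @rdname block_spec
#' @param classes Number of subjects `P` (`>= 2`).
#' @param stem List with `kernel` and `filters` for the initial convolution.
#' @param blocks List of exactly five [block_spec()]s.
#' @param pooling `"gap"`, `"gmp"` or `"spp"`.
#' @param spp_levels Pyramid levels when `pooling = "spp"`.
#' @param in_channels Input channel count (3 for x, y, z coordinates).
#' @export
model_config <- function(classes,
                         stem = list(kernel = 3L, filters = 16L),
                         blocks = list(
                           block_spec(3L, 16L, 1L),
                           block_spec(3L, 32L, 2L),
                           block_spec(3L, 32L, 1L),
                           block_spec(3L, 64L, 2L),
                           block_spec(3L, 64L, 1L)),
                         pooling = c("gap", "gmp", "spp"),
                         spp_levels = c(1L, 2L, 4L),
                         in_channels = 3L,
                         bn_momentum = 0.9) {
  pooling <- match.arg(pooling)
  if (length(blocks) != 5L) {
    abort("The architecture uses exactly five residual stages.")
  }
  blocks <- lapply(blocks, function(b) {
    if (inherits(b, "block_spec")) b else do.call(block_spec, b)
  })
  if (classes < 2L) abort("`classes` must be >= 2.")
  # an identity-skip first stage needs matching channels; a projection is
  # inserted automatically when channels change or stride is 2
  structure(list(classes = as.integer(classes),
                 stem = list(kernel = as.integer(stem$kernel),
                             filters = as.integer(stem$filters)),
                 blocks = blocks, pooling = pooling,
                 spp_levels = as.integer(spp_levels),
                 in_channels = as.integer(in_channels),
                 bn_momentum = bn_momentum),
            class = "gait_model_config")
}

# He-uniform fan-in initialization
he_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(runif(prod(dims), -lim, lim), dims)
}

new_conv_params <- function(params, state, name, k, cin, cout) {
  params[[paste0(name, ".w")]] <- he_uniform(c(k, k, cin, cout), k * k * cin)
  list(params = params, state = state)
}

new_bn_params <- function(params, state, name, cc) {
  params[[paste0(name, ".gamma")]] <- rep(1, cc)
  params[[paste0(name, ".beta")]] <- rep(0, cc)
  state[[paste0(name, ".mean")]] <- rep(0, cc)
  state[[paste0(name, ".var")]] <- rep(1, cc)
  list(params = params, state = state)
}

#' Build the gait-recognition network
#'
#' Allocates all weights (He-uniform fan-in initialization for convolutions
#' and the dense head; batch-norm scale 1 / shift 0; running mean 0 /
#' variance 1) for a [model_config()]. The returned model accepts input
#' tensors of shape `(Nf, Nb, 3)` with `Nf` free: pooling produces the same
#' embedding length for every input size, so no resampling is ever applied.
#'
#' @param config A [model_config()].
#' @param seed Optional integer seed for reproducible initialization.
#' @return A `gait_cnn` object: list with `config`, `params` (named list of
#'   weight arrays), `state` (batch-norm running statistics) and `ops` (the
#'   layer plan).
#' @export
build_model <- function(config, seed = NULL) {
  stopifnot(inherits(config, "gait_model_config"))
  if (!is.null(seed)) set.seed(seed)
  params <- list()
  state <- list()
  ops <- list()
  ps <- new_conv_params(params, state, "stem.conv",
                        config$stem$kernel, config$in_channels,
                        config$stem$filters)
  ps <- new_bn_params(ps$params, ps$state, "stem.bn", config$stem$filters)
  params <- ps$params; state <- ps$state
  ops[[length(ops) + 1L]] <- list(op = "conv", w = "stem.conv.w", stride = 1L)
  ops[[length(ops) + 1L]] <- list(op = "bn", name = "stem.bn")
  ops[[length(ops) + 1L]] <- list(op = "relu")
  cin <- config$stem$filters
  for (s in seq_along(config$blocks)) {
    b <- config$blocks[[s]]
    for (r in seq_len(b$repeats)) {
      stride <- if (r == 1L) b$stride else 1L
      proj <- r == 1L && (stride == 2L || cin != b$filters)
      if (stride == 1L && !proj && cin != b$filters) {
        abort("Identity residual block needs matching channel counts.")
      }
      nm <- sprintf("b%d.r%d", s, r)
      ps <- new_conv_params(params, state, paste0(nm, ".conv1"),
                            b$kernel, cin, b$filters)
      ps <- new_bn_params(ps$params, ps$state, paste0(nm, ".bn1"), b$filters)
      ps <- new_conv_params(ps$params, ps$state, paste0(nm, ".conv2"),
                            b$kernel, b$filters, b$filters)
      ps <- new_bn_params(ps$params, ps$state, paste0(nm, ".bn2"), b$filters)
      if (proj) {
        ps <- new_conv_params(ps$params, ps$state, paste0(nm, ".proj"),
                              1L, cin, b$filters)
        ps <- new_bn_params(ps$params, ps$state, paste0(nm, ".bnp"), b$filters)
      }
      params <- ps$params; state <- ps$state
      ops[[length(ops) + 1L]] <- list(op = "resblock", name = nm,
                                      stride = stride, proj = proj)
      cin <- b$filters
    }
  }
  embed <- if (config$pooling == "spp") cin * sum(config$spp_levels ^ 2) else cin
  params[["head.w"]] <- he_uniform(c(embed, config$classes), embed)
  params[["head.b"]] <- rep(0, config$classes)
  ops[[length(ops) + 1L]] <- list(op = "pool", mode = config$pooling,
                                  levels = config$spp_levels)
  ops[[length(ops) + 1L]] <- list(op = "dense", w = "head.w", b = "head.b")
  structure(list(config = config, params = params, state = state,
                 ops = ops, embed_dim = embed),
            class = "gait_cnn")
}

#' @export
print.gait_cnn <- function(x, ...) {
  pc <- count_params(x)
  cat(sprintf(
    "<gait_cnn: %d classes, pooling=%s, embedding=%d; %s trainable / %s non-trainable params>\n",
    x$config$classes, x$config$pooling, x$embed_dim,
    format(pc$trainable, big.mark = ","), format(pc$non_trainable, big.mark = ",")))
  invisible(x)
}

# Forward pass. `xs` is a mixed batch: a list of (H, W, N, C) arrays (one
# per cycle length present in the batch; a plain array is wrapped). All
# groups share one set of batch-norm statistics, so a mixed batch behaves
# statistically like a single i.i.d. batch while every group keeps its own
# spatial extent (no padding). Returns stacked probabilities (group order),
# per-layer caches, and (in training mode) updated BN running statistics.
net_forward <- function(model, xs, training = FALSE) {
  if (!is.list(xs)) xs <- list(xs)
  params <- model$params
  state <- model$state
  mom <- model$config$bn_momentum %||% 0.9
  caches <- vector("list", length(model$ops))
  x <- xs
  for (i in seq_along(model$ops)) {
    op <- model$ops[[i]]
    if (op$op == "conv") {
      r <- lapply(x, conv_fwd, w = params[[op$w]], stride = op$stride)
      x <- lapply(r, `[[`, "out")
      caches[[i]] <- lapply(r, `[[`, "cache")
    } else if (op$op == "bn") {
      r <- bn_layer_fwd(params, state, op$name, x, training, mom)
      x <- r$out
      caches[[i]] <- r$cache
      state[[paste0(op$name, ".mean")]] <- r$rmean
      state[[paste0(op$name, ".var")]] <- r$rvar
    } else if (op$op == "relu") {
      r <- lapply(x, relu_fwd)
      x <- lapply(r, `[[`, "out")
      caches[[i]] <- lapply(r, `[[`, "cache")
    } else if (op$op == "resblock") {
      r <- resblock_fwd(params, state, op, x, training, mom)
      x <- r$out
      caches[[i]] <- r$cache
      state <- r$state
    } else if (op$op == "pool") {
      r <- lapply(x, pool_fwd, mode = op$mode, levels = op$levels)
      x <- do.call(rbind, lapply(r, `[[`, "out"))
      caches[[i]] <- lapply(r, `[[`, "cache")
    } else if (op$op == "dense") {
      r <- dense_fwd(x, params[[op$w]], params[[op$b]])
      x <- r$out
      caches[[i]] <- r$cache
    }
  }
  list(logits = x, probs = softmax(x), caches = caches, state = state)
}

bn_layer_fwd <- function(params, state, name, xs, training, momentum = 0.9) {
  bn_fwd(xs,
         gamma = params[[paste0(name, ".gamma")]],
         beta = params[[paste0(name, ".beta")]],
         rmean = state[[paste0(name, ".mean")]],
         rvar = state[[paste0(name, ".var")]],
         training = training, momentum = momentum)
}

resblock_fwd <- function(params, state, op, xs, training, momentum = 0.9) {
  nm <- op$name
  c1 <- lapply(xs, conv_fwd, w = params[[paste0(nm, ".conv1.w")]],
               stride = op$stride)
  b1 <- bn_layer_fwd(params, state, paste0(nm, ".bn1"),
                     lapply(c1, `[[`, "out"), training, momentum)
  state[[paste0(nm, ".bn1.mean")]] <- b1$rmean
  state[[paste0(nm, ".bn1.var")]] <- b1$rvar
  r1 <- lapply(b1$out, relu_fwd)
  c2 <- lapply(lapply(r1, `[[`, "out"), conv_fwd,
               w = params[[paste0(nm, ".conv2.w")]], stride = 1L)
  b2 <- bn_layer_fwd(params, state, paste0(nm, ".bn2"),
                     lapply(c2, `[[`, "out"), training, momentum)
  state[[paste0(nm, ".bn2.mean")]] <- b2$rmean
  state[[paste0(nm, ".bn2.var")]] <- b2$rvar
  if (op$proj) {
    cp <- lapply(xs, conv_fwd, w = params[[paste0(nm, ".proj.w")]],
                 stride = op$stride)
    bp <- bn_layer_fwd(params, state, paste0(nm, ".bnp"),
                       lapply(cp, `[[`, "out"), training, momentum)
    state[[paste0(nm, ".bnp.mean")]] <- bp$rmean
    state[[paste0(nm, ".bnp.var")]] <- bp$rvar
    shortcut <- bp$out
    pcache <- list(conv = lapply(cp, `[[`, "cache"), bn = bp$cache)
  } else {
    shortcut <- xs
    pcache <- NULL
  }
  rout <- lapply(seq_along(xs), function(g) relu_fwd(b2$out[[g]] + shortcut[[g]]))
  list(out = lapply(rout, `[[`, "out"),
       cache = list(c1 = lapply(c1, `[[`, "cache"), b1 = b1$cache,
                    r1 = lapply(r1, `[[`, "cache"),
                    c2 = lapply(c2, `[[`, "cache"), b2 = b2$cache,
                    proj = pcache, rout = lapply(rout, `[[`, "cache")),
       state = state)
}

# Backward pass: dlogits is the gradient w.r.t. the dense output. Returns a
# named list of gradients matching model$params.
net_backward <- function(model, caches, dlogits) {
  params <- model$params
  grads <- list()
  d <- dlogits
  for (i in rev(seq_along(model$ops))) {
    op <- model$ops[[i]]
    if (op$op == "dense") {
      r <- dense_bwd(d, caches[[i]], params[[op$w]])
      grads[[op$w]] <- r$dw
      grads[[op$b]] <- r$db
      d <- r$dx
    } else if (op$op == "pool") {
      # split embedding rows back into their Nf groups
      sizes <- vapply(caches[[i]], function(cc) cc$dims[3L], numeric(1))
      ends <- cumsum(sizes)
      d <- lapply(seq_along(sizes), function(g) {
        pool_bwd(d[(ends[g] - sizes[g] + 1L):ends[g], , drop = FALSE],
                 caches[[i]][[g]])
      })
    } else if (op$op == "resblock") {
      r <- resblock_bwd(params, op, caches[[i]], d)
      for (nm in names(r$grads)) grads[[nm]] <- r$grads[[nm]]
      d <- r$dx
    } else if (op$op == "relu") {
      d <- lapply(seq_along(d), function(g) relu_bwd(d[[g]], caches[[i]][[g]]))
    } else if (op$op == "bn") {
      r <- bn_bwd(d, caches[[i]])
      grads[[paste0(op$name, ".gamma")]] <- r$dgamma
      grads[[paste0(op$name, ".beta")]] <- r$dbeta
      d <- r$dx
    } else if (op$op == "conv") {
      r <- lapply(seq_along(d), function(g) {
        conv_bwd(d[[g]], caches[[i]][[g]], params[[op$w]])
      })
      grads[[op$w]] <- Reduce(`+`, lapply(r, `[[`, "dw"))
      d <- lapply(r, `[[`, "dx")
    }
  }
  grads
}

resblock_bwd <- function(params, op, cache, douts) {
  nm <- op$name
  grads <- list()
  dsum <- lapply(seq_along(douts), function(g) {
    relu_bwd(douts[[g]], cache$rout[[g]])
  })
  # main branch
  b2 <- bn_bwd(dsum, cache$b2)
  grads[[paste0(nm, ".bn2.gamma")]] <- b2$dgamma
  grads[[paste0(nm, ".bn2.beta")]] <- b2$dbeta
  c2 <- lapply(seq_along(douts), function(g) {
    conv_bwd(b2$dx[[g]], cache$c2[[g]], params[[paste0(nm, ".conv2.w")]])
  })
  grads[[paste0(nm, ".conv2.w")]] <- Reduce(`+`, lapply(c2, `[[`, "dw"))
  dr1 <- lapply(seq_along(douts), function(g) {
    relu_bwd(c2[[g]]$dx, cache$r1[[g]])
  })
  b1 <- bn_bwd(dr1, cache$b1)
  grads[[paste0(nm, ".bn1.gamma")]] <- b1$dgamma
  grads[[paste0(nm, ".bn1.beta")]] <- b1$dbeta
  c1 <- lapply(seq_along(douts), function(g) {
    conv_bwd(b1$dx[[g]], cache$c1[[g]], params[[paste0(nm, ".conv1.w")]])
  })
  grads[[paste0(nm, ".conv1.w")]] <- Reduce(`+`, lapply(c1, `[[`, "dw"))
  dx <- lapply(c1, `[[`, "dx")
  # shortcut branch
  if (op$proj) {
    bp <- bn_bwd(dsum, cache$proj$bn)
    grads[[paste0(nm, ".bnp.gamma")]] <- bp$dgamma
    grads[[paste0(nm, ".bnp.beta")]] <- bp$dbeta
    cp <- lapply(seq_along(douts), function(g) {
      conv_bwd(bp$dx[[g]], cache$proj$conv[[g]], params[[paste0(nm, ".proj.w")]])
    })
    grads[[paste0(nm, ".proj.w")]] <- Reduce(`+`, lapply(cp, `[[`, "dw"))
    dx <- lapply(seq_along(dx), function(g) dx[[g]] + cp[[g]]$dx)
  } else {
    dx <- lapply(seq_along(dx), function(g) dx[[g]] + dsum[[g]])
  }
  list(dx = dx, grads = grads)
}

#' Run a residual block forward
#'
#' Functional forward pass of a single residual block with explicit weights,
#' exposed for inspection and testing. `params` is a named list with
#' elements `conv1.w`, `bn1.gamma`, `bn1.beta`, `bn1.mean`, `bn1.var`,
#' `conv2.w`, `bn2.*`, and for a projection block also `proj.w`, `bnp.*`.
#' [residual_block_params()] allocates such a list (He-uniform weights,
#' identity batch norm).
#'
#' @param x Feature map `(H, W, C)` or batch `(H, W, N, C)`.
#' @param params Named weight list as above.
#' @param stride 1 (identity skip; input channels must equal the block's
#'   filters) or 2 (projection shortcut; both spatial axes halve).
#' @param training Use batch statistics (`TRUE`) or running statistics?
#' @return Feature map of the same arrangement as `x`.
#' @export
residual_block <- function(x, params, stride = 1L, training = FALSE) {
  single <- length(dim(x)) == 3L
  if (single) {
    d <- dim(x)
    dim(x) <- c(d[1L], d[2L], 1L, d[3L])
  }
  proj <- "proj.w" %in% names(params)
  filters <- dim(params$conv1.w)[4L]
  if (!proj && dim(x)[4L] != filters) {
    abort(paste0("Identity residual block: input has ", dim(x)[4L],
                 " channels but the block has ", filters,
                 " filters; a stride-2 (projection) block must precede."))
  }
  p <- list()
  st <- list()
  for (nm in names(params)) {
    if (grepl("\\.(mean|var)$", nm)) st[[paste0("blk.", nm)]] <- params[[nm]]
    else p[[paste0("blk.", nm)]] <- params[[nm]]
  }
  op <- list(op = "resblock", name = "blk", stride = as.integer(stride),
             proj = proj)
  out <- resblock_fwd(p, st, op, list(x), training)$out[[1L]]
  if (single) {
    d <- dim(out)
    dim(out) <- d[c(1L, 2L, 4L)]
  }
  out
}

#' @rdname residual_block
#' @param in_channels,filters,kernel Block shape.
#' @param proj Allocate the 1x1 projection shortcut (required when
#'   `stride = 2` or channels change)?
#' @export
residual_block_params <- function(in_channels, filters, kernel = 3L,
                                  proj = in_channels != filters) {
  p <- list(
    conv1.w = he_uniform(c(kernel, kernel, in_channels, filters),
                         kernel * kernel * in_channels),
    bn1.gamma = rep(1, filters), bn1.beta = rep(0, filters),
    bn1.mean = rep(0, filters), bn1.var = rep(1, filters),
    conv2.w = he_uniform(c(kernel, kernel, filters, filters),
                         kernel * kernel * filters),
    bn2.gamma = rep(1, filters), bn2.beta = rep(0, filters),
    bn2.mean = rep(0, filters), bn2.var = rep(1, filters))
  if (proj) {
    p$proj.w <- he_uniform(c(1L, 1L, in_channels, filters), in_channels)
    p$bnp.gamma <- rep(1, filters); p$bnp.beta <- rep(0, filters)
    p$bnp.mean <- rep(0, filters); p$bnp.var <- rep(1, filters)
  }
  p
}

#' Predict subject probabilities for gait tensors
#'
#' Groups tensors by their frame count `Nf` (the network requires a
#' homogeneous spatial size within one batch, and pooling makes the output
#' comparable across sizes), runs inference with batch-norm running
#' statistics, and returns one softmax row per tensor in input order.
#'
#' @param object A `gait_cnn` (or a fitted model from [fit_gait_cnn()]).
#' @param tensors A `gait_dataset`, a list of `gait_tensor` arrays, or a
#'   single tensor.
#' @param type `"prob"` for the `N x P` probability matrix, `"class"` for
#'   0-based predicted labels.
#' @param ... Unused.
#' @export
predict.gait_cnn <- function(object, tensors, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.data.frame(tensors)) tensors <- tensors$tensor
  if (is.array(tensors) && !is.list(tensors)) tensors <- list(tensors)
  n <- length(tensors)
  p <- object$config$classes
  probs <- matrix(NA_real_, n, p)
  nf <- vapply(tensors, function(t) dim(t)[1L], integer(1))
  for (len in unique(nf)) {
    ii <- which(nf == len)
    xb <- batch_array(tensors[ii])
    probs[ii, ] <- net_forward(object, xb, training = FALSE)$probs
  }
  if (type == "class") max.col(probs, ties.method = "first") - 1L else probs
}

# stack a list of (H, W, C) tensors of equal H into an (H, W, N, C) batch
batch_array <- function(tensors) {
  d <- dim(tensors[[1L]])
  n <- length(tensors)
  xb <- array(0, c(d[1L], d[2L], n, d[3L]))
  for (i in seq_len(n)) xb[, , i, ] <- tensors[[i]]
  xb
}

#' Count model parameters
#'
#' `count_params()` sums the lengths of a built model's weight arrays
#' (trainable) and batch-norm running statistics (non-trainable).
#' `param_count()` computes the same quantities in closed form from a
#' [model_config()] alone — `K*K*Cin*Cout` per convolution, `2C` trainable
#' plus `2C` non-trainable per batch norm, `D*P + P` for the head — without
#' allocating anything; the two routes agreeing is a structural check on the
#' architecture.
#'
#' @param model A `gait_cnn`.
#' @return A one-row tibble with `trainable`, `non_trainable`, `total`.
#' @examples
#' param_count(model_config(classes = 30))  # 171886 trainable, 1056 non-trainable
#' @export
count_params <- function(model) {
  if (inherits(model, "gait_cnn_fit")) model <- model$model
  stopifnot(inherits(model, "gait_cnn"))
  tr <- sum(vapply(model$params, length, integer(1)))
  nt <- sum(vapply(model$state, length, integer(1)))
  tibble(trainable = tr, non_trainable = nt, total = tr + nt)
}

#' @rdname count_params
#' @param config A [model_config()].
#' @export
param_count <- function(config) {
  stopifnot(inherits(config, "gait_model_config"))
  conv <- function(k, cin, cout) k * k * cin * cout
  tr <- conv(config$stem$kernel, config$in_channels, config$stem$filters) +
    2L * config$stem$filters
  nt <- 2L * config$stem$filters
  cin <- config$stem$filters
  for (b in config$blocks) {
    for (r in seq_len(b$repeats)) {
      proj <- r == 1L && (b$stride == 2L || cin != b$filters)
      tr <- tr + conv(b$kernel, cin, b$filters) + 2L * b$filters +
        conv(b$kernel, b$filters, b$filters) + 2L * b$filters
      nt <- nt + 4L * b$filters
      if (proj) {
        tr <- tr + conv(1L, cin, b$filters) + 2L * b$filters
        nt <- nt + 2L * b$filters
      }
      cin <- b$filters
    }
  }
  d <- if (config$pooling == "spp") cin * sum(config$spp_levels ^ 2) else cin
  tr <- tr + d * config$classes + config$classes
  tibble(trainable = tr, non_trainable = nt, total = tr + nt)
}
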
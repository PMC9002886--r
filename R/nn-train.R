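# Optimizers operate on flat named lists of arrays. `opt$state` holds the
# per-parameter moment estimates.

make_optimizer <- function(name = c("adam", "sgd", "rmsprop"), lr = NULL) {
  name <- match.arg(name)
  lr <- lr %||% switch(name, adam = 1e-3, sgd = 1e-2, rmsprop = 1e-3)
  list(name = name, lr = lr, state = list(), t = 0L)
}

optimizer_step <- function(opt, params, grads) {
  lr <- opt$lr
  if (opt$name == "sgd") {
    for (nm in names(grads)) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
    return(list(opt = opt, params = params))
  }
  if (opt$name == "rmsprop") {
    rho <- 0.9; eps <- 1e-7
    for (nm in names(grads)) {
      g <- grads[[nm]]
      v <- opt$state[[nm]] %||% (g * 0)
      v <- rho * v + (1 - rho) * g * g
      opt$state[[nm]] <- v
      params[[nm]] <- params[[nm]] - lr * g / (sqrt(v) + eps)
    }
    return(list(opt = opt, params = params))
  }
  # adam
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-7
  opt$t <- opt$t + 1L
  bc1 <- 1 - b1 ^ opt$t
  bc2 <- 1 - b2 ^ opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- opt$state[[paste0(nm, ".m")]] %||% (g * 0)
    v <- opt$state[[paste0(nm, ".v")]] %||% (g * 0)
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    opt$state[[paste0(nm, ".m")]] <- m
    opt$state[[paste0(nm, ".v")]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  list(opt = opt, params = params)
}

# Replace the EMA batch-norm running statistics with exact statistics of
# every normalization layer over the given tensors (one forward sweep,
# aggregating per-batch moments into the global mean and total variance).
# EMA statistics track subject-correlated length buckets too loosely for
# reliable inference; exact statistics make inference deterministic and
# faithful to the data the model was trained on.
recalibrate_bn_stats <- function(model, tensors, nf, batch_size = 32L) {
  s1 <- list(); s2 <- list(); mt <- list()
  batches <- make_batches(nf, batch_size, shuffle = FALSE)
  for (b in batches) {
    xb <- batch_array(tensors[b])
    fw <- net_forward(model, xb, training = TRUE)
    for (i in seq_along(model$ops)) {
      op <- model$ops[[i]]
      bn_caches <- if (op$op == "bn") {
        setNames(list(fw$caches[[i]]), op$name)
      } else if (op$op == "resblock") {
        cc <- fw$caches[[i]]
        out <- list(cc$b1, cc$b2)
        names(out) <- paste0(op$name, c(".bn1", ".bn2"))
        if (!is.null(cc$proj)) out[[paste0(op$name, ".bnp")]] <- cc$proj$bn
        out
      } else NULL
      for (nm in names(bn_caches)) {
        cb <- bn_caches[[nm]]
        m <- sum(cb$ms)
        s1[[nm]] <- (s1[[nm]] %||% 0) + m * cb$mu
        s2[[nm]] <- (s2[[nm]] %||% 0) + m * (cb$v + cb$mu ^ 2)
        mt[[nm]] <- (mt[[nm]] %||% 0) + m
      }
    }
  }
  for (nm in names(s1)) {
    mu <- s1[[nm]] / mt[[nm]]
    model$state[[paste0(nm, ".mean")]] <- mu
    model$state[[paste0(nm, ".var")]] <- pmax(s2[[nm]] / mt[[nm]] - mu ^ 2, 0)
  }
  model
}

# group sample indices into batches of equal Nf (length bucketing): padding
# is never used, so pooling statistics are exact for every sample
make_batches <- function(nf, batch_size, shuffle = TRUE) {
  buckets <- split(seq_along(nf), nf)
  batches <- list()
  for (b in buckets) {
    if (shuffle) b <- b[sample.int(length(b))]
    starts <- seq(1L, length(b), by = batch_size)
    for (s in starts) {
      batches[[length(batches) + 1L]] <- b[s:min(s + batch_size - 1L, length(b))]
    }
  }
  if (shuffle && length(batches) > 1L) batches <- batches[sample.int(length(batches))]
  batches
}

# Mixed-composition optimization steps: samples are drawn i.i.d. into
# batches of up to batch_size and each batch is split into equal-Nf compute
# groups (so tensors are never padded) that share one set of batch-norm
# statistics. Returns a list of steps, each a list of index groups.
make_mixed_batches <- function(nf, batch_size, shuffle = TRUE) {
  idx <- if (shuffle) sample.int(length(nf)) else seq_along(nf)
  starts <- seq(1L, length(idx), by = batch_size)
  lapply(starts, function(s) {
    chunk <- idx[s:min(s + batch_size - 1L, length(idx))]
    unname(split(chunk, nf[chunk]))
  })
}

#' Train the network on a gait dataset
#'
#' Minimizes categorical cross-entropy between the softmax output and the
#' one-hot subject labels. Variable-length cycles are handled by length
#' bucketing, never by padding: each optimization batch (up to `batch_size`
#' cycles drawn i.i.d.) is split into equal-`Nf` compute groups, and the
#' groups share one set of batch-normalization statistics, so a step
#' behaves statistically like an ordinary i.i.d. batch while the pooled
#' features stay exact for every cycle length (cycle length correlates with
#' identity, so normalizing per length group would confound the two).
#' A per-epoch history of training and
#' validation loss/accuracy is recorded; validation uses a held-out fraction
#' of the training cycles, stratified by subject.
#'
#' @param dataset A `gait_dataset` (the training split).
#' @param config A [model_config()]; defaults to the reference architecture
#'   with `classes = n_classes(dataset)`.
#' @param optimizer `"adam"` (default), `"sgd"` or `"rmsprop"`.
#' @param lr Learning rate; `NULL` uses the optimizer's default (Adam and
#'   RMSProp 1e-3, SGD 1e-2).
#' @param batch_size Maximum batch size (default 32).
#' @param epochs Training epochs (default 100).
#' @param validation_split Fraction of training cycles held out for the
#'   validation curve (default 0.1; 0 disables validation).
#' @details After the last epoch the batch-normalization running statistics
#'   are replaced by the exact activation statistics over the training
#'   cycles (one stat-only sweep), so inference is deterministic and does
#'   not depend on how well an exponential moving average happened to track
#'   the length-bucketed batches.
#' @param seed Integer seed controlling initialization, the validation split
#'   and batch shuffling; fixed seed gives an identical loss trajectory.
#' @param model Optionally a pre-built `gait_cnn` to continue training.
#' @param verbose Print per-epoch progress?
#' @return A `gait_cnn_fit`: list with `model` (trained `gait_cnn`),
#'   `history` (tibble `epoch`, `loss`, `accuracy`, `val_loss`,
#'   `val_accuracy`) and the training settings.
#' @export
fit_gait_cnn <- function(dataset, config = NULL, optimizer = "adam", lr = NULL,
                         batch_size = 32L, epochs = 100L,
                         validation_split = 0.1, seed = NULL,
                         model = NULL, verbose = FALSE) {
  stopifnot(inherits(dataset, "gait_dataset"), batch_size >= 1L, epochs >= 1L)
  if (!is.null(seed)) set.seed(seed)
  p <- n_classes(dataset)
  if (is.null(model)) {
    config <- config %||% model_config(classes = p)
    if (config$classes != p) abort("config$classes must equal n_classes(dataset).")
    model <- build_model(config)
  }
  opt <- make_optimizer(optimizer, lr)

  n <- nrow(dataset)
  val_idx <- integer()
  if (validation_split > 0 && n >= 10L) {
    by_lab <- split(seq_len(n), dataset$label)
    val_idx <- sort(unlist(lapply(by_lab, function(ii) {
      k <- max(1L, round(length(ii) * validation_split))
      if (length(ii) <= 1L) return(integer())
      sample(ii, min(k, length(ii) - 1L))
    }), use.names = FALSE))
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  tensors <- dataset$tensor
  labels <- dataset$label
  y_all <- one_hot(labels, p)
  nf <- dataset$nf

  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    steps <- make_mixed_batches(nf[tr_idx], batch_size, shuffle = TRUE)
    ep_loss <- 0
    ep_hit <- 0L
    for (st in steps) {
      ii <- tr_idx[unlist(st)]
      xs <- lapply(st, function(b) batch_array(tensors[tr_idx[b]]))
      yb <- y_all[ii, , drop = FALSE]
      fw <- net_forward(model, xs, training = TRUE)
      model$state <- fw$state
      ls <- xent_loss(fw$probs, yb)
      if (!is.finite(ls$loss)) {
        abort(sprintf("Non-finite loss at epoch %d (batch of %d); try a lower learning rate.",
                      ep, length(ii)))
      }
      grads <- net_backward(model, fw$caches, ls$dlogits)
      stp <- optimizer_step(opt, model$params, grads)
      opt <- stp$opt
      model$params <- stp$params
      ep_loss <- ep_loss + ls$loss * length(ii)
      ep_hit <- ep_hit + sum(max.col(fw$probs, ties.method = "first") == labels[ii] + 1L)
    }
    row <- list(epoch = ep,
                loss = ep_loss / length(tr_idx),
                accuracy = ep_hit / length(tr_idx),
                val_loss = NA_real_, val_accuracy = NA_real_)
    if (length(val_idx)) {
      vp <- predict(model, tensors[val_idx])
      vl <- xent_loss(vp, y_all[val_idx, , drop = FALSE])$loss
      row$val_loss <- vl
      row$val_accuracy <- mean(max.col(vp, ties.method = "first") == labels[val_idx] + 1L)
    }
    hist[[ep]] <- tibble::as_tibble(row)
    if (verbose) {
      inform(sprintf("epoch %3d  loss %.4f  acc %.3f  val_loss %s",
                     ep, row$loss, row$accuracy,
                     ifelse(is.na(row$val_loss), "-", sprintf("%.4f", row$val_loss))))
    }
  }
  # finalize batch-norm statistics exactly over the training cycles
  model <- recalibrate_bn_stats(model, tensors[tr_idx], nf[tr_idx], batch_size)
  structure(list(model = model,
                 history = dplyr::bind_rows(hist),
                 optimizer = opt$name, lr = opt$lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 validation_split = validation_split,
                 n_train = length(tr_idx), n_val = length(val_idx)),
            class = "gait_cnn_fit")
}

#' @export
predict.gait_cnn_fit <- function(object, tensors, type = c("prob", "class"), ...) {
  predict(object$model, tensors, type = match.arg(type), ...)
}

#' @export
print.gait_cnn_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<gait_cnn_fit: %s, %d epochs, batch %d; final loss %.4f, accuracy %.3f>\n",
              x$optimizer, x$epochs, x$batch_size, last$loss, last$accuracy))
  invisible(x)
}

#' @export
tidy.gait_cnn_fit <- function(x, ...) x$history

#' @export
glance.gait_cnn_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  pc <- count_params(x$model)
  tibble(optimizer = x$optimizer, lr = x$lr, batch_size = x$batch_size,
         epochs = x$epochs, loss = last$loss, accuracy = last$accuracy,
         val_loss = last$val_loss, val_accuracy = last$val_accuracy,
         trainable = pc$trainable, non_trainable = pc$non_trainable)
}
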
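#' Subject-wise k-fold plan over walking sequences
#'
#' Each subject contributes the same number of walking sequences (k of
#' them); fold `f` tests on every subject's `f`-th sequence (sequences
#' ordered lexicographically within subject) and trains on the rest. Every
#' sequence therefore appears in exactly one test fold, every fold's test
#' set covers all subjects, and no gait cycle is in both the train and test
#' side of any fold.
#'
#' @param dataset A `gait_dataset`.
#' @param k Number of folds (default 5).
#' @return Tibble of class `fold_plan`: columns `subject_id`, `sequence_id`,
#'   `fold` (the fold in which the sequence is tested).
#' @export
make_folds <- function(dataset, k = 5L) {
  stopifnot(inherits(dataset, "gait_dataset"), k >= 2L)
  seqs <- dplyr::distinct(as_tibble(dataset)[, c("subject_id", "sequence_id")])
  counts <- dplyr::count(seqs, .data$subject_id)
  bad <- counts[counts$n != k, ]
  if (nrow(bad)) {
    abort(paste0("Every subject must have exactly ", k, " sequences; offenders: ",
                 paste(sprintf("%s (%d)", bad$subject_id, bad$n), collapse = ", ")))
  }
  seqs <- dplyr::arrange(seqs, .data$subject_id, .data$sequence_id)
  seqs$fold <- stats::ave(seq_len(nrow(seqs)), seqs$subject_id,
                          FUN = seq_along)
  out <- as_tibble(seqs)
  class(out) <- c("fold_plan", class(out))
  out
}

subset_dataset <- function(dataset, rows) {
  out <- dataset[rows, ]
  attributes(out)[c("n_classes", "label_map", "schema")] <-
    attributes(dataset)[c("n_classes", "label_map", "schema")]
  class(out) <- class(dataset)
  out
}

#' Subject-wise cross-validated training and evaluation
#'
#' For each fold of [make_folds()], trains a fresh network on the training
#' sequences (the registration phase) and scores the held-out sequences with
#' frozen weights (the identification phase). Per-fold accuracy and macro
#' precision/recall/F-score are averaged across folds; the CMC curve and the
#' macro-averaged ROC (with nAUC and EER) are computed from the pooled test
#' scores, since every cycle is tested exactly once across the k folds.
#'
#' @inheritParams fit_gait_cnn
#' @param k Number of folds (default 5).
#' @param level Evaluation level, see [evaluate_model()].
#' @param verbose Print fold progress?
#' @return A `gait_cv` object: list with `folds` (per-fold metric tibble),
#'   `summary` (fold means), `cmc` (tibble), `roc` (`macro_roc`), `nauc`,
#'   `eer`, `history` (per-fold, per-epoch loss tibble), `scores`, `labels`.
#' @export
cross_validate <- function(dataset, config = NULL, k = 5L, optimizer = "adam",
                           lr = NULL, batch_size = 32L, epochs = 100L,
                           validation_split = 0.1, seed = NULL,
                           level = "cycle", verbose = FALSE) {
  plan <- make_folds(dataset, k)
  if (!is.null(seed)) set.seed(seed)
  fold_seeds <- sample.int(.Machine$integer.max, k)
  key <- paste(dataset$subject_id, dataset$sequence_id, sep = "\r")
  plan_key <- paste(plan$subject_id, plan$sequence_id, sep = "\r")
  n <- nrow(dataset)
  p <- n_classes(dataset)
  scores <- matrix(NA_real_, n, p)
  fold_rows <- vector("list", k)
  hists <- vector("list", k)
  evals <- vector("list", k)
  for (f in seq_len(k)) {
    test_keys <- plan_key[plan$fold == f]
    te <- which(key %in% test_keys)
    tr <- setdiff(seq_len(n), te)
    fit <- fit_gait_cnn(subset_dataset(dataset, tr), config = config,
                        optimizer = optimizer, lr = lr,
                        batch_size = batch_size, epochs = epochs,
                        validation_split = validation_split,
                        seed = fold_seeds[f])
    ev <- evaluate_model(fit, subset_dataset(dataset, te), level = level)
    evals[[f]] <- ev
    if (level == "cycle") scores[te, ] <- ev$scores
    fold_rows[[f]] <- dplyr::bind_cols(tibble(fold = f), ev$metrics,
                                       tibble(n_test = length(ev$labels)))
    hists[[f]] <- dplyr::bind_cols(tibble(fold = f), fit$history)
    if (verbose) {
      inform(sprintf("fold %d/%d: accuracy %.3f", f, k, ev$metrics$accuracy))
    }
  }
  if (level == "cycle") {
    pooled_scores <- scores
    pooled_labels <- dataset$label
  } else {
    pooled_scores <- do.call(rbind, lapply(evals, `[[`, "scores"))
    pooled_labels <- unlist(lapply(evals, `[[`, "labels"))
  }
  folds <- dplyr::bind_rows(fold_rows)
  summ <- dplyr::summarise(folds, dplyr::across(c("accuracy", "precision",
                                                  "recall", "f_score"), mean))
  roc <- roc_macro(pooled_scores, pooled_labels)
  structure(list(folds = folds, summary = summ,
                 cmc = cmc_curve(pooled_scores, pooled_labels),
                 roc = roc, nauc = roc$nauc, eer = roc$eer,
                 history = dplyr::bind_rows(hists),
                 scores = pooled_scores, labels = pooled_labels,
                 k = k, optimizer = optimizer, batch_size = batch_size,
                 epochs = epochs, level = level,
                 label_map = attr(dataset, "label_map")),
            class = "gait_cv")
}

#' @export
print.gait_cv <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<gait_cv: %d-fold, %s, batch %d, %d epochs>\n",
              x$k, x$optimizer, x$batch_size, x$epochs))
  cat(sprintf("  mean accuracy %.4f  precision %.4f  recall %.4f  F %.4f\n",
              s$accuracy, s$precision, s$recall, s$f_score))
  cat(sprintf("  rank-1 %.4f  nAUC %.4f  EER %.4f\n",
              x$cmc$cmc[1], x$nauc, x$eer))
  invisible(x)
}

#' Tidiers for cross-validation reports
#'
#' `tidy()` returns the per-fold metric table; `glance()` a one-row summary
#' with fold-averaged metrics, rank-1 identification rate, nAUC and EER.
#'
#' @param x A `gait_cv`.
#' @param ... Unused.
#' @export
tidy.gait_cv <- function(x, ...) x$folds

#' @rdname tidy.gait_cv
#' @export
glance.gait_cv <- function(x, ...) {
  dplyr::bind_cols(x$summary,
                   tibble(rank1 = x$cmc$cmc[1], nauc = x$nauc, eer = x$eer,
                          k = x$k, optimizer = x$optimizer,
                          batch_size = x$batch_size, epochs = x$epochs))
}

run_setting_table <- function(dataset, settings, runner, label_col, k, seed,
                              verbose = FALSE) {
  rows <- vector("list", length(settings))
  for (i in seq_along(settings)) {
    if (verbose) inform(paste0(label_col, " = ", settings[i]))
    cv <- runner(settings[i])
    rows[[i]] <- dplyr::bind_cols(tibble(!!label_col := settings[i]),
                                  cv$summary)
  }
  dplyr::bind_rows(rows)
}

#' Comparison harnesses: optimizer, batch size, pooling
#'
#' Re-run the full cross-validated experiment while varying one training
#' choice, and tabulate fold-averaged accuracy and macro
#' precision/recall/F-score per setting — the standard ablation tables for
#' this kind of biometric study. Values are dataset-dependent and are
#' reported, not asserted.
#'
#' @inheritParams cross_validate
#' @param optimizers,batch_sizes,poolings Settings to compare.
#' @return A tibble with one row per setting.
#' @export
compare_optimizers <- function(dataset, optimizers = c("adam", "sgd", "rmsprop"),
                               config = NULL, k = 5L, batch_size = 32L,
                               epochs = 100L, seed = NULL, verbose = FALSE, ...) {
  run_setting_table(dataset, optimizers, function(o) {
    cross_validate(dataset, config = config, k = k, optimizer = o,
                   batch_size = batch_size, epochs = epochs, seed = seed, ...)
  }, "optimizer", k, seed, verbose)
}

#' @rdname compare_optimizers
#' @export
compare_batch_sizes <- function(dataset, batch_sizes = c(32L, 64L, 128L),
                                config = NULL, k = 5L, optimizer = "adam",
                                epochs = 100L, seed = NULL, verbose = FALSE, ...) {
  run_setting_table(dataset, batch_sizes, function(b) {
    cross_validate(dataset, config = config, k = k, optimizer = optimizer,
                   batch_size = b, epochs = epochs, seed = seed, ...)
  }, "batch_size", k, seed, verbose)
}

#' @rdname compare_optimizers
#' @param classes Passed to [model_config()] when `config` is `NULL`.
#' @export
compare_pooling <- function(dataset, poolings = c("spp", "gmp", "gap"),
                            k = 5L, optimizer = "adam", batch_size = 32L,
                            epochs = 100L, seed = NULL, verbose = FALSE, ...) {
  run_setting_table(dataset, poolings, function(pl) {
    cfg <- model_config(classes = n_classes(dataset), pooling = pl)
    cross_validate(dataset, config = cfg, k = k, optimizer = optimizer,
                   batch_size = batch_size, epochs = epochs, seed = seed, ...)
  }, "pooling", k, seed, verbose)
}
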
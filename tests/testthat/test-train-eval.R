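test_that("fold plan: each subject's f-th sequence is tested exactly once", {
  walks <- simulate_population(4, sequences_per_subject = 5, duration = 6,
                               seed = 10)
  ds <- assemble_dataset(walks)
  plan <- make_folds(ds, 5)
  # every sequence appears in test exactly once across folds
  expect_equal(nrow(plan), 20L)
  expect_equal(anyDuplicated(plan[, c("subject_id", "sequence_id")]), 0L)
  # each fold's test set covers all subjects
  for (f in 1:5) {
    expect_setequal(plan$subject_id[plan$fold == f], unique(ds$subject_id))
  }
  # cycle-level partition: train and test are disjoint, union is everything
  key <- paste(ds$subject_id, ds$sequence_id)
  pk <- paste(plan$subject_id, plan$sequence_id)
  for (f in 1:5) {
    te <- which(key %in% pk[plan$fold == f])
    tr <- setdiff(seq_len(nrow(ds)), te)
    expect_length(intersect(te, tr), 0L)
    expect_setequal(c(te, tr), seq_len(nrow(ds)))
  }
  # minimal 2x2 case
  w2 <- simulate_population(2, sequences_per_subject = 2, duration = 6,
                            seed = 11)
  p2 <- make_folds(assemble_dataset(w2), 2)
  expect_equal(sort(unique(p2$fold)), 1:2)
  # unbalanced subjects are rejected with the offender named
  expect_error(make_folds(ds, 4), "S01")
})

test_that("evaluation metrics match hand-computed confusion-matrix values", {
  # toy 3-class score matrix with known prediction pattern
  scores <- rbind(c(0.7, 0.2, 0.1),   # true 0, pred 0
                  c(0.1, 0.8, 0.1),   # true 0, pred 1
                  c(0.2, 0.6, 0.2),   # true 1, pred 1
                  c(0.1, 0.3, 0.6),   # true 1, pred 2
                  c(0.2, 0.2, 0.6),   # true 2, pred 2
                  c(0.9, 0.05, 0.05)) # true 2, pred 0
  labels <- c(0L, 0L, 1L, 1L, 2L, 2L)
  m <- classification_metrics(scores, labels)
  expect_equal(m$accuracy, 0.5)
  # per class: precision = c(1/2, 1/2, 1/2), recall = c(1/2, 1/2, 1/2)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f_score, 0.5)

  # independent oracle via table() on another random matrix
  withr::local_seed(5)
  sc <- matrix(runif(40 * 4), 40, 4)
  lb <- sample(0:3, 40, replace = TRUE)
  got <- classification_metrics(sc, lb)
  pred <- max.col(sc, ties.method = "first") - 1L
  cm <- table(factor(pred, 0:3), factor(lb, 0:3))
  prec <- diag(cm) / pmax(rowSums(cm), 1)
  rec <- diag(cm) / pmax(colSums(cm), 1)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  expect_equal(got$accuracy, mean(pred == lb))
  expect_equal(got$precision, mean(prec))
  expect_equal(got$recall, mean(rec))
  expect_equal(got$f_score, mean(f1))

  # degenerate cases
  perfect <- one_hot(lb, 4)
  mp <- classification_metrics(perfect, lb)
  expect_equal(unlist(mp), c(accuracy = 1, precision = 1, recall = 1,
                             f_score = 1))
  onecls <- matrix(rep(c(1, 0), each = 10), 10, 2)
  mo <- classification_metrics(onecls, rep(0:1, 5))
  expect_equal(mo$accuracy, 0.5)
  expect_equal(mo$recall, 0.5)
})

test_that("CMC curve matches brute-force ranks and is monotone to 1", {
  # one rank-2 error among three samples
  scores <- rbind(c(0.6, 0.3, 0.1),
                  c(0.4, 0.5, 0.1),   # true 0 ranked 2nd
                  c(0.1, 0.2, 0.7))
  labels <- c(0L, 0L, 2L)
  cmc <- cmc_curve(scores, labels)
  expect_equal(cmc$cmc, c(2 / 3, 1, 1))
  # perfect classifier: all ones
  expect_equal(cmc_curve(one_hot(labels, 3), labels)$cmc, rep(1, 3))
  # random scores: monotone, ends at 1, rank-1 equals accuracy
  withr::local_seed(8)
  sc <- matrix(runif(60 * 5), 60, 5)
  lb <- sample(0:4, 60, replace = TRUE)
  cm <- cmc_curve(sc, lb)
  expect_true(all(diff(cm$cmc) >= 0))
  expect_equal(cm$cmc[5], 1)
  expect_equal(cm$cmc[1], classification_metrics(sc, lb)$accuracy)
})

test_that("macro ROC nAUC matches threshold-sweep and pROC oracles", {
  withr::local_seed(17)
  sc <- matrix(runif(80 * 3), 80, 3)
  sc <- sc / rowSums(sc)
  lb <- sample(0:2, 80, replace = TRUE)
  roc <- roc_macro(sc, lb)
  expect_equal(roc$nauc, oracle_macro_auc(sc, lb), tolerance = 2e-3)
  expect_true(roc$nauc >= 0 && roc$nauc <= 1)
  expect_true(roc$eer >= 0 && roc$eer <= 1)

  # binary cross-check against pROC on each one-vs-rest problem
  skip_if_not_installed("pROC")
  aucs <- vapply(0:2, function(cl) {
    as.numeric(pROC::auc(pROC::roc(lb == cl, sc[, cl + 1], quiet = TRUE,
                                   direction = "<")))
  }, numeric(1))
  expect_equal(roc$nauc, mean(aucs), tolerance = 2e-3)

  # perfectly separating scores
  perf <- roc_macro(one_hot(lb, 3) + matrix(runif(240), 80) * 0.1, lb)
  expect_equal(perf$nauc, 1, tolerance = 1e-6)
  expect_equal(perf$eer, 0, tolerance = 1e-6)

  # uninformative scores: diagonal curve
  flat <- roc_macro(matrix(1 / 3, 80, 3), lb)
  expect_equal(flat$nauc, 0.5, tolerance = 1e-6)
  expect_equal(flat$eer, 0.5, tolerance = 1e-6)

  # a class absent from the labels is excluded with a warning
  expect_warning(r2 <- roc_macro(sc, pmin(lb, 1L)), "absent")
  expect_equal(r2$n_classes, 2L)
})

test_that("EER interpolates the FPR = 1 - TPR crossing on a toy curve", {
  curve <- tibble::tibble(fpr = c(0, 0.2, 1), tpr = c(0, 0.9, 1))
  # independent oracle: dense sampling of the polyline
  want <- oracle_eer(curve$fpr, curve$tpr)
  expect_equal(eer(curve), want, tolerance = 1e-4)
  expect_equal(eer(curve), 2 / 11, tolerance = 1e-10)  # closed form 0.1818...
  # endpoints
  expect_equal(eer(tibble::tibble(fpr = c(0, 1), tpr = c(1, 1))), 0)
  expect_equal(eer(tibble::tibble(fpr = c(0, 1), tpr = c(0, 1))), 0.5)
})

test_that("training on two well-separated subjects reaches perfect accuracy", {
  walks <- simulate_population(2, sequences_per_subject = 2, duration = 8,
                               separation = 2, seed = 3)
  ds <- assemble_dataset(walks)
  fit <- fit_gait_cnn(ds, config = tiny_config(2), epochs = 30, seed = 5,
                      validation_split = 0)
  expect_equal(max(fit$history$accuracy), 1)
  # loss decreased substantially from the first epoch
  expect_lt(tail(fit$history$loss, 1), fit$history$loss[1] / 2)
})

test_that("training is deterministic under a fixed seed", {
  walks <- simulate_population(2, sequences_per_subject = 2, duration = 6,
                               seed = 19)
  ds <- assemble_dataset(walks)
  f1 <- fit_gait_cnn(ds, config = tiny_config(2), epochs = 3, seed = 77)
  f2 <- fit_gait_cnn(ds, config = tiny_config(2), epochs = 3, seed = 77)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("compute batches are homogeneous in Nf and capped at batch_size", {
  nf <- c(rep(30L, 10), rep(31L, 5), rep(33L, 70))
  withr::local_seed(2)
  batches <- skelgait:::make_batches(nf, batch_size = 32)
  for (b in batches) {
    expect_length(unique(nf[b]), 1L)
    expect_lte(length(b), 32L)
  }
  expect_setequal(unlist(batches), seq_along(nf))
  # mixed optimization steps: every compute group is still single-Nf and a
  # step never exceeds batch_size samples in total
  steps <- skelgait:::make_mixed_batches(nf, batch_size = 32)
  for (st in steps) {
    expect_lte(length(unlist(st)), 32L)
    for (g in st) expect_length(unique(nf[g]), 1L)
  }
  expect_setequal(unlist(steps), seq_along(nf))
})

test_that("evaluate_model reports cycle metrics and optional sequence voting", {
  walks <- simulate_population(2, sequences_per_subject = 2, duration = 6,
                               seed = 23)
  ds <- assemble_dataset(walks)
  fit <- fit_gait_cnn(ds, config = tiny_config(2), epochs = 2, seed = 1,
                      validation_split = 0)
  ev <- evaluate_model(fit, ds)
  expect_equal(nrow(ev$scores), nrow(ds))
  expect_equal(ev$metrics$accuracy,
               mean(max.col(ev$scores) - 1L == ds$label))
  evs <- evaluate_model(fit, ds, level = "sequence")
  expect_equal(nrow(evs$scores), 4L)  # 2 subjects x 2 sequences
  expect_error(evaluate_model(fit, skelgait:::subset_dataset(ds, integer())),
               "empty")
})
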
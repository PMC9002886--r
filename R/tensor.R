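#' Build the 3D input tensor for one gait cycle
#'
#' Each gait cycle is converted to a rank-3 numeric array of shape
#' `(Nf, Nb, 3)`: frames of the cycle by body joints by (x, y, z). The copy
#' is exact — no resampling, interpolation or normalization — so cycles of
#' different lengths yield tensors with different first dimensions; the
#' network downstream accepts that variability directly. Optionally the
#' per-frame hip-center position can be subtracted to remove global
#' translation, which is off by default (raw coordinates are the canonical
#' input representation).
#'
#' @param seq A [skeleton_sequence].
#' @param cycle A one-row data frame with `start_frame`/`end_frame` (as
#'   produced by [segment_cycles()]) or a numeric `c(start, end)`.
#' @param center_hip Subtract the per-frame position of the first schema
#'   joint (the hip center on the Kinect skeleton)? Default `FALSE`.
#' @return A `gait_tensor`: numeric array `(Nf, Nb, 3)` with attributes
#'   `subject_id`, `sequence_id`, `start_frame`.
#' @examples
#' seq <- synthesize_sequence(sample_population(2, seed = 1)[1, ],
#'                            duration = 5, seed = 1)
#' cyc <- segment_cycles(seq)
#' dim(build_tensor(seq, cyc[1, ]))
#' @export
build_tensor <- function(seq, cycle, center_hip = FALSE) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  if (is.data.frame(cycle)) {
    stopifnot(nrow(cycle) == 1L)
    s <- cycle$start_frame
    e <- cycle$end_frame
  } else {
    s <- cycle[1L]
    e <- cycle[2L]
  }
  fr <- frame_index(seq)
  pos <- which(fr >= s & fr <= e)
  if (!length(pos) || !(s %in% fr) || !(e %in% fr)) {
    abort(sprintf("Cycle [%s, %s] is out of the sequence's frame range [%s, %s].",
                  s, e, min(fr), max(fr)))
  }
  a <- seq_array(seq)[pos, , , drop = FALSE]
  if (isTRUE(center_hip)) {
    a <- a - a[, rep(1L, dim(a)[2L]), , drop = FALSE]
  }
  structure(a,
            subject_id = attr(seq, "subject_id"),
            sequence_id = attr(seq, "sequence_id"),
            start_frame = as.integer(s),
            class = "gait_tensor")
}

#' One-hot encode class labels
#'
#' @param labels Integer vector of 0-based class indices.
#' @param n_classes Number of classes `P`.
#' @return A binary matrix of shape `length(labels) x P`; each row a unit
#'   vector.
#' @examples
#' one_hot(c(2L, 0L), 4)
#' @export
one_hot <- function(labels, n_classes) {
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 0L) || any(labels >= n_classes)) {
    abort(sprintf("Labels must lie in [0, %d).", n_classes))
  }
  m <- matrix(0, length(labels), n_classes)
  m[cbind(seq_along(labels), labels + 1L)] <- 1
  m
}

#' Assemble a labeled gait-cycle dataset
#'
#' Runs [segment_cycles()] over every sequence, converts each detected cycle
#' with [build_tensor()], and assigns integer class labels `0..P-1` by
#' lexicographic subject-id order (deterministic across reruns). Sequences in
#' which no complete cycle is found are skipped with a warning.
#'
#' @param sequences List of [skeleton_sequence] objects.
#' @param ... Segmentation parameters passed to [segment_cycles()].
#' @param center_hip Passed to [build_tensor()].
#' @return A tibble of class `gait_dataset` with one row per cycle: columns
#'   `subject_id`, `sequence_id`, `start_frame`, `end_frame`, `nf`, `label`
#'   (0-based integer) and `tensor` (list column of `gait_tensor` arrays).
#'   Attributes: `n_classes` (`P`), `label_map` (tibble `subject_id`,
#'   `label`), `schema`.
#' @export
assemble_dataset <- function(sequences, ..., center_hip = FALSE) {
  stopifnot(length(sequences) > 0L)
  rows <- purrr::map(sequences, function(s) {
    cyc <- suppressWarnings(segment_cycles(s, ...))
    if (nrow(cyc) == 0L) {
      warn(sprintf("Sequence %s/%s yielded no cycles; skipped.",
                   attr(s, "subject_id"), attr(s, "sequence_id")))
      return(NULL)
    }
    cyc$tensor <- purrr::map(seq_len(nrow(cyc)),
                             function(i) build_tensor(s, cyc[i, ], center_hip = center_hip))
    cyc
  })
  out <- dplyr::bind_rows(rows)
  if (is.null(out) || nrow(out) == 0L) {
    abort("No usable gait cycles were found in any sequence.")
  }
  subjects <- sort(unique(out$subject_id))
  label_map <- tibble(subject_id = subjects,
                      label = seq_along(subjects) - 1L)
  out$label <- label_map$label[match(out$subject_id, label_map$subject_id)]
  out <- out[, c("subject_id", "sequence_id", "start_frame", "end_frame",
                 "nf", "label", "tensor")]
  structure(out,
            class = c("gait_dataset", class(tibble())),
            n_classes = nrow(label_map),
            label_map = label_map,
            schema = attr(sequences[[1L]], "schema"))
}

#' @export
print.gait_dataset <- function(x, ...) {
  cat(sprintf("<gait_dataset: %d cycles, %d subjects, Nf in [%d, %d]>\n",
              nrow(x), attr(x, "n_classes"), min(x$nf), max(x$nf)))
  NextMethod()
}

#' Dataset accessors
#'
#' @param dataset A `gait_dataset`.
#' @return `n_classes()` the number of subjects `P`; `label_matrix()` the
#'   `N x P` one-hot label matrix.
#' @export
n_classes <- function(dataset) attr(dataset, "n_classes")

#' @rdname n_classes
#' @export
label_matrix <- function(dataset) one_hot(dataset$label, n_classes(dataset))
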
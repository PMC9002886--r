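#' Skeleton sequences
#'
#' A skeleton sequence is one walking recording of one subject: an ordered set
#' of frames, each holding the (x, y, z) position in meters of every joint in
#' a [joint_schema]. It is stored as a tidy tibble with one row per
#' (frame, joint) pair and columns `frame`, `joint`, `x`, `y`, `z`, carrying
#' the subject id, sequence id, frame rate and schema as attributes.
#'
#' @param data Data frame with columns `frame` (integer), `joint` (name or
#'   1-based index into the schema), `x`, `y`, `z` (meters).
#' @param subject_id,sequence_id Identifier strings.
#' @param fps Frames per second of the recording (Kinect streams at 30).
#' @param schema A [joint_schema]; defaults to the 20-joint Kinect skeleton.
#' @return A tibble of class `skeleton_sequence`.
#' @examples
#' frames <- expand.grid(frame = 0:1, joint = 1:20)
#' frames$x <- 0; frames$y <- 1; frames$z <- frames$frame * 0.04
#' seq <- skeleton_sequence(frames, "S01", "walk1")
#' n_frames(seq)
#' @export
skeleton_sequence <- function(data, subject_id, sequence_id, fps = 30,
                              schema = kinect20_schema()) {
  stopifnot(inherits(schema, "joint_schema"))
  data <- as_tibble(data)
  req <- c("frame", "joint", "x", "y", "z")
  miss <- setdiff(req, names(data))
  if (length(miss)) {
    abort(paste0("skeleton data is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (is.character(data$joint) || is.factor(data$joint)) {
    idx <- match(as.character(data$joint), schema$names)
    if (anyNA(idx)) {
      bad <- unique(as.character(data$joint)[is.na(idx)])
      abort(paste0("Unknown joint name(s): ", paste(bad, collapse = ", ")))
    }
    data$joint <- idx
  }
  data$frame <- as.integer(data$frame)
  data$joint <- as.integer(data$joint)
  for (cc in c("x", "y", "z")) data[[cc]] <- as.numeric(data[[cc]])
  data <- dplyr::arrange(data, .data$frame, .data$joint)
  validate_skeleton(data, schema)
  structure(
    data[req],
    class = c("skeleton_sequence", class(tibble())),
    subject_id = as.character(subject_id),
    sequence_id = as.character(sequence_id),
    fps = as.numeric(fps),
    schema = schema
  )
}

validate_skeleton <- function(data, schema) {
  nb <- schema$n_joints
  if (nrow(data) == 0L) return(invisible(TRUE))
  if (!all(is.finite(data$x) & is.finite(data$y) & is.finite(data$z))) {
    abort("All joint coordinates must be finite (no NA/NaN/Inf).")
  }
  if (any(data$frame < 0L)) abort("Frame indices must be >= 0.")
  counts <- table(data$frame)
  if (any(counts != nb)) {
    bad <- names(counts)[counts != nb][1L]
    abort(sprintf("Frame %s has %d joint rows; schema requires exactly %d.",
                  bad, counts[[bad]], nb))
  }
  per <- split(data$joint, data$frame)
  ok <- vapply(per, function(j) identical(sort(j), seq_len(nb)), logical(1))
  if (!all(ok)) {
    abort(sprintf("Frame %s does not contain each joint exactly once.",
                  names(per)[!ok][1L]))
  }
  invisible(TRUE)
}

#' Sequence accessors
#'
#' @param seq A [skeleton_sequence].
#' @return `n_frames()` the number of frames; `frame_index()` the sorted
#'   vector of frame numbers; `seq_array()` a numeric array of shape
#'   `(n_frames, Nb, 3)` with coordinate order (x, y, z).
#' @export
n_frames <- function(seq) length(unique(seq$frame))

#' @rdname n_frames
#' @export
frame_index <- function(seq) sort(unique(seq$frame))

#' @rdname n_frames
#' @export
seq_array <- function(seq) {
  sch <- attr(seq, "schema")
  fr <- frame_index(seq)
  nf <- length(fr)
  nb <- sch$n_joints
  a <- array(NA_real_, c(nf, nb, 3L),
             dimnames = list(NULL, sch$names, c("x", "y", "z")))
  # rows are sorted by (frame, joint), so a straight fill works
  a[, , 1L] <- matrix(seq$x, nf, nb, byrow = TRUE)
  a[, , 2L] <- matrix(seq$y, nf, nb, byrow = TRUE)
  a[, , 3L] <- matrix(seq$z, nf, nb, byrow = TRUE)
  a
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat(sprintf("<skeleton_sequence %s/%s: %d frames x %d joints @ %g fps>\n",
              attr(x, "subject_id"), attr(x, "sequence_id"),
              n_frames(x), attr(x, "schema")$n_joints, attr(x, "fps")))
  NextMethod()
}

seq_meta <- function(seq) {
  list(subject_id = attr(seq, "subject_id"),
       sequence_id = attr(seq, "sequence_id"),
       fps = attr(seq, "fps"),
       schema = attr(seq, "schema"))
}
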
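#' Segment gait cycles from a skeleton sequence
#'
#' One gait cycle (two successive steps) spans three consecutive local maxima
#' of the denoised inter-ankle distance signal, because the ankles reach
#' maximum separation twice per cycle. The pipeline is: inter-ankle distance
#' -> moving average -> median filter -> local maxima -> pair maxima into
#' cycles. In the default `"triplet"` mode maxima `m1, m2, ..., mk` yield the
#' non-overlapping cycles `(m1, m3), (m3, m5), ...` that share only their
#' boundary frame; `"sliding"` mode instead extracts every consecutive triple
#' `(m1, m3), (m2, m4), ...`, trading independence for more training samples.
#' Trailing maxima that do not complete a triple are discarded, as are cycles
#' shorter than `min_cycle_len` frames.
#'
#' @param seq A [skeleton_sequence].
#' @param ma_window,median_window Odd smoothing windows in frames (default 5).
#' @param min_separation Minimum frames between detected maxima (default 10,
#'   about a third of a second at 30 fps, below any plausible step interval).
#' @param min_cycle_len Minimum cycle length in frames (default 10); shorter
#'   detections are reported with a warning and dropped.
#' @param overlap `"triplet"` (default) or `"sliding"`; see Details.
#' @return A tibble of class `gait_cycles` with columns `subject_id`,
#'   `sequence_id`, `start_frame`, `end_frame` (inclusive) and `nf`
#'   (`end - start + 1`, the cycle length in frames). Zero rows (with a
#'   warning) when fewer than three maxima are found.
#' @examples
#' seq <- synthesize_sequence(sample_population(2, seed = 1)[1, ],
#'                            duration = 10, seed = 1)
#' segment_cycles(seq)
#' @export
segment_cycles <- function(seq, ma_window = 5L, median_window = 5L,
                           min_separation = 10L, min_cycle_len = 10L,
                           overlap = c("triplet", "sliding")) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  overlap <- match.arg(overlap)
  if (n_frames(seq) == 0L) abort("Cannot segment an empty sequence.")
  sig <- ankle_distance(seq)
  sm <- median_filter(moving_average(sig$value, ma_window), median_window)
  pk <- local_maxima(sm, min_separation)
  meta <- seq_meta(seq)
  empty <- tibble(subject_id = character(), sequence_id = character(),
                  start_frame = integer(), end_frame = integer(), nf = integer())
  if (length(pk) < 3L) {
    warn(sprintf("Sequence %s/%s: only %d maxima found; no complete gait cycle.",
                 meta$subject_id, meta$sequence_id, length(pk)))
    return(structure(empty, class = c("gait_cycles", class(empty))))
  }
  if (overlap == "triplet") {
    starts <- seq(1L, length(pk) - 2L, by = 2L)
  } else {
    starts <- seq_len(length(pk) - 2L)
  }
  s <- pk[starts]
  e <- pk[starts + 2L]
  frames <- sig$frame
  out <- tibble(subject_id = meta$subject_id, sequence_id = meta$sequence_id,
                start_frame = frames[s], end_frame = frames[e],
                nf = e - s + 1L)
  short <- out$nf < min_cycle_len
  if (any(short)) {
    warn(sprintf("Sequence %s/%s: dropped %d cycle(s) shorter than %d frames.",
                 meta$subject_id, meta$sequence_id, sum(short), min_cycle_len))
    out <- out[!short, ]
  }
  structure(out, class = c("gait_cycles", class(empty)))
}
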
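#' Inter-ankle distance signal
#'
#' The inter-ankle Euclidean distance traces a periodic signal over a walking
#' recording: it peaks twice per gait cycle (once per step, at maximum leg
#' separation) and dips as the feet pass each other. Because it is a distance
#' it is invariant to any rigid rotation or translation of the skeleton,
#' which makes it a robust segmentation signal regardless of walking
#' direction relative to the sensor.
#'
#' @param seq A [skeleton_sequence] whose schema declares both ankles.
#' @return A tibble with columns `frame` and `value` (meters), one row per
#'   frame; zero rows for an empty sequence.
#' @export
ankle_distance <- function(seq) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  sch <- attr(seq, "schema")
  if (n_frames(seq) == 0L) return(tibble(frame = integer(), value = double()))
  a <- seq_array(seq)
  d <- a[, sch$left_ankle, , drop = FALSE] - a[, sch$right_ankle, , drop = FALSE]
  tibble(frame = frame_index(seq), value = sqrt(rowSums(matrix(d, nrow = dim(a)[1]) ^ 2)))
}

check_window <- function(window) {
  if (length(window) != 1L || is.na(window) || window < 1 || window %% 2 == 0) {
    abort("`window` must be a positive odd integer.")
  }
  as.integer(window)
}

pad_replicate <- function(x, h) {
  if (h == 0L || length(x) == 0L) return(x)
  c(rep(x[1L], h), x, rep(x[length(x)], h))
}

#' Signal smoothing filters
#'
#' Centered moving-average and running-median filters with replicate padding
#' at the boundaries (the first/last sample is repeated so the output has the
#' input's length). Denoising the ankle-distance trace with a moving average
#' followed by a median filter suppresses sensor jitter before peak picking.
#'
#' @param x Numeric vector (a per-frame signal).
#' @param window Odd positive integer window width; `1` is the identity.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' moving_average(c(0, 3, 0, 3, 0), 3)  # 1 1 2 1 1
#' median_filter(c(1, 9, 1), 3)         # 1 1 1
#' @export
moving_average <- function(x, window) {
  w <- check_window(window)
  n <- length(x)
  if (w == 1L || n == 0L) return(as.numeric(x))
  h <- (w - 1L) %/% 2L
  xp <- pad_replicate(as.numeric(x), h)
  cs <- cumsum(c(0, xp))
  (cs[(w + 1L):(n + w)] - cs[1:n]) / w
}

#' @rdname moving_average
#' @export
median_filter <- function(x, window) {
  w <- check_window(window)
  n <- length(x)
  if (w == 1L || n == 0L) return(as.numeric(x))
  h <- (w - 1L) %/% 2L
  xp <- pad_replicate(as.numeric(x), h)
  vapply(seq_len(n), function(i) stats::median(xp[i:(i + w - 1L)]), numeric(1))
}

#' Local maxima of a signal
#'
#' A position `i` is a local maximum when the signal strictly rises into it
#' (`x[i-1] < x[i]`) and does not rise out of it (`x[i] >= x[i+1]`); for a
#' flat-topped peak this reports the first plateau position. Endpoints are
#' never maxima. Maxima closer than `min_separation` positions apart are
#' pruned greedily, keeping the larger value (earlier position on ties).
#'
#' @param x Numeric vector.
#' @param min_separation Minimum spacing, in positions, between reported
#'   maxima (`>= 1`; `1` disables pruning).
#' @return Integer vector of 1-based positions, increasing; possibly empty.
#' @examples
#' local_maxima(c(0, 1, 0, 2, 0, 3, 0))  # 2 4 6
#' local_maxima(c(0, 2, 2, 0))           # 2 (plateau start)
#' @export
local_maxima <- function(x, min_separation = 1L) {
  if (length(min_separation) != 1L || is.na(min_separation) || min_separation < 1) {
    abort("`min_separation` must be a positive integer.")
  }
  n <- length(x)
  if (n < 3L) return(integer())
  i <- 2:(n - 1L)
  cand <- i[x[i - 1L] < x[i] & x[i] >= x[i + 1L]]
  if (length(cand) <= 1L || min_separation == 1L) return(cand)
  # greedy non-maximum suppression: strongest first, earlier position on ties
  ord <- cand[order(-x[cand], cand)]
  kept <- integer()
  for (p in ord) {
    if (!length(kept) || all(abs(kept - p) >= min_separation)) kept <- c(kept, p)
  }
  sort(kept)
}
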
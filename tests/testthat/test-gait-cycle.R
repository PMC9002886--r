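test_that("ankle distance is the per-frame Euclidean norm between ankles", {
  seq <- make_toy_sequence(3)
  df <- as.data.frame(seq)
  # plant a 3-4-5 triangle at frame 0 and identical ankles at frame 1
  df[df$frame == 0 & df$joint == 15, c("x", "y", "z")] <- c(0, 0, 0)
  df[df$frame == 0 & df$joint == 19, c("x", "y", "z")] <- c(0.3, 0, 0.4)
  df[df$frame == 1 & df$joint == 15, c("x", "y", "z")] <- c(1, 2, 3)
  df[df$frame == 1 & df$joint == 19, c("x", "y", "z")] <- c(1, 2, 3)
  seq <- skeleton_sequence(df, "s", "q")
  sig <- ankle_distance(seq)
  expect_equal(sig$value[1], 0.5)
  expect_equal(sig$value[2], 0)
  expect_true(all(sig$value >= 0))

  empty <- skeleton_sequence(df[0, ], "s", "q")
  expect_equal(nrow(ankle_distance(empty)), 0L)
})

test_that("ankle distance and segmentation are rigid-motion invariant", {
  prof <- sample_population(2, seed = 5)[1, ]
  seq <- synthesize_sequence(prof, duration = 6, seed = 9)
  rot <- fixed_rotation()
  moved <- apply_rigid(seq, rot)
  expect_equal(ankle_distance(moved)$value, ankle_distance(seq)$value,
               tolerance = 1e-12)
  expect_equal(as.data.frame(segment_cycles(moved)),
               as.data.frame(segment_cycles(seq)))
})

test_that("moving average uses replicate padding and is length-preserving", {
  expect_equal(moving_average(c(0, 3, 0, 3, 0), 3), c(1, 1, 2, 1, 1))
  x <- rep(2.5, 10)
  expect_equal(moving_average(x, 5), x)           # constant is a fixed point
  y <- rnorm(20)
  expect_equal(moving_average(y, 1), y)           # window 1 is the identity
  expect_length(moving_average(y, 7), 20)
  expect_error(moving_average(y, 4), "odd")
  expect_error(moving_average(y, -3), "odd")
})

test_that("median filter removes single outliers and preserves monotone signals", {
  expect_equal(median_filter(c(1, 9, 1), 3), c(1, 1, 1))
  x <- rep(7, 8)
  expect_equal(median_filter(x, 3), x)
  mono <- cumsum(runif(15))
  expect_equal(median_filter(mono, 3), mono)      # sorted windows keep order
  expect_equal(median_filter(mono, 1), mono)
  expect_error(median_filter(mono, 2), "odd")
})

test_that("local maxima follow the strict-rise / plateau-start rule", {
  expect_equal(local_maxima(c(0, 1, 0, 2, 0, 3, 0)), c(2L, 4L, 6L))
  expect_equal(local_maxima(c(0, 2, 2, 0)), 2L)        # plateau start
  expect_equal(local_maxima(c(0, 1, 2, 3)), integer()) # monotone: none
  expect_equal(local_maxima(numeric()), integer())
  # endpoints are never maxima
  expect_equal(local_maxima(c(5, 1, 2, 1, 9)), 3L)
  # pruning keeps the larger of two close peaks
  x <- c(0, 5, 0, 7, 0, 0, 0, 0, 0, 0, 0, 4, 0)
  expect_equal(local_maxima(x, min_separation = 4), c(4L, 12L))
  expect_error(local_maxima(x, 0), "positive")
})

test_that("maxima pairing yields non-overlapping boundary-sharing cycles", {
  # synthetic signal with maxima at known positions: bumps at 5,20,34,50,66
  pk <- c(5, 20, 34, 50, 66)
  x <- numeric(75)
  x[pk] <- 10
  x[pk - 1] <- 5
  x[pk + 1] <- 5  # sharp triangular bumps, maxima exactly at pk
  seqlen <- length(x)
  # drive segment_cycles through a crafted sequence whose ankle distance is x
  nb <- 20L
  dat <- expand.grid(joint = seq_len(nb), frame = seq_len(seqlen) - 1L)[, 2:1]
  dat$x <- 0; dat$y <- 0; dat$z <- 0
  dat$x[dat$joint == 15] <- x[dat$frame[dat$joint == 15] + 1]
  seq <- skeleton_sequence(dat, "s", "q")
  cyc <- segment_cycles(seq, ma_window = 1, median_window = 1,
                        min_separation = 5)
  expect_equal(cyc$start_frame, c(5, 34) - 1L)
  expect_equal(cyc$end_frame, c(34, 66) - 1L)
  # sliding mode: every consecutive triple
  cyc2 <- segment_cycles(seq, ma_window = 1, median_window = 1,
                         min_separation = 5, overlap = "sliding")
  expect_equal(nrow(cyc2), 3L)
  expect_equal(cyc2$start_frame, c(5, 20, 34) - 1L)

  # four maxima: trailing pair discarded
  x4 <- numeric(40)
  x4[c(3, 11, 19, 27)] <- 10
  x4[c(3, 11, 19, 27) - 1] <- 5
  x4[c(3, 11, 19, 27) + 1] <- 5
  dat$x[dat$joint == 15] <- 0
  dat <- dat[dat$frame < 40, ]
  dat$x[dat$joint == 15] <- x4[dat$frame[dat$joint == 15] + 1]
  seq4 <- skeleton_sequence(dat, "s", "q")
  cyc4 <- segment_cycles(seq4, ma_window = 1, median_window = 1,
                         min_separation = 5)
  expect_equal(nrow(cyc4), 1L)
  expect_equal(c(cyc4$start_frame, cyc4$end_frame), c(2, 18))
})

test_that("fewer than three maxima gives an empty result with a warning", {
  seq <- make_toy_sequence(6)
  expect_warning(cyc <- segment_cycles(seq), "maxima")
  expect_equal(nrow(cyc), 0L)
})

test_that("noiseless periodic walker: cycle count and Nf match the period", {
  prof <- sample_population(2, seed = 3)[1, ]
  prof$stride_freq <- 1.0
  seq <- synthesize_sequence(prof, duration = 10, fps = 30, seed = 4,
                             noise_sd = 0)
  sig <- ankle_distance(seq)$value
  # exact periodicity with period fps / stride_freq = 30 frames
  expect_equal(sig[1:270], sig[31:300], tolerance = 1e-10)
  cyc <- segment_cycles(seq)
  expect_gte(nrow(cyc), 9)
  expect_lte(nrow(cyc), 10)
  expect_true(all(abs(cyc$nf - 30) <= 1))
  # cycles share exactly their boundary frame and never otherwise overlap
  expect_true(all(diff(cyc$start_frame) > 0))
  expect_equal(cyc$start_frame[-1], cyc$end_frame[-nrow(cyc)])
})

test_that("detected cycle length tracks the stride period across subjects", {
  pop <- sample_population(4, seed = 21)
  for (i in seq_len(4)) {
    seq <- synthesize_sequence(pop[i, ], duration = 8, seed = 100 + i,
                               noise_sd = 0)
    cyc <- segment_cycles(seq)
    period <- 30 / pop$stride_freq[i]
    # a cycle spans one period of maxima; nf counts both boundary frames
    expect_true(all(abs(cyc$nf - (period + 1)) <= 1),
                label = sprintf("subject %d: Nf near %.1f", i, period + 1))
  }
})
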
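test_that("sequences are constructed and validated against the schema", {
  seq <- make_toy_sequence(2)
  expect_s3_class(seq, "skeleton_sequence")
  expect_equal(n_frames(seq), 2L)
  expect_equal(attr(seq, "schema")$n_joints, 20L)

  a <- seq_array(seq)
  expect_equal(dim(a), c(2L, 20L, 3L))
  df <- as.data.frame(seq)
  expect_equal(a[2, 7, 1], df$x[df$frame == 1 & df$joint == 7])

  # missing a joint in one frame
  bad <- as.data.frame(seq)[-5, ]
  expect_error(skeleton_sequence(bad, "s", "q"), "exactly 20")
  # non-finite coordinate
  bad2 <- as.data.frame(seq)
  bad2$x[3] <- NaN
  expect_error(skeleton_sequence(bad2, "s", "q"), "finite")
  # duplicated joint within a frame
  bad3 <- as.data.frame(seq)
  bad3$joint[2] <- 1L
  expect_error(skeleton_sequence(bad3, "s", "q"), "exactly once")
})

test_that("canonical CSV round-trips sequences bit-exactly", {
  withr::local_seed(7)
  for (rep in 1:5) {
    nf <- sample(1:6, 1)
    dat <- expand.grid(joint = 1:20, frame = seq_len(nf) - 1L)[, 2:1]
    dat$x <- rnorm(nrow(dat))
    dat$y <- rnorm(nrow(dat))
    dat$z <- rnorm(nrow(dat)) * 1e-7   # exercise small magnitudes
    seq <- skeleton_sequence(dat, paste0("subj", rep), "walkA", fps = 30)
    f <- withr::local_tempfile(fileext = ".csv")
    write_skeleton_csv(seq, f)
    back <- read_skeleton_csv(f)
    expect_identical(as.data.frame(back), as.data.frame(seq))
    expect_identical(attr(back, "subject_id"), attr(seq, "subject_id"))
    expect_identical(attr(back, "sequence_id"), attr(seq, "sequence_id"))
    expect_identical(attr(back, "fps"), attr(seq, "fps"))
  }
})

test_that("an empty sequence writes a header-only file and reads back empty", {
  seq <- skeleton_sequence(
    data.frame(frame = integer(), joint = integer(),
               x = double(), y = double(), z = double()),
    "s", "q")
  f <- withr::local_tempfile(fileext = ".csv")
  write_skeleton_csv(seq, f)
  expect_length(grep("^[^#]", readLines(f)), 1L)  # only the column header
  expect_equal(n_frames(read_skeleton_csv(f)), 0L)
})

test_that("a one-frame sequence writes exactly Nb data rows", {
  seq <- make_toy_sequence(1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_skeleton_csv(seq, f)
  expect_length(grep("^[^#]", readLines(f)), 21L)  # header + 20 joints
})

test_that("parse errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".csv")
  seq <- make_toy_sequence(2)
  write_skeleton_csv(seq, f)
  lines <- readLines(f)
  lines[10] <- sub(",[^,]*$", ",oops", lines[10])
  writeLines(lines, f)
  expect_error(read_skeleton_csv(f), "line 10")

  writeLines(c("frame,joint,x,y,z", "0,HipCenter,1,2"), f)
  expect_error(read_skeleton_csv(f), "expected 5 fields")

  # wrong joint count: 19 rows for a frame
  write_skeleton_csv(seq, f)
  writeLines(readLines(f)[-6], f)
  expect_error(read_skeleton_csv(f), "requires exactly 20")

  expect_error(read_skeleton_csv(tempfile()), "not found")
})

test_that("NaN and Inf coordinates are rejected at parse time", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_skeleton_csv(make_toy_sequence(1), f)
  lines <- readLines(f)
  lines[6] <- sub(",[^,]*$", ",Inf", lines[6])
  writeLines(lines, f)
  expect_error(read_skeleton_csv(f), "non-numeric or non-finite")
})

test_that("dialects adapt column order and implicit frame/joint layout", {
  seq <- make_toy_sequence(3)
  df <- as.data.frame(seq)
  f <- withr::local_tempfile(fileext = ".txt")
  # layout: x y z only, semicolon-separated, 20 consecutive rows per frame
  writeLines(sprintf("%.10f;%.10f;%.10f", df$x, df$y, df$z), f)
  d <- skeleton_dialect(delim = ";", columns = c("x", "y", "z"))
  back <- read_skeleton_csv(f, dialect = d, subject_id = "S01",
                            sequence_id = "walk1")
  expect_equal(n_frames(back), 3L)
  expect_equal(back$x, df$x, tolerance = 1e-9)

  # named-joint dialect in a shuffled joint order
  sch <- kinect20_schema()
  shuf <- rev(sch$names)
  df2 <- df[order(df$frame, match(sch$names[df$joint], shuf)), ]
  writeLines(c("frame|joint|x|y|z",
               sprintf("%d|%s|%g|%g|%g", df2$frame, sch$names[df2$joint],
                       df2$x, df2$y, df2$z)), f)
  d2 <- skeleton_dialect(delim = "|")
  back2 <- read_skeleton_csv(f, dialect = d2, subject_id = "S01",
                             sequence_id = "walk1")
  expect_equal(seq_array(back2), seq_array(seq), tolerance = 1e-6)

  # dialect loadable from YAML
  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("delim: ';'", "columns: [x, y, z]"), y)
  d3 <- read_dialect(y)
  expect_equal(d3$delim, ";")
  expect_equal(d3$columns, c("x", "y", "z"))
})
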
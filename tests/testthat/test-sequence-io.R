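test_that("frame_sequence enforces its invariants", {
  f <- matrix(1, 4, 4)
  expect_error(frame_sequence(list(f, f)), class = "cdkd_validation_error")
  expect_error(frame_sequence(list(f, f, matrix(1, 3, 4))),
               class = "cdkd_shape_error")
  expect_error(frame_sequence(list(f, f, f - 5)),
               class = "cdkd_validation_error")
  expect_error(frame_sequence(list(f, f, f), max_value = 0.5),
               class = "cdkd_validation_error")
  s <- frame_sequence(list(f, f, f))
  expect_s3_class(s, "frame_sequence")
  expect_length(s, 3L)
})

test_that("PNG sequences round-trip and order numerically", {
  dir <- withr::local_tempdir()
  set.seed(41)
  # deliberately unpadded names: numeric-aware order must hold
  for (k in c(1, 2, 10)) {
    img <- matrix(sample(0:255, 64 * 48, replace = TRUE), 64, 48)
    png::writePNG(img / 255, file.path(dir, sprintf("f%d.png", k)))
  }
  s <- read_sequence(dir, "png")
  expect_identical(s$source_ids, c("f1.png", "f2.png", "f10.png"))
  expect_equal(s$max_value, 255)

  out <- withr::local_tempdir()
  write_sequence(s, out)
  s2 <- read_sequence(out, "png")
  expect_equal(s2$frames, s$frames)
})

test_that("read_sequence rejects missing, short, and ragged inputs", {
  expect_error(read_sequence(file.path(tempdir(), "no-such-dir")),
               class = "cdkd_input_error")
  dir <- withr::local_tempdir()
  expect_error(read_sequence(dir), class = "cdkd_input_error")
  png::writePNG(matrix(0.5, 8, 8), file.path(dir, "a1.png"))
  png::writePNG(matrix(0.5, 8, 8), file.path(dir, "a2.png"))
  expect_error(read_sequence(dir, "png"), class = "cdkd_input_error")
  png::writePNG(matrix(0.5, 9, 8), file.path(dir, "a3.png"))
  err <- tryCatch(read_sequence(dir, "png"), error = identity)
  expect_s3_class(err, "cdkd_shape_error")
  expect_match(conditionMessage(err), "a3.png")
})

test_that("TIFF sequences round-trip including 16-bit dynamic range", {
  dir <- withr::local_tempdir()
  set.seed(42)
  frames <- replicate(4, matrix(sample(0:65535, 16 * 16, replace = TRUE),
                                16, 16), simplify = FALSE)
  s <- frame_sequence(frames, max_value = 65535)
  write_sequence(s, dir, force = TRUE)
  s2 <- read_sequence(dir, "tiff")
  expect_equal(s2$max_value, 65535)
  expect_equal(s2$frames, s$frames)
})

test_that("multi-channel images are averaged to one channel", {
  dir <- withr::local_tempdir()
  arr <- array(runif(6 * 6 * 3), c(6, 6, 3))
  for (k in 1:3) png::writePNG(arr, file.path(dir, sprintf("c%d.png", k)))
  s <- read_sequence(dir, "png")
  # writePNG quantizes each channel to 8 bits before we average
  expect_equal(s$frames[[1L]],
               round(apply(round(arr * 255), c(1, 2), mean)))
})

test_that("labels round-trip and are validated", {
  path <- withr::local_tempfile(fileext = ".csv")
  labels <- c(1L, 0L, 0L, 1L, 0L)
  write_labels(labels, path)
  expect_identical(read_labels(path), labels)
  expect_identical(read_labels(path, n_frames = 5L), labels)
  expect_error(read_labels(path, n_frames = 7L),
               class = "cdkd_validation_error")

  # out-of-order rows are re-ordered by frame_index
  writeLines(c("frame_index,label", "3,1", "0,1", "1,0", "2,0"), path)
  expect_identical(read_labels(path), c(1L, 0L, 0L, 1L))

  writeLines(c("frame_index,label", "0,2", "1,0", "2,0"), path)
  expect_error(read_labels(path), class = "cdkd_validation_error")
  writeLines(c("frame_index,label", "0,1", "2,0", "3,0"), path)
  expect_error(read_labels(path), class = "cdkd_validation_error")
})

test_that("embedding matrices round-trip within 1e-9 and reject bad input", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(7)
  m <- matrix(rnorm(6 * 8), 6, 8)
  write_embeddings(m, path)
  m2 <- read_embeddings(path)
  expect_equal(dim(m2), c(6L, 8L))
  expect_lt(max(abs(m2 - m)), 1e-9 * max(1, max(abs(m))))

  writeLines(c("1,2,3", "4,5"), path)
  expect_error(read_embeddings(path), class = "cdkd_parse_error")
  writeLines(c("1,2,3", "4,x,6"), path)
  expect_error(read_embeddings(path), class = "cdkd_parse_error")

  # TSV dialect is auto-detected
  writeLines(c("1\t2", "3\t4", "5\t6"), path)
  expect_equal(read_embeddings(path), matrix(c(1, 3, 5, 2, 4, 6), 3, 2))
})

test_that("detection results round-trip through JSON", {
  ph <- generate_phantom(phantom_config(n_frames = 20, period = 10,
                                        height = 32, width = 32))
  res <- detect_keyframes(ph$sequence)
  path <- withr::local_tempfile(fileext = ".json")
  write_result(res, path)
  res2 <- read_result(path)
  expect_identical(res2$keyframes, as.integer(res$keyframes))
  expect_equal(res2$provenance$value, res$provenance$value)
  expect_equal(res2$parameters$metric, "cosine")
})

test_that("phantom written to disk re-reads bit-exactly", {
  ph <- generate_phantom(phantom_config(n_frames = 12, period = 6,
                                        height = 24, width = 24,
                                        noise_sigma = 3, seed = 5))
  dir <- withr::local_tempdir()
  write_phantom(ph, dir, force = TRUE)
  s <- read_sequence(dir, "png")
  expect_equal(s$frames, ph$sequence$frames)
  expect_identical(read_labels(file.path(dir, "labels.csv")), ph$labels)
  expect_error(write_phantom(ph, dir), class = "cdkd_io_error")
})
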